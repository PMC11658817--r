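# Independent scalar (non-vectorized) oracles used to verify the
# vectorized implementations, plus small fixture builders.

sigmoid_scalar <- function(x) 1 / (1 + exp(-x))

act_scalar <- function(name) switch(name,
  elu = function(z) if (z > 0) z else exp(z) - 1,
  relu = function(z) max(z, 0),
  identity = function(z) z)

# one attention layer evaluated edge-by-edge with explicit loops
oracle_attention_layer <- function(H, W, vs, vr, nbrs, activation = "elu") {
  n <- nrow(H)
  act <- act_scalar(activation)
  d_out <- nrow(W)
  AW <- matrix(0, n, d_out)
  for (i in seq_len(n)) for (q in seq_len(d_out))
    AW[i, q] <- act(sum(W[q, ] * H[i, ]))
  e <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in c(nbrs[[i]], i))
    e[i, j] <- sigmoid_scalar(sum(vs * AW[i, ]) + sum(vr * AW[j, ]))
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- c(nbrs[[i]], i)
    den <- sum(exp(e[i, js]))
    for (j in js) alpha[i, j] <- exp(e[i, j]) / den
  }
  H_out <- matrix(0, n, d_out)
  for (i in seq_len(n)) for (j in c(nbrs[[i]], i))
    H_out[i, ] <- H_out[i, ] + alpha[i, j] * AW[j, ]
  list(e = e, alpha = alpha, H = H_out)
}

oracle_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; Wsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    Wsum <- Wsum + W[i, j]
  }
  (n / Wsum) * num / sum((x - xb)^2)
}

oracle_geary <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; Wsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (x[i] - x[j])^2
    Wsum <- Wsum + W[i, j]
  }
  ((n - 1) * num) / (2 * Wsum * sum((x - xb)^2))
}

# exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# choose(m+n, m) assignments of ranks to group a (no ties assumed)
oracle_wilcoxon_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney U of a
  all_w <- apply(utils::combn(m + n, m), 2, function(ix)
    sum(ix) - m * (m + 1) / 2)
  mu <- m * n / 2
  min(1, mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9))
}

# textbook BH step-up without p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[ro]
}

# small random graph over n nodes: each undirected pair kept with prob pr
random_graph_coords <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n) * 4, runif(n) * 4)
}

# tiny preprocessed dataset + graph for model tests
tiny_fixture <- function(seed = 1, n_rows = 6, n_cols = 6, n_genes = 20) {
  sim <- simulate_visium(n_rows = n_rows, n_cols = n_cols, n_genes = n_genes,
                         n_svg_per_domain = 4, n_domains = 2, seed = seed)
  ds <- normalize_log(qc_filter(sim$dataset), target_sum = 100)
  g <- build_sng(ds$coords)
  list(sim = sim, ds = ds, g = g)
}

# graph object from explicit neighbor lists (for hand-constructed cases)
graph_from_neighbors <- function(nbrs, coords = NULL) {
  n <- length(nbrs)
  coords <- coords %||% cbind(seq_len(n), 0)
  trip_i <- rep.int(seq_len(n), vapply(nbrs, length, 1L))
  trip_j <- unlist(nbrs, use.names = FALSE)
  structure(list(
    n_spots = n, neighbors = nbrs,
    adjacency = Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1, dims = c(n, n)),
    weights = Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1, dims = c(n, n)),
    rad_cutoff = NA_real_, mode = "radius", coords = coords),
    class = "spatial_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
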