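# Synthetic Visium-style fixtures with known ground truth: hexagonal
# lattice, contiguous planted domains, negative-binomial counts with
# domain-enriched genes.

#' Hexagonal (offset-row) lattice coordinates
#'
#' Rows are offset by half a spacing and packed at `spacing * sqrt(3)/2`
#' vertically, so interior spots have exactly six equidistant neighbors —
#' the Visium spot geometry.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param spacing center-to-center spot distance.
#' @return Numeric matrix (n_rows * n_cols) x 2 with columns `x`, `y`.
#' @export
hex_lattice <- function(n_rows, n_cols, spacing = 1) {
  if (n_rows < 1 || n_cols < 1) stop2("lattice dimensions must be >= 1")
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  c0 <- rep(seq_len(n_cols) - 1L, times = n_rows)
  cbind(x = (c0 + (r %% 2) / 2) * spacing,
        y = r * spacing * sqrt(3) / 2)
}

#' Plant contiguous spatial domains on a lattice
#'
#' Multi-source breadth-first region growing: K seed spots are chosen by
#' farthest-point sampling, then domains claim unlabeled lattice
#' neighbors in round-robin order.  Every domain is nonempty and
#' connected in the lattice adjacency; sizes are roughly balanced.
#'
#' @param coords lattice coordinates from [hex_lattice()].
#' @param K number of domains (<= number of spots).
#' @param seed integer seed (first region seed is drawn randomly).
#' @param spacing lattice spacing (adjacency = distance < 1.05 * spacing).
#' @return Integer label vector in 1..K.
#' @export
plant_domains <- function(coords, K, seed = 0, spacing = NULL) {
  n <- nrow(coords)
  if (K > n) stop2("more domains than spots")
  if (K == 1) return(rep(1L, n))
  D <- as.matrix(stats::dist(coords))
  spacing <- spacing %||% min(D[D > 0])
  adj <- lapply(seq_len(n), function(i) which(D[i, ] < 1.05 * spacing & D[i, ] > 0))
  set.seed(seed)
  seeds <- integer(K)
  seeds[1] <- sample.int(n, 1)
  for (k in seq_len(K - 1)) {                # farthest-point sampling
    mind <- apply(D[, seeds[seq_len(k)], drop = FALSE], 1, min)
    seeds[k + 1] <- which.max(mind)
  }
  labels <- integer(n)
  labels[seeds] <- seq_len(K)
  frontier <- lapply(seq_len(K), function(k) adj[[seeds[k]]])
  while (any(labels == 0L)) {
    grew <- FALSE
    for (k in seq_len(K)) {
      cand <- frontier[[k]][labels[frontier[[k]]] == 0L]
      if (length(cand) > 0) {
        take <- cand[1]
        labels[take] <- k
        frontier[[k]] <- c(frontier[[k]], adj[[take]])
        grew <- TRUE
      }
    }
    if (!grew) {                             # disconnected leftovers: nearest seed
      left <- which(labels == 0L)
      labels[left] <- apply(D[left, seeds, drop = FALSE], 1, which.min)
      break
    }
  }
  labels
}

#' Simulate negative-binomial counts with planted domain-enriched genes
#'
#' Background genes share mean `base_mean` everywhere; each planted gene
#' has mean `base_mean * fold_change` inside its assigned domain and
#' `base_mean` outside.  Counts are negative binomial with shared
#' overdispersion `dispersion` (variance `mu + dispersion * mu^2`, i.e.
#' size `1/dispersion`).
#'
#' @param coords spot coordinates.
#' @param labels integer domain labels per spot.
#' @param n_genes total number of genes.
#' @param n_svg_per_domain planted genes per domain.
#' @param base_mean baseline NB mean (default 2).
#' @param fold_change in-domain mean multiplier for planted genes
#'   (default 4; 1 gives a null fixture).
#' @param dispersion NB overdispersion (default 0.5).
#' @param seed integer seed.
#' @return List with `dataset` (a [spatial_dataset()]) and `truth`
#'   (list `true_labels`, `true_svg`: domain -> planted gene ids).
#' @export
simulate_counts <- function(coords, labels, n_genes = 200,
                            n_svg_per_domain = 10, base_mean = 2,
                            fold_change = 4, dispersion = 0.5, seed = 0) {
  if (fold_change < 1) stop2("`fold_change` must be >= 1")
  assert_scalar_num(dispersion, "dispersion", lower = 1e-12)
  K <- length(unique(labels))
  n_planted <- K * n_svg_per_domain
  if (n_planted > n_genes) stop2("more planted genes than total genes")
  n <- nrow(coords)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  mu <- matrix(base_mean, n, n_genes)
  true_svg <- list()
  doms <- sort(unique(labels))
  for (di in seq_along(doms)) {
    gidx <- (di - 1) * n_svg_per_domain + seq_len(n_svg_per_domain)
    mu[labels == doms[di], gidx] <- base_mean * fold_change
    true_svg[[as.character(doms[di])]] <- gene_ids[gidx]
  }
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n * n_genes, mu = mu, size = 1 / dispersion),
                   n, n_genes)
  ds <- spatial_dataset(counts, coords, gene_ids = gene_ids)
  list(dataset = ds,
       truth = list(true_labels = as.integer(labels), true_svg = true_svg))
}

#' Generate a complete synthetic Visium-style experiment
#'
#' Hexagonal lattice, contiguous domains, NB counts with planted
#' domain-enriched genes.  Defaults are the desk-scale study conditions
#' used throughout the package's tests: a 20 x 20 lattice, four domains,
#' 200 genes with ten planted per domain, baseline mean 2, fold change 4,
#' overdispersion 0.5.
#'
#' @param n_rows,n_cols,spacing lattice geometry.
#' @param n_domains number of contiguous domains.
#' @param n_genes,n_svg_per_domain,base_mean,fold_change,dispersion
#'   passed to [simulate_counts()].
#' @param seed integer seed controlling domains and counts.
#' @return List of class `visium_sim`: `dataset`, `truth`, `config`.
#' @export
simulate_visium <- function(n_rows = 20, n_cols = 20, spacing = 1,
                            n_domains = 4, n_genes = 200,
                            n_svg_per_domain = 10, base_mean = 2,
                            fold_change = 4, dispersion = 0.5, seed = 0) {
  coords <- hex_lattice(n_rows, n_cols, spacing)
  labels <- plant_domains(coords, n_domains, seed = seed, spacing = spacing)
  sim <- simulate_counts(coords, labels, n_genes = n_genes,
                         n_svg_per_domain = n_svg_per_domain,
                         base_mean = base_mean, fold_change = fold_change,
                         dispersion = dispersion, seed = seed + 1L)
  structure(c(sim, list(config = list(
    n_rows = n_rows, n_cols = n_cols, spacing = spacing,
    n_domains = n_domains, n_genes = n_genes,
    n_svg_per_domain = n_svg_per_domain, base_mean = base_mean,
    fold_change = fold_change, dispersion = dispersion, seed = seed))),
    class = "visium_sim")
}

#' @export
print.visium_sim <- function(x, ...) {
  cat(sprintf("visium_sim: %d spots, %d genes, %d domains, fold change %.3g\n",
              nrow(x$dataset$counts), ncol(x$dataset$counts),
              x$config$n_domains, x$config$fold_change))
  invisible(x)
}
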