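# Stacked graph attention auto-encoder.
#
# Encoder layer k:  e_ij = sigmoid(vs' sigma(W h_i) + vr' sigma(W h_j)),
# alpha_ij = softmax_j(e_ij) over N_i u {i},  h_i = sum_j alpha_ij sigma(W h_j).
# Decoder mirrors the encoder with its own parameters, mapping the latent
# embedding back to the input dimension.  Objective:
#   Loss = sum_i ||x_i - xhat_i||_2
#          - lambda * sum_i sum_{j in N_i} log sigmoid(h_i' h_j)
# Training is full-batch with hand-derived analytic gradients and Adam.

# --- edge bookkeeping --------------------------------------------------

# directed edge list over N_i u {i}: self-loops appended after neighbors
graph_edges <- function(g) {
  n <- g$n_spots
  deg <- vapply(g$neighbors, length, 1L)
  ei <- c(rep.int(seq_len(n), deg), seq_len(n))
  ej <- c(unlist(g$neighbors, use.names = FALSE), seq_len(n))
  ord <- order(ei, ej)
  list(ei = ei[ord], ej = ej[ord], n = n)
}

# row-indexed sums of edge values: length-n vector of sum over edges with ei == i
edge_rowsum <- function(x, ei, n) {
  out <- numeric(n)
  agg <- rowsum(x, ei)                       # rows sorted by unique ei
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

edge_softmax <- function(e, ei, n) {
  ex <- exp(e)                               # e in (0,1): no overflow
  ex / edge_rowsum(ex, ei, n)[ei]
}

edge_sparse <- function(ei, ej, x, n) {
  Matrix::sparseMatrix(i = ei, j = ej, x = x, dims = c(n, n))
}

# --- configuration and initialization ---------------------------------

#' Configuration for the graph attention auto-encoder
#'
#' @param layer_dims encoder output dimension per layer; the decoder
#'   mirrors them in reverse.  Default `c(512, 30)`, the two-layer design
#'   customary for spatial graph auto-encoders.
#' @param lambda_struct weight of the graph-structure reconstruction term
#'   (default 0.1).
#' @param activation `"elu"` (default), `"relu"` or `"identity"`.
#' @param epochs,learning_rate,weight_decay Adam training schedule
#'   (defaults 500, 1e-4, 1e-4, full batch).
#' @param gradient_clip global gradient-norm clip (default 5).
#' @param alpha_refine mixing weight of the attention refinement module
#'   in `[0, 1]`; 0 (default) disables it.
#' @param tie_weights use transposed encoder weight matrices in the
#'   decoder instead of free parameters.
#' @param seed integer seed controlling initialization.
#' @return A list of class `gaae_config`.
#' @export
gaae_config <- function(layer_dims = c(512, 30), lambda_struct = 0.1,
                        activation = c("elu", "relu", "identity"),
                        epochs = 500, learning_rate = 1e-4,
                        weight_decay = 1e-4, gradient_clip = 5,
                        alpha_refine = 0, tie_weights = FALSE, seed = 0) {
  activation <- match.arg(activation)
  if (length(layer_dims) < 1 || any(layer_dims < 1))
    stop2("`layer_dims` must be a vector of positive integers")
  assert_scalar_num(lambda_struct, "lambda_struct", lower = 0)
  assert_scalar_num(alpha_refine, "alpha_refine", 0, 1)
  structure(list(layer_dims = as.integer(layer_dims),
                 lambda_struct = lambda_struct, activation = activation,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, gradient_clip = gradient_clip,
                 alpha_refine = alpha_refine, tie_weights = tie_weights,
                 seed = as.integer(seed)),
            class = "gaae_config")
}

glorot <- function(nout, nin) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -a, a), nout, nin)
}

# parameters: enc[[k]] = list(W (d_k x d_{k-1}), vs (d_k), vr (d_k));
# dec[[k]] reverses layer k: W (d_{k-1} x d_k), vs/vr (d_{k-1})
gaae_init <- function(input_dim, cfg) {
  set.seed(cfg$seed)
  dims <- c(input_dim, cfg$layer_dims)
  L <- length(cfg$layer_dims)
  enc <- lapply(seq_len(L), function(k)
    list(W = glorot(dims[k + 1], dims[k]),
         vs = numeric(dims[k + 1]), vr = numeric(dims[k + 1])))
  dec <- lapply(seq_len(L), function(k)
    list(W = if (cfg$tie_weights) t(enc[[k]]$W) else glorot(dims[k], dims[k + 1]),
         vs = numeric(dims[k]), vr = numeric(dims[k])))
  structure(list(enc = enc, dec = dec, L = L, dims = dims,
                 activation = cfg$activation, tie_weights = cfg$tie_weights),
            class = "gaae_model")
}

#' @export
print.gaae_model <- function(x, ...) {
  cat(sprintf("gaae_model: %d encoder layer(s), dims %s, activation %s\n",
              x$L, paste(x$dims, collapse = " -> "), x$activation))
  invisible(x)
}

# --- single-layer operations (exposed for testing/inspection) ----------

#' Raw attention relevance scores for one layer
#'
#' `e_ij = sigmoid(vs' sigma(W h_i) + vr' sigma(W h_j))` for every edge
#' `j in N_i u {i}`; values lie in (0, 1).
#'
#' @param h_prev input representations (spots x d_in).
#' @param W,vs,vr layer parameters.
#' @param g a [build_sng()] graph.
#' @param activation activation name for `sigma`.
#' @return Sparse matrix with entry (i, j) holding `e_ij`.
#' @export
attention_scores <- function(h_prev, W, vs, vr, g, activation = "elu") {
  if (any(!is.finite(h_prev))) stop2("non-finite input representations")
  ed <- graph_edges(g)
  A <- activation_fun(activation)(h_prev %*% t(W))
  s <- as.vector(A %*% vs)
  r <- as.vector(A %*% vr)
  e <- stats::plogis(s[ed$ei] + r[ed$ej])
  edge_sparse(ed$ei, ed$ej, e, ed$n)
}

#' Softmax normalization of attention scores
#'
#' Normalizes each spot's relevance scores over its neighborhood
#' (including itself) so they sum to one.
#'
#' @param e sparse score matrix as returned by [attention_scores()].
#' @param g the graph the scores were computed on.
#' @return Sparse row-stochastic attention matrix.
#' @export
normalize_attention <- function(e, g) {
  ed <- graph_edges(g)
  ev <- e[cbind(ed$ei, ed$ej)]
  edge_sparse(ed$ei, ed$ej, edge_softmax(ev, ed$ei, ed$n), ed$n)
}

#' One encoder layer forward pass
#'
#' `h_i = sum_{j in N_i u {i}} alpha_ij sigma(W h_j)` with attention from
#' [attention_scores()] and [normalize_attention()].
#'
#' @inheritParams attention_scores
#' @param params list with elements `W`, `vs`, `vr`.
#' @return Matrix of new representations (spots x d_out).
#' @export
encoder_layer <- function(h_prev, params, g, activation = "elu") {
  fw <- layer_forward(h_prev, params, graph_edges(g), activation)
  fw$H
}

#' One decoder layer forward pass
#'
#' Identical propagation rule to [encoder_layer()] but with the decoder's
#' own parameters, reconstructing the representation one level down.
#'
#' @inheritParams encoder_layer
#' @return Matrix of reconstructed representations.
#' @export
decoder_layer <- function(h_next, params, g, activation = "elu") {
  fw <- layer_forward(h_next, params, graph_edges(g), activation)
  fw$H
}

# shared forward for one attention layer; returns intermediates for backprop
layer_forward <- function(H_in, params, ed, activation, refine = 0) {
  act <- activation_fun(activation)
  Z <- H_in %*% t(params$W)
  A <- act(Z)
  s <- as.vector(A %*% params$vs)
  r <- as.vector(A %*% params$vr)
  u <- s[ed$ei] + r[ed$ej]
  e <- stats::plogis(u)
  alpha <- edge_softmax(e, ed$ei, ed$n)
  if (refine > 0) alpha <- refine_edge_values(alpha, ed, refine)
  P <- edge_sparse(ed$ei, ed$ej, alpha, ed$n)
  H <- as.matrix(P %*% A)
  list(H = H, A = A, Z = Z, s = s, r = r, e = e, alpha = alpha, P = P)
}

refine_edge_values <- function(alpha, ed, alpha_refine) {
  deg <- edge_rowsum(rep(1, length(ed$ei)), ed$ei, ed$n)   # |N_i u {i}|
  (1 - alpha_refine) * alpha + alpha_refine / deg[ed$ei]
}

#' Mix learned attention with a uniform neighborhood prior
#'
#' The spatial-domain refinement module: each attention row is blended
#' with the uniform distribution over the spot's neighborhood (self
#' included), `mixed = (1 - alpha_refine) * alpha + alpha_refine * u`.
#' Rows remain stochastic.  `alpha_refine = 0` leaves the learned
#' attention untouched; `alpha_refine = 1` is plain neighborhood
#' averaging.
#'
#' @param alpha sparse row-stochastic attention matrix.
#' @param g the underlying graph.
#' @param alpha_refine mixing weight in `[0, 1]`.
#' @return Sparse row-stochastic matrix.
#' @export
refine_attention <- function(alpha, g, alpha_refine) {
  assert_scalar_num(alpha_refine, "alpha_refine", 0, 1)
  ed <- graph_edges(g)
  av <- alpha[cbind(ed$ei, ed$ej)]
  edge_sparse(ed$ei, ed$ej, refine_edge_values(av, ed, alpha_refine), ed$n)
}

# --- loss --------------------------------------------------------------

#' Auto-encoder training objective
#'
#' Feature reconstruction (sum of per-spot Euclidean norms of the
#' residual) minus `lambda_struct` times the graph-structure likelihood
#' `sum_i sum_{j in N_i} log sigmoid(h_i' h_j)` over all directed stored
#' edges (self-loops excluded).
#'
#' @param x,x_hat original and reconstructed expression (spots x genes).
#' @param latent latent embeddings (spots x d).
#' @param g the graph.
#' @param lambda_struct structure-term weight.
#' @return A single finite number.
#' @export
gaae_loss <- function(x, x_hat, latent, g, lambda_struct) {
  if (!all(dim(x) == dim(x_hat))) stop2("x and x_hat dimensions differ")
  recon <- sum(sqrt(rowSums((x - x_hat)^2)))
  struct <- 0
  if (lambda_struct != 0) {
    si <- rep.int(seq_len(g$n_spots), vapply(g$neighbors, length, 1L))
    sj <- unlist(g$neighbors, use.names = FALSE)
    if (length(si) > 0) {
      dots <- rowSums(latent[si, , drop = FALSE] * latent[sj, , drop = FALSE])
      struct <- sum(log_sigmoid(dots))
    }
  }
  loss <- recon - lambda_struct * struct
  if (!is.finite(loss)) stop2("non-finite loss")
  loss
}

# --- full forward / backward ------------------------------------------

gaae_forward <- function(model, X, ed, refine = 0) {
  L <- model$L
  enc_fw <- vector("list", L)
  H <- X
  for (k in seq_len(L)) {
    enc_fw[[k]] <- layer_forward(H, model$enc[[k]], ed, model$activation, refine)
    H <- enc_fw[[k]]$H
  }
  latent <- H
  dec_fw <- vector("list", L)
  for (k in rev(seq_len(L))) {
    dec_fw[[k]] <- layer_forward(H, model$dec[[k]], ed, model$activation, refine)
    H <- dec_fw[[k]]$H
  }
  list(enc = enc_fw, dec = dec_fw, latent = latent, x_hat = H)
}

# backprop through one attention layer: G = dLoss/dH_out -> grads + dH_in
layer_backward <- function(G, H_in, params, fw, ed, activation) {
  agrad <- activation_grad(activation)
  n <- ed$n
  # through aggregation H = P A
  dA <- as.matrix(Matrix::t(fw$P) %*% G)
  galpha <- rowSums(G[ed$ei, , drop = FALSE] * fw$A[ed$ej, , drop = FALSE])
  # softmax backward
  dot <- edge_rowsum(fw$alpha * galpha, ed$ei, n)
  de <- fw$alpha * (galpha - dot[ed$ei])
  du <- de * fw$e * (1 - fw$e)
  ds <- edge_rowsum(du, ed$ei, n)
  dr <- edge_rowsum(du, ed$ej, n)
  dA <- dA + outer(ds, params$vs) + outer(dr, params$vr)
  dvs <- as.vector(crossprod(fw$A, ds))
  dvr <- as.vector(crossprod(fw$A, dr))
  dZ <- dA * agrad(fw$Z)
  list(W = crossprod(dZ, H_in), vs = dvs, vr = dvr,
       dH_in = dZ %*% params$W)
}

gaae_backward <- function(model, X, fw, ed, g, lambda_struct) {
  L <- model$L
  n <- nrow(X)
  # feature reconstruction: d/dxhat sum_i ||x_i - xhat_i||
  R <- X - fw$x_hat
  nrm <- pmax(sqrt(rowSums(R^2)), 1e-12)
  G <- -R / nrm
  dec_gr <- vector("list", L)
  for (k in seq_len(L)) {                    # decoder applied L..1; backprop 1..L
    H_in <- if (k == L) fw$latent else fw$dec[[k + 1]]$H
    bk <- layer_backward(G, H_in, model$dec[[k]], fw$dec[[k]], ed, model$activation)
    dec_gr[[k]] <- bk[c("W", "vs", "vr")]
    G <- bk$dH_in
  }
  # structure term gradient on the latent embedding
  if (lambda_struct != 0) {
    si <- rep.int(seq_len(g$n_spots), vapply(g$neighbors, length, 1L))
    sj <- unlist(g$neighbors, use.names = FALSE)
    if (length(si) > 0) {
      dots <- rowSums(fw$latent[si, , drop = FALSE] * fw$latent[sj, , drop = FALSE])
      coef <- 1 - stats::plogis(dots)
      M <- Matrix::sparseMatrix(i = si, j = sj, x = coef, dims = c(n, n))
      G <- G - lambda_struct *
        as.matrix(M %*% fw$latent + Matrix::t(M) %*% fw$latent)
    }
  }
  enc_gr <- vector("list", L)
  for (k in rev(seq_len(L))) {
    H_in <- if (k == 1) X else fw$enc[[k - 1]]$H
    bk <- layer_backward(G, H_in, model$enc[[k]], fw$enc[[k]], ed, model$activation)
    enc_gr[[k]] <- bk[c("W", "vs", "vr")]
    G <- bk$dH_in
  }
  list(enc = enc_gr, dec = dec_gr)
}

# --- Adam training loop ------------------------------------------------

flatten_params <- function(model) c(
  lapply(model$enc, function(p) p[c("W", "vs", "vr")]),
  lapply(model$dec, function(p) p[c("W", "vs", "vr")]))

#' Train the graph attention auto-encoder
#'
#' Full-batch gradient training with Adam, analytic gradients, and
#' global-norm gradient clipping.  Deterministic given the seed (fixed
#' initialization, no stochastic sampling).
#'
#' @param ds a preprocessed [spatial_dataset()] (normalized expression
#'   present), or a plain numeric matrix of features.
#' @param g a [build_sng()] graph over the same spots.
#' @param cfg a [gaae_config()].
#' @return List of class `gaae_fit` with elements `model`
#'   (trained parameters), `latent`, `reconstruction`, `attention`
#'   (per-layer sparse encoder/decoder matrices from the final forward
#'   pass), `loss_history` (initial loss followed by one value per
#'   epoch), and `attn_rowsum_dev`, the maximum absolute deviation of any
#'   attention row sum from 1 observed across all layers and epochs.
#' @export
gaae_train <- function(ds, g, cfg = gaae_config()) {
  X <- if (inherits(ds, "spatial_dataset")) {
    if (is.null(ds$expr)) stop2("dataset has no normalized expression; run normalize_log()")
    ds$expr
  } else as.matrix(ds)
  if (any(!is.finite(X))) stop2("non-finite values in the input features")
  if (nrow(X) != g$n_spots) stop2("graph and dataset disagree on spot count")
  ed <- graph_edges(g)
  model <- gaae_init(ncol(X), cfg)
  params <- flatten_params(model)
  mstate <- lapply(params, function(p) lapply(p, function(q) q * 0))
  vstate <- mstate
  nlay <- model$L
  set_params <- function(model, params) {
    for (k in seq_len(nlay)) {
      model$enc[[k]][c("W", "vs", "vr")] <- params[[k]]
      model$dec[[k]][c("W", "vs", "vr")] <- params[[nlay + k]]
    }
    model
  }
  loss_history <- numeric(0)
  rowsum_dev <- 0
  track_dev <- function(fws) {
    for (f in fws) {
      dev <- max(abs(edge_rowsum(f$alpha, ed$ei, ed$n) - 1))
      if (dev > rowsum_dev) rowsum_dev <<- dev
    }
  }
  fw <- gaae_forward(model, X, ed)
  loss_history <- gaae_loss(X, fw$x_hat, fw$latent, g, cfg$lambda_struct)
  track_dev(c(fw$enc, fw$dec))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (cfg$epochs > 0) for (epoch in seq_len(cfg$epochs)) {
    gr <- gaae_backward(model, X, fw, ed, g, cfg$lambda_struct)
    grads <- c(gr$enc, gr$dec)
    if (model$tie_weights) {               # share W between mirror layers
      for (k in seq_len(nlay)) {
        shared <- grads[[k]]$W + t(grads[[nlay + k]]$W)
        grads[[k]]$W <- shared
        grads[[nlay + k]]$W <- t(shared)
      }
    }
    # weight decay + global norm clip
    gnorm2 <- 0
    for (li in seq_along(grads)) for (pn in names(grads[[li]])) {
      grads[[li]][[pn]] <- grads[[li]][[pn]] + cfg$weight_decay * params[[li]][[pn]]
      gnorm2 <- gnorm2 + sum(grads[[li]][[pn]]^2)
    }
    scale <- if (sqrt(gnorm2) > cfg$gradient_clip) cfg$gradient_clip / sqrt(gnorm2) else 1
    bc1 <- 1 - b1^epoch; bc2 <- 1 - b2^epoch
    for (li in seq_along(grads)) for (pn in names(grads[[li]])) {
      gv <- grads[[li]][[pn]] * scale
      mstate[[li]][[pn]] <- b1 * mstate[[li]][[pn]] + (1 - b1) * gv
      vstate[[li]][[pn]] <- b2 * vstate[[li]][[pn]] + (1 - b2) * gv^2
      params[[li]][[pn]] <- params[[li]][[pn]] -
        cfg$learning_rate * (mstate[[li]][[pn]] / bc1) /
        (sqrt(vstate[[li]][[pn]] / bc2) + eps)
    }
    if (model$tie_weights)
      for (k in seq_len(nlay)) params[[nlay + k]]$W <- t(params[[k]]$W)
    model <- set_params(model, params)
    fw <- gaae_forward(model, X, ed)
    l <- tryCatch(gaae_loss(X, fw$x_hat, fw$latent, g, cfg$lambda_struct),
                  error = function(e)
                    stop2("training diverged at epoch ", epoch, ": ",
                          conditionMessage(e)))
    loss_history <- c(loss_history, l)
    track_dev(c(fw$enc, fw$dec))
  }
  if (cfg$alpha_refine > 0)                  # refined forward pass for outputs
    fw <- gaae_forward(model, X, ed, refine = cfg$alpha_refine)
  structure(list(
    model = model,
    latent = fw$latent,
    reconstruction = fw$x_hat,
    attention = list(enc = lapply(fw$enc, `[[`, "P"),
                     dec = lapply(fw$dec, `[[`, "P")),
    loss_history = loss_history,
    attn_rowsum_dev = rowsum_dev,
    config = cfg
  ), class = "gaae_fit")
}

#' @export
print.gaae_fit <- function(x, ...) {
  cat(sprintf("gaae_fit: latent %d x %d; loss %.4g -> %.4g over %d epoch(s)\n",
              nrow(x$latent), ncol(x$latent),
              x$loss_history[1], x$loss_history[length(x$loss_history)],
              length(x$loss_history) - 1L))
  invisible(x)
}
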