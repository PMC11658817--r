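#' Moran's I spatial autocorrelation
#'
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij w_ij`.  Values near 1 indicate a coherent spatial
#' pattern, near 0 a random one, negative a dispersed one.
#'
#' @param x numeric vector over spots.
#' @param Wm spatial weight matrix (sparse or dense), e.g. from
#'   [autocorr_weights()].
#' @return A single number, or `NA` when `x` has zero variance (an
#'   explicit undefined flag, never silently 0).
#' @export
morans_i <- function(x, Wm) {
  n <- length(x)
  if (n < 2) stop2("need at least 2 observations")
  if (nrow(Wm) != n || ncol(Wm) != n) stop2("weight matrix dimension mismatch")
  Wsum <- sum(Wm)
  if (Wsum <= 0) stop2("weight matrix has zero total weight")
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) return(NA_real_)
  num <- as.numeric(t(z) %*% (Wm %*% z))
  (n / Wsum) * num / den
}

#' Geary's C spatial autocorrelation
#'
#' `C = (N-1) sum_ij w_ij (x_i - x_j)^2 / (2 W sum_i (x_i - xbar)^2)`.
#' C is 1 under no autocorrelation, below 1 for positive spatial
#' autocorrelation, and more sensitive to local structure than Moran's I.
#'
#' @inheritParams morans_i
#' @return A single non-negative number, or `NA` for zero variance.
#' @export
gearys_c <- function(x, Wm) {
  n <- length(x)
  if (n < 2) stop2("need at least 2 observations")
  if (nrow(Wm) != n || ncol(Wm) != n) stop2("weight matrix dimension mismatch")
  Wsum <- sum(Wm)
  if (Wsum <= 0) stop2("weight matrix has zero total weight")
  z <- x - mean(x)
  den <- sum(z^2)
  if (den == 0) return(NA_real_)
  tr <- sparse_triplets(Wm)
  num <- sum(tr$x * (x[tr$i] - x[tr$j])^2)
  ((n - 1) * num) / (2 * Wsum * den)
}

#' Spatial autocorrelation scores for every gene
#'
#' Vectorized per-gene Moran's I and Geary's C on the normalized
#' expression, plus the similarity transform `1 - C` (reported alongside
#' raw C because on the `1 - C` scale positive autocorrelation tracks
#' Moran's I).  Genes with zero variance get `NA` scores and an
#' `undefined` flag.
#'
#' @param ds a [spatial_dataset()] with normalized expression.
#' @param g a [build_sng()] graph over the same spots.
#' @param scheme weight scheme passed to [autocorr_weights()].
#' @return `data.frame` with columns `gene_id`, `morans_i`, `gearys_c`,
#'   `gearys_c_similarity`, `undefined`.
#' @export
score_genes <- function(ds, g, scheme = c("binary", "eq1")) {
  scheme <- match.arg(scheme)
  if (is.null(ds$expr)) stop2("normalized expression missing; run normalize_log()")
  X <- ds$expr
  n <- nrow(X)
  Wm <- autocorr_weights(g, scheme)
  Wsum <- sum(Wm)
  if (Wsum <= 0) stop2("graph has no edges")
  Z <- sweep(X, 2, colMeans(X))
  den <- colSums(Z^2)
  num_i <- colSums(Z * as.matrix(Wm %*% Z))
  I <- (n / Wsum) * num_i / den
  tr <- sparse_triplets(Wm)
  Dm <- X[tr$i, , drop = FALSE] - X[tr$j, , drop = FALSE]
  num_c <- colSums(tr$x * Dm^2)
  C <- ((n - 1) * num_c) / (2 * Wsum * den)
  undef <- den == 0
  I[undef] <- NA_real_
  C[undef] <- NA_real_
  data.frame(gene_id = ds$gene_ids, morans_i = unname(I), gearys_c = unname(C),
             gearys_c_similarity = unname(1 - C), undefined = unname(undef),
             stringsAsFactors = FALSE)
}
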