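#' Cluster spots into spatial domains
#'
#' Fits a Gaussian mixture by expectation-maximization (via the mclust
#' package) to the chosen representation of the trained auto-encoder.
#' The low-dimensional latent embedding is used as-is; the decoder
#' reconstruction is first reduced to 20 principal components.  With a
#' fixed `K` that many components are fitted; with a range of candidates
#' the number of domains is chosen by best BIC.  The default covariance
#' model is `"EEE"` (one full covariance shared by all components), the
#' customary choice when clustering auto-encoder embeddings of spots;
#' per-component covariances (`model_names = "VVV"`) tend to overfit
#' moderate spot counts.
#'
#' @param emb a `gaae_fit` from [gaae_train()], or a plain numeric
#'   matrix of spot representations.
#' @param K integer number of domains (>= 2), or an integer vector of
#'   candidates scanned by BIC.
#' @param source `"latent"` (default) or `"reconstruction"`.
#' @param seed integer seed (EM initialization is deterministic, but the
#'   seed is fixed for reproducibility of any subset-based init).
#' @param n_pcs principal components kept when clustering the
#'   reconstruction (default 20).
#' @param model_names mclust covariance model(s) to consider
#'   (default `"EEE"`).
#' @return Object of class `domain_labels`: list with `labels` (integer
#'   vector in 1..K), `K`, `source`, `bic`.
#' @export
cluster_domains <- function(emb, K, source = c("latent", "reconstruction"),
                            seed = 0, n_pcs = 20, model_names = "EEE") {
  source <- match.arg(source)
  X <- if (inherits(emb, "gaae_fit")) {
    if (source == "latent") emb$latent else emb$reconstruction
  } else as.matrix(emb)
  if (source == "reconstruction" && ncol(X) > n_pcs)
    X <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
  if (any(K < 2)) stop2("the number of spatial domains must be at least 2")
  set.seed(seed)
  # Mclust evaluates a mclustBIC() call in the caller's frame, so the
  # function must be visible here even though mclust is not attached
  mclustBIC <- mclust::mclustBIC
  mfit <- function(models)
    mclust::Mclust(X, G = K, modelNames = models, verbose = FALSE)
  fit <- tryCatch(mfit(model_names), error = function(e) NULL)
  if (is.null(fit))                          # degenerate covariance: retry diagonal
    fit <- mfit(c("EII", "EEI", "VVI"))
  if (is.null(fit)) stop2("Gaussian mixture fitting failed for every candidate model")
  structure(list(labels = as.integer(fit$classification),
                 K = as.integer(fit$G), source = source,
                 bic = unname(fit$bic)),
            class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("domain_labels: %d spots in %d domains (source: %s)\n",
              length(x$labels), x$K, x$source))
  print(table(domain = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' up to relabeling, approximately 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A single number (<= 1).
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop2("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(labels_a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)          # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}
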