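#' Fit the spatial graph-attention auto-encoder pipeline
#'
#' The package's main entry point.  Runs the full analysis on a spatial
#' transcriptomics dataset: QC filtering, depth normalization and log
#' transform, highly-variable-gene selection, spatial neighbor graph
#' construction, graph attention auto-encoder training, and
#' Gaussian-mixture assignment of spots to spatial domains.  Spatially
#' variable genes are then detected from the fitted object with
#' [detect_svgs()] / [svgs()].
#'
#' @param x a [spatial_dataset()], a `visium_sim`, or a spots x genes
#'   count matrix (then `coords` is required).
#' @param coords spot coordinates when `x` is a plain matrix.
#' @param n_domains number of spatial domains (>= 2), or an integer
#'   vector of candidates scanned by BIC.
#' @param strict_qc,target_sum,n_hvg preprocessing options, see
#'   [preprocess()].
#' @param rad_cutoff,graph_mode,k,target_avg graph options, see
#'   [build_sng()].
#' @param cluster_on `"latent"` (default) or `"reconstruction"`.
#' @param seed integer seed for initialization and clustering.
#' @param ... model options forwarded to [gaae_config()]
#'   (`layer_dims`, `epochs`, `learning_rate`, `lambda_struct`,
#'   `alpha_refine`, ...).
#' @return Object of class `gaade`: list with `dataset` (preprocessed),
#'   `graph`, `fit` (the trained `gaae_fit`), `domains`
#'   (`domain_labels`), `scores` (per-gene autocorrelation), `config`
#'   and `call`.  Supports `print`, `summary`, `plot`, `coef`, `fitted`
#'   and `residuals`.
#' @examples
#' sim <- simulate_visium(n_rows = 8, n_cols = 8, n_genes = 40,
#'                        n_svg_per_domain = 5, n_domains = 2, seed = 1)
#' fit <- gaade(sim, n_domains = 2, layer_dims = c(16, 4), epochs = 30,
#'              learning_rate = 1e-3, seed = 1)
#' fit
#' @export
gaade <- function(x, coords = NULL, n_domains = 2:8,
                  strict_qc = FALSE, target_sum = 1e4, n_hvg = 3000,
                  rad_cutoff = NULL, graph_mode = "radius", k = 6,
                  target_avg = 6, cluster_on = c("latent", "reconstruction"),
                  seed = 0, ...) {
  cluster_on <- match.arg(cluster_on)
  ds <- if (inherits(x, "visium_sim")) x$dataset
        else if (inherits(x, "spatial_dataset")) x
        else {
          if (is.null(coords)) stop2("`coords` required when `x` is a matrix")
          spatial_dataset(x, coords)
        }
  ds <- preprocess(ds, strict_qc = strict_qc, target_sum = target_sum,
                   n_hvg = n_hvg)
  g <- build_sng(ds$coords, rad_cutoff = rad_cutoff, mode = graph_mode,
                 k = k, target_avg = target_avg)
  cfg <- gaae_config(seed = seed, ...)
  fit <- gaae_train(ds, g, cfg)
  domains <- cluster_domains(fit, K = n_domains, source = cluster_on, seed = seed)
  scores <- score_genes(ds, g, scheme = "binary")
  structure(list(dataset = ds, graph = g, fit = fit, domains = domains,
                 scores = scores, config = cfg, cluster_on = cluster_on,
                 call = match.call()),
            class = "gaade")
}

#' Spatially variable genes of a fitted model
#'
#' Convenience wrapper running [detect_svgs()] on the components of a
#' [gaade()] fit.
#'
#' @param object a `gaade` fit.
#' @param ... thresholds forwarded to [detect_svgs()].
#' @return An `svg_table`.
#' @export
svgs <- function(object, ...) {
  stopifnot(inherits(object, "gaade"))
  detect_svgs(object$dataset, object$graph, object$domains,
              ac = object$scores, ...)
}

#' @export
print.gaade <- function(x, ...) {
  cat("Spatial graph attention auto-encoder fit\n")
  cat(sprintf("  %d spots x %d genes; %d spatial domains (clustered on %s)\n",
              nrow(x$dataset$counts), ncol(x$dataset$counts),
              x$domains$K, x$cluster_on))
  lh <- x$fit$loss_history
  cat(sprintf("  loss %.4g -> %.4g over %d epochs\n",
              lh[1], lh[length(lh)], length(lh) - 1L))
  invisible(x)
}

#' @export
summary.gaade <- function(object, ...) {
  out <- list(
    n_spots = nrow(object$dataset$counts),
    n_genes = ncol(object$dataset$counts),
    mean_degree = mean(vapply(object$graph$neighbors, length, 1L)),
    K = object$domains$K,
    domain_sizes = table(object$domains$labels),
    bic = object$domains$bic,
    initial_loss = object$fit$loss_history[1],
    final_loss = object$fit$loss_history[length(object$fit$loss_history)],
    median_morans_i = stats::median(object$scores$morans_i, na.rm = TRUE))
  class(out) <- "summary.gaade"
  out
}

#' @export
print.summary.gaade <- function(x, ...) {
  cat(sprintf("spots: %d  genes: %d  mean graph degree: %.2f\n",
              x$n_spots, x$n_genes, x$mean_degree))
  cat(sprintf("domains: %d (BIC %.1f), sizes: %s\n", x$K, x$bic,
              paste(as.integer(x$domain_sizes), collapse = ", ")))
  cat(sprintf("training loss: %.4g -> %.4g\n", x$initial_loss, x$final_loss))
  cat(sprintf("median Moran's I across genes: %.4f\n", x$median_morans_i))
  invisible(x)
}

#' @export
coef.gaade <- function(object, ...) {
  flatten_params(object$fit$model)
}

#' @export
fitted.gaade <- function(object, ...) object$fit$reconstruction

#' @export
residuals.gaade <- function(object, ...) object$dataset$expr - object$fit$reconstruction

#' Plot spatial domains
#'
#' Scatter of spot coordinates colored by assigned domain.
#' @param x a `gaade` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gaade <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(x$domains$K, 3), "Dark 3")
  graphics::plot(x$dataset$coords, col = cols[x$domains$labels], pch = 16,
                 asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("%d spatial domains", x$domains$K), ...)
  invisible(x)
}

#' Evaluate domain and SVG recovery on synthetic data
#'
#' Runs the full pipeline (preprocess, graph, train, cluster, detect) on
#' freshly simulated fixtures over several seeds and measures recovery
#' against the planted truth: adjusted Rand index of the domain
#' partition, sensitivity (fraction of planted genes recovered among the
#' reported SVGs), and false discovery rate (fraction of reported SVGs
#' that were not planted).
#'
#' @param n_seeds number of independent replicates (default 5).
#' @param seed base seed; replicate s uses `seed + s`.
#' @param sim_args list of overrides for [simulate_visium()].
#' @param layer_dims,epochs,learning_rate,lambda_struct model settings
#'   for the desk-scale fixtures.
#' @param ... further arguments to [gaade()].
#' @return `data.frame` with one row per seed: `seed`, `ari`,
#'   `sensitivity`, `fdr`, `n_svg`.
#' @export
gaade_evaluate <- function(n_seeds = 5, seed = 0, sim_args = list(),
                           layer_dims = c(64, 16), epochs = 200,
                           learning_rate = 1e-3, lambda_struct = 0.1, ...) {
  res <- lapply(seq_len(n_seeds), function(s) {
    sim <- do.call(simulate_visium, c(list(seed = seed + s), sim_args))
    fit <- gaade(sim, n_domains = sim$config$n_domains,
                 layer_dims = layer_dims, epochs = epochs,
                 learning_rate = learning_rate, lambda_struct = lambda_struct,
                 seed = seed + s, ...)
    tab <- svgs(fit)
    found <- attr(tab, "svg_genes")
    planted <- unlist(sim$truth$true_svg, use.names = FALSE)
    data.frame(seed = seed + s,
               ari = ari(fit$domains$labels, sim$truth$true_labels),
               sensitivity = if (length(planted)) mean(planted %in% found) else NA_real_,
               fdr = if (length(found)) mean(!found %in% planted) else 0,
               n_svg = length(found))
  })
  do.call(rbind, res)
}
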