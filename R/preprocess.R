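#' Quality-control filtering of spots and genes
#'
#' Applies the standard spatial transcriptomics QC cascade: optional
#' spot-level filters (mitochondrial UMI fraction, minimum detected
#' genes), then gene-level filters (identifier deny-list, mitochondrial
#' prefixes, minimum number of expressing spots).  Spot filters are
#' evaluated on the full gene set before any gene is removed, so the
#' mitochondrial fraction is computed on all genes; gene filters then run
#' on the surviving spots.  The operation is idempotent.
#'
#' @param ds a [spatial_dataset()]
#' @param min_spots_per_gene drop genes expressed (count > 0) in fewer
#'   spots than this (default 3).
#' @param mito_prefixes identifier prefixes treated as mitochondrial.
#' @param drop_mito drop mitochondrial genes (default `TRUE`).
#' @param max_mito_fraction if non-`NULL`, drop spots whose mitochondrial
#'   UMI fraction exceeds this (the strict-QC profile uses 0.15).
#' @param min_genes_per_spot if non-`NULL`, drop spots with fewer detected
#'   genes (the strict-QC profile uses 100).
#' @param deny_prefixes extra identifier prefixes to drop unconditionally
#'   (e.g. spike-in/exogenous constructs).
#' @return The filtered [spatial_dataset()]; row/column order preserved.
#' @export
qc_filter <- function(ds, min_spots_per_gene = 3,
                      mito_prefixes = c("MT-", "mt-"),
                      drop_mito = TRUE,
                      max_mito_fraction = NULL,
                      min_genes_per_spot = NULL,
                      deny_prefixes = character()) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!is.null(max_mito_fraction))
    assert_scalar_num(max_mito_fraction, "max_mito_fraction", 0, 1)
  counts <- ds$counts
  is_mito <- startsWith_any(ds$gene_ids, mito_prefixes)

  denied <- startsWith_any(ds$gene_ids, deny_prefixes)
  keep_spot <- rep(TRUE, nrow(counts))
  if (!is.null(max_mito_fraction)) {
    tot <- rowSums(counts)
    mito_frac <- ifelse(tot > 0, rowSums(counts[, is_mito, drop = FALSE]) / tot, 0)
    keep_spot <- keep_spot & mito_frac <= max_mito_fraction
  }
  if (!is.null(min_genes_per_spot)) {
    # detected genes counted on the gene set that survives the prefix
    # filters, so that re-applying the filter reproduces the same counts
    retained <- !(denied | (drop_mito & is_mito))
    keep_spot <- keep_spot &
      rowSums(counts[, retained, drop = FALSE] > 0) >= min_genes_per_spot
  }
  if (!any(keep_spot)) stop2("QC removed every spot")
  if (!all(keep_spot)) ds <- subset_dataset(ds, spots = which(keep_spot))

  keep_gene <- !startsWith_any(ds$gene_ids, deny_prefixes)
  if (drop_mito) keep_gene <- keep_gene & !startsWith_any(ds$gene_ids, mito_prefixes)
  keep_gene <- keep_gene & colSums(ds$counts > 0) >= min_spots_per_gene
  if (!any(keep_gene)) stop2("QC removed every gene")
  if (!all(keep_gene)) ds <- subset_dataset(ds, genes = which(keep_gene))
  ds
}

startsWith_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' Library-size normalization and log transform
#'
#' Scales each spot to a common total (`expr = log(1 + count *
#' target_sum / total)`), the usual count-depth normalization for UMI
#' data.  Raw counts are retained alongside the normalized matrix.
#'
#' @param ds a [spatial_dataset()]; every spot must have total count > 0.
#' @param target_sum per-spot total after scaling (default 10000).
#' @return The dataset with `expr` filled in.
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "spatial_dataset"))
  assert_scalar_num(target_sum, "target_sum", lower = 1e-12)
  tot <- rowSums(ds$counts)
  if (any(tot == 0))
    stop2(sum(tot == 0), " spot(s) have zero total count; run qc_filter() first")
  ds$expr <- log1p(ds$counts * (target_sum / tot))
  dimnames(ds$expr) <- dimnames(ds$counts)
  ds
}

#' Select highly variable genes
#'
#' Ranks genes by a dispersion-based variability score on the normalized
#' log expression: per-gene dispersion (variance / mean) is z-scored
#' within 20 equal-frequency mean-expression bins, and the top `n_hvg`
#' genes are kept.  Ties are broken by gene identifier order so the
#' selection is deterministic and invariant to input gene order.
#'
#' @param ds a [spatial_dataset()] with normalized expression (run
#'   [normalize_log()] first).
#' @param n_hvg number of genes to keep (default 3000).  If the dataset
#'   has fewer genes, all are kept with a warning.
#' @param n_bins number of mean-expression bins for dispersion scaling.
#' @return The dataset restricted to the selected genes (original column
#'   order preserved).
#' @export
select_hvg <- function(ds, n_hvg = 3000, n_bins = 20) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$expr)) stop2("normalized expression missing; run normalize_log() first")
  if (n_hvg < 1) stop2("`n_hvg` must be >= 1")
  n_genes <- ncol(ds$expr)
  if (n_genes <= n_hvg) {
    if (n_genes < n_hvg)
      warning(sprintf("only %d genes available; keeping all (n_hvg = %d)",
                      n_genes, n_hvg))
    return(ds)
  }
  score <- hvg_score(ds$expr, n_bins = n_bins)
  ord <- order(-score, ds$gene_ids)           # ties -> lexicographically earlier gene
  keep <- sort(ord[seq_len(n_hvg)])           # preserve original column order
  subset_dataset(ds, genes = keep)
}

hvg_score <- function(expr, n_bins = 20) {
  mu <- colMeans(expr)
  v <- apply(expr, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins of mean expression; z-score dispersion within bin
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = qs, include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  z
}

#' Full preprocessing pipeline
#'
#' [qc_filter()], then [normalize_log()], then [select_hvg()].
#'
#' @param ds a [spatial_dataset()]
#' @param strict_qc enable the comparison-protocol spot filters
#'   (mitochondrial fraction > 15% and fewer than 100 detected genes).
#' @param target_sum,n_hvg see the component functions.
#' @param ... further arguments to [qc_filter()].
#' @return The preprocessed dataset.
#' @export
preprocess <- function(ds, strict_qc = FALSE, target_sum = 1e4, n_hvg = 3000, ...) {
  ds <- qc_filter(ds,
                  max_mito_fraction = if (strict_qc) 0.15 else NULL,
                  min_genes_per_spot = if (strict_qc) 100 else NULL,
                  ...)
  ds <- normalize_log(ds, target_sum = target_sum)
  select_hvg(ds, n_hvg = n_hvg)
}
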