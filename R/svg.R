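#' First- and second-order neighborhoods of a spatial domain
#'
#' BFS rings over the spatial neighbor graph: `first_order` holds spots
#' adjacent to a domain member but outside the domain; `second_order`
#' holds spots adjacent to the first ring, excluding both the domain and
#' the first ring.  The three sets are pairwise disjoint.
#'
#' @param g a [build_sng()] graph.
#' @param labels a `domain_labels` object or integer vector of labels.
#' @param domain the domain label to expand around.
#' @return List with integer index vectors `members`, `first_order`,
#'   `second_order` and the scalar `domain`.
#' @export
domain_neighbors <- function(g, labels, domain) {
  lab <- if (inherits(labels, "domain_labels")) labels$labels else as.integer(labels)
  if (length(lab) != g$n_spots) stop2("labels and graph disagree on spot count")
  members <- which(lab == domain)
  if (length(members) == 0) stop2("domain ", domain, " has no spots")
  ring1 <- setdiff(unique(unlist(g$neighbors[members], use.names = FALSE)), members)
  ring2 <- setdiff(unique(unlist(g$neighbors[ring1], use.names = FALSE)),
                   c(members, ring1))
  if (length(ring1) == 0)
    warning("domain ", domain, " has no spatial neighbors")
  list(domain = domain, members = members,
       first_order = sort(ring1), second_order = sort(ring2))
}

#' Within-spot expression percentages
#'
#' Converts each spot's counts to the percentage of its total UMIs:
#' `100 * count_ij / sum_j count_ij`.  Rows sum to 100.
#'
#' @param counts spots x genes count matrix with positive spot totals.
#' @return Matrix of percentages, same dimensions.
#' @export
expression_percentage <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop2("zero-total spot(s); filter them before computing percentages")
  100 * counts / tot
}

#' Fraction of domain spots expressing a gene
#'
#' The in-domain expression density behind the 80% rule.  By default the
#' fraction of target-domain spots with nonzero count for the gene; the
#' alternative reading — the share of all expressing spots that lie in
#' the domain — is available via `definition`.
#'
#' @param ds a [spatial_dataset()].
#' @param members integer indices of the domain's spots.
#' @param gene gene identifier or column index.
#' @param definition `"within_domain"` (default) or `"share_of_expressing"`.
#' @return A fraction in `[0, 1]`.
#' @export
in_domain_fraction <- function(ds, members, gene,
                               definition = c("within_domain", "share_of_expressing")) {
  definition <- match.arg(definition)
  v <- ds$counts[, gene] > 0
  if (definition == "within_domain") mean(v[members])
  else if (sum(v) == 0) 0 else sum(v[members]) / sum(v)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples (each nonempty).
#' @return Two-sided p-value in `[0, 1]`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop2("both samples must be nonempty")
  if (length(unique(c(a, b))) == 1L) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  out <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  min(out$p.value, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`p * m / rank`, cumulative minimum from the
#' largest p down, capped at 1); preserves the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Detect spatially variable genes by domain-restricted DE
#'
#' For every spatial domain, genes passing the in-domain expression
#' prefilter (expressed in more than `frac_cutoff` of the domain's
#' spots) are tested by Wilcoxon rank-sum on normalized expression,
#' domain members versus the union of the first- and second-order
#' neighborhoods; p-values are BH-adjusted within the domain (or
#' globally with `per_domain_bh = FALSE`).  A gene is called an SVG in a
#' domain when all four filters hold: adjusted p below `p_cutoff`,
#' strictly positive Moran's I, in-domain expression fraction above
#' `frac_cutoff`, and mean within-spot expression percentage in the
#' domain exceeding `min_fold` times its mean in both neighborhood
#' rings.
#'
#' @param ds preprocessed [spatial_dataset()] (counts + normalized expr).
#' @param g a [build_sng()] graph.
#' @param labels `domain_labels` or integer label vector.
#' @param ac optional [score_genes()] result (computed with binary
#'   weights when omitted).
#' @param p_cutoff adjusted p-value threshold (default 0.05).
#' @param frac_cutoff in-domain expression-fraction threshold, strict
#'   (default 0.8).
#' @param min_fold minimum fold difference of expression percentages
#'   (default 1: simply higher).
#' @param per_domain_bh adjust within each domain (default) or across
#'   all domains jointly.
#' @param frac_definition passed to [in_domain_fraction()].
#' @return `data.frame` of class `svg_table`, one row per tested
#'   (domain, gene) pair: `gene_id`, `domain`, `expr_pct_target`,
#'   `expr_pct_nbr1`, `expr_pct_nbr2`, `in_domain_frac`, `morans_i`,
#'   `p_value`, `p_adj`, `is_svg`.  Attribute `svg_genes` holds the
#'   deduplicated dataset-level SVG identifiers.
#' @export
detect_svgs <- function(ds, g, labels, ac = NULL,
                        p_cutoff = 0.05, frac_cutoff = 0.8, min_fold = 1,
                        per_domain_bh = TRUE,
                        frac_definition = c("within_domain", "share_of_expressing")) {
  frac_definition <- match.arg(frac_definition)
  if (is.null(ds$expr)) stop2("normalized expression missing; run normalize_log()")
  lab <- if (inherits(labels, "domain_labels")) labels$labels else as.integer(labels)
  if (is.null(ac)) ac <- score_genes(ds, g, scheme = "binary")
  moran <- ac$morans_i[match(ds$gene_ids, ac$gene_id)]
  pct <- expression_percentage(ds$counts)
  rows <- list()
  for (d in sort(unique(lab))) {
    sets <- domain_neighbors(g, lab, d)
    nbr <- c(sets$first_order, sets$second_order)
    if (length(nbr) == 0) {
      warning("domain ", d, " has empty neighborhoods; skipped")
      next
    }
    members <- sets$members
    frac <- if (frac_definition == "within_domain") {
      colMeans(ds$counts[members, , drop = FALSE] > 0)
    } else {
      expr_spots <- colSums(ds$counts > 0)
      ifelse(expr_spots == 0, 0,
             colSums(ds$counts[members, , drop = FALSE] > 0) / expr_spots)
    }
    tested <- which(frac > frac_cutoff)
    if (length(tested) == 0) next
    pv <- vapply(tested, function(j)
      wilcoxon_rank_sum(ds$expr[members, j], ds$expr[nbr, j]), 1.0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = ds$gene_ids[tested],
      domain = d,
      expr_pct_target = colMeans(pct[members, tested, drop = FALSE]),
      expr_pct_nbr1 = if (length(sets$first_order) > 0)
        colMeans(pct[sets$first_order, tested, drop = FALSE]) else 0,
      expr_pct_nbr2 = if (length(sets$second_order) > 0)
        colMeans(pct[sets$second_order, tested, drop = FALSE]) else 0,
      in_domain_frac = unname(frac[tested]),
      morans_i = moran[tested],
      p_value = pv,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(gene_id = character(0), domain = integer(0),
                      expr_pct_target = numeric(0), expr_pct_nbr1 = numeric(0),
                      expr_pct_nbr2 = numeric(0), in_domain_frac = numeric(0),
                      morans_i = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), is_svg = logical(0))
    attr(out, "svg_genes") <- character(0)
    class(out) <- c("svg_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- if (per_domain_bh) {
    stats::ave(out$p_value, out$domain, FUN = bh_adjust)
  } else bh_adjust(out$p_value)
  out$is_svg <- out$p_adj < p_cutoff &
    !is.na(out$morans_i) & out$morans_i > 0 &
    out$in_domain_frac > frac_cutoff &
    out$expr_pct_target > min_fold * pmax(out$expr_pct_nbr1, out$expr_pct_nbr2)
  attr(out, "svg_genes") <- sort(unique(out$gene_id[out$is_svg]))
  class(out) <- c("svg_table", "data.frame")
  out
}

#' @export
print.svg_table <- function(x, ...) {
  cat(sprintf("svg_table: %d tested (domain, gene) pairs; %d SVG calls; %d unique SVGs\n",
              nrow(x), sum(x$is_svg), length(attr(x, "svg_genes"))))
  NextMethod()
}
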