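chain_graph <- function(n = 5) {
  nbrs <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L, if (i < n) i + 1L)))
  graph_from_neighbors(nbrs)
}

test_that("BFS rings around a domain are exact on a chain", {
  g <- chain_graph(5)
  sets <- domain_neighbors(g, c(2L, 2L, 1L, 2L, 2L), domain = 1)
  expect_equal(sets$members, 3L)
  expect_equal(sets$first_order, c(2L, 4L))
  expect_equal(sets$second_order, c(1L, 5L))

  # a domain covering every spot has empty rings
  all1 <- suppressWarnings(domain_neighbors(g, rep(1L, 5), domain = 1))
  expect_length(all1$first_order, 0)
  expect_length(all1$second_order, 0)

  # isolated-spot domain warns and has empty rings
  g_iso <- graph_from_neighbors(list(c(2L), c(1L), integer(0)))
  expect_warning(s_iso <- domain_neighbors(g_iso, c(1L, 1L, 2L), domain = 2),
                 "no spatial neighbors")
  expect_length(s_iso$first_order, 0)

  expect_error(domain_neighbors(g, rep(1L, 5), domain = 9), "no spots")
})

test_that("expression percentages normalize each spot to 100", {
  out <- expression_percentage(rbind(c(2, 3, 5), c(1, 1, 2)))
  expect_equal(out[1, ], c(20, 30, 50), ignore_attr = TRUE)
  expect_equal(rowSums(out), c(100, 100), ignore_attr = TRUE)
  # scale invariance per spot; single-gene saturation
  expect_equal(expression_percentage(rbind(c(4, 6, 10))),
               expression_percentage(rbind(c(2, 3, 5))))
  expect_equal(expression_percentage(matrix(c(3, 7), 2, 1)),
               matrix(100, 2, 1), ignore_attr = TRUE)
  expect_error(expression_percentage(rbind(c(0, 0))), "zero-total")
})

test_that("in-domain expression fraction covers both readings", {
  counts <- rbind(5, 2, 0, 1, 0, 3, 2)    # 7 spots, 1 gene
  ds <- spatial_dataset(counts, cbind(1:7, 0))
  members <- 1:5
  expect_equal(in_domain_fraction(ds, members, 1), 3 / 5)
  expect_equal(in_domain_fraction(ds, 1:2, 1), 1.0)
  expect_equal(in_domain_fraction(ds, c(3, 5), 1), 0.0)
  # 4 of 5 expressing -> 0.8 exactly, failing a strict > 0.8 rule
  ds2 <- spatial_dataset(rbind(1, 1, 1, 1, 0), cbind(1:5, 0))
  expect_equal(in_domain_fraction(ds2, 1:5, 1), 0.8)
  expect_false(in_domain_fraction(ds2, 1:5, 1) > 0.8)
  # share-of-expressing reading
  expect_equal(in_domain_fraction(ds, members, 1,
                                  definition = "share_of_expressing"), 3 / 5)
  expect_equal(in_domain_fraction(ds, 1:2, 1,
                                  definition = "share_of_expressing"), 2 / 5)
})

test_that("Wilcoxon p-values match exact enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), 1)

  set.seed(41)
  for (m in 2:5) for (n in 2:(10 - m)) {
    a <- rnorm(m); b <- rnorm(n)
    expect_equal(wilcoxon_rank_sum(a, b), oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-12,
                 label = sprintf("m=%d n=%d", m, n))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("large-sample Wilcoxon p-values are null-uniform", {
  set.seed(42)
  ps <- replicate(400, wilcoxon_rank_sum(rnorm(200), rnorm(200)))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(43)
  for (rep in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

svg_fixture <- function(seed = 44) {
  # one 10x10 lattice, two domains, strong planted genes so every filter
  # in the cascade is genuinely satisfiable
  sim <- simulate_visium(n_rows = 10, n_cols = 10, n_domains = 2,
                         n_genes = 60, n_svg_per_domain = 5, base_mean = 2,
                         fold_change = 4, dispersion = 0.5, seed = seed)
  ds <- normalize_log(qc_filter(sim$dataset))
  g <- build_sng(ds$coords)
  list(sim = sim, ds = ds, g = g, labels = sim$truth$true_labels)
}

test_that("planted domain-enriched genes are called SVGs, flat genes are not", {
  fx <- svg_fixture()
  tab <- detect_svgs(fx$ds, fx$g, fx$labels)
  planted <- unlist(fx$sim$truth$true_svg, use.names = FALSE)
  planted <- intersect(planted, fx$ds$gene_ids)
  found <- attr(tab, "svg_genes")
  expect_gt(mean(planted %in% found), 0.8)
  # background genes essentially never pass
  bg <- setdiff(fx$ds$gene_ids, planted)
  expect_lt(mean(bg %in% found), 0.1)

  # every reported SVG satisfies all four filter conditions
  hit <- tab[tab$is_svg, ]
  expect_true(all(hit$p_adj < 0.05))
  expect_true(all(hit$morans_i > 0))
  expect_true(all(hit$in_domain_frac > 0.8))
  expect_true(all(hit$expr_pct_target > pmax(hit$expr_pct_nbr1, hit$expr_pct_nbr2)))
  expect_true(all(tab$p_adj >= tab$p_value - 1e-12))
})

test_that("detection is invariant to gene and spot order", {
  fx <- svg_fixture(seed = 45)
  tab <- detect_svgs(fx$ds, fx$g, fx$labels)

  set.seed(1)
  gp <- sample(ncol(fx$ds$counts))
  ds_g <- subset_ds <- fx$ds
  ds_g$counts <- ds_g$counts[, gp]; ds_g$expr <- ds_g$expr[, gp]
  ds_g$gene_ids <- ds_g$gene_ids[gp]
  tab_g <- detect_svgs(ds_g, fx$g, fx$labels)
  expect_setequal(attr(tab_g, "svg_genes"), attr(tab, "svg_genes"))

  sp <- sample(nrow(fx$ds$counts))
  ds_s <- fx$ds
  ds_s$counts <- ds_s$counts[sp, ]; ds_s$expr <- ds_s$expr[sp, ]
  ds_s$coords <- ds_s$coords[sp, ]; ds_s$spot_ids <- ds_s$spot_ids[sp]
  g_s <- build_sng(ds_s$coords, rad_cutoff = fx$g$rad_cutoff)
  tab_s <- detect_svgs(ds_s, g_s, fx$labels[sp])
  expect_setequal(attr(tab_s, "svg_genes"), attr(tab, "svg_genes"))
})

test_that("under a global null few genes reach significance", {
  set.seed(46)
  frac_sig <- vapply(1:5, function(s) {
    sim <- simulate_visium(n_rows = 10, n_cols = 10, n_domains = 2,
                           n_genes = 50, n_svg_per_domain = 5,
                           fold_change = 1, seed = 100 + s)
    ds <- normalize_log(qc_filter(sim$dataset))
    g <- build_sng(ds$coords)
    tab <- detect_svgs(ds, g, sim$truth$true_labels)
    if (nrow(tab) == 0) 0 else length(attr(tab, "svg_genes")) / ncol(ds$counts)
  }, 1.0)
  expect_lt(mean(frac_sig), 0.05 + 2 * sd(frac_sig) / sqrt(5) + 1e-9)
})

test_that("genes below the in-domain density cutoff are never tested", {
  fx <- svg_fixture(seed = 47)
  tab <- detect_svgs(fx$ds, fx$g, fx$labels, frac_cutoff = 0.8)
  for (d in unique(tab$domain)) {
    members <- which(fx$labels == d)
    fr <- colMeans(fx$ds$counts[members, , drop = FALSE] > 0)
    expect_true(all(fr[match(tab$gene_id[tab$domain == d],
                             fx$ds$gene_ids)] > 0.8))
  }
})
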