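test_that("G statistic matches hand-derived values and conventions", {
  expect_equal(g_statistic(10, 10, 10, 10), 0)
  # all expected cells 12.5: 2 (2*20 ln(20/12.5) + 2*5 ln(5/12.5))
  expect_equal(g_statistic(20, 5, 5, 20), 19.2745, tolerance = 1e-4)
  # all expected cells 5; zero cells contribute nothing: 40 ln 2
  expect_equal(g_statistic(0, 10, 10, 0), 40 * log(2), tolerance = 1e-12)
  # zero margin: uninformative site
  expect_equal(g_statistic(0, 0, 10, 20), 0)
  expect_equal(g_statistic(10, 0, 20, 0), 0)
  expect_error(g_statistic(-1, 2, 3, 4), "nonnegative")
})

test_that("G equals the independent 2N*KL oracle on random tables", {
  set.seed(8)
  for (i in 1:200) {
    tab <- rpois(4, lambda = sample(c(2, 10, 50), 1)) + c(1, 0, 0, 1)
    got <- g_statistic(tab[1], tab[2], tab[3], tab[4])
    want <- g_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_lt(abs(got - want), 1e-9)
  }
})

test_that("tricube smoothing reproduces hand-evaluated kernels", {
  # a lone SNP keeps its own G
  expect_equal(tricube_smooth(1000, 5, 1e6), 5)
  # constant G stays constant
  expect_equal(
    tricube_smooth(seq(1, 2e6, by = 1e5), rep(3.3, 20), 1e6),
    rep(3.3, 20)
  )
  # three SNPs at 0, 250k, 500k with h = 500k: outer weights (1-(1/2)^3)^3
  g <- tricube_smooth(c(0, 250000, 500000), c(2, 4, 6), 1e6)
  w <- (1 - 0.5^3)^3
  expect_equal(g[2], (w * 2 + 4 + w * 6) / (2 * w + 1), tolerance = 1e-12)
  expect_equal(g[2], 4) # symmetry forces the mean
  expect_error(tricube_smooth(c(2, 1), c(1, 1), 1e6), "sorted")
})

test_that("tricube smoothing is shift-invariant and linear in G", {
  set.seed(15)
  pos <- sort(sample(1:5e6, 300))
  g1 <- rexp(300)
  g2 <- rexp(300)
  s <- tricube_smooth(pos, g1, 1e6)
  expect_equal(tricube_smooth(pos + 12345, g1, 1e6), s, tolerance = 1e-12)
  expect_equal(
    tricube_smooth(pos, 2 * g1 + 3 * g2, 1e6),
    2 * s + 3 * tricube_smooth(pos, g2, 1e6),
    tolerance = 1e-10
  )
})

test_that("null model calibrates p-values on log-normal G'", {
  set.seed(21)
  n <- 10000
  gprime <- rlnorm(n, meanlog = 1, sdlog = 0.3)
  delta <- runif(n, -0.09, 0.09)
  pq <- fit_null_pvalues(gprime, delta, scan_config())

  # the fitted median maps to p = 0.5
  mu <- attr(pq, "null_mu")
  p_at_median <- fit_null_pvalues(
    c(exp(mu), gprime), c(0, delta), scan_config()
  )$pvalue[1]
  expect_equal(p_at_median, 0.5, tolerance = 1e-6)

  # p is strictly decreasing in G'
  ord <- order(gprime)
  expect_true(all(diff(pq$pvalue[ord]) <= 0))

  # type-I error recovery at the 1% level: 0.01 +/- 0.003
  expect_lt(abs(mean(pq$pvalue < 0.01) - 0.01), 0.003)
})

test_that("too few null SNPs is a clear error", {
  expect_error(
    fit_null_pvalues(rlnorm(100), rep(0.5, 100), scan_config()),
    "filter_threshold"
  )
})

test_that("interval calling groups significant runs and honours the merge gap", {
  rec <- tibble::tibble(
    chrom = "Chr1",
    pos = c(100, 500, 900, 2000, 3200100, 3200500),
    sig = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  iv <- call_qtl_intervals(rec, scan_config(window_size = 1e6))
  expect_equal(nrow(iv), 2) # runs 2.2 Mb apart stay separate
  expect_equal(iv$start_bp, c(100, 3200100))
  expect_equal(iv$end_bp, c(900, 3200500))
  expect_equal(iv$qtl_id, c(1L, 2L))

  # nothing significant: empty but well-formed
  none <- call_qtl_intervals(
    dplyr::mutate(rec, sig = FALSE), scan_config()
  )
  expect_equal(nrow(none), 0)

  # runs 0.5 Mb apart merge under a 1 Mb gap
  rec2 <- tibble::tibble(
    chrom = "Chr1", pos = c(100, 900, 500900, 501300),
    sig = TRUE
  )
  iv2 <- call_qtl_intervals(rec2, scan_config(window_size = 1e6))
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$end_bp - iv2$start_bp, 501200)
})

test_that("interval summaries reproduce the published overview arithmetic", {
  regions <- exa_qtl_regions()
  tab <- summarize_qtl(regions)

  expect_equal(tab$area_bp[tab$qtl_id == 3], 41187)
  expect_equal(tab$area_bp[tab$qtl_id == 6], 8263689)
  expect_equal(tab$area_bp[tab$qtl_id == 10], 63682)
  expect_equal(tab$gene_density[tab$qtl_id == 3], 292L)
  expect_equal(tab$gene_density[tab$qtl_id == 1], 25L) # ceil(24.29)
  expect_equal(tab$gene_density[tab$qtl_id == 7], 81L) # ceil(80.25)
  expect_equal(tab$gene_density[tab$qtl_id == 10], 16L) # ceil(15.70)

  tot <- summarize_qtl_totals(tab)
  expect_equal(tot$total_area_bp, 27219564)
  expect_equal(tot$total_genes, 2325)
  expect_equal(tot$mean_gene_density, 96.5)
  expect_equal(tot$total_snps, 589463)

  # a single interval's totals equal the interval itself
  one <- summarize_qtl_totals(tab[1, ])
  expect_equal(one$total_area_bp, tab$area_bp[1])
  expect_equal(one$mean_gene_density, tab$gene_density[1])
})

test_that("gene overlap counting agrees with an interval-tree oracle", {
  set.seed(33)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    chrom = sample(c("Chr1", "Chr2"), 200, replace = TRUE),
    start = sample(1:1e6, 200)
  ) |>
    dplyr::mutate(end = start + sample(500:5000, 200, replace = TRUE))
  iv <- tibble::tibble(
    chrom = c("Chr1", "Chr2", "Chr1"),
    start_bp = c(1e5, 4e5, 900000), end_bp = c(3e5, 8e5, 999000)
  )
  got <- summarize_qtl(iv, genes = genes)$n_genes
  want <- vapply(seq_len(nrow(iv)), function(i) {
    gr_g <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start, genes$end)
    )
    gr_i <- GenomicRanges::GRanges(
      iv$chrom[i], IRanges::IRanges(iv$start_bp[i], iv$end_bp[i])
    )
    sum(IRanges::overlapsAny(gr_g, gr_i))
  }, integer(1))
  expect_equal(got, want)

  # unknown chromosome: zero genes with a warning
  expect_warning(
    res <- summarize_qtl(
      tibble::tibble(chrom = "Chr9", start_bp = 1, end_bp = 100),
      genes = genes
    ),
    "absent"
  )
  expect_equal(res$n_genes, 0L)
})

test_that("SNP counts inside intervals distinguish bulk-exclusive SNPs", {
  snps <- tibble::tibble(
    chrom = "Chr1", pos = c(50, 150, 250, 350),
    difference = c(TRUE, FALSE, TRUE, TRUE)
  )
  iv <- tibble::tibble(chrom = "Chr1", start_bp = 100, end_bp = 300)
  out <- summarize_qtl(iv, snps = snps)
  expect_equal(out$n_snps_total, 2L)
  expect_equal(out$n_snps_unique_to_a_bulk, 1L)
})

test_that("a planted QTL is recovered by the full scan", {
  rep1 <- simulate_scan_replicate(seed = 42)
  iv <- rep1$scan$intervals
  hit <- any(
    iv$chrom == rep1$qtl_chrom &
      iv$start_bp <= rep1$qtl_pos & iv$end_bp >= rep1$qtl_pos
  )
  expect_true(hit)
})
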