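#' Simulate a genotyping panel for association testing
#'
#' Emulates the presence/absence spreadsheet a targeted
#' genotyping-by-sequencing provider returns for a variety panel: one call
#' (`"ref"`, `"alt"` or `"missing"`) per variety and panel SNP. Varieties
#' carry a latent drought-tolerance index (DRYM-like, mean 0) that fixes
#' their ranking. For neutral SNPs the carrier probability is constant
#' across varieties; for SNPs named in `assoc_snps` it depends on the
#' variety's tolerance through a logistic model, planting a true
#' marker-trait association.
#'
#' @param panel_snps Tibble with at least `chrom`, `pos`, `alt` (a `snp_id`
#'   column is honoured, otherwise built as `chrom:pos:alt`).
#' @param n_varieties Panel size (default 34 varieties).
#' @param assoc_snps Character vector of `snp_id`s that carry a true
#'   association.
#' @param effect_logodds Log-odds of carrying the alternative allele per
#'   standard deviation of tolerance, for associated SNPs.
#' @param missing_rate Probability a call is missing.
#' @param drym_sd Standard deviation of the latent tolerance index.
#' @param seed Optional integer seed.
#' @return A list: `varieties` (tibble `variety_id`, `drym`, `rank`; rank 1
#'   is the most tolerant) and `genotypes` (long tibble `variety_id`,
#'   `snp_id`, `state`).
#' @export
simulate_panel <- function(panel_snps, n_varieties = 34,
                           assoc_snps = character(),
                           effect_logodds = 2,
                           missing_rate = 0.02,
                           drym_sd = 0.1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_id <- if ("snp_id" %in% names(panel_snps)) {
    panel_snps$snp_id
  } else {
    snp_key(panel_snps$chrom, panel_snps$pos, panel_snps$alt)
  }

  varieties <- tibble(
    variety_id = sprintf("V%02d", seq_len(n_varieties)),
    drym = rnorm(n_varieties, 0, drym_sd)
  ) %>%
    dplyr::mutate(rank = rank(-.data$drym, ties.method = "first"))

  z <- as.numeric(scale(varieties$drym))
  base_p <- runif(length(snp_id), 0.2, 0.8)

  genotypes <- purrr::imap(snp_id, function(id, i) {
    p <- if (id %in% assoc_snps) {
      stats::plogis(stats::qlogis(base_p[i]) + effect_logodds * z)
    } else {
      rep(base_p[i], n_varieties)
    }
    state <- ifelse(rbinom(n_varieties, 1, p) == 1, "alt", "ref")
    state[runif(n_varieties) < missing_rate] <- "missing"
    tibble(variety_id = varieties$variety_id, snp_id = id, state = state)
  }) %>% purrr::list_rbind()

  list(varieties = varieties, genotypes = genotypes)
}
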