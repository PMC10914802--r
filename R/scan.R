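#' G statistic for a 2x2 allele-depth table
#'
#' The likelihood-ratio statistic `G = 2 sum n_i log(n_i / e_i)` over the
#' four cells (ref/alt x tolerant/sensitive), with expected cells `e_i`
#' from the row and column margins under independence. Cells with zero
#' observed count contribute zero; a table with a zero margin carries no
#' allele-frequency contrast and returns `G = 0`. All arguments are
#' vectorised.
#'
#' @param ref_tol,alt_tol,ref_sen,alt_sen Nonnegative read counts.
#' @return Numeric vector of G values (>= 0).
#' @export
#' @examples
#' g_statistic(10, 10, 10, 10) # 0: exact independence
#' g_statistic(20, 5, 5, 20) # 19.27
g_statistic <- function(ref_tol, alt_tol, ref_sen, alt_sen) {
  o <- cbind(ref_tol, alt_tol, ref_sen, alt_sen)
  if (any(o < 0, na.rm = TRUE)) abort("counts must be nonnegative")
  n <- rowSums(o)
  r1 <- o[, 1] + o[, 2]
  r2 <- o[, 3] + o[, 4]
  c1 <- o[, 1] + o[, 3]
  c2 <- o[, 2] + o[, 4]
  e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  term <- o * log(o / e)
  term[o == 0] <- 0
  g <- 2 * rowSums(term)
  g[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0 | n == 0] <- 0
  pmax(g, 0)
}

#' Tricube-weighted smoothing of G values along a chromosome
#'
#' For a focal SNP at position x, every neighbour within half a window
#' (`h = window_size / 2`) receives the tricube weight
#' `w = (1 - (d/h)^3)^3` with `d` the distance to the focal SNP, and G' is
#' the weighted mean of the neighbours' G values (the focal SNP itself has
#' weight 1). Smoothing never crosses chromosome boundaries; the caller
#' passes one chromosome at a time.
#'
#' @param positions Sorted numeric positions (bp) on one chromosome.
#' @param values G values at those positions.
#' @param window_size Full smoothing window in bp (default 1e6).
#' @return Numeric vector of smoothed values (G').
#' @export
tricube_smooth <- function(positions, values, window_size = 1e6) {
  n <- length(positions)
  if (n == 0) {
    return(numeric(0))
  }
  if (is.unsorted(positions)) abort("`positions` must be sorted")
  if (window_size <= 0) abort("`window_size` must be > 0")
  h <- window_size / 2
  lo <- findInterval(positions - h, positions, left.open = TRUE) + 1
  hi <- findInterval(positions + h, positions)
  vapply(seq_len(n), function(i) {
    j <- lo[i]:hi[i]
    w <- (1 - (abs(positions[j] - positions[i]) / h)^3)^3
    sum(w * values[j]) / sum(w)
  }, numeric(1))
}

#' G' scan settings
#'
#' @param window_size Full tricube window in bp (default 1e6).
#' @param filter_threshold |delta SNP-index| below which a SNP is treated
#'   as null when estimating the G' null distribution (default 0.1).
#' @param alpha Significance level after correction (default 0.01).
#' @param correction `"bonferroni"` or `"bh"`.
#' @param min_null Minimum number of null SNPs required for the fit.
#' @param merge_gap Significant runs closer than this (bp) are merged into
#'   one QTL interval; defaults to `window_size`.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_size = 1e6, filter_threshold = 0.1,
                        alpha = 0.01, correction = c("bonferroni", "bh"),
                        min_null = 50, merge_gap = window_size) {
  if (window_size <= 0) abort("`window_size` must be > 0")
  if (filter_threshold < 0 || filter_threshold >= 1) {
    abort("`filter_threshold` must lie in [0, 1)")
  }
  structure(
    list(
      window_size = window_size, filter_threshold = filter_threshold,
      alpha = alpha, correction = match.arg(correction),
      min_null = min_null, merge_gap = merge_gap
    ),
    class = "scan_config"
  )
}

#' Log-normal null model and p-values for G'
#'
#' Fits a log-normal null to the G' of SNPs with |delta SNP-index| below
#' `cfg$filter_threshold` - SNPs carrying no bulk contrast, whose smoothed
#' G reflects sampling noise only - using the robust location/scale pair
#' median and MAD of `log(G')`. P-values are the upper-tail survival of
#' that law at each SNP's G'; q-values are Benjamini-Hochberg, and a
#' Bonferroni-corrected significance flag at `cfg$alpha` is included.
#'
#' @param gprime Smoothed G' values.
#' @param delta_snp Per-SNP allele-frequency difference between bulks.
#' @param cfg A [scan_config()].
#' @return Tibble with `pvalue`, `qvalue`, `sig` plus attributes
#'   `null_mu` and `null_sigma`.
#' @export
fit_null_pvalues <- function(gprime, delta_snp, cfg = scan_config()) {
  null_set <- abs(delta_snp) < cfg$filter_threshold & gprime > 0 &
    !is.na(gprime) & !is.na(delta_snp)
  if (sum(null_set) < cfg$min_null) {
    abort(sprintf(
      "only %d SNPs with |delta SNP| < %g for the null fit (need >= %d); raise `filter_threshold`",
      sum(null_set), cfg$filter_threshold, cfg$min_null
    ))
  }
  lg <- log(gprime[null_set])
  mu <- median(lg)
  sigma <- mad(lg)
  if (sigma == 0) abort("degenerate null: MAD of log(G') is zero")

  pvalue <- plnorm(gprime, mu, sigma, lower.tail = FALSE)
  pvalue[is.na(gprime) | gprime <= 0] <- 1
  qvalue <- p.adjust(pvalue, method = "BH")
  sig <- switch(cfg$correction,
    bonferroni = p.adjust(pvalue, method = "bonferroni") < cfg$alpha,
    bh = qvalue < cfg$alpha
  )
  out <- tibble(pvalue = pvalue, qvalue = qvalue, sig = sig)
  attr(out, "null_mu") <- mu
  attr(out, "null_sigma") <- sigma
  out
}

#' Call QTL intervals from a scanned SNP table
#'
#' Groups significant SNPs (per the chosen correction at `cfg$alpha`) into
#' maximal runs per chromosome; runs separated by less than
#' `cfg$merge_gap` bp are merged. Each interval spans from the first to
#' the last significant SNP and intervals are numbered in genome order.
#'
#' @param records Tibble with at least `chrom`, `pos`, `sig` (as produced
#'   by [run_gprime_scan()]).
#' @param cfg A [scan_config()].
#' @return Tibble with `qtl_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps_sig`; zero rows when nothing is significant.
#' @export
call_qtl_intervals <- function(records, cfg = scan_config()) {
  sig <- records %>%
    dplyr::filter(.data$sig) %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)
  if (nrow(sig) == 0) {
    return(tibble(
      qtl_id = integer(), chrom = character(),
      start_bp = numeric(), end_bp = numeric(), n_snps_sig = integer()
    ))
  }
  sig %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(
      run = cumsum(c(0, diff(.data$pos)) >= cfg$merge_gap)
    ) %>%
    dplyr::group_by(.data$chrom, .data$run) %>%
    dplyr::summarise(
      start_bp = min(.data$pos), end_bp = max(.data$pos),
      n_snps_sig = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$start_bp) %>%
    dplyr::mutate(qtl_id = dplyr::row_number(), .before = 1) %>%
    dplyr::select(-"run")
}

#' Run the full G' scan on a joint bulk table
#'
#' Computes per-SNP delta SNP-index and G from the four allelic depths,
#' smooths G with the tricube kernel per chromosome, fits the log-normal
#' null, and calls QTL intervals. Only rows passing the filter in at least
#' one bulk contribute (passing both is not required: a bulk-exclusive SNP
#' is exactly the signal sought).
#'
#' @param joint Output of [intersect_bulks()], or any tibble with columns
#'   `chrom`, `pos`, `ad_ref_tol`, `ad_alt_tol`, `ad_ref_sen`,
#'   `ad_alt_sen`.
#' @param cfg A [scan_config()].
#' @param keep `"any_pass"` (default) keeps rows passing in either bulk if
#'   pass columns are present; `"all"` scans every row.
#' @return An object of class `gprime_scan`: list with `snps` (per-SNP
#'   tibble: `delta_snp`, `g`, `gprime`, `pvalue`, `qvalue`, `sig`),
#'   `intervals`, `null` (mu, sigma) and `cfg`. Use [tidy()] / [glance()]
#'   or [autoplot()].
#' @export
run_gprime_scan <- function(joint, cfg = scan_config(),
                            keep = c("any_pass", "all")) {
  keep <- match.arg(keep)
  if (keep == "any_pass" && all(c("pass_tol", "pass_sen") %in% names(joint))) {
    joint <- dplyr::filter(joint, .data$pass_tol | .data$pass_sen)
  }
  snps <- joint %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos) %>%
    dplyr::mutate(
      af_tol = .data$ad_alt_tol / pmax(.data$ad_ref_tol + .data$ad_alt_tol, 1),
      af_sen = .data$ad_alt_sen / pmax(.data$ad_ref_sen + .data$ad_alt_sen, 1),
      delta_snp = .data$af_tol - .data$af_sen,
      g = g_statistic(
        .data$ad_ref_tol, .data$ad_alt_tol,
        .data$ad_ref_sen, .data$ad_alt_sen
      )
    ) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(gprime = tricube_smooth(.data$pos, .data$g, cfg$window_size)) %>%
    dplyr::ungroup()

  pq <- fit_null_pvalues(snps$gprime, snps$delta_snp, cfg)
  snps <- dplyr::bind_cols(snps, pq)
  intervals <- call_qtl_intervals(snps, cfg)

  structure(
    list(
      snps = snps,
      intervals = intervals,
      null = c(mu = attr(pq, "null_mu"), sigma = attr(pq, "null_sigma")),
      cfg = cfg
    ),
    class = "gprime_scan"
  )
}

#' @export
print.gprime_scan <- function(x, ...) {
  cat(sprintf(
    "<gprime_scan> %d SNPs, %d significant (%s, alpha %g), %d QTL interval(s)\n",
    nrow(x$snps), sum(x$snps$sig), x$cfg$correction, x$cfg$alpha,
    nrow(x$intervals)
  ))
  cat(sprintf(
    "  null log-normal: mu %.3f, sigma %.3f\n",
    x$null["mu"], x$null["sigma"]
  ))
  invisible(x)
}
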