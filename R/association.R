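#' Split a ranked variety panel into tolerant and sensitive groups
#'
#' The panel is ordered by drought-tolerance rank (rank 1 = most
#' tolerant); the top half becomes the tolerant group and the bottom half
#' the sensitive group. With an odd panel the middle variety goes to the
#' sensitive group.
#'
#' @param varieties Tibble with `variety_id` and either a `rank` column
#'   or a `drym` column (ranked descending).
#' @return The input with a `group` column
#'   (`"tolerant"`/`"sensitive"`).
#' @export
#' @examples
#' v <- tibble::tibble(variety_id = letters[1:5], rank = 1:5)
#' split_panel(v) # 2 tolerant, 3 sensitive
split_panel <- function(varieties) {
  n <- nrow(varieties)
  if (n < 4) abort("need at least 4 varieties to form two groups")
  rk <- if ("rank" %in% names(varieties)) {
    varieties$rank
  } else if ("drym" %in% names(varieties)) {
    rank(-varieties$drym, ties.method = "first")
  } else {
    abort("`varieties` needs a `rank` or `drym` column")
  }
  n_tol <- floor(n / 2)
  varieties %>%
    dplyr::mutate(
      group = dplyr::if_else(rk <= n_tol, "tolerant", "sensitive")
    )
}

#' Fisher exact association of panel SNPs with the tolerance split
#'
#' Per SNP, varieties are dichotomised into carriers and non-carriers of
#' the alternative allele (missing calls dropped per SNP), crossed with
#' the tolerant/sensitive group, and tested with the two-sided Fisher
#' exact test (sum of hypergeometric probabilities of tables as or more
#' extreme than the observed one). A SNP monomorphic across the panel is
#' uninformative and gets `p = 1`.
#'
#' @param genotypes Long tibble with `variety_id`, `snp_id`, `state`
#'   (`"ref"`, `"alt"`, `"missing"`).
#' @param groups Output of [split_panel()].
#' @param alpha Significance level (default 0.05, uncorrected as is usual
#'   for a targeted panel; BH q-values are emitted informationally).
#' @return Tibble per SNP: carrier counts per group, `fisher_p`,
#'   `qvalue`, `significant`.
#' @export
fisher_association <- function(genotypes, groups, alpha = 0.05) {
  dat <- genotypes %>%
    dplyr::inner_join(
      dplyr::select(groups, "variety_id", "group"),
      by = "variety_id"
    ) %>%
    dplyr::filter(.data$state != "missing")

  out <- dat %>%
    dplyr::group_by(.data$snp_id) %>%
    dplyr::summarise(
      carrier_tol = sum(.data$state == "alt" & .data$group == "tolerant"),
      noncarrier_tol = sum(.data$state == "ref" & .data$group == "tolerant"),
      carrier_sen = sum(.data$state == "alt" & .data$group == "sensitive"),
      noncarrier_sen = sum(.data$state == "ref" & .data$group == "sensitive"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      fisher_p = purrr::pmap_dbl(
        list(
          .data$carrier_tol, .data$noncarrier_tol,
          .data$carrier_sen, .data$noncarrier_sen
        ),
        function(a, b, c, d) {
          fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
        }
      ),
      qvalue = p.adjust(.data$fisher_p, method = "BH"),
      significant = .data$fisher_p < alpha
    )
  out
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based one-way test of a quantitative tolerance index across
#' genotype classes, with the tie-corrected H statistic, chi-squared
#' p-value on k - 1 degrees of freedom, and the effect size
#' `eta^2 = (H - k + 1) / (n - k)` (can be slightly negative under the
#' null by construction).
#'
#' @param values Numeric tolerance values (e.g. DRYM), one per variety.
#' @param classes Genotype class per variety (>= 2 distinct classes, each
#'   with >= 1 observation).
#' @return One-row tibble with `kw_h`, `df`, `kw_p`, `eta_squared`, `n`,
#'   `k`.
#' @export
#' @examples
#' kruskal_wallis_eta2(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis_eta2 <- function(values, classes) {
  keep <- !is.na(values) & !is.na(classes)
  values <- values[keep]
  classes <- as.factor(as.character(classes[keep]))
  k <- nlevels(classes)
  n <- length(values)
  if (k < 2) {
    return(tibble(
      kw_h = NA_real_, df = NA_real_, kw_p = NA_real_,
      eta_squared = NA_real_, n = n, k = k
    ))
  }
  if (length(unique(values)) == 1) {
    # complete ties: zero rank variance, H = 0 by convention
    return(tibble(
      kw_h = 0, df = k - 1, kw_p = 1,
      eta_squared = (0 - k + 1) / (n - k), n = n, k = k
    ))
  }
  kt <- kruskal.test(values, classes)
  h <- unname(kt$statistic)
  tibble(
    kw_h = h,
    df = unname(kt$parameter),
    kw_p = kt$p.value,
    eta_squared = (h - k + 1) / (n - k),
    n = n, k = k
  )
}

#' Kruskal-Wallis association across a panel
#'
#' Applies [kruskal_wallis_eta2()] per SNP, using the variety genotype
#' state (or dosage class when a `dosage` column is present) as the
#' grouping and the varieties' DRYM as the response.
#'
#' @param genotypes Long tibble with `variety_id`, `snp_id`, `state` and
#'   optionally `dosage`.
#' @param varieties Tibble with `variety_id` and `drym`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble per SNP with the [kruskal_wallis_eta2()] columns and
#'   `significant`.
#' @export
kw_association <- function(genotypes, varieties, alpha = 0.05) {
  class_col <- if ("dosage" %in% names(genotypes)) "dosage" else "state"
  dat <- genotypes %>%
    dplyr::filter(.data$state != "missing") %>%
    dplyr::inner_join(
      dplyr::select(varieties, "variety_id", "drym"),
      by = "variety_id"
    )
  dat %>%
    dplyr::group_by(.data$snp_id) %>%
    dplyr::group_modify(~ kruskal_wallis_eta2(.x$drym, .x[[class_col]])) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(significant = !is.na(.data$kw_p) & .data$kw_p < alpha)
}

#' Exact two-sided Fisher p by exhaustive hypergeometric enumeration
#'
#' Independent oracle for the exact test: enumerates every 2x2 table with
#' the observed margins, sums the hypergeometric probabilities of all
#' tables no more probable than the observed one (with the conventional
#' relative tolerance for ties). Used to cross-check
#' [fisher_association()]; exported because it is handy for audits.
#'
#' @param a,b,c,d Cell counts (carriers/non-carriers x group).
#' @return Two-sided p-value.
#' @export
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b # margin: group 1
  n2 <- c + d # margin: group 2
  kk <- a + c # margin: carriers
  lo <- max(0, kk - n2)
  hi <- min(kk, m)
  x <- lo:hi
  # hypergeometric pmf from first principles (log factorials)
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  logp <- lchoose2(m, x) + lchoose2(n2, kk - x) - lchoose2(m + n2, kk)
  p <- exp(logp)
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}
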