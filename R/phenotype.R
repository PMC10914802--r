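#' Relative starch yield per genotype and experiment
#'
#' For every genotype x experiment pair with both treatments observed,
#' computes the relative starch yield `relsy = SY(stress) / SY(control)`,
#' the within-experiment normalisation that makes drought trials with
#' different yield levels comparable.
#'
#' Pairs with a missing treatment, or with a control yield of zero (the
#' ratio is undefined), are dropped with a warning.
#'
#' @param records Long-format tibble with columns `genotype_id`,
#'   `experiment_id`, `treatment` (`"stress"`/`"control"`) and
#'   `starch_yield`.
#' @return Tibble with `genotype_id`, `experiment_id`, `relsy`.
#' @export
#' @examples
#' ph <- tibble::tibble(
#'   genotype_id = "g1", experiment_id = "E1",
#'   treatment = c("control", "stress"), starch_yield = c(21, 10.5)
#' )
#' compute_relsy(ph) # relsy 0.5
compute_relsy <- function(records) {
  need <- c("genotype_id", "experiment_id", "treatment", "starch_yield")
  if (!all(need %in% names(records))) {
    abort(paste("`records` needs columns:", paste(need, collapse = ", ")))
  }
  bad_treat <- setdiff(unique(records$treatment), c("stress", "control"))
  if (length(bad_treat) > 0) {
    abort(paste("unknown treatment label(s):", paste(bad_treat, collapse = ", ")))
  }
  wide <- records %>%
    dplyr::group_by(.data$genotype_id, .data$experiment_id, .data$treatment) %>%
    dplyr::summarise(starch_yield = mean(.data$starch_yield), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "starch_yield")
  if (!"stress" %in% names(wide)) wide$stress <- NA_real_
  if (!"control" %in% names(wide)) wide$control <- NA_real_

  incomplete <- is.na(wide$stress) | is.na(wide$control)
  zero_ctrl <- !incomplete & wide$control == 0
  if (any(incomplete)) {
    warn(sprintf(
      "%d genotype x experiment pair(s) missing a treatment; excluded",
      sum(incomplete)
    ))
  }
  if (any(zero_ctrl)) {
    warn(sprintf(
      "%d pair(s) with control starch yield 0; excluded",
      sum(zero_ctrl)
    ))
  }
  wide %>%
    dplyr::filter(!incomplete & !zero_ctrl) %>%
    dplyr::mutate(relsy = .data$stress / .data$control) %>%
    dplyr::select("genotype_id", "experiment_id", "relsy")
}

#' DRYM: deviation of relative starch yield from the experiment median
#'
#' `drym = relsy - median(relsy)` within each experiment. A positive DRYM
#' marks a genotype more drought tolerant than the experiment's population
#' median, a negative DRYM a more sensitive one; by construction the index
#' is centred within every experiment and insensitive to the experiment's
#' overall yield level.
#'
#' @param relsy_table Output of [compute_relsy()].
#' @return The input with a `drym` column appended.
#' @export
compute_drym <- function(relsy_table) {
  n_per_exp <- relsy_table %>% dplyr::count(.data$experiment_id)
  if (any(n_per_exp$n < 2)) {
    abort(paste(
      "experiments with a single genotype have no tolerance contrast:",
      paste(n_per_exp$experiment_id[n_per_exp$n < 2], collapse = ", ")
    ))
  }
  relsy_table %>%
    dplyr::group_by(.data$experiment_id) %>%
    dplyr::mutate(drym = .data$relsy - median(.data$relsy)) %>%
    dplyr::ungroup()
}

#' Select contrasting phenotypic bulks by mean rank
#'
#' Within each experiment genotypes are ranked by DRYM (rank 1 = most
#' tolerant; ties get average ranks), and ranks are averaged over the
#' experiments in which a genotype was observed. The `n_bulk` genotypes
#' with the lowest mean rank form one bulk and the `n_bulk` highest the
#' other; orientation is fixed so that the tolerant bulk is the one with
#' the higher mean DRYM. Optionally genotypes flagged as outliers
#' (any per-experiment DRYM beyond `iqr_mult` interquartile ranges from
#' the experiment's quartiles) are removed before selection.
#'
#' @param drym_table Output of [compute_drym()].
#' @param n_bulk Bulk size (default 20).
#' @param flag_outliers Apply the IQR outlier filter before selection?
#' @param iqr_mult IQR multiplier for the outlier rule.
#' @return A list of class `bulk_assignment`: `tolerant_ids`,
#'   `sensitive_ids`, and `ranks` (per-genotype tibble with `mean_rank`,
#'   `min_rank`, `max_rank`, `mean_drym`, `outlier`, `bulk`).
#' @export
select_bulks <- function(drym_table, n_bulk = 20,
                         flag_outliers = FALSE, iqr_mult = 1.5) {
  ranked <- drym_table %>%
    dplyr::group_by(.data$experiment_id) %>%
    dplyr::mutate(
      tol_rank = rank(-.data$drym, ties.method = "average"),
      .lo = quantile(.data$drym, 0.25) - iqr_mult * stats::IQR(.data$drym),
      .hi = quantile(.data$drym, 0.75) + iqr_mult * stats::IQR(.data$drym)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(out_flag = .data$drym < .data$.lo | .data$drym > .data$.hi)

  ranks <- ranked %>%
    dplyr::group_by(.data$genotype_id) %>%
    dplyr::summarise(
      mean_rank = mean(.data$tol_rank),
      min_rank = min(.data$tol_rank),
      max_rank = max(.data$tol_rank),
      mean_drym = mean(.data$drym),
      outlier = any(.data$out_flag),
      .groups = "drop"
    )

  eligible <- if (flag_outliers) dplyr::filter(ranks, !.data$outlier) else ranks
  if (nrow(eligible) < 2 * n_bulk) {
    abort(sprintf(
      "need at least %d eligible genotypes for two bulks of %d, have %d",
      2 * n_bulk, n_bulk, nrow(eligible)
    ))
  }

  eligible <- dplyr::arrange(eligible, .data$mean_rank, .data$genotype_id)
  low <- head(eligible, n_bulk) # lowest mean rank = most tolerant
  high <- tail(eligible, n_bulk)
  if (mean(low$mean_drym) >= mean(high$mean_drym)) {
    tolerant <- low$genotype_id
    sensitive <- high$genotype_id
  } else {
    tolerant <- high$genotype_id
    sensitive <- low$genotype_id
  }

  ranks$bulk <- dplyr::case_when(
    ranks$genotype_id %in% tolerant ~ "tolerant",
    ranks$genotype_id %in% sensitive ~ "sensitive",
    .default = NA_character_
  )
  structure(
    list(tolerant_ids = tolerant, sensitive_ids = sensitive, ranks = ranks),
    class = "bulk_assignment"
  )
}

#' @export
print.bulk_assignment <- function(x, ...) {
  cat(sprintf(
    "<bulk_assignment> %d tolerant / %d sensitive clones (of %d ranked)\n",
    length(x$tolerant_ids), length(x$sensitive_ids), nrow(x$ranks)
  ))
  invisible(x)
}

#' Welch two-sample test of bulk separation
#'
#' Tests whether the mean DRYM of the tolerant and sensitive bulks differ,
#' using the unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom. When both groups are constant and equal the test is
#' uninformative and `p = 1`, `t = 0` is returned by convention.
#'
#' @param drym_tol,drym_sen Numeric DRYM values of the two bulks (each of
#'   length >= 2).
#' @return One-row tibble with `statistic`, `df`, `p_value`, and the two
#'   group means.
#' @export
bulk_separation_test <- function(drym_tol, drym_sen) {
  if (length(drym_tol) < 2 || length(drym_sen) < 2) {
    abort("both groups need at least 2 values")
  }
  if (sd(drym_tol) == 0 && sd(drym_sen) == 0) {
    if (mean(drym_tol) == mean(drym_sen)) {
      return(tibble(
        statistic = 0, df = NA_real_, p_value = 1,
        mean_tolerant = mean(drym_tol), mean_sensitive = mean(drym_sen)
      ))
    }
    return(tibble(
      statistic = sign(mean(drym_tol) - mean(drym_sen)) * Inf,
      df = NA_real_, p_value = 0,
      mean_tolerant = mean(drym_tol), mean_sensitive = mean(drym_sen)
    ))
  }
  tt <- t.test(drym_tol, drym_sen, var.equal = FALSE)
  tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_tolerant = mean(drym_tol),
    mean_sensitive = mean(drym_sen)
  )
}
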