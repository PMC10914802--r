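#' Simulate starch-yield phenotypes for an F1 population
#'
#' Generates a long-format phenotyping table over `n_experiments`
#' independent trials and two treatments. Per genotype and experiment the
#' control starch yield is drawn around a common baseline, and the stress
#' yield is `control * relsy` where the true relative starch yield follows
#' the additive dosage model
#' `relsy = base_relsy + sum_q effect_q * (dosage_q - 2) / 2 + N(0, residual_sd)`,
#' clipped at 0. A clone carrying dosage 4 at a QTL of effect 0.2 therefore
#' sits 0.2 above a dosage-2 clone in expected relative yield.
#'
#' @param f1 Dosage matrix from [simulate_f1()].
#' @param parents Result of [simulate_parents()] (supplies loci and config).
#' @param seed Optional integer seed.
#' @param control_mean,control_sd Baseline control starch yield (arbitrary
#'   mass x fraction units).
#' @return Tibble with columns `genotype_id`, `experiment_id`, `treatment`
#'   (`"control"`/`"stress"`) and `starch_yield`; one row per genotype x
#'   experiment x treatment.
#' @export
simulate_phenotypes <- function(f1, parents, seed = NULL,
                                control_mean = 100, control_sd = 10) {
  if (is.null(dim(f1)) || ncol(f1) < 1) abort("`f1` must be a nonempty dosage matrix")
  if (!is.null(seed)) set.seed(seed)
  cfg <- parents$cfg
  loci <- parents$loci

  qtl_rows <- which(loci$is_qtl)
  genetic <- rep(0, ncol(f1))
  if (length(qtl_rows) > 0 && !is.null(cfg$qtl_loci)) {
    eff <- cfg$qtl_loci$effect[match(
      paste(loci$chrom[qtl_rows], loci$pos[qtl_rows]),
      paste(paste0("Chr", cfg$qtl_loci$chrom), cfg$qtl_loci$pos)
    )]
    for (i in seq_along(qtl_rows)) {
      genetic <- genetic + eff[i] * (f1[qtl_rows[i], ] - 2) / 2
    }
  }

  grid <- tidyr::expand_grid(
    genotype_id = colnames(f1),
    experiment_id = sprintf("E%d", seq_len(cfg$n_experiments))
  )
  ng <- nrow(grid)
  control <- pmax(rnorm(ng, control_mean, control_sd), 0)
  relsy <- pmax(
    cfg$base_relsy + genetic[match(grid$genotype_id, colnames(f1))] +
      rnorm(ng, 0, cfg$residual_sd),
    0
  )
  dplyr::bind_rows(
    dplyr::mutate(grid, treatment = "control", starch_yield = control),
    dplyr::mutate(grid, treatment = "stress", starch_yield = control * relsy)
  ) %>%
    dplyr::arrange(.data$genotype_id, .data$experiment_id, .data$treatment)
}
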