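#' Simulation configuration for a synthetic autotetraploid cross
#'
#' Bundles every generative parameter of the synthetic tetraploid
#' bulked-segregant experiment: the genome layout, the planted QTLs, the F1
#' population and bulk sizes, the pooled-sequencing depth model, and the
#' phenotype noise model. Defaults emulate a scaled-down starch-potato
#' biparental cross (parents "A" and "E"): five 5-Mb chromosomes, one SNP per
#' 10 kb, 120x pooled coverage, three independent yield trials.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param snp_density Expected SNPs per bp (loci are placed by a Poisson
#'   process, i.e. uniform positions with Poisson count).
#' @param qtl_loci Data frame with columns `chrom` (integer index), `pos`,
#'   `effect` (additive shift of relative starch yield per two alternative
#'   doses, see [simulate_phenotypes()]) and `tolerant_parent` (`"A"` or
#'   `"E"`). Use `NULL` for no planted QTL.
#' @param n_f1 Number of F1 clones.
#' @param bulk_size Clones per phenotypic bulk.
#' @param coverage_mean Mean pooled read depth per site.
#' @param coverage_dispersion Negative-binomial overdispersion of depth
#'   (0 gives Poisson depth).
#' @param seq_error_rate Per-read probability of miscalling the allele.
#' @param n_experiments Number of independent phenotyping experiments.
#' @param base_relsy Baseline relative starch yield (stress/control) of a
#'   dosage-2 genotype.
#' @param residual_sd Standard deviation of the genotype-by-experiment noise
#'   on relative starch yield.
#' @param linkage_block_bp Size of co-inherited blocks in bp: within a block
#'   one gamete draws a single pair of parental homologues, creating locally
#'   correlated allele frequencies (realistic QTL peak widths). `NULL`
#'   simulates fully unlinked loci.
#' @param double_reduction Probability that a gamete carries two sister
#'   copies of the same homologue (default 0: random bivalent pairing).
#' @param qtl_dosage Length-2 integer vector: alternative-allele dosage of
#'   the tolerant and the other parent at each planted QTL locus (default
#'   triplex x simplex, which segregates in the F1).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 1e6, seed = 7)
#' cfg$coverage_mean
sim_config <- function(n_chromosomes = 5,
                       chrom_length_bp = 5e6,
                       snp_density = 1e-4,
                       qtl_loci = tibble::tibble(
                         chrom = 2L, pos = 2.5e6,
                         effect = 0.2, tolerant_parent = "A"
                       ),
                       n_f1 = 100,
                       bulk_size = 20,
                       coverage_mean = 120,
                       coverage_dispersion = 0.2,
                       seq_error_rate = 0.002,
                       n_experiments = 3,
                       base_relsy = 0.5,
                       residual_sd = 0.05,
                       linkage_block_bp = 1e6,
                       double_reduction = 0,
                       qtl_dosage = c(3L, 1L),
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    snp_density = snp_density,
    qtl_loci = if (is.null(qtl_loci)) NULL else tibble::as_tibble(qtl_loci),
    n_f1 = as.integer(n_f1),
    bulk_size = as.integer(bulk_size),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    seq_error_rate = seq_error_rate,
    n_experiments = as.integer(n_experiments),
    base_relsy = base_relsy,
    residual_sd = residual_sd,
    linkage_block_bp = linkage_block_bp,
    double_reduction = double_reduction,
    qtl_dosage = as.integer(qtl_dosage),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1) abort("`n_chromosomes` must be >= 1")
  if (cfg$chrom_length_bp < 1) abort("`chrom_length_bp` must be >= 1")
  if (!is.numeric(cfg$snp_density) || cfg$snp_density <= 0) {
    abort("`snp_density` must be > 0")
  }
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate >= 0.5) {
    abort("`seq_error_rate` must lie in [0, 0.5)")
  }
  if (cfg$coverage_mean <= 0) abort("`coverage_mean` must be > 0")
  if (cfg$coverage_dispersion < 0) abort("`coverage_dispersion` must be >= 0")
  if (cfg$n_f1 < 1) abort("`n_f1` must be >= 1")
  if (cfg$bulk_size < 1) abort("`bulk_size` must be >= 1")
  if (cfg$residual_sd < 0) abort("`residual_sd` must be >= 0")
  if (cfg$double_reduction < 0 || cfg$double_reduction > 1) {
    abort("`double_reduction` must lie in [0, 1]")
  }
  if (!all(cfg$qtl_dosage %in% 0:4) || length(cfg$qtl_dosage) != 2) {
    abort("`qtl_dosage` must be two dosages in 0..4")
  }
  if (!is.null(cfg$qtl_loci) && nrow(cfg$qtl_loci) > 0) {
    q <- cfg$qtl_loci
    need <- c("chrom", "pos", "effect", "tolerant_parent")
    if (!all(need %in% names(q))) {
      abort(paste("`qtl_loci` needs columns:", paste(need, collapse = ", ")))
    }
    if (any(q$pos < 1 | q$pos > cfg$chrom_length_bp)) {
      abort("QTL positions must lie within [1, chrom_length_bp]")
    }
    if (any(q$chrom < 1 | q$chrom > cfg$n_chromosomes)) {
      abort("QTL chromosomes must lie within 1..n_chromosomes")
    }
    if (!all(q$tolerant_parent %in% c("A", "E"))) {
      abort("`tolerant_parent` must be \"A\" or \"E\"")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d chromosome(s) x %s bp, snp_density %g\n",
    x$n_chromosomes, format(x$chrom_length_bp, big.mark = ","), x$snp_density
  ))
  nq <- if (is.null(x$qtl_loci)) 0L else nrow(x$qtl_loci)
  cat(sprintf(
    "  cross: %d F1, bulks of %d, %d planted QTL(s)\n",
    x$n_f1, x$bulk_size, nq
  ))
  cat(sprintf(
    "  sequencing: %gx (dispersion %g), error %g; seed %d\n",
    x$coverage_mean, x$coverage_dispersion, x$seq_error_rate, x$seed
  ))
  invisible(x)
}
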