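# shared fixture builders; everything is generated in code

# a parents object with hand-set dosages (phase placed deterministically),
# bypassing the random locus placement of simulate_parents()
manual_parents <- function(dosage_a, dosage_e,
                           chrom = "Chr1",
                           pos = seq(1000, by = 1000, length.out = length(dosage_a)),
                           cfg = sim_config(
                             n_chromosomes = 1, chrom_length_bp = max(pos) + 1000,
                             qtl_loci = NULL, seed = 1
                           ),
                           is_qtl = rep(FALSE, length(dosage_a))) {
  phase <- function(d) {
    t(vapply(d, function(k) c(rep(1L, k), rep(0L, 4 - k)), integer(4)))
  }
  structure(
    list(
      loci = tibble::tibble(
        chrom = chrom, pos = as.numeric(pos),
        ref = "A", alt = "T",
        dosage_A = as.integer(dosage_a), dosage_E = as.integer(dosage_e),
        is_qtl = is_qtl
      ),
      haplo_A = phase(dosage_a),
      haplo_E = phase(dosage_e),
      cfg = cfg
    ),
    class = "bsa_parents"
  )
}

# variant record rows in the shape read_vcf() returns
make_records <- function(ad_ref, ad_alt,
                         dp = ad_ref + ad_alt,
                         gq = 99L,
                         chrom = "Chr1",
                         pos = seq(100, by = 100, length.out = length(ad_ref)),
                         ref = "A", alt = "T", is_snp = TRUE,
                         sample_id = "s") {
  tibble::tibble(
    chrom = chrom, pos = as.numeric(pos), ref = ref, alt = alt,
    sample_id = sample_id,
    ad_ref = as.numeric(ad_ref), ad_alt = as.numeric(ad_alt),
    dp = as.integer(dp), gq = as.integer(gq),
    af = ifelse(ad_ref + ad_alt > 0, ad_alt / (ad_ref + ad_alt), NA_real_),
    is_snp = is_snp
  )
}

# independent G oracle: 2 N KL(observed || expected), written against the
# information-theoretic identity rather than the cell-sum formula
g_oracle <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  if (n == 0) return(0)
  p <- o / n
  q <- c(
    (a + b) * (a + c), (a + b) * (b + d),
    (c + d) * (a + c), (c + d) * (b + d)
  ) / n^2
  if (any(q == 0)) return(0)
  kl <- sum(ifelse(p > 0, p * log(p / q), 0))
  2 * n * kl
}

# one in-memory simulated BSA replicate: returns the gprime_scan and truth
simulate_scan_replicate <- function(seed, coverage_mean = 80,
                                    qtl_chrom = 2, qtl_pos = 2.5e6,
                                    effect = 0.2) {
  cfg <- sim_config(
    qtl_loci = tibble::tibble(
      chrom = qtl_chrom, pos = qtl_pos,
      effect = effect, tolerant_parent = "A"
    ),
    coverage_mean = coverage_mean, seed = seed
  )
  parents <- simulate_parents(cfg)
  f1 <- simulate_f1(parents, cfg$n_f1)
  drym <- simulate_phenotypes(f1, parents) |>
    compute_relsy() |>
    compute_drym()
  bulks <- select_bulks(drym, n_bulk = cfg$bulk_size)
  tol <- simulate_bulk_records(parents, f1, bulks$tolerant_ids, "TOL")
  sen <- simulate_bulk_records(parents, f1, bulks$sensitive_ids, "SEN")
  joint <- intersect_bulks(tol, sen)
  list(
    scan = run_gprime_scan(joint, scan_config()),
    qtl_chrom = paste0("Chr", qtl_chrom), qtl_pos = qtl_pos
  )
}
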