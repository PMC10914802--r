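#' Simulate pooled sequencing of a bulk and write a VCF
#'
#' Models equimolar pooling of the bulk members: the pool alternative-allele
#' frequency at a locus is `mean(dosage)/4` over members. Site depth is
#' negative-binomial with mean `coverage_mean` and overdispersion
#' `coverage_dispersion` (Poisson when 0); the alternative read count is
#' binomial with success probability `f(1-e) + (1-f)e` where `e` is the
#' sequencing error rate. Genotype quality is written as 99 for sites at
#' comfortable depth and degrades below `gq_full_depth`.
#'
#' @param parents Result of [simulate_parents()].
#' @param f1 Dosage matrix from [simulate_f1()].
#' @param members Character vector of clone ids (columns of `f1`) in the bulk.
#' @param path Output VCF path.
#' @param sample_name Sample name written in the VCF header.
#' @param seed Optional integer seed.
#' @param gq_full_depth Depth at and above which GQ is 99.
#' @return Invisibly, the tibble of simulated records (chrom, pos, ref, alt,
#'   ad_ref, ad_alt, dp, gq, gt).
#' @export
simulate_bulk_vcf <- function(parents, f1, members, path,
                              sample_name = "bulk", seed = NULL,
                              gq_full_depth = 20) {
  if (!all(members %in% colnames(f1))) {
    abort("all `members` must be columns of `f1`")
  }
  f <- rowMeans(f1[, members, drop = FALSE]) / 4
  simulate_pool_vcf(parents, f, path, sample_name, seed, gq_full_depth)
}

#' Simulate sequencing of a parent cultivar and write a VCF
#'
#' As [simulate_bulk_vcf()] but the allele frequency at each locus is the
#' parent's own dosage / 4.
#'
#' @inheritParams simulate_bulk_vcf
#' @param parent `"A"` or `"E"`.
#' @export
simulate_parent_vcf <- function(parents, parent = c("A", "E"), path,
                                sample_name = NULL, seed = NULL,
                                gq_full_depth = 20) {
  parent <- match.arg(parent)
  f <- parents$loci[[paste0("dosage_", parent)]] / 4
  sample_name <- sample_name %||% paste0("parent", parent)
  simulate_pool_vcf(parents, f, path, sample_name, seed, gq_full_depth)
}

#' Simulate pooled sequencing of a bulk in memory
#'
#' The sequencing model of [simulate_bulk_vcf()] without the VCF
#' round-trip: returns records in the shape [read_vcf()] produces, ready
#' for [filter_variants()] / [intersect_bulks()]. Convenient for
#' simulation studies with many replicates.
#'
#' @inheritParams simulate_bulk_vcf
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `ad_ref`, `ad_alt`, `dp`, `gq`, `af`, `is_snp`.
#' @export
simulate_bulk_records <- function(parents, f1, members,
                                  sample_name = "bulk", seed = NULL,
                                  gq_full_depth = 20) {
  if (!all(members %in% colnames(f1))) {
    abort("all `members` must be columns of `f1`")
  }
  f <- rowMeans(f1[, members, drop = FALSE]) / 4
  simulate_pool_counts(parents, f, sample_name, seed, gq_full_depth)
}

#' @rdname simulate_bulk_records
#' @param parent `"A"` or `"E"`.
#' @export
simulate_parent_records <- function(parents, parent = c("A", "E"),
                                    sample_name = NULL, seed = NULL,
                                    gq_full_depth = 20) {
  parent <- match.arg(parent)
  f <- parents$loci[[paste0("dosage_", parent)]] / 4
  sample_name <- sample_name %||% paste0("parent", parent)
  simulate_pool_counts(parents, f, sample_name, seed, gq_full_depth)
}

simulate_pool_counts <- function(parents, f, sample_name, seed,
                                 gq_full_depth) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- parents$cfg
  loci <- parents$loci
  n <- nrow(loci)

  dp <- if (cfg$coverage_dispersion > 0) {
    rnbinom(n, size = 1 / cfg$coverage_dispersion, mu = cfg$coverage_mean)
  } else {
    rpois(n, cfg$coverage_mean)
  }
  e <- cfg$seq_error_rate
  p_alt <- f * (1 - e) + (1 - f) * e
  ad_alt <- rbinom(n, dp, p_alt)
  ad_ref <- dp - ad_alt
  gq <- ifelse(dp >= gq_full_depth, 99L, pmin(98L, as.integer(5 * dp)))
  tibble(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    sample_id = sample_name,
    ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq,
    af = ifelse(dp > 0, ad_alt / dp, NA_real_),
    is_snp = TRUE
  )
}

simulate_pool_vcf <- function(parents, f, path, sample_name, seed,
                              gq_full_depth) {
  cfg <- parents$cfg
  rec <- simulate_pool_counts(parents, f, sample_name, seed, gq_full_depth)

  # naive tetraploid genotype call from the observed allele frequency
  af_hat <- ifelse(rec$dp > 0, rec$ad_alt / rec$dp, 0)
  dose_call <- pmin(pmax(round(4 * af_hat), 0), 4)
  rec$gt <- vapply(
    dose_call,
    function(d) paste(c(rep("0", 4 - d), rep("1", d)), collapse = "/"),
    character(1)
  )

  write_vcf(rec, path, sample_name,
    contig_lengths = setNames(
      rep(cfg$chrom_length_bp, cfg$n_chromosomes),
      paste0("Chr", seq_len(cfg$n_chromosomes))
    )
  )
  invisible(rec)
}

#' Write variant records as a single-sample VCF 4.2 file
#'
#' Emits the four FORMAT fields the downstream filters use (GT, AD, DP, GQ).
#'
#' @param records Tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ad_ref`, `ad_alt`, `dp`, `gq` and optionally `gt` (default `"./."`).
#' @param path Output file path.
#' @param sample_name Sample column name.
#' @param contig_lengths Optional named numeric vector of contig lengths for
#'   the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "sample",
                      contig_lengths = NULL) {
  gt <- if ("gt" %in% names(records)) records$gt else rep("./.", nrow(records))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    if (!is.null(contig_lengths)) {
      sprintf(
        "##contig=<ID=%s,length=%d>",
        names(contig_lengths), as.integer(contig_lengths)
      )
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name
    )
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP:GQ\t%s:%d,%d:%d:%d",
    records$chrom, as.integer(records$pos), records$ref, records$alt,
    gt, as.integer(records$ad_ref), as.integer(records$ad_alt),
    as.integer(records$dp), as.integer(records$gq)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
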