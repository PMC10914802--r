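#' Read a VCF sample into a tidy variant table
#'
#' Parses a VCF 4.x file through \pkg{vcfR} and normalises one sample's
#' calls to one row per (site, alternative allele). Multiallelic sites are
#' split into one record per alternative allele; each allele's frequency is
#' computed against the site's total allelic depth,
#' `af = ad_alt / (ad_ref + sum(ad_alt))`, a conservative apportionment
#' that can never exceed the frequency the allele would have at a
#' biallelic site. Missing FORMAT fields are carried as `NA` and fail
#' closed in [filter_variants()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample Sample name; default the first sample column.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#'   `ad_ref`, `ad_alt`, `dp`, `gq`, `af`, `is_snp`.
#' @export
read_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  sample <- sample %||% samples[1]
  if (!sample %in% samples) {
    abort(sprintf("sample '%s' not in VCF (has: %s)", sample, paste(samples, collapse = ", ")))
  }
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m) # single-record files
  fix <- tibble::as_tibble(fix_m)
  get_fmt <- function(field) {
    m <- vcfR::extract.gt(v, field)
    if (is.null(dim(m))) m <- t(m)
    unname(m[, sample])
  }
  ad <- get_fmt("AD")
  dp <- suppressWarnings(as.integer(get_fmt("DP")))
  gq <- suppressWarnings(as.integer(get_fmt("GQ")))

  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)

  ad_num <- lapply(ad_split, function(x) suppressWarnings(as.numeric(x)))
  ad_ref_site <- vapply(
    ad_num, function(x) if (length(x) >= 1) x[1] else NA_real_, numeric(1)
  )
  # pad/truncate the per-alt depths to the site's alt count
  ad_alt_flat <- unlist(purrr::map2(ad_num, n_alt, function(x, k) {
    v <- if (length(x) >= 2) x[-1] else numeric(0)
    length(v) <- k
    v
  }), use.names = FALSE)

  idx <- rep.int(seq_along(n_alt), n_alt)
  sum_alt_site <- unname(vapply(
    split(ad_alt_flat, idx), sum, numeric(1)
  )[as.character(seq_along(n_alt))])
  total <- (ad_ref_site + sum_alt_site)[idx]
  alt <- unlist(alt_split, use.names = FALSE)

  tibble(
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = alt,
    sample_id = sample,
    ad_ref = ad_ref_site[idx],
    ad_alt = ad_alt_flat,
    dp = dp[idx],
    gq = gq[idx],
    af = ifelse(is.na(total) | total == 0, NA_real_, ad_alt_flat / total),
    is_snp = nchar(fix$REF[idx]) == 1 & nchar(alt) == 1 &
      alt != "." & fix$REF[idx] != "."
  )
}

#' Variant filter settings
#'
#' Inclusive bounds on per-sample depth, alternative-allele frequency and
#' genotype quality for pooled-bulk SNP filtering. The defaults keep SNPs
#' with depth in \[20, 360\], allele frequency in \[0.10, 0.90\] and GQ of
#' at least 99 - the standard pre-scan filter for ~120x pooled potato
#' bulks, discarding near-monomorphic sites and collapsed repeats.
#'
#' @param min_depth,max_depth Inclusive depth bounds.
#' @param min_af,max_af Inclusive allele-frequency bounds.
#' @param min_gq Minimum genotype quality.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 20, max_depth = 360,
                          min_af = 0.10, max_af = 0.90, min_gq = 99) {
  if (!(min_depth < max_depth)) abort("`min_depth` must be < `max_depth`")
  if (!(min_af >= 0 && min_af < max_af && max_af <= 1)) {
    abort("need 0 <= min_af < max_af <= 1")
  }
  structure(
    list(
      min_depth = min_depth, max_depth = max_depth,
      min_af = min_af, max_af = max_af, min_gq = min_gq
    ),
    class = "filter_config"
  )
}

variant_pass <- function(records, cfg) {
  with(records, !is.na(dp) & !is.na(af) & !is.na(gq) & is_snp &
    dp >= cfg$min_depth & dp <= cfg$max_depth &
    af >= cfg$min_af & af <= cfg$max_af &
    gq >= cfg$min_gq)
}

#' Filter variant records for the G' scan
#'
#' Retains biallelic-normalised SNP records whose depth, allele frequency
#' and genotype quality all lie inside the (inclusive) bounds of `cfg`.
#' Rejected records are tallied by the first failing rule, in the order
#' missing-field, not-snp, depth, frequency, gq, so the per-rule counts
#' plus the retained count always reproduce the input count.
#'
#' @param records Tibble from [read_vcf()].
#' @param cfg A [filter_config()].
#' @return The retained records; the rejection tally is attached as
#'   attribute `"tally"` and retrievable with [filter_tally()].
#' @export
filter_variants <- function(records, cfg = filter_config()) {
  reason <- with(records, dplyr::case_when(
    is.na(dp) | is.na(af) | is.na(gq) ~ "missing-field",
    !is_snp ~ "not-snp",
    dp < cfg$min_depth | dp > cfg$max_depth ~ "depth",
    af < cfg$min_af | af > cfg$max_af ~ "frequency",
    gq < cfg$min_gq ~ "gq",
    .default = "retained"
  ))
  tally <- tibble(rule = c("missing-field", "not-snp", "depth", "frequency", "gq")) %>%
    dplyr::left_join(
      tibble(rule = reason) %>% dplyr::count(.data$rule, name = "rejected"),
      by = "rule"
    ) %>%
    dplyr::mutate(rejected = dplyr::coalesce(.data$rejected, 0L))
  out <- records[reason == "retained", , drop = FALSE]
  attr(out, "tally") <- tally
  out
}

#' Rejection tally of a [filter_variants()] result
#'
#' @param x Result of [filter_variants()].
#' @return Tibble with columns `rule`, `rejected`.
#' @export
filter_tally <- function(x) {
  attr(x, "tally") %||% abort("no filter tally attached; run filter_variants()")
}

#' Join the two bulks' variant records at shared keys
#'
#' Produces one row per (chrom, pos, alt) key seen in either bulk, with
#' each bulk's allelic depths, frequency and filter status side by side.
#' A key is a *difference SNP* when it passes the filter in exactly one
#' bulk (the exclusivity criterion used for candidate selection);
#' alternatively, with `af_diff` set, keys passing in both bulks whose
#' allele frequencies differ by more than `af_diff` are also flagged.
#'
#' @param tol_records,sen_records Tibbles from [read_vcf()] for the
#'   tolerant and sensitive bulk, sorted by position within chromosome.
#' @param cfg [filter_config()] applied to each bulk.
#' @param af_diff Optional allele-frequency difference threshold for the
#'   frequency-difference mode.
#' @return Tibble keyed by `chrom`, `pos`, `ref`, `alt` with per-bulk
#'   columns (`*_tol`, `*_sen`), `present_tol`/`present_sen` (record
#'   exists), `pass_tol`/`pass_sen` (record passes filters), `delta_snp`
#'   (`af_tol - af_sen`, zero-filled AD for an absent bulk), `difference`
#'   and `difference_class` (`"tolerant_only"`, `"sensitive_only"`,
#'   `"af_diff"` or `"shared"`).
#' @export
intersect_bulks <- function(tol_records, sen_records,
                            cfg = filter_config(), af_diff = NULL) {
  check_sorted <- function(x, label) {
    bad <- x %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::filter(.data$pos < dplyr::lag(.data$pos, default = -Inf)) %>%
      dplyr::ungroup()
    if (nrow(bad) > 0) {
      abort(sprintf(
        "%s records not sorted: first offending position %s:%d",
        label, bad$chrom[1], as.integer(bad$pos[1])
      ))
    }
  }
  check_sorted(tol_records, "tolerant")
  check_sorted(sen_records, "sensitive")

  prep <- function(x, suffix) {
    x %>%
      dplyr::mutate(pass = variant_pass(., cfg), present = TRUE) %>%
      dplyr::select(
        "chrom", "pos", "ref", "alt",
        "ad_ref", "ad_alt", "dp", "gq", "af", "pass", "present"
      ) %>%
      dplyr::rename_with(
        ~ paste0(.x, "_", suffix),
        c("ad_ref", "ad_alt", "dp", "gq", "af", "pass", "present")
      )
  }

  joint <- dplyr::full_join(
    prep(tol_records, "tol"), prep(sen_records, "sen"),
    by = c("chrom", "pos", "ref", "alt")
  ) %>%
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("present_"), ~ dplyr::coalesce(.x, FALSE)),
      dplyr::across(dplyr::starts_with("pass_"), ~ dplyr::coalesce(.x, FALSE)),
      dplyr::across(dplyr::starts_with("ad_"), ~ dplyr::coalesce(.x, 0)),
      af_tol = dplyr::coalesce(.data$af_tol, 0),
      af_sen = dplyr::coalesce(.data$af_sen, 0),
      delta_snp = .data$af_tol - .data$af_sen
    ) %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos, .data$alt)

  joint %>%
    dplyr::mutate(
      difference_class = dplyr::case_when(
        .data$pass_tol & !.data$pass_sen ~ "tolerant_only",
        .data$pass_sen & !.data$pass_tol ~ "sensitive_only",
        !is.null(af_diff) & .data$pass_tol & .data$pass_sen &
          abs(.data$delta_snp) > (af_diff %||% Inf) ~ "af_diff",
        .default = "shared"
      ),
      difference = .data$difference_class != "shared"
    )
}
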