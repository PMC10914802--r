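#' Classify bulk SNPs by parental origin
#'
#' Assigns each bulk SNP key (chrom, pos, alt) to `A-only`, `E-only`,
#' `both` or `neither` according to its presence among the two parents'
#' calls. Parent presence should come from *unfiltered* calls: a SNP
#' genuinely present in both parents can otherwise appear parent-unique
#' simply because it failed a depth or quality filter in one of them.
#'
#' @param bulk_snps Tibble with `chrom`, `pos`, `alt` (filtered bulk
#'   calls).
#' @param parent_a_snps,parent_e_snps Tibbles with `chrom`, `pos`, `alt`
#'   (unfiltered parent calls).
#' @param min_alt_reads When the parent tables carry an `ad_alt` column,
#'   a parent counts as carrying the SNP only with at least this many
#'   alternative reads (default 3), so isolated sequencing-error reads
#'   do not create spurious parental calls.
#' @return `bulk_snps` with logical `in_parent_a`, `in_parent_e` and an
#'   `origin` factor appended.
#' @export
classify_origin <- function(bulk_snps, parent_a_snps, parent_e_snps,
                            min_alt_reads = 3) {
  called <- function(x) {
    if ("ad_alt" %in% names(x)) {
      x <- x[!is.na(x$ad_alt) & x$ad_alt >= min_alt_reads, , drop = FALSE]
    }
    x
  }
  parent_a_snps <- called(parent_a_snps)
  parent_e_snps <- called(parent_e_snps)
  key_a <- snp_key(parent_a_snps$chrom, parent_a_snps$pos, parent_a_snps$alt)
  key_e <- snp_key(parent_e_snps$chrom, parent_e_snps$pos, parent_e_snps$alt)
  keys <- snp_key(bulk_snps$chrom, bulk_snps$pos, bulk_snps$alt)
  bulk_snps %>%
    dplyr::mutate(
      in_parent_a = keys %in% key_a,
      in_parent_e = keys %in% key_e,
      origin = factor(
        dplyr::case_when(
          .data$in_parent_a & .data$in_parent_e ~ "both",
          .data$in_parent_a ~ "A-only",
          .data$in_parent_e ~ "E-only",
          .default = "neither"
        ),
        levels = c("A-only", "E-only", "both", "neither")
      )
    )
}

#' Venn-style origin counts and percentages
#'
#' Tallies the four origin classes of [classify_origin()] genome-wide,
#' and per interval when a QTL interval set is supplied. Percentages are
#' over the classified SNPs of each region, so the four classes always
#' sum to 100.
#'
#' @param origins Output of [classify_origin()].
#' @param intervals Optional tibble with `chrom`, `start_bp`, `end_bp`
#'   and `qtl_id`.
#' @return Tibble with `region`, `origin`, `n`, `pct`.
#' @export
venn_counts <- function(origins, intervals = NULL) {
  tally_one <- function(x, region) {
    x %>%
      dplyr::count(.data$origin, .drop = FALSE) %>%
      dplyr::mutate(
        region = region,
        pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0
      ) %>%
      dplyr::select("region", "origin", "n", "pct")
  }
  out <- tally_one(origins, "genome")
  if (!is.null(intervals)) {
    per <- purrr::map(seq_len(nrow(intervals)), function(i) {
      iv <- intervals[i, ]
      tally_one(
        dplyr::filter(
          origins,
          .data$chrom == iv$chrom,
          .data$pos >= iv$start_bp, .data$pos <= iv$end_bp
        ),
        paste0("QTL", iv$qtl_id)
      )
    })
    out <- dplyr::bind_rows(out, purrr::list_rbind(per))
  }
  out
}

#' Rolling-window summary of an allele-frequency track
#'
#' Overlapping windows of `win_size` bp advanced by `win_step` bp,
#' anchored at position 1 of each chromosome; the final partial window is
#' retained. Windows report the SNP count and the mean and standard
#' deviation of the chosen value column; empty windows are emitted with
#' `n_snps = 0` and `NA` statistics, single-SNP windows with `NA`
#' standard deviation.
#'
#' @param snps Tibble with `chrom`, `pos` and the value column, sorted by
#'   position within chromosome.
#' @param value Name of the value column (default `"af"`).
#' @param win_size,win_step Window size and step in bp (defaults 1e6 and
#'   5e5: half-overlapping megabase windows).
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the last SNP position per chromosome.
#' @return Tibble with `chrom`, `window_start`, `window_end`, `n_snps`,
#'   `mean`, `sd`.
#' @export
rolling_windows <- function(snps, value = "af",
                            win_size = 1e6, win_step = 5e5,
                            chrom_lengths = NULL) {
  if (win_step > win_size) {
    warn("`win_step` > `win_size`: windows leave uncovered gaps")
  }
  v <- snps[[value]]
  if (is.null(v)) abort(sprintf("column '%s' not found", value))

  per_chrom <- snps %>%
    dplyr::mutate(.value = v) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_split()

  purrr::map(per_chrom, function(x) {
    if (is.unsorted(x$pos)) abort("positions must be sorted within chromosome")
    chrom <- x$chrom[1]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(x$pos)
    }
    starts <- seq(1, max(len - win_size + 1, 1), by = win_step)
    # a trailing partial window whenever the tiling stops short of the end
    if (max(starts) + win_size - 1 < len) {
      starts <- c(starts, max(starts) + win_step)
    }
    purrr::map(starts, function(s) {
      e <- min(s + win_size - 1, len)
      inside <- x$.value[x$pos >= s & x$pos <= e]
      tibble(
        chrom = chrom, window_start = s, window_end = e,
        n_snps = length(inside),
        mean = if (length(inside) > 0) mean(inside) else NA_real_,
        sd = if (length(inside) > 1) sd(inside) else NA_real_
      )
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()
}
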