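#' Summarize QTL intervals against a gene annotation and SNP table
#'
#' Completes an interval table with the span, gene content and SNP content
#' columns of a standard QTL overview table: `area_bp = end - start`
#' (coordinate span between the outermost significant SNPs), `n_genes` =
#' genes overlapping the interval by any basepair, `gene_density` =
#' `ceiling(n_genes / (area_bp / 1e6))` genes per Mbp, `n_snps_total` =
#' SNPs inside the interval, and `n_snps_unique_to_a_bulk` = difference
#' SNPs inside the interval.
#'
#' When `genes` is `NULL` an existing `n_genes` column is kept (useful for
#' re-deriving the arithmetic of a published table); likewise for `snps`
#' and an existing `n_snps_total` column.
#'
#' @param intervals Tibble with `chrom`, `start_bp`, `end_bp` (e.g. from
#'   [call_qtl_intervals()]).
#' @param genes `NULL`, a tibble with `chrom`, `start`, `end` (and
#'   `gene_id`), or a path to a GFF3 file.
#' @param snps `NULL` or a tibble with `chrom`, `pos` and optionally a
#'   logical `difference` column (e.g. from [intersect_bulks()]).
#' @return The interval tibble with `area_bp`, `n_genes`, `gene_density`,
#'   `n_snps_total`, `n_snps_unique_to_a_bulk` columns as available.
#' @export
summarize_qtl <- function(intervals, genes = NULL, snps = NULL) {
  out <- intervals %>%
    dplyr::mutate(area_bp = .data$end_bp - .data$start_bp)
  if (any(out$area_bp <= 0)) abort("intervals must satisfy start < end")

  if (is.character(genes)) genes <- read_gff_genes(genes)
  if (!is.null(genes)) {
    known <- unique(genes$chrom)
    if (any(!out$chrom %in% known)) {
      warn(paste(
        "interval chromosome(s) absent from annotation:",
        paste(setdiff(out$chrom, known), collapse = ", ")
      ))
    }
    out$n_genes <- purrr::map_int(seq_len(nrow(out)), function(i) {
      sum(genes$chrom == out$chrom[i] &
        genes$start <= out$end_bp[i] &
        genes$end >= out$start_bp[i])
    })
  }
  if ("n_genes" %in% names(out)) {
    out$gene_density <- as.integer(ceiling(out$n_genes / (out$area_bp / 1e6)))
  }

  if (!is.null(snps)) {
    inside <- function(i, tab) {
      tab$chrom == out$chrom[i] &
        tab$pos >= out$start_bp[i] & tab$pos <= out$end_bp[i]
    }
    out$n_snps_total <- purrr::map_int(
      seq_len(nrow(out)), ~ sum(inside(.x, snps))
    )
    if ("difference" %in% names(snps)) {
      out$n_snps_unique_to_a_bulk <- purrr::map_int(
        seq_len(nrow(out)), ~ sum(inside(.x, snps) & snps$difference)
      )
    }
  }
  out
}

#' Genome-wide totals over a set of QTL intervals
#'
#' The summary row of a QTL overview table: total span, total genes and
#' total SNPs are sums over intervals; the summary gene density is the
#' arithmetic mean of the per-interval densities, rounded to one decimal.
#'
#' @param intervals Completed interval tibble from [summarize_qtl()].
#' @return One-row tibble with `n_qtl`, `total_area_bp`, `total_genes`,
#'   `mean_gene_density`, `total_snps` (columns present as available).
#' @export
summarize_qtl_totals <- function(intervals) {
  if (nrow(intervals) < 1) abort("need at least one interval")
  out <- tibble(
    n_qtl = nrow(intervals),
    total_area_bp = sum(intervals$area_bp)
  )
  if ("n_genes" %in% names(intervals)) {
    out$total_genes <- sum(intervals$n_genes)
  }
  if ("gene_density" %in% names(intervals)) {
    out$mean_gene_density <- round(mean(intervals$gene_density), 1)
  }
  if ("n_snps_total" %in% names(intervals)) {
    out$total_snps <- sum(intervals$n_snps_total)
  }
  if ("n_snps_unique_to_a_bulk" %in% names(intervals)) {
    out$total_snps_unique <- sum(intervals$n_snps_unique_to_a_bulk)
  }
  out
}

#' Published QTL regions of the Euroresa x Albatros drought cross
#'
#' The 15 drought-tolerance QTL regions reported for the starch-potato
#' cross Euroresa x Albatros (DM v4.03 coordinates), with the published
#' per-region gene and SNP counts. Spans and densities are *not* stored:
#' they are recomputed by [summarize_qtl()] / [summarize_qtl_totals()], which is
#' how the package validates its interval arithmetic against the
#' published overview.
#'
#' @return Tibble with `qtl_id`, `chrom`, `start_bp`, `end_bp`, `n_genes`,
#'   `n_snps_total`.
#' @export
#' @examples
#' exa_qtl_regions() |> summarize_qtl() |> summarize_qtl_totals()
exa_qtl_regions <- function() {
  path <- system.file("extdata", "exa_qtl_regions.tsv", package = "bsaqtl")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export QTL intervals as BED
#'
#' Converts the 1-based inclusive internal coordinates to BED's 0-based
#' half-open convention.
#'
#' @param intervals Tibble with `chrom`, `start_bp`, `end_bp` and
#'   optionally `qtl_id`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(intervals, path) {
  name <- if ("qtl_id" %in% names(intervals)) {
    paste0("QTL", intervals$qtl_id)
  } else {
    paste0("QTL", seq_len(nrow(intervals)))
  }
  readr::write_tsv(
    tibble(
      chrom = intervals$chrom,
      start = as.integer(intervals$start_bp - 1),
      end = as.integer(intervals$end_bp),
      name = name
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}
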