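#' Tidy a G' scan into its per-SNP table
#'
#' @param x A `gprime_scan` object.
#' @param ... Unused.
#' @return Tibble with one row per scanned SNP (`chrom`, `pos`,
#'   `delta_snp`, `g`, `gprime`, `pvalue`, `qvalue`, `sig`).
#' @export
#' @method tidy gprime_scan
tidy.gprime_scan <- function(x, ...) {
  dplyr::select(
    x$snps, "chrom", "pos", dplyr::any_of(c("ref", "alt")),
    "delta_snp", "g", "gprime", "pvalue", "qvalue", "sig"
  )
}

#' One-row summary of a G' scan
#'
#' @param x A `gprime_scan` object.
#' @param ... Unused.
#' @return One-row tibble: SNP and QTL counts, null-model parameters.
#' @export
#' @method glance gprime_scan
glance.gprime_scan <- function(x, ...) {
  tibble(
    n_snps = nrow(x$snps),
    n_significant = sum(x$snps$sig),
    n_qtl = nrow(x$intervals),
    null_mu = unname(x$null["mu"]),
    null_sigma = unname(x$null["sigma"]),
    window_size = x$cfg$window_size,
    alpha = x$cfg$alpha,
    correction = x$cfg$correction
  )
}

#' Tidy a bulk assignment into its per-genotype rank table
#'
#' @param x A `bulk_assignment` from [select_bulks()].
#' @param ... Unused.
#' @return The per-genotype tibble with ranks, mean DRYM and bulk label.
#' @export
#' @method tidy bulk_assignment
tidy.bulk_assignment <- function(x, ...) x$ranks

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
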