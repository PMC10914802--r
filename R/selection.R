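#' Candidate-SNP selection settings
#'
#' @param upstream_bp 5'-flank window beyond the gene extent (strand
#'   aware; default 2000 bp, covering promoter/5'-UTR variation).
#' @param downstream_bp 3'-flank window (default 500 bp).
#' @param max_snps_per_gene Per-gene cap in round 1 (default 3).
#' @param literature_genes Character vector of gene ids with published
#'   evidence for the trait (round-1 scope).
#' @param qtl_intervals Optional interval tibble (`chrom`, `start_bp`,
#'   `end_bp`); genes outside every interval are excluded.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(upstream_bp = 2000, downstream_bp = 500,
                             max_snps_per_gene = 3,
                             literature_genes = character(),
                             qtl_intervals = NULL) {
  if (max_snps_per_gene < 1) abort("`max_snps_per_gene` must be >= 1")
  structure(
    list(
      upstream_bp = upstream_bp, downstream_bp = downstream_bp,
      max_snps_per_gene = max_snps_per_gene,
      literature_genes = literature_genes,
      qtl_intervals = qtl_intervals
    ),
    class = "selection_config"
  )
}

# strand-aware extension of gene extents by the 5'/3' flank windows
extend_genes <- function(genes, upstream_bp, downstream_bp) {
  genes %>%
    dplyr::mutate(
      ext_start = dplyr::if_else(
        .data$strand == "-",
        .data$start - downstream_bp,
        .data$start - upstream_bp
      ),
      ext_end = dplyr::if_else(
        .data$strand == "-",
        .data$end + upstream_bp,
        .data$end + downstream_bp
      )
    )
}

genes_in_intervals <- function(genes, intervals) {
  if (is.null(intervals)) {
    return(genes)
  }
  keep <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
    any(intervals$chrom == genes$chrom[i] &
      intervals$start_bp <= genes$end[i] &
      intervals$end_bp >= genes$start[i])
  })
  genes[keep, , drop = FALSE]
}

#' Round-1 candidate selection: literature genes under the QTLs
#'
#' From the bulk-exclusive (difference) SNPs, keeps those falling inside a
#' literature gene's extent extended by the strand-aware 5' (2000 bp) and
#' 3' (500 bp) flank windows, and caps the picks per gene at
#' `max_snps_per_gene`, prioritised by effect severity
#' (nonsense > missense > coding-synonymous > UTR > intron >
#' up/downstream), ties broken by position.
#'
#' @param difference_snps Tibble of bulk-exclusive SNPs (`chrom`, `pos`,
#'   `alt`, and a `difference_class` or `bulk` label if available).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param effects Effect table from [parse_effects()] (or the simulator).
#' @param cfg A [selection_config()]; round 1 uses its
#'   `literature_genes` and `qtl_intervals`.
#' @return Tibble of selected SNPs with `gene_id`, `effect_class`,
#'   `round = 1`.
#' @export
round1_select <- function(difference_snps, genes, effects,
                          cfg = selection_config()) {
  if (length(cfg$literature_genes) == 0) {
    warn("empty literature gene list: round 1 selects nothing")
    return(empty_selection())
  }
  scope <- genes %>%
    dplyr::filter(.data$gene_id %in% cfg$literature_genes) %>%
    genes_in_intervals(cfg$qtl_intervals) %>%
    extend_genes(cfg$upstream_bp, cfg$downstream_bp)
  if (nrow(scope) == 0) {
    return(empty_selection())
  }

  hits <- purrr::map(seq_len(nrow(scope)), function(i) {
    g <- scope[i, ]
    difference_snps %>%
      dplyr::filter(
        .data$chrom == g$chrom,
        .data$pos >= g$ext_start, .data$pos <= g$ext_end
      ) %>%
      dplyr::mutate(gene_id = g$gene_id)
  }) %>% purrr::list_rbind()
  if (nrow(hits) == 0) {
    return(empty_selection())
  }

  hits %>%
    dplyr::left_join(
      dplyr::select(effects, "chrom", "pos", "alt", "effect_class", eff_gene = "gene_id"),
      by = c("chrom", "pos", "alt")
    ) %>%
    dplyr::mutate(
      effect_class = dplyr::coalesce(.data$effect_class, "other"),
      severity = effect_severity(.data$effect_class)
    ) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(.data$severity, .data$pos, .by_group = TRUE) %>%
    dplyr::slice_head(n = cfg$max_snps_per_gene) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(round = 1L) %>%
    dplyr::select(-"severity", -"eff_gene") %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)
}

#' Round-2 candidate selection: coding-disruptive SNPs in any QTL gene
#'
#' Adds difference SNPs annotated as missense or nonsense in *any* gene
#' under a QTL - not just literature genes - excluding SNPs already
#' selected in round 1. The union of the two rounds is the panel design
#' set.
#'
#' @param difference_snps Tibble of bulk-exclusive SNPs.
#' @param effects Effect table from [parse_effects()].
#' @param genes_under_qtl Gene tibble restricted to the QTL intervals (or
#'   all genes plus `qtl_intervals` in `cfg`).
#' @param round1_result Output of [round1_select()].
#' @param cfg A [selection_config()].
#' @return Tibble of additional SNPs with `round = 2`.
#' @export
round2_select <- function(difference_snps, effects, genes_under_qtl,
                          round1_result = empty_selection(),
                          cfg = selection_config()) {
  scope <- genes_in_intervals(genes_under_qtl, cfg$qtl_intervals)
  cand <- difference_snps %>%
    dplyr::inner_join(
      dplyr::select(effects, "chrom", "pos", "alt", "effect_class", "gene_id"),
      by = c("chrom", "pos", "alt")
    ) %>%
    dplyr::filter(
      .data$effect_class %in% c("missense", "nonsense"),
      .data$gene_id %in% scope$gene_id
    ) %>%
    dplyr::anti_join(round1_result, by = c("chrom", "pos", "alt")) %>%
    dplyr::mutate(round = 2L) %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)
  cand
}

empty_selection <- function() {
  tibble(
    chrom = character(), pos = numeric(), alt = character(),
    gene_id = character(), effect_class = character(), round = integer()
  )
}

#' Combine selection rounds into a panel design table
#'
#' @param round1,round2 Outputs of [round1_select()] and
#'   [round2_select()].
#' @return Combined tibble with a `snp_id` key; duplicate keys across
#'   rounds are impossible by construction and guarded here.
#' @export
panel_design <- function(round1, round2) {
  out <- dplyr::bind_rows(round1, round2) %>%
    dplyr::mutate(snp_id = snp_key(.data$chrom, .data$pos, .data$alt), .before = 1)
  if (anyDuplicated(out$snp_id) > 0) {
    abort("duplicate SNP keys across selection rounds")
  }
  out
}

#' Export probe-design flanks for a panel as BED
#'
#' Targeted genotyping providers require flanking sequence context around
#' each SNP for allele-specific oligo design; this writes `flank_bp`
#' (default 200) on both sides of each panel SNP in BED (0-based,
#' half-open).
#'
#' @param panel Output of [panel_design()].
#' @param path Output BED path.
#' @param flank_bp Flank width per side.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(panel, path, flank_bp = 200) {
  readr::write_tsv(
    tibble(
      chrom = panel$chrom,
      start = as.integer(pmax(panel$pos - 1 - flank_bp, 0)),
      end = as.integer(panel$pos + flank_bp),
      name = panel$snp_id
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Probe-design yield of a panel submission
#'
#' Percentage of submitted panel SNPs for which the vendor could design
#' allele-specific oligonucleotides, truncated to one decimal (the
#' reporting convention of design-yield summaries: a 39.65% yield is
#' quoted as 39.6%, never rounded up).
#'
#' @param n_designed SNPs with a successful oligo design.
#' @param n_submitted SNPs submitted.
#' @return One-row tibble with `n_designed`, `n_submitted`, `pct`.
#' @export
#' @examples
#' probe_design_yield(410, 1034) # 39.6 percent
probe_design_yield <- function(n_designed, n_submitted) {
  if (n_submitted <= 0 || n_designed < 0 || n_designed > n_submitted) {
    abort("need 0 <= n_designed <= n_submitted, n_submitted > 0")
  }
  tibble(
    n_designed = n_designed, n_submitted = n_submitted,
    pct = floor(1000 * n_designed / n_submitted) / 10
  )
}

#' Parse SnpEff-style effect annotations
#'
#' Accepts either a VCF whose INFO column carries pipe-delimited `ANN`
#' entries (`allele|effect|impact|gene...`) or a tab-separated table with
#' columns chrom, pos, (alt,) effect, gene. SnpEff effect terms are
#' mapped onto the package's closed vocabulary (nonsense, missense,
#' synonymous, 5'UTR, 3'UTR, intron, upstream, downstream, intergenic,
#' other); unknown terms become
#' `"other"` and are tallied in the `"unknown_terms"` attribute. When a
#' SNP carries several annotations for the same gene only the most
#' severe is kept.
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @return Tibble with `chrom`, `pos`, `alt`, `effect_class`, `gene_id`.
#' @export
parse_effects <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    out <- parse_effects_vcf(path)
  } else {
    out <- parse_effects_tsv(path)
  }
  unknown <- attr(out, "unknown_terms")
  out <- out %>%
    dplyr::mutate(severity = effect_severity(.data$effect_class)) %>%
    dplyr::group_by(.data$chrom, .data$pos, .data$alt, .data$gene_id) %>%
    dplyr::arrange(.data$severity, .by_group = TRUE) %>%
    dplyr::slice_head(n = 1) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"severity") %>%
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)
  attr(out, "unknown_terms") <- unknown
  out
}

SNPEFF_MAP <- c(
  missense_variant = "missense",
  stop_gained = "nonsense",
  stop_lost = "nonsense",
  synonymous_variant = "synonymous",
  intron_variant = "intron",
  `5_prime_UTR_variant` = "5'UTR",
  `5_prime_UTR_premature_start_codon_gain_variant` = "5'UTR",
  `3_prime_UTR_variant` = "3'UTR",
  upstream_gene_variant = "upstream",
  downstream_gene_variant = "downstream",
  intergenic_region = "intergenic"
)

parse_effects_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v, getINFO = TRUE))
  ann <- sub(".*ANN=([^;]*).*", "\\1", fix$INFO)
  ann[!grepl("ANN=", fix$INFO)] <- NA

  skipped <- 0L
  unknown <- character()
  rows <- purrr::imap(ann, function(a, i) {
    if (is.na(a)) {
      return(NULL)
    }
    entries <- strsplit(a, ",", fixed = TRUE)[[1]]
    parsed <- purrr::map(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(f) < 4) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      cls <- SNPEFF_MAP[f[2]]
      if (is.na(cls)) {
        unknown <<- c(unknown, f[2])
        cls <- "other"
      }
      tibble(
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        alt = f[1], effect_class = unname(cls), gene_id = f[4]
      )
    })
    purrr::list_rbind(parsed)
  })
  out <- purrr::list_rbind(rows)
  if (skipped > 0) warn(sprintf("skipped %d malformed ANN entr(ies)", skipped))
  attr(out, "unknown_terms") <- table(unknown)
  out
}

parse_effects_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"alt" %in% names(tab)) tab$alt <- NA_character_
  cls_col <- intersect(c("effect_class", "effect"), names(tab))[1]
  if (is.na(cls_col)) abort("TSV needs an 'effect' or 'effect_class' column")
  gene_col <- intersect(c("gene_id", "gene"), names(tab))[1]
  if (is.na(gene_col)) abort("TSV needs a 'gene' or 'gene_id' column")
  raw <- tab[[cls_col]]
  cls <- ifelse(raw %in% EFFECT_LEVELS, raw, unname(SNPEFF_MAP[raw]))
  unknown <- raw[is.na(cls)]
  cls[is.na(cls)] <- "other"
  out <- tibble(
    chrom = tab$chrom, pos = as.numeric(tab$pos), alt = tab$alt,
    effect_class = cls, gene_id = tab[[gene_col]]
  )
  attr(out, "unknown_terms") <- table(unknown)
  out
}
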