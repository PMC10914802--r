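#' Simulate a gene annotation and per-SNP effect classes
#'
#' Tiles non-overlapping gene models of a fixed internal structure
#' (5'UTR - exon - intron - exon - intron - 3'UTR) along every chromosome,
#' alternating strands, and classifies each SNP locus by its position
#' relative to the nearest gene model: exonic SNPs draw a coding consequence
#' (missense / synonymous / nonsense), SNPs in the strand-aware flanking
#' windows are `upstream` / `downstream`, and everything else is
#' `intergenic`. The layout mirrors what a SnpEff-style annotation of a real
#' assembly provides, at a density (default one gene per 20 kb, about 50
#' genes/Mb) comparable to a gene-rich plant genome.
#'
#' @param parents Result of [simulate_parents()] (supplies loci and genome
#'   size).
#' @param gene_spacing_bp Distance between consecutive gene starts.
#' @param gene_length_bp Gene model length; the internal segment layout is
#'   scaled from a 3000-bp template.
#' @param upstream_bp,downstream_bp Flank widths used for the
#'   upstream/downstream classes.
#' @param coding_probs Probabilities of missense, synonymous and nonsense
#'   for exonic SNPs.
#' @param seed Optional integer seed.
#' @return A list of class `bsa_annotation`: `genes` (tibble `gene_id`,
#'   `chrom`, `start`, `end`, `strand`), `features` (child intervals with
#'   `type`), and `effects` (tibble `chrom`, `pos`, `ref`, `alt`,
#'   `effect_class`, `gene_id`).
#' @export
simulate_annotation <- function(parents,
                                gene_spacing_bp = 20000,
                                gene_length_bp = 3000,
                                upstream_bp = 2000,
                                downstream_bp = 500,
                                coding_probs = c(0.5, 0.45, 0.05),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- parents$cfg
  loci <- parents$loci
  if (nrow(loci) == 0) abort("no loci to annotate")

  # segment template, proportions of the gene length (5' to 3' in gene sense)
  seg_prop <- c(
    `five_prime_UTR` = 200, exon1 = 800, intron1 = 500,
    exon2 = 800, intron2 = 500, `three_prime_UTR` = 200
  ) / 3000

  chroms <- paste0("Chr", seq_len(cfg$n_chromosomes))
  genes <- purrr::map(seq_along(chroms), function(ci) {
    starts <- seq(5001, cfg$chrom_length_bp - gene_length_bp,
      by = gene_spacing_bp
    )
    if (length(starts) == 0) {
      return(NULL)
    }
    tibble(
      gene_id = sprintf("G%02d%04d", ci, seq_along(starts)),
      chrom = chroms[ci],
      start = starts,
      end = starts + gene_length_bp - 1,
      strand = rep_len(c("+", "-"), length(starts))
    )
  }) %>% dplyr::bind_rows()

  seg_len <- round(seg_prop * gene_length_bp)
  seg_len[length(seg_len)] <- gene_length_bp - sum(seg_len[-length(seg_len)])

  features <- purrr::pmap(genes, function(gene_id, chrom, start, end, strand) {
    # genomic left-to-right segment order: '+' as template, '-' mirrored
    types <- names(seg_len)
    lens <- unname(seg_len)
    if (strand == "-") {
      types <- rev(types)
      lens <- rev(lens)
    }
    s <- start + c(0, cumsum(lens[-length(lens)]))
    tibble(
      gene_id = gene_id, chrom = chrom,
      start = s, end = s + lens - 1,
      type = sub("[0-9]+$", "", types), strand = strand
    )
  }) %>% purrr::list_rbind()

  effects <- classify_loci(
    loci, genes, features, upstream_bp, downstream_bp, coding_probs
  )

  structure(
    list(genes = genes, features = features, effects = effects),
    class = "bsa_annotation"
  )
}

classify_loci <- function(loci, genes, features, upstream_bp, downstream_bp,
                          coding_probs) {
  eff <- rep("intergenic", nrow(loci))
  gene_of <- rep(NA_character_, nrow(loci))

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    on_chrom <- loci$chrom == g$chrom
    if (g$strand == "+") {
      up <- on_chrom & loci$pos >= g$start - upstream_bp & loci$pos < g$start
      down <- on_chrom & loci$pos > g$end & loci$pos <= g$end + downstream_bp
    } else {
      up <- on_chrom & loci$pos > g$end & loci$pos <= g$end + upstream_bp
      down <- on_chrom & loci$pos >= g$start - downstream_bp & loci$pos < g$start
    }
    eff[up] <- "upstream"
    gene_of[up] <- g$gene_id
    eff[down] <- "downstream"
    gene_of[down] <- g$gene_id
  }

  fmap <- c(
    five_prime_UTR = "5'UTR", three_prime_UTR = "3'UTR",
    intron = "intron", exon = "exon"
  )
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    inside <- loci$chrom == f$chrom & loci$pos >= f$start & loci$pos <= f$end
    if (!any(inside)) next
    eff[inside] <- fmap[[f$type]]
    gene_of[inside] <- f$gene_id
  }

  exonic <- eff == "exon"
  eff[exonic] <- sample(
    c("missense", "synonymous", "nonsense"),
    sum(exonic),
    replace = TRUE, prob = coding_probs
  )

  tibble(
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    effect_class = eff, gene_id = gene_of
  )
}

#' Write a simulated annotation as GFF3
#'
#' Exports gene, mRNA and child features (exon, UTRs) with `ID`/`Parent`
#' attributes through \pkg{rtracklayer}.
#'
#' @param annotation Result of [simulate_annotation()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  genes <- annotation$genes
  feats <- dplyr::filter(annotation$features, .data$type != "intron")
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id
  )
  gr_mrna <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "mRNA", ID = paste0(genes$gene_id, ".1"), Parent = genes$gene_id
  )
  gr_feat <- GenomicRanges::GRanges(
    feats$chrom,
    IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = feats$type,
    ID = paste0(feats$gene_id, ".1.", feats$type, ".", seq_len(nrow(feats))),
    Parent = paste0(feats$gene_id, ".1")
  )
  rtracklayer::export(c(gr_gene, gr_mrna, gr_feat), path, format = "gff3")
  invisible(path)
}

#' Read gene extents from a GFF3 file
#'
#' @param path GFF3 file with `gene` features carrying an `ID` attribute.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write a per-SNP effect table as TSV
#'
#' @param effects Tibble as produced by [simulate_annotation()] (`effects`
#'   element) or [parse_effects()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  readr::write_tsv(effects, path)
  invisible(path)
}
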