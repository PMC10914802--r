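toy_gene <- function(gene_id = "GeneX", chrom = "Chr1",
                     start = 10000, end = 13000, strand = "+") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand
  )
}

toy_diff <- function(pos, chrom = "Chr1", alt = "T") {
  tibble::tibble(chrom = chrom, pos = as.numeric(pos), alt = alt)
}

toy_effects <- function(pos, effect_class, gene_id = "GeneX",
                        chrom = "Chr1", alt = "T") {
  tibble::tibble(
    chrom = chrom, pos = as.numeric(pos), alt = alt,
    effect_class = effect_class, gene_id = gene_id
  )
}

test_that("round 1 honours the strand-aware flank windows", {
  genes <- toy_gene() # + strand, 10000-13000
  cfg <- selection_config(literature_genes = "GeneX")

  # 1500 bp 5' of the start: inside the 2000 bp window
  # 600 bp 3' of the end: beyond the 500 bp window
  snps <- toy_diff(c(8500, 13600))
  eff <- toy_effects(c(8500, 13600), c("upstream", "downstream"))
  r1 <- round1_select(snps, genes, eff, cfg)
  expect_equal(r1$pos, 8500)

  # on the minus strand the windows flip
  genes_m <- toy_gene(strand = "-")
  # 5' flank is now to the right of end; 2000 bp window
  snps_m <- toy_diff(c(14500, 9400)) # 1500 bp right of end; 600 bp left of start
  eff_m <- toy_effects(c(14500, 9400), c("upstream", "downstream"))
  r1_m <- round1_select(snps_m, genes_m, eff_m, cfg)
  expect_equal(r1_m$pos, 14500)
})

test_that("round 1 caps SNPs per gene by severity then position", {
  genes <- toy_gene()
  cfg <- selection_config(literature_genes = "GeneX", max_snps_per_gene = 3)
  pos <- c(10100, 10200, 10300, 10400, 10500)
  cls <- c("intron", "missense", "synonymous", "nonsense", "intron")
  r1 <- round1_select(toy_diff(pos), genes, toy_effects(pos, cls), cfg)
  expect_equal(nrow(r1), 3)
  # nonsense > missense > synonymous beat the introns
  expect_setequal(r1$pos, c(10400, 10200, 10300))
  expect_setequal(r1$effect_class, c("nonsense", "missense", "synonymous"))

  # all-equal severity: ties broken by position
  cls2 <- rep("intron", 5)
  r2 <- round1_select(toy_diff(pos), genes, toy_effects(pos, cls2), cfg)
  expect_equal(sort(r2$pos), pos[1:3])

  # empty literature list warns and selects nothing
  expect_warning(
    r0 <- round1_select(toy_diff(pos), genes, toy_effects(pos, cls),
      selection_config(literature_genes = character())
    ),
    "literature"
  )
  expect_equal(nrow(r0), 0)
})

test_that("round 2 adds coding-disruptive SNPs not already selected", {
  genes <- dplyr::bind_rows(
    toy_gene("GeneX"),
    toy_gene("GeneY", start = 20000, end = 23000)
  )
  pos <- seq(10100, by = 100, length.out = 10)
  cls <- c(
    "missense", "missense", "missense", "nonsense",
    rep(c("intron", "synonymous", "3'UTR"), 2)
  )
  eff <- toy_effects(pos, cls, gene_id = rep(c("GeneX", "GeneY"), 5))
  diff <- toy_diff(pos)
  round1 <- panel_head <- tibble::tibble(
    chrom = "Chr1", pos = pos[1:2], alt = "T",
    gene_id = c("GeneX", "GeneY"), effect_class = "missense", round = 1L
  )
  r2 <- round2_select(diff, eff, genes, round1)
  # 3 missense + 1 nonsense, minus the 2 already selected
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$pos, pos[3:4])
  expect_true(all(r2$effect_class %in% c("missense", "nonsense")))

  # a missense SNP in a non-literature gene is in round-2 scope
  expect_true("GeneY" %in% eff$gene_id[eff$pos %in% r2$pos] |
    "GeneX" %in% eff$gene_id[eff$pos %in% r2$pos])

  # the combined panel has unique keys and carries the round labels
  panel <- panel_design(round1, r2)
  expect_equal(anyDuplicated(panel$snp_id), 0)
  expect_equal(sort(unique(panel$round)), c(1L, 2L))
})

test_that("shrinking the flank windows never adds round-1 candidates", {
  set.seed(77)
  genes <- dplyr::bind_rows(
    toy_gene("GeneX"),
    toy_gene("GeneY", start = 30000, end = 34000, strand = "-")
  )
  pos <- sort(sample(5000:40000, 150))
  eff <- toy_effects(pos, sample(
    c("missense", "intron", "upstream", "downstream", "synonymous"),
    150,
    replace = TRUE
  ), gene_id = NA)
  diff <- toy_diff(pos)
  lit <- selection_config(literature_genes = c("GeneX", "GeneY"))
  n_prev <- Inf
  for (up in c(2000, 1000, 500, 0)) {
    cfg <- selection_config(
      upstream_bp = up, downstream_bp = up / 4,
      literature_genes = c("GeneX", "GeneY")
    )
    n_now <- nrow(round1_select(diff, genes, eff, cfg))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("selected SNPs verifiably sit in their gene's extended extent", {
  cfg_sim <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 1e6, snp_density = 1e-3,
    qtl_loci = NULL, seed = 41
  )
  par <- simulate_parents(cfg_sim)
  ann <- simulate_annotation(par, seed = 2)
  diff <- par$loci[seq(1, nrow(par$loci), by = 3), c("chrom", "pos", "alt")]
  cfg <- selection_config(literature_genes = ann$genes$gene_id)
  r1 <- round1_select(diff, ann$genes, ann$effects, cfg)
  expect_gt(nrow(r1), 0)

  # independent interval-tree check with strand-aware extension
  ext <- ann$genes |>
    dplyr::mutate(
      s = ifelse(strand == "-", start - 500, start - 2000),
      e = ifelse(strand == "-", end + 2000, end + 500)
    )
  gr_gene <- GenomicRanges::GRanges(ext$chrom, IRanges::IRanges(ext$s, ext$e))
  names(gr_gene) <- ext$gene_id
  gr_snp <- GenomicRanges::GRanges(r1$chrom, IRanges::IRanges(r1$pos, r1$pos))
  hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
  ok <- vapply(seq_len(nrow(r1)), function(i) {
    r1$gene_id[i] %in% names(gr_gene)[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i
    ]]
  }, logical(1))
  expect_true(all(ok))

  # per-gene cap enforced
  expect_true(all(table(r1$gene_id) <= 3))
})

test_that("ANN and TSV effect inputs parse to the same table", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "Chr1\t100\t.\tA\tT\t.\tPASS\tANN=T|missense_variant|MODERATE|GeneX|gx|transcript|t1|p|1/2|c|p|1|2|3|",
    "Chr1\t200\t.\tG\tC\t.\tPASS\tANN=C|synonymous_variant|LOW|GeneY|gy|transcript|t2|p|1/2|c|p|1|2|3|",
    paste0(
      "Chr1\t300\t.\tT\tA\t.\tPASS\tANN=",
      "A|intron_variant|MODIFIER|GeneZ|gz|transcript|t3|p|1/2|c|p|1|2|3|,",
      "A|stop_gained|HIGH|GeneZ|gz|transcript|t3b|p|1/2|c|p|1|2|3|"
    ),
    "Chr1\t400\t.\tC\tG\t.\tPASS\tANN=G|weird_new_term|LOW|GeneW|gw|transcript|t4|p|1/2|c|p|1|2|3|"
  ), vcf)
  from_vcf <- parse_effects(vcf)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "Chr1", pos = c(100, 200, 300, 400),
    alt = c("T", "C", "A", "G"),
    effect = c("missense_variant", "synonymous_variant", "stop_gained", "weird_new_term"),
    gene = c("GeneX", "GeneY", "GeneZ", "GeneW")
  ), tsv)
  from_tsv <- parse_effects(tsv)

  expect_equal(
    from_vcf[, c("chrom", "pos", "alt", "effect_class", "gene_id")],
    from_tsv[, c("chrom", "pos", "alt", "effect_class", "gene_id")]
  )
  # multiple annotations: the most severe is kept
  expect_equal(from_vcf$effect_class[from_vcf$pos == 300], "nonsense")
  # unknown terms fall back to 'other' and are tallied
  expect_equal(from_vcf$effect_class[from_vcf$pos == 400], "other")
  expect_equal(
    as.integer(attr(parse_effects(vcf), "unknown_terms")["weird_new_term"]),
    1L
  )
})

test_that("probe yield arithmetic rounds to one decimal", {
  y <- probe_design_yield(410, 1034)
  expect_equal(y$pct, 39.6)
  expect_error(probe_design_yield(10, 5), "n_submitted")
})
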