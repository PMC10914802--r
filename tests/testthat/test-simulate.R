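test_that("locus placement follows the density and is reproducible", {
  cfg <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 1e6, snp_density = 1e-3,
    qtl_loci = NULL, seed = 11
  )
  p1 <- simulate_parents(cfg)
  p2 <- simulate_parents(cfg)
  expect_identical(p1$loci, p2$loci)
  expect_identical(p1$haplo_A, p2$haplo_A)

  # ~1000 per chromosome, Poisson: allow 5 sigma
  counts <- table(p1$loci$chrom)
  expect_true(all(abs(counts - 1000) < 5 * sqrt(1000)))

  # ref and alt alleles always differ
  expect_true(all(p1$loci$ref != p1$loci$alt))
})

test_that("zero simulated loci is an error", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 100, snp_density = 1e-6,
    qtl_loci = NULL, seed = 3
  )
  expect_error(simulate_parents(cfg), "zero loci")
})

test_that("parental dosages follow the uniform prior", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e6, snp_density = 0.1,
    qtl_loci = NULL, seed = 5
  )
  p <- simulate_parents(cfg)
  n <- nrow(p$loci)
  expect_gt(n, 90000)
  counts <- tabulate(p$loci$dosage_A + 1, nbins = 5)
  # multinomial sd for each of 5 equiprobable cells
  sd_cell <- sqrt(n * 0.2 * 0.8)
  expect_true(all(abs(counts - n / 5) < 3 * sd_cell))
  # phases always sum to the dosage
  expect_identical(rowSums(p$haplo_A), as.numeric(p$loci$dosage_A))
})

test_that("gamete dosage follows the bivalent hypergeometric law", {
  par <- manual_parents(dosage_a = c(0L, 2L, 4L), dosage_e = c(0L, 0L, 0L))
  f1 <- simulate_f1(par, 60000, seed = 7, linkage_block_bp = NULL)

  # dosage-0 and dosage-4 parents are forced (E contributes nothing here)
  expect_true(all(f1[1, ] == 0))
  expect_true(all(f1[3, ] == 2))

  # dosage 2: k = 0,1,2 with 1/6, 4/6, 1/6
  obs <- tabulate(f1[2, ] + 1, nbins = 3)
  gof <- chisq.test(obs, p = c(1, 4, 1) / 6)
  expect_gt(gof$p.value, 0.001)

  # and the analytic law matches direct enumeration of C(4,2) pairs
  pairs <- combn(4, 2)
  hap2 <- c(1L, 1L, 0L, 0L)
  enum <- tabulate(colSums(matrix(hap2[pairs], nrow = 2)) + 1, nbins = 3) / 6
  expect_equal(enum, c(1, 4, 1) / 6)
})

test_that("simulate_f1 is deterministic under a seed and validates input", {
  par <- manual_parents(dosage_a = c(1L, 3L), dosage_e = c(2L, 2L))
  expect_identical(
    simulate_f1(par, 10, seed = 1),
    simulate_f1(par, 10, seed = 1)
  )
  expect_error(simulate_f1(par, 0), "n_f1")
})

test_that("linkage blocks co-inherit and double reduction reaches dosage 2 gametes", {
  # two loci in one block, parent A duplex at both with aligned phase
  par <- manual_parents(
    dosage_a = c(2L, 2L), dosage_e = c(0L, 0L),
    pos = c(1000, 2000)
  )
  f1 <- simulate_f1(par, 500, seed = 2, linkage_block_bp = 1e4)
  # same block, identical phase: offspring dosage identical at both loci
  expect_true(all(f1[1, ] == f1[2, ]))

  # simplex parent cannot transmit 2 copies without double reduction
  par1 <- manual_parents(dosage_a = c(1L), dosage_e = c(0L))
  f_nodr <- simulate_f1(par1, 2000, seed = 3, linkage_block_bp = NULL)
  expect_true(all(f_nodr <= 1))
  f_dr <- simulate_f1(par1, 2000,
    seed = 3, linkage_block_bp = NULL,
    double_reduction = 0.5
  )
  expect_true(any(f_dr == 2))
})

test_that("phenotypes follow the additive dosage model", {
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e4,
    qtl_loci = tibble::tibble(
      chrom = 1, pos = 2000, effect = 0.2, tolerant_parent = "A"
    ),
    n_experiments = 2, residual_sd = 0, seed = 9
  )
  par <- manual_parents(
    dosage_a = c(1L, 3L), dosage_e = c(2L, 1L),
    pos = c(1000, 2000), cfg = cfg, is_qtl = c(FALSE, TRUE)
  )
  f1 <- matrix(c(2L, 4L, 2L, 2L, 2L, 0L), nrow = 2)
  colnames(f1) <- c("g1", "g2", "g3")

  ph <- simulate_phenotypes(f1, par, seed = 1)
  expect_equal(nrow(ph), 3 * 2 * 2) # n_f1 x n_experiments x 2 treatments

  relsy <- compute_relsy(ph)
  by_geno <- tapply(relsy$relsy, relsy$genotype_id, mean)
  # g1 has QTL dosage 4, g2 dosage 2, g3 dosage 0: +0.2 steps
  expect_equal(unname(by_geno["g1"] - by_geno["g2"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(by_geno["g2"] - by_geno["g3"]), 0.2, tolerance = 1e-12)

  # no QTL effect and no noise: all genotypes identical RelSY
  cfg0 <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e4, qtl_loci = NULL,
    residual_sd = 0, seed = 9
  )
  par0 <- manual_parents(
    dosage_a = c(1L, 3L), dosage_e = c(2L, 1L),
    pos = c(1000, 2000), cfg = cfg0
  )
  ph0 <- simulate_phenotypes(f1, par0, seed = 1)
  r0 <- compute_relsy(ph0)
  expect_equal(var(r0$relsy), 0, tolerance = 1e-20)
})

test_that("pooled sequencing respects degenerate and large-depth limits", {
  # f = 0 everywhere and no sequencing error: zero alt reads
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e5, snp_density = 1e-3,
    qtl_loci = NULL, seq_error_rate = 0, coverage_mean = 50, seed = 13
  )
  par <- simulate_parents(cfg)
  par$loci$dosage_A <- 0L
  par$haplo_A[] <- 0L
  rec0 <- simulate_parent_records(par, "A", seed = 1)
  expect_true(all(rec0$ad_alt == 0))

  # f = 0.5 at high depth: mean observed AF within 3 binomial sigmas
  cfg2 <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e5, snp_density = 5e-3,
    qtl_loci = NULL, seq_error_rate = 0, coverage_mean = 400,
    coverage_dispersion = 0, seed = 13
  )
  par2 <- simulate_parents(cfg2)
  par2$loci$dosage_E <- 2L
  rec <- simulate_parent_records(par2, "E", seed = 2)
  n <- nrow(rec)
  se <- sqrt(0.25 / mean(rec$dp)) / sqrt(n)
  expect_lt(abs(mean(rec$af) - 0.5), 3 * se)
})

test_that("a written bulk VCF round-trips through the reader", {
  withr::local_seed(1)
  cfg <- sim_config(
    n_chromosomes = 1, chrom_length_bp = 1e5, snp_density = 1e-3,
    qtl_loci = NULL, seed = 17
  )
  par <- simulate_parents(cfg)
  f1 <- simulate_f1(par, 10)
  path <- withr::local_tempfile(fileext = ".vcf")
  written <- simulate_bulk_vcf(par, f1, colnames(f1)[1:5], path, "BULK")
  back <- read_vcf(path, "BULK")
  expect_equal(back$chrom, written$chrom)
  expect_equal(back$pos, written$pos)
  expect_equal(back$ref, written$ref)
  expect_equal(back$alt, written$alt)
  expect_equal(back$ad_ref, as.numeric(written$ad_ref))
  expect_equal(back$ad_alt, as.numeric(written$ad_alt))
  expect_equal(back$dp, as.integer(written$dp))
  expect_equal(back$gq, as.integer(written$gq))
})

test_that("with no QTL the expected bulk allele-frequency difference is zero", {
  cfg <- sim_config(
    n_chromosomes = 5, chrom_length_bp = 5e6, snp_density = 4e-4,
    qtl_loci = NULL, residual_sd = 0.05, seed = 19
  )
  par <- simulate_parents(cfg)
  f1 <- simulate_f1(par, 100)
  drym <- simulate_phenotypes(f1, par) |>
    compute_relsy() |>
    compute_drym()
  bulks <- select_bulks(drym, n_bulk = 20)
  delta <- (rowMeans(f1[, bulks$tolerant_ids]) -
    rowMeans(f1[, bulks$sensitive_ids])) / 4
  se <- sd(delta) / sqrt(length(delta))
  expect_gt(length(delta), 5000)
  expect_lt(abs(mean(delta)), 3 * se)
})

test_that("phenotypic selection concentrates the QTL allele in the bulks", {
  # unlinked loci: only the QTL locus carries a selection signal
  cfg <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 2e6, snp_density = 5e-4,
    qtl_loci = tibble::tibble(
      chrom = 1, pos = 1e6, effect = 0.2, tolerant_parent = "A"
    ),
    linkage_block_bp = NULL, seed = 23
  )
  par <- simulate_parents(cfg)
  f1 <- simulate_f1(par, 100)
  drym <- simulate_phenotypes(f1, par) |>
    compute_relsy() |>
    compute_drym()
  bulks <- select_bulks(drym, n_bulk = 20)
  delta <- abs(rowMeans(f1[, bulks$tolerant_ids]) -
    rowMeans(f1[, bulks$sensitive_ids])) / 4
  at_qtl <- delta[par$loci$is_qtl]
  frac_higher <- mean(delta[!par$loci$is_qtl] >= at_qtl)
  expect_lt(frac_higher, 0.01)
})

test_that("simulated effect classes agree with the gene models positionally", {
  cfg <- sim_config(
    n_chromosomes = 2, chrom_length_bp = 5e5, snp_density = 2e-3,
    qtl_loci = NULL, seed = 29
  )
  par <- simulate_parents(cfg)
  ann <- simulate_annotation(par, seed = 1)
  eff <- ann$effects
  genes <- ann$genes

  in_gene <- purrr::map_lgl(seq_len(nrow(eff)), function(i) {
    any(genes$chrom == eff$chrom[i] &
      genes$start <= eff$pos[i] & genes$end >= eff$pos[i])
  })
  genic_classes <- c(
    "missense", "nonsense", "synonymous", "intron", "5'UTR", "3'UTR"
  )
  expect_true(all(eff$effect_class[in_gene] %in% genic_classes))
  expect_true(all(!eff$effect_class[!in_gene] %in% genic_classes))

  # intergenic SNPs are outside every gene extended by its flanks
  flank_hit <- purrr::map_lgl(seq_len(nrow(eff)), function(i) {
    any(genes$chrom == eff$chrom[i] &
      genes$start - 2000 <= eff$pos[i] & genes$end + 2000 >= eff$pos[i])
  })
  expect_true(all(eff$effect_class[!flank_hit] == "intergenic"))
  expect_true(all(!is.na(eff$gene_id[eff$effect_class != "intergenic"])))

  # the written GFF3 round-trips the gene extents
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff_genes(path)
  expect_equal(nrow(back), nrow(genes))
  expect_setequal(back$gene_id, genes$gene_id)
  joined <- dplyr::inner_join(back, genes, by = "gene_id")
  expect_equal(joined$start.x, joined$start.y)
  expect_equal(joined$end.x, joined$end.y)
  expect_equal(joined$strand.x, joined$strand.y)
})
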