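#' Simulate two autotetraploid parents
#'
#' Places SNP loci along each chromosome by a Poisson process at
#' `cfg$snp_density` and draws, per locus and parent, an alternative-allele
#' dosage from a uniform prior on 0..4. Dosages are phased onto four
#' homologues so that gametes can later be drawn by bivalent pairing. Loci
#' where both parents carry dosage 0 (or 4) are retained: they model sites
#' where the cultivars jointly differ (or not) from the reference assembly
#' and therefore segregate in neither bulk. At each planted QTL locus the
#' tolerant parent receives dosage `cfg$qtl_dosage[1]` and the other parent
#' `cfg$qtl_dosage[2]` (default triplex x simplex), so the locus segregates
#' in the F1.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `bsa_parents` with elements `loci` (tibble:
#'   `chrom`, `pos`, `ref`, `alt`, `dosage_A`, `dosage_E`, `is_qtl`),
#'   `haplo_A` and `haplo_E` (0/1 matrices, loci x 4 homologues), and `cfg`.
#' @export
#' @examples
#' p <- simulate_parents(sim_config(n_chromosomes = 1, chrom_length_bp = 1e5,
#'                                  snp_density = 1e-3, qtl_loci = NULL))
#' head(p$loci)
simulate_parents <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")

  per_chrom <- purrr::map(seq_len(cfg$n_chromosomes), function(ch) {
    n <- rpois(1, cfg$snp_density * cfg$chrom_length_bp)
    if (n == 0) {
      return(NULL)
    }
    pos <- sort(sample.int(cfg$chrom_length_bp, n))
    tibble(chrom = paste0("Chr", ch), chrom_idx = ch, pos = as.numeric(pos))
  })
  loci <- dplyr::bind_rows(per_chrom)
  if (is.null(loci) || nrow(loci) == 0) {
    abort("simulated zero loci; increase `snp_density` or `chrom_length_bp`")
  }

  # make sure every planted QTL has a locus exactly at its position
  loci$is_qtl <- FALSE
  loci$tolerant_parent <- NA_character_
  if (!is.null(cfg$qtl_loci) && nrow(cfg$qtl_loci) > 0) {
    for (i in seq_len(nrow(cfg$qtl_loci))) {
      q <- cfg$qtl_loci[i, ]
      hit <- which(loci$chrom_idx == q$chrom & loci$pos == q$pos)
      if (length(hit) == 0) {
        loci <- dplyr::bind_rows(loci, tibble(
          chrom = paste0("Chr", q$chrom), chrom_idx = as.integer(q$chrom),
          pos = as.numeric(q$pos), is_qtl = TRUE,
          tolerant_parent = q$tolerant_parent
        ))
      } else {
        loci$is_qtl[hit] <- TRUE
        loci$tolerant_parent[hit] <- q$tolerant_parent
      }
    }
    loci <- dplyr::arrange(loci, .data$chrom_idx, .data$pos)
  }

  n <- nrow(loci)
  loci$ref <- sample(bases, n, replace = TRUE)
  loci$alt <- bases[(match(loci$ref, bases) + sample(1:3, n, replace = TRUE) - 1) %% 4 + 1]

  dosage_A <- sample(0:4, n, replace = TRUE)
  dosage_E <- sample(0:4, n, replace = TRUE)
  qtl <- which(loci$is_qtl)
  if (length(qtl) > 0) {
    tol_is_A <- loci$tolerant_parent[qtl] == "A"
    dosage_A[qtl] <- ifelse(tol_is_A, cfg$qtl_dosage[1], cfg$qtl_dosage[2])
    dosage_E[qtl] <- ifelse(tol_is_A, cfg$qtl_dosage[2], cfg$qtl_dosage[1])
  }

  loci$dosage_A <- as.integer(dosage_A)
  loci$dosage_E <- as.integer(dosage_E)
  loci$chrom_idx <- NULL

  structure(
    list(
      loci = tibble::as_tibble(loci[, c(
        "chrom", "pos", "ref", "alt", "dosage_A", "dosage_E", "is_qtl"
      )]),
      haplo_A = phase_dosage(dosage_A),
      haplo_E = phase_dosage(dosage_E),
      cfg = cfg
    ),
    class = "bsa_parents"
  )
}

# place `dosage` alt alleles uniformly at random on 4 homologues per locus
phase_dosage <- function(dosage) {
  n <- length(dosage)
  h <- matrix(0L, n, 4)
  ord <- vapply(seq_len(n), function(i) sample.int(4), integer(4))
  for (d in 1:4) {
    rows <- which(dosage >= d)
    if (length(rows) > 0) h[cbind(rows, ord[d, rows])] <- 1L
  }
  stopifnot(all(rowSums(h) == dosage))
  h
}

#' Simulate F1 clones by tetrasomic inheritance
#'
#' Each F1 genotype is the sum of one gamete from each parent. A gamete is
#' formed by random bivalent pairing: two of the four parental homologues are
#' drawn uniformly (all `choose(4,2) = 6` pairs equally likely), so a parent
#' of dosage d transmits k alternative alleles with hypergeometric
#' probability C(d,k) C(4-d,2-k) / C(4,2). With `linkage_block_bp` set (the
#' default from the config), all loci inside one block share a single
#' homologue-pair draw, producing locally correlated inheritance; with
#' `linkage_block_bp = NULL` every locus draws independently. With
#' probability `double_reduction` a block instead transmits two copies of a
#' single homologue.
#'
#' @param parents Result of [simulate_parents()].
#' @param n_f1 Number of F1 clones to draw.
#' @param seed Optional integer seed (default: continue the current RNG
#'   stream).
#' @param linkage_block_bp,double_reduction Override the values stored in
#'   `parents$cfg`.
#' @return An integer dosage matrix (loci x clones) of class `bsa_f1` with
#'   clone identifiers as column names.
#' @export
simulate_f1 <- function(parents, n_f1,
                        seed = NULL,
                        linkage_block_bp = parents$cfg$linkage_block_bp,
                        double_reduction = parents$cfg$double_reduction) {
  if (n_f1 < 1) abort("`n_f1` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  loci <- parents$loci
  n <- nrow(loci)

  block <- if (is.null(linkage_block_bp)) {
    seq_len(n)
  } else {
    as.integer(factor(paste(loci$chrom, floor((loci$pos - 1) / linkage_block_bp))))
  }
  n_blocks <- max(block)
  pairs <- utils::combn(4, 2)

  draw_gamete <- function(haplo) {
    p <- sample.int(6, n_blocks, replace = TRUE)
    i1 <- pairs[1, p][block]
    i2 <- pairs[2, p][block]
    g <- haplo[cbind(seq_len(n), i1)] + haplo[cbind(seq_len(n), i2)]
    if (double_reduction > 0) {
      dr <- runif(n_blocks) < double_reduction
      if (any(dr)) {
        hom <- sample.int(4, n_blocks, replace = TRUE)
        take <- dr[block]
        g[take] <- 2L * haplo[cbind(which(take), hom[block][take])]
      }
    }
    g
  }

  out <- matrix(0L, n, n_f1)
  for (k in seq_len(n_f1)) {
    out[, k] <- draw_gamete(parents$haplo_A) + draw_gamete(parents$haplo_E)
  }
  colnames(out) <- sprintf("F1_%03d", seq_len(n_f1))
  structure(out, class = c("bsa_f1", class(out)))
}
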