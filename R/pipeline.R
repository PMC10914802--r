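#' Default end-to-end pipeline configuration
#'
#' Nested per-stage settings mirroring the standard analysis defaults:
#' depth 20-360, allele frequency 0.10-0.90, GQ >= 99 for the filter;
#' window 1 Mb, |delta SNP| < 0.1 null subset, Bonferroni alpha 0.01 for
#' the scan; 2000/500 bp flank windows and a 3-SNP-per-gene cap for the
#' selection; alpha 0.05 on a 34-variety panel for the association.
#' Any subset of keys can be overridden via a YAML file or a nested list
#' passed to [run_pipeline()].
#'
#' @return Nested named list with sections `sim`, `filter`, `scan`,
#'   `selection`, `association`.
#' @export
default_pipeline_config <- function() {
  list(
    sim = list(
      n_chromosomes = 5, chrom_length_bp = 5e6, snp_density = 1e-4,
      qtl_chrom = 2, qtl_pos = 2.5e6, qtl_effect = 0.2,
      qtl_tolerant_parent = "A",
      n_f1 = 100, bulk_size = 20, coverage_mean = 120,
      coverage_dispersion = 0.2, seq_error_rate = 0.002,
      n_experiments = 3, base_relsy = 0.5, residual_sd = 0.05,
      linkage_block_bp = 1e6, seed = 1
    ),
    filter = list(
      min_depth = 20, max_depth = 360, min_af = 0.10, max_af = 0.90,
      min_gq = 99
    ),
    scan = list(
      window_size = 1e6, filter_threshold = 0.1, alpha = 0.01,
      correction = "bonferroni"
    ),
    selection = list(
      upstream_bp = 2000, downstream_bp = 500, max_snps_per_gene = 3,
      literature_genes = NULL
    ),
    association = list(alpha = 0.05, n_varieties = 34)
  )
}

merge_config <- function(user) {
  base <- default_pipeline_config()
  bad_top <- setdiff(names(user), names(base))
  if (length(bad_top) > 0) {
    abort(paste("unknown config section(s):", paste(bad_top, collapse = ", ")))
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "unknown key(s) in section '%s': %s", sec, paste(bad, collapse = ", ")
      ))
    }
    base[[sec]] <- utils::modifyList(base[[sec]], user[[sec]])
  }
  base
}

#' Run the whole bulked-segregant analysis on simulated data
#'
#' Orchestrates simulate, drym, bulks, filter, scan, attribute, select and
#' assoc in dependency order, writing every intermediate table in a
#' standard plain-text format under `out_dir` plus a JSON run manifest
#' recording per-stage outputs and record counts. A stage failure marks
#' all downstream stages skipped; reruns with the same seed reproduce
#' identical record counts.
#'
#' @param config `NULL` (defaults), a nested list, or a path to a YAML
#'   file with any subset of [default_pipeline_config()]'s keys. Unknown
#'   keys raise an error naming them.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding `config$sim$seed`.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("bsaqtl_run_"),
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config %||% list())
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_names <- c(
    "simulate", "drym", "bulks", "filter", "scan",
    "attribute", "select", "assoc"
  )
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$sim$seed,
    parameter_hash = rlang::hash(cfg),
    out_dir = out_dir,
    stages = setNames(
      lapply(stage_names, function(s) list(status = "pending")),
      stage_names
    )
  )
  env <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(
        status = "failed", error = conditionMessage(res)
      )
    } else {
      manifest$stages[[name]] <<- c(list(status = "complete"), res)
    }
    invisible(NULL)
  }
  p <- function(...) file.path(out_dir, ...)

  run_stage("simulate", function() {
    sc <- cfg$sim
    env$sim_cfg <- sim_config(
      n_chromosomes = sc$n_chromosomes, chrom_length_bp = sc$chrom_length_bp,
      snp_density = sc$snp_density,
      qtl_loci = tibble(
        chrom = as.integer(sc$qtl_chrom), pos = sc$qtl_pos,
        effect = sc$qtl_effect, tolerant_parent = sc$qtl_tolerant_parent
      ),
      n_f1 = sc$n_f1, bulk_size = sc$bulk_size,
      coverage_mean = sc$coverage_mean,
      coverage_dispersion = sc$coverage_dispersion,
      seq_error_rate = sc$seq_error_rate, n_experiments = sc$n_experiments,
      base_relsy = sc$base_relsy, residual_sd = sc$residual_sd,
      linkage_block_bp = sc$linkage_block_bp, seed = sc$seed
    )
    env$parents <- simulate_parents(env$sim_cfg)
    env$f1 <- simulate_f1(env$parents, env$sim_cfg$n_f1)
    env$pheno <- simulate_phenotypes(env$f1, env$parents)
    env$annot <- simulate_annotation(env$parents)
    readr::write_tsv(env$pheno, p("phenotypes.tsv"))
    write_gff3(env$annot, p("annotation.gff3"))
    write_effects(env$annot$effects, p("effects.tsv"))
    list(
      outputs = p(c("phenotypes.tsv", "annotation.gff3", "effects.tsv")),
      counts = list(
        loci = nrow(env$parents$loci), f1 = ncol(env$f1),
        genes = nrow(env$annot$genes)
      )
    )
  })

  run_stage("drym", function() {
    env$drym <- env$pheno %>%
      compute_relsy() %>%
      compute_drym()
    readr::write_tsv(env$drym, p("drym.tsv"))
    list(outputs = p("drym.tsv"), counts = list(records = nrow(env$drym)))
  })

  run_stage("bulks", function() {
    env$bulks <- select_bulks(env$drym, n_bulk = cfg$sim$bulk_size)
    readr::write_tsv(env$bulks$ranks, p("bulk_ranks.tsv"))
    sep <- bulk_separation_test(
      env$drym$drym[env$drym$genotype_id %in% env$bulks$tolerant_ids],
      env$drym$drym[env$drym$genotype_id %in% env$bulks$sensitive_ids]
    )
    readr::write_tsv(sep, p("bulk_separation.tsv"))
    simulate_bulk_vcf(
      env$parents, env$f1, env$bulks$tolerant_ids,
      p("bulk_tolerant.vcf"), "HROEXATOL"
    )
    simulate_bulk_vcf(
      env$parents, env$f1, env$bulks$sensitive_ids,
      p("bulk_sensitive.vcf"), "HROEXASEN"
    )
    simulate_parent_vcf(env$parents, "A", p("parent_A.vcf"))
    simulate_parent_vcf(env$parents, "E", p("parent_E.vcf"))
    list(
      outputs = p(c(
        "bulk_ranks.tsv", "bulk_separation.tsv", "bulk_tolerant.vcf",
        "bulk_sensitive.vcf", "parent_A.vcf", "parent_E.vcf"
      )),
      counts = list(
        tolerant = length(env$bulks$tolerant_ids),
        sensitive = length(env$bulks$sensitive_ids),
        separation_p = sep$p_value
      )
    )
  })

  run_stage("filter", function() {
    fc <- cfg$filter
    env$filter_cfg <- filter_config(
      fc$min_depth, fc$max_depth, fc$min_af, fc$max_af, fc$min_gq
    )
    env$tol_raw <- read_vcf(p("bulk_tolerant.vcf"))
    env$sen_raw <- read_vcf(p("bulk_sensitive.vcf"))
    tol_f <- filter_variants(env$tol_raw, env$filter_cfg)
    sen_f <- filter_variants(env$sen_raw, env$filter_cfg)
    readr::write_tsv(
      dplyr::bind_rows(
        dplyr::mutate(filter_tally(tol_f), bulk = "tolerant"),
        dplyr::mutate(filter_tally(sen_f), bulk = "sensitive")
      ),
      p("filter_tally.tsv")
    )
    list(
      outputs = p("filter_tally.tsv"),
      counts = list(
        input_tol = nrow(env$tol_raw), retained_tol = nrow(tol_f),
        input_sen = nrow(env$sen_raw), retained_sen = nrow(sen_f)
      )
    )
  })

  run_stage("scan", function() {
    sc <- cfg$scan
    env$scan_cfg <- scan_config(
      window_size = sc$window_size, filter_threshold = sc$filter_threshold,
      alpha = sc$alpha, correction = sc$correction
    )
    env$joint <- intersect_bulks(env$tol_raw, env$sen_raw, env$filter_cfg)
    env$scan <- run_gprime_scan(env$joint, env$scan_cfg)
    readr::write_tsv(
      dplyr::select(
        env$scan$snps, "chrom", "pos", "ref", "alt", "delta_snp",
        "g", "gprime", "pvalue", "qvalue", "sig"
      ),
      p("scan.tsv")
    )
    env$qtl <- summarize_qtl(
      env$scan$intervals,
      genes = env$annot$genes, snps = env$joint
    )
    readr::write_tsv(env$qtl, p("qtl_table.tsv"))
    if (nrow(env$qtl) > 0) write_qtl_bed(env$qtl, p("qtl.bed"))
    list(
      outputs = p(c("scan.tsv", "qtl_table.tsv")),
      counts = list(
        scanned = nrow(env$scan$snps),
        difference_snps = sum(env$joint$difference),
        qtls = nrow(env$qtl)
      )
    )
  })

  run_stage("attribute", function() {
    bulk_pass <- dplyr::filter(env$joint, .data$pass_tol | .data$pass_sen)
    env$origins <- classify_origin(
      bulk_pass,
      read_vcf(p("parent_A.vcf")), # unfiltered parent calls
      read_vcf(p("parent_E.vcf"))
    )
    venn <- venn_counts(env$origins, if (nrow(env$qtl) > 0) env$qtl else NULL)
    readr::write_tsv(venn, p("venn.tsv"))
    win <- rolling_windows(
      dplyr::filter(env$joint, .data$present_tol) %>%
        dplyr::mutate(af = .data$af_tol),
      win_size = cfg$scan$window_size,
      win_step = cfg$scan$window_size / 2
    )
    readr::write_tsv(win, p("windows_tolerant.tsv"))
    list(
      outputs = p(c("venn.tsv", "windows_tolerant.tsv")),
      counts = list(classified = nrow(env$origins))
    )
  })

  run_stage("select", function() {
    sl <- cfg$selection
    genes_under <- genes_in_intervals(env$annot$genes, env$qtl)
    lit <- sl$literature_genes %||% genes_under$gene_id
    env$sel_cfg <- selection_config(
      upstream_bp = sl$upstream_bp, downstream_bp = sl$downstream_bp,
      max_snps_per_gene = sl$max_snps_per_gene,
      literature_genes = lit, qtl_intervals = env$qtl
    )
    diff_snps <- dplyr::filter(env$joint, .data$difference)
    effects <- env$annot$effects
    r1 <- suppressWarnings(
      round1_select(diff_snps, env$annot$genes, effects, env$sel_cfg)
    )
    r2 <- round2_select(diff_snps, effects, genes_under, r1, env$sel_cfg)
    env$panel <- panel_design(r1, r2)
    readr::write_tsv(env$panel, p("panel_design.tsv"))
    write_probe_bed(env$panel, p("probe_flanks.bed"))
    list(
      outputs = p(c("panel_design.tsv", "probe_flanks.bed")),
      counts = list(
        round1 = nrow(r1), round2 = nrow(r2), panel = nrow(env$panel)
      )
    )
  })

  run_stage("assoc", function() {
    ac <- cfg$association
    if (nrow(env$panel) == 0) {
      readr::write_tsv(
        tibble(
          snp_id = character(), fisher_p = numeric(),
          significant = logical()
        ),
        p("association.tsv")
      )
      return(list(
        outputs = p("association.tsv"),
        counts = list(panel_snps = 0, significant = 0)
      ))
    }
    # SNPs near a planted QTL carry a true association in the panel
    qtl_pos <- dplyr::filter(env$parents$loci, .data$is_qtl)
    near_qtl <- env$panel$snp_id[purrr::map_lgl(
      seq_len(nrow(env$panel)),
      function(i) {
        any(qtl_pos$chrom == env$panel$chrom[i] &
          abs(qtl_pos$pos - env$panel$pos[i]) < 5e4)
      }
    )]
    panel_sim <- simulate_panel(
      env$panel,
      n_varieties = ac$n_varieties, assoc_snps = near_qtl
    )
    groups <- split_panel(panel_sim$varieties)
    fisher <- fisher_association(panel_sim$genotypes, groups, ac$alpha)
    kw <- kw_association(panel_sim$genotypes, panel_sim$varieties, ac$alpha)
    assoc <- dplyr::left_join(
      fisher, kw,
      by = "snp_id", suffix = c("", "_kw")
    ) %>%
      dplyr::left_join(
        dplyr::select(
          env$panel, "snp_id", "chrom", "pos", "alt", "gene_id",
          "effect_class", "round"
        ),
        by = "snp_id"
      )
    readr::write_tsv(assoc, p("association.tsv"))
    list(
      outputs = p("association.tsv"),
      counts = list(
        panel_snps = nrow(fisher),
        significant = sum(fisher$significant)
      )
    )
  })

  class(manifest) <- "run_manifest"
  jsonlite::write_json(
    unclass(manifest), file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$out_dir, "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cnt <- if (!is.null(st$counts)) {
      paste(names(st$counts), unlist(st$counts),
        sep = "=", collapse = ", "
      )
    } else {
      ""
    }
    cat(sprintf("  %-9s %-8s %s\n", s, st$status, cnt))
  }
  invisible(x)
}
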