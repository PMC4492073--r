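#' Published summary tables of the MSGI 1.2 atlas
#'
#' The published per-tissue expression-profile, SNP and differential
#' expression summary tables plus headline counts, shipped as package data
#' so that their internal arithmetic (column sums, union identities,
#' percentages) can be recomputed mechanically through the same report
#' schemas the pipeline emits.
#'
#' @return List with components `table1`, `table2`, `table3`, `table6`
#'   and `headline`.
#' @export
msgi_tables <- function() {
  path <- system.file("extdata", "msgi12_printed.json", package = "msatlas",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Arithmetic on report-schema summary tables
#'
#' Helpers recomputing derived dataset-level quantities from the summary
#' table shapes: the between-genotype DE total is the sum of the per-tissue
#' cells; the SNP grand total is the sum of the per-class totals; the
#' tissue-specific union obeys
#' `|specific(g1)| + |specific(g2)| - |common|`, per tissue or overall.
#'
#' @param table3 List with `de_transcripts` per tissue (or a bare vector).
#' @return `de_total_from_table3`: the summed DE count.
#' @export
de_total_from_table3 <- function(table3) {
  v <- if (is.list(table3)) table3$de_transcripts else table3
  sum(as.numeric(v))
}

#' @rdname de_total_from_table3
#' @param table2 List with `total_snps` per class (or a bare vector).
#' @return `snp_total_from_table2`: the summed SNP count.
#' @export
snp_total_from_table2 <- function(table2) {
  v <- if (is.list(table2)) table2$total_snps else table2
  sum(as.numeric(v))
}

#' @rdname de_total_from_table3
#' @param table6 A table-6-shaped list (see [expression_summary()] or
#'   [msgi_tables()]`$table6`).
#' @param tissue Optional tissue label; `NULL` uses the totals row.
#' @return `tissue_specific_union_from_table6`: size of the union of
#'   tissue-specific calls across the two genotypes.
#' @export
tissue_specific_union_from_table6 <- function(table6, tissue = NULL) {
  g <- names(table6$tissue_specific)
  if (is.null(tissue)) {
    ts <- table6$totals$tissue_specific
    return(as.numeric(ts[[g[1]]]) + as.numeric(ts[[g[2]]]) -
             as.numeric(table6$totals$common))
  }
  i <- match(tissue, table6$tissues)
  if (is.na(i)) stop("unknown tissue: ", tissue)
  as.numeric(table6$tissue_specific[[g[1]]][i]) +
    as.numeric(table6$tissue_specific[[g[2]]][i]) -
    as.numeric(table6$common[i])
}

#' @rdname de_total_from_table3
#' @param numerator,denominator Counts.
#' @return `recompute_pct`: `100 * numerator / denominator`.
#' @export
recompute_pct <- function(numerator, denominator) {
  100 * as.numeric(numerator) / as.numeric(denominator)
}

#' Run the full atlas pipeline on synthetic or file inputs
#'
#' Executes the enabled stages in dependency order — expression
#' normalization and classification, between-genotype differential
#' expression, SNP filtering and classification, gene-family clustering and
#' expansion testing, six-frame motif scanning joined with nodule
#' specificity, and GO enrichment of the common nodule-specific set — and
#' (optionally) writes the machine-readable reports: per-stage TSV tables
#' plus JSON summaries mirroring the published table shapes. All writes are
#' atomic, so rerunning a subset of stages never corrupts earlier outputs;
#' with a fixed configuration the report bundle is byte-identical across
#' runs.
#'
#' @param input A [simulation_config()] (inputs are generated in memory) or
#'   a pre-built [simulate_atlas()] bundle.
#' @param out_dir Output directory for the report bundle; `NULL` skips
#'   writing.
#' @param stages Character subset of
#'   `c("expression", "de", "snp", "families", "motifs", "enrich")`.
#' @param presence,absence RPKM thresholds for [classify_expression()].
#' @param min_reads,min_reps Retention-filter thresholds.
#' @param fc_min,q_min,pseudo DE thresholds for [call_de()].
#' @param min_alt_reads SNP per-replicate threshold.
#' @param family_evalue,expected_ratio,alpha_expansion,min_total
#'   Family-clustering and expansion-test parameters.
#' @param alpha_go Enrichment significance level.
#' @return Invisibly, a list of per-stage results plus `report`, the
#'   combined JSON-shaped summary.
#' @export
run_pipeline <- function(input = simulation_config(),
                         out_dir = NULL,
                         stages = c("expression", "de", "snp", "families",
                                    "motifs", "enrich"),
                         presence = 1, absence = 1,
                         min_reads = 10, min_reps = 2,
                         fc_min = 2, q_min = 0.95, pseudo = 0.5,
                         min_alt_reads = 10,
                         family_evalue = 0, expected_ratio = 2,
                         alpha_expansion = 0.01, min_total = 5,
                         alpha_go = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(input, "simulation_config")) {
    data <- simulate_atlas(input)
  } else if (is.list(input) && !is.null(input$counts)) {
    data <- input
  } else {
    stop("input must be a simulation_config or a simulate_atlas() bundle")
  }
  res <- list()
  report <- list()

  # expression underpins de and motifs
  need_expr <- any(c("expression", "de", "motifs", "enrich") %in% stages)
  if (need_expr) {
    counts <- data$counts$counts
    design <- data$counts$design
    rpkm <- rpkm_normalize(counts, data$counts$lengths)
    retained <- retention_filter(counts, design, min_reads, min_reps)
    cls <- classify_expression(rpkm, design, presence, absence)
    res$expression <- list(rpkm = rpkm, retained = retained,
                           classification = cls)
    if ("expression" %in% stages) {
      s6 <- expression_summary(cls)
      stable <- stable_transcripts(rpkm, design)
      tops <- lapply(cls$genotypes, function(g) {
        top_expressed(rpkm, design, g,
                      n = min(500, nrow(rpkm)))
      })
      names(tops) <- cls$genotypes
      res$expression$summary <- s6
      res$expression$stable <- stable
      res$expression$top <- tops
      report$table6 <- s6
      report$n_retained <- length(retained)
      report$top_overlap <- length(top_overlap(tops[[1]], tops[[2]]))
    }
  }

  if ("de" %in% stages) {
    de <- de_between_genotypes(res$expression$rpkm, data$counts$design,
                               fc_min = fc_min, q_min = q_min,
                               pseudo = pseudo)
    res$de <- de
    report$table3 <- list(tissues = unique(data$counts$design$tissue),
                          de_transcripts = unname(de$per_tissue),
                          total_union = de$total_union)
  }

  if ("snp" %in% stages) {
    cand <- call_replicate_snps(data$variants$evidence, min_alt_reads)
    passed <- consolidate_snps(cand,
                               replicates = max(data$counts$design$replicate))
    classified <- classify_snps(passed,
                                genotypes = unique(data$counts$design$genotype))
    res$snp <- classified
    report$table2 <- snp_summary(classified)
  }

  if ("families" %in% stages) {
    fam <- cluster_families(data$homology$hits, data$homology$species,
                            family_evalue)
    sp <- unique(unname(data$homology$species))
    exp_res <- expansion_test(fam, focal = sp[1], reference = sp[2],
                              expected_ratio = expected_ratio,
                              alpha = alpha_expansion, min_total = min_total)
    res$families <- list(families = fam, expansion = exp_res)
    report$families <- list(n_families = length(unique(fam$family)),
                            n_tested = nrow(exp_res),
                            n_significant = sum(exp_res$significant))
  }

  if ("motifs" %in% stages) {
    frames <- six_frame_translate(data$sequences$sequences)
    pattern <- if (inherits(input, "simulation_config")) {
      input$motif_pattern
    } else {
      data$config$motif_pattern
    }
    hits <- scan_ncr(frames, pattern)
    join <- nodule_ncr_join(hits, res$expression$classification)
    res$motifs <- list(frames = frames, hits = hits, join = join)
    report$ncr <- join$counts
  }

  if ("enrich" %in% stages) {
    cls <- res$expression$classification
    common_nodule <- cls$transcripts[
      !is.na(cls$common_tissue_specific) &
        cls$common_tissue_specific == "Nodule"]
    enr <- fisher_enrichment(common_nodule, data$go$annotations,
                             universe = data$go$universe, alpha = alpha_go)
    res$enrich <- enr
    report$enrichment <- list(n_terms = nrow(enr),
                              n_significant = sum(enr$significant),
                              top_term = if (nrow(enr)) enr$term[1] else NA)
  }

  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if ("expression" %in% stages) {
      cls <- res$expression$classification
      write_tsv_atomic(data.frame(
        transcript = cls$transcripts,
        genotype_specific = cls$genotype_specific,
        common_tissue_specific = cls$common_tissue_specific),
        file.path(out_dir, "classification.tsv"))
      write_tsv_atomic(res$expression$stable,
                       file.path(out_dir, "stable_transcripts.tsv"))
    }
    if ("snp" %in% stages) {
      write_tsv_atomic(res$snp$records, file.path(out_dir, "snp_records.tsv"))
    }
    if ("families" %in% stages) {
      write_tsv_atomic(res$families$families,
                       file.path(out_dir, "families.tsv"))
      write_tsv_atomic(res$families$expansion,
                       file.path(out_dir, "expansion_test.tsv"))
    }
    if ("motifs" %in% stages) {
      write_tsv_atomic(res$motifs$hits, file.path(out_dir, "motif_hits.tsv"))
    }
    if ("enrich" %in% stages) {
      write_tsv_atomic(res$enrich, file.path(out_dir, "enrichment.tsv"))
    }
    write_json_atomic(report, file.path(out_dir, "report.json"))
  }
  invisible(res)
}

#' Run the pipeline from a YAML configuration file
#'
#' A thin wrapper turning a YAML document of [simulation_config()] and
#' [run_pipeline()] arguments into a pipeline run. Recognized top-level
#' keys: `simulation` (passed to [simulation_config()]), `out_dir`,
#' `stages`, and any threshold argument of [run_pipeline()].
#'
#' @param path YAML file path.
#' @return See [run_pipeline()].
#' @export
run_pipeline_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, cfg$simulation %||% list())
  args <- cfg[setdiff(names(cfg), "simulation")]
  do.call(run_pipeline, c(list(input = sim), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
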