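# End-to-end orchestration: simulate (or load) -> catalog comparison ->
# lncRNA identification -> consensus differential expression -> fraction
# enrichment -> candidate intersection -> characterization -> co-expression
# -> final report. Every stage writes a TSV plus a log line with row counts
# (the discovery funnel), and completed stages are skipped on rerun when
# inputs and parameters are unchanged.

#' Pipeline configuration
#'
#' All thresholds default to the decision rules of the underlying study:
#' TPM > 1 and >= 2 exons and > 200 nt for candidate transcripts, FPKM
#' floor 0.1 for the fraction ratio, |log2FC| > 1 with adjusted p < 0.01
#' (or PPDE > 0.99) for differential expression, 5th/95th housekeeping
#' percentiles with >= 4 cell lines for enrichment, a +/- 1000 bp promoter
#' window, >= 2 cells and < 67% for lineage-specific embryo expression,
#' PCC >= 0.6 with p < 0.05 for partners, prevalence 0.2, k = 3 clusters,
#' and FPKM < 0.5 in >= 5 lines for the not-expressed flag.
#'
#' @param seed Integer seed for the simulated study.
#' @param outdir Output directory for stage TSVs.
#' @param generator A `generator_config` (defaults to
#'   `generator_config(seed)`).
#' @param input_dir Optional directory holding a study written by
#'   [write_simulation()]; when given, inputs are read from disk instead
#'   of being simulated in memory.
#' @param tpm_min,min_exons,min_length,fpkm_floor,lfc_min,de_alpha,ppde_min
#'   Candidate and DE thresholds.
#' @param percentiles,required_lines,min_housekeeping Enrichment thresholds.
#' @param promoter_window,embryo_min_cells,embryo_max_fraction Promoter and
#'   embryo thresholds.
#' @param pcc_min,coexpr_alpha,prevalence,k_clusters Co-expression
#'   thresholds.
#' @param ne_fpkm,ne_lines Not-expressed rule.
#' @param survival_alpha Survival significance cutoff.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("fracseq_run_"),
                            generator = generator_config(seed),
                            input_dir = NULL,
                            tpm_min = 1, min_exons = 2L, min_length = 200,
                            fpkm_floor = 0.1,
                            lfc_min = 1, de_alpha = 0.01, ppde_min = 0.99,
                            percentiles = c(0.05, 0.95), required_lines = 4L,
                            min_housekeeping = 30L,
                            promoter_window = 1000L,
                            embryo_min_cells = 2L, embryo_max_fraction = 0.67,
                            pcc_min = 0.6, coexpr_alpha = 0.05,
                            prevalence = 0.2, k_clusters = 3L,
                            ne_fpkm = 0.5, ne_lines = 5L,
                            survival_alpha = 0.05) {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(state, line)
}

# parameter fingerprint for stage skipping
.config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("outdir", "generator"))]
  gen <- unclass(config$generator)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(c(cfg, gen), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each writes its outputs under
#' `config$outdir`. A rerun with identical configuration detects the
#' stored configuration fingerprint and returns the previous results
#' without recomputation.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the stage results: `codes`, `support`,
#'   `lncrna_status`, `consensus`, `separation`, `enrichment_calls`,
#'   `reference_range`, `marker_report`, `candidates`, `edges`, `clusters`,
#'   `report`, `funnel` (log lines), `truth`.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("input directory does not exist: ", config$input_dir)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  state_file <- file.path(outdir, "pipeline_state.json")
  result_file <- file.path(outdir, "pipeline_result.rds")
  if (file.exists(state_file) && file.exists(result_file)) {
    st <- jsonlite::read_json(state_file)
    if (identical(st$config_hash, hash) && isTRUE(st$complete)) {
      message("[pipeline] configuration unchanged; reusing completed run")
      return(invisible(readRDS(result_file)))
    }
  }
  jsonlite::write_json(list(config_hash = hash, complete = FALSE),
                       state_file, auto_unbox = TRUE)
  log <- character(0)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 0: inputs -------------------------------------------------------
  sim <- if (is.null(config$input_dir)) simulate_study(config$generator)
         else read_simulation(config$input_dir)
  truth <- sim$truth
  log <- .stage_log(log, "simulate",
                    sprintf("%d genes, %d cell lines, %d tumor pairs",
                            nrow(truth), config$generator$n_cell_lines,
                            config$generator$n_tumor_pairs))

  # stage 1: catalog comparison ------------------------------------------
  assembled <- sim$catalogs$assembled
  codes <- assign_class_codes(assembled, sim$catalogs$reference)
  codes$reference_biotype <-
    truth$reference_biotype[match(codes$gene_id, truth$gene_id)]
  codes$reference_biotype[codes$class_code != "="] <- NA_character_
  support <- assembly_support_table(assembled, sim$cohort$sample_catalogs,
                                    sim$cohort$conditions)
  tsv(codes, "class_codes.tsv"); tsv(support, "assembly_support.tsv")
  log <- .stage_log(log, "catalog",
                    sprintf("%d assembled transcripts, %d with code '='",
                            nrow(codes), sum(codes$class_code == "=")))

  # stage 2: lncRNA identification ---------------------------------------
  cand_tx <- filter_candidates(assembled, sim$cohort$tpm, sim$catalogs$mask,
                               min_exons = config$min_exons,
                               min_length = config$min_length,
                               tpm_min = config$tpm_min)
  status <- classify_transcripts(cand_tx, codes, sim$cp_labels,
                                 required_predictors = unique(sim$cp_labels$predictor))
  tsv(status, "lncrna_status.tsv")
  lnc_tx <- status$transcript_id[status$category %in%
                                   c("annotated_lncRNA", "unannotated_lncRNA")]
  log <- .stage_log(log, "identify",
                    sprintf("%d candidate transcripts -> %d lncRNA (%d annotated, %d unannotated)",
                            length(cand_tx), length(lnc_tx),
                            sum(status$category == "annotated_lncRNA"),
                            sum(status$category == "unannotated_lncRNA")))

  # stage 3: consensus differential expression ---------------------------
  builtin <- builtin_de_test(sim$cohort$counts_tumor, sim$cohort$counts_adjacent)
  calls <- list(
    builtin_mwu = threshold_method(builtin, "fdr", config$lfc_min,
                                   config$de_alpha),
    sim_deseq = threshold_method(sim$method_tables$sim_deseq, "fdr",
                                 config$lfc_min, config$de_alpha),
    sim_ebseq = threshold_method(sim$method_tables$sim_ebseq, "ppde",
                                 config$lfc_min, ppde_min = config$ppde_min))
  consensus <- de_consensus(calls)
  tsv(consensus, "consensus_de.tsv")
  log <- .stage_log(log, "de",
                    sprintf("per-method calls %s -> consensus %d",
                            paste(vapply(calls, nrow, 0L), collapse = "/"),
                            nrow(consensus)))

  # dysregulated lncRNA transcripts separate tumor from adjacent samples
  dys_lnc <- intersect(consensus$transcript_id, lnc_tx)
  separation <- if (length(dys_lnc) >= 2L) {
    st <- ifelse(sim$cohort$conditions == "tumor", "tumor", "nontumor")
    names(st) <- colnames(sim$cohort$tpm)
    validate_separation(sim$cohort$tpm[dys_lnc, , drop = FALSE], st)
  } else NULL
  if (!is.null(separation))
    log <- .stage_log(log, "de",
                      sprintf("cluster-vs-status chi-square %.2f (p = %.3g) over %d dysregulated lncRNA transcripts",
                              separation$statistic, separation$p_value,
                              length(dys_lnc)))

  # stage 4: fraction enrichment -----------------------------------------
  all_fpkm <- cbind(sim$fractions$cyto, sim$fractions$nuc)
  colnames(all_fpkm) <- c(paste0(colnames(sim$fractions$cyto), "_cyto"),
                          paste0(colnames(sim$fractions$nuc), "_nuc"))
  norm <- normalize_fpkm(all_fpkm)
  nl <- ncol(sim$fractions$cyto)
  cyto_n <- norm[, seq_len(nl), drop = FALSE]
  nuc_n <- norm[, nl + seq_len(nl), drop = FALSE]
  colnames(cyto_n) <- colnames(nuc_n) <- colnames(sim$fractions$cyto)
  profiles <- compute_log_ratios(cyto_n, nuc_n, floor = config$fpkm_floor)
  rng <- reference_range(profiles, sim$fractions$housekeeping,
                         probs = config$percentiles,
                         min_genes = config$min_housekeeping)
  enrich <- classify_enrichment(profiles, rng,
                                required_lines = config$required_lines)
  markers <- validate_markers(enrich, c(GAPDH = "cytoplasmic_enriched",
                                        RPS14 = "cytoplasmic_enriched",
                                        MALAT1 = "nuclear_enriched"))
  tsv(enrich, "enrichment_calls.tsv")
  jsonlite::write_json(rng, file.path(outdir, "reference_range.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- .stage_log(log, "enrich",
                    sprintf("reference range [%.3f, %.3f] from %d housekeeping genes; %d nuclear / %d cytoplasmic; markers %s",
                            rng$lower_limit, rng$upper_limit,
                            rng$n_housekeeping_used,
                            sum(enrich$status == "nuclear_enriched"),
                            sum(enrich$status == "cytoplasmic_enriched"),
                            if (markers$overall_pass) "pass" else "FAIL"))

  # stage 5: candidate intersection --------------------------------------
  up_tx <- consensus$transcript_id[consensus$direction == "up_in_tumor"]
  up_lnc_tx <- intersect(up_tx, lnc_tx)
  up_genes <- unique(vapply(up_lnc_tx, function(id)
    assembled$transcripts[[id]]$gene_id, character(1)))
  nuclear_genes <- enrich$gene_id[enrich$status == "nuclear_enriched"]
  candidates <- sort(intersect(up_genes, nuclear_genes))
  writeLines(candidates, file.path(outdir, "candidates.txt"))
  log <- .stage_log(log, "intersect",
                    sprintf("%d tumor-up lncRNA genes x %d nuclear-enriched -> %d candidates",
                            length(up_genes), length(nuclear_genes),
                            length(candidates)))

  # stage 6: characterization --------------------------------------------
  promoter <- do.call(rbind, lapply(candidates, function(g) {
    hits <- promoter_mark_hits(assembled$transcripts[[paste0(g, ".t1")]],
                               sim$characterization$peak_sets,
                               window = config$promoter_window)
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(hits)))
  }))
  embryo_calls <- do.call(rbind, lapply(candidates, function(g) {
    ec <- embryo_expression_call(g, sim$characterization$embryo,
                                 supported = TRUE,
                                 tpm_min = config$tpm_min,
                                 max_fraction = config$embryo_max_fraction,
                                 min_cells = config$embryo_min_cells)
    cbind(gene_id = g, ec, stringsAsFactors = FALSE)
  }))
  surv <- survival_screen(sim$cohort$survival, candidates)
  report <- build_report(candidates, enrich, promoter, embryo_calls, surv,
                         cellline_fpkm = sim$fractions$cyto + sim$fractions$nuc,
                         ne_fpkm = config$ne_fpkm, ne_lines = config$ne_lines,
                         survival_alpha = config$survival_alpha)
  log <- .stage_log(log, "characterize",
                    sprintf("%d candidates, %d survival-significant at %.2f",
                            nrow(report), sum(report$survival_significant),
                            config$survival_alpha))

  # stage 7: co-expression -----------------------------------------------
  coexpr <- prevalence_filter(sim$coexpression$tpm, config$prevalence)
  have <- intersect(candidates, rownames(coexpr))
  edges <- clusters <- NULL
  if (length(have) >= 1L) {
    all_edges <- coexpression_edges(coexpr, have)
    edges <- select_partners(all_edges, config$pcc_min, config$coexpr_alpha)
    tsv(edges, "coexpression_edges.tsv")
    if (length(unique(edges$lncrna_gene)) >= config$k_clusters) {
      clusters <- cluster_candidates(partner_matrix(edges, all_edges),
                                     k = config$k_clusters)
      tsv(clusters, "coexpression_clusters.tsv")
    }
    log <- .stage_log(log, "coexpress",
                      sprintf("%d partner edges over %d candidates",
                              nrow(edges), length(unique(edges$lncrna_gene))))
  }

  tsv(report, "candidate_report.tsv")
  writeLines(log, file.path(outdir, "pipeline_log.txt"))
  result <- list(codes = codes, support = support, lncrna_status = status,
                 consensus = consensus, separation = separation,
                 enrichment_calls = enrich, reference_range = rng,
                 marker_report = markers, candidates = candidates,
                 edges = edges, clusters = clusters, report = report,
                 funnel = log, truth = truth)
  saveRDS(result, result_file)
  jsonlite::write_json(list(config_hash = hash, complete = TRUE),
                       state_file, auto_unbox = TRUE)
  invisible(result)
}

#' Read a simulated study back from disk
#'
#' Counterpart of [write_simulation()]: reconstructs the in-memory study
#' object (catalogs, matrices, tables, peak sets, truth) from the file
#' tree it wrote.
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list in the [simulate_study()] layout.
#' @export
read_simulation <- function(dir) {
  mat <- function(f) as.matrix(utils::read.delim(file.path(dir, f),
                                                 row.names = 1L,
                                                 check.names = FALSE))
  man <- utils::read.delim(file.path(dir, "sample_manifest.tsv"),
                           stringsAsFactors = FALSE)
  sample_catalogs <- lapply(man$path, function(p)
    read_catalog(file.path(dir, p)))
  names(sample_catalogs) <- sub("\\.gtf$", "", basename(man$path))
  method_files <- list.files(dir, pattern = "^de_.*\\.tsv$")
  method_tables <- lapply(method_files, function(f)
    read_de_results(file.path(dir, f)))
  names(method_tables) <- sub("^de_(.*)\\.tsv$", "\\1", method_files)
  truth <- as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                             simplifyVector = TRUE))
  list(
    catalogs = list(reference = read_catalog(file.path(dir, "reference.gtf")),
                    assembled = read_catalog(file.path(dir, "assembled.gtf")),
                    mask = NULL),
    fractions = list(cyto = mat("fpkm_cyto.tsv"), nuc = mat("fpkm_nuc.tsv"),
                     housekeeping = readLines(file.path(dir, "housekeeping.txt")),
                     truth = truth),
    cohort = list(counts_tumor = mat("counts_tumor.tsv"),
                  counts_adjacent = mat("counts_adjacent.tsv"),
                  tpm = mat("tpm.tsv"),
                  sample_catalogs = sample_catalogs,
                  conditions = man$condition,
                  survival = utils::read.delim(file.path(dir, "survival.tsv"),
                                               stringsAsFactors = FALSE),
                  truth = truth),
    method_tables = method_tables,
    characterization = list(
      peak_sets = read_peak_manifest(file.path(dir, "peak_manifest.tsv")),
      embryo = utils::read.delim(file.path(dir, "embryo_tpm.tsv"),
                                 stringsAsFactors = FALSE),
      truth = truth),
    coexpression = list(tpm = mat("coexpr_tpm.tsv"), truth = truth),
    cp_labels = utils::read.delim(file.path(dir, "cp_labels.tsv"),
                                  stringsAsFactors = FALSE),
    truth = truth)
}
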