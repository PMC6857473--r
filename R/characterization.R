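# Candidate characterization: active-promoter H3K4me3 marks per epigenome
# class, preimplantation embryo expression calls, Kaplan-Meier/log-rank
# survival screening, and the summary report joining all the evidence.

EMBRYO_STAGES <- c("oocyte", "zygote", "2cell", "4cell", "8cell",
                   "morula", "late_blastocyst")
PEAK_CATEGORIES <- c("ESC", "ESC_derived", "iPSC", "cancer")

#' Construct a peak set for one epigenome
#'
#' @param epigenome_id Identifier of the epigenome (cell line).
#' @param category One of `"ESC"`, `"ESC_derived"`, `"iPSC"`, `"cancer"`.
#' @param peaks data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) or a `GRanges`.
#' @return Object of class `peak_set`.
#' @export
peak_set <- function(epigenome_id, category, peaks) {
  category <- match.arg(category, PEAK_CATEGORIES)
  if (methods::is(peaks, "GRanges"))
    peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                        start = GenomicRanges::start(peaks) - 1L,
                        end = GenomicRanges::end(peaks),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(peaks$start < peaks$end))
  structure(list(epigenome_id = epigenome_id, category = category,
                 peaks = peaks), class = "peak_set")
}

#' Read peak sets from a manifest of BED files
#'
#' @param manifest_path TSV with columns `epigenome_id`, `category`, `path`
#'   (BED paths, absolute or relative to the manifest).
#' @return List of `peak_set` objects.
#' @export
read_peak_manifest <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    peak_set(man$epigenome_id[i], man$category[i], read_mask_bed(p))
  })
}

#' Promoter H3K4me3 hits per epigenome category
#'
#' Counts, per category, the epigenomes with at least one peak sharing at
#' least one base with the window `tss - window .. tss + window` (endpoints
#' inclusive, clipped at 0) around the transcript's 5' end (smallest
#' coordinate on `+`, largest on `-`).
#'
#' @param t A `transcript_model` with known strand.
#' @param peak_sets List of `peak_set` objects.
#' @param window Half-width in bp (default 1000).
#' @return Named integer vector over the four categories.
#' @export
promoter_mark_hits <- function(t, peak_sets, window = 1000L) {
  if (t$strand == "unknown")
    stop("promoter-mark analysis requires a known strand (transcript '",
         t$transcript_id, "')")
  tss <- if (t$strand == "+") t$exons[1L, 1L] else t$exons[nrow(t$exons), 2L]
  lo <- max(0, tss - window)  # window covers bases lo..hi inclusive
  hi <- tss + window
  counts <- stats::setNames(integer(length(PEAK_CATEGORIES)), PEAK_CATEGORIES)
  for (ps in peak_sets) {
    pk <- ps$peaks[ps$peaks$chrom == t$chrom, , drop = FALSE]
    if (nrow(pk) == 0L) next
    # peak covers bases start..end-1
    if (any(pk$start <= hi & pk$end - 1 >= lo))
      counts[ps$category] <- counts[ps$category] + 1L
  }
  counts
}

#' Per-stage embryo expression call for one gene
#'
#' A gene is `expressed` at a stage if >= 2 embryos there contain >= 1 cell
#' with TPM > 1; it is additionally `lineage_specific` if some embryo at
#' the stage has >= 2 expressing cells amounting to < 67% of its cells.
#' Stages with < 2 embryos are non-evaluable. Genes without assembly
#' support in any embryo dataset are filtered before calling.
#'
#' @param gene_id Gene to evaluate.
#' @param embryo_tpm data.frame with columns `stage`, `embryo_id`,
#'   `cell_id` and one numeric column per gene.
#' @param supported Logical: does the gene (or an isoform) have assembly
#'   support in the embryo datasets? `FALSE` short-circuits to a
#'   `"filtered"` result.
#' @param tpm_min,max_fraction,min_cells Call thresholds
#'   (defaults 1, 0.67, 2).
#' @return data.frame with one row per stage: `stage`, `n_embryos`,
#'   `expressed`, `lineage_specific`, `call` in
#'   `{expressed, lineage_specific, not_expressed, non_evaluable, filtered}`.
#' @export
embryo_expression_call <- function(gene_id, embryo_tpm, supported = TRUE,
                                   tpm_min = 1, max_fraction = 0.67,
                                   min_cells = 2L) {
  stages <- EMBRYO_STAGES
  out <- data.frame(stage = stages, n_embryos = 0L, expressed = NA,
                    lineage_specific = NA, call = "non_evaluable",
                    stringsAsFactors = FALSE)
  if (!supported) { out$call <- "filtered"; return(out) }
  if (!gene_id %in% names(embryo_tpm))
    stop("gene '", gene_id, "' absent from the embryo TPM table")
  for (si in seq_along(stages)) {
    d <- embryo_tpm[embryo_tpm$stage == stages[si], , drop = FALSE]
    embryos <- split(d[[gene_id]], d$embryo_id)
    out$n_embryos[si] <- length(embryos)
    if (length(embryos) < 2L) next
    n_expr_cells <- vapply(embryos, function(v) sum(v > tpm_min), integer(1))
    frac <- n_expr_cells / vapply(embryos, length, integer(1))
    expressed <- sum(n_expr_cells >= 1L) >= 2L
    lineage <- any(n_expr_cells >= min_cells & frac < max_fraction)
    out$expressed[si] <- expressed
    out$lineage_specific[si] <- lineage
    out$call[si] <- if (lineage) "lineage_specific"
      else if (expressed) "expressed" else "not_expressed"
  }
  out
}

#' Kaplan-Meier / log-rank survival screen for one gene
#'
#' Patients are split at the median expression of the gene (ties to the
#' low group); overall survival is compared between groups with the
#' two-group log-rank test (statistic (sum(O - E))^2 / sum(V), p from
#' chi-square with 1 df) and per-group Kaplan-Meier product-limit curves
#' are returned.
#'
#' @param time Numeric follow-up times (> 0).
#' @param event Event indicator: 1/TRUE = death observed, 0/FALSE = censored.
#' @param expression Numeric expression of the gene, one value per patient.
#' @param split Split rule; only `"median"` is implemented.
#' @return List with `p_value`, `statistic`, `group_sizes` (low/high),
#'   `km` (a `survival::survfit` object).
#' @export
km_logrank <- function(time, event, expression, split = "median") {
  split <- match.arg(split, "median")
  event <- as.integer(event)
  stopifnot(length(time) == length(event),
            length(time) == length(expression), all(time > 0))
  if (sum(event) < 1L) stop("all patients censored; log-rank undefined")
  if (stats::var(expression) == 0)
    stop("zero-variance expression; median split impossible")
  group <- factor(ifelse(expression > stats::median(expression),
                         "high", "low"), levels = c("low", "high"))
  if (min(table(group)) < 2L)
    stop("median split leaves < 2 patients in a group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  list(p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       statistic = unname(sd$chisq),
       group_sizes = table(group),
       km = fit)
}

#' Survival screen across candidate genes
#'
#' @param surv data.frame with `patient_id`, `time`, `event`, and one
#'   numeric column per gene.
#' @param genes Character vector of gene ids to screen.
#' @return data.frame with `gene_id`, `logrank_p`, `logrank_p_bh`
#'   (BH-adjusted across the screened genes).
#' @export
survival_screen <- function(surv, genes) {
  p <- vapply(genes, function(g) {
    if (!g %in% names(surv)) return(NA_real_)
    km_logrank(surv$time, surv$event, surv[[g]])$p_value
  }, numeric(1))
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(gene_id = genes, logrank_p = unname(p), logrank_p_bh = padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the candidate characterization report
#'
#' One row per candidate gene, merging the enrichment call, per-category
#' promoter-mark counts, per-stage embryo calls, the survival p-value, and
#' the "not expressed" flag (FPKM < `ne_fpkm` in >= `ne_lines` cell lines).
#' Rows are ordered by gene id.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param enrichment_calls data.frame from [classify_enrichment()]; every
#'   candidate must be present.
#' @param promoter_counts Optional data.frame: `gene_id` plus one integer
#'   column per peak category.
#' @param embryo_calls Optional data.frame: `gene_id`, `stage`, `call`.
#' @param survival_res Optional data.frame from [survival_screen()].
#' @param cellline_fpkm Optional matrix genes x cell lines for the
#'   not-expressed flag.
#' @param ne_fpkm,ne_lines Not-expressed rule (defaults 0.5, 5).
#' @param survival_alpha Significance cutoff reported in
#'   `survival_significant` (default 0.05).
#' @return data.frame, one row per candidate.
#' @export
build_report <- function(candidates, enrichment_calls,
                         promoter_counts = NULL, embryo_calls = NULL,
                         survival_res = NULL, cellline_fpkm = NULL,
                         ne_fpkm = 0.5, ne_lines = 5L,
                         survival_alpha = 0.05) {
  candidates <- sort(unique(candidates))
  if (length(candidates) == 0L)
    return(data.frame(gene_id = character(0), enrichment_status = character(0),
                      stringsAsFactors = FALSE))
  idx <- match(candidates, enrichment_calls$gene_id)
  if (anyNA(idx))
    stop("candidate(s) without an enrichment call: ",
         paste(candidates[is.na(idx)], collapse = ", "))
  rep_df <- data.frame(gene_id = candidates,
                       enrichment_status = enrichment_calls$status[idx],
                       mean_log2_ratio = enrichment_calls$mean_log2_ratio[idx],
                       stringsAsFactors = FALSE)
  for (cat in PEAK_CATEGORIES) {
    col <- paste0("h3k4me3_", cat)
    rep_df[[col]] <- if (is.null(promoter_counts)) NA_integer_ else
      promoter_counts[[cat]][match(candidates, promoter_counts$gene_id)]
  }
  for (st in EMBRYO_STAGES) {
    col <- paste0("embryo_", st)
    rep_df[[col]] <- if (is.null(embryo_calls)) NA_character_ else {
      e <- embryo_calls[embryo_calls$stage == st, , drop = FALSE]
      e$call[match(candidates, e$gene_id)]
    }
  }
  if (is.null(survival_res)) {
    rep_df$survival_p <- NA_real_
  } else {
    rep_df$survival_p <- survival_res$logrank_p[
      match(candidates, survival_res$gene_id)]
  }
  rep_df$survival_significant <- !is.na(rep_df$survival_p) &
    rep_df$survival_p < survival_alpha
  if (is.null(cellline_fpkm)) {
    rep_df$not_expressed <- NA
  } else {
    idx2 <- match(candidates, rownames(cellline_fpkm))
    nlow <- rowSums(cellline_fpkm < ne_fpkm)[idx2]
    rep_df$not_expressed <- !is.na(nlow) & nlow >= ne_lines
  }
  rep_df
}
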