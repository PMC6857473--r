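# Subcellular fraction enrichment: the core statistic of the pipeline.
#
# Per gene and cell line, the fraction-bias metric is
# log2(FPKM_cyto / FPKM_nuc): negative = nuclear bias, positive =
# cytoplasmic bias. A housekeeping-gene reference range (5th/95th
# percentiles of their mean log ratios) calibrates what counts as normal
# variation; genes beyond a limit in >= 4 cell lines are called enriched.

#' Median-of-ratios normalization of an FPKM matrix
#'
#' Per-library size factors computed DESeq-style: for genes positive in all
#' libraries, the per-library median of gene / geometric-mean ratios; each
#' column is divided by its factor. Genes not positive everywhere are
#' ignored for estimation but preserved in the output.
#'
#' @param raw Numeric matrix, genes x fraction libraries (>= 2 columns).
#' @return Normalized matrix with a `size_factors` attribute.
#' @export
normalize_fpkm <- function(raw) {
  if (ncol(raw) < 2L) stop("normalization requires >= 2 libraries")
  pos <- rowSums(raw > 0) == ncol(raw)
  if (!any(pos))
    stop("no gene is positive in all libraries; size factors undefined")
  logs <- log(raw[pos, , drop = FALSE])
  loggeo <- rowMeans(logs)
  sf <- apply(logs, 2L, function(col) exp(stats::median(col - loggeo)))
  out <- sweep(raw, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Per-gene cytoplasm/nucleus log ratios across cell lines
#'
#' A line's ratio is defined only when both fractions reach the expression
#' floor (default 0.1 FPKM); the per-gene mean is taken over lines with a
#' defined ratio.
#'
#' @param cyto,nuc Numeric matrices, genes x cell lines, with identical
#'   row and column names.
#' @param floor Minimum FPKM in *both* fractions for a line to count.
#' @return Object of class `fraction_profiles`: list with `ratios`
#'   (genes x lines, NA where undefined), `mean_log2_ratio`,
#'   `n_evaluable`, `floor`.
#' @export
compute_log_ratios <- function(cyto, nuc, floor = 0.1) {
  if (!identical(rownames(cyto), rownames(nuc)))
    stop("cyto and nuc matrices must share an identical gene index")
  if (!identical(colnames(cyto), colnames(nuc)))
    stop("cyto and nuc matrices must share identical cell-line columns")
  ok <- cyto >= floor & nuc >= floor
  ratios <- log2(cyto / nuc)
  ratios[!ok] <- NA_real_
  structure(
    list(ratios = ratios,
         mean_log2_ratio = rowMeans(ratios, na.rm = TRUE),
         n_evaluable = rowSums(ok),
         floor = floor),
    class = "fraction_profiles")
}

#' @export
print.fraction_profiles <- function(x, ...) {
  cat(sprintf("<fraction_profiles> %d gene(s) x %d cell line(s), floor %g\n",
              nrow(x$ratios), ncol(x$ratios), x$floor))
  invisible(x)
}

#' Housekeeping reference range for fraction bias
#'
#' Percentiles (default 5th and 95th) of the mean log2(cyto/nuc) ratios of
#' housekeeping genes, computed by linear interpolation between order
#' statistics (`stats::quantile` type 7; `type = "nearest"` uses type 1).
#'
#' @param profiles A `fraction_profiles` object.
#' @param housekeeping_ids Character vector of housekeeping gene ids.
#' @param probs Length-2 probabilities (default `c(0.05, 0.95)`).
#' @param min_genes Minimum evaluable housekeeping genes (default 30).
#' @param type Percentile convention: `"linear"` or `"nearest"`.
#' @return List with `lower_limit`, `upper_limit`, `n_housekeeping_used`,
#'   `percentiles`.
#' @export
reference_range <- function(profiles, housekeeping_ids,
                            probs = c(0.05, 0.95), min_genes = 30L,
                            type = c("linear", "nearest")) {
  type <- match.arg(type)
  means <- profiles$mean_log2_ratio
  hk <- means[intersect(housekeeping_ids, names(means))]
  hk <- hk[is.finite(hk)]
  if (length(hk) < min_genes)
    stop("only ", length(hk), " evaluable housekeeping gene(s); >= ",
         min_genes, " required")
  q <- stats::quantile(hk, probs = probs,
                       type = if (type == "linear") 7L else 1L, names = FALSE)
  if (q[1L] >= q[2L])
    stop("degenerate reference range (lower >= upper)")
  list(lower_limit = q[1L], upper_limit = q[2L],
       n_housekeeping_used = length(hk), percentiles = probs)
}

#' Classify genes by subcellular fraction enrichment
#'
#' A gene is `nuclear_enriched` if its ratio lies strictly below the lower
#' limit in >= `required_lines` cell lines, `cytoplasmic_enriched` if
#' strictly above the upper limit in >= `required_lines` lines,
#' `insufficient_data` with zero evaluable lines, else
#' `non_fraction_specific`. With `required_lines` above half the lines the
#' two enriched statuses are mutually exclusive by arithmetic.
#'
#' @param profiles A `fraction_profiles` object.
#' @param range Reference range from [reference_range()].
#' @param required_lines Minimum qualifying cell lines (default 4).
#' @return data.frame with `gene_id`, `status`, `mean_log2_ratio`,
#'   `n_lines_below_lower`, `n_lines_above_upper`, `n_lines_evaluable`.
#' @export
classify_enrichment <- function(profiles, range, required_lines = 4L) {
  n_lines <- ncol(profiles$ratios)
  if (required_lines < 1L || required_lines > n_lines)
    stop("required_lines must be between 1 and the number of cell lines (",
         n_lines, ")")
  below <- rowSums(profiles$ratios < range$lower_limit, na.rm = TRUE)
  above <- rowSums(profiles$ratios > range$upper_limit, na.rm = TRUE)
  nev <- profiles$n_evaluable
  status <- rep("non_fraction_specific", nrow(profiles$ratios))
  status[above >= required_lines] <- "cytoplasmic_enriched"
  status[below >= required_lines] <- "nuclear_enriched"
  status[nev == 0L] <- "insufficient_data"
  data.frame(gene_id = rownames(profiles$ratios), status = status,
             mean_log2_ratio = unname(profiles$mean_log2_ratio),
             n_lines_below_lower = as.integer(below),
             n_lines_above_upper = as.integer(above),
             n_lines_evaluable = as.integer(nev),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate enrichment calls against marker genes
#'
#' Classical fractionation markers (e.g. GAPDH and RPS14 cytoplasmic,
#' MALAT1 nuclear) should be recovered by the classification; missing
#' markers are reported, not fatal.
#'
#' @param calls data.frame from [classify_enrichment()].
#' @param markers Named character vector: names are gene ids, values the
#'   expected status.
#' @return List with `per_marker` data.frame (`gene_id`, `expected`,
#'   `observed`, `present`, `pass`) and `overall_pass`.
#' @export
validate_markers <- function(calls, markers) {
  if (length(markers) == 0L) {
    warning("empty marker map: vacuous pass")
    return(list(per_marker = data.frame(gene_id = character(0),
                                        expected = character(0),
                                        observed = character(0),
                                        present = logical(0),
                                        pass = logical(0)),
                overall_pass = TRUE))
  }
  obs <- calls$status[match(names(markers), calls$gene_id)]
  present <- !is.na(obs)
  if (any(!present))
    message("marker(s) absent from calls: ",
            paste(names(markers)[!present], collapse = ", "))
  per <- data.frame(gene_id = names(markers),
                    expected = unname(markers),
                    observed = ifelse(present, obs, NA_character_),
                    present = present,
                    pass = present & obs == unname(markers),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_marker = per, overall_pass = all(per$pass[per$present]))
}
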