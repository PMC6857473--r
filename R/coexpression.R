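# Co-expression partner analysis: pairwise Pearson correlation of candidate
# lncRNA genes against all other genes across tumor datasets, partner
# selection at PCC >= 0.6 and p < 0.05, and hierarchical clustering of the
# candidates by their partner-correlation profiles.

#' Prevalence filter on an expression matrix
#'
#' Keeps genes with a positive value in at least `min_fraction` of the
#' samples (>= comparison: exactly 20% passes at the default).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param min_fraction Minimum fraction of positive samples, in (0, 1\].
#' @return The filtered matrix.
#' @export
prevalence_filter <- function(expr, min_fraction = 0.2) {
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must lie in (0, 1]")
  if (nrow(expr) == 0L) stop("empty expression matrix")
  expr[rowMeans(expr > 0) >= min_fraction, , drop = FALSE]
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' r is clamped to \[-1, 1\] against rounding; p comes from
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 df (exactly 0 for |r| = 1). Zero
#' variance in either vector yields `pcc = NA`, `p = 1` with a warning.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return List with `pcc` and `p_value`.
#' @export
pcc_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance input: correlation undefined, reported non-significant")
    return(list(pcc = NA_real_, p_value = 1))
  }
  r <- max(-1, min(1, stats::cor(x, y)))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(pcc = r, p_value = p)
}

#' All candidate-vs-gene co-expression edges
#'
#' Correlates each candidate lncRNA gene with every other gene of the
#' (prevalence-filtered) matrix on `log2(x + 1)`-transformed values.
#'
#' @param expr Numeric matrix, genes x samples (TPM scale).
#' @param candidates Character vector of candidate gene ids (rows of `expr`).
#' @param log_transform Apply `log2(x + 1)` before correlating
#'   (default TRUE).
#' @return data.frame with `lncrna_gene`, `partner_gene`, `pcc`, `p_value`.
#' @export
coexpression_edges <- function(expr, candidates, log_transform = TRUE) {
  candidates <- intersect(candidates, rownames(expr))
  if (length(candidates) == 0L) stop("no candidate is present in the matrix")
  m <- if (log_transform) log2(expr + 1) else expr
  n <- ncol(m)
  partners <- setdiff(rownames(m), candidates)
  keep <- apply(m, 1L, stats::var) > 0
  cc <- suppressWarnings(
    stats::cor(t(m[candidates, , drop = FALSE]),
               t(m[partners, , drop = FALSE])))
  cc[!keep[candidates], ] <- NA
  cc[, !keep[partners]] <- NA
  r <- pmax(-1, pmin(1, as.vector(cc)))
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE))
  p[is.na(r)] <- 1
  data.frame(
    lncrna_gene = rep(candidates, times = length(partners)),
    partner_gene = rep(partners, each = length(candidates)),
    pcc = r, p_value = p,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select significant co-expression partners
#'
#' Keeps edges with `pcc >= pcc_min` (inclusive) and `p < alpha` (strict).
#' The default signed rule passes only positive correlations; `absolute =
#' TRUE` applies the threshold to |pcc|.
#'
#' @param edges data.frame from [coexpression_edges()].
#' @param pcc_min,alpha Thresholds (defaults 0.6, 0.05).
#' @param absolute Use |pcc| instead of signed pcc.
#' @return The selected subset of `edges`.
#' @export
select_partners <- function(edges, pcc_min = 0.6, alpha = 0.05,
                            absolute = FALSE) {
  v <- if (absolute) abs(edges$pcc) else edges$pcc
  keep <- !is.na(v) & v >= pcc_min & edges$p_value < alpha
  edges[keep, , drop = FALSE]
}

#' Partner-correlation matrix of the candidates
#'
#' @param edges Selected edges from [select_partners()].
#' @param all_edges Full edge set (to fill in correlations of candidates
#'   with partners selected via other candidates); defaults to `edges`.
#' @return Numeric matrix, candidates x union-of-partners, with missing
#'   entries as 0.
#' @export
partner_matrix <- function(edges, all_edges = edges) {
  cands <- sort(unique(edges$lncrna_gene))
  partners <- sort(unique(edges$partner_gene))
  m <- matrix(0, length(cands), length(partners),
              dimnames = list(cands, partners))
  sub <- all_edges[all_edges$lncrna_gene %in% cands &
                     all_edges$partner_gene %in% partners, , drop = FALSE]
  m[cbind(sub$lncrna_gene, sub$partner_gene)] <-
    ifelse(is.na(sub$pcc), 0, sub$pcc)
  m
}

#' Cluster candidate lncRNAs by partner profile
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) of the candidates' partner-PCC rows, cut into `k` clusters.
#' Cluster ids are renumbered in order of first appearance so the result
#' is deterministic.
#'
#' @param pm Numeric matrix, candidates x partners (missing entries 0).
#' @param k Number of clusters (default 3).
#' @return data.frame with `gene_id`, `cluster_id`.
#' @export
cluster_candidates <- function(pm, k = 3L) {
  if (k > nrow(pm))
    stop("k (", k, ") exceeds the number of candidates (", nrow(pm), ")")
  cl <- if (k == nrow(pm)) stats::setNames(seq_len(nrow(pm)), rownames(pm))
    else stats::cutree(stats::hclust(stats::dist(pm), method = "average"), k = k)
  relabel <- stats::setNames(seq_along(unique(cl)), unique(cl))
  data.frame(gene_id = names(cl),
             cluster_id = as.integer(relabel[as.character(cl)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
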