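# Consensus differential expression: per-method thresholding, a built-in
# nonparametric test, intersection, and the clustering/chi-square check that
# the dysregulated set separates tumor from nontumor samples.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values (monotone in rank order, capped at 1),
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Built-in nonparametric differential-expression test
#'
#' Library-size-scales the two count matrices to a common depth, computes a
#' per-transcript log2 fold change of pseudocounted means (tumor over
#' adjacent, pseudocount 0.5), and a two-sided Mann-Whitney U p-value
#' (exact when both groups are small and untied, tie-corrected normal
#' approximation otherwise), BH-adjusted across transcripts.
#'
#' @param counts_tumor,counts_adjacent Numeric count matrices with matching
#'   row (transcript) names and >= 2 samples each.
#' @return data.frame with `transcript_id`, `method` (`"builtin_mwu"`),
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `ppde` (NA).
#' @export
builtin_de_test <- function(counts_tumor, counts_adjacent) {
  if (ncol(counts_tumor) < 2L || ncol(counts_adjacent) < 2L)
    stop("at least 2 samples per condition are required")
  if (!identical(rownames(counts_tumor), rownames(counts_adjacent)))
    stop("count matrices must share an identical transcript index")
  depth <- c(colSums(counts_tumor), colSums(counts_adjacent))
  target <- mean(depth)
  tum <- sweep(counts_tumor, 2L, colSums(counts_tumor) / target, "/")
  adj <- sweep(counts_adjacent, 2L, colSums(counts_adjacent) / target, "/")
  lfc <- log2((rowMeans(tum) + 0.5) / (rowMeans(adj) + 0.5))
  p <- vapply(seq_len(nrow(tum)), function(i) {
    x <- tum[i, ]; y <- adj[i, ]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) return(1)
    .mwu_p(x, y)
  }, numeric(1))
  data.frame(transcript_id = rownames(tum), method = "builtin_mwu",
             log2_fold_change = unname(lfc), p_value = p,
             adjusted_p = bh_adjust(p), ppde = NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided Mann-Whitney U p-value. For tiny samples (C(n, n1) <= 100,
# e.g. 4 vs 4) the exact null distribution is enumerated over all group
# assignments of the midranks, so ties within a group do not force the
# normal approximation; otherwise wilcox.test decides (exact when both
# groups are small and untied, tie-corrected normal approximation
# otherwise).
.mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (choose(n1 + n2, n1) <= 100) {
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sets <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    lo <- mean(u_all <= u_obs + 1e-9)
    hi <- mean(u_all >= u_obs - 1e-9)
    return(min(1, 2 * min(lo, hi)))
  }
  suppressWarnings(stats::wilcox.test(x, y, correct = FALSE)$p.value)
}

#' Threshold one method's differential-expression results
#'
#' Rule `"fdr"`: |log2FC| > `lfc_min` and adjusted p < `alpha`.
#' Rule `"ppde"`: |log2FC| > `lfc_min` and PPDE > `ppde_min`.
#' Inequalities are strict, as printed; direction follows the fold-change
#' sign.
#'
#' @param results data.frame with `transcript_id`, `log2_fold_change`, and
#'   `adjusted_p` or `ppde` as the rule requires.
#' @param rule `"fdr"` or `"ppde"`.
#' @param lfc_min,alpha,ppde_min Thresholds (defaults 1, 0.01, 0.99).
#' @return data.frame with `transcript_id`, `direction`
#'   (`"up_in_tumor"`/`"down_in_tumor"`).
#' @export
threshold_method <- function(results, rule = c("fdr", "ppde"),
                             lfc_min = 1, alpha = 0.01, ppde_min = 0.99) {
  rule <- match.arg(rule)
  method <- if (!is.null(results$method)) results$method[1L] else "<unnamed>"
  stat <- switch(rule, fdr = results$adjusted_p, ppde = results$ppde)
  field <- switch(rule, fdr = "adjusted_p", ppde = "ppde")
  if (is.null(stat) || all(is.na(stat)))
    stop("method '", method, "': rule '", rule, "' requires field '", field, "'")
  ok <- !is.na(stat) & !is.na(results$log2_fold_change) &
    abs(results$log2_fold_change) > lfc_min &
    (if (rule == "fdr") stat < alpha else stat > ppde_min)
  data.frame(
    transcript_id = results$transcript_id[ok],
    direction = ifelse(results$log2_fold_change[ok] > 0,
                       "up_in_tumor", "down_in_tumor"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus of per-method differential-expression calls
#'
#' Intersection over transcript id with identical direction in every
#' call set; transcripts with conflicting directions across methods are
#' excluded (and reported via a message).
#'
#' @param calls List of >= 2 data.frames as returned by
#'   [threshold_method()], optionally named by method.
#' @return data.frame with `transcript_id`, `direction`, ordered by id.
#' @export
de_consensus <- function(calls) {
  if (length(calls) < 2L) stop("consensus requires >= 2 method call sets")
  ids <- Reduce(intersect, lapply(calls, `[[`, "transcript_id"))
  if (length(ids) == 0L)
    return(data.frame(transcript_id = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  dirs <- vapply(calls, function(cs)
    cs$direction[match(ids, cs$transcript_id)], character(length(ids)))
  dirs <- matrix(dirs, nrow = length(ids))
  agree <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  if (any(!agree))
    message(sum(!agree), " transcript(s) excluded from the consensus for ",
            "conflicting directions: ", paste(ids[!agree], collapse = ", "))
  out <- data.frame(transcript_id = ids[agree], direction = dirs[agree, 1L],
                    stringsAsFactors = FALSE)
  out[order(out$transcript_id), , drop = FALSE]
}

#' Read a per-method differential-expression result table
#'
#' TSV columns: `transcript_id`, `method`, `log2fc`, `pvalue`, `padj`,
#' `ppde` (empty fields allowed).
#'
#' @param path TSV file path.
#' @return data.frame in the [builtin_de_test()] column layout.
#' @export
read_de_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(transcript_id = as.character(df$transcript_id),
             method = as.character(df$method),
             log2_fold_change = as.numeric(df$log2fc),
             p_value = as.numeric(df$pvalue),
             adjusted_p = as.numeric(df$padj),
             ppde = as.numeric(df$ppde),
             stringsAsFactors = FALSE)
}

#' Validate that dysregulated lncRNAs separate tumor from nontumor samples
#'
#' Features are log2(TPM + 1)-transformed and standardized; samples are
#' clustered by average linkage on the 1 - Pearson correlation distance and
#' the 2-cluster cut is tested against the sample status with a chi-square
#' test of independence (1 df, no continuity correction). Zero-variance
#' features are dropped with a message.
#'
#' @param expr Numeric matrix over the dysregulated features
#'   (rows = features, cols = samples), TPM scale.
#' @param sample_status Character vector (`"tumor"`/`"nontumor"`), one per
#'   column, or a named vector matching the column names.
#' @return List with `clusters` (named integer vector), `table` (2x2),
#'   `statistic`, `p_value`.
#' @export
validate_separation <- function(expr, sample_status) {
  if (!is.null(names(sample_status)))
    sample_status <- sample_status[colnames(expr)]
  if (length(sample_status) != ncol(expr))
    stop("one status per sample column is required")
  if (min(table(sample_status)) < 2L || length(unique(sample_status)) != 2L)
    stop("need two status groups with >= 2 samples each")
  if (nrow(expr) < 2L) stop("need >= 2 features")
  m <- log2(expr + 1)
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance feature(s) dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("all features have zero variance")
  m <- t(scale(t(m)))
  d <- stats::as.dist(1 - stats::cor(m))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
  tab <- table(cluster = cl, status = sample_status)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(clusters = cl, table = tab,
       statistic = unname(ct$statistic), p_value = ct$p.value)
}
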