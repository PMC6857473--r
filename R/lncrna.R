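# lncRNA identification: filter cascade and dual coding-potential consensus.

#' Candidate filter cascade for lncRNA discovery
#'
#' Retains transcripts with >= `min_exons` exons, spliced length >
#' `min_length` nt, known strand, maximum TPM across samples > `tpm_min`,
#' and a repeat-masked fraction of exonic bases <= `max_repeat_fraction`
#' (default 0: no exonic base inside the mask). The five filters commute;
#' a transcript missing from the expression matrix is treated as TPM 0.
#'
#' @param catalog A `transcript_catalog`.
#' @param expr Numeric matrix of TPM, rows = transcript ids, cols = samples.
#' @param mask Optional repeat mask: `GRanges`, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), or `NULL`.
#' @param min_exons,min_length,tpm_min,max_repeat_fraction Filter thresholds.
#' @return Character vector of retained transcript ids, with attribute
#'   `rejections`: data.frame (`transcript_id`, `reason`) for the rest.
#' @export
filter_candidates <- function(catalog, expr, mask = NULL,
                              min_exons = 2L, min_length = 200,
                              tpm_min = 1, max_repeat_fraction = 0) {
  mask_df <- .as_mask_df(mask)
  ids <- catalog_ids(catalog)
  missing_expr <- setdiff(ids, rownames(expr))
  if (length(missing_expr))
    message(length(missing_expr),
            " transcript(s) missing from the TPM matrix; treated as TPM 0")
  reasons <- character(0); rejected <- character(0)
  keep <- logical(length(ids)); names(keep) <- ids
  for (id in ids) {
    t <- catalog$transcripts[[id]]
    reason <- NA_character_
    if (nrow(t$exons) < min_exons) reason <- "mono-exonic"
    else if (transcript_length(t) <= min_length) reason <- "short"
    else if (t$strand == "unknown") reason <- "no_strand"
    else {
      tpm <- if (id %in% rownames(expr)) max(expr[id, ]) else 0
      if (!(tpm > tpm_min)) reason <- "low_expression"
      else if (.repeat_fraction(t, mask_df) > max_repeat_fraction)
        reason <- "repeat_masked"
    }
    if (is.na(reason)) keep[id] <- TRUE
    else { rejected <- c(rejected, id); reasons <- c(reasons, reason) }
  }
  structure(ids[keep],
            rejections = data.frame(transcript_id = rejected, reason = reasons,
                                    stringsAsFactors = FALSE))
}

.as_mask_df <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (methods::is(mask, "GRanges")) {
    if (length(mask) == 0L) return(NULL)
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(mask)),
                      start = GenomicRanges::start(mask) - 1L,
                      end = GenomicRanges::end(mask),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(mask), all(c("chrom", "start", "end") %in% names(mask)))
  if (nrow(mask) == 0L) NULL else mask
}

# fraction of exonic bases covered by the mask
.repeat_fraction <- function(t, mask_df) {
  if (is.null(mask_df)) return(0)
  m <- mask_df[mask_df$chrom == t$chrom, , drop = FALSE]
  if (nrow(m) == 0L) return(0)
  covered <- 0
  for (i in seq_len(nrow(t$exons))) {
    e <- t$exons[i, ]
    ov <- pmin(e[2L], m$end) - pmax(e[1L], m$start)
    covered <- covered + sum(pmax(0, ov))
  }
  covered / transcript_length(t)
}

#' Read a repeat mask from BED
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Classify candidate transcripts into lncRNA categories
#'
#' Class code `"="` with reference biotype `lincRNA`/`antisense` gives
#' `annotated_lncRNA`; `"="` with `protein_coding` gives `protein_coding`;
#' any other code is unannotated and kept as `unannotated_lncRNA` only if
#' every required coding-potential predictor labels it `noncoding`,
#' otherwise rejected with reason `"coding_potential"`. An `"="` match to
#' any other biotype is rejected with reason `"annotated_other_biotype"`.
#'
#' @param candidates Character vector of transcript ids.
#' @param codes data.frame with `transcript_id`, `class_code`, and
#'   `reference_biotype` (NA for non-`"="` codes).
#' @param cp_labels data.frame with `transcript_id`, `predictor`, `label`
#'   (`"noncoding"`/`"coding"`).
#' @param required_predictors Character vector of predictor names whose
#'   unanimous `noncoding` label is required for unannotated lncRNAs.
#' @return data.frame with `transcript_id`, `class_code`,
#'   `reference_biotype`, `category`, `rejection_reason`.
#' @export
classify_transcripts <- function(candidates, codes, cp_labels,
                                 required_predictors) {
  stopifnot(length(required_predictors) >= 1L)
  miss <- setdiff(candidates, codes$transcript_id)
  if (length(miss))
    stop("candidates without a class code: ", paste(miss, collapse = ", "))
  codes <- codes[match(candidates, codes$transcript_id), , drop = FALSE]
  unannotated <- candidates[codes$class_code != "="]
  for (p in required_predictors) {
    have <- cp_labels$transcript_id[cp_labels$predictor == p]
    miss <- setdiff(unannotated, have)
    if (length(miss))
      stop("missing '", p, "' coding-potential label for: ",
           paste(miss, collapse = ", "))
  }
  category <- character(length(candidates))
  reason <- rep(NA_character_, length(candidates))
  for (i in seq_along(candidates)) {
    id <- candidates[i]
    if (codes$class_code[i] == "=") {
      bt <- codes$reference_biotype[i]
      if (!is.na(bt) && bt %in% c("lincRNA", "antisense")) {
        category[i] <- "annotated_lncRNA"
      } else if (!is.na(bt) && bt == "protein_coding") {
        category[i] <- "protein_coding"
      } else {
        category[i] <- "rejected"; reason[i] <- "annotated_other_biotype"
      }
    } else {
      lab <- cp_labels$label[cp_labels$transcript_id == id &
                               cp_labels$predictor %in% required_predictors]
      if (length(lab) >= length(required_predictors) && all(lab == "noncoding")) {
        category[i] <- "unannotated_lncRNA"
      } else {
        category[i] <- "rejected"; reason[i] <- "coding_potential"
      }
    }
  }
  data.frame(transcript_id = candidates, class_code = codes$class_code,
             reference_biotype = codes$reference_biotype,
             category = category, rejection_reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Built-in open-reading-frame coding-potential predictor
#'
#' A deliberately simple stand-in for external coding-potential tools so
#' that synthetic runs need no dependencies: the spliced transcript sequence
#' (reverse-complemented for minus-strand transcripts) is scanned in its
#' three sense frames and labelled `coding` iff the longest ATG-initiated,
#' stop-terminated open reading frame reaches `min_aa` amino acids
#' (stop excluded).
#'
#' @param t A `transcript_model`.
#' @param genome Named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences.
#' @param min_aa Minimum ORF length in amino acids (default 100).
#' @return List with `transcript_id`, `predictor` (`"builtin_orf"`),
#'   `label`, and `longest_orf_aa`.
#' @export
builtin_orf_predictor <- function(t, genome, min_aa = 100L) {
  chrom_seq <- if (methods::is(genome, "DNAStringSet"))
    as.character(genome[[t$chrom]]) else genome[[t$chrom]]
  if (is.null(chrom_seq)) stop("genome lacks chromosome '", t$chrom, "'")
  if (max(t$exons[, 2]) > nchar(chrom_seq))
    stop("transcript '", t$transcript_id, "' extends beyond chromosome '",
         t$chrom, "' (", nchar(chrom_seq), " nt)")
  pieces <- substring(chrom_seq, t$exons[, 1] + 1L, t$exons[, 2])
  tx_seq <- paste(pieces, collapse = "")
  if (t$strand == "-")
    tx_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))
  longest <- .longest_orf_aa(tx_seq)
  list(transcript_id = t$transcript_id, predictor = "builtin_orf",
       label = if (longest >= min_aa) "coding" else "noncoding",
       longest_orf_aa = longest)
}

# longest ATG..stop ORF (aa count, stop excluded) over the 3 forward frames
.longest_orf_aa <- function(seq) {
  best <- 0L
  n <- nchar(seq)
  for (frame in 0:2) {
    if (n - frame < 3L) next
    sub <- substr(seq, frame + 1L, frame + 3L * ((n - frame) %/% 3L))
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(sub),
                            if.fuzzy.codon = "X")))
    m <- gregexpr("M[^*]*\\*", aa)[[1L]]
    if (m[1L] != -1L)
      best <- max(best, attr(m, "match.length") - 1L)
  }
  best
}
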