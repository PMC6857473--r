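# Transcript catalog data model and intron-chain comparison.
#
# Internal coordinates are 0-based half-open [start, end); GTF I/O converts
# from/to the 1-based inclusive convention of the format. Transcript
# equivalence throughout the package is *intron-chain identity* on
# (chrom, strand): terminal exon ends are assembler-sensitive and are
# deliberately ignored. Mono-exonic transcripts have an empty intron chain
# and therefore never match under this notion; they are excluded upstream
# by the lncRNA filter in any case.

#' Construct a transcript model
#'
#' The unit of catalog comparison: an exon-structured transcript on a genome
#' with strand. Exons use 0-based half-open coordinates.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"unknown"`.
#' @param exons Two-column numeric matrix (start, end), 0-based half-open,
#'   sorted ascending, non-overlapping, introns of positive length.
#' @param source_label Free-text provenance label.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             source_label = "") {
  if (!is.matrix(exons)) exons <- matrix(as.numeric(exons), ncol = 2, byrow = TRUE)
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L)
    stop("transcript '", transcript_id, "': exons must be non-empty")
  if (any(exons[, 1] >= exons[, 2]))
    stop("transcript '", transcript_id, "': each exon must have start < end")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1], strictly = TRUE))
      stop("transcript '", transcript_id, "': exons must be sorted ascending")
    if (any(exons[-1L, 1] < exons[-nrow(exons), 2] + 1L))
      stop("transcript '", transcript_id, "': introns must have positive length")
  }
  strand <- match.arg(strand, c("+", "-", "unknown"))
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         source_label = as.character(source_label)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Spliced transcript length (summed exon length)
#' @param t A `transcript_model`.
#' @return Integer-valued scalar.
#' @export
transcript_length <- function(t) sum(t$exons[, 2] - t$exons[, 1])

#' Intron chain of a transcript
#'
#' Gaps between consecutive exons, 0-based half-open; empty (0-row) matrix
#' for mono-exonic transcripts.
#'
#' @param t A `transcript_model`.
#' @return Two-column matrix of intron intervals.
#' @export
intron_chain <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = t$exons[-n, 2], end = t$exons[-1L, 1])
}

# Canonical string key for intron-chain identity on (chrom, strand).
# NA for mono-exonic transcripts (never matchable).
chain_key <- function(t) {
  ic <- intron_chain(t)
  if (nrow(ic) == 0L) return(NA_character_)
  paste(t$chrom, t$strand, paste(ic[, 1], ic[, 2], sep = "-", collapse = ","),
        sep = "|")
}

#' Construct a transcript catalog
#'
#' @param transcripts List of `transcript_model` objects with unique ids.
#' @return An object of class `transcript_catalog` with a gene index
#'   mapping `gene_id` to member transcript ids.
#' @export
transcript_catalog <- function(transcripts = list()) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  genes <- vapply(transcripts, `[[`, "", "gene_id")
  gene_index <- split(ids, genes)
  structure(list(transcripts = transcripts, gene_index = gene_index),
            class = "transcript_catalog")
}

#' @export
length.transcript_catalog <- function(x) length(x$transcripts)

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("<transcript_catalog> %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(x$gene_index)))
  invisible(x)
}

#' Transcript ids of a catalog
#' @param catalog A `transcript_catalog`.
#' @return Character vector.
#' @export
catalog_ids <- function(catalog) names(catalog$transcripts)

#' Subset a catalog by transcript id
#' @param catalog A `transcript_catalog`.
#' @param ids Transcript ids to keep.
#' @return A `transcript_catalog`.
#' @export
catalog_subset <- function(catalog, ids) {
  transcript_catalog(catalog$transcripts[intersect(names(catalog$transcripts), ids)])
}

#' Read a transcript catalog from GTF
#'
#' Exon records are grouped per transcript; 1-based inclusive GTF coordinates
#' become internal 0-based half-open; a `"."` strand maps to `"unknown"`.
#'
#' @param path GTF file path.
#' @param dialect Only `"gtf"` is supported.
#' @param source_label Provenance label stored on every transcript
#'   (defaults to the file name).
#' @return A `transcript_catalog`.
#' @export
read_catalog <- function(path, dialect = "gtf", source_label = basename(path)) {
  dialect <- match.arg(dialect, "gtf")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    return(transcript_catalog())
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) return(transcript_catalog())
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id) ||
      anyNA(mc$transcript_id) || anyNA(mc$gene_id))
    stop("GTF '", path, "': exon records must carry transcript_id and gene_id")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx = as.character(mc$transcript_id),
    gene = as.character(mc$gene_id),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "unknown"
  txs <- lapply(split(df, df$tx), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    transcript_model(d$tx[1L], d$gene[1L], d$chrom[1L], d$strand[1L],
                     cbind(d$start, d$end), source_label = source_label)
  })
  transcript_catalog(unname(txs))
}

#' Write a transcript catalog to GTF
#'
#' @param catalog A `transcript_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  txs <- catalog$transcripts[order(names(catalog$transcripts))]
  if (length(txs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- lapply(txs, function(t) {
    st <- if (t$strand == "unknown") "*" else t$strand
    data.frame(chrom = t$chrom, start = t$exons[, 1] + 1L, end = t$exons[, 2],
               strand = st, tx = t$transcript_id, gene = t$gene_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = "exon", gene_id = df$gene, transcript_id = df$tx)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# helpers for class-code geometry ------------------------------------------

.span <- function(t) c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])

.intervals_overlap <- function(a, b) a[1L] < b[2L] && b[1L] < a[2L]

.exonic_overlap <- function(q, r) {
  for (i in seq_len(nrow(q$exons)))
    for (j in seq_len(nrow(r$exons)))
      if (.intervals_overlap(q$exons[i, ], r$exons[j, ])) return(TRUE)
  FALSE
}

# is `sub` a contiguous sub-chain of `full`? (both k x 2 matrices, k >= 1)
.is_subchain <- function(sub, full) {
  ns <- nrow(sub); nf <- nrow(full)
  if (ns > nf) return(FALSE)
  for (off in 0:(nf - ns)) {
    if (all(sub == full[seq_len(ns) + off, , drop = FALSE])) return(TRUE)
  }
  FALSE
}

#' Assign a transfrag-style class code
#'
#' Compares a multi-exonic query transcript against a reference catalog and
#' returns one of the codes `=`, `c`, `j`, `i`, `x`, `o`, `u`, decided in
#' that precedence order:
#' \itemize{
#'   \item `=` identical intron chain with a same-strand reference;
#'   \item `c` query chain is a contiguous sub-chain of a same-strand
#'     reference chain and the query span lies within the reference span;
#'   \item `j` at least one splice junction (identical intron interval)
#'     shared with a same-strand reference;
#'   \item `i` query span entirely within an intron of a reference
#'     transcript (either strand);
#'   \item `x` exonic overlap with reference transcripts only on the
#'     opposite strand;
#'   \item `o` any exonic overlap with a same-strand reference;
#'   \item `u` none of the above (intergenic).
#' }
#'
#' @param query A multi-exonic `transcript_model` with known strand.
#' @param reference A `transcript_catalog` (may be empty).
#' @return Single character code.
#' @export
assign_class_code <- function(query, reference) {
  if (query$strand == "unknown")
    stop("class-code assignment requires a known query strand (transcript '",
         query$transcript_id, "')")
  qic <- intron_chain(query)
  qspan <- .span(query)
  # every non-"u" relation requires the reference span to overlap the query
  # span, so distant transcripts can be dropped up front
  refs <- Filter(function(r) r$chrom == query$chrom &&
                   .intervals_overlap(.span(r), qspan), reference$transcripts)
  same <- Filter(function(r) r$strand == query$strand, refs)
  opp <- Filter(function(r) r$strand != query$strand &&
                  r$strand != "unknown", refs)

  if (nrow(qic) > 0L) {
    for (r in same) {
      ric <- intron_chain(r)
      if (nrow(ric) == nrow(qic) && all(ric == qic)) return("=")
    }
    for (r in same) {
      ric <- intron_chain(r)
      if (nrow(ric) >= nrow(qic) && .is_subchain(qic, ric)) {
        rspan <- .span(r)
        if (qspan[1L] >= rspan[1L] && qspan[2L] <= rspan[2L]) return("c")
      }
    }
    qj <- paste(qic[, 1], qic[, 2])
    for (r in same) {
      ric <- intron_chain(r)
      if (nrow(ric) > 0L && any(paste(ric[, 1], ric[, 2]) %in% qj)) return("j")
    }
  }
  for (r in refs) {
    ric <- intron_chain(r)
    for (k in seq_len(nrow(ric)))
      if (qspan[1L] >= ric[k, 1L] && qspan[2L] <= ric[k, 2L]) return("i")
  }
  same_ov <- any(vapply(same, function(r) .exonic_overlap(query, r), logical(1)))
  opp_ov <- any(vapply(opp, function(r) .exonic_overlap(query, r), logical(1)))
  if (opp_ov && !same_ov) return("x")
  if (same_ov) return("o")
  "u"
}

#' Class codes for every transcript of a catalog
#'
#' @param query_catalog,reference `transcript_catalog` objects.
#' @return data.frame with columns `transcript_id`, `gene_id`, `class_code`.
#' @export
assign_class_codes <- function(query_catalog, reference) {
  ids <- catalog_ids(query_catalog)
  # span index over the reference: only span-overlapping transcripts on the
  # same chromosome can yield a non-"u" code, so each query is compared
  # against a small pre-filtered sub-catalog
  rmods <- reference$transcripts
  rchrom <- vapply(rmods, `[[`, "", "chrom")
  rstart <- vapply(rmods, function(r) r$exons[1L, 1L], numeric(1))
  rend <- vapply(rmods, function(r) r$exons[nrow(r$exons), 2L], numeric(1))
  codes <- vapply(query_catalog$transcripts, function(q) {
    qs <- .span(q)
    near <- rchrom == q$chrom & rstart < qs[2L] & qs[1L] < rend
    assign_class_code(q, structure(list(transcripts = rmods[near]),
                                   class = "transcript_catalog"))
  }, character(1))
  data.frame(transcript_id = ids,
             gene_id = vapply(query_catalog$transcripts, `[[`, "", "gene_id"),
             class_code = unname(codes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect two assemblies by intron-chain identity
#'
#' Returns the transcripts of `a` whose (chrom, strand, intron chain) exactly
#' matches some transcript of `b`. Identifiers and exon coordinates of `a`
#' are kept; terminal exon ends need not match. Mono-exonic transcripts are
#' never matched (intron-chain identity is undefined for them).
#'
#' @param a,b `transcript_catalog` objects in the same coordinate space.
#' @return A `transcript_catalog` (subset of `a`).
#' @export
intersect_assemblies <- function(a, b) {
  keys_b <- vapply(b$transcripts, chain_key, character(1))
  keys_b <- keys_b[!is.na(keys_b)]
  keys_a <- vapply(a$transcripts, chain_key, character(1))
  keep <- !is.na(keys_a) & keys_a %in% keys_b
  transcript_catalog(unname(a$transcripts[keep]))
}

#' Per-condition assembly support of a transcript
#'
#' Counts, separately for tumor and adjacent sample catalogs, how many
#' contain a transcript with identical (chrom, strand, intron chain).
#'
#' @param t A `transcript_model`.
#' @param sample_catalogs List of `transcript_catalog` objects.
#' @param conditions Character vector (`"tumor"`/`"adjacent"`), one per catalog.
#' @return List with `transcript_id`, `tumor_support`, `adjacent_support`.
#' @export
assembly_support <- function(t, sample_catalogs, conditions) {
  if (length(conditions) != length(sample_catalogs))
    stop("one condition label is required per sample catalog")
  if (!all(conditions %in% c("tumor", "adjacent")))
    stop("conditions must be 'tumor' or 'adjacent'")
  key <- chain_key(t)
  hit <- if (is.na(key)) rep(FALSE, length(sample_catalogs)) else
    vapply(sample_catalogs, function(cat) {
      key %in% vapply(cat$transcripts, chain_key, character(1))
    }, logical(1))
  list(transcript_id = t$transcript_id,
       tumor_support = sum(hit & conditions == "tumor"),
       adjacent_support = sum(hit & conditions == "adjacent"))
}

#' Assembly support for every transcript of a catalog
#'
#' @param catalog Target `transcript_catalog`.
#' @param sample_catalogs,conditions As in [assembly_support()].
#' @return data.frame with `transcript_id`, `tumor_support`, `adjacent_support`.
#' @export
assembly_support_table <- function(catalog, sample_catalogs, conditions) {
  if (length(conditions) != length(sample_catalogs))
    stop("one condition label is required per sample catalog")
  if (!all(conditions %in% c("tumor", "adjacent")))
    stop("conditions must be 'tumor' or 'adjacent'")
  sample_keys <- lapply(sample_catalogs, function(cat)
    stats::na.omit(vapply(cat$transcripts, chain_key, character(1))))
  keys <- vapply(catalog$transcripts, chain_key, character(1))
  hits <- vapply(sample_keys, function(sk) !is.na(keys) & keys %in% sk,
                 logical(length(keys)))
  hits <- matrix(hits, nrow = length(keys))
  data.frame(
    transcript_id = catalog_ids(catalog),
    tumor_support = as.integer(rowSums(hits[, conditions == "tumor", drop = FALSE])),
    adjacent_support = as.integer(rowSums(hits[, conditions == "adjacent", drop = FALSE])),
    row.names = NULL, stringsAsFactors = FALSE)
}
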