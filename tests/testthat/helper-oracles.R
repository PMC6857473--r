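# Independent brute-force oracles and small fixture builders.
# These deliberately use different primitives (explicit base-set
# enumeration, hand-tabulated formulas) than the package implementation.

# terse transcript builder
tx <- function(id, exons, strand = "+", chrom = "chr1", gene = paste0("g_", id)) {
  transcript_model(id, gene, chrom, strand, exons)
}

ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# --- brute-force class-code oracle (base-set logic) -----------------------

.o_bases <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)), function(i)
    seq(exons[i, 1], exons[i, 2] - 1)))
}
.o_introns <- function(exons) {
  if (nrow(exons) < 2) return(list())
  lapply(seq_len(nrow(exons) - 1), function(i) c(exons[i, 2], exons[i + 1, 1]))
}
.o_same_chain <- function(a, b) {
  length(a) == length(b) && all(mapply(function(x, y) all(x == y), a, b))
}
.o_contiguous_sub <- function(sub, full) {
  ns <- length(sub); nf <- length(full)
  if (ns == 0 || ns > nf) return(FALSE)
  any(vapply(0:(nf - ns), function(off)
    .o_same_chain(sub, full[off + seq_len(ns)]), logical(1)))
}

oracle_class_code <- function(q, refs) {
  refs <- Filter(function(r) r$chrom == q$chrom, refs)
  same <- Filter(function(r) r$strand == q$strand, refs)
  opp <- Filter(function(r) r$strand != q$strand && r$strand != "unknown", refs)
  qi <- .o_introns(q$exons)
  qb <- .o_bases(q$exons)
  span <- c(min(qb), max(qb))  # first/last exonic base
  if (length(qi) > 0) {
    for (r in same) if (.o_same_chain(qi, .o_introns(r$exons))) return("=")
    for (r in same) {
      ri <- .o_introns(r$exons)
      rb <- .o_bases(r$exons)
      if (.o_contiguous_sub(qi, ri) &&
          span[1] >= min(rb) && span[2] <= max(rb)) return("c")
    }
    for (r in same) {
      ri <- .o_introns(r$exons)
      shared <- any(vapply(qi, function(a)
        any(vapply(ri, function(b) all(a == b), logical(1))), logical(1)))
      if (shared) return("j")
    }
  }
  for (r in refs) {
    for (iv in .o_introns(r$exons))
      if (span[1] >= iv[1] && span[2] <= iv[2] - 1) return("i")
  }
  same_ov <- any(vapply(same, function(r)
    length(intersect(qb, .o_bases(r$exons))) > 0, logical(1)))
  opp_ov <- any(vapply(opp, function(r)
    length(intersect(qb, .o_bases(r$exons))) > 0, logical(1)))
  if (opp_ov && !same_ov) return("x")
  if (same_ov) return("o")
  "u"
}

# --- hand-tabulated two-group log-rank oracle -----------------------------

oracle_logrank <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# --- Kaplan-Meier product-limit oracle (no ties in censoring needed) ------

oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# --- brute-force ORF scan over the three sense frames ---------------------

oracle_longest_orf <- function(seq) {
  best <- 0L
  n <- nchar(seq)
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at) && codons[k] == "ATG") open_at <- k
      if (!is.na(open_at) && codons[k] %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}

# --- BH step-up oracle ----------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- exhaustive permutations (for permutation-test oracles) --------------

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# small reduced generator config for module-level tests
small_config <- function(seed = 7L, ...) {
  generator_config(seed = seed, n_genes = 400L, n_lncrna = 80L,
                   n_housekeeping = 60L, planted_nuclear = 30L,
                   planted_cytoplasmic = 30L, planted_de = 20L,
                   n_candidates = 5L, planted_prognostic = 5L,
                   partners_per_factor = 10L, n_patients = 120L,
                   n_coexpr_samples = 60L, n_tumor_pairs = 8L,
                   n_tumor_specific = 3L, ...)
}
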