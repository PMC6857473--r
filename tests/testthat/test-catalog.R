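# Transcript catalog model, GTF I/O, intron chains, class codes,
# assembly intersection and per-condition support.

test_that("GTF reading converts 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    f)
  cat <- read_catalog(f)
  expect_length(cat, 1L)
  t1 <- cat$transcripts[["T1"]]
  expect_equal(unname(t1$exons), rbind(c(100, 200), c(300, 400)))
  expect_equal(t1$gene_id, "G1")
  expect_equal(t1$strand, "+")
})

test_that("empty GTF gives an empty catalog; malformed coordinates error", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(0), f)
  expect_length(read_catalog(f), 0L)
  writeLines('chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id "G"; transcript_id "T";', f)
  expect_error(read_catalog(f))
})

test_that("GTF round-trip preserves coordinates, strand and ids", {
  cat1 <- transcript_catalog(list(
    tx("A", ex(100, 200, 300, 400), "+"),
    tx("B", ex(50, 150, 200, 320), "-", chrom = "chr2"),
    tx("C", ex(10, 500), "unknown")))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_catalog(cat1, f)
  cat2 <- read_catalog(f)
  for (id in c("A", "B", "C")) {
    expect_equal(unname(cat2$transcripts[[id]]$exons),
                 unname(cat1$transcripts[[id]]$exons), info = id)
    expect_equal(cat2$transcripts[[id]]$strand, cat1$transcripts[[id]]$strand)
  }
})

test_that("transcript_model enforces exon invariants", {
  expect_error(tx("bad", ex(200, 100)), "start < end")
  expect_error(tx("bad", ex(100, 200, 150, 300)), "sorted|positive")
  expect_error(tx("bad", ex(100, 200, 200, 300)), "positive")
  expect_error(transcript_catalog(list(tx("A", ex(0, 10)), tx("A", ex(0, 10)))),
               "duplicate")
})

test_that("intron_chain returns inter-exon gaps", {
  expect_equal(unname(intron_chain(tx("a", ex(100, 200, 300, 400)))),
               rbind(c(200, 300)))
  expect_equal(nrow(intron_chain(tx("b", ex(0, 50)))), 0L)
  expect_equal(unname(intron_chain(tx("c", ex(0, 10, 20, 30, 40, 50)))),
               rbind(c(10, 20), c(30, 40)))
})

# hand-built reference for the class-code suite: a 3-exon gene on each
# strand, plus a long-intron host
class_code_reference <- function() {
  transcript_catalog(list(
    tx("R1", ex(1000, 1300, 1500, 1800, 2000, 2300), "+"),
    tx("R2", ex(1000, 1300, 1500, 1800, 2000, 2300), "-", chrom = "chr2"),
    tx("R3", ex(5000, 5200, 7600, 7800), "+"),     # intron [5200, 7600)
    tx("R4", ex(9000, 9300, 9500, 9800), "-"),
    tx("R5", ex(12000, 12200, 12400, 12600), "+")))
}

test_that("each class code is assigned on its engineered geometry", {
  ref <- class_code_reference()
  cases <- list(
    list(q = tx("q_eq", ex(1100, 1300, 1500, 1800, 2000, 2200), "+"), code = "="),
    list(q = tx("q_c", ex(1600, 1800, 2000, 2100), "+"), code = "c"),
    list(q = tx("q_j", ex(1100, 1300, 1500, 1700, 1750, 1790), "+"), code = "j"),
    list(q = tx("q_i", ex(5500, 5700, 6000, 6200), "+"), code = "i"),
    list(q = tx("q_x", ex(9100, 9250, 9600, 9700), "+"), code = "x"),
    list(q = tx("q_o", ex(11900, 12100, 12250, 12300), "+"), code = "o"),
    list(q = tx("q_u", ex(50000, 50200, 50400, 50600), "+"), code = "u"))
  for (cs in cases) {
    expect_equal(assign_class_code(cs$q, ref), cs$code,
                 info = cs$q$transcript_id)
    expect_equal(oracle_class_code(cs$q, ref$transcripts), cs$code,
                 info = paste("oracle", cs$q$transcript_id))
  }
})

test_that("class codes agree with the brute-force oracle over an exhaustive geometry sweep", {
  ref <- class_code_reference()
  set.seed(42)
  n_checked <- 0L
  for (rep in 1:120) {
    anchor <- sample(c(1000, 5000, 9000, 12000, 40000), 1)
    k <- sample(2:4, 1)
    starts <- sort(sample(seq(anchor - 500, anchor + 1500, by = 10), k))
    ends <- starts + sample(30:180, k, replace = TRUE)
    ok <- all(ends[-k] + 1 <= starts[-1])
    if (!ok) next
    for (st in c("+", "-")) {
      q <- tx(paste0("q", rep, st), cbind(starts, ends), st)
      expect_equal(assign_class_code(q, ref),
                   oracle_class_code(q, ref$transcripts),
                   info = paste(rep, st, paste(starts, ends, collapse = " ")))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 100L)
})

test_that("unknown-strand queries are rejected for class codes", {
  expect_error(assign_class_code(tx("q", ex(0, 10, 20, 30), "unknown"),
                                 class_code_reference()),
               "strand")
})

test_that("assembly intersection keeps intron-chain matches and is idempotent", {
  a <- transcript_catalog(list(
    tx("a1", ex(100, 200, 300, 400), "+"),
    tx("a2", ex(1000, 1100, 1200, 1300), "-"),
    tx("a3", ex(5000, 5100), "+")))          # mono-exonic: never matched
  b <- transcript_catalog(list(
    tx("b1", ex(50, 200, 300, 450), "+"),    # same introns, wider ends
    tx("b3", ex(5000, 5100), "+")))
  got <- intersect_assemblies(a, b)
  expect_equal(catalog_ids(got), "a1")
  expect_equal(catalog_ids(intersect_assemblies(a, a)),
               setdiff(catalog_ids(a), "a3"))
  empty <- transcript_catalog(list(tx("z", ex(9e5, 9.1e5, 9.2e5, 9.3e5), "+")))
  expect_length(intersect_assemblies(a, empty), 0L)
})

test_that("intersection membership is symmetric and a subset (random catalogs)", {
  set.seed(11)
  rand_cat <- function(prefix, n) {
    transcript_catalog(lapply(seq_len(n), function(i) {
      s <- sample(seq(0, 5000, by = 500), 1)
      tx(paste0(prefix, i), ex(s, s + 100, s + 200, s + 300),
         sample(c("+", "-"), 1))
    }))
  }
  for (rep in 1:10) {
    a <- rand_cat("a", 8); b <- rand_cat("b", 8)
    ia <- intersect_assemblies(a, b); ib <- intersect_assemblies(b, a)
    expect_true(all(catalog_ids(ia) %in% catalog_ids(a)))
    # symmetric in membership: matched chain keys coincide
    key <- function(cat) sort(unique(vapply(cat$transcripts, function(t)
      paste(t$chrom, t$strand,
            paste(intron_chain(t), collapse = ","), sep = "|"), "")))
    expect_equal(key(ia), key(ib))
  }
})

test_that("assembly support counts per condition and is monotone", {
  t0 <- tx("T", ex(100, 200, 300, 400), "+")
  present <- transcript_catalog(list(tx("s1", ex(90, 200, 300, 410), "+")))
  absent <- transcript_catalog(list(tx("s2", ex(1000, 1100, 1200, 1300), "+")))
  cats <- list(present, present, present, absent, absent,
               absent, absent, absent, absent, absent)
  conds <- rep(c("tumor", "adjacent"), each = 5)
  s <- assembly_support(t0, cats, conds)
  expect_equal(s$tumor_support, 3L)
  expect_equal(s$adjacent_support, 0L)
  s0 <- assembly_support(tx("Z", ex(0, 10, 20, 30), "-"), cats, conds)
  expect_equal(c(s0$tumor_support, s0$adjacent_support), c(0L, 0L))
  # monotone: appending a catalog containing T never decreases either count
  s2 <- assembly_support(t0, c(cats, list(present)), c(conds, "adjacent"))
  expect_gte(s2$adjacent_support, s$adjacent_support)
  expect_equal(s2$tumor_support, s$tumor_support)
  # table form agrees with the scalar form
  tab <- assembly_support_table(transcript_catalog(list(t0)), cats, conds)
  expect_equal(tab$tumor_support, 3L)
  expect_error(assembly_support(t0, cats, conds[-1]), "condition")
})
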