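# Promoter-mark hits, embryo expression calls, Kaplan-Meier/log-rank
# screening, and the candidate report.

peaks1 <- function(df, id = "E1", category = "ESC") list(peak_set(id, category, df))

test_that("promoter window hits follow the +/-1000 bp rule on both strands", {
  t_plus <- tx("tp", ex(5000, 5200, 5400, 5600), "+")   # tss = 5000
  hit <- promoter_mark_hits(t_plus, peaks1(
    data.frame(chrom = "chr1", start = 5500, end = 5600)))
  expect_equal(unname(hit["ESC"]), 1L)
  # peak entirely left of tss - 1000: last base 3998 < 4000 -> no hit
  none <- promoter_mark_hits(t_plus, peaks1(
    data.frame(chrom = "chr1", start = 3900, end = 3999)))
  expect_equal(unname(none["ESC"]), 0L)
  # peak whose last covered base is exactly tss - 1000 -> hit (inclusive)
  edge <- promoter_mark_hits(t_plus, peaks1(
    data.frame(chrom = "chr1", start = 3900, end = 4001)))
  expect_equal(unname(edge["ESC"]), 1L)
  # minus strand: tss is the largest coordinate
  t_minus <- tx("tm", ex(100, 200, 300, 400), "-")      # tss = 400
  close_by <- promoter_mark_hits(t_minus, peaks1(
    data.frame(chrom = "chr1", start = 900, end = 1000)))
  expect_equal(unname(close_by["ESC"]), 1L)
  far <- promoter_mark_hits(t_minus, peaks1(
    data.frame(chrom = "chr1", start = 1500, end = 1600)))
  expect_equal(unname(far["ESC"]), 0L)
  expect_error(promoter_mark_hits(tx("tu", ex(0, 10, 20, 30), "unknown"),
                                  peaks1(data.frame(chrom = "chr1", start = 0,
                                                    end = 10))),
               "strand")
})

test_that("promoter hits count epigenomes per category and grow with the window", {
  t_plus <- tx("tp", ex(5000, 5200, 5400, 5600), "+")
  sets <- list(
    peak_set("E1", "ESC", data.frame(chrom = "chr1", start = 4500, end = 4600)),
    peak_set("E2", "ESC", data.frame(chrom = "chr1", start = 7000, end = 7100)),
    peak_set("C1", "cancer", data.frame(chrom = "chr1", start = 5900, end = 6000)),
    peak_set("I1", "iPSC", data.frame(chrom = "chr2", start = 5000, end = 5100)))
  for (w in c(0L, 500L, 1000L, 2500L)) {
    hits_small <- promoter_mark_hits(t_plus, sets, window = w)
    hits_big <- promoter_mark_hits(t_plus, sets, window = w + 500L)
    expect_true(all(hits_big >= hits_small))        # monotone in window
  }
  h <- promoter_mark_hits(t_plus, sets, window = 1000L)
  expect_equal(unname(h[c("ESC", "cancer", "iPSC", "ESC_derived")]),
               c(1L, 1L, 0L, 0L))
})

embryo_table <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(stage = r$stage, embryo_id = r$embryo,
               cell_id = paste0(r$embryo, "_c", seq_along(r$tpm)),
               G = r$tpm, stringsAsFactors = FALSE)))
}

test_that("embryo calls implement the 2-embryo and <67% minority rules", {
  d <- embryo_table(list(
    list(stage = "8cell", embryo = "e1", tpm = c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
    list(stage = "8cell", embryo = "e2", tpm = c(3, 2, 0, 0, 0, 0, 0, 0, 0, 0)),
    list(stage = "8cell", embryo = "e3", tpm = rep(0, 10)),
    list(stage = "morula", embryo = "m1", tpm = c(5, 4, 3, 0, 0, 0, 0, 0, 0, 0)),
    list(stage = "morula", embryo = "m2", tpm = rep(0, 10)),
    list(stage = "4cell", embryo = "f1", tpm = c(5, 5, 5)),
    list(stage = "4cell", embryo = "f2", tpm = c(5, 5, 5)),
    list(stage = "2cell", embryo = "t1", tpm = c(5, 5))))
  out <- embryo_expression_call("G", d)
  get <- function(st, col) out[[col]][out$stage == st]
  # 8cell: expressing cells in 2 embryos -> expressed; no embryo with a
  # >= 2-cell minority (e2 has 2 of 10 = 0.2 -> also lineage-specific)
  expect_true(get("8cell", "expressed"))
  expect_true(get("8cell", "lineage_specific"))
  # morula: 3 of 10 cells expressing in one embryo -> lineage-specific,
  # but only 1 expressing embryo -> not expressed
  expect_false(get("morula", "expressed"))
  expect_true(get("morula", "lineage_specific"))
  expect_equal(get("morula", "call"), "lineage_specific")
  # 4cell: all 3 cells expressing (fraction 1.0) -> expressed, not minority
  expect_true(get("4cell", "expressed"))
  expect_false(get("4cell", "lineage_specific"))
  expect_equal(get("4cell", "call"), "expressed")
  # 2cell: single embryo -> non-evaluable; absent stages too
  expect_equal(get("2cell", "call"), "non_evaluable")
  expect_equal(get("oocyte", "call"), "non_evaluable")
  # lineage-specific always requires >= 2 expressing cells in some embryo
  ls_rows <- out[!is.na(out$lineage_specific) & out$lineage_specific, ]
  expect_true(all(ls_rows$stage %in% c("8cell", "morula")))
})

test_that("unsupported genes are filtered before embryo calling", {
  d <- embryo_table(list(list(stage = "morula", embryo = "m1", tpm = c(5, 5))))
  out <- embryo_expression_call("G", d, supported = FALSE)
  expect_true(all(out$call == "filtered"))
})

test_that("log-rank matches the hand-tabulated O/E/V oracle and survdiff symmetry", {
  # 6 distinct event times, complete follow-up
  time <- c(1, 2, 3, 10, 20, 30)
  event <- rep(1L, 6)
  expression <- c(1, 1, 1, 2, 2, 2)   # median split puts 1,2,3 in 'low'
  got <- km_logrank(time, event, expression)
  orc <- oracle_logrank(time, event, group1 = expression <= 1.5)
  expect_equal(got$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  expect_equal(unname(as.vector(got$group_sizes)), c(3L, 3L))
  # identical event times in both groups: no evidence of a difference
  sym <- km_logrank(c(1, 2, 3, 1, 2, 3), rep(1L, 6), c(0, 0, 0, 9, 9, 9))
  expect_equal(sym$statistic, 0, tolerance = 1e-12)
  expect_equal(sym$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank oracle agreement holds on random censored cohorts", {
  set.seed(27)
  for (rep in 1:15) {
    n <- 40
    time <- round(rexp(n, 0.1), 1) + 0.1
    event <- rbinom(n, 1, 0.8)
    expression <- rlnorm(n)
    if (sum(event) == 0) next
    got <- km_logrank(time, event, expression)
    orc <- oracle_logrank(time, event,
                          group1 = expression <= median(expression))
    expect_equal(got$statistic, orc$statistic, tolerance = 1e-8)
  }
})

test_that("Kaplan-Meier curves are monotone and equal the empirical survival without censoring", {
  set.seed(13)
  time <- sample(1:100, 30, replace = FALSE)
  event <- rep(1L, 30)
  expression <- rnorm(30)
  fit <- km_logrank(time, event, expression)$km
  strata_id <- rep(seq_along(fit$strata), fit$strata)
  for (surv_k in split(fit$surv, strata_id)) {
    expect_true(all(diff(surv_k) <= 1e-12))
    expect_lte(max(surv_k), 1)
  }
  grp <- ifelse(expression > median(expression), "high", "low")
  for (g in c("low", "high")) {
    sel <- grp == g
    o <- oracle_km(time[sel], event[sel])
    idx <- which(summary(fit)$strata == paste0("group=", g))
    expect_equal(summary(fit)$surv[idx], o$surv, tolerance = 1e-12)
  }
})

test_that("degenerate survival inputs are rejected", {
  expect_error(km_logrank(1:10, rep(0L, 10), rnorm(10)), "censored")
  expect_error(km_logrank(1:10, rep(1L, 10), rep(2, 10)), "zero-variance")
})

test_that("planted hazard effects are detected; null genes stay null", {
  set.seed(61)
  n <- 200
  expr_p <- rlnorm(n, log(10), 1)
  high <- expr_p > median(expr_p)
  time <- rexp(n, (1 / 1000) * 3^high)
  cens <- runif(n) < 0.2
  event <- as.integer(!cens)
  time[cens] <- runif(sum(cens), 0, time[cens])
  expect_lt(km_logrank(time, event, expr_p)$p_value, 0.05)
  null_p <- replicate(50, km_logrank(time, event, rlnorm(n))$p_value)
  expect_gt(median(null_p), 0.25)
  expect_lt(median(null_p), 0.75)
})

test_that("candidate report joins evidence and applies the not-expressed rule", {
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      status = c("nuclear_enriched", "nuclear_enriched",
                                 "non_fraction_specific"),
                      mean_log2_ratio = c(-3, -2.5, 0),
                      stringsAsFactors = FALSE)
  fpkm <- rbind(g1 = c(rep(0.4, 4), rep(2, 4)),    # < 0.5 in 4 of 8: kept
                g2 = c(rep(0.4, 5), rep(2, 3)),    # < 0.5 in 5 of 8: flagged
                g3 = rep(1, 8))
  surv <- data.frame(gene_id = c("g1", "g2"), logrank_p = c(0.01, 0.2),
                     logrank_p_bh = c(0.02, 0.2))
  rep_df <- build_report(c("g2", "g1"), calls, survival_res = surv,
                         cellline_fpkm = fpkm)
  expect_equal(rep_df$gene_id, c("g1", "g2"))      # deterministic order
  expect_equal(rep_df$not_expressed, c(FALSE, TRUE))
  expect_equal(rep_df$survival_significant, c(TRUE, FALSE))
  expect_error(build_report("missing", calls), "enrichment")
  expect_equal(nrow(build_report(character(0), calls)), 0L)
})
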