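# Synthetic-data generator: determinism, planted-structure consistency,
# and recoverability of every planted property.

test_that("the generator is fully deterministic under the seed", {
  cfg <- small_config(seed = 33)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$fractions$cyto, s2$fractions$cyto)
  expect_identical(s1$cohort$counts_tumor, s2$cohort$counts_tumor)
  expect_identical(s1$coexpression$tpm, s2$coexpression$tpm)
  expect_identical(catalog_ids(s1$catalogs$assembled),
                   catalog_ids(s2$catalogs$assembled))
  # a different seed changes the draws
  s3 <- generate_fraction_matrices(small_config(seed = 34))
  expect_false(identical(s3$cyto, s1$fractions$cyto))
})

test_that("written simulation trees are byte-identical across runs", {
  cfg <- small_config(seed = 35)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  md5_1 <- unname(tools::md5sum(file.path(d1, f1)))
  md5_2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(md5_1, md5_2)
})

test_that("every class code occurs and matches the recorded expectation", {
  cats <- generate_genome_and_catalog(small_config(seed = 36))
  codes <- assign_class_codes(cats$assembled, cats$reference)
  expected <- cats$expected_codes$class_code[
    match(codes$transcript_id, cats$expected_codes$transcript_id)]
  expect_equal(codes$class_code, expected)
  expect_setequal(unique(codes$class_code), c("=", "c", "j", "i", "u", "x", "o"))
})

test_that("planted biotypes drive the built-in ORF predictor", {
  cfg <- small_config(seed = 37)
  cats <- generate_genome_and_catalog(cfg)
  truth <- generate_truth(cfg)
  pick <- function(bt) utils::head(truth$gene_id[truth$biotype == bt], 8)
  for (g in pick("protein_coding")) {
    t <- cats$assembled$transcripts[[paste0(g, ".t1")]]
    expect_equal(builtin_orf_predictor(t, cats$genome)$label, "coding",
                 info = g)
  }
  for (g in pick("lncRNA")) {
    t <- cats$assembled$transcripts[[paste0(g, ".t1")]]
    expect_equal(builtin_orf_predictor(t, cats$genome)$label, "noncoding",
                 info = g)
  }
})

test_that("fraction matrices carry the planted population structure", {
  cfg <- generator_config(seed = 38)
  fr <- generate_fraction_matrices(cfg)
  truth <- fr$truth
  pr <- compute_log_ratios(fr$cyto, fr$nuc)
  # lncRNA population is nuclear-shifted relative to mRNA (MWU p < 0.001)
  lnc <- pr$mean_log2_ratio[truth$biotype == "lncRNA"]
  pcg <- pr$mean_log2_ratio[truth$biotype == "protein_coding"]
  expect_lt(wilcox.test(lnc, pcg)$p.value, 1e-3)
  expect_lt(mean(lnc), mean(pcg))
  # housekeeping genes sit inside their stated band
  hk <- pr$mean_log2_ratio[truth$is_housekeeping]
  expect_lt(abs(mean(hk) - cfg$hk_band_mean), 0.25)
  # planted genes point the right way
  expect_lt(max(pr$mean_log2_ratio[truth$true_mean_ratio == cfg$nuclear_shift]),
            0)
  expect_gt(min(pr$mean_log2_ratio[truth$true_mean_ratio == cfg$cytoplasmic_shift]),
            2)
})

test_that("housekeeping band percentiles converge to the normal quantiles", {
  cfg <- generator_config(seed = 39, n_genes = 4000L, n_lncrna = 300L,
                          n_housekeeping = 3000L)
  fr <- generate_fraction_matrices(cfg)
  hk_true <- fr$truth$true_mean_ratio[fr$truth$is_housekeeping]
  q <- quantile(hk_true, c(0.05, 0.95), names = FALSE)
  expect_lt(abs(q[1] - (cfg$hk_band_mean - 1.645 * cfg$hk_band_sd)), 0.1)
  expect_lt(abs(q[2] - (cfg$hk_band_mean + 1.645 * cfg$hk_band_sd)), 0.1)
})

test_that("in the zero-noise limit planted nuclear genes fall below the band in all lines", {
  cfg <- small_config(seed = 40, line_noise_sd = 1e-6)
  fr <- generate_fraction_matrices(cfg)
  pr <- compute_log_ratios(fr$cyto, fr$nuc)
  hk_lo <- quantile(pr$mean_log2_ratio[fr$truth$is_housekeeping], 0.05)
  planted <- fr$truth$true_mean_ratio == cfg$nuclear_shift
  expect_true(all(pr$ratios[planted, ] < hk_lo, na.rm = TRUE))
  expect_true(all(pr$n_evaluable[planted] > 0))
})

test_that("assembly support truth is recovered exactly and tumor-specific transcripts have none in adjacent", {
  cfg <- small_config(seed = 41)
  cats <- generate_genome_and_catalog(cfg)
  co <- generate_tumor_cohort(cfg, cats)
  tab <- assembly_support_table(cats$assembled, co$sample_catalogs,
                                co$conditions)
  expect_equal(tab$tumor_support, co$support_truth$tumor_support)
  expect_equal(tab$adjacent_support, co$support_truth$adjacent_support)
  ts <- co$truth$gene_id[co$truth$tumor_specific]
  expect_true(length(ts) >= 1)
  expect_true(all(tab$adjacent_support[match(paste0(ts, ".t1"),
                                             tab$transcript_id)] == 0L))
})

test_that("planted lineage-specific genes are silent before onset and minority-expressed after", {
  cfg <- small_config(seed = 42)
  ch <- generate_characterization_inputs(cfg)
  truth <- ch$truth
  ls_genes <- truth$gene_id[truth$lineage_specific]
  expect_true(length(ls_genes) >= 1)
  for (g in ls_genes) {
    out <- embryo_expression_call(g, ch$embryo)
    pre <- out$call[out$stage %in% c("oocyte", "zygote", "2cell")]
    expect_true(all(pre %in% c("not_expressed", "non_evaluable")), info = g)
    expect_equal(out$call[out$stage == "morula"], "lineage_specific", info = g)
  }
  broad <- setdiff(truth$gene_id[truth$is_candidate], ls_genes)
  for (g in broad) {
    out <- embryo_expression_call(g, ch$embryo)
    expect_equal(out$call[out$stage == "oocyte"], "not_expressed", info = g)
    expect_true(all(out$call[out$stage != "oocyte"] == "expressed"), info = g)
  }
})

test_that("marked promoter categories give the full epigenome count, unmarked give zero", {
  cfg <- small_config(seed = 43)
  cats <- generate_genome_and_catalog(cfg)
  ch <- generate_characterization_inputs(cfg, cats)
  truth <- ch$truth
  n_per_cat <- table(vapply(ch$peak_sets, `[[`, "", "category"))
  for (g in truth$gene_id[truth$is_candidate]) {
    hits <- promoter_mark_hits(cats$assembled$transcripts[[paste0(g, ".t1")]],
                               ch$peak_sets)
    row <- truth[truth$gene_id == g, ]
    for (cat in names(n_per_cat)) {
      expected <- if (row[[paste0("marked_", cat)]])
        unname(n_per_cat[cat]) else 0L
      expect_equal(unname(hits[cat]), as.integer(expected),
                   info = paste(g, cat))
    }
  }
})
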