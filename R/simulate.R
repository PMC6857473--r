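# Seeded synthetic-data generator.
#
# Emulates the statistical structure the pipeline assumes — mRNAs centred
# near log-ratio 0 with a cytoplasm-shifted housekeeping band, a
# nuclear-shifted lncRNA population, planted fraction-enriched genes,
# planted tumor-dysregulated transcripts with heterogeneous assembly
# support, planted prognostic effects, planted promoter peaks, planted
# lineage-restricted embryo expression, and latent-factor co-expression —
# with every planted property recorded as ground truth. The seed fully
# determines all outputs.

#' Generator configuration
#'
#' Defaults describe the test-scale world: 2,000 genes over 8 cell lines
#' and 10 tumor/adjacent pairs, 100 + 100 planted fraction-enriched genes
#' beyond the housekeeping band (band mean 1, sd 1 on the log2 cyto/nuc
#' scale), per-line noise sd 0.5, 50 planted differentially expressed
#' transcripts at |log2FC| = 2, 10 candidate genes planted with both
#' properties, hazard ratio 3 prognostic effects and 20% censoring.
#' Background (non-planted) gene mean ratios keep a margin of one
#' line-noise sd from the band limits so the planted classes are separable
#' but noisy.
#'
#' @param seed Integer seed (< 2^31 - 1000); fully determines all outputs.
#' @param n_genes,n_lncrna,n_housekeeping,n_cell_lines,n_tumor_pairs Sizes.
#' @param planted_nuclear,planted_cytoplasmic Planted enriched gene counts.
#' @param nuclear_shift,cytoplasmic_shift Planted mean log2(cyto/nuc)
#'   ratios (beyond the housekeeping band).
#' @param line_noise_sd Per-line log-ratio noise sd.
#' @param hk_band_mean,hk_band_sd Housekeeping band location/spread.
#' @param lnc_shift_mean,lnc_shift_sd Background lncRNA population shift.
#' @param mrna_sd Background mRNA mean-ratio spread.
#' @param planted_de,de_log2fc,nb_dispersion Differential-expression world.
#' @param n_candidates Genes planted with BOTH tumor-up DE and nuclear
#'   enrichment (the pipeline's expected final candidates).
#' @param planted_prognostic,hazard_ratio,n_patients,censoring_fraction
#'   Survival world.
#' @param coexpr_factors,factor_loading,partners_per_factor,n_coexpr_samples
#'   Latent-factor co-expression world.
#' @param embryos_per_stage,cells_per_embryo Embryo world.
#' @param n_tumor_specific Transcripts present only in tumor assemblies.
#' @param n_chroms,tile_bp Genome layout (one gene tile per `tile_bp`).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_genes = 2000L, n_lncrna = 300L,
                             n_housekeeping = 200L, n_cell_lines = 8L,
                             n_tumor_pairs = 10L,
                             planted_nuclear = 100L, planted_cytoplasmic = 100L,
                             nuclear_shift = -3.5, cytoplasmic_shift = 5.0,
                             line_noise_sd = 0.5,
                             hk_band_mean = 1.0, hk_band_sd = 1.0,
                             lnc_shift_mean = -1.2, lnc_shift_sd = 0.7,
                             mrna_sd = 0.3,
                             planted_de = 50L, de_log2fc = 2.0,
                             nb_dispersion = 0.05,
                             n_candidates = 10L,
                             planted_prognostic = 10L, hazard_ratio = 3.0,
                             n_patients = 200L, censoring_fraction = 0.2,
                             coexpr_factors = 3L, factor_loading = 0.9,
                             partners_per_factor = 30L, n_coexpr_samples = 100L,
                             embryos_per_stage = 3L, cells_per_embryo = 8L,
                             n_tumor_specific = 5L,
                             n_chroms = 2L, tile_bp = 4000L) {
  cfg <- as.list(environment())
  stopifnot(seed == as.integer(seed), abs(seed) < 2^31 - 1000,
            n_lncrna < n_genes,
            n_candidates <= n_lncrna,
            n_candidates <= planted_de,
            planted_nuclear <= n_lncrna,
            n_candidates <= planted_nuclear,
            planted_cytoplasmic + n_housekeeping + 2L <= n_genes - n_lncrna,
            n_cell_lines >= 4L, n_tumor_pairs >= 2L)
  structure(cfg, class = "generator_config")
}

# Deterministic gene universe + planted truth. Seeded internally so every
# generate_* function recovers the identical universe from cfg alone.
.gene_universe <- function(cfg) {
  set.seed(cfg$seed + 101L)
  lnc <- sprintf("LNC%04d", seq_len(cfg$n_lncrna))
  lnc[cfg$n_lncrna] <- "MALAT1"
  pcg <- sprintf("PCG%04d", seq_len(cfg$n_genes - cfg$n_lncrna))
  pcg[length(pcg) - 1L] <- "GAPDH"
  pcg[length(pcg)] <- "RPS14"
  genes <- c(lnc, pcg)
  biotype <- rep(c("lncRNA", "protein_coding"), c(length(lnc), length(pcg)))

  candidates <- lnc[seq_len(cfg$n_candidates)]
  # annotated status alternates over lncRNAs so candidates mix both kinds
  annotated <- biotype == "protein_coding" |
    (biotype == "lncRNA" & (seq_along(genes) %% 2L == 1L))
  annotated[genes == "MALAT1"] <- TRUE
  ref_biotype <- ifelse(biotype == "protein_coding", "protein_coding",
                        ifelse(seq_along(genes) %% 4L == 1L, "lincRNA",
                               "antisense"))
  ref_biotype[genes == "MALAT1"] <- "lincRNA"
  ref_biotype[!annotated] <- NA_character_

  housekeeping <- pcg[seq_len(cfg$n_housekeeping)]
  n_extra_nuc <- cfg$planted_nuclear - cfg$n_candidates - 1L  # MALAT1 counts
  nuclear <- c(candidates, "MALAT1",
               lnc[cfg$n_candidates + seq_len(max(0L, n_extra_nuc))])
  cyto_pool <- setdiff(pcg, housekeeping)
  cytoplasmic <- c("GAPDH", "RPS14",
                   cyto_pool[seq_len(cfg$planted_cytoplasmic - 2L)])

  # planted DE: candidates are up; remainder split over extra lnc up/down
  # and pcg up/down, all outside the nuclear and cytoplasmic planted sets
  rem <- cfg$planted_de - cfg$n_candidates
  lnc_free <- setdiff(lnc, nuclear)
  pcg_free <- setdiff(cyto_pool, cytoplasmic)
  q <- rem %/% 4L
  de_up <- c(candidates, lnc_free[seq_len(q)],
             pcg_free[seq_len(q)])
  de_down <- c(lnc_free[q + seq_len(q)],
               pcg_free[q + seq_len(rem - 3L * q)])
  true_de <- rep(NA_character_, length(genes))
  true_de[genes %in% de_up] <- "up"
  true_de[genes %in% de_down] <- "down"

  prognostic <- candidates[seq_len(min(cfg$planted_prognostic,
                                       cfg$n_candidates))]
  if (cfg$planted_prognostic > cfg$n_candidates)
    prognostic <- c(prognostic, lnc_free[seq_len(cfg$planted_prognostic -
                                                   cfg$n_candidates)])

  block <- rep(NA_integer_, length(genes))
  block[match(candidates, genes)] <-
    rep_len(seq_len(cfg$coexpr_factors), cfg$n_candidates)
  partner_pool <- setdiff(pcg_free, de_up)
  partner_pool <- setdiff(partner_pool, de_down)
  partner_of <- rep(NA_integer_, length(genes))
  for (b in seq_len(cfg$coexpr_factors)) {
    ids <- partner_pool[(b - 1L) * cfg$partners_per_factor +
                          seq_len(cfg$partners_per_factor)]
    partner_of[match(ids, genes)] <- b
  }

  lineage <- genes %in% candidates[seq_along(candidates) %% 2L == 1L]
  onset <- ifelse(lineage, "4cell",
                  ifelse(genes %in% candidates, "zygote", NA))

  # true mean log2(cyto/nuc) ratios; background genes keep a margin of one
  # line-noise sd from the band limits (separable but noisy)
  lower <- cfg$hk_band_mean - stats::qnorm(0.95) * cfg$hk_band_sd
  upper <- cfg$hk_band_mean + stats::qnorm(0.95) * cfg$hk_band_sd
  margin <- cfg$line_noise_sd
  draw_bg <- function(n, mean, sd) {
    out <- numeric(0)
    while (length(out) < n) {
      r <- stats::rnorm(2L * n, mean, sd)
      r <- r[abs(r - lower) > margin & abs(r - upper) > margin]
      out <- c(out, r)
    }
    out[seq_len(n)]
  }
  ratio <- numeric(length(genes))
  is_hk <- genes %in% housekeeping
  is_nuc <- genes %in% nuclear
  is_cyt <- genes %in% cytoplasmic
  bg_lnc <- biotype == "lncRNA" & !is_nuc & !is_cyt
  bg_pcg <- biotype == "protein_coding" & !is_nuc & !is_cyt & !is_hk
  ratio[is_hk] <- stats::rnorm(sum(is_hk), cfg$hk_band_mean, cfg$hk_band_sd)
  ratio[is_nuc] <- cfg$nuclear_shift
  ratio[is_cyt] <- cfg$cytoplasmic_shift
  ratio[bg_lnc] <- draw_bg(sum(bg_lnc), cfg$lnc_shift_mean, cfg$lnc_shift_sd)
  ratio[bg_pcg] <- draw_bg(sum(bg_pcg), 0, cfg$mrna_sd)

  status <- ifelse(is_nuc, "nuclear_enriched",
                   ifelse(is_cyt, "cytoplasmic_enriched",
                          ifelse(ratio < lower, "nuclear_enriched",
                                 ifelse(ratio > upper, "cytoplasmic_enriched",
                                        "non_fraction_specific"))))

  marked <- matrix(FALSE, length(genes), length(PEAK_CATEGORIES),
                   dimnames = list(genes, PEAK_CATEGORIES))
  ci <- match(candidates, genes)
  marked[ci, c("ESC", "ESC_derived", "iPSC")] <- TRUE
  marked[ci[seq_along(ci) %% 2L == 0L], "cancer"] <- TRUE

  data.frame(gene_id = genes, biotype = biotype, annotated = annotated,
             reference_biotype = ref_biotype,
             is_housekeeping = is_hk,
             is_candidate = genes %in% candidates,
             true_mean_ratio = ratio,
             true_enrichment = status,
             true_de = true_de,
             true_prognostic = genes %in% prognostic,
             coexpr_block = block, partner_block = partner_of,
             lineage_specific = lineage, embryo_onset = onset,
             marked_ESC = marked[, "ESC"],
             marked_ESC_derived = marked[, "ESC_derived"],
             marked_iPSC = marked[, "iPSC"],
             marked_cancer = marked[, "cancer"],
             tumor_specific = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ground truth of the synthetic world
#'
#' @param cfg A `generator_config`.
#' @return data.frame, one row per gene, with all planted properties.
#' @export
generate_truth <- function(cfg) {
  truth <- .gene_universe(cfg)
  un <- truth$gene_id[truth$biotype == "lncRNA" & !truth$annotated]
  truth$tumor_specific <- truth$gene_id %in% un[seq_len(min(cfg$n_tumor_specific,
                                                            length(un)))]
  truth
}

# non-stop codons for ORF planting
.SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")),
                               1L, paste, collapse = ""),
                         c("TAA", "TAG", "TGA"))

# 1-based genome positions of a transcript's exonic bases, genomic order
.exon_positions <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)), function(i)
    (exons[i, 1L] + 1L):exons[i, 2L]))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate genome, reference annotation, assembled catalog and repeat mask
#'
#' Lays one gene per `tile_bp` tile, alternating chromosomes and strands.
#' Annotated genes get a reference transcript and an assembled copy with
#' jittered terminal exon ends (class code `=`); unannotated lncRNA genes
#' cycle through geometries engineered to yield every remaining class code
#' (`j`, `u`, `i`, `x`, `o`, `c`) against per-tile host reference
#' transcripts. Protein-coding transcripts carry a planted >= 290-codon
#' ORF; lncRNA transcripts have stop codons scrubbed into all frames. The
#' repeat mask tiles inter-gene gaps and never touches an exon.
#'
#' @param cfg A `generator_config`.
#' @return List with `genome` (named character vector), `reference` and
#'   `assembled` (`transcript_catalog`), `mask` (data.frame), and
#'   `expected_codes` (data.frame `transcript_id`, `class_code`).
#' @export
generate_genome_and_catalog <- function(cfg) {
  set.seed(cfg$seed + 102L)
  truth <- generate_truth(cfg)
  n <- nrow(truth)
  per_chrom <- ceiling(n / cfg$n_chroms)
  chrom_len <- cfg$tile_bp * per_chrom + 1000L
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE))
  names(genome_chars) <- chroms

  ref_list <- vector("list", 2L * n); asm_list <- vector("list", n)
  nref <- 0L
  codes <- character(n)
  write_idx <- write_val <- stats::setNames(
    rep(list(list()), cfg$n_chroms), chroms)
  unannot_cycle <- c("j", "u", "i", "x", "o", "c")
  uncount <- 0L
  for (i in seq_len(n)) {
    g <- truth$gene_id[i]
    ch <- chroms[(i - 1L) %% cfg$n_chroms + 1L]
    s <- ((i - 1L) %/% cfg$n_chroms) * cfg$tile_bp + 100L
    st <- if (i %% 2L == 0L) "-" else "+"
    ref_ex <- rbind(c(s, s + 300L), c(s + 500L, s + 800L),
                    c(s + 1000L, s + 1300L))
    if (truth$annotated[i]) {
      nref <- nref + 1L
      ref_list[[nref]] <-
        transcript_model(paste0(g, ".r1"), g, ch, st, ref_ex, "reference")
      d1 <- sample(0:60, 1L); d2 <- sample(0:60, 1L)
      asm_ex <- ref_ex; asm_ex[1L, 1L] <- asm_ex[1L, 1L] + d1
      asm_ex[3L, 2L] <- asm_ex[3L, 2L] + d2
      asm_list[[i]] <-
        transcript_model(paste0(g, ".t1"), g, ch, st, asm_ex, "assembled")
      codes[i] <- "="
    } else {
      uncount <- uncount + 1L
      code <- unannot_cycle[(uncount - 1L) %% length(unannot_cycle) + 1L]
      host_id <- paste0("HOST_", g)
      opp <- if (st == "+") "-" else "+"
      if (code != "u") {
        host_ex <- if (code == "i")
          rbind(c(s, s + 200L), c(s + 2600L, s + 2800L)) else ref_ex
        nref <- nref + 1L
        ref_list[[nref]] <-
          transcript_model(paste0(host_id, ".r1"), host_id, ch, st, host_ex,
                           "reference")
      }
      asm_ex <- switch(code,
        u = rbind(c(s, s + 300L), c(s + 500L, s + 800L)),
        i = rbind(c(s + 700L, s + 1000L), c(s + 1200L, s + 1500L)),
        j = rbind(c(s + 100L, s + 300L), c(s + 500L, s + 800L),
                  c(s + 900L, s + 950L)),
        c = rbind(c(s + 520L, s + 800L), c(s + 1000L, s + 1250L)),
        x = rbind(c(s + 50L, s + 250L), c(s + 600L, s + 700L)),
        o = rbind(c(s + 150L, s + 350L), c(s + 600L, s + 650L)))
      asm_st <- if (code == "x") opp else st
      asm_list[[i]] <-
        transcript_model(paste0(g, ".t1"), g, ch, asm_st, asm_ex, "assembled")
      codes[i] <- code
    }
    # plant coding content / scrub ORFs on the assembled transcript
    t_asm <- asm_list[[i]]
    len <- transcript_length(t_asm)
    if (truth$biotype[i] == "protein_coding" && len >= 820L) {
      # 272-codon ORF (816 nt) fits every jittered 3-exon transcript
      orf <- c("A", "T", "G",
               unlist(strsplit(sample(.SENSE_CODONS, 270L, replace = TRUE), "")),
               "T", "A", "A")
      pad <- len - length(orf)
      spliced <- c(sample(c("A", "C", "G", "T"), pad %/% 2L, replace = TRUE),
                   orf,
                   sample(c("A", "C", "G", "T"), pad - pad %/% 2L,
                          replace = TRUE))
    } else {
      # step 31 walks the stop through all three frames -> no ORF >= 31 aa
      spliced <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      for (p in seq(1L, len - 3L, by = 31L))
        spliced[p:(p + 2L)] <- c("T", "A", "A")
    }
    genomic <- if (t_asm$strand == "-")
      unlist(strsplit(.revcomp(paste(spliced, collapse = "")), "")) else spliced
    write_idx[[ch]][[length(write_idx[[ch]]) + 1L]] <- .exon_positions(t_asm$exons)
    write_val[[ch]][[length(write_val[[ch]]) + 1L]] <- genomic
  }
  # batched genome writes: one vectorized assignment per chromosome
  for (ch in chroms)
    if (length(write_idx[[ch]]))
      genome_chars[[ch]][unlist(write_idx[[ch]])] <- unlist(write_val[[ch]])
  genome <- vapply(genome_chars, paste, character(1), collapse = "")

  gap0 <- 3400L  # tiles span [100, 3400) at most; mask sits beyond
  mask <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    tiles <- seq_len(per_chrom) - 1L
    data.frame(chrom = chroms[ci],
               start = tiles * cfg$tile_bp + gap0 + 100L,
               end = tiles * cfg$tile_bp + gap0 + 300L,
               stringsAsFactors = FALSE)
  }))
  list(genome = genome,
       reference = transcript_catalog(ref_list[seq_len(nref)]),
       assembled = transcript_catalog(asm_list),
       mask = mask,
       expected_codes = data.frame(transcript_id = paste0(truth$gene_id, ".t1"),
                                   class_code = codes,
                                   stringsAsFactors = FALSE))
}

#' Generate paired cytoplasmic/nuclear FPKM matrices
#'
#' Per-gene baseline log2 FPKM ~ Normal(4, 1.5); each cell line's
#' log2(cyto/nuc) offset is the gene's true mean ratio plus
#' Normal(0, line_noise_sd) noise, split symmetrically between the two
#' fractions.
#'
#' @param cfg A `generator_config`.
#' @return List with `cyto`, `nuc` (genes x cell lines FPKM matrices),
#'   `housekeeping` (gene ids), `truth`.
#' @export
generate_fraction_matrices <- function(cfg) {
  truth <- generate_truth(cfg)
  set.seed(cfg$seed + 103L)
  n <- nrow(truth); L <- cfg$n_cell_lines
  lines <- sprintf("line%02d", seq_len(L))
  base <- stats::rnorm(n, 4, 1.5)
  ratio <- truth$true_mean_ratio +
    matrix(stats::rnorm(n * L, 0, cfg$line_noise_sd), n, L)
  cyto <- 2^(base + ratio / 2)
  nuc <- 2^(base - ratio / 2)
  dimnames(cyto) <- dimnames(nuc) <- list(truth$gene_id, lines)
  list(cyto = cyto, nuc = nuc,
       housekeeping = truth$gene_id[truth$is_housekeeping],
       truth = truth)
}

#' Generate the tumor cohort: counts, per-sample assemblies, survival
#'
#' Negative-binomial counts with planted fold changes; per-sample
#' assemblies include each transcript with probability
#' `1 - exp(-count / 50)` (tumor-specific transcripts never enter adjacent
#' assemblies); survival times are exponential with the hazard scaled by
#' `hazard_ratio` per above-median planted prognostic gene, with uniform
#' censoring.
#'
#' @param cfg A `generator_config`.
#' @param catalogs Optional result of [generate_genome_and_catalog()]
#'   (regenerated from `cfg` when omitted) supplying the assembled models
#'   used for the per-sample catalogs.
#' @return List with `counts_tumor`, `counts_adjacent`, `tpm`,
#'   `sample_catalogs`, `conditions`, `support_truth`, `survival`, `truth`.
#' @export
generate_tumor_cohort <- function(cfg, catalogs = NULL) {
  if (is.null(catalogs)) catalogs <- generate_genome_and_catalog(cfg)
  truth <- generate_truth(cfg)
  set.seed(cfg$seed + 104L)
  n <- nrow(truth)
  tx_ids <- paste0(truth$gene_id, ".t1")
  np <- cfg$n_tumor_pairs
  base <- stats::rlnorm(n, log(200), 1)
  de <- !is.na(truth$true_de)
  base[de] <- stats::rlnorm(sum(de), log(300), 0.5)
  lfc <- ifelse(is.na(truth$true_de), 0,
                ifelse(truth$true_de == "up", cfg$de_log2fc, -cfg$de_log2fc))
  mu_t <- base * 2^(lfc / 2); mu_a <- base * 2^(-lfc / 2)
  size <- 1 / cfg$nb_dispersion
  lib_t <- stats::runif(np, 0.85, 1.15)
  lib_a <- stats::runif(np, 0.85, 1.15)
  counts_tumor <- vapply(seq_len(np), function(j)
    stats::rnbinom(n, mu = mu_t * lib_t[j], size = size), numeric(n))
  counts_adjacent <- vapply(seq_len(np), function(j)
    stats::rnbinom(n, mu = mu_a * lib_a[j], size = size), numeric(n))
  dimnames(counts_tumor) <- list(tx_ids, sprintf("tumor%02d", seq_len(np)))
  dimnames(counts_adjacent) <- list(tx_ids, sprintf("adjacent%02d", seq_len(np)))
  tpm <- sweep(cbind(counts_tumor, counts_adjacent), 2L,
               colSums(cbind(counts_tumor, counts_adjacent)) / 1e6, "/")

  models <- catalogs$assembled$transcripts[tx_ids]
  all_counts <- cbind(counts_tumor, counts_adjacent)
  conditions <- rep(c("tumor", "adjacent"), each = np)
  incl <- matrix(stats::runif(n * 2L * np) < 1 - exp(-all_counts / 50),
                 n, 2L * np)
  incl[truth$tumor_specific, conditions == "adjacent"] <- FALSE
  sample_catalogs <- lapply(seq_len(2L * np), function(j)
    transcript_catalog(unname(models[incl[, j]])))
  names(sample_catalogs) <- colnames(all_counts)
  support_truth <- data.frame(
    transcript_id = tx_ids,
    tumor_support = as.integer(rowSums(incl[, conditions == "tumor", drop = FALSE])),
    adjacent_support = as.integer(rowSums(incl[, conditions == "adjacent", drop = FALSE])),
    stringsAsFactors = FALSE)

  # survival cohort over candidate + background lncRNA genes
  prog <- truth$gene_id[truth$true_prognostic]
  surv_genes <- truth$gene_id[truth$biotype == "lncRNA"]
  expr <- matrix(stats::rlnorm(cfg$n_patients * length(surv_genes), log(10), 1),
                 cfg$n_patients, length(surv_genes),
                 dimnames = list(sprintf("P%03d", seq_len(cfg$n_patients)),
                                 surv_genes))
  high <- vapply(prog, function(g)
    expr[, g] > stats::median(expr[, g]), logical(cfg$n_patients))
  k <- if (length(prog)) rowSums(matrix(high, ncol = length(prog))) else
    numeric(cfg$n_patients)
  rate <- (1 / 1000) * cfg$hazard_ratio^(k - length(prog) / 2)
  time <- stats::rexp(cfg$n_patients, rate)
  cens <- stats::runif(cfg$n_patients) < cfg$censoring_fraction
  event <- as.integer(!cens)
  time[cens] <- stats::runif(sum(cens), 0, time[cens])
  survival <- data.frame(patient_id = rownames(expr),
                         time = time, event = event,
                         stringsAsFactors = FALSE)
  survival <- cbind(survival, as.data.frame(expr))

  list(counts_tumor = counts_tumor, counts_adjacent = counts_adjacent,
       tpm = tpm, sample_catalogs = sample_catalogs, conditions = conditions,
       support_truth = support_truth, survival = survival, truth = truth)
}

#' Simulated per-method differential-expression result tables
#'
#' Two pseudo-method tables drawn from the recorded truth with noise: an
#' FDR-style table (`sim_deseq`, adjusted p) and a posterior-probability
#' table (`sim_ebseq`, PPDE). Planted transcripts get |log2FC| near
#' `de_log2fc` with the planted sign and decisive statistics; nulls get
#' near-zero fold changes and non-significant statistics.
#'
#' @param cfg A `generator_config`.
#' @return Named list of two data.frames in the [builtin_de_test()] layout.
#' @export
generate_method_tables <- function(cfg) {
  truth <- generate_truth(cfg)
  set.seed(cfg$seed + 105L)
  tx_ids <- paste0(truth$gene_id, ".t1")
  n <- length(tx_ids)
  de <- !is.na(truth$true_de)
  sgn <- ifelse(is.na(truth$true_de), 0,
                ifelse(truth$true_de == "up", 1, -1))
  mk <- function(method, use_ppde) {
    lfc <- sgn * cfg$de_log2fc + stats::rnorm(n, 0, 0.2)
    lfc[!de] <- stats::rnorm(sum(!de), 0, 0.2)
    if (use_ppde) {
      ppde <- ifelse(de, stats::runif(n, 0.992, 1), stats::runif(n, 0, 0.9))
      data.frame(transcript_id = tx_ids, method = method,
                 log2_fold_change = lfc, p_value = NA_real_,
                 adjusted_p = NA_real_, ppde = ppde,
                 stringsAsFactors = FALSE)
    } else {
      padj <- ifelse(de, stats::runif(n, 0, 0.003), stats::runif(n, 0.05, 1))
      data.frame(transcript_id = tx_ids, method = method,
                 log2_fold_change = lfc, p_value = padj,
                 adjusted_p = padj, ppde = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }
  list(sim_deseq = mk("sim_deseq", FALSE), sim_ebseq = mk("sim_ebseq", TRUE))
}

#' Generate promoter peak sets and the embryo expression table
#'
#' 28 epigenomes in the four stem/cancer categories receive an H3K4me3
#' peak within +/- 1000 bp of a gene's TSS in every epigenome of each
#' category the gene is flagged marked for. The embryo table covers the
#' seven preimplantation stages with `embryos_per_stage` embryos of
#' `cells_per_embryo` cells; planted lineage-specific genes express in
#' exactly 3 cells per embryo (a minority) from their onset stage, broadly
#' expressed candidates in all cells from the zygote stage on.
#'
#' @param cfg A `generator_config`.
#' @param catalogs Optional result of [generate_genome_and_catalog()].
#' @return List with `peak_sets` (list of `peak_set`), `embryo`
#'   (data.frame), `truth`.
#' @export
generate_characterization_inputs <- function(cfg, catalogs = NULL) {
  if (is.null(catalogs)) catalogs <- generate_genome_and_catalog(cfg)
  truth <- generate_truth(cfg)
  set.seed(cfg$seed + 106L)
  epi <- data.frame(
    epigenome_id = c(sprintf("ESC%02d", 1:8), sprintf("DRV%02d", 1:8),
                     sprintf("IPS%02d", 1:6), sprintf("CAN%02d", 1:6)),
    category = rep(PEAK_CATEGORIES, c(8L, 8L, 6L, 6L)),
    stringsAsFactors = FALSE)
  cand <- truth[truth$is_candidate, , drop = FALSE]
  tss_of <- function(g) {
    t <- catalogs$assembled$transcripts[[paste0(g, ".t1")]]
    list(chrom = t$chrom,
         tss = if (t$strand == "+") t$exons[1L, 1L] else t$exons[nrow(t$exons), 2L])
  }
  peak_sets <- lapply(seq_len(nrow(epi)), function(i) {
    rows <- lapply(cand$gene_id, function(g) {
      if (!cand[[paste0("marked_", epi$category[i])]][cand$gene_id == g])
        return(NULL)
      p <- tss_of(g)
      data.frame(chrom = p$chrom, start = max(0L, p$tss - 200L),
                 end = p$tss + 300L, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
      rows <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
    peak_set(epi$epigenome_id[i], epi$category[i], rows)
  })

  stages <- EMBRYO_STAGES
  grid <- expand.grid(cell = seq_len(cfg$cells_per_embryo),
                      embryo = seq_len(cfg$embryos_per_stage),
                      stage = stages, stringsAsFactors = FALSE)
  embryo <- data.frame(
    stage = grid$stage,
    embryo_id = sprintf("%s_e%d", grid$stage, grid$embryo),
    cell_id = sprintf("%s_e%d_c%d", grid$stage, grid$embryo, grid$cell),
    stringsAsFactors = FALSE)
  stage_rank <- stats::setNames(seq_along(stages), stages)
  for (g in truth$gene_id[truth$biotype == "lncRNA"]) {
    tpm <- stats::runif(nrow(embryo), 0, 0.5)  # background: not expressed
    if (g %in% cand$gene_id) {
      onset <- cand$embryo_onset[cand$gene_id == g]
      ls <- cand$lineage_specific[cand$gene_id == g]
      on <- stage_rank[embryo$stage] >= stage_rank[onset]
      if (ls) {
        expressing <- on & grid$cell <= 3L  # 3 of cells_per_embryo: a minority
        tpm[expressing] <- stats::runif(sum(expressing), 2, 10)
      } else {
        tpm[on] <- stats::runif(sum(on), 2, 10)
      }
    }
    embryo[[g]] <- tpm
  }
  list(peak_sets = peak_sets, embryo = embryo, truth = truth)
}

#' Generate the tumor co-expression matrix
#'
#' Latent-factor structure: each co-expression block has one standard
#' normal factor per sample; candidate and partner genes of the block load
#' on it with `factor_loading` (noise sd `sqrt(1 - loading^2)` on the
#' log2 scale), all other genes are independent noise.
#'
#' @param cfg A `generator_config`.
#' @return List with `tpm` (genes x samples matrix), `truth`.
#' @export
generate_coexpression_matrix <- function(cfg) {
  truth <- generate_truth(cfg)
  set.seed(cfg$seed + 107L)
  n <- nrow(truth); m <- cfg$n_coexpr_samples
  factors <- matrix(stats::rnorm(cfg$coexpr_factors * m), cfg$coexpr_factors, m)
  a <- cfg$factor_loading
  z <- matrix(stats::rnorm(n * m, 0, sqrt(1 - a^2)), n, m)
  blk <- ifelse(!is.na(truth$coexpr_block), truth$coexpr_block,
                truth$partner_block)
  has <- !is.na(blk)
  z[has, ] <- z[has, ] + a * factors[blk[has], , drop = FALSE]
  logtpm <- 3 + z
  tpm <- 2^logtpm - 1
  tpm[tpm < 0] <- 0
  dimnames(tpm) <- list(truth$gene_id, sprintf("T%03d", seq_len(m)))
  list(tpm = tpm, truth = truth)
}

#' Generate every pipeline input with recorded ground truth
#'
#' Runs all generators under one configuration and optionally writes the
#' complete input tree (GTFs, TSV matrices, BED peaks with a manifest,
#' survival and embryo tables, housekeeping list, coding-potential labels,
#' truth JSON) to `outdir`.
#'
#' @param cfg A `generator_config`.
#' @param outdir Optional output directory.
#' @return List with components `catalogs`, `fractions`, `cohort`,
#'   `method_tables`, `characterization`, `coexpression`, `cp_labels`,
#'   `truth`.
#' @export
simulate_study <- function(cfg, outdir = NULL) {
  catalogs <- generate_genome_and_catalog(cfg)
  fractions <- generate_fraction_matrices(cfg)
  cohort <- generate_tumor_cohort(cfg, catalogs)
  method_tables <- generate_method_tables(cfg)
  characterization <- generate_characterization_inputs(cfg, catalogs)
  coexpression <- generate_coexpression_matrix(cfg)
  truth <- cohort$truth
  # noiseless coding-potential labels from the planted biotypes
  tx_ids <- paste0(truth$gene_id, ".t1")
  lab <- ifelse(truth$biotype == "lncRNA", "noncoding", "coding")
  cp_labels <- rbind(
    data.frame(transcript_id = tx_ids, predictor = "cpc2_sim", label = lab,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = tx_ids, predictor = "come_sim", label = lab,
               stringsAsFactors = FALSE))
  sim <- list(catalogs = catalogs, fractions = fractions, cohort = cohort,
              method_tables = method_tables,
              characterization = characterization,
              coexpression = coexpression, cp_labels = cp_labels,
              truth = truth)
  if (!is.null(outdir)) write_simulation(sim, outdir)
  sim
}

#' Write a simulated study to disk
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  }
  write_catalog(sim$catalogs$reference, file.path(outdir, "reference.gtf"))
  write_catalog(sim$catalogs$assembled, file.path(outdir, "assembled.gtf"))
  sampdir <- file.path(outdir, "samples")
  dir.create(sampdir, showWarnings = FALSE)
  for (nm in names(sim$cohort$sample_catalogs))
    write_catalog(sim$cohort$sample_catalogs[[nm]],
                  file.path(sampdir, paste0(nm, ".gtf")))
  tsv(data.frame(path = file.path("samples",
                                  paste0(names(sim$cohort$sample_catalogs), ".gtf")),
                 condition = sim$cohort$conditions), "sample_manifest.tsv")
  tsv(sim$fractions$cyto, "fpkm_cyto.tsv", rn = TRUE)
  tsv(sim$fractions$nuc, "fpkm_nuc.tsv", rn = TRUE)
  writeLines(sim$fractions$housekeeping, file.path(outdir, "housekeeping.txt"))
  tsv(sim$cohort$counts_tumor, "counts_tumor.tsv", rn = TRUE)
  tsv(sim$cohort$counts_adjacent, "counts_adjacent.tsv", rn = TRUE)
  tsv(sim$cohort$tpm, "tpm.tsv", rn = TRUE)
  for (nm in names(sim$method_tables)) {
    mt <- sim$method_tables[[nm]]
    tsv(data.frame(transcript_id = mt$transcript_id, method = mt$method,
                   log2fc = mt$log2_fold_change, pvalue = mt$p_value,
                   padj = mt$adjusted_p, ppde = mt$ppde),
        paste0("de_", nm, ".tsv"))
  }
  tsv(sim$cp_labels, "cp_labels.tsv")
  tsv(sim$cohort$survival, "survival.tsv")
  tsv(sim$characterization$embryo, "embryo_tpm.tsv")
  peakdir <- file.path(outdir, "peaks")
  dir.create(peakdir, showWarnings = FALSE)
  man <- do.call(rbind, lapply(sim$characterization$peak_sets, function(ps) {
    f <- file.path("peaks", paste0(ps$epigenome_id, ".bed"))
    pk <- ps$peaks
    utils::write.table(
      data.frame(pk$chrom, format(pk$start, scientific = FALSE, trim = TRUE),
                 format(pk$end, scientific = FALSE, trim = TRUE)),
      file.path(outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    data.frame(epigenome_id = ps$epigenome_id, category = ps$category,
               path = f, stringsAsFactors = FALSE)
  }))
  tsv(man, "peak_manifest.tsv")
  tsv(sim$coexpression$tpm, "coexpr_tpm.tsv", rn = TRUE)
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       digits = NA, na = "null")
  invisible(outdir)
}
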