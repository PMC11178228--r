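test_that("empty genome request yields empty but valid outputs", {
  g <- simulate_genome(genome_spec(n_genes = 0), 1)
  expect_s3_class(g, "sim_genome")
  expect_length(g$sequences, 0)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$introns), 0)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  expect_length(Biostrings::readDNAStringSet(fa), 0)
})

test_that("degeneracy-0 introns carry exact consensus motifs", {
  spec <- genome_spec(n_genes = 8, frac_intron_genes = 1, degeneracy = 0)
  g <- simulate_genome(spec, 42)
  seqs <- as.character(intron_sequences(g$introns, g$sequences))
  expect_gt(length(seqs), 0)
  expect_true(all(substr(seqs, 1, 6) == "GTAAGT"))
  expect_true(all(substring(seqs, nchar(seqs) - 2) == "TAG"))
  # branch point ends 10 nt upstream of the intron 3' end
  bp <- substr(seqs, nchar(seqs) - 14, nchar(seqs) - 10)
  expect_true(all(bp == "CTAAC"))
  expect_true(all(g$introns$mismatch_5ss == 0))
})

test_that("invariant GT/AG dinucleotides survive degeneracy", {
  spec <- genome_spec(n_genes = 30, frac_intron_genes = 1, degeneracy = 0.5)
  g <- simulate_genome(spec, 7)
  seqs <- as.character(intron_sequences(g$introns, g$sequences))
  expect_true(all(substr(seqs, 1, 2) == "GT"))
  expect_true(all(substring(seqs, nchar(seqs) - 1) == "AG"))
})

test_that("genome simulation is deterministic and insensitive to growth", {
  spec <- genome_spec(n_genes = 25)
  a <- simulate_genome(spec, 5)
  b <- simulate_genome(spec, 5)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$introns, b$introns)
  # adding genes does not perturb earlier ones
  big <- simulate_genome(genome_spec(n_genes = 40), 5)
  expect_identical(big$genes$n_introns[1:25], a$genes$n_introns)
  expect_identical(
    big$introns$length[big$introns$gene_id %in% a$genes$gene_id],
    a$introns$length)
})

test_that("transcription rates are log-normal with the requested centre", {
  g <- list(gene_id = sprintf("g%d", 1:10000))
  r <- assign_rates(as.data.frame(g), mu = 2, sigma = 1, seed = 3)
  expect_true(all(r$rate > 0))
  expect_lt(abs(mean(log(r$rate)) - 2), 0.05)
  # degenerate sigma
  r0 <- assign_rates(as.data.frame(g), mu = 2, sigma = 0, seed = 3)
  expect_true(all(r0$rate == exp(2)))
  expect_identical(assign_rates(as.data.frame(g), 2, 1, 3)$rate, r$rate)
  expect_equal(nrow(assign_rates(data.frame(gene_id = character()), 2, 1, 3)),
               0)
})

test_that("defect model kinds transform the baseline as specified", {
  genes <- data.frame(gene_id = c("a", "b"))
  introns <- data.frame(intron_id = c("a.i1", "a.i2", "b.i1"),
                        gene_id = c("a", "a", "b"),
                        intron_index = c(1L, 2L, 1L),
                        mismatch_5ss = c(0L, 3L, 6L))
  rates <- data.frame(gene_id = c("a", "b"), rate = c(10, 10))

  none <- apply_defect_model(genes, introns, rates, defect_model("none"), 1)
  expect_equal(none$true_se, none$baseline_se)

  full <- apply_defect_model(genes, introns, rates,
                             defect_model("motif_dependent", gamma = 1), 1)
  # m = 6 mismatches with gamma = 1 abolishes splicing
  expect_equal(full$true_se[3], 0)
  expect_equal(full$true_se[1], full$baseline_se[1])
  expect_equal(full$true_se[2], full$baseline_se[2] * (1 - 3 / 6))

  expect_error(defect_model("motif_dependent", gamma = 1.5), "gamma")
})

test_that("transcription-coupled affection matches the logistic closed form", {
  n <- 10000
  genes <- data.frame(gene_id = sprintf("g%d", 1:n))
  introns <- data.frame(intron_id = sprintf("g%d.i1", 1:n),
                        gene_id = genes$gene_id, intron_index = 1L)
  model <- defect_model("transcription_coupled", alpha = -6, beta = 3)
  p_hat <- vapply(c(2, 0), function(lr) {
    rates <- data.frame(gene_id = genes$gene_id, rate = exp(lr))
    tt <- apply_defect_model(genes, introns, rates, model, 11)
    mean(tt$gene_affected)
  }, 0)
  # sigmoid(-6 + 3*2) = 0.5 ; sigmoid(-6) ~ 0.0025
  expect_lt(abs(p_hat[1] - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(p_hat[2] - plogis(-6)), 3 * sqrt(0.0025 / n) + 1e-3)
})

test_that("junction-count emission respects the binomial model", {
  truth <- data.frame(intron_id = sprintf("i%d", 1:200),
                      true_se = 0.7, true_rate = 5000)
  jc <- simulate_junction_counts(truth, depth = 1, seed = 9)
  se <- splicing_efficiency(jc)
  expect_true(all(abs(se$se - 0.7) < 0.02))

  perfect <- data.frame(intron_id = "i1", true_se = 1, true_rate = 100)
  jp <- simulate_junction_counts(perfect, depth = 1, seed = 2)
  expect_equal(jp$unspliced5 + jp$unspliced3, 0L)

  expect_error(simulate_junction_counts(truth, depth = 0, seed = 1),
               "depth")
  expect_identical(simulate_junction_counts(truth, 1, 9), jc)
})

test_that("gene-count simulation hits configured fold changes", {
  rates <- data.frame(gene_id = sprintf("g%d", 1:50), rate = 100)
  # Poisson limit, no DE: group means agree
  m <- simulate_gene_counts(rates, dispersion = Inf, n_reps = 2, seed = 1,
                            depth = 10)
  grp <- attr(m, "groups")
  ratio <- rowMeans(m[, grp == "mut"]) / rowMeans(m[, grp == "WT"])
  expect_lt(abs(mean(ratio) - 1), 0.05)

  # fold-change recovery over many NB replicates
  de <- data.frame(gene_id = "g1", fold_change = 4)
  m2 <- simulate_gene_counts(rates, de, dispersion = 5, n_reps = 100,
                             seed = 2, depth = 10)
  grp2 <- attr(m2, "groups")
  r <- mean(m2["g1", grp2 == "mut"]) / mean(m2["g1", grp2 == "WT"])
  expect_lt(abs(r - 4) / 4, 0.25)

  expect_error(simulate_gene_counts(rates, dispersion = 0), "dispersion")
  empty <- simulate_gene_counts(data.frame(gene_id = character(),
                                           rate = numeric()))
  expect_equal(nrow(empty), 0)
})

test_that("plate simulation couples YFP to splicing efficiency", {
  se_map <- data.frame(strain = c("hi", "half", "zero"), reporter = "wt",
                       se = c(1, 0.5, 0))
  layout <- data.frame(well = c("A1", "A2", "A3", "A4"),
                       strain = c("hi", "half", "zero", "untr"),
                       reporter = c("wt", "wt", "wt", "none"),
                       role = c("sample", "sample", "sample",
                                "autofluor_control"))
  params <- cytometry_sim_params(n_events_per_well = 20000,
                                 se_map = se_map,
                                 autofluor_yfp_mean = 0,
                                 autofluor_yfp_sd = 0)
  plate <- simulate_plate(layout, params, 3)
  expect_true(all(plate$A3[["FITC-A"]] == 0))
  med <- vapply(plate[c("A1", "A2")], function(w)
    median(w[["FITC-A"]]) /
      (median(w[["PETexasRed-A"]]) -
         median(plate$A4[["PETexasRed-A"]])), 0)
  expect_lt(abs(med["A1"] / med["A2"] - 2), 0.1)
  expect_identical(simulate_plate(layout, params, 3)$A1, plate$A1)
  bad <- layout; bad$strain[1] <- "nope"
  expect_error(simulate_plate(bad, params, 3), "se_map")
})

test_that("efficiency recovery: estimates track truth at deep coverage", {
  run <- make_toy_se_run(seed = 6, n_genes = 150, kind = "none",
                         depth = 150)
  truth_wt <- run$truth[run$truth$genotype == "WT", ]
  true_se <- stats::setNames(truth_wt$true_se, truth_wt$intron_id)
  est <- run$se_wt[!is.na(run$se_wt)]
  # restrict to deep introns (expected boundary reads >= 5000)
  deep <- names(est)[2 * 150 *
                       truth_wt$true_rate[match(names(est),
                                                truth_wt$intron_id)] >= 5000]
  err <- abs(est[deep] - true_se[deep])
  expect_gte(mean(err < 0.02), 0.95)
})

test_that("defect structure: coupling is gene-level only when transcription-coupled", {
  run_tc <- make_toy_se_run(seed = 4, n_genes = 300,
                            kind = "transcription_coupled")
  tt <- run_tc$truth
  d <- tt[tt$genotype == "WT", "true_se"] -
    tt[tt$genotype == "mut", "true_se"]
  gene <- tt$gene_id[tt$genotype == "WT"]
  multi <- names(which(table(gene) >= 2))
  # within-gene correlation of the WT - mut drop across intron pairs
  pairs <- do.call(rbind, lapply(multi, function(gn) {
    idx <- which(gene == gn)
    t(utils::combn(idx, 2))
  }))
  expect_gt(cor(d[pairs[, 1]], d[pairs[, 2]]), 0.5)

  run_md <- make_toy_se_run(seed = 4, n_genes = 300,
                            kind = "motif_dependent")
  ttm <- run_md$truth
  dm <- ttm[ttm$genotype == "WT", "true_se"] -
    ttm[ttm$genotype == "mut", "true_se"]
  mism <- run_md$genome$introns$mismatch_5ss
  # motif model: drop is driven by 5'SS mismatches, not shared gene state
  worst <- order(-dm)[seq_len(ceiling(0.05 * length(dm)))]
  expect_gt(mean(mism[worst]), mean(mism))
})
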