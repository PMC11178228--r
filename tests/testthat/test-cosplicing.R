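toy_profiles <- function() {
  # four 3-intron genes; A and B are hit at intron 1 in the mutant
  data.frame(
    gene_id = rep(c("A", "B", "C", "D"), each = 3),
    intron_index = rep(1:3, 4),
    intron_id = sprintf("%s.i%d", rep(c("A", "B", "C", "D"), each = 3),
                        rep(1:3, 4)),
    se_wt = rep(c(0.9, 0.8, 0.9, 0.95), each = 3),
    se_mut = c(0.2, 0.3, 0.25,   # A: affected
               0.3, 0.2, 0.35,   # B: affected
               0.88, 0.78, 0.89, # C: unaffected
               0.94, 0.93, 0.94))
}

test_that("co-splicing profiles average over anchor-filtered genes", {
  p <- toy_profiles()
  prof <- cosplicing_profile(p, anchor = 1, threshold = 0.5, "<")
  expect_setequal(prof$gene_set, c("A", "B"))
  expect_equal(prof$profile$mean_se_mut,
               c(mean(c(0.2, 0.3)), mean(c(0.3, 0.2)),
                 mean(c(0.25, 0.35))))
  expect_equal(prof$profile$mean_se_wt, rep(mean(c(0.9, 0.8)), 3))

  ctrl <- cosplicing_profile(p, anchor = 1, threshold = 0.9, ">")
  expect_setequal(ctrl$gene_set, c("C", "D"))

  none <- cosplicing_profile(p, anchor = 1, threshold = 0.01, "<")
  expect_equal(none$n_genes, 0)
  expect_equal(nrow(none$profile), 0)
})

test_that("gene profiles keep only fully quantified n-intron genes", {
  introns <- data.frame(
    intron_id = c("A.i1", "A.i2", "A.i3", "B.i1", "B.i2", "B.i3",
                  "C.i1", "C.i2"),
    gene_id = c(rep("A", 3), rep("B", 3), rep("C", 2)),
    intron_index = c(1:3, 1:3, 1:2))
  se_wt <- stats::setNames(rep(0.9, 8), introns$intron_id)
  se_mut <- se_wt; se_mut["B.i2"] <- NA
  prof <- gene_splice_profiles(se_wt, se_mut, introns, n_introns = 3)
  # B dropped for the NA, C for having two introns
  expect_setequal(unique(prof$gene_id), "A")
})

test_that("anchored defects propagate along the gene only under coupling", {
  run <- make_toy_se_run(seed = 19, n_genes = 500,
                         kind = "transcription_coupled", depth = 20)
  fpkm <- data.frame(gene_id = run$rates$gene_id, fpkm = run$rates$rate)
  prof <- gene_splice_profiles(run$se_wt, run$se_mut,
                               run$genome$introns, fpkm)
  case <- cosplicing_profile(prof, 1, 0.5, "<")
  ctrl <- cosplicing_profile(prof, 1, 0.9, ">")
  expect_gt(case$n_genes, 0)
  non_anchor <- case$profile$intron_index != 1
  drop_case <- mean(case$profile$mean_se_wt[non_anchor] -
                      case$profile$mean_se_mut[non_anchor])
  drop_ctrl <- mean(ctrl$profile$mean_se_wt[non_anchor] -
                      ctrl$profile$mean_se_mut[non_anchor])
  expect_gt(drop_case, drop_ctrl + 0.2)
})

test_that("expression association compares host-gene FPKM of extremes", {
  introns <- data.frame(intron_id = sprintf("i%d", 1:6),
                        gene_id = sprintf("g%d", 1:6),
                        intron_index = 1L)
  ranked <- data.frame(intron_id = sprintf("i%d", 1:6),
                       se_wt = 0.9, se_mut = seq(0.1, 0.6, by = 0.1),
                       score = seq(0.8, 0.3, by = -0.1))
  fpkm <- data.frame(gene_id = sprintf("g%d", 1:6),
                     fpkm = c(100, 90, 80, 3, 2, 1))
  ea <- expression_association(ranked, introns, fpkm, k = 3)
  expect_equal(ea$mean_fpkm_worst, 90)
  expect_equal(ea$mean_fpkm_best, 2)
  o <- oracle_welch(log(c(100, 90, 80)), log(c(1, 2, 3)))
  expect_equal(ea$p_value, o$p, tolerance = 1e-12)

  # constant FPKM: no signal
  flat <- data.frame(gene_id = sprintf("g%d", 1:6), fpkm = 5)
  ef <- expression_association(ranked, introns, flat, k = 3)
  expect_equal(ef$mean_fpkm_worst, ef$mean_fpkm_best)
  expect_gte(ef$p_value, 0.999)

  # shortfall: fewer than k introns available per side
  expect_message(
    es <- expression_association(ranked, introns, fpkm, k = 50),
    "available")
  expect_equal(es$k_used, 3)
})

test_that("cumulative mature fraction is the product of efficiencies", {
  expect_equal(cumulative_mature_fraction(numeric(0)), 1)
  expect_equal(cumulative_mature_fraction(0.6), 0.6)
  expect_equal(cumulative_mature_fraction(c(0.74, 0.71, 0.95, 0.85)),
               0.4242605, tolerance = 1e-7)
  # permutation invariance, monotone decrease, bounded by smallest factor
  x <- c(0.9, 0.7, 0.95, 0.6)
  for (i in 1:5) {
    p <- sample(x)
    expect_equal(cumulative_mature_fraction(p),
                 cumulative_mature_fraction(x))
  }
  expect_lte(cumulative_mature_fraction(c(x, 0.5)),
             cumulative_mature_fraction(x))
  expect_lte(cumulative_mature_fraction(x), min(x))
  expect_error(cumulative_mature_fraction(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fpkm normalises by exonic kilobases and library millions", {
  counts <- c(g1 = 100, g2 = 300)
  len <- c(g1 = 1000, g2 = 2000)
  f <- fpkm_from_counts(counts, len)
  # library of 400 reads = 4e-4 million; g1 length 1 kb
  expect_equal(unname(f["g1"]), 100 / (1 * 400e-6), tolerance = 1e-12)
  expect_equal(unname(f["g2"]), 300 / (2 * 400e-6), tolerance = 1e-12)
})

test_that("percent splicing and retention are complementary", {
  expect_equal(percent_splicing(3, 1), 75)
  expect_equal(percent_splicing(5, 0), 100)
  expect_equal(percent_splicing(0, 5), 0)
  expect_equal(percent_retention(0, 5), 100)
  for (s in c(0.3, 2, 11)) for (u in c(0.1, 4))
    expect_equal(percent_splicing(s, u) + percent_retention(s, u), 100)
  expect_warning(out <- percent_splicing(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(percent_splicing(-1, 2), "non-negative")
})
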