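mk_events <- function(fsc, fsch = fsc, ssc = fsc, yfp = 1, red = 1) {
  d <- data.frame(fsc, fsch, ssc, yfp, red)
  names(d) <- c("FSC-A", "FSC-H", "SSC-A", "FITC-A", "PETexasRed-A")
  d
}

# drop the per-stage gate log and row names before comparing event content
strip_events <- function(d) {
  attr(d, "gate_log") <- NULL
  rownames(d) <- NULL
  d
}

test_that("gating filters by explicit bounds and is idempotent", {
  ev <- mk_events(fsc = c(5, 10, 20, 30, 50, 100),
                  fsch = c(5, 10, 20, 30, 50, 100),
                  ssc = c(5, 10, 20, 30, 50, 100))
  g <- gate_config(fsc_bounds = c(8, 60), ssc_bounds = c(8, 60),
                   singlet_slope = 1)
  out <- gate_events(ev, g)
  # hand enumeration: rows 2..5 are inside both scatter rectangles
  expect_equal(out[["FSC-A"]], c(10, 20, 30, 50))
  expect_equal(strip_events(gate_events(out, g)), strip_events(out))

  # empty table and full-range gates
  expect_equal(nrow(gate_events(ev[0, ], g)), 0)
  wide <- gate_config(c(-Inf, Inf), c(-Inf, Inf), singlet_slope = 1,
                      singlet_tol = 1e6)
  expect_equal(strip_events(gate_events(ev, wide)), strip_events(ev))

  expect_error(gate_events(ev[, -1], g), "missing channel")

  # optional fluorescence stage filters on FITC-A / PETexasRed-A bounds
  ev$`FITC-A` <- c(1, 5, 50, 500, 5, 5)
  gf <- gate_config(c(8, 60), c(8, 60), singlet_slope = 1,
                    fluor_bounds = list(yfp = c(0, 100)))
  expect_equal(gate_events(ev, gf)[["FSC-A"]], c(10, 20, 50))
})

test_that("singlet gate removes FSC-H outliers", {
  ev <- mk_events(fsc = c(100, 100, 100), fsch = c(100, 95, 50))
  g <- gate_config(c(0, 1000), c(0, 1000), singlet_slope = 1,
                   singlet_tol = 0.25)
  expect_equal(nrow(gate_events(ev, g)), 2)
})

test_that("gating idempotence holds on simulated wells", {
  plate <- make_toy_plate("s1", n_events = 1000, n_reps = 1, seed = 2)
  for (w in names(plate)) {
    g <- fit_gates(plate[[w]])
    once <- gate_events(plate[[w]], g)
    twice <- gate_events(once, g)
    expect_identical(strip_events(twice), strip_events(once))
  }
})

test_that("well summaries report medians and the 1000-event QC rule", {
  ev <- mk_events(fsc = rep(1, 5), yfp = c(1, 2, 3, 4, 5),
                  red = c(1, 9, 2, 8, 5))
  meta <- list(well_id = "A1", strain_id = "s", reporter_id = "r")
  s <- summarize_well(ev, meta, min_events = 3)
  expect_equal(s$median_red, oracle_median(c(1, 9, 2, 8, 5)))
  expect_equal(s$median_red, 5)

  one <- summarize_well(mk_events(1, yfp = 7, red = 3), meta, 1)
  expect_equal(c(one$median_yfp, one$median_red), c(7, 3))

  big <- mk_events(fsc = rep(1, 1000))
  expect_false(summarize_well(big[1:999, ], meta)$qc_pass)
  expect_true(summarize_well(big, meta)$qc_pass)

  zero <- summarize_well(big[0, ], meta)
  expect_true(is.na(zero$median_yfp))
  expect_false(zero$qc_pass)
})

test_that("autofluorescence correction subtracts the control red median", {
  wells <- data.frame(well_id = c("A1", "A2"), strain_id = "s",
                      reporter_id = "r", n_gated = 2000,
                      median_yfp = c(800, 300), median_red = c(500, 100),
                      corrected_red = NA_real_, ratio = NA_real_,
                      qc_pass = TRUE)
  ctrl <- data.frame(well_id = "H12", median_red = 100, median_yfp = 10,
                     qc_pass = TRUE)
  out <- correct_autofluorescence(wells, ctrl)
  expect_equal(out$corrected_red, c(400, 0))
  expect_equal(out$ratio, c(2, NA))

  ctrl0 <- ctrl; ctrl0$median_red <- 0
  out0 <- correct_autofluorescence(wells, ctrl0)
  expect_equal(out0$corrected_red, wells$median_red)

  both <- correct_autofluorescence(wells, ctrl, channels = "both")
  expect_equal(both$corrected_yfp, c(790, 290))
  expect_equal(both$ratio[1], 790 / 400)

  bad <- ctrl; bad$qc_pass <- FALSE
  expect_error(correct_autofluorescence(wells, bad), "H12")
})

test_that("hit calling matches a hand-computed Welch t-test", {
  ratios <- data.frame(
    strain = rep(c("mut", "WT"), each = 3),
    ratio = c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9))
  res <- call_hits(ratios, "WT")
  o <- oracle_welch(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9))
  expect_equal(res$p_value, o$p, tolerance = 1e-12)
  expect_equal(res$log2fc, log2(1 / 2), tolerance = 1e-12)
  expect_true(res$significant)

  # identical constant replicates: no effect, not significant
  flat <- data.frame(strain = rep(c("s", "WT"), each = 3), ratio = 2)
  rf <- call_hits(flat, "WT")
  expect_equal(rf$log2fc, 0)
  expect_false(rf$significant)

  # single replicate: p NA, never a hit
  single <- rbind(ratios, data.frame(strain = "solo", ratio = 5))
  rs <- call_hits(single, "WT")
  expect_true(is.na(rs$p_value[rs$strain == "solo"]))
  expect_false(rs$significant[rs$strain == "solo"])

  expect_error(call_hits(data.frame(strain = "WT", ratio = 1), "WT"),
               "replicates")
})

test_that("corrected ratios increase monotonically with true SE", {
  ses <- c(0, 0.2, 0.5, 0.8, 1.0)
  strains <- sprintf("s%d", seq_along(ses))
  ok <- vapply(1:20, function(seed) {
    plate <- make_toy_plate(strains,
                            planted_se = stats::setNames(ses, strains),
                            n_events = 1500, n_reps = 2, seed = seed)
    res <- run_screen_workflow(list(plate = plate, seed = seed,
                                    min_events = 500))
    r <- tapply(res$wells$ratio, res$wells$strain_id, mean)[strains]
    all(diff(r) > 0)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("ratio is gain-invariant jointly and linear in YFP coupling", {
  base <- list(n_events = 5000, n_reps = 2, seed = 8,
               autofluor_yfp_mean = 0, autofluor_yfp_sd = 0,
               autofluor_red_mean = 0, autofluor_red_sd = 0)
  ratio_of <- function(...) {
    plate <- do.call(make_toy_plate,
                     c(list(strains = "s1",
                            planted_se = c(s1 = 0.5)), base, list(...)))
    res <- run_screen_workflow(list(plate = plate, seed = 8,
                                    min_events = 500))
    res$wells$ratio[res$wells$strain_id == "s1"][1]
  }
  r1 <- ratio_of()
  r_scaled <- ratio_of(coupling_red = 3, coupling_yfp = 3)
  r_yfp <- ratio_of(coupling_yfp = 2)
  expect_equal(r_scaled, r1, tolerance = 1e-6)
  expect_equal(r_yfp, 2 * r1, tolerance = 1e-6)
})

test_that("null screens call about 5% of strains at p < 0.05", {
  # reduced null simulation: replicate ratios drawn from the reference
  # distribution, no true effects
  n_sims <- 400; n_strains <- 10
  fp <- with_seed_local <- NULL
  set.seed(101)
  fp <- vapply(seq_len(n_sims), function(i) {
    ratios <- data.frame(
      strain = rep(c(sprintf("s%d", seq_len(n_strains)), "WT"), each = 3),
      ratio = rnorm(3 * (n_strains + 1), mean = 1, sd = 0.05))
    mean(call_hits(ratios, "WT")$p_value < 0.05)
  }, 0)
  n_tests <- n_sims * n_strains
  expect_lt(mean(fp), 0.05 + 3 * sqrt(0.05 * 0.95 / n_tests))
})
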