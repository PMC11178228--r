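# Independent brute-force oracles used across tests. These deliberately
# avoid the code paths they check.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_pearson <- function(x, y) {
  xm <- sum(x) / length(x); ym <- sum(y) / length(y)
  sum((x - xm) * (y - ym)) /
    sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# median-of-ratios by explicit loops over genes and samples
oracle_size_factors <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[pos, , drop = FALSE], 1,
               function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j)
    oracle_median(m[pos, j] / geo), 0)
}

# position probabilities and information content by direct table counting
oracle_ppm_info <- function(windows) {
  W <- nchar(windows[1])
  bases <- c("A", "C", "G", "T")
  ppm <- matrix(0, 4, W, dimnames = list(bases, NULL))
  for (j in seq_len(W)) {
    col <- substr(windows, j, j)
    col <- col[col %in% bases]
    for (b in bases) ppm[b, j] <- sum(col == b) / length(col)
  }
  info <- numeric(W)
  for (j in seq_len(W)) {
    h <- 0
    for (b in bases) {
      p <- ppm[b, j]
      if (p > 0) h <- h - p * log2(p)
    }
    info[j] <- 2 - h
  }
  list(ppm = ppm, info = info)
}

# a tiny genome + two-genotype truth + SE tables, shared by several tests
make_toy_se_run <- function(seed = 1, n_genes = 200,
                            kind = "transcription_coupled",
                            depth = 5, ...) {
  spec <- genome_spec(n_genes = n_genes)
  g <- simulate_genome(spec, subseed(seed, 1))
  rates <- assign_rates(g$genes, 3, 1.2, subseed(seed, 2))
  truth <- simulate_truth_table(
    g$genes, g$introns, rates,
    list(WT = defect_model("none"), mut = defect_model(kind, ...)),
    subseed(seed, 3))
  jc <- simulate_junction_counts(truth, depth, subseed(seed, 4))
  se <- splicing_efficiency(jc)
  se_of <- function(gt) {
    d <- se[se$genotype == gt, ]
    stats::setNames(d$se, d$intron_id)
  }
  list(genome = g, rates = rates, truth = truth, se_table = se,
       se_wt = se_of("WT"), se_mut = se_of("mut"))
}

with_seed_rates <- function(seed, n = 150) {
  set.seed(seed)
  rlnorm(n, 3, 1)
}

# standard small plate fixture: mutant strains at reference efficiency
# except planted ones, plus reference and autofluorescence control wells
make_toy_plate <- function(strains, planted_se = c(), ref_se = 0.9,
                           n_events = 2000, n_reps = 3, seed = 1, ...) {
  layout <- make_screen_layout(strains, n_reps = n_reps)
  se <- rep(ref_se, length(strains))
  se[match(names(planted_se), strains)] <- planted_se
  se_map <- data.frame(strain = c(strains, "WT"),
                       reporter = "dmut", se = c(se, ref_se))
  params <- cytometry_sim_params(n_events_per_well = n_events,
                                 se_map = se_map, ...)
  simulate_plate(layout, params, seed)
}
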