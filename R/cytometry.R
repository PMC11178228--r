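#' Concrete gate configuration for cytometry events
#'
#' Gates are pure filters applied in fixed order: scatter (FSC-A, SSC-A
#' rectangle) -> singlet (FSC-H within a relative band around a line through
#' the origin in FSC-A) -> optional fluorescence rectangle. Because bounds
#' are concrete, gating is idempotent. Use [fit_gates()] to estimate bounds
#' from data.
#'
#' @param fsc_bounds,ssc_bounds numeric length-2 `(lo, hi)` scatter bounds.
#' @param singlet_slope slope of the FSC-H vs FSC-A singlet line.
#' @param singlet_tol relative half-width of the singlet acceptance band
#'   (default 0.25: FSC-H within +/-25% of `slope * FSC-A`).
#' @param fluor_bounds optional named list with `yfp` and/or `red`
#'   length-2 bounds on FITC-A / PETexasRed-A.
#' @return an object of class `"gate_config"`.
#' @export
gate_config <- function(fsc_bounds, ssc_bounds, singlet_slope = 1,
                        singlet_tol = 0.25, fluor_bounds = NULL) {
  stopifnot(length(fsc_bounds) == 2L, length(ssc_bounds) == 2L)
  structure(list(fsc_bounds = sort(fsc_bounds),
                 ssc_bounds = sort(ssc_bounds),
                 singlet_slope = check_positive(singlet_slope,
                                                "singlet_slope"),
                 singlet_tol = check_positive(singlet_tol, "singlet_tol"),
                 fluor_bounds = fluor_bounds),
            class = "gate_config")
}

required_channels <- c("FSC-A", "FSC-H", "SSC-A", "FITC-A", "PETexasRed-A")

check_channels <- function(events) {
  miss <- setdiff(required_channels, names(events))
  if (length(miss))
    stop("event table is missing channel column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(events)
}

#' Estimate gate bounds from an event table
#'
#' Scatter bounds are the central density quantiles of FSC-A and SSC-A
#' (default central 90%); the singlet line slope is the median FSC-H/FSC-A
#' ratio (robust to doublets). The returned [gate_config()] holds concrete
#' bounds, so the subsequent [gate_events()] filter is idempotent.
#'
#' @param events event data frame with the standard channel columns.
#' @param scatter_quantiles length-2 quantile pair for scatter bounds.
#' @param singlet_tol relative singlet band half-width.
#' @return a [gate_config()].
#' @export
fit_gates <- function(events, scatter_quantiles = c(0.05, 0.95),
                      singlet_tol = 0.25) {
  check_channels(events)
  if (nrow(events) == 0L)
    return(gate_config(c(-Inf, Inf), c(-Inf, Inf), 1, singlet_tol))
  fscq <- quantile(events[["FSC-A"]], scatter_quantiles, names = FALSE)
  sscq <- quantile(events[["SSC-A"]], scatter_quantiles, names = FALSE)
  slope <- median(events[["FSC-H"]] / events[["FSC-A"]])
  gate_config(fscq, sscq, slope, singlet_tol)
}

#' Filter events through the hierarchical gate sequence
#'
#' Applies scatter, then singlet, then (if configured) fluorescence gates.
#' Per-stage retained counts are attached as attribute `"gate_log"`. With
#' `gates = NULL`, bounds are first estimated from the input via
#' [fit_gates()].
#'
#' @param events event data frame (may be empty).
#' @param gates a [gate_config()], or `NULL` to fit from `events`.
#' @return the subset of `events` passing all gates.
#' @export
gate_events <- function(events, gates = NULL) {
  check_channels(events)
  if (is.null(gates)) gates <- fit_gates(events)
  stopifnot(inherits(gates, "gate_config"))
  n0 <- nrow(events)
  keep <- events[["FSC-A"]] >= gates$fsc_bounds[1] &
    events[["FSC-A"]] <= gates$fsc_bounds[2] &
    events[["SSC-A"]] >= gates$ssc_bounds[1] &
    events[["SSC-A"]] <= gates$ssc_bounds[2]
  s1 <- events[keep, , drop = FALSE]
  expect_h <- gates$singlet_slope * s1[["FSC-A"]]
  keep2 <- abs(s1[["FSC-H"]] - expect_h) <= gates$singlet_tol * abs(expect_h)
  s2 <- s1[keep2, , drop = FALSE]
  s3 <- s2
  if (!is.null(gates$fluor_bounds)) {
    keep3 <- rep(TRUE, nrow(s2))
    fb <- gates$fluor_bounds
    if (!is.null(fb$yfp))
      keep3 <- keep3 & s2[["FITC-A"]] >= fb$yfp[1] &
        s2[["FITC-A"]] <= fb$yfp[2]
    if (!is.null(fb$red))
      keep3 <- keep3 & s2[["PETexasRed-A"]] >= fb$red[1] &
        s2[["PETexasRed-A"]] <= fb$red[2]
    s3 <- s2[keep3, , drop = FALSE]
  }
  attr(s3, "gate_log") <- data.frame(
    stage = c("input", "scatter", "singlet", "fluorescence"),
    n = c(n0, nrow(s1), nrow(s2), nrow(s3)))
  s3
}

#' Summarize a gated well: medians, event count, QC flag
#'
#' Medians of the raw FITC-A (YFP) and PETexasRed-A (RFP) channels over the
#' gated population. Wells with fewer than `min_events` gated events fail QC
#' (default 1000, the minimal event count considered trustworthy). The
#' corrected red value and the ratio are left `NA` until
#' [correct_autofluorescence()] is applied.
#'
#' @param gated gated event data frame from [gate_events()].
#' @param meta named list or one-row data frame with `well_id`, `strain_id`,
#'   `reporter_id`.
#' @param min_events QC threshold on gated event count.
#' @return one-row `WellSummary` data frame: `well_id`, `strain_id`,
#'   `reporter_id`, `n_gated`, `median_yfp`, `median_red`, `corrected_red`,
#'   `ratio`, `qc_pass`.
#' @export
summarize_well <- function(gated, meta, min_events = 1000L) {
  check_channels(gated)
  n <- nrow(gated)
  data.frame(
    well_id = meta$well_id, strain_id = meta$strain_id,
    reporter_id = meta$reporter_id,
    n_gated = n,
    median_yfp = if (n) median(gated[["FITC-A"]]) else NA_real_,
    median_red = if (n) median(gated[["PETexasRed-A"]]) else NA_real_,
    corrected_red = NA_real_, ratio = NA_real_,
    qc_pass = n >= min_events
  )
}

#' Subtract control-strain autofluorescence and compute YFP/RFP ratios
#'
#' The untransformed wild-type control well's PE-Texas Red median is
#' subtracted from every well's red median; the ratio is then
#' `median_yfp / corrected_red`. With `channels = "both"` the control's
#' FITC median is subtracted from the numerator as well (the default
#' corrects the red channel only). The ratio is `NA` whenever the corrected
#' red is non-positive or the well failed QC.
#'
#' @param wells `WellSummary` data frame (rows from [summarize_well()]).
#' @param wt_control one-row `WellSummary` for the autofluorescence control;
#'   must pass QC.
#' @param channels `"red_only"` (default) or `"both"`.
#' @return `wells` with `corrected_red` (and `corrected_yfp` when
#'   `channels = "both"`) and `ratio` filled in.
#' @export
correct_autofluorescence <- function(wells, wt_control,
                                     channels = c("red_only", "both")) {
  channels <- match.arg(channels)
  if (!isTRUE(wt_control$qc_pass))
    stop(sprintf("autofluorescence control well '%s' failed QC",
                 wt_control$well_id), call. = FALSE)
  wells$corrected_red <- wells$median_red - wt_control$median_red
  num <- wells$median_yfp
  if (channels == "both") {
    wells$corrected_yfp <- wells$median_yfp - wt_control$median_yfp
    num <- wells$corrected_yfp
  }
  ratio <- num / wells$corrected_red
  ratio[wells$corrected_red <= 0 | !wells$qc_pass] <- NA_real_
  wells$ratio <- ratio
  wells
}

# Welch two-sided t-test p-value with a guard for zero-variance samples.
welch_p <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  t.test(x, y, var.equal = FALSE)$p.value
}

#' Call screen hits from replicate YFP/RFP ratios
#'
#' Each strain's replicate ratios are compared with the reference strain's
#' by a two-sided Welch t-test; the effect size is the log2 fold change of
#' strain mean over reference mean. A strain is significant when its
#' (optionally multiplicity-adjusted) p-value is below `p_threshold` and
#' `|log2fc| >= lfc_threshold`. Strains with fewer than 2 replicates get an
#' `NA` p-value and are never significant.
#'
#' @param ratios data frame with columns `strain` and `ratio` (one row per
#'   replicate well); `NA` ratios are dropped.
#' @param reference_strain the control strain name (>= 2 replicates).
#' @param p_threshold,lfc_threshold significance thresholds; p is exclusive
#'   (`p < p_threshold`), log2fc inclusive (`|log2fc| >= lfc_threshold`).
#' @param p_adjust method passed to [stats::p.adjust()] (`"none"` by
#'   default: the screen reports raw p-values; `"BH"` enables
#'   Benjamini-Hochberg).
#' @return `ScreenResult` data frame sorted by p-value: `strain`,
#'   `n_replicates`, `mean_ratio`, `reference_ratio`, `log2fc`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
call_hits <- function(ratios, reference_strain, p_threshold = 0.05,
                      lfc_threshold = 0, p_adjust = "none") {
  stopifnot(all(c("strain", "ratio") %in% names(ratios)))
  ratios <- ratios[!is.na(ratios$ratio), ]
  ref <- ratios$ratio[ratios$strain == reference_strain]
  if (length(ref) < 2L)
    stop(sprintf("reference strain '%s' needs >= 2 replicates",
                 reference_strain), call. = FALSE)
  strains <- setdiff(unique(ratios$strain), reference_strain)
  res <- do.call(rbind, lapply(strains, function(s) {
    x <- ratios$ratio[ratios$strain == s]
    data.frame(strain = s, n_replicates = length(x),
               mean_ratio = mean(x), reference_ratio = mean(ref),
               log2fc = log2(mean(x) / mean(ref)),
               p_value = welch_p(x, ref))
  }))
  res$p_adjusted <- p.adjust(res$p_value, method = p_adjust)
  res$significant <- !is.na(res$p_adjusted) &
    res$p_adjusted < p_threshold & abs(res$log2fc) >= lfc_threshold
  res[order(res$p_value, na.last = TRUE), ]
}
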