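#' Parameters for simulating cytometry plates
#'
#' Per-cell reporter expression is log-normal; the red channel reads
#' expression through `coupling_red`, while yellow reads
#' `coupling_yfp * se * expression` — YFP is produced only from spliced
#' transcripts, so the YFP/RFP ratio tracks splicing efficiency. Both
#' channels receive additive Gaussian autofluorescence and multiplicative
#' measurement noise. Scatter channels are drawn so that configurable
#' fractions of events fail the scatter (debris) and singlet (doublet)
#' gates.
#'
#' @param n_events_per_well events recorded per well (default 10000).
#' @param expr_meanlog,expr_sdlog log-normal per-cell expression parameters.
#' @param coupling_red,coupling_yfp channel gain factors (> 0).
#' @param autofluor_red_mean,autofluor_red_sd,autofluor_yfp_mean,autofluor_yfp_sd
#'   additive autofluorescence (Gaussian, fluorescence units).
#' @param noise_cv multiplicative measurement noise CV.
#' @param se_map data frame (`strain`, `reporter`, `se`) giving the true
#'   splicing efficiency of each strain x reporter combination, in `[0, 1]`.
#' @param fsc_meanlog,fsc_sdlog,ssc_meanlog,ssc_sdlog scatter distributions.
#' @param debris_frac fraction of events with collapsed scatter (fail the
#'   scatter gate).
#' @param doublet_frac fraction of events with FSC-H far off the FSC-A diag
#'   (fail the singlet gate).
#' @return an object of class `"cytometry_sim_params"`.
#' @export
cytometry_sim_params <- function(n_events_per_well = 10000L,
                                 expr_meanlog = log(5000),
                                 expr_sdlog = 0.5,
                                 coupling_red = 1, coupling_yfp = 1,
                                 autofluor_red_mean = 30,
                                 autofluor_red_sd = 10,
                                 autofluor_yfp_mean = 5,
                                 autofluor_yfp_sd = 2,
                                 noise_cv = 0.1,
                                 se_map = NULL,
                                 fsc_meanlog = log(50000), fsc_sdlog = 0.3,
                                 ssc_meanlog = log(30000), ssc_sdlog = 0.35,
                                 debris_frac = 0.05,
                                 doublet_frac = 0.05) {
  check_count(n_events_per_well, "n_events_per_well", min = 1L)
  check_positive(c(coupling_red, coupling_yfp), "coupling gains")
  check_fraction(c(debris_frac, doublet_frac), "gate-fail fractions")
  if (!is.null(se_map)) {
    stopifnot(all(c("strain", "reporter", "se") %in% names(se_map)))
    check_fraction(se_map$se, "se_map$se")
  }
  structure(as.list(environment()), class = "cytometry_sim_params")
}

#' Simulate per-well cytometry event tables for a plate
#'
#' Every layout well must name a `(strain, reporter)` pair present in
#' `params$se_map`, or carry role `"autofluor_control"` (an untransformed
#' strain: zero coupling, autofluorescence only). Each well draws from its
#' own child seed so adding wells never perturbs earlier ones.
#'
#' @param layout data frame with columns `well`, `strain`, `reporter`,
#'   `role` (one of `"sample"`, `"reference"`, `"autofluor_control"`).
#' @param params a [cytometry_sim_params()] with a populated `se_map`.
#' @param seed integer master seed.
#' @return named list (by well) of event data frames with columns
#'   `FSC-A`, `FSC-H`, `SSC-A`, `FITC-A`, `PETexasRed-A`; the layout is
#'   attached as attribute `"layout"`.
#' @export
simulate_plate <- function(layout, params, seed) {
  stopifnot(inherits(params, "cytometry_sim_params"))
  stopifnot(all(c("well", "strain", "reporter", "role") %in% names(layout)))
  is_ctrl <- layout$role == "autofluor_control"
  if (!is.null(params$se_map)) {
    key <- paste(layout$strain, layout$reporter)
    map_key <- paste(params$se_map$strain, params$se_map$reporter)
    unknown <- !is_ctrl & !(key %in% map_key)
    if (any(unknown))
      stop("layout strain/reporter without se_map entry: ",
           paste(unique(key[unknown]), collapse = ", "), call. = FALSE)
    se_lookup <- setNames(params$se_map$se, map_key)
  } else if (!all(is_ctrl)) {
    stop("`params$se_map` is required for non-control wells", call. = FALSE)
  }
  wells <- vector("list", nrow(layout))
  names(wells) <- layout$well
  for (i in seq_len(nrow(layout))) {
    se <- if (is_ctrl[i]) 0 else
      unname(se_lookup[paste(layout$strain[i], layout$reporter[i])])
    coupling_red <- if (is_ctrl[i]) 0 else params$coupling_red
    coupling_yfp <- if (is_ctrl[i]) 0 else params$coupling_yfp
    wells[[i]] <- with_seed(subseed(seed, i), {
      n <- params$n_events_per_well
      x <- rlnorm(n, params$expr_meanlog, params$expr_sdlog)
      red <- coupling_red * x * (1 + rnorm(n, 0, params$noise_cv)) +
        rnorm(n, params$autofluor_red_mean, params$autofluor_red_sd)
      yfp <- coupling_yfp * se * x * (1 + rnorm(n, 0, params$noise_cv)) +
        rnorm(n, params$autofluor_yfp_mean, params$autofluor_yfp_sd)
      fsc <- rlnorm(n, params$fsc_meanlog, params$fsc_sdlog)
      ssc <- rlnorm(n, params$ssc_meanlog, params$ssc_sdlog)
      fsch <- fsc * (1 + rnorm(n, 0, 0.03))
      debris <- runif(n) < params$debris_frac
      fsc[debris] <- fsc[debris] * 0.05
      ssc[debris] <- ssc[debris] * 0.05
      doublet <- runif(n) < params$doublet_frac
      fsch[doublet] <- fsch[doublet] * 0.55
      ev <- data.frame(fsc, fsch, ssc, yfp, red, check.names = FALSE)
      names(ev) <- c("FSC-A", "FSC-H", "SSC-A", "FITC-A", "PETexasRed-A")
      ev
    })
  }
  attr(wells, "layout") <- layout
  wells
}

#' Write simulated plate wells as per-well CSV files
#'
#' One `<well>.csv` per well plus a `layout.csv`, the screen workflow's
#' on-disk input format.
#'
#' @param plate output of [simulate_plate()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_csv <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in names(plate))
    utils::write.csv(plate[[w]], file.path(dir, paste0(w, ".csv")),
                     row.names = FALSE)
  utils::write.csv(attr(plate, "layout"), file.path(dir, "layout.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a plate written by [write_plate_csv()]
#'
#' @param dir directory containing per-well CSVs and `layout.csv`.
#' @return named list of event data frames with the layout attached, as from
#'   [simulate_plate()].
#' @export
read_plate_csv <- function(dir) {
  layout <- utils::read.csv(file.path(dir, "layout.csv"),
                            stringsAsFactors = FALSE)
  wells <- lapply(layout$well, function(w)
    utils::read.csv(file.path(dir, paste0(w, ".csv")), check.names = FALSE))
  names(wells) <- layout$well
  attr(wells, "layout") <- layout
  wells
}
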