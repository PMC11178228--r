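merge_config <- function(defaults, config) {
  for (k in names(config)) defaults[[k]] <- config[[k]]
  defaults
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

stage_record <- function(manifest, stage, params = list(),
                         outputs = character(), warnings = character()) {
  manifest$stages[[stage]] <- list(
    params = params,
    outputs = as.list(outputs),
    output_md5 = as.list(if (length(outputs))
      unname(tools::md5sum(outputs)) else character()),
    warnings = as.list(warnings))
  manifest
}

new_manifest <- function(workflow, seed) {
  list(workflow = workflow,
       package_version = as.character(utils::packageVersion("splicescreen")),
       master_seed = seed, stages = list())
}

#' Build a plate layout with replicate strain wells and fixed controls
#'
#' Lays `n_reps` wells per strain across a plate, adds reference-reporter
#' wells for `reference_strain` and one untransformed autofluorescence
#' control well.
#'
#' @param strains character vector of mutant strain names.
#' @param reference_strain reference (wild-type background) strain.
#' @param reporter reporter name for all sample wells (default `"dmut"`,
#'   the sensitised double-mutant reporter).
#' @param n_reps replicate wells per strain (default 3).
#' @return layout data frame (`well`, `strain`, `reporter`, `role`).
#' @export
make_screen_layout <- function(strains, reference_strain = "WT",
                               reporter = "dmut", n_reps = 3L) {
  rows <- LETTERS[1:8]
  entries <- rbind(
    expand.grid(strain = strains, rep = seq_len(n_reps),
                stringsAsFactors = FALSE),
    expand.grid(strain = reference_strain, rep = seq_len(n_reps),
                stringsAsFactors = FALSE))
  n <- nrow(entries) + 1L
  if (n > 96L) stop("layout exceeds 96 wells", call. = FALSE)
  wells <- sprintf("%s%d", rows[(seq_len(n) - 1L) %/% 12L + 1L],
                   (seq_len(n) - 1L) %% 12L + 1L)
  data.frame(
    well = wells,
    strain = c(entries$strain, "untransformed"),
    reporter = c(rep(reporter, n - 1L), "none"),
    role = c(ifelse(entries$strain == reference_strain,
                    "reference", "sample"), "autofluor_control"))
}

#' Run the screen workflow: events -> gating -> ratios -> hit calls
#'
#' Chains [simulate_plate()] (or on-disk event CSV ingestion) through
#' [gate_events()], [summarize_well()], [correct_autofluorescence()] and
#' [call_hits()]. The configuration (a list, or path to a YAML file) must
#' provide either `events_dir` (per-well CSVs plus `layout.csv`) or a
#' simulation block (`layout` + `sim_params`), and may override `seed`,
#' `min_events`, `reference_strain`, `p_threshold`, `lfc_threshold`,
#' `p_adjust`, `channels`, `scatter_quantiles`, `singlet_tol`, `out_dir`.
#' Missing control wells abort before any computation.
#'
#' @param config list or YAML path; `plate` may also be passed directly as
#'   a ready [simulate_plate()] object in the list.
#' @return list with `wells`, `results`, `volcano` data frames and the
#'   run `manifest`; when `out_dir` is set, `wells.tsv`,
#'   `screen_results.tsv`, `volcano.tsv` and `manifest.json` are written.
#' @export
run_screen_workflow <- function(config) {
  config <- load_config(config)
  cfg <- merge_config(list(
    seed = 1L, min_events = 1000L, reference_strain = NULL,
    p_threshold = 0.05, lfc_threshold = 0, p_adjust = "none",
    channels = "red_only", scatter_quantiles = c(0.05, 0.95),
    singlet_tol = 0.25, out_dir = NULL), config)
  manifest <- new_manifest("screen", cfg$seed)

  # stage: events
  plate <- if (!is.null(cfg$plate)) cfg$plate
  else if (!is.null(cfg$events_dir)) read_plate_csv(cfg$events_dir)
  else if (!is.null(cfg$layout) && !is.null(cfg$sim_params))
    simulate_plate(cfg$layout, cfg$sim_params, cfg$seed)
  else stop("screen workflow config needs `events_dir`, `plate`, or ",
            "`layout` + `sim_params` [stage: events]", call. = FALSE)
  layout <- attr(plate, "layout")

  # pre-flight: controls present before any computation
  if (!any(layout$role == "autofluor_control"))
    stop("layout has no autofluorescence control well [stage: preflight]",
         call. = FALSE)
  ref_strain <- cfg$reference_strain %||%
    unique(layout$strain[layout$role == "reference"])
  if (length(ref_strain) != 1L || !any(layout$strain == ref_strain &
                                       layout$role != "autofluor_control"))
    stop("reference strain missing or ambiguous [stage: preflight]",
         call. = FALSE)
  manifest <- stage_record(manifest, "events",
                           params = list(n_wells = nrow(layout)))

  # stage: gate + summarize per well
  wells <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    ev <- plate[[layout$well[i]]]
    gates <- fit_gates(ev, cfg$scatter_quantiles, cfg$singlet_tol)
    gated <- gate_events(ev, gates)
    summarize_well(gated,
                   list(well_id = layout$well[i],
                        strain_id = layout$strain[i],
                        reporter_id = layout$reporter[i]),
                   min_events = cfg$min_events)
  }))
  manifest <- stage_record(manifest, "gate_summarize",
                           params = list(min_events = cfg$min_events,
                                         singlet_tol = cfg$singlet_tol))

  # stage: autofluorescence correction
  ctrl_wells <- layout$well[layout$role == "autofluor_control"]
  ctrl <- wells[wells$well_id %in% ctrl_wells & wells$qc_pass, ]
  if (nrow(ctrl) == 0L)
    stop("no autofluorescence control well passed QC [stage: correct]",
         call. = FALSE)
  wells <- correct_autofluorescence(wells, ctrl[1, ],
                                    channels = cfg$channels)
  manifest <- stage_record(manifest, "correct",
                           params = list(control_well = ctrl$well_id[1],
                                         channels = cfg$channels))

  # stage: hit calling
  sample_wells <- wells[wells$well_id %in%
                          layout$well[layout$role != "autofluor_control"], ]
  ratios <- data.frame(strain = sample_wells$strain_id,
                       ratio = sample_wells$ratio)
  results <- call_hits(ratios, ref_strain, cfg$p_threshold,
                       cfg$lfc_threshold, cfg$p_adjust)
  volcano <- data.frame(strain = results$strain, log2fc = results$log2fc,
                        neg_log10_p = -log10(results$p_value),
                        significant = results$significant)
  manifest <- stage_record(manifest, "call_hits",
                           params = list(reference_strain = ref_strain,
                                         p_threshold = cfg$p_threshold,
                                         lfc_threshold = cfg$lfc_threshold,
                                         p_adjust = cfg$p_adjust))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(workflow = "screen", seed = cfg$seed)
    paths <- c(
      write_stage_tsv(wells, file.path(cfg$out_dir, "wells.tsv"), meta),
      write_stage_tsv(results,
                      file.path(cfg$out_dir, "screen_results.tsv"), meta),
      write_stage_tsv(volcano, file.path(cfg$out_dir, "volcano.tsv"),
                      meta))
    manifest <- stage_record(manifest, "write", outputs = paths)
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(wells = wells, results = results, volcano = volcano,
       manifest = manifest)
}

#' Default configuration for the synthetic RNA-seq workflow
#'
#' Scenario sizes are chosen for desk-scale simulation: a few hundred genes
#' reproduce the qualitative genotype signatures while keeping runs fast.
#'
#' @param n_genes genome size.
#' @param defect_kind genotype defect model for the mutant.
#' @param ... overrides for any other field (see source for the full list).
#' @return named configuration list for [run_rnaseq_workflow()].
#' @export
rnaseq_config <- function(n_genes = 400L,
                          defect_kind = "transcription_coupled", ...) {
  cfg <- list(
    seed = 1L, n_genes = n_genes, frac_intron_genes = 0.43,
    degeneracy = 0.25, rate_mu = 3, rate_sigma = 1.2,
    defect_kind = defect_kind,
    alpha = -6, beta = 1.5, delta_shape_a = 1.5, delta_shape_b = 3,
    gamma = 0.8, depth = 5, min_coverage = 10L,
    extreme_fraction = 0.05, k_expression = 50L,
    n_introns_profile = 3L, cosplice_threshold = 0.5,
    cosplice_control_threshold = 0.9,
    gene_count_dispersion = 10, gene_count_reps = 2L,
    window_exonic = 3L, window_intronic = 8L,
    out_dir = NULL)
  merge_config(cfg, list(...))
}

#' Run the synthetic RNA-seq workflow end to end
#'
#' Chains genome simulation -> transcription rates -> genotype truth table
#' (wild type plus one mutant defect model) -> junction counts -> splicing
#' efficiency -> decile report, extreme selection, splice-site and
#' composition features, co-splicing profiles, expression association, and
#' the simplified differential-expression surrogate. All randomness derives
#' from the master seed via [subseed()].
#'
#' @param config list or YAML path; see [rnaseq_config()] for fields and
#'   defaults.
#' @return list with `genome`, `rates`, `truth`, `se_table`, `se_wt`,
#'   `se_mut`, `deciles`, `ranked`, `worst`, `best`, `features`,
#'   `cosplicing`, `expression`, `de`, `manifest`.
#' @export
run_rnaseq_workflow <- function(config = rnaseq_config()) {
  config <- load_config(config)
  cfg <- merge_config(rnaseq_config(), config)
  manifest <- new_manifest("rnaseq", cfg$seed)

  spec <- genome_spec(n_genes = cfg$n_genes,
                      frac_intron_genes = cfg$frac_intron_genes,
                      degeneracy = cfg$degeneracy)
  genome <- simulate_genome(spec, subseed(cfg$seed, 1L))
  manifest <- stage_record(manifest, "genome",
                           params = list(n_genes = cfg$n_genes,
                                         degeneracy = cfg$degeneracy))

  rates <- assign_rates(genome$genes, cfg$rate_mu, cfg$rate_sigma,
                        subseed(cfg$seed, 2L))
  mut_model <- defect_model(cfg$defect_kind, alpha = cfg$alpha,
                            beta = cfg$beta,
                            delta_shape_a = cfg$delta_shape_a,
                            delta_shape_b = cfg$delta_shape_b,
                            gamma = cfg$gamma)
  truth <- simulate_truth_table(genome$genes, genome$introns, rates,
                                list(WT = defect_model("none"),
                                     mut = mut_model),
                                subseed(cfg$seed, 3L))
  manifest <- stage_record(manifest, "truth",
                           params = list(defect_kind = cfg$defect_kind))

  jc <- simulate_junction_counts(truth, cfg$depth, subseed(cfg$seed, 4L))
  se_table <- splicing_efficiency(jc, cfg$min_coverage)
  se_of <- function(g) {
    d <- se_table[se_table$genotype == g, ]
    setNames(d$se, d$intron_id)
  }
  se_wt <- se_of("WT"); se_mut <- se_of("mut")
  manifest <- stage_record(manifest, "splicing_efficiency",
                           params = list(depth = cfg$depth,
                                         min_coverage = cfg$min_coverage))

  deciles <- decile_report(se_wt, se_mut)
  ranked <- rank_affected(se_wt, se_mut)
  worst <- select_extremes(ranked, cfg$extreme_fraction, "worst")
  best <- select_extremes(ranked, cfg$extreme_fraction, "best")
  manifest <- stage_record(manifest, "deciles_extremes",
                           params = list(fraction = cfg$extreme_fraction))

  introns <- genome$introns
  quantified <- introns[introns$intron_id %in% ranked$intron_id, ]
  sets <- list(all = quantified,
               worst = introns[introns$intron_id %in% worst, ],
               best = introns[introns$intron_id %in% best, ])
  win5 <- lapply(sets, function(s) extract_junction_windows(
    s, genome$sequences, "5prime", cfg$window_exonic,
    cfg$window_intronic))
  mats5 <- lapply(win5, splice_site_matrix)
  features <- list(
    matrices_5prime = mats5,
    worst_vs_all_5prime = compare_to_background(mats5$worst, mats5$all),
    composition = composition_stats(sets, genome$sequences))
  manifest <- stage_record(manifest, "features",
                           params = list(window = c(cfg$window_exonic,
                                                    cfg$window_intronic)))

  fpkm <- data.frame(gene_id = rates$gene_id, fpkm = rates$rate)
  profiles <- gene_splice_profiles(se_wt, se_mut, introns, fpkm,
                                   cfg$n_introns_profile)
  cosplicing <- list(
    case = lapply(seq_len(cfg$n_introns_profile), function(a)
      cosplicing_profile(profiles, a, cfg$cosplice_threshold, "<")),
    control = lapply(seq_len(cfg$n_introns_profile), function(a)
      cosplicing_profile(profiles, a, cfg$cosplice_control_threshold,
                         ">")))
  expression <- expression_association(ranked, introns, fpkm,
                                       cfg$k_expression)
  manifest <- stage_record(manifest, "cosplicing_expression",
                           params = list(k = cfg$k_expression))

  counts <- simulate_gene_counts(rates, dispersion =
                                   cfg$gene_count_dispersion,
                                 n_reps = cfg$gene_count_reps,
                                 seed = subseed(cfg$seed, 5L))
  de <- differential_expression(counts, groups = attr(counts, "groups"))
  qc <- replicate_qc(counts[, 1], counts[, 2])
  manifest <- stage_record(manifest, "expression_de",
                           params = list(method = "simplified-surrogate",
                                         replicate_r = qc$r))

  out <- list(genome = genome, rates = rates, truth = truth,
              se_table = se_table, se_wt = se_wt, se_mut = se_mut,
              deciles = deciles, ranked = ranked, worst = worst,
              best = best, features = features, cosplicing = cosplicing,
              expression = expression, de = de, replicate_qc = qc,
              manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(workflow = "rnaseq", seed = cfg$seed,
                 method = "simplified-surrogate")
    paths <- c(
      write_stage_tsv(se_table, file.path(cfg$out_dir, "se_table.tsv"),
                      meta),
      write_stage_tsv(deciles, file.path(cfg$out_dir,
                                         "decile_report.tsv"), meta),
      write_stage_tsv(ranked, file.path(cfg$out_dir, "ranked.tsv"), meta),
      write_stage_tsv(de, file.path(cfg$out_dir, "de_results.tsv"), meta))
    writeLines(worst, file.path(cfg$out_dir, "extremes_worst.txt"))
    writeLines(best, file.path(cfg$out_dir, "extremes_best.txt"))
    paths <- c(paths, file.path(cfg$out_dir, c("extremes_worst.txt",
                                               "extremes_best.txt")))
    manifest <- stage_record(manifest, "write", outputs = paths)
    out$manifest <- manifest
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
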