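#' Genotype-specific splicing-defect model
#'
#' Three generative models for per-intron true splicing efficiency (SE):
#'
#' * `"none"` — every intron keeps its wild-type baseline SE, drawn per
#'   intron from `Beta(baseline_se_a, baseline_se_b)`.
#' * `"transcription_coupled"` — a gene is affected with probability
#'   `sigmoid(alpha + beta * log(rate))`, so highly transcribed genes are
#'   more likely to be hit; an affected gene multiplies the baseline SE of
#'   *every* one of its introns by a single shared draw
#'   `delta_g ~ Beta(delta_shape_a, delta_shape_b)`. This couples defects
#'   across introns of the same pre-mRNA.
#' * `"motif_dependent"` — each intron's SE is
#'   `baseline * (1 - gamma * m / 6)` where `m` is the Hamming mismatch count
#'   of the intron's first 6 nt to the donor consensus; defects are
#'   intron-intrinsic and independent of transcription rate.
#'
#' The baseline default `Beta(30, 1.5)` gives mostly-high wild-type
#' efficiencies (mean ~0.95) with a low-efficiency tail.
#'
#' @param kind one of `"none"`, `"transcription_coupled"`,
#'   `"motif_dependent"`.
#' @param alpha,beta logistic intercept and slope on log transcription rate
#'   (transcription_coupled only).
#' @param delta_shape_a,delta_shape_b Beta parameters of the shared
#'   gene-level multiplier `delta_g`.
#' @param gamma penalty per donor-consensus mismatch, in `[0, 1]`
#'   (motif_dependent only).
#' @param baseline_se_a,baseline_se_b Beta parameters of the wild-type
#'   per-intron baseline SE.
#' @return an object of class `"defect_model"`.
#' @export
defect_model <- function(kind = c("none", "transcription_coupled",
                                  "motif_dependent"),
                         alpha = -6, beta = 1.5,
                         delta_shape_a = 1.5, delta_shape_b = 3,
                         gamma = 0.8,
                         baseline_se_a = 30, baseline_se_b = 1.5) {
  kind <- match.arg(kind)
  check_fraction(gamma, "gamma")
  check_positive(c(delta_shape_a, delta_shape_b), "delta_shape")
  check_positive(c(baseline_se_a, baseline_se_b), "baseline_se shape")
  structure(list(kind = kind, alpha = alpha, beta = beta,
                 delta_shape_a = delta_shape_a,
                 delta_shape_b = delta_shape_b, gamma = gamma,
                 baseline_se_a = baseline_se_a,
                 baseline_se_b = baseline_se_b),
            class = "defect_model")
}

#' Assign log-normal transcription rates to genes
#'
#' Rates play the role of an FPKM-like transcription-rate covariate.
#'
#' @param genes gene data frame with a `gene_id` column (may be empty).
#' @param mu,sigma mean and sd of log rate; `sigma` may be 0 (all rates equal
#'   `exp(mu)`).
#' @param seed integer seed.
#' @return data frame with columns `gene_id`, `rate` (strictly positive).
#' @export
assign_rates <- function(genes, mu = 3, sigma = 1.2, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  n <- nrow(genes)
  if (n == 0L)
    return(data.frame(gene_id = character(), rate = numeric()))
  rate <- with_seed(subseed(seed, 0L),
                    if (sigma == 0) rep(exp(mu), n) else rlnorm(n, mu, sigma))
  data.frame(gene_id = genes$gene_id, rate = rate)
}

#' Draw wild-type baseline splicing efficiencies per intron
#'
#' @param introns intron data frame with `intron_id`.
#' @param model a [defect_model()] supplying `baseline_se_a/b`.
#' @param seed integer seed.
#' @return named numeric vector of baseline SE in `[0, 1]`, one per intron.
#' @export
draw_baseline_se <- function(introns, model, seed) {
  n <- nrow(introns)
  se <- with_seed(subseed(seed, 0L),
                  rbeta(n, model$baseline_se_a, model$baseline_se_b))
  setNames(se, introns$intron_id)
}

#' Apply a defect model to produce true per-intron splicing efficiencies
#'
#' @param genes gene data frame (`gene_id`).
#' @param introns intron data frame (`intron_id`, `gene_id`,
#'   `intron_index`; `mismatch_5ss` required for motif_dependent models —
#'   present on [simulate_genome()] output).
#' @param rates data frame from [assign_rates()].
#' @param model a [defect_model()].
#' @param seed integer seed.
#' @param baseline optional named baseline SE vector (e.g. shared between a
#'   wild-type and mutant genotype so both see the same intron-intrinsic
#'   baseline); drawn internally from the model when `NULL`.
#' @return a truth-table data frame: `gene_id`, `intron_id`, `intron_index`,
#'   `true_se`, `baseline_se`, `true_rate`, `gene_affected`.
#' @export
apply_defect_model <- function(genes, introns, rates, model, seed,
                               baseline = NULL) {
  stopifnot(inherits(model, "defect_model"))
  if (is.null(baseline))
    baseline <- draw_baseline_se(introns, model, subseed(seed, 1L))
  baseline <- baseline[introns$intron_id]
  rate <- setNames(rates$rate, rates$gene_id)[introns$gene_id]

  affected_by_gene <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  true_se <- unname(baseline)

  if (model$kind == "transcription_coupled") {
    gene_rate <- setNames(rates$rate, rates$gene_id)[genes$gene_id]
    p_aff <- stats::plogis(model$alpha + model$beta * log(gene_rate))
    draws <- with_seed(subseed(seed, 2L), {
      aff <- runif(length(p_aff)) < p_aff
      delta <- rbeta(length(p_aff), model$delta_shape_a,
                     model$delta_shape_b)
      list(aff = aff, delta = delta)
    })
    affected_by_gene[] <- draws$aff
    delta_by_gene <- setNames(ifelse(draws$aff, draws$delta, 1),
                              genes$gene_id)
    true_se <- unname(baseline) * delta_by_gene[introns$gene_id]
  } else if (model$kind == "motif_dependent") {
    if (!"mismatch_5ss" %in% names(introns))
      stop("motif_dependent model needs `mismatch_5ss` in the intron table",
           call. = FALSE)
    m <- introns$mismatch_5ss
    true_se <- unname(baseline) * (1 - model$gamma * m / 6)
    affected_by_gene <- NULL
  }

  data.frame(
    gene_id = introns$gene_id,
    intron_id = introns$intron_id,
    intron_index = introns$intron_index,
    true_se = pmin(pmax(unname(true_se), 0), 1),
    baseline_se = unname(baseline),
    true_rate = unname(rate),
    gene_affected = if (is.null(affected_by_gene)) FALSE
                    else unname(affected_by_gene[introns$gene_id])
  )
}

#' Build a multi-genotype truth table with a shared baseline
#'
#' Draws one wild-type baseline SE per intron and applies each genotype's
#' defect model to it, so genotype differences reflect the defect model
#' alone. A rate multiplier `rho` (slowed-transcription scenarios such as
#' transcription-elongation inhibition) can scale rates before the defect
#' model is applied, per genotype.
#'
#' @param genes,introns,rates as in [apply_defect_model()].
#' @param models named list of [defect_model()]s, one per genotype.
#' @param seed integer master seed.
#' @param rho named numeric multiplier in `(0, 1]` applied to rates per
#'   genotype (default 1 for all).
#' @return truth-table data frame with a `genotype` column; every annotated
#'   intron appears exactly once per genotype.
#' @export
simulate_truth_table <- function(genes, introns, rates, models, seed,
                                 rho = NULL) {
  stopifnot(length(names(models)) == length(models))
  base_model <- models[[1]]
  baseline <- draw_baseline_se(introns, base_model, subseed(seed, 1L))
  out <- lapply(seq_along(models), function(k) {
    r <- rates
    mult <- if (!is.null(rho) && names(models)[k] %in% names(rho))
      rho[[names(models)[k]]] else 1
    check_positive(mult, "rho")
    r$rate <- r$rate * mult
    tt <- apply_defect_model(genes, introns, r, models[[k]],
                             subseed(seed, 100L + k), baseline = baseline)
    tt$genotype <- names(models)[k]
    tt
  })
  do.call(rbind, out)
}
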