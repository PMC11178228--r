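#' Simulate junction read counts from a truth table
#'
#' For each intron and each of its two boundaries (5' and 3'), the total
#' boundary read count is `n_b ~ Poisson(depth * rate)` and the spliced
#' fraction `spliced_b ~ Binomial(n_b, true_se)`; unspliced reads are the
#' remainder. Replicates draw from distinct child seeds.
#'
#' @param truth truth-table data frame from [apply_defect_model()] or
#'   [simulate_truth_table()] (needs `intron_id`, `true_se`, `true_rate`;
#'   an optional `genotype` column is carried into the sample name).
#' @param depth sequencing-depth scaler (> 0); expected boundary reads per
#'   intron are `depth * true_rate`.
#' @param seed integer seed.
#' @param n_reps replicates per genotype.
#' @return data frame: `intron_id`, `sample`, `genotype`, `replicate`,
#'   `spliced5`, `unspliced5`, `spliced3`, `unspliced3`.
#' @export
simulate_junction_counts <- function(truth, depth, seed, n_reps = 1L) {
  check_positive(depth, "depth")
  check_count(n_reps, "n_reps", min = 1L)
  if (!"genotype" %in% names(truth)) truth$genotype <- "sample"
  genotypes <- unique(truth$genotype)
  out <- vector("list", length(genotypes) * n_reps)
  k <- 0L
  for (gi in seq_along(genotypes)) {
    tt <- truth[truth$genotype == genotypes[gi], ]
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      draws <- with_seed(subseed(seed, gi * 1000L + r), {
        lambda <- depth * tt$true_rate
        n5 <- rpois(nrow(tt), lambda)
        n3 <- rpois(nrow(tt), lambda)
        s5 <- rbinom(nrow(tt), n5, tt$true_se)
        s3 <- rbinom(nrow(tt), n3, tt$true_se)
        list(n5 = n5, n3 = n3, s5 = s5, s3 = s3)
      })
      out[[k]] <- data.frame(
        intron_id = tt$intron_id,
        sample = sprintf("%s_rep%d", genotypes[gi], r),
        genotype = genotypes[gi],
        replicate = r,
        spliced5 = draws$s5, unspliced5 = draws$n5 - draws$s5,
        spliced3 = draws$s3, unspliced3 = draws$n3 - draws$s3
      )
    }
  }
  do.call(rbind, out)
}

#' Simulate a raw gene-count matrix for two genotypes
#'
#' Counts are negative binomial with mean `depth * rate * fold_change`
#' (fold change applied in the mutant group only) and size parameter
#' `dispersion`; `dispersion = Inf` gives the Poisson limit.
#'
#' @param rates data frame from [assign_rates()].
#' @param de_config optional data frame (`gene_id`, `fold_change`) of induced
#'   or repressed genes in the mutant group; genes not listed have fold
#'   change 1.
#' @param dispersion NB size parameter (> 0, may be `Inf`).
#' @param n_reps replicates per group (>= 2, matching duplicate RNA-seq
#'   designs).
#' @param seed integer seed.
#' @param depth library-depth scaler.
#' @param group_names character(2), reference then mutant group name.
#' @return integer count matrix (genes x samples) with a `groups` attribute
#'   mapping sample to group.
#' @export
simulate_gene_counts <- function(rates, de_config = NULL, dispersion = 10,
                                 n_reps = 2L, seed = 1L, depth = 10,
                                 group_names = c("WT", "mut")) {
  if (!is.numeric(dispersion) || is.na(dispersion) || dispersion <= 0)
    stop("`dispersion` must be > 0 (Inf allowed for the Poisson limit)",
         call. = FALSE)
  check_count(n_reps, "n_reps", min = 2L)
  n <- nrow(rates)
  fc <- setNames(rep(1, n), rates$gene_id)
  if (!is.null(de_config) && nrow(de_config))
    fc[de_config$gene_id] <- de_config$fold_change
  samples <- c(sprintf("%s_rep%d", group_names[1], seq_len(n_reps)),
               sprintf("%s_rep%d", group_names[2], seq_len(n_reps)))
  groups <- rep(group_names, each = n_reps)
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(rates$gene_id, samples))
  if (n == 0L) {
    attr(counts, "groups") <- setNames(groups, samples)
    return(counts)
  }
  for (j in seq_along(samples)) {
    mu <- depth * rates$rate * (if (groups[j] == group_names[2])
      unname(fc[rates$gene_id]) else 1)
    counts[, j] <- with_seed(subseed(seed, j), {
      if (is.infinite(dispersion)) rpois(n, mu)
      else rnbinom(n, size = dispersion, mu = mu)
    })
  }
  attr(counts, "groups") <- setNames(groups, samples)
  counts
}
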