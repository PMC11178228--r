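#' Assemble per-gene splice profiles for genes with a fixed intron count
#'
#' Restricts to genes with exactly `n_introns` introns, all quantified
#' (non-`NA`) in both genotypes, and orders SE values by intron position.
#'
#' @param se_wt,se_mut named numeric SE vectors per intron.
#' @param introns intron data frame (`intron_id`, `gene_id`,
#'   `intron_index`).
#' @param fpkm optional data frame (`gene_id`, `fpkm`); carried through when
#'   supplied.
#' @param n_introns required intron count per gene (default 3).
#' @return data frame (one row per gene x intron position): `gene_id`,
#'   `intron_index`, `intron_id`, `se_wt`, `se_mut`, `fpkm`.
#' @export
gene_splice_profiles <- function(se_wt, se_mut, introns, fpkm = NULL,
                                 n_introns = 3L) {
  df <- introns[, c("intron_id", "gene_id", "intron_index")]
  df$se_wt <- unname(se_wt[df$intron_id])
  df$se_mut <- unname(se_mut[df$intron_id])
  n_by_gene <- table(df$gene_id)
  eligible <- names(n_by_gene)[n_by_gene == n_introns]
  df <- df[df$gene_id %in% eligible, ]
  complete <- tapply(!is.na(df$se_wt) & !is.na(df$se_mut), df$gene_id, all)
  df <- df[df$gene_id %in% names(complete)[complete], ]
  df <- df[order(df$gene_id, df$intron_index), ]
  if (!is.null(fpkm))
    df$fpkm <- setNames(fpkm$fpkm, fpkm$gene_id)[df$gene_id]
  rownames(df) <- NULL
  df
}

#' Anchor-conditioned co-splicing profile of multi-intron genes
#'
#' Selects genes whose anchor intron passes a relative-efficiency filter —
#' default `se_mut/se_wt < 0.5`, i.e. a 50% drop in splicing efficiency at
#' the anchor; the control variant uses `> 0.9` (essentially unaffected
#' anchors) — and reports the mean SE at every intron position for each
#' genotype over the passing genes. A co-ordinated (gene-level) defect shows
#' up as depressed mutant SE at the non-anchor positions too.
#'
#' @param profiles data frame from [gene_splice_profiles()].
#' @param anchor 1-based anchor intron position.
#' @param threshold ratio threshold (default 0.5).
#' @param comparator `"<"` (affected anchors, default) or `">"` (control).
#' @return object of class `"cosplicing_profile"`: list with `gene_set`
#'   (ids), `n_genes`, `anchor`, `filter` (human-readable), and `profile`
#'   (data frame: `intron_index`, `mean_se_wt`, `mean_se_mut`, `sd_se_mut`).
#'   Zero passing genes give `n_genes = 0` and an empty profile.
#' @export
cosplicing_profile <- function(profiles, anchor = 1L, threshold = 0.5,
                               comparator = c("<", ">")) {
  comparator <- match.arg(comparator)
  n_pos <- max(profiles$intron_index, 0L)
  if (nrow(profiles) && (anchor < 1L || anchor > n_pos))
    stop("`anchor` outside the intron positions present", call. = FALSE)
  anc <- profiles[profiles$intron_index == anchor, ]
  ratio <- anc$se_mut / anc$se_wt
  pass <- if (comparator == "<") ratio < threshold else ratio > threshold
  genes <- anc$gene_id[pass & !is.na(pass)]
  sel <- profiles[profiles$gene_id %in% genes, ]
  prof <- if (nrow(sel)) do.call(rbind, lapply(
    split(sel, sel$intron_index), function(d)
      data.frame(intron_index = d$intron_index[1],
                 mean_se_wt = mean(d$se_wt),
                 mean_se_mut = mean(d$se_mut),
                 sd_se_mut = sd(d$se_mut))))
  else data.frame(intron_index = integer(), mean_se_wt = numeric(),
                  mean_se_mut = numeric(), sd_se_mut = numeric())
  structure(list(gene_set = genes, n_genes = length(genes),
                 anchor = anchor,
                 filter = sprintf("se_mut/se_wt %s %g", comparator,
                                  threshold),
                 profile = prof),
            class = "cosplicing_profile")
}

#' Host-gene expression of the worst- versus best-spliced introns
#'
#' Takes the `k` most-affected and `k` least-affected introns from a
#' [rank_affected()] ranking and compares the FPKM of their host genes with
#' a two-sided Welch t-test on log FPKM. If fewer than `k` introns are
#' available on either end, all available are used and the shortfall is
#' recorded.
#'
#' @param ranked data frame from [rank_affected()].
#' @param introns intron data frame (`intron_id`, `gene_id`).
#' @param fpkm data frame (`gene_id`, `fpkm`); every ranked intron's gene
#'   must be present.
#' @param k group size (default 50).
#' @return list with `worst`, `best` (data frames: intron_id, gene_id,
#'   fpkm), `mean_fpkm_worst`, `mean_fpkm_best`, `p_value` (Welch on log
#'   FPKM), `k_requested`, `k_used`.
#' @export
expression_association <- function(ranked, introns, fpkm, k = 50L) {
  check_count(k, "k", min = 1L)
  gene_of <- setNames(introns$gene_id, introns$intron_id)
  fpkm_of <- setNames(fpkm$fpkm, fpkm$gene_id)
  if (anyNA(fpkm_of[gene_of[ranked$intron_id]]))
    stop("every ranked intron's gene needs an fpkm value", call. = FALSE)
  k_used <- min(k, floor(nrow(ranked) / 2))
  if (k_used < k)
    message("expression_association: only ", k_used,
            " introns per group available (requested ", k, ")")
  grab <- function(ids) data.frame(
    intron_id = ids, gene_id = unname(gene_of[ids]),
    fpkm = unname(fpkm_of[gene_of[ids]]))
  worst <- grab(select_extremes(ranked, fraction = 1, "worst")[
    seq_len(k_used)])
  best <- grab(select_extremes(ranked, fraction = 1, "best")[
    seq_len(k_used)])
  list(worst = worst, best = best,
       mean_fpkm_worst = mean(worst$fpkm),
       mean_fpkm_best = mean(best$fpkm),
       p_value = welch_p(log(worst$fpkm), log(best$fpkm)),
       k_requested = k, k_used = k_used)
}

#' Cumulative mature-mRNA fraction of a multi-intron gene
#'
#' Under independent splicing of each intron, the fraction of transcripts
#' with every intron correctly removed is the product of the per-intron
#' splicing efficiencies. An empty vector returns 1 (no introns to
#' remove). The independence assumption ignores within-gene co-splicing
#' correlation.
#'
#' @param per_intron_se numeric vector of per-intron SE in `[0, 1]`,
#'   ordered along the transcript (order does not change the result).
#' @return the product, a fraction in `[0, 1]`.
#' @export
#' @examples
#' cumulative_mature_fraction(c(0.74, 0.71, 0.95, 0.85))
cumulative_mature_fraction <- function(per_intron_se) {
  if (length(per_intron_se) == 0L) return(1)
  check_fraction(per_intron_se, "per_intron_se")
  prod(per_intron_se)
}

#' Percent splicing from spliced / unspliced signal intensities
#'
#' `100 * spliced / (spliced + unspliced)`, the RT-PCR band-intensity
#' estimator; intron retention is the complement (`100 - result`).
#'
#' @param spliced_signal,unspliced_signal non-negative intensities.
#' @return percentage in `[0, 100]`; `NA` with a warning when both signals
#'   are zero.
#' @export
percent_splicing <- function(spliced_signal, unspliced_signal) {
  if (any(spliced_signal < 0) || any(unspliced_signal < 0))
    stop("signals must be non-negative", call. = FALSE)
  tot <- spliced_signal + unspliced_signal
  out <- 100 * spliced_signal / tot
  if (any(tot == 0)) {
    warning("both signals zero: percent splicing undefined (NA)",
            call. = FALSE)
    out[tot == 0] <- NA_real_
  }
  out
}

#' Percent intron retention
#'
#' @inheritParams percent_splicing
#' @return `100 - percent_splicing(...)`.
#' @export
percent_retention <- function(spliced_signal, unspliced_signal) {
  100 - percent_splicing(spliced_signal, unspliced_signal)
}

#' FPKM from a count vector and gene lengths
#'
#' `count / (gene length in kb * library size in millions)`; gene length is
#' the exonic (exon-union) length.
#'
#' @param counts named integer vector of gene counts.
#' @param exonic_len named vector of exonic gene lengths (nt).
#' @return named numeric FPKM vector.
#' @export
fpkm_from_counts <- function(counts, exonic_len) {
  lib <- sum(counts) / 1e6
  len_kb <- exonic_len[names(counts)] / 1000
  counts / (len_kb * lib)
}
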