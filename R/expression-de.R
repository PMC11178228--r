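#' Median-of-ratios size factors
#'
#' The classic normalisation: a pseudo-reference sample is the per-gene
#' geometric mean across samples; each sample's size factor is the median
#' over genes (with all-positive counts) of its count over the
#' pseudo-reference. This module is a deliberately simplified,
#' fully-documented surrogate for a shrinkage-based differential-expression
#' package; outputs are labelled `method=simplified-surrogate` and
#' numerical agreement with such packages is not a goal.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has positive counts in every sample; consider adding a ",
         "pseudocount before normalisation", call. = FALSE)
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  apply(logc, 2L, function(x) exp(median(x - ref)))
}

#' Simplified differential expression: normalise, log2 fold change, Welch t
#'
#' Counts are divided by their size factors; the fold change is
#' `log2((mean_mut + pseudocount) / (mean_wt + pseudocount))` on normalised
#' means; the p-value is a two-sided Welch t-test on
#' `log2(normalised + pseudocount)`. Significance follows the volcano rule:
#' `|log2fc| >= lfc_threshold` (inclusive) and `p < p_threshold`
#' (exclusive). With only two replicates per group the t-test is
#' underpowered; a warning notes this.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors from [size_factors()] (recomputed when
#'   `NULL`).
#' @param groups named character vector (sample -> group) or character
#'   vector along columns; exactly two groups, reference first by
#'   `ref_group`.
#' @param ref_group reference (wild-type) group name.
#' @param pseudocount added before log transforms (default 1).
#' @param p_threshold,lfc_threshold volcano significance thresholds
#'   (defaults 0.05 exclusive, 1 inclusive).
#' @return `DEResult` data frame: `gene_id`, `base_mean`, `mean_ref`,
#'   `mean_alt`, `log2fc`, `p_value`, `significant`; attribute `"method"`
#'   is `"simplified-surrogate"`.
#' @export
differential_expression <- function(counts, factors = NULL, groups = NULL,
                                    ref_group = NULL, pseudocount = 1,
                                    p_threshold = 0.05,
                                    lfc_threshold = 1) {
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- attr(counts, "groups")
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  if (length(groups) != ncol(counts))
    stop("`groups` must map every sample column", call. = FALSE)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(ref_group)) ref_group <- lv[1]
  alt_group <- setdiff(lv, ref_group)
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- sweep(counts, 2L, factors, "/")
  iref <- which(groups == ref_group)
  ialt <- which(groups == alt_group)
  if (min(length(iref), length(ialt)) == 2L)
    warning("only two replicates per group: the t-test is underpowered",
            call. = FALSE)
  mean_ref <- rowMeans(norm[, iref, drop = FALSE])
  mean_alt <- rowMeans(norm[, ialt, drop = FALSE])
  log2fc <- log2((mean_alt + pseudocount) / (mean_ref + pseudocount))
  lnorm <- log2(norm + pseudocount)
  p <- vapply(seq_len(nrow(norm)), function(g)
    welch_p(lnorm[g, ialt], lnorm[g, iref]), 0)
  sig <- volcano_significant(log2fc, p, p_threshold, lfc_threshold)
  out <- data.frame(gene_id = rownames(counts) %||%
                      as.character(seq_len(nrow(counts))),
                    base_mean = rowMeans(norm),
                    mean_ref = mean_ref, mean_alt = mean_alt,
                    log2fc = log2fc, p_value = p, significant = sig,
                    row.names = NULL)
  attr(out, "method") <- "simplified-surrogate"
  out
}

#' Volcano-plot significance rule
#'
#' A gene is significant when `|log2fc| >= lfc_threshold` (inclusive: a
#' fold change of exactly the threshold counts) and `p < p_threshold`
#' (exclusive). `NA` p-values are never significant.
#'
#' @param log2fc,p_value numeric vectors.
#' @param p_threshold,lfc_threshold thresholds (defaults 0.05 and 1).
#' @return logical vector.
#' @export
volcano_significant <- function(log2fc, p_value, p_threshold = 0.05,
                                lfc_threshold = 1) {
  !is.na(p_value) & !is.na(log2fc) & p_value < p_threshold &
    abs(log2fc) >= lfc_threshold
}

#' Replicate concordance QC by Pearson correlation
#'
#' Pearson correlation of two replicate count vectors, by default on
#' `log2(count + 1)`; replicates pass when `r > threshold` (0.98 default).
#' Zero variance in either vector yields `NA` and a failing flag.
#'
#' @param sample_a,sample_b equal-length count vectors (n >= 3).
#' @param threshold pass threshold on r.
#' @param log_transform correlate on `log2(count + 1)` (default `TRUE`).
#' @return list with `r` and `pass`.
#' @export
replicate_qc <- function(sample_a, sample_b, threshold = 0.98,
                         log_transform = TRUE) {
  if (length(sample_a) != length(sample_b) || length(sample_a) < 3L)
    stop("need equal-length vectors of n >= 3", call. = FALSE)
  a <- if (log_transform) log2(sample_a + 1) else sample_a
  b <- if (log_transform) log2(sample_b + 1) else sample_b
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, pass = FALSE))
  r <- cor(a, b)
  list(r = r, pass = r > threshold)
}
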