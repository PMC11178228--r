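`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count spliced and unspliced junction reads per intron boundary
#'
#' A read supports the spliced form of an intron when its alignment skips
#' exactly `[start, end]` (an N-gap matching the intron coordinates) with at
#' least `min_overhang` aligned reference bases on each side of the gap; it
#' then increments both `spliced5` and `spliced3`. A read supports the
#' unspliced form at a boundary when one contiguous aligned block spans that
#' boundary with at least `min_overhang` bases on each side. A read counts
#' at most once per boundary. Skip blocks matching no annotated intron are
#' tallied in the `"novel_junctions"` attribute, never treated as an error.
#'
#' This is the alignment-ingestion path; simulation scenarios emit junction
#' counts directly via [simulate_junction_counts()].
#'
#' @param alignments path to a SAM or BAM file, or a
#'   [GenomicAlignments::GAlignments] object.
#' @param introns intron data frame (`intron_id`, `chrom`, `start`, `end`;
#'   1-based inclusive genomic coordinates).
#' @param min_overhang minimum aligned bases required on each side of a
#'   junction or boundary (default 6).
#' @param sample_name sample label attached to the output.
#' @return `JunctionCounts` data frame: `intron_id`, `sample`, `spliced5`,
#'   `unspliced5`, `spliced3`, `unspliced3`; unannotated junctions (key
#'   `"chrom start end"`, value read count) in attribute
#'   `"novel_junctions"`.
#' @export
count_junction_reads <- function(alignments, introns, min_overhang = 6L,
                                 sample_name = "sample") {
  check_count(min_overhang, "min_overhang", min = 1L)
  if (is.character(alignments)) {
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE))
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    alignments <- GenomicAlignments::readGAlignments(path)
  }
  stopifnot(is(alignments, "GAlignments"))

  nI <- nrow(introns)
  counts <- matrix(0L, nrow = nI, ncol = 4L,
                   dimnames = list(introns$intron_id,
                                   c("spliced5", "unspliced5",
                                     "spliced3", "unspliced3")))
  novel <- list()
  if (length(alignments) && nI) {
    blocks <- GenomicAlignments::grglist(alignments, drop.D.ranges = TRUE)
    intron_by_key <- setNames(seq_len(nI),
                              paste(introns$chrom, introns$start,
                                    introns$end))
    for (r in seq_along(blocks)) {
      b <- blocks[[r]]
      chrom <- as.character(GenomicRanges::seqnames(b))[1]
      s <- GenomicRanges::start(b); e <- GenomicRanges::end(b)
      o <- order(s); s <- s[o]; e <- e[o]
      w <- e - s + 1L
      spl <- logical(nI)          # read skips this intron
      un5 <- logical(nI); un3 <- logical(nI)
      if (length(s) > 1L) {
        for (j in seq_len(length(s) - 1L)) {
          if (w[j] < min_overhang || w[j + 1L] < min_overhang) next
          gap_start <- e[j] + 1L; gap_end <- s[j + 1L] - 1L
          if (gap_end < gap_start) next
          idx <- intron_by_key[paste(chrom, gap_start, gap_end)]
          if (!is.na(idx)) spl[idx] <- TRUE
          else {
            k <- paste(chrom, gap_start, gap_end)
            novel[[k]] <- (novel[[k]] %||% 0L) + 1L
          }
        }
      }
      same_chrom <- introns$chrom == chrom
      for (j in seq_along(s)) {
        if (w[j] < 2L * min_overhang) next
        un5 <- un5 | (same_chrom &
                        s[j] <= introns$start - min_overhang &
                        e[j] >= introns$start + min_overhang - 1L)
        un3 <- un3 | (same_chrom &
                        s[j] <= introns$end - min_overhang + 1L &
                        e[j] >= introns$end + min_overhang)
      }
      # at most one count per read per boundary; spliced evidence wins
      un5 <- un5 & !spl
      un3 <- un3 & !spl
      counts[, "spliced5"] <- counts[, "spliced5"] + spl
      counts[, "spliced3"] <- counts[, "spliced3"] + spl
      counts[, "unspliced5"] <- counts[, "unspliced5"] + un5
      counts[, "unspliced3"] <- counts[, "unspliced3"] + un3
    }
  }
  out <- data.frame(intron_id = introns$intron_id, sample = sample_name,
                    counts, row.names = NULL)
  attr(out, "novel_junctions") <- novel
  out
}

#' Compute per-intron splicing efficiency from junction counts
#'
#' The pooled-boundary estimator:
#' `se = (spliced5 + spliced3) / (spliced5 + unspliced5 + spliced3 +
#' unspliced3)`. Coverage is the denominator; introns below `min_coverage`
#' get `NA`. Intron retention is `1 - se`.
#'
#' @param counts `JunctionCounts` data frame (`intron_id`, `sample`,
#'   `spliced5`, `unspliced5`, `spliced3`, `unspliced3`).
#' @param min_coverage minimum total boundary reads for a quantifiable
#'   intron (default 10).
#' @return `SpliceEfficiencyTable` data frame: the input columns plus
#'   `coverage`, `se`, `intron_retention`.
#' @export
splicing_efficiency <- function(counts, min_coverage = 10L) {
  check_count(min_coverage, "min_coverage")
  need <- c("intron_id", "spliced5", "unspliced5", "spliced3", "unspliced3")
  stopifnot(all(need %in% names(counts)))
  if (any(counts[, need[-1]] < 0))
    stop("junction counts must be non-negative", call. = FALSE)
  cov <- counts$spliced5 + counts$unspliced5 +
    counts$spliced3 + counts$unspliced3
  se <- (counts$spliced5 + counts$spliced3) / cov
  se[cov < min_coverage] <- NA_real_
  counts$coverage <- cov
  counts$se <- se
  counts$intron_retention <- 1 - se
  counts
}

# Rank-based decile assignment: ranks ascending by SE, ties broken by
# intron id, bins sized within 1 of each other.
assign_deciles <- function(se, n_bins = 10L) {
  ord <- order(se, names(se))
  rank <- integer(length(se))
  rank[ord] <- seq_along(se)
  as.integer(floor((rank - 1) * n_bins / length(se)) + 1L)
}

#' Compare mutant splicing efficiency to wild type by WT deciles
#'
#' Introns quantified (non-`NA`) in the wild type are partitioned into ten
#' rank-based deciles of wild-type SE (decile 1 = least-spliced tenth).
#' Within each decile, each mutant genotype's SE values are compared with
#' the wild-type values of the same introns by a two-sided Welch t-test
#' (mutant `NA`s dropped pairwise).
#'
#' @param se_wt named numeric vector of wild-type SE per intron.
#' @param se_mut named numeric vector, or named list of such vectors (one
#'   per genotype).
#' @param n_bins number of bins (default 10).
#' @return `DecileReport` data frame: `decile`, `genotype`, `n_wt`, `n_mut`,
#'   `mean_wt`, `mean_mut`, `mean_diff`, `t`, `p_value`; the decile
#'   assignment (named integer vector) is attached as attribute
#'   `"deciles"`.
#' @export
decile_report <- function(se_wt, se_mut, n_bins = 10L) {
  se_wt <- se_wt[!is.na(se_wt)]
  if (!is.list(se_mut)) se_mut <- list(mut = se_mut)
  dec <- setNames(assign_deciles(se_wt, n_bins), names(se_wt))
  rows <- list()
  for (g in names(se_mut)) {
    mu <- se_mut[[g]]
    for (d in seq_len(n_bins)) {
      ids <- names(dec)[dec == d]
      wt_vals <- se_wt[ids]
      mut_vals <- mu[ids]
      ok <- !is.na(mut_vals)
      tt <- if (sum(ok) >= 2L && length(wt_vals) >= 2L &&
                (sd(wt_vals) > 0 || sd(mut_vals[ok]) > 0))
        t.test(mut_vals[ok], wt_vals) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        decile = d, genotype = g,
        n_wt = length(wt_vals), n_mut = sum(ok),
        mean_wt = mean(wt_vals),
        mean_mut = if (any(ok)) mean(mut_vals[ok]) else NA_real_,
        mean_diff = if (any(ok)) mean(wt_vals[ok]) - mean(mut_vals[ok])
                    else NA_real_,
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        p_value = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "deciles") <- dec
  out
}

#' Rank introns by how strongly splicing is affected in a mutant
#'
#' `metric = "difference"` ranks by `se_wt - se_mut`, largest first;
#' `metric = "ratio"` ranks by `se_mut / se_wt`, smallest first. Ties are
#' broken by lower mutant SE, then lexicographic intron id. Introns `NA` in
#' either sample are excluded (count recorded in attribute
#' `"n_excluded"`).
#'
#' @param se_wt,se_mut named numeric SE vectors over the same introns.
#' @param metric `"difference"` (default) or `"ratio"`.
#' @return data frame sorted most-affected first: `intron_id`, `se_wt`,
#'   `se_mut`, `score`.
#' @export
rank_affected <- function(se_wt, se_mut,
                          metric = c("difference", "ratio")) {
  metric <- match.arg(metric)
  ids <- intersect(names(se_wt), names(se_mut))
  wt <- se_wt[ids]; mu <- se_mut[ids]
  ok <- !is.na(wt) & !is.na(mu)
  n_excluded <- sum(!ok)
  wt <- wt[ok]; mu <- mu[ok]; ids <- ids[ok]
  score <- if (metric == "difference") wt - mu else mu / wt
  ord <- if (metric == "difference")
    order(-score, mu, ids) else order(score, mu, ids)
  out <- data.frame(intron_id = ids[ord], se_wt = unname(wt[ord]),
                    se_mut = unname(mu[ord]), score = unname(score[ord]))
  attr(out, "metric") <- metric
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Select the extreme fraction of a ranked intron list
#'
#' Returns `floor(fraction * N)` introns (at least 1) from the stated end of
#' a [rank_affected()] ranking: `"worst"` takes the most-affected head,
#' `"best"` the least-affected tail.
#'
#' @param ranked data frame from [rank_affected()].
#' @param fraction fraction of introns to select, in `(0, 1]` (default 0.05).
#' @param direction `"worst"` or `"best"`.
#' @return character vector of intron ids (empty for an empty ranking).
#' @export
select_extremes <- function(ranked, fraction = 0.05,
                            direction = c("worst", "best")) {
  direction <- match.arg(direction)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  n <- nrow(ranked)
  if (n == 0L) return(character(0))
  k <- max(1L, floor(fraction * n))
  if (direction == "worst") ranked$intron_id[seq_len(k)]
  else rev(ranked$intron_id)[seq_len(k)]
}
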