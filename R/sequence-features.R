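#' Extract splice-junction sequence windows
#'
#' For the 5' (exon-intron) junction the window holds `n_exonic` exonic
#' bases followed by `n_intronic` intronic bases; for the 3' (intron-exon)
#' junction, `n_intronic` intronic bases followed by `n_exonic` exonic
#' bases. Windows are reported 5'->3' on the annotated strand (minus-strand
#' introns are reverse-complemented). Introns too close to a chromosome end
#' for the full window are skipped with a warning.
#'
#' @param introns intron data frame (`intron_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param sequences chromosome [Biostrings::DNAStringSet].
#' @param site `"5prime"` or `"3prime"`.
#' @param n_exonic,n_intronic window widths (defaults 3 exonic + 8 intronic).
#' @return named character vector of equal-length windows.
#' @export
extract_junction_windows <- function(introns, sequences,
                                     site = c("5prime", "3prime"),
                                     n_exonic = 3L, n_intronic = 8L) {
  site <- match.arg(site)
  missing_chr <- setdiff(unique(introns$chrom), names(sequences))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  chrom_len <- setNames(Biostrings::width(sequences), names(sequences))
  out <- character(0)
  skipped <- character(0)
  for (i in seq_len(nrow(introns))) {
    st <- introns$strand[i]
    # The junction sits at the intron's genomic start for (5', +) and
    # (3', -), at its genomic end otherwise; reverse-complementation below
    # restores exon->intron (5') / intron->exon (3') reading order.
    if ((site == "5prime") == (st == "+")) {
      lo <- introns$start[i] - n_exonic
      hi <- introns$start[i] + n_intronic - 1L
    } else {
      lo <- introns$end[i] - n_intronic + 1L
      hi <- introns$end[i] + n_exonic
    }
    if (lo < 1L || hi > chrom_len[introns$chrom[i]]) {
      skipped <- c(skipped, introns$intron_id[i])
      next
    }
    s <- Biostrings::subseq(sequences[[introns$chrom[i]]], lo, hi)
    if (st == "-") s <- Biostrings::reverseComplement(s)
    out[introns$intron_id[i]] <- as.character(s)
  }
  if (length(skipped))
    warning(length(skipped), " intron window(s) truncated at chromosome ",
            "bounds, skipped: ", paste(head(skipped, 5), collapse = ", "),
            call. = FALSE)
  out
}

#' Build a position probability matrix from junction windows
#'
#' Counts bases per position (`N` excluded from column totals), normalises
#' to a position probability matrix, and computes per-position information
#' content `2 + sum_b p_b log2 p_b` bits (uniform-background convention;
#' `0 * log 0 = 0`). An optional small-sample correction subtracts the
#' expected entropy bias `3 / (2 ln 2 * n)`.
#'
#' @param windows character vector of equal-length windows over
#'   `{A,C,G,T,N}`.
#' @param small_sample_correction apply the correction (default `FALSE`).
#' @return object of class `"splice_site_matrix"`: list with `counts`
#'   (4 x width), `ppm`, `info` (bits per position), `n` (windows).
#' @export
splice_site_matrix <- function(windows, small_sample_correction = FALSE) {
  if (length(windows) == 0L)
    stop("`windows` must contain at least one sequence", call. = FALSE)
  if (length(unique(nchar(windows))) != 1L)
    stop("windows must all have the same length", call. = FALSE)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4L, ncol = nchar(windows[1]),
                   dimnames = list(bases, NULL))
  present <- intersect(bases, rownames(cm))
  counts[present, ] <- cm[present, , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("a window column contains only N", call. = FALSE)
  ppm <- sweep(counts, 2L, totals, "/")
  plogp <- ifelse(ppm > 0, ppm * log2(ppm), 0)
  info <- 2 + colSums(plogp)
  if (small_sample_correction)
    info <- pmax(0, info - 3 / (2 * log(2) * length(windows)))
  structure(list(counts = counts, ppm = ppm, info = info,
                 n = length(windows)),
            class = "splice_site_matrix")
}

# Pool bases whose expected count under the background is < 1 into the most
# frequent retained base, then chi-square against the pooled expectation.
position_chisq <- function(obs, bg_p) {
  bg_p <- bg_p / sum(bg_p)
  low <- bg_p * sum(obs) < 1
  pooled <- any(low)
  if (pooled) {
    keep <- !low
    if (!any(keep))
      return(list(stat = NA_real_, p = NA_real_, pooled = TRUE))
    sink <- which(keep)[which.max(bg_p[keep])]
    obs[sink] <- obs[sink] + sum(obs[low])
    bg_p[sink] <- bg_p[sink] + sum(bg_p[low])
    obs <- obs[keep]
    bg_p <- bg_p[keep]
  }
  if (length(obs) < 2L || sum(obs) == 0)
    return(list(stat = NA_real_, p = NA_real_, pooled = pooled))
  suppressWarnings(ct <- chisq.test(obs, p = bg_p / sum(bg_p)))
  list(stat = unname(ct$statistic), p = ct$p.value, pooled = pooled)
}

#' Compare a splice-site matrix against a background matrix
#'
#' Per position, the intron set's base counts are tested against expected
#' counts under the background's base frequencies (chi-square goodness of
#' fit; bases with expected count below 1 are pooled and the position
#' flagged `low_count`), with Benjamini-Hochberg adjustment across
#' positions. Per-position Kullback-Leibler divergence (set vs background,
#' bits) is reported alongside. The test statistic is reported as added
#' plumbing beyond the visual logo comparison it supports.
#'
#' @param set_matrix,background_matrix [splice_site_matrix()] objects with
#'   identical window geometry.
#' @return data frame: `position`, `chisq`, `p_value`, `p_adjusted`, `kl`,
#'   `low_count`.
#' @export
compare_to_background <- function(set_matrix, background_matrix) {
  stopifnot(inherits(set_matrix, "splice_site_matrix"),
            inherits(background_matrix, "splice_site_matrix"))
  if (ncol(set_matrix$ppm) != ncol(background_matrix$ppm))
    stop("matrices have different window widths", call. = FALSE)
  W <- ncol(set_matrix$ppm)
  res <- lapply(seq_len(W), function(j) {
    obs <- set_matrix$counts[, j]
    bg_p <- background_matrix$ppm[, j]
    ct <- position_chisq(obs, bg_p)
    ps <- set_matrix$ppm[, j]
    kl_terms <- ifelse(ps > 0, ps * log2(ps / bg_p), 0)
    data.frame(position = j, chisq = ct$stat, p_value = ct$p,
               kl = sum(kl_terms), low_count = ct$pooled)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out[, c("position", "chisq", "p_value", "p_adjusted", "kl", "low_count")]
}

#' Intron length and A/T content of named intron sets
#'
#' Computes per-intron length (`end - start + 1`) and A/T fraction for each
#' named set, summary statistics per set, and pairwise two-sided Welch
#' t-tests between sets for both features.
#'
#' @param sets named list of intron data frames (subsets of an intron
#'   table, with `intron_id`, `chrom`, `start`, `end`, `strand`).
#' @param sequences chromosome [Biostrings::DNAStringSet].
#' @return object of class `"composition_stats"`: list with `per_intron`
#'   (set, intron_id, length, at_fraction), `summary` (per set), and
#'   `tests` (set_a, set_b, feature, p_value).
#' @export
composition_stats <- function(sets, sequences) {
  stopifnot(length(names(sets)) == length(sets), all(nzchar(names(sets))))
  per <- do.call(rbind, lapply(names(sets), function(nm) {
    introns <- sets[[nm]]
    if (nrow(introns) == 0L) stop("set '", nm, "' is empty", call. = FALSE)
    seqs <- intron_sequences(introns, sequences)
    at <- Biostrings::letterFrequency(seqs, "AT", as.prob = TRUE)[, 1]
    data.frame(set = nm, intron_id = introns$intron_id,
               length = introns$end - introns$start + 1L,
               at_fraction = unname(at))
  }))
  summ <- do.call(rbind, lapply(split(per, per$set), function(d)
    data.frame(set = d$set[1], n = nrow(d),
               mean_length = mean(d$length),
               median_length = median(d$length),
               mean_at = mean(d$at_fraction))))
  pairs <- if (length(sets) >= 2L)
    utils::combn(names(sets), 2, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- per[per$set == pr[1], ]; b <- per[per$set == pr[2], ]
    data.frame(set_a = pr[1], set_b = pr[2],
               feature = c("length", "at_fraction"),
               p_value = c(welch_p(a$length, b$length),
                           welch_p(a$at_fraction, b$at_fraction)))
  }))
  structure(list(per_intron = per, summary = summ, tests = tests),
            class = "composition_stats")
}
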