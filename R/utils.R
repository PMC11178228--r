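#' Derive a child seed from a master seed
#'
#' Child seeds are produced by a fixed counter scheme
#' `(master * 69069 + index * 10007) mod 2147483629` so that every
#' simulation unit (gene, well, replicate, stage) owns an independent seed
#' and adding units never perturbs the draws of earlier ones. All randomness
#' in the package flows from a single master seed through this function.
#' The factors keep every intermediate below 2^53, so the arithmetic is
#' exact in double precision.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter (unit index).
#' @return an integer seed in `[0, 2147483628]`.
#' @export
#' @examples
#' subseed(1L, 0:3)
subseed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(index))
  # modulus is the largest prime below 2^31 so the result is a valid seed;
  # 69069 is the classic VAX LCG multiplier
  as.integer((as.double(master) %% 2147483629 * 69069 +
                as.double(index) * 10007) %% 2147483629)
}

# Evaluate `expr` under seed `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a data frame as TSV with `# key=value` header comments
#'
#' The interchange dialect between pipeline stages: plain TSV preceded by
#' comment lines recording provenance (stage parameters, package version).
#'
#' @param x data frame.
#' @param path output path.
#' @param meta named list of scalar values written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage TSV written by [write_stage_tsv()]
#'
#' @param path input path.
#' @return data frame; header comments are attached as attribute `"meta"`.
#' @export
read_stage_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    kv <- strsplit(kv, "=", fixed = TRUE)
    meta <- setNames(lapply(kv, function(z) paste(z[-1], collapse = "=")),
                     vapply(kv, `[`, "", 1L))
  }
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  attr(x, "meta") <- meta
  x
}

# Scalar validation helpers ---------------------------------------------

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be in [0, 1]", name), call. = FALSE)
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < min) || any(x != floor(x)))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  x
}
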