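#' Specification for a synthetic intron-bearing genome
#'
#' Defaults emulate the fission-yeast gene landscape: about 43% of genes
#' carry introns, up to 15 per gene, with a mean intron length of 83 nt and
#' degenerate donor (`GTAAGT`), branch-point (`CTAAC`) and acceptor (`TAG`)
#' motifs. Intron sequences are AT-rich relative to exons. Generated introns
#' always begin `GT` and end `AG` unless `protect_invariant = FALSE` lets the
#' degeneracy process touch the invariant dinucleotides.
#'
#' @param n_genes number of genes.
#' @param frac_intron_genes fraction of genes carrying at least one intron.
#' @param intron_count_probs probabilities over 1..15 introns for an
#'   intron-bearing gene (normalised internally).
#' @param intron_len_mean,intron_len_min mean and minimum intron length (nt);
#'   lengths are `min + NB(size = 2)` so the distribution is right-skewed.
#' @param exon_len_meanlog,exon_len_sdlog,exon_len_min log-normal exon length
#'   parameters (nt).
#' @param consensus_5ss,consensus_bp,consensus_3ss donor 6-mer, branch-point
#'   5-mer and acceptor 3-mer stamped into every intron.
#' @param degeneracy per-position probability that a stamped motif base is
#'   substituted by a random other base.
#' @param protect_invariant if `TRUE` (default) the first two and last two
#'   intron nucleotides are exempt from degeneracy so every intron remains
#'   annotatable as GT..AG.
#' @param bp_offset the branch-point 5-mer ends this many nt upstream of the
#'   intron 3' end.
#' @param intergenic_len spacer length between consecutive genes.
#' @param intron_base_probs,exon_base_probs background base compositions
#'   (named A/C/G/T vectors, normalised internally).
#' @return an object of class `"genome_spec"`.
#' @export
genome_spec <- function(n_genes,
                        frac_intron_genes = 0.43,
                        intron_count_probs = 0.5 ^ (0:14),
                        intron_len_mean = 83,
                        intron_len_min = 30,
                        exon_len_meanlog = log(200),
                        exon_len_sdlog = 0.4,
                        exon_len_min = 30,
                        consensus_5ss = "GTAAGT",
                        consensus_bp = "CTAAC",
                        consensus_3ss = "TAG",
                        degeneracy = 0.25,
                        protect_invariant = TRUE,
                        bp_offset = 10,
                        intergenic_len = 100,
                        intron_base_probs = c(A = 0.35, C = 0.15,
                                              G = 0.15, T = 0.35),
                        exon_base_probs = c(A = 0.3, C = 0.2,
                                            G = 0.2, T = 0.3)) {
  check_count(n_genes, "n_genes")
  check_fraction(frac_intron_genes, "frac_intron_genes")
  check_fraction(degeneracy, "degeneracy")
  if (length(intron_count_probs) != 15L || any(intron_count_probs < 0) ||
      sum(intron_count_probs) <= 0)
    stop("`intron_count_probs` must be 15 non-negative weights over 1..15",
         call. = FALSE)
  check_positive(intron_len_mean, "intron_len_mean")
  check_count(intron_len_min, "intron_len_min", min = 1L)
  check_count(exon_len_min, "exon_len_min", min = 1L)
  if (intron_len_mean <= intron_len_min)
    stop("`intron_len_mean` must exceed `intron_len_min`", call. = FALSE)
  if (nchar(consensus_5ss) != 6L || nchar(consensus_bp) != 5L ||
      nchar(consensus_3ss) != 3L)
    stop("consensus motifs must be a 6-mer (5'SS), 5-mer (BP), 3-mer (3'SS)",
         call. = FALSE)
  if (intron_len_min < 6L + 5L + bp_offset + 1L)
    stop("`intron_len_min` too short to hold 5'SS, BP and 3'SS motifs",
         call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    frac_intron_genes = frac_intron_genes,
    intron_count_probs = intron_count_probs / sum(intron_count_probs),
    intron_len_mean = intron_len_mean,
    intron_len_min = as.integer(intron_len_min),
    exon_len_meanlog = exon_len_meanlog,
    exon_len_sdlog = exon_len_sdlog,
    exon_len_min = as.integer(exon_len_min),
    consensus_5ss = consensus_5ss,
    consensus_bp = consensus_bp,
    consensus_3ss = consensus_3ss,
    degeneracy = degeneracy,
    protect_invariant = isTRUE(protect_invariant),
    bp_offset = as.integer(bp_offset),
    intergenic_len = as.integer(intergenic_len),
    intron_base_probs = intron_base_probs / sum(intron_base_probs),
    exon_base_probs = exon_base_probs / sum(exon_base_probs)
  ), class = "genome_spec")
}

random_dna <- function(n, probs) {
  if (n == 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Stamp a motif into a character vector of bases at positions pos, then
# apply per-position degeneracy, skipping protected (absolute) positions.
stamp_motif <- function(chars, pos, motif, degeneracy, protected) {
  m <- strsplit(motif, "")[[1]]
  chars[pos] <- m
  if (degeneracy > 0) {
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (p %in% protected) next
      if (runif(1) < degeneracy)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
  }
  chars
}

build_intron_seq <- function(len, spec) {
  chars <- strsplit(random_dna(len, spec$intron_base_probs), "")[[1]]
  protected <- if (spec$protect_invariant)
    c(1L, 2L, len - 1L, len) else integer(0)
  chars <- stamp_motif(chars, 1:6, spec$consensus_5ss,
                       spec$degeneracy, protected)
  bp_end <- len - spec$bp_offset
  chars <- stamp_motif(chars, (bp_end - 4L):bp_end, spec$consensus_bp,
                       spec$degeneracy, protected)
  chars <- stamp_motif(chars, (len - 2L):len, spec$consensus_3ss,
                       spec$degeneracy, protected)
  paste(chars, collapse = "")
}

#' Simulate an intron-bearing genome with annotation
#'
#' Generates one chromosome carrying `spec$n_genes` genes separated by
#' intergenic spacers. Each gene is built exon-by-exon on its transcript
#' strand; minus-strand genes are reverse-complemented into the chromosome so
#' splice motifs sit on the annotated strand. Intron coordinates are 1-based
#' inclusive. Each gene (and each spacer) draws from its own child seed
#' (see [subseed()]), so enlarging the genome never changes earlier genes.
#'
#' @param spec a [genome_spec()].
#' @param seed integer master seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @return a list of class `"sim_genome"` with elements
#'   `sequences` (a [Biostrings::DNAStringSet] of chromosomes),
#'   `genes` (data frame: gene_id, chrom, start, end, strand, n_introns,
#'   exonic_len), `introns` (data frame: intron_id, gene_id, intron_index,
#'   chrom, start, end, strand, length, ss5, mismatch_5ss) and
#'   `exons` (gene_id, chrom, start, end, strand, exon_index), plus the spec.
#' @export
simulate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  n <- spec$n_genes
  gene_seqs <- character(n)
  genes <- vector("list", n)
  introns <- vector("list", n)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    g <- with_seed(subseed(seed, i), simulate_one_gene(spec, i))
    gene_seqs[i] <- g$seq
    genes[[i]] <- g$gene
    introns[[i]] <- g$introns
    exons[[i]] <- g$exons
  }
  spacers <- vapply(seq_len(max(n - 1L, 0L)), function(i)
    with_seed(subseed(seed, 1000000L + i),
              random_dna(spec$intergenic_len, spec$exon_base_probs)), "")

  genes <- do.call(rbind, genes)
  introns <- do.call(rbind, introns)
  exons <- do.call(rbind, exons)
  if (n == 0L) {
    return(structure(list(
      sequences = Biostrings::DNAStringSet(),
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), n_introns = integer(),
                         exonic_len = integer()),
      introns = empty_intron_table(),
      exons = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), exon_index = integer()),
      spec = spec), class = "sim_genome"))
  }

  # lay genes head-to-tail on one chromosome with spacers between them
  lens <- nchar(gene_seqs)
  offsets <- cumsum(c(0L, head(lens, -1L) + spec$intergenic_len))
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- gene_seqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- spacers
  chrom_seq <- paste(pieces, collapse = "")

  shift_coords <- function(df, off_by_gene) {
    off <- off_by_gene[df$gene_id]
    df$start <- df$start + off
    df$end <- df$end + off
    df
  }
  off_by_gene <- setNames(offsets, genes$gene_id)
  genes <- shift_coords(genes, off_by_gene)
  introns <- shift_coords(introns, off_by_gene)
  exons <- shift_coords(exons, off_by_gene)

  structure(list(
    sequences = Biostrings::DNAStringSet(c(chr1 = chrom_seq)),
    genes = genes, introns = introns, exons = exons, spec = spec
  ), class = "sim_genome")
}

empty_intron_table <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             intron_index = integer(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             length = integer(), ss5 = character(),
             mismatch_5ss = integer())
}

# Build one gene on its transcript strand, then orient into the chromosome.
# Coordinates returned are 1-based inclusive *within the gene*.
simulate_one_gene <- function(spec, i) {
  gene_id <- sprintf("g%04d", i)
  has_introns <- runif(1) < spec$frac_intron_genes
  n_introns <- if (has_introns)
    sample.int(15L, 1L, prob = spec$intron_count_probs) else 0L
  strand <- sample(c("+", "-"), 1L)

  exon_lens <- pmax(spec$exon_len_min,
                    round(rlnorm(n_introns + 1L, spec$exon_len_meanlog,
                                 spec$exon_len_sdlog)))
  intron_lens <- if (n_introns > 0L)
    spec$intron_len_min +
      rnbinom(n_introns, size = 2,
              mu = spec$intron_len_mean - spec$intron_len_min)
  else integer(0)

  exon_seqs <- vapply(exon_lens, random_dna, "",
                      probs = spec$exon_base_probs)
  intron_seqs <- vapply(intron_lens, build_intron_seq, "", spec = spec)

  # interleave exon1 intron1 exon2 ... on the transcript strand
  parts <- character(2L * n_introns + 1L)
  parts[seq(1L, length(parts), by = 2L)] <- exon_seqs
  if (n_introns > 0L)
    parts[seq(2L, length(parts) - 1L, by = 2L)] <- intron_seqs
  tx_seq <- paste(parts, collapse = "")
  part_lens <- nchar(parts)
  part_start <- cumsum(c(1L, head(part_lens, -1L)))
  part_end <- part_start + part_lens - 1L
  gene_len <- sum(part_lens)

  is_intron <- seq_along(parts) %% 2L == 0L
  tx2gen <- function(s, e) {
    # map transcript-strand interval to gene-local genomic interval
    if (strand == "+") c(s, e) else c(gene_len - e + 1L, gene_len - s + 1L)
  }
  mk <- function(idx) {
    t(vapply(idx, function(j) tx2gen(part_start[j], part_end[j]),
             numeric(2)))
  }

  intron_idx <- which(is_intron)
  exon_idx <- which(!is_intron)
  intron_coords <- if (length(intron_idx)) mk(intron_idx) else
    matrix(numeric(0), ncol = 2)
  exon_coords <- mk(exon_idx)

  ss5 <- vapply(intron_seqs, substr, "", 1L, 6L, USE.NAMES = FALSE)
  introns <- if (n_introns > 0L) data.frame(
    intron_id = sprintf("%s.i%d", gene_id, seq_len(n_introns)),
    gene_id = gene_id,
    intron_index = seq_len(n_introns),
    chrom = "chr1",
    start = as.integer(intron_coords[, 1]),
    end = as.integer(intron_coords[, 2]),
    strand = strand,
    length = as.integer(intron_lens),
    ss5 = ss5,
    mismatch_5ss = vapply(ss5, hamming, 0, b = spec$consensus_5ss,
                          USE.NAMES = FALSE)
  ) else empty_intron_table()

  exons <- data.frame(
    gene_id = gene_id, chrom = "chr1",
    start = as.integer(exon_coords[, 1]),
    end = as.integer(exon_coords[, 2]),
    strand = strand,
    exon_index = seq_along(exon_idx)
  )

  gene_genomic_seq <- if (strand == "+") tx_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))

  list(seq = gene_genomic_seq,
       gene = data.frame(gene_id = gene_id, chrom = "chr1",
                         start = 1L, end = gene_len, strand = strand,
                         n_introns = n_introns,
                         exonic_len = as.integer(sum(exon_lens))),
       introns = introns, exons = exons)
}

#' Write simulated chromosome sequences as FASTA
#'
#' @param sim a `"sim_genome"` from [simulate_genome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sim, path) {
  stopifnot(inherits(sim, "sim_genome"))
  Biostrings::writeXStringSet(sim$sequences, path)
  invisible(path)
}

#' Write simulated gene models as GFF3
#'
#' Emits `gene`, `exon` and explicit `intron` features with 1-based inclusive
#' coordinates, introns carrying `ID` (intron id), `Parent` (gene id) and
#' `intron_index` attributes.
#'
#' @param sim a `"sim_genome"` from [simulate_genome()].
#' @param path output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(sim, path) {
  stopifnot(inherits(sim, "sim_genome"))
  g <- sim$genes; ii <- sim$introns; ee <- sim$exons
  gr <- c(
    GenomicRanges::GRanges(g$chrom,
                           IRanges::IRanges(g$start, g$end), g$strand,
                           type = "gene", ID = g$gene_id,
                           Parent = NA_character_,
                           intron_index = NA_integer_),
    GenomicRanges::GRanges(ee$chrom,
                           IRanges::IRanges(ee$start, ee$end), ee$strand,
                           type = "exon",
                           ID = sprintf("%s.e%d", ee$gene_id, ee$exon_index),
                           Parent = ee$gene_id,
                           intron_index = NA_integer_),
    GenomicRanges::GRanges(ii$chrom,
                           IRanges::IRanges(ii$start, ii$end), ii$strand,
                           type = "intron", ID = ii$intron_id,
                           Parent = ii$gene_id,
                           intron_index = ii$intron_index)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read intron records from a GFF3 annotation
#'
#' Expects explicit `intron` features as written by
#' [write_annotation_gff3()]; `Parent` gives the gene id. If no
#' `intron_index` attribute is present, introns are numbered 5' to 3' along
#' the annotated strand within each gene.
#'
#' @param path GFF3 path.
#' @return an intron data frame (intron_id, gene_id, intron_index, chrom,
#'   start, end, strand).
#' @export
read_intron_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "intron"]
  parent <- as.character(gr$Parent)
  df <- data.frame(
    intron_id = as.character(gr$ID),
    gene_id = parent,
    intron_index = if ("intron_index" %in%
                       names(S4Vectors::mcols(gr)))
      as.integer(gr$intron_index) else NA_integer_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (anyNA(df$intron_index)) {
    df <- df[order(df$gene_id, df$start), ]
    df$intron_index <- stats::ave(
      df$start, df$gene_id,
      FUN = function(s) seq_along(s))
    minus <- df$strand == "-"
    if (any(minus)) {
      n_by_gene <- stats::ave(df$start, df$gene_id, FUN = length)
      df$intron_index[minus] <-
        n_by_gene[minus] - df$intron_index[minus] + 1L
    }
    df$intron_index <- as.integer(df$intron_index)
  }
  df
}

#' Extract intron sequences on the annotated strand
#'
#' @param introns intron data frame (chrom, start, end, strand).
#' @param sequences chromosome [Biostrings::DNAStringSet].
#' @return a [Biostrings::DNAStringSet], one entry per intron, 5'->3' on the
#'   transcript strand (minus-strand introns reverse-complemented), named by
#'   `intron_id`.
#' @export
intron_sequences <- function(introns, sequences) {
  if (nrow(introns) == 0L) return(Biostrings::DNAStringSet())
  missing_chr <- setdiff(unique(introns$chrom), names(sequences))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(introns)), function(i) {
    s <- Biostrings::subseq(sequences[[introns$chrom[i]]],
                            introns$start[i], introns$end[i])
    if (introns$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, ""))
  names(out) <- introns$intron_id
  out
}
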