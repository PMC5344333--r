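# Hand-built fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately avoid the implementation's code paths
# (no findOverlaps / coverage()): plain loops over reads and bases.

# A small two-contig gene set covering all window cases: a chloroplast
# gene + 23S, plus nuclear genes on both strands, a short terminal exon,
# and a convergent overlapping pair.
tinyModels <- function() {
  df <- data.frame(
    gene_id = c("cpA", "rrl_23S", "plusG", "minusG", "shortG",
                "convP", "convM"),
    contig = c("chloroplast", "chloroplast", "nuclear", "nuclear",
               "nuclear", "nuclear", "nuclear"),
    start = c(100, 700, 1001, 3001, 5001, 7001, 7851),
    end = c(600, 1400, 2000, 4000, 6000, 7900, 8750),
    strand = c("+", "+", "+", "-", "+", "+", "-"),
    compartment = c("chloroplast", "chloroplast", rep("nuclear", 5)),
    gene_type = c("protein", "rRNA", rep("protein", 5)),
    housekeeping_role = c("none", "chloro_norm", "nuclear_norm", "none",
                          "none", "none", "none"),
    stringsAsFactors = FALSE
  )
  exons <- list(
    IRanges::IRanges(100, 600),
    IRanges::IRanges(700, 1400),
    IRanges::IRanges(1001, 2000),
    IRanges::IRanges(3001, 4000),
    IRanges::IRanges(c(5001, 5701), c(5600, 6000)),  # terminal exon 300 nt
    IRanges::IRanges(7001, 7900),
    IRanges::IRanges(7851, 8750)                     # overlaps convP by 50
  )
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig, ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    seqlengths = c(chloroplast = 2000L, nuclear = 10000L)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = df$gene_id, compartment = df$compartment,
    gene_type = df$gene_type, housekeeping_role = df$housekeeping_role,
    cds_start = NA_integer_, cds_end = NA_integer_,
    exons = IRanges::IRangesList(exons)
  )
  names(gr) <- df$gene_id
  GeneModelSet(gr)
}

# Alignment-table row builder.
alnRow <- function(start, end, reference = "nuclear", sample_id = "s1",
                   strand = "+", read_id = NULL) {
  data.frame(
    read_id = if (is.null(read_id)) sprintf("r_%d_%d", start, end)
    else read_id,
    reference = reference, start = start, end = end, strand = strand,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

# Brute-force counting oracle: per-read loop over all windows, greatest
# overlap wins, exact ties dropped.
bruteCount <- function(alignments, windows) {
  genes <- S4Vectors::mcols(windows)$gene_id
  samples <- unique(alignments$sample_id)
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (i in seq_len(nrow(alignments))) {
    ov <- integer(length(windows))
    for (j in seq_along(windows)) {
      if (alignments$reference[i] !=
            as.character(GenomicRanges::seqnames(windows)[j])) next
      o <- min(alignments$end[i], GenomicRanges::end(windows)[j]) -
        max(alignments$start[i], GenomicRanges::start(windows)[j]) + 1L
      if (o > 0) ov[j] <- o
    }
    if (all(ov == 0)) next
    winners <- which(ov == max(ov))
    if (length(winners) != 1L) next  # tie: dropped
    mat[winners, alignments$sample_id[i]] <-
      mat[winners, alignments$sample_id[i]] + 1L
  }
  mat
}

# Brute-force per-base coverage oracle.
bruteCoverage <- function(alignments, contig, len) {
  depth <- integer(len)
  aln <- alignments[alignments$reference == contig, , drop = FALSE]
  for (b in seq_len(len)) {
    depth[b] <- sum(aln$start <= b & aln$end >= b)
  }
  depth
}

# Random counting fixture: k windows on one contig plus n reads.
randomCountingFixture <- function(n_reads, n_windows = 5L, len = 5000L) {
  ws <- sort(sample.int(len - 600L, n_windows))
  windows <- GenomicRanges::GRanges(
    seqnames = "ctg", ranges = IRanges::IRanges(ws, ws + 399L),
    strand = "+"
  )
  S4Vectors::mcols(windows) <- S4Vectors::DataFrame(
    gene_id = sprintf("g%02d", seq_len(n_windows)),
    compartment = "nuclear", housekeeping_role = "none",
    basis = "terminal_403"
  )
  st <- sample.int(len - 60L, n_reads, replace = TRUE)
  aln <- data.frame(
    read_id = sprintf("r%05d", seq_len(n_reads)), reference = "ctg",
    start = st, end = st + sample(20:50, n_reads, replace = TRUE),
    strand = sample(c("+", "-"), n_reads, replace = TRUE),
    sample_id = sample(c("s1", "s2"), n_reads, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(windows = windows, alignments = aln)
}

# Translate a CDS interval of a genome, honouring strand.
translateCDS <- function(genome, contig, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[contig]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(Biostrings::translate(s))
}

# Small normalized TagSeqExperiment built directly from a count matrix,
# bypassing read simulation (for DE-level tests).
tseFromCounts <- function(counts, compartment = "nuclear",
                          status = NULL, design = NULL) {
  ng <- nrow(counts)
  hk <- "GAPDH" %in% rownames(counts)
  rd <- S4Vectors::DataFrame(
    gene_id = rownames(counts),
    compartment = compartment,
    housekeeping_role = ifelse(rownames(counts) == "GAPDH",
                               "nuclear_norm", "none"),
    status = if (is.null(status)) "counted" else status,
    row.names = rownames(counts)
  )
  cd <- if (is.null(design)) {
    S4Vectors::DataFrame(sample_id = colnames(counts),
                         row.names = colnames(counts))
  } else {
    S4Vectors::DataFrame(design[match(colnames(counts), design$sample_id), ],
                         row.names = colnames(counts))
  }
  stopifnot(hk)
  x <- new("TagSeqExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd
  ))
  normalizeToHousekeeping(x)
}
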