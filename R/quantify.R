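#' Derive per-gene counting windows
#'
#' Chloroplast genes are counted over their full annotated span. Nuclear
#' genes, whose non-directional libraries are strongly 3'-biased, are
#' counted over the last 403 nucleotides of the terminal (3'-most) exon:
#' for a (+)-strand gene the 403 nt ending at the last exon's end, for a
#' (-)-strand gene the 403 nt starting at the first (reference-coordinate)
#' exon's start — the biological 3' terminus in both cases. Terminal exons
#' shorter than 403 nt yield a window equal to the whole terminal exon;
#' windows are never extended across exon junctions.
#'
#' @param models A [GeneModelSet-class].
#' @return `GRanges` of windows, one per gene, with metadata columns
#'   gene_id, compartment, housekeeping_role, basis ("full_span" or
#'   "terminal_403").
#' @examples
#' gen <- generateGenomeAnnotation(simConfig(seed = 1))
#' deriveCountWindows(gen$models)
#' @export
deriveCountWindows <- function(models) {
  stopifnot(is(models, "GeneModelSet"))
  g <- geneModels(models)
  m <- S4Vectors::mcols(g)
  n <- length(g)
  ws <- we <- integer(n)
  basis <- character(n)
  for (i in seq_len(n)) {
    ex <- m$exons[[i]]
    if (length(ex) == 0L) stop(m$gene_id[i], ": gene without exons")
    if (m$compartment[i] == "chloroplast") {
      ws[i] <- GenomicRanges::start(g)[i]
      we[i] <- GenomicRanges::end(g)[i]
      basis[i] <- "full_span"
    } else {
      if (as.character(GenomicRanges::strand(g)[i]) == "+") {
        term <- ex[length(ex)]
        we[i] <- IRanges::end(term)
        ws[i] <- max(IRanges::start(term), IRanges::end(term) - 402L)
      } else {
        term <- ex[1L]
        ws[i] <- IRanges::start(term)
        we[i] <- min(IRanges::end(term), IRanges::start(term) + 402L)
      }
      basis[i] <- "terminal_403"
    }
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(g),
    ranges = IRanges::IRanges(ws, we),
    strand = GenomicRanges::strand(g)
  )
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = m$gene_id, compartment = m$compartment,
    housekeeping_role = m$housekeeping_role, basis = basis
  )
  names(out) <- m$gene_id
  out
}

#' Flag genes whose windows cannot be counted gene-specifically
#'
#' Two rules, both consequences of 3'-biased non-directional reads:
#' \itemize{
#'   \item \strong{excluded_overlap}: both members of any opposite-strand
#'     (convergent) gene pair whose counting windows overlap. Reads in the
#'     shared 3' region cannot be assigned to either gene. Same-strand
#'     overlaps are \emph{not} excluded by this rule.
#'   \item \strong{merged_identical}: genes whose window sequences are
#'     byte-identical (paralogs identical over the counted region). Their
#'     reads are interchangeable, so they are reported as one joint record.
#'     Requires `genome`; skipped when no genome is supplied.
#' }
#'
#' @param models A [GeneModelSet-class].
#' @param genome Optional named `DNAStringSet` (for the identity rule).
#' @param windows Optional precomputed windows from [deriveCountWindows()].
#' @return data.frame with columns gene_id, status ("counted",
#'   "excluded_overlap" or "merged_identical") and merged_with (the joint
#'   record's gene ids, NA otherwise).
#' @export
flagExclusions <- function(models, genome = NULL,
                           windows = deriveCountWindows(models)) {
  m <- S4Vectors::mcols(windows)
  status <- rep("counted", length(windows))
  merged_with <- rep(NA_character_, length(windows))

  hits <- GenomicRanges::findOverlaps(windows, windows,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- qh < sh &
    as.character(GenomicRanges::strand(windows))[qh] !=
      as.character(GenomicRanges::strand(windows))[sh]
  status[unique(c(qh[keep], sh[keep]))] <- "excluded_overlap"

  if (!is.null(genome)) {
    seqs <- character(length(windows))
    for (i in seq_along(windows)) {
      contig <- as.character(GenomicRanges::seqnames(windows)[i])
      seqs[i] <- as.character(Biostrings::subseq(
        genome[[contig]],
        GenomicRanges::start(windows)[i], GenomicRanges::end(windows)[i]
      ))
    }
    for (comp in unique(m$compartment)) {
      idx <- which(m$compartment == comp & status == "counted")
      dup_groups <- split(idx, seqs[idx])
      for (grp in dup_groups) {
        if (length(grp) > 1L) {
          status[grp] <- "merged_identical"
          merged_with[grp] <- paste(sort(m$gene_id[grp]), collapse = "+")
        }
      }
    }
  }
  data.frame(gene_id = m$gene_id, status = status,
             merged_with = merged_with, stringsAsFactors = FALSE)
}

#' Count reads in gene windows
#'
#' A read increments a gene when its interval overlaps the gene's counting
#' window by at least one base, irrespective of the recorded strand (the
#' libraries are non-directional). A read overlapping several windows is
#' assigned to the window of greatest overlap; exact ties are dropped, so
#' every read is counted at most once and counts are deterministic.
#'
#' @param alignments Alignment table (data.frame with read_id, reference,
#'   start, end, strand, sample_id).
#' @param windows Windows from [deriveCountWindows()].
#' @return Integer matrix, genes x samples (all samples present in
#'   `alignments`; an empty table yields a 0-column matrix).
#' @export
countReads <- function(alignments, windows) {
  genes <- S4Vectors::mcols(windows)$gene_id
  samples <- unique(alignments$sample_id)
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (nrow(alignments) == 0L) return(mat)
  bad <- alignments$start > alignments$end
  if (any(bad)) {
    stop("malformed interval (start > end) for read ",
         alignments$read_id[which(bad)[1]])
  }
  reads <- GenomicRanges::GRanges(
    seqnames = alignments$reference,
    ranges = IRanges::IRanges(alignments$start, alignments$end)
  )
  hits <- GenomicRanges::findOverlaps(reads, windows, ignore.strand = TRUE)
  if (length(hits) == 0L) return(mat)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(alignments$end[qh], GenomicRanges::end(windows)[sh]) -
    pmax(alignments$start[qh], GenomicRanges::start(windows)[sh]) + 1L
  best <- tapply(ov, qh, max)
  n_best <- tapply(seq_along(qh), qh, function(i) {
    sum(ov[i] == max(ov[i]))
  })
  read_idx <- as.integer(names(best))
  keep_reads <- read_idx[n_best == 1L]  # ties dropped
  sel <- qh %in% keep_reads & ov == best[as.character(qh)]
  assigned_gene <- genes[sh[sel]]
  assigned_sample <- alignments$sample_id[qh[sel]]
  tab <- table(factor(assigned_gene, levels = genes),
               factor(assigned_sample, levels = samples))
  mat[] <- as.integer(tab)
  mat
}

#' Quantify an experiment into a TagSeqExperiment
#'
#' Runs window derivation, exclusion flagging and read counting, merging
#' identical-window gene groups into one joint record (counts summed,
#' gene_id joined with "+").
#'
#' @param models A [GeneModelSet-class].
#' @param alignments Alignment table.
#' @param genome Optional genome (`DNAStringSet`) for the window-identity
#'   rule.
#' @param design Optional sample design; rows are matched to the count
#'   matrix columns by sample_id.
#' @return A [TagSeqExperiment-class] with a `"counts"` assay.
#' @examples
#' cfg <- simConfig(seed = 1, total_reads_per_sample = 2000)
#' gen <- generateGenomeAnnotation(cfg)
#' aln <- simulateAlignments(gen$models, gen$truth, cfg)
#' tse <- quantifyExperiment(gen$models, aln, gen$genome)
#' tse
#' @export
quantifyExperiment <- function(models, alignments, genome = NULL,
                               design = NULL) {
  windows <- deriveCountWindows(models)
  flags <- flagExclusions(models, genome, windows)
  counts <- countReads(alignments, windows)
  m <- S4Vectors::mcols(windows)
  rd <- data.frame(
    gene_id = m$gene_id, compartment = m$compartment,
    housekeeping_role = m$housekeeping_role, basis = m$basis,
    window_start = GenomicRanges::start(windows),
    window_end = GenomicRanges::end(windows),
    status = flags$status, stringsAsFactors = FALSE
  )

  merged <- !is.na(flags$merged_with)
  if (any(merged)) {
    for (joint in unique(flags$merged_with[merged])) {
      grp <- which(flags$merged_with == joint & merged)
      rep_i <- grp[1]
      counts[rep_i, ] <- as.integer(colSums(counts[grp, , drop = FALSE]))
      rd$gene_id[rep_i] <- joint
      drop_i <- grp[-1]
      counts <- counts[-drop_i, , drop = FALSE]
      rd <- rd[-drop_i, , drop = FALSE]
      flags <- flags[-drop_i, , drop = FALSE]
      merged <- !is.na(flags$merged_with)
    }
  }
  rownames(counts) <- rd$gene_id

  cd <- if (!is.null(design)) {
    S4Vectors::DataFrame(design[match(colnames(counts), design$sample_id), ],
                         row.names = colnames(counts))
  } else {
    S4Vectors::DataFrame(sample_id = colnames(counts),
                         row.names = colnames(counts))
  }
  new("TagSeqExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(rd, row.names = rd$gene_id),
    colData = cd
  ))
}

#' Normalize counts to compartment housekeeping genes
#'
#' Chloroplast counts are divided by the sample's 23S rRNA count (summed
#' over all copies carrying the `chloro_norm` role) and nuclear counts by
#' the sample's GAPDH count (`nuclear_norm` role). Ratios are exact
#' (raw / housekeeping, no pseudocounts); a zero housekeeping count in any
#' sample is a hard error naming the sample.
#'
#' @param x A [TagSeqExperiment-class] with a `"counts"` assay.
#' @return `x` with a `"normalized"` assay added and the per-sample
#'   housekeeping denominators in `metadata(x)$housekeeping`.
#' @export
normalizeToHousekeeping <- function(x) {
  stopifnot(is(x, "TagSeqExperiment"))
  counts <- SummarizedExperiment::assay(x, "counts")
  rd <- SummarizedExperiment::rowData(x)
  hk <- list()
  norm <- matrix(NA_real_, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  for (comp in unique(rd$compartment)) {
    role <- if (comp == "chloroplast") "chloro_norm" else "nuclear_norm"
    hk_rows <- which(rd$compartment == comp & rd$housekeeping_role == role)
    if (!length(hk_rows)) {
      stop("no ", role, " housekeeping gene for compartment ", comp)
    }
    denom <- colSums(counts[hk_rows, , drop = FALSE])
    zero <- denom == 0
    if (any(zero)) {
      stop("zero housekeeping (", role, ") count in sample ",
           colnames(counts)[which(zero)[1]])
    }
    rows <- rd$compartment == comp
    norm[rows, ] <- sweep(counts[rows, , drop = FALSE], 2, denom, "/")
    hk[[comp]] <- denom
  }
  SummarizedExperiment::assay(x, "normalized") <- norm
  S4Vectors::metadata(x)$housekeeping <- hk
  x
}
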