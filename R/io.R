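#' Write / read pipeline file formats
#'
#' Plain-text formats at every stage boundary: genome as FASTA, gene
#' models as GFF3 (1-based inclusive, `ID`/`Parent` attributes),
#' alignments as a tab-delimited table (read_id, reference, start, end,
#' strand, sample_id), everything else as CSV, ground truth and the run
#' manifest as JSON.
#'
#' @name dielshift-io
NULL

#' @rdname dielshift-io
#' @param genome Named `DNAStringSet`.
#' @param path Output file path.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname dielshift-io
#' @export
readGenomeFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname dielshift-io
#' @param models A [GeneModelSet-class].
#' @export
writeAnnotationGFF3 <- function(models, path) {
  g <- geneModels(models)
  m <- S4Vectors::mcols(g)
  feats <- list()
  for (i in seq_along(g)) {
    contig <- as.character(GenomicRanges::seqnames(g)[i])
    strand <- as.character(GenomicRanges::strand(g)[i])
    gid <- m$gene_id[i]
    feats[[length(feats) + 1L]] <- data.frame(
      contig = contig, start = GenomicRanges::start(g)[i],
      end = GenomicRanges::end(g)[i], strand = strand, type = "gene",
      ID = gid, Parent = NA_character_, compartment = m$compartment[i],
      gene_type = m$gene_type[i],
      housekeeping_role = m$housekeeping_role[i],
      phase = NA_integer_, stringsAsFactors = FALSE
    )
    ex <- m$exons[[i]]
    for (k in seq_along(ex)) {
      feats[[length(feats) + 1L]] <- data.frame(
        contig = contig, start = IRanges::start(ex)[k],
        end = IRanges::end(ex)[k], strand = strand, type = "exon",
        ID = sprintf("%s.exon%d", gid, k), Parent = gid,
        compartment = NA, gene_type = NA, housekeeping_role = NA,
        phase = NA_integer_, stringsAsFactors = FALSE
      )
    }
    if (!is.na(m$cds_start[i])) {
      feats[[length(feats) + 1L]] <- data.frame(
        contig = contig, start = m$cds_start[i], end = m$cds_end[i],
        strand = strand, type = "CDS", ID = sprintf("%s.cds", gid),
        Parent = gid, compartment = NA, gene_type = NA,
        housekeeping_role = NA, phase = 0L, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig, ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, ID = df$ID,
    Parent = IRanges::CharacterList(
      lapply(df$Parent, function(p) if (is.na(p)) character() else p)
    ),
    compartment = df$compartment, gene_type = df$gene_type,
    housekeeping_role = df$housekeeping_role, phase = df$phase
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname dielshift-io
#' @param seqlengths Optional named contig lengths to set on the result.
#' @export
readAnnotationGFF3 <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  parent <- vapply(m$Parent, function(p) {
    if (length(p)) p[1] else NA_character_
  }, character(1))
  is_gene <- m$type == "gene"
  genes <- gr[is_gene]
  gm <- S4Vectors::mcols(genes)
  exons <- lapply(gm$ID, function(gid) {
    ex <- gr[m$type == "exon" & parent == gid]
    ex <- ex[order(GenomicRanges::start(ex))]
    IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex))
  })
  cds <- lapply(gm$ID, function(gid) {
    cc <- gr[m$type == "CDS" & parent == gid]
    if (length(cc)) c(GenomicRanges::start(cc)[1],
                      GenomicRanges::end(cc)[1])
    else c(NA_integer_, NA_integer_)
  })
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::ranges(genes),
    strand = GenomicRanges::strand(genes)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlengths(out) <- seqlengths[
      GenomeInfoDb::seqlevels(out)
    ]
  }
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gm$ID, compartment = gm$compartment,
    gene_type = gm$gene_type, housekeeping_role = gm$housekeeping_role,
    cds_start = vapply(cds, `[`, integer(1), 1),
    cds_end = vapply(cds, `[`, integer(1), 2),
    exons = IRanges::IRangesList(exons)
  )
  names(out) <- gm$ID
  GeneModelSet(out)
}

#' @rdname dielshift-io
#' @param alignments Alignment table.
#' @export
writeAlignmentTable <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname dielshift-io
#' @export
readAlignmentTable <- function(path) {
  aln <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("read_id", "reference", "start", "end", "strand")
  missing_cols <- setdiff(req, colnames(aln))
  if (length(missing_cols)) {
    stop("alignment table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  aln
}
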