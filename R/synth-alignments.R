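#' Simulate a table of read alignments
#'
#' Draws per-gene read totals from a negative-binomial distribution whose
#' mean is the gene's expected abundance share times the sample depth, then
#' places reads on the reference: chloroplast reads uniformly over the
#' gene's (true) span, nuclear reads with probability `three_prime_bias`
#' starting within 8 read lengths of the transcript 3' end and otherwise
#' uniformly along the transcript. Each read lies fully within one exon.
#' Recorded strands are random: the libraries emulated here are
#' non-directional, and downstream counting must ignore strand.
#'
#' The truncated-CDS gene's reads cover its true (pre-truncation) span and
#' the planted unannotated ORF is expressed, so coverage-based refinement
#' has signal to recover both.
#'
#' @param models A [GeneModelSet-class].
#' @param truth Ground-truth list from [generateGenomeAnnotation()].
#' @param config A [SimConfig-class].
#' @param design Sample design from [experimentDesign()] (its `group`
#'   column must match the columns of `truth$multiplier`).
#' @return data.frame with columns read_id, reference, start, end, strand,
#'   sample_id (the alignment-table format consumed by all counting and
#'   coverage operations). Zero depth yields an empty table.
#' @examples
#' gen <- generateGenomeAnnotation(simConfig(seed = 1,
#'   total_reads_per_sample = 500))
#' aln <- simulateAlignments(gen$models, gen$truth, simConfig(seed = 1,
#'   total_reads_per_sample = 500))
#' head(aln)
#' @export
simulateAlignments <- function(models, truth, config,
                               design = experimentDesign()) {
  stopifnot(is(models, "GeneModelSet"), is(config, "SimConfig"))
  validObject(config)
  set.seed(deriveSeed(config@seed, "alignments"))

  g <- geneModels(models)
  m <- S4Vectors::mcols(g)
  clens <- GenomeInfoDb::seqlengths(g)
  rl <- config@read_length
  base <- truth$base_expression
  mult <- truth$multiplier

  # Read-placement span per gene: annotation span, overridden by the true
  # span for the truncated gene; the novel ORF is an extra expression unit.
  units <- data.frame(
    gene_id = m$gene_id,
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    compartment = m$compartment,
    housekeeping = m$housekeeping_role %in% c("chloro_norm",
                                              "nuclear_norm"),
    stringsAsFactors = FALSE
  )
  if (!is.null(truth$truncated)) {
    i <- match(truth$truncated$gene_id, units$gene_id)
    units$end[i] <- pmax(units$end[i], truth$truncated$true_cds_end)
  }
  if (!is.null(truth$novel_orfs)) {
    units <- rbind(units, data.frame(
      gene_id = truth$novel_orfs$orf_id, contig = truth$novel_orfs$contig,
      start = truth$novel_orfs$start, end = truth$novel_orfs$end,
      strand = truth$novel_orfs$strand, compartment = "chloroplast",
      housekeeping = FALSE, stringsAsFactors = FALSE
    ))
  }
  units <- units[units$gene_id %in% names(base), ]

  # Transcript-coordinate to reference-position maps for nuclear genes
  # (biological 5' -> 3' order; position 1 is the transcript 5' end).
  txmap <- list()
  for (i in seq_along(g)) {
    if (m$compartment[i] != "nuclear") next
    ex <- m$exons[[i]]
    refpos <- unlist(lapply(seq_along(ex), function(k) {
      seq(IRanges::start(ex)[k], IRanges::end(ex)[k])
    }))
    if (as.character(GenomicRanges::strand(g)[i]) == "-") {
      refpos <- rev(refpos)
    }
    exidx <- findInterval(refpos, IRanges::start(ex))
    txmap[[m$gene_id[i]]] <- list(
      refpos = refpos,
      exon_start = IRanges::start(ex)[exidx],
      exon_end = IRanges::end(ex)[exidx]
    )
  }

  frac <- c(chloroplast = config@chloroplast_read_fraction,
            nuclear = 1 - config@chloroplast_read_fraction)
  out <- vector("list", nrow(design) * nrow(units))
  k <- 0L
  for (s in seq_len(nrow(design))) {
    smp <- design$sample_id[s]
    grp <- design$group[s]
    expr <- base[units$gene_id] * mult[units$gene_id, grp]
    for (comp in c("chloroplast", "nuclear")) {
      sel <- which(units$compartment == comp)
      if (!length(sel) || frac[[comp]] == 0) next
      share <- expr[sel] / sum(expr[sel])
      mu <- share * frac[[comp]] * config@total_reads_per_sample
      # housekeeping genes are stable by selection: they draw with their
      # own, lower overdispersion
      disp <- ifelse(units$housekeeping[sel], config@hk_dispersion,
                     config@dispersion)
      n <- integer(length(mu))
      pois <- disp == 0
      n[pois] <- stats::rpois(sum(pois), mu[pois])
      n[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                 size = 1 / disp[!pois])
      for (jj in seq_along(sel)) {
        if (n[jj] == 0L) next
        u <- units[sel[jj], ]
        if (comp == "chloroplast" || is.null(txmap[[u$gene_id]])) {
          # read starts uniform over the transcribed span; tails may run
          # past the annotated end (transcripts extend beyond the stop)
          st <- sample.int(u$end - u$start + 1L, n[jj],
                           replace = TRUE) + u$start - 1L
          en <- pmin(st + rl - 1L, clens[[u$contig]])
        } else {
          tm <- txmap[[u$gene_id]]
          L <- length(tm$refpos)
          biased <- stats::runif(n[jj]) < config@three_prime_bias
          t0 <- max(1L, L - 8L * rl + 1L)
          tpos <- integer(n[jj])
          tpos[biased] <- sample(t0:L, sum(biased), replace = TRUE)
          tpos[!biased] <- sample.int(L, sum(!biased), replace = TRUE)
          p <- tm$refpos[tpos]
          es <- tm$exon_start[tpos]
          ee <- tm$exon_end[tpos]
          st <- pmax(es, pmin(p, ee - rl + 1L))
          en <- pmin(st + rl - 1L, ee)
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          reference = u$contig, start = st, end = en,
          strand = sample(c("+", "-"), n[jj], replace = TRUE),
          sample_id = smp, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(
      read_id = character(), reference = character(), start = integer(),
      end = integer(), strand = character(), sample_id = character(),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out[seq_len(k)])
  res$read_id <- sprintf("read_%07d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("read_id", "reference", "start", "end", "strand", "sample_id")]
}
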