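#' Sample design of the light-shift experiments
#'
#' Two experiments are run in parallel, each with its own control culture:
#' a shift to high light (HL) and a shift to high light plus UV radiation
#' (HL+UV). Biological triplicates are taken from the control at T0, T1 and
#' T2.5 h after the shift, and from the treatment at T1 and T2.5.
#'
#' @param replicates Biological replicates per group (default 3).
#' @return data.frame with columns sample_id, experiment, condition, time,
#'   replicate, group (experiment_condition_time label).
#' @examples
#' head(experimentDesign())
#' @export
experimentDesign <- function(replicates = 3L) {
  grid <- rbind(
    expand.grid(
      experiment = "HL_experiment", condition = "control",
      time = c(0, 1, 2.5), stringsAsFactors = FALSE
    ),
    expand.grid(
      experiment = "HL_experiment", condition = "HL",
      time = c(1, 2.5), stringsAsFactors = FALSE
    ),
    expand.grid(
      experiment = "HLUV_experiment", condition = "control",
      time = c(0, 1, 2.5), stringsAsFactors = FALSE
    ),
    expand.grid(
      experiment = "HLUV_experiment", condition = "HLUV",
      time = c(1, 2.5), stringsAsFactors = FALSE
    )
  )
  out <- grid[rep(seq_len(nrow(grid)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), times = nrow(grid))
  out$group <- paste(out$experiment, out$condition, out$time, sep = "_")
  out$sample_id <- paste0(out$group, "_rep", out$replicate)
  rownames(out) <- NULL
  out[, c("sample_id", "experiment", "condition", "time", "replicate",
          "group")]
}

#' Default growth rates by irradiance
#'
#' Specific growth rates (d^-1) of light-acclimated cultures across the
#' irradiance gradient (umol photons m^-2 s^-1). The curve is unimodal with
#' slow growth at 6, a maximum of 1.78 d^-1 at 240 and photoinhibited
#' growth (0.96 d^-1) at 750.
#'
#' @return Named numeric vector (names are irradiance levels).
#' @export
defaultGrowthRates <- function() {
  c(`6` = 0.28, `55` = 1.04, `150` = 1.55, `240` = 1.78,
    `350` = 1.70, `470` = 1.50, `620` = 1.22, `750` = 0.96)
}

#' Default qPCR effect sizes
#'
#' True expression folds (relative to the T0 calibrator, after
#' endogenous-control correction) emulated for three chloroplast-targeted
#' nuclear genes: a strongly UV-induced NPQ gene (LHCSR2-like, 33-fold at
#' T1 and 42-fold at T2.5 under HL+UV), a prasinophyte light-harvesting
#' gene repressed by the shifts (LHCP1-like) and a one-helix protein gene
#' massively induced by UV (OHP2-like).
#'
#' @return data.frame with columns target, condition, time, fold (ratio
#'   scale: 1/1.7 means a -1.7 signed fold).
#' @export
defaultQPCRFolds <- function() {
  rbind(
    data.frame(
      target = "LHCSR2",
      condition = rep(c("control", "HL", "HLUV"), each = 2),
      time = rep(c(1, 2.5), 3),
      fold = c(1.1, 1.2, 2.0, 1.3, 33, 42)
    ),
    data.frame(
      target = "LHCP1",
      condition = rep(c("control", "HL", "HLUV"), each = 2),
      time = rep(c(1, 2.5), 3),
      fold = c(1 / 1.7, 1 / 1.6, 1 / 2.7, 1 / 3.2, 1 / 3.9, 1 / 3.7)
    ),
    data.frame(
      target = "OHP2",
      condition = rep(c("control", "HL", "HLUV"), each = 2),
      time = rep(c(1, 2.5), 3),
      fold = c(1 / 1.5, 1 / 1.5, 1 / 2, 1 / 2, 15, 20)
    )
  )
}

# Build one protein-coding CDS sequence: ATG + (codons-2) sense codons + TAA.
makeCDS <- function(n_codons, exclude_atg = FALSE) {
  paste0("ATG", paste(randomCodons(n_codons - 2L, exclude_atg = exclude_atg),
                      collapse = ""), "TAA")
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Builds a two-contig genome (a small high-copy "chloroplast" and a
#' "nuclear" contig) with gene models and a complete ground-truth record.
#' The annotation plants the features the downstream stages are designed to
#' handle:
#' \itemize{
#'   \item chloroplast protein genes plus a 23S rRNA housekeeping gene
#'     (normalization denominator for the chloroplast compartment);
#'   \item a chloroplast gene whose annotated CDS stops 90 nt short of the
#'     true in-frame stop codon (CDS-extension target);
#'   \item an expressed but unannotated 603-codon ORF (novel-ORF target);
#'   \item nuclear genes with exon structure and 3' UTRs, including GAPDH
#'     (nuclear normalization) and Actin (qPCR endogenous control);
#'   \item a convergent overlapping 3'-UTR pair on opposite strands
#'     (excluded from counting), a pair of genes with byte-identical
#'     counting windows (merged in counting), and a gene whose terminal
#'     exon is shorter than 403 nt.
#' }
#' True CDSs are multiples of 3 ending at a stop codon; per-gene expression
#' multipliers encode diel drift in controls, modest high-light effects and
#' drastic HL+UV effects, with all housekeeping genes held at fold 1.
#'
#' @param config A [SimConfig-class] from [simConfig()].
#' @return List with elements `genome` (named `DNAStringSet`), `models`
#'   (a [GeneModelSet-class]) and `truth` (ground-truth list: `groups`,
#'   `multiplier` gene x group matrix, `base_expression`, `novel_orfs`,
#'   `truncated`, `special` planted-feature ids, `mu_by_irradiance`,
#'   `qpcr_true_fold`).
#' @examples
#' gen <- generateGenomeAnnotation(simConfig(seed = 1))
#' gen$models
#' @export
generateGenomeAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(deriveSeed(config@seed, "genome"))

  ## ---- chloroplast compartment -------------------------------------------
  n_cp <- config@n_chloro_genes
  cp <- list()  # per-element: id, type, role, strand, seq, annotate, extra
  for (i in seq_len(n_cp)) {
    cp[[length(cp) + 1L]] <- list(
      id = sprintf("cp_g%02d", i), type = "protein", role = "none",
      strand = if (stats::runif(1) < 0.75) "+" else "-",
      seq = makeCDS(sample(80:200, 1L)), annotate = TRUE, kind = "plain"
    )
  }
  cp[[length(cp) + 1L]] <- list(
    id = "rrl_23S", type = "rRNA", role = "chloro_norm", strand = "+",
    seq = randomDNA(1500L), annotate = TRUE, kind = "rRNA"
  )
  # Truncated-CDS gene: true CDS of 150 codons; the annotation stops 90 nt
  # (30 codons, including the stop) short of the true stop.
  cp[[length(cp) + 1L]] <- list(
    id = "cp_trunc", type = "protein", role = "none", strand = "+",
    seq = makeCDS(150L), annotate = TRUE, kind = "truncated",
    truncate_nt = 90L
  )
  # Planted unannotated ORF: 603 codons + stop = 1812 nt, expressed but
  # absent from the annotation. Internal ATGs are excluded so the ORF call
  # is unique at the planted coordinates.
  cp[[length(cp) + 1L]] <- list(
    id = "orf603", type = "protein", role = "none", strand = "+",
    seq = makeCDS(604L, exclude_atg = TRUE), annotate = FALSE, kind = "novel"
  )
  cp <- cp[sample(length(cp))]

  widths <- vapply(cp, function(e) nchar(e$seq), integer(1))
  gaps <- sample(60:150, length(cp), replace = TRUE)
  if (sum(widths) + sum(gaps) + 200L > config@chloroplast_length) {
    stop("infeasible packing: chloroplast genes exceed contig length ",
         config@chloroplast_length)
  }
  pos <- 100L + cumsum(gaps) + c(0L, cumsum(widths))[seq_along(cp)]
  cp_genome <- randomDNA(config@chloroplast_length)
  cp_rows <- list()
  truncated <- NULL
  novel_orfs <- NULL
  for (i in seq_along(cp)) {
    e <- cp[[i]]
    s <- pos[i]
    eend <- s + nchar(e$seq) - 1L
    ins <- if (e$strand == "+") e$seq else revComp(e$seq)
    cp_genome <- spliceIn(cp_genome, s, ins)
    if (e$kind == "novel") {
      novel_orfs <- data.frame(
        orf_id = e$id, contig = "chloroplast", start = s, end = eend,
        strand = e$strand, n_codons = as.integer(nchar(e$seq) / 3L) - 1L
      )
      next
    }
    if (e$kind == "truncated") {
      ann_end <- eend - e$truncate_nt
      truncated <- data.frame(
        gene_id = e$id, annotated_cds_end = ann_end, true_cds_end = eend,
        extension_nt = e$truncate_nt
      )
      cds <- c(s, ann_end)
      span <- c(s, ann_end)
    } else if (e$kind == "rRNA") {
      cds <- c(NA_integer_, NA_integer_)
      span <- c(s, eend)
    } else {
      cds <- c(s, eend)
      span <- c(s, eend)
    }
    cp_rows[[length(cp_rows) + 1L]] <- data.frame(
      gene_id = e$id, contig = "chloroplast", start = span[1], end = span[2],
      strand = e$strand, compartment = "chloroplast", gene_type = e$type,
      housekeeping_role = e$role, cds_start = cds[1], cds_end = cds[2]
    )
  }
  cp_df <- do.call(rbind, cp_rows)
  cp_exons <- lapply(seq_len(nrow(cp_df)), function(i) {
    IRanges::IRanges(cp_df$start[i], cp_df$end[i])
  })

  ## ---- nuclear compartment -----------------------------------------------
  nuc_df <- NULL
  nuc_exons <- list()
  nuc_genome <- randomDNA(config@nuclear_length)
  special <- list()
  if (config@n_nuclear_genes > 0L) {
    nuc <- list()
    addNucGene <- function(id, role = "none", n_exons = NULL,
                           terminal_width = NULL, kind = "plain") {
      if (is.null(n_exons)) n_exons <- sample(1:3, 1L)
      ws <- sample(500:900, n_exons, replace = TRUE)
      if (!is.null(terminal_width)) ws[n_exons] <- terminal_width
      list(id = id, role = role, n_exons = n_exons, widths = ws,
           introns = if (n_exons > 1L) {
             sample(60:150, n_exons - 1L, replace = TRUE)
           } else integer(0),
           strand = if (stats::runif(1) < 0.7) "+" else "-", kind = kind)
    }
    for (i in seq_len(config@n_nuclear_genes)) {
      nuc[[length(nuc) + 1L]] <- addNucGene(sprintf("nuc_g%02d", i))
    }
    nuc[[length(nuc) + 1L]] <- addNucGene("GAPDH", role = "nuclear_norm")
    nuc[[length(nuc) + 1L]] <- addNucGene("Actin", role = "qpcr_endogenous")
    g1 <- addNucGene("LHCP2.1", n_exons = 1L, terminal_width = 1000L,
                     kind = "identical1")
    g1$strand <- "+"
    g2 <- addNucGene("LHCP2.2", n_exons = 1L, terminal_width = 1000L,
                     kind = "identical2")
    g2$strand <- "+"
    nuc[[length(nuc) + 1L]] <- g1
    nuc[[length(nuc) + 1L]] <- g2
    short <- addNucGene("nuc_short", n_exons = 2L, terminal_width = 300L)
    short$strand <- "+"
    nuc[[length(nuc) + 1L]] <- short

    rows <- list()
    exlist <- list()
    cursor <- 200L
    placeGene <- function(g, offset) {
      n <- g$n_exons
      starts <- integer(n)
      ends <- integer(n)
      p <- offset
      for (k in seq_len(n)) {
        starts[k] <- p
        ends[k] <- p + g$widths[k] - 1L
        p <- ends[k] + (if (k < n) g$introns[k] else 0L) + 1L
      }
      list(starts = starts, ends = ends, next_pos = ends[n] + 1L)
    }
    for (g in nuc) {
      pl <- placeGene(g, cursor)
      cursor <- pl$next_pos + sample(150:300, 1L)
      # CDS: contiguous interval at the biological 5' end of the gene,
      # leaving the terminal-exon 3' UTR free of coding sequence.
      n_codons <- sample(80:150, 1L)
      cds_len <- 3L * n_codons
      if (g$strand == "+") {
        cds_start <- pl$starts[1]
        cds_end <- cds_start + cds_len - 1L
        if (cds_end > pl$ends[1]) {  # clip to first exon
          cds_len <- (pl$ends[1] - cds_start + 1L) %/% 3L * 3L
          cds_end <- cds_start + cds_len - 1L
        }
        nuc_genome <- spliceIn(nuc_genome, cds_start, makeCDS(cds_len / 3L))
      } else {
        cds_end <- pl$ends[g$n_exons]
        cds_start <- cds_end - cds_len + 1L
        if (cds_start < pl$starts[g$n_exons]) {
          cds_len <- (cds_end - pl$starts[g$n_exons] + 1L) %/% 3L * 3L
          cds_start <- cds_end - cds_len + 1L
        }
        nuc_genome <- spliceIn(nuc_genome, cds_start,
                               revComp(makeCDS(cds_len / 3L)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$id, contig = "nuclear", start = pl$starts[1],
        end = pl$ends[g$n_exons], strand = g$strand, compartment = "nuclear",
        gene_type = "protein", housekeeping_role = g$role,
        cds_start = cds_start, cds_end = cds_end
      )
      exlist[[length(exlist) + 1L]] <- IRanges::IRanges(pl$starts, pl$ends)
    }

    # Convergent overlapping pair: a (+)-strand gene whose 3' UTR overlaps
    # the 3' UTR of a (-)-strand gene by 50 bp.
    a_start <- cursor
    a_end <- a_start + 899L
    b_start <- a_end - 49L
    b_end <- b_start + 899L
    cursor <- b_end + 200L
    if (cursor > config@nuclear_length) {
      stop("infeasible packing: nuclear genes exceed contig length ",
           config@nuclear_length)
    }
    nuc_genome <- spliceIn(nuc_genome, a_start, makeCDS(100L))
    nuc_genome <- spliceIn(nuc_genome, b_end - 299L, revComp(makeCDS(100L)))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = "nuc_convA", contig = "nuclear", start = a_start,
      end = a_end, strand = "+", compartment = "nuclear",
      gene_type = "protein", housekeeping_role = "none",
      cds_start = a_start, cds_end = a_start + 299L
    )
    exlist[[length(exlist) + 1L]] <- IRanges::IRanges(a_start, a_end)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = "nuc_convB", contig = "nuclear", start = b_start,
      end = b_end, strand = "-", compartment = "nuclear",
      gene_type = "protein", housekeeping_role = "none",
      cds_start = b_end - 299L, cds_end = b_end
    )
    exlist[[length(exlist) + 1L]] <- IRanges::IRanges(b_start, b_end)

    nuc_df <- do.call(rbind, rows)
    nuc_exons <- exlist
    if (max(nuc_df$end) > config@nuclear_length) {
      stop("infeasible packing: nuclear genes exceed contig length ",
           config@nuclear_length)
    }

    # Make the LHCP2.1 / LHCP2.2 counting windows byte-identical: copy the
    # last 403 nt of the first gene's terminal exon onto the second.
    i1 <- which(nuc_df$gene_id == "LHCP2.1")
    i2 <- which(nuc_df$gene_id == "LHCP2.2")
    w1 <- substr(nuc_genome, nuc_df$end[i1] - 402L, nuc_df$end[i1])
    nuc_genome <- spliceIn(nuc_genome, nuc_df$end[i2] - 402L, w1)
    special <- list(
      identical_pair = c("LHCP2.1", "LHCP2.2"),
      convergent_pair = c("nuc_convA", "nuc_convB"),
      short_terminal_exon = "nuc_short"
    )
  }

  ## ---- assemble GeneModelSet ---------------------------------------------
  ann_df <- rbind(cp_df, nuc_df)
  exons <- c(cp_exons, nuc_exons)
  gr <- GenomicRanges::GRanges(
    seqnames = ann_df$contig,
    ranges = IRanges::IRanges(ann_df$start, ann_df$end),
    strand = ann_df$strand,
    seqlengths = c(chloroplast = config@chloroplast_length,
                   nuclear = config@nuclear_length)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = ann_df$gene_id, compartment = ann_df$compartment,
    gene_type = ann_df$gene_type,
    housekeeping_role = ann_df$housekeeping_role,
    cds_start = ann_df$cds_start, cds_end = ann_df$cds_end,
    exons = IRanges::IRangesList(exons)
  )
  names(gr) <- ann_df$gene_id
  models <- GeneModelSet(gr)

  genome <- Biostrings::DNAStringSet(c(
    chloroplast = cp_genome, nuclear = nuc_genome
  ))

  ## ---- ground truth -------------------------------------------------------
  design_groups <- unique(experimentDesign()[, c(
    "experiment", "condition", "time", "group"
  )])
  all_ids <- c(ann_df$gene_id, if (!is.null(novel_orfs)) novel_orfs$orf_id)
  hk_ids <- c("rrl_23S", "GAPDH", "Actin")
  n_genes <- length(all_ids)

  # Per-gene drift over the full control time course and treatment effects.
  drift <- stats::setNames(rep(1, n_genes), all_ids)
  pick <- stats::runif(n_genes) < 0.3 & !(all_ids %in% hk_ids)
  drift[pick] <- exp(stats::runif(sum(pick),
                                  -log(config@diel_amplitude),
                                  log(config@diel_amplitude)))
  hl_eff <- stats::setNames(rep(1, n_genes), all_ids)
  u <- stats::runif(n_genes)
  hl_eff[u < 0.15 & !(all_ids %in% hk_ids)] <-
    sample(c(1.5, 2, 4), sum(u < 0.15 & !(all_ids %in% hk_ids)),
           replace = TRUE)
  hl_eff[u >= 0.15 & u < 0.20 & !(all_ids %in% hk_ids)] <-
    sample(c(1 / 1.5, 1 / 2),
           sum(u >= 0.15 & u < 0.20 & !(all_ids %in% hk_ids)),
           replace = TRUE)
  uv_eff <- stats::setNames(rep(1, n_genes), all_ids)
  v <- stats::runif(n_genes)
  uv_eff[v < 0.30 & !(all_ids %in% hk_ids)] <-
    sample(c(1 / 10, 1 / 30, 1 / 50),
           sum(v < 0.30 & !(all_ids %in% hk_ids)), replace = TRUE)
  uv_eff[v >= 0.30 & v < 0.40 & !(all_ids %in% hk_ids)] <-
    sample(c(10, 32, 50),
           sum(v >= 0.30 & v < 0.40 & !(all_ids %in% hk_ids)),
           replace = TRUE)

  multiplier <- matrix(1, n_genes, nrow(design_groups),
                       dimnames = list(all_ids, design_groups$group))
  for (j in seq_len(nrow(design_groups))) {
    gfrac <- design_groups$time[j] / 2.5
    m <- drift^gfrac
    if (design_groups$condition[j] == "HL") m <- m * hl_eff
    if (design_groups$condition[j] == "HLUV") m <- m * uv_eff
    multiplier[, j] <- m
  }

  base <- stats::setNames(numeric(n_genes), all_ids)
  cp_prot <- setdiff(all_ids[all_ids %in%
                               c(cp_df$gene_id, "orf603")], "rrl_23S")
  base[cp_prot] <- stats::rlnorm(length(cp_prot), 0, 0.7)
  base["orf603"] <- max(base[cp_prot]) # well-expressed novel ORF
  base["rrl_23S"] <- sum(base[cp_prot]) # rRNA dominates its compartment
  nuc_ids <- setdiff(all_ids, c(cp_prot, "rrl_23S"))
  if (length(nuc_ids)) {
    base[nuc_ids] <- stats::rlnorm(length(nuc_ids), 0, 0.7)
    base["GAPDH"] <- 0.25 * sum(base[setdiff(nuc_ids, c("GAPDH", "Actin"))])
    base["Actin"] <- 0.12 * sum(base[setdiff(nuc_ids, c("GAPDH", "Actin"))])
  }

  truth <- list(
    groups = design_groups,
    multiplier = multiplier,
    base_expression = base,
    novel_orfs = novel_orfs,
    truncated = truncated,
    special = special,
    housekeeping = hk_ids,
    mu_by_irradiance = defaultGrowthRates(),
    qpcr_true_fold = defaultQPCRFolds()
  )
  list(genome = genome, models = models, truth = truth)
}

#' True signed fold between two design groups
#'
#' @param truth Ground-truth list from [generateGenomeAnnotation()].
#' @param gene Gene identifier.
#' @param groupA,groupB Group labels (columns of `truth$multiplier`).
#' @return The true signed fold of `groupA` relative to `groupB`.
#' @export
trueFold <- function(truth, gene, groupA, groupB) {
  signedFold(truth$multiplier[gene, groupA] / truth$multiplier[gene, groupB])
}
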