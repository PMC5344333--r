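#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData
NULL

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic diel light-shift experiment generator. The
#' defaults encode the statistical structure the generator emulates: a small
#' high-copy chloroplast compartment receiving about half of all reads, a
#' strong 3' bias for nuclear reads (most read starts within 8 read lengths
#' of the transcript end), negative-binomially overdispersed replicate
#' counts, stable housekeeping genes, a modest diel drift in controls, and
#' drastic transcriptional effects under the high-light + UV treatment.
#'
#' @slot seed integer; global seed, from which all stage substreams derive.
#' @slot chloroplast_length integer; chloroplast contig length in bp
#'   (a desk-scale stand-in for a 73 kb organelle genome).
#' @slot nuclear_length integer; nuclear contig length in bp.
#' @slot n_chloro_genes,n_nuclear_genes integer; protein-coding genes per
#'   compartment (housekeeping and planted special genes are added on top).
#' @slot chloroplast_read_fraction numeric in [0,1]; expected share of reads
#'   mapping to the chloroplast contig.
#' @slot three_prime_bias numeric in [0,1]; probability that a nuclear read
#'   starts within 8 read lengths of the transcript 3' end.
#' @slot read_length integer bp.
#' @slot total_reads_per_sample integer.
#' @slot dispersion numeric >= 0; negative-binomial overdispersion of
#'   per-gene counts across replicates (size = 1/dispersion).
#' @slot hk_dispersion numeric >= 0; overdispersion of the housekeeping
#'   genes (23S, GAPDH, Actin), lower than `dispersion` by design: these
#'   genes are chosen precisely because they vary little across
#'   treatments, and the generator emulates that stability.
#' @slot diel_amplitude numeric >= 1; maximal control drift fold over the
#'   full T0 -> T2.5 course.
#' @slot fcm_sdlog numeric > 0; log-scale spread of cytometry events.
#' @slot fcm_bead_mean numeric; bead channel mean in arbitrary units.
#' @slot fcm_events_cell,fcm_events_bead integer; events per population.
#' @slot qpcr_sd_ct numeric >= 0; Gaussian noise on Ct values.
#' @slot growth_noise numeric >= 0; relative noise on bulk fluorescence.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  chloroplast_length = "integer",
  nuclear_length = "integer",
  n_chloro_genes = "integer",
  n_nuclear_genes = "integer",
  chloroplast_read_fraction = "numeric",
  three_prime_bias = "numeric",
  read_length = "integer",
  total_reads_per_sample = "integer",
  dispersion = "numeric",
  hk_dispersion = "numeric",
  diel_amplitude = "numeric",
  fcm_sdlog = "numeric",
  fcm_bead_mean = "numeric",
  fcm_events_cell = "integer",
  fcm_events_bead = "integer",
  qpcr_sd_ct = "numeric",
  growth_noise = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  prop <- c(
    chloroplast_read_fraction = object@chloroplast_read_fraction,
    three_prime_bias = object@three_prime_bias
  )
  bad <- prop < 0 | prop > 1
  if (any(bad)) {
    msg <- c(msg, paste0(names(prop)[bad], " must be in [0, 1]"))
  }
  pos <- c(
    chloroplast_length = object@chloroplast_length,
    nuclear_length = object@nuclear_length,
    read_length = object@read_length,
    fcm_bead_mean = object@fcm_bead_mean,
    fcm_sdlog = object@fcm_sdlog
  )
  if (any(pos <= 0)) {
    msg <- c(msg, paste0(names(pos)[pos <= 0], " must be > 0"))
  }
  nonneg <- c(
    n_chloro_genes = object@n_chloro_genes,
    n_nuclear_genes = object@n_nuclear_genes,
    total_reads_per_sample = object@total_reads_per_sample,
    dispersion = object@dispersion,
    hk_dispersion = object@hk_dispersion,
    qpcr_sd_ct = object@qpcr_sd_ct,
    growth_noise = object@growth_noise
  )
  if (any(nonneg < 0)) {
    msg <- c(msg, paste0(names(nonneg)[nonneg < 0], " must be >= 0"))
  }
  if (object@diel_amplitude < 1) msg <- c(msg, "diel_amplitude must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param seed Global seed (integer).
#' @param chloroplast_length,nuclear_length Contig lengths (bp).
#' @param n_chloro_genes,n_nuclear_genes Protein-coding genes per compartment.
#' @param chloroplast_read_fraction Expected chloroplast read share.
#' @param three_prime_bias Probability of a nuclear read starting within
#'   8 read lengths of the transcript 3' end.
#' @param read_length Read length (bp).
#' @param total_reads_per_sample Sequencing depth per sample.
#' @param dispersion NB overdispersion of replicate counts.
#' @param hk_dispersion NB overdispersion of housekeeping-gene counts
#'   (low: housekeeping genes are stable by selection).
#' @param diel_amplitude Maximal control drift fold over the time course.
#' @param fcm_sdlog,fcm_bead_mean,fcm_events_cell,fcm_events_bead Cytometry
#'   event-noise parameters.
#' @param qpcr_sd_ct Gaussian Ct noise (cycles).
#' @param growth_noise Relative fluorescence noise.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      chloroplast_length = 20000L,
                      nuclear_length = 80000L,
                      n_chloro_genes = 25L,
                      n_nuclear_genes = 25L,
                      chloroplast_read_fraction = 0.5,
                      three_prime_bias = 0.9,
                      read_length = 50L,
                      total_reads_per_sample = 20000L,
                      dispersion = 0.05,
                      hk_dispersion = 0.005,
                      diel_amplitude = 1.5,
                      fcm_sdlog = 0.15,
                      fcm_bead_mean = 4000,
                      fcm_events_cell = 2000L,
                      fcm_events_bead = 500L,
                      qpcr_sd_ct = 0.15,
                      growth_noise = 0.02) {
  new("SimConfig",
    seed = as.integer(seed),
    chloroplast_length = as.integer(chloroplast_length),
    nuclear_length = as.integer(nuclear_length),
    n_chloro_genes = as.integer(n_chloro_genes),
    n_nuclear_genes = as.integer(n_nuclear_genes),
    chloroplast_read_fraction = chloroplast_read_fraction,
    three_prime_bias = three_prime_bias,
    read_length = as.integer(read_length),
    total_reads_per_sample = as.integer(total_reads_per_sample),
    dispersion = dispersion,
    hk_dispersion = hk_dispersion,
    diel_amplitude = diel_amplitude,
    fcm_sdlog = fcm_sdlog,
    fcm_bead_mean = fcm_bead_mean,
    fcm_events_cell = as.integer(fcm_events_cell),
    fcm_events_bead = as.integer(fcm_events_bead),
    qpcr_sd_ct = qpcr_sd_ct,
    growth_noise = growth_noise
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  contigs: chloroplast ", object@chloroplast_length, " bp, nuclear ",
    object@nuclear_length, " bp\n", sep = "")
  cat("  genes: ", object@n_chloro_genes, " chloroplast / ",
    object@n_nuclear_genes, " nuclear protein-coding (+ housekeeping)\n",
    sep = "")
  cat("  reads: ", object@total_reads_per_sample, " per sample, length ",
    object@read_length, ", chloroplast share ",
    object@chloroplast_read_fraction, ", 3' bias ",
    object@three_prime_bias, "\n", sep = "")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# GeneModelSet
# ---------------------------------------------------------------------------

#' Gene model collection
#'
#' Holds the gene models of both genome compartments as a `GRanges` (one
#' row per gene, spanning the exon union) with per-gene metadata columns:
#' \describe{
#'   \item{gene_id}{unique identifier}
#'   \item{compartment}{"chloroplast" or "nuclear"}
#'   \item{gene_type}{"protein", "tRNA" or "rRNA"}
#'   \item{housekeeping_role}{"none", "chloro_norm" (23S rRNA),
#'     "nuclear_norm" (GAPDH) or "qpcr_endogenous" (Actin)}
#'   \item{cds_start, cds_end}{CDS interval (1-based inclusive; NA for
#'     non-protein genes)}
#'   \item{exons}{`IRangesList` of sorted, non-overlapping exon intervals
#'     in reference coordinates}
#' }
#' All coordinates are 1-based inclusive, the GFF3 convention.
#'
#' @slot genes A `GRanges` as described above, with `seqlengths` set.
#' @export
setClass("GeneModelSet", representation(genes = "GRanges"))

setValidity("GeneModelSet", function(object) {
  g <- object@genes
  m <- S4Vectors::mcols(g)
  req <- c("gene_id", "compartment", "gene_type", "housekeeping_role",
           "cds_start", "cds_end", "exons")
  missing_cols <- setdiff(req, colnames(m))
  if (length(missing_cols)) {
    return(paste("missing metadata columns:",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$gene_id)) return("gene_id values must be unique")
  msg <- character()
  for (i in seq_along(g)) {
    ex <- m$exons[[i]]
    if (length(ex) == 0L) {
      msg <- c(msg, paste0(m$gene_id[i], ": gene without exons"))
      next
    }
    if (is.unsorted(IRanges::start(ex)) ||
        any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)])) {
      msg <- c(msg, paste0(m$gene_id[i],
                           ": exons must be sorted and non-overlapping"))
    }
    if (!is.na(m$cds_start[i])) {
      cds <- IRanges::IRanges(m$cds_start[i], m$cds_end[i])
      cov <- IRanges::intersect(cds, ex)
      if (sum(IRanges::width(cov)) != IRanges::width(cds)) {
        msg <- c(msg, paste0(m$gene_id[i], ": CDS not within exon union"))
      }
    }
  }
  for (comp in unique(m$compartment)) {
    role <- if (comp == "chloroplast") "chloro_norm" else "nuclear_norm"
    n_norm <- sum(m$housekeeping_role[m$compartment == comp] == role)
    if (n_norm < 1L) {
      msg <- c(msg, paste0("compartment ", comp,
                           " has no ", role, " housekeeping gene"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#' @param genes A `GRanges` with the metadata columns documented in
#'   [GeneModelSet-class].
#' @return A validated `GeneModelSet`.
#' @export
GeneModelSet <- function(genes) new("GeneModelSet", genes = genes)

setMethod("show", "GeneModelSet", function(object) {
  m <- S4Vectors::mcols(object@genes)
  cat("GeneModelSet with ", length(object@genes), " genes (",
    sum(m$compartment == "chloroplast"), " chloroplast, ",
    sum(m$compartment == "nuclear"), " nuclear)\n", sep = "")
  tt <- table(m$gene_type)
  cat("  types: ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n",
    sep = "")
  hk <- m$gene_id[m$housekeeping_role != "none"]
  cat("  housekeeping: ", paste(hk, collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

# ---------------------------------------------------------------------------
# TagSeqExperiment
# ---------------------------------------------------------------------------

#' 3'-tag RNA-seq count container
#'
#' Extends `SummarizedExperiment`. The `"counts"` assay holds raw window
#' counts (gene x sample, nonnegative integers); after
#' [normalizeToHousekeeping()] a `"normalized"` assay holds abundance ratios
#' relative to the compartment housekeeping count, and
#' `metadata(x)$housekeeping` records the per-sample denominators.
#' `rowData` carries compartment, housekeeping role, counting-window
#' coordinates and per-gene status flags
#' ("counted", "excluded_overlap" or "merged_identical").
#'
#' @export
setClass("TagSeqExperiment", contains = "SummarizedExperiment")

setValidity("TagSeqExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "a 'counts' assay is required")
  } else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt))) {
      msg <- c(msg, "counts must be nonnegative integers")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  req <- c("gene_id", "compartment", "housekeeping_role", "status")
  missing_cols <- setdiff(req, colnames(rd))
  if (length(missing_cols)) {
    msg <- c(msg, paste("rowData lacks:", paste(missing_cols, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# QPCRPlate
# ---------------------------------------------------------------------------

#' qPCR plate
#'
#' A plate of threshold-cycle measurements plus a dilution-series block for
#' efficiency / linear-dynamic-range checks.
#'
#' @slot wells data.frame with columns sample_id, condition, time,
#'   replicate, target, ct. Ct values lie in (0, 40]; an endogenous-control
#'   target must be present for every sample.
#' @slot dilution data.frame with columns target, log10_quantity, ct.
#' @slot endogenous character; name of the endogenous-control target.
#' @export
setClass("QPCRPlate", representation(
  wells = "data.frame",
  dilution = "data.frame",
  endogenous = "character"
))

setValidity("QPCRPlate", function(object) {
  w <- object@wells
  msg <- character()
  req <- c("sample_id", "condition", "time", "replicate", "target", "ct")
  missing_cols <- setdiff(req, colnames(w))
  if (length(missing_cols)) {
    return(paste("wells lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(w$ct <= 0 | w$ct > 40)) msg <- c(msg, "Ct values must be in (0, 40]")
  have_endo <- tapply(w$target, w$sample_id,
                      function(t) object@endogenous %in% t)
  if (!all(unlist(have_endo))) {
    msg <- c(msg, paste0("endogenous control '", object@endogenous,
                         "' missing for some samples"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QPCRPlate
#' @param wells,dilution,endogenous See [QPCRPlate-class].
#' @return A validated `QPCRPlate`.
#' @export
QPCRPlate <- function(wells, dilution = data.frame(), endogenous = "Actin") {
  new("QPCRPlate", wells = wells, dilution = dilution, endogenous = endogenous)
}

setMethod("show", "QPCRPlate", function(object) {
  cat("QPCRPlate: ", nrow(object@wells), " wells, ",
    length(unique(object@wells$target)), " targets (endogenous: ",
    object@endogenous, "), ", nrow(object@dilution),
    " dilution-series wells\n", sep = "")
  invisible(NULL)
})
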