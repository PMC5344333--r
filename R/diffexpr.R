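#' Minimum-read inclusion filter
#'
#' A gene enters differential-expression analysis only if at least
#' `threshold` raw reads map to it in one or more samples (guarding
#' against fold changes estimated from near-zero counts). Genes flagged
#' `excluded_overlap` are never included, regardless of their counts.
#'
#' @param x A [TagSeqExperiment-class].
#' @param threshold Minimal per-sample raw count (default 100; the
#'   boundary is inclusive, a gene whose maximum is exactly 100 passes).
#' @return data.frame with columns gene_id, included (logical), reason
#'   ("", "below_min_reads" or "overlap").
#' @export
filterMinReads <- function(x, threshold = 100) {
  counts <- SummarizedExperiment::assay(x, "counts")
  rd <- SummarizedExperiment::rowData(x)
  max_count <- apply(counts, 1, max)
  included <- max_count >= threshold & rd$status != "excluded_overlap"
  reason <- ifelse(rd$status == "excluded_overlap", "overlap",
                   ifelse(max_count < threshold, "below_min_reads", ""))
  data.frame(gene_id = rd$gene_id, included = included, reason = reason,
             stringsAsFactors = FALSE)
}

#' Compare two sample groups gene by gene
#'
#' The expression ratio of group A to group B is the ratio of arithmetic
#' means of normalized abundances, reported as a signed fold (+r for
#' r >= 1, -1/r otherwise). Significance comes from a one-way
#' fixed-effects ANOVA on log2-transformed abundances (with two groups
#' this is the pooled-variance F test); a small offset — half the smallest
#' nonzero abundance in the matrix — is added inside the log transform
#' only, so folds are computed on un-offset means.
#'
#' @param norm Normalized abundance matrix (genes x samples).
#' @param groupA,groupB Column names or indices of the two groups
#'   (>= 2 replicates each).
#' @param log_offset Offset used inside the log transform; defaults to
#'   half the smallest nonzero value of `norm`.
#' @return data.frame with columns gene_id, fold (signed), p, flag
#'   ("" or "undefined_fold" when the group-B mean is zero).
#' @export
compareGroups <- function(norm, groupA, groupB, log_offset = NULL) {
  a <- norm[, groupA, drop = FALSE]
  b <- norm[, groupB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  if (is.null(log_offset)) {
    nz <- norm[norm > 0]
    log_offset <- if (length(nz)) min(nz) / 2 else 1e-8
  }
  meanA <- rowMeans(a)
  meanB <- rowMeans(b)
  ratio <- meanA / meanB
  fold <- signedFold(ratio)
  flag <- ifelse(meanB == 0, "undefined_fold", "")
  fold[meanB == 0] <- NA_real_

  grp <- factor(rep(c("A", "B"), c(ncol(a), ncol(b))))
  logm <- log2(cbind(a, b) + log_offset)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    y <- logm[i, ]
    if (all(y == y[1])) return(1)  # no variation at all
    within_var <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
    if (within_var == 0) {
      # zero variance within both groups: identical means would have been
      # caught above, so the group means differ exactly
      return(0)
    }
    stats::anova(stats::lm(y ~ grp))[["Pr(>F)"]][1]
  }, numeric(1))
  data.frame(gene_id = rownames(norm), fold = fold, p = p, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin a signed fold into a fold-change category
#'
#' Magnitudes are binned into \{<1.5, 1.5 to <2, 2 to <4, 4 to <10,
#' 10 to <30, 30 to <50, >=50\}; the sign is preserved in the label for
#' magnitudes of at least 1.5 (e.g. -45 becomes "-(30 to <50)").
#'
#' @param fold Signed fold vector (|fold| >= 1 by convention).
#' @param edges Bin edges (config-exposed).
#' @return Character vector of category labels (NA for NA folds).
#' @examples
#' categorizeFold(c(12, -45, 1))
#' @export
categorizeFold <- function(fold, edges = c(1.5, 2, 4, 10, 30, 50)) {
  labs <- c(
    paste0("<", edges[1]),
    paste0(utils::head(edges, -1), " to <", edges[-1]),
    paste0(">=", edges[length(edges)])
  )
  mag <- abs(fold)
  idx <- findInterval(mag, edges) + 1L
  out <- labs[idx]
  neg <- !is.na(fold) & fold < 0 & idx > 1L
  out[neg] <- paste0("-(", out[neg], ")")
  out[is.na(fold)] <- NA_character_
  out
}

#' Run the dual-baseline differential-expression framework
#'
#' For each experiment, treatments are compared both to the experiment's
#' T0 control and to the time-matched control; control time points are
#' compared both to T0 and to the immediately preceding time point; and
#' the two experiments' T0 controls are compared to each other (a
#' cross-experiment consistency check). No multiple-testing correction is
#' applied by default: a gene is significant in a contrast when it passed
#' the inclusion filter, |signed fold| >= `min_fold` and raw p < `alpha`.
#'
#' @param x A normalized [TagSeqExperiment-class] (see
#'   [normalizeToHousekeeping()]) whose `colData` carries the design
#'   (columns experiment, condition, time, group).
#' @param alpha Significance level on the raw ANOVA p-value.
#' @param min_fold Minimal fold-change magnitude.
#' @param min_reads Inclusion filter threshold (raw counts).
#' @param p_adjust Multiple-testing correction method (a `p.adjust`
#'   method name, applied per contrast); "none" by default, matching the
#'   raw-p framework.
#' @return data.frame of DE records: gene_id, contrast, experiment, fold,
#'   p, significant, category, status, included. Contrasts whose groups
#'   are missing from the design are skipped with a warning.
#' @examples
#' cfg <- simConfig(seed = 1, total_reads_per_sample = 5000)
#' gen <- generateGenomeAnnotation(cfg)
#' aln <- simulateAlignments(gen$models, gen$truth, cfg)
#' tse <- quantifyExperiment(gen$models, aln, gen$genome,
#'   design = experimentDesign())
#' tse <- normalizeToHousekeeping(tse)
#' de <- runDEFramework(tse)
#' head(de)
#' @export
runDEFramework <- function(x, alpha = 0.01, min_fold = 1.5,
                           min_reads = 100, p_adjust = "none") {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  stopifnot(all(c("experiment", "condition", "time", "group") %in%
                  colnames(cd)))
  norm <- normalizedCounts(x)
  rd <- SummarizedExperiment::rowData(x)
  incl <- filterMinReads(x, min_reads)
  nz <- norm[norm > 0]
  log_offset <- if (length(nz)) min(nz) / 2 else 1e-8

  samplesOf <- function(exp, cond, time) {
    cd$sample_id[cd$experiment == exp & cd$condition == cond &
                   cd$time == time]
  }
  contrasts <- list()
  addContrast <- function(label, exp, A, B) {
    contrasts[[length(contrasts) + 1L]] <<- list(
      label = label, experiment = exp, A = A, B = B
    )
  }
  for (exp in unique(cd$experiment)) {
    treat <- setdiff(unique(cd$condition[cd$experiment == exp]), "control")
    for (tr in treat) {
      for (tt in sort(unique(cd$time[cd$experiment == exp &
                                       cd$condition == tr]))) {
        addContrast(sprintf("%s_T%s_vs_T0", tr, tt), exp,
                    samplesOf(exp, tr, tt), samplesOf(exp, "control", 0))
        addContrast(sprintf("%s_T%s_vs_control_T%s", tr, tt, tt), exp,
                    samplesOf(exp, tr, tt), samplesOf(exp, "control", tt))
      }
    }
    ctimes <- sort(unique(cd$time[cd$experiment == exp &
                                    cd$condition == "control"]))
    ctimes <- setdiff(ctimes, 0)
    for (j in seq_along(ctimes)) {
      prev <- if (j == 1L) 0 else ctimes[j - 1L]
      addContrast(sprintf("control_T%s_vs_T0", ctimes[j]), exp,
                  samplesOf(exp, "control", ctimes[j]),
                  samplesOf(exp, "control", 0))
      if (prev != 0) {
        addContrast(sprintf("control_T%s_vs_T%s", ctimes[j], prev), exp,
                    samplesOf(exp, "control", ctimes[j]),
                    samplesOf(exp, "control", prev))
      }
    }
  }
  exps <- unique(cd$experiment)
  if (length(exps) == 2L) {
    addContrast("control_T0_cross_experiment", "both",
                samplesOf(exps[1], "control", 0),
                samplesOf(exps[2], "control", 0))
  }

  out <- list()
  for (ct in contrasts) {
    if (length(ct$A) < 2L || length(ct$B) < 2L) {
      warning("skipping contrast ", ct$label,
              ": missing or under-replicated group")
      next
    }
    res <- compareGroups(norm, ct$A, ct$B, log_offset = log_offset)
    res$p <- stats::p.adjust(res$p, method = p_adjust)
    res$contrast <- ct$label
    res$experiment <- ct$experiment
    res$included <- incl$included[match(res$gene_id, incl$gene_id)]
    res$status <- rd$status[match(res$gene_id, rd$gene_id)]
    res$significant <- res$included & !is.na(res$fold) &
      abs(res$fold) >= min_fold & res$p < alpha
    res$category <- categorizeFold(res$fold)
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  res[, c("gene_id", "contrast", "experiment", "fold", "p", "significant",
          "category", "status", "included")]
}
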