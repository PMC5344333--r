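#' Amplification efficiency from a dilution series
#'
#' Fits Ct against log10(input quantity) by least squares. The
#' amplification efficiency is E = 10^(-1/slope) - 1: perfect 2-fold
#' chemistry gives a slope of -log2(10) = -3.3219 cycles per decade and
#' E = 1 (100%). The series is flagged as within the linear dynamic range
#' when R^2 meets the threshold.
#'
#' @param dilution data.frame with columns log10_quantity and ct (one
#'   target); at least 3 points.
#' @param r2_threshold Minimal R^2 for the linear-range flag.
#' @return List with slope, efficiency, r_squared, linear_range.
#' @examples
#' d <- data.frame(log10_quantity = 0:-3, ct = 20 - (0:-3) * log2(10))
#' qpcrEfficiency(d)$efficiency  # 1
#' @export
qpcrEfficiency <- function(dilution, r2_threshold = 0.99) {
  stopifnot(all(c("log10_quantity", "ct") %in% colnames(dilution)))
  if (nrow(dilution) < 3L) {
    stop("at least 3 dilution points are required")
  }
  fit <- stats::lm(ct ~ log10_quantity, data = dilution)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-9) {
    stop("efficiency undefined: dilution series has zero slope")
  }
  # R^2 computed directly (summary.lm warns on numerically perfect fits,
  # which noiseless synthetic chemistry legitimately produces)
  tss <- sum((dilution$ct - mean(dilution$ct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  list(slope = slope, efficiency = 10^(-1 / slope) - 1, r_squared = r2,
       linear_range = r2 >= r2_threshold)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(endogenous control); ddCt subtracts
#' the mean dCt of the calibrator group (T0 control); the expression fold
#' is 2^-ddCt. The method assumes amplification efficiency near 1 (checked
#' separately via [qpcrEfficiency()]); `pfaffl = TRUE` switches to
#' efficiency-corrected ratios using the supplied per-target efficiencies.
#'
#' @param plate A [QPCRPlate-class].
#' @param target Target gene name.
#' @param endogenous Endogenous-control name (default the plate's).
#' @param calibrator list(condition=, time=) identifying the calibrator
#'   group (default control at T0).
#' @param pfaffl Use efficiency-corrected ratios instead of 2^-ddCt.
#' @param efficiencies Named vector of per-target efficiencies (only used
#'   when `pfaffl = TRUE`).
#' @return List with `per_sample` (data.frame sample_id, condition, time,
#'   replicate, dct, ddct, fold) and `per_group` (condition, time,
#'   mean_fold, sd_fold, n). Samples missing an endogenous Ct are dropped
#'   with a warning.
#' @examples
#' plate <- simulateQPCR(sd_ct = 0)
#' ddctFold(plate, "LHCSR2")$per_group
#' @export
ddctFold <- function(plate, target, endogenous = plate@endogenous,
                     calibrator = list(condition = "control", time = 0),
                     pfaffl = FALSE, efficiencies = NULL) {
  w <- plate@wells
  tg <- w[w$target == target, ]
  en <- w[w$target == endogenous, ]
  if (nrow(tg) == 0L) stop("target ", target, " not on plate")
  idx <- match(tg$sample_id, en$sample_id)
  if (anyNA(idx)) {
    warning("dropping samples without endogenous Ct: ",
            paste(tg$sample_id[is.na(idx)], collapse = ", "))
    tg <- tg[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  dct <- tg$ct - en$ct[idx]
  cal <- tg$condition == calibrator$condition & tg$time == calibrator$time
  if (!any(cal)) stop("calibrator group absent from plate")
  ddct <- dct - mean(dct[cal])
  fold <- if (!pfaffl) {
    2^(-ddct)
  } else {
    if (is.null(efficiencies)) {
      stop("pfaffl = TRUE requires per-target efficiencies")
    }
    e_t <- 1 + unname(efficiencies[target])
    e_r <- 1 + unname(efficiencies[endogenous])
    dct_t <- tg$ct - mean(tg$ct[cal])
    dct_r <- en$ct[idx] - mean(en$ct[idx][cal])
    e_t^(-dct_t) / e_r^(-dct_r)
  }
  per_sample <- data.frame(
    sample_id = tg$sample_id, condition = tg$condition, time = tg$time,
    replicate = tg$replicate, dct = dct, ddct = ddct, fold = fold,
    stringsAsFactors = FALSE
  )
  per_group <- do.call(rbind, lapply(
    split(per_sample, list(per_sample$condition, per_sample$time),
          drop = TRUE),
    function(d) data.frame(
      condition = d$condition[1], time = d$time[1],
      mean_fold = mean(d$fold),
      sd_fold = if (nrow(d) > 1L) stats::sd(d$fold) else NA_real_,
      n = nrow(d)
    )
  ))
  per_group <- per_group[order(per_group$time, per_group$condition), ]
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}

#' Condition-wise significance of qPCR folds
#'
#' One-way ANOVA of log2 folds (equivalently -ddCt) across condition
#' groups at each time point, flagged at p < alpha.
#'
#' @param per_sample Per-sample fold table from [ddctFold()].
#' @param alpha Significance level (default 0.01).
#' @return data.frame with columns time, p, significant, n_groups
#'   (time points with fewer than 2 conditions or under-replicated groups
#'   are skipped with a warning).
#' @export
qpcrSignificance <- function(per_sample, alpha = 0.01) {
  out <- list()
  for (tt in sort(setdiff(unique(per_sample$time), 0))) {
    d <- per_sample[per_sample$time == tt, ]
    sizes <- table(d$condition)
    if (length(sizes) < 2L || any(sizes < 2L)) {
      warning("time ", tt, ": under-replicated groups; test skipped")
      next
    }
    y <- log2(d$fold)
    if (all(y == y[1])) {
      p <- 1
    } else {
      p <- stats::anova(stats::lm(y ~ factor(d$condition)))[["Pr(>F)"]][1]
    }
    out[[length(out) + 1L]] <- data.frame(
      time = tt, p = p, significant = p < alpha, n_groups = length(sizes)
    )
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}
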