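#' Default flow-cytometry trajectories for the light-shift experiments
#'
#' Target bead-relative means of forward-angle light scatter (FALS, a cell
#' size proxy) and chlorophyll-derived red fluorescence over the sampling
#' times of the shift experiments. Controls and HL rise through the light
#' period and drop after the light-to-dark transition (minimum at T19.5);
#' under HL+UV both proxies collapse, red fluorescence reaching -93% of its
#' T0 value at T19.5.
#'
#' @param replicates Biological replicates per condition (default 3).
#' @param base_fals,base_red Bead-relative values at T0.
#' @return data.frame with columns sample_id, condition, time, replicate,
#'   fals_rel, red_rel (target bead-relative means per sample).
#' @export
defaultFCMParams <- function(replicates = 3L, base_fals = 1.2,
                             base_red = 0.8) {
  times <- c(0, 1, 2.5, 6, 9.5, 19.5)
  pc <- list( # percent change from T0 per condition, FALS then red
    control = list(fals = c(0, 15, 35, 85, 136, -20),
                   red = c(0, 12, 30, 70, 110, -15)),
    HL = list(fals = c(0, 15, 35, 80, 130, -20),
              red = c(0, 8, 18, 35, 55, -25)),
    HLUV = list(fals = c(0, 5, -10, -25, -35, -40),
                red = c(0, -20, -45, -65, -80, -93))
  )
  rows <- lapply(names(pc), function(cond) {
    grid <- expand.grid(time = times, replicate = seq_len(replicates))
    i <- match(grid$time, times)
    data.frame(
      sample_id = sprintf("%s_T%s_rep%d", cond, grid$time, grid$replicate),
      condition = cond, time = grid$time, replicate = grid$replicate,
      fals_rel = base_fals * (1 + pc[[cond]]$fals[i] / 100),
      red_rel = base_red * (1 + pc[[cond]]$red[i] / 100),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate flow-cytometry event tables
#'
#' Generates per-event FALS / SSC / red-fluorescence values for a cell
#' population following the configured diel trajectory and a spiked bead
#' population whose location is constant across samples (the normalization
#' standard). Channel values are log-normal with the requested mean.
#'
#' @param sample_params data.frame as returned by [defaultFCMParams()]
#'   (columns sample_id, condition, time, replicate, fals_rel, red_rel).
#' @param config A [SimConfig-class] (bead mean, event counts, spread).
#' @param sdlog Log-scale spread of events; must be positive.
#' @param n_cells,n_beads Events per population (defaults from `config`);
#'   zero yields an empty table.
#' @return data.frame with columns sample_id, condition, time, replicate,
#'   population ("cell"/"bead"), fals, ssc, red.
#' @export
simulateFCM <- function(sample_params, config, sdlog = config@fcm_sdlog,
                        n_cells = config@fcm_events_cell,
                        n_beads = config@fcm_events_bead) {
  stopifnot(is(config, "SimConfig"))
  if (sdlog <= 0) stop("event scale (sdlog) must be positive")
  set.seed(deriveSeed(config@seed, "fcm"))
  empty <- data.frame(
    sample_id = character(), condition = character(), time = numeric(),
    replicate = integer(), population = character(), fals = numeric(),
    ssc = numeric(), red = numeric(), stringsAsFactors = FALSE
  )
  if (n_cells + n_beads == 0L || nrow(sample_params) == 0L) return(empty)
  rlog <- function(n, mean) { # log-normal with expectation = mean
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
  bead_mean <- config@fcm_bead_mean
  rows <- lapply(seq_len(nrow(sample_params)), function(i) {
    p <- sample_params[i, ]
    cell <- if (n_cells > 0) data.frame(
      sample_id = p$sample_id, condition = p$condition, time = p$time,
      replicate = p$replicate, population = "cell",
      fals = rlog(n_cells, p$fals_rel * bead_mean),
      ssc = rlog(n_cells, 0.5 * bead_mean),
      red = rlog(n_cells, p$red_rel * bead_mean),
      stringsAsFactors = FALSE
    )
    bead <- if (n_beads > 0) data.frame(
      sample_id = p$sample_id, condition = p$condition, time = p$time,
      replicate = p$replicate, population = "bead",
      fals = rlog(n_beads, bead_mean),
      ssc = rlog(n_beads, bead_mean),
      red = rlog(n_beads, bead_mean),
      stringsAsFactors = FALSE
    )
    rbind(cell, bead)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate bulk-fluorescence growth series
#'
#' Emulates semi-continuous batch cultures followed by daily bulk
#' fluorescence at a fixed clock time: within each transfer the signal is
#' F(t) = F0 * exp(mu * t) * (1 + eps), and each transfer starts again from
#' F0 (the dilution). With `noise = 0` and mu = ln 2 the signal exactly
#' doubles between consecutive daily samples.
#'
#' @param mu_by_irradiance Named numeric vector of true growth rates
#'   (d^-1) per irradiance, e.g. [defaultGrowthRates()].
#' @param times Sampling times within a transfer (days, sorted ascending).
#' @param noise Relative (Gaussian) fluorescence noise.
#' @param seed Integer seed.
#' @param replicates Biological replicates per irradiance.
#' @param n_transfers Consecutive transfers per replicate.
#' @param f0 Post-dilution fluorescence.
#' @return data.frame with columns irradiance, replicate, transfer, day
#'   (time within transfer), time_d (absolute time), fluorescence.
#' @export
simulateGrowth <- function(mu_by_irradiance, times = 0:3, noise = 0.02,
                           seed = 1L, replicates = 3L, n_transfers = 4L,
                           f0 = 10) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop("sampling times must be strictly increasing")
  }
  stopifnot(all(is.finite(mu_by_irradiance)))
  set.seed(deriveSeed(seed, "growth"))
  span <- max(times) + 1
  grid <- expand.grid(
    day = times, transfer = seq_len(n_transfers),
    replicate = seq_len(replicates),
    irradiance = as.numeric(names(mu_by_irradiance))
  )
  mu <- mu_by_irradiance[as.character(grid$irradiance)]
  eps <- if (noise > 0) stats::rnorm(nrow(grid), 0, noise) else 0
  out <- data.frame(
    irradiance = grid$irradiance, replicate = grid$replicate,
    transfer = grid$transfer, day = grid$day,
    time_d = (grid$transfer - 1) * span + grid$day,
    fluorescence = f0 * exp(mu * grid$day) * (1 + eps)
  )
  out <- out[order(out$irradiance, out$replicate, out$transfer, out$day), ]
  rownames(out) <- NULL
  out
}

#' Simulate qPCR plates
#'
#' Generates threshold cycles consistent with exponential amplification at
#' the given efficiency: Ct = intercept - log_(1+E)(quantity), so at
#' efficiency 1 each doubling of input lowers Ct by one cycle. True
#' expression folds (relative to the T0-control calibrator, after
#' endogenous correction) are encoded as Ct shifts of the target gene; the
#' endogenous-control Ct is constant up to noise. A 10-fold dilution-series
#' block is emitted per target for efficiency / linear-range checks.
#'
#' @param true_folds data.frame (target, condition, time, fold) of true
#'   expression ratios vs the calibrator, e.g. [defaultQPCRFolds()].
#' @param efficiency Amplification efficiency in (0, 1].
#' @param sd_ct Gaussian Ct noise (cycles); 0 for exact chemistry.
#' @param seed Integer seed.
#' @param replicates Biological replicates per group.
#' @param endogenous Endogenous-control target name.
#' @param ct_target,ct_endo Baseline Ct of targets / endogenous control in
#'   the calibrator.
#' @param dilution_log10 log10 input amounts of the dilution series.
#' @return A [QPCRPlate-class].
#' @examples
#' plate <- simulateQPCR(defaultQPCRFolds(), sd_ct = 0)
#' plate
#' @export
simulateQPCR <- function(true_folds = defaultQPCRFolds(), efficiency = 1,
                         sd_ct = 0.15, seed = 1L, replicates = 3L,
                         endogenous = "Actin", ct_target = 28, ct_endo = 22,
                         dilution_log10 = 0:-3) {
  if (efficiency <= 0 || efficiency > 1) {
    stop("efficiency must be in (0, 1]")
  }
  set.seed(deriveSeed(seed, "qpcr"))
  targets <- unique(true_folds$target)
  groups <- rbind(
    data.frame(condition = "control", time = 0),
    unique(true_folds[, c("condition", "time")])
  )
  groups <- unique(groups)
  lbase <- log(1 + efficiency)
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    cond <- groups$condition[i]
    tt <- groups$time[i]
    for (r in seq_len(replicates)) {
      sid <- sprintf("%s_T%s_rep%d", cond, tt, r)
      for (tg in targets) {
        f <- if (cond == "control" && tt == 0) 1 else {
          hit <- true_folds$target == tg & true_folds$condition == cond &
            true_folds$time == tt
          if (any(hit)) true_folds$fold[hit][1] else 1
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, time = tt, replicate = r,
          target = tg,
          ct = ct_target - log(f) / lbase +
            (if (sd_ct > 0) stats::rnorm(1, 0, sd_ct) else 0)
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, condition = cond, time = tt, replicate = r,
        target = endogenous,
        ct = ct_endo + (if (sd_ct > 0) stats::rnorm(1, 0, sd_ct) else 0)
      )
    }
  }
  wells <- do.call(rbind, rows)
  dil <- do.call(rbind, lapply(c(targets, endogenous), function(tg) {
    data.frame(
      target = tg, log10_quantity = dilution_log10,
      ct = ct_target - dilution_log10 * log(10) / lbase +
        (if (sd_ct > 0) {
          stats::rnorm(length(dilution_log10), 0, sd_ct)
        } else 0)
    )
  }))
  QPCRPlate(wells = wells, dilution = dil, endogenous = endogenous)
}
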