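#' Bead-normalize flow-cytometry events
#'
#' Converts per-event channel values into bead relative units: the
#' arithmetic mean of the cell population divided by the arithmetic mean
#' of the spiked reference-bead population, per channel and sample. Since
#' any instrument gain multiplies both populations equally, bead relative
#' units are exactly gain-invariant.
#'
#' @param events Event table (columns sample_id, population, fals, red,
#'   optionally condition/time/replicate carried through).
#' @param min_events Minimal events per population; samples below it are
#'   dropped with a warning.
#' @return FCMSummary data.frame: sample_id (+ carried design columns),
#'   n_cells, n_beads, fals_rel, red_rel.
#' @examples
#' ev <- data.frame(sample_id = "s1", population = rep(c("cell", "bead"),
#'   each = 50), fals = c(rnorm(50, 1500, 10), rnorm(50, 3000, 10)),
#'   red = c(rnorm(50, 1500, 10), rnorm(50, 3000, 10)))
#' beadNormalize(ev)
#' @export
beadNormalize <- function(events, min_events = 10L) {
  stopifnot(all(c("sample_id", "population", "fals", "red") %in%
                  colnames(events)))
  carry <- intersect(c("condition", "time", "replicate"), colnames(events))
  out <- list()
  for (sid in unique(events$sample_id)) {
    ev <- events[events$sample_id == sid, ]
    cells <- ev[ev$population == "cell", ]
    beads <- ev[ev$population == "bead", ]
    if (nrow(beads) == 0L) {
      stop("no bead population in sample ", sid,
           ": bead normalization impossible")
    }
    if (nrow(cells) < min_events || nrow(beads) < min_events) {
      warning("sample ", sid, " has fewer than ", min_events,
              " events per population; skipped")
      next
    }
    row <- data.frame(
      sample_id = sid, n_cells = nrow(cells), n_beads = nrow(beads),
      fals_rel = mean(cells$fals) / mean(beads$fals),
      red_rel = mean(cells$red) / mean(beads$red),
      stringsAsFactors = FALSE
    )
    for (cc in carry) row[[cc]] <- ev[[cc]][1]
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent change from a reference value
#'
#' 100 * (x - x0) / x0, the convention used for trajectories of
#' bead-normalized cell properties relative to their T0 value.
#'
#' @param x Numeric vector of values.
#' @param x0 Reference (T0) value; must be positive.
#' @return Percent change per element of `x`.
#' @examples
#' percentChange(c(25, 10, 0.7), 10)  # +150, 0, -93
#' @export
percentChange <- function(x, x0) {
  if (length(x0) != 1L || !is.finite(x0) || x0 <= 0) {
    stop("reference value must be a single positive number")
  }
  100 * (x - x0) / x0
}

#' Estimate growth rates from bulk-fluorescence series
#'
#' Within each transfer, the specific growth rate mu (d^-1) is the
#' least-squares slope of ln(fluorescence) against time; the series mean
#' mu and its standard error are taken over transfers. This is exact on
#' noiseless exponentials.
#'
#' @param series Growth series data.frame (columns transfer, day,
#'   fluorescence; typically from [simulateGrowth()] for one
#'   irradiance/replicate).
#' @return List with `per_transfer` (data.frame transfer, mu, n_points),
#'   `mu` (mean over transfers), `se` (standard error over transfers; NA
#'   for a single transfer) and `k` (divisions per day).
#' @examples
#' s <- simulateGrowth(c(`240` = log(2)), noise = 0, replicates = 1,
#'   n_transfers = 3)
#' growthRate(s)$mu  # ln 2
#' @export
growthRate <- function(series) {
  stopifnot(all(c("transfer", "day", "fluorescence") %in% colnames(series)))
  if (any(series$fluorescence <= 0)) {
    stop("nonpositive fluorescence signal")
  }
  per <- lapply(split(series, series$transfer), function(tr) {
    if (nrow(tr) < 2L) {
      stop("transfer ", tr$transfer[1], " has fewer than 2 time points")
    }
    fit <- stats::lm(log(fluorescence) ~ day, data = tr)
    data.frame(transfer = tr$transfer[1],
               mu = unname(stats::coef(fit)[2]), n_points = nrow(tr))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  mu <- mean(per$mu)
  se <- if (nrow(per) > 1L) stats::sd(per$mu) / sqrt(nrow(per)) else NA_real_
  list(per_transfer = per, mu = mu, se = se, k = divisionsPerDay(mu))
}

#' Convert a specific growth rate to divisions per day
#'
#' k = mu / ln 2: a culture growing at mu = ln 2 per day doubles exactly
#' once per day, and mu = 1.0 d^-1 corresponds to about 1.44 divisions
#' per day.
#'
#' @param mu Specific growth rate (d^-1).
#' @return Divisions per day.
#' @examples
#' divisionsPerDay(1.0)  # 1.4427
#' @export
divisionsPerDay <- function(mu) mu / log(2)

#' Summarize growth rate as a function of irradiance
#'
#' @param rates data.frame with columns irradiance and mu (one row per
#'   replicate or transfer estimate).
#' @return List with `table` (irradiance, mean_mu, se, n), `mu_max` and
#'   `optimum_irradiance` (the level where the mean is maximal).
#' @export
growthVsIrradiance <- function(rates) {
  stopifnot(all(c("irradiance", "mu") %in% colnames(rates)))
  tab <- do.call(rbind, lapply(split(rates, rates$irradiance), function(d) {
    data.frame(
      irradiance = d$irradiance[1], mean_mu = mean(d$mu),
      se = if (nrow(d) > 1L) stats::sd(d$mu) / sqrt(nrow(d)) else NA_real_,
      n = nrow(d)
    )
  }))
  rownames(tab) <- NULL
  tab <- tab[order(tab$irradiance), ]
  i <- which.max(tab$mean_mu)
  list(table = tab, mu_max = tab$mean_mu[i],
       optimum_irradiance = tab$irradiance[i])
}

#' Group tests for cytometry summaries and growth rates
#'
#' `fcmANOVA` runs a one-way ANOVA of a bead-relative property across
#' light levels (or conditions) at each time point; `growthTTest` runs a
#' two-sample t-test between two sets of growth-rate estimates. Groups
#' with a single replicate are skipped with a warning.
#'
#' @param summaries FCMSummary data.frame with columns time, a grouping
#'   column and the value column.
#' @param value Name of the value column (e.g. "fals_rel").
#' @param group Name of the grouping column (e.g. "condition").
#' @return data.frame with columns time, p, n_groups.
#' @export
fcmANOVA <- function(summaries, value = "fals_rel", group = "condition") {
  out <- list()
  for (tt in sort(unique(summaries$time))) {
    d <- summaries[summaries$time == tt, ]
    sizes <- table(d[[group]])
    if (length(sizes) < 2L || any(sizes < 2L)) {
      warning("time ", tt, ": under-replicated groups; test skipped")
      next
    }
    y <- d[[value]]
    p <- if (all(y == y[1])) 1 else {
      stats::anova(stats::lm(y ~ factor(d[[group]])))[["Pr(>F)"]][1]
    }
    out[[length(out) + 1L]] <- data.frame(
      time = tt, p = p, n_groups = length(sizes)
    )
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' @rdname fcmANOVA
#' @param ratesA,ratesB Numeric vectors of growth-rate estimates.
#' @param ... Passed to [stats::t.test()].
#' @export
growthTTest <- function(ratesA, ratesB, ...) {
  if (length(ratesA) < 2L || length(ratesB) < 2L) {
    warning("under-replicated growth-rate sets; test skipped")
    return(NA_real_)
  }
  stats::t.test(ratesA, ratesB, ...)$p.value
}
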