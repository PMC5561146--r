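## Normalization, Pearson correlation analyses and condition comparison:
## the inferential machinery linking activity/burst features to propagation
## velocity across modules and recording days.

#' Normalize a module's series to its grand mean
#'
#' Divides each value of a per-DIV feature series by the series' own mean
#' over the entire study, neutralizing large between-module activity
#' differences; the normalized non-missing values average exactly 1. The
#' operation is idempotent.
#'
#' @param x numeric values (missing values allowed and preserved).
#' @return \code{x / mean(x, na.rm = TRUE)}.
#' @examples
#' normalizeSeries(c(2, 4, 6))
#' @export
normalizeSeries <- function(x) {
  if (all(is.na(x))) stop("need at least one non-missing value")
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("series mean is zero; cannot normalize")
  x / m
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p value from the t transform;
#' missing pairs are dropped. Zero-variance (degenerate) input is flagged
#' rather than producing spurious correlations.
#'
#' @param x,y paired numeric vectors.
#' @return List with \code{r}, \code{p}, \code{n} (pairs used) and
#'   \code{degenerate}.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}

#' Feature-velocity correlation table
#'
#' Correlates each activity/burst feature with the propagation velocity
#' across module-DIV observations, either pooled over all recording days or
#' for each day separately. Each module at each DIV contributes one data
#' point. Optionally both variables are first normalized per module to
#' their study-long means.
#'
#' @param features \code{data.frame} with columns \code{module_id},
#'   \code{div} and one column per feature.
#' @param velocities \code{data.frame} with columns \code{module_id},
#'   \code{div}, \code{velocity}.
#' @param mode \code{"pooled"} (all DIVs, one row per feature) or
#'   \code{"per-day"} (one row per DIV and feature).
#' @param normalize logical; normalize each module's feature and velocity
#'   series with \code{\link{normalizeSeries}} before correlating.
#' @return \code{data.frame} with columns (\code{div},) \code{feature},
#'   \code{r}, \code{p}, \code{n}.
#' @export
activityVelocityTable <- function(features, velocities,
                                  mode = c("pooled", "per-day"),
                                  normalize = FALSE) {
  mode <- match.arg(mode)
  for (nm in c("module_id", "div"))
    if (!nm %in% names(features) || !nm %in% names(velocities))
      stop("missing alignment key: ", nm)
  if (!"velocity" %in% names(velocities))
    stop("missing alignment key: velocity")
  featCols <- setdiff(names(features), c("module_id", "div"))
  dat <- merge(features, velocities, by = c("module_id", "div"))
  if (!nrow(dat)) stop("no module-DIV keys shared by features and velocities")
  if (normalize) {
    for (m in unique(dat$module_id)) {
      i <- dat$module_id == m
      for (cl in c(featCols, "velocity"))
        dat[[cl]][i] <- normalizeSeries(dat[[cl]][i])
    }
  }
  corRows <- function(sub, div = NULL) {
    rows <- lapply(featCols, function(fc) {
      res <- tryCatch(pearsonCorrelation(sub[[fc]], sub$velocity),
                      error = function(e) list(r = NA_real_, p = NA_real_,
                                               n = sum(stats::complete.cases(
                                                 sub[[fc]], sub$velocity)),
                                               degenerate = NA))
      data.frame(feature = fc, r = res$r, p = res$p, n = res$n,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(div)) cbind(div = div, out) else out
  }
  if (mode == "pooled") return(corRows(dat))
  do.call(rbind, lapply(sort(unique(dat$div)),
                        function(d) corRows(dat[dat$div == d, ], d)))
}

#' Compare conditions with paired t tests
#'
#' Pairs units (electrodes or channels) between a baseline and a treated
#' condition (e.g. before and after GABA-A blockade) and reports, per
#' feature, means and s.d. per condition, the paired mean difference and a
#' paired t test. Unpaired units are excluded with a warning.
#'
#' @param baseline,treated \code{data.frame}s with a shared unit key column
#'   and one column per feature.
#' @param by unit key column name (default \code{"electrode_id"}).
#' @param features feature column names (default: all shared numeric
#'   columns except \code{by}).
#' @return \code{data.frame} with one row per feature:
#'   \code{mean_baseline}, \code{sd_baseline}, \code{mean_treated},
#'   \code{sd_treated}, \code{mean_difference}, \code{t}, \code{p},
#'   \code{n_pairs}.
#' @export
compareConditions <- function(baseline, treated, by = "electrode_id",
                              features = NULL) {
  if (!by %in% names(baseline) || !by %in% names(treated))
    stop("unit key column '", by, "' missing")
  if (is.null(features)) {
    shared <- intersect(names(baseline), names(treated))
    features <- shared[shared != by &
                         vapply(baseline[shared], is.numeric, logical(1))]
  }
  nUnpaired <- sum(!baseline[[by]] %in% treated[[by]]) +
    sum(!treated[[by]] %in% baseline[[by]])
  if (nUnpaired > 0)
    warning(nUnpaired, " unpaired unit(s) excluded")
  dat <- merge(baseline[, c(by, features)], treated[, c(by, features)],
               by = by, suffixes = c(".base", ".treat"))
  rows <- lapply(features, function(fc) {
    b <- dat[[paste0(fc, ".base")]]
    tr <- dat[[paste0(fc, ".treat")]]
    ok <- is.finite(b) & is.finite(tr)
    b <- b[ok]; tr <- tr[ok]
    d <- tr - b
    tt <- if (length(d) >= 2 && stats::sd(d) > 0)
      stats::t.test(tr, b, paired = TRUE) else NULL
    data.frame(
      feature = fc,
      mean_baseline = mean(b), sd_baseline = stats::sd(b),
      mean_treated = mean(tr), sd_treated = stats::sd(tr),
      mean_difference = mean(d),
      t = if (is.null(tt)) if (length(d) && all(d == 0)) 0 else NA_real_
          else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      n_pairs = length(d), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate an age-driven activity-velocity study
#'
#' Feature-level simulation reproducing the confound structure of a
#' long-term culture study: culture age (DIV) drives both burst features
#' and conduction velocity upward (inter-spike and inter-burst intervals
#' downward), while the day-to-day fluctuations of features and velocity
#' are independent. Pooling across days therefore yields positive
#' feature-velocity correlations even though, at any fixed age, features
#' and velocity are uncorrelated.
#'
#' @param nModules number of microchannel modules (default 42).
#' @param divs recording days in vitro (default \code{seq(13, 95, by = 6)}).
#' @param velocityRangeMS velocity means at the first and last DIV, m/s
#'   (default \code{c(0.46, 0.57)}).
#' @param burstRateRange burst rate means at first/last DIV, bursts/s.
#' @param noiseSd relative s.d. of the day-to-day fluctuations.
#' @param seed integer seed or \code{NULL}.
#' @return List with \code{features} (module_id, div, spike_rate,
#'   burst_rate, pct_spikes_in_bursts, mean_burst_duration_s,
#'   mean_spikes_per_burst, mean_sf_in_burst, mean_isi_in_burst_s,
#'   mean_ibi_s) and \code{velocities} (module_id, div, velocity).
#' @export
simulateAgingStudy <- function(nModules = 42L, divs = seq(13, 95, by = 6),
                               velocityRangeMS = c(0.46, 0.57),
                               burstRateRange = c(0.05, 0.4),
                               noiseSd = 0.1, seed = NULL) {
  run <- function() {
    age <- (divs - min(divs)) / diff(range(divs))  # 0..1
    grid <- expand.grid(module_id = seq_len(nModules), div = divs)
    a <- age[match(grid$div, divs)]
    modEff <- stats::rnorm(nModules, 1, 0.05)[grid$module_id]
    trendUp <- function(lo, hi)
      pmax((lo + (hi - lo) * a) * modEff *
             (1 + stats::rnorm(nrow(grid), 0, noiseSd)), 1e-6)
    features <- data.frame(
      grid,
      spike_rate = trendUp(1.5, 6),
      burst_rate = trendUp(burstRateRange[1], burstRateRange[2]),
      pct_spikes_in_bursts = pmin(trendUp(25, 70), 100),
      mean_burst_duration_s = trendUp(0.03, 0.08),
      mean_spikes_per_burst = trendUp(4.5, 9),
      mean_sf_in_burst = trendUp(120, 180),
      mean_isi_in_burst_s = trendUp(0.009, 0.0055),
      mean_ibi_s = trendUp(8, 2.5)
    )
    velocities <- data.frame(
      grid,
      velocity = pmax((velocityRangeMS[1] +
                         diff(velocityRangeMS) * a) * modEff *
                        (1 + stats::rnorm(nrow(grid), 0, noiseSd)), 0.1)
    )
    list(features = features, velocities = velocities)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate disinhibition of a feature table
#'
#' Emulates GABA-A blockade at fixed culture age: firing and bursting
#' features are scaled up (default 3-fold) while conduction velocity is
#' left unchanged, each perturbed by independent measurement noise.
#'
#' @param features baseline feature \code{data.frame} (long or wide; all
#'   numeric columns except keys are scaled).
#' @param velocities baseline velocity \code{data.frame} with a
#'   \code{velocity} column.
#' @param rateFactor multiplicative activity increase (default 3).
#' @param velocityFactor multiplicative velocity change (default 1: none).
#' @param noiseSd relative measurement noise s.d.
#' @param seed integer seed or \code{NULL}.
#' @return List with \code{features} and \code{velocities} in the input
#'   shapes.
#' @export
simulateDisinhibition <- function(features, velocities, rateFactor = 3,
                                  velocityFactor = 1, noiseSd = 0.05,
                                  seed = NULL) {
  run <- function() {
    keys <- c("module_id", "div", "electrode_id")
    f <- features
    for (cl in setdiff(names(f), keys))
      if (is.numeric(f[[cl]]))
        f[[cl]] <- f[[cl]] * rateFactor *
          (1 + stats::rnorm(nrow(f), 0, noiseSd))
    v <- velocities
    v$velocity <- v$velocity * velocityFactor *
      (1 + stats::rnorm(nrow(v), 0, noiseSd))
    list(features = f, velocities = v)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
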