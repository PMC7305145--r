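#' Cubic-spline interpolation of a sparse measured series
#'
#' Interpolates measured concentrations or OD values onto a uniform grid with
#' a natural cubic spline, mirroring the common practice of densifying sparse
#' batch-culture measurements before curve fitting (the default `n_out = 49`
#' matches the training-set size used downstream for AIC). Negative
#' interpolants are clipped to zero, since concentrations and OD cannot be
#' negative.
#'
#' @param times Numeric vector of measurement times, hours, non-decreasing.
#' @param values Numeric vector of non-negative measurements.
#' @param n_out Number of output points (>= number of input points).
#' @return Data frame with columns `time_h`, `value`; `n_out` rows spanning
#'   `range(times)` uniformly.
#' @examples
#' interpolate_series(0:5, c(0.2, 0.18, 0.12, 0.05, 0.01, 0), n_out = 11)
#' @export
interpolate_series <- function(times, values, n_out = 49L) {
  if (length(times) != length(values)) stop("`times`/`values` length mismatch")
  if (length(times) < 4L) stop("at least 4 points are required for splining")
  if (any(diff(times) < 0)) stop("`times` must be non-decreasing")
  if (n_out < length(times)) stop("`n_out` must be >= number of input points")
  grid <- seq(min(times), max(times), length.out = n_out)
  sp <- stats::spline(times, values, xout = grid, method = "natural")
  data.frame(time_h = sp$x, value = pmax(sp$y, 0))
}

#' Interpolate each replicate, then average on the common grid
#'
#' @param data Tidy data frame with columns `time_h`, `species_id`,
#'   `replicate_id`, `value`.
#' @param n_out Number of output grid points per species.
#' @return Tidy data frame `time_h`, `species_id`, `value` (replicates
#'   averaged after per-replicate interpolation).
#' @export
interpolate_replicates <- function(data, n_out = 49L) {
  stopifnot(all(c("time_h", "species_id", "replicate_id", "value") %in%
                  names(data)))
  out <- lapply(split(data, data$species_id), function(sp) {
    reps <- lapply(split(sp, sp$replicate_id), function(rep_df) {
      rep_df <- rep_df[order(rep_df$time_h), ]
      interpolate_series(rep_df$time_h, rep_df$value, n_out)$value
    })
    grid <- seq(min(sp$time_h), max(sp$time_h), length.out = n_out)
    data.frame(time_h = grid, species_id = sp$species_id[1],
               value = rowMeans(do.call(cbind, reps)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Log-linear growth rate within a time window
#'
#' Fits ordinary least squares to `ln(OD)` versus time inside the window and
#' returns the slope as the specific growth rate. Windows are explicit inputs:
#' phase boundaries of a multi-auxic curve are a judgement call, and the rate
#' depends on them.
#'
#' @param times Numeric vector of times, hours.
#' @param od Numeric vector of positive OD values.
#' @param window Length-2 numeric, inclusive time window; default the whole
#'   series.
#' @return List with `rate` (1/h), `se` (standard error of the slope) and
#'   `n` (points used).
#' @examples
#' t <- 0:10
#' estimate_growth_rate(t, 0.1 * exp(0.02 * t))$rate  # 0.02
#' @export
estimate_growth_rate <- function(times, od, window = range(times)) {
  if (length(times) != length(od)) stop("`times`/`od` length mismatch")
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3L) stop("window must contain at least 3 points")
  if (any(od[sel] <= 0)) stop("window contains non-positive OD values")
  fit <- stats::lm(log(od[sel]) ~ times[sel])
  co <- summary(fit)$coefficients
  list(rate = unname(co[2, 1]), se = unname(co[2, 2]), n = sum(sel))
}

#' Detect growth lags on a biomass curve
#'
#' Finds the maximal time intervals in which the instantaneous specific
#' growth rate — the centred finite difference of spline-smoothed `ln(OD)` —
#' falls below a threshold. This formalizes the "switch points" one marks by
#' eye on a multi-auxic growth curve: episodes where growth stalls between
#' consumption phases.
#'
#' @param times Numeric vector of times, hours.
#' @param od Numeric vector of positive OD values.
#' @param rate_threshold Rate below which growth counts as stalled, 1/h.
#'   Default: 10% of the maximum observed instantaneous rate.
#' @param smooth_n Running-mean window (samples) applied to `ln(OD)` before
#'   differencing; default 3.
#' @param drop_terminal If `TRUE` (default) a stalled interval that extends to
#'   the last time point is discarded as the terminal plateau rather than an
#'   internal lag.
#' @return Data frame with columns `start`, `end` (hours), possibly 0 rows;
#'   intervals are disjoint and sorted.
#' @examples
#' t <- seq(0, 10, 0.25)
#' detect_lags(t, 0.1 * exp(0.2 * t))  # pure exponential: no lags
#' @export
detect_lags <- function(times, od, rate_threshold = NULL, smooth_n = 3L,
                        drop_terminal = TRUE) {
  if (length(times) != length(od)) stop("`times`/`od` length mismatch")
  if (any(od <= 0)) stop("OD values must be positive")
  if (!is.null(rate_threshold) && rate_threshold <= 0)
    stop("`rate_threshold` must be positive")
  lod <- log(od)
  if (smooth_n > 1L)
    lod <- stats::filter(lod, rep(1 / smooth_n, smooth_n), sides = 2) |>
      fill_ends(lod)
  k <- length(times)
  rate <- numeric(k)
  rate[2:(k - 1)] <- (lod[3:k] - lod[1:(k - 2)]) / (times[3:k] - times[1:(k - 2)])
  rate[1] <- rate[2]; rate[k] <- rate[k - 1]
  if (is.null(rate_threshold)) rate_threshold <- 0.1 * max(rate)
  if (rate_threshold <= 0) return(data.frame(start = numeric(), end = numeric()))
  low <- rate < rate_threshold
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  if (drop_terminal) keep <- keep & ends < k
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}

# replace NA ends left by a centred running mean with the raw values
fill_ends <- function(smoothed, raw) {
  smoothed <- as.numeric(smoothed)
  na <- is.na(smoothed)
  smoothed[na] <- raw[na]
  smoothed
}
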