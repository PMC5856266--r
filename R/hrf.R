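#' Canonical double-gamma haemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking near 5 s minus a
#' later gamma undershoot at ratio 1/6,
#' `h(t) = g(t; shape 6, rate 1) - g(t; shape 16, rate 1) / 6`,
#' sampled on `[0, duration]` and rescaled to unit peak.
#'
#' @param dt Sampling interval, seconds.
#' @param peak_shape,undershoot_shape,rate Gamma shape/rate constants
#'   (defaults 6, 16, 1).
#' @param undershoot_ratio Undershoot weight (default 1/6).
#' @param duration Kernel support, seconds (default 32).
#' @return An `hrf_kernel`: list with `dt`, `times`, `values` (unit peak).
#' @export
#' @examples
#' h <- canonical_hrf(0.1)
#' h$times[which.max(h$values)]  # ~5 s
canonical_hrf <- function(dt, peak_shape = 6, undershoot_shape = 16,
                          rate = 1, undershoot_ratio = 1 / 6,
                          duration = 32) {
  check_positive(dt, "dt")
  times <- seq(0, duration, by = dt)
  v <- stats::dgamma(times, shape = peak_shape, rate = rate) -
    undershoot_ratio * stats::dgamma(times, shape = undershoot_shape, rate = rate)
  v <- v / max(v)
  structure(list(dt = dt, times = times, values = v), class = "hrf_kernel")
}

# Resample an hrf_kernel onto a new dt grid (linear interpolation).
resample_hrf <- function(hrf, dt) {
  if (isTRUE(all.equal(hrf$dt, dt))) return(hrf)
  times <- seq(0, max(hrf$times), by = dt)
  v <- stats::approx(hrf$times, hrf$values, xout = times, rule = 2)$y
  structure(list(dt = dt, times = times, values = v), class = "hrf_kernel")
}

# Boxcar-convolved condition regressor sampled at frame times.
# Microtime oversampling: the boxcar is laid out at dt = tr/oversample,
# convolved with the HRF sampled at the same dt, then picked up at frame
# onsets. The convolution is scaled so a sustained epoch plateaus at the
# condition's amplitude (HRF normalized to unit integral inside this step);
# betas are then in the simulator's signal units.
convolved_regressor <- function(onsets, durations, tr, n_scans, hrf,
                                oversample = 16) {
  dt <- tr / oversample
  h <- resample_hrf(hrf, dt)
  n_fine <- n_scans * oversample
  kernel <- h$values / sum(h$values)   # unit-integral HRF
  # The boxcar is a difference of unit steps, so its discrete convolution
  # with the kernel is a difference of shifted kernel cumsums: exact and
  # O(n) per epoch.
  csum <- c(0, cumsum(kernel))
  p <- length(kernel)
  look <- function(k) csum[pmin(pmax(k, 0), p) + 1]
  tt <- seq_len(n_fine)
  r <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- floor((onsets[i] + durations[i]) / dt)
    if (b >= a) r <- r + look(tt - a + 1) - look(tt - b)
  }
  r[seq(1, n_fine, by = oversample)]
}
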