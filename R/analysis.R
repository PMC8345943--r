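#' Construct a time-series observable
#'
#' A scalar observable sampled at the trajectory's recorded times, with a
#' transient cutoff: summaries ([amplitude()], [dominant_frequency()])
#' only use samples at `t >= transient_cutoff`. The default cutoff of
#' 0.5e-9 s is the interval over which runs at all drive frequencies look
#' alike before their periodic components separate.
#'
#' @param times Sampling instants (s), strictly increasing.
#' @param values Observable values (rad).
#' @param transient_cutoff Transient cutoff (s), >= 0.
#' @return An object of class `series_observable`.
#' @export
series_observable <- function(times, values, transient_cutoff = 0.5e-9) {
  if (length(times) != length(values) || length(times) < 1L)
    stop("`times` and `values` must have equal positive length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.numeric(transient_cutoff) || transient_cutoff < 0)
    stop("`transient_cutoff` must be >= 0")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 transient_cutoff = transient_cutoff),
            class = "series_observable")
}

post_cutoff <- function(series) {
  keep <- series$times >= series$transient_cutoff
  if (!any(keep))
    stop("no samples at or after the transient cutoff")
  list(times = series$times[keep], values = series$values[keep])
}

#' Chain-mean angular deviation
#'
#' The primary observable: the unweighted mean over all n sites of the
#' chain's angles at each recorded time,
#' phibar_j(t) = (1/n) sum_i phi_ji(t).
#'
#' @param traj A `duplex_trajectory`.
#' @param chain 1 or 2.
#' @param transient_cutoff Cutoff attached to the returned series (s).
#' @return A `series_observable`.
#' @export
mean_angular_deviation <- function(traj, chain = 1, transient_cutoff = 0.5e-9) {
  stopifnot(inherits(traj, "duplex_trajectory"))
  if (!chain %in% c(1, 2)) stop("`chain` must be 1 or 2")
  vals <- if (chain == 1) traj$mean_phi1 else traj$mean_phi2
  series_observable(traj$times, vals, transient_cutoff = transient_cutoff)
}

#' Post-transient oscillation amplitude
#'
#' Default estimator: half the peak-to-trough range of the post-cutoff
#' segment after subtracting its mean. The signals are neither sinusoidal
#' nor stationary (their periodic components decay), so half-range tracks
#' what is visible on a trajectory plot better than RMS-based estimators;
#' `method` exposes the alternatives for sensitivity reporting.
#'
#' @param series A `series_observable`.
#' @param method `"half_range"` (default), `"rms"` (sqrt(2) x standard
#'   deviation, exact for a sinusoid), or `"max_abs"` (largest deviation
#'   from the segment mean).
#' @return Amplitude (rad), >= 0.
#' @export
amplitude <- function(series, method = c("half_range", "rms", "max_abs")) {
  stopifnot(inherits(series, "series_observable"))
  method <- match.arg(method)
  seg <- post_cutoff(series)
  x <- seg$values - mean(seg$values)
  switch(method,
         half_range = (max(x) - min(x)) / 2,
         rms = sqrt(2) * stats::sd(x),
         max_abs = max(abs(x)))
}

#' Dominant frequency of the post-transient segment
#'
#' Periodogram of the mean-subtracted, Hann-windowed post-cutoff segment;
#' the returned value is the location of the largest non-zero-frequency
#' peak, refined by parabolic interpolation of log power over the peak and
#' its two neighbours. Reported as ordinary frequency (cycles per second);
#' compare against a drive via f = omega / (2 pi). The raw bin resolution
#' 1/(segment duration) is attached as attribute `"resolution"`.
#'
#' @param series A `series_observable` sampled uniformly.
#' @param min_samples Minimal post-cutoff segment length; shorter segments
#'   are rejected with the attainable resolution floor.
#' @return Dominant frequency (s^-1) with attribute `"resolution"`.
#' @export
dominant_frequency <- function(series, min_samples = 8L) {
  stopifnot(inherits(series, "series_observable"))
  seg <- post_cutoff(series)
  m <- length(seg$values)
  dts <- diff(seg$times)
  if (m < min_samples)
    stop(sprintf(
      "post-cutoff segment has %d samples; at least %d needed (frequency resolution floor is 1/duration = %g s^-1)",
      m, min_samples, 1 / (seg$times[m] - seg$times[1L])))
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("series is not uniformly sampled")
  dt <- mean(dts)
  x <- seg$values - mean(seg$values)
  w <- 0.5 * (1 - cos(2 * pi * seqalong(x) / (m - 1)))
  p <- Mod(stats::fft(x * w))^2
  half <- floor(m / 2)
  if (half < 2L) stop("segment too short for a periodogram")
  pk <- which.max(p[2:(half + 1L)])  # bins 1..half (zero bin excluded)
  # parabolic refinement on log power, guarded at the edges
  delta <- 0
  if (pk > 1L && pk < half) {
    lp <- log(pmax(p[pk:(pk + 2L)], .Machine$double.xmin))
    den <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (is.finite(den) && den < 0) delta <- 0.5 * (lp[1L] - lp[3L]) / den
    if (!is.finite(delta) || abs(delta) > 0.5) delta <- 0
  }
  f <- (pk + delta) / (m * dt)
  structure(f, resolution = 1 / (m * dt))
}

# 0-based index helper used by the Hann window
seqalong <- function(x) seq_len(length(x)) - 1

#' Sliding-window frequency track
#'
#' [dominant_frequency()] evaluated on windows of fixed duration sliding
#' over the post-cutoff segment. Descriptive only: it shows how the
#' frequency of the periodic component drifts with time, with no model of
#' the drift.
#'
#' @param series A `series_observable`.
#' @param window Window duration (s).
#' @param hop Hop between window starts (s); default `window / 2`.
#' @return A data frame with columns `time` (window center, s) and
#'   `frequency` (s^-1).
#' @export
time_resolved_frequency <- function(series, window, hop = window / 2) {
  stopifnot(inherits(series, "series_observable"))
  seg <- post_cutoff(series)
  span <- seg$times[length(seg$times)] - seg$times[1L]
  if (window > span) stop("`window` exceeds the post-cutoff span")
  dt <- mean(diff(seg$times))
  if (window < 2 * dt) stop("`window` shorter than 2 samples")
  starts <- seq(seg$times[1L], seg$times[length(seg$times)] - window, by = hop)
  rows <- lapply(starts, function(s) {
    keep <- seg$times >= s & seg$times <= s + window
    sub <- series_observable(seg$times[keep], seg$values[keep],
                             transient_cutoff = 0)
    f <- tryCatch(as.numeric(dominant_frequency(sub)),
                  error = function(e) NA_real_)
    data.frame(time = s + window / 2, frequency = f)
  })
  do.call(rbind, rows)
}

#' Summarize one run
#'
#' Computes the chain-1 mean angular deviation of a trajectory and its
#' post-transient amplitude and dominant frequency, keeping the series and
#' run metadata for reporting.
#'
#' @param traj A `duplex_trajectory`.
#' @param transient_cutoff Transient cutoff (s).
#' @param amplitude_method Estimator passed to [amplitude()].
#' @param track Logical; also compute a [time_resolved_frequency()] track
#'   (window = a quarter of the post-cutoff span).
#' @return An object of class `run_summary` with fields `amplitude`,
#'   `dominant_frequency`, `frequency_track` (or `NULL`), `series`, and
#'   `metadata`.
#' @export
run_summary <- function(traj, transient_cutoff = 0.5e-9,
                        amplitude_method = "half_range", track = FALSE) {
  stopifnot(inherits(traj, "duplex_trajectory"))
  s <- mean_angular_deviation(traj, 1, transient_cutoff = transient_cutoff)
  amp <- amplitude(s, method = amplitude_method)
  f <- tryCatch(as.numeric(dominant_frequency(s)), error = function(e) NA_real_)
  tr <- NULL
  if (isTRUE(track)) {
    seg <- post_cutoff(s)
    span <- seg$times[length(seg$times)] - seg$times[1L]
    tr <- tryCatch(time_resolved_frequency(s, window = span / 4),
                   error = function(e) NULL)
  }
  structure(list(amplitude = amp, dominant_frequency = f,
                 frequency_track = tr, series = s,
                 amplitude_method = amplitude_method,
                 metadata = traj$metadata),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<run_summary> %s (omega = %g s^-1, F0 = %g J, %s)\n  amplitude = %g rad (%s), dominant frequency = %g s^-1\n",
    m$sequence_id, m$omega, m$F0, m$variant, x$amplitude,
    x$amplitude_method, x$dominant_frequency))
  invisible(x)
}

#' Ratio of two runs' amplitudes
#'
#' @param a,b `run_summary` objects computed with the same transient
#'   cutoff and amplitude estimator.
#' @return `a$amplitude / b$amplitude`.
#' @export
amplitude_ratio <- function(a, b) {
  stopifnot(inherits(a, "run_summary"), inherits(b, "run_summary"))
  if (!isTRUE(all.equal(a$series$transient_cutoff, b$series$transient_cutoff)) ||
      !identical(a$amplitude_method, b$amplitude_method))
    stop("summaries were computed with different cutoffs or estimators")
  if (b$amplitude == 0) stop("reference amplitude is zero")
  a$amplitude / b$amplitude
}
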