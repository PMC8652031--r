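#' Remove a least-squares linear trend
#'
#' @param s a complete [cyc_series] or numeric vector on a uniform grid,
#'   length >= 3.
#' @return A [cyc_series] of residuals (mean ~ 0, zero linear correlation
#'   with time).
#' @export
detrend_linear <- function(s) {
  s <- as_series(s)
  stopifnot(length(s$values) >= 3, !anyNA(s$values))
  t_c <- s$times - mean(s$times)
  beta <- sum(t_c * s$values) / sum(t_c^2)
  cyc_series(s$times, s$values - mean(s$values) - beta * t_c)
}

#' Centered moving average with boundary truncation
#'
#' Averages over the window `[i - h, i + h]` (with `h = (window-1)/2`)
#' intersected with the series, so the window shrinks near the boundaries
#' and the output length is unchanged.
#'
#' @param s a complete [cyc_series] or numeric vector.
#' @param window odd window width, at most the series length.
#' @return Same kind as the input.
#' @export
moving_average <- function(s, window = 3) {
  numeric_in <- !inherits(s, "cyc_series")
  s <- as_series(s)
  x <- s$values
  n <- length(x)
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window > n) stop("'window' exceeds series length")
  h <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  if (numeric_in) out else cyc_series(s$times, out)
}

#' Estimate period, phase and amplitude of an oscillation
#'
#' Works on the replicate-averaged, imputed but *unscaled* series, so that
#' amplitude is reported in input expression units. The series is linearly
#' detrended and smoothed with a centered moving average; the discrete
#' Fourier transform of the smoothed residuals selects the (up to) three
#' non-zero frequencies of largest magnitude. The trend line and the
#' selected harmonics are then re-fit jointly by least squares to the raw
#' series — fitting the unsmoothed data keeps bin-aligned sinusoids exact,
#' since a moving average would otherwise attenuate every harmonic by its
#' transfer-function gain. From the fitted harmonic part:
#' period = 1 / frequency of the dominant harmonic (the largest-magnitude
#' harmonic whose period lies within `[expected_period_h/2,
#' 2*expected_period_h]`, guarding against trend leakage at the lowest
#' bins); phase = time of the first maximum of the fitted curve within one
#' period, in `[0, period)`; amplitude = half the peak-to-trough range of
#' the fitted curve.
#'
#' @param s a complete [cyc_series] or numeric vector on a uniform grid
#'   with at least 8 points.
#' @param expected_period_h prior guess of the period (hours), default 24;
#'   only used to bound the dominant-harmonic search.
#' @param window moving-average width for the frequency-selection step.
#' @return A list with `period_h`, `phase_h`, `amplitude` (all `NA` for a
#'   flat series).
#' @export
estimate_rhythm <- function(s, expected_period_h = 24, window = 3) {
  s <- as_series(s)
  x <- s$values
  t <- s$times
  n <- length(x)
  stopifnot(n >= 8, !anyNA(x))
  if (!is_uniform_grid(t)) stop("estimate_rhythm() requires a uniform grid")
  undefined <- list(period_h = NA_real_, phase_h = NA_real_,
                    amplitude = NA_real_)
  if (stats::sd(x) < 1e-12) return(undefined)
  dt <- t[2] - t[1]

  # frequency selection on the detrended, smoothed signal
  xs <- moving_average(detrend_linear(s), window = window)$values
  sp <- stats::fft(xs)
  ks <- seq_len(floor(n / 2))                 # positive-frequency bins
  mags <- Mod(sp[ks + 1])
  freqs <- ks / (n * dt)                      # cycles per hour
  keep <- ks[mags > 1e-9 * max(mags, 1e-300)]
  if (length(keep) == 0 || max(mags) < 1e-10 * stats::sd(x)) return(undefined)
  keep <- keep[order(mags[keep], decreasing = TRUE)][seq_len(min(3, length(keep)))]

  periods <- 1 / freqs[keep]
  in_band <- periods >= expected_period_h / 2 & periods <= expected_period_h * 2
  dom <- if (any(in_band)) keep[in_band][which.max(mags[keep[in_band]])] else
    keep[which.max(mags[keep])]
  period <- 1 / freqs[dom]

  # joint least-squares fit: line + selected harmonics, on the raw series
  X <- cbind(1, t)
  for (k in keep) {
    w <- 2 * pi * freqs[k]
    X <- cbind(X, cos(w * t), sin(w * t))
  }
  beta <- qr.coef(qr(X), x)
  beta[is.na(beta)] <- 0

  harmonic <- function(tt) {
    out <- numeric(length(tt))
    for (q in seq_along(keep)) {
      w <- 2 * pi * freqs[keep[q]]
      out <- out + beta[1 + 2 * q] * cos(w * tt) + beta[2 + 2 * q] * sin(w * tt)
    }
    out
  }

  step <- period / 4800
  tt_phase <- seq(0, period - step, by = step)
  phase <- tt_phase[which.max(harmonic(tt_phase))]
  span_steps <- ceiling((t[n] - t[1]) / step)
  tt_amp <- t[1] + step * (0:span_steps)
  hh <- harmonic(tt_amp)
  amplitude <- (max(hh) - min(hh)) / 2
  if (amplitude < 1e-10 * stats::sd(x)) return(undefined)

  list(period_h = period, phase_h = phase, amplitude = amplitude)
}
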