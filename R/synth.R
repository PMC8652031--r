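#' @rdname waveform_spec
#' @format NULL
#' @export
CYCLIC_SHAPES <- c("sine", "peak", "sawtooth", "linear_trend", "damped",
                   "amplified", "contractile")

#' @rdname waveform_spec
#' @format NULL
#' @export
NONCYCLIC_SHAPES <- c("flat", "linear", "sigmoid", "exponential")

#' Synthetic waveform specification
#'
#' The benchmark simulates 11 base waveform families mimicking expression
#' patterns observed in nature. Seven are considered cyclic (`sine`,
#' `peak`, `sawtooth`, `linear_trend`, `damped`, `amplified`,
#' `contractile`) and four non-cyclic (`flat`, `linear`, `sigmoid`,
#' `exponential`).
#'
#' Canonical forms (t in hours, amplitude `a`, period `P`, phase `phi` in
#' hours, baseline `b`):
#' \describe{
#'   \item{sine}{`a*sin(2*pi*(t+phi)/P) + b`}
#'   \item{peak}{`a*exp(kappa*(cos(2*pi*(t+phi)/P)-1)) + b`, `kappa >= 2`
#'     sharpens the peak}
#'   \item{sawtooth}{periodic asymmetric ramp between `b-a` and `b+a`;
#'     `asym` in (0,1) is the rising fraction of the period}
#'   \item{linear_trend}{sine plus `slope*t`}
#'   \item{damped}{`exp(-rate*t)` envelope on a sine}
#'   \item{amplified}{`exp(+rate*t)` envelope on a sine}
#'   \item{contractile}{sine with period shrinking linearly in time,
#'     `P(t) = max(P - rate*t, P/4)`}
#'   \item{flat}{`b`}
#'   \item{linear}{`b + slope*t`}
#'   \item{sigmoid}{`a/(1+exp(-steep*(t-t_mid))) + b`}
#'   \item{exponential}{`a*exp(steep*t) + b`}
#' }
#'
#' @param shape one of the 11 shape names.
#' @param amplitude,period,phase,baseline common parameters (see above).
#' @param kappa,asym,slope,rate,steep,t_mid shape-specific parameters.
#' @return A list of class `waveform_spec` with an `is_cyclic` flag.
#' @export
waveform_spec <- function(shape, amplitude = 1, period = 24, phase = 0,
                          baseline = 0, kappa = 4, asym = 0.5, slope = 0,
                          rate = 0, steep = 0.2, t_mid = 24) {
  shape <- match.arg(shape, c(CYCLIC_SHAPES, NONCYCLIC_SHAPES))
  structure(list(shape = shape, amplitude = amplitude, period = period,
                 phase = phase, baseline = baseline, kappa = kappa,
                 asym = asym, slope = slope, rate = rate, steep = steep,
                 t_mid = t_mid, is_cyclic = shape %in% CYCLIC_SHAPES),
            class = "waveform_spec")
}

#' Evaluate a waveform at given times
#'
#' @param w a [waveform_spec].
#' @param t numeric vector of times (hours, non-negative).
#' @return Numeric vector of noiseless waveform values.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "waveform_spec"))
  a <- w$amplitude; P <- w$period; b <- w$baseline
  ang <- 2 * pi * (t + w$phase) / P
  switch(w$shape,
    sine = a * sin(ang) + b,
    peak = a * exp(w$kappa * (cos(ang) - 1)) + b,
    sawtooth = {
      u <- ((t + w$phase) %% P) / P
      rising <- u < w$asym
      v <- ifelse(rising, 2 * u / w$asym - 1,
                  1 - 2 * (u - w$asym) / (1 - w$asym))
      a * v + b
    },
    linear_trend = a * sin(ang) + w$slope * t + b,
    damped = exp(-w$rate * t) * a * sin(ang) + b,
    amplified = exp(w$rate * t) * a * sin(ang) + b,
    contractile = {
      Pt <- pmax(P - w$rate * t, P / 4)
      a * sin(2 * pi * (t + w$phase) / Pt) + b
    },
    flat = rep(b, length(t)),
    linear = b + w$slope * t,
    sigmoid = a / (1 + exp(-w$steep * (t - w$t_mid))) + b,
    exponential = a * exp(w$steep * t) + b
  )
}

#' Sampling scheme specification
#'
#' The benchmark grid crosses sampling interval (1, 2, 4 h), duration (36,
#' 48, 72, 96 h), replicates (1-3) and Gaussian noise at 10-40% of each
#' waveform's amplitude; free-form values outside the grid are allowed.
#'
#' @param interval_h sampling interval in hours.
#' @param length_h sampling duration in hours.
#' @param replicates number of replicates.
#' @param noise_frac noise standard deviation as a fraction of waveform
#'   amplitude.
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(interval_h = 2, length_h = 48, replicates = 1,
                          noise_frac = 0.1) {
  stopifnot(interval_h > 0, length_h >= 2 * interval_h,
            replicates >= 1, noise_frac >= 0)
  structure(list(interval_h = interval_h, length_h = length_h,
                 replicates = as.integer(replicates),
                 noise_frac = noise_frac),
            class = "sampling_spec")
}

# nominal time grid of a sampling spec: 0, interval, ..., length - interval
spec_times <- function(spec) {
  seq(0, spec$length_h - spec$interval_h, by = spec$interval_h)
}

# draw one random waveform_spec of a given shape; parameter ranges are the
# package's declared stand-ins for the benchmark's generator (documented in
# the methods vignette): amplitude log-uniform over a 4-fold range, phase
# uniform over the period, shape rates uniform over ranges chosen so the
# shape feature is visible but does not dwarf the oscillation by 96 h
draw_waveform <- function(shape, period = 24) {
  a <- exp(runif(1, log(1), log(4)))
  b <- runif(1, 5, 10)
  sgn <- sample(c(-1, 1), 1)
  waveform_spec(
    shape,
    amplitude = a, period = period, phase = runif(1, 0, period), baseline = b,
    kappa = runif(1, 2, 8),
    asym = runif(1, 0.1, 0.9),
    slope = if (shape %in% c("linear_trend", "linear")) {
      sgn * runif(1, 0.5, 2) * a / 96
    } else 0,
    rate = switch(shape,
                  damped = ,
                  amplified = log(2) / runif(1, 24, 96),
                  contractile = runif(1, 0.05, 0.12),
                  0),
    steep = switch(shape,
                   sigmoid = runif(1, 0.1, 0.5),
                   exponential = sgn * runif(1, 0.005, 0.02),
                   0.2),
    t_mid = runif(1, 12, 36)
  )
}

#' Simulate a synthetic benchmark dataset
#'
#' Generates `11 * n_per_shape` genes (1000 per shape in the full
#' benchmark): for each gene a random waveform of its family is drawn
#' (amplitude log-uniform over a 4-fold range, phase uniform over the
#' period, shape rates uniform over documented ranges), sampled on the
#' nominal grid, and replicate columns receive independent Gaussian noise
#' with standard deviation `noise_frac * amplitude` around the shared base
#' curve.
#'
#' @param spec a [sampling_spec].
#' @param n_per_shape genes per waveform family.
#' @param seed optional integer seed (uses, and restores, the global RNG).
#' @return A list with `data` (an [expr_ts]) and `labels` (data frame with
#'   `gene`, `shape`, `is_cyclic`).
#' @export
simulate_dataset <- function(spec, n_per_shape = 1000, seed = NULL) {
  stopifnot(inherits(spec, "sampling_spec"), n_per_shape >= 1)
  if (!is.null(seed)) return(with_local_seed(seed, simulate_dataset(spec, n_per_shape)))
  t0 <- spec_times(spec)
  nrep <- spec$replicates
  # time-major column layout: ZT_0_1, ZT_0_2, ..., ZT_2_1, ...
  times <- rep(t0, each = nrep)
  reps <- rep(seq_len(nrep), times = length(t0))
  shapes <- c(CYCLIC_SHAPES, NONCYCLIC_SHAPES)
  n_genes <- length(shapes) * n_per_shape
  vals <- matrix(NA_real_, n_genes, length(times))
  ids <- character(n_genes)
  lab_shape <- character(n_genes)
  g <- 0L
  for (shape in shapes) {
    for (i in seq_len(n_per_shape)) {
      g <- g + 1L
      w <- draw_waveform(shape)
      base <- waveform_value(w, t0)
      noise <- matrix(rnorm(length(t0) * nrep, sd = spec$noise_frac * w$amplitude),
                      nrow = nrep)
      vals[g, ] <- as.vector(noise + rep(base, each = nrep))
      ids[g] <- sprintf("%s_%04d", shape, i)
      lab_shape[g] <- shape
    }
  }
  list(
    data = expr_ts(vals, times, reps, gene_ids = ids),
    labels = data.frame(gene = ids, shape = lab_shape,
                        is_cyclic = lab_shape %in% CYCLIC_SHAPES,
                        stringsAsFactors = FALSE)
  )
}

#' The full 144-condition benchmark grid
#'
#' Crosses replicates (1, 2, 3) x intervals (1, 2, 4 h) x durations (36,
#' 48, 72, 96 h) x noise levels (10-40%), yielding 144 sampling
#' specifications, each realized by [simulate_dataset()].
#'
#' @param n_per_shape genes per waveform family per dataset.
#' @param seed integer seed; per-dataset sub-seeds are drawn from it so
#'   any single dataset can be regenerated independently.
#' @param apply optional `function(dataset, spec)` applied to each dataset
#'   in turn; when supplied, only the 144 return values are kept (use this
#'   to avoid holding all datasets in memory).
#' @return A list of 144 datasets (or of `apply` results), with the
#'   sampling grid as attribute `grid`.
#' @export
simulate_grid <- function(n_per_shape = 1000, seed = 1234, apply = NULL) {
  grid <- expand.grid(replicates = c(1, 2, 3), interval_h = c(1, 2, 4),
                      length_h = c(36, 48, 72, 96),
                      noise_frac = c(0.1, 0.2, 0.3, 0.4),
                      KEEP.OUT.ATTRS = FALSE)
  sub_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, nrow(grid)))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- sampling_spec(grid$interval_h[i], grid$length_h[i],
                          grid$replicates[i], grid$noise_frac[i])
    ds <- simulate_dataset(spec, n_per_shape, seed = sub_seeds[i])
    if (is.null(apply)) ds else apply(ds, spec)
  })
  attr(out, "grid") <- grid
  out
}

#' Mask entries at random to emulate missing data
#'
#' Per gene, `floor(frac_missing * N)` entries are masked uniformly at
#' random, never leaving fewer than 2 observed values.
#'
#' @param es an [expr_ts].
#' @param frac_missing fraction in `[0, 1)`.
#' @param seed optional integer seed.
#' @return An [expr_ts] with additional `NA` entries.
#' @export
degrade_missing <- function(es, frac_missing, seed = NULL) {
  stopifnot(inherits(es, "expr_ts"), frac_missing >= 0, frac_missing < 1)
  if (!is.null(seed)) return(with_local_seed(seed, degrade_missing(es, frac_missing)))
  if (frac_missing == 0) return(es)
  n <- ncol(es$values)
  n_mask <- min(floor(frac_missing * n), n - 2)
  if (n_mask <= 0) return(es)
  vals <- es$values
  for (g in seq_len(nrow(vals))) {
    vals[g, sample.int(n, n_mask)] <- NA_real_
  }
  expr_ts(vals, es$times, es$replicates, gene_ids = es$gene_ids)
}

#' Inject outliers into an expression set
#'
#' Each cell is independently replaced with probability `rate` by a draw
#' uniform on `[mu - 4*sigma, mu - 3*sigma]` or `[mu + 3*sigma, mu +
#' 4*sigma]` (side chosen with probability 1/2), where `mu` and `sigma`
#' are that gene's observed diurnal mean and standard deviation before
#' injection.
#'
#' @param es an [expr_ts].
#' @param rate per-cell outlier probability in `[0, 1)`.
#' @param seed optional integer seed.
#' @return An [expr_ts] with outliers injected.
#' @export
inject_outliers <- function(es, rate, seed = NULL) {
  stopifnot(inherits(es, "expr_ts"), rate >= 0, rate < 1)
  if (!is.null(seed)) return(with_local_seed(seed, inject_outliers(es, rate)))
  if (rate == 0) return(es)
  vals <- es$values
  for (g in seq_len(nrow(vals))) {
    x <- vals[g, ]
    mu <- mean(x, na.rm = TRUE)
    sigma <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sigma)) next
    hit <- which(!is.na(x) & runif(length(x)) < rate)
    if (length(hit) == 0) next
    side <- sample(c(-1, 1), length(hit), replace = TRUE)
    vals[g, hit] <- mu + side * runif(length(hit), 3 * sigma, 4 * sigma)
  }
  expr_ts(vals, es$times, es$replicates, gene_ids = es$gene_ids)
}
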