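#' Average replicate time-points
#'
#' Collapses an expression set to one column per unique time, averaging
#' across replicates and ignoring missing entries; a cell is missing only
#' when it is missing in every replicate. With a single replicate this is
#' the identity transform (up to column ordering by time).
#'
#' @param es an [expr_ts] object.
#' @return An [expr_ts] with one column per unique time, replicate label 1.
#' @export
average_replicates <- function(es) {
  stopifnot(inherits(es, "expr_ts"))
  reps <- unique(es$replicates)
  grids <- lapply(reps, function(r) sort(es$times[es$replicates == r]))
  if (length(reps) > 1) {
    ref <- grids[[1]]
    same <- vapply(grids[-1], function(g) {
      length(g) == length(ref) && all(abs(g - ref) < 1e-9)
    }, TRUE)
    if (!all(same)) {
      stop("replicates cover different time grids; cannot average")
    }
  }
  ut <- sort(unique(es$times))
  avg <- matrix(NA_real_, nrow(es$values), length(ut),
                dimnames = list(es$gene_ids, NULL))
  for (j in seq_along(ut)) {
    cols <- which(abs(es$times - ut[j]) < 1e-9)
    block <- es$values[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(block))
    s <- rowSums(block, na.rm = TRUE)
    avg[, j] <- ifelse(n_obs > 0, s / n_obs, NA_real_)
  }
  expr_ts(avg, ut, rep(1L, length(ut)), gene_ids = es$gene_ids)
}

#' Impute missing values by linear interpolation
#'
#' Interior gaps are filled by linear interpolation in time between the
#' nearest observed neighbours; leading and trailing gaps are filled by
#' constant extension of the nearest observed value (linear extrapolation
#' could manufacture trends that the embedding would read as drift).
#'
#' @param s a [cyc_series] (or numeric vector) with at least 2 observed
#'   values.
#' @return A [cyc_series] on the same grid with no missing entries;
#'   observed values are preserved exactly.
#' @export
impute_linear <- function(s) {
  s <- as_series(s)
  obs <- !is.na(s$values)
  if (sum(obs) < 2) stop("need at least 2 non-missing values to impute")
  if (all(obs)) return(s)
  filled <- stats::approx(s$times[obs], s$values[obs], xout = s$times,
                          method = "linear", rule = 2)$y
  filled[obs] <- s$values[obs]
  cyc_series(s$times, filled)
}

#' Mean-center and scale to unit variance
#'
#' Standardizes a complete series to mean 0 and sample (n-1) standard
#' deviation 1. Zero-variance input cannot be standardized: the returned
#' series is all zeros and carries `attr(, "degenerate") = TRUE`, which the
#' detection pipeline maps to persistence 0 / p = 1.
#'
#' @param s a complete [cyc_series] or numeric vector, length >= 2.
#' @return A [cyc_series] with attribute `degenerate` (logical).
#' @export
standardize <- function(s) {
  s <- as_series(s)
  if (anyNA(s$values)) stop("standardize() requires a complete series")
  if (length(s$values) < 2) stop("need at least 2 points")
  sdev <- stats::sd(s$values)
  if (!is.finite(sdev) || sdev < 1e-12) {
    out <- cyc_series(s$times, rep(0, length(s$values)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- cyc_series(s$times, (s$values - mean(s$values)) / sdev)
  attr(out, "degenerate") <- FALSE
  out
}

#' Resample a series onto a uniform time grid
#'
#' Identity when the sampling is already uniform (to 1e-9 h); otherwise the
#' observed values are linearly interpolated onto a uniform grid spanning
#' the same range at the minimum observed interval. Missing values are
#' dropped before interpolation, so the output is complete.
#'
#' @param s a [cyc_series] or numeric vector.
#' @return A [cyc_series] on a uniform grid.
#' @export
regularize_grid <- function(s) {
  s <- as_series(s)
  if (length(s$times) < 3 || is_uniform_grid(s$times)) return(s)
  dt <- min(diff(s$times))
  n_steps <- floor((max(s$times) - min(s$times)) / dt + 1e-9)
  grid <- min(s$times) + dt * (0:n_steps)
  obs <- !is.na(s$values)
  if (sum(obs) < 2) stop("need at least 2 non-missing values to regularize")
  vals <- stats::approx(s$times[obs], s$values[obs], xout = grid,
                        method = "linear", rule = 2)$y
  cyc_series(grid, vals)
}
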