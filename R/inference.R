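#' Permute the finite differences of a series
#'
#' Builds a random series with the same starting value and the same
#' multiset of step-to-step changes as the input: the first differences are
#' permuted uniformly at random and re-accumulated. Because the marginal
#' distribution of expression changes is preserved, the resulting null
#' series respect the transcription and degradation rates present in the
#' data, unlike fully randomized time-series. The first and last values
#' are always preserved (the sum of the permuted differences is invariant).
#'
#' Uses the global R random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param s a complete [cyc_series] or numeric vector, length >= 3.
#' @return An object of the same kind as the input (series or vector).
#' @export
permute_differences <- function(s) {
  numeric_in <- !inherits(s, "cyc_series")
  s <- as_series(s)
  x <- s$values
  if (anyNA(x)) stop("permute_differences() requires a complete series")
  if (length(x) < 3) stop("need at least 3 points")
  d <- diff(x)
  out <- x[1] + cumsum(c(0, d[sample.int(length(d))]))
  if (numeric_in) out else cyc_series(s$times, out)
}

#' Shared null distribution of persistence scores
#'
#' Because every gene is standardized before scoring, a single set of
#' permuted series can serve as the null for all genes. Each resample picks
#' a source gene uniformly at random (with replacement), permutes its
#' finite differences, re-standardizes, and computes the persistence score.
#' Candidates are ordered canonically (lexicographically by their values)
#' before sampling, so the null does not depend on gene order. The null is
#' built from the post-imputation series so that the smoothness assumptions
#' introduced by imputation are shared by the null model.
#'
#' @param std_values numeric matrix of standardized, complete series
#'   (genes in rows); degenerate (zero-variance) genes must be excluded.
#' @param n_resamples number of permuted series to score.
#' @param lag_set,k_neighbors,heat_scale passed to [persistence_score()].
#' @param seed integer seed for the resampling stream.
#' @return An object of class `null_dist`: list with `scores`
#'   (length `n_resamples`), `n_resamples`, `seed`.
#' @export
build_shared_null <- function(std_values, n_resamples = 1000, lag_set = 2:5,
                              k_neighbors = 6, heat_scale = "auto",
                              seed = 1234) {
  std_values <- as.matrix(std_values)
  if (nrow(std_values) == 0) {
    stop("no non-degenerate genes available to build a null distribution")
  }
  if (n_resamples < 100) {
    warning("fewer than 100 resamples gives a coarse p-value grid")
  }
  feasible <- feasible_lags(ncol(std_values), lag_set)
  if (length(feasible) == 0) {
    stop("no feasible lag for series of length ", ncol(std_values))
  }
  heat <- if (identical(heat_scale, "auto")) -1 else as.numeric(heat_scale)

  # canonical gene order: the null must be invariant to row permutations
  ord <- do.call(order, as.data.frame(std_values))
  pool <- std_values[ord, , drop = FALSE]

  scores <- with_local_seed(seed, {
    vapply(seq_len(n_resamples), function(r) {
      x <- pool[sample.int(nrow(pool), 1L), ]
      xp <- permute_differences(x)
      sdev <- stats::sd(xp)
      if (sdev < 1e-12) return(0)
      xp <- (xp - mean(xp)) / sdev
      mean(cpp_score_series(xp, as.integer(feasible),
                            as.integer(k_neighbors), heat))
    }, numeric(1))
  })
  structure(list(scores = scores, n_resamples = n_resamples, seed = seed),
            class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("<null_dist> %d resamples, median %.4g, max %.4g (seed %d)\n",
              x$n_resamples, stats::median(x$scores), max(x$scores), x$seed))
  invisible(x)
}

#' Empirical p-value against a null distribution
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_resamples)` (add-one rule), so
#' p = 0 is never emitted and the smallest attainable p-value is
#' `1 / (n_resamples + 1)`.
#'
#' @param observed numeric vector of observed persistence scores.
#' @param null a `null_dist` object or numeric vector of null scores.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_p <- function(observed, null) {
  ns <- if (inherits(null, "null_dist")) null$scores else as.numeric(null)
  if (length(ns) == 0) stop("empty null distribution")
  vapply(observed, function(o) (1 + sum(ns >= o)) / (1 + length(ns)),
         numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Monotone step-up FDR adjustment, capped at 1, order preserved.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values aligned to the input.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  n <- length(pvals)
  if (n == 1) return(pvals)
  o <- order(pvals)
  q_sorted <- pvals[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
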