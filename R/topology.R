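#' Maximum H1 persistence of a Vietoris-Rips filtration
#'
#' Grows a ball of radius `eps` around every point, connecting points at
#' most `2*eps` apart, and tracks the most persistent 1-dimensional hole
#' (loop): the H1 class maximizing `eps_death - eps_birth` on the radius
#' scale (distance threshold / 2). Field coefficients Z/2; the filtration
#' is capped at the cloud diameter, where every loop has died. A circular
#' cloud — the embedding of a rhythmic signal — earns a large value;
#' degenerate clouds (fewer than 3 points, or all coincident) return 0.
#'
#' @param pc a `point_cloud` matrix (rows are points).
#' @return A non-negative scalar.
#' @export
rips_h1_max_persistence <- function(pc) {
  if (is.null(pc)) return(0)
  pc <- as.matrix(pc)
  if (nrow(pc) < 3) return(0)
  cpp_rips_h1_max(pc)
}

#' Persistence score of a standardized series
#'
#' Sweeps the lag set, computing for each feasible lag the maximum H1
#' persistence of the 2-D Laplacian-Eigenmap reduction of the 3-D delay
#' embedding, and averages: if a signal is truly rhythmic, the state-space
#' manifold should be approximately circular on average across lags.
#'
#' @param s a complete, standardized [cyc_series] or numeric vector.
#' @param lag_set integer vector of candidate lags (samples).
#' @inheritParams laplacian_eigenmap
#' @return A list of class `persistence_score` with elements `score` (mean
#'   over feasible lags), `per_lag` (named numeric), and `lags`.
#' @export
persistence_score <- function(s, lag_set = 2:5, k_neighbors = 6,
                              heat_scale = "auto") {
  s <- as_series(s)
  x <- s$values
  if (anyNA(x)) stop("persistence_score() requires a complete series")
  feasible <- feasible_lags(length(x), lag_set)
  if (length(feasible) == 0) stop("no feasible lag for series of length ", length(x))
  if (stats::sd(x) < 1e-12) {
    per_lag <- stats::setNames(rep(0, length(feasible)), paste0("lag_", feasible))
    return(structure(list(score = 0, per_lag = per_lag, lags = feasible),
                     class = "persistence_score"))
  }
  heat <- if (identical(heat_scale, "auto")) -1 else as.numeric(heat_scale)
  per_lag <- cpp_score_series(x, as.integer(feasible), as.integer(k_neighbors),
                              heat)
  names(per_lag) <- paste0("lag_", feasible)
  structure(list(score = mean(per_lag), per_lag = per_lag, lags = feasible),
            class = "persistence_score")
}

#' @export
print.persistence_score <- function(x, ...) {
  cat(sprintf("<persistence_score> %.4g (lags %s)\n", x$score,
              paste(x$lags, collapse = ",")))
  invisible(x)
}
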