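#' Time-delay embedding of a series
#'
#' Represents a scalar series as points `(x_t, x_{t-lag}, ..., x_{t-(d-1)lag})`
#' in `d`-dimensional space. For a series of length `N` the embedding has
#' exactly `N - (d-1) * lag` points; by Takens' theorem a rhythmic signal
#' traces a closed loop in this space while drift stretches the loop into a
#' helix along additional coordinates.
#'
#' @param s a complete [cyc_series] or numeric vector.
#' @param dim embedding dimension (number of coordinates), default 3.
#' @param lag delay between coordinates, in samples.
#' @return A numeric matrix of class `point_cloud` (`N-(dim-1)*lag` rows,
#'   `dim` columns) with attribute `source_lag`.
#' @export
delay_embed <- function(s, dim = 3, lag) {
  s <- as_series(s)
  x <- s$values
  if (anyNA(x)) stop("delay_embed() requires a complete series")
  stopifnot(dim >= 2, lag >= 1)
  n <- length(x)
  need <- (dim - 1) * lag + 3
  if (n < need) {
    stop(sprintf("series too short: need >= %d points for dim %d, lag %d (got %d)",
                 need, dim, lag, n))
  }
  idx <- ((dim - 1) * lag + 1):n
  pts <- vapply(0:(dim - 1), function(j) x[idx - j * lag], numeric(length(idx)))
  pts <- matrix(pts, ncol = dim)
  structure(pts, class = c("point_cloud", class(pts)), source_lag = as.integer(lag))
}

#' Laplacian Eigenmap projection to 2-D
#'
#' Projects a point cloud onto the eigenvectors of the symmetric normalized
#' Laplacian of its heat-kernel weighted symmetric k-nearest-neighbour graph
#' (edge whenever either endpoint selects the other), keeping the
#' eigenvectors of the 2nd and 3rd smallest eigenvalues. Local circular
#' geometry — the loop of a rhythmic signal — survives the projection while
#' a drift axis is discarded. If the graph is disconnected the largest
#' component is embedded and excluded points are placed at its centroid.
#'
#' @param pc a `point_cloud` matrix (any dimension, typically 3).
#' @param k_neighbors neighbours per point (clamped to `n - 1`).
#' @param heat_scale heat-kernel bandwidth; `"auto"` uses the median
#'   pairwise distance.
#' @return A 2-column `point_cloud` (same row count, `source_lag`
#'   preserved), or `NULL` when the cloud is degenerate (all points
#'   coincide or fewer than 3 usable points).
#' @export
laplacian_eigenmap <- function(pc, k_neighbors = 6, heat_scale = "auto") {
  pc <- as.matrix(pc)
  heat <- if (identical(heat_scale, "auto")) -1 else as.numeric(heat_scale)
  out <- cpp_laplacian_eigenmap(pc, as.integer(k_neighbors), heat)
  if (is.null(out)) return(NULL)
  structure(out, class = c("point_cloud", class(out)),
            source_lag = attr(pc, "source_lag"))
}

#' Embed a series over a sweep of lags
#'
#' For each feasible lag, builds the 3-D delay embedding and reduces it to
#' 2-D with [laplacian_eigenmap()]. Lags too large for the series length
#' (fewer than 3 points would remain) are skipped with a warning.
#'
#' @inheritParams delay_embed
#' @param lag_set integer vector of candidate lags (samples).
#' @inheritParams laplacian_eigenmap
#' @return A named list of 2-D `point_cloud`s (or `NULL` for degenerate
#'   clouds), one per feasible lag.
#' @export
embed_over_lags <- function(s, lag_set = 2:5, k_neighbors = 6,
                            heat_scale = "auto") {
  s <- as_series(s)
  n <- length(s$values)
  feasible <- feasible_lags(n, lag_set)
  if (length(feasible) < length(lag_set)) {
    warning(sprintf("skipping infeasible lag(s) %s for series of length %d",
                    paste(setdiff(lag_set, feasible), collapse = ", "), n))
  }
  if (length(feasible) == 0) {
    stop("no feasible lag for series of length ", n)
  }
  out <- lapply(feasible, function(tau) {
    laplacian_eigenmap(delay_embed(s, dim = 3, lag = tau),
                       k_neighbors = k_neighbors, heat_scale = heat_scale)
  })
  names(out) <- paste0("lag_", feasible)
  out
}

# lags leaving at least 3 embedded points for a length-n series (dim 3)
feasible_lags <- function(n, lag_set) {
  lag_set <- sort(unique(as.integer(lag_set)))
  lag_set[lag_set >= 1 & (n - 2 * lag_set) >= 3]
}
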