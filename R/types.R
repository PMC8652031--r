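#' Expression time-series container
#'
#' A light S3 container for a genes-by-samples expression matrix with
#' per-sample collection times (hours) and replicate labels. Missing
#' measurements are `NA` entries of `values`.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param times numeric vector of collection times in hours, one per column.
#' @param replicates integer vector of replicate labels aligned to columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)` or `gene_1 ...` when absent.
#'
#' @return An object of class `expr_ts`: a list with elements `values`,
#'   `times`, `replicates`, `gene_ids`.
#'
#' @details Invariants enforced: column count equals `length(times)` and
#'   `length(replicates)`; gene ids unique; within each replicate the times
#'   are strictly increasing.
#' @export
expr_ts <- function(values, times, replicates = rep(1L, length(times)),
                    gene_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  times <- as.numeric(times)
  replicates <- as.integer(replicates)
  if (ncol(values) != length(times) || ncol(values) != length(replicates)) {
    stop("columns of 'values' must match length of 'times' and 'replicates'")
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(dups, collapse = ", "))
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("'times' must be finite non-negative hours")
  }
  for (r in unique(replicates)) {
    tr <- times[replicates == r]
    if (length(tr) > 1 && any(diff(tr) <= 0)) {
      stop("times must be strictly increasing within replicate ", r)
    }
  }
  rownames(values) <- gene_ids
  structure(
    list(values = values, times = times, replicates = replicates,
         gene_ids = gene_ids),
    class = "expr_ts"
  )
}

#' @export
print.expr_ts <- function(x, ...) {
  cat(sprintf(
    "<expr_ts> %d genes x %d samples | %d replicate(s) | t = %g..%g h\n",
    nrow(x$values), ncol(x$values), length(unique(x$replicates)),
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' @export
dim.expr_ts <- function(x) dim(x$values)

#' Single-gene time series
#'
#' @param times strictly increasing numeric vector of hours.
#' @param values numeric vector of the same length; `NA` marks missing
#'   observations.
#' @return An object of class `cyc_series` with elements `times`, `values`.
#' @export
cyc_series <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have equal length")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  structure(list(times = times, values = values), class = "cyc_series")
}

#' @export
print.cyc_series <- function(x, ...) {
  cat(sprintf("<cyc_series> %d points, t = %g..%g h, %d missing\n",
              length(x$times), min(x$times), max(x$times),
              sum(is.na(x$values))))
  invisible(x)
}

# accept either a cyc_series or a bare numeric vector (values on an implied
# uniform grid); returns a cyc_series
as_series <- function(s, times = NULL) {
  if (inherits(s, "cyc_series")) return(s)
  if (is.numeric(s)) {
    if (is.null(times)) times <- seq_along(s) - 1
    return(cyc_series(times, s))
  }
  stop("expected a 'cyc_series' or numeric vector")
}

# TRUE when the grid spacing is uniform to within `tol` hours
is_uniform_grid <- function(times, tol = 1e-9) {
  if (length(times) < 3) return(TRUE)
  d <- diff(times)
  max(d) - min(d) < tol
}
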