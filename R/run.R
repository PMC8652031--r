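#' Analysis settings for [cycletope()]
#'
#' @param lag_set integer lags (samples) for the delay-embedding sweep.
#' @param resamples size of the shared permutation null (10,000 recommended
#'   for production; 1,000 is adequate for exploration).
#' @param seed integer seed; the null is generated once from this seed
#'   before any gene is scored, so results are deterministic and do not
#'   depend on gene order.
#' @param period_h expected period in hours (bounds the dominant-harmonic
#'   search in [estimate_rhythm()]).
#' @param k_neighbors,heat_scale Laplacian-Eigenmap graph settings.
#' @param fdr_method only `"BH"` is supported.
#' @return A list of class `cycle_config`.
#' @export
cycle_config <- function(lag_set = 2:5, resamples = 10000, seed = 1234,
                         period_h = 24, k_neighbors = 6, heat_scale = "auto",
                         fdr_method = "BH") {
  fdr_method <- match.arg(fdr_method, "BH")
  stopifnot(length(lag_set) >= 1, all(lag_set >= 1), resamples >= 1)
  structure(list(lag_set = sort(unique(as.integer(lag_set))),
                 resamples = as.integer(resamples), seed = as.integer(seed),
                 period_h = period_h, k_neighbors = as.integer(k_neighbors),
                 heat_scale = heat_scale, fdr_method = fdr_method),
            class = "cycle_config")
}

#' Detect cycling genes in an expression time-series
#'
#' Runs the full detection pipeline: average replicates, resample uneven
#' grids, impute missing values by linear interpolation, standardize each
#' gene, score circularity of the lag-swept state-space embedding by
#' maximum H1 persistence, compare against a shared finite-difference
#' permutation null (built post-imputation, from the standardized series),
#' and adjust p-values by Benjamini-Hochberg. Period, phase and amplitude
#' are estimated from the replicate-averaged, imputed but *unscaled*
#' series, preserving amplitude in input units.
#'
#' Genes with fewer than 3 usable time points, or with no variance, are
#' reported with persistence 0, p = 1 and undefined rhythm parameters.
#'
#' @param es an [expr_ts] (see [read_expression_matrix()]).
#' @param config a [cycle_config].
#' @param verbose emit per-stage timings to stderr.
#' @return A data frame with one row per input gene, in input order:
#'   `gene`, `persistence`, `pVal`, `qVal`, `period`, `phase`,
#'   `amplitude`.
#' @export
cycletope <- function(es, config = cycle_config(), verbose = FALSE) {
  stopifnot(inherits(es, "expr_ts"), inherits(config, "cycle_config"))
  say <- function(fmt, ...) {
    if (verbose) message(sprintf("[cycletope] %s", sprintf(fmt, ...)))
  }
  t_start <- proc.time()[["elapsed"]]

  avg <- average_replicates(es)
  times <- avg$times
  n_genes <- nrow(avg$values)

  # common uniform grid shared by all genes (required for the shared null)
  if (is_uniform_grid(times)) {
    grid <- times
  } else {
    dt <- min(diff(times))
    grid <- min(times) + dt * (0:floor((max(times) - min(times)) / dt + 1e-9))
  }
  n_t <- length(grid)

  unscaled <- matrix(NA_real_, n_genes, n_t)
  standardized <- matrix(NA_real_, n_genes, n_t)
  degenerate <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    x <- avg$values[g, ]
    obs <- which(!is.na(x))
    if (length(obs) < 3) {
      degenerate[g] <- TRUE
      next
    }
    xi <- stats::approx(times[obs], x[obs], xout = grid, method = "linear",
                        rule = 2)$y
    unscaled[g, ] <- xi
    sdev <- stats::sd(xi)
    if (!is.finite(sdev) || sdev < 1e-12) {
      degenerate[g] <- TRUE
    } else {
      standardized[g, ] <- (xi - mean(xi)) / sdev
    }
  }
  n_deg <- sum(degenerate)
  if (n_deg > 0) {
    warning(n_deg, " gene(s) with <3 usable points or zero variance; ",
            "reported with persistence 0 and p = 1")
  }
  say("preprocessing: %d genes, %d grid points, %d degenerate (%.1fs)",
      n_genes, n_t, n_deg, proc.time()[["elapsed"]] - t_start)

  feasible <- feasible_lags(n_t, config$lag_set)
  if (length(feasible) == 0) {
    stop("no feasible lag in {", paste(config$lag_set, collapse = ","),
         "} for ", n_t, " time points")
  }
  if (length(feasible) < length(config$lag_set)) {
    say("using feasible lags {%s}", paste(feasible, collapse = ","))
  }
  heat <- if (identical(config$heat_scale, "auto")) -1 else
    as.numeric(config$heat_scale)

  # shared null first, from a seeded generator, so gene order is irrelevant
  t0 <- proc.time()[["elapsed"]]
  p_val <- rep(1, n_genes)
  score <- rep(0, n_genes)
  ok <- which(!degenerate)
  if (length(ok) > 0) {
    null <- build_shared_null(standardized[ok, , drop = FALSE],
                              n_resamples = config$resamples,
                              lag_set = feasible,
                              k_neighbors = config$k_neighbors,
                              heat_scale = config$heat_scale,
                              seed = config$seed)
    say("null distribution: %d resamples (%.1fs)", config$resamples,
        proc.time()[["elapsed"]] - t0)

    t0 <- proc.time()[["elapsed"]]
    for (g in ok) {
      score[g] <- mean(cpp_score_series(standardized[g, ],
                                        as.integer(feasible),
                                        config$k_neighbors, heat))
    }
    p_val[ok] <- empirical_p(score[ok], null)
    say("persistence scores (%.1fs)", proc.time()[["elapsed"]] - t0)
  }
  q_val <- bh_fdr(p_val)

  t0 <- proc.time()[["elapsed"]]
  period <- phase <- amplitude <- rep(NA_real_, n_genes)
  if (n_t >= 8) {
    for (g in ok) {
      est <- estimate_rhythm(cyc_series(grid, unscaled[g, ]),
                             expected_period_h = config$period_h)
      period[g] <- est$period_h
      phase[g] <- est$phase_h
      amplitude[g] <- est$amplitude
    }
  }
  say("rhythm parameters (%.1fs); total %.1fs",
      proc.time()[["elapsed"]] - t0, proc.time()[["elapsed"]] - t_start)

  data.frame(gene = avg$gene_ids, persistence = score, pVal = p_val,
             qVal = q_val, period = period, phase = phase,
             amplitude = amplitude, stringsAsFactors = FALSE)
}
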