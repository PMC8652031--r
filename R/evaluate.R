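#' ROC curve and AUC
#'
#' Builds the receiver operating characteristic for a score in which larger
#' values indicate cycling (use `-log10(p)` or the persistence score). A
#' point is called positive when its score is at or above the threshold;
#' thresholds run from above the maximum score through the midpoints of
#' consecutive distinct scores to below the minimum. The AUC is the
#' Mann-Whitney U statistic scaled by `n1 * n0`, counting ties as 1/2 —
#' identical to the trapezoidal integral of TPR over FPR.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = cycling), both classes present.
#' @return An object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  r <- rank(scores)  # average ranks: ties get half credit in U
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  u <- sort(unique(scores))
  midpoints <- u[-length(u)] + diff(u) / 2
  thresholds <- c(Inf, rev(midpoints), -Inf)
  tpr <- vapply(thresholds, function(th) sum(scores >= th & labels) / n1, 0)
  fpr <- vapply(thresholds, function(th) sum(scores >= th & !labels) / n0, 0)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Youden-J optimal threshold
#'
#' Returns the threshold maximizing `J = TPR - FPR`; ties are broken
#' toward higher specificity (lower FPR, then the higher threshold).
#'
#' @param rc a `roc_curve`.
#' @return A list with `threshold` and `j`.
#' @export
youden_threshold <- function(rc) {
  stopifnot(inherits(rc, "roc_curve"))
  j <- rc$tpr - rc$fpr
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[order(rc$fpr[best], -rc$thresholds[best])][1]
  }
  list(threshold = rc$thresholds[best], j = j[best])
}

#' Fraction of correct calls per waveform shape
#'
#' For each shape, the fraction of genes whose cycling call matches the
#' shape's ground-truth label (true positives for cyclic shapes, true
#' negatives for non-cyclic ones).
#'
#' @param calls logical vector of cycling calls.
#' @param shapes character vector of waveform shape labels.
#' @param truth logical ground-truth cycling labels.
#' @return A named numeric vector, one fraction in `[0, 1]` per shape.
#' @export
percent_correct_by_shape <- function(calls, shapes, truth) {
  stopifnot(length(calls) == length(shapes), length(calls) == length(truth))
  known <- c(CYCLIC_SHAPES, NONCYCLIC_SHAPES)
  if (!all(shapes %in% known)) {
    stop("unknown shape label(s): ",
         paste(unique(setdiff(shapes, known)), collapse = ", "))
  }
  correct <- as.logical(calls) == as.logical(truth)
  vapply(split(correct, factor(shapes, levels = intersect(known, shapes))),
         mean, numeric(1))
}
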