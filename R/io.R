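#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-delimited text file with genes in rows and samples
#' in columns. The first column holds gene ids; every other column header
#' encodes the collection time and replicate under the Zeitgeber-time
#' convention `ZT<hours>_<replicate>` (an underscore after `ZT` is
#' optional, e.g. `ZT_0_1` or `ZT22_3`). Cells that do not parse as numbers
#' become missing values.
#'
#' @param path path to the file.
#' @param sep field separator; `NULL` (default) picks `","` for `.csv`
#'   files and tab otherwise.
#' @param time_regex regular expression with two capture groups (time in
#'   hours, replicate label) applied to each sample header.
#' @param na_strings strings read as missing.
#' @return An [expr_ts] object; row order follows the file.
#' @export
read_expression_matrix <- function(path, sep = NULL,
                                   time_regex = "^ZT_?([0-9]+(?:\\.[0-9]+)?)_([0-9]+)$",
                                   na_strings = c("NA", "NaN", "")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 4) stop("need at least 3 sample columns, found ", ncol(raw) - 1)
  headers <- colnames(raw)[-1]
  m <- regmatches(headers, regexec(time_regex, headers))
  bad <- headers[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0) {
    stop("malformed sample header(s): ", paste(bad, collapse = ", "),
         " (expected e.g. ZT_0_1)")
  }
  times <- vapply(m, function(g) as.numeric(g[2]), 0)
  reps <- vapply(m, function(g) as.integer(g[3]), 0L)

  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals %in% na_strings] <- NA_character_
  suppressWarnings(storage.mode(vals) <- "double")

  # order columns by replicate then time so the expr_ts invariant holds even
  # for scrambled files; the (time, replicate) annotation is preserved
  ord <- order(reps, times)
  expr_ts(vals[, ord, drop = FALSE], times[ord], reps[ord], gene_ids = gene_ids)
}

#' Write per-gene results
#'
#' Writes a tab-delimited table with header
#' `gene persistence pVal qVal period phase amplitude`, one row per gene in
#' input order; undefined fields are written as `NA`.
#'
#' @param results data frame as returned by [cycletope()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  out <- data.frame(
    gene = results$gene,
    persistence = results$persistence,
    pVal = results$pVal,
    qVal = results$qVal,
    period = results$period,
    phase = results$phase,
    amplitude = results$amplitude,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path path to the TSV file.
#' @return A data frame with one row per gene.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
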