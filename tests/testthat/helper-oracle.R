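# Independent brute-force oracle for max H1 persistence of a Rips filtration.
# Enumerates the full simplicial filtration (vertices, edges, triangles) and
# reduces the complete dense boundary matrix over GF(2) -- no code shared
# with the production implementation. Only sensible for tiny clouds (n <= 8).
oracle_rips_h1_max <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  D <- as.matrix(stats::dist(pts))

  simplices <- vector("list", 0)
  filt <- numeric(0)
  sdim <- integer(0)
  add <- function(v, f) {
    simplices[[length(simplices) + 1]] <<- v
    filt[length(filt) + 1] <<- f
    sdim[length(sdim) + 1] <<- length(v) - 1L
  }
  for (i in seq_len(n)) add(i, 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) add(c(i, j), D[i, j])
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    add(c(i, j, k), max(D[i, j], D[i, k], D[j, k]))
  }

  ord <- order(filt, sdim)
  filt <- filt[ord]
  sdim <- sdim[ord]
  simplices <- simplices[ord]
  key <- vapply(simplices, paste, "", collapse = "-")
  index_of <- stats::setNames(seq_along(key), key)

  N <- length(simplices)
  B <- matrix(FALSE, N, N)
  for (j in seq_len(N)) {
    if (sdim[j] == 0) next
    v <- simplices[[j]]
    for (drop in seq_along(v)) {
      facet <- paste(v[-drop], collapse = "-")
      B[index_of[[facet]], j] <- TRUE
    }
  }

  low_of <- function(col) {
    w <- which(col)
    if (length(w) == 0) 0L else max(w)
  }
  pivot_col <- integer(N)
  best <- 0
  for (j in seq_len(N)) {
    repeat {
      l <- low_of(B[, j])
      if (l == 0L || pivot_col[l] == 0L) break
      B[, j] <- xor(B[, j], B[, pivot_col[l]])
    }
    l <- low_of(B[, j])
    if (l > 0L) {
      pivot_col[l] <- j
      if (sdim[j] == 2L) {
        best <- max(best, (filt[j] - filt[l]) / 2)
      }
    }
  }
  best
}
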