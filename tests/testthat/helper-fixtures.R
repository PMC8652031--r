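# shared fixture builders -- everything is generated in code at test time

# standardized numeric vector
std <- function(x) (x - mean(x)) / sd(x)

# sinusoid sampled every `interval` h for `length_h` h (endpoint-exclusive)
sine_series <- function(period = 24, interval = 2, length_h = 48, phase = 0,
                        amplitude = 1) {
  t <- seq(0, length_h - interval, by = interval)
  cyc_series(t, amplitude * sin(2 * pi * (t + phase) / period))
}

# small expression set: n_sine noiseless sines (random phase) + n_flat flats
# with low noise, 2-h/48-h sampling
sine_flat_eset <- function(n_sine = 20, n_flat = 20, noise_flat = 0.05,
                           seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    t0 <- seq(0, 46, 2)
    sines <- t(sapply(seq_len(n_sine), function(i) {
      sin(2 * pi * (t0 + runif(1, 0, 24)) / 24)
    }))
    flats <- t(sapply(seq_len(n_flat), function(i) {
      rnorm(length(t0), mean = 5, sd = noise_flat)
    }))
    expr_ts(rbind(sines, flats), t0,
            gene_ids = c(sprintf("sine_%02d", seq_len(n_sine)),
                         sprintf("flat_%02d", seq_len(n_flat))))
  })
}

# write an expr_ts-shaped matrix as a ZT-header TSV and return the path
write_zt_tsv <- function(mat, times, reps, gene_ids,
                         path = tempfile(fileext = ".tsv")) {
  hdr <- sprintf("ZT_%g_%d", times, reps)
  df <- data.frame(gene = gene_ids, mat, check.names = FALSE)
  colnames(df) <- c("gene", hdr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}
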