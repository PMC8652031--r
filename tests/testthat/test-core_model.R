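test_that("read_expression_matrix parses the ZT header convention", {
  t0 <- seq(0, 46, 2)
  mat <- matrix(seq_len(3 * 24), 3, 24)
  path <- write_zt_tsv(mat, t0, rep(1L, 24), c("g1", "g2", "g3"))
  es <- read_expression_matrix(path)
  expect_s3_class(es, "expr_ts")
  expect_equal(es$times, t0)
  expect_equal(unique(es$replicates), 1L)
  expect_equal(es$gene_ids, c("g1", "g2", "g3"))
  expect_equal(unname(es$values[2, 3]), mat[2, 3])
})

test_that("unparseable cells become missing and replicate headers group", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tZT_0_1\tZT_0_2\tZT_2_1\tZT_2_2",
    "g1\t1.5\tNA\t2.5\tx",
    "g2\t1\t2\t3\t4"
  ), path)
  es <- read_expression_matrix(path)
  expect_equal(es$times, c(0, 2, 0, 2))           # ordered replicate-major
  expect_equal(es$replicates, c(1L, 1L, 2L, 2L))
  # ZT_0_2 ("NA") and ZT_2_2 ("x") of g1 are missing
  expect_equal(sum(is.na(es$values["g1", ])), 2)
  expect_false(anyNA(es$values["g2", ]))
})

test_that("reader errors name the offending input", {
  t0 <- c(0, 2, 4)
  mat <- matrix(1:6, 2, 3)
  bad_hdr <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tZT_0_1\tsampleB\tZT_4_1", "g1\t1\t2\t3", "g2\t4\t5\t6"),
             bad_hdr)
  expect_error(read_expression_matrix(bad_hdr), "sampleB")

  dup <- write_zt_tsv(mat, t0, rep(1L, 3), c("g1", "g1"))
  expect_error(read_expression_matrix(dup), "duplicate.*g1")

  narrow <- write_zt_tsv(mat[, 1:2], t0[1:2], rep(1L, 2), c("g1", "g2"))
  expect_error(read_expression_matrix(narrow), "3 sample")
})

test_that("write_results round-trips fields and encodes NA", {
  res <- data.frame(gene = c("a", "b"), persistence = c(0.1234567, 0),
                    pVal = c(0.01, 1), qVal = c(0.02, 1),
                    period = c(23.456789, NA), phase = c(1.23456789, NA),
                    amplitude = c(2.3456789, NA))
  path <- tempfile(fileext = ".tsv")
  write_results(res, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_match(lines[1], "^gene\tpersistence\tpVal\tqVal\tperiod\tphase\tamplitude$")
  expect_match(lines[3], "\tNA\tNA\tNA$")
  back <- read_results(path)
  for (col in c("persistence", "pVal", "qVal", "period", "phase", "amplitude")) {
    expect_equal(signif(back[[col]], 6), signif(res[[col]], 6))
  }
})

test_that("pipeline separates noiseless sines from flats perfectly", {
  es <- sine_flat_eset(n_sine = 30, n_flat = 30, seed = 3)
  res <- cycletope(es, cycle_config(resamples = 300, seed = 7))
  is_sine <- grepl("^sine", res$gene)
  expect_equal(roc_auc(-log10(res$pVal), is_sine)$auc, 1.0)
  expect_true(max(res$pVal[is_sine]) < min(res$pVal[!is_sine]))
})

test_that("all-constant matrix gives persistence 0 and p 1", {
  t0 <- seq(0, 46, 2)
  es <- expr_ts(matrix(5, 4, 24), t0, gene_ids = paste0("g", 1:4))
  expect_warning(res <- cycletope(es, cycle_config(resamples = 200, seed = 1)),
                 "degenerate|zero variance|persistence 0")
  expect_equal(res$persistence, rep(0, 4))
  expect_equal(res$pVal, rep(1, 4))
  expect_true(all(is.na(res$period)))
})

test_that("runs are deterministic under a fixed seed", {
  es <- sine_flat_eset(n_sine = 5, n_flat = 5, seed = 4)
  cfg <- cycle_config(resamples = 150, seed = 11)
  r1 <- cycletope(es, cfg)
  r2 <- cycletope(es, cfg)
  expect_identical(r1, r2)
})

test_that("permuting gene rows permutes results identically", {
  es <- sine_flat_eset(n_sine = 6, n_flat = 6, seed = 5)
  cfg <- cycle_config(resamples = 150, seed = 11)
  r1 <- cycletope(es, cfg)
  perm <- c(7, 3, 11, 1, 9, 5, 12, 2, 10, 4, 8, 6)
  es_p <- expr_ts(es$values[perm, ], es$times, es$replicates,
                  gene_ids = es$gene_ids[perm])
  r2 <- cycletope(es_p, cfg)
  r2_back <- r2[match(r1$gene, r2$gene), ]
  rownames(r2_back) <- NULL
  expect_equal(r1, r2_back)
})

test_that("genes with <3 usable points get p 1 and undefined parameters", {
  t0 <- seq(0, 46, 2)
  good <- sin(2 * pi * t0 / 24)
  bad <- rep(NA_real_, 24)
  bad[c(1, 10)] <- c(1, 2)
  es <- expr_ts(rbind(good, bad), t0, gene_ids = c("good", "bad"))
  expect_warning(res <- cycletope(es, cycle_config(resamples = 150, seed = 2)),
                 "usable|zero variance")
  expect_equal(res$pVal[res$gene == "bad"], 1)
  expect_equal(res$persistence[res$gene == "bad"], 0)
  expect_true(is.na(res$period[res$gene == "bad"]))
  expect_lt(res$pVal[res$gene == "good"], 0.05)
})
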