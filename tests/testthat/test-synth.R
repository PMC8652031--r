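test_that("waveform families evaluate to their canonical forms", {
  expect_equal(waveform_value(waveform_spec("flat", baseline = 5), c(0, 7, 100)),
               rep(5, 3))
  expect_equal(waveform_value(waveform_spec("sine", amplitude = 1, period = 24,
                                            phase = 0, baseline = 0), 6), 1.0)
  # damped wave = envelope * sine, and the ln2/24 envelope halves every 24 h
  w <- waveform_spec("damped", amplitude = 1, period = 24, rate = log(2) / 24)
  s <- waveform_spec("sine", amplitude = 1, period = 24)
  tt <- c(3, 17, 30, 55)
  expect_equal(waveform_value(w, tt),
               exp(-w$rate * tt) * waveform_value(s, tt))
  expect_equal(exp(-w$rate * 24), 0.5)
  expect_error(waveform_spec("squarewave"), "arg")
})

test_that("simulate_dataset produces the labelled 11-family layout", {
  ds <- simulate_dataset(sampling_spec(2, 48, 1, 0.1), n_per_shape = 5, seed = 20)
  expect_equal(nrow(ds$data$values), 55)
  expect_equal(ncol(ds$data$values), 24)
  expect_equal(sum(ds$labels$is_cyclic), 35)
  expect_equal(sum(!ds$labels$is_cyclic), 20)
  expect_setequal(unique(ds$labels$shape), c(CYCLIC_SHAPES, NONCYCLIC_SHAPES))

  # determinism
  ds2 <- simulate_dataset(sampling_spec(2, 48, 1, 0.1), n_per_shape = 5, seed = 20)
  expect_identical(ds$data$values, ds2$data$values)
  expect_identical(ds$labels, ds2$labels)

  # noise_frac = 0 makes replicate columns identical
  ds0 <- simulate_dataset(sampling_spec(2, 48, 2, 0), n_per_shape = 2, seed = 21)
  v <- ds0$data$values
  r1 <- v[, ds0$data$replicates == 1]
  r2 <- v[, ds0$data$replicates == 2]
  expect_equal(r1, r2)
})

test_that("noise scales with the drawn waveform amplitude", {
  # flat genes: residual sd about the constant baseline should average to
  # noise_frac * amplitude within 10%
  nz <- 0.3
  ds <- simulate_dataset(sampling_spec(1, 96, 1, nz), n_per_shape = 300, seed = 22)
  flat <- ds$data$values[ds$labels$shape == "flat", ]
  ratio <- apply(flat, 1, sd)  # sd in units of noise sd = noise_frac * a
  # a is log-uniform on [1,4]: E[sd] = nz * E[a]
  e_a <- (4 - 1) / log(4)
  expect_lt(abs(mean(ratio) / (nz * e_a) - 1), 0.1)
})

test_that("the benchmark grid has 144 distinct conditions", {
  counts <- simulate_grid(n_per_shape = 1, seed = 23, apply = function(ds, spec) {
    c(spec$interval_h, spec$length_h, spec$replicates, spec$noise_frac,
      nrow(ds$data$values))
  })
  expect_length(counts, 144)
  grid <- attr(counts, "grid")
  expect_equal(nrow(unique(grid)), 144)
  expect_equal(sum(grid$length_h == 48), 36)
  expect_true(all(vapply(counts, function(z) z[5], 1) == 11))
})

test_that("degrade_missing masks the floor-rule count and keeps 2 observed", {
  ds <- simulate_dataset(sampling_spec(2, 48, 1, 0.1), n_per_shape = 3, seed = 24)
  expect_identical(degrade_missing(ds$data, 0), ds$data)

  half <- degrade_missing(ds$data, 0.5, seed = 25)
  expect_true(all(rowSums(is.na(half$values)) == 12))

  worst <- degrade_missing(ds$data, 0.999, seed = 26)
  expect_true(all(rowSums(!is.na(worst$values)) == 2))
})

test_that("injected outliers live in the 3-4 sigma bands", {
  ds <- simulate_dataset(sampling_spec(1, 96, 1, 0.2), n_per_shape = 20, seed = 27)
  out <- inject_outliers(ds$data, 0.05, seed = 28)
  changed <- which(out$values != ds$data$values, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  mu <- rowMeans(ds$data$values)
  sg <- apply(ds$data$values, 1, sd)
  z <- abs(out$values[changed] - mu[changed[, 1]]) / sg[changed[, 1]]
  expect_true(all(z >= 3 - 1e-9 & z <= 4 + 1e-9))
  # rate 0 is the identity
  expect_identical(inject_outliers(ds$data, 0), ds$data)
  # injected count is near binomial expectation
  n_cells <- length(ds$data$values)
  expect_lt(abs(nrow(changed) / n_cells - 0.05), 0.01)
})
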