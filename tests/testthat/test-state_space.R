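test_that("delay_embed follows the coordinate rule and point-count formula", {
  pc <- delay_embed(as.numeric(0:9), dim = 3, lag = 2)
  expect_equal(nrow(pc), 6)
  expect_equal(unname(pc[1, ]), c(4, 2, 0))
  # all points collinear for a linear series
  expect_lt(rips_h1_max_persistence(pc), 1e-12)

  const <- delay_embed(rep(1, 24), dim = 3, lag = 3)
  expect_equal(nrow(const), 18)
  expect_equal(max(dist(const)), 0)

  expect_error(delay_embed(rnorm(5), dim = 3, lag = 3), ">= 9")
})

test_that("delay_embed point count is N-(dim-1)*lag over random cases", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    d <- sample(2:4, 1)
    lag <- sample(1:3, 1)
    if (n < (d - 1) * lag + 3) next
    expect_equal(nrow(delay_embed(rnorm(n), dim = d, lag = lag)),
                 n - (d - 1) * lag)
  }
})

test_that("delay_embed commutes with affine maps of the values", {
  set.seed(11)
  x <- rnorm(20)
  a <- 2.5; b <- -1.25
  expect_equal(unclass(delay_embed(a * x + b, 3, 2)),
               unclass(a * delay_embed(x, 3, 2) + b),
               ignore_attr = TRUE)
})

test_that("laplacian_eigenmap maps a ring graph to a circle", {
  # kNN with k=2 on equally spaced circle points is exactly the cycle graph
  # C_n, whose 2nd/3rd Laplacian eigenvectors are cos/sin(2*pi*j/n) up to
  # rotation: the image must be a circle traversed in input order
  n <- 24
  th <- 2 * pi * (0:(n - 1)) / n
  pc <- cbind(cos(th), sin(th), 0)
  y <- laplacian_eigenmap(pc, k_neighbors = 2)
  expect_equal(nrow(y), n)
  ctr <- colMeans(y)
  r <- sqrt(rowSums(sweep(y, 2, ctr)^2))
  expect_lt(max(abs(r - mean(r))), 1e-9)
  # cyclic nearest-neighbour ordering preserved: angular steps all one sign
  ang <- atan2(y[, 2] - ctr[2], y[, 1] - ctr[1])
  steps <- diff(ang)
  steps <- (steps + pi) %% (2 * pi) - pi
  expect_true(all(steps > 0) || all(steps < 0))
})

test_that("laplacian_eigenmap returns NULL for coincident points", {
  pc <- matrix(1, 10, 3)
  expect_null(laplacian_eigenmap(pc))
})

test_that("eigenmap recovers the cycle from a drifting oscillation (helix)", {
  # sine + linear trend embeds as a helix; the 2-D eigenmap preserves the
  # loop better than dropping the third coordinate does (clouds normalized
  # to unit rms radius to compare shapes, not scales)
  t <- seq(0, 46, 2)
  x <- std(sin(2 * pi * t / 24) + 0.03 * t)
  nrm <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(mean(rowSums(m^2)))
  }
  for (lag in 2:5) {
    pc3 <- delay_embed(x, 3, lag)
    le <- laplacian_eigenmap(pc3)
    expect_gt(rips_h1_max_persistence(nrm(le)),
              rips_h1_max_persistence(nrm(pc3[, 1:2])))
  }
})

test_that("sinusoid beats its own i.i.d. shuffles at every default lag", {
  t <- seq(0, 46, 2)
  x <- std(sin(2 * pi * t / 24))
  obs_min <- min(persistence_score(x)$per_lag)
  set.seed(12)
  shuf_max <- max(vapply(1:20, function(i) {
    max(persistence_score(std(sample(x)))$per_lag)
  }, numeric(1)))
  expect_gt(obs_min, shuf_max)
})

test_that("embed_over_lags yields one cloud per feasible lag", {
  x <- rnorm(24)
  clouds <- embed_over_lags(x, lag_set = 2:5)
  expect_named(clouds, paste0("lag_", 2:5))
  expect_equal(vapply(clouds, nrow, 1L, USE.NAMES = FALSE), c(20, 18, 16, 14))

  expect_error(suppressWarnings(embed_over_lags(x, lag_set = 50)),
               "no feasible lag")
  expect_warning(res <- embed_over_lags(x, lag_set = c(2, 50)), "infeasible")
  expect_length(res, 1)

  const_clouds <- embed_over_lags(rep(2, 24), lag_set = 2:3)
  expect_true(all(vapply(const_clouds, is.null, TRUE)))
})
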