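test_that("KSG MI is zero for independent normals (3 SE over 50 seeds)", {
  n <- 1000L
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    as.numeric(ksg_mutual_information(rnorm(n), rnorm(n)))
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("KSG MI matches the Gaussian closed form at rho = 0.9", {
  rho <- 0.9
  set.seed(42)
  xy <- rmvn(2000, matrix(c(1, rho, rho, 1), 2))
  est <- as.numeric(ksg_mutual_information(xy[, 1], xy[, 2]))
  expect_lt(abs(est - gauss_mi_true(rho)), 0.05)
  # freeze the oracle itself: -0.5 * log(1 - 0.81)
  expect_equal(gauss_mi_true(0.9), 0.8303661, tolerance = 1e-6)
})

test_that("KSG MI and CMI match a plain-R brute-force implementation", {
  set.seed(7)
  n <- 150L
  x <- matrix(rnorm(n * 2), n)
  y <- matrix(0.5 * x[, 1] + rnorm(n), n)
  z <- matrix(0.3 * x[, 2] + rnorm(n), n)
  cfg <- ncfg_exact(T = 5L)
  expect_equal(as.numeric(ksg_mutual_information(x, y, cfg)),
               ksg_mi_bruteforce(x, y, T = 5L), tolerance = 1e-12)
  expect_equal(as.numeric(ksg_conditional_mutual_information(x, y, z, cfg)),
               ksg_cmi_bruteforce(x, y, z, T = 5L), tolerance = 1e-12)
  # and with a Theiler window
  cfg2 <- ncfg_exact(T = 5L, theiler = 3L)
  expect_equal(as.numeric(ksg_conditional_mutual_information(x, y, z, cfg2)),
               ksg_cmi_bruteforce(x, y, z, T = 5L, theiler = 3L),
               tolerance = 1e-12)
})

test_that("CMI with an empty conditioning block is bit-identical to MI", {
  set.seed(11)
  x <- rnorm(300); y <- 0.4 * x + rnorm(300)
  cfg <- neighbor_config(jitter_seed = 3L)
  mi <- as.numeric(ksg_mutual_information(x, y, cfg))
  expect_identical(
    as.numeric(ksg_conditional_mutual_information(x, y, NULL, cfg)), mi)
  expect_identical(
    as.numeric(ksg_conditional_mutual_information(
      x, y, matrix(numeric(0), 300, 0), cfg)), mi)
})

test_that("Markov chain X -> Z -> Y: CMI vanishes while MI stays large", {
  # standardized chain with correlation 0.9 per link
  n <- 2000L
  cmis <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(n)
    z <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
    y <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
    c(as.numeric(ksg_conditional_mutual_information(x, y, z)),
      as.numeric(ksg_mutual_information(x, y)))
  }, numeric(2))
  se <- sd(cmis[1, ]) / sqrt(ncol(cmis))
  expect_lt(abs(mean(cmis[1, ])), 3 * se + 1e-12)
  expect_gt(mean(cmis[2, ]), 0.2)
})

test_that("KSG CMI matches the Gaussian log-determinant closed form", {
  set.seed(5)
  Sigma <- random_cov(3)
  xyz <- rmvn(2000, Sigma)
  est <- as.numeric(ksg_conditional_mutual_information(
    xyz[, 1], xyz[, 2], xyz[, 3]))
  expect_lt(abs(est - gauss_cmi_true(Sigma, 1, 2, 3)), 0.05)
})

test_that("tie-breaking jitter is deterministic in the seed", {
  set.seed(1)
  x <- sample(1:20, 400, replace = TRUE)   # heavy ties
  y <- sample(1:20, 400, replace = TRUE)
  a <- as.numeric(ksg_mutual_information(x, y, neighbor_config(jitter_seed = 9L)))
  b <- as.numeric(ksg_mutual_information(x, y, neighbor_config(jitter_seed = 9L)))
  expect_identical(a, b)
  expect_true(is.finite(a))
})

test_that("estimator input validation", {
  expect_error(ksg_mutual_information(rnorm(10), rnorm(11)),
               "same number of realizations")
  expect_error(ksg_mutual_information(rnorm(5), rnorm(5),
                                      neighbor_config(T = 10L)),
               "infeasible")
  expect_error(ksg_conditional_mutual_information(rnorm(20), rnorm(20),
                                                  rnorm(19)),
               "same number of realizations")
})
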