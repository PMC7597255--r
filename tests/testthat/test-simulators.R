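test_that("simulate_henon returns bounded, seed-deterministic trajectories", {
  a <- simulate_henon(512L, Q = 0.6, seed = 7L)
  b <- simulate_henon(512L, Q = 0.6, seed = 7L)
  expect_identical(a, b)
  expect_equal(dim(a), c(512L, 5L))
  expect_equal(colnames(a), paste0("Y", 1:5))
  expect_true(all(is.finite(a)))
  expect_lt(max(abs(a)), 1e4)
  expect_false(identical(a, simulate_henon(512L, Q = 0.6, seed = 8L)))
})

test_that("simulate_henon follows the stated recursion given the state", {
  # drive the map from an explicit two-row history with no burn-in and
  # replay the recursion by hand
  init <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.05,
                   0.15, 0.25, 0.35, 0.45, 0.12), 2, 5, byrow = TRUE)
  Q <- 0.6
  n <- 50L
  sim <- simulate_henon(n, Q = Q, transient = 0L, init = init)
  y <- rbind(init, matrix(0, n, 5))
  for (t in 3:(n + 2)) {
    for (l in c(1, 5))
      y[t, l] <- 1.4 - y[t - 1, l]^2 + 0.3 * y[t - 2, l]
    for (l in 2:4)
      y[t, l] <- 1.4 - (0.5 * Q * (y[t - 1, l - 1] + y[t - 1, l + 1]) +
                          (1 - Q) * y[t - 1, l])^2 + 0.3 * y[t - 2, l]
  }
  expect_equal(unname(sim), y[-(1:2), ], tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("outer Henon nodes are autonomous (identical for any Q)", {
  a <- simulate_henon(256L, Q = 0.2, seed = 3L)
  b <- simulate_henon(256L, Q = 0.8, seed = 3L)
  expect_identical(a[, c(1, 5)], b[, c(1, 5)])
  expect_false(identical(a[, 3], b[, 3]))
})

test_that("simulate_ar follows the stated recursion given the innovations", {
  n <- 40L; burn <- 5L
  set.seed(99)
  w <- matrix(rnorm((n + burn) * 5), n + burn, 5)
  sim <- simulate_ar(n, transient = burn, innovations = w)
  p1 <- 0.95 * sqrt(2); p2 <- -0.9125; cc <- 0.25 * sqrt(2)
  y <- matrix(0, n + burn + 3L, 5)
  for (t in 4:(n + burn + 3L)) {
    e <- w[t - 3L, ]
    y[t, 1] <- p1 * y[t - 1, 1] + p2 * y[t - 2, 1] + e[1]
    y[t, 2] <- 0.5 * y[t - 2, 1]^2 + e[2]
    y[t, 3] <- -0.4 * y[t - 3, 1] + 0.4 * y[t - 1, 2] + e[3]
    y[t, 4] <- -0.5 * y[t - 1, 1]^2 + cc * y[t - 1, 4] + e[4]
    y[t, 5] <- -cc * y[t - 1, 4] + cc * y[t - 2, 5] + e[5]
  }
  expect_equal(unname(sim), unname(tail(y, n)), tolerance = 1e-12)
})

test_that("simulate_ar is seed-deterministic and stationary-scaled", {
  a <- simulate_ar(512L, seed = 5L)
  expect_identical(a, simulate_ar(512L, seed = 5L))
  expect_equal(dim(a), c(512L, 5L))
  expect_true(all(is.finite(a)))
  expect_error(simulate_ar(100L, innovations = matrix(0, 10, 5)),
               "innovations")
})

test_that("mix_instantaneous implements (1-alpha) I + alpha (J - I)", {
  d <- matrix(as.numeric(1:12), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  alpha <- 0.2
  mixed <- mix_instantaneous(d, alpha)
  A <- (1 - alpha) * diag(3) + alpha * (matrix(1, 3, 3) - diag(3))
  expect_equal(unname(mixed), unname(d %*% t(A)), tolerance = 1e-14)
  expect_identical(mix_instantaneous(d, 0), d)     # alpha = 0 identity
  expect_error(mix_instantaneous(d, 0.31), "alpha")
  expect_error(mix_instantaneous(d, -0.1), "alpha")
})

test_that("ground truths carry the documented positive edges", {
  gh <- ground_truth("henon")
  ga <- ground_truth("ar")
  expect_equal(dim(gh), c(5L, 5L))
  expect_equal(sum(gh), 6)
  expect_equal(sum(ga), 5)
  henon_edges <- rbind(c(1, 2), c(3, 2), c(2, 3), c(4, 3), c(3, 4), c(5, 4))
  ar_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(4, 5))
  expect_true(all(gh[henon_edges] == 1))
  expect_true(all(ga[ar_edges] == 1))
  expect_true(all(diag(gh) == 0) && all(diag(ga) == 0))
  expect_error(ground_truth("other"))
})
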