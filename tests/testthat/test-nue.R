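test_that("build_candidate_set enumerates process-major, lag-minor", {
  cs <- build_candidate_set(3L, m = 2L, d = 2L)
  expect_s3_class(cs, "candidate_set")
  expect_equal(cs$process, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(cs$lag, c(2L, 4L, 2L, 4L, 2L, 4L))
  expect_error(build_candidate_set(1L), "L")
})

test_that("standardize uses the population variance and validates input", {
  set.seed(1)
  d <- cbind(10 + 3 * rnorm(50), rnorm(50))
  s <- standardize(d)
  expect_equal(colMeans(s), c(0, 0), tolerance = 1e-12)
  expect_equal(colMeans(s^2), c(1, 1), tolerance = 1e-12)
  expect_error(standardize(cbind(rnorm(10), rep(1, 10))), "zero variance")
})

test_that("run_nue recovers the true driving lag of a linear system first", {
  set.seed(21)
  n <- 600L
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  y <- c(0, 0, 0.9 * x[1:(n - 2)]) + 0.3 * rnorm(n)
  sel <- run_nue(cbind(x, y), 2L, nue_config(lambda = 0.5, gamma = 0.01,
                                             seed = 3L))
  expect_equal(sel$trace$process[1], 1L)
  expect_equal(sel$trace$lag[1], 2L)
  expect_true(all(c("k", "process", "lag", "criterion", "msr", "aic",
                    "threshold", "accepted") %in% names(sel$trace)))
  expect_equal(sel$n_iterations, nrow(sel$trace))
})

test_that("run_nue is deterministic given the config seed", {
  set.seed(30)
  d <- simulate_ar(256L, seed = 9L)
  a <- run_nue(d, 2L, nue_config(seed = 17L))
  b <- run_nue(d, 2L, nue_config(seed = 17L))
  expect_identical(a$selected, b$selected)
  expect_identical(a$trace, b$trace)
})

test_that("msr variant: large gamma stops after one accepted candidate", {
  d <- simulate_ar(256L, seed = 4L)
  sel <- run_nue(d, 3L, nue_config(lambda = 1, gamma = 10, seed = 2L))
  expect_equal(nrow(sel$selected), 1L)
  expect_equal(sel$termination_reason, "msr_no_improvement")
  expect_equal(sel$n_iterations, 2L)   # one accepted + the rejected test
  expect_true(sel$trace$accepted[1])
  expect_false(sel$trace$accepted[2])
})

test_that("msr lambda=0 ranking coincides with the bootstrap CMI ranking", {
  d <- standardize(simulate_ar(300L, seed = 6L))
  s0 <- run_nue(d, 3L, nue_config(variant = "msr", lambda = 0, gamma = 1,
                                  seed = 5L))
  sb <- run_nue(d, 3L, nue_config(variant = "bootstrap", seed = 5L))
  k <- min(nrow(s0$trace), nrow(sb$trace))
  expect_gte(k, 1L)
  expect_equal(s0$trace$process[1:k], sb$trace$process[1:k])
  expect_equal(s0$trace$lag[1:k], sb$trace$lag[1:k])
  expect_equal(s0$trace$criterion[1:k], sb$trace$criterion[1:k],
               tolerance = 1e-12)
})

test_that("bootstrap termination statistics behave like a shuffle null", {
  d <- standardize(simulate_ar(300L, seed = 8L))
  cfg <- nue_config(variant = "bootstrap", seed = 8L)
  winner <- data.frame(process = 1L, lag = 3L)
  thr95 <- bootstrap_threshold(d, 3L, winner, cfg = cfg)
  cfg50 <- cfg; cfg50$level <- 0.5
  thr50 <- bootstrap_threshold(d, 3L, winner, cfg = cfg50)
  expect_gt(thr95, thr50)           # quantiles are monotone in the level
  expect_identical(thr95, bootstrap_threshold(d, 3L, winner, cfg = cfg))
  # the null of a shuffled pair sits near zero, far below the true CMI
  obs <- as.numeric(ksg_mutual_information(
    nuecte:::lag_block(d, winner, 5L),
    nuecte:::lag_block(d, data.frame(process = 3L, lag = 0L), 5L),
    cfg$neighbor))
  expect_gt(obs, thr95)
})

test_that("select_candidate_* agree with run_nue's first iteration", {
  d <- standardize(simulate_ar(300L, seed = 12L))
  cfg <- nue_config(lambda = 0.5, seed = 12L)
  first <- run_nue(d, 2L, cfg)$trace[1, ]
  pick <- select_candidate_msr(d, 2L, cfg = cfg)
  expect_equal(pick$winner$process, first$process)
  expect_equal(pick$winner$lag, first$lag)
  cmi_pick <- select_candidate_cmi(d, 2L, cfg = cfg)
  la_pick <- select_candidate_la(d, 2L, cfg = cfg)
  # with an empty selection the LA criterion reduces to plain MI = CMI rank
  expect_equal(la_pick$winner, cmi_pick$winner)
})

test_that("aic variant terminates and records AIC values in the trace", {
  d <- simulate_ar(300L, seed = 14L)
  sel <- run_nue(d, 2L, nue_config(variant = "aic", seed = 14L))
  expect_true(all(is.finite(sel$trace$aic)))
  expect_true(sel$trace$accepted[1])   # first winner is auto-accepted
  expect_true(sel$termination_reason %in%
                c("aic_no_improvement", "candidates_exhausted"))
  # the two acceptance directions are both available and differ in general
  sel2 <- run_nue(d, 2L, nue_config(variant = "aic", seed = 14L,
                                    aic_accept = "decrease"))
  expect_true(is.data.frame(sel2$trace))
})

test_that("nue_config validates its arguments", {
  expect_error(nue_config(lambda = 1.5), "lambda")
  expect_error(nue_config(gamma = -0.1), "gamma")
  expect_error(nue_config(level = 0), "level")
  expect_error(nue_config(variant = "nope"))
  expect_error(run_nue(matrix(rnorm(30), ncol = 1), 1L), "two channels")
  expect_error(run_nue(matrix(rnorm(60), ncol = 2), 3L), "out of range")
  expect_error(run_nue(matrix(rnorm(20), ncol = 2), 1L), "too short")
})
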