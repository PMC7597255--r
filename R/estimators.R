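#' Neighbor-search configuration
#'
#' Settings shared by all nearest-neighbor computations: the KSG mutual
#' information / conditional mutual information estimators and the
#' nearest-neighbor regression behind the MSR criterion.
#'
#' The KSG estimators always use the max-norm in the joint search space (the
#' canonical KSG construction); nearest-neighbor prediction always uses the
#' Euclidean metric. Exact ties in neighbor distances are broken by adding a
#' deterministic, seeded uniform jitter of amplitude
#' `jitter_amp * sd(column)` to every column before any search; degenerate
#' (duplicated) coordinates otherwise break the strict-inequality range
#' counts of the KSG estimator.
#'
#' @param T positive integer, number of nearest neighbors.
#' @param theiler non-negative integer Theiler window: samples `j` with
#'   `|i - j| <= theiler` are excluded from the neighborhood of sample `i`,
#'   guarding against serial-correlation bias. Default 0 (only the point
#'   itself is excluded).
#' @param exclude_self logical; if `TRUE` (default) a point is never its own
#'   neighbor in `nn_predict()`, i.e. prediction is leave-one-out.
#' @param jitter_seed integer seed for the tie-breaking jitter.
#' @param jitter_amp jitter amplitude relative to each column's standard
#'   deviation; set to 0 to disable.
#' @return A list of class `neighbor_config`.
#' @export
neighbor_config <- function(T = 10L, theiler = 0L, exclude_self = TRUE,
                            jitter_seed = 0L, jitter_amp = 1e-10) {
  stop_if_not_scalar_count(T, "T", min = 1)
  stop_if_not_scalar_count(theiler, "theiler", min = 0)
  structure(list(T = as.integer(T), theiler = as.integer(theiler),
                 exclude_self = isTRUE(exclude_self),
                 jitter_seed = as.integer(jitter_seed),
                 jitter_amp = as.numeric(jitter_amp)),
            class = "neighbor_config")
}

# Seeded tie-breaking jitter; draws are column-major so the noise applied to
# a leading block of columns does not depend on how many columns follow it.
apply_jitter <- function(m, cfg) {
  if (cfg$jitter_amp <= 0 || ncol(m) == 0 || nrow(m) == 0) return(m)
  sds <- apply(m, 2, sd)
  noise <- with_seed(cfg$jitter_seed,
                     matrix(runif(length(m), -1, 1), nrow = nrow(m)))
  m + sweep(noise, 2, cfg$jitter_amp * sds, "*")
}

check_neighbors_feasible <- function(n, cfg) {
  avail <- n - 1 - 2 * cfg$theiler
  if (cfg$T >= n || cfg$T > avail)
    stop(sprintf(
      "T = %d neighbors infeasible: only %d candidate points remain after excluding self and the Theiler window",
      cfg$T, max(avail, 0)))
}

info_estimate <- function(value, estimator, cfg) {
  structure(value, estimator = estimator, T = cfg$T,
            class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("<%s> %.6f nats (T = %d)\n", attr(x, "estimator"),
              as.numeric(x), attr(x, "T")))
  if (isTRUE(attr(x, "no_source_lag")))
    cat("  flag: no source lag selected; CTE fixed at 0\n")
  invisible(x)
}

# numeric cores used by the embedding loop (no S3 wrapping, minimal checks)

ksg_mi_num <- function(x, y, cfg) {
  joint <- apply_jitter(cbind(x, y), cfg)
  ksg_mi_cpp(joint, ncol(x), cfg$T, cfg$theiler)
}

ksg_cmi_num <- function(x, y, z, cfg) {
  if (is.null(z) || ncol(z) == 0) return(ksg_mi_num(x, y, cfg))
  joint <- apply_jitter(cbind(x, y, z), cfg)
  ksg_cmi_cpp(joint, ncol(x), ncol(y), cfg$T, cfg$theiler)
}

knn_msr <- function(u, y, cfg) {
  pred <- knn_regress_cpp(apply_jitter(u, cfg), y, cfg$T,
                          cfg$exclude_self, cfg$theiler)
  mean((y - pred)^2)
}

#' KSG mutual information
#'
#' Kraskov-Stoegbauer-Grassberger estimator (algorithm 1) of the mutual
#' information I(X;Y) in nats from continuous samples: for each point the
#' distance to its T-th nearest neighbor in the joint (X,Y) space under the
#' max-norm sets a search radius, points strictly inside the radius are
#' counted in each marginal space, and the estimate combines the counts
#' through digamma functions. The estimate is asymptotically unbiased but
#' can be slightly negative at finite N; callers must not assume
#' non-negativity.
#'
#' @param x,y numeric vectors or matrices with the same number of rows
#'   (realizations in rows, variables in columns).
#' @param cfg a [neighbor_config()].
#' @return A scalar of class `info_estimate` (nats).
#' @export
ksg_mutual_information <- function(x, y, cfg = neighbor_config()) {
  x <- as_block(x); y <- as_block(y)
  if (nrow(x) != nrow(y))
    stop("x and y must have the same number of realizations")
  if (ncol(x) < 1 || ncol(y) < 1)
    stop("x and y must each have at least one column")
  check_neighbors_feasible(nrow(x), cfg)
  info_estimate(ksg_mi_num(x, y, cfg), "ksg_mi", cfg)
}

#' KSG conditional mutual information
#'
#' Estimates I(X;Y|Z) in nats with the KSG construction: the T-th neighbor
#' radius is found in the full (X,Y,Z) joint space and strict range counts
#' in the (X,Z), (Y,Z) and Z subspaces enter a four-term digamma formula.
#' An empty conditioning block (`z = NULL` or zero columns) is legal and
#' returns exactly `ksg_mutual_information(x, y, cfg)`.
#'
#' @inheritParams ksg_mutual_information
#' @param z conditioning block: numeric vector/matrix with the same number
#'   of rows, or `NULL` / zero-column matrix for no conditioning.
#' @return A scalar of class `info_estimate` (nats).
#' @export
ksg_conditional_mutual_information <- function(x, y, z = NULL,
                                               cfg = neighbor_config()) {
  x <- as_block(x); y <- as_block(y); z <- as_block(z, n = nrow(x))
  if (nrow(x) != nrow(y) || nrow(z) != nrow(x))
    stop("x, y and z must have the same number of realizations")
  if (ncol(x) < 1 || ncol(y) < 1)
    stop("x and y must each have at least one column")
  check_neighbors_feasible(nrow(x), cfg)
  info_estimate(ksg_cmi_num(x, y, z, cfg), "ksg_cmi", cfg)
}

#' Nearest-neighbor nonlinear prediction
#'
#' Predicts each realization of `y` as the average of the `y`-values whose
#' row indices are the `T` nearest neighbors (Euclidean metric) of the
#' corresponding row of the embedding matrix `u`. With
#' `cfg$exclude_self = TRUE` the prediction is leave-one-out, so the mean
#' squared residual (MSR) honestly measures out-of-sample predictability:
#' it is near 0 when `u` determines `y` and near `var(y)` when the
#' neighbors are uninformative.
#'
#' @param u numeric matrix (N rows, at least one column) of predictor
#'   realizations.
#' @param y numeric vector of length N, the prediction target.
#' @param cfg a [neighbor_config()].
#' @return A list of class `nn_prediction` with elements `predictions`,
#'   `residuals` (`y - predictions`) and `msr` (mean of squared residuals).
#' @export
nn_predict <- function(u, y, cfg = neighbor_config()) {
  if (is.null(u) || (is.matrix(u) && ncol(u) == 0))
    stop("prediction requires at least one predictor column")
  u <- as_block(u)
  y <- as.numeric(y)
  if (nrow(u) != length(y))
    stop("u and y must have the same number of realizations")
  check_neighbors_feasible(nrow(u), cfg)
  pred <- knn_regress_cpp(apply_jitter(u, cfg), y, cfg$T,
                          cfg$exclude_self, cfg$theiler)
  res <- y - pred
  structure(list(predictions = pred, residuals = res, msr = mean(res^2)),
            class = "nn_prediction")
}

#' @export
print.nn_prediction <- function(x, ...) {
  cat(sprintf("<nn_prediction> N = %d, MSR = %.6f\n",
              length(x$predictions), x$msr))
  invisible(x)
}

#' Kernel-density (Nadaraya-Watson) regression with model complexity
#'
#' Gaussian-kernel regression of `y` on the rows of `u` using the
#' Mahalanobis distance (coordinates whitened by the sample covariance of
#' `u`) and the Gaussian reference bandwidth
#' `h = (4/(k+2))^(1/(k+4)) * N^(-1/(k+4))`. Alongside the fitted values it
#' returns the effective number of parameters
#' `p = sum_i K(u_i,u_i) / sum_j K(u_i,u_j)`, which ranges from 1 (all
#' points coincide) to N (all points isolated) and is the complexity term
#' of [aic_score()].
#'
#' A near-singular covariance is ridge-regularized by `1e-8 * trace/k` on
#' the diagonal; if it remains singular an error is raised.
#'
#' @inheritParams nn_predict
#' @return A list with `predictions`, `complexity_p` and `bandwidth`.
#' @export
kde_predict <- function(u, y) {
  if (is.null(u) || (is.matrix(u) && ncol(u) == 0))
    stop("prediction requires at least one predictor column")
  u <- as_block(u)
  y <- as.numeric(y)
  n <- nrow(u); k <- ncol(u)
  if (n != length(y))
    stop("u and y must have the same number of realizations")
  h <- (4 / (k + 2))^(1 / (k + 4)) * n^(-1 / (k + 4))
  if (n == 1)
    return(list(predictions = y, complexity_p = 1, bandwidth = h))
  C <- cov(u)
  tr <- sum(diag(C))
  if (tr < .Machine$double.xmin) {
    # all rows identical: every Mahalanobis distance is 0, kernel matrix all 1
    K <- matrix(1, n, n)
  } else {
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch) || rcond(C) < 1e-12) {
      C <- C + diag(1e-8 * tr / k, k)
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(ch))
        stop("covariance of u is singular even after regularization")
    }
    w <- u %*% backsolve(ch, diag(k))       # whitened coordinates
    s <- rowSums(w^2)
    D2 <- outer(s, s, "+") - 2 * tcrossprod(w)
    D2[D2 < 0] <- 0
    diag(D2) <- 0
    K <- exp(-D2 / (2 * h^2))
  }
  denom <- rowSums(K)
  list(predictions = as.vector(K %*% y) / denom,
       complexity_p = sum(1 / denom),
       bandwidth = h)
}

#' Akaike information criterion of the KDE regression
#'
#' `AIC = N * log(mean squared residual) + 2 * p`, with residuals and
#' effective parameter count `p` taken from [kde_predict()] (natural
#' logarithm). A perfect fit (zero mean squared residual) yields `-Inf`
#' with attribute `perfect_fit = TRUE`.
#'
#' @inheritParams kde_predict
#' @return A numeric scalar; `-Inf` flags a degenerate perfect fit.
#' @export
aic_score <- function(u, y) {
  fit <- kde_predict(u, y)
  y <- as.numeric(y)
  mse <- mean((y - fit$predictions)^2)
  if (mse == 0)
    return(structure(-Inf, perfect_fit = TRUE,
                     complexity_p = fit$complexity_p))
  structure(length(y) * log(mse) + 2 * fit$complexity_p,
            perfect_fit = FALSE, complexity_p = fit$complexity_p)
}

#' Conditional transfer entropy on a selected embedding
#'
#' Evaluates CTE(source -> target | rest) = I(Y_n ; selected source lags |
#' remaining selected lags) on the non-uniformly selected embedding of a
#' target channel: the selected lags of `source` form the source block and
#' every other selected lag (the target's own past and other channels'
#' pasts) forms the conditioning block. If the embedding contains no lag of
#' the source process the transfer entropy is exactly 0 and the result
#' carries the attribute `no_source_lag = TRUE` -- the significance rule
#' used throughout the benchmark harness.
#'
#' @param data numeric matrix (time in rows, channels in columns) on the
#'   same scale the selection was computed on (normally standardized).
#' @param selection a [run_nue()] result for `target`, or a data frame with
#'   columns `process` and `lag`.
#' @param source,target channel indices (1-based); must differ.
#' @param cfg optional [neighbor_config()]; defaults to the configuration
#'   stored in `selection`.
#' @return A scalar of class `info_estimate` (nats).
#' @export
estimate_cte <- function(data, selection, source, target, cfg = NULL) {
  data <- as_block(data)
  if (source == target)
    stop("source and target must be different channels")
  if (inherits(selection, "nue_selection")) {
    if (!is.null(selection$target) && selection$target != target)
      stop(sprintf("selection was computed for target %d, not %d",
                   selection$target, target))
    sel <- selection$selected
    lag0 <- selection$cfg$d * selection$cfg$m
    cfg <- cfg %||% selection$neighbor
  } else {
    sel <- as.data.frame(selection)
    lag0 <- if (nrow(sel) == 0) 0L else max(sel$lag)
    cfg <- cfg %||% neighbor_config()
  }
  if (nrow(sel) == 0 || !any(sel$process == source)) {
    out <- info_estimate(0, "ksg_cte", cfg)
    attr(out, "no_source_lag") <- TRUE
    return(out)
  }
  yv <- lag_block(data, data.frame(process = target, lag = 0), lag0)
  xb <- lag_block(data, sel[sel$process == source, , drop = FALSE], lag0)
  zb <- lag_block(data, sel[sel$process != source, , drop = FALSE], lag0)
  check_neighbors_feasible(nrow(yv), cfg)
  out <- info_estimate(ksg_cmi_num(xb, yv, zb, cfg), "ksg_cte", cfg)
  attr(out, "no_source_lag") <- FALSE
  out
}

# Time-aligned realization block for (process, lag) pairs. All blocks drop
# the first `lag0` rows so every lagged column shares the same time support.
lag_block <- function(data, vars, lag0) {
  n <- nrow(data)
  if (lag0 >= n) stop("maximum lag exceeds the data length")
  idx <- seq.int(lag0 + 1L, n)
  if (nrow(vars) == 0)
    return(matrix(numeric(0), nrow = length(idx), ncol = 0))
  out <- vapply(seq_len(nrow(vars)),
                function(i) data[idx - vars$lag[i], vars$process[i]],
                numeric(length(idx)))
  matrix(out, nrow = length(idx))
}
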