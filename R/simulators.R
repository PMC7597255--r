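#' Coupled Henon-map benchmark system
#'
#' Simulates five unidirectionally-coupled Henon maps. The outer nodes
#' evolve autonomously,
#' `Y[l,n] = 1.4 - Y[l,n-1]^2 + 0.3 * Y[l,n-2]` for `l = 1, 5`, while the
#' inner nodes `l = 2, 3, 4` are driven by both neighbors through a convex
#' combination inside the quadratic term:
#' `Y[l,n] = 1.4 - (0.5 * Q * (Y[l-1,n-1] + Y[l+1,n-1]) +
#' (1 - Q) * Y[l,n-1])^2 + 0.3 * Y[l,n-2]`.
#' The coupling strength `Q` therefore induces directed dependencies
#' `l-1 -> l` and `l+1 -> l` for the inner nodes; see [ground_truth()].
#'
#' Initial states are drawn uniformly on `[0, 0.5]`; a burn-in of
#' `transient` samples is discarded. Henon maps can escape to infinity for
#' unlucky initial conditions, so trajectories exceeding `1e4` in absolute
#' value are redrawn (up to `max_retries`; the number of redraws is
#' recorded in the `"retries"` attribute).
#'
#' @param N output length (>= 32).
#' @param Q coupling strength in `[0, 1]` (the benchmark sweeps 0.2-0.8).
#' @param transient burn-in samples discarded before recording.
#' @param seed integer seed for the initial conditions (optional).
#' @param init optional 2 x 5 matrix of fixed initial states (row 1 =
#'   state at time n-2, row 2 = state at n-1); disables the retry logic.
#' @param max_retries maximum number of initial-condition redraws.
#' @return An `N x 5` numeric matrix (columns `Y1`..`Y5`).
#' @export
simulate_henon <- function(N, Q = 0.6, transient = 1000L, seed = NULL,
                           init = NULL, max_retries = 100L) {
  stop_if_not_scalar_count(N, "N", 32)
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]")
  runs <- function(ini) {
    y2 <- ini[1, ]; y1 <- ini[2, ]       # states at n-2 and n-1
    total <- transient + N
    out <- matrix(NA_real_, total, 5)
    for (n in seq_len(total)) {
      new <- numeric(5)
      for (l in c(1L, 5L)) new[l] <- 1.4 - y1[l]^2 + 0.3 * y2[l]
      for (l in 2:4) {
        a <- 0.5 * Q * (y1[l - 1] + y1[l + 1]) + (1 - Q) * y1[l]
        new[l] <- 1.4 - a^2 + 0.3 * y2[l]
      }
      if (any(!is.finite(new)) || any(abs(new) > 1e4)) return(NULL)
      out[n, ] <- new
      y2 <- y1; y1 <- new
    }
    out[(transient + 1):total, , drop = FALSE]
  }
  draw_init <- function() matrix(runif(10, 0, 0.5), nrow = 2)
  if (!is.null(init)) {
    out <- runs(matrix(init, nrow = 2))
    if (is.null(out)) stop("trajectory diverged for the supplied initial state")
    retries <- 0L
  } else {
    out <- with_seed(seed %||% 1L, {
      res <- NULL
      tries <- 0L
      while (is.null(res)) {
        if (tries > max_retries)
          stop("Henon simulation diverged repeatedly; retry budget exhausted")
        res <- runs(draw_init())
        tries <- tries + 1L
      }
      attr(res, "retries") <- tries - 1L
      res
    })
    retries <- attr(out, "retries")
  }
  colnames(out) <- paste0("Y", 1:5)
  attr(out, "retries") <- retries
  out
}

# AR-system coefficients: the first node is a stochastic AR(2) oscillator,
# the off-diagonal couplings are 0.25*sqrt(2).
.ar_phi1 <- 0.95 * sqrt(2)
.ar_phi2 <- -0.9125
.ar_c <- 0.25 * sqrt(2)

#' Nonlinear autoregressive benchmark system
#'
#' Simulates the five-channel nonlinear AR system
#' \deqn{Y_{1,n} = 0.95\sqrt{2}\,Y_{1,n-1} - 0.9125\,Y_{1,n-2} + \epsilon_1}
#' \deqn{Y_{2,n} = 0.5\,Y_{1,n-2}^2 + \epsilon_2}
#' \deqn{Y_{3,n} = -0.4\,Y_{1,n-3} + 0.4\,Y_{2,n-1} + \epsilon_3}
#' \deqn{Y_{4,n} = -0.5\,Y_{1,n-1}^2 + 0.25\sqrt{2}\,Y_{4,n-1} + \epsilon_4}
#' \deqn{Y_{5,n} = -0.25\sqrt{2}\,Y_{4,n-1} + 0.25\sqrt{2}\,Y_{5,n-2} + \epsilon_5}
#' with mutually independent standard-normal innovations. Node 1 drives
#' nodes 2-4 (quadratically for 2 and 4), node 2 drives node 3 and node 4
#' drives node 5; see [ground_truth()]. Initial states are zero and a
#' burn-in of `transient` samples is discarded (the system forgets its
#' initial state geometrically).
#'
#' @param N output length (>= 32).
#' @param transient burn-in samples.
#' @param seed integer seed for the innovations (optional).
#' @param innovations optional `(N + transient) x 5` matrix of innovations
#'   replacing the random draws (testing hook, e.g. all-zero noise).
#' @return An `N x 5` numeric matrix (columns `Y1`..`Y5`).
#' @export
simulate_ar <- function(N, transient = 1000L, seed = NULL,
                        innovations = NULL) {
  stop_if_not_scalar_count(N, "N", 32)
  total <- transient + N
  if (is.null(innovations)) {
    eps <- with_seed(seed %||% 1L, matrix(rnorm(total * 5), total, 5))
  } else {
    eps <- as.matrix(innovations)
    if (nrow(eps) != total || ncol(eps) != 5)
      stop("innovations must be a (N + transient) x 5 matrix")
  }
  y <- matrix(0, total + 3, 5)            # rows 1..3 hold the zero history
  for (n in seq_len(total)) {
    r <- n + 3
    y[r, 1] <- .ar_phi1 * y[r - 1, 1] + .ar_phi2 * y[r - 2, 1] + eps[n, 1]
    y[r, 2] <- 0.5 * y[r - 2, 1]^2 + eps[n, 2]
    y[r, 3] <- -0.4 * y[r - 3, 1] + 0.4 * y[r - 1, 2] + eps[n, 3]
    y[r, 4] <- -0.5 * y[r - 1, 1]^2 + .ar_c * y[r - 1, 4] + eps[n, 4]
    y[r, 5] <- -.ar_c * y[r - 1, 4] + .ar_c * y[r - 2, 5] + eps[n, 5]
  }
  out <- y[(3 + transient + 1):(3 + total), , drop = FALSE]
  colnames(out) <- paste0("Y", 1:5)
  out
}

#' Instantaneous channel mixing
#'
#' Applies the zero-lag mixing `Y_mixed = Y %*% A` with
#' `A = (1 - alpha) * I + alpha * (J - I)` (diagonal `1 - alpha`,
#' off-diagonal `alpha`), emulating instantaneous couplings such as volume
#' conduction in scalp or intracranial recordings: each output channel is
#' `(1 - alpha)` times its own source plus `alpha` times every other
#' source. `alpha = 0` is the identity; the benchmark sweeps 0.1-0.3.
#'
#' @param data numeric matrix of source channels (time in rows).
#' @param alpha mixing strength in `[0, 0.3]`.
#' @return The mixed matrix, same shape and dimnames as `data`.
#' @export
mix_instantaneous <- function(data, alpha) {
  data <- as_block(data)
  if (length(alpha) != 1 || alpha < 0 || alpha > 0.3)
    stop("alpha must be a single value in [0, 0.3]")
  L <- ncol(data)
  A <- matrix(alpha, L, L)
  diag(A) <- 1 - alpha
  out <- data %*% A
  dimnames(out) <- dimnames(data)
  out
}

#' Ground-truth directed-dependency network of a benchmark system
#'
#' Adjacency matrix of the simulated couplings: entry `(i, j) = 1` when
#' channel `i` drives channel `j`. The Henon system has 6 directed edges
#' (both neighbors into each inner node), the AR system 5. The diagonal is
#' zero and excluded from scoring.
#'
#' @param model `"henon"` or `"ar"`.
#' @return A 5 x 5 binary matrix of class `ground_truth`.
#' @export
ground_truth <- function(model = c("henon", "ar")) {
  model <- match.arg(model)
  adj <- matrix(0L, 5, 5, dimnames = list(paste0("Y", 1:5), paste0("Y", 1:5)))
  edges <- switch(model,
                  henon = rbind(c(1, 2), c(3, 2), c(2, 3), c(4, 3),
                                c(3, 4), c(5, 4)),
                  ar = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(4, 5)))
  adj[edges] <- 1L
  structure(adj, model = model, class = c("ground_truth", class(adj)))
}
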