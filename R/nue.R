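#' Non-uniform embedding configuration
#'
#' All knobs of the greedy embedding search. The candidate pool contains
#' every channel at lags `m, 2m, ..., d*m`. Candidates are ranked and the
#' loop terminated according to `variant`:
#'
#' * `"msr"` -- rank by `(1-lambda) * CMI - lambda * MSR` (mutual
#'   information for the first pick, conditional MI afterwards; MSR is the
#'   leave-one-out mean squared residual of nearest-neighbor prediction
#'   from the tentative embedding). The first winner is always accepted;
#'   from the second iteration a candidate is kept only when it lowers the
#'   MSR by more than `gamma`.
#' * `"bootstrap"` -- rank by CMI; keep a candidate when its CMI exceeds
#'   the `level` percentile of `B` estimates recomputed after independently
#'   shuffling the candidate and the target (conditioning block intact).
#' * `"la"` -- ranking and the shuffled null use the low-dimensional
#'   approximation of the CMI (pairwise redundancy and conditional-
#'   redundancy sums instead of one high-dimensional estimate); the winner
#'   is kept when its full CMI exceeds the LA-null critical value.
#' * `"aic"` -- rank by CMI; from the second iteration keep a candidate
#'   only while the AIC of a kernel-regression prediction of the target
#'   from the tentative embedding keeps moving in the `aic_accept`
#'   direction (`"increase"` by default, see below).
#'
#' @param variant one of `"msr"`, `"bootstrap"`, `"la"`, `"aic"`.
#' @param m embedding delay in samples (lag spacing of the candidate pool).
#' @param d embedding dimension (number of lags per channel); the maximum
#'   lag is `d * m` and the pool holds `L * d` candidates.
#' @param T neighbor count used by both the KSG estimators and the
#'   nearest-neighbor predictor.
#' @param lambda weight in `[0, 1]` mixing CMI (`lambda = 0`) and MSR
#'   (`lambda = 1`) in the `"msr"` ranking. Standardized channels make the
#'   two terms commensurable.
#' @param gamma non-negative minimum MSR improvement (units of standardized
#'   target variance, so meaningful values lie in `[0, 1]`) required to
#'   accept a candidate; larger gamma trades true positives for true
#'   negatives, e.g. against instantaneous-coupling confounds.
#' @param B bootstrap size for the shuffle null (default 100).
#' @param level percentile of the shuffle null used as critical value
#'   (default 0.95).
#' @param seed integer seed governing every stochastic ingredient
#'   (tie-breaking jitter, bootstrap shuffles).
#' @param theiler Theiler window passed to the neighbor searches.
#' @param jitter_amp tie-breaking jitter amplitude (see
#'   [neighbor_config()]).
#' @param aic_accept direction of the `"aic"` termination rule: with the
#'   default `"increase"` a candidate is kept while the AIC of the kernel
#'   regression keeps increasing (the published rule: the effective
#'   parameter count of the widening Gaussian kernel drops faster than the
#'   fit improves, so informative candidates raise the AIC); `"decrease"`
#'   gives the classical minimization direction instead.
#' @return A list of class `nue_config`.
#' @export
nue_config <- function(variant = c("msr", "bootstrap", "la", "aic"),
                       m = 1L, d = 5L, T = 10L, lambda = 0.5, gamma = 0,
                       B = 100L, level = 0.95, seed = 1L, theiler = 0L,
                       jitter_amp = 1e-10,
                       aic_accept = c("increase", "decrease")) {
  variant <- match.arg(variant)
  aic_accept <- match.arg(aic_accept)
  stop_if_not_scalar_count(m, "m", 1)
  stop_if_not_scalar_count(d, "d", 1)
  stop_if_not_scalar_count(B, "B", 1)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  cfg <- list(variant = variant, m = as.integer(m), d = as.integer(d),
              T = as.integer(T), lambda = lambda, gamma = gamma,
              B = as.integer(B), level = level, seed = as.integer(seed),
              theiler = as.integer(theiler), jitter_amp = jitter_amp,
              aic_accept = aic_accept)
  cfg$neighbor <- neighbor_config(T = cfg$T, theiler = cfg$theiler,
                                  jitter_seed = cfg$seed,
                                  jitter_amp = jitter_amp)
  structure(cfg, class = "nue_config")
}

#' Candidate set of lagged variables
#'
#' Enumerates the pool of `L * d` candidate past variables: every channel
#' at lags `m, 2m, ..., d*m`, ordered process-major / lag-minor. The
#' deterministic order doubles as the tie-break rule of the greedy search.
#'
#' @param L number of channels (>= 2).
#' @param m embedding delay.
#' @param d embedding dimension.
#' @return A data frame of class `candidate_set` with columns `process`
#'   and `lag`.
#' @export
build_candidate_set <- function(L, m = 1L, d = 5L) {
  stop_if_not_scalar_count(L, "L", 2)
  stop_if_not_scalar_count(m, "m", 1)
  stop_if_not_scalar_count(d, "d", 1)
  out <- data.frame(process = rep(seq_len(L), each = d),
                    lag = rep.int(as.integer(m) * seq_len(d), L))
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Standardize channels to zero mean and unit variance
#'
#' Centers and scales each column using the population-variance convention
#' (divide by N). Standardizing every channel puts the mutual-information
#' (nats) and mean-squared-residual (target-variance units) terms of the
#' weighted ranking criterion on commensurable scales.
#'
#' @param data numeric matrix, channels in columns.
#' @return The standardized matrix (dimnames preserved).
#' @export
standardize <- function(data) {
  data <- as_block(data)
  mu <- colMeans(data)
  centered <- sweep(data, 2, mu)
  s <- sqrt(colMeans(centered^2))
  bad <- which(s <= 0)
  if (length(bad))
    stop(sprintf("channel%s %s ha%s zero variance and cannot be standardized",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", "),
                 if (length(bad) > 1) "ve" else "s"))
  sweep(centered, 2, s, "/")
}

is_standardized <- function(data, tol = 1e-6) {
  all(abs(colMeans(data)) < tol) && all(abs(colMeans(data^2) - 1) < tol)
}

# Low-dimensional approximation criterion for candidate j given selected S:
# I(W;Y) - (2/|S|) sum_j I(W;Wj) + (2/|S|) sum_j I(W;Wj|Y).
# The base and pairwise terms are cached across iterations (they do not
# depend on the iteration counter, only on the pair of columns).
la_criterion <- function(j, S, Xc, yv, ncfg, cache) {
  jkey <- as.character(j)
  if (is.null(cache$base[[jkey]]))
    cache$base[[jkey]] <- ksg_mi_num(Xc[, j, drop = FALSE], yv, ncfg)
  base <- cache$base[[jkey]]
  if (length(S) == 0) return(base)
  red <- 0
  cred <- 0
  for (s in S) {
    key <- paste(min(j, s), max(j, s), sep = "_")
    if (is.null(cache$mi[[key]])) {
      cache$mi[[key]] <- ksg_mi_num(Xc[, j, drop = FALSE],
                                    Xc[, s, drop = FALSE], ncfg)
      cache$cmi[[key]] <- ksg_cmi_num(Xc[, j, drop = FALSE],
                                      Xc[, s, drop = FALSE], yv, ncfg)
    }
    red <- red + cache$mi[[key]]
    cred <- cred + cache$cmi[[key]]
  }
  base - (2 / length(S)) * red + (2 / length(S)) * cred
}

#' Shuffle-null critical value for the embedding termination test
#'
#' Draws `cfg$B` independent row permutations of the target vector and of
#' the winning candidate's column (two independent shuffles per draw; the
#' conditioning block of already-selected lags is left intact), recomputes
#' the selection criterion (CMI, or its low-dimensional approximation for
#' the `"la"` variant) for each draw, and returns the `cfg$level` empirical
#' percentile (linear interpolation). The candidate enters the embedding
#' when the observed statistic -- the CMI for `"bootstrap"`, and also the
#' full CMI (not the low-dimensional approximation) for `"la"` -- exceeds
#' this critical value.
#'
#' @param data numeric matrix of (standardized) channels.
#' @param target target channel index.
#' @param winner a one-row data frame (`process`, `lag`): the candidate
#'   under test.
#' @param selected data frame of already-selected candidates (may be
#'   empty/NULL).
#' @param cfg a [nue_config()] (variant `"bootstrap"` or `"la"`).
#' @param seed optional integer overriding `cfg$seed` for the shuffle RNG.
#' @return The critical value (scalar, nats).
#' @export
bootstrap_threshold <- function(data, target, winner, selected = NULL,
                                cfg = nue_config(variant = "bootstrap"),
                                seed = cfg$seed) {
  data <- as_block(data)
  lag0 <- cfg$d * cfg$m
  sel <- if (is.null(selected)) data.frame(process = integer(),
                                           lag = integer()) else selected
  yv <- drop(lag_block(data, data.frame(process = target, lag = 0), lag0))
  w <- lag_block(data, winner, lag0)
  Smat <- lag_block(data, sel, lag0)
  # jitter the blocks once (order: candidate, target, conditioning block);
  # the shuffled draws then permute the already-jittered rows
  jm <- apply_jitter(cbind(w, yv, Smat), cfg$neighbor)
  w <- jm[, 1L, drop = FALSE]
  yv <- jm[, 2L]
  Smat <- jm[, -(1:2), drop = FALSE]
  boot_threshold_core(w, yv, Smat, la = cfg$variant == "la", cfg, seed)
}

# w: N x 1 jittered candidate column, yv: jittered target vector, Smat:
# jittered conditioning block. No further jitter is applied inside.
boot_threshold_core <- function(w, yv, Smat, la, cfg, seed) {
  n <- length(yv)
  perms <- with_seed(seed, lapply(seq_len(cfg$B), function(b)
    list(w = sample.int(n), y = sample.int(n))))
  permw <- do.call(rbind, lapply(perms, `[[`, "w"))
  permy <- do.call(rbind, lapply(perms, `[[`, "y"))
  stats <- if (la)
    boot_la_cpp(drop(w), yv, Smat, permw, permy, cfg$T, cfg$theiler)
  else
    boot_cmi_cpp(drop(w), yv, Smat, permw, permy, cfg$T, cfg$theiler)
  quantile(stats, cfg$level, names = FALSE, type = 7)
}

#' Greedy non-uniform embedding of a target channel
#'
#' Iteratively selects, from the pool of all channels' lagged variables,
#' the embedding most informative about the present of `target`. At each
#' iteration every remaining candidate is scored (see [nue_config()] for
#' the variant-specific criterion), the best one is tested against the
#' variant's termination rule, and the loop stops at the first rejection
#' (or when the pool is exhausted). For the `"msr"` and `"aic"` variants
#' the first winner is accepted without a test; the `"bootstrap"` and
#' `"la"` variants test from the first iteration onward.
#'
#' Channels are standardized internally (population variance) if they are
#' not already, so the information and prediction terms share a scale.
#'
#' @param data numeric matrix, time in rows, channels in columns.
#' @param target index of the target channel.
#' @param cfg a [nue_config()].
#' @return An object of class `nue_selection`: list with `target`,
#'   `selected` (data frame of accepted `process`/`lag` in acceptance
#'   order), `trace` (one row per tested iteration: winner, criterion
#'   value, MSR of the tentative embedding, termination statistic,
#'   `accepted` flag), `termination_reason`, `n_iterations` (accepted
#'   iterations plus the final rejected test, if any), `cfg` and
#'   `neighbor`.
#' @export
run_nue <- function(data, target, cfg = nue_config()) {
  data <- as_block(data)
  L <- ncol(data)
  if (L < 2) stop("at least two channels are required")
  if (target < 1 || target > L) stop("target out of range")
  if (!is_standardized(data)) data <- standardize(data)
  lag0 <- cfg$d * cfg$m
  neff <- nrow(data) - lag0
  if (neff <= cfg$T + 1)
    stop(sprintf("data too short: N - d*m = %d must exceed T + 1 = %d",
                 neff, cfg$T + 1))
  ncfg <- cfg$neighbor
  cand <- build_candidate_set(L, cfg$m, cfg$d)
  nC <- nrow(cand)
  Xc <- lag_block(data, cand, lag0)
  yv <- data[(lag0 + 1):nrow(data), target]
  # apply the tie-breaking jitter once per run (candidate columns first,
  # target last) so every iteration's neighbor searches see the same noise
  # realization; downstream estimator calls must not jitter again
  jm <- apply_jitter(cbind(Xc, yv), ncfg)
  Xcj <- jm[, seq_len(nC), drop = FALSE]
  yj <- jm[, nC + 1L]
  ymj <- matrix(yj, ncol = 1)
  ncfg0 <- ncfg
  ncfg0$jitter_amp <- 0

  S <- integer(0)
  msr_sel <- NA_real_
  aic_prev <- NA_real_
  la_cache <- new.env(parent = emptyenv())
  la_cache$base <- list(); la_cache$mi <- list(); la_cache$cmi <- list()
  trace <- list()
  reason <- "candidates_exhausted"

  k <- 0L
  repeat {
    k <- k + 1L
    remaining <- setdiff(seq_len(nC), S)
    if (length(remaining) == 0) break
    Smat <- Xcj[, S, drop = FALSE]

    msr_cand <- rep(NA_real_, length(remaining))
    if (cfg$variant == "la") {
      crit <- vapply(remaining, la_criterion, numeric(1), S = S, Xc = Xcj,
                     yv = ymj, ncfg = ncfg0, cache = la_cache)
    } else {
      need_cmi <- cfg$variant != "msr" || cfg$lambda < 1
      need_msr <- cfg$variant == "msr" && cfg$lambda > 0
      ev <- nue_eval_iteration_cpp(Xcj, yj, S - 1L, remaining - 1L,
                                   cfg$T, cfg$T, cfg$theiler,
                                   need_cmi, need_msr)
      if (need_msr) msr_cand <- ev$msr
      crit <- if (cfg$variant == "msr")
        (1 - cfg$lambda) * (if (need_cmi) ev$cmi else 0) -
          cfg$lambda * (if (need_msr) ev$msr else 0)
      else ev$cmi                             # bootstrap and aic variants
    }
    win <- which.max(crit)                    # first index wins ties
    j <- remaining[win]
    wrow <- cand[j, , drop = FALSE]

    msr_k <- NA_real_
    thr <- NA_real_
    aic_k <- NA_real_
    accepted <- FALSE
    if (cfg$variant %in% c("msr", "aic")) {
      if (cfg$variant == "msr") {
        msr_k <- if (!is.na(msr_cand[win])) msr_cand[win] else
          knn_msr(cbind(Xcj[, j, drop = FALSE], Smat), yj, ncfg0)
        thr <- cfg$gamma
        accepted <- k == 1L || (msr_sel - msr_k) > cfg$gamma
        if (!accepted) reason <- "msr_no_improvement"
      } else {
        aic_k <- as.numeric(aic_score(cbind(Xc[, j, drop = FALSE],
                                            Xc[, S, drop = FALSE]), yv))
        thr <- aic_prev
        accepted <- k == 1L ||
          (if (cfg$aic_accept == "increase") aic_k > aic_prev
           else aic_k < aic_prev)
        if (!accepted) reason <- "aic_no_improvement"
      }
    } else {
      thr <- boot_threshold_core(Xcj[, j, drop = FALSE], yj, Smat,
                                 la = cfg$variant == "la", cfg,
                                 child_seed(cfg$seed, k))
      # the tested statistic is the winner's full CMI given the selected
      # block; for the la variant only the ranking and the shuffle null use
      # the low-dimensional approximation of that CMI
      obs <- if (cfg$variant == "la")
        ksg_cmi_cpp(cbind(Xcj[, j, drop = FALSE], ymj, Smat), 1L, 1L,
                    cfg$T, cfg$theiler)
      else crit[win]
      accepted <- obs > thr
      if (!accepted) reason <- "below_threshold"
    }

    trace[[k]] <- data.frame(k = k, process = wrow$process, lag = wrow$lag,
                             criterion = crit[win], msr = msr_k,
                             aic = aic_k, threshold = thr,
                             accepted = accepted)
    if (!accepted) break
    S <- c(S, j)
    if (cfg$variant == "msr") msr_sel <- msr_k
    if (cfg$variant == "aic") aic_prev <- aic_k
  }

  trace <- do.call(rbind, trace)
  selected <- cand[S, , drop = FALSE]
  rownames(selected) <- NULL
  structure(list(target = target,
                 selected = selected,
                 trace = trace,
                 termination_reason = reason,
                 n_iterations = nrow(trace),
                 cfg = cfg, neighbor = ncfg),
            class = "nue_selection")
}

#' @export
print.nue_selection <- function(x, ...) {
  cat(sprintf("<nue_selection> target %d, variant '%s': %d lag(s) selected (%s)\n",
              x$target, x$cfg$variant, nrow(x$selected),
              x$termination_reason))
  if (nrow(x$selected) > 0)
    cat(paste(sprintf("  channel %d, lag %d", x$selected$process,
                      x$selected$lag), collapse = "\n"), "\n")
  invisible(x)
}

#' Best candidate under the conditional-mutual-information criterion
#'
#' Scores every remaining candidate by its KSG conditional mutual
#' information with the target's present given the already-selected lags
#' (plain mutual information when nothing is selected yet) and returns the
#' maximizer; ties go to the earliest candidate in pool order.
#'
#' @param data numeric matrix of (standardized) channels.
#' @param target target channel index.
#' @param selected data frame of already-selected (`process`, `lag`) rows;
#'   may be empty or NULL.
#' @param candidates data frame of candidates still in the pool; defaults
#'   to the full pool minus `selected`.
#' @param cfg a [nue_config()].
#' @return A list with `winner` (one-row data frame) and `criterion`.
#' @export
select_candidate_cmi <- function(data, target, selected = NULL,
                                 candidates = NULL, cfg = nue_config()) {
  select_candidate(data, target, selected, candidates, cfg,
                   mode = "cmi")
}

#' Best candidate under the low-dimensional-approximation criterion
#'
#' As [select_candidate_cmi()] but the high-dimensional CMI is replaced by
#' its low-dimensional approximation: the candidate's mutual information
#' with the target, penalized by `2/|S|` times its summed redundancy with
#' the selected lags and rewarded by `2/|S|` times the summed conditional
#' redundancy given the target. With an empty selection the criterion
#' reduces to plain mutual information.
#'
#' @inheritParams select_candidate_cmi
#' @return A list with `winner` and `criterion`.
#' @export
select_candidate_la <- function(data, target, selected = NULL,
                                candidates = NULL,
                                cfg = nue_config(variant = "la")) {
  select_candidate(data, target, selected, candidates, cfg, mode = "la")
}

#' Best candidate under the weighted CMI/MSR criterion
#'
#' Scores each candidate by `(1 - lambda) * CMI - lambda * MSR`, where the
#' MSR is the leave-one-out mean squared residual of the nearest-neighbor
#' prediction of the target from the candidate joined to the selected lags.
#' `lambda = 0` reproduces the pure-CMI ranking; `lambda = 1` ranks by
#' prediction alone and computes no information estimates.
#'
#' @inheritParams select_candidate_cmi
#' @return A list with `winner`, `criterion` and `msr` (the tentative
#'   embedding's MSR, `NA` when `lambda = 0`).
#' @export
select_candidate_msr <- function(data, target, selected = NULL,
                                 candidates = NULL, cfg = nue_config()) {
  select_candidate(data, target, selected, candidates, cfg, mode = "msr")
}

select_candidate <- function(data, target, selected, candidates, cfg, mode) {
  data <- as_block(data)
  if (!is_standardized(data)) data <- standardize(data)
  lag0 <- cfg$d * cfg$m
  sel <- if (is.null(selected) || nrow(as.data.frame(selected)) == 0)
    data.frame(process = integer(), lag = integer()) else
      as.data.frame(selected)
  if (is.null(candidates)) {
    pool <- build_candidate_set(ncol(data), cfg$m, cfg$d)
    if (nrow(sel) > 0) {
      keys <- paste(pool$process, pool$lag)
      pool <- pool[!keys %in% paste(sel$process, sel$lag), , drop = FALSE]
    }
  } else pool <- as.data.frame(candidates)
  if (nrow(pool) == 0) stop("no candidates remain")
  ncfg <- cfg$neighbor
  yv <- drop(lag_block(data, data.frame(process = target, lag = 0), lag0))
  ym <- matrix(yv, ncol = 1)
  Smat <- lag_block(data, sel, lag0)
  crit <- numeric(nrow(pool))
  msrv <- rep(NA_real_, nrow(pool))
  la_cache <- new.env(parent = emptyenv())
  la_cache$mi <- list(); la_cache$cmi <- list()
  Xp <- lag_block(data, pool, lag0)
  Xs <- if (nrow(sel) > 0) Smat else NULL
  for (i in seq_len(nrow(pool))) {
    wcol <- Xp[, i, drop = FALSE]
    crit[i] <- switch(
      mode,
      cmi = ksg_cmi_num(wcol, ym, Smat, ncfg),
      la = {
        base <- ksg_mi_num(wcol, ym, ncfg)
        if (nrow(sel) == 0) base else {
          red <- sum(vapply(seq_len(ncol(Smat)), function(s)
            ksg_mi_num(wcol, Smat[, s, drop = FALSE], ncfg), numeric(1)))
          cred <- sum(vapply(seq_len(ncol(Smat)), function(s)
            ksg_cmi_num(wcol, Smat[, s, drop = FALSE], ym, ncfg),
            numeric(1)))
          base - (2 / ncol(Smat)) * red + (2 / ncol(Smat)) * cred
        }
      },
      msr = {
        mval <- if (cfg$lambda > 0) {
          msrv[i] <- knn_msr(cbind(wcol, Smat), yv, ncfg)
          msrv[i]
        } else 0
        ival <- if (cfg$lambda < 1) ksg_cmi_num(wcol, ym, Smat, ncfg) else 0
        (1 - cfg$lambda) * ival - cfg$lambda * mval
      })
  }
  win <- which.max(crit)
  out <- list(winner = pool[win, , drop = FALSE], criterion = crit[win])
  if (mode == "msr") out$msr <- msrv[win]
  out
}
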