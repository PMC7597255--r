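# Closed-form Gaussian information oracles and brute-force reference
# implementations used to validate the compiled estimators.

# Multivariate normal sampler (Cholesky), deterministic given the RNG state.
rmvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  matrix(rnorm(n * k), n, k) %*% chol(Sigma)
}

# MI of a bivariate Gaussian with correlation rho (nats).
gauss_mi_true <- function(rho) -0.5 * log(1 - rho^2)

# I(X;Y|Z) for a jointly Gaussian vector with covariance Sigma, where ix,
# iy, iz index the X, Y and Z blocks. Log-determinant identity:
# I = 0.5 * log( det(S_xz) * det(S_yz) / (det(S_z) * det(S_xyz)) ).
gauss_cmi_true <- function(Sigma, ix, iy, iz) {
  ld <- function(idx) {
    if (length(idx) == 0) return(0)
    determinant(Sigma[idx, idx, drop = FALSE], logarithm = TRUE)$modulus
  }
  as.numeric(0.5 * (ld(c(ix, iz)) + ld(c(iy, iz)) - ld(iz) -
                      ld(c(ix, iy, iz))))
}

# Random valid covariance for a (dx+dy+dz)-dimensional Gaussian: A A' + I.
random_cov <- function(k) {
  A <- matrix(rnorm(k * k, sd = 0.6), k, k)
  tcrossprod(A) + diag(k)
}

# Plain-R KSG algorithm-1 mutual information (max-norm, strict counts).
ksg_mi_bruteforce <- function(x, y, T = 10L, theiler = 0L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  dmax <- function(m) {
    d <- matrix(0, n, n)
    for (c in seq_len(ncol(m)))
      d <- pmax(d, abs(outer(m[, c], m[, c], "-")))
    d
  }
  dx <- dmax(x); dy <- dmax(y)
  dj <- pmax(dx, dy)
  acc <- 0
  for (i in seq_len(n)) {
    valid <- abs(seq_len(n) - i) > theiler
    eps <- sort(dj[i, valid])[T]
    nx <- sum(dx[i, valid] < eps)
    ny <- sum(dy[i, valid] < eps)
    acc <- acc + digamma(nx + 1) + digamma(ny + 1)
  }
  digamma(T) + digamma(n) - acc / n
}

# Plain-R KSG conditional mutual information.
ksg_cmi_bruteforce <- function(x, y, z, T = 10L, theiler = 0L) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  n <- nrow(x)
  dmax <- function(m) {
    d <- matrix(0, n, n)
    for (c in seq_len(ncol(m)))
      d <- pmax(d, abs(outer(m[, c], m[, c], "-")))
    d
  }
  dx <- dmax(x); dy <- dmax(y); dz <- dmax(z)
  dj <- pmax(dx, dy, dz)
  acc <- 0
  for (i in seq_len(n)) {
    valid <- abs(seq_len(n) - i) > theiler
    eps <- sort(dj[i, valid])[T]
    nxz <- sum(pmax(dx[i, ], dz[i, ])[valid] < eps)
    nyz <- sum(pmax(dy[i, ], dz[i, ])[valid] < eps)
    nz <- sum(dz[i, valid] < eps)
    acc <- acc + digamma(nxz + 1) + digamma(nyz + 1) - digamma(nz + 1)
  }
  digamma(T) - acc / n
}

# Brute-force leave-one-out nearest-neighbor prediction with the package's
# documented tie rule: neighbors ordered by (distance, index).
nn_predict_bruteforce <- function(u, y, T = 10L, theiler = 0L) {
  u <- as.matrix(u)
  n <- nrow(u)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(u) - u[i, ])^2)
    cand <- which(abs(seq_len(n) - i) > theiler)
    ord <- cand[order(d2[cand], cand)]
    # sequential double-precision sum in neighbor order (mean() accumulates
    # in long double, which differs from the implementation by one ulp)
    s <- 0
    for (v in ord[seq_len(T)]) s <- s + y[v]
    pred[i] <- s / T
  }
  pred
}

# Brute-force Nadaraya-Watson oracle mirroring kde_predict's definition:
# Mahalanobis-whitened coordinates, Gaussian kernel, reference bandwidth.
kde_predict_bruteforce <- function(u, y) {
  u <- as.matrix(u)
  n <- nrow(u); k <- ncol(u)
  h <- (4 / (k + 2))^(1 / (k + 4)) * n^(-1 / (k + 4))
  Ci <- solve(cov(u))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- u[i, ] - u[j, ]
    K[i, j] <- exp(-c(d %*% Ci %*% d) / (2 * h^2))
  }
  denom <- rowSums(K)
  list(predictions = as.vector(K %*% y) / denom,
       complexity_p = sum(1 / denom), bandwidth = h)
}

# A no-jitter neighbor configuration for exact comparisons on tie-free data.
ncfg_exact <- function(T = 10L, theiler = 0L)
  neighbor_config(T = T, theiler = theiler, jitter_amp = 0)
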