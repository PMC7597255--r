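#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Column-major max-norm distance between rows i and j over columns
// [c0, c0 + nc) of an N-row matrix stored in `m`.
static inline double maxnorm(const std::vector<double> &m, int N, int i,
                             int j, int c0, int nc) {
  double d = 0.0;
  for (int c = c0; c < c0 + nc; ++c) {
    double v = std::abs(m[(size_t)c * N + i] - m[(size_t)c * N + j]);
    if (v > d) d = v;
  }
  return d;
}

// KSG algorithm 1 mutual information.
// xy: joint matrix, first nx columns are X, remaining are Y.
// For each point: eps = max-norm distance to its k-th nearest neighbor in
// the joint space (self and |i-j| <= theiler excluded); marginal counts use
// strict inequality (< eps).
// [[Rcpp::export]]
double ksg_mi_cpp(const NumericMatrix &xy, int nx, int k, int theiler) {
  const int N = xy.nrow(), ncol = xy.ncol(), ny = ncol - nx;
  const std::vector<double> m(xy.begin(), xy.end());
  std::vector<double> dj;
  dj.reserve(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    dj.clear();
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      dj.push_back(maxnorm(m, N, i, j, 0, ncol));
    }
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.end());
    const double eps = dj[k - 1];
    int cx = 0, cy = 0;
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      if (maxnorm(m, N, i, j, 0, nx) < eps) ++cx;
      if (maxnorm(m, N, i, j, nx, ny) < eps) ++cy;
    }
    acc += R::digamma(cx + 1.0) + R::digamma(cy + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)N) - acc / N;
}

// KSG conditional mutual information I(X;Y|Z).
// xyz: joint matrix with column blocks X (nx), Y (ny), Z (rest, >= 1 col).
// I = psi(k) - < psi(n_xz+1) + psi(n_yz+1) - psi(n_z+1) >.
// [[Rcpp::export]]
double ksg_cmi_cpp(const NumericMatrix &xyz, int nx, int ny, int k,
                   int theiler) {
  const int N = xyz.nrow(), ncol = xyz.ncol(), nz = ncol - nx - ny;
  const std::vector<double> m(xyz.begin(), xyz.end());
  std::vector<double> dj;
  dj.reserve(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    dj.clear();
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      dj.push_back(maxnorm(m, N, i, j, 0, ncol));
    }
    std::nth_element(dj.begin(), dj.begin() + (k - 1), dj.end());
    const double eps = dj[k - 1];
    int cxz = 0, cyz = 0, cz = 0;
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      const double dz = maxnorm(m, N, i, j, nx + ny, nz);
      if (dz >= eps) continue;       // z-distance bounds both joint blocks
      ++cz;
      if (std::max(dz, maxnorm(m, N, i, j, 0, nx)) < eps) ++cxz;
      if (std::max(dz, maxnorm(m, N, i, j, nx, ny)) < eps) ++cyz;
    }
    acc += R::digamma(cxz + 1.0) + R::digamma(cyz + 1.0)
         - R::digamma(cz + 1.0);
  }
  return R::digamma((double)k) - acc / N;
}

// Shared core for the embedding loop: KSG MI/CMI of two scalar series
// given a precomputed max-norm distance matrix dS of the conditioning
// block (row-major, N x N; ignored when hasS is false).
static double ksg_core(const double *w, const double *y,
                       const std::vector<double> &dS, bool hasS, int N,
                       int k, int theiler, const std::vector<double> &dig,
                       std::vector<double> &dwv, std::vector<double> &dyv,
                       std::vector<double> &dsv, std::vector<double> &buf) {
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    int nv = 0;
    const double wi = w[i], yi = y[i];
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      const double dw = std::abs(wi - w[j]);
      const double dy = std::abs(yi - y[j]);
      const double ds = hasS ? dS[(size_t)i * N + j] : 0.0;
      double joint = dw > dy ? dw : dy;
      if (ds > joint) joint = ds;
      dwv[nv] = dw; dyv[nv] = dy; dsv[nv] = ds; buf[nv] = joint;
      ++nv;
    }
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.begin() + nv);
    const double eps = buf[k - 1];
    if (hasS) {
      int cxz = 0, cyz = 0, cz = 0;
      for (int t = 0; t < nv; ++t) {
        const double ds = dsv[t];
        if (ds >= eps) continue;
        ++cz;
        if ((dwv[t] > ds ? dwv[t] : ds) < eps) ++cxz;
        if ((dyv[t] > ds ? dyv[t] : ds) < eps) ++cyz;
      }
      acc += dig[cxz + 1] + dig[cyz + 1] - dig[cz + 1];
    } else {
      int cx = 0, cy = 0;
      for (int t = 0; t < nv; ++t) {
        if (dwv[t] < eps) ++cx;
        if (dyv[t] < eps) ++cy;
      }
      acc += dig[cx + 1] + dig[cy + 1];
    }
  }
  return hasS ? dig[k] - acc / N
              : dig[k] + R::digamma((double)N) - acc / N;
}

static std::vector<double> digamma_table(int N) {
  std::vector<double> dig(N + 2);
  for (int t = 1; t <= N + 1; ++t) dig[t] = R::digamma((double)t);
  return dig;
}

// Evaluate every remaining candidate of one embedding iteration.
// Xc: N x nC matrix of all candidate columns (already jittered), y: target.
// Sidx/Cidx: 0-based columns of the selected block / remaining candidates.
// Returns the KSG CMI of (candidate; y | selected) and/or the
// nearest-neighbor MSR of y given [candidate, selected], per candidate.
// The conditioning-block distance matrices are built once and shared.
// [[Rcpp::export]]
List nue_eval_iteration_cpp(const NumericMatrix &Xc, const NumericVector &yv,
                            const IntegerVector &Sidx,
                            const IntegerVector &Cidx, int k, int T,
                            int theiler, bool need_cmi, bool need_msr) {
  const int N = Xc.nrow(), nS = Sidx.size(), nC = Cidx.size();
  const std::vector<double> X(Xc.begin(), Xc.end());
  const std::vector<double> y(yv.begin(), yv.end());
  std::vector<double> dS, e2S;
  if (nS > 0) {
    dS.assign((size_t)N * N, 0.0);
    if (need_msr) e2S.assign((size_t)N * N, 0.0);
    for (int s = 0; s < nS; ++s) {
      const double *col = &X[(size_t)Sidx[s] * N];
      for (int i = 0; i < N; ++i) {
        const double ci = col[i];
        for (int j = i + 1; j < N; ++j) {
          const double a = std::abs(ci - col[j]);
          const size_t ij = (size_t)i * N + j, ji = (size_t)j * N + i;
          if (a > dS[ij]) { dS[ij] = a; dS[ji] = a; }
          if (need_msr) { e2S[ij] += a * a; e2S[ji] = e2S[ij]; }
        }
      }
    }
  }
  const std::vector<double> dig = digamma_table(N);
  std::vector<double> dwv(N), dyv(N), dsv(N), buf(N);
  std::vector<std::pair<double, int> > dj(N);
  NumericVector cmi(nC, NA_REAL), msr(nC, NA_REAL);
  for (int c = 0; c < nC; ++c) {
    const double *w = &X[(size_t)Cidx[c] * N];
    if (need_cmi)
      cmi[c] = ksg_core(w, &y[0], dS, nS > 0, N, k, theiler, dig,
                        dwv, dyv, dsv, buf);
    if (need_msr) {
      double sse = 0.0;
      for (int i = 0; i < N; ++i) {
        int nv = 0;
        const double wi = w[i];
        for (int j = 0; j < N; ++j) {
          if (std::abs(i - j) <= theiler) continue;
          const double dw = wi - w[j];
          const double d2 = dw * dw +
            (nS > 0 ? e2S[(size_t)i * N + j] : 0.0);
          dj[nv++] = std::make_pair(d2, j);
        }
        std::partial_sort(dj.begin(), dj.begin() + T, dj.begin() + nv);
        double s = 0.0;
        for (int t = 0; t < T; ++t) s += y[dj[t].second];
        const double r = y[i] - s / T;
        sse += r * r;
      }
      msr[c] = sse / N;
    }
  }
  return List::create(Named("cmi") = cmi, Named("msr") = msr);
}

// Shuffle-null statistics for the bootstrap termination test: for each of
// the B rows of permw/permy (1-based permutations), the KSG CMI between
// the permuted candidate column and the permuted target given the intact
// conditioning block. The block's distance matrix is built once.
// [[Rcpp::export]]
NumericVector boot_cmi_cpp(const NumericVector &wv, const NumericVector &yv,
                           const NumericMatrix &S,
                           const IntegerMatrix &permw,
                           const IntegerMatrix &permy, int k, int theiler) {
  const int N = wv.size(), nS = S.ncol(), B = permw.nrow();
  const std::vector<double> w0(wv.begin(), wv.end());
  const std::vector<double> y0(yv.begin(), yv.end());
  std::vector<double> dS;
  if (nS > 0) {
    const std::vector<double> Sm(S.begin(), S.end());
    dS.assign((size_t)N * N, 0.0);
    for (int s = 0; s < nS; ++s) {
      const double *col = &Sm[(size_t)s * N];
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          const double a = std::abs(col[i] - col[j]);
          if (a > dS[(size_t)i * N + j]) {
            dS[(size_t)i * N + j] = a;
            dS[(size_t)j * N + i] = a;
          }
        }
    }
  }
  const std::vector<double> dig = digamma_table(N);
  std::vector<double> dwv(N), dyv(N), dsv(N), buf(N);
  std::vector<double> wp(N), yp(N);
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < N; ++i) {
      wp[i] = w0[permw(b, i) - 1];
      yp[i] = y0[permy(b, i) - 1];
    }
    out[b] = ksg_core(&wp[0], &yp[0], dS, nS > 0, N, k, theiler, dig,
                      dwv, dyv, dsv, buf);
  }
  return out;
}

// Shuffle-null statistics for the low-dimensional-approximation criterion:
// for each draw, MI(wp; yp) - (2/nS) * sum_s MI(wp; S_s)
//                          + (2/nS) * sum_s CMI(wp; S_s | yp),
// with wp/yp the permuted candidate and target and the selected columns S
// left intact. The conditional terms share the permuted target's distance
// matrix, rebuilt once per draw.
// [[Rcpp::export]]
NumericVector boot_la_cpp(const NumericVector &wv, const NumericVector &yv,
                          const NumericMatrix &S,
                          const IntegerMatrix &permw,
                          const IntegerMatrix &permy, int k, int theiler) {
  const int N = wv.size(), nS = S.ncol(), B = permw.nrow();
  const std::vector<double> w0(wv.begin(), wv.end());
  const std::vector<double> y0(yv.begin(), yv.end());
  const std::vector<double> Sm(S.begin(), S.end());
  const std::vector<double> dig = digamma_table(N);
  std::vector<double> dwv(N), dyv(N), dsv(N), buf(N);
  std::vector<double> wp(N), yp(N);
  std::vector<double> dY, empty;
  if (nS > 0) dY.assign((size_t)N * N, 0.0);
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < N; ++i) {
      wp[i] = w0[permw(b, i) - 1];
      yp[i] = y0[permy(b, i) - 1];
    }
    double val = ksg_core(&wp[0], &yp[0], empty, false, N, k, theiler, dig,
                          dwv, dyv, dsv, buf);
    if (nS > 0) {
      for (int i = 0; i < N; ++i) {
        const double yi = yp[i];
        for (int j = 0; j < N; ++j)
          dY[(size_t)i * N + j] = std::abs(yi - yp[j]);
      }
      double red = 0.0, cred = 0.0;
      for (int s = 0; s < nS; ++s) {
        const double *col = &Sm[(size_t)s * N];
        red += ksg_core(&wp[0], col, empty, false, N, k, theiler, dig,
                        dwv, dyv, dsv, buf);
        cred += ksg_core(&wp[0], col, dY, true, N, k, theiler, dig,
                         dwv, dyv, dsv, buf);
      }
      val += (2.0 / nS) * (cred - red);
    }
    out[b] = val;
  }
  return out;
}

// Nearest-neighbor regression: prediction[i] = mean of y over the T nearest
// rows of u to row i (Euclidean metric). Exact ties broken by row index so
// the result matches order(distance, index) in R.
// [[Rcpp::export]]
NumericVector knn_regress_cpp(const NumericMatrix &um, const NumericVector &y,
                              int T, bool exclude_self, int theiler) {
  const int N = um.nrow(), kdim = um.ncol();
  const std::vector<double> u(um.begin(), um.end());
  NumericVector pred(N);
  std::vector<std::pair<double, int> > dj(N);
  for (int i = 0; i < N; ++i) {
    int nvalid = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) {
        if (exclude_self || theiler > 0) continue;
      } else if (std::abs(i - j) <= theiler) {
        continue;
      }
      double d2 = 0.0;
      for (int c = 0; c < kdim; ++c) {
        double v = u[(size_t)c * N + i] - u[(size_t)c * N + j];
        d2 += v * v;
      }
      dj[nvalid++] = std::make_pair(d2, j);
    }
    // lexicographic (distance, index) order makes tie handling deterministic
    std::partial_sort(dj.begin(), dj.begin() + T, dj.begin() + nvalid);
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += y[dj[t].second];
    pred[i] = s / T;
  }
  return pred;
}
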