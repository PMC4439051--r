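#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polygon primitives.  Polygons are simple rings, vertices in order, NOT
// closed (first vertex not repeated); closure is implicit.  Points on the
// boundary count as inside throughout the package.
// ---------------------------------------------------------------------------

static double poly_tol(const NumericVector& vx, const NumericVector& vy) {
  double m = 1.0;
  for (R_xlen_t i = 0; i < vx.size(); ++i) {
    m = std::max(m, std::fabs(vx[i]));
    m = std::max(m, std::fabs(vy[i]));
  }
  return 1e-9 * m;
}

static bool on_segment(double px, double py, double ax, double ay,
                       double bx, double by, double tol) {
  double abx = bx - ax, aby = by - ay;
  double apx = px - ax, apy = py - ay;
  double len2 = abx * abx + aby * aby;
  if (len2 < tol * tol) return std::hypot(apx, apy) <= tol;
  double cross = abx * apy - aby * apx;
  if (std::fabs(cross) / std::sqrt(len2) > tol) return false;
  double dot = apx * abx + apy * aby;
  return dot >= -tol * std::sqrt(len2) && dot <= len2 + tol * std::sqrt(len2);
}

static bool point_in_poly(double px, double py, const NumericVector& vx,
                          const NumericVector& vy, double tol) {
  int n = vx.size();
  for (int i = 0, j = n - 1; i < n; j = i++)
    if (on_segment(px, py, vx[j], vy[j], vx[i], vy[i], tol)) return true;
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if ((vy[i] > py) != (vy[j] > py)) {
      double xint = vx[j] + (py - vy[j]) / (vy[i] - vy[j]) * (vx[i] - vx[j]);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector pip_cpp(NumericVector px, NumericVector py,
                      NumericVector vx, NumericVector vy) {
  double tol = poly_tol(vx, vy);
  R_xlen_t n = px.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = point_in_poly(px[i], py[i], vx, vy, tol);
  return out;
}

// Fraction of the circumference of the circle centred at (cx, cy) with
// radius r that lies inside the polygon.  Exact circular-arc / polygon
// intersection: intersection angles with every edge are found from the
// quadratic along each segment; the circle is cut into arcs at those angles
// and each arc is classified by its midpoint.
// [[Rcpp::export]]
double arc_frac_cpp(double cx, double cy, double r,
                    NumericVector vx, NumericVector vy) {
  double tol = poly_tol(vx, vy);
  if (r <= 0) return 1.0;
  int n = vx.size();
  std::vector<double> ang;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double ax = vx[j] - cx, ay = vy[j] - cy;
    double dx = vx[i] - vx[j], dy = vy[i] - vy[j];
    double A = dx * dx + dy * dy;
    if (A < tol * tol) continue;
    double B = 2.0 * (ax * dx + ay * dy);
    double C = ax * ax + ay * ay - r * r;
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0) continue;
    double sq = std::sqrt(disc);
    for (int s = -1; s <= 1; s += 2) {
      double t = (-B + s * sq) / (2.0 * A);
      if (t > -1e-12 && t < 1.0 + 1e-12) {
        double px = ax + t * dx, py = ay + t * dy;
        ang.push_back(std::atan2(py, px));
      }
    }
  }
  if (ang.empty())
    return point_in_poly(cx + r, cy, vx, vy, tol) ? 1.0 : 0.0;
  std::sort(ang.begin(), ang.end());
  ang.push_back(ang.front() + 2.0 * M_PI);
  double inside_len = 0.0;
  for (size_t k = 0; k + 1 < ang.size(); ++k) {
    double mid = 0.5 * (ang[k] + ang[k + 1]);
    double px = cx + r * std::cos(mid), py = cy + r * std::sin(mid);
    if (point_in_poly(px, py, vx, vy, tol)) inside_len += ang[k + 1] - ang[k];
  }
  return inside_len / (2.0 * M_PI);
}

static double iso_weight(double cx, double cy, double r,
                         const NumericVector& vx, const NumericVector& vy) {
  double f = arc_frac_cpp(cx, cy, r, vx, vy);
  if (f < 1e-6) f = 1e-6;  // guard: point on the boundary, sliver window
  return 1.0 / f;
}

// ---------------------------------------------------------------------------
// K function.  K(s_k) = area / n^2 * sum over ordered pairs (i, j), i != j,
// d_ij <= s_k, of w_ij; w_ij = 1 (no correction) or Ripley's isotropic
// weight, the reciprocal circumference fraction of the circle centred at i
// through j.  Zero-distance pairs (duplicate addresses) count at every s.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector kfun_cpp(NumericVector x, NumericVector y,
                       NumericVector vx, NumericVector vy,
                       NumericVector sgrid, double area, bool iso) {
  int n = x.size(), nb = sgrid.size();
  double smax = sgrid[nb - 1];
  std::vector<double> acc(nb, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::hypot(x[i] - x[j], y[i] - y[j]);
      if (d > smax) continue;
      int b = std::lower_bound(sgrid.begin(), sgrid.end(), d) - sgrid.begin();
      if (b >= nb) continue;
      double w = 2.0;
      if (iso && d > 0)
        w = iso_weight(x[i], y[i], d, vx, vy) + iso_weight(x[j], y[j], d, vx, vy);
      acc[b] += w;
    }
  }
  NumericVector k(nb);
  double run = 0.0;
  for (int b = 0; b < nb; ++b) { run += acc[b]; k[b] = area / ((double)n * n) * run; }
  return k;
}

// Pair table for case-control permutation work: unordered pairs with
// d <= max(sgrid), each carrying w_ij + w_ji and the index of the first grid
// distance >= d.  Geometry only, so it is computed once and reused across
// random labelings.
// [[Rcpp::export]]
List cc_pairs_cpp(NumericVector x, NumericVector y,
                  NumericVector vx, NumericVector vy,
                  NumericVector sgrid, bool iso) {
  int n = x.size(), nb = sgrid.size();
  double smax = sgrid[nb - 1];
  std::vector<int> pi, pj, bin;
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::hypot(x[i] - x[j], y[i] - y[j]);
      if (d > smax) continue;
      int b = std::lower_bound(sgrid.begin(), sgrid.end(), d) - sgrid.begin();
      if (b >= nb) continue;
      double ww = 2.0;
      if (iso && d > 0)
        ww = iso_weight(x[i], y[i], d, vx, vy) + iso_weight(x[j], y[j], d, vx, vy);
      pi.push_back(i + 1); pj.push_back(j + 1); bin.push_back(b); w.push_back(ww);
    }
  }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["bin"] = wrap(bin), _["w"] = wrap(w));
}

// D(s) for a set of labelings over a fixed pair table.  labels: n x m matrix,
// 1 = case, 0 = control.  Returns m x nbins matrix of D values.
// [[Rcpp::export]]
NumericMatrix dfun_perm_cpp(IntegerVector pi, IntegerVector pj,
                            IntegerVector bin, NumericVector w,
                            int nbins, double area, IntegerMatrix labels) {
  int m = labels.ncol(), np = pi.size(), n = labels.nrow();
  NumericMatrix out(m, nbins);
  std::vector<double> ca(nbins), co(nbins);
  for (int c = 0; c < m; ++c) {
    std::fill(ca.begin(), ca.end(), 0.0);
    std::fill(co.begin(), co.end(), 0.0);
    double nc = 0;
    for (int i = 0; i < n; ++i) nc += labels(i, c);
    double nk = n - nc;
    for (int p = 0; p < np; ++p) {
      int a = labels(pi[p] - 1, c), b = labels(pj[p] - 1, c);
      if (a == 1 && b == 1) ca[bin[p]] += w[p];
      else if (a == 0 && b == 0) co[bin[p]] += w[p];
    }
    double runc = 0.0, runk = 0.0;
    for (int b = 0; b < nbins; ++b) {
      runc += ca[b]; runk += co[b];
      out(c, b) = area * (runc / (nc * nc) - runk / (nk * nk));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bernoulli scan statistic.  Windows are closed discs centred at case
// locations; candidate radii are the distances from the centre to every
// at-risk point within max_radius (ties handled together, so each distinct
// inside-set is evaluated once).  Kernel 0 is the case-control likelihood
// kernel n*log(n/N) + m*log(m/M) on the indicator n/N > m/M; kernel 1 is the
// full Bernoulli log likelihood ratio.
// ---------------------------------------------------------------------------

static inline double xlogy(double a, double b) {
  return a > 0 ? a * std::log(b) : 0.0;
}

static double llr_counts(double n_in, double N_in, double C, double N,
                         int kernel) {
  double m = C - n_in, M = N - N_in;
  if (M <= 0) return R_NegInf;                 // whole-region window
  if (n_in * M <= m * N_in) return R_NegInf;   // indicator I() = 0
  if (kernel == 0)
    return xlogy(n_in, n_in / N_in) + xlogy(m, m / M);
  double ll = xlogy(n_in, n_in / N_in) + xlogy(N_in - n_in, (N_in - n_in) / N_in) +
              xlogy(m, m / M) + xlogy(M - m, (M - m) / M);
  double l0 = xlogy(C, C / N) + xlogy(N - C, (N - C) / N);
  return ll - l0;
}

// [[Rcpp::export]]
double llr_counts_cpp(double n_in, double N_in, double n_out, double M_out,
                      int kernel) {
  return llr_counts(n_in, N_in, n_in + n_out, N_in + M_out, kernel);
}

// Neighbour structure: for each point, indices (0-based, flat) of all points
// within max_radius of it (itself included), sorted by distance.
// [[Rcpp::export]]
List scan_prep_cpp(NumericVector x, NumericVector y, double max_radius) {
  int n = x.size();
  IntegerVector off(n + 1);
  std::vector<int> idx;
  std::vector<double> dd;
  std::vector<std::pair<double, int> > row;
  for (int i = 0; i < n; ++i) {
    row.clear();
    for (int j = 0; j < n; ++j) {
      double d = std::hypot(x[i] - x[j], y[i] - y[j]);
      if (d <= max_radius) row.push_back(std::make_pair(d, j));
    }
    std::sort(row.begin(), row.end());
    for (size_t k = 0; k < row.size(); ++k) {
      dd.push_back(row[k].first);
      idx.push_back(row[k].second);
    }
    off[i + 1] = (int)idx.size();
  }
  return List::create(_["offsets"] = off, _["idx"] = wrap(idx),
                      _["dist"] = wrap(dd));
}

struct BestWin { double llr, radius; int n_in, N_in, center; };

// Scan all windows centred at case locations for one labeling; fills per
// centre bests when `per_center` non-null, returns the global best with
// ties broken by smaller radius then lower centre index.
static BestWin scan_one(const IntegerVector& off, const IntegerVector& idx,
                        const NumericVector& dist, const int* is_case,
                        int n, int kernel,
                        std::vector<BestWin>* per_center) {
  double C = 0;
  for (int i = 0; i < n; ++i) C += is_case[i];
  BestWin best; best.llr = R_NegInf; best.radius = R_PosInf;
  best.n_in = 0; best.N_in = 0; best.center = -1;
  for (int c = 0; c < n; ++c) {
    if (!is_case[c]) continue;
    BestWin cb; cb.llr = R_NegInf; cb.radius = R_PosInf;
    cb.n_in = 0; cb.N_in = 0; cb.center = c;
    int lo = off[c], hi = off[c + 1];
    int n_in = 0, N_in = 0;
    int k = lo;
    while (k < hi) {
      double r = dist[k];
      while (k < hi && dist[k] == r) {        // absorb distance ties: closed disc
        n_in += is_case[idx[k]];
        ++N_in; ++k;
      }
      double llr = llr_counts(n_in, N_in, C, n, kernel);
      if (llr > cb.llr + 1e-12 ||
          (llr > cb.llr - 1e-12 && r < cb.radius - 1e-12)) {
        cb.llr = llr; cb.radius = r; cb.n_in = n_in; cb.N_in = N_in;
      }
    }
    if (per_center) per_center->push_back(cb);
    if (cb.llr > best.llr + 1e-12 ||
        (cb.llr > best.llr - 1e-12 &&
         (cb.radius < best.radius - 1e-12 ||
          (cb.radius < best.radius + 1e-12 && cb.center < best.center)))) {
      best = cb;
    }
  }
  return best;
}

// Observed scan: best window per case centre.
// [[Rcpp::export]]
DataFrame scan_observed_cpp(IntegerVector offsets, IntegerVector idx,
                            NumericVector dist, IntegerVector is_case,
                            int kernel) {
  int n = is_case.size();
  std::vector<BestWin> pc;
  scan_one(offsets, idx, dist, INTEGER(is_case), n, kernel, &pc);
  int m = pc.size();
  IntegerVector center(m), n_in(m), N_in(m);
  NumericVector llr(m), radius(m);
  for (int i = 0; i < m; ++i) {
    center[i] = pc[i].center + 1; llr[i] = pc[i].llr;
    radius[i] = pc[i].radius == R_PosInf ? NA_REAL : pc[i].radius;
    n_in[i] = pc[i].n_in; N_in[i] = pc[i].N_in;
  }
  return DataFrame::create(_["center"] = center, _["radius"] = radius,
                           _["n_in"] = n_in, _["N_in"] = N_in,
                           _["llr"] = llr);
}

// Monte Carlo null: C case labels re-drawn uniformly over all at-risk
// locations per replicate (random labeling), max statistic recorded.
// Windows are centred at the replicate's own case locations, so replicates
// are exchangeable with the observed statistic.  Uses R's RNG.
// [[Rcpp::export]]
NumericVector scan_null_cpp(IntegerVector offsets, IntegerVector idx,
                            NumericVector dist, int n, int C,
                            int kernel, int nrep) {
  NumericVector out(nrep);
  std::vector<int> lab(n);
  for (int r = 0; r < nrep; ++r) {
    std::fill(lab.begin(), lab.end(), 0);
    IntegerVector pick = Rcpp::sample(n, C, false);  // 1-based
    for (int k = 0; k < C; ++k) lab[pick[k] - 1] = 1;
    BestWin b = scan_one(offsets, idx, dist, lab.data(), n, kernel, 0);
    out[r] = b.llr;
  }
  return out;
}
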