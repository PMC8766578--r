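#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted squared-distance row for treated unit i against all controls,
// written k-outer / j-inner so the compiler can vectorize the inner loop.
static inline void dist_row(const double *xt, const double *xc,
                            const double *w, int nt, int nc, int k, int i,
                            std::vector<double> &buf) {
  std::fill(buf.begin(), buf.end(), 0.0);
  for (int m = 0; m < k; ++m) {
    const double ti = xt[i + (size_t)m * nt];
    const double wm = w[m];
    const double *col = xc + (size_t)m * nc;
    for (int j = 0; j < nc; ++j) {
      const double diff = ti - col[j];
      buf[j] += wm * diff * diff;
    }
  }
}

// Index of the nearest eligible control for treated i, or -1 when the
// caliper excludes every control. Ties keep the lowest control index.
static inline int nearest_control(const double *xt, const double *xc,
                                  int nt, int nc, int k, int i,
                                  double caliper,
                                  const std::vector<double> &buf) {
  int best_j = -1;
  double best = R_PosInf;
  if (caliper > 0.0) {
    for (int j = 0; j < nc; ++j) {
      bool ok = true;
      for (int m = 0; m < k; ++m) {
        const double diff = xt[i + (size_t)m * nt] - xc[j + (size_t)m * nc];
        if (std::abs(diff) > caliper) { ok = false; break; }
      }
      if (ok && buf[j] < best) { best = buf[j]; best_j = j; }
    }
  } else {
    for (int j = 0; j < nc; ++j) {
      if (buf[j] < best) { best = buf[j]; best_j = j; }
    }
  }
  return best_j;
}

// One-to-one nearest-control match with replacement under weighted
// squared Euclidean distance on standardized covariates. Optional
// per-covariate caliper: a control is eligible only when |z_t - z_c| <=
// caliper on every covariate; treated units with no eligible control get
// NA. caliper <= 0 disables it.
// [[Rcpp::export]]
List nn_match_cpp(NumericMatrix xt, NumericMatrix xc, NumericVector w,
                  double caliper) {
  const int nt = xt.nrow(), nc = xc.nrow(), k = xt.ncol();
  if (xc.ncol() != k || w.size() != k)
    stop("dimension mismatch between treated, control and weights");
  IntegerVector match(nt, NA_INTEGER);
  NumericVector dist(nt, NA_REAL);
  std::vector<double> buf(nc);
  const double *pt = REAL(xt), *pc = REAL(xc), *pw = REAL(w);
  for (int i = 0; i < nt; ++i) {
    dist_row(pt, pc, pw, nt, nc, k, i, buf);
    const int j = nearest_control(pt, pc, nt, nc, k, i, caliper, buf);
    if (j >= 0) {
      match[i] = j + 1; // 1-based
      dist[i] = std::sqrt(buf[j]);
    }
  }
  return List::create(_["match"] = match, _["distance"] = dist);
}

// Balance fitness for a whole population of weight vectors: for each row
// of W, run the nearest-control match and score it by the mean absolute
// standardized mean difference across covariates, with the control-group
// post-matching sample SD as denominator (0 SMD when both the SD and the
// mean difference vanish, +Inf when only the SD does). Returns the
// fitness per candidate and each candidate's per-covariate SMD.
// [[Rcpp::export]]
List ga_fitness_cpp(NumericMatrix xt, NumericMatrix xc, NumericMatrix W,
                    double caliper) {
  const int nt = xt.nrow(), nc = xc.nrow(), k = xt.ncol();
  const int npop = W.nrow();
  if (xc.ncol() != k || W.ncol() != k)
    stop("dimension mismatch between treated, control and weights");
  NumericVector fitness(npop);
  NumericMatrix smds(npop, k);
  std::vector<double> buf(nc), wv(k);
  std::vector<int> mt(nt);
  const double *pt = REAL(xt), *pc = REAL(xc);
  for (int p = 0; p < npop; ++p) {
    for (int m = 0; m < k; ++m) wv[m] = W(p, m);
    int kept = 0;
    for (int i = 0; i < nt; ++i) {
      dist_row(pt, pc, wv.data(), nt, nc, k, i, buf);
      mt[i] = nearest_control(pt, pc, nt, nc, k, i, caliper, buf);
      if (mt[i] >= 0) ++kept;
    }
    if (kept == 0) {
      fitness[p] = R_PosInf;
      for (int m = 0; m < k; ++m) smds(p, m) = R_PosInf;
      continue;
    }
    double acc = 0.0;
    for (int m = 0; m < k; ++m) {
      double st = 0.0, sc = 0.0, scc = 0.0;
      for (int i = 0; i < nt; ++i) {
        if (mt[i] < 0) continue;
        st += pt[i + (size_t)m * nt];
        const double cv = pc[mt[i] + (size_t)m * nc];
        sc += cv;
        scc += cv * cv;
      }
      const double mt_mean = st / kept, mc_mean = sc / kept;
      const double var_c = kept > 1
        ? (scc - sc * sc / kept) / (kept - 1) : 0.0;
      const double sd_c = var_c > 0 ? std::sqrt(var_c) : 0.0;
      double smd;
      if (sd_c == 0.0) {
        smd = (mt_mean == mc_mean) ? 0.0 : R_PosInf;
      } else {
        smd = (mt_mean - mc_mean) / sd_c;
      }
      smds(p, m) = smd;
      acc += std::abs(smd);
    }
    fitness[p] = acc / k;
  }
  return List::create(_["fitness"] = fitness, _["smd"] = smds);
}
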