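#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted pool-adjacent-violators along the given sequence.
// v, w: values/weights already arranged in the candidate order.
// Writes fitted values into fit, returns weighted SSE.
static double pava_core(const double* v, const double* w, int n, double* fit) {
  std::vector<double> bval(n), bwt(n);
  std::vector<int> blen(n);
  int nb = 0;
  for (int i = 0; i < n; ++i) {
    double cv = v[i], cw = w[i];
    int cl = 1;
    while (nb > 0 && bval[nb - 1] > cv) {
      cv = (bval[nb - 1] * bwt[nb - 1] + cv * cw) / (bwt[nb - 1] + cw);
      cw += bwt[nb - 1];
      cl += blen[nb - 1];
      --nb;
    }
    bval[nb] = cv; bwt[nb] = cw; blen[nb] = cl; ++nb;
  }
  int pos = 0;
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < blen[b]; ++k) fit[pos++] = bval[b];
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = v[i] - fit[i];
    sse += w[i] * d * d;
  }
  return sse;
}

// SSE only, for inner search loops (no fitted output needed); caller supplies
// scratch buffers of length n (bval, bwt, bsum, bsumsq) to avoid allocation.
static double pava_sse(const double* v, const double* w, int n,
                       double* bval, double* bwt, double* bsum, double* bsumsq) {
  int nb = 0;
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double cv = v[i], cw = w[i];
    double csum = w[i] * v[i], csumsq = w[i] * v[i] * v[i];
    while (nb > 0 && bval[nb - 1] > cv) {
      double tw = bwt[nb - 1] + cw;
      csum += bsum[nb - 1];
      csumsq += bsumsq[nb - 1];
      cv = csum / tw;
      cw = tw;
      --nb;
    }
    bval[nb] = cv; bwt[nb] = cw; bsum[nb] = csum; bsumsq[nb] = csumsq; ++nb;
  }
  for (int b = 0; b < nb; ++b)
    sse += bsumsq[b] - bsum[b] * bsum[b] / bwt[b];
  return sse < 0 ? 0.0 : sse;  // guard tiny negative round-off
}

struct CmrData {
  const double *x, *wx, *y, *wy;
  int n;
  mutable std::vector<double> bx, bwx, by, bwy, s1, s2, s3, s4;
  CmrData(const double* x_, const double* wx_, const double* y_, const double* wy_, int n_)
    : x(x_), wx(wx_), y(y_), wy(wy_), n(n_), bx(n_), bwx(n_), by(n_), bwy(n_),
      s1(n_), s2(n_), s3(n_), s4(n_) {}
  // combined SSE of the two isotonic fits under a common order (first k entries of ord)
  double eval_prefix(const int* ord, int k) const {
    for (int i = 0; i < k; ++i) {
      int j = ord[i];
      bx[i] = x[j]; bwx[i] = wx[j];
      by[i] = y[j]; bwy[i] = wy[j];
    }
    return pava_sse(bx.data(), bwx.data(), k, s1.data(), s2.data(), s3.data(), s4.data()) +
           pava_sse(by.data(), bwy.data(), k, s1.data(), s2.data(), s3.data(), s4.data());
  }
  double eval(const int* ord) const { return eval_prefix(ord, n); }
};

// Local search over total orders with an insertion (remove-and-reinsert)
// neighbourhood; first-improvement sweeps until a full sweep finds nothing.
static double local_search(const CmrData& d, std::vector<int>& ord) {
  int n = d.n;
  double best = d.eval(ord.data());
  std::vector<int> cand(n);
  bool improved = true;
  while (improved && best > 1e-12) {
    improved = false;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        cand = ord;
        int el = cand[i];
        cand.erase(cand.begin() + i);
        cand.insert(cand.begin() + j, el);
        double s = d.eval(cand.data());
        if (s < best - 1e-12) {
          best = s;
          ord = cand;
          improved = true;
          break;  // take the move immediately, rescan from here
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_pava(NumericVector values, NumericVector weights) {
  int n = values.size();
  NumericVector fit(n);
  double sse = pava_core(values.begin(), weights.begin(), n, fit.begin());
  return List::create(_["fitted"] = fit, _["sse"] = sse);
}

// [[Rcpp::export]]
double cpp_cmr_eval(NumericVector x, NumericVector wx, NumericVector y,
                    NumericVector wy, IntegerVector order) {
  CmrData d(x.begin(), wx.begin(), y.begin(), wy.begin(), x.size());
  std::vector<int> ord(order.begin(), order.end());
  return d.eval(ord.data());
}

// [[Rcpp::export]]
List cpp_cmr_exhaustive(NumericVector x, NumericVector wx, NumericVector y,
                        NumericVector wy) {
  int n = x.size();
  CmrData d(x.begin(), wx.begin(), y.begin(), wy.begin(), n);
  std::vector<int> perm(n), best_ord(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  best_ord = perm;
  double best = d.eval(perm.data());
  // Heap's algorithm
  std::vector<int> c(n, 0);
  int i = 0;
  while (i < n && best > 1e-15) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(perm[0], perm[i]);
      else std::swap(perm[c[i]], perm[i]);
      double s = d.eval(perm.data());
      if (s < best) { best = s; best_ord = perm; }
      ++c[i];
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return List::create(_["order"] = IntegerVector(best_ord.begin(), best_ord.end()),
                      _["sse"] = best);
}

// [[Rcpp::export]]
List cpp_cmr_multistart(NumericVector x, NumericVector wx, NumericVector y,
                        NumericVector wy, IntegerMatrix starts) {
  int n = x.size();
  CmrData d(x.begin(), wx.begin(), y.begin(), wy.begin(), n);
  double best = R_PosInf;
  std::vector<int> best_ord(n), ord(n);
  for (int s = 0; s < starts.nrow(); ++s) {
    for (int i = 0; i < n; ++i) ord[i] = starts(s, i);
    double v = local_search(d, ord);
    if (v < best) { best = v; best_ord = ord; }
    if (best <= 1e-15) break;
  }
  return List::create(_["order"] = IntegerVector(best_ord.begin(), best_ord.end()),
                      _["sse"] = best);
}

static void bb_rec(const CmrData& d, std::vector<int>& prefix, std::vector<bool>& used,
                   double& best, std::vector<int>& best_ord) {
  int n = d.n;
  int k = (int)prefix.size();
  if (k == n) {
    double s = d.eval(prefix.data());
    if (s < best) { best = s; best_ord = prefix; }
    return;
  }
  if (k >= 2) {
    // prefix-only PAVA SSE is a valid lower bound on any completion
    double lb = d.eval_prefix(prefix.data(), k);
    if (lb >= best - 1e-12) return;
  }
  for (int c = 0; c < n; ++c) {
    if (used[c]) continue;
    used[c] = true;
    prefix.push_back(c);
    bb_rec(d, prefix, used, best, best_ord);
    prefix.pop_back();
    used[c] = false;
    if (best <= 1e-15) return;
  }
}

// [[Rcpp::export]]
List cpp_cmr_branch_bound(NumericVector x, NumericVector wx, NumericVector y,
                          NumericVector wy, IntegerMatrix starts) {
  int n = x.size();
  CmrData d(x.begin(), wx.begin(), y.begin(), wy.begin(), n);
  // seed the incumbent with multistart local search
  double best = R_PosInf;
  std::vector<int> best_ord(n), ord(n);
  for (int s = 0; s < starts.nrow(); ++s) {
    for (int i = 0; i < n; ++i) ord[i] = starts(s, i);
    double v = local_search(d, ord);
    if (v < best) { best = v; best_ord = ord; }
  }
  if (best > 1e-15) {
    std::vector<int> prefix;
    prefix.reserve(n);
    std::vector<bool> used(n, false);
    bb_rec(d, prefix, used, best, best_ord);
  }
  return List::create(_["order"] = IntegerVector(best_ord.begin(), best_ord.end()),
                      _["sse"] = best);
}
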