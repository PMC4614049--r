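// Connected-component clustering of suprathreshold channel x frequency x
// time statistic maps, and the sign-flip permutation null of the maximum
// cluster statistic. Cells are indexed ch + nch*(f + nf*t) (0-based);
// adjacency is the electrode graph (CSR) plus chain adjacency on the
// frequency and time axes. t-values with (numerically) zero variance are
// capped at +/-TCAP and treated as suprathreshold.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TCAP = 1e6;

// flood fill from seed over same-sign suprathreshold cells; returns mass
// and size, marks labels
static void flood(const double* t, int ncell, int nch, int nf, int nt,
                  double thresh, int sgn, int seed, int label,
                  int* labels, std::vector<int>& stack,
                  const int* adjPtr, const int* adjIdx,
                  double* mass, int* size) {
  *mass = 0.0; *size = 0;
  stack.clear();
  stack.push_back(seed);
  labels[seed] = label;
  while (!stack.empty()) {
    int cell = stack.back(); stack.pop_back();
    *mass += t[cell];
    (*size)++;
    int ch = cell % nch;
    int rest = cell / nch;
    int f = rest % nf;
    int ti = rest / nf;
    // candidate neighbours
    int nbr[2];
    int nn = 0;
    if (f > 0) { nbr[nn++] = cell - nch; }
    if (f < nf - 1) { nbr[nn++] = cell + nch; }
    for (int k = 0; k < nn; ++k) {
      int c2 = nbr[k];
      if (labels[c2] == 0 && sgn * t[c2] > thresh) {
        labels[c2] = label; stack.push_back(c2);
      }
    }
    if (ti > 0) {
      int c2 = cell - nch * nf;
      if (labels[c2] == 0 && sgn * t[c2] > thresh) {
        labels[c2] = label; stack.push_back(c2);
      }
    }
    if (ti < nt - 1) {
      int c2 = cell + nch * nf;
      if (labels[c2] == 0 && sgn * t[c2] > thresh) {
        labels[c2] = label; stack.push_back(c2);
      }
    }
    for (int a = adjPtr[ch]; a < adjPtr[ch + 1]; ++a) {
      int c2 = adjIdx[a] + nch * (f + nf * ti);
      if (labels[c2] == 0 && sgn * t[c2] > thresh) {
        labels[c2] = label; stack.push_back(c2);
      }
    }
  }
}

// label all clusters of a t map; returns labels (1-based, 0 = none) and
// per-cluster sign, mass, size
// [[Rcpp::export]]
List cppLabelClusters(NumericVector tvals, int nch, int nf, int nt,
                      double thresh, IntegerVector adjPtr,
                      IntegerVector adjIdx) {
  int ncell = nch * nf * nt;
  if (tvals.size() != ncell) stop("t map size disagrees with dimensions");
  IntegerVector labels(ncell, 0);
  std::vector<double> masses;
  std::vector<int> sizes, signs;
  std::vector<int> stack;
  const double* t = tvals.begin();
  int label = 0;
  for (int i = 0; i < ncell; ++i) {
    if (labels[i] != 0) continue;
    int sgn = t[i] > thresh ? 1 : (t[i] < -thresh ? -1 : 0);
    if (sgn == 0) continue;
    double mass; int size;
    ++label;
    flood(t, ncell, nch, nf, nt, thresh, sgn, i, label, labels.begin(),
          stack, adjPtr.begin(), adjIdx.begin(), &mass, &size);
    masses.push_back(mass);
    sizes.push_back(size);
    signs.push_back(sgn);
  }
  return List::create(_["labels"] = labels, _["mass"] = wrap(masses),
                      _["size"] = wrap(sizes), _["sign"] = wrap(signs));
}

// max cluster statistic of one already-computed t map
static double maxStat(const double* t, int nch, int nf, int nt,
                      double thresh, int useSize,
                      const int* adjPtr, const int* adjIdx,
                      std::vector<int>& labels, std::vector<int>& stack) {
  int ncell = nch * nf * nt;
  std::fill(labels.begin(), labels.end(), 0);
  double best = 0.0;
  int label = 0;
  for (int i = 0; i < ncell; ++i) {
    if (labels[i] != 0) continue;
    int sgn = t[i] > thresh ? 1 : (t[i] < -thresh ? -1 : 0);
    if (sgn == 0) continue;
    double mass; int size;
    ++label;
    flood(t, ncell, nch, nf, nt, thresh, sgn, i, label, labels.data(),
          stack, adjPtr, adjIdx, &mass, &size);
    double stat = useSize ? (double)size : std::fabs(mass);
    if (stat > best) best = stat;
  }
  return best;
}

// Time-shift surrogate null of the maximum |cluster statistic|.
// L: power over an extended time grid, laid out
// [chf + CF*tt + CF*ntExt*tr] with chf = ch + nch*f and CF = nch*nf
// (logInput = 1: L is log power, geometric baseline; logInput = 0: L is
// raw power and the arithmetic baseline mean is taken before the log
// ratio). anaPos/basePos: 0-based indices of the analysis/baseline bins
// on the extended grid at zero shift; offsets: the admissible bin
// offsets; shiftIdx: trials x resamples of 0-based indices into
// offsets, such that all shifted indices stay inside the grid. Per
// resample and trial, the normalized value is (log) L at the shifted
// analysis bin minus the (log of the) mean over the shifted baseline
// bins; the max |cluster statistic| of the t map is recorded.
// [[Rcpp::export]]
NumericVector cppShiftMaxStat(NumericVector L, int n, int nch, int nf,
                              int ntExt, IntegerVector anaPos,
                              IntegerVector basePos,
                              IntegerVector offsets,
                              const arma::imat& shiftIdx, double thresh,
                              int useSize, int logInput,
                              IntegerVector adjPtr,
                              IntegerVector adjIdx) {
  int CF = nch * nf;
  int nt = anaPos.size();
  int nb = basePos.size();
  int K = offsets.size();
  int ncell = CF * nt;
  int nperm = shiftIdx.n_cols;
  if ((int)shiftIdx.n_rows != n)
    stop("shiftIdx row count disagrees with trials");
  if ((R_xlen_t)CF * ntExt * n != L.size())
    stop("power size disagrees with dimensions");
  const double* Lp = L.begin();
  // per-(trial, offset) baseline log-means, each a CF-vector
  std::vector<double> BM((R_xlen_t)n * K * CF);
  double binv = 1.0 / nb;
  for (int tr = 0; tr < n; ++tr) {
    const double* Ltr = Lp + (R_xlen_t)CF * ntExt * tr;
    for (int k = 0; k < K; ++k) {
      double* bm = BM.data() + ((R_xlen_t)tr * K + k) * CF;
      std::fill(bm, bm + CF, 0.0);
      for (int b = 0; b < nb; ++b) {
        const double* page = Ltr + (R_xlen_t)CF * (basePos[b] + offsets[k]);
        for (int c = 0; c < CF; ++c) bm[c] += page[c];
      }
      for (int c = 0; c < CF; ++c) {
        bm[c] *= binv;
        if (!logInput) bm[c] = std::log(bm[c]);
      }
    }
  }
  NumericVector out(nperm);
  std::vector<int> labels(ncell), stack;
  std::vector<double> tbuf(ncell), su(ncell), sc(ncell);
  double dfinv = 1.0 / (n - 1);
  // fast path: precompute all per-(trial, offset) normalized maps, then
  // accumulate by streaming whole columns (vectorizable); skipped when
  // the table would be too large
  R_xlen_t vbytes = (R_xlen_t)ncell * n * K * 8;
  std::vector<double> V;
  bool fast = vbytes <= (R_xlen_t)1e9;
  if (fast) {
    V.resize((R_xlen_t)ncell * n * K);
    for (int tr = 0; tr < n; ++tr) {
      const double* Ltr = Lp + (R_xlen_t)CF * ntExt * tr;
      for (int k = 0; k < K; ++k) {
        const double* __restrict bm =
          BM.data() + ((R_xlen_t)tr * K + k) * CF;
        double* __restrict vt = V.data() + (R_xlen_t)ncell * (tr * K + k);
        for (int t = 0; t < nt; ++t) {
          const double* __restrict page =
            Ltr + (R_xlen_t)CF * (anaPos[t] + offsets[k]);
          double* __restrict vrow = vt + (R_xlen_t)CF * t;
          for (int c = 0; c < CF; ++c)
            vrow[c] = (logInput ? page[c] : std::log(page[c])) - bm[c];
        }
      }
    }
  }
  for (int j = 0; j < nperm; ++j) {
    std::fill(su.begin(), su.end(), 0.0);
    std::fill(sc.begin(), sc.end(), 0.0);
    double* __restrict sup = su.data();
    double* __restrict scp = sc.data();
    for (int tr = 0; tr < n; ++tr) {
      int k = shiftIdx(tr, j);
      if (fast) {
        const double* __restrict vcol =
          V.data() + (R_xlen_t)ncell * (tr * K + k);
        for (int i = 0; i < ncell; ++i) {
          double v = vcol[i];
          sup[i] += v;
          scp[i] += v * v;
        }
      } else {
        const double* Ltr = Lp + (R_xlen_t)CF * ntExt * tr;
        const double* __restrict bm =
          BM.data() + ((R_xlen_t)tr * K + k) * CF;
        for (int t = 0; t < nt; ++t) {
          const double* __restrict page =
            Ltr + (R_xlen_t)CF * (anaPos[t] + offsets[k]);
          double* __restrict st = sup + (R_xlen_t)CF * t;
          double* __restrict qt = scp + (R_xlen_t)CF * t;
          for (int c = 0; c < CF; ++c) {
            double v = (logInput ? page[c] : std::log(page[c])) - bm[c];
            st[c] += v;
            qt[c] += v * v;
          }
        }
      }
    }
    for (int i = 0; i < ncell; ++i) {
      double mean = sup[i] / n;
      double var = (scp[i] - n * mean * mean) * dfinv;
      double tv;
      if (var < 1e-20) tv = mean > 0 ? TCAP : (mean < 0 ? -TCAP : 0.0);
      else {
        tv = mean / std::sqrt(var / n);
        if (tv > TCAP) tv = TCAP;
        if (tv < -TCAP) tv = -TCAP;
      }
      tbuf[i] = tv;
    }
    out[j] = maxStat(tbuf.data(), nch, nf, nt, thresh, useSize,
                     adjPtr.begin(), adjIdx.begin(), labels, stack);
  }
  return out;
}

// Monte Carlo null of the maximum |cluster statistic|.
// X: trials x cells of (centered, for the bootstrap) normalized power;
// S: trials x resamples of weights - +/-1 sign flips (bootstrap = 0,
// per-cell sum of squares then constant and passed as ss) or bootstrap
// multiplicities (bootstrap = 1, per-cell per-resample sum of squares is
// (X^2)' S).
// [[Rcpp::export]]
NumericVector cppPermMaxStat(const arma::mat& X, const arma::mat& S,
                             const arma::vec& ss, double thresh,
                             int nch, int nf, int nt, int useSize,
                             int bootstrap,
                             IntegerVector adjPtr, IntegerVector adjIdx) {
  int n = X.n_rows;
  int ncell = X.n_cols;
  if (ncell != nch * nf * nt) stop("cell count disagrees with dimensions");
  int nperm = S.n_cols;
  NumericVector out(nperm);
  std::vector<int> labels(ncell), stack;
  std::vector<double> tbuf(ncell);
  int chunk = std::max(1, (int)(8e6 / std::max(1, ncell)));
  double dfinv = 1.0 / (n - 1);
  arma::mat X2;
  if (bootstrap) X2 = X % X;
  for (int p0 = 0; p0 < nperm; p0 += chunk) {
    int p1 = std::min(nperm, p0 + chunk);
    arma::mat T = X.t() * S.cols(p0, p1 - 1);   // ncell x chunk of sums
    arma::mat Q;
    if (bootstrap) Q = X2.t() * S.cols(p0, p1 - 1); // sums of squares
    for (int j = 0; j < p1 - p0; ++j) {
      const double* col = T.colptr(j);
      const double* qcol = bootstrap ? Q.colptr(j) : (const double*)0;
      for (int i = 0; i < ncell; ++i) {
        double mean = col[i] / n;
        double sq = bootstrap ? qcol[i] : ss(i);
        double var = (sq - n * mean * mean) * dfinv;
        double tv;
        if (var < 1e-20) tv = mean > 0 ? TCAP : (mean < 0 ? -TCAP : 0.0);
        else {
          tv = mean / std::sqrt(var / n);
          if (tv > TCAP) tv = TCAP;
          if (tv < -TCAP) tv = -TCAP;
        }
        tbuf[i] = tv;
      }
      out[p0 + j] = maxStat(tbuf.data(), nch, nf, nt, thresh, useSize,
                            adjPtr.begin(), adjIdx.begin(), labels, stack);
    }
  }
  return out;
}
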