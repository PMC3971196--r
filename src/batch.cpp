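#include <Rcpp.h>
using namespace Rcpp;

// Batch kernels used by the guide-tree and distance stages: same Gotoh
// recursion as affine_align_dp, specialised to residue index vectors so
// thousands of short-domain pairs can be processed without R-level
// allocation per pair.

struct DpBuf {
  std::vector<double> M, X, Y;
  std::vector<signed char> pM, pX, pY;
  void resize(size_t sz) {
    M.assign(sz, -1e100); X.assign(sz, -1e100); Y.assign(sz, -1e100);
    pM.assign(sz, 0); pX.assign(sz, 0); pY.assign(sz, 0);
  }
};

static double pair_identity(const std::vector<int> &a, const std::vector<int> &b,
                            const std::vector<double> &sub, int ns,
                            double go, double ge, DpBuf &buf) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = n + 1;
  buf.resize((size_t)(m + 1) * W);
  auto at = [W](int i, int j) { return (size_t)i * W + j; };
  buf.M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) { buf.X[at(i, 0)] = go + i * ge; buf.pX[at(i, 0)] = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= n; ++j) { buf.Y[at(0, j)] = go + j * ge; buf.pY[at(0, j)] = (j == 1) ? 0 : 2; }
  for (int i = 1; i <= m; ++i) {
    const double *srow = &sub[(size_t)(a[i - 1] - 1) * ns];
    for (int j = 1; j <= n; ++j) {
      const size_t c = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);
      double best = buf.M[d]; int arg = 0;
      if (buf.X[d] > best) { best = buf.X[d]; arg = 1; }
      if (buf.Y[d] > best) { best = buf.Y[d]; arg = 2; }
      buf.M[c] = best + srow[b[j - 1] - 1];
      buf.pM[c] = (signed char)arg;
      double bx = buf.M[u] + go + ge; int argx = 0;
      if (buf.X[u] + ge > bx) { bx = buf.X[u] + ge; argx = 1; }
      if (buf.Y[u] + go + ge > bx) { bx = buf.Y[u] + go + ge; argx = 2; }
      buf.X[c] = bx; buf.pX[c] = (signed char)argx;
      double by = buf.M[l] + go + ge; int argy = 0;
      if (buf.Y[l] + ge > by) { by = buf.Y[l] + ge; argy = 2; }
      if (buf.X[l] + go + ge > by) { by = buf.X[l] + go + ge; argy = 1; }
      buf.Y[c] = by; buf.pY[c] = (signed char)argy;
    }
  }
  int state = 0;
  double score = buf.M[at(m, n)];
  if (buf.X[at(m, n)] > score) { score = buf.X[at(m, n)]; state = 1; }
  if (buf.Y[at(m, n)] > score) { score = buf.Y[at(m, n)]; state = 2; }
  (void)score;
  int i = m, j = n, cols = 0, matches = 0;
  while (i > 0 || j > 0) {
    ++cols;
    if (state == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      state = buf.pM[at(i, j)]; --i; --j;
    } else if (state == 1) {
      state = buf.pX[at(i, j)]; --i;
    } else {
      state = buf.pY[at(i, j)]; --j;
    }
  }
  return 1.0 - (double)matches / (double)cols;
}

// [[Rcpp::export]]
NumericMatrix pairwise_identity_matrix_cpp(List seqs, NumericMatrix sub,
                                           double gap_open, double gap_extend) {
  const int n = seqs.size();
  std::vector<std::vector<int>> sv(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    sv[i] = std::vector<int>(v.begin(), v.end());
  }
  const int ns = sub.nrow();
  std::vector<double> subv((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) subv[(size_t)i * ns + j] = sub(i, j);
  DpBuf buf;
  NumericMatrix d(n, n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double val = pair_identity(sv[i], sv[j], subv, ns, gap_open, gap_extend, buf);
      d(i, j) = val;
      d(j, i) = val;
    }
  }
  return d;
}

// Pairwise ML distance under a reversible model from its spectral
// decomposition: maximises sum_sites log(pi_a P(t)_ab) by golden-section
// search on [0, d_max].
// [[Rcpp::export]]
NumericMatrix ml_pair_distances_cpp(IntegerMatrix idx, NumericVector evals,
                                    NumericMatrix eleft, NumericMatrix erightT,
                                    NumericVector logpi, double d_max) {
  const int n = idx.nrow(), S = idx.ncol(), K = evals.size();
  NumericMatrix d(n, n);
  std::vector<double> counts(400);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same = true;
      std::fill(counts.begin(), counts.end(), 0.0);
      for (int s = 0; s < S; ++s) {
        int a = idx(i, s) - 1, b = idx(j, s) - 1;
        if (a != b) same = false;
        counts[a * 20 + b] += 1.0;
      }
      if (same) { d(i, j) = d(j, i) = 0.0; continue; }
      std::vector<int> ca, cb; std::vector<double> cn;
      double lp = 0.0;
      for (int c = 0; c < 400; ++c) {
        if (counts[c] > 0) {
          int a = c / 20, b = c % 20;
          ca.push_back(a); cb.push_back(b); cn.push_back(counts[c]);
          lp += counts[c] * logpi[a];
        }
      }
      const int nc = (int)ca.size();
      std::vector<double> W((size_t)nc * K);
      for (int c = 0; c < nc; ++c)
        for (int k = 0; k < K; ++k)
          W[(size_t)c * K + k] = eleft(ca[c], k) * erightT(cb[c], k);
      std::vector<double> ex(K);
      auto f = [&](double t) {
        for (int k = 0; k < K; ++k) ex[k] = std::exp(evals[k] * t);
        double ll = lp;
        for (int c = 0; c < nc; ++c) {
          double p = 0.0;
          const double *w = &W[(size_t)c * K];
          for (int k = 0; k < K; ++k) p += w[k] * ex[k];
          if (p < 1e-300) p = 1e-300;
          ll += cn[c] * std::log(p);
        }
        return ll;
      };
      // golden-section maximisation on [0, d_max]
      const double gr = 0.6180339887498949;
      double lo = 0.0, hi = d_max;
      double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
      double f1 = f(x1), f2 = f(x2);
      for (int it = 0; it < 60; ++it) {
        if (f1 >= f2) {
          hi = x2; x2 = x1; f2 = f1;
          x1 = hi - gr * (hi - lo); f1 = f(x1);
        } else {
          lo = x1; x1 = x2; f1 = f2;
          x2 = lo + gr * (hi - lo); f2 = f(x2);
        }
      }
      double est = (lo + hi) / 2.0;
      double fe = (f1 >= f2) ? f1 : f2;
      if (est > d_max - 1e-4 && f(d_max) >= fe - 1e-9) est = d_max;
      if (est < 1e-6 && f(0.0) >= fe - 1e-9) est = 0.0;
      d(i, j) = d(j, i) = est;
    }
  }
  return d;
}

// Shortest-match-at-each-start pattern scan over precomputed per-element
// run lengths (runlen(e, p) = consecutive residues from position p matching
// element e; R supplies it vectorised). Returns 1-based [start, end] spans
// of all non-overlapping matches, left to right.
// [[Rcpp::export]]
IntegerMatrix scan_spans_cpp(IntegerMatrix runlen, IntegerVector minr,
                             IntegerVector maxr, int min_total) {
  const int n_el = runlen.nrow();
  const int n = runlen.ncol() - 1;
  const int max_total_bound = n; // offsets cannot exceed remaining length
  std::vector<int> starts, ends;
  std::vector<char> cur((size_t)max_total_bound + 1), nxt((size_t)max_total_bound + 1);
  int s = 1;
  while (s <= n - min_total + 1) {
    const int avail_total = n - s + 1;
    std::fill(cur.begin(), cur.end(), 0);
    cur[0] = 1;
    int hi_off = 0;
    bool alive = true;
    for (int e = 0; e < n_el && alive; ++e) {
      std::fill(nxt.begin(), nxt.end(), 0);
      alive = false;
      int new_hi = 0;
      for (int o = 0; o <= hi_off; ++o) {
        if (!cur[o]) continue;
        const int p = s + o; // 1-based position of next residue
        const int run = (p <= n) ? runlen(e, p - 1) : 0;
        int lo = minr[e];
        int top = maxr[e];
        if (top > run) top = run;
        if (top > avail_total - o) top = avail_total - o;
        for (int r = lo; r <= top; ++r) {
          nxt[o + r] = 1;
          alive = true;
          if (o + r > new_hi) new_hi = o + r;
        }
      }
      std::swap(cur, nxt);
      hi_off = new_hi;
    }
    int len = -1;
    if (alive) {
      for (int o = 0; o <= hi_off; ++o) {
        if (cur[o]) { len = o; break; }
      }
    }
    if (len > 0) {
      starts.push_back(s);
      ends.push_back(s + len - 1);
      s += len;
    } else {
      ++s;
    }
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (size_t k = 0; k < starts.size(); ++k) {
    out((int)k, 0) = starts[k];
    out((int)k, 1) = ends[k];
  }
  return out;
}
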