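#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping accumulated cost with squared-difference local cost
// and unit steps (match / insert / delete). Two-row dynamic program;
// band < 0 disables the Sakoe-Chiba constraint.
static double dtw_cost(const double* a, int n, const double* b, int m,
                       int band) {
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      const double d = a[i - 1] - b[j - 1];
      const double step = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = d * d + step;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b, int band) {
  return dtw_cost(a.begin(), a.size(), b.begin(), b.size(), band);
}

// Candidate-window context distances for gap imputation. `series` is the
// full day x feature matrix (NA = missing); `starts` are 1-based window
// start rows; `ctx_off`/`mid_off` are 1-based offsets of the context and
// gap-aligned positions within the window; `feat_cols` are 1-based columns
// used for the distance, `target_col` the gapped feature; `query` holds
// the (already normalised) query context, one column per distance feature;
// `feat_mu`/`feat_sd` give the per-feature normalisation applied to
// candidate contexts (0/1 when normalisation is off). Returns the
// per-candidate summed distance, NA where the candidate is unusable
// (missing values in the target window or a context feature).
// [[Rcpp::export]]
NumericVector gap_distances_cpp(NumericMatrix series, IntegerVector starts,
                                IntegerVector ctx_off, IntegerVector mid_off,
                                IntegerVector feat_cols, int target_col,
                                NumericMatrix query, NumericVector feat_mu,
                                NumericVector feat_sd, int band,
                                bool euclid) {
  const int nc = ctx_off.size(), nf = feat_cols.size();
  const int len = nc + mid_off.size();
  NumericVector out(starts.size());
  std::vector<double> ctx(nc);
  for (int s = 0; s < starts.size(); ++s) {
    const int base = starts[s] - 1;
    bool ok = true;
    for (int r = 0; r < len && ok; ++r)
      if (!R_finite(series(base + r, target_col - 1))) ok = false;
    double total = 0;
    for (int f = 0; f < nf && ok; ++f) {
      const int col = feat_cols[f] - 1;
      const double mu = feat_mu[f], sd = feat_sd[f] > 0 ? feat_sd[f] : 1.0;
      for (int r = 0; r < nc; ++r) {
        const double v = series(base + ctx_off[r] - 1, col);
        if (!R_finite(v)) { ok = false; break; }
        ctx[r] = (v - mu) / sd;
      }
      if (!ok) break;
      if (euclid) {
        double ss = 0;
        for (int r = 0; r < nc; ++r) {
          const double d = query(r, f) - ctx[r];
          ss += d * d;
        }
        total += std::sqrt(ss);
      } else {
        total += std::sqrt(dtw_cost(&query(0, f), nc, ctx.data(), nc, band));
      }
    }
    out[s] = ok ? total : NA_REAL;
  }
  return out;
}
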