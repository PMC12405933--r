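// Counting kernels for discrete structure learning.
//
// Data arrive as an integer matrix of 1-based level codes (either raw rows
// or unique contingency cells) plus per-row weights. Both kernels do one
// pass over the rows; everything else is O(#configurations).

#include <Rcpp.h>
using namespace Rcpp;

// Decomposable family score of `node` given `parents` (0-based column
// indices). score_type: 0 = BIC, 1 = BDeu(ess). `n` is the (weighted)
// sample size used in the BIC penalty.
// [[Rcpp::export]]
double cpp_family_score(const IntegerMatrix& cells, const NumericVector& w,
                        int node, const IntegerVector& parents,
                        const IntegerVector& nlev, int score_type, double ess,
                        double n) {
  const int ncells = cells.nrow();
  const int np = parents.size();
  const int nx = nlev[node];
  R_xlen_t ncfg = 1;
  std::vector<const int*> pcol(np);
  std::vector<R_xlen_t> pstride(np);
  const int* base = INTEGER(cells);
  for (int j = 0; j < np; j++) {
    pcol[j] = base + (R_xlen_t)ncells * parents[j];
    pstride[j] = ncfg;
    ncfg *= nlev[parents[j]];
  }
  const int* xcol = base + (R_xlen_t)ncells * node;
  const double* wp = REAL(w);
  std::vector<double> cnt((size_t)nx * ncfg, 0.0);
  for (int i = 0; i < ncells; i++) {
    const double wi = wp[i];
    if (wi == 0.0) continue;
    R_xlen_t idx = 0;
    for (int j = 0; j < np; j++) idx += (R_xlen_t)(pcol[j][i] - 1) * pstride[j];
    cnt[(size_t)(xcol[i] - 1) + (size_t)nx * idx] += wi;
  }
  double res = 0.0;
  if (score_type == 0) {
    for (R_xlen_t k = 0; k < ncfg; k++) {
      double tot = 0.0;
      for (int x = 0; x < nx; x++) tot += cnt[(size_t)nx * k + x];
      if (tot <= 0.0) continue;
      for (int x = 0; x < nx; x++) {
        const double c = cnt[(size_t)nx * k + x];
        if (c > 0.0) res += c * std::log(c / tot);
      }
    }
    res -= 0.5 * std::log(n) * (double)(nx - 1) * (double)ncfg;
  } else {
    const double a_cell = ess / ((double)nx * (double)ncfg);
    const double a_row = ess / (double)ncfg;
    const double lg_cell = lgamma(a_cell), lg_row = lgamma(a_row);
    for (R_xlen_t k = 0; k < ncfg; k++) {
      double tot = 0.0;
      for (int x = 0; x < nx; x++) tot += cnt[(size_t)nx * k + x];
      res += lg_row - lgamma(a_row + tot);
      for (int x = 0; x < nx; x++) {
        res += lgamma(a_cell + cnt[(size_t)nx * k + x]) - lg_cell;
      }
    }
  }
  return res;
}

// G2 (or Pearson X2) statistic of x _|_ y | z with per-stratum degrees of
// freedom adjusted for zero margins. Returns c(stat, df, nonempty_strata).
// [[Rcpp::export]]
NumericVector cpp_ci_stat(const IntegerMatrix& cells, const NumericVector& w,
                          int x, int y, const IntegerVector& zc,
                          const IntegerVector& nlev, int pearson) {
  const int ncells = cells.nrow();
  const int nx = nlev[x], ny = nlev[y];
  const int nz = zc.size();
  R_xlen_t ncfg = 1;
  std::vector<const int*> zcol(nz);
  std::vector<R_xlen_t> zstride(nz);
  const int* base = INTEGER(cells);
  for (int j = 0; j < nz; j++) {
    zcol[j] = base + (R_xlen_t)ncells * zc[j];
    zstride[j] = ncfg;
    ncfg *= nlev[zc[j]];
  }
  const int* xcol = base + (R_xlen_t)ncells * x;
  const int* ycol = base + (R_xlen_t)ncells * y;
  const double* wp = REAL(w);
  std::vector<double> cnt((size_t)nx * ny * ncfg, 0.0);
  for (int i = 0; i < ncells; i++) {
    const double wi = wp[i];
    if (wi == 0.0) continue;
    R_xlen_t idx = 0;
    for (int j = 0; j < nz; j++) idx += (R_xlen_t)(zcol[j][i] - 1) * zstride[j];
    cnt[(size_t)(xcol[i] - 1) + (size_t)nx * (ycol[i] - 1) +
        (size_t)nx * ny * idx] += wi;
  }
  double stat = 0.0, df = 0.0;
  int nonempty = 0;
  std::vector<double> rs(nx), cs(ny);
  for (R_xlen_t k = 0; k < ncfg; k++) {
    const double* tab = &cnt[(size_t)nx * ny * k];
    double tot = 0.0;
    std::fill(rs.begin(), rs.end(), 0.0);
    std::fill(cs.begin(), cs.end(), 0.0);
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        const double c = tab[i + nx * j];
        rs[i] += c;
        cs[j] += c;
        tot += c;
      }
    }
    if (tot <= 0.0) continue;
    nonempty++;
    int nzr = 0, nzc = 0;
    for (int i = 0; i < nx; i++) if (rs[i] > 0.0) nzr++;
    for (int j = 0; j < ny; j++) if (cs[j] > 0.0) nzc++;
    df += (double)std::max(nzr - 1, 0) * (double)std::max(nzc - 1, 0);
    for (int j = 0; j < ny; j++) {
      if (cs[j] <= 0.0) continue;
      for (int i = 0; i < nx; i++) {
        const double e = rs[i] * cs[j] / tot;
        const double c = tab[i + nx * j];
        if (pearson) {
          if (e > 0.0) stat += (c - e) * (c - e) / e;
        } else if (c > 0.0) {
          stat += 2.0 * c * std::log(c / e);
        }
      }
    }
  }
  return NumericVector::create(stat, df, (double)nonempty);
}
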