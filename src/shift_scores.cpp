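#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Type-7 quantile (matches stats::quantile default) via partial selection;
// x is reordered but need not be pre-sorted.
static double quantile7(std::vector<double>& x, double p) {
  const int n = x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  std::nth_element(x.begin(), x.begin() + lo, x.end());
  double xlo = x[lo];
  if (lo + 1 >= n || h == lo) return xlo;
  double xhi = *std::min_element(x.begin() + lo + 1, x.end());
  return xlo + (h - lo) * (xhi - xlo);
}

// Bootstrap n_boot log2 ratios from pre-logged DRM/DSF values; returns
// median and IQR of the bootstrap sample.
static void boot_stats(const std::vector<double>& l2a,
                       const std::vector<double>& l2b,
                       int n_boot, std::vector<double>& buf,
                       double& med, double& iqr) {
  const int na = l2a.size(), nb = l2b.size();
  buf.resize(n_boot);
  for (int i = 0; i < n_boot; ++i) {
    int ia = (int)(unif_rand() * na); if (ia == na) --ia;
    int ib = (int)(unif_rand() * nb); if (ib == nb) --ib;
    buf[i] = l2a[ia] - l2b[ib];
  }
  med = quantile7(buf, 0.5);
  iqr = quantile7(buf, 0.75) - quantile7(buf, 0.25);
}

// Raw difference of bootstrap ratio medians and its pooled spread (the
// root-mean-square of the two IQR-based sigma estimates, IQR/1.349).
// Division (and optional cohort-median centering of d) happens in R.
static void score_pair(const std::vector<double>& wt_drm,
                       const std::vector<double>& wt_dsf,
                       const std::vector<double>& mut_drm,
                       const std::vector<double>& mut_dsf,
                       int n_boot, std::vector<double>& buf,
                       double& med_wt, double& med_mut,
                       double& d, double& spread) {
  double iqr_wt, iqr_mut;
  boot_stats(wt_drm, wt_dsf, n_boot, buf, med_wt, iqr_wt);
  boot_stats(mut_drm, mut_dsf, n_boot, buf, med_mut, iqr_mut);
  double s_wt = iqr_wt / 1.349, s_mut = iqr_mut / 1.349;
  spread = std::sqrt((s_wt * s_wt + s_mut * s_mut) / 2.0);
  d = med_mut - med_wt;
}

static void shuffle(std::vector<double>& v) {
  for (int i = v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1)); if (j == i + 1) --j;
    std::swap(v[i], v[j]);
  }
}

// Assemble one permuted pseudo-genotype pair from a fraction's wildtype and
// mutant values. balanced == true forces each pseudo-group to draw half its
// members from each true genotype (cancels genuine shifts, keeping the null
// clean of alternative-hypothesis contamination); balanced == false is the
// naive pooled shuffle.
static void perm_split(std::vector<double>& wt, std::vector<double>& mut,
                       bool balanced,
                       std::vector<double>& pwt, std::vector<double>& pmut) {
  const int nw = wt.size(), nm = mut.size();
  shuffle(wt);
  shuffle(mut);
  int k;  // members of pseudo-wt taken from true wt
  if (balanced) {
    double half = nw / 2.0;
    k = (int)std::floor(half);
    if (nw % 2 == 1 && unif_rand() < 0.5) ++k;
    if (nw - k > nm) k = nw - nm;
  } else {
    // pooled shuffle: hypergeometric draw realized by shuffling the pool
    std::vector<double> pool(wt);
    pool.insert(pool.end(), mut.begin(), mut.end());
    shuffle(pool);
    pwt.assign(pool.begin(), pool.begin() + nw);
    pmut.assign(pool.begin() + nw, pool.end());
    return;
  }
  pwt.clear(); pmut.clear();
  pwt.insert(pwt.end(), wt.begin(), wt.begin() + k);
  pwt.insert(pwt.end(), mut.begin(), mut.begin() + (nw - k));
  pmut.insert(pmut.end(), wt.begin() + k, wt.end());
  pmut.insert(pmut.end(), mut.begin() + (nw - k), mut.end());
}

// Observed scores plus a genotype-label-permutation null for every protein.
// Inputs are lists (one element per protein) of strictly positive abundance
// vectors. Genotype labels are permuted within each fraction's pooled
// replicate values; fraction structure is preserved.
// [[Rcpp::export]]
List shift_scores_cpp(List wt_drm, List wt_dsf, List mut_drm, List mut_dsf,
                      int n_boot, int n_perm, bool balanced = true) {
  const int n = wt_drm.size();
  NumericVector diff(n), spread(n), med_wt(n), med_mut(n);
  NumericMatrix null_diff(n, n_perm), null_spread(n, n_perm);
  std::vector<double> buf;
  const double L2 = std::log(2.0);

  for (int p = 0; p < n; ++p) {
    NumericVector a = wt_drm[p], b = wt_dsf[p], c = mut_drm[p],
                  d = mut_dsf[p];
    std::vector<double> la(a.size()), lb(b.size()), lc(c.size()),
        ld(d.size());
    for (int i = 0; i < a.size(); ++i) la[i] = std::log(a[i]) / L2;
    for (int i = 0; i < b.size(); ++i) lb[i] = std::log(b[i]) / L2;
    for (int i = 0; i < c.size(); ++i) lc[i] = std::log(c[i]) / L2;
    for (int i = 0; i < d.size(); ++i) ld[i] = std::log(d[i]) / L2;

    double mw, mm, dd, sp;
    score_pair(la, lb, lc, ld, n_boot, buf, mw, mm, dd, sp);
    med_wt[p] = mw; med_mut[p] = mm; diff[p] = dd; spread[p] = sp;

    if (n_perm > 0) {
      std::vector<double> wa(la), wb(lb), wc(lc), wd(ld);
      std::vector<double> pa, pb, pc, pd;
      for (int r = 0; r < n_perm; ++r) {
        perm_split(wa, wc, balanced, pa, pc);
        perm_split(wb, wd, balanced, pb, pd);
        score_pair(pa, pb, pc, pd, n_boot, buf, mw, mm, dd, sp);
        null_diff(p, r) = dd; null_spread(p, r) = sp;
      }
    }
  }
  return List::create(_["diff"] = diff, _["spread"] = spread,
                      _["log2_ratio_wt"] = med_wt,
                      _["log2_ratio_mut"] = med_mut,
                      _["null_diff"] = null_diff,
                      _["null_spread"] = null_spread);
}
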