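#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity bookkeeping: haplotypes in a subset are
// partitioned into identity classes extending outward from a core marker;
// EHH(x) = sum_g C(c_g, 2) / C(n, 2). A haplotype whose ancestry switches
// away from the target before x becomes (and stays) a singleton class from
// its switch point onward -- the ancestry-aware truncation rule.

struct EhhState {
  std::vector<int> grp;        // group id per member; -1 = singleton forever
  int n;                       // subset size (fixed)
  int next_id;
  explicit EhhState(int n_) : grp(n_, 0), n(n_), next_id(1) {}

  // advance one marker; returns EHH after incorporating marker j
  double step(const IntegerMatrix& haps, const std::vector<int>& rows, int j,
              const IntegerMatrix* labels, int target) {
    std::unordered_map<long long, int> remap;
    remap.reserve(grp.size() * 2);
    for (size_t i = 0; i < grp.size(); ++i) {
      if (grp[i] < 0) continue;
      if (labels && (*labels)(rows[i], j) != target) { grp[i] = -1; continue; }
      long long key = (long long)grp[i] * 2LL + haps(rows[i], j);
      auto it = remap.find(key);
      if (it == remap.end()) { remap[key] = next_id; grp[i] = next_id++; }
      else grp[i] = it->second;
    }
    std::unordered_map<int, int> cnt;
    for (size_t i = 0; i < grp.size(); ++i)
      if (grp[i] >= 0) cnt[grp[i]]++;
    double pairs = 0.0;
    for (auto& kv : cnt) pairs += 0.5 * kv.second * (kv.second - 1.0);
    return pairs / (0.5 * (double)n * (n - 1.0));
  }
};

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix haps, IntegerVector rows, int core, int dir,
                   int last, double stop_below,
                   Nullable<IntegerMatrix> labels_, int target) {
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;  // 0-based
  IntegerMatrix labs;
  const IntegerMatrix* lab_p = nullptr;
  if (labels_.isNotNull()) { labs = labels_.get(); lab_p = &labs; }
  EhhState st((int)rr.size());
  std::vector<double> ehh;
  std::vector<int> idx;
  int c0 = core - 1, l0 = last - 1;
  for (int j = c0 + dir; dir > 0 ? j <= l0 : j >= l0; j += dir) {
    double e = st.step(haps, rr, j, lab_p, target - 0);
    ehh.push_back(e);
    idx.push_back(j + 1);
    if (e < stop_below) break;
  }
  return List::create(_["ehh"] = wrap(ehh), _["marker"] = wrap(idx));
}

// trapezoidal iHH over physical distance with interpolation to the cutoff
// crossing and down-weighting of segments spanning gaps larger than maxgap
static double integrate_side(const IntegerMatrix& haps,
                             const std::vector<int>& rows,
                             const NumericVector& pos, int core0, int dir,
                             int lim0, double cutoff, double maxgap,
                             const IntegerMatrix* labels, int target,
                             bool& edge) {
  EhhState st((int)rows.size());
  double area = 0.0, prev_e = 1.0, prev_x = pos[core0];
  edge = true;  // stays true if we run off the chromosome above the cutoff
  if (core0 == lim0) return 0.0;  // no room to extend; caller flags edge
  for (int j = core0 + dir; dir > 0 ? j <= lim0 : j >= lim0; j += dir) {
    double e = st.step(haps, rows, j, labels, target);
    double x = pos[j];
    double gap = std::abs(x - prev_x);
    double scale = (maxgap > 0 && gap > maxgap) ? maxgap / gap : 1.0;
    if (e < cutoff) {
      // interpolate to the exact crossing point
      double frac = (prev_e > e) ? (prev_e - cutoff) / (prev_e - e) : 0.0;
      area += scale * 0.5 * (prev_e + cutoff) * gap * frac;
      edge = false;
      return area;
    }
    area += scale * 0.5 * (prev_e + e) * gap;
    prev_e = e;
    prev_x = x;
    if (e == 0.0) { edge = false; return area; }
  }
  return area;
}

// [[Rcpp::export(name = ".ihs_scan_cpp")]]
List ihs_scan_cpp(IntegerMatrix haps, NumericVector pos_bp,
                  IntegerVector chrom_id, LogicalVector derived_is_alt,
                  Nullable<IntegerMatrix> labels_, int target, int mode,
                  double cutoff, double maxgap, double fmin, double fmax,
                  int min_class, int exclude_snps) {
  int H = haps.nrow(), M = haps.ncol();
  IntegerMatrix labs;
  const IntegerMatrix* lab_p = nullptr;
  if (labels_.isNotNull()) { labs = labels_.get(); lab_p = &labs; }
  // chromosome bounds per marker
  std::vector<int> chr_lo(M), chr_hi(M);
  for (int m = 0, lo = 0; m < M; ++m) {
    if (m > 0 && chrom_id[m] != chrom_id[m - 1]) lo = m;
    chr_lo[m] = lo;
  }
  for (int m = M - 1, hi = M - 1; m >= 0; --m) {
    if (m < M - 1 && chrom_id[m] != chrom_id[m + 1]) hi = m;
    chr_hi[m] = hi;
  }
  NumericVector daf(M, NA_REAL), ihh_a(M, NA_REAL), ihh_d(M, NA_REAL);
  IntegerVector n_a(M, NA_INTEGER), n_d(M, NA_INTEGER), skip(M, 0);
  LogicalVector edge(M, false);
  const IntegerMatrix* trunc_lab = (mode == 0) ? lab_p : nullptr;
  for (int m = 0; m < M; ++m) {
    // qualified haplotypes at this core
    std::vector<int> der, anc;
    int derived_allele = derived_is_alt[m] ? 1 : 0;
    for (int h = 0; h < H; ++h) {
      if (lab_p) {
        if ((*lab_p)(h, m) != target) continue;
        if (mode == 1) {
          // exclude haplotypes with an ancestry change within exclude_snps
          bool ok = true;
          int lo = std::max(chr_lo[m], m - exclude_snps);
          int hi = std::min(chr_hi[m], m + exclude_snps);
          for (int j = lo; j <= hi; ++j)
            if ((*lab_p)(h, j) != target) { ok = false; break; }
          if (!ok) continue;
        }
      }
      if (haps(h, m) == derived_allele) der.push_back(h);
      else anc.push_back(h);
    }
    int n_qual = (int)(der.size() + anc.size());
    if (n_qual < 2) { skip[m] = 3; continue; }
    double f = (double)der.size() / n_qual;
    daf[m] = f;
    n_a[m] = (int)anc.size();
    n_d[m] = (int)der.size();
    if (f < fmin || f > fmax) { skip[m] = 1; continue; }
    if ((int)der.size() < min_class || (int)anc.size() < min_class) {
      skip[m] = 2;
      continue;
    }
    bool eL, eR;
    double a_l = integrate_side(haps, anc, pos_bp, m, -1, chr_lo[m], cutoff,
                                maxgap, trunc_lab, target, eL);
    double a_r = integrate_side(haps, anc, pos_bp, m, +1, chr_hi[m], cutoff,
                                maxgap, trunc_lab, target, eR);
    bool e_anc = eL || eR || (m == chr_lo[m]) || (m == chr_hi[m]);
    double d_l = integrate_side(haps, der, pos_bp, m, -1, chr_lo[m], cutoff,
                                maxgap, trunc_lab, target, eL);
    double d_r = integrate_side(haps, der, pos_bp, m, +1, chr_hi[m], cutoff,
                                maxgap, trunc_lab, target, eR);
    bool e_der = eL || eR || (m == chr_lo[m]) || (m == chr_hi[m]);
    ihh_a[m] = a_l + a_r;
    ihh_d[m] = d_l + d_r;
    edge[m] = e_anc || e_der;
  }
  return List::create(_["daf"] = daf, _["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["n_a"] = n_a, _["n_d"] = n_d, _["edge"] = edge,
                      _["skip"] = skip);
}
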