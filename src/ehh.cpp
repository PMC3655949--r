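// Extended haplotype homozygosity kernels.
//
// Homozygosity uses the unbiased pair-count form sum_h C(n_h,2) / C(n,2).
// Identity classes only refine as the span grows, so EHH is non-increasing
// away from the core by construction. Class refinement uses flat scratch
// arrays (class ids are < n, alleles binary, so keys fit in [0, 2n)).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Reusable scratch for one panel's refinement steps.
struct Refiner {
  std::vector<int> remap;  // key -> new class id, -1 = unseen
  std::vector<int> touched;
  std::vector<int> cnt;
  explicit Refiner(int n) : remap(2 * n, -1) {
    touched.reserve(2 * n);
    cnt.reserve(n);
  }
  // Refine classes `id` (over `members`) by the binary alleles in column
  // `col` (pointer to the hap matrix column). Returns pair-count sum.
  double step(const int* col, const std::vector<int>& members,
              std::vector<int>& id) {
    const int n = (int)members.size();
    touched.clear();
    cnt.clear();
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int key = 2 * id[i] + col[members[i]];
      int g = remap[key];
      if (g < 0) {
        g = next++;
        remap[key] = g;
        touched.push_back(key);
        cnt.push_back(0);
      }
      id[i] = g;
      cnt[g]++;
    }
    for (size_t k = 0; k < touched.size(); ++k) remap[touched[k]] = -1;
    double s = 0.0;
    for (int k = 0; k < next; ++k)
      s += 0.5 * (double)cnt[k] * (double)(cnt[k] - 1);
    return s;
  }
};

double init_hom(const int* col, const std::vector<int>& members,
                std::vector<int>& id) {
  int c0 = 0, c1 = 0;
  for (size_t i = 0; i < members.size(); ++i) {
    int a = col[members[i]];
    id[i] = a;
    if (a == 0) c0++; else c1++;
  }
  return 0.5 * ((double)c0 * (c0 - 1) + (double)c1 * (c1 - 1));
}

// One-sided trapezoid integration with incremental refinement.
// Sets `bad` when border_rule = discard fails (chromosome end reached
// before crossing the floor, or a gap > max_gap).
double side_area(const IntegerMatrix& hap, Refiner& rf,
                 const std::vector<int>& members, const std::vector<int>& id0,
                 double norm, double denom, const NumericVector& pos, int core,
                 int dir, double floor_, double max_gap, bool discard,
                 bool& bad) {
  const int M = hap.ncol(), N = hap.nrow();
  const int* base = hap.begin();
  std::vector<int> id(id0);
  double area = 0.0, prev_pos = pos[core], prev_e = 1.0;
  for (int t = core + dir; t >= 0 && t < M; t += dir) {
    double gap = std::fabs(pos[t] - prev_pos);
    if (gap > max_gap) {
      if (discard) { bad = true; return NA_REAL; }
      return area;  // truncate before the gap
    }
    double e = prev_e > 0.0 ? rf.step(base + (size_t)t * N, members, id) / (denom * norm)
                            : 0.0;
    area += gap * 0.5 * (prev_e + e);
    if (e < floor_) return area;  // floor crossed; this vertex included
    prev_pos = pos[t];
    prev_e = e;
  }
  if (discard) { bad = true; return NA_REAL; }
  return area;  // truncate at the chromosome border
}

}  // namespace

// Full EHH curve for one core. mode: 0 = conditioned on `allele` at the core,
// 1 = site EHHS (all haplotypes, normalized to 1 at the core).
// Returns a length-M vector (NA where undefined).
// [[Rcpp::export]]
NumericVector ehh_curve_cpp(IntegerMatrix hap, int core, int mode, int allele) {
  const int M = hap.ncol(), N = hap.nrow();
  const int* base = hap.begin();
  NumericVector out(M, NA_REAL);
  std::vector<int> members;
  if (mode == 0) {
    for (int i = 0; i < N; ++i)
      if (base[(size_t)core * N + i] == allele) members.push_back(i);
  } else {
    for (int i = 0; i < N; ++i) members.push_back(i);
  }
  if ((int)members.size() < 2) return out;  // curve undefined
  const double denom = 0.5 * (double)members.size() * (double)(members.size() - 1);
  double norm = 1.0;
  std::vector<int> id0(members.size(), 0);
  if (mode == 1) {
    norm = init_hom(base + (size_t)core * N, members, id0) / denom;
    if (norm <= 0.0) return out;  // core homozygosity zero: undefined
  }
  out[core] = 1.0;
  Refiner rf(members.size());
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> id(id0);
    double e = 1.0;
    for (int t = core + dir; t >= 0 && t < M; t += dir) {
      if (e > 0.0) e = rf.step(base + (size_t)t * N, members, id) / (denom * norm);
      out[t] = e;
    }
  }
  return out;
}

// Per-marker iHH_A, iHH_D and iES over a whole panel.
// hap must be polarized (1 = derived). Returns an M x 5 matrix:
// n_anc, n_der, ihh_a, ihh_d, ies.
// [[Rcpp::export]]
NumericMatrix ehh_scan_cpp(IntegerMatrix hap, NumericVector pos, double floor_,
                           double max_gap, bool discard) {
  const int M = hap.ncol(), N = hap.nrow();
  const int* base = hap.begin();
  NumericMatrix out(M, 5);
  colnames(out) = CharacterVector::create("n_anc", "n_der", "ihh_a", "ihh_d", "ies");
  std::vector<int> all(N);
  for (int i = 0; i < N; ++i) all[i] = i;
  const double denom_all = 0.5 * (double)N * (double)(N - 1);
  Refiner rf(N);
  std::vector<int> anc, der, id0_site(N);
  for (int c = 0; c < M; ++c) {
    const int* col = base + (size_t)c * N;
    anc.clear(); der.clear();
    for (int i = 0; i < N; ++i)
      (col[i] == 1 ? der : anc).push_back(i);
    out(c, 0) = (double)anc.size();
    out(c, 1) = (double)der.size();
    for (int which = 0; which < 2; ++which) {
      const std::vector<int>& mem = (which == 0) ? anc : der;
      double val = NA_REAL;
      if ((int)mem.size() >= 2) {
        std::vector<int> id0(mem.size(), 0);
        double denom = 0.5 * (double)mem.size() * (double)(mem.size() - 1);
        bool bad = false;
        double left = side_area(hap, rf, mem, id0, 1.0, denom, pos, c, -1,
                                floor_, max_gap, discard, bad);
        if (!bad) {
          double right = side_area(hap, rf, mem, id0, 1.0, denom, pos, c, +1,
                                   floor_, max_gap, discard, bad);
          if (!bad) val = left + right;
        }
      }
      out(c, 2 + which) = val;
    }
    double ies = NA_REAL;
    if (N >= 2) {
      double norm = init_hom(col, all, id0_site) / denom_all;
      if (norm > 0.0) {
        bool bad = false;
        double left = side_area(hap, rf, all, id0_site, norm, denom_all, pos,
                                c, -1, floor_, max_gap, discard, bad);
        if (!bad) {
          double right = side_area(hap, rf, all, id0_site, norm, denom_all,
                                   pos, c, +1, floor_, max_gap, discard, bad);
          if (!bad) ies = left + right;
        }
      }
    }
    out(c, 4) = ies;
  }
  return out;
}
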