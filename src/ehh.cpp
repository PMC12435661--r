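#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Scratch buffers reused across cores to avoid per-step allocation.
struct EhhScratch {
  std::vector<int> grp, relabel, cnt;
};

// Extended haplotype homozygosity decay from a core SNP, one direction.
//
// hap: haplotypes x sites, 0/1, no missing. Groups of haplotypes identical
// over {core} U {extended SNPs} are refined one SNP at a time; EHH at each
// extension is sum_g C(n_g,2) / C(n,2). Extension stops when EHH drops
// below `cutoff` (the sub-cutoff point is not recorded), when the physical
// distance exceeds `max_extend` bp, when an inter-SNP gap exceeds
// `max_gap` bp, or at the chromosome end.
static void ehh_direction(const IntegerMatrix &hap, const IntegerVector &pos,
                          int core, int dir, double cutoff, double max_extend,
                          double max_gap, EhhScratch &sc,
                          std::vector<double> &dist,
                          std::vector<double> &ehh) {
  const int nhap = hap.nrow();
  const int nsnp = hap.ncol();
  const double npairs = (double)nhap * (nhap - 1) / 2.0;
  dist.clear(); ehh.clear();
  dist.push_back(0.0); ehh.push_back(1.0);
  if (npairs <= 0) return;
  sc.grp.assign(nhap, 0);
  sc.relabel.assign(2 * nhap, -1);
  sc.cnt.assign(nhap, 0);
  int ngrp = 1;
  int prev_pos = pos[core];
  for (int j = core; j >= 0 && j < nsnp; j += dir) {
    if (j != core) {
      double d = std::abs((double)pos[j] - (double)pos[core]);
      double gap = std::abs((double)pos[j] - (double)prev_pos);
      if (d > max_extend || gap > max_gap) break;
    }
    // refine groups by the allele at SNP j
    std::fill(sc.relabel.begin(), sc.relabel.begin() + 2 * ngrp, -1);
    int nnew = 0;
    for (int i = 0; i < nhap; ++i) {
      int key = 2 * sc.grp[i] + hap(i, j);
      if (sc.relabel[key] < 0) sc.relabel[key] = nnew++;
      sc.grp[i] = sc.relabel[key];
    }
    ngrp = nnew;
    std::fill(sc.cnt.begin(), sc.cnt.begin() + ngrp, 0);
    for (int i = 0; i < nhap; ++i) sc.cnt[sc.grp[i]]++;
    double pairs = 0.0;
    for (int g = 0; g < ngrp; ++g)
      pairs += (double)sc.cnt[g] * (sc.cnt[g] - 1) / 2.0;
    double e = pairs / npairs;
    // at j == core the profile value is 1 by definition; the refinement by
    // the core allele only seeds the grouping for subsequent steps
    if (j != core) {
      if (e < cutoff) break;
      dist.push_back(std::abs((double)pos[j] - (double)pos[core]));
      ehh.push_back(e);
    }
    // all haplotypes distinct: EHH is 0 from here on
    if (ngrp == nhap) break;
    prev_pos = pos[j];
  }
}

static double trapezoid(const std::vector<double> &x,
                        const std::vector<double> &y) {
  double s = 0.0;
  for (size_t i = 1; i < x.size(); ++i)
    s += 0.5 * (y[i] + y[i - 1]) * (x[i] - x[i - 1]);
  return s;
}

// [[Rcpp::export]]
List ehh_profile_cpp(IntegerMatrix hap, IntegerVector pos, int core1,
                     double cutoff, double max_extend, double max_gap) {
  int core = core1 - 1;
  if (core < 0 || core >= hap.ncol()) stop("core index out of range");
  EhhScratch sc;
  std::vector<double> dl, el, dr, er;
  ehh_direction(hap, pos, core, -1, cutoff, max_extend, max_gap, sc, dl, el);
  ehh_direction(hap, pos, core, +1, cutoff, max_extend, max_gap, sc, dr, er);
  double ihh = trapezoid(dl, el) + trapezoid(dr, er);
  return List::create(_["dist_left"] = wrap(dl), _["ehh_left"] = wrap(el),
                      _["dist_right"] = wrap(dr), _["ehh_right"] = wrap(er),
                      _["ihh"] = ihh);
}

// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix hap, IntegerVector pos,
                           IntegerVector cores1, double cutoff,
                           double max_extend, double max_gap) {
  NumericVector out(cores1.size());
  EhhScratch sc;
  std::vector<double> dl, el, dr, er;
  dl.reserve(1024); el.reserve(1024); dr.reserve(1024); er.reserve(1024);
  for (int k = 0; k < cores1.size(); ++k) {
    int core = cores1[k] - 1;
    if (core < 0 || core >= hap.ncol()) stop("core index out of range");
    ehh_direction(hap, pos, core, -1, cutoff, max_extend, max_gap, sc, dl, el);
    ehh_direction(hap, pos, core, +1, cutoff, max_extend, max_gap, sc, dr, er);
    out[k] = trapezoid(dl, el) + trapezoid(dr, er);
  }
  return out;
}
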