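// Structured coalescent with recombination (Hudson-style ARG sampler) plus
// the Poisson kernel for blockwise SFS configuration probabilities.
//
// Conventions (shared with the R layer):
//  * time in units of 4*Nref generations, backwards from the present;
//  * population sizes relative to Nref; pair-coalescence rate in a population
//    of relative size f is 2/f, i.e. n(n-1)/f for n lineages;
//  * migration matrix entries mig(i,j) are the *backward* rate at which a
//    single lineage currently in population i jumps to population j,
//    in units of 4*Nref*m;
//  * the block occupies the unit interval [0,1); the total recombination
//    rate for a lineage carrying ancestral material spanning [lo,hi] is
//    rho*(hi-lo) where rho is the block-scaled recombination rate.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double a, b;        // genomic interval [a,b) in [0,1)
  uint64_t mask;      // set of sampled genomes this segment is ancestral to
};

struct Lin {
  int pop;
  std::vector<Seg> segs;
  double lo, hi;      // extremes of carried material (recombination target)
};

// branch-length record over a genomic interval for one mutation-class mask
struct Rec {
  double a, b, len;
  uint64_t mask;
};

void updateExtremes(Lin &l) {
  if (l.segs.empty()) { l.lo = l.hi = 0.0; return; }
  l.lo = l.segs.front().a;
  l.hi = l.segs.back().b;
}

// merge the segment lists of two coalescing lineages; intervals where the
// union mask covers the full sample have found their MRCA and are dropped
std::vector<Seg> mergeSegs(const std::vector<Seg> &x, const std::vector<Seg> &y,
                           uint64_t full) {
  std::vector<double> cuts;
  cuts.reserve(2 * (x.size() + y.size()));
  for (const Seg &s : x) { cuts.push_back(s.a); cuts.push_back(s.b); }
  for (const Seg &s : y) { cuts.push_back(s.a); cuts.push_back(s.b); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  std::vector<Seg> out;
  size_t ix = 0, iy = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    double a = cuts[c], b = cuts[c + 1];
    while (ix < x.size() && x[ix].b <= a) ++ix;
    while (iy < y.size() && y[iy].b <= a) ++iy;
    uint64_t m = 0;
    if (ix < x.size() && x[ix].a <= a && x[ix].b >= b) m |= x[ix].mask;
    if (iy < y.size() && y[iy].a <= a && y[iy].b >= b) m |= y[iy].mask;
    if (m == 0 || m == full) continue;
    if (!out.empty() && out.back().b == a && out.back().mask == m)
      out.back().b = b;
    else
      out.push_back(Seg{a, b, m});
  }
  return out;
}

// unfolded joint-SFS class index of a genome mask: classes are the vectors
// (i_1,...,i_X), 0 <= i_x <= b_x, in lexicographic order (i_1 most
// significant), excluding the all-zero and all-b vectors.  The mixed-radix
// code of the count vector minus one is the class index.
int classIndex(uint64_t mask, const std::vector<uint64_t> &popMasks,
               const std::vector<int> &radixWeight) {
  int code = 0;
  for (size_t x = 0; x < popMasks.size(); ++x) {
#if defined(__GNUC__) || defined(__clang__)
    int cnt = __builtin_popcountll(mask & popMasks[x]);
#else
    uint64_t v = mask & popMasks[x];
    int cnt = 0;
    while (v) { v &= v - 1; ++cnt; }
#endif
    code += cnt * radixWeight[x];
  }
  return code - 1;
}

struct EventRow { double time; int code, i, j; double value; };

struct SimState {
  int npop;
  std::vector<double> sz;      // size (relative) at anchor time
  std::vector<double> gr;      // scaled growth rate
  std::vector<double> anchor;  // anchor time for sz
  std::vector<std::vector<double>> mig;
  std::vector<double> migRowTot;
  void refreshRow(int i) {
    double s = 0.0;
    for (int j = 0; j < npop; ++j) s += mig[i][j];
    migRowTot[i] = s;
  }
  double sizeAt(int i, double t) const {
    return sz[i] * std::exp(-gr[i] * (t - anchor[i]));
  }
};

} // namespace

// Sample blockwise ARGs and accumulate branch length per mutation-class mask.
//
// mode 0: return an (nreps*nblocks) x C matrix of span-weighted average class
//         lengths t_{i,A} per block (rows grouped by replicate);
// mode 1: additionally return, per replicate, the recombination breakpoints
//         and the raw (a,b,mask,len) records for oracle-style recounts;
// mode 2: return only the per-replicate records (for mutation dropping).
//
// blockBounds: increasing cut points in [0,1], length nblocks+1 with 0 and 1
// at the ends; a single block is c(0,1).
// [[Rcpp::export(name = ".simArgs")]]
List simArgs(IntegerVector sampleSizes, NumericVector popSize,
             NumericVector growth, NumericMatrix migration,
             NumericMatrix events, double rho, NumericVector blockBounds,
             int nreps, int mode, int maxIter = 50000000) {
  const int npop0 = sampleSizes.size();
  int nsam = 0;
  for (int x = 0; x < npop0; ++x) nsam += sampleSizes[x];
  if (nsam < 2) stop("need at least two sampled genomes");
  if (nsam > 40) stop("at most 40 sampled genomes are supported");
  const int npop = popSize.size(); // may exceed npop0 (unsampled demes)
  if (npop < npop0) stop("popSize shorter than sampleSizes");

  // per-population genome masks and class radix weights
  std::vector<uint64_t> popMasks(npop0, 0);
  std::vector<int> radixWeight(npop0, 1);
  {
    int k = 0;
    for (int x = 0; x < npop0; ++x)
      for (int g = 0; g < sampleSizes[x]; ++g)
        popMasks[x] |= (uint64_t(1) << (k++));
    for (int x = npop0 - 2; x >= 0; --x)
      radixWeight[x] = radixWeight[x + 1] * (sampleSizes[x + 1] + 1);
  }
  const uint64_t full = (nsam == 64) ? ~uint64_t(0)
                                     : ((uint64_t(1) << nsam) - 1);
  int nClass = 1;
  for (int x = 0; x < npop0; ++x) nClass *= sampleSizes[x] + 1;
  nClass -= 2;

  const int nblock = blockBounds.size() - 1;
  if (nblock < 1) stop("blockBounds must contain at least two cut points");

  std::vector<EventRow> evs;
  for (int r = 0; r < events.nrow(); ++r)
    evs.push_back(EventRow{events(r, 0), (int)events(r, 1), (int)events(r, 2),
                           (int)events(r, 3), events(r, 4)});
  std::stable_sort(evs.begin(), evs.end(),
                   [](const EventRow &a, const EventRow &b) {
                     return a.time < b.time;
                   });

  NumericMatrix tA;
  if (mode != 2) tA = NumericMatrix(nreps * nblock, nClass);
  List detail(mode == 0 ? 0 : nreps);

  RNGScope scope;

  for (int rep = 0; rep < nreps; ++rep) {
    SimState st;
    st.npop = npop;
    st.sz.assign(popSize.begin(), popSize.end());
    st.gr.assign(growth.begin(), growth.end());
    st.anchor.assign(npop, 0.0);
    st.mig.assign(npop, std::vector<double>(npop, 0.0));
    st.migRowTot.assign(npop, 0.0);
    for (int i = 0; i < npop; ++i) {
      for (int j = 0; j < npop; ++j)
        if (i != j) st.mig[i][j] = migration(i, j);
      st.refreshRow(i);
    }

    std::vector<Lin> lins;
    {
      int k = 0;
      for (int x = 0; x < npop0; ++x)
        for (int g = 0; g < sampleSizes[x]; ++g) {
          Lin l;
          l.pop = x;
          l.segs.push_back(Seg{0.0, 1.0, uint64_t(1) << k});
          updateExtremes(l);
          lins.push_back(l);
          ++k;
        }
    }

    std::vector<Rec> recs;          // modes 1 and 2
    std::vector<double> breaks;     // mode 1
    double *tArow = (mode != 2) ? &tA(rep * nblock, 0) : nullptr;
    // column-major offsets for direct accumulation
    const int nrowTA = nreps * nblock;

    auto accumulate = [&](double dt) {
      if (dt <= 0.0) return;
      for (const Lin &l : lins)
        for (const Seg &s : l.segs) {
          if (mode == 0) {
            int ci = classIndex(s.mask, popMasks, radixWeight);
            if (nblock == 1) {
              tArow[ci * nrowTA] += dt * (s.b - s.a);
            } else {
              // distribute across the block windows the segment overlaps
              int bl = (int)(std::upper_bound(blockBounds.begin(),
                                              blockBounds.end(), s.a) -
                             blockBounds.begin()) - 1;
              if (bl < 0) bl = 0;
              for (; bl < nblock && blockBounds[bl] < s.b; ++bl) {
                double lo = std::max(s.a, (double)blockBounds[bl]);
                double hi = std::min(s.b, (double)blockBounds[bl + 1]);
                if (hi > lo)
                  tArow[bl + ci * nrowTA] +=
                      dt * (hi - lo) / (blockBounds[bl + 1] - blockBounds[bl]);
              }
            }
          } else {
            if (!recs.empty() && recs.back().a == s.a && recs.back().b == s.b &&
                recs.back().mask == s.mask)
              recs.back().len += dt;
            else
              recs.push_back(Rec{s.a, s.b, dt, s.mask});
          }
        }
    };

    double t = 0.0;
    size_t evPtr = 0;
    int iter = 0;
    while (!lins.empty()) {
      if (++iter > maxIter)
        stop("ARG simulation exceeded the iteration cap; the scaled event "
             "list may leave lineages unable to coalesce");
      // lineage counts per population
      std::vector<int> nlin(npop, 0);
      for (const Lin &l : lins) nlin[l.pop]++;

      // candidate waiting times
      double uMig = R_PosInf, uRec = R_PosInf, uCoal = R_PosInf;
      int coalPop = -1;
      double totMig = 0.0, totSpan = 0.0;
      for (const Lin &l : lins) {
        totMig += st.migRowTot[l.pop];
        totSpan += (l.hi - l.lo);
      }
      if (totMig > 0.0) uMig = exp_rand() / totMig;
      if (rho > 0.0 && totSpan > 0.0) uRec = exp_rand() / (rho * totSpan);
      for (int i = 0; i < npop; ++i) {
        if (nlin[i] < 2) continue;
        double rate0 = nlin[i] * (nlin[i] - 1) / st.sizeAt(i, t);
        double g = st.gr[i], E = exp_rand(), u;
        if (g == 0.0) {
          u = E / rate0;
        } else {
          double arg = 1.0 + g * E / rate0;
          u = (arg > 0.0) ? std::log(arg) / g : R_PosInf;
        }
        if (u < uCoal) { uCoal = u; coalPop = i; }
      }
      double uEvent =
          (evPtr < evs.size()) ? (evs[evPtr].time - t) : R_PosInf;
      if (uEvent < 0.0) uEvent = 0.0;

      double u = std::min(std::min(uMig, uRec), std::min(uCoal, uEvent));
      if (!R_FINITE(u))
        stop("no further coalescence, migration or demographic event is "
             "possible: lineages are stranded in isolated populations");

      accumulate(u);
      t += u;

      if (uEvent <= std::min(uMig, std::min(uRec, uCoal))) {
        // demographic event
        const EventRow &e = evs[evPtr++];
        switch (e.code) {
        case 1: { // join: lineages in i move to j; migration of i ceases
          for (Lin &l : lins)
            if (l.pop == e.i) l.pop = e.j;
          for (int j = 0; j < npop; ++j) st.mig[e.i][j] = 0.0;
          for (int i = 0; i < npop; ++i) st.mig[i][e.i] = 0.0;
          for (int i = 0; i < npop; ++i) st.refreshRow(i);
          break;
        }
        case 2: // size change (relative size), growth reset to 0
          st.sz[e.i] = e.value; st.gr[e.i] = 0.0; st.anchor[e.i] = t;
          break;
        case 3: // growth change
          st.sz[e.i] = st.sizeAt(e.i, t); st.gr[e.i] = e.value;
          st.anchor[e.i] = t;
          break;
        case 4: // backward migration rate i -> j
          st.mig[e.i][e.j] = e.value; st.refreshRow(e.i);
          break;
        case 5: { // pulse: each lineage in i moves to j with prob value
          for (Lin &l : lins)
            if (l.pop == e.i && unif_rand() < e.value) l.pop = e.j;
          break;
        }
        default:
          stop("unknown event code");
        }
        continue;
      }

      if (uMig <= std::min(uRec, uCoal)) {
        // migration: pick lineage weighted by its total outward rate
        double z = unif_rand() * totMig, acc = 0.0;
        size_t li = 0;
        for (; li < lins.size(); ++li) {
          acc += st.migRowTot[lins[li].pop];
          if (acc >= z) break;
        }
        if (li == lins.size()) li = lins.size() - 1;
        int from = lins[li].pop;
        double z2 = unif_rand() * st.migRowTot[from], acc2 = 0.0;
        int dest = -1;
        for (int j = 0; j < npop; ++j) {
          acc2 += st.mig[from][j];
          if (acc2 >= z2) { dest = j; break; }
        }
        if (dest < 0) dest = npop - 1;
        lins[li].pop = dest;
        continue;
      }

      if (uRec <= uCoal) {
        // recombination: pick lineage weighted by carried span
        double z = unif_rand() * totSpan, acc = 0.0;
        size_t li = 0;
        for (; li < lins.size(); ++li) {
          acc += (lins[li].hi - lins[li].lo);
          if (acc >= z) break;
        }
        if (li == lins.size()) li = lins.size() - 1;
        Lin &l = lins[li];
        double x = l.lo + unif_rand() * (l.hi - l.lo);
        if (x <= l.lo || x >= l.hi) continue; // boundary draw: no-op
        Lin left, right;
        left.pop = right.pop = l.pop;
        for (const Seg &s : l.segs) {
          if (s.b <= x) left.segs.push_back(s);
          else if (s.a >= x) right.segs.push_back(s);
          else {
            left.segs.push_back(Seg{s.a, x, s.mask});
            right.segs.push_back(Seg{x, s.b, s.mask});
          }
        }
        if (left.segs.empty() || right.segs.empty()) continue;
        if (mode == 1) breaks.push_back(x);
        updateExtremes(left);
        updateExtremes(right);
        lins[li] = left;
        lins.push_back(right);
        continue;
      }

      // coalescence in population coalPop
      {
        std::vector<size_t> idx;
        for (size_t i = 0; i < lins.size(); ++i)
          if (lins[i].pop == coalPop) idx.push_back(i);
        int n = idx.size();
        int i1 = (int)(unif_rand() * n); if (i1 >= n) i1 = n - 1;
        int i2 = (int)(unif_rand() * (n - 1)); if (i2 >= n - 1) i2 = n - 2;
        if (i2 >= i1) ++i2;
        size_t a = idx[i1], b = idx[i2];
        Lin merged;
        merged.pop = coalPop;
        merged.segs = mergeSegs(lins[a].segs, lins[b].segs, full);
        updateExtremes(merged);
        if (a < b) std::swap(a, b); // erase larger index first
        lins.erase(lins.begin() + a);
        lins.erase(lins.begin() + b);
        if (!merged.segs.empty()) lins.push_back(merged);
      }
    }

    if (mode != 0) {
      // assemble per-replicate records (and derive tA in mode 1)
      NumericMatrix rm(recs.size(), 4);
      for (size_t i = 0; i < recs.size(); ++i) {
        rm(i, 0) = recs[i].a;
        rm(i, 1) = recs[i].b;
        rm(i, 2) = (double)recs[i].mask;
        rm(i, 3) = recs[i].len;
      }
      colnames(rm) = CharacterVector::create("a", "b", "mask", "len");
      if (mode == 1) {
        for (const Rec &r : recs) {
          int ci = classIndex(r.mask, popMasks, radixWeight);
          for (int bl = 0; bl < nblock; ++bl) {
            double lo = std::max(r.a, (double)blockBounds[bl]);
            double hi = std::min(r.b, (double)blockBounds[bl + 1]);
            if (hi > lo)
              tA(rep * nblock + bl, ci) +=
                  r.len * (hi - lo) / (blockBounds[bl + 1] - blockBounds[bl]);
          }
        }
        std::sort(breaks.begin(), breaks.end());
        detail[rep] = List::create(_["breakpoints"] = NumericVector(
                                       breaks.begin(), breaks.end()),
                                   _["records"] = rm);
      } else {
        detail[rep] = rm;
      }
    }
  }

  if (mode == 0) return List::create(_["tA"] = tA);
  if (mode == 1) return List::create(_["tA"] = tA, _["detail"] = detail);
  return List::create(_["detail"] = detail);
}

// Poisson kernel: mean over sampled ARGs of the per-configuration
// probability  prod_i p(k_i | theta * t_{i,A}).
//
// T: M x C matrix of class lengths; K: J x C integer matrix of configuration
// counts where -1 codes the lumped ">kmax" entry; kmax < 0 means no lumping.
// Per-ARG products are formed in log space and exponentiated; the average
// over ARGs uses compensated (Kahan) summation in linear space.
// [[Rcpp::export(name = ".bsfsProbKernel")]]
NumericVector bsfsProbKernel(NumericMatrix T, IntegerMatrix K, double theta,
                             int kmax) {
  const int M = T.nrow(), C = T.ncol(), J = K.nrow();
  if (K.ncol() != C) stop("configuration and class-length dimensions differ");
  NumericVector out(J), comp(J);
  // per-configuration invariants: sum of log k! and whether lumped
  std::vector<double> lfactSum(J, 0.0);
  std::vector<bool> anyLumped(J, false);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < C; ++i) {
      int k = K(j, i);
      if (k > 0) lfactSum[j] += R::lgammafn((double)k + 1.0);
      else if (k < 0) {
        if (kmax < 0) stop("lumped entry in a table without a k_max");
        anyLumped[j] = true;
      }
    }
  std::vector<double> loglam(C), lam(C);
  for (int d = 0; d < M; ++d) {
    double lamSum = 0.0;
    for (int i = 0; i < C; ++i) {
      lam[i] = theta * T(d, i);
      lamSum += lam[i];
      loglam[i] = (lam[i] > 0.0) ? std::log(lam[i]) : R_NegInf;
    }
    for (int j = 0; j < J; ++j) {
      // log prod_i p(k_i | lam_i); the zero-branch convention falls out of
      // loglam = -Inf: k > 0 on a zero-length class annihilates the product
      double lp = -lamSum - lfactSum[j];
      for (int i = 0; i < C; ++i) {
        int k = K(j, i);
        if (k > 0) {
          if (lam[i] == 0.0) { lp = R_NegInf; break; }
          lp += k * loglam[i];
        } else if (k < 0) {
          // lumped entry: replace this class's Poisson factor by its upper
          // tail mass (complemented regularized incomplete gamma)
          lp += lam[i] + R::ppois((double)kmax, lam[i], 0, 1);
          if (lp == R_NegInf) break;
        }
      }
      double p = (lp == R_NegInf) ? 0.0 : std::exp(lp);
      // Kahan accumulation of the Monte-Carlo mean
      double y = p - comp[j];
      double s = out[j] + y;
      comp[j] = (s - out[j]) - y;
      out[j] = s;
    }
  }
  for (int j = 0; j < J; ++j) out[j] /= (double)M;
  return out;
}
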