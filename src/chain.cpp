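// Metropolis-Hastings core over mapping matrices.
//
// Semantics mirror the R-level functions in R/mcmc.R exactly: the same move
// classes (N, Z, Zbar, S), the same conditioned-Bernoulli recipes for Zbar
// and S, and the same proposal probability q assembled from all classes able
// to produce a transition, weighted by the uniform choice among classes
// possible from the departing state. Only ratios of the target are used.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <sstream>
#include <cmath>

using namespace Rcpp;

namespace {

// PCG32: small, fast, reproducible across platforms
struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() {  // in (0, 1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  int sampleInt(int n) {  // uniform 0..n-1
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

struct Diff {
  std::vector<int> rows;   // 0-based movable row indices
  std::vector<int> from;   // 0 = unassigned, else 1-based column
  std::vector<int> to;
  void clear() { rows.clear(); from.clear(); to.clear(); }
  size_t size() const { return rows.size(); }
};

struct Chain {
  int m, n;
  std::vector<std::vector<int> > Ri;     // per-row candidate columns (1-based)
  std::vector<std::vector<int> > Rj;     // per-column movable rows (0-based)
  std::vector<int> rmov;                 // |Rj|
  std::vector<int> fixedSupport;
  NumericMatrix colLogP;                 // n x (maxK+1)
  double eta, logPerr, pErr;
  // S-move pairs
  std::vector<int> pairJ, pairK, pairW;
  std::vector<std::vector<int> > pairRows;

  std::vector<int> gamma;                // 0 or 1..n
  std::vector<int> supMov;               // movable support per column

  int totalSup(int j) const { return fixedSupport[j] + supMov[j]; }

  double colTerm(int j) const {
    int k = totalSup(j);
    return k > 0 ? colLogP(j, k) : 0.0;
  }

  double logTargetFull() const {
    double v = std::log(eta);
    int V = 0, nerr = 0;
    for (int j = 0; j < n; ++j) {
      if (totalSup(j) > 0) { ++V; v += colLogP(j, totalSup(j)); }
    }
    for (int i = 0; i < m; ++i) if (gamma[i] == 0) ++nerr;
    return v - eta * V + nerr * logPerr;
  }

  bool pairEligible(size_t p) const {
    int j = pairJ[p], k = pairK[p];
    const std::vector<int> &rows = pairRows[p];
    for (size_t t = 0; t < rows.size(); ++t) {
      int g = gamma[rows[t]];
      if (g == j || g == k) return true;
    }
    return false;
  }

  int pairSwappable(size_t p) const {
    int j = pairJ[p], k = pairK[p], r = 0;
    const std::vector<int> &rows = pairRows[p];
    for (size_t t = 0; t < rows.size(); ++t) {
      int g = gamma[rows[t]];
      if (g == j || g == k) ++r;
    }
    return r;
  }

  // class availability from the current state
  int nSupCols() const {
    int c = 0;
    for (int j = 0; j < n; ++j) if (supMov[j] > 0) ++c;
    return c;
  }
  int nZeroCols() const {
    int c = 0;
    for (int j = 0; j < n; ++j) if (supMov[j] == 0 && rmov[j] >= 1) ++c;
    return c;
  }
  int nEligPairs() const {
    int c = 0;
    for (size_t p = 0; p < pairJ.size(); ++p) if (pairEligible(p)) ++c;
    return c;
  }
  int nClasses(int vz, int nz, int ne) const {
    return 1 + (vz > 0 ? 1 : 0) + (nz > 0 ? 1 : 0) + (ne > 0 ? 1 : 0);
  }

  // q(M, M') for the transition `d` leaving the *current* state; all class
  // terms summed, weighted by 1/2 * 1/#classes(current state)
  double qTotal(const Diff &d) const {
    int vz = nSupCols(), nz = nZeroCols(), ne = nEligPairs();
    double chi = 0.5 / nClasses(vz, nz, ne);
    double total = 0.0;

    if (d.size() == 1) {  // class N
      int i = d.rows[0], from = d.from[0], to = d.to[0];
      int s = (int)Ri[i].size();
      double term;
      if (from == 0) term = 1.0 / ((double)m * s);
      else if (to == 0) term = (s == 1 ? 1.0 : pErr) / m;
      else term = (1.0 - pErr) / (s - 1) / m;
      total += term;
    }

    // class Z: all moved rows leave one supported column j
    if (vz > 0 && d.size() >= 1) {
      int j = d.from[0];
      bool ok = j > 0;
      for (size_t t = 0; ok && t < d.size(); ++t)
        ok = d.from[t] == j && d.to[t] != j;
      if (ok) {
        // moved rows must be exactly the rows currently assigned to j
        int cnt = 0;
        for (size_t t = 0; t < Rj[j - 1].size(); ++t)
          if (gamma[Rj[j - 1][t]] == j) ++cnt;
        if (cnt == (int)d.size()) {
          double f = 1.0 / vz;
          for (size_t t = 0; t < d.size(); ++t) {
            int i = d.rows[t], to = d.to[t];
            int s = (int)Ri[i].size();
            if (to == 0) f *= (s >= 2 ? pErr : 1.0);
            else f *= (1.0 - pErr) / (s - 1);
          }
          total += f;
        }
      }
    }

    // class Zbar: all moved rows pulled into one unsupported column j
    if (nz > 0 && d.size() >= 1) {
      int j = d.to[0];
      bool ok = j > 0 && supMov[j - 1] == 0 && rmov[j - 1] >= 1;
      for (size_t t = 0; ok && t < d.size(); ++t) ok = d.to[t] == j;
      if (ok) {
        int r = rmov[j - 1];
        double ps = std::pow(0.5, r);
        total += (1.0 / nz) * ps / (1.0 - ps);
      }
    }

    // class S: moved rows swap between two columns sharing them
    if (ne > 0 && d.size() >= 1) {
      int j = 0, k = 0;
      bool ok = true;
      for (size_t t = 0; ok && t < d.size(); ++t) {
        int f = d.from[t], g = d.to[t];
        if (f == 0 || g == 0) { ok = false; break; }
        int lo = f < g ? f : g, hi = f < g ? g : f;
        if (j == 0) { j = lo; k = hi; }
        else if (j != lo || k != hi) ok = false;
      }
      if (ok && j != k && j > 0) {
        // find the pair entry
        long pi = -1;
        for (size_t p = 0; p < pairJ.size(); ++p)
          if (pairJ[p] == j && pairK[p] == k) { pi = (long)p; break; }
        if (pi >= 0) {
          double W = 0.0;
          for (size_t p = 0; p < pairJ.size(); ++p)
            if (pairEligible(p)) W += pairW[p];
          int r = pairSwappable((size_t)pi);
          if (r >= 1 && W > 0) {
            double ps = std::pow(0.5, r);
            total += (pairW[pi] / W) * ps / (1.0 - ps);
          }
        }
      }
    }
    return chi * total;
  }

  // apply diff; returns the change in log target
  double apply(const Diff &d) {
    double dlt = 0.0;
    // affected columns: snapshot old terms
    std::vector<int> cols;
    for (size_t t = 0; t < d.size(); ++t) {
      if (d.from[t] > 0) cols.push_back(d.from[t] - 1);
      if (d.to[t] > 0) cols.push_back(d.to[t] - 1);
    }
    std::sort(cols.begin(), cols.end());
    cols.erase(std::unique(cols.begin(), cols.end()), cols.end());
    std::vector<int> oldSup(cols.size());
    for (size_t c = 0; c < cols.size(); ++c) {
      oldSup[c] = totalSup(cols[c]);
      // active columns contribute colLogP(j, k) - eta (the -eta*V prior)
      if (oldSup[c] > 0) dlt -= colLogP(cols[c], oldSup[c]) - eta;
    }
    int errDelta = 0;
    for (size_t t = 0; t < d.size(); ++t) {
      int i = d.rows[t];
      if (d.from[t] > 0) supMov[d.from[t] - 1]--;
      else --errDelta;
      if (d.to[t] > 0) supMov[d.to[t] - 1]++;
      else ++errDelta;
      gamma[i] = d.to[t];
    }
    for (size_t c = 0; c < cols.size(); ++c) {
      int ns = totalSup(cols[c]);
      if (ns > 0) dlt += colLogP(cols[c], ns) - eta;
    }
    dlt += errDelta * logPerr;
    return dlt;
  }

  void revert(const Diff &d) {
    for (size_t t = 0; t < d.size(); ++t) {
      int i = d.rows[t];
      if (d.to[t] > 0) supMov[d.to[t] - 1]--;
      if (d.from[t] > 0) supMov[d.from[t] - 1]++;
      gamma[i] = d.from[t];
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List chain_run(IntegerMatrix A, NumericMatrix colLogP,
               IntegerVector fixedSupport, double eta, double logPerr,
               IntegerVector gammaInit, IntegerVector pairJ,
               IntegerVector pairK, IntegerVector pairRowsFlat,
               IntegerVector pairRowsLen, double burnin, double nSamples,
               int seed, bool collectStates) {
  Chain ch;
  ch.m = A.nrow();
  ch.n = A.ncol();
  ch.colLogP = colLogP;
  ch.eta = eta;
  ch.logPerr = logPerr;
  ch.pErr = std::exp(logPerr);
  ch.fixedSupport.assign(fixedSupport.begin(), fixedSupport.end());
  ch.Ri.resize(ch.m);
  ch.Rj.resize(ch.n);
  ch.rmov.assign(ch.n, 0);
  for (int i = 0; i < ch.m; ++i)
    for (int j = 0; j < ch.n; ++j)
      if (A(i, j)) {
        ch.Ri[i].push_back(j + 1);
        ch.Rj[j].push_back(i);
        ch.rmov[j]++;
      }
  int nPairs = pairJ.size();
  ch.pairJ.assign(pairJ.begin(), pairJ.end());
  ch.pairK.assign(pairK.begin(), pairK.end());
  ch.pairRows.resize(nPairs);
  {
    int off = 0;
    for (int p = 0; p < nPairs; ++p) {
      for (int t = 0; t < pairRowsLen[p]; ++t)
        ch.pairRows[p].push_back(pairRowsFlat[off + t] - 1);
      off += pairRowsLen[p];
      ch.pairW.push_back(pairRowsLen[p]);
    }
  }
  ch.gamma.assign(gammaInit.begin(), gammaInit.end());
  ch.supMov.assign(ch.n, 0);
  for (int i = 0; i < ch.m; ++i)
    if (ch.gamma[i] > 0) ch.supMov[ch.gamma[i] - 1]++;

  Pcg32 rng((uint64_t)(uint32_t)seed);

  long long nBurn = (long long)burnin;
  long long nSamp = (long long)nSamples;

  NumericMatrix mbarCounts(ch.m, ch.n + 1);
  int maxK = colLogP.ncol() - 1;
  NumericMatrix supportHist(ch.n, maxK + 1);
  NumericMatrix acceptRates(4, 2);  // N, Z, Zbar, S x proposed, accepted

  // optional full-state tallies (small instances)
  bool doStates = collectStates;
  double nStatesD = 1.0;
  for (int i = 0; i < ch.m; ++i) nStatesD *= (ch.Ri[i].size() + 1);
  std::vector<double> stateCounts;
  std::vector<long long> radix(ch.m, 0);
  if (doStates && nStatesD <= 4e6) {
    long long r = 1;
    for (int i = 0; i < ch.m; ++i) { radix[i] = r; r *= (ch.n + 1); }
    stateCounts.assign((size_t)r, 0.0);
  } else {
    doStates = false;
  }

  Diff d;
  std::vector<int> scratch;

  for (long long it = 0; it < nBurn + nSamp; ++it) {
    if (rng.unif() >= 0.5) {  // attempt a move with probability 1/2
      // enumerate possible classes
      int vz = ch.nSupCols(), nz = ch.nZeroCols(), ne = ch.nEligPairs();
      int classes[4];
      int nc = 0;
      classes[nc++] = 0;                 // N always possible (m >= 1)
      if (vz > 0) classes[nc++] = 1;
      if (nz > 0) classes[nc++] = 2;
      if (ne > 0) classes[nc++] = 3;
      int cl = classes[rng.sampleInt(nc)];
      d.clear();

      if (cl == 0) {  // N
        int i = rng.sampleInt(ch.m);
        int g = ch.gamma[i];
        const std::vector<int> &cand = ch.Ri[i];
        int to;
        if (g == 0) {
          to = cand[rng.sampleInt((int)cand.size())];
        } else if (cand.size() == 1 || rng.unif() < ch.pErr) {
          to = 0;
        } else {
          int pick = rng.sampleInt((int)cand.size() - 1);
          scratch.clear();
          for (size_t t = 0; t < cand.size(); ++t)
            if (cand[t] != g) scratch.push_back(cand[t]);
          to = scratch[pick];
        }
        d.rows.push_back(i); d.from.push_back(g); d.to.push_back(to);
      } else if (cl == 1) {  // Z
        int pick = rng.sampleInt(vz), j = -1;
        for (int jj = 0; jj < ch.n; ++jj)
          if (ch.supMov[jj] > 0 && pick-- == 0) { j = jj + 1; break; }
        for (size_t t = 0; t < ch.Rj[j - 1].size(); ++t) {
          int i = ch.Rj[j - 1][t];
          if (ch.gamma[i] != j) continue;
          const std::vector<int> &cand = ch.Ri[i];
          int to;
          if (cand.size() == 1 || rng.unif() < ch.pErr) to = 0;
          else {
            int pick2 = rng.sampleInt((int)cand.size() - 1);
            scratch.clear();
            for (size_t t2 = 0; t2 < cand.size(); ++t2)
              if (cand[t2] != j) scratch.push_back(cand[t2]);
            to = scratch[pick2];
          }
          d.rows.push_back(i); d.from.push_back(j); d.to.push_back(to);
        }
      } else if (cl == 2) {  // Zbar
        int pick = rng.sampleInt(nz), j = -1;
        for (int jj = 0; jj < ch.n; ++jj)
          if (ch.supMov[jj] == 0 && ch.rmov[jj] >= 1 && pick-- == 0) {
            j = jj + 1; break;
          }
        const std::vector<int> &rows = ch.Rj[j - 1];
        bool any = false;
        std::vector<bool> pull(rows.size());
        while (!any) {
          for (size_t t = 0; t < rows.size(); ++t) {
            pull[t] = rng.unif() < 0.5;
            if (pull[t]) any = true;
          }
        }
        for (size_t t = 0; t < rows.size(); ++t) {
          if (!pull[t]) continue;
          int i = rows[t];
          d.rows.push_back(i); d.from.push_back(ch.gamma[i]);
          d.to.push_back(j);
        }
      } else {  // S
        double W = 0.0;
        for (size_t p = 0; p < ch.pairJ.size(); ++p)
          if (ch.pairEligible(p)) W += ch.pairW[p];
        double u = rng.unif() * W;
        long pi = -1;
        for (size_t p = 0; p < ch.pairJ.size(); ++p) {
          if (!ch.pairEligible(p)) continue;
          u -= ch.pairW[p];
          if (u <= 0) { pi = (long)p; break; }
        }
        if (pi < 0) pi = (long)(ch.pairJ.size() - 1);
        int j = ch.pairJ[pi], k = ch.pairK[pi];
        scratch.clear();
        const std::vector<int> &rows = ch.pairRows[pi];
        for (size_t t = 0; t < rows.size(); ++t) {
          int g = ch.gamma[rows[t]];
          if (g == j || g == k) scratch.push_back(rows[t]);
        }
        bool any = false;
        std::vector<bool> sw(scratch.size());
        while (!any) {
          for (size_t t = 0; t < scratch.size(); ++t) {
            sw[t] = rng.unif() < 0.5;
            if (sw[t]) any = true;
          }
        }
        for (size_t t = 0; t < scratch.size(); ++t) {
          if (!sw[t]) continue;
          int i = scratch[t], g = ch.gamma[i];
          d.rows.push_back(i); d.from.push_back(g);
          d.to.push_back(g == j ? k : j);
        }
      }

      acceptRates(cl, 0) += 1;
      double qf = ch.qTotal(d);
      double dlt = ch.apply(d);
      Diff rd;
      rd.rows = d.rows; rd.from = d.to; rd.to = d.from;
      double qb = ch.qTotal(rd);
      double la = std::log(qb) - std::log(qf) + dlt;
      bool accept = la >= 0 || rng.unif() < std::exp(la);
      if (accept) acceptRates(cl, 1) += 1;
      else ch.revert(d);
    }

    if (it >= nBurn) {
      for (int i = 0; i < ch.m; ++i) {
        int g = ch.gamma[i];
        mbarCounts(i, g == 0 ? ch.n : g - 1) += 1;
      }
      for (int j = 0; j < ch.n; ++j)
        supportHist(j, ch.totalSup(j)) += 1;
      if (doStates) {
        long long idx = 0;
        for (int i = 0; i < ch.m; ++i) idx += ch.gamma[i] * radix[i];
        stateCounts[(size_t)idx] += 1;
      }
    }
  }

  List out = List::create(
    Named("mbarCounts") = mbarCounts,
    Named("supportHist") = supportHist,
    Named("acceptRates") = acceptRates,
    Named("nSamples") = (double)nSamp);
  if (doStates) {
    std::vector<double> cnt;
    std::vector<std::string> keys;
    for (size_t s = 0; s < stateCounts.size(); ++s) {
      if (stateCounts[s] <= 0) continue;
      long long rem = (long long)s;
      std::ostringstream key;
      for (int i = 0; i < ch.m; ++i) {
        if (i) key << ",";
        key << (int)(rem % (ch.n + 1));
        rem /= (ch.n + 1);
      }
      cnt.push_back(stateCounts[s]);
      keys.push_back(key.str());
    }
    out["stateCounts"] = wrap(cnt);
    out["stateKeys"] = wrap(keys);
  }
  return out;
}

// number of elements of the sorted vector `vec` that are <= each x
// (findInterval without the per-call validation scans)
// [[Rcpp::export]]
IntegerVector count_le(NumericVector x, NumericVector vec) {
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = (int)(std::upper_bound(vec.begin(), vec.end(), x[i]) -
                   vec.begin());
  }
  return out;
}
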