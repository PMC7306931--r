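// Haploid Kingman coalescent with infinite-sites mutation.
//
// Two demographies: a single constant-size population, and D sub-populations
// that each coalesce internally at rate C(k,2)/Ne until their divergence time,
// then join an ancestral pool of size neAnc which coalesces to the root.
// Continuous-time exponential approximation to discrete generations.
//
// All randomness goes through R's RNG so set.seed() on the R side gives
// bit-identical output. The batch ABC path consumes the RNG stream in exactly
// the same order as cpp_simulate_locus so the two can be cross-checked.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Tree {
  int n;                      // tips
  std::vector<int> parent;    // 2n-1 nodes, tips 0..n-1, root 2n-2, parent[root] = -1
  std::vector<double> time;   // node times in generations before present
};

static Tree sim_genealogy_core(const IntegerVector& sampleSizes, double ne,
                               double neAnc, const NumericVector& tdiv) {
  const int D = sampleSizes.size();
  const bool split = tdiv.size() > 0;
  int n = 0;
  for (int d = 0; d < D; ++d) n += sampleSizes[d];
  if (n < 1) stop("need at least one lineage");

  Tree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  // active lineages per population; population D is the ancestral pool
  std::vector<std::vector<int> > act(D + 1);
  int id = 0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < sampleSizes[d]; ++i) act[d].push_back(id++);
  if (!split) {  // single population: treat deme 0 as the only pool
    // nothing to transfer; pool sizes handled below
  }

  std::vector<int> bOrder;  // demes ordered by divergence time
  if (split) {
    bOrder.resize(D);
    for (int d = 0; d < D; ++d) bOrder[d] = d;
    std::stable_sort(bOrder.begin(), bOrder.end(),
                     [&](int a, int b) { return tdiv[a] < tdiv[b]; });
  }
  size_t bNext = 0;

  int nActive = n, nextNode = n;
  double t = 0.0;

  while (nActive > 1) {
    // total coalescence rate over populations with >= 2 lineages
    double rate = 0.0;
    std::vector<double> popRate(D + 1, 0.0);
    for (int p = 0; p <= D; ++p) {
      double k = (double)act[p].size();
      if (k >= 2.0) {
        double sz = (p == D) ? neAnc : ne;
        popRate[p] = k * (k - 1.0) / 2.0 / sz;
        rate += popRate[p];
      }
    }
    double boundary = R_PosInf;
    if (split && bNext < bOrder.size()) boundary = tdiv[bOrder[bNext]];

    double w = (rate > 0.0) ? exp_rand() / rate : R_PosInf;
    if (t + w >= boundary) {
      // deme joins the ancestral pool
      t = boundary;
      int d = bOrder[bNext++];
      for (size_t i = 0; i < act[d].size(); ++i) act[D].push_back(act[d][i]);
      act[d].clear();
      continue;
    }
    if (!R_FINITE(w)) stop("coalescent stalled: no rate and no pending divergence");
    t += w;
    // choose population proportional to its rate
    double u = unif_rand() * rate;
    int p = 0;
    double acc = 0.0;
    for (; p <= D; ++p) {
      acc += popRate[p];
      if (u <= acc && popRate[p] > 0.0) break;
    }
    if (p > D) { for (p = D; p >= 0 && popRate[p] <= 0.0; --p) {} }
    // merge a uniformly random pair within population p
    int k = (int)act[p].size();
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = act[p][i], b = act[p][j];
    int v = nextNode++;
    tr.parent[a] = v;
    tr.parent[b] = v;
    tr.time[v] = t;
    // remove b then a (indices), push v
    if (i > j) std::swap(i, j);
    act[p].erase(act[p].begin() + j);
    act[p].erase(act[p].begin() + i);
    act[p].push_back(v);
    --nActive;
  }
  return tr;
}

// Poisson(mu*L*branch length) mutations; each creates one site at a uniform
// position whose derived state is carried by the branch's descendant tips.
static void drop_mutations_core(const Tree& tr, double mu, double L,
                                std::vector<double>& pos, std::vector<int>& node) {
  const int m = 2 * tr.n - 1;
  std::vector<double> cum;
  double tot = 0.0;
  if (tr.n >= 2) {
    cum.resize(m - 1);
    for (int v = 0; v < m - 1; ++v) {
      tot += tr.time[tr.parent[v]] - tr.time[v];
      cum[v] = tot;
    }
  }
  int M = (tot > 0.0 && mu > 0.0) ? (int)R::rpois(mu * L * tot) : 0;
  pos.resize(M);
  node.resize(M);
  for (int s = 0; s < M; ++s) {
    double u = unif_rand() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v > m - 2) v = m - 2;
    node[s] = v;
    pos[s] = unif_rand() * L;
  }
}

// descendant tip count below each node
static std::vector<int> tip_counts(const Tree& tr) {
  const int m = 2 * tr.n - 1;
  std::vector<int> cnt(m, 0);
  for (int i = 0; i < tr.n; ++i) cnt[i] = 1;
  for (int v = 0; v < m - 1; ++v)
    if (tr.parent[v] >= 0) cnt[tr.parent[v]] += cnt[v];
  return cnt;
}

struct TajimaConst {
  double a1, e1, e2;
};

static TajimaConst tajima_constants(int n) {
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) {
    a1 += 1.0 / i;
    a2 += 1.0 / ((double)i * i);
  }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  TajimaConst tc;
  tc.a1 = a1;
  tc.e1 = c1 / a1;
  tc.e2 = c2 / (a1 * a1 + a2);
  return tc;
}

// undefined below n = 4: the variance constants vanish identically at n = 3
static double tajima_d_from(double S, double piTot, const TajimaConst& tc, int n) {
  if (S <= 0.0 || n < 4) return NA_REAL;
  double v = tc.e1 * S + tc.e2 * S * (S - 1.0);
  if (v <= 0.0) return NA_REAL;
  return (piTot - S / tc.a1) / std::sqrt(v);
}

// summaries: S, pi_total, D, windowed-D mean, windowed-D sd
static void summarize_sites(const std::vector<double>& pos,
                            const std::vector<int>& node,
                            const std::vector<int>& cnt, int n, double L,
                            int nWindows, double* out) {
  const int S = (int)pos.size();
  const double nn = (double)n;
  TajimaConst tc = tajima_constants(n);
  double piTot = 0.0;
  std::vector<double> wS(nWindows, 0.0), wPi(nWindows, 0.0);
  const double wlen = L / nWindows;
  for (int s = 0; s < S; ++s) {
    double c = (double)cnt[node[s]];
    double contrib = 2.0 * c * (nn - c) / (nn * (nn - 1.0));
    piTot += contrib;
    int w = (int)(pos[s] / wlen);
    if (w >= nWindows) w = nWindows - 1;
    wS[w] += 1.0;
    wPi[w] += contrib;
  }
  double D = tajima_d_from((double)S, piTot, tc, n);
  int used = 0;
  double mean = 0.0, m2 = 0.0;
  for (int w = 0; w < nWindows; ++w) {
    if (wS[w] > 0.0) {
      double dw = tajima_d_from(wS[w], wPi[w], tc, n);
      if (!ISNA(dw)) {
        ++used;
        double delta = dw - mean;
        mean += delta / used;
        m2 += delta * (dw - mean);
      }
    }
  }
  out[0] = (double)S;
  out[1] = piTot;
  out[2] = D;
  out[3] = (used >= 1) ? mean : NA_REAL;
  out[4] = (used >= 2) ? std::sqrt(m2 / (used - 1)) : NA_REAL;
}

// [[Rcpp::export]]
List cpp_sim_genealogy(IntegerVector sampleSizes, double ne, double neAnc,
                       NumericVector tdiv) {
  Tree tr = sim_genealogy_core(sampleSizes, ne, neAnc, tdiv);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["n"] = tr.n);
}

static List materialize(const Tree& tr, std::vector<double>& pos,
                        std::vector<int>& node) {
  const int n = tr.n, m = 2 * n - 1;
  const int S = (int)pos.size();
  // sort sites by position
  std::vector<int> ord(S);
  for (int s = 0; s < S; ++s) ord[s] = s;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });
  // ancestor-or-self indicator per tip
  std::vector<char> anc((size_t)n * m, 0);
  for (int i = 0; i < n; ++i) {
    int v = i;
    while (v >= 0) {
      anc[(size_t)i * m + v] = 1;
      v = tr.parent[v];
    }
  }
  IntegerMatrix states(n, S);
  NumericVector position(S);
  for (int s = 0; s < S; ++s) {
    int v = node[ord[s]];
    position[s] = pos[ord[s]];
    for (int i = 0; i < n; ++i) states(i, s) = anc[(size_t)i * m + v];
  }
  return List::create(_["positions"] = position, _["states"] = states);
}

// [[Rcpp::export]]
List cpp_drop_mutations(IntegerVector parent, NumericVector time, int n,
                        double mu, double L) {
  Tree tr;
  tr.n = n;
  tr.parent.assign(parent.begin(), parent.end());
  tr.time.assign(time.begin(), time.end());
  std::vector<double> pos;
  std::vector<int> node;
  drop_mutations_core(tr, mu, L, pos, node);
  return materialize(tr, pos, node);
}

// [[Rcpp::export]]
List cpp_simulate_locus(IntegerVector sampleSizes, double ne, double neAnc,
                        NumericVector tdiv, double mu, double L) {
  Tree tr = sim_genealogy_core(sampleSizes, ne, neAnc, tdiv);
  std::vector<double> pos;
  std::vector<int> node;
  drop_mutations_core(tr, mu, L, pos, node);
  List out = materialize(tr, pos, node);
  out["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end());
  out["time"] = NumericVector(tr.time.begin(), tr.time.end());
  return out;
}

// Batch simulate-and-summarize for rejection ABC.
// params: one row per simulation; column 0 = Ne, columns 1..nTdiv = per-deme
// divergence times (split model only). Ancestral size = Ne of the draw.
// [[Rcpp::export]]
NumericMatrix cpp_abc_batch(IntegerVector sampleSizes, NumericMatrix params,
                            int nTdiv, double mu, double L, int nWindows) {
  const int nSims = params.nrow();
  NumericMatrix out(nSims, 5);
  colnames(out) = CharacterVector::create("S", "pi_total", "D", "D_win_mean",
                                          "D_win_sd");
  NumericVector tdiv(nTdiv);
  for (int r = 0; r < nSims; ++r) {
    double ne = params(r, 0);
    for (int d = 0; d < nTdiv; ++d) tdiv[d] = params(r, 1 + d);
    Tree tr = sim_genealogy_core(sampleSizes, ne, ne, tdiv);
    std::vector<double> pos;
    std::vector<int> node;
    drop_mutations_core(tr, mu, L, pos, node);
    std::vector<int> cnt = tip_counts(tr);
    double buf[5];
    summarize_sites(pos, node, cnt, tr.n, L, nWindows, buf);
    for (int k = 0; k < 5; ++k) out(r, k) = buf[k];
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
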