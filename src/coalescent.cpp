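// Coalescent simulation of sequence windows with recombination (Hudson's
// ancestral recombination graph), stepwise demography (population joins and
// instantaneous admixture pulses) and finite-site HKY mutation.
//
// Conventions (ms-compatible):
//  - time is measured in units of 4N generations; a pair of lineages in one
//    population coalesces at rate 2, so k lineages coalesce at rate k(k-1);
//  - recombination: a lineage whose ancestral material spans g base pairs
//    recombines at rate rho_win * g / L, where rho_win = 4Nr * L is the
//    population recombination rate for the whole window;
//  - branch lengths are in 4N units and are multiplied by `mut_scale`
//    (substitutions per site per 4N generations) before mutation.
//
// All randomness is drawn from R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Seg {
  double l, r;  // half-open interval [l, r) in [0, L)
  int node;     // ARG node carrying this material
  int ns;       // number of samples subtended on this interval
};

typedef std::vector<Seg> Lineage;

double span_of(const Lineage &x) {
  if (x.empty()) return 0.0;
  return x.back().r - x.front().l;
}

// Merge two lineages at a coalescence event. Creates (at most) one new node
// `u` for the intervals where both carry ancestral material; where only one
// does, the segment passes through unchanged. Intervals on which the merged
// node subtends all `n_total` samples have found their local MRCA and are
// dropped. Returns the merged lineage; appends edges (parent u, child, l, r).
Lineage merge_lineages(const Lineage &a, const Lineage &b, int n_total,
                       int &next_node, int &u, double t,
                       std::vector<double> &ntime,
                       std::vector<int> &e_par, std::vector<int> &e_chd,
                       std::vector<double> &e_l, std::vector<double> &e_r) {
  Lineage out;
  out.reserve(a.size() + b.size());
  size_t ia = 0, ib = 0;
  u = -1;
  double pos = std::min(a.front().l, b.front().l);
  while (ia < a.size() || ib < b.size()) {
    // next elementary interval starting at `pos`
    bool ina = ia < a.size() && a[ia].l <= pos && pos < a[ia].r;
    bool inb = ib < b.size() && b[ib].l <= pos && pos < b[ib].r;
    double nxt = R_PosInf;
    if (ia < a.size()) nxt = std::min(nxt, ina ? a[ia].r : a[ia].l);
    if (ib < b.size()) nxt = std::min(nxt, inb ? b[ib].r : b[ib].l);
    if (!ina && !inb) {  // gap: jump to next segment start
      pos = nxt;
      continue;
    }
    double hi = nxt;
    if (ina && inb) {
      if (u < 0) { u = next_node++; ntime.push_back(t); }
      e_par.push_back(u); e_chd.push_back(a[ia].node);
      e_l.push_back(pos); e_r.push_back(hi);
      e_par.push_back(u); e_chd.push_back(b[ib].node);
      e_l.push_back(pos); e_r.push_back(hi);
      int ns = a[ia].ns + b[ib].ns;
      if (ns < n_total) {
        if (!out.empty() && out.back().r == pos && out.back().node == u &&
            out.back().ns == ns)
          out.back().r = hi;
        else
          out.push_back(Seg{pos, hi, u, ns});
      }
    } else {
      const Seg &s = ina ? a[ia] : b[ib];
      if (!out.empty() && out.back().r == pos && out.back().node == s.node &&
          out.back().ns == s.ns)
        out.back().r = hi;
      else
        out.push_back(Seg{pos, hi, s.node, s.ns});
    }
    pos = hi;
    if (ia < a.size() && pos >= a[ia].r) ++ia;
    if (ib < b.size() && pos >= b[ib].r) ++ib;
  }
  return out;
}

// HKY85 transition probability matrix for branch length t (expected
// substitutions per site), base order A, C, G, T. Closed form for the
// Tamura-Nei family with equal purine and pyrimidine transition rates.
void hky_pmat(double t, double kappa, const double *pi, double P[4][4]) {
  const int A = 0, C = 1, G = 2, T = 3;
  double piR = pi[A] + pi[G], piY = pi[C] + pi[T];
  // normalize so that mean substitution rate is 1
  double beta = 1.0 / (2.0 * (piR * piY + kappa * (pi[A] * pi[G] + pi[C] * pi[T])));
  double alpha = kappa * beta;
  double e2 = std::exp(-beta * t);
  double eR = std::exp(-(piR * alpha + piY * beta) * t);
  double eY = std::exp(-(piY * alpha + piR * beta) * t);

  P[A][A] = pi[A] + pi[A] * (piY / piR) * e2 + (pi[G] / piR) * eR;
  P[A][G] = pi[G] + pi[G] * (piY / piR) * e2 - (pi[G] / piR) * eR;
  P[G][G] = pi[G] + pi[G] * (piY / piR) * e2 + (pi[A] / piR) * eR;
  P[G][A] = pi[A] + pi[A] * (piY / piR) * e2 - (pi[A] / piR) * eR;
  P[C][C] = pi[C] + pi[C] * (piR / piY) * e2 + (pi[T] / piY) * eY;
  P[C][T] = pi[T] + pi[T] * (piR / piY) * e2 - (pi[T] / piY) * eY;
  P[T][T] = pi[T] + pi[T] * (piR / piY) * e2 + (pi[C] / piY) * eY;
  P[T][C] = pi[C] + pi[C] * (piR / piY) * e2 - (pi[C] / piY) * eY;
  P[A][C] = pi[C] * (1.0 - e2);  P[A][T] = pi[T] * (1.0 - e2);
  P[G][C] = pi[C] * (1.0 - e2);  P[G][T] = pi[T] * (1.0 - e2);
  P[C][A] = pi[A] * (1.0 - e2);  P[C][G] = pi[G] * (1.0 - e2);
  P[T][A] = pi[A] * (1.0 - e2);  P[T][G] = pi[G] * (1.0 - e2);
}

int sample4(const double *cum) {
  double v = unif_rand();
  if (v < cum[0]) return 0;
  if (v < cum[1]) return 1;
  if (v < cum[2]) return 2;
  return 3;
}

}  // namespace

//' @keywords internal
// [[Rcpp::export(name = ".hky_pmat_cpp")]]
NumericMatrix hky_pmat_cpp(double t, double kappa, NumericVector base_freq) {
  double pi[4] = {base_freq[0], base_freq[1], base_freq[2], base_freq[3]};
  double P[4][4];
  hky_pmat(t, kappa, pi, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i][j];
  return out;
}

// Simulate one window: genealogies under the ARG, then HKY sequences.
// `joins`: matrix with columns (time, from, to), rows sorted by time.
// `pulses`: matrix with columns (time, from, to, prob); at each pulse every
// lineage currently in `from` moves to `to` independently with `prob`
// (the ms -es/-ej idiom; prob = f, the introgression proportion).
// Returns an integer matrix (samples x L), alleles coded 0..3 = A,C,G,T.
//' @keywords internal
// [[Rcpp::export(name = ".sim_window_cpp")]]
IntegerMatrix sim_window_cpp(int n_per_pop, int n_pops, int L,
                             NumericMatrix joins, NumericMatrix pulses,
                             double rho_win, double mut_scale, double kappa,
                             NumericVector base_freq) {
  RNGScope scope;
  const int N = n_per_pop * n_pops;
  const double Ld = static_cast<double>(L);

  // unified, time-sorted demographic event list: type 0 = join, 1 = pulse
  struct Ev { double t; int type; int from; int to; double prob; };
  std::vector<Ev> evs;
  for (int i = 0; i < joins.nrow(); ++i)
    evs.push_back(Ev{joins(i, 0), 0, (int)joins(i, 1), (int)joins(i, 2), 0.0});
  for (int i = 0; i < pulses.nrow(); ++i)
    evs.push_back(Ev{pulses(i, 0), 1, (int)pulses(i, 1), (int)pulses(i, 2),
                     pulses(i, 3)});
  std::stable_sort(evs.begin(), evs.end(),
                   [](const Ev &a, const Ev &b) { return a.t < b.t; });

  std::vector<Lineage> lin;
  std::vector<int> pop;
  lin.reserve(4 * N);
  for (int p = 0; p < n_pops; ++p)
    for (int i = 0; i < n_per_pop; ++i) {
      Lineage l;
      l.push_back(Seg{0.0, Ld, p * n_per_pop + i, 1});
      lin.push_back(l);
      pop.push_back(p + 1);
    }

  std::vector<double> ntime(N, 0.0);
  int next_node = N;
  std::vector<int> e_par, e_chd;
  std::vector<double> e_l, e_r;
  std::vector<double> breaks;
  breaks.push_back(0.0);
  breaks.push_back(Ld);

  double t = 0.0;
  size_t ev = 0;
  long guard = 0;
  long n_coal = 0, n_rec = 0;
  size_t max_lin = lin.size();
  while (!lin.empty()) {
    if (lin.size() > max_lin) max_lin = lin.size();
    if (++guard > 100000000L) stop("coalescent simulation failed to converge");
    // event rates
    std::vector<int> k(n_pops + 2, 0);
    for (size_t i = 0; i < lin.size(); ++i) k[pop[i]]++;
    double coal_tot = 0.0;
    for (int p = 1; p <= n_pops + 1; ++p)
      coal_tot += static_cast<double>(k[p]) * (k[p] - 1);
    double rec_tot = 0.0;
    for (size_t i = 0; i < lin.size(); ++i) rec_tot += span_of(lin[i]);
    rec_tot *= rho_win / Ld;
    double tot = coal_tot + rec_tot;

    double dt = (tot > 0) ? exp_rand() / tot : R_PosInf;
    if (ev < evs.size() && (t + dt >= evs[ev].t || tot <= 0)) {
      t = evs[ev].t;
      if (evs[ev].type == 0) {
        for (size_t i = 0; i < lin.size(); ++i)
          if (pop[i] == evs[ev].from) pop[i] = evs[ev].to;
      } else {
        for (size_t i = 0; i < lin.size(); ++i)
          if (pop[i] == evs[ev].from && unif_rand() < evs[ev].prob)
            pop[i] = evs[ev].to;
      }
      ++ev;
      continue;
    }
    if (tot <= 0) stop("no possible events but uncoalesced lineages remain");
    t += dt;

    if (unif_rand() * tot < coal_tot) {
      // coalescence: choose population weighted by k(k-1), then a pair
      double v = unif_rand() * coal_tot;
      int cp = 1;
      for (int p = 1; p <= n_pops + 1; ++p) {
        double w = static_cast<double>(k[p]) * (k[p] - 1);
        if (v < w) { cp = p; break; }
        v -= w;
      }
      int i1 = (int)std::floor(unif_rand() * k[cp]);
      int i2 = (int)std::floor(unif_rand() * (k[cp] - 1));
      if (i2 >= i1) ++i2;
      int a = -1, b = -1, seen = 0;
      for (size_t i = 0; i < lin.size(); ++i)
        if (pop[i] == cp) {
          if (seen == i1) a = (int)i;
          if (seen == i2) b = (int)i;
          ++seen;
        }
      int u;
      ++n_coal;
      Lineage m = merge_lineages(lin[a], lin[b], N, next_node, u, t, ntime,
                                 e_par, e_chd, e_l, e_r);
      // replace a with merged, drop b
      lin[a] = m;
      lin.erase(lin.begin() + b);
      pop.erase(pop.begin() + b);
      if (b < a) --a;
      if (lin[a].empty()) {
        lin.erase(lin.begin() + a);
        pop.erase(pop.begin() + a);
      }
    } else {
      // recombination: choose lineage weighted by span, split at x
      double v = unif_rand() * (rec_tot / (rho_win / Ld));
      size_t ri = 0;
      for (; ri < lin.size(); ++ri) {
        double w = span_of(lin[ri]);
        if (v < w) break;
        v -= w;
      }
      if (ri == lin.size()) ri = lin.size() - 1;
      const Lineage &src = lin[ri];
      double lmin = src.front().l, rmax = src.back().r;
      double x = lmin + unif_rand() * (rmax - lmin);
      if (x <= lmin || x >= rmax) continue;  // degenerate draw; no split
      Lineage left, right;
      for (size_t s = 0; s < src.size(); ++s) {
        if (src[s].r <= x) left.push_back(src[s]);
        else if (src[s].l >= x) right.push_back(src[s]);
        else {
          left.push_back(Seg{src[s].l, x, src[s].node, src[s].ns});
          right.push_back(Seg{x, src[s].r, src[s].node, src[s].ns});
        }
      }
      if (left.empty() || right.empty()) continue;
      breaks.push_back(x);
      ++n_rec;
      int p = pop[ri];
      lin[ri] = left;
      lin.push_back(right);
      pop.push_back(p);
    }
  }

  // --- marginal trees and HKY mutation ---
  // Mutation uses uniformization of the HKY rate matrix: substitution
  // events along a branch spanning n sites arrive as Poisson(qmax * blen *
  // n); each event picks a site uniformly and applies one step of the
  // uniformized jump chain (self-transitions absorb the thinning), which
  // reproduces the exact finite-site transition probabilities.
  std::sort(breaks.begin(), breaks.end());
  breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());

  IntegerMatrix out(N, L);
  out.attr("n_coal") = (double)n_coal;
  out.attr("n_rec") = (double)n_rec;
  out.attr("n_iter") = (double)guard;
  out.attr("max_lineages") = (double)max_lin;
  const int n_nodes = next_node;
  std::vector<int> par(n_nodes);
  std::vector<char> intree(n_nodes);
  std::vector<std::vector<int> > children(n_nodes);
  double pi[4] = {base_freq[0], base_freq[1], base_freq[2], base_freq[3]};
  double cpi[4] = {pi[0], pi[0] + pi[1], pi[0] + pi[1] + pi[2], 1.0};
  const size_t n_edges = e_par.size();

  // uniformized jump chain of the normalized HKY rate matrix
  const double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  const double beta =
      1.0 / (2.0 * (piR * piY + kappa * (pi[0] * pi[2] + pi[1] * pi[3])));
  double q[4][4];
  double qmax = 0.0;
  for (int a = 0; a < 4; ++a) {
    double qa = 0.0;
    for (int b = 0; b < 4; ++b) {
      if (a == b) continue;
      // A(0)<->G(2) and C(1)<->T(3) are the transitions
      bool transition = (a == 0 && b == 2) || (a == 2 && b == 0) ||
                        (a == 1 && b == 3) || (a == 3 && b == 1);
      q[a][b] = (transition ? kappa : 1.0) * beta * pi[b];
      qa += q[a][b];
    }
    q[a][a] = qa;  // temporarily store the leave rate
    if (qa > qmax) qmax = qa;
  }
  double jump_cum[4][4];
  for (int a = 0; a < 4; ++a) {
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) {
      double pr = (a == b) ? (1.0 - q[a][a] / qmax) : (q[a][b] / qmax);
      acc += pr;
      jump_cum[a][b] = acc;
    }
    jump_cum[a][3] = 1.0;
  }

  // sweep-line bookkeeping: each edge is added once (at its left end) and
  // retired once (at its right end), so marginal-tree construction is
  // O(edges) overall instead of O(intervals x edges)
  std::vector<size_t> add_order(n_edges), rem_order(n_edges);
  for (size_t e = 0; e < n_edges; ++e) add_order[e] = rem_order[e] = e;
  std::sort(add_order.begin(), add_order.end(),
            [&](size_t a, size_t b) { return e_l[a] < e_l[b]; });
  std::sort(rem_order.begin(), rem_order.end(),
            [&](size_t a, size_t b) { return e_r[a] < e_r[b]; });
  std::vector<long> par_edge(n_nodes, -1);
  std::fill(par.begin(), par.end(), -1);
  size_t next_add = 0, next_rem = 0;
  std::vector<int> tree_nodes;

  int site = 0;
  for (size_t bi = 0; bi + 1 < breaks.size() && site < L; ++bi) {
    double hi = breaks[bi + 1];
    int s0 = site;
    while (site < L && site + 0.5 < hi) ++site;
    int ns = site - s0;
    if (ns == 0) continue;  // no whole site falls in this slice
    double mid = 0.5 * (breaks[bi] + hi);

    while (next_rem < n_edges && e_r[rem_order[next_rem]] <= mid) {
      size_t e = rem_order[next_rem++];
      if (par_edge[e_chd[e]] == (long)e) {
        par[e_chd[e]] = -1;
        par_edge[e_chd[e]] = -1;
      }
    }
    while (next_add < n_edges && e_l[add_order[next_add]] <= mid) {
      size_t e = add_order[next_add++];
      if (e_r[e] > mid) {
        par[e_chd[e]] = e_par[e];
        par_edge[e_chd[e]] = (long)e;
      }
    }

    std::fill(intree.begin(), intree.end(), 0);
    tree_nodes.clear();
    int root = -1;
    for (int i = 0; i < N; ++i) {
      int v = i;
      while (!intree[v]) {
        intree[v] = 1;
        tree_nodes.push_back(v);
        if (par[v] < 0) { root = v; break; }
        v = par[v];
      }
    }
    for (size_t k = 0; k < tree_nodes.size(); ++k)
      children[tree_nodes[k]].clear();
    for (size_t k = 0; k < tree_nodes.size(); ++k) {
      int v = tree_nodes[k];
      if (par[v] >= 0) children[par[v]].push_back(v);
    }

    // root states from the equilibrium frequencies
    std::vector<unsigned char> rstate(ns);
    for (int j = 0; j < ns; ++j) rstate[j] = (unsigned char)sample4(cpi);

    // iterative DFS, copying the parent's site states down each branch
    std::vector<std::pair<int, std::vector<unsigned char> > > stack;
    stack.push_back(std::make_pair(root, rstate));
    while (!stack.empty()) {
      int v = stack.back().first;
      std::vector<unsigned char> st = stack.back().second;
      stack.pop_back();
      if (par[v] >= 0) {
        double blen = (ntime[par[v]] - ntime[v]) * mut_scale;
        double lambda = qmax * blen * ns;
        int nev = (int)R::rpois(lambda);
        for (int k = 0; k < nev; ++k) {
          int j = (int)std::floor(unif_rand() * ns);
          if (j >= ns) j = ns - 1;
          st[j] = (unsigned char)sample4(jump_cum[st[j]]);
        }
      }
      if (v < N) {
        for (int j = 0; j < ns; ++j) out(v, s0 + j) = st[j];
      }
      for (size_t c = 0; c < children[v].size(); ++c)
        stack.push_back(std::make_pair(children[v][c], st));
    }
  }
  return out;
}

// Pairwise sequence differences with pairwise deletion of missing data.
// `h`: samples x sites matrix, alleles coded as non-negative integers,
// negatives = missing. Returns per-pair difference and comparable-site
// counts. If `within`, all unordered pairs of idxA are used (optionally
// excluding pairs with equal `indiv` label); otherwise all idxA x idxB
// cross pairs. Indices are 1-based.
//' @keywords internal
// [[Rcpp::export(name = ".pairwise_diff_cpp")]]
List pairwise_diff_cpp(IntegerMatrix h, IntegerVector idxA, IntegerVector idxB,
                       bool within, IntegerVector indiv,
                       bool exclude_same_indiv) {
  const int L = h.ncol();
  std::vector<int> diffs, comps;
  std::vector<std::pair<int, int> > pairs;
  if (within) {
    for (int i = 0; i < idxA.size(); ++i)
      for (int j = i + 1; j < idxA.size(); ++j) {
        if (exclude_same_indiv && indiv.size() == idxA.size() &&
            indiv[i] == indiv[j])
          continue;
        pairs.push_back(std::make_pair(idxA[i] - 1, idxA[j] - 1));
      }
  } else {
    for (int i = 0; i < idxA.size(); ++i)
      for (int j = 0; j < idxB.size(); ++j)
        pairs.push_back(std::make_pair(idxA[i] - 1, idxB[j] - 1));
  }
  const int np = (int)pairs.size();
  diffs.assign(np, 0);
  comps.assign(np, 0);
  const int N = h.nrow();
  const int *hp = INTEGER(h);
  // site-outer iteration: each site's column is contiguous in memory
  for (int s = 0; s < L; ++s) {
    const int *col = hp + (size_t)s * N;
    for (int p = 0; p < np; ++p) {
      int x = col[pairs[p].first], y = col[pairs[p].second];
      if (x < 0 || y < 0) continue;
      ++comps[p];
      if (x != y) ++diffs[p];
    }
  }
  return List::create(_["diffs"] = wrap(diffs), _["sites"] = wrap(comps));
}

// Per-group allele counts: returns an integer array (4 alleles x L sites x
// n_groups). `group` gives a 1-based group id per row of `h` (0 = ignore).
//' @keywords internal
// [[Rcpp::export(name = ".allele_counts_cpp")]]
IntegerVector allele_counts_cpp(IntegerMatrix h, IntegerVector group,
                                int n_groups) {
  const int N = h.nrow(), L = h.ncol();
  IntegerVector out(4 * L * n_groups);
  int *op = INTEGER(out);
  const int *hp = INTEGER(h);
  for (int s = 0; s < L; ++s) {
    const int *col = hp + (size_t)s * N;
    for (int i = 0; i < N; ++i) {
      int g = group[i];
      if (g < 1 || g > n_groups) continue;
      int a = col[i];
      if (a >= 0 && a < 4) op[(size_t)(g - 1) * 4 * L + s * 4 + a]++;
    }
  }
  out.attr("dim") = IntegerVector::create(4, L, n_groups);
  return out;
}

// Single-pass window statistics for complete (no-missing) alignments: the
// simulation hot path. `g6` assigns each haplotype to P1=1, P2=2, O=4 and
// the interleaved P3 halves 5/6 (P3 = 5 u 6). Returns the polarized
// ABBA/BABA sums and count-based diversity; the R wrappers turn sums into
// D and the f estimators. Matches the general R path exactly on complete
// data (property-tested).
//' @keywords internal
// [[Rcpp::export(name = ".window_core_cpp")]]
NumericVector window_core_cpp(IntegerMatrix h, IntegerVector g6) {
  const int N = h.nrow(), L = h.ncol();
  const int *hp = INTEGER(h);
  int nsz[7] = {0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < N; ++i) nsz[g6[i]]++;
  const int n1 = nsz[1], n2 = nsz[2], n5 = nsz[5], n6 = nsz[6],
            n4 = nsz[4], n3 = n5 + n6;
  double num = 0, tot_d = 0, den_g = 0, den_hom = 0, den_d = 0;
  double pi1 = 0, pi2 = 0, pi3 = 0, d12 = 0, d13 = 0, d23 = 0;
  long used = 0;

  for (int s = 0; s < L; ++s) {
    const int *col = hp + (size_t)s * N;
    int c[7][4] = {{0}};
    for (int i = 0; i < N; ++i) {
      int a = col[i];
      if (a < 0 || a > 3) continue;
      c[g6[i]][a]++;
    }
    int c3[4], tot[4];
    for (int a = 0; a < 4; ++a) {
      c3[a] = c[5][a] + c[6][a];
      tot[a] = c[1][a] + c[2][a] + c3[a] + c[4][a];
    }
    // diversity over all sites from allele counts (complete data)
    double s1 = 0, s2 = 0, s3 = 0, s4 = 0, x12 = 0, x13 = 0, x23 = 0,
           x14 = 0;
    for (int a = 0; a < 4; ++a) {
      s1 += (double)c[1][a] * c[1][a];
      s2 += (double)c[2][a] * c[2][a];
      s3 += (double)c3[a] * c3[a];
      x12 += (double)c[1][a] * c[2][a];
      x13 += (double)c[1][a] * c3[a];
      x23 += (double)c[2][a] * c3[a];
      (void)s4; (void)x14;
    }
    if (n1 >= 2) pi1 += ((double)n1 * n1 - s1) / ((double)n1 * (n1 - 1));
    if (n2 >= 2) pi2 += ((double)n2 * n2 - s2) / ((double)n2 * (n2 - 1));
    if (n3 >= 2) pi3 += ((double)n3 * n3 - s3) / ((double)n3 * (n3 - 1));
    d12 += ((double)n1 * n2 - x12) / ((double)n1 * n2);
    d13 += ((double)n1 * n3 - x13) / ((double)n1 * n3);
    d23 += ((double)n2 * n3 - x23) / ((double)n2 * n3);

    // polarization: biallelic sites with every group represented
    int present = 0, a1 = -1, a2 = -1;
    for (int a = 0; a < 4; ++a)
      if (tot[a] > 0) {
        if (present == 0) a1 = a; else a2 = a;
        ++present;
      }
    if (present != 2) continue;
    int anc;
    int out_alleles = 0, out_a = -1;
    for (int a = 0; a < 4; ++a)
      if (c[4][a] > 0) { ++out_alleles; out_a = a; }
    if (out_alleles == 1) {
      anc = out_a;
    } else {  // overall majority; ties to the lowest allele index
      anc = (tot[a2] > tot[a1]) ? a2 : a1;
    }
    int der = (anc == a1) ? a2 : a1;
    double p1 = (double)c[1][der] / n1;
    double p2 = (double)c[2][der] / n2;
    double p3 = (double)c3[der] / n3;
    double p4 = (double)c[4][der] / n4;
    double p3a = n5 > 0 ? (double)c[5][der] / n5 : p3;
    double p3b = n6 > 0 ? (double)c[6][der] / n6 : p3;
    double w = 1.0 - p4;
    double cabba = (1 - p1) * p2 * p3 * w;
    double cbaba = p1 * (1 - p2) * p3 * w;
    num += cabba - cbaba;
    tot_d += cabba + cbaba;
    den_hom += ((1 - p1) * p3 - p1 * (1 - p3)) * p3 * w;
    den_g += ((1 - p1) * p3a - p1 * (1 - p3a)) * p3b * w;
    double pd = p2 > p3 ? p2 : p3;
    den_d += ((1 - p1) * pd - p1 * (1 - pd)) * pd * w;
    ++used;
  }
  return NumericVector::create(
      _["sitesUsed"] = (double)used, _["num"] = num, _["tot"] = tot_d,
      _["den_g"] = den_g, _["den_hom"] = den_hom, _["den_d"] = den_d,
      _["pi_P1"] = n1 >= 2 ? pi1 / L : NA_REAL,
      _["pi_P2"] = n2 >= 2 ? pi2 / L : NA_REAL,
      _["pi_P3"] = n3 >= 2 ? pi3 / L : NA_REAL,
      _["dxy_P1P2"] = d12 / L, _["dxy_P1P3"] = d13 / L,
      _["dxy_P2P3"] = d23 / L);
}
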