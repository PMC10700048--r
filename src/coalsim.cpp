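// Hudson-style coalescent for independent biallelic SNP loci under a
// piecewise-constant multi-deme history with merge and admixture events.
// Time runs backward in generations; within a deme of diploid size N each
// lineage pair coalesces at rate 1/(2N).  Uses R's RNG so set.seed()
// governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct EventSet {
  std::vector<double> time;
  std::vector<int> kind;  // 0 merge, 1 admixture
  std::vector<int> a, b, c;  // merge: a=source, b=dest; admix: a moves to b (prob rate) else c
  std::vector<double> rate, newsize;
};

// Simulate one genealogy.  Node indexing: 0..n-1 leaves at time 0, internal
// nodes appended in coalescence order; root = 2n-2.
void sim_tree(const std::vector<int>& ss, std::vector<double> N,
              const EventSet& ev,
              std::vector<double>& ntime, std::vector<int>& parent,
              std::vector<int>& child1, std::vector<int>& child2) {
  const int nd = (int)ss.size();
  int n = 0;
  for (int d = 0; d < nd; d++) n += ss[d];
  const int nn = 2 * n - 1;
  ntime.assign(nn, 0.0);
  parent.assign(nn, -1);
  child1.assign(nn, -1);
  child2.assign(nn, -1);

  std::vector<std::vector<int> > lin(nd);
  int idx = 0;
  for (int d = 0; d < nd; d++)
    for (int i = 0; i < ss[d]; i++) lin[d].push_back(idx++);

  int next_node = n, total = n, ei = 0;
  const int nev = (int)ev.time.size();
  double t = 0.0;

  while (total > 1) {
    // candidate next coalescence: min over demes of an Exp(k(k-1)/(4N)) wait
    double tmin = R_PosInf;
    int dmin = -1;
    for (int d = 0; d < nd; d++) {
      const int k = (int)lin[d].size();
      if (k >= 2) {
        if (!(N[d] > 0.0))
          stop("lineages present in a deme with no positive size");
        const double rate = k * (k - 1.0) / (4.0 * N[d]);
        const double w = exp_rand() / rate;
        if (t + w < tmin) { tmin = t + w; dmin = d; }
      }
    }
    const double tev = (ei < nev) ? ev.time[ei] : R_PosInf;
    if (tev <= tmin) {
      if (!R_finite(tev))
        stop("lineages stranded in disconnected demes: no common ancestor");
      t = tev;
      const int a = ev.a[ei], b = ev.b[ei];
      if (ev.kind[ei] == 0) {  // merge a -> b
        for (size_t i = 0; i < lin[a].size(); i++) lin[b].push_back(lin[a][i]);
        lin[a].clear();
        if (ev.newsize[ei] > 0.0) N[b] = ev.newsize[ei];
      } else {  // admixture: each lineage of a -> b w.p. rate, else c
        const int c = ev.c[ei];
        for (size_t i = 0; i < lin[a].size(); i++) {
          if (unif_rand() < ev.rate[ei]) lin[b].push_back(lin[a][i]);
          else lin[c].push_back(lin[a][i]);
        }
        lin[a].clear();
      }
      ei++;
    } else {
      t = tmin;
      const int k = (int)lin[dmin].size();
      int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) j++;
      const int p = next_node++;
      ntime[p] = t;
      parent[lin[dmin][i]] = p;
      parent[lin[dmin][j]] = p;
      child1[p] = lin[dmin][i];
      child2[p] = lin[dmin][j];
      lin[dmin][i] = p;
      lin[dmin].erase(lin[dmin].begin() + j);
      total--;
    }
  }
}

// One mutation uniform on total branch length (root has no branch, so the
// locus is polymorphic by construction); marks derived leaves.
void drop_mutation(int n, const std::vector<double>& ntime,
                   const std::vector<int>& parent,
                   const std::vector<int>& child1,
                   const std::vector<int>& child2,
                   std::vector<int>& der) {
  const int nn = 2 * n - 1;
  double L = 0.0;
  for (int v = 0; v < nn; v++)
    if (parent[v] >= 0) L += ntime[parent[v]] - ntime[v];
  double u = unif_rand() * L;
  int bsel = -1;
  for (int v = 0; v < nn; v++) {
    if (parent[v] >= 0) {
      const double bl = ntime[parent[v]] - ntime[v];
      if (u < bl) { bsel = v; break; }
      u -= bl;
    }
  }
  if (bsel < 0) bsel = nn - 2;  // guard against rounding at u == L
  der.assign(n, 0);
  std::vector<int> stack;
  stack.push_back(bsel);
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    if (v < n) der[v] = 1;
    else { stack.push_back(child1[v]); stack.push_back(child2[v]); }
  }
}

EventSet make_events(NumericVector ev_time, IntegerVector ev_kind,
                     IntegerVector ev_a, IntegerVector ev_b,
                     IntegerVector ev_c, NumericVector ev_rate,
                     NumericVector ev_newsize) {
  EventSet ev;
  const int m = ev_time.size();
  for (int i = 0; i < m; i++) {
    ev.time.push_back(ev_time[i]);
    ev.kind.push_back(ev_kind[i]);
    ev.a.push_back(ev_a[i]);
    ev.b.push_back(ev_b[i]);
    ev.c.push_back(ev_c[i]);
    ev.rate.push_back(ev_rate[i]);
    ev.newsize.push_back(ev_newsize[i]);
  }
  return ev;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix sim_dataset_cpp(int n_loci, IntegerVector sample_sizes,
                              NumericVector deme_sizes, NumericVector ev_time,
                              IntegerVector ev_kind, IntegerVector ev_a,
                              IntegerVector ev_b, IntegerVector ev_c,
                              NumericVector ev_rate, NumericVector ev_newsize,
                              double min_maf) {
  const int nd = sample_sizes.size();
  std::vector<int> ss(nd);
  int n = 0;
  for (int d = 0; d < nd; d++) {
    if (sample_sizes[d] % 2 != 0)
      stop("gene-copy counts must be even (diploid individuals)");
    ss[d] = sample_sizes[d];
    n += ss[d];
  }
  if (n < 2) stop("need at least two gene copies");
  std::vector<double> N(deme_sizes.begin(), deme_sizes.end());
  EventSet ev = make_events(ev_time, ev_kind, ev_a, ev_b, ev_c,
                            ev_rate, ev_newsize);
  const int n_ind = n / 2;
  IntegerMatrix G(n_ind, n_loci);

  std::vector<double> ntime;
  std::vector<int> parent, child1, child2, der;
  for (int l = 0; l < n_loci; l++) {
    int tries = 0;
    for (;;) {
      sim_tree(ss, N, ev, ntime, parent, child1, child2);
      drop_mutation(n, ntime, parent, child1, child2, der);
      if (min_maf <= 0.0) break;
      int dc = 0;
      for (int i = 0; i < n; i++) dc += der[i];
      const double f = (double)dc / n;
      if (std::min(f, 1.0 - f) > min_maf) break;
      if (++tries >= 10000)
        stop("minor-allele-frequency rejection failed after 10000 tries");
    }
    for (int i = 0; i < n_ind; i++)
      G(i, l) = der[2 * i] + der[2 * i + 1];
    if (l % 64 == 0) checkUserInterrupt();
  }
  return G;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector sample_sizes, NumericVector deme_sizes,
                       NumericVector ev_time, IntegerVector ev_kind,
                       IntegerVector ev_a, IntegerVector ev_b,
                       IntegerVector ev_c, NumericVector ev_rate,
                       NumericVector ev_newsize) {
  const int nd = sample_sizes.size();
  std::vector<int> ss(nd);
  int n = 0;
  for (int d = 0; d < nd; d++) { ss[d] = sample_sizes[d]; n += ss[d]; }
  if (n < 2) stop("need at least two gene copies");
  std::vector<double> N(deme_sizes.begin(), deme_sizes.end());
  EventSet ev = make_events(ev_time, ev_kind, ev_a, ev_b, ev_c,
                            ev_rate, ev_newsize);
  std::vector<double> ntime;
  std::vector<int> parent, child1, child2;
  sim_tree(ss, N, ev, ntime, parent, child1, child2);
  const int nn = 2 * n - 1;
  IntegerVector par(nn);
  NumericVector tim(nn);
  double L = 0.0;
  for (int v = 0; v < nn; v++) {
    par[v] = parent[v] + 1;  // 1-based, 0 = root
    tim[v] = ntime[v];
    if (parent[v] >= 0) L += ntime[parent[v]] - ntime[v];
  }
  return List::create(_["n_leaves"] = n, _["times"] = tim,
                      _["parent"] = par, _["total_length"] = L);
}
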