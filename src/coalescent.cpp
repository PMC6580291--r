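#include <Rcpp.h>
using namespace Rcpp;

// Structured-coalescent simulation under a piecewise-constant demography.
//
// Time runs backward from the present in units of 2*Nref generations.
// Within a deme of relative size nu, each pair of lineages coalesces at
// rate 1/nu; a lineage in deme a jumps to deme b at the per-lineage rate
// mig[a][b] (already scaled by the caller, i.e. M_ab/2).  Discrete events
// (lineage moves at splits, probabilistic reassignment at admixture
// pulses) happen at fixed times.  Branch lengths are accumulated into
// joint-SFS cells indexed by the number of descendant leaves per deme:
// a lineage's whole lifespan belongs to one cell because migration does
// not change its descendant set.

struct Demography {
  int n_demes;
  std::vector<double> seg_end;            // segment right edges, last = +Inf
  std::vector<std::vector<double>> nu;    // [seg][deme]
  std::vector<std::vector<double>> mig;   // [seg][a*n_demes+b] per-lineage a->b
  std::vector<double> ev_time;
  std::vector<int> ev_type;               // 1 = move all a->b, 2 = admix: a -> b w.p. f else c
  std::vector<int> ev_a, ev_b, ev_c;
  std::vector<double> ev_f;
};

static Demography unpack(const List& sched) {
  Demography d;
  d.n_demes = as<int>(sched["n_demes"]);
  NumericVector se = sched["seg_end"];
  NumericMatrix nu = sched["nu"];          // nseg x n_demes
  NumericVector mg = sched["mig"];         // dim c(nseg, n_demes, n_demes)
  int nseg = se.size();
  d.seg_end.assign(se.begin(), se.end());
  d.nu.resize(nseg);
  d.mig.resize(nseg);
  for (int s = 0; s < nseg; ++s) {
    d.nu[s].resize(d.n_demes);
    d.mig[s].assign(d.n_demes * d.n_demes, 0.0);
    for (int a = 0; a < d.n_demes; ++a) {
      d.nu[s][a] = nu(s, a);
      if (d.nu[s][a] <= 0) stop("deme sizes must be positive");
      for (int b = 0; b < d.n_demes; ++b)
        d.mig[s][a * d.n_demes + b] = mg[s + nseg * (a + d.n_demes * b)];
    }
  }
  NumericVector et = sched["ev_time"];
  IntegerVector ty = sched["ev_type"], ea = sched["ev_a"], eb = sched["ev_b"], ec = sched["ev_c"];
  NumericVector ef = sched["ev_f"];
  d.ev_time.assign(et.begin(), et.end());
  d.ev_type.assign(ty.begin(), ty.end());
  d.ev_a.assign(ea.begin(), ea.end());
  d.ev_b.assign(eb.begin(), eb.end());
  d.ev_c.assign(ec.begin(), ec.end());
  d.ev_f.assign(ef.begin(), ef.end());
  return d;
}

struct Lineage {
  int deme;
  int leaves[4];      // descendant leaf counts per sampled deme
  double birth;
  int pos;            // index within its deme's member list
};

class Simulator {
public:
  Demography dem;
  std::vector<int> n_sample;
  int n_tot;
  bool track_leaves;
  std::vector<Lineage> lin;
  std::vector<std::vector<int>> lin_leaves;   // leaf ids per lineage (if tracked)
  std::vector<std::vector<int>> members;      // per deme: lineage slots

  Simulator(const Demography& d, const std::vector<int>& ns, bool track = false)
    : dem(d), n_sample(ns), track_leaves(track) {
    n_tot = 0;
    for (size_t i = 0; i < ns.size(); ++i) n_tot += ns[i];
  }

  void reset() {
    lin.clear();
    lin_leaves.clear();
    members.assign(dem.n_demes, std::vector<int>());
    int leaf_id = 0;
    for (int d = 0; d < (int)n_sample.size(); ++d)
      for (int i = 0; i < n_sample[d]; ++i) {
        Lineage L; L.deme = d; L.leaves[0] = L.leaves[1] = L.leaves[2] = L.leaves[3] = 0;
        L.leaves[d] = 1; L.birth = 0.0;
        L.pos = members[d].size();
        members[d].push_back(lin.size());
        lin.push_back(L);
        if (track_leaves) lin_leaves.push_back(std::vector<int>(1, leaf_id));
        ++leaf_id;
      }
  }

  int n_active() const {
    int k = 0;
    for (size_t d = 0; d < members.size(); ++d) k += members[d].size();
    return k;
  }

  void remove_from_deme(int slot) {
    Lineage& L = lin[slot];
    std::vector<int>& v = members[L.deme];
    int last = v.back();
    v[L.pos] = last;
    lin[last].pos = L.pos;
    v.pop_back();
  }

  void add_to_deme(int slot, int deme) {
    lin[slot].deme = deme;
    lin[slot].pos = members[deme].size();
    members[deme].push_back(slot);
  }

  // Run one genealogy; sink(slot, length) fires for every completed branch.
  template <class Sink>
  void run(Sink&& sink) {
    reset();
    double t = 0.0;
    size_t seg = 0, ev = 0;
    long guard = 0;
    while (n_active() > 1) {
      if (++guard > 500000000L) stop("coalescent simulation stalled");
      double rate = 0.0;
      double coal_rate[4] = {0, 0, 0, 0}, mig_rate[4] = {0, 0, 0, 0};
      for (int d = 0; d < dem.n_demes; ++d) {
        double k = (double)members[d].size();
        coal_rate[d] = k * (k - 1.0) * 0.5 / dem.nu[seg][d];
        double out = 0.0;
        for (int b = 0; b < dem.n_demes; ++b) out += dem.mig[seg][d * dem.n_demes + b];
        mig_rate[d] = k * out;
        rate += coal_rate[d] + mig_rate[d];
      }
      double boundary = dem.seg_end[seg];
      if (ev < dem.ev_time.size() && dem.ev_time[ev] < boundary) boundary = dem.ev_time[ev];
      double wait = (rate > 0.0) ? exp_rand() / rate : R_PosInf;
      if (t + wait >= boundary) {
        if (!R_finite(boundary))
          stop("demography has no common root: lineages remain isolated forever");
        t = boundary;
        while (ev < dem.ev_time.size() && dem.ev_time[ev] <= t) apply_event(ev++);
        while (seg + 1 < dem.seg_end.size() && dem.seg_end[seg] <= t) ++seg;
        continue;
      }
      t += wait;
      double u = unif_rand() * rate;
      for (int d = 0; d < dem.n_demes; ++d) {
        if (u < coal_rate[d]) { do_coalesce(d, t, sink); break; }
        u -= coal_rate[d];
        if (u < mig_rate[d]) { do_migrate(d, seg); break; }
        u -= mig_rate[d];
      }
    }
  }

  template <class Sink>
  void do_coalesce(int d, double t, Sink&& sink) {
    std::vector<int>& v = members[d];
    int k = v.size();
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int si = v[i], sj = v[j];
    sink(si, t - lin[si].birth);
    sink(sj, t - lin[sj].birth);
    Lineage L;
    L.deme = d;
    for (int a = 0; a < 4; ++a) L.leaves[a] = lin[si].leaves[a] + lin[sj].leaves[a];
    L.birth = t;
    remove_from_deme(si);
    remove_from_deme(sj);
    int slot = lin.size();
    L.pos = members[d].size();
    members[d].push_back(slot);
    lin.push_back(L);
    if (track_leaves) {
      std::vector<int> s(lin_leaves[si]);
      s.insert(s.end(), lin_leaves[sj].begin(), lin_leaves[sj].end());
      lin_leaves.push_back(s);
    }
  }

  void do_migrate(int d, size_t seg) {
    std::vector<int>& v = members[d];
    int k = v.size();
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int slot = v[i];
    double out = 0.0;
    for (int b = 0; b < dem.n_demes; ++b) out += dem.mig[seg][d * dem.n_demes + b];
    double x = unif_rand() * out;
    int dest = d;
    for (int b = 0; b < dem.n_demes; ++b) {
      if (dem.mig[seg][d * dem.n_demes + b] <= 0) continue;
      dest = b;
      x -= dem.mig[seg][d * dem.n_demes + b];
      if (x <= 0) break;
    }
    remove_from_deme(slot);
    add_to_deme(slot, dest);
  }

  void apply_event(size_t ev) {
    int type = dem.ev_type[ev];
    int a = dem.ev_a[ev], b = dem.ev_b[ev], c = dem.ev_c[ev];
    if (type == 1) {                       // move all lineages a -> b
      while (!members[a].empty()) {
        int slot = members[a].back();
        members[a].pop_back();
        add_to_deme(slot, b);
      }
    } else if (type == 2) {                // admixture pulse
      double f = dem.ev_f[ev];
      while (!members[a].empty()) {
        int slot = members[a].back();
        members[a].pop_back();
        // f of 0 or 1 is a plain move; skip the RNG so nested models
        // reproduce their limit exactly under a shared seed
        int dest = (f >= 1.0) ? b : (f <= 0.0) ? c : (unif_rand() < f ? b : c);
        add_to_deme(slot, dest);
      }
    }
  }
};

// [[Rcpp::export]]
NumericVector cpp_expected_jafs(List sched, IntegerVector n_sample, int n_reps) {
  Demography dem = unpack(sched);
  std::vector<int> ns(n_sample.begin(), n_sample.end());
  std::vector<int> ns3(ns); while (ns3.size() < 4) ns3.push_back(0);
  int d1 = ns3[0] + 1, d2 = ns3[1] + 1, d3 = ns3[2] + 1, d4 = ns3[3] + 1;
  NumericVector acc(d1 * d2 * d3 * d4);
  Simulator sim(dem, ns3);
  for (int r = 0; r < n_reps; ++r) {
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
    sim.run([&](int slot, double len) {
      const int* lv = sim.lin[slot].leaves;
      acc[lv[0] + d1 * (lv[1] + d2 * (lv[2] + d3 * lv[3]))] += len;
    });
  }
  // mutations arise at rate theta/2 per unit branch length
  for (int i = 0; i < acc.size(); ++i) acc[i] /= (2.0 * n_reps);
  if (ns.size() == 2) acc.attr("dim") = Dimension(d1, d2);
  else if (ns.size() == 3) acc.attr("dim") = Dimension(d1, d2, d3);
  else if (ns.size() == 4) acc.attr("dim") = IntegerVector::create(d1, d2, d3, d4);
  else acc.attr("dim") = Dimension(d1);
  return acc;
}

// Simulate one genealogy per RAD tag and drop mutations on it at rate
// theta/2 per unit branch length (infinite sites; each mutation is an
// independent branch draw on the shared tree, so SNPs of a tag are
// linked).  With theta = 0, exactly n_tags mutations are placed across
// the pooled branches of all trees, each chosen with probability
// proportional to branch length: this is the small-theta limit of
// infinite sites conditioned on the total number of segregating sites,
// under which a tree contributes SNPs in proportion to its length
// (sampling one branch per tree instead would weight every tree equally
// and bias the spectrum by the ratio E[L_cell/L_tot] vs
// E[L_cell]/E[L_tot]).  Returns the derived-allele state of every
// sampled haploid genome for every SNP, the tag index of every SNP, and
// the total branch length of every tag's tree.
// [[Rcpp::export]]
List cpp_sim_tags(List sched, IntegerVector n_sample, int n_tags, double theta) {
  Demography dem = unpack(sched);
  std::vector<int> ns(n_sample.begin(), n_sample.end());
  std::vector<int> ns3(ns); while (ns3.size() < 4) ns3.push_back(0);
  int n_tot = 0;
  for (size_t i = 0; i < ns.size(); ++i) n_tot += ns[i];
  Simulator sim(dem, ns3, true);
  std::vector<int> bslot;
  std::vector<double> bcum;
  std::vector<int> snp_tag;
  std::vector<std::vector<int>> snp_leaves;
  NumericVector tree_len(n_tags);
  if (theta > 0) {
    for (int tag = 0; tag < n_tags; ++tag) {
      if (tag % 256 == 0) Rcpp::checkUserInterrupt();
      bslot.clear(); bcum.clear();
      double total = 0.0;
      sim.run([&](int slot, double len) {
        total += len;
        bslot.push_back(slot);
        bcum.push_back(total);
      });
      tree_len[tag] = total;
      int k = (int)R::rpois(theta * total / 2.0);
      for (int m = 0; m < k; ++m) {
        double u = unif_rand() * total;
        size_t lo = 0, hi = bcum.size() - 1;
        while (lo < hi) {
          size_t mid = (lo + hi) / 2;
          if (bcum[mid] < u) lo = mid + 1; else hi = mid;
        }
        snp_tag.push_back(tag + 1);
        snp_leaves.push_back(sim.lin_leaves[bslot[lo]]);
      }
    }
  } else {
    // pool every branch of every tree, then place n_tags mutations on
    // branches drawn (with replacement) proportionally to length
    std::vector<std::vector<int>> pool_leaves;
    std::vector<int> pool_tag;
    std::vector<double> pool_cum;
    double grand = 0.0;
    for (int tag = 0; tag < n_tags; ++tag) {
      if (tag % 256 == 0) Rcpp::checkUserInterrupt();
      double total = 0.0;
      sim.run([&](int slot, double len) {
        total += len;
        grand += len;
        pool_leaves.push_back(sim.lin_leaves[slot]);
        pool_tag.push_back(tag + 1);
        pool_cum.push_back(grand);
      });
      tree_len[tag] = total;
    }
    std::vector<std::pair<double, int>> draws(n_tags);
    for (int m = 0; m < n_tags; ++m)
      draws[m] = std::make_pair(unif_rand() * grand, m);
    std::sort(draws.begin(), draws.end());
    snp_leaves.resize(n_tags);
    snp_tag.resize(n_tags);
    for (int m = 0; m < n_tags; ++m) {
      double u = draws[m].first;
      size_t lo = 0, hi = pool_cum.size() - 1;
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (pool_cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      snp_leaves[m] = pool_leaves[lo];
      snp_tag[m] = pool_tag[lo];
    }
  }
  IntegerMatrix derived(snp_tag.size(), n_tot);
  for (size_t s = 0; s < snp_leaves.size(); ++s)
    for (size_t i = 0; i < snp_leaves[s].size(); ++i)
      derived(s, snp_leaves[s][i]) = 1;
  return List::create(_["derived"] = derived,
                      _["tag"] = wrap(snp_tag),
                      _["tree_length"] = tree_len);
}

// Simulate n_loci independent genealogies; for each, drop one mutation on
// a branch chosen with probability proportional to its length
// (infinite sites, conditioned on the locus segregating in the sample)
// and report the derived-allele state of every sampled haploid genome.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_loci(List sched, IntegerVector n_sample, int n_loci) {
  Demography dem = unpack(sched);
  std::vector<int> ns(n_sample.begin(), n_sample.end());
  std::vector<int> ns3(ns); while (ns3.size() < 4) ns3.push_back(0);
  int n_tot = 0;
  for (size_t i = 0; i < ns.size(); ++i) n_tot += ns[i];
  IntegerMatrix out(n_loci, n_tot);
  Simulator sim(dem, ns3, true);
  std::vector<int> bslot;
  std::vector<double> bcum;
  for (int loc = 0; loc < n_loci; ++loc) {
    if (loc % 256 == 0) Rcpp::checkUserInterrupt();
    bslot.clear(); bcum.clear();
    double total = 0.0;
    sim.run([&](int slot, double len) {
      total += len;
      bslot.push_back(slot);
      bcum.push_back(total);
    });
    double u = unif_rand() * total;
    size_t lo = 0, hi = bcum.size() - 1;
    while (lo < hi) {                      // first branch with cum >= u
      size_t mid = (lo + hi) / 2;
      if (bcum[mid] < u) lo = mid + 1; else hi = mid;
    }
    const std::vector<int>& leaves = sim.lin_leaves[bslot[lo]];
    for (size_t i = 0; i < leaves.size(); ++i) out(loc, leaves[i]) = 1;
  }
  return out;
}
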