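// Diploid Wright-Fisher forward simulator with multiplicative selection,
// dominance, Poisson crossovers and infinite-sites mutation restricted to
// a supplied set of mutable (coding) positions.
//
// Haplotypes are sorted vectors of mutation ids (sorted by genomic
// position; positions of live mutations are unique, so position order is a
// strict total order). All randomness flows through R's RNG so that
// set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct MutStore {
  std::vector<int> pos;      // 0-based genomic position
  std::vector<double> s;     // selection coefficient (0 for neutral)
  std::vector<int> cls;      // 1 = neutral, 2 = deleterious-class
  std::vector<int> origin;   // generation of origin
  std::vector<char> alive;   // still occupies its position
  size_t size() const { return pos.size(); }
};

typedef std::vector<int> Hap;
typedef std::vector<Hap> Pop;  // 2N haplotypes

}  // namespace

// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(int genome_length,
                 IntegerVector mutable_pos,
                 IntegerVector mutable_class,
                 double mu,
                 double rec,
                 double gamma_mean,
                 double gamma_shape,
                 double dominance,
                 IntegerVector phase1_sizes,
                 IntegerMatrix phase2_sizes,
                 int sample_n,
                 int purge_interval,
                 double mutation_cap) {
  const int L = genome_length;
  const int n_mutable = mutable_pos.size();
  if (n_mutable == 0) stop("no mutable positions");
  if (phase1_sizes.size() < 1) stop("phase 1 must span at least one generation");

  MutStore mut;
  std::vector<char> pos_used(L, 0);
  long used_count = 0;
  const bool selection_on = (gamma_mean != 0.0);
  const double gamma_scale = (gamma_mean != 0.0) ? (-gamma_mean / gamma_shape) : 0.0;
  const double rec_len = rec * (double)(L - 1);
  const double mut_len = mu * (double)n_mutable;

  int cur_gen = 0;

  // ---- mutation creation -------------------------------------------------
  auto new_mutation = [&]() -> int {
    if ((double)mut.size() >= mutation_cap)
      stop("mutation cap exceeded at generation %d", cur_gen);
    if (used_count >= n_mutable)
      stop("all mutable positions are occupied at generation %d", cur_gen);
    for (;;) {
      int idx = (int)(unif_rand() * n_mutable);
      if (idx >= n_mutable) idx = n_mutable - 1;
      int p = mutable_pos[idx];
      if (!pos_used[p]) {
        pos_used[p] = 1;
        ++used_count;
        double sv = 0.0;
        int cl = mutable_class[idx];
        if (cl == 2 && selection_on) sv = -R::rgamma(gamma_shape, gamma_scale);
        mut.pos.push_back(p);
        mut.s.push_back(sv);
        mut.cls.push_back(cl);
        mut.origin.push_back(cur_gen);
        mut.alive.push_back(1);
        return (int)mut.size() - 1;
      }
    }
  };

  // ---- gamete formation --------------------------------------------------
  std::vector<int> bp;
  auto make_gamete = [&](const Hap& A, const Hap& B, Hap& out) {
    int k = (rec_len > 0.0) ? (int)R::rpois(rec_len) : 0;
    if (k == 0) {
      out = (unif_rand() < 0.5) ? A : B;
    } else {
      bp.clear();
      for (int i = 0; i < k; ++i) {
        int b = 1 + (int)(unif_rand() * (L - 1));
        if (b > L - 1) b = L - 1;
        bp.push_back(b);
      }
      std::sort(bp.begin(), bp.end());
      bp.push_back(L);  // sentinel: final segment
      out.clear();
      bool use_a = unif_rand() < 0.5;
      size_t ia = 0, ib = 0;
      int prev = 0;
      for (size_t seg = 0; seg < bp.size(); ++seg) {
        int end = bp[seg];
        while (ia < A.size() && mut.pos[A[ia]] < prev) ++ia;
        while (ib < B.size() && mut.pos[B[ib]] < prev) ++ib;
        if (use_a) {
          while (ia < A.size() && mut.pos[A[ia]] < end) out.push_back(A[ia++]);
        } else {
          while (ib < B.size() && mut.pos[B[ib]] < end) out.push_back(B[ib++]);
        }
        prev = end;
        use_a = !use_a;
      }
    }
    int m = (mut_len > 0.0) ? (int)R::rpois(mut_len) : 0;
    for (int j = 0; j < m; ++j) {
      int id = new_mutation();
      int p = mut.pos[id];
      auto it = std::lower_bound(out.begin(), out.end(), id,
                                 [&](int a, int) { return mut.pos[a] < p; });
      out.insert(it, id);
    }
  };

  // ---- fitness -----------------------------------------------------------
  auto diploid_fitness = [&](const Hap& A, const Hap& B) -> double {
    double w = 1.0;
    size_t i = 0, j = 0;
    while (i < A.size() && j < B.size()) {
      if (A[i] == B[j]) {
        if (mut.s[A[i]] != 0.0) w *= 1.0 + mut.s[A[i]];
        ++i; ++j;
      } else if (mut.pos[A[i]] < mut.pos[B[j]]) {
        if (mut.s[A[i]] != 0.0) w *= 1.0 + dominance * mut.s[A[i]];
        ++i;
      } else {
        if (mut.s[B[j]] != 0.0) w *= 1.0 + dominance * mut.s[B[j]];
        ++j;
      }
    }
    for (; i < A.size(); ++i)
      if (mut.s[A[i]] != 0.0) w *= 1.0 + dominance * mut.s[A[i]];
    for (; j < B.size(); ++j)
      if (mut.s[B[j]] != 0.0) w *= 1.0 + dominance * mut.s[B[j]];
    return (w > 0.0) ? w : 0.0;
  };

  // ---- one Wright-Fisher step: parents -> n_off offspring ---------------
  std::vector<double> cumw;
  auto reproduce = [&](const Pop& parents, int n_off, Pop& children) {
    int n_par = (int)parents.size() / 2;
    if (n_par < 1) stop("population extinct at generation %d", cur_gen);
    bool weighted = false;
    if (selection_on) {
      cumw.resize(n_par);
      double tot = 0.0;
      for (int i = 0; i < n_par; ++i) {
        tot += diploid_fitness(parents[2 * i], parents[2 * i + 1]);
        cumw[i] = tot;
      }
      if (tot <= 0.0) stop("total fitness zero at generation %d", cur_gen);
      weighted = true;
    }
    auto pick = [&]() -> int {
      if (!weighted) {
        int i = (int)(unif_rand() * n_par);
        return (i >= n_par) ? n_par - 1 : i;
      }
      double u = unif_rand() * cumw[n_par - 1];
      return (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
    };
    children.resize(2 * (size_t)n_off);
    for (int i = 0; i < n_off; ++i) {
      int p1 = pick(), p2 = pick();
      make_gamete(parents[2 * p1], parents[2 * p1 + 1], children[2 * i]);
      make_gamete(parents[2 * p2], parents[2 * p2 + 1], children[2 * i + 1]);
    }
  };

  // ---- bookkeeping of fixed / lost mutations -----------------------------
  std::vector<Pop> pops(1);
  std::vector<std::vector<int> > fixed_ids;   // per population, since split
  std::vector<int> anc_fixed;                 // fixed before the split
  std::vector<char> fixed_any(0);
  bool split_done = false;

  std::vector<std::vector<long> > cnt;
  auto purge = [&]() {
    size_t nm = mut.size();
    fixed_any.resize(nm, 0);
    size_t np = pops.size();
    cnt.assign(np, std::vector<long>(nm, 0));
    for (size_t p = 0; p < np; ++p)
      for (size_t hpi = 0; hpi < pops[p].size(); ++hpi)
        for (size_t k = 0; k < pops[p][hpi].size(); ++k)
          ++cnt[p][pops[p][hpi][k]];
    for (size_t p = 0; p < np; ++p) {
      long nh = (long)pops[p].size();
      std::vector<char> fix_here(nm, 0);
      bool any_fix = false;
      for (size_t id = 0; id < nm; ++id) {
        if (cnt[p][id] == nh && nh > 0) {
          fix_here[id] = 1;
          any_fix = true;
          fixed_any[id] = 1;
          if (!split_done) anc_fixed.push_back((int)id);
          else fixed_ids[p].push_back((int)id);
          cnt[p][id] = 0;  // no longer segregating here
        }
      }
      if (any_fix) {
        for (size_t hpi = 0; hpi < pops[p].size(); ++hpi) {
          Hap& h = pops[p][hpi];
          size_t w = 0;
          for (size_t k = 0; k < h.size(); ++k)
            if (!fix_here[h[k]]) h[w++] = h[k];
          h.resize(w);
        }
      }
    }
    // free positions of mutations lost everywhere and never fixed
    for (size_t id = 0; id < nm; ++id) {
      if (!mut.alive[id] || fixed_any[id]) continue;
      long tot = 0;
      for (size_t p = 0; p < np; ++p) tot += cnt[p][id];
      if (tot == 0) {
        mut.alive[id] = 0;
        pos_used[mut.pos[id]] = 0;
        --used_count;
      }
    }
  };

  // ---- phase 1: single ancestral population ------------------------------
  {
    int n0 = phase1_sizes[0];
    if (n0 < 2) stop("ancestral size must be >= 2");
    pops[0].assign(2 * (size_t)n0, Hap());
    Pop buf;
    for (int t = 1; t < phase1_sizes.size(); ++t) {
      cur_gen = t;
      if (phase1_sizes[t] < 1) stop("population size below 1 at generation %d", t);
      reproduce(pops[0], phase1_sizes[t], buf);
      pops[0].swap(buf);
      if (t % purge_interval == 0) purge();
      if (t % 200 == 0) Rcpp::checkUserInterrupt();
    }
    purge();
  }

  // ---- phase 2: daughter populations -------------------------------------
  int t1 = phase1_sizes.size() - 1;
  if (phase2_sizes.nrow() > 0) {
    int np = phase2_sizes.ncol();
    Pop ancestral;
    ancestral.swap(pops[0]);
    pops.assign(np, Pop());
    fixed_ids.assign(np, std::vector<int>());
    cur_gen = t1 + 1;
    for (int p = 0; p < np; ++p)
      reproduce(ancestral, phase2_sizes(0, p), pops[p]);
    ancestral.clear();
    split_done = true;
    Pop buf;
    for (int t = 1; t < phase2_sizes.nrow(); ++t) {
      cur_gen = t1 + 1 + t;
      for (int p = 0; p < np; ++p) {
        if (phase2_sizes(t, p) < 1)
          stop("population %d size below 1 at generation %d", p + 1, cur_gen);
        reproduce(pops[p], phase2_sizes(t, p), buf);
        pops[p].swap(buf);
      }
      if (t % purge_interval == 0) purge();
      if (t % 200 == 0) Rcpp::checkUserInterrupt();
    }
    purge();
  } else {
    fixed_ids.assign(1, std::vector<int>());
  }

  // ---- outputs ------------------------------------------------------------
  size_t np = pops.size();
  size_t nm = mut.size();
  cnt.assign(np, std::vector<long>(nm, 0));
  for (size_t p = 0; p < np; ++p)
    for (size_t hpi = 0; hpi < pops[p].size(); ++hpi)
      for (size_t k = 0; k < pops[p][hpi].size(); ++k)
        ++cnt[p][pops[p][hpi][k]];

  // compact id map over everything reported
  std::vector<int> remap(nm, -1);
  std::vector<int> keep;
  auto mark = [&](int id) {
    if (remap[id] < 0) { remap[id] = (int)keep.size(); keep.push_back(id); }
  };
  for (size_t id = 0; id < nm; ++id)
    for (size_t p = 0; p < np; ++p)
      if (cnt[p][id] > 0) { mark((int)id); break; }
  for (size_t k = 0; k < anc_fixed.size(); ++k) mark(anc_fixed[k]);
  for (size_t p = 0; p < np; ++p)
    for (size_t k = 0; k < fixed_ids[p].size(); ++k) mark(fixed_ids[p][k]);

  int nk = (int)keep.size();
  IntegerVector out_pos(nk), out_cls(nk), out_origin(nk);
  NumericVector out_s(nk);
  for (int k = 0; k < nk; ++k) {
    out_pos[k] = mut.pos[keep[k]];
    out_s[k] = mut.s[keep[k]];
    out_cls[k] = mut.cls[keep[k]];
    out_origin[k] = mut.origin[keep[k]];
  }

  List pop_out(np);
  for (size_t p = 0; p < np; ++p) {
    int nh = (int)pops[p].size();
    int nd = nh / 2;
    std::vector<int> seg;
    for (size_t id = 0; id < nm; ++id)
      if (cnt[p][id] > 0) seg.push_back((int)id);
    int ns = (int)seg.size();
    IntegerVector seg_idx(ns), seg_count(ns);
    for (int k = 0; k < ns; ++k) {
      seg_idx[k] = remap[seg[k]] + 1;  // 1-based into mutation table
      seg_count[k] = (int)cnt[p][seg[k]];
    }
    IntegerVector fx(fixed_ids[p].size());
    for (size_t k = 0; k < fixed_ids[p].size(); ++k)
      fx[k] = remap[fixed_ids[p][k]] + 1;

    // sample without replacement
    int ns_ind = std::min(sample_n, nd);
    std::vector<int> idx(nd);
    for (int i = 0; i < nd; ++i) idx[i] = i;
    for (int i = 0; i < ns_ind; ++i) {
      int j = i + (int)(unif_rand() * (nd - i));
      if (j > nd - 1) j = nd - 1;
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> lookup(nm, -1);
    for (int k = 0; k < ns; ++k) lookup[seg[k]] = k;
    IntegerMatrix geno(ns, ns_ind);
    for (int i = 0; i < ns_ind; ++i) {
      for (int c = 0; c < 2; ++c) {
        const Hap& h = pops[p][2 * idx[i] + c];
        for (size_t k = 0; k < h.size(); ++k) {
          int r = lookup[h[k]];
          if (r >= 0) geno(r, i) += 1;
        }
      }
    }
    pop_out[p] = List::create(
        _["n_diploid"] = nd,
        _["seg_idx"] = seg_idx,
        _["seg_count"] = seg_count,
        _["fixed_idx"] = fx,
        _["sample_geno"] = geno);
  }

  IntegerVector anc(anc_fixed.size());
  for (size_t k = 0; k < anc_fixed.size(); ++k) anc[k] = remap[anc_fixed[k]] + 1;

  return List::create(
      _["pos"] = out_pos,
      _["s"] = out_s,
      _["class"] = out_cls,
      _["origin"] = out_origin,
      _["anc_fixed_idx"] = anc,
      _["populations"] = pop_out,
      _["n_mutations_total"] = (double)nm);
}
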