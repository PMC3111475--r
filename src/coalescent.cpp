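// Two-phase coalescent engine for three-taxon domestication histories.
//
// Time is measured in units of 4*N_R generations (ms convention); population
// sizes enter as ratios c = N_x / N_R, so a pair of haploid lineages in a
// population of relative size c coalesces at rate 2/c per time unit and
// E[T2] = c/2.  Leaves are ordered R (wild), then I, then J.
//
// Phase 1 (present back to domestication): the cultivar lineages coalesce in
// their own bottlenecked populations with no recombination (selfing), so one
// shared genealogy fragment ("forest") applies to every sub-segment of the
// locus.  Phase 2 (wild / ancestral): the locus is partitioned into
// non-recombining sub-segments with geometric breakpoints; per sub-segment the
// wild lineages coalesce independently from time 0, the cultivar forest roots
// join the wild population at the domestication time, and the merged set
// coalesces to its MRCA.
//
// All randomness comes from R's RNG (Rcpp RNGScope), so set.seed() on the R
// side makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Genealogy {
  std::vector<int> parent;   // -1 = no parent yet / root
  std::vector<double> time;  // node times, increasing from leaves (t = 0)
};

int pick_index(int k) {
  int i = (int)(unif_rand() * k);
  if (i >= k) i = k - 1;
  return i;
}

// Coalesce `active` lineages in a population of relative size c from time *t
// until t_end (R_PosInf allowed) or until one lineage remains.  Merged nodes
// are appended to g; *t is advanced.
void coalesce(std::vector<int>& active, double* t, double t_end, double c,
              Genealogy& g) {
  while ((int)active.size() > 1) {
    int k = (int)active.size();
    double rate = k * (k - 1.0) / 2.0 * 2.0 / c;
    double wait = R::rexp(1.0 / rate);
    if (*t + wait > t_end) { *t = t_end; return; }
    *t += wait;
    int i = pick_index(k);
    int j = pick_index(k - 1);
    if (j >= i) j++;
    int node = (int)g.parent.size();
    g.parent.push_back(-1);
    g.time.push_back(*t);
    g.parent[active[i]] = node;
    g.parent[active[j]] = node;
    active[i] = node;
    active.erase(active.begin() + j);
  }
}

// Phase-1 cultivar forest: coalesce I and J (and, for the sequential model,
// their shared domesticated stem) from time 0 back to T_d.  Returns the
// surviving lineage ids; nodes are appended to g.
std::vector<int> build_forest(int n_R, int n_I, int n_J, double c_I,
                              double c_J, double c_D, int topology,
                              double T_split, double T_d, Genealogy& g) {
  std::vector<int> act_I, act_J;
  for (int i = 0; i < n_I; i++) act_I.push_back(n_R + i);
  for (int j = 0; j < n_J; j++) act_J.push_back(n_R + n_I + j);
  double t;
  std::vector<int> roots;
  if (topology == 0) {  // independent: I and J run separately to T_d
    t = 0.0; coalesce(act_I, &t, T_d, c_I, g);
    t = 0.0; coalesce(act_J, &t, T_d, c_J, g);
    roots = act_I;
    roots.insert(roots.end(), act_J.begin(), act_J.end());
  } else {              // sequential: split at T_split, shared stem to T_d
    t = 0.0; coalesce(act_I, &t, T_split, c_I, g);
    t = 0.0; coalesce(act_J, &t, T_split, c_J, g);
    std::vector<int> stem = act_I;
    stem.insert(stem.end(), act_J.begin(), act_J.end());
    t = T_split;
    coalesce(stem, &t, T_d, c_D, g);
    roots = stem;
  }
  return roots;
}

// Complete one sub-segment: copy the shared forest, run the wild-phase
// coalescent for the R sample from 0 to T_d, merge, coalesce to the MRCA.
List finish_segment(const Genealogy& forest, const std::vector<int>& roots,
                    int n_R, int n_tot, double T_d, double start, double end) {
  Genealogy g = forest;  // copy: forest parents get set during the wild phase
  std::vector<int> act_R;
  for (int i = 0; i < n_R; i++) act_R.push_back(i);
  double t = 0.0;
  coalesce(act_R, &t, T_d, 1.0, g);
  std::vector<int> all = act_R;
  all.insert(all.end(), roots.begin(), roots.end());
  t = T_d;
  coalesce(all, &t, R_PosInf, 1.0, g);
  return List::create(_["start"] = start, _["end"] = end,
                      _["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["n_leaves"] = n_tot);
}

}  // namespace

// [[Rcpp::export]]
List cpp_two_phase_locus(int n_R, int n_I, int n_J, double c_I, double c_J,
                         double c_D, int topology, double T_split, double T_d,
                         double locus_length, double breakpoint_rate,
                         double refresh_rate) {
  RNGScope scope;
  int n_tot = n_R + n_I + n_J;
  // geometric (exponential-spacing) breakpoints in the wild phase
  std::vector<double> bounds;
  bounds.push_back(0.0);
  if (breakpoint_rate > 0) {
    double x = 0.0;
    for (;;) {
      x += R::rexp(1.0 / breakpoint_rate);
      if (x >= locus_length) break;
      bounds.push_back(x);
    }
  }
  bounds.push_back(locus_length);

  Genealogy forest;
  forest.parent.assign(n_tot, -1);
  forest.time.assign(n_tot, 0.0);
  std::vector<int> roots =
      build_forest(n_R, n_I, n_J, c_I, c_J, c_D, topology, T_split, T_d, forest);

  int n_seg = (int)bounds.size() - 1;
  List segments(n_seg);
  for (int s = 0; s < n_seg; s++) {
    double len = bounds[s + 1] - bounds[s];
    bool refresh = refresh_rate > 0 &&
                   unif_rand() < 1.0 - std::exp(-refresh_rate * len);
    if (refresh) {
      // residual selfing-phase recombination: this sub-segment gets its own
      // cultivar forest instead of the shared one (approximation; exact only
      // in the limits selfing_rate = 1 or 0)
      Genealogy f2;
      f2.parent.assign(n_tot, -1);
      f2.time.assign(n_tot, 0.0);
      std::vector<int> r2 = build_forest(n_R, n_I, n_J, c_I, c_J, c_D,
                                         topology, T_split, T_d, f2);
      segments[s] = finish_segment(f2, r2, n_R, n_tot, T_d,
                                   bounds[s], bounds[s + 1]);
    } else {
      segments[s] = finish_segment(forest, roots, n_R, n_tot, T_d,
                                   bounds[s], bounds[s + 1]);
    }
  }
  return segments;
}

// [[Rcpp::export]]
List cpp_overlay_mutations(List segments, double theta_site) {
  RNGScope scope;
  std::vector<double> positions;
  std::vector<std::vector<int> > columns;  // leaf index lists per mutation
  for (int s = 0; s < segments.size(); s++) {
    List seg = segments[s];
    IntegerVector parent = seg["parent"];
    NumericVector time = seg["time"];
    int n_leaves = seg["n_leaves"];
    double start = seg["start"], end = seg["end"];
    double theta_seg = theta_site * (end - start);
    int n_nodes = parent.size();
    // child index < parent index always holds, so one upward pass collects
    // the descendant-leaf set of every node
    std::vector<std::vector<int> > leafset(n_nodes);
    for (int v = 0; v < n_nodes; v++) {
      if (v < n_leaves) leafset[v].push_back(v);
      if (parent[v] >= 0) {
        std::vector<int>& up = leafset[parent[v]];
        up.insert(up.end(), leafset[v].begin(), leafset[v].end());
      }
    }
    for (int v = 0; v < n_nodes; v++) {
      if (parent[v] < 0) continue;
      double blen = time[parent[v]] - time[v];
      if (blen <= 0) continue;
      int m = (int)R::rpois(theta_seg * blen);
      for (int k = 0; k < m; k++) {
        positions.push_back(start + unif_rand() * (end - start));
        columns.push_back(leafset[v]);
      }
    }
  }
  int S = (int)positions.size();
  int n_leaves = 0;
  if (segments.size() > 0) {
    List seg0 = segments[0];
    n_leaves = seg0["n_leaves"];
  }
  // sort by position
  std::vector<int> ord(S);
  for (int i = 0; i < S; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return positions[a] < positions[b];
  });
  NumericVector pos_out(S);
  IntegerMatrix mat(n_leaves, S);
  for (int i = 0; i < S; i++) {
    pos_out[i] = positions[ord[i]];
    const std::vector<int>& ls = columns[ord[i]];
    for (size_t k = 0; k < ls.size(); k++) mat(ls[k], i) = 1;
  }
  return List::create(_["positions"] = pos_out, _["mat"] = mat);
}
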