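#include <Rcpp.h>
using namespace Rcpp;

// Kingman coalescent over many independent loci.
//
// For locus l the active lineages are roots[offsets[l] .. offsets[l+1]-1]
// (0-based offsets, C order). Starting at start_time[l] (generations before
// present), pairs coalesce at rate k(k-1)/2 * 1/(2N) until one lineage
// remains. New internal nodes are numbered consecutively from `first_node`.
// Uses R's RNG so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List kingman_coalesce(IntegerVector offsets, IntegerVector roots,
                      NumericVector start_time, double ne_diploid,
                      int first_node) {
  const int n_loci = offsets.size() - 1;
  const int total = roots.size();
  std::vector<int> e_child, e_parent, e_locus, new_node;
  std::vector<double> new_time;
  e_child.reserve(2 * total);
  e_parent.reserve(2 * total);
  e_locus.reserve(2 * total);
  new_node.reserve(total);
  new_time.reserve(total);
  IntegerVector final_root(n_loci);
  NumericVector final_root_time(n_loci);
  int next = first_node;
  RNGScope scope;
  for (int l = 0; l < n_loci; ++l) {
    int k = offsets[l + 1] - offsets[l];
    std::vector<int> act(roots.begin() + offsets[l],
                         roots.begin() + offsets[l + 1]);
    double t = start_time[l];
    while (k >= 2) {
      double rate = (double)k * (k - 1) / 2.0 / (2.0 * ne_diploid);
      t += R::exp_rand() / rate;
      int i = (int)(R::unif_rand() * k);
      if (i >= k) i = k - 1;
      int j = (int)(R::unif_rand() * (k - 1));
      if (j >= k - 1) j = k - 2;
      if (j >= i) j += 1;
      e_child.push_back(act[i]);
      e_parent.push_back(next);
      e_locus.push_back(l + 1);
      e_child.push_back(act[j]);
      e_parent.push_back(next);
      e_locus.push_back(l + 1);
      new_node.push_back(next);
      new_time.push_back(t);
      // replace slot i with the new node, swap-remove slot j
      act[i] = next;
      act[j] = act[k - 1];
      act.pop_back();
      --k;
      ++next;
    }
    final_root[l] = act.empty() ? NA_INTEGER : act[0];
    final_root_time[l] = act.empty() ? NA_REAL : t;
  }
  return List::create(
      _["edge_child"] = IntegerVector(e_child.begin(), e_child.end()),
      _["edge_parent"] = IntegerVector(e_parent.begin(), e_parent.end()),
      _["edge_locus"] = IntegerVector(e_locus.begin(), e_locus.end()),
      _["node"] = IntegerVector(new_node.begin(), new_node.end()),
      _["time"] = NumericVector(new_time.begin(), new_time.end()),
      _["root"] = final_root, _["root_time"] = final_root_time,
      _["next_node"] = next);
}
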