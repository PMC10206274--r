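#include <Rcpp.h>
using namespace Rcpp;

// Single-site Kingman coalescent under a piecewise-constant diploid Ne
// schedule. Sites are simulated independently (free recombination between
// retained sites); linkage within the base population is therefore absent,
// which the package documents as a stated approximation.
//
// epoch_t: epoch start times in generations ago (epoch_t[0] == 0, increasing)
// epoch_N: diploid effective size within each epoch
//
// conditional = true  -> exactly one mutation placed on a branch chosen
//                        proportional to branch length (site is segregating
//                        by construction; SFS is the standard
//                        conditional-on-one-mutation spectrum)
// conditional = false -> mutation occurs with prob 1 - exp(-mu * total branch
//                        length); monomorphic columns are retained (used by
//                        the neutral-diversity control, where E[pi] = 4*Ne*mu)
// [[Rcpp::export]]
IntegerMatrix coalescent_sites_cpp(int n_hap, int n_sites,
                                   NumericVector epoch_t, NumericVector epoch_N,
                                   bool conditional, double mu) {
  if (n_hap < 2) stop("need at least 2 haplotypes");
  const int n_epoch = epoch_t.size();
  IntegerMatrix out(n_hap, n_sites);
  const int n_nodes = 2 * n_hap - 1;
  std::vector<double> time(n_nodes);
  std::vector<int> child1(n_nodes), child2(n_nodes);
  std::vector<int> active(n_hap);

  for (int s = 0; s < n_sites; ++s) {
    for (int i = 0; i < n_hap; ++i) { active[i] = i; time[i] = 0.0; }
    for (int i = 0; i < n_nodes; ++i) { child1[i] = -1; child2[i] = -1; }
    int k = n_hap, next_id = n_hap, e = 0;
    double t = 0.0;
    while (k > 1) {
      double N = epoch_N[e];
      double rate = (double)k * (k - 1) / 2.0 / (2.0 * N);
      double dt = R::rexp(1.0 / rate);
      double bound = (e + 1 < n_epoch) ? epoch_t[e + 1] : R_PosInf;
      if (t + dt > bound) { t = bound; ++e; continue; }
      t += dt;
      int ia = (int)(R::unif_rand() * k); if (ia == k) ia = k - 1;
      int ib = (int)(R::unif_rand() * (k - 1)); if (ib == k - 1) ib = k - 2;
      if (ib >= ia) ++ib;
      int a = active[ia], b = active[ib];
      int node = next_id++;
      time[node] = t; child1[node] = a; child2[node] = b;
      // replace a by node, remove b
      active[ia] = node;
      active[ib] = active[k - 1];
      --k;
    }
    // total branch length (root has no branch above it)
    // parent time lookup: walk internal nodes
    double total_len = 0.0;
    for (int v = n_hap; v < n_nodes; ++v) {
      total_len += (time[v] - time[child1[v]]) + (time[v] - time[child2[v]]);
    }
    bool mutate = true;
    if (!conditional) {
      double p = 1.0 - std::exp(-mu * total_len);
      mutate = (R::unif_rand() < p);
    }
    if (!mutate) continue; // column stays all zero
    // choose a branch proportional to its length; branch identified by its
    // lower node
    double u = R::unif_rand() * total_len, acc = 0.0;
    int chosen = -1;
    for (int v = n_hap; v < n_nodes && chosen < 0; ++v) {
      acc += time[v] - time[child1[v]];
      if (u <= acc) { chosen = child1[v]; break; }
      acc += time[v] - time[child2[v]];
      if (u <= acc) { chosen = child2[v]; break; }
    }
    if (chosen < 0) chosen = child2[n_nodes - 1]; // numerical edge
    // mark tip descendants of chosen node
    std::vector<int> stack; stack.push_back(chosen);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_hap) { out(v, s) = 1; }
      else { stack.push_back(child1[v]); stack.push_back(child2[v]); }
    }
  }
  return out;
}
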