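#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent with piecewise-constant demography.
//
// A demography is a list of epochs ordered from the present backward.
// Each epoch is a list with elements
//   end : time (units of 2*Nref generations) at which the epoch ends
//         (R_PosInf for the terminal epoch),
//   nu  : relative deme sizes (length P),
//   mig : P x P backward migration rates; mig(i,j) is the rate at which a
//         lineage currently in deme i jumps to deme j, per 2*Nref
//         generations (the 2*Nref*m convention),
//   move: P x P row-stochastic matrix applied to every lineage when the
//         epoch ends (deterministic rows encode population joins, mixed
//         rows encode admixture), or R_NilValue.
//
// Coalescence rate in deme i with k lineages is k*(k-1)/2 / nu_i.

namespace {

struct Lineage {
  int deme;
  // SFS mode: descendant counts per sampled population.
  std::vector<int> cnt;
  // genotype mode: descendant leaf ids.
  std::vector<int> leaves;
};

int sample_index(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

void apply_move(std::vector<Lineage>& lin, const NumericMatrix& move) {
  int P = move.nrow();
  for (size_t l = 0; l < lin.size(); ++l) {
    int i = lin[l].deme;
    double u = unif_rand(), acc = 0.0;
    for (int j = 0; j < P; ++j) {
      acc += move(i, j);
      if (u <= acc) { lin[l].deme = j; break; }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".coal_expected_sfs")]]
NumericVector coal_expected_sfs(List epochs, IntegerVector samp, int nreps) {
  int npop = samp.size();
  int ntot = 0;
  std::vector<int> dim(npop);
  for (int i = 0; i < npop; ++i) { dim[i] = samp[i] + 1; ntot += samp[i]; }
  int ncell = 1;
  for (int i = 0; i < npop; ++i) ncell *= dim[i];
  std::vector<double> acc(ncell, 0.0);

  int nep = epochs.size();
  std::vector<NumericVector> nu(nep);
  std::vector<NumericMatrix> mig(nep);
  std::vector<double> epoch_end(nep);
  std::vector<SEXP> move(nep);
  for (int e = 0; e < nep; ++e) {
    List ep = epochs[e];
    epoch_end[e] = as<double>(ep["end"]);
    nu[e] = as<NumericVector>(ep["nu"]);
    mig[e] = as<NumericMatrix>(ep["mig"]);
    move[e] = ep.containsElementNamed("move") ? (SEXP)ep["move"] : R_NilValue;
  }
  int P = nu[0].size();

  for (int rep = 0; rep < nreps; ++rep) {
    std::vector<Lineage> lin;
    for (int i = 0; i < npop; ++i)
      for (int s = 0; s < samp[i]; ++s) {
        Lineage L; L.deme = i; L.cnt.assign(npop, 0); L.cnt[i] = 1;
        lin.push_back(L);
      }
    double t = 0.0;
    int e = 0;
    while ((int)lin.size() > 1) {
      // per-deme lineage counts
      std::vector<int> k(P, 0);
      for (size_t l = 0; l < lin.size(); ++l) k[lin[l].deme]++;
      std::vector<double> coal_rate(P, 0.0);
      double mig_total = 0.0, total = 0.0;
      for (int i = 0; i < P; ++i) {
        coal_rate[i] = k[i] * (k[i] - 1) / 2.0 / nu[e][i];
        total += coal_rate[i];
        double mrow = 0.0;
        for (int j = 0; j < P; ++j) mrow += mig[e](i, j);
        mig_total += k[i] * mrow;
      }
      total += mig_total;
      double dt = (total > 0) ? exp_rand() / total : R_PosInf;
      double tev = t + dt;
      double tstop = std::min(tev, epoch_end[e]);
      // accumulate branch lengths over [t, tstop)
      double span = tstop - t;
      if (span > 0) {
        for (size_t l = 0; l < lin.size(); ++l) {
          int idx = 0, mult = 1;
          for (int i = 0; i < npop; ++i) { idx += lin[l].cnt[i] * mult; mult *= dim[i]; }
          acc[idx] += span;
        }
      }
      if (tev >= epoch_end[e]) {
        t = epoch_end[e];
        if (move[e] != R_NilValue) {
          NumericMatrix mv(move[e]);
          apply_move(lin, mv);
        }
        ++e;
        continue;
      }
      t = tev;
      double u = unif_rand() * total, cum = 0.0;
      int ev_deme = -1; bool is_coal = false;
      for (int i = 0; i < P; ++i) {
        cum += coal_rate[i];
        if (u <= cum) { ev_deme = i; is_coal = true; break; }
      }
      if (is_coal) {
        // pick two distinct lineages in ev_deme
        std::vector<int> ids;
        for (size_t l = 0; l < lin.size(); ++l)
          if (lin[l].deme == ev_deme) ids.push_back((int)l);
        int a = (int)(unif_rand() * ids.size());
        int b = (int)(unif_rand() * (ids.size() - 1));
        if (b >= a) ++b;
        int la = ids[a], lb = ids[b];
        for (int i = 0; i < npop; ++i) lin[la].cnt[i] += lin[lb].cnt[i];
        lin.erase(lin.begin() + lb);
      } else {
        // migration: pick (lineage, destination) weighted by rates
        double u2 = u - cum, c2 = 0.0;
        bool done = false;
        for (size_t l = 0; l < lin.size() && !done; ++l) {
          int i = lin[l].deme;
          for (int j = 0; j < P && !done; ++j) {
            c2 += mig[e](i, j);
            if (u2 <= c2) { lin[l].deme = j; done = true; }
          }
        }
        if (!done) lin.back().deme = P - 1; // numerical guard
      }
    }
  }
  NumericVector out(ncell);
  for (int c = 0; c < ncell; ++c) out[c] = acc[c] / nreps;
  return out;
}

// Simulate one non-recombining locus: a tree over all sampled allele copies
// plus Poisson mutations at rate theta_locus/2 per branch per unit time.
// Returns a list of integer vectors, one per mutation, holding 0-based ids of
// carrier allele copies (ids ordered by deme, then sample order).
// [[Rcpp::export(name = ".coal_sim_locus")]]
List coal_sim_locus(List epochs, IntegerVector samp, double theta_locus) {
  int npop = samp.size();
  int nep = epochs.size();
  std::vector<NumericVector> nu(nep);
  std::vector<NumericMatrix> mig(nep);
  std::vector<double> epoch_end(nep);
  std::vector<SEXP> move(nep);
  for (int e = 0; e < nep; ++e) {
    List ep = epochs[e];
    epoch_end[e] = as<double>(ep["end"]);
    nu[e] = as<NumericVector>(ep["nu"]);
    mig[e] = as<NumericMatrix>(ep["mig"]);
    move[e] = ep.containsElementNamed("move") ? (SEXP)ep["move"] : R_NilValue;
  }
  int P = nu[0].size();
  double half_theta = theta_locus / 2.0;

  std::vector<Lineage> lin;
  int id = 0;
  for (int i = 0; i < npop; ++i)
    for (int s = 0; s < samp[i]; ++s) {
      Lineage L; L.deme = i; L.leaves.push_back(id++);
      lin.push_back(L);
    }
  std::vector<std::vector<int> > mut_carriers;

  double t = 0.0;
  int e = 0;
  while ((int)lin.size() > 1) {
    std::vector<int> k(P, 0);
    for (size_t l = 0; l < lin.size(); ++l) k[lin[l].deme]++;
    std::vector<double> coal_rate(P, 0.0);
    double mig_total = 0.0, total = 0.0;
    for (int i = 0; i < P; ++i) {
      coal_rate[i] = k[i] * (k[i] - 1) / 2.0 / nu[e][i];
      total += coal_rate[i];
      double mrow = 0.0;
      for (int j = 0; j < P; ++j) mrow += mig[e](i, j);
      mig_total += k[i] * mrow;
    }
    total += mig_total;
    double dt = (total > 0) ? exp_rand() / total : R_PosInf;
    double tev = t + dt;
    double tstop = std::min(tev, epoch_end[e]);
    double span = tstop - t;
    if (span > 0 && half_theta > 0) {
      for (size_t l = 0; l < lin.size(); ++l) {
        int nm = (int)R::rpois(span * half_theta);
        for (int m = 0; m < nm; ++m) mut_carriers.push_back(lin[l].leaves);
      }
    }
    if (tev >= epoch_end[e]) {
      t = epoch_end[e];
      if (move[e] != R_NilValue) {
        NumericMatrix mv(move[e]);
        apply_move(lin, mv);
      }
      ++e;
      continue;
    }
    t = tev;
    double u = unif_rand() * total, cum = 0.0;
    int ev_deme = -1; bool is_coal = false;
    for (int i = 0; i < P; ++i) {
      cum += coal_rate[i];
      if (u <= cum) { ev_deme = i; is_coal = true; break; }
    }
    if (is_coal) {
      std::vector<int> ids;
      for (size_t l = 0; l < lin.size(); ++l)
        if (lin[l].deme == ev_deme) ids.push_back((int)l);
      int a = (int)(unif_rand() * ids.size());
      int b = (int)(unif_rand() * (ids.size() - 1));
      if (b >= a) ++b;
      int la = ids[a], lb = ids[b];
      lin[la].leaves.insert(lin[la].leaves.end(),
                            lin[lb].leaves.begin(), lin[lb].leaves.end());
      lin.erase(lin.begin() + lb);
    } else {
      double u2 = u - cum, c2 = 0.0;
      bool done = false;
      for (size_t l = 0; l < lin.size() && !done; ++l) {
        int i = lin[l].deme;
        for (int j = 0; j < P && !done; ++j) {
          c2 += mig[e](i, j);
          if (u2 <= c2) { lin[l].deme = j; done = true; }
        }
      }
      if (!done) lin.back().deme = P - 1;
    }
  }
  List out(mut_carriers.size());
  for (size_t m = 0; m < mut_carriers.size(); ++m)
    out[m] = IntegerVector(mut_carriers[m].begin(), mut_carriers[m].end());
  return out;
}
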