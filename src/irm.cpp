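// MCMC core for the infinite relational model with a Dirichlet compound
// multinomial likelihood on streamline counts.
//
// State: a symmetric binary graph G (diag 0), a partition z of the P ROIs,
// and hyperparameters (xi, alpha, beta, delta0, delta1).  The sampler
// alternates (a) a Metropolis sweep over unordered edge flips, (b) a Gibbs
// sweep over ROI cluster assignments with the Beta-Bernoulli block prior
// collapsed, and (c) one Jain-Neal restricted-Gibbs split-merge proposal.
// All randomness flows through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

class IRMSampler {
public:
  int P, K;
  double xi, alpha, beta, d0, d1, lbeta0;
  NumericMatrix S;
  IntegerMatrix G;
  std::vector<int> z;                    // 0-based labels, contiguous
  std::vector<double> nsize;             // cluster sizes
  std::vector< std::vector<double> > Mp, Mm; // edge / non-edge pair tallies
  std::vector<double> rowTot, B, rowLL;  // per-row caches for the DM likelihood

  IRMSampler(NumericMatrix S_, IntegerMatrix G0, IntegerVector z0,
             double xi_, double alpha_, double beta_, double d0_, double d1_)
    : S(S_), G(clone(G0)), xi(xi_), alpha(alpha_), beta(beta_), d0(d0_), d1(d1_) {
    P = S.nrow();
    z.resize(P);
    for (int i = 0; i < P; ++i) z[i] = z0[i] - 1;
    relabel();
    lbeta0 = R::lbeta(alpha, beta);
    rowTot.assign(P, 0.0); B.assign(P, 0.0); rowLL.assign(P, 0.0);
    rebuildRows();
    rebuildTallies();
  }

  // -- caches ---------------------------------------------------------------

  void relabel() {
    std::vector<int> map(P, -1);
    int k = 0;
    for (int i = 0; i < P; ++i) {
      if (map[z[i]] < 0) map[z[i]] = k++;
      z[i] = map[z[i]];
    }
    K = k;
    nsize.assign(K, 0.0);
    for (int i = 0; i < P; ++i) nsize[z[i]] += 1.0;
  }

  void rebuildRows() {
    for (int i = 0; i < P; ++i) {
      double T = 0.0, Bi = 0.0, ll = 0.0;
      for (int j = 0; j < P; ++j) {
        if (j == i) continue;
        double s = S(i, j);
        double b = G(i, j) ? d1 : d0;
        T += s; Bi += b;
        ll += -lgamma(s + 1.0) + lgamma(b + s) - lgamma(b);
      }
      ll += lgamma(T + 1.0) + lgamma(Bi) - lgamma(Bi + T);
      rowTot[i] = T; B[i] = Bi; rowLL[i] = ll;
    }
  }

  void rebuildTallies() {
    Mp.assign(K, std::vector<double>(K, 0.0));
    Mm.assign(K, std::vector<double>(K, 0.0));
    for (int i = 0; i < P - 1; ++i) {
      for (int j = i + 1; j < P; ++j) {
        int a = z[i], b = z[j];
        double e = G(i, j) ? 1.0 : 0.0;
        Mp[a][b] += e; Mm[a][b] += 1.0 - e;
        if (a != b) { Mp[b][a] += e; Mm[b][a] += 1.0 - e; }
      }
    }
  }

  // -- log-density pieces ---------------------------------------------------

  double crpLL() const {
    double s = K * std::log(xi) + lgamma(xi) - lgamma(xi + P);
    for (int a = 0; a < K; ++a) s += lgamma(nsize[a]);
    return s;
  }

  double graphPriorLL() const {
    double s = 0.0;
    for (int a = 0; a < K; ++a)
      for (int b = a; b < K; ++b)
        s += R::lbeta(alpha + Mp[a][b], beta + Mm[a][b]) - lbeta0;
    return s;
  }

  double rowLLSum() const {
    double s = 0.0;
    for (int i = 0; i < P; ++i) s += rowLL[i];
    return s;
  }

  double logPost() const { return rowLLSum() + graphPriorLL() + crpLL(); }

  // partition target (CRP prior x collapsed graph prior) for an arbitrary
  // labeling, computed from scratch; used in split-merge accept ratios
  double partitionTarget(const std::vector<int>& zv) const {
    std::vector<int> map(P, -1), lab(P);
    int k = 0;
    for (int i = 0; i < P; ++i) {
      if (map[zv[i]] < 0) map[zv[i]] = k++;
      lab[i] = map[zv[i]];
    }
    std::vector<double> ns(k, 0.0);
    for (int i = 0; i < P; ++i) ns[lab[i]] += 1.0;
    std::vector< std::vector<double> > mp(k, std::vector<double>(k, 0.0));
    std::vector< std::vector<double> > mm(k, std::vector<double>(k, 0.0));
    for (int i = 0; i < P - 1; ++i)
      for (int j = i + 1; j < P; ++j) {
        int a = lab[i], b = lab[j];
        double e = G(i, j) ? 1.0 : 0.0;
        mp[a][b] += e; mm[a][b] += 1.0 - e;
        if (a != b) { mp[b][a] += e; mm[b][a] += 1.0 - e; }
      }
    double s = k * std::log(xi) + lgamma(xi) - lgamma(xi + P);
    for (int a = 0; a < k; ++a) s += lgamma(ns[a]);
    for (int a = 0; a < k; ++a)
      for (int b = a; b < k; ++b)
        s += R::lbeta(alpha + mp[a][b], beta + mm[a][b]) - lbeta0;
    return s;
  }

  // -- Metropolis sweep over edge flips (likelihood x collapsed prior ratio) --

  double rowFlipDelta(int i, int j, double b, double bp) const {
    double db = bp - b, s = S(i, j);
    return lgamma(B[i] + db) - lgamma(B[i] + db + rowTot[i])
         - lgamma(B[i]) + lgamma(B[i] + rowTot[i])
         + lgamma(bp + s) - lgamma(bp) - lgamma(b + s) + lgamma(b);
  }

  int metropolisSweep() {
    int acc = 0;
    for (int i = 0; i < P - 1; ++i) {
      for (int j = i + 1; j < P; ++j) {
        int g = G(i, j);
        double b = g ? d1 : d0, bp = g ? d0 : d1;
        double di = rowFlipDelta(i, j, b, bp);
        double dj = rowFlipDelta(j, i, b, bp);
        int a = z[i], c = z[j];
        double dpr;
        if (g == 0) dpr = std::log(alpha + Mp[a][c]) - std::log(beta + Mm[a][c] - 1.0);
        else        dpr = std::log(beta + Mm[a][c]) - std::log(alpha + Mp[a][c] - 1.0);
        if (std::log(unif_rand()) < di + dj + dpr) {
          int gn = 1 - g;
          G(i, j) = gn; G(j, i) = gn;
          double db = bp - b;
          B[i] += db; B[j] += db;
          rowLL[i] += di; rowLL[j] += dj;
          double e = gn ? 1.0 : -1.0;
          Mp[a][c] += e; Mm[a][c] -= e;
          if (a != c) { Mp[c][a] += e; Mm[c][a] -= e; }
          ++acc;
        }
      }
    }
    return acc;
  }

  // -- partition bookkeeping ------------------------------------------------

  // remove ROI i from its cluster; r[d] receives the edge count from i to
  // cluster d (computed with i absent); deletes emptied clusters
  void removeItem(int i, std::vector<double>& r) {
    int a = z[i];
    r.assign(K, 0.0);
    for (int j = 0; j < P; ++j) {
      if (j == i) continue;
      if (G(i, j)) r[z[j]] += 1.0;
    }
    nsize[a] -= 1.0;
    for (int d = 0; d < K; ++d) {
      double ne = nsize[d] - r[d];
      Mp[a][d] -= r[d]; Mm[a][d] -= ne;
      if (d != a) { Mp[d][a] -= r[d]; Mm[d][a] -= ne; }
    }
    z[i] = -1;
    if (nsize[a] == 0.0) {
      nsize.erase(nsize.begin() + a);
      Mp.erase(Mp.begin() + a);
      Mm.erase(Mm.begin() + a);
      for (int c = 0; c < K - 1; ++c) {
        Mp[c].erase(Mp[c].begin() + a);
        Mm[c].erase(Mm[c].begin() + a);
      }
      for (int j = 0; j < P; ++j) if (z[j] > a) z[j] -= 1;
      r.erase(r.begin() + a);
      K -= 1;
    }
  }

  // log change of the collapsed graph prior when i joins cluster c
  double joinDelta(int c, const std::vector<double>& r) const {
    double s = 0.0;
    for (int d = 0; d < K; ++d) {
      double ne = nsize[d] - r[d];
      s += R::lbeta(alpha + Mp[c][d] + r[d], beta + Mm[c][d] + ne)
         - R::lbeta(alpha + Mp[c][d], beta + Mm[c][d]);
    }
    return s;
  }

  double newClusterDelta(const std::vector<double>& r) const {
    double s = 0.0;
    for (int d = 0; d < K; ++d)
      s += R::lbeta(alpha + r[d], beta + nsize[d] - r[d]) - lbeta0;
    return s;
  }

  // insert ROI i into cluster c (c == K means a new cluster)
  void insertItem(int i, int c, std::vector<double>& r) {
    if (c == K) {
      K += 1;
      nsize.push_back(0.0);
      r.push_back(0.0);
      for (int a = 0; a < K - 1; ++a) {
        Mp[a].push_back(0.0); Mm[a].push_back(0.0);
      }
      Mp.push_back(std::vector<double>(K, 0.0));
      Mm.push_back(std::vector<double>(K, 0.0));
    }
    for (int d = 0; d < K; ++d) {
      double ne = nsize[d] - r[d];
      Mp[c][d] += r[d]; Mm[c][d] += ne;
      if (d != c) { Mp[d][c] += r[d]; Mm[d][c] += ne; }
    }
    nsize[c] += 1.0;
    z[i] = c;
  }

  // -- Gibbs sweep over cluster assignments (CRP x collapsed prior weights) --

  void gibbsSweep() {
    std::vector<double> r, lw;
    for (int i = 0; i < P; ++i) {
      removeItem(i, r);
      lw.assign(K + 1, 0.0);
      for (int c = 0; c < K; ++c)
        lw[c] = std::log(nsize[c]) + joinDelta(c, r);
      lw[K] = std::log(xi) + newClusterDelta(r);
      int c = sampleLog(lw);
      insertItem(i, c, r);
    }
  }

  int sampleLog(const std::vector<double>& lw) const {
    double mx = lw[0];
    for (size_t k = 1; k < lw.size(); ++k) if (lw[k] > mx) mx = lw[k];
    double tot = 0.0;
    std::vector<double> w(lw.size());
    for (size_t k = 0; k < lw.size(); ++k) { w[k] = std::exp(lw[k] - mx); tot += w[k]; }
    double u = unif_rand() * tot, cum = 0.0;
    for (size_t k = 0; k < lw.size(); ++k) {
      cum += w[k];
      if (u <= cum) return (int)k;
    }
    return (int)lw.size() - 1;
  }

  // -- Jain-Neal split-merge ------------------------------------------------

  // one restricted Gibbs step for item l between clusters A and Bc;
  // force >= 0 pins the choice; logq accumulates the transition log-density
  void restrictedStep(int l, int A, int Bc, int force, double* logq) {
    std::vector<double> r;
    removeItem(l, r);
    double lwA = std::log(nsize[A]) + joinDelta(A, r);
    double lwB = std::log(nsize[Bc]) + joinDelta(Bc, r);
    double mx = std::max(lwA, lwB);
    double pA = std::exp(lwA - mx) / (std::exp(lwA - mx) + std::exp(lwB - mx));
    int choice;
    if (force >= 0) choice = force;
    else choice = (unif_rand() < pA) ? A : Bc;
    if (logq) *logq += std::log(choice == A ? pA : 1.0 - pA);
    insertItem(l, choice, r);
  }

  int splitMerge(int nscans) {
    if (P < 2) return 0;
    int i = (int)std::floor(unif_rand() * P); if (i >= P) i = P - 1;
    int j = i;
    while (j == i) { j = (int)std::floor(unif_rand() * P); if (j >= P) j = P - 1; }
    std::vector<int> zsave = z;
    std::vector<double> r;

    if (z[i] == z[j]) {
      // ---- split proposal
      double logT_cur = partitionTarget(z);
      removeItem(i, r);
      insertItem(i, K, r);            // i seeds a new cluster
      int A = z[i], Bc = z[j];
      std::vector<int> comp;
      for (int l = 0; l < P; ++l)
        if (l != i && l != j && zsave[l] == zsave[i]) comp.push_back(l);
      for (size_t t = 0; t < comp.size(); ++t) {
        int l = comp[t];
        removeItem(l, r);
        int c = (unif_rand() < 0.5) ? A : Bc;
        insertItem(l, c, r);
      }
      for (int sc = 0; sc < nscans; ++sc)
        for (size_t t = 0; t < comp.size(); ++t)
          restrictedStep(comp[t], A, Bc, -1, NULL);
      double logq = 0.0;
      for (size_t t = 0; t < comp.size(); ++t)
        restrictedStep(comp[t], A, Bc, -1, &logq);
      double logT_prop = partitionTarget(z);
      if (std::log(unif_rand()) < logT_prop - logT_cur - logq) {
        relabel(); rebuildTallies();
        return 1;
      }
      z = zsave; relabel(); rebuildTallies();
      return 0;
    } else {
      // ---- merge proposal
      double logT_split = partitionTarget(z);
      std::vector<int> zmerge = z;
      int la = z[i], lb = z[j];
      for (int l = 0; l < P; ++l) if (zmerge[l] == la) zmerge[l] = lb;
      double logT_merge = partitionTarget(zmerge);
      // reverse-move density: launch + restricted scans back to the current split
      int A = z[i], Bc = z[j];
      std::vector<int> comp; std::vector<int> ztrue;
      for (int l = 0; l < P; ++l)
        if (l != i && l != j && (z[l] == A || z[l] == Bc)) {
          comp.push_back(l); ztrue.push_back(z[l]);
        }
      for (size_t t = 0; t < comp.size(); ++t) {
        int l = comp[t];
        removeItem(l, r);
        int c = (unif_rand() < 0.5) ? A : Bc;
        insertItem(l, c, r);
      }
      for (int sc = 0; sc < nscans; ++sc)
        for (size_t t = 0; t < comp.size(); ++t)
          restrictedStep(comp[t], A, Bc, -1, NULL);
      double logq = 0.0;
      for (size_t t = 0; t < comp.size(); ++t)
        restrictedStep(comp[t], A, Bc, ztrue[t], &logq);
      // state is back to the original split configuration
      if (std::log(unif_rand()) < logT_merge - logT_split + logq) {
        z = zmerge; relabel(); rebuildTallies();
        return 1;
      }
      z = zsave; relabel(); rebuildTallies();
      return 0;
    }
  }

  IntegerVector labels1() const {
    IntegerVector out(P);
    for (int i = 0; i < P; ++i) out[i] = z[i] + 1;
    return out;
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_irm_mcmc(NumericMatrix S, IntegerMatrix G0, IntegerVector z0,
                  double xi, double alpha, double beta, double d0, double d1,
                  int n_iter, int burnin, int sm_scans, int g_keep) {
  IRMSampler sam(S, G0, z0, xi, alpha, beta, d0, d1);
  int P = sam.P;
  int n_ret = n_iter - burnin;
  NumericVector trace(n_iter);
  IntegerVector kTrace(n_iter);
  NumericMatrix Mmean(P, P), Gmean(P, P);
  IntegerMatrix labels(n_ret, P);
  List gsamples;
  int g_stride = (g_keep > 0 && n_ret > g_keep) ? n_ret / g_keep : 1;
  int nacc_sm = 0;
  for (int it = 0; it < n_iter; ++it) {
    sam.metropolisSweep();
    sam.gibbsSweep();
    nacc_sm += sam.splitMerge(sm_scans);
    trace[it] = sam.logPost();
    kTrace[it] = sam.K;
    if (it >= burnin) {
      int rr = it - burnin;
      for (int i = 0; i < P; ++i) {
        labels(rr, i) = sam.z[i] + 1;
        Mmean(i, i) += 1.0;
        for (int jj = i + 1; jj < P; ++jj) {
          if (sam.z[i] == sam.z[jj]) { Mmean(i, jj) += 1.0; Mmean(jj, i) += 1.0; }
          if (sam.G(i, jj)) { Gmean(i, jj) += 1.0; Gmean(jj, i) += 1.0; }
        }
      }
      if (g_keep > 0 && rr % g_stride == 0)
        gsamples.push_back(clone(sam.G));
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_ret > 0)
    for (int i = 0; i < P; ++i)
      for (int jj = 0; jj < P; ++jj) {
        Mmean(i, jj) /= n_ret; Gmean(i, jj) /= n_ret;
      }
  return List::create(_["labels"] = labels, _["M_mean"] = Mmean,
                      _["G_mean"] = Gmean, _["log_post"] = trace,
                      _["K_trace"] = kTrace, _["G_samples"] = gsamples,
                      _["sm_accepts"] = nacc_sm);
}

// [[Rcpp::export]]
List cpp_graph_sweep(NumericMatrix S, IntegerMatrix G, IntegerVector z,
                     double xi, double alpha, double beta, double d0, double d1) {
  IRMSampler sam(S, G, z, xi, alpha, beta, d0, d1);
  int acc = sam.metropolisSweep();
  return List::create(_["G"] = sam.G, _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_gibbs_sweep(NumericMatrix S, IntegerMatrix G, IntegerVector z,
                     double xi, double alpha, double beta, double d0, double d1) {
  IRMSampler sam(S, G, z, xi, alpha, beta, d0, d1);
  sam.gibbsSweep();
  sam.relabel();
  return List::create(_["labels"] = sam.labels1());
}

// [[Rcpp::export]]
List cpp_split_merge(NumericMatrix S, IntegerMatrix G, IntegerVector z,
                     double xi, double alpha, double beta, double d0, double d1,
                     int nscans) {
  IRMSampler sam(S, G, z, xi, alpha, beta, d0, d1);
  int acc = sam.splitMerge(nscans);
  return List::create(_["labels"] = sam.labels1(), _["accepted"] = acc);
}

// [[Rcpp::export]]
List cpp_log_posterior(NumericMatrix S, IntegerMatrix G, IntegerVector z,
                       double xi, double alpha, double beta, double d0, double d1) {
  IRMSampler sam(S, G, z, xi, alpha, beta, d0, d1);
  return List::create(_["row_loglik"] = sam.rowLLSum(),
                      _["graph_log_prior"] = sam.graphPriorLL(),
                      _["crp_log_prior"] = sam.crpLL(),
                      _["log_post"] = sam.logPost());
}

// [[Rcpp::export]]
List cpp_tallies(IntegerMatrix G, IntegerVector z) {
  int P = G.nrow();
  NumericMatrix S(P, P);
  IRMSampler sam(S, G, z, 1.0, 1.0, 1.0, 0.1, 1.0);
  NumericMatrix mp(sam.K, sam.K), mm(sam.K, sam.K);
  for (int a = 0; a < sam.K; ++a)
    for (int b = 0; b < sam.K; ++b) { mp(a, b) = sam.Mp[a][b]; mm(a, b) = sam.Mm[a][b]; }
  return List::create(_["M_plus"] = mp, _["M_minus"] = mm,
                      _["labels"] = sam.labels1());
}

// runs a random mix of updates, then reports the worst discrepancy between the
// incrementally maintained caches and a from-scratch recomputation
// [[Rcpp::export]]
double cpp_consistency_check(NumericMatrix S, IntegerMatrix G0, IntegerVector z0,
                             double xi, double alpha, double beta,
                             double d0, double d1, int nsweeps, int mode = 0) {
  IRMSampler sam(S, G0, z0, xi, alpha, beta, d0, d1);
  for (int t = 0; t < nsweeps; ++t) {
    double u = unif_rand();
    if (mode == 1) { sam.metropolisSweep(); continue; }
    if (mode == 2) { sam.gibbsSweep(); continue; }
    if (mode == 3) { sam.splitMerge(3); continue; }
    if (u < 0.4) sam.metropolisSweep();
    else if (u < 0.8) sam.gibbsSweep();
    else sam.splitMerge(3);
  }
  double worst = 0.0;
  // the reference sampler relabels clusters by first appearance; map the
  // live sampler's labels onto that canonical order before comparing
  IRMSampler ref(sam.S, sam.G, sam.labels1(), xi, alpha, beta, d0, d1);
  for (int i = 0; i < sam.P; ++i) {
    worst = std::max(worst, std::fabs(sam.B[i] - ref.B[i]));
    worst = std::max(worst, std::fabs(sam.rowLL[i] - ref.rowLL[i]));
  }
  if (sam.K != ref.K) return 1e9;
  std::vector<int> perm(sam.K, -1);
  for (int i = 0; i < sam.P; ++i) perm[sam.z[i]] = ref.z[i];
  for (int a = 0; a < sam.K; ++a)
    for (int b = 0; b < sam.K; ++b) {
      worst = std::max(worst, std::fabs(sam.Mp[a][b] - ref.Mp[perm[a]][perm[b]]));
      worst = std::max(worst, std::fabs(sam.Mm[a][b] - ref.Mm[perm[a]][perm[b]]));
    }
  return worst;
}
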