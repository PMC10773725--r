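// HKY+Gamma pruning engine.
//
// Likelihoods are computed by Felsenstein pruning over site patterns, with
// equal-weight discrete gamma rate categories. Edge lengths are optimised
// by cyclic per-edge Newton steps on the log-likelihood, using outside
// ("up") and subtree ("down") partials so each 1-d optimisation touches a
// single transition matrix. Trees here are small (<= ~24 taxa in the import
// path, <= 8 in simulation studies) so no per-node scaling is required:
// per-pattern likelihoods stay far above the double underflow threshold.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  double U[4][4], V[4][4], lam[4], pi[4];
  std::vector<double> rates;  // gamma category rates, mean 1
  int K;
};

Model unpack_model(const List& model) {
  Model M;
  NumericMatrix U = model["U"], V = model["Uinv"];
  NumericVector lam = model["lambda"], pi = model["pi"], r = model["rates"];
  for (int i = 0; i < 4; ++i) {
    M.lam[i] = lam[i];
    M.pi[i] = pi[i];
    for (int j = 0; j < 4; ++j) { M.U[i][j] = U(i, j); M.V[i][j] = V(i, j); }
  }
  M.rates.assign(r.begin(), r.end());
  M.K = (int)M.rates.size();
  return M;
}

// P(t) for one rate category into p[16] (row-major i -> j)
inline void pmat(const Model& M, double t, double rate, double* p) {
  double e[4];
  for (int s = 0; s < 4; ++s) e[s] = std::exp(M.lam[s] * t * rate);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double x = 0.0;
      for (int s = 0; s < 4; ++s) x += M.U[i][s] * e[s] * M.V[s][j];
      p[4 * i + j] = x > 0.0 ? x : 0.0;  // clip tiny negative round-off
    }
}

struct Tree {
  int nnode, ntip, root;
  std::vector<std::vector<int>> children;   // node -> child nodes
  std::vector<int> parent_edge;             // node -> incoming edge row (-1 root)
  std::vector<double> len;                  // per edge row
  IntegerMatrix edge;                       // (parent, child), 1-based from R
};

class Fitter {
public:
  Fitter(const Model& M, const IntegerMatrix& tips, const NumericVector& w)
    : M_(M), tips_(tips), w_(w), npat_(tips.ncol()), ntip_(tips.nrow()) {}

  // returns loglik; fills pattern logliks and (if optimise) new lengths
  double run(Tree& T, NumericVector& patll, bool optimise, int max_cycles,
             double tol, int& cycles_used) {
    T_ = &T;
    int stride = npat_ * M_.K * 4;
    down_.assign((size_t)T.nnode * stride, 0.0);
    out_.assign((size_t)T.nnode * stride, 0.0);
    P_.assign((size_t)T.len.size() * M_.K * 16, 0.0);
    scratch_.assign(stride, 0.0);
    hbuf_.assign(stride, 0.0);
    g_.assign((size_t)npat_ * M_.K * 4, 0.0);

    for (size_t e = 0; e < T.len.size(); ++e) update_P((int)e);
    for (int tip = 0; tip < ntip_; ++tip) fill_tip(tip);
    full_down(T.root);
    double ll = root_loglik(patll);
    cycles_used = 0;
    if (!optimise) return ll;

    for (int cyc = 0; cyc < max_cycles; ++cyc) {
      // O at root = pi
      double* Or = &out_[(size_t)T.root * stride];
      for (int p = 0; p < npat_; ++p)
        for (int k = 0; k < M_.K; ++k)
          for (int i = 0; i < 4; ++i) Or[(p * M_.K + k) * 4 + i] = M_.pi[i];
      visit(T.root);
      refresh_down(T.root);
      double ll_new = root_loglik(patll);
      cycles_used = cyc + 1;
      if (std::fabs(ll_new - ll) < tol) { ll = ll_new; break; }
      ll = ll_new;
    }
    return ll;
  }

private:
  const Model& M_;
  const IntegerMatrix& tips_;
  const NumericVector& w_;
  int npat_, ntip_;
  Tree* T_;
  std::vector<double> down_, out_, P_, scratch_, hbuf_, g_;

  inline double* node_arr(std::vector<double>& a, int node) {
    return &a[(size_t)node * npat_ * M_.K * 4];
  }
  inline double* Pcat(int e, int k) { return &P_[((size_t)e * M_.K + k) * 16]; }

  void update_P(int e) {
    for (int k = 0; k < M_.K; ++k) pmat(M_, T_->len[e], M_.rates[k], Pcat(e, k));
  }

  void fill_tip(int tip) {
    double* d = node_arr(down_, tip);
    for (int p = 0; p < npat_; ++p) {
      int s = tips_(tip, p);
      for (int k = 0; k < M_.K; ++k) {
        double* row = d + (p * M_.K + k) * 4;
        row[0] = row[1] = row[2] = row[3] = 0.0;
        row[s] = 1.0;
      }
    }
  }

  // h = fold of child c through its edge: h[i] = sum_j P[i][j] down_c[j]
  void fold_child(int c, double* h) {
    int e = T_->parent_edge[c];
    const double* d = node_arr(down_, c);
    for (int p = 0; p < npat_; ++p)
      for (int k = 0; k < M_.K; ++k) {
        const double* Pm = Pcat(e, k);
        const double* dr = d + (p * M_.K + k) * 4;
        double* hr = h + (p * M_.K + k) * 4;
        for (int i = 0; i < 4; ++i)
          hr[i] = Pm[4 * i + 0] * dr[0] + Pm[4 * i + 1] * dr[1] +
                  Pm[4 * i + 2] * dr[2] + Pm[4 * i + 3] * dr[3];
      }
  }

  // down[v] = prod over children of fold(child)
  void refresh_down(int v) {
    double* d = node_arr(down_, v);
    int n = npat_ * M_.K * 4;
    bool first = true;
    for (int c : T_->children[v]) {
      fold_child(c, hbuf_.data());
      if (first) std::copy(hbuf_.begin(), hbuf_.begin() + n, d);
      else for (int i = 0; i < n; ++i) d[i] *= hbuf_[i];
      first = false;
    }
  }

  void full_down(int v) {
    for (int c : T_->children[v])
      if (!T_->children[c].empty()) full_down(c);
    if (!T_->children[v].empty()) refresh_down(v);
  }

  double root_loglik(NumericVector& patll) {
    const double* d = node_arr(down_, T_->root);
    double ll = 0.0;
    for (int p = 0; p < npat_; ++p) {
      double L = 0.0;
      for (int k = 0; k < M_.K; ++k) {
        const double* dr = d + (p * M_.K + k) * 4;
        L += M_.pi[0] * dr[0] + M_.pi[1] * dr[1] + M_.pi[2] * dr[2] + M_.pi[3] * dr[3];
      }
      L /= M_.K;
      double l = L > 0.0 ? std::log(L) : -1e10;  // -inf guard for impossible patterns
      patll[p] = l;
      ll += w_[p] * l;
    }
    return ll;
  }

  // Newton optimisation of edge into child c; 'outc' = outside partial at
  // the parent end of the edge (pi-weighted), down[c] valid.
  void optimise_edge(int c, const double* outc) {
    int e = T_->parent_edge[c];
    const double* d = node_arr(down_, c);
    // g[pat,k,s] = (sum_i outc_i U[i][s]) * (sum_j V[s][j] down_j)
    for (int p = 0; p < npat_; ++p)
      for (int k = 0; k < M_.K; ++k) {
        const double* o = outc + (p * M_.K + k) * 4;
        const double* dr = d + (p * M_.K + k) * 4;
        double* gr = &g_[(size_t)(p * M_.K + k) * 4];
        for (int s = 0; s < 4; ++s) {
          double a = o[0] * M_.U[0][s] + o[1] * M_.U[1][s] +
                     o[2] * M_.U[2][s] + o[3] * M_.U[3][s];
          double b = M_.V[s][0] * dr[0] + M_.V[s][1] * dr[1] +
                     M_.V[s][2] * dr[2] + M_.V[s][3] * dr[3];
          gr[s] = a * b;
        }
      }
    double t = T_->len[e];
    const double tmax = 10.0;
    for (int iter = 0; iter < 8; ++iter) {
      double E[32], dE[32], ddE[32];  // K*4 <= 8*4
      for (int k = 0; k < M_.K; ++k)
        for (int s = 0; s < 4; ++s) {
          double lr = M_.lam[s] * M_.rates[k];
          double ex = std::exp(lr * t);
          E[4 * k + s] = ex; dE[4 * k + s] = lr * ex; ddE[4 * k + s] = lr * lr * ex;
        }
      double d1 = 0.0, d2 = 0.0;
      for (int p = 0; p < npat_; ++p) {
        double f = 0.0, fp = 0.0, fpp = 0.0;
        const double* gr = &g_[(size_t)p * M_.K * 4];
        for (int q = 0; q < M_.K * 4; ++q) {
          f += gr[q] * E[q]; fp += gr[q] * dE[q]; fpp += gr[q] * ddE[q];
        }
        if (f < 1e-300) f = 1e-300;
        double r1 = fp / f;
        d1 += w_[p] * r1;
        d2 += w_[p] * (fpp / f - r1 * r1);
      }
      if (t <= 0.0 && d1 <= 0.0) break;          // boundary optimum at 0
      if (t >= tmax && d1 >= 0.0) break;
      if (std::fabs(d1) < 1e-4) break;           // curvature is O(n): loglik
      double step = (d2 < 0.0) ? -d1 / d2 : (d1 > 0.0 ? 0.5 : -0.5);
      if (step > 1.0) step = 1.0;                // error already < ~1e-8
      if (step < -1.0) step = -1.0;
      double tn = t + step;
      if (tn < 0.0) tn = 0.0;
      if (tn > tmax) tn = tmax;
      if (std::fabs(tn - t) < 1e-7) { t = tn; break; }
      t = tn;
    }
    T_->len[e] = t;
    update_P(e);
  }

  // preorder sweep optimising each edge with exact current partials
  void visit(int p) {
    int stride = npat_ * M_.K * 4;
    const double* Op = node_arr(out_, p);
    size_t nch = T_->children[p].size();
    // folds of every child of p, refreshed as edges/subtrees change
    std::vector<double> folds((size_t)nch * stride);
    for (size_t si = 0; si < nch; ++si)
      fold_child(T_->children[p][si], &folds[si * stride]);
    for (size_t ci = 0; ci < nch; ++ci) {
      int c = T_->children[p][ci];
      // outc = O_p * prod over siblings of fold(sibling)
      std::copy(Op, Op + stride, scratch_.begin());
      for (size_t si = 0; si < nch; ++si) {
        if (si == ci) continue;
        const double* h = &folds[si * stride];
        for (int i = 0; i < stride; ++i) scratch_[i] *= h[i];
      }
      optimise_edge(c, scratch_.data());
      if (!T_->children[c].empty()) {
        // O_c[i] = sum_j outc[j] P_c[j][i]
        int e = T_->parent_edge[c];
        double* Oc = node_arr(out_, c);
        for (int pp = 0; pp < npat_; ++pp)
          for (int k = 0; k < M_.K; ++k) {
            const double* Pm = Pcat(e, k);
            const double* sr = &scratch_[(size_t)(pp * M_.K + k) * 4];
            double* orow = Oc + (pp * M_.K + k) * 4;
            for (int i = 0; i < 4; ++i)
              orow[i] = sr[0] * Pm[4 * 0 + i] + sr[1] * Pm[4 * 1 + i] +
                        sr[2] * Pm[4 * 2 + i] + sr[3] * Pm[4 * 3 + i];
          }
        visit(c);
        refresh_down(c);
      }
      // edge length (and possibly the subtree) changed: refresh this
      // child's fold so later siblings see current values
      if (ci + 1 < nch) fold_child(c, &folds[ci * stride]);
    }
  }
};

Tree unpack_tree(const List& tr, int ntip) {
  Tree T;
  T.edge = as<IntegerMatrix>(tr["edge"]);
  NumericVector len = tr["length"];
  T.len.assign(len.begin(), len.end());
  int nnode = 0;
  for (int e = 0; e < T.edge.nrow(); ++e) {
    nnode = std::max(nnode, std::max(T.edge(e, 0), T.edge(e, 1)));
  }
  T.nnode = nnode;
  T.ntip = ntip;
  T.children.assign(nnode, {});
  T.parent_edge.assign(nnode, -1);
  std::vector<bool> is_child(nnode, false);
  for (int e = 0; e < T.edge.nrow(); ++e) {
    int p = T.edge(e, 0) - 1, c = T.edge(e, 1) - 1;
    T.children[p].push_back(c);
    T.parent_edge[c] = e;
    is_child[c] = true;
  }
  T.root = -1;
  for (int v = ntip; v < nnode; ++v) if (!is_child[v]) T.root = v;
  if (T.root < 0) stop("tree has no internal root node");
  return T;
}

}  // namespace

// [[Rcpp::export]]
List fit_trees_cpp(List trees, IntegerMatrix tipstates, NumericVector weights,
                   List model, bool optimise, int max_cycles, double tol) {
  Model M = unpack_model(model);
  Fitter F(M, tipstates, weights);
  int ntree = trees.size(), npat = tipstates.ncol();
  NumericMatrix patll(ntree, npat);
  NumericVector loglik(ntree);
  IntegerVector cycles(ntree);
  List lens(ntree);
  for (int i = 0; i < ntree; ++i) {
    Tree T = unpack_tree(trees[i], tipstates.nrow());
    NumericVector pl(npat);
    int cyc = 0;
    loglik[i] = F.run(T, pl, optimise, max_cycles, tol, cyc);
    patll(i, _) = pl;
    cycles[i] = cyc;
    lens[i] = NumericVector(T.len.begin(), T.len.end());
  }
  return List::create(_["loglik"] = loglik, _["pattern_loglik"] = patll,
                      _["lengths"] = lens, _["cycles"] = cycles);
}

// Multinomial RELL weights: B columns of pattern counts, each distributing
// round(r*n) draws over patterns with probability prob (pattern weight / n).
// The bulk draws use a xoshiro256+ stream whose state is seeded from R's
// RNG, so results remain reproducible under set.seed() without paying R's
// per-call RNG overhead for the ~1e7 draws a study replicate needs.
namespace {
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(double u1, double u2, double u3, double u4) {
    // splitmix64 over four R uniforms to fill the state
    uint64_t seed = (uint64_t)(u1 * 9007199254740992.0) ^
                    ((uint64_t)(u2 * 9007199254740992.0) << 11) ^
                    ((uint64_t)(u3 * 9007199254740992.0) << 23) ^
                    ((uint64_t)(u4 * 9007199254740992.0) << 37);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline double next() {  // uniform in [0, 1)
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return (result >> 11) * 0x1.0p-53;
  }
};
}  // namespace

// pattern_index: site -> pattern (1-based, length n). Drawing a site
// uniformly and binning by its pattern is exactly the multinomial over
// patterns with probabilities weight/n.
// [[Rcpp::export]]
NumericMatrix rell_weights_cpp(IntegerVector pattern_index, int npat,
                               int ndraw, int B) {
  int n = pattern_index.size();
  NumericMatrix W(npat, B);
  RNGScope scope;
  Xoshiro rng(unif_rand(), unif_rand(), unif_rand(), unif_rand());
  for (int b = 0; b < B; ++b) {
    double* col = &W(0, b);
    for (int k = 0; k < ndraw; ++k) {
      int site = (int)(rng.next() * n);
      if (site >= n) site = n - 1;
      col[pattern_index[site] - 1] += 1.0;
    }
  }
  return W;
}

// Per-column argmax with equal tie-splitting: returns per-row counts of
// (possibly fractional) wins over the B columns.
// [[Rcpp::export]]
NumericVector col_argmax_share_cpp(NumericMatrix S) {
  int nr = S.nrow(), nc = S.ncol();
  NumericVector wins(nr);
  for (int b = 0; b < nc; ++b) {
    double mx = S(0, b);
    for (int i = 1; i < nr; ++i) if (S(i, b) > mx) mx = S(i, b);
    int nt = 0;
    for (int i = 0; i < nr; ++i) if (S(i, b) == mx) ++nt;
    double share = 1.0 / nt;
    for (int i = 0; i < nr; ++i) if (S(i, b) == mx) wins[i] += share;
  }
  return wins;
}

// [[Rcpp::export]]
NumericVector col_max_cpp(NumericMatrix S) {
  int nr = S.nrow(), nc = S.ncol();
  NumericVector out(nc);
  for (int b = 0; b < nc; ++b) {
    double mx = S(0, b);
    for (int i = 1; i < nr; ++i) if (S(i, b) > mx) mx = S(i, b);
    out[b] = mx;
  }
  return out;
}
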