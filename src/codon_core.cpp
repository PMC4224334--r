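// Codon-model likelihood core: Felsenstein pruning over sense-codon states,
// transition probabilities from the cached spectral decomposition of the
// reversible generator, and branch-length optimization by per-edge line
// searches on cached directional partials (eigen-space trick: along one edge
// the per-pattern likelihood is sum_k exp(lambda_k t) z_k, so a line search
// costs O(61 * npat) per evaluation).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat prob_matrix(const arma::mat& A, const arma::mat& Ainv,
                             const arma::vec& lambda, double t) {
  arma::mat P = A * arma::diagmat(arma::exp(lambda * t)) * Ainv;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

struct EigenSet {
  std::vector<arma::mat> A, Ainv;
  std::vector<arma::vec> lambda;
};

static EigenSet unpack_eigens(const List& eigens) {
  EigenSet es;
  for (int k = 0; k < eigens.size(); ++k) {
    List e = eigens[k];
    es.A.push_back(as<arma::mat>(e["A"]));
    es.Ainv.push_back(as<arma::mat>(e["Ainv"]));
    es.lambda.push_back(as<arma::vec>(e["lambda"]));
  }
  return es;
}

// tipstate: ntip x npat, 1-based sense-codon index, 0 = missing (gap/ambiguous)
static void down_partials(const IntegerMatrix& tipstate,
                          const arma::imat& edge,  // nedge x 2, 0-based, postorder
                          const arma::vec& lengths,
                          const arma::ivec& eclass, // 0-based eigen index per edge
                          const EigenSet& es, int nstate, int nnode,
                          std::vector<arma::mat>& D,
                          std::vector<arma::rowvec>& dlog,
                          std::vector<arma::mat>* DP = nullptr) {
  const int ntip = tipstate.nrow(), npat = tipstate.ncol();
  D.assign(nnode, arma::mat());
  dlog.assign(nnode, arma::rowvec());
  if (DP) DP->assign(edge.n_rows, arma::mat());
  for (int v = 0; v < ntip; ++v) {
    D[v].zeros(nstate, npat);
    for (int p = 0; p < npat; ++p) {
      int s = tipstate(v, p);
      if (s > 0) D[v](s - 1, p) = 1.0; else D[v].col(p).ones();
    }
    dlog[v].zeros(npat);
  }
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    int k = eclass(e);
    arma::mat P = prob_matrix(es.A[k], es.Ainv[k], es.lambda[k], lengths(e));
    arma::mat contrib;
    if (ch < ntip) {
      // tip child: indicator partials, so P * D is a column gather
      contrib.set_size(nstate, npat);
      arma::vec rs = arma::sum(P, 1);  // row sums, for missing states
      for (int p = 0; p < npat; ++p) {
        int s = tipstate(ch, p);
        if (s > 0) contrib.col(p) = P.col(s - 1); else contrib.col(p) = rs;
      }
    } else {
      contrib = P * D[ch];
    }
    if (DP) (*DP)[e] = contrib;
    if (D[par].n_elem == 0) {
      D[par] = contrib;
      dlog[par] = dlog[ch];
    } else {
      D[par] %= contrib;
      dlog[par] += dlog[ch];
    }
    // rescale columns
    arma::rowvec m = arma::max(D[par], 0);
    for (int p = 0; p < npat; ++p) {
      if (m(p) > 0 && m(p) < 1e-120) { D[par].col(p) /= m(p); dlog[par](p) += std::log(m(p)); }
    }
  }
}

// [[Rcpp::export]]
List cpp_loglik(IntegerMatrix tipstate, IntegerMatrix edge_r, int nnode,
                int root_r, NumericVector lengths_r, IntegerVector eclass_r,
                List eigens, NumericVector pi_r, NumericVector weights,
                bool site_loglik = false) {
  const int npat = tipstate.ncol();
  const int nstate = pi_r.size();
  arma::imat edge(edge_r.nrow(), 2);
  for (int e = 0; e < edge_r.nrow(); ++e) {
    edge(e, 0) = edge_r(e, 0) - 1;
    edge(e, 1) = edge_r(e, 1) - 1;
  }
  arma::vec lengths = as<arma::vec>(lengths_r);
  arma::ivec eclass = as<arma::ivec>(eclass_r) - 1;
  arma::vec pi = as<arma::vec>(pi_r);
  EigenSet es = unpack_eigens(eigens);
  std::vector<arma::mat> D;
  std::vector<arma::rowvec> dlog;
  down_partials(tipstate, edge, lengths, eclass, es, nstate, nnode, D, dlog);
  int root = root_r - 1;
  arma::rowvec site(npat);
  for (int p = 0; p < npat; ++p) {
    double L = arma::dot(pi, D[root].col(p));
    site(p) = std::log(std::max(L, 1e-300)) + dlog[root](p);
  }
  double lnL = 0.0;
  for (int p = 0; p < npat; ++p) lnL += weights[p] * site(p);
  List out = List::create(_["loglik"] = lnL);
  if (site_loglik) out["site_loglik"] = NumericVector(site.begin(), site.end());
  return out;
}

struct GoldenResult { double t; double f; };

// maximize f over log t in [lo, hi]; zt: nstate x npat (eigen-space products),
// lambda: eigen values; f(t) = sum_p w_p log(max(eps, sum_k exp(lambda_k t) zt(k,p)))
static double edge_obj(const arma::mat& Z, const arma::vec& lambda,
                       const arma::vec& w, double t) {
  arma::vec e = arma::exp(lambda * t);
  arma::rowvec val = e.t() * Z;
  double f = 0.0;
  for (arma::uword p = 0; p < val.n_elem; ++p)
    f += w(p) * std::log(std::max(val(p), 1e-300));
  return f;
}

static GoldenResult golden_max(const arma::mat& Z, const arma::vec& lambda,
                               const arma::vec& w, double tmin, double tmax,
                               int maxit) {
  const double gr = 0.61803398874989485;
  double lo = std::log(tmin), hi = std::log(tmax);
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = edge_obj(Z, lambda, w, std::exp(x1));
  double f2 = edge_obj(Z, lambda, w, std::exp(x2));
  for (int it = 0; it < maxit; ++it) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = edge_obj(Z, lambda, w, std::exp(x2));
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = edge_obj(Z, lambda, w, std::exp(x1));
    }
  }
  double xm = (f1 > f2) ? x1 : x2;
  double fm = std::max(f1, f2);
  // also probe the lower boundary (effectively-zero branch)
  double f0 = edge_obj(Z, lambda, w, tmin);
  if (f0 >= fm) return {tmin, f0};
  return {std::exp(xm), fm};
}

// [[Rcpp::export]]
List cpp_optimize_bl(IntegerMatrix tipstate, IntegerMatrix edge_r, int nnode,
                     int root_r, NumericVector lengths_r, IntegerVector eclass_r,
                     List eigens, NumericVector pi_r, NumericVector weights,
                     int nsweeps = 3, double tol = 1e-6, double tmin = 1e-9,
                     double tmax = 50.0, int line_iter = 30) {
  const int ntip = tipstate.nrow(), npat = tipstate.ncol();
  const int nstate = pi_r.size();
  const int nedge = edge_r.nrow();
  arma::imat edge(nedge, 2);
  for (int e = 0; e < nedge; ++e) {
    edge(e, 0) = edge_r(e, 0) - 1;
    edge(e, 1) = edge_r(e, 1) - 1;
  }
  arma::vec lengths = as<arma::vec>(lengths_r);
  arma::ivec eclass = as<arma::ivec>(eclass_r) - 1;
  arma::vec pi = as<arma::vec>(pi_r);
  arma::vec w = as<arma::vec>(weights);
  EigenSet es = unpack_eigens(eigens);
  int root = root_r - 1;

  // children edge lists
  std::vector<std::vector<int>> child_edges(nnode);
  for (int e = 0; e < nedge; ++e) child_edges[edge(e, 0)].push_back(e);

  auto full_loglik = [&](void) {
    std::vector<arma::mat> D;
    std::vector<arma::rowvec> dlog;
    down_partials(tipstate, edge, lengths, eclass, es, nstate, nnode, D, dlog);
    double lnL = 0.0;
    for (int p = 0; p < npat; ++p) {
      double L = arma::dot(pi, D[root].col(p));
      lnL += w(p) * (std::log(std::max(L, 1e-300)) + dlog[root](p));
    }
    return lnL;
  };

  double prev = full_loglik();
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    std::vector<arma::mat> D;
    std::vector<arma::rowvec> dlog;
    down_partials(tipstate, edge, lengths, eclass, es, nstate, nnode, D, dlog);
    // preorder over nodes with an explicit stack; O = outside partials
    std::vector<arma::mat> O(nnode);
    std::vector<arma::rowvec> olog(nnode, arma::rowvec());
    O[root] = arma::repmat(pi, 1, npat);
    olog[root] = arma::rowvec(npat, arma::fill::zeros);
    std::vector<int> stack{root};
    while (!stack.empty()) {
      int pnode = stack.back(); stack.pop_back();
      const std::vector<int>& ce = child_edges[pnode];
      if (ce.empty()) continue;
      // fresh child contributions under current lengths
      auto child_contrib = [&](const arma::mat& P, int ch) {
        if (ch >= ntip) return arma::mat(P * D[ch]);
        arma::mat contrib(nstate, npat);
        arma::vec rs = arma::sum(P, 1);
        for (int p = 0; p < npat; ++p) {
          int s = tipstate(ch, p);
          if (s > 0) contrib.col(p) = P.col(s - 1); else contrib.col(p) = rs;
        }
        return contrib;
      };
      std::vector<arma::mat> DP(ce.size());
      for (size_t a = 0; a < ce.size(); ++a) {
        int e = ce[a], k = eclass(e);
        arma::mat P = prob_matrix(es.A[k], es.Ainv[k], es.lambda[k], lengths(e));
        DP[a] = child_contrib(P, edge(e, 1));
      }
      for (size_t a = 0; a < ce.size(); ++a) {
        int e = ce[a], ch = edge(e, 1), k = eclass(e);
        arma::mat Oraw = O[pnode];
        arma::rowvec olraw = olog[pnode];
        for (size_t b = 0; b < ce.size(); ++b) {
          if (b == a) continue;
          Oraw %= DP[b];
          olraw += dlog[edge(ce[b], 1)];
        }
        // rescale
        arma::rowvec m = arma::max(Oraw, 0);
        for (int p = 0; p < npat; ++p) {
          if (m(p) > 0 && m(p) < 1e-120) { Oraw.col(p) /= m(p); olraw(p) += std::log(m(p)); }
        }
        // eigen-space reduction: val_p(t) = sum_k exp(l_k t) (A' Oraw)_{kp} (Ainv D_ch)_{kp}
        arma::mat AiD;
        if (ch < ntip) {
          AiD.set_size(nstate, npat);
          arma::vec rs = arma::sum(es.Ainv[k], 1);
          for (int p = 0; p < npat; ++p) {
            int s = tipstate(ch, p);
            if (s > 0) AiD.col(p) = es.Ainv[k].col(s - 1); else AiD.col(p) = rs;
          }
        } else {
          AiD = es.Ainv[k] * D[ch];
        }
        arma::mat Z = (es.A[k].t() * Oraw) % AiD;
        double fcur = edge_obj(Z, es.lambda[k], w, lengths(e));
        GoldenResult g = golden_max(Z, es.lambda[k], w, tmin, tmax, line_iter);
        if (g.f > fcur) lengths(e) = g.t;
        // descend with updated edge length (only internal children need O)
        if (ch >= ntip) {
          arma::mat P = prob_matrix(es.A[k], es.Ainv[k], es.lambda[k], lengths(e));
          O[ch] = P.t() * Oraw;
          olog[ch] = olraw;
          arma::rowvec mm = arma::max(O[ch], 0);
          for (int p = 0; p < npat; ++p) {
            if (mm(p) > 0 && mm(p) < 1e-120) { O[ch].col(p) /= mm(p); olog[ch](p) += std::log(mm(p)); }
          }
          stack.push_back(ch);
        }
      }
    }
    double cur = full_loglik();
    if (cur - prev < tol && sweep > 0) { prev = std::max(cur, prev); break; }
    prev = cur;
  }
  return List::create(_["lengths"] = NumericVector(lengths.begin(), lengths.end()),
                      _["loglik"] = prev);
}
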