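// Phylogenetic likelihood engine for branch-site codon mixtures.
//
// The model: a reversible generator Q_k per omega class (alpha enters as a
// pure time rescaling, Q(alpha, omega) = alpha * Q(1, omega)), omega drawn
// independently per (branch, site) with weights p, alpha per site with
// weights q.  Independence across branches makes mixing the per-class
// transition matrices within each branch exact, so pruning runs on the
// per-branch marginal matrix  Pbar_m(t) = sum_k p_k expm(Q_k alpha_m t s).
//
// All functions are generic in the state count (61 for codons, 4 for the
// nucleotide GTR used in phase 1); reversibility is exploited by
// eigendecomposing the symmetrized generator once per omega class.
//
// Tree encoding: `edge` is a postorder (children before parents) matrix of
// 1-based node ids, tips 1..ntip; `tipstate` holds 1-based state indices
// with 0 meaning fully missing (gap/ambiguous).

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

namespace {

struct EigSet {
  int N = 0, S = 0;
  arma::mat Ucat;            // S x S*N, [U_1 ... U_N]
  arma::mat Vcat;            // S*N x S, rows k scaled by p_k
  arma::mat lam;             // S x N
  std::vector<arma::mat> U;  // per-class factors for pure-class matrices
  std::vector<arma::mat> Vi;
  arma::vec p;
};

EigSet make_eigset(List eigs, const vec& p) {
  EigSet E;
  E.N = eigs.size();
  E.p = p;
  for (int k = 0; k < E.N; ++k) {
    List e = eigs[k];
    mat U = as<mat>(e["U"]);
    mat Vi = as<mat>(e["Uinv"]);
    vec lam = as<vec>(e["lam"]);
    if (k == 0) {
      E.S = U.n_rows;
      E.Ucat.set_size(E.S, E.S * E.N);
      E.Vcat.set_size(E.S * E.N, E.S);
      E.lam.set_size(E.S, E.N);
    }
    E.Ucat.cols(k * E.S, (k + 1) * E.S - 1) = U;
    E.Vcat.rows(k * E.S, (k + 1) * E.S - 1) = p[k] * Vi;
    E.lam.col(k) = lam;
    E.U.push_back(U);
    E.Vi.push_back(Vi);
  }
  return E;
}

// sum_k p_k expm(Q_k * x); tiny negative entries from roundoff clamped to 0
mat mix_P(const EigSet& E, double x) {
  mat W = E.Ucat;
  for (int k = 0; k < E.N; ++k)
    W.cols(k * E.S, (k + 1) * E.S - 1).each_row() %= exp(x * E.lam.col(k).t());
  mat P = W * E.Vcat;
  P.clamp(0.0, 1.0);
  return P;
}

mat class_P(const EigSet& E, int k, double x) {
  mat W = E.U[k];
  W.each_row() %= exp(x * E.lam.col(k).t());
  mat P = W * E.Vi[k];
  P.clamp(0.0, 1.0);
  return P;
}

int find_root(const imat& edge) {
  int nnode = std::max(edge.col(0).max(), edge.col(1).max());
  std::vector<bool> ischild(nnode + 1, false);
  for (uword e = 0; e < edge.n_rows; ++e) ischild[edge(e, 1)] = true;
  for (uword e = 0; e < edge.n_rows; ++e)
    if (!ischild[edge(e, 0)]) return edge(e, 0);
  stop("malformed tree: no root found");
  return -1;
}

// message from a tip: column of P at the observed state, ones if missing
mat tip_msg(const mat& P, const imat& tipstate, int tip0, int S, int npat) {
  mat msg(S, npat);
  for (int s = 0; s < npat; ++s) {
    int st = tipstate(tip0, s);
    if (st == 0)
      msg.col(s).ones();
    else
      msg.col(s) = P.col(st - 1);
  }
  return msg;
}

struct Inside {
  std::vector<mat> part;     // per internal node, scaled partials
  std::vector<rowvec> C;     // per node, cumulative log scale
  std::vector<mat> msgs;     // per edge, message into the parent
  std::vector<rowvec> CM;    // per edge, log scale carried by the message
  int root = 0;
};

// one post-order pass for alpha class m; keep_edges stores per-edge messages
// (needed by the outside recursion)
Inside inside_pass(const EigSet& E, double alpha_m, const imat& edge,
                   const vec& elen, double scale, const imat& tipstate,
                   int npat, bool keep_edges) {
  int S = E.S, nE = edge.n_rows;
  int ntip = tipstate.n_rows;
  int nnode = std::max(edge.col(0).max(), edge.col(1).max());
  Inside I;
  I.part.resize(nnode + 1);
  I.C.assign(nnode + 1, rowvec(npat, fill::zeros));
  if (keep_edges) {
    I.msgs.resize(nE);
    I.CM.assign(nE, rowvec(npat, fill::zeros));
  }
  I.root = find_root(edge);
  for (int e = 0; e < nE; ++e) {
    int pa = edge(e, 0), ch = edge(e, 1);
    mat P = mix_P(E, alpha_m * elen[e] * scale);
    mat msg = (ch <= ntip) ? tip_msg(P, tipstate, ch - 1, S, npat)
                           : mat(P * I.part[ch]);
    rowvec msc = (ch <= ntip) ? rowvec(npat, fill::zeros) : I.C[ch];
    if (keep_edges) {
      I.msgs[e] = msg;
      I.CM[e] = msc;
    }
    if (I.part[pa].n_elem == 0)
      I.part[pa] = msg;
    else
      I.part[pa] %= msg;
    I.C[pa] += msc;
    rowvec mx = max(I.part[pa], 0);
    mx.transform([](double v) { return v > 0 ? v : 1.0; });
    I.part[pa].each_row() /= mx;
    I.C[pa] += log(mx);
  }
  return I;
}

// log of freq' * part[root] per pattern, with accumulated scales
rowvec root_loglik(const Inside& I, const vec& freq) {
  rowvec lik = freq.t() * I.part[I.root];
  lik.transform([](double v) { return v > 1e-320 ? std::log(v) : -737.0; });
  return lik + I.C[I.root];
}

double total_loglik(const mat& sitelog, const vec& q, const vec& patw) {
  int npat = sitelog.n_rows, M = sitelog.n_cols;
  vec lq = log(q);
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -datum::inf;
    for (int m = 0; m < M; ++m) mx = std::max(mx, lq[m] + sitelog(s, m));
    double acc = 0.0;
    for (int m = 0; m < M; ++m) acc += std::exp(lq[m] + sitelog(s, m) - mx);
    ll += patw[s] * (mx + std::log(acc));
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
List cpp_mix_loglik(List eigs, arma::vec p, arma::vec alphas, arma::vec q,
                    arma::imat edge, arma::vec elen, double scale,
                    arma::imat tipstate, arma::vec patw, arma::vec freq,
                    bool want_sitelog = false) {
  EigSet E = make_eigset(eigs, p);
  int M = alphas.n_elem, npat = tipstate.n_cols;
  mat sitelog(npat, M);
  for (int m = 0; m < M; ++m) {
    Inside I = inside_pass(E, alphas[m], edge, elen, scale, tipstate, npat, false);
    sitelog.col(m) = root_loglik(I, freq).t();
  }
  double ll = total_loglik(sitelog, q, patw);
  if (want_sitelog)
    return List::create(_["loglik"] = ll, _["sitelog"] = sitelog);
  return List::create(_["loglik"] = ll);
}

// Site log-likelihoods with one branch's omega class forced to k
// (all other branches keep the mixture), marginalized over alpha classes.
// Returns an nE x npat x N cube of log-likelihoods.
// [[Rcpp::export]]
arma::cube cpp_forced_logliks(List eigs, arma::vec p, arma::vec alphas,
                              arma::vec q, arma::imat edge, arma::vec elen,
                              double scale, arma::imat tipstate,
                              arma::vec patw, arma::vec freq) {
  EigSet E = make_eigset(eigs, p);
  int S = E.S, N = E.N, M = alphas.n_elem;
  int nE = edge.n_rows, npat = tipstate.n_cols, ntip = tipstate.n_rows;
  int nnode = std::max(edge.col(0).max(), edge.col(1).max());
  vec lq = log(q);
  std::vector<cube> per_m(M);

  for (int m = 0; m < M; ++m) {
    Inside I = inside_pass(E, alphas[m], edge, elen, scale, tipstate, npat, true);
    std::vector<mat> A(nnode + 1);
    std::vector<rowvec> CA(nnode + 1);
    A[I.root] = repmat(freq, 1, npat);
    CA[I.root] = rowvec(npat, fill::zeros);
    // children of each parent
    std::vector<std::vector<int>> kids(nnode + 1);
    for (int e = 0; e < nE; ++e) kids[edge(e, 0)].push_back(e);
    cube F(nE, npat, N);
    for (int e = nE - 1; e >= 0; --e) {  // reverse postorder = preorder
      int pa = edge(e, 0), ch = edge(e, 1);
      mat T = A[pa];
      rowvec CT = CA[pa];
      for (int e2 : kids[pa]) {
        if (e2 == e) continue;
        T %= I.msgs[e2];
        CT += I.CM[e2];
      }
      rowvec mx = max(T, 0);
      mx.transform([](double v) { return v > 0 ? v : 1.0; });
      T.each_row() /= mx;
      CT += log(mx);
      double x = alphas[m] * elen[e] * scale;
      for (int k = 0; k < N; ++k) {
        mat Pk = class_P(E, k, x);
        mat Z = (ch <= ntip) ? tip_msg(Pk, tipstate, ch - 1, S, npat)
                             : mat(Pk * I.part[ch]);
        rowvec val = sum(T % Z, 0);
        val.transform([](double v) { return v > 1e-320 ? std::log(v) : -737.0; });
        rowvec chC = (ch <= ntip) ? rowvec(npat, fill::zeros) : I.C[ch];
        F.subcube(e, 0, k, e, npat - 1, k) = val + CT + chC;
      }
      if (ch > ntip) {
        mat Pbar = mix_P(E, x);
        A[ch] = Pbar.t() * T;
        CA[ch] = CT;
        rowvec mx2 = max(A[ch], 0);
        mx2.transform([](double v) { return v > 0 ? v : 1.0; });
        A[ch].each_row() /= mx2;
        CA[ch] += log(mx2);
      }
    }
    per_m[m] = F;
  }
  cube out(nE, npat, N);
  for (int e = 0; e < nE; ++e)
    for (int s = 0; s < npat; ++s)
      for (int k = 0; k < N; ++k) {
        double mx = -datum::inf;
        for (int m = 0; m < M; ++m)
          mx = std::max(mx, lq[m] + per_m[m](e, s, k));
        double a = 0.0;
        for (int m = 0; m < M; ++m)
          a += std::exp(lq[m] + per_m[m](e, s, k) - mx);
        out(e, s, k) = mx + std::log(a);
      }
  return out;
}

namespace {

// coefficients for the 1-D branch-length objective on edge e:
// loglik_m(s; t) = log( sum_k p_k sum_j Cf_{k,m}(j,s) exp(lam_{j,k} a_m t s) ) + cst_m(s)
struct EdgeObj {
  std::vector<std::vector<mat>> Cf;  // [m][k] S x npat
  std::vector<rowvec> cst;           // [m]
};

double edge_loglik_at(const EdgeObj& O, const EigSet& E, const vec& alphas,
                      const vec& lq, const vec& patw, double scale, double t) {
  int M = alphas.n_elem, N = E.N;
  int npat = O.cst[0].n_elem;
  mat sl(npat, M);
  for (int m = 0; m < M; ++m) {
    rowvec v(npat, fill::zeros);
    for (int k = 0; k < N; ++k) {
      vec ex = exp(E.lam.col(k) * (alphas[m] * t * scale));
      v += E.p[k] * (ex.t() * O.Cf[m][k]);
    }
    v.transform([](double x) { return x > 1e-320 ? std::log(x) : -737.0; });
    sl.col(m) = (v + O.cst[m]).t();
  }
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -datum::inf;
    for (int m = 0; m < M; ++m) mx = std::max(mx, lq[m] + sl(s, m));
    double a = 0.0;
    for (int m = 0; m < M; ++m) a += std::exp(lq[m] + sl(s, m) - mx);
    ll += patw[s] * (mx + std::log(a));
  }
  return ll;
}

}  // namespace

// One Jacobi-style pass of per-branch length optimization: inside/outside
// vectors are computed once at the incoming lengths, each branch is then
// optimized by golden-section on log(t) against the eigen-coefficient form
// of its 1-D profile likelihood.  Returns updated lengths and the exactly
// recomputed log-likelihood at those lengths; the caller decides acceptance.
// [[Rcpp::export]]
List cpp_optimize_blens(List eigs, arma::vec p, arma::vec alphas, arma::vec q,
                        arma::imat edge, arma::vec elen, double scale,
                        arma::imat tipstate, arma::vec patw, arma::vec freq,
                        double lower, double upper, int gs_iter = 40) {
  EigSet E = make_eigset(eigs, p);
  int S = E.S, N = E.N, M = alphas.n_elem;
  int nE = edge.n_rows, npat = tipstate.n_cols, ntip = tipstate.n_rows;
  int nnode = std::max(edge.col(0).max(), edge.col(1).max());
  vec lq = log(q);
  vec newlen = elen;

  // per-m inside/outside state at the incoming lengths
  std::vector<Inside> Ins(M);
  std::vector<std::vector<mat>> A(M);
  std::vector<std::vector<rowvec>> CA(M);
  std::vector<std::vector<int>> kids(nnode + 1);
  for (int e = 0; e < nE; ++e) kids[edge(e, 0)].push_back(e);
  for (int m = 0; m < M; ++m) {
    Ins[m] = inside_pass(E, alphas[m], edge, elen, scale, tipstate, npat, true);
    A[m].resize(nnode + 1);
    CA[m].resize(nnode + 1);
    A[m][Ins[m].root] = repmat(freq, 1, npat);
    CA[m][Ins[m].root] = rowvec(npat, fill::zeros);
  }
  // outside vectors via one preorder sweep per m (at incoming lengths)
  for (int m = 0; m < M; ++m) {
    for (int e = nE - 1; e >= 0; --e) {
      int pa = edge(e, 0), ch = edge(e, 1);
      if (ch <= ntip) continue;
      mat T = A[m][pa];
      rowvec CT = CA[m][pa];
      for (int e2 : kids[pa]) {
        if (e2 == e) continue;
        T %= Ins[m].msgs[e2];
        CT += Ins[m].CM[e2];
      }
      mat Pbar = mix_P(E, alphas[m] * elen[e] * scale);
      A[m][ch] = Pbar.t() * T;
      CA[m][ch] = CT;
      rowvec mx = max(A[m][ch], 0);
      mx.transform([](double v) { return v > 0 ? v : 1.0; });
      A[m][ch].each_row() /= mx;
      CA[m][ch] += log(mx);
    }
  }

  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  for (int e = 0; e < nE; ++e) {
    int pa = edge(e, 0), ch = edge(e, 1);
    EdgeObj O;
    O.Cf.resize(M);
    O.cst.resize(M);
    for (int m = 0; m < M; ++m) {
      mat T = A[m][pa];
      rowvec CT = CA[m][pa];
      for (int e2 : kids[pa]) {
        if (e2 == e) continue;
        T %= Ins[m].msgs[e2];
        CT += Ins[m].CM[e2];
      }
      rowvec mx = max(T, 0);
      mx.transform([](double v) { return v > 0 ? v : 1.0; });
      T.each_row() /= mx;
      CT += log(mx);
      rowvec chC(npat, fill::zeros);
      O.Cf[m].resize(N);
      for (int k = 0; k < N; ++k) {
        mat X = E.U[k].t() * T;  // S x npat
        mat Y;
        if (ch <= ntip) {
          Y.set_size(S, npat);
          vec rs = sum(E.Vi[k], 1);
          for (int s = 0; s < npat; ++s) {
            int st = tipstate(ch - 1, s);
            Y.col(s) = (st == 0) ? rs : vec(E.Vi[k].col(st - 1));
          }
        } else {
          Y = E.Vi[k] * Ins[m].part[ch];
          chC = Ins[m].C[ch];
        }
        O.Cf[m][k] = X % Y;
      }
      O.cst[m] = CT + chC;
    }
    // golden-section on u = log(t)
    double lo = std::log(lower), hi = std::log(upper);
    double a = lo, b = hi;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = edge_loglik_at(O, E, alphas, lq, patw, scale, std::exp(c));
    double fd = edge_loglik_at(O, E, alphas, lq, patw, scale, std::exp(d));
    for (int it = 0; it < gs_iter; ++it) {
      if (fc > fd) {
        b = d; d = c; fd = fc;
        c = b - gr * (b - a);
        fc = edge_loglik_at(O, E, alphas, lq, patw, scale, std::exp(c));
      } else {
        a = c; c = d; fc = fd;
        d = a + gr * (b - a);
        fd = edge_loglik_at(O, E, alphas, lq, patw, scale, std::exp(d));
      }
    }
    double tbest = std::exp(0.5 * (a + b));
    double fbest = edge_loglik_at(O, E, alphas, lq, patw, scale, tbest);
    double fcur = edge_loglik_at(O, E, alphas, lq, patw, scale, newlen[e]);
    if (fbest > fcur) newlen[e] = tbest;
  }

  // exact loglik at the updated lengths
  mat sitelog(npat, M);
  for (int m = 0; m < M; ++m) {
    Inside I2 = inside_pass(E, alphas[m], edge, newlen, scale, tipstate, npat, false);
    sitelog.col(m) = root_loglik(I2, freq).t();
  }
  double ll = total_loglik(sitelog, q, patw);
  return List::create(_["elen"] = newlen, _["loglik"] = ll);
}

// Reversible-generator eigendecomposition: Q = D^{-1/2} B D^{1/2} with B
// symmetric, D = diag(freq).  expm(Q x) = U diag(exp(lam x)) Uinv.
// [[Rcpp::export]]
List cpp_eig_rev(arma::mat Q, arma::vec freq) {
  vec s = sqrt(freq);
  mat B = Q;
  B.each_col() %= s;
  B.each_row() /= s.t();
  B = 0.5 * (B + B.t());
  vec lam;
  mat V;
  if (!eig_sym(lam, V, B)) stop("eigendecomposition failed");
  mat U = V;
  U.each_col() /= s;
  mat Uinv = V.t();
  Uinv.each_row() %= s.t();
  return List::create(_["U"] = U, _["Uinv"] = Uinv, _["lam"] = lam);
}

// MG94xREV generator at alpha = 1.  `nb` has one row per ordered
// single-nucleotide codon pair: from, to, theta pair index (1..6),
// codon position (1..3), target nucleotide (1..4), synonymous flag.
// [[Rcpp::export]]
arma::mat cpp_build_mg94(arma::imat nb, arma::vec theta6, arma::mat pi34,
                         double omega) {
  mat Q(61, 61, fill::zeros);
  for (uword i = 0; i < nb.n_rows; ++i) {
    double r = theta6[nb(i, 2) - 1] * pi34(nb(i, 3) - 1, nb(i, 4) - 1);
    if (nb(i, 5) == 0) r *= omega;
    Q(nb(i, 0) - 1, nb(i, 1) - 1) = r;
  }
  Q.diag() = -sum(Q, 1);
  return Q;
}
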