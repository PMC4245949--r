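#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Sequences are encoded as integer vectors with A=1, C=2, G=3, T=4 and N=0.
// An N is emission-marginalized: its emission factor is 1 in every state,
// so it neither favors nor penalizes any state.
//
// Binding-site HMM topologies are sparse (chains plus a background hub), so
// all kernels iterate precomputed edge lists instead of dense S x S loops.

// [[Rcpp::export]]
List encode_dna_c(CharacterVector seqs) {
  List out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = (int)strlen(s);
    IntegerVector v(L);
    for (int t = 0; t < L; ++t) {
      switch (s[t]) {
        case 'A': case 'a': v[t] = 1; break;
        case 'C': case 'c': v[t] = 2; break;
        case 'G': case 'g': v[t] = 3; break;
        case 'T': case 't': case 'U': case 'u': v[t] = 4; break;
        default: v[t] = 0;
      }
    }
    out[i] = v;
  }
  return out;
}

struct Edge { int from, to; double p; };

struct Model {
  int S;
  std::vector<double> emis;            // S x 4, column-major
  std::vector<double> pi;
  std::vector<double> endw;            // terminal weights (end-state wiring)
  std::vector<char> allowed;
  std::vector< std::vector<Edge> > in;   // edges into state j (allowed only)
  std::vector< std::vector<Edge> > out;  // edges out of state i (allowed only)
  double b(int j, int x) const { return x == 0 ? 1.0 : emis[j + S * (x - 1)]; }

  Model(NumericMatrix trans, NumericMatrix emis_, NumericVector pi_,
        NumericVector endw_, LogicalVector allowed_) {
    S = trans.nrow();
    emis.assign(emis_.begin(), emis_.end());
    pi.assign(pi_.begin(), pi_.end());
    endw.assign(endw_.begin(), endw_.end());
    allowed.assign(allowed_.begin(), allowed_.end());
    in.resize(S); out.resize(S);
    for (int i = 0; i < S; ++i) {
      if (!allowed[i]) continue;
      for (int j = 0; j < S; ++j) {
        double a = trans(i, j);
        if (a > 0.0 && allowed[j]) {
          Edge e = {i, j, a};
          in[j].push_back(e);
          out[i].push_back(e);
        }
      }
    }
  }
};

// Scaled forward pass with terminal end weighting; optionally stores the
// scaled alphas, scale constants and the terminal constant.
static double forward_scaled(const Model &m, const int *x, int T,
                             std::vector<double> *alpha_out,
                             std::vector<double> *scale_out,
                             double *c_end_out = NULL) {
  const int S = m.S;
  std::vector<double> alpha(S), prev(S);
  double loglik = 0.0;
  for (int j = 0; j < S; ++j)
    alpha[j] = m.allowed[j] ? m.pi[j] * m.b(j, x[0]) : 0.0;
  double c = 0.0;
  for (int j = 0; j < S; ++j) c += alpha[j];
  if (c <= 0.0) return R_NegInf;
  for (int j = 0; j < S; ++j) alpha[j] /= c;
  loglik += std::log(c);
  if (alpha_out) std::copy(alpha.begin(), alpha.end(), alpha_out->begin());
  if (scale_out) (*scale_out)[0] = c;
  for (int t = 1; t < T; ++t) {
    prev.swap(alpha);
    c = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      if (m.allowed[j]) {
        for (const Edge &e : m.in[j]) s += prev[e.from] * e.p;
        s *= m.b(j, x[t]);
      }
      alpha[j] = s;
      c += s;
    }
    if (c <= 0.0) return R_NegInf;
    for (int j = 0; j < S; ++j) alpha[j] /= c;
    loglik += std::log(c);
    if (alpha_out)
      std::copy(alpha.begin(), alpha.end(), alpha_out->begin() + (size_t)t * S);
    if (scale_out) (*scale_out)[t] = c;
  }
  double c_end = 0.0;
  for (int j = 0; j < S; ++j) c_end += alpha[j] * m.endw[j];
  if (c_end <= 0.0) return R_NegInf;
  if (c_end_out) *c_end_out = c_end;
  return loglik + std::log(c_end);
}

// Log-likelihood of each sequence part under the (possibly state-restricted)
// model. parts: list of integer vectors; allowed: logical state mask.
// [[Rcpp::export]]
NumericVector hmm_loglik_c(List parts, NumericMatrix trans, NumericMatrix emis,
                           NumericVector pi, NumericVector endw,
                           LogicalVector allowed) {
  Model m(trans, emis, pi, endw, allowed);
  NumericVector out(parts.size());
  for (int p = 0; p < parts.size(); ++p) {
    IntegerVector x = parts[p];
    out[p] = x.size() == 0 ? 0.0
                           : forward_scaled(m, x.begin(), x.size(), NULL, NULL);
  }
  return out;
}

// Weighted expected-count accumulation via scaled forward-backward.
// Returns per-part log-likelihoods plus
//   A = sum_p w_p E_p[transition counts]  (S x S; initial-state counts are
//       folded into row `bg` since pi is tied to the background row), and
//   E = sum_p w_p E_p[emission counts]    (S x 4; N positions contribute 0).
// With want_trans = false the transition counts are skipped (cheaper; used
// when only emission gradients are needed).
// [[Rcpp::export]]
List hmm_fb_counts_c(List parts, NumericMatrix trans, NumericMatrix emis,
                     NumericVector pi, NumericVector endw,
                     NumericVector weights, LogicalVector allowed, int bg,
                     bool want_trans = true) {
  Model m(trans, emis, pi, endw, allowed);
  const int S = m.S;
  NumericMatrix A(S, S), E(S, 4);
  NumericVector loglik(parts.size());
  const int bg0 = bg - 1;
  std::vector<double> alpha, scale, beta(S), beta_next(S);
  for (int p = 0; p < parts.size(); ++p) {
    IntegerVector xs = parts[p];
    const int T = xs.size();
    const double w = weights[p];
    if (T == 0) { loglik[p] = 0.0; continue; }
    const int *x = xs.begin();
    alpha.assign((size_t)T * S, 0.0);
    scale.assign(T, 0.0);
    double c_end = 1.0;
    double ll = forward_scaled(m, x, T, &alpha, &scale, &c_end);
    loglik[p] = ll;
    if (!R_FINITE(ll) || w == 0.0) continue;
    for (int j = 0; j < S; ++j) beta[j] = m.endw[j] / c_end;
    for (int t = T - 2; t >= 0; --t) {
      beta_next = beta;
      const double ct1 = scale[t + 1];
      for (int i = 0; i < S; ++i) beta[i] = 0.0;
      for (int i = 0; i < S; ++i) {
        if (!m.allowed[i]) continue;
        double s = 0.0;
        for (const Edge &e : m.out[i])
          s += e.p * m.b(e.to, x[t + 1]) * beta_next[e.to];
        beta[i] = s / ct1;
      }
      if (want_trans) {
        const double *al = alpha.data() + (size_t)t * S;
        for (int i = 0; i < S; ++i) {
          const double ai = al[i];
          if (ai <= 0.0) continue;
          for (const Edge &e : m.out[i])
            A(i, e.to) += w * ai * e.p * m.b(e.to, x[t + 1]) *
                          beta_next[e.to] / ct1;
        }
      }
      if (x[t] != 0) {
        const int c = x[t] - 1;
        const double *al = alpha.data() + (size_t)t * S;
        for (int j = 0; j < S; ++j) E(j, c) += w * al[j] * beta[j];
      }
    }
    if (x[T - 1] != 0) {
      const int c = x[T - 1] - 1;
      const double *al = alpha.data() + (size_t)(T - 1) * S;
      if (T >= 2) {
        for (int j = 0; j < S; ++j)
          E(j, c) += w * al[j] * m.endw[j] / c_end;
      } else {
        for (int j = 0; j < S; ++j)
          E(j, c) += w * al[j] * m.endw[j] / c_end;
      }
    }
    if (!want_trans) continue;
    // initial-state counts -> background transition row (pi tied to it)
    if (T >= 2) {
      for (int j = 0; j < S; ++j) A(bg0, j) += w * alpha[j] * beta[j];
    } else {
      for (int j = 0; j < S; ++j)
        A(bg0, j) += w * alpha[j] * m.endw[j] / c_end;
    }
  }
  return List::create(_["loglik"] = loglik, _["A"] = A, _["E"] = E);
}

// Viterbi decoding (log space). Returns the 1-based most probable state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_c(IntegerVector xs, NumericMatrix trans,
                            NumericMatrix emis, NumericVector pi,
                            NumericVector endw) {
  const int S = trans.nrow(), T = xs.size();
  if (T == 0) return IntegerVector(0);
  LogicalVector allw(S, true);
  Model m(trans, emis, pi, endw, allw);
  const int *x = xs.begin();
  // log-space edges
  std::vector< std::vector<Edge> > lin(S);
  for (int j = 0; j < S; ++j) {
    lin[j] = m.in[j];
    for (Edge &e : lin[j]) e.p = std::log(e.p);
  }
  std::vector<double> v(S), vprev(S);
  std::vector<int> bp((size_t)T * S, -1);
  for (int j = 0; j < S; ++j) {
    double e = m.b(j, x[0]);
    v[j] = (m.pi[j] > 0.0 && e > 0.0) ? std::log(m.pi[j]) + std::log(e)
                                      : R_NegInf;
  }
  for (int t = 1; t < T; ++t) {
    vprev.swap(v);
    for (int j = 0; j < S; ++j) {
      double best = R_NegInf;
      int arg = -1;
      for (const Edge &e : lin[j]) {
        double s = vprev[e.from] + e.p;
        if (s > best) { best = s; arg = e.from; }
      }
      double em = m.b(j, x[t]);
      v[j] = (em > 0.0 && R_FINITE(best)) ? best + std::log(em) : R_NegInf;
      bp[(size_t)t * S + j] = arg;
    }
  }
  // terminal selection respects the end-state wiring
  for (int j = 0; j < S; ++j)
    v[j] = m.endw[j] > 0.0 ? v[j] + std::log(m.endw[j]) : R_NegInf;
  int arg = 0;
  for (int j = 1; j < S; ++j) if (v[j] > v[arg]) arg = j;
  IntegerVector path(T);
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = bp[(size_t)t * S + arg];
    path[t - 1] = arg + 1;
  }
  return path;
}
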