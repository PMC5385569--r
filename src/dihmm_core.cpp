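#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout: pair (j, mu) with j = nucleosome state (0..Kn-1),
// mu = domain state (0..Kd-1), flattened column-major as s = j + mu*Kn,
// matching R's as.vector() on a Kn x Kd matrix.
//
// Block convention (0-based bins): the step entering bin i allows a
// domain-level transition iff i % D == 0 and i > 0; elsewhere the composite
// transition carries a Kronecker delta on the domain index.  Nucleosome
// transitions always use the tensor slice of the destination domain.

static inline double nt_at(const NumericVector& nt, int Kn, int j, int k, int v) {
  return nt[j + k * Kn + v * Kn * Kn];
}

// Per-bin emission likelihoods under independent Bernoulli marks.
// X: L x M 0/1 observations; E: Kn x M success probabilities.
// [[Rcpp::export]]
NumericMatrix emission_matrix_cpp(IntegerMatrix X, NumericMatrix E) {
  int L = X.nrow(), M = X.ncol(), Kn = E.nrow();
  NumericMatrix B(L, Kn);
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < Kn; ++k) {
      double p = 1.0;
      for (int m = 0; m < M; ++m)
        p *= X(i, m) ? E(k, m) : (1.0 - E(k, m));
      B(i, k) = p;
    }
  }
  return B;
}

// Scaled forward pass.  Returns rescaled forward variables (rows sum to 1),
// the per-position scaling factors, and log-likelihood = sum(log(scales)).
// [[Rcpp::export]]
List forward_cpp(NumericMatrix B, NumericVector nt, NumericMatrix dt,
                 NumericMatrix P0, int D) {
  int L = B.nrow(), Kn = P0.nrow(), Kd = P0.ncol(), K = Kn * Kd;
  NumericMatrix alpha(L, K);
  NumericVector scales(L);
  std::vector<double> pred(K), coll(K);
  double loglik = 0.0;

  double s = 0.0;
  for (int mu = 0; mu < Kd; ++mu)
    for (int j = 0; j < Kn; ++j) {
      double v = P0(j, mu) * B(0, j);
      alpha(0, j + mu * Kn) = v;
      s += v;
    }
  if (s <= 1e-300)
    stop("total probability mass underflow at position 1");
  for (int q = 0; q < K; ++q) alpha(0, q) /= s;
  scales[0] = s;
  loglik += std::log(s);

  for (int i = 1; i < L; ++i) {
    bool boundary = (i % D == 0);
    if (!boundary) {
      for (int v = 0; v < Kd; ++v)
        for (int k = 0; k < Kn; ++k) {
          double acc = 0.0;
          for (int j = 0; j < Kn; ++j)
            acc += alpha(i - 1, j + v * Kn) * nt_at(nt, Kn, j, k, v);
          pred[k + v * Kn] = acc;
        }
    } else {
      // coll[j + v*Kn] = sum_mu alpha(i-1, j, mu) * T(mu, v)
      for (int v = 0; v < Kd; ++v)
        for (int j = 0; j < Kn; ++j) {
          double acc = 0.0;
          for (int mu = 0; mu < Kd; ++mu)
            acc += alpha(i - 1, j + mu * Kn) * dt(mu, v);
          coll[j + v * Kn] = acc;
        }
      for (int v = 0; v < Kd; ++v)
        for (int k = 0; k < Kn; ++k) {
          double acc = 0.0;
          for (int j = 0; j < Kn; ++j)
            acc += coll[j + v * Kn] * nt_at(nt, Kn, j, k, v);
          pred[k + v * Kn] = acc;
        }
    }
    s = 0.0;
    for (int v = 0; v < Kd; ++v)
      for (int k = 0; k < Kn; ++k) {
        double val = pred[k + v * Kn] * B(i, k);
        alpha(i, k + v * Kn) = val;
        s += val;
      }
    if (s <= 1e-300)
      stop("total probability mass underflow at position %d", i + 1);
    for (int q = 0; q < K; ++q) alpha(i, q) /= s;
    scales[i] = s;
    loglik += std::log(s);
  }
  return List::create(_["alpha"] = alpha, _["scales"] = scales,
                      _["loglik"] = loglik);
}

// Rescaled backward pass using the forward scaling factors; with this
// convention alpha_hat * beta_hat is the joint posterior (rows sum to 1).
// [[Rcpp::export]]
NumericMatrix backward_cpp(NumericMatrix B, NumericVector nt, NumericMatrix dt,
                           int D, NumericVector scales) {
  int L = B.nrow(), Kd = dt.nrow();
  int Kn = B.ncol(), K = Kn * Kd;
  NumericMatrix beta(L, K);
  std::vector<double> tmp(K), inner(K);
  for (int q = 0; q < K; ++q) beta(L - 1, q) = 1.0;
  for (int i = L - 2; i >= 0; --i) {
    bool boundary = ((i + 1) % D == 0);
    double sc = scales[i + 1];
    for (int v = 0; v < Kd; ++v)
      for (int k = 0; k < Kn; ++k)
        tmp[k + v * Kn] = B(i + 1, k) * beta(i + 1, k + v * Kn);
    if (!boundary) {
      for (int mu = 0; mu < Kd; ++mu)
        for (int j = 0; j < Kn; ++j) {
          double acc = 0.0;
          for (int k = 0; k < Kn; ++k)
            acc += nt_at(nt, Kn, j, k, mu) * tmp[k + mu * Kn];
          beta(i, j + mu * Kn) = acc / sc;
        }
    } else {
      // inner[j + v*Kn] = sum_k t^(v)_{jk} * tmp(k, v)
      for (int v = 0; v < Kd; ++v)
        for (int j = 0; j < Kn; ++j) {
          double acc = 0.0;
          for (int k = 0; k < Kn; ++k)
            acc += nt_at(nt, Kn, j, k, v) * tmp[k + v * Kn];
          inner[j + v * Kn] = acc;
        }
      for (int mu = 0; mu < Kd; ++mu)
        for (int j = 0; j < Kn; ++j) {
          double acc = 0.0;
          for (int v = 0; v < Kd; ++v)
            acc += dt(mu, v) * inner[j + v * Kn];
          beta(i, j + mu * Kn) = acc / sc;
        }
    }
  }
  return beta;
}

// Expected transition counts for Baum-Welch, accumulated without
// materializing the per-step pair marginals.  xi_nuc is credited to the
// destination domain; xi_boundary accumulates only at block boundaries.
// [[Rcpp::export]]
List stats_cpp(NumericMatrix B, NumericMatrix alpha, NumericMatrix beta,
               NumericVector scales, NumericVector nt, NumericMatrix dt,
               int D) {
  int L = B.nrow(), Kd = dt.nrow(), Kn = B.ncol();
  NumericMatrix xi_boundary(Kd, Kd);
  NumericVector xi_nuc(Kn * Kn * Kd);  // [j, k, v]
  for (int i = 0; i < L - 1; ++i) {
    bool boundary = ((i + 1) % D == 0);
    double sc = scales[i + 1];
    if (!boundary) {
      for (int v = 0; v < Kd; ++v)
        for (int j = 0; j < Kn; ++j) {
          double aj = alpha(i, j + v * Kn);
          if (aj == 0.0) continue;
          for (int k = 0; k < Kn; ++k) {
            double w = aj * nt_at(nt, Kn, j, k, v) * B(i + 1, k) *
                       beta(i + 1, k + v * Kn) / sc;
            xi_nuc[j + k * Kn + v * Kn * Kn] += w;
          }
        }
    } else {
      for (int mu = 0; mu < Kd; ++mu)
        for (int v = 0; v < Kd; ++v) {
          double tb = dt(mu, v);
          if (tb == 0.0) continue;
          double cell = 0.0;
          for (int j = 0; j < Kn; ++j) {
            double aj = alpha(i, j + mu * Kn);
            if (aj == 0.0) continue;
            for (int k = 0; k < Kn; ++k) {
              double w = aj * tb * nt_at(nt, Kn, j, k, v) * B(i + 1, k) *
                         beta(i + 1, k + v * Kn) / sc;
              xi_nuc[j + k * Kn + v * Kn * Kn] += w;
              cell += w;
            }
          }
          xi_boundary(mu, v) += cell;
        }
    }
  }
  xi_nuc.attr("dim") = IntegerVector::create(Kn, Kn, Kd);
  return List::create(_["xi_boundary"] = xi_boundary, _["xi_nuc"] = xi_nuc);
}

// Joint Viterbi decoding in log space; ties broken toward the lowest
// (nucleosome, domain) index pair in lexicographic order.
// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix B, NumericVector nt, NumericMatrix dt,
                 NumericMatrix P0, int D) {
  int L = B.nrow(), Kn = P0.nrow(), Kd = P0.ncol(), K = Kn * Kd;
  NumericMatrix delta(L, K);
  IntegerMatrix psi(L, K);
  for (int mu = 0; mu < Kd; ++mu)
    for (int j = 0; j < Kn; ++j)
      delta(0, j + mu * Kn) = std::log(P0(j, mu)) + std::log(B(0, j));
  for (int i = 1; i < L; ++i) {
    bool boundary = (i % D == 0);
    for (int v = 0; v < Kd; ++v)
      for (int k = 0; k < Kn; ++k) {
        double best = -INFINITY;
        int arg = -1;
        // iterate predecessors in (j, mu) lexicographic order, strict >
        for (int j = 0; j < Kn; ++j) {
          if (!boundary) {
            double cand = delta(i - 1, j + v * Kn) +
                          std::log(nt_at(nt, Kn, j, k, v));
            if (cand > best) { best = cand; arg = j + v * Kn; }
          } else {
            for (int mu = 0; mu < Kd; ++mu) {
              double cand = delta(i - 1, j + mu * Kn) + std::log(dt(mu, v)) +
                            std::log(nt_at(nt, Kn, j, k, v));
              if (cand > best) { best = cand; arg = j + mu * Kn; }
            }
          }
        }
        delta(i, k + v * Kn) = best + std::log(B(i, k));
        psi(i, k + v * Kn) = arg;
      }
  }
  double best = -INFINITY;
  int s = -1;
  for (int j = 0; j < Kn; ++j)
    for (int mu = 0; mu < Kd; ++mu) {
      double cand = delta(L - 1, j + mu * Kn);
      if (cand > best) { best = cand; s = j + mu * Kn; }
    }
  if (s < 0 || !std::isfinite(best))
    stop("no admissible state path has positive probability");
  IntegerVector nuc(L), dom(L);
  for (int i = L - 1; i >= 0; --i) {
    nuc[i] = s % Kn + 1;
    dom[i] = s / Kn + 1;
    if (i > 0) s = psi(i, s);
  }
  return List::create(_["nuc"] = nuc, _["dom"] = dom, _["logprob"] = best);
}
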