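#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fast non-negative least squares (Bro & De Jong 1997) working on the
// normal equations: minimise ||A x - b||^2 subject to x >= 0, given
// AtA = A'A and Atb = A'b. Active-set with exact subproblem solves, so
// each call returns the exact constrained minimiser (up to tolerance);
// this is what guarantees the monotone-residual property of the ALS.
static vec fnnls_one(const mat& AtA, const vec& Atb, double tol) {
  const uword k = AtA.n_cols;
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);
  vec w = Atb; // gradient of -0.5||Ax-b||^2 at x = 0
  const uword maxiter = 50 * k + 50;
  uword iter = 0;

  while (true) {
    double wmax = tol;
    sword cand = -1;
    for (uword j = 0; j < k; ++j) {
      if (passive(j) == 0 && w(j) > wmax) { wmax = w(j); cand = (sword) j; }
    }
    if (cand < 0) break;
    passive((uword) cand) = 1;

    while (true) {
      if (++iter > maxiter) return x;
      uvec P = find(passive == 1);
      if (P.n_elem == 0) { x.zeros(); break; }
      vec z;
      bool ok = solve(z, AtA.submat(P, P), Atb.elem(P),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok || !z.is_finite()) z = pinv(AtA.submat(P, P)) * Atb.elem(P);
      if (z.n_elem > 0 && z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step from x toward z until the first passive variable hits zero
      double alpha = datum::inf;
      for (uword t = 0; t < P.n_elem; ++t) {
        if (z(t) <= 0) {
          double xi = x(P(t));
          double denom = xi - z(t);
          double a = denom > 0 ? xi / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword t = 0; t < P.n_elem; ++t) {
        x(P(t)) += alpha * (z(t) - x(P(t)));
      }
      for (uword t = 0; t < P.n_elem; ++t) {
        if (x(P(t)) <= tol) { passive(P(t)) = 0; x(P(t)) = 0.0; }
      }
    }
    w = Atb - AtA * x;
  }
  return x;
}

static double nnls_tol(const mat& AtA) {
  double t = 10.0 * datum::eps * norm(AtA, "inf") * AtA.n_cols;
  return (t > 0 && std::isfinite(t)) ? t : datum::eps;
}

// Warm-started variant: start from the support of x0 (the previous ALS
// iterate). The KKT conditions of this convex problem are verified on
// exit, so the solution is the exact constrained minimiser regardless of
// the starting set; warm starts only shorten the path to it.
static vec fnnls_warm(const mat& AtA, const vec& Atb, double tol,
                      const vec& x0) {
  const uword k = AtA.n_cols;
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);
  for (uword j = 0; j < k; ++j) if (x0(j) > tol) passive(j) = 1;
  const uword maxiter = 50 * k + 50;
  uword iter = 0;

  // feasibility loop on the starting passive set
  while (accu(passive) > 0) {
    if (++iter > maxiter) break;
    uvec P = find(passive == 1);
    vec z;
    bool ok = solve(z, AtA.submat(P, P), Atb.elem(P),
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !z.is_finite()) z = pinv(AtA.submat(P, P)) * Atb.elem(P);
    if (z.n_elem > 0 && z.min() > 0) {
      x.zeros();
      x.elem(P) = z;
      break;
    }
    double alpha = datum::inf;
    for (uword t = 0; t < P.n_elem; ++t) {
      if (z(t) <= 0) {
        double xi = x(P(t));
        double denom = xi - z(t);
        double a = denom > 0 ? xi / denom : 0.0;
        if (a < alpha) alpha = a;
      }
    }
    if (!std::isfinite(alpha)) alpha = 0.0;
    for (uword t = 0; t < P.n_elem; ++t) x(P(t)) += alpha * (z(t) - x(P(t)));
    for (uword t = 0; t < P.n_elem; ++t) {
      if (x(P(t)) <= tol) { passive(P(t)) = 0; x(P(t)) = 0.0; }
    }
  }

  vec w = Atb - AtA * x;
  while (true) {
    double wmax = tol;
    sword cand = -1;
    for (uword j = 0; j < k; ++j) {
      if (passive(j) == 0 && w(j) > wmax) { wmax = w(j); cand = (sword) j; }
    }
    if (cand < 0) break;
    passive((uword) cand) = 1;
    while (true) {
      if (++iter > maxiter) return x;
      uvec P = find(passive == 1);
      if (P.n_elem == 0) { x.zeros(); break; }
      vec z;
      bool ok = solve(z, AtA.submat(P, P), Atb.elem(P),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok || !z.is_finite()) z = pinv(AtA.submat(P, P)) * Atb.elem(P);
      if (z.n_elem > 0 && z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword t = 0; t < P.n_elem; ++t) {
        if (z(t) <= 0) {
          double xi = x(P(t));
          double denom = xi - z(t);
          double a = denom > 0 ? xi / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword t = 0; t < P.n_elem; ++t) x(P(t)) += alpha * (z(t) - x(P(t)));
      for (uword t = 0; t < P.n_elem; ++t) {
        if (x(P(t)) <= tol) { passive(P(t)) = 0; x(P(t)) = 0.0; }
      }
    }
    w = Atb - AtA * x;
  }
  return x;
}

//' Column-wise non-negative least squares
//'
//' Solves min ||A X - B||_F with X >= 0, one NNLS problem per column of B.
//' @noRd
// [[Rcpp::export(name = ".nnlsMultiRHS")]]
arma::mat nnlsMultiRHS(const arma::mat& A, const arma::mat& B) {
  mat AtA = A.t() * A;
  mat AtB = A.t() * B;
  double tol = nnls_tol(AtA);
  mat X(A.n_cols, B.n_cols);
  for (uword j = 0; j < B.n_cols; ++j) {
    X.col(j) = fnnls_one(AtA, AtB.col(j), tol);
  }
  return X;
}

// One full ALS alternation: S from C (per-bin NNLS), then C from S
// (per-sample NNLS). D is n x p, C n x k, S p x k. The previous S and C
// warm-start their own updates (first = true uses cold starts).
static void als_alternate(const mat& D, mat& C, mat& S, bool first) {
  {
    mat AtA = C.t() * C;
    mat AtB = C.t() * D;
    double tol = nnls_tol(AtA);
    mat X(C.n_cols, D.n_cols);
    for (uword j = 0; j < D.n_cols; ++j) {
      X.col(j) = first ? fnnls_one(AtA, AtB.col(j), tol)
                       : fnnls_warm(AtA, AtB.col(j), tol, S.row(j).t());
    }
    S = X.t();
  }
  {
    mat AtA = S.t() * S;
    mat AtB = S.t() * D.t();
    double tol = nnls_tol(AtA);
    mat X(S.n_cols, D.n_rows);
    for (uword j = 0; j < D.n_rows; ++j) {
      X.col(j) = first ? fnnls_one(AtA, AtB.col(j), tol)
                       : fnnls_warm(AtA, AtB.col(j), tol, C.row(j).t());
    }
    C = X.t();
  }
}

//' Alternating least squares engine with non-negativity constraints
//' @noRd
// [[Rcpp::export(name = ".alsEngine")]]
Rcpp::List alsEngine(const arma::mat& D, const arma::mat& Cinit,
                     const arma::mat& Sinit, double tol, int maxIter) {
  mat C = Cinit;
  mat S = Sinit;
  std::vector<double> trace;
  trace.reserve(maxIter);
  double ssePrev = datum::inf;
  double sse = datum::inf;
  bool converged = false;
  int it = 0;
  const double dnorm2 = accu(square(D));

  for (it = 1; it <= maxIter; ++it) {
    als_alternate(D, C, S, it == 1);
    sse = accu(square(D - C * S.t()));
    trace.push_back(sse);
    if (std::isfinite(ssePrev)) {
      double denom = std::max(ssePrev, datum::eps * std::max(dnorm2, 1.0));
      double rel = (ssePrev - sse) / denom;
      if (rel < tol) { converged = true; break; }
    } else if (sse <= tol * std::max(dnorm2, 1.0)) {
      converged = true;
      break;
    }
    ssePrev = sse;
  }
  if (it > maxIter) it = maxIter;

  return Rcpp::List::create(
    Rcpp::Named("C") = C,
    Rcpp::Named("S") = S,
    Rcpp::Named("residualSSE") = sse,
    Rcpp::Named("sseTrace") = trace,
    Rcpp::Named("nIter") = it,
    Rcpp::Named("converged") = converged);
}

//' Leaf-set signatures of every internal node of an hclust merge matrix
//'
//' Node i's signature is the comma-separated sorted list of leaf indices
//' under it. Used for bootstrap-probability counting.
//' @noRd
// [[Rcpp::export(name = ".treeSignatures")]]
Rcpp::CharacterVector treeSignatures(const Rcpp::IntegerMatrix& merge) {
  const int m = merge.nrow();
  std::vector< std::vector<int> > sets((size_t) m);
  Rcpp::CharacterVector out(m);
  for (int i = 0; i < m; ++i) {
    std::vector<int> s;
    for (int c = 0; c < 2; ++c) {
      int v = merge(i, c);
      if (v < 0) {
        s.push_back(-v);
      } else {
        const std::vector<int>& t = sets[(size_t)(v - 1)];
        s.insert(s.end(), t.begin(), t.end());
      }
    }
    std::sort(s.begin(), s.end());
    sets[(size_t) i] = s;
    std::string sig;
    sig.reserve(s.size() * 4);
    for (size_t t = 0; t < s.size(); ++t) {
      if (t) sig.push_back(',');
      sig += std::to_string(s[t]);
    }
    out[i] = sig;
  }
  return out;
}

//' Leaf index sets of every internal node of an hclust merge matrix
//' @noRd
// [[Rcpp::export(name = ".treeLeafSets")]]
Rcpp::List treeLeafSets(const Rcpp::IntegerMatrix& merge) {
  const int m = merge.nrow();
  std::vector< std::vector<int> > sets((size_t) m);
  Rcpp::List out(m);
  for (int i = 0; i < m; ++i) {
    std::vector<int> s;
    for (int c = 0; c < 2; ++c) {
      int v = merge(i, c);
      if (v < 0) {
        s.push_back(-v);
      } else {
        const std::vector<int>& t = sets[(size_t)(v - 1)];
        s.insert(s.end(), t.begin(), t.end());
      }
    }
    std::sort(s.begin(), s.end());
    sets[(size_t) i] = s;
    out[i] = Rcpp::IntegerVector(s.begin(), s.end());
  }
  return out;
}
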