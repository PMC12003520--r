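// Adaptive Gauss-Hermite marginal likelihoods for country-random-intercept
// binary and multinomial logit models, with analytic gradients in
// (beta, log sigma). Records must arrive sorted by cluster; cl_start/cl_size
// are 0-based offsets into the row dimension.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SIGMA_ZERO_TOL = 1e-10;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double log_dnorm(double x, double sd) {
  double z = x / sd;
  return -0.5 * std::log(2.0 * M_PI) - std::log(sd) - 0.5 * z * z;
}

static double logsumexp(const vec& v) {
  double m = v.max();
  return m + std::log(accu(exp(v - m)));
}

// ---------------------------------------------------------------------------
// Binary random-intercept logit
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_binary_loglik")]]
Rcpp::List cpp_binary_loglik(const arma::vec& y, const arma::mat& X,
                             const arma::uvec& cl_start,
                             const arma::uvec& cl_size,
                             const arma::vec& beta, double sigma,
                             const arma::vec& z, const arma::vec& w,
                             bool adaptive, bool want_grad) {
  const uword J = cl_start.n_elem, Q = z.n_elem, p = X.n_cols;
  // scores saturate; the clamp keeps log(1 - p) finite at separation-scale
  // coefficients (handled upstream by the separation diagnostic)
  vec eta = clamp(X * beta, -35.0, 35.0);
  double ll = 0.0;
  vec gbeta(p, fill::zeros);
  double glogsig = 0.0;

  if (sigma < SIGMA_ZERO_TOL) {            // exact pooled logit, no quadrature
    for (uword i = 0; i < y.n_elem; ++i)
      ll += y(i) * eta(i) - log1p_exp(eta(i));
    if (want_grad) {
      vec r = y - 1.0 / (1.0 + exp(-eta));
      gbeta = X.t() * r;
    }
    return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                              Rcpp::Named("grad_beta") = gbeta,
                              Rcpp::Named("grad_logsigma") = 0.0);
  }

  const double s2 = sigma * sigma;
  for (uword j = 0; j < J; ++j) {
    const uword a = cl_start(j), n = cl_size(j);
    vec ej = eta.subvec(a, a + n - 1);
    vec yj = y.subvec(a, a + n - 1);

    double mode = 0.0, H = -1.0 / s2;
    if (adaptive) {                        // Newton for the posterior mode
      for (int it = 0; it < 60; ++it) {
        vec pr = 1.0 / (1.0 + exp(-(ej + mode)));
        double g = accu(yj - pr) - mode / s2;
        H = -accu(pr % (1.0 - pr)) - 1.0 / s2;
        double step = g / H;
        mode -= step;
        if (std::abs(step) < 1e-11) break;
      }
    }
    double tau = adaptive ? 1.0 / std::sqrt(-H) : sigma;
    double centre = adaptive ? mode : 0.0;

    vec lt(Q), uq(Q);
    mat Pq(n, want_grad ? Q : 0);            // node probabilities, reused
    for (uword q = 0; q < Q; ++q) {
      double u = centre + M_SQRT2 * tau * z(q);
      uq(q) = u;
      vec eu = ej + u;
      double lj = 0.0;
      if (want_grad) {
        vec pr = 1.0 / (1.0 + exp(-eu));
        Pq.col(q) = pr;
        // log(1 - pr) = -log(1 + e^eu); valid to |eu| ~ 700
        lj = dot(yj, eu) + accu(log(1.0 - pr));
      } else {
        for (uword i = 0; i < n; ++i) lj += yj(i) * eu(i) - log1p_exp(eu(i));
      }
      lt(q) = std::log(w(q)) + z(q) * z(q) + 0.5 * std::log(2.0) +
              std::log(tau) + lj + log_dnorm(u, sigma);
    }
    double llj = logsumexp(lt);
    ll += llj;

    if (want_grad) {
      vec c = exp(lt - llj);
      vec r = yj * accu(c) - Pq * c;
      glogsig += dot(c, square(uq)) / s2 - accu(c);
      gbeta += X.rows(a, a + n - 1).t() * r;
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("grad_beta") = gbeta,
                            Rcpp::Named("grad_logsigma") = glogsig);
}

// ---------------------------------------------------------------------------
// Multinomial random-intercept logit (reference category = column 0 score 0)
// ---------------------------------------------------------------------------

// per-record log-likelihood at random-effect value u (3-vector)
static double mnl_cluster_ll(const mat& Eta, const ivec& yj, const vec& u) {
  double out = 0.0;
  const uword n = Eta.n_rows;
  for (uword i = 0; i < n; ++i) {
    double m = 0.0;                        // max score for stability
    double s0 = 0.0;
    for (uword k = 0; k < 3; ++k) m = std::max(m, Eta(i, k) + u(k));
    double denom = std::exp(s0 - m);
    for (uword k = 0; k < 3; ++k) denom += std::exp(Eta(i, k) + u(k) - m);
    double num = (yj(i) > 0) ? (Eta(i, yj(i) - 1) + u(yj(i) - 1)) : 0.0;
    out += num - m - std::log(denom);
  }
  return out;
}

// softmax probabilities (n x 4, col 0 = reference) at u
static mat mnl_probs(const mat& Eta, const vec& u) {
  const uword n = Eta.n_rows;
  mat P(n, 4);
  for (uword i = 0; i < n; ++i) {
    double m = 0.0;
    for (uword k = 0; k < 3; ++k) m = std::max(m, Eta(i, k) + u(k));
    double e0 = std::exp(-m), s = e0;
    vec ek(3);
    for (uword k = 0; k < 3; ++k) { ek(k) = std::exp(Eta(i, k) + u(k) - m); s += ek(k); }
    P(i, 0) = e0 / s;
    for (uword k = 0; k < 3; ++k) P(i, k + 1) = ek(k) / s;
  }
  return P;
}

// y: 0 = reference ("none"), 1..3 = non-reference categories.
// betas: p x 3 matrix; sigma: length-3 (per-category independent random
// intercepts). shared = true collapses to a single common intercept (sigma(0))
// added to all three non-reference scores, integrated in one dimension.
// The per-cluster quadrature sum is organised as matrix products: with
// B = exp(eta) (n x 3) and C = exp(U) over the node grid (nq x 3), all node
// denominators are the single GEMM 1 + B C'.
// [[Rcpp::export(name = ".cpp_mnl_loglik")]]
Rcpp::List cpp_mnl_loglik(const arma::ivec& y, const arma::mat& X,
                          const arma::uvec& cl_start,
                          const arma::uvec& cl_size,
                          const arma::mat& betas, const arma::vec& sigma,
                          const arma::vec& z, const arma::vec& w,
                          bool adaptive, bool shared, bool want_grad) {
  const uword J = cl_start.n_elem, Q = z.n_elem, p = X.n_cols;
  mat Eta = clamp(X * betas, -60.0, 60.0);   // n x 3; scores saturate anyway
  double ll = 0.0;
  mat gbeta(p, 3, fill::zeros);
  vec glogsig(3, fill::zeros);

  // active integration dimensions
  uvec act;
  if (shared) {
    act = (sigma(0) >= SIGMA_ZERO_TOL) ? uvec{0} : uvec{};
  } else {
    act = find(sigma >= SIGMA_ZERO_TOL);
  }
  const uword d = act.n_elem;

  // map a d-vector v of integration variables to the 3-vector u
  auto expand_u = [&](const vec& v) {
    vec u(3, fill::zeros);
    if (shared) { if (d == 1) u.fill(v(0)); }
    else for (uword k = 0; k < d; ++k) u(act(k)) = v(k);
    return u;
  };

  // tensor-product grid bookkeeping (depends only on d and Q)
  uword nq = 1;
  for (uword r = 0; r < d; ++r) nq *= Q;
  mat Zg(nq, d);                             // raw node combinations
  vec lw(nq, fill::zeros);                   // log weight + z^2 terms
  {
    uvec idx(d, fill::zeros);
    for (uword q = 0; q < nq; ++q) {
      for (uword r = 0; r < d; ++r) {
        Zg(q, r) = z(idx(r));
        lw(q) += std::log(w(idx(r))) + Zg(q, r) * Zg(q, r);
      }
      for (uword r = 0; r < d; ++r) {
        if (++idx(r) < Q) break;
        idx(r) = 0;
      }
    }
  }

  for (uword j = 0; j < J; ++j) {
    const uword a = cl_start(j), n = cl_size(j);
    mat Ej = Eta.rows(a, a + n - 1);
    mat Bx = exp(Ej);
    ivec yj = conv_to<ivec>::from(y.subvec(a, a + n - 1));
    mat ind(n, 3, fill::zeros);              // category indicators
    double obs_eta = 0.0;                    // sum of observed-category scores
    for (uword i = 0; i < n; ++i)
      if (yj(i) > 0) { ind(i, yj(i) - 1) = 1.0; obs_eta += Ej(i, yj(i) - 1); }
    vec nk = sum(ind, 0).t();                // counts per non-reference type

    if (d == 0) {                            // pooled multinomial logit
      vec denom = 1.0 + sum(Bx, 1);
      ll += obs_eta - accu(log(denom));
      if (want_grad) {
        mat P3 = Bx.each_col() / denom;
        gbeta += X.rows(a, a + n - 1).t() * (ind - P3);
      }
      continue;
    }

    // posterior mode in the d active dimensions; the log integrand is
    // strictly concave so Newton converges, step length capped
    vec v(d, fill::zeros);
    mat Hd(d, d);
    for (int it = 0; it < 100; ++it) {
      vec cu = exp(expand_u(v));
      vec denom = 1.0 + Bx * cu;
      mat P3 = Bx.each_col() / denom;        // n x 3 at current u
      for (uword k = 0; k < 3; ++k) P3.col(k) *= cu(k);
      vec g(d);
      Hd.zeros();
      if (shared) {
        vec psum = sum(P3, 1);
        g(0) = accu(nk) - accu(psum) - v(0) / (sigma(0) * sigma(0));
        Hd(0, 0) = -(accu(psum) - dot(psum, psum)) -
                   1.0 / (sigma(0) * sigma(0));
      } else {
        for (uword r = 0; r < d; ++r) {
          uword k = act(r);
          g(r) = nk(k) - accu(P3.col(k)) - v(r) / (sigma(k) * sigma(k));
          for (uword c = 0; c < d; ++c) {
            uword l = act(c);
            double hh = (k == l ? accu(P3.col(k)) : 0.0) -
                        dot(P3.col(k), P3.col(l));
            Hd(r, c) = -hh - (r == c ? 1.0 / (sigma(k) * sigma(k)) : 0.0);
          }
        }
      }
      // tiny ridge keeps the solve well posed when a category is flat
      for (uword r = 0; r < d; ++r)
        Hd(r, r) -= 1e-9 * (1.0 + std::abs(Hd(r, r)));
      // equilibrate: 1/sigma^2 terms can differ by many orders of magnitude
      vec dsc = sqrt(abs(Hd.diag()));
      mat Hs = Hd;
      Hs.each_col() /= dsc;
      Hs.each_row() /= dsc.t();
      vec step = solve(Hs, g / dsc) / dsc;
      double sn = norm(step, "inf");
      if (sn > 5.0) step *= 5.0 / sn;
      v -= step;
      if (norm(step, "inf") < 1e-11) break;
    }

    mat L;
    vec centre(d, fill::zeros);
    if (adaptive) {
      vec dsc = sqrt(abs(Hd.diag()));
      mat Hs = -Hd;
      Hs.each_col() /= dsc;
      Hs.each_row() /= dsc.t();
      mat Ln = chol(inv_sympd(Hs), "lower");
      L = Ln.each_col() / dsc;               // chol of inv(-Hd), lower
      centre = v;
    } else {
      L.zeros(d, d);
      for (uword r = 0; r < d; ++r) L(r, r) = sigma(shared ? 0 : act(r));
    }
    double logdetL = accu(log(L.diag()));

    // all nodes at once: V (nq x d) in integration space, U3 (nq x 3)
    mat V = (Zg * (M_SQRT2 * L.t())).eval();
    V.each_row() += centre.t();
    mat U3(nq, 3, fill::zeros);
    for (uword r = 0; r < d; ++r) {
      if (shared) { for (uword k = 0; k < 3; ++k) U3.col(k) = V.col(0); }
      else U3.col(act(r)) = V.col(r);
    }
    vec lphi(nq, fill::zeros);
    for (uword r = 0; r < d; ++r) {
      double sg = sigma(shared ? 0 : act(r));
      lphi += -0.5 * std::log(2.0 * M_PI) - std::log(sg) -
              0.5 * square(V.col(r)) / (sg * sg);
    }
    mat C = exp(clamp(U3, -300.0, 300.0));   // nq x 3
    mat D = 1.0 + Bx * C.t();                // n x nq: all denominators
    vec slog = sum(log(D), 0).t();           // nq
    vec lt = lw + 0.5 * d * std::log(2.0) + logdetL + obs_eta +
             U3 * nk + lphi - slog;
    double llj = logsumexp(lt);
    ll += llj;

    if (want_grad) {
      vec c = exp(lt - llj);
      mat T = C.each_col() % c;              // nq x 3
      mat S = (1.0 / D) * T;                 // n x 3: sum_q c_q p_ikq / B_ik
      mat R = ind - Bx % S;
      gbeta += X.rows(a, a + n - 1).t() * R;
      for (uword r = 0; r < d; ++r) {
        uword k = shared ? 0 : act(r);
        double s2 = sigma(k) * sigma(k);
        glogsig(k) += dot(c, square(V.col(r))) / s2 - 1.0;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("grad_beta") = gbeta,
                            Rcpp::Named("grad_logsigma") = glogsig);
}

// ---------------------------------------------------------------------------
// Population-averaged (marginal over random intercept) predictions
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_predict_binary_marg")]]
arma::vec cpp_predict_binary_marg(const arma::vec& eta, double sigma,
                                  const arma::vec& z, const arma::vec& w) {
  const uword n = eta.n_elem, Q = z.n_elem;
  vec out(n, fill::zeros);
  if (sigma < SIGMA_ZERO_TOL) {
    for (uword i = 0; i < n; ++i) out(i) = 1.0 / (1.0 + std::exp(-eta(i)));
    return out;
  }
  double wsum = accu(w);
  for (uword q = 0; q < Q; ++q) {
    double u = M_SQRT2 * sigma * z(q);
    for (uword i = 0; i < n; ++i)
      out(i) += w(q) * (1.0 / (1.0 + std::exp(-(eta(i) + u))));
  }
  return out / wsum;                       // weights sum to sqrt(pi)
}

// [[Rcpp::export(name = ".cpp_predict_mnl_marg")]]
arma::mat cpp_predict_mnl_marg(const arma::mat& Eta, const arma::vec& sigma,
                               const arma::vec& z, const arma::vec& w,
                               bool shared) {
  const uword n = Eta.n_rows, Q = z.n_elem;
  mat out(n, 4, fill::zeros);

  uvec act;
  if (shared) act = (sigma(0) >= SIGMA_ZERO_TOL) ? uvec{0} : uvec{};
  else act = find(sigma >= SIGMA_ZERO_TOL);
  const uword d = act.n_elem;

  if (d == 0) return mnl_probs(Eta, vec(3, fill::zeros));

  uword nq = 1;
  for (uword r = 0; r < d; ++r) nq *= Q;
  uvec idx(d, fill::zeros);
  double wtot = 0.0;
  for (uword q = 0; q < nq; ++q) {
    double wt = 1.0;
    vec u(3, fill::zeros);
    for (uword r = 0; r < d; ++r) {
      wt *= w(idx(r));
      double ur = M_SQRT2 * sigma(shared ? 0 : act(r)) * z(idx(r));
      if (shared) u.fill(ur); else u(act(r)) = ur;
    }
    out += wt * mnl_probs(Eta, u);
    wtot += wt;
    for (uword r = 0; r < d; ++r) {
      if (++idx(r) < Q) break;
      idx(r) = 0;
    }
  }
  return out / wtot;
}
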