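// Marginal maximum likelihood EM for the simplified 3PL (discrimination 1,
// fixed guessing) and its bifactor extension with a single equality-constrained
// event-specific trait variance.
//
// The latent trait is integrated over a fixed, equally spaced quadrature grid;
// the normal prior enters through normalised weights re-evaluated at the
// current variance, so the discretised model is constant across EM iterations
// and the marginal log-likelihood is monotone by construction.
//
// Layout note: person-indexed arrays are kept column-per-person (and
// pattern-indexed arrays column-per-pattern) so all inner loops run over
// contiguous memory without temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// normalised log prior weights of N(0, sigma^2) on a fixed grid
static vec norm_log_prior(const vec& nodes, double sigma) {
  vec lw = -0.5 * square(nodes / sigma);
  double m = lw.max();
  lw -= m + std::log(accu(exp(lw - m)));
  return lw;
}

// log(sum(exp(x))) over a contiguous block, no allocation
static inline double lse(const double* x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// item response probability on the grid: P(j,q) = c + (1-c) logistic(node_q - beta_j)
// logistic(node - beta) = 1 / (1 + e^{-node} e^{beta}): the exponentials are
// precomputed per node and per item, so the grid fill is transcendental-free.
static void prob_matrix(const vec& beta, const vec& nodes, double c, mat& P) {
  const int J = beta.n_elem, Q = nodes.n_elem;
  vec eneg = exp(-nodes), eb = exp(beta);
  for (int q = 0; q < Q; ++q) {
    double* col = P.colptr(q);
    double en = eneg(q);
    for (int j = 0; j < J; ++j)
      col[j] = c + (1.0 - c) / (1.0 + en * eb(j));
  }
}

// expected complete-data log-likelihood of item j at difficulty b
static double item_q(double b, const double* r, const double* nn,
                     const vec& nodes, double c) {
  double s = 0.0;
  for (unsigned q = 0; q < nodes.n_elem; ++q) {
    double x = nodes(q) - b;
    double L = 1.0 / (1.0 + std::exp(-x));
    double P = c + (1.0 - c) * L;
    s += r[q] * std::log(P) + (nn[q] - r[q]) * std::log1p(-P);
  }
  return s;
}

// golden-section maximisation of item_q over [lo, hi]
static double golden_item(const double* r, const double* nn, const vec& nodes,
                          double c, double lo, double hi) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = item_q(x1, r, nn, nodes, c), f2 = item_q(x2, r, nn, nodes, c);
  while (b - a > 1e-7) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = item_q(x2, r, nn, nodes, c);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = item_q(x1, r, nn, nodes, c);
    }
  }
  return 0.5 * (a + b);
}

// M-step for all difficulties. r, nn are Q x J (column per item): expected
// correct counts and exposures on the grid. Vectorised Fisher scoring with a
// golden-section fallback that guarantees ascent item by item.
static void update_beta(vec& beta, const mat& r, const mat& nn,
                        const vec& nodes, double c, double bound) {
  const int J = beta.n_elem, Q = nodes.n_elem;
  vec beta_start = beta;
  const double omc = 1.0 - c;
  vec eneg = exp(-nodes);
  bool clean = false;
  for (int it = 0; it < 12; ++it) {
    double max_step = 0.0;
    for (int j = 0; j < J; ++j) {
      const double* rj = r.colptr(j);
      const double* nj = nn.colptr(j);
      double eb = std::exp(beta(j));
      double g1 = 0.0, info = 0.0;
      for (int q = 0; q < Q; ++q) {
        double P = c + omc / (1.0 + eneg(q) * eb);
        double Pc = P - c;
        g1 -= (rj[q] - nj[q] * P) * Pc / (omc * P);
        info += nj[q] * Pc * Pc * (1.0 - P) / (omc * omc * P);
      }
      double step = g1 / (info + 1e-12);
      if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
      beta(j) += step;
      if (beta(j) > bound) beta(j) = bound;
      else if (beta(j) < -bound) beta(j) = -bound;
      if (std::fabs(step) > max_step) max_step = std::fabs(step);
    }
    if (max_step < 1e-8) { clean = true; break; }
  }
  if (!clean)   // scoring hit its cap: verify ascent item by item
    for (int j = 0; j < J; ++j) {
      double q0 = item_q(beta_start(j), r.colptr(j), nn.colptr(j), nodes, c);
      double q1 = item_q(beta(j), r.colptr(j), nn.colptr(j), nodes, c);
      if (q1 < q0 - 1e-10)
        beta(j) = golden_item(r.colptr(j), nn.colptr(j), nodes, c, -bound, bound);
    }
}

// golden-section maximisation of sum_q w_q log pi_q(sigma) over sigma
static double golden_sigma(const vec& w, const vec& nodes,
                           double lo, double hi) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  auto f = [&](double s) { return dot(w, norm_log_prior(nodes, s)); };
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > 1e-6) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = f(x1);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
Rcpp::List em_unidimensional(const arma::mat& A, const arma::mat& M,
                             double guess, int n_quad, double theta_lim,
                             double tol, int max_iter, double beta_bound,
                             arma::vec beta, double sigma) {
  const int N = A.n_rows, J = A.n_cols;
  const int Q = n_quad;
  vec nodes = linspace<vec>(-theta_lim, theta_lim, Q);
  mat At = A.t();                                // J x N
  mat Mt = M.t();
  mat P(J, Q), logP(J, Q), log1mP(J, Q);
  std::vector<double> trace;
  bool converged = false;
  int iter = 0;
  mat Wt(Q, N);                                  // posterior, column per person
  vec ll_i(N);

  auto e_step = [&]() {
    prob_matrix(beta, nodes, guess, P);
    logP = log(P);
    log1mP = log(1.0 - P);
    Wt = logP.t() * At + log1mP.t() * (Mt - At); // Q x N
    vec lpi = norm_log_prior(nodes, sigma);
    for (int i = 0; i < N; ++i) {
      double* col = Wt.colptr(i);
      for (int q = 0; q < Q; ++q) col[q] += lpi(q);
      double l = lse(col, Q);
      ll_i(i) = l;
      for (int q = 0; q < Q; ++q) col[q] = std::exp(col[q] - l);
    }
    return accu(ll_i);
  };

  mat r(Q, J), nn(Q, J);
  for (iter = 1; iter <= max_iter; ++iter) {
    double ll = e_step();
    trace.push_back(ll);
    r = Wt * A;                                  // Q x J expected correct
    nn = Wt * M;                                 // Q x J expected exposure
    vec beta_old = beta;
    double sigma_old = sigma;
    update_beta(beta, r, nn, nodes, guess, beta_bound);
    vec nq = sum(Wt, 1);
    sigma = golden_sigma(nq, nodes, 0.01, 6.0);
    double delta = std::max(abs(beta - beta_old).max(),
                            std::fabs(sigma - sigma_old));
    if (delta < tol) { converged = true; break; }
  }
  double ll_final = e_step();                    // at converged parameters
  trace.push_back(ll_final);

  vec eap = Wt.t() * nodes;
  vec m2 = Wt.t() * square(nodes);
  vec psd = sqrt(clamp(m2 - square(eap), 0.0, datum::inf));

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("sigma2") = sigma * sigma,
    Rcpp::Named("loglik") = ll_final,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("eap") = eap,
    Rcpp::Named("psd") = psd);
}

// Bifactor EM with dimension reduction: outer quadrature over the general
// trait, an independent inner quadrature per event over the specific trait.
// Complete data only; persons enter the E-step through their per-event
// response patterns (at most 2^(items per event) distinct ones).
// [[Rcpp::export]]
Rcpp::List em_bifactor(const arma::umat& U, const arma::ivec& item_event,
                       double guess, int n_quad_g, double lim_g,
                       int n_quad_s, double lim_s,
                       double tol, int max_iter, double beta_bound,
                       arma::vec beta, double sigma_g, double sigma_s) {
  const int N = U.n_rows, J = U.n_cols;
  const int E = item_event.max() + 1;
  const int Qg = n_quad_g, Qs = n_quad_s, QQ = Qg * Qs;

  std::vector<std::vector<int>> ev_items(E);
  for (int j = 0; j < J; ++j) ev_items[item_event(j)].push_back(j);
  for (int e = 0; e < E; ++e) {
    if (ev_items[e].size() < 2)
      Rcpp::stop("each event needs at least two items");
    if (ev_items[e].size() > 12)
      Rcpp::stop("more than 12 items per event is not supported");
  }

  vec tg = linspace<vec>(-lim_g, lim_g, Qg);
  vec ts = linspace<vec>(-lim_s, lim_s, Qs);
  vec s_flat(QQ);                                // combined trait grid
  for (int q = 0; q < Qg; ++q)
    for (int r = 0; r < Qs; ++r) s_flat(q * Qs + r) = tg(q) + ts(r);

  // response pattern per person x event
  umat Pat(N, E);
  for (int i = 0; i < N; ++i)
    for (int e = 0; e < E; ++e) {
      unsigned p = 0;
      for (size_t k = 0; k < ev_items[e].size(); ++k)
        p |= (U(i, ev_items[e][k]) & 1u) << k;
      Pat(i, e) = p;
    }

  mat Pall(J, QQ), logPall(J, QQ), log1mPall(J, QQ);
  std::vector<double> trace;
  bool converged = false;
  int iter = 0;
  mat Wt(Qg, N);                                 // outer posterior, col/person
  vec ll_i(N), nq(Qg), nv(Qs);
  mat rj(QQ, J), nj(QQ, J);                      // col per item
  std::vector<mat> logB(E), Me(E);               // col per pattern

  // per-event pattern log-likelihood tables on the (theta, eta) grid;
  // depend on beta only.  logB[e] is QQ x NP, column per pattern.
  auto compute_logB = [&]() {
    prob_matrix(beta, s_flat, guess, Pall);
    logPall = log(Pall);
    log1mPall = log(1.0 - Pall);
    mat logPt = logPall.t();                     // QQ x J, col per item
    mat log1mPt = log1mPall.t();
    for (int e = 0; e < E; ++e) {
      const int ne = ev_items[e].size(), NP = 1 << ne;
      logB[e].zeros(QQ, NP);
      for (int p = 0; p < NP; ++p) {
        double* col = logB[e].colptr(p);
        for (int k = 0; k < ne; ++k) {
          const double* src = ((p >> k) & 1) ? logPt.colptr(ev_items[e][k])
                                             : log1mPt.colptr(ev_items[e][k]);
          for (int x = 0; x < QQ; ++x) col[x] += src[x];
        }
      }
    }
  };

  std::vector<double> buf(Qs);
  // integrate the inner trait out: Me[e](q, p) = log sum_r v_r B_e(p, q, r)
  auto compute_Me = [&](const vec& lvs) {
    for (int e = 0; e < E; ++e) {
      const int NP = logB[e].n_cols;
      Me[e].set_size(Qg, NP);
      for (int p = 0; p < NP; ++p) {
        const double* col = logB[e].colptr(p);
        for (int q = 0; q < Qg; ++q) {
          const double* seg = col + q * Qs;
          for (int r = 0; r < Qs; ++r) buf[r] = seg[r] + lvs(r);
          Me[e](q, p) = lse(buf.data(), Qs);
        }
      }
    }
  };

  // marginal log-likelihood (and posterior Wt) at (sg, ss); Me must be fresh
  auto outer_ll = [&](double sg, bool want_post) {
    vec lpg = norm_log_prior(tg, sg);
    double total = 0.0;
    for (int i = 0; i < N; ++i) {
      double* col = Wt.colptr(i);
      for (int q = 0; q < Qg; ++q) col[q] = lpg(q);
      for (int e = 0; e < E; ++e) {
        const double* me = Me[e].colptr(Pat(i, e));
        for (int q = 0; q < Qg; ++q) col[q] += me[q];
      }
      double l = lse(col, Qg);
      ll_i(i) = l;
      total += l;
      if (want_post)
        for (int q = 0; q < Qg; ++q) col[q] = std::exp(col[q] - l);
    }
    return total;
  };

  // accumulate expected counts given a fresh posterior Wt
  auto accumulate = [&](const vec& lvs) {
    nq = sum(Wt, 1);
    nv.zeros();
    rj.zeros();
    nj.zeros();
    std::vector<double> cseg(Qs);
    for (int e = 0; e < E; ++e) {
      const int ne = ev_items[e].size(), NP = logB[e].n_cols;
      mat Ge(Qg, NP, fill::zeros);
      for (int i = 0; i < N; ++i) {
        double* g = Ge.colptr(Pat(i, e));
        const double* w = Wt.colptr(i);
        for (int q = 0; q < Qg; ++q) g[q] += w[q];
      }
      for (int p = 0; p < NP; ++p) {
        double mass = accu(Ge.col(p));
        if (mass <= 0.0) continue;
        const double* bcol = logB[e].colptr(p);
        const double* gcol = Ge.colptr(p);
        for (int q = 0; q < Qg; ++q) {
          if (gcol[q] <= 0.0) continue;
          const double* seg = bcol + q * Qs;
          double me = Me[e](q, p);
          double g = gcol[q];
          for (int r = 0; r < Qs; ++r) {
            double cval = g * std::exp(seg[r] + lvs(r) - me);
            cseg[r] = cval;
            nv(r) += cval;
          }
          for (int k = 0; k < ne; ++k) {
            int j = ev_items[e][k];
            double* njc = nj.colptr(j) + q * Qs;
            for (int r = 0; r < Qs; ++r) njc[r] += cseg[r];
            if ((p >> k) & 1) {
              double* rjc = rj.colptr(j) + q * Qs;
              for (int r = 0; r < Qs; ++r) rjc[r] += cseg[r];
            }
          }
        }
      }
    }
  };

  // golden-section maximisation of the profile marginal log-likelihood in
  // sigma_s at the current beta and sigma_g; jumps over the slow EM crawl
  // that variance components exhibit near the boundary.  logB must be fresh.
  auto profile_sigma_s = [&]() {
    const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
    auto f = [&](double s) {
      compute_Me(norm_log_prior(ts, s));
      return outer_ll(sigma_g, false);
    };
    double a = 1e-3, b = 2.5;
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = f(x1), f2 = f(x2);
    while (b - a > 1e-4) {
      if (f1 < f2) {
        a = x1; x1 = x2; f1 = f2; x2 = a + gr * (b - a); f2 = f(x2);
      } else {
        b = x2; x2 = x1; f2 = f1; x1 = b - gr * (b - a); f1 = f(x1);
      }
    }
    double mid = 0.5 * (a + b);
    if (f(mid) >= f(sigma_s)) sigma_s = mid;
  };

  for (iter = 1; iter <= max_iter; ++iter) {
    compute_logB();
    if (iter % 10 == 1) profile_sigma_s();
    vec lvs = norm_log_prior(ts, sigma_s);
    compute_Me(lvs);
    double ll = outer_ll(sigma_g, true);
    trace.push_back(ll);
    accumulate(lvs);
    vec beta_old = beta;
    double sg_old = sigma_g, ss_old = sigma_s;
    update_beta(beta, rj, nj, s_flat, guess, beta_bound);
    sigma_g = golden_sigma(nq, tg, 0.01, 6.0);
    sigma_s = golden_sigma(nv, ts, 1e-3, 2.5);
    double delta = std::max({abs(beta - beta_old).max(),
                             std::fabs(sigma_g - sg_old),
                             std::fabs(sigma_s - ss_old)});
    if (delta < tol) { converged = true; break; }
  }
  compute_logB();
  profile_sigma_s();
  compute_Me(norm_log_prior(ts, sigma_s));
  double ll_final = outer_ll(sigma_g, false);
  trace.push_back(ll_final);

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("sigma2_general") = sigma_g * sigma_g,
    Rcpp::Named("sigma2_specific") = sigma_s * sigma_s,
    Rcpp::Named("loglik") = ll_final,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
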