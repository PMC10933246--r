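// Prior-knowledge time-domain fitting of damped complex exponentials.
// Model per voxel: y(t) = sum_k a_k * exp(i*(2*pi*f_k*t + phi)) * exp(-d_k*t)
// with one zero-order phase phi shared by all resonances.
// Parameter vector: [a_1..a_K, f_1..f_K, d_1..d_K, phi], P = 3K+1.
// Bounded Levenberg-Marquardt on the stacked real/imaginary residuals with
// an analytic Jacobian; box constraints handled by projection.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void eval_model(const vec& par, const vec& t, int K,
                       cx_vec& y, mat* J) {
  const int N = t.n_elem;
  y.zeros(N);
  const double phi = par(3 * K);
  for (int k = 0; k < K; ++k) {
    const double a = par(k), f = par(K + k), d = par(2 * K + k);
    vec env = exp(-d * t);
    vec ang = 2.0 * datum::pi * f * t + phi;
    vec c = env % cos(ang);
    vec s = env % sin(ang);
    y += cx_vec(a * c, a * s);
    if (J) {
      J->col(k).rows(0, N - 1) = c;
      J->col(k).rows(N, 2 * N - 1) = s;
      J->col(K + k).rows(0, N - 1) = -2.0 * datum::pi * a * (t % s);
      J->col(K + k).rows(N, 2 * N - 1) = 2.0 * datum::pi * a * (t % c);
      J->col(2 * K + k).rows(0, N - 1) = -a * (t % c);
      J->col(2 * K + k).rows(N, 2 * N - 1) = -a * (t % s);
    }
  }
  if (J) {
    J->col(3 * K).rows(0, N - 1) = -imag(y);
    J->col(3 * K).rows(N, 2 * N - 1) = real(y);
  }
}

static double cost_of(const cx_vec& y, const cx_vec& fid) {
  cx_vec r = fid - y;
  return accu(square(real(r))) + accu(square(imag(r)));
}

// elementwise box projection (arma::clamp only takes scalar bounds)
static vec clamp_par(const vec& p, const vec& lb, const vec& ub) {
  return arma::min(arma::max(p, lb), ub);
}

// [[Rcpp::export]]
Rcpp::List fit_fids_cpp(const arma::cx_mat& fids,      // N x V
                        const arma::vec& t,            // N
                        const arma::vec& f0,           // K init frequencies
                        const arma::vec& d0,           // K init dampings
                        const arma::vec& lb,           // P lower bounds
                        const arma::vec& ub,           // P upper bounds
                        const int max_iter,
                        const double tol,
                        const double tail_frac) {
  const int N = fids.n_rows, V = fids.n_cols, K = f0.n_elem;
  const int P = 3 * K + 1;
  mat amp(V, K), freq(V, K), damp(V, K), crlb_unit(V, K);
  vec phase(V), sigma(V), resid(V), init_resid(V);
  ivec converged(V), niter(V);

  // basis at the prior initial values, for the linear amplitude init
  cx_mat B(N, K);
  for (int k = 0; k < K; ++k) {
    B.col(k) = exp(cx_vec(-d0(k) * t, 2.0 * datum::pi * f0(k) * t));
  }

  const int ntail = std::max(4, (int)std::floor(tail_frac * N));

  for (int v = 0; v < V; ++v) {
    cx_vec fid = fids.col(v);
    // noise sd per real/imag channel from the FID tail
    vec tail_re = real(fid.tail(ntail)), tail_im = imag(fid.tail(ntail));
    double sg = std::sqrt((var(tail_re) + var(tail_im)) / 2.0);
    sigma(v) = sg;

    if (norm(fid, "inf") == 0.0) {
      amp.row(v).zeros(); freq.row(v) = f0.t(); damp.row(v) = d0.t();
      phase(v) = 0.0; resid(v) = 0.0; init_resid(v) = 0.0;
      crlb_unit.row(v).fill(datum::inf);
      converged(v) = 0; niter(v) = 0;
      continue;
    }

    // linear init: complex LS amplitudes on the prior basis
    cx_vec c;
    bool ok = solve(c, B, fid);
    if (!ok) c.zeros(K);
    cx_double wsum(0, 0);
    for (int k = 0; k < K; ++k) wsum += c(k) * std::abs(c(k));
    double phi0 = (std::abs(wsum) > 0) ? std::arg(wsum) : 0.0;

    vec par(P);
    for (int k = 0; k < K; ++k) {
      double a0 = std::real(c(k) * std::exp(cx_double(0, -phi0)));
      par(k) = std::max(a0, 1e-8);
      par(K + k) = f0(k);
      par(2 * K + k) = d0(k);
    }
    par(P - 1) = phi0;
    par = clamp_par(par, lb, ub);

    cx_vec y;
    mat J(2 * N, P);
    eval_model(par, t, K, y, &J);
    double cost = cost_of(y, fid);
    init_resid(v) = cost;
    // Levenberg-Marquardt with Nielsen's gain-ratio damping update
    double lambda = 1e-3, nu = 2.0;
    int it = 0;
    bool conv = false;
    vec r2(2 * N);
    const int plateau_win = 10;
    double plateau_ref = cost;
    while (it < max_iter) {
      ++it;
      cx_vec rr = fid - y;
      r2.rows(0, N - 1) = real(rr);
      r2.rows(N, 2 * N - 1) = imag(rr);
      vec g = J.t() * r2;
      mat A = J.t() * J;
      // active set: freeze parameters pinned at a bound whose gradient
      // points outward (classic projected Newton), and the frequency /
      // damping of any resonance whose amplitude is frozen at zero
      uvec free = find((par > lb || g > 0) && (par < ub || g < 0));
      std::vector<unsigned> keep;
      for (unsigned ii = 0; ii < free.n_elem; ++ii) {
        int j = free(ii);
        if (j >= K && j < 3 * K) {
          int kres = (j - K) % K;
          if (par(kres) <= lb(kres) && g(kres) <= 0) continue;
        }
        keep.push_back(j);
      }
      free = conv_to<uvec>::from(keep);
      if (free.n_elem == 0) { conv = true; break; }
      mat Af = A.submat(free, free);
      vec gf = g.elem(free);
      vec dA = Af.diag();
      double floor_d = 1e-14 * (dA.max() + 1e-300);
      dA = arma::clamp(dA, floor_d, datum::inf);
      bool improved = false;
      for (int tries = 0; tries < 60; ++tries) {
        mat Areg = Af;
        Areg.diag() = Af.diag() + lambda * dA;
        vec stepf;
        if (!solve(stepf, Areg, gf, solve_opts::no_approx)) {
          lambda *= nu; nu *= 2.0;
          continue;
        }
        vec step(P, fill::zeros);
        step.elem(free) = stepf;
        vec cand = clamp_par(par + step, lb, ub);
        cx_vec ycand;
        eval_model(cand, t, K, ycand, nullptr);
        double ccand = cost_of(ycand, fid);
        if (ccand < cost) {
          double rel = (cost - ccand) / std::max(cost, 1e-300);
          vec h = cand - par;  // actual (possibly clamped) step
          vec hf = h.elem(free);
          double pred = dot(hf, gf) + lambda * dot(hf, dA % hf);
          double rho = pred > 0 ? (cost - ccand) / pred : 1.0;
          double shrink = 1.0 - std::pow(2.0 * rho - 1.0, 3);
          lambda = std::max(lambda * std::max(1.0 / 3.0, shrink), 1e-12);
          nu = 2.0;
          par = cand;
          cost = ccand;
          eval_model(par, t, K, y, &J);
          improved = true;
          if (rel < tol) conv = true;
          break;
        }
        lambda *= nu; nu *= 2.0;
        if (lambda > 1e14) break;
      }
      if (!improved) { conv = true; break; }  // stalled at a (bound) minimum
      // plateau: negligible total progress over a window of iterations
      if (!conv && it % plateau_win == 0) {
        if (plateau_ref - cost < 1e-6 * std::max(cost, 1e-300)) conv = true;
        plateau_ref = cost;
      }
      if (conv) break;
    }
    niter(v) = it;
    converged(v) = conv ? 1 : 0;
    resid(v) = cost;

    for (int k = 0; k < K; ++k) {
      amp(v, k) = par(k);
      freq(v, k) = par(K + k);
      damp(v, k) = par(2 * K + k);
    }
    phase(v) = par(P - 1);

    // CRLB per unit noise sd: sqrt(diag(inv(J^T J))) for the amplitudes
    mat A = J.t() * J;
    mat Ainv;
    if (inv_sympd(Ainv, A) || pinv(Ainv, A)) {
      for (int k = 0; k < K; ++k) {
        double d = Ainv(k, k);
        crlb_unit(v, k) = d > 0 ? std::sqrt(d) : datum::inf;
      }
    } else {
      crlb_unit.row(v).fill(datum::inf);
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("amplitude") = amp,
    Rcpp::Named("frequency_hz") = freq,
    Rcpp::Named("damping") = damp,
    Rcpp::Named("phase_rad") = phase,
    Rcpp::Named("crlb_unit") = crlb_unit,
    Rcpp::Named("sigma_tail") = sigma,
    Rcpp::Named("residual") = resid,
    Rcpp::Named("initial_residual") = init_resid,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = niter);
}
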