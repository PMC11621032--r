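// Stochastic variational inference engine for the circular (and interval)
// manifold count models.  The model factorizes into two stages:
//   manifold learning : S_cg ~ NB(exp(zeta(phi_c) . nu_g + dnu_bg), alpha_s)
//   velocity learning : U_cg ~ NB((s_g(phi)/beta_g) relu(omega(phi) dlogs + gamma_g), alpha_u)
// Both stages are fit by maximizing a single-sample reparameterized ELBO with
// Adam (optional per-block gradient-norm clipping, geometrically decaying
// learning rate).
// Dispersion parameters use Dirac-delta (MAP) guides; their NB gradients use
// per-gene tables of distinct counts so no per-entry digamma is needed.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat fill_randn(uword nr, uword nc) {
  mat X(nr, nc);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      X(i, j) = R::norm_rand();
  return X;
}

static vec fill_randn_v(uword n) {
  vec x(n);
  for (uword i = 0; i < n; ++i) x(i) = R::norm_rand();
  return x;
}

// design matrix of the circular Fourier basis and its phase derivative
static void fourier_design(const vec& phi, int k, mat& Z, mat& Zd) {
  const uword n = phi.n_elem;
  Z.set_size(n, 2 * k + 1);
  Zd.set_size(n, 2 * k + 1);
  Z.col(0).ones();
  Zd.col(0).zeros();
  for (int h = 1; h <= k; ++h) {
    vec ch = cos(h * phi), sh = sin(h * phi);
    Z.col(2 * h - 1) = ch;
    Z.col(2 * h) = sh;
    Zd.col(2 * h - 1) = -h * sh;
    Zd.col(2 * h) = h * ch;
  }
}

// Per-gene tables of distinct observed counts.  For integer-like counts,
//   sum_c [lgamma(x_cg + r) - lgamma(r)]  and the digamma analogue
// collapse to sums over distinct values, which is much cheaper than
// elementwise special functions inside the optimization loop.
struct CountTables {
  std::vector< std::vector< std::pair<double,double> > > tab; // (value, freq)
  void build(const mat& X) {
    tab.resize(X.n_cols);
    for (uword j = 0; j < X.n_cols; ++j) {
      std::map<double,double> m;
      for (uword i = 0; i < X.n_rows; ++i) {
        double v = X(i, j);
        if (v > 0) m[v] += 1.0;
      }
      tab[j].assign(m.begin(), m.end());
    }
  }
  double lgam(uword j, double r) const {
    double s = 0.0, lr = R::lgammafn(r);
    for (const auto& p : tab[j]) s += p.second * (R::lgammafn(p.first + r) - lr);
    return s;
  }
  double digam(uword j, double r) const {
    double s = 0.0, dr = R::digamma(r);
    for (const auto& p : tab[j]) s += p.second * (R::digamma(p.first + r) - dr);
    return s;
  }
};

struct Adam {
  mat m, v;
  int t = 0;
  void init(uword nr, uword nc) { m.zeros(nr, nc); v.zeros(nr, nc); }
  // Gradient ascent step on x (maximize ELBO). Clipping rescales the whole
  // gradient block to the given L2 norm: elementwise clamping of stochastic
  // gradients biases their mean (count gradients are heavily skewed) and was
  // observed to collapse the velocity scale, while norm clipping preserves
  // the direction.
  void step(mat& x, mat g, double lr, double clip) {
    double nrm = norm(g, "fro");
    if (nrm > clip) g *= clip / nrm;
    ++t;
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * square(g);
    x += lr * (m / (1.0 - std::pow(0.9, t))) /
         (sqrt(v / (1.0 - std::pow(0.999, t))) + 1e-8);
  }
};

// ----------------------------------------------------------------------------
// Manifold learning (also used, with a fixed precomputed basis, for the
// B-spline interval model's geometry stage)
// ----------------------------------------------------------------------------

struct ManifoldProb {
  mat S;            // cells x genes
  uvec batch;       // 0-based batch index per cell
  int nb, k, F;
  mat prior_mu, prior_sd;   // genes x F (nu prior)
  mat prior_xy;             // cells x 2
  bool learn_phi, learn_nu, fixed_basis;
  vec phi_fixed;
  mat Zfix, Zdfix;
  mat nu_fixed;
  CountTables tabs;
  std::vector<uvec> bidx;   // cells per batch
};

struct ManifoldPar {
  mat l;        // cells x 2 variational location of phi_xy
  mat m_nu, ls_nu; // genes x F
  vec la;       // log alpha_s per gene
  mat dnu;      // nb x genes, row 0 pinned at zero
};

struct ManifoldGrad {
  mat l, m_nu, ls_nu, dnu;
  vec la;
};

static double manifold_step(const ManifoldProb& P, const ManifoldPar& par,
                            const mat& eps_xy, const mat& eps_nu,
                            ManifoldGrad& gr, bool want_value,
                            bool want_alpha) {
  const uword nc = P.S.n_rows, ng = P.S.n_cols;

  // latent draws
  mat xy;
  vec phi;
  mat Z, Zd;
  if (P.fixed_basis) {
    Z = P.Zfix; Zd = P.Zdfix;
  } else if (P.learn_phi) {
    xy = par.l + eps_xy;
    phi = atan2(xy.col(1), xy.col(0));
    fourier_design(phi, P.k, Z, Zd);
  } else {
    phi = P.phi_fixed;
    fourier_design(phi, P.k, Z, Zd);
  }

  mat nu, s_nu;
  if (P.learn_nu) {
    s_nu = exp(par.ls_nu);
    nu = par.m_nu + s_nu % eps_nu;
  } else {
    nu = P.nu_fixed;
  }

  mat logmu = Z * nu.t();
  if (P.nb > 1)
    for (uword c = 0; c < nc; ++c)
      if (P.batch(c) > 0) logmu.row(c) += par.dnu.row(P.batch(c));
  logmu = clamp(logmu, -25.0, 25.0);
  mat mu = exp(logmu);

  rowvec r = exp(-par.la.t());        // NB size = 1/alpha
  rowvec alpha = exp(par.la.t());

  mat denom = mu; denom.each_row() += r;
  mat T = P.S; T.each_row() += r; T /= denom;   // (S + r)/(r + mu)
  mat D = P.S - mu % T;                          // d loglik / d logmu

  // value and dispersion gradient need per-entry log(r + mu); both are
  // requested only periodically by the SVI loop
  double elbo = 0.0;
  if (want_value || want_alpha) {
    mat Lden = log(denom);
    rowvec colLden = sum(Lden, 0);
    if (want_value) {
      double ll = 0.0;
      for (uword j = 0; j < ng; ++j) ll += P.tabs.lgam(j, r(j));
      ll += accu(P.S % logmu) - accu(P.S % Lden);
      for (uword j = 0; j < ng; ++j)
        ll += r(j) * ((double)nc * std::log(r(j)) - colLden(j));
      elbo = ll;
    }
    if (want_alpha) {
      rowvec colT = sum(T, 0);
      vec dlldr(ng);
      for (uword j = 0; j < ng; ++j)
        dlldr(j) = P.tabs.digam(j, r(j)) +
                   (double)nc * (std::log(r(j)) + 1.0) - colLden(j) - colT(j);
      gr.la = -conv_to<vec>::from(r) % dlldr -
              2.0 * conv_to<vec>::from(alpha);
    }
  }
  elbo += accu(std::log(2.0) - 2.0 * alpha);

  if (P.learn_nu) {
    mat Gnu = D.t() * Z;   // genes x F
    // KL(q(nu) || p(nu)) with diagonal normals
    mat dm = par.m_nu - P.prior_mu;
    mat v0 = square(P.prior_sd);
    elbo -= accu(log(P.prior_sd) - par.ls_nu +
                 (square(s_nu) + square(dm)) / (2.0 * v0) - 0.5);
    gr.m_nu = Gnu - dm / v0;
    gr.ls_nu = Gnu % eps_nu % s_nu - (square(s_nu) / v0 - 1.0);
  }

  if (P.learn_phi && !P.fixed_basis) {
    vec gphi = sum(D % (Zd * nu.t()), 1);
    vec x = xy.col(0), y = xy.col(1);
    vec rsq = square(x) + square(y);
    mat dl = par.l - P.prior_xy;
    elbo -= 0.5 * accu(square(dl));
    gr.l.set_size(nc, 2);
    gr.l.col(0) = gphi % (-y / rsq) - dl.col(0);
    gr.l.col(1) = gphi % (x / rsq) - dl.col(1);
  }

  if (P.nb > 1) {
    gr.dnu.zeros(P.nb, ng);
    for (int b = 1; b < P.nb; ++b)
      gr.dnu.row(b) = sum(D.rows(P.bidx[b]), 0);
  }

  return elbo;
}

static ManifoldProb make_manifold_prob(const mat& S, const uvec& batch, int nb,
                                       int k, const mat& prior_mu,
                                       const mat& prior_sd, const mat& prior_xy,
                                       bool learn_phi, bool learn_nu,
                                       const vec& phi_fixed, const mat& nu_fixed,
                                       bool fixed_basis, const mat& Zfix,
                                       const mat& Zdfix) {
  ManifoldProb P;
  P.S = S; P.batch = batch; P.nb = nb; P.k = k;
  P.F = fixed_basis ? (int)Zfix.n_cols : 2 * k + 1;
  P.prior_mu = prior_mu; P.prior_sd = prior_sd; P.prior_xy = prior_xy;
  P.learn_phi = learn_phi; P.learn_nu = learn_nu;
  P.phi_fixed = phi_fixed; P.nu_fixed = nu_fixed;
  P.fixed_basis = fixed_basis; P.Zfix = Zfix; P.Zdfix = Zdfix;
  if (P.F > 32) Rcpp::stop("basis dimension above 32 is not supported");
  P.tabs.build(S);
  P.bidx.resize(nb);
  for (int b = 0; b < nb; ++b) P.bidx[b] = find(batch == (uword)b);
  return P;
}

// [[Rcpp::export]]
Rcpp::List manifold_svi_cpp(const arma::mat& S, const arma::uvec& batch, int nb,
                            int k, const arma::mat& prior_mu,
                            const arma::mat& prior_sd,
                            const arma::mat& prior_xy, const arma::mat& l0,
                            const arma::mat& m_nu0, const arma::mat& ls_nu0,
                            const arma::vec& la0, const arma::mat& dnu0,
                            bool learn_phi, bool learn_nu,
                            const arma::vec& phi_fixed,
                            const arma::mat& nu_fixed, bool fixed_basis,
                            const arma::mat& Zfix, const arma::mat& Zdfix,
                            int n_steps, double lr0, double lr1, double clip,
                            bool early_stop) {
  ManifoldProb P = make_manifold_prob(S, batch, nb, k, prior_mu, prior_sd,
                                      prior_xy, learn_phi, learn_nu, phi_fixed,
                                      nu_fixed, fixed_basis, Zfix, Zdfix);
  const uword nc = S.n_rows, ng = S.n_cols;
  ManifoldPar par{l0, m_nu0, ls_nu0, la0, dnu0};
  ManifoldGrad gr;
  Adam a_l, a_m, a_s, a_la, a_dnu;
  a_l.init(nc, 2); a_m.init(ng, P.F); a_s.init(ng, P.F);
  a_la.init(ng, 1); a_dnu.init(nb, ng);

  std::vector<double> trace;
  trace.reserve(n_steps);
  double decay = (n_steps > 1) ? std::pow(lr1 / lr0, 1.0 / (n_steps - 1)) : 1.0;
  int done = n_steps;

  for (int t = 0; t < n_steps; ++t) {
    bool wa = (t % 5 == 0) || t == n_steps - 1;
    bool wv = (t % 10 == 0) || t == n_steps - 1;
    mat eps_xy = (P.learn_phi && !P.fixed_basis) ? fill_randn(nc, 2) : mat();
    mat eps_nu = P.learn_nu ? fill_randn(ng, P.F) : mat();
    double elbo = manifold_step(P, par, eps_xy, eps_nu, gr, wv, wa);
    if (wv) {
      if (!std::isfinite(elbo))
        Rcpp::stop("manifold SVI diverged at iteration %d (non-finite ELBO)",
                   t + 1);
      trace.push_back(-elbo);
    }
    double lr = lr0 * std::pow(decay, t);
    if (P.learn_phi && !P.fixed_basis) a_l.step(par.l, gr.l, lr, clip);
    if (P.learn_nu) {
      a_m.step(par.m_nu, gr.m_nu, lr, clip);
      a_s.step(par.ls_nu, gr.ls_nu, lr, clip);
    }
    if (wa) {
      mat laM(par.la), gM(gr.la);
      a_la.step(laM, gM, lr, clip);
      par.la = laM.col(0);
    }
    if (nb > 1) a_dnu.step(par.dnu, gr.dnu, lr, clip);
    if (nb > 1) par.dnu.row(0).zeros();
    if (early_stop && (int)trace.size() >= 11) {
      size_t nrec = trace.size();
      double m100 = 0;
      for (size_t i = nrec - 10; i < nrec; ++i) m100 += trace[i];
      if (std::abs(m100 / 10.0 - trace[nrec - 1]) < 5.0) { done = t + 1; break; }
    }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("l") = par.l, Rcpp::Named("m_nu") = par.m_nu,
      Rcpp::Named("ls_nu") = par.ls_nu, Rcpp::Named("la") = par.la,
      Rcpp::Named("dnu") = par.dnu, Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = done);
}

// single-evaluation entry point used by the gradient-consistency tests
// [[Rcpp::export]]
Rcpp::List manifold_elbo_cpp(const arma::mat& S, const arma::uvec& batch,
                             int nb, int k, const arma::mat& prior_mu,
                             const arma::mat& prior_sd,
                             const arma::mat& prior_xy, const arma::mat& l,
                             const arma::mat& m_nu, const arma::mat& ls_nu,
                             const arma::vec& la, const arma::mat& dnu,
                             bool learn_phi, bool learn_nu,
                             const arma::vec& phi_fixed,
                             const arma::mat& nu_fixed, bool fixed_basis,
                             const arma::mat& Zfix, const arma::mat& Zdfix,
                             const arma::mat& eps_xy, const arma::mat& eps_nu) {
  ManifoldProb P = make_manifold_prob(S, batch, nb, k, prior_mu, prior_sd,
                                      prior_xy, learn_phi, learn_nu, phi_fixed,
                                      nu_fixed, fixed_basis, Zfix, Zdfix);
  ManifoldPar par{l, m_nu, ls_nu, la, dnu};
  ManifoldGrad gr;
  double elbo = manifold_step(P, par, eps_xy, eps_nu, gr, true, true);
  return Rcpp::List::create(
      Rcpp::Named("elbo") = elbo, Rcpp::Named("g_l") = gr.l,
      Rcpp::Named("g_m_nu") = gr.m_nu, Rcpp::Named("g_ls_nu") = gr.ls_nu,
      Rcpp::Named("g_la") = gr.la, Rcpp::Named("g_dnu") = gr.dnu);
}

// ----------------------------------------------------------------------------
// Velocity learning
// ----------------------------------------------------------------------------

struct VelProb {
  mat U, sbar, log_sbar;  // cells x genes; sbar fixed from the manifold stage
  mat W;                  // cells x genes: sum_f nu_gf d/dphi zeta_f(phi_c)
  mat Zw;                 // cells x Fw basis for omega(phi)
  uvec cond;              // 0-based condition index per cell
  int nt, Fw;
  double floor_;          // relu floor on omega * W + gamma
  // priors
  double pm_lb, ps_lb, pm_lg, ps_lg;
  vec pm_w, ps_w;         // length Fw
  CountTables tabs;
  std::vector<uvec> tidx;
};

// Log-likelihood of the unspliced NB model and its gradients at a point.
// Fused single pass over entries (no cell x gene temporaries): the per-step
// cost is dominated by memory traffic over U, W, sbar. Dispersion gradients
// (dlldr) and the value itself need per-entry logs, so they are only
// computed when requested (the SVI loops request them periodically).
static double vel_ll_grads(const VelProb& P, const vec& lb, const vec& lg,
                           const mat& wmat, const vec& la, vec& g_lb, vec& g_lg,
                           mat& g_w, vec& dlldr, bool want_value,
                           bool want_alpha) {
  const uword nc = P.U.n_rows, ng = P.U.n_cols;
  vec omega(nc);
  for (int t = 0; t < P.nt; ++t)
    omega.elem(P.tidx[t]) = P.Zw.rows(P.tidx[t]) * wmat.row(t).t();
  const double* om = omega.memptr();

  g_lb.zeros(ng); g_lg.zeros(ng);
  dlldr.zeros(ng);
  vec E(nc, fill::zeros);
  double* Ep = E.memptr();
  double ll = 0.0;

  for (uword j = 0; j < ng; ++j) {
    const double gam = std::exp(lg(j));
    const double invb = std::exp(-lb(j));
    const double r = std::exp(-la(j));
    const double* Uj = P.U.colptr(j);
    const double* Wj = P.W.colptr(j);
    const double* sj = P.sbar.colptr(j);
    const double* lsj = P.log_sbar.colptr(j);
    double glb = 0.0, glg = 0.0, colLden = 0.0, colT = 0.0, vUlog = 0.0;
    for (uword c = 0; c < nc; ++c) {
      double A = om[c] * Wj[c] + gam;
      bool mask = A > P.floor_;
      double Ar = mask ? A : P.floor_;
      double mu = sj[c] * Ar * invb;
      double den = mu + r;
      double T = (Uj[c] + r) / den;
      double D = Uj[c] - mu * T;
      glb -= D;
      if (mask) {
        double t = D / A;
        glg += t;
        Ep[c] += t * Wj[c];
      }
      if (want_alpha || want_value) {
        double ld = std::log(den);
        colLden += ld;
        colT += T;
        if (want_value && Uj[c] > 0)
          vUlog += Uj[c] * (lsj[c] + std::log(Ar) - lb(j) - ld);
      }
    }
    g_lb(j) = glb;
    g_lg(j) = gam * glg;
    if (want_alpha)
      dlldr(j) = P.tabs.digam(j, r) +
                 (double)nc * (std::log(r) + 1.0) - colLden - colT;
    if (want_value)
      ll += P.tabs.lgam(j, r) + vUlog +
            r * ((double)nc * std::log(r) - colLden);
  }

  g_w.set_size(P.nt, P.Fw);
  for (int t = 0; t < P.nt; ++t) {
    vec Et = E.elem(P.tidx[t]);
    g_w.row(t) = Et.t() * P.Zw.rows(P.tidx[t]);
  }
  return ll;
}

static VelProb make_vel_prob(const mat& U, const mat& log_sbar, const mat& W,
                             const mat& Zw, const uvec& cond, int nt,
                             double floor_, double pm_lb, double ps_lb,
                             double pm_lg, double ps_lg, const vec& pm_w,
                             const vec& ps_w) {
  VelProb P;
  P.U = U; P.log_sbar = log_sbar; P.sbar = exp(log_sbar); P.W = W; P.Zw = Zw;
  P.cond = cond; P.nt = nt; P.Fw = (int)Zw.n_cols; P.floor_ = floor_;
  P.pm_lb = pm_lb; P.ps_lb = ps_lb; P.pm_lg = pm_lg; P.ps_lg = ps_lg;
  P.pm_w = pm_w; P.ps_w = ps_w;
  P.tabs.build(U);
  P.tidx.resize(nt);
  for (int t = 0; t < nt; ++t) P.tidx[t] = find(cond == (uword)t);
  return P;
}

// ---- mean-field guide ----

struct VelMFPar { vec m_lb, ls_lb, m_lg, ls_lg, la; mat m_w, ls_w; };
struct VelMFGrad { vec m_lb, ls_lb, m_lg, ls_lg, la; mat m_w, ls_w; };

static double vel_mf_step(const VelProb& P, const VelMFPar& par,
                          const vec& eps_b, const vec& eps_g, const mat& eps_w,
                          VelMFGrad& gr, bool want_value, bool want_alpha) {
  vec s_lb = exp(par.ls_lb), s_lg = exp(par.ls_lg);
  mat s_w = exp(par.ls_w);
  vec lb = par.m_lb + s_lb % eps_b;
  vec lg = par.m_lg + s_lg % eps_g;
  mat wmat = par.m_w + s_w % eps_w;

  vec g_lb, g_lg, dlldr;
  mat g_w;
  double ll = vel_ll_grads(P, lb, lg, wmat, par.la, g_lb, g_lg, g_w, dlldr,
                           want_value, want_alpha);

  double elbo = ll;
  // KL terms against the independent normal priors
  double v_lb = P.ps_lb * P.ps_lb, v_lg = P.ps_lg * P.ps_lg;
  elbo -= accu(std::log(P.ps_lb) - par.ls_lb +
               (square(s_lb) + square(par.m_lb - P.pm_lb)) / (2 * v_lb) - 0.5);
  elbo -= accu(std::log(P.ps_lg) - par.ls_lg +
               (square(s_lg) + square(par.m_lg - P.pm_lg)) / (2 * v_lg) - 0.5);
  gr.m_lb = g_lb - (par.m_lb - P.pm_lb) / v_lb;
  gr.ls_lb = g_lb % eps_b % s_lb - (square(s_lb) / v_lb - 1.0);
  gr.m_lg = g_lg - (par.m_lg - P.pm_lg) / v_lg;
  gr.ls_lg = g_lg % eps_g % s_lg - (square(s_lg) / v_lg - 1.0);

  gr.m_w.set_size(P.nt, P.Fw); gr.ls_w.set_size(P.nt, P.Fw);
  for (int f = 0; f < P.Fw; ++f) {
    double v0 = P.ps_w(f) * P.ps_w(f);
    for (int t = 0; t < P.nt; ++t) {
      double s = s_w(t, f), m = par.m_w(t, f) - P.pm_w(f);
      elbo -= std::log(P.ps_w(f)) - par.ls_w(t, f) + (s * s + m * m) / (2 * v0) - 0.5;
      gr.m_w(t, f) = g_w(t, f) - m / v0;
      gr.ls_w(t, f) = g_w(t, f) * eps_w(t, f) * s - (s * s / v0 - 1.0);
    }
  }

  vec alpha = exp(par.la);
  if (want_alpha) gr.la = -exp(-par.la) % dlldr - 2.0 * alpha;
  elbo += accu(std::log(2.0) - 2.0 * alpha);
  return elbo;
}

// [[Rcpp::export]]
Rcpp::List velocity_svi_meanfield_cpp(
    const arma::mat& U, const arma::mat& log_sbar, const arma::mat& W,
    const arma::mat& Zw, const arma::uvec& cond, int nt, double relu_floor,
    double pm_lb, double ps_lb, double pm_lg, double ps_lg,
    const arma::vec& pm_w, const arma::vec& ps_w, const arma::vec& m_lb0,
    const arma::vec& ls_lb0, const arma::vec& m_lg0, const arma::vec& ls_lg0,
    const arma::mat& m_w0, const arma::mat& ls_w0, const arma::vec& la0,
    int n_steps, double lr0, double lr1, double clip, bool early_stop) {
  VelProb P = make_vel_prob(U, log_sbar, W, Zw, cond, nt, relu_floor, pm_lb,
                            ps_lb, pm_lg, ps_lg, pm_w, ps_w);
  const uword ng = U.n_cols;
  VelMFPar par{m_lb0, ls_lb0, m_lg0, ls_lg0, la0, m_w0, ls_w0};
  VelMFGrad gr;
  Adam a[7];
  a[0].init(ng, 1); a[1].init(ng, 1); a[2].init(ng, 1); a[3].init(ng, 1);
  a[4].init(nt, P.Fw); a[5].init(nt, P.Fw); a[6].init(ng, 1);
  std::vector<double> trace; trace.reserve(n_steps);
  double decay = (n_steps > 1) ? std::pow(lr1 / lr0, 1.0 / (n_steps - 1)) : 1.0;
  int done = n_steps;
  auto vstep = [&](Adam& ad, vec& x, const vec& g, double lr) {
    mat xm(x), gm(g); ad.step(xm, gm, lr, clip); x = xm.col(0);
  };
  for (int t = 0; t < n_steps; ++t) {
    bool wa = (t % 5 == 0) || t == n_steps - 1;
    bool wv = (t % 10 == 0) || t == n_steps - 1;
    vec eb = fill_randn_v(ng), eg = fill_randn_v(ng);
    mat ew = fill_randn(nt, P.Fw);
    double elbo = vel_mf_step(P, par, eb, eg, ew, gr, wv, wa);
    if (wv) {
      if (!std::isfinite(elbo))
        Rcpp::stop("velocity SVI diverged at iteration %d (non-finite ELBO)", t + 1);
      trace.push_back(-elbo);
    }
    double lr = lr0 * std::pow(decay, t);
    vstep(a[0], par.m_lb, gr.m_lb, lr);  vstep(a[1], par.ls_lb, gr.ls_lb, lr);
    vstep(a[2], par.m_lg, gr.m_lg, lr);  vstep(a[3], par.ls_lg, gr.ls_lg, lr);
    a[4].step(par.m_w, gr.m_w, lr, clip); a[5].step(par.ls_w, gr.ls_w, lr, clip);
    if (wa) vstep(a[6], par.la, gr.la, lr);
    // windows expressed in recorded (every-10th) values: 10 records ~ 100
    // iterations, the last record ~ the recent loss
    if (early_stop && (int)trace.size() >= 11) {
      size_t n = trace.size();
      double m100 = 0;
      for (size_t i = n - 10; i < n; ++i) m100 += trace[i];
      if (std::abs(m100 / 10.0 - trace[n - 1]) < 5.0) { done = t + 1; break; }
    }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("m_lb") = par.m_lb, Rcpp::Named("ls_lb") = par.ls_lb,
      Rcpp::Named("m_lg") = par.m_lg, Rcpp::Named("ls_lg") = par.ls_lg,
      Rcpp::Named("m_w") = par.m_w, Rcpp::Named("ls_w") = par.ls_w,
      Rcpp::Named("la") = par.la, Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = done);
}

// [[Rcpp::export]]
Rcpp::List velocity_elbo_meanfield_cpp(
    const arma::mat& U, const arma::mat& log_sbar, const arma::mat& W,
    const arma::mat& Zw, const arma::uvec& cond, int nt, double relu_floor,
    double pm_lb, double ps_lb, double pm_lg, double ps_lg,
    const arma::vec& pm_w, const arma::vec& ps_w, const arma::vec& m_lb,
    const arma::vec& ls_lb, const arma::vec& m_lg, const arma::vec& ls_lg,
    const arma::mat& m_w, const arma::mat& ls_w, const arma::vec& la,
    const arma::vec& eps_b, const arma::vec& eps_g, const arma::mat& eps_w) {
  VelProb P = make_vel_prob(U, log_sbar, W, Zw, cond, nt, relu_floor, pm_lb,
                            ps_lb, pm_lg, ps_lg, pm_w, ps_w);
  VelMFPar par{m_lb, ls_lb, m_lg, ls_lg, la, m_w, ls_w};
  VelMFGrad gr;
  double elbo = vel_mf_step(P, par, eps_b, eps_g, eps_w, gr, true, true);
  return Rcpp::List::create(
      Rcpp::Named("elbo") = elbo, Rcpp::Named("g_m_lb") = gr.m_lb,
      Rcpp::Named("g_ls_lb") = gr.ls_lb, Rcpp::Named("g_m_lg") = gr.m_lg,
      Rcpp::Named("g_ls_lg") = gr.ls_lg, Rcpp::Named("g_m_w") = gr.m_w,
      Rcpp::Named("g_ls_w") = gr.ls_w, Rcpp::Named("g_la") = gr.la);
}

// ---- low-rank multivariate normal guide ----
// x = [log gamma_1..ng, nuomega (nt*Fw, row-major by condition)] ~ N(m, FF' + diag(d));
// log beta_g | log gamma_g is conditionally normal with correlation rho_g.

struct VelLRPar {
  vec m;     // n = ng + nt*Fw
  mat Fm;    // n x rank
  vec ld;    // log d
  vec mu_b, lsb, qr, la;  // per gene
};
struct VelLRGrad {
  vec m; mat Fm; vec ld, mu_b, lsb, qr, la;
};

static double vel_lr_step(const VelProb& P, const VelLRPar& par,
                          const vec& eps1, const vec& eps2, const vec& eps3,
                          VelLRGrad& gr, bool want_value, bool want_alpha) {
  const uword ng = P.U.n_cols;
  const uword n = par.m.n_elem;
  const uword rank = par.Fm.n_cols;
  vec d = exp(par.ld);
  vec sqd = sqrt(d);
  vec dx = par.Fm * eps1 + sqd % eps2;      // x - m
  vec x = par.m + dx;
  vec varx = sum(square(par.Fm), 1) + d;    // diag of Sigma
  vec lg = x.head(ng);
  mat wmat(P.nt, P.Fw);
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) wmat(t, f) = x(ng + t * P.Fw + f);

  vec sgam = sqrt(varx.head(ng));
  vec rho = 1.0 / (1.0 + exp(-par.qr));
  vec sb = exp(par.lsb);
  vec som = sqrt(1.0 - square(rho));
  vec c1 = rho % sb / sgam;
  vec dxg = dx.head(ng);
  vec lb = par.mu_b + c1 % dxg + sb % som % eps3;

  vec g_lb, g_lg, dlldr;
  mat g_w;
  double ll = vel_ll_grads(P, lb, lg, wmat, par.la, g_lb, g_lg, g_w, dlldr,
                           want_value, want_alpha);

  // total sensitivity of the likelihood to the x draw
  vec G(n);
  G.head(ng) = g_lg + g_lb % c1;
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) G(ng + t * P.Fw + f) = g_w(t, f);

  // prior moments over x (diagonal): log gamma then nu_omega blocks
  vec mu0(n), s0(n);
  mu0.head(ng).fill(P.pm_lg); s0.head(ng).fill(P.ps_lg);
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) {
      mu0(ng + t * P.Fw + f) = P.pm_w(f);
      s0(ng + t * P.Fw + f) = P.ps_w(f);
    }
  vec v0 = square(s0);

  // entropy of the LRMN via the matrix determinant lemma / Woodbury
  vec dinv = 1.0 / d;
  mat FD = par.Fm.each_col() % dinv;
  mat K = eye(rank, rank) + par.Fm.t() * FD;
  mat Kinv = inv_sympd(K);
  mat SinvF = FD * Kinv;
  vec Sinv_diag = dinv - sum(SinvF % FD, 1);
  double ld_sigma;
  { double sign; log_det(ld_sigma, sign, K); ld_sigma += accu(par.ld); }

  double elbo = ll;
  elbo += -accu((square(par.m - mu0) + varx) / (2.0 * v0));       // E log p(x)
  elbo += -accu((square(par.mu_b - P.pm_lb) + square(sb)) /
                (2.0 * P.ps_lb * P.ps_lb));                        // E log p(log beta)
  elbo += 0.5 * ld_sigma + accu(par.lsb + 0.5 * log(1.0 - square(rho))); // entropy
  vec alpha = exp(par.la);
  elbo += accu(std::log(2.0) - 2.0 * alpha);

  // gradients
  gr.m = G; gr.m.head(ng) = g_lg;   // beta term has no net m-dependence
  gr.m += -(par.m - mu0) / v0;

  vec h = -g_lb % c1 % dxg / varx.head(ng);
  gr.Fm = G * eps1.t();
  {
    mat Fg = par.Fm.rows(0, ng - 1);
    gr.Fm.rows(0, ng - 1) += Fg.each_col() % h;
  }
  gr.Fm += SinvF;                                // entropy
  gr.Fm -= par.Fm.each_col() % (1.0 / v0);       // E log p(x)

  vec g_d = G % eps2 / (2.0 * sqd);
  g_d.head(ng) += 0.5 * h;
  g_d += 0.5 * Sinv_diag;
  g_d -= 1.0 / (2.0 * v0);
  gr.ld = g_d % d;

  gr.mu_b = g_lb - (par.mu_b - P.pm_lb) / (P.ps_lb * P.ps_lb);
  gr.lsb = g_lb % (rho % dxg / sgam + som % eps3) % sb + 1.0 -
           square(sb) / (P.ps_lb * P.ps_lb);
  gr.qr = (g_lb % (sb % dxg / sgam - sb % rho / som % eps3) -
           rho / (1.0 - square(rho))) % rho % (1.0 - rho);
  if (want_alpha) gr.la = -exp(-par.la) % dlldr - 2.0 * alpha;
  return elbo;
}

// [[Rcpp::export]]
Rcpp::List velocity_svi_lrmn_cpp(
    const arma::mat& U, const arma::mat& log_sbar, const arma::mat& W,
    const arma::mat& Zw, const arma::uvec& cond, int nt, double relu_floor,
    double pm_lb, double ps_lb, double pm_lg, double ps_lg,
    const arma::vec& pm_w, const arma::vec& ps_w, const arma::vec& m0,
    const arma::mat& Fm0, const arma::vec& ld0, const arma::vec& mu_b0,
    const arma::vec& lsb0, const arma::vec& qr0, const arma::vec& la0,
    int n_steps, double lr0, double lr1, double clip, bool early_stop) {
  VelProb P = make_vel_prob(U, log_sbar, W, Zw, cond, nt, relu_floor, pm_lb,
                            ps_lb, pm_lg, ps_lg, pm_w, ps_w);
  const uword ng = U.n_cols, n = m0.n_elem, rank = Fm0.n_cols;
  VelLRPar par{m0, Fm0, ld0, mu_b0, lsb0, qr0, la0};
  VelLRGrad gr;
  Adam a_m, a_F, a_ld, a_mb, a_sb, a_qr, a_la;
  a_m.init(n, 1); a_F.init(n, rank); a_ld.init(n, 1);
  a_mb.init(ng, 1); a_sb.init(ng, 1); a_qr.init(ng, 1); a_la.init(ng, 1);
  std::vector<double> trace; trace.reserve(n_steps);
  double decay = (n_steps > 1) ? std::pow(lr1 / lr0, 1.0 / (n_steps - 1)) : 1.0;
  int done = n_steps;
  auto vstep = [&](Adam& ad, vec& xv, const vec& g, double lr) {
    mat xm(xv), gm(g); ad.step(xm, gm, lr, clip); xv = xm.col(0);
  };
  for (int t = 0; t < n_steps; ++t) {
    bool wa = (t % 5 == 0) || t == n_steps - 1;
    bool wv = (t % 10 == 0) || t == n_steps - 1;
    vec e1 = fill_randn_v(rank), e2 = fill_randn_v(n), e3 = fill_randn_v(ng);
    double elbo = vel_lr_step(P, par, e1, e2, e3, gr, wv, wa);
    if (wv) {
      if (!std::isfinite(elbo))
        Rcpp::stop("velocity SVI (lrmn) diverged at iteration %d", t + 1);
      trace.push_back(-elbo);
    }
    double lr = lr0 * std::pow(decay, t);
    vstep(a_m, par.m, gr.m, lr);
    a_F.step(par.Fm, gr.Fm, lr, clip);
    vstep(a_ld, par.ld, gr.ld, lr);
    par.ld = clamp(par.ld, -12.0, 6.0);
    vstep(a_mb, par.mu_b, gr.mu_b, lr);
    vstep(a_sb, par.lsb, gr.lsb, lr);
    par.lsb = clamp(par.lsb, -8.0, 3.0);
    vstep(a_qr, par.qr, gr.qr, lr);
    par.qr = clamp(par.qr, -8.0, 8.0);
    if (wa) vstep(a_la, par.la, gr.la, lr);
    if (early_stop && (int)trace.size() >= 11) {
      size_t nrec = trace.size();
      double m100 = 0;
      for (size_t i = nrec - 10; i < nrec; ++i) m100 += trace[i];
      if (std::abs(m100 / 10.0 - trace[nrec - 1]) < 5.0) { done = t + 1; break; }
    }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("m") = par.m, Rcpp::Named("Fm") = par.Fm,
      Rcpp::Named("ld") = par.ld, Rcpp::Named("mu_b") = par.mu_b,
      Rcpp::Named("lsb") = par.lsb, Rcpp::Named("qr") = par.qr,
      Rcpp::Named("la") = par.la, Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = done);
}

// [[Rcpp::export]]
Rcpp::List velocity_elbo_lrmn_cpp(
    const arma::mat& U, const arma::mat& log_sbar, const arma::mat& W,
    const arma::mat& Zw, const arma::uvec& cond, int nt, double relu_floor,
    double pm_lb, double ps_lb, double pm_lg, double ps_lg,
    const arma::vec& pm_w, const arma::vec& ps_w, const arma::vec& m,
    const arma::mat& Fm, const arma::vec& ld, const arma::vec& mu_b,
    const arma::vec& lsb, const arma::vec& qr, const arma::vec& la,
    const arma::vec& eps1, const arma::vec& eps2, const arma::vec& eps3) {
  VelProb P = make_vel_prob(U, log_sbar, W, Zw, cond, nt, relu_floor, pm_lb,
                            ps_lb, pm_lg, ps_lg, pm_w, ps_w);
  VelLRPar par{m, Fm, ld, mu_b, lsb, qr, la};
  VelLRGrad gr;
  double elbo = vel_lr_step(P, par, eps1, eps2, eps3, gr, true, true);
  return Rcpp::List::create(
      Rcpp::Named("elbo") = elbo, Rcpp::Named("g_m") = gr.m,
      Rcpp::Named("g_Fm") = gr.Fm, Rcpp::Named("g_ld") = gr.ld,
      Rcpp::Named("g_mu_b") = gr.mu_b, Rcpp::Named("g_lsb") = gr.lsb,
      Rcpp::Named("g_qr") = gr.qr, Rcpp::Named("g_la") = gr.la);
}

// ---- Hamiltonian Monte Carlo over (log beta, log gamma, nu_omega, log alpha) ----

static double vel_logpost_grad(const VelProb& P, const vec& theta, vec& grad) {
  const uword ng = P.U.n_cols;
  const uword nw = (uword)(P.nt * P.Fw);
  vec lb = theta.subvec(0, ng - 1);
  vec lg = theta.subvec(ng, 2 * ng - 1);
  mat wmat(P.nt, P.Fw);
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) wmat(t, f) = theta(2 * ng + t * P.Fw + f);
  vec la = theta.subvec(2 * ng + nw, 2 * ng + nw + ng - 1);

  vec g_lb, g_lg, dlldr;
  mat g_w;
  double ll = vel_ll_grads(P, lb, lg, wmat, la, g_lb, g_lg, g_w, dlldr, true,
                           true);

  double lp = ll;
  // normal priors
  lp += -accu(square(lb - P.pm_lb)) / (2 * P.ps_lb * P.ps_lb);
  lp += -accu(square(lg - P.pm_lg)) / (2 * P.ps_lg * P.ps_lg);
  g_lb -= (lb - P.pm_lb) / (P.ps_lb * P.ps_lb);
  g_lg -= (lg - P.pm_lg) / (P.ps_lg * P.ps_lg);
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) {
      double v0 = P.ps_w(f) * P.ps_w(f);
      lp += -std::pow(wmat(t, f) - P.pm_w(f), 2) / (2 * v0);
      g_w(t, f) -= (wmat(t, f) - P.pm_w(f)) / v0;
    }
  // alpha ~ Gamma(1,2) on the log scale (includes the Jacobian term)
  vec alpha = exp(la);
  lp += accu(la - 2.0 * alpha);
  vec g_la = -exp(-la) % dlldr - 2.0 * alpha + 1.0;

  grad.set_size(theta.n_elem);
  grad.subvec(0, ng - 1) = g_lb;
  grad.subvec(ng, 2 * ng - 1) = g_lg;
  for (int t = 0; t < P.nt; ++t)
    for (int f = 0; f < P.Fw; ++f) grad(2 * ng + t * P.Fw + f) = g_w(t, f);
  grad.subvec(2 * ng + nw, 2 * ng + nw + ng - 1) = g_la;
  return lp;
}

// [[Rcpp::export]]
Rcpp::List velocity_hmc_cpp(const arma::mat& U, const arma::mat& log_sbar,
                            const arma::mat& W, const arma::mat& Zw,
                            const arma::uvec& cond, int nt, double relu_floor,
                            double pm_lb, double ps_lb, double pm_lg,
                            double ps_lg, const arma::vec& pm_w,
                            const arma::vec& ps_w, const arma::vec& theta0,
                            const arma::vec& minv, int n_warmup, int n_samples,
                            int n_leapfrog, double target_accept) {
  VelProb P = make_vel_prob(U, log_sbar, W, Zw, cond, nt, relu_floor, pm_lb,
                            ps_lb, pm_lg, ps_lg, pm_w, ps_w);
  const uword dim = theta0.n_elem;
  vec theta = theta0, grad;
  double lp = vel_logpost_grad(P, theta, grad);

  // dual averaging for the step size (Nesterov-style, as in standard NUTS)
  double eps = 0.02, mu_da = std::log(10.0 * eps), lbar = 0.0, hbar = 0.0;
  const double gam = 0.05, t0 = 10.0, kap = 0.75;
  vec sqm = sqrt(minv);     // minv = inverse mass diagonal (posterior variances)
  int divergences = 0, accepted = 0, total = 0;
  mat samples(n_samples, dim);

  for (int it = 0; it < n_warmup + n_samples; ++it) {
    vec p = fill_randn_v(dim) / sqm;
    double H0 = -lp + 0.5 * accu(square(p) % minv);
    vec th = theta, g = grad, pp = p;
    double lp_new = lp;
    int L = n_leapfrog + (int)std::floor(R::unif_rand() * n_leapfrog);
    bool bad = false;
    for (int s = 0; s < L; ++s) {
      pp += 0.5 * eps * g;
      th += eps * (minv % pp);
      lp_new = vel_logpost_grad(P, th, g);
      if (!std::isfinite(lp_new)) { bad = true; break; }
      pp += 0.5 * eps * g;
    }
    double H1 = bad ? datum::inf : -lp_new + 0.5 * accu(square(pp) % minv);
    double dH = H0 - H1;
    double a = std::isfinite(dH) ? std::min(1.0, std::exp(dH)) : 0.0;
    if (bad || dH < -1000.0) ++divergences;
    ++total;
    if (R::unif_rand() < a) {
      theta = th; lp = lp_new; grad = g; ++accepted;
    } else {
      // restore gradient at the retained point
      lp = vel_logpost_grad(P, theta, grad);
    }
    if (it < n_warmup) {
      double m = it + 1;
      hbar = (1.0 - 1.0 / (m + t0)) * hbar + (target_accept - a) / (m + t0);
      double leps = mu_da - std::sqrt(m) / gam * hbar;
      double w = std::pow(m, -kap);
      lbar = w * leps + (1.0 - w) * lbar;
      eps = std::exp(leps);
    } else {
      eps = std::exp(lbar);
      samples.row(it - n_warmup) = theta.t();
    }
    if ((it & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("samples") = samples,
      Rcpp::Named("accept_rate") = (double)accepted / total,
      Rcpp::Named("divergences") = divergences,
      Rcpp::Named("step_size") = eps);
}
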