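#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical normalization model.
//
// Generative structure (one chain; R drives chains and seeding):
//   x_j ~ NB(mean = lambda_j, size = 1/phi_x)
//   y_j ~ NB(mean = lambda_j * 2^(mu + b*c_j + eps_j), size = 1/phi_y)
//   log lambda_j ~ Normal(m0, s0)              (weak empirical prior)
//   eps_j        ~ Normal(0, sigma_fit)        (region-level residual, log2)
//   mu           ~ Normal(anchor, sigma_mean)
//   b            ~ Normal(0, 1)
//   sigma_fit^2, sigma_mean^2 ~ InvGamma(shape, rate)   (conjugate updates)
//   phi_x, phi_y ~ HalfNormal(disp_scale)      (overdispersion 1/size)
//
// lambda_j and eps_j are updated with vectorised random-walk Metropolis,
// mu / b / phi with scalar random walks; variance components are exact
// Gibbs draws. Step sizes adapt in batches during burn-in only, so the
// retained draws target the exact posterior. All randomness comes from
// R's RNG, making runs reproducible under set.seed().

static const double LN2 = 0.6931471805599453;

// NB log-density with mean parameterisation; cterm caches the
// lgamma(x+a) - lgamma(a) - lgamma(x+1) part (constant while 'a' is fixed).
static inline double nb_ll(double x, double a, double mu, double cterm) {
  double denom = a + mu;
  double v = cterm + a * std::log(a / denom);
  if (x > 0.0) v += x * std::log(mu / denom);
  return v;
}

static void nb_cterms(const NumericVector& x, double a, std::vector<double>& out) {
  double la = R::lgammafn(a);
  for (int j = 0; j < x.size(); ++j)
    out[j] = R::lgammafn(x[j] + a) - la - R::lgammafn(x[j] + 1.0);
}

// [[Rcpp::export(name = ".vsi_mcmc_chain")]]
List vsi_mcmc_chain(NumericVector x, NumericVector y, NumericVector cvec,
                    double anchor, double m0, double s0,
                    double sigma_shape, double sigma_rate, double disp_scale,
                    int draws, int burn, List init) {
  const int J = x.size();
  RNGScope scope;

  std::vector<double> loglam = as<std::vector<double> >(init["loglam"]);
  std::vector<double> eps(J, 0.0);
  double mu = as<double>(init["mu"]);
  double b = 0.0;
  double s2f = as<double>(init["s2f"]);
  double s2m = as<double>(init["s2m"]);
  double phix = as<double>(init["phix"]);
  double phiy = as<double>(init["phiy"]);

  double ax = 1.0 / phix, ay = 1.0 / phiy;
  std::vector<double> ctx(J), cty(J), lam(J), muy(J);
  nb_cterms(x, ax, ctx);
  nb_cterms(y, ay, cty);
  for (int j = 0; j < J; ++j) {
    lam[j] = std::exp(loglam[j]);
    muy[j] = lam[j] * std::exp(LN2 * (mu + b * cvec[j]));
  }

  double step_l = 0.5, step_e = 0.3, step_mu = 0.1, step_b = 0.1, step_p = 0.5;
  const int batch = 50;
  double acc_l = 0, acc_e = 0, acc_mu = 0, acc_b = 0, acc_px = 0, acc_py = 0;
  int nbatch = 0;

  NumericMatrix out(draws, 6);
  const int total = burn + draws;

  for (int it = 0; it < total; ++it) {
    // --- per-region latent abundance ---------------------------------
    for (int j = 0; j < J; ++j) {
      double prop = loglam[j] + step_l * norm_rand();
      double lamp = std::exp(prop);
      double muyp = muy[j] * (lamp / lam[j]);
      double cur = nb_ll(x[j], ax, lam[j], ctx[j]) + nb_ll(y[j], ay, muy[j], cty[j]) +
                   R::dnorm(loglam[j], m0, s0, 1);
      double pll = nb_ll(x[j], ax, lamp, ctx[j]) + nb_ll(y[j], ay, muyp, cty[j]) +
                   R::dnorm(prop, m0, s0, 1);
      if (std::log(unif_rand()) < pll - cur) {
        loglam[j] = prop; lam[j] = lamp; muy[j] = muyp;
        acc_l += 1.0 / J;
      }
    }

    // --- per-region residual (log2) ----------------------------------
    double sf = std::sqrt(s2f);
    for (int j = 0; j < J; ++j) {
      double d = step_e * norm_rand();
      double muyp = muy[j] * std::exp(LN2 * d);
      double cur = nb_ll(y[j], ay, muy[j], cty[j]) + R::dnorm(eps[j], 0.0, sf, 1);
      double pll = nb_ll(y[j], ay, muyp, cty[j]) + R::dnorm(eps[j] + d, 0.0, sf, 1);
      if (std::log(unif_rand()) < pll - cur) {
        eps[j] += d; muy[j] = muyp;
        acc_e += 1.0 / J;
      }
    }

    // --- slope (the log2 normalization factor) -----------------------
    {
      double d = step_mu * norm_rand();
      double mult = std::exp(LN2 * d), cur = 0, pll = 0;
      for (int j = 0; j < J; ++j) {
        cur += nb_ll(y[j], ay, muy[j], cty[j]);
        pll += nb_ll(y[j], ay, muy[j] * mult, cty[j]);
      }
      cur += R::dnorm(mu, anchor, std::sqrt(s2m), 1);
      pll += R::dnorm(mu + d, anchor, std::sqrt(s2m), 1);
      if (std::log(unif_rand()) < pll - cur) {
        mu += d;
        for (int j = 0; j < J; ++j) muy[j] *= mult;
        acc_mu += 1;
      }
    }

    // --- intercept over the centered intensity covariate -------------
    {
      double d = step_b * norm_rand(), cur = 0, pll = 0;
      for (int j = 0; j < J; ++j) {
        cur += nb_ll(y[j], ay, muy[j], cty[j]);
        pll += nb_ll(y[j], ay, muy[j] * std::exp(LN2 * d * cvec[j]), cty[j]);
      }
      cur += R::dnorm(b, 0.0, 1.0, 1);
      pll += R::dnorm(b + d, 0.0, 1.0, 1);
      if (std::log(unif_rand()) < pll - cur) {
        for (int j = 0; j < J; ++j) muy[j] *= std::exp(LN2 * d * cvec[j]);
        b += d;
        acc_b += 1;
      }
    }

    // --- exact recentering (Gibbs) -----------------------------------
    // mu and mean(eps) are only weakly identified by the likelihood;
    // conditional on t_j = mu + eps_j the likelihood is constant and
    // mu | t, sigmas is conjugate Normal, so redraw it exactly and push
    // the complement back into eps. Same for the intercept along c_j.
    {
      double sume = 0;
      for (int j = 0; j < J; ++j) sume += mu + eps[j];
      double prec = 1.0 / s2m + J / s2f;
      double mean = (anchor / s2m + sume / s2f) / prec;
      double mu_new = mean + norm_rand() / std::sqrt(prec);
      double shift = mu_new - mu;
      for (int j = 0; j < J; ++j) eps[j] -= shift;
      mu = mu_new;
    }
    {
      double st = 0, scc = 0;
      for (int j = 0; j < J; ++j) {
        st += cvec[j] * (b * cvec[j] + eps[j]);
        scc += cvec[j] * cvec[j];
      }
      double prec = 1.0 + scc / s2f;
      double mean = (st / s2f) / prec;
      double b_new = mean + norm_rand() / std::sqrt(prec);
      for (int j = 0; j < J; ++j) eps[j] -= (b_new - b) * cvec[j];
      b = b_new;
    }

    // --- variance components (conjugate InvGamma) --------------------
    {
      double sse = 0;
      for (int j = 0; j < J; ++j) sse += eps[j] * eps[j];
      s2f = 1.0 / R::rgamma(sigma_shape + 0.5 * J, 1.0 / (sigma_rate + 0.5 * sse));
      double dm = mu - anchor;
      s2m = 1.0 / R::rgamma(sigma_shape + 0.5, 1.0 / (sigma_rate + 0.5 * dm * dm));
    }

    // --- joint scale move on (eps, sigma_fit^2) ----------------------
    // The residual layer and the NB overdispersion of y compete to
    // explain extra-Poisson ratio noise; scaling all eps_j and sigma_fit
    // together moves along that ridge. The move is a slice sample on the
    // scaling exponent d, (eps, s2f) -> (e^d eps, e^2d s2f): the target
    // combines the likelihood change, the InvGamma prior change, and a
    // net +2d from the eps prior and the Jacobian.
    {
      double base = 0;
      for (int j = 0; j < J; ++j) base += nb_ll(y[j], ay, muy[j], cty[j]);
      auto fd = [&](double d) -> double {
        double r = std::exp(d), pll = 0;
        for (int j = 0; j < J; ++j)
          pll += nb_ll(y[j], ay, muy[j] * std::exp(LN2 * (r - 1.0) * eps[j]), cty[j]);
        double s2fp = r * r * s2f;
        double dig = -(sigma_shape + 1.0) * 2.0 * d
                     - sigma_rate * (1.0 / s2fp - 1.0 / s2f);
        return (pll - base) + dig + 2.0 * d;
      };
      double z = -exp_rand();             // log slice height below f(0)=0
      double w = 0.3;
      double lo = -w * unif_rand(), hi = lo + w;
      for (int k = 0; k < 8 && fd(lo) > z; ++k) lo -= w;
      for (int k = 0; k < 8 && fd(hi) > z; ++k) hi += w;
      double d = 0;
      for (int k = 0; k < 20; ++k) {
        d = lo + (hi - lo) * unif_rand();
        if (fd(d) > z) break;
        if (d < 0) lo = d; else hi = d;
        d = 0;
      }
      if (d != 0) {
        double r = std::exp(d);
        for (int j = 0; j < J; ++j) {
          muy[j] *= std::exp(LN2 * (r - 1.0) * eps[j]);
          eps[j] *= r;
        }
        s2f *= r * r;
      }
    }

    // --- overdispersions (random walk on log phi) --------------------
    {
      double lp = std::log(phix) + step_p * norm_rand();
      double phip = std::exp(lp), ap = 1.0 / phip;
      double lap = R::lgammafn(ap), cur = 0, pll = 0;
      for (int j = 0; j < J; ++j) {
        cur += nb_ll(x[j], ax, lam[j], ctx[j]);
        double ct = R::lgammafn(x[j] + ap) - lap - R::lgammafn(x[j] + 1.0);
        pll += nb_ll(x[j], ap, lam[j], ct);
      }
      cur += -0.5 * phix * phix / (disp_scale * disp_scale) + std::log(phix);
      pll += -0.5 * phip * phip / (disp_scale * disp_scale) + lp;
      if (std::log(unif_rand()) < pll - cur) {
        phix = phip; ax = ap; nb_cterms(x, ax, ctx);
        acc_px += 1;
      }
    }
    {
      double lp = std::log(phiy) + step_p * norm_rand();
      double phip = std::exp(lp), ap = 1.0 / phip;
      double lap = R::lgammafn(ap), cur = 0, pll = 0;
      for (int j = 0; j < J; ++j) {
        cur += nb_ll(y[j], ay, muy[j], cty[j]);
        double ct = R::lgammafn(y[j] + ap) - lap - R::lgammafn(y[j] + 1.0);
        pll += nb_ll(y[j], ap, muy[j], ct);
      }
      cur += -0.5 * phiy * phiy / (disp_scale * disp_scale) + std::log(phiy);
      pll += -0.5 * phip * phip / (disp_scale * disp_scale) + lp;
      if (std::log(unif_rand()) < pll - cur) {
        phiy = phip; ay = ap; nb_cterms(y, ay, cty);
        acc_py += 1;
      }
    }

    // --- step-size adaptation, burn-in only --------------------------
    if (it < burn && (it + 1) % batch == 0) {
      nbatch++;
      double g = 1.0 / std::sqrt((double)nbatch);
      step_l *= std::exp(g * (acc_l / batch - 0.35));
      step_e *= std::exp(g * (acc_e / batch - 0.35));
      step_mu *= std::exp(g * (acc_mu / batch - 0.44));
      step_b *= std::exp(g * (acc_b / batch - 0.44));
      step_p *= std::exp(g * (0.5 * (acc_px + acc_py) / batch - 0.44));
      acc_l = acc_e = acc_mu = acc_b = acc_px = acc_py = 0;
    }

    if (it >= burn) {
      int k = it - burn;
      out(k, 0) = mu;
      out(k, 1) = b;
      out(k, 2) = std::sqrt(s2f);
      out(k, 3) = std::sqrt(s2m);
      out(k, 4) = phix;
      out(k, 5) = phiy;
    }
  }

  colnames(out) = CharacterVector::create("mu_slope", "intercept", "sigma_fit",
                                          "sigma_mean", "phi_x", "phi_y");
  return List::create(_["draws"] = out,
                      _["steps"] = NumericVector::create(step_l, step_e, step_mu,
                                                         step_b, step_p));
}
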