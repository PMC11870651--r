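#include <Rcpp.h>
using namespace Rcpp;

// Shared settling kernel: rate code under pooled FFFB inhibition with a
// fixed excitatory drive. See settle.cpp for the exported single-layer
// version; this static copy avoids cross-TU linkage.
static void settle_core(const std::vector<double>& ge, int n,
                        double gbar_e, double gamma, double a, double b,
                        double Gi, double ff_gain, double ff_floor,
                        double fb_gain, double fb_tau, int n_cycles,
                        double tol, std::vector<double>& y) {
  y.assign(n, 0.0);
  double gemean = 0.0;
  for (int i = 0; i < n; ++i) gemean += ge[i];
  gemean /= n;
  double ff = ff_gain * std::max(0.0, gemean - ff_floor);
  double fb_avg = 0.0;
  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    double ymean = 0.0;
    for (int i = 0; i < n; ++i) ymean += y[i];
    ymean /= n;
    fb_avg += fb_tau * (ymean - fb_avg);
    double gi = Gi * (ff + fb_gain * fb_avg);
    double theta = a * gi + b;
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double excess = ge[i] * gbar_e - theta;
      double tgt = 0.0;
      if (excess > 0) {
        double gx = gamma * excess;
        tgt = gx / (1.0 + gx);
      }
      double ynew = y[i] + 0.5 * (tgt - y[i]);
      double d = std::fabs(ynew - y[i]);
      if (d > delta) delta = d;
      y[i] = ynew;
    }
    if (delta < tol) break;
  }
}

// population-vector decode; returns resultant length, writes angle
static double decode_angle(const std::vector<double>& y,
                           const std::vector<double>& cosp,
                           const std::vector<double>& sinp,
                           double& theta) {
  double tot = 0.0, zx = 0.0, zy = 0.0;
  const int n = (int)y.size();
  for (int i = 0; i < n; ++i) {
    tot += y[i];
    zx += y[i] * cosp[i];
    zy += y[i] * sinp[i];
  }
  if (tot <= 0) { theta = NA_REAL; return 0.0; }
  zx /= tot; zy /= tot;
  double r = std::sqrt(zx * zx + zy * zy);
  theta = std::atan2(zy, zx);
  if (theta < 0) theta += 2.0 * M_PI;
  return r;
}

// positive remainder modulo 2*pi without fmod (keeps the shared object
// free of recently versioned libm symbols)
static inline double wrap2pi(double x) {
  const double tau = 2.0 * M_PI;
  return x - tau * std::floor(x / tau);
}

static double circ_err_deg(double a, double b) {
  double d = wrap2pi(a - b);
  if (d > M_PI) d -= 2.0 * M_PI;
  return d * 180.0 / M_PI;
}

// Run a block of episodes through the full circuit, mutating the learned
// state in place (the caller passes fresh copies). All randomness comes in
// through `task`, pre-generated from R's RNG, so results are reproducible
// and the compiled path can be compared against the R reference
// implementation on identical inputs.
// [[Rcpp::export(name = ".run_episodes_core")]]
List run_episodes_core(List net, List cfg, List task, bool learn) {
  NumericMatrix go_in = clone(as<NumericMatrix>(net["go_in"]));
  NumericMatrix nogo_in = clone(as<NumericMatrix>(net["nogo_in"]));
  NumericMatrix go_out = clone(as<NumericMatrix>(net["go_out"]));
  NumericMatrix nogo_out = clone(as<NumericMatrix>(net["nogo_out"]));
  NumericMatrix w_direct = clone(as<NumericMatrix>(net["w_direct"]));
  List w_pfc_in = net["w_pfc_out"];
  double V = as<double>(net["V"]);

  const int ns = as<int>(cfg["ns"]);
  const int nu = as<int>(cfg["nu"]);
  const int n_store = as<int>(cfg["n_store"]);
  const int chunk_stripe = as<int>(cfg["chunk_stripe"]); // 0-based, -1 none
  const int nc = go_in.nrow();
  const int n_orient = as<int>(cfg["n_orient"]);
  const double bump_w2 = 2.0 * std::pow(as<double>(cfg["bump_width"]), 2);
  const double tag_decay = as<double>(cfg["tag_decay"]);
  const double gate_decay = as<double>(cfg["gate_decay"]);
  const double suppress_scale = as<double>(cfg["suppress_scale"]);
  const double lrate_go = as<double>(cfg["lrate_go"]);
  const double lrate_nogo = as<double>(cfg["lrate_nogo"]);
  const double lrate_out = as<double>(cfg["lrate_out"]);
  const double w_decay = as<double>(cfg["w_decay"]);
  const double target_amp = as<double>(cfg["target_amp"]);
  const double alpha_v = as<double>(cfg["alpha_v"]);
  const double burst_gain = as<double>(cfg["burst_gain"]);
  const double dip_gain = as<double>(cfg["dip_gain"]);
  const double reward_span = as<double>(cfg["reward_span"]);
  const double resultant_floor = as<double>(cfg["resultant_floor"]);
  const double out_floor = as<double>(cfg["out_floor"]);
  const double gate_compete = as<double>(cfg["gate_compete"]);

  // settling constants: chunk layer and response layer
  NumericVector chs = cfg["chunk_settle"];   // gbar_e,gamma,a,b,Gi,ff_gain,ff_floor,fb_gain,fb_tau,cycles
  NumericVector outs = cfg["out_settle"];
  NumericMatrix kernel = cfg["chunk_kernel"]; // nu x nu (empty 0x0 if no chunk)
  const double in_scale = as<double>(cfg["chunk_in_scale"]);
  const double pfc_scale = as<double>(cfg["chunk_pfc_scale"]);
  const double total_rel = as<double>(cfg["chunk_total_rel"]);

  IntegerMatrix t_orient = task["orient"];   // K x n_store
  NumericMatrix t_color = task["colors"];    // K x n_store
  IntegerVector t_probe = task["probe"];     // K, 1-based
  NumericMatrix t_noise = task["noise"];     // K x (n_store+1)*ns
  NumericVector t_guess = task["guess"];     // K, uniform angle

  const int K = t_probe.size();

  std::vector<double> cosp(nu), sinp(nu), pref(nu);
  for (int i = 0; i < nu; ++i) {
    pref[i] = 2.0 * M_PI * i / nu;
    cosp[i] = std::cos(pref[i]);
    sinp[i] = std::sin(pref[i]);
  }
  auto encode = [&](double theta, std::vector<double>& out, double amp) {
    for (int i = 0; i < nu; ++i) {
      double d = wrap2pi(pref[i] - theta);
      if (d > M_PI) d -= 2.0 * M_PI;
      out[i] = amp * std::exp(-(d * d) / bump_w2);
    }
  };

  // flatten per-stripe readout weights for fast access
  std::vector<NumericMatrix> w_pfc(ns);
  for (int j = 0; j < ns; ++j)
    w_pfc[j] = clone(as<NumericMatrix>(w_pfc_in[j]));

  NumericMatrix records(K, 7 + ns);
  std::vector<double> deep(nu * ns), sens(nu), chunk_ge(nu), chunk_y(nu),
      superf(nu), resp_ge(nu), resp_y(nu), tb(nu);
  std::vector<double> tags_in(nc * ns), tags_out(nc * ns),
      tags_in_s(nc * ns), tags_out_s(nc * ns), control(nc);
  std::vector<int> maintained(ns);
  std::vector<double> drives(ns);
  std::vector<int> fired(ns);

  for (int k = 0; k < K; ++k) {
    std::fill(deep.begin(), deep.end(), 0.0);
    std::fill(maintained.begin(), maintained.end(), 0);
    std::fill(tags_in.begin(), tags_in.end(), 0.0);
    std::fill(tags_out.begin(), tags_out.end(), 0.0);
    std::fill(tags_in_s.begin(), tags_in_s.end(), 0.0);
    std::fill(tags_out_s.begin(), tags_out_s.end(), 0.0);

    for (int t = 0; t < n_store; ++t) {
      double theta = t_color(k, t);
      encode(theta, sens, 1.0);
      // chunk-layer settle on the current stimulus given maintained content
      double m_theta = theta;
      if (chunk_stripe >= 0) {
        for (int i = 0; i < nu; ++i) {
          double acc = 0.0;
          for (int s = 0; s < nu; ++s) acc += kernel(s, i) * sens[s];
          chunk_ge[i] = in_scale * acc / nu;
        }
        for (int j = 0; j < ns; ++j) {
          if (!maintained[j]) continue;
          const double* dj = &deep[j * nu];
          for (int i = 0; i < nu; ++i) {
            double acc = 0.0;
            for (int s = 0; s < nu; ++s) acc += kernel(s, i) * dj[s];
            chunk_ge[i] += pfc_scale * acc / nu;
          }
        }
        for (int i = 0; i < nu; ++i) chunk_ge[i] /= total_rel;
        settle_core(chunk_ge, nu, chs[0], chs[1], chs[2], chs[3], chs[4],
                    chs[5], chs[6], chs[7], chs[8], (int)chs[9], 1e-4,
                    chunk_y);
        double th_dec;
        double r = decode_angle(chunk_y, cosp, sinp, th_dec);
        if (r >= 0.05) m_theta = th_dec;
      }
      // control inputs: orientation one-hot, store bit, occupancy
      std::fill(control.begin(), control.end(), 0.0);
      control[t_orient(k, t) - 1] = 1.0;
      control[n_orient] = 1.0;
      for (int j = 0; j < ns; ++j)
        control[n_orient + 2 + j] = maintained[j] ? 1.0 : 0.0;
      // input gating decisions (independent thresholds)
      for (int j = 0; j < ns; ++j) {
        double d = 0.0;
        for (int c = 0; c < nc; ++c)
          d += (go_in(c, j) - nogo_in(c, j)) * control[c];
        d += t_noise(k, t * ns + j);
        fired[j] = d > 0;
      }
      for (int j = 0; j < ns; ++j) {
        if (fired[j]) {
          if (j == chunk_stripe) {
            encode(m_theta, superf, 1.0);
          } else {
            std::copy(sens.begin(), sens.end(), superf.begin());
          }
          std::copy(superf.begin(), superf.end(), deep.begin() + j * nu);
          maintained[j] = 1;
          for (int c = 0; c < nc; ++c) tags_in[j * nc + c] += control[c];
        } else {
          for (int c = 0; c < nc; ++c) tags_in_s[j * nc + c] += control[c];
        }
      }
      // direct report pathway trains on every store trial
      if (learn) {
        double mx = 0.0;
        for (int i = 0; i < nu; ++i) {
          double acc = 0.0;
          for (int s = 0; s < nu; ++s) acc += w_direct(s, i) * sens[s];
          resp_ge[i] = acc / nu;
          if (resp_ge[i] > mx) mx = resp_ge[i];
        }
        if (mx < out_floor) {
          std::fill(resp_y.begin(), resp_y.end(), 0.0);
        } else {
          settle_core(resp_ge, nu, outs[0], outs[1], outs[2], outs[3],
                      outs[4], outs[5], outs[6], outs[7], outs[8],
                      (int)outs[9], 1e-4, resp_y);
        }
        const double wd = 1.0 - w_decay;
        for (int i = 0; i < nu; ++i) {
          double err = target_amp * sens[i] - resp_y[i];
          for (int s = 0; s < nu; ++s) {
            double w = wd * w_direct(s, i) + lrate_out * sens[s] * err;
            w_direct(s, i) = std::min(1.0, std::max(0.0, w));
          }
        }
      }
      for (int i = 0; i < nc * ns; ++i) {
        tags_in[i] *= tag_decay; tags_out[i] *= tag_decay;
        tags_in_s[i] *= tag_decay; tags_out_s[i] *= tag_decay;
      }
    }
    // occupancy at maximal load
    int n_occ = 0;
    for (int j = 0; j < ns; ++j) n_occ += maintained[j];
    // recall probe
    const int probe = t_probe[k] - 1;
    const double target = t_color(k, probe);
    std::fill(control.begin(), control.end(), 0.0);
    control[t_orient(k, probe) - 1] = 1.0;
    control[n_orient + 1] = 1.0;
    for (int j = 0; j < ns; ++j)
      control[n_orient + 2 + j] = maintained[j] ? 1.0 : 0.0;
    for (int j = 0; j < ns; ++j) {
      double d = 0.0;
      for (int c = 0; c < nc; ++c)
        d += (go_out(c, j) - nogo_out(c, j)) * control[c];
      d += t_noise(k, n_store * ns + j);
      drives[j] = d;
    }
    // pallidal competition on read-out
    if (ns > 1 && gate_compete > 0) {
      double mx1 = 0.0, mx2 = 0.0; int i1 = -1;
      for (int j = 0; j < ns; ++j) {
        double dp = std::max(drives[j], 0.0);
        if (dp > mx1) { mx2 = mx1; mx1 = dp; i1 = j; }
        else if (dp > mx2) mx2 = dp;
      }
      for (int j = 0; j < ns; ++j)
        drives[j] -= gate_compete * (j == i1 ? mx2 : mx1);
    }
    int n_fired = 0;
    std::fill(resp_ge.begin(), resp_ge.end(), 0.0);
    for (int j = 0; j < ns; ++j) {
      fired[j] = drives[j] > 0;
      if (fired[j]) {
        ++n_fired;
        for (int c = 0; c < nc; ++c) tags_out[j * nc + c] += control[c];
        const double* dj = &deep[j * nu];
        NumericMatrix& wj = w_pfc[j];
        for (int i = 0; i < nu; ++i) {
          double acc = 0.0;
          for (int s = 0; s < nu; ++s) acc += wj(s, i) * dj[s];
          resp_ge[i] += acc / nu;
        }
      } else {
        for (int c = 0; c < nc; ++c) tags_out_s[j * nc + c] += control[c];
      }
    }
    bool decodable = false;
    double reported = NA_REAL;
    if (n_fired > 0) {
      double mx = 0.0;
      for (int i = 0; i < nu; ++i) {
        resp_ge[i] /= n_fired;
        if (resp_ge[i] > mx) mx = resp_ge[i];
      }
      if (mx < out_floor) {
        std::fill(resp_y.begin(), resp_y.end(), 0.0);
      } else {
        settle_core(resp_ge, nu, outs[0], outs[1], outs[2], outs[3], outs[4],
                    outs[5], outs[6], outs[7], outs[8], (int)outs[9], 1e-4,
                    resp_y);
      }
      double th_dec;
      double r = decode_angle(resp_y, cosp, sinp, th_dec);
      if (r >= resultant_floor) { decodable = true; reported = th_dec; }
    } else {
      std::fill(resp_y.begin(), resp_y.end(), 0.0);
    }
    const bool non_resp = (n_fired == 0) || !decodable;
    const double eff_report = non_resp ? t_guess[k] : reported;
    const double err = circ_err_deg(eff_report, target);
    const double reward = 1.0 - std::fabs(err) / reward_span;
    const double delta = reward - V;
    V += alpha_v * delta;
    const double eff = delta > 0 ? burst_gain * delta : dip_gain * delta;
    if (learn) {
      const double gd = 1.0 - gate_decay;
      for (int j = 0; j < ns; ++j) {
        for (int c = 0; c < nc; ++c) {
          double ti = tags_in[j * nc + c] - suppress_scale * tags_in_s[j * nc + c];
          double to = tags_out[j * nc + c] - suppress_scale * tags_out_s[j * nc + c];
          go_in(c, j) = std::min(1.0, std::max(0.0, gd * go_in(c, j) + lrate_go * eff * ti));
          nogo_in(c, j) = std::min(1.0, std::max(0.0, gd * nogo_in(c, j) - lrate_nogo * eff * ti));
          go_out(c, j) = std::min(1.0, std::max(0.0, gd * go_out(c, j) + lrate_go * eff * to));
          nogo_out(c, j) = std::min(1.0, std::max(0.0, gd * nogo_out(c, j) - lrate_nogo * eff * to));
        }
      }
      // supervised read-out mapping for every stripe that was gated out
      encode(target, tb, target_amp);
      const double wd = 1.0 - w_decay;
      for (int j = 0; j < ns; ++j) {
        if (!(fired[j] && maintained[j])) continue;
        const double* dj = &deep[j * nu];
        NumericMatrix& wj = w_pfc[j];
        for (int i = 0; i < nu; ++i) {
          double errj = tb[i] - resp_y[i];
          for (int s = 0; s < nu; ++s) {
            double w = wd * wj(s, i) + lrate_out * dj[s] * errj;
            wj(s, i) = std::min(1.0, std::max(0.0, w));
          }
        }
      }
    }
    // out-of-cluster variance of the non-probed items (degrees)
    double ocv = NA_REAL;
    if (n_store >= 3) {
      double cx = 0.0, cy = 0.0;
      for (int t = 0; t < n_store; ++t) {
        if (t == probe) continue;
        cx += std::cos(t_color(k, t));
        cy += std::sin(t_color(k, t));
      }
      cx /= (n_store - 1); cy /= (n_store - 1);
      double R = std::sqrt(cx * cx + cy * cy);
      if (R > 1.0) R = 1.0;
      ocv = R <= 0 ? R_PosInf : std::sqrt(-2.0 * std::log(R)) * 180.0 / M_PI;
    }
    records(k, 0) = err;
    records(k, 1) = reward;
    records(k, 2) = delta;
    records(k, 3) = non_resp ? 1.0 : 0.0;
    records(k, 4) = n_fired;
    records(k, 5) = n_store - probe;  // lag in trials
    records(k, 6) = ocv;
    for (int j = 0; j < ns; ++j) records(k, 7 + j) = maintained[j];
  }

  List w_out(ns);
  for (int j = 0; j < ns; ++j) w_out[j] = w_pfc[j];
  return List::create(_["go_in"] = go_in, _["nogo_in"] = nogo_in,
                      _["go_out"] = go_out, _["nogo_out"] = nogo_out,
                      _["w_direct"] = w_direct, _["w_pfc_out"] = w_out,
                      _["V"] = V, _["records"] = records);
}
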