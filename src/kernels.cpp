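// Time-stepped kernels: analog-substrate emulation (forward) and BPTT through
// the unrolled LIF computation graph (backward). These loops dominate runtime,
// hence compiled; all randomness goes through R's RNG so results are
// reproducible from set.seed().
//
// Conventions shared with the R level:
//  * input cube x: (batch, n_in, T), slice t = spikes in sampling bin t
//    (0-based); bin t feeds the synaptic current entering state t+1.
//  * state/recording cubes: slice j holds the state at sampling step j+1,
//    j = 0..T-1 (state 0 is the initial condition and is not recorded).
//  * the substrate integrates at fine step delta = dt / fine_factor; membrane
//    values at sampling boundaries reproduce the coarse-grid recursion
//    V[t+1] = V[t]*exp(-dt/tau_m) + I[t],  I[t+1] = I[t]*exp(-dt/tau_s) + W*S[t]
//    exactly for bin-aligned inputs, for any fine_factor (see step_alpha).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec step_alpha(const arma::vec& mum, const arma::vec& mus, int F) {
  // alpha * (mum^F - mus^F) / (mum - mus) == 1, so F fine substeps compose to
  // one coarse step with unit coupling of I into V.
  arma::vec a(mum.n_elem);
  for (arma::uword i = 0; i < mum.n_elem; ++i) {
    double dm = mum(i) - mus(i);
    if (std::fabs(dm) < 1e-12) {
      a(i) = 1.0 / (F * std::pow(mum(i), F - 1));
    } else {
      a(i) = dm / (std::pow(mum(i), F) - std::pow(mus(i), F));
    }
  }
  return a;
}

static void add_noise(arma::mat& m, double sd) {
  if (sd <= 0.0) return;
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) += R::norm_rand() * sd;
}

// leaky integration step: out = v_leak + (V - v_leak) .* mum + I .* alpha
static arma::mat leak_step(const arma::mat& V, const arma::mat& I,
                           const arma::vec& v_leak, const arma::vec& mum,
                           const arma::vec& alpha) {
  arma::mat out = V;
  out.each_row() -= v_leak.t();
  out.each_row() %= mum.t();
  out.each_row() += v_leak.t();
  arma::mat drive = I;
  drive.each_row() %= alpha.t();
  return out + drive;
}

// [[Rcpp::export]]
List substrate_kernel(const arma::cube& x,
                      const arma::mat& w_in, const arma::mat& w_rec,
                      const arma::mat& w_out,
                      const arma::vec& tau_m_h, const arma::vec& tau_s_h,
                      const arma::vec& thr_h, const arma::vec& v_leak_h,
                      const arma::vec& v_reset_h,
                      const arma::vec& tau_m_o, const arma::vec& tau_s_o,
                      const arma::vec& v_leak_o,
                      double dt, int fine_factor,
                      double mem_sd, double readout_sd,
                      const arma::vec& mask, const arma::vec& i_ext,
                      bool record_events,
                      const arma::mat& v0_h, const arma::mat& i0_h,
                      const arma::mat& v0_o, const arma::mat& i0_o,
                      int refractory) {
  const int B = x.n_rows, T = x.n_slices;
  const int n_h = w_in.n_rows, n_out = w_out.n_rows;
  const bool rec = w_rec.n_elem > 0;
  const int F = fine_factor;
  const double delta = dt / F;

  arma::vec mum_h = arma::exp(-delta / tau_m_h), mus_h = arma::exp(-delta / tau_s_h);
  arma::vec mum_o = arma::exp(-delta / tau_m_o), mus_o = arma::exp(-delta / tau_s_o);
  arma::vec alpha_h = step_alpha(mum_h, mus_h, F);
  arma::vec alpha_o = step_alpha(mum_o, mus_o, F);
  // exact exponential integration of a constant external drive over one delta
  arma::vec dext = tau_m_h % (1.0 - mum_h) % i_ext;
  const bool has_ext = arma::any(arma::abs(i_ext) > 0);
  const double fine_noise = mem_sd > 0 ? mem_sd / std::sqrt((double)F) : 0.0;

  arma::mat V = v0_h.n_elem ? v0_h : arma::repmat(v_leak_h.t(), B, 1);
  arma::mat I = i0_h.n_elem ? i0_h : arma::mat(B, n_h, arma::fill::zeros);
  arma::mat Vo = v0_o.n_elem ? v0_o : arma::repmat(v_leak_o.t(), B, 1);
  arma::mat Io = i0_o.n_elem ? i0_o : arma::mat(B, n_out, arma::fill::zeros);
  arma::imat refrac(B, n_h, arma::fill::zeros);

  // spikes at the current fine step (state 0 can fire only for
  // leak-over-threshold units)
  arma::mat S(B, n_h, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < n_h; ++j)
      if (mask(j) > 0 && V(b, j) >= thr_h(j)) S(b, j) = 1.0;

  arma::cube v_h(B, n_h, T), s_h(B, n_h, T, arma::fill::zeros), v_o(B, n_out, T);
  std::vector<double> ev_time; std::vector<int> ev_neuron, ev_sample;

  for (int n = 0; n < T * F; ++n) {
    const int bin = n / F;
    // membrane updates use the pre-update currents (I[t] feeds V[t+1])
    arma::mat Vnew = leak_step(V, I, v_leak_h, mum_h, alpha_h);
    if (has_ext) Vnew.each_row() += dext.t();
    add_noise(Vnew, fine_noise);
    arma::mat Vonew = leak_step(Vo, Io, v_leak_o, mum_o, alpha_o);
    // reset at the step after threshold crossing
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < n_h; ++j) {
        if (S(b, j) > 0) { Vnew(b, j) = v_reset_h(j); refrac(b, j) = refractory; }
        else if (refrac(b, j) > 0) { Vnew(b, j) = v_reset_h(j); refrac(b, j)--; }
      }

    // synaptic currents: I[n+1] = I[n]*mus + inputs at fine step n;
    // bin-aligned input events enter at the last substep of their bin
    I.each_row() %= mus_h.t();
    if (n % F == F - 1) I += x.slice(bin) * w_in.t();
    if (rec) I += S * w_rec.t();
    Io.each_row() %= mus_o.t();
    Io += S * w_out.t();

    V = Vnew; Vo = Vonew;
    S.zeros();
    for (int b = 0; b < B; ++b)
      for (int j = 0; j < n_h; ++j)
        if (mask(j) > 0 && refrac(b, j) == 0 && V(b, j) >= thr_h(j)) S(b, j) = 1.0;

    if (!V.is_finite() || !Vo.is_finite())
      stop("substrate state became non-finite at fine step %d", n + 1);

    // fine index n+1 lies in sampling bin ceil((n+1)/F)
    const int sbin = (n + 1 + F - 1) / F;  // 1..T
    if (sbin <= T && arma::accu(S) > 0) {
      s_h.slice(sbin - 1) = arma::clamp(s_h.slice(sbin - 1) + S, 0.0, 1.0);
      if (record_events)
        for (int b = 0; b < B; ++b)
          for (int j = 0; j < n_h; ++j)
            if (S(b, j) > 0) {
              ev_time.push_back((n + 1) * delta);
              ev_neuron.push_back(j + 1);
              ev_sample.push_back(b + 1);
            }
    }
    if ((n + 1) % F == 0) {
      const int t = (n + 1) / F - 1;
      v_h.slice(t) = V; v_o.slice(t) = Vo;
      if (readout_sd > 0) { add_noise(v_h.slice(t), readout_sd); add_noise(v_o.slice(t), readout_sd); }
    }
  }

  arma::mat events(ev_time.size(), 3);
  for (size_t k = 0; k < ev_time.size(); ++k) {
    events(k, 0) = ev_time[k]; events(k, 1) = ev_neuron[k]; events(k, 2) = ev_sample[k];
  }
  return List::create(_["v_hidden"] = v_h, _["s_hidden"] = s_h, _["v_out"] = v_o,
                      _["events"] = events,
                      _["final"] = List::create(_["v_h"] = V, _["i_h"] = I,
                                                _["v_o"] = Vo, _["i_o"] = Io));
}

static inline double surr_deriv(double v, double thr, double beta, int form, double eps) {
  const double u = std::fabs(v - thr);
  switch (form) {
  case 0: { const double d = 1.0 + beta * u; return 1.0 / (d * d); }           // regularized
  case 1: { const double d = beta * std::max(u, eps); return 1.0 / (d * d); }  // as printed, floored
  default: return 0.0;                                                         // disabled
  }
}

// BPTT through the unrolled graph. s_h / v_h are the forward-used spike and
// membrane values (recorded ones under trace injection, model ones in pure
// simulation); g_vout and g_sh are the direct loss gradients w.r.t. the
// output traces and hidden spikes. Returns weight gradients summed over the
// batch (loss gradients are expected to carry any 1/batch factor).
// [[Rcpp::export]]
List graph_backward_kernel(const arma::cube& x, const arma::cube& s_h,
                           const arma::cube& v_h,
                           const arma::cube& g_vout, const arma::cube& g_sh,
                           const arma::mat& w_in, const arma::mat& w_rec,
                           const arma::mat& w_out,
                           const arma::vec& lam_m_h, const arma::vec& lam_s_h,
                           const arma::vec& lam_m_o, const arma::vec& lam_s_o,
                           const arma::vec& thr,
                           double beta, int surr_form, double surr_eps,
                           const arma::vec& mask, bool detach_reset) {
  const int B = x.n_rows, n_in = x.n_cols, T = x.n_slices;
  const int n_h = s_h.n_cols, n_out = g_vout.n_cols;
  const bool rec = w_rec.n_elem > 0;

  arma::cube i_model;
  if (!detach_reset) {
    // replay the model current recursion I[t] = I[t-1]*lam_s + W_in X[t-1]
    // + W_rec S[t-1]; needed for the reset-gate gradient
    i_model.set_size(B, n_h, T);
    arma::mat I(B, n_h, arma::fill::zeros);
    for (int t = 1; t <= T; ++t) {
      I.each_row() %= lam_s_h.t();
      I += x.slice(t - 1) * w_in.t();
      if (rec && t >= 2) I += s_h.slice(t - 2) * w_rec.t();
      i_model.slice(t - 1) = I;
    }
  }

  arma::mat gW_in(n_h, n_in, arma::fill::zeros);
  arma::mat gW_rec(rec ? n_h : 0, rec ? n_h : 0, arma::fill::zeros);
  arma::mat gW_out(n_out, n_h, arma::fill::zeros);

  arma::mat aV(B, n_h, arma::fill::zeros), aI(B, n_h, arma::fill::zeros);
  arma::mat aVo(B, n_out, arma::fill::zeros), aIo(B, n_out, arma::fill::zeros);

  for (int t = T; t >= 1; --t) {
    const int j = t - 1;
    // output layer: V_o[t+1] = V_o[t]*lam_m + I_o[t];  I_o[t+1] = I_o[t]*lam_s + W_out S[t]
    arma::mat aVo_t = g_vout.slice(j);
    { arma::mat d = aVo; d.each_row() %= lam_m_o.t(); aVo_t += d; }
    arma::mat aIo_t = aVo;
    { arma::mat d = aIo; d.each_row() %= lam_s_o.t(); aIo_t += d; }

    // gradient w.r.t. S[t]: consumers are I[t+1] (recurrent), I_o[t+1],
    // the reset gate on V[t+1], and any direct regularizer term
    arma::mat gS = g_sh.slice(j) + aIo * w_out;
    if (rec) gS += aI * w_rec;
    if (!detach_reset) {
      // reset gate on V[t+1] = (1 - S[t]) * (V[t]*lam_m + I[t])
      arma::mat vcur = v_h.slice(j);
      vcur.each_row() %= lam_m_h.t();
      gS -= (vcur + i_model.slice(j)) % aV;
    }

    // surrogate route: dS~[t]/dV~[t], evaluated on the forward-used membrane
    arma::mat sd(B, n_h);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < n_h; ++k)
        sd(b, k) = mask(k) * surr_deriv(v_h(b, k, j), thr(k), beta, surr_form, surr_eps);

    arma::mat gate = 1.0 - s_h.slice(j);
    arma::mat aV_t = aV;
    aV_t.each_row() %= lam_m_h.t();
    aV_t %= gate;
    aV_t += sd % gS;
    arma::mat aI_t = gate % aV;
    { arma::mat d = aI; d.each_row() %= lam_s_h.t(); aI_t += d; }

    // weight gradients: I[t] = I[t-1]*lam_s + W_in X[t-1] + W_rec S[t-1]
    gW_in += aI_t.t() * x.slice(j);
    if (t >= 2) {
      if (rec) gW_rec += aI_t.t() * s_h.slice(j - 1);
      gW_out += aIo_t.t() * s_h.slice(j - 1);
    }

    aV = aV_t; aI = aI_t; aVo = aVo_t; aIo = aIo_t;
  }

  return List::create(_["w_in"] = gW_in, _["w_rec"] = gW_rec, _["w_out"] = gW_out);
}
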