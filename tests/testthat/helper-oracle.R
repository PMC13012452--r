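# Closed-form oracles for the piecewise curve family, independent of the
# Euler integration / trapezoid paths in the package. Time is measured
# from the first emitted sample (at ignition volume v0); the ODE solution
# is exponential on the rising limb and power-law on the descending limb.

analytic_curve_solution <- function(params) {
  F <- params$fvc_true; P <- params$pef_true
  vp <- params$v_peak_frac * F; upk <- F - vp
  k <- params$shape_k; thr <- params$end_flow_threshold
  v0 <- min(P * params$dt, vp / 100)
  t_pk <- (vp / P) * log(vp / v0)
  u_end <- upk * (thr / P)^(1 / k)
  # time from peak to reach residual volume u (u <= upk)
  s_of_u <- function(u) {
    if (abs(k - 1) < 1e-12) (upk / P) * log(upk / u)
    else (u^(1 - k) - upk^(1 - k)) * upk^k / ((k - 1) * P)
  }
  # absolute exhaled volume at time t since first sample
  v_of_t <- function(t) {
    if (t <= t_pk) return(v0 * exp(P * t / vp))
    s <- t - t_pk
    u <- if (abs(k - 1) < 1e-12) {
      upk * exp(-P * s / upk)
    } else {
      base <- upk^(1 - k) + (k - 1) * P * s / upk^k
      if (k < 1 && base <= 0) 0 else base^(1 / (1 - k))
    }
    F - u
  }
  t_of_v <- function(v) {
    if (v <= vp) (vp / P) * log(v / v0) else t_pk + s_of_u(F - v)
  }
  list(F = F, P = P, vp = vp, upk = upk, k = k, v0 = v0,
       t_pk = t_pk, u_end = u_end, t_end = t_pk + s_of_u(u_end),
       v_of_t = v_of_t, t_of_v = t_of_v)
}

# Analytic values of the measured spirometric indices under the package's
# definitions (time zero at 5% of peak flow, volumes referenced to time
# zero, truncation at the end-flow threshold).
analytic_indices <- function(params) {
  sol <- analytic_curve_solution(params)
  v_t0 <- max(sol$v0, 0.05 * sol$vp)
  t0 <- if (sol$v0 >= 0.05 * sol$vp) 0 else sol$t_of_v(v_t0)
  fvc <- (sol$F - sol$u_end) - v_t0
  t_end <- sol$t_end
  fev1 <- if (t_end - t0 >= 1) sol$v_of_t(t0 + 1) - v_t0 else NA_real_
  t25 <- sol$t_of_v(v_t0 + 0.25 * fvc) - t0
  t75 <- sol$t_of_v(v_t0 + 0.75 * fvc) - t0
  list(FVC = fvc, FEV1 = fev1, PEF = sol$P,
       t25 = t25, t75 = t75,
       FEF25_75 = 0.5 * fvc / (t75 - t25),
       FEF75 = flow_at_volume(params, v_t0 + 0.75 * fvc))
}

# Concavity index of the truncated power-law limb under the package's
# chord definition (triangle from (v_peak, PEF) to the observed end).
analytic_truncated_concavity <- function(k, pef, thr) {
  r <- (thr / pef)^(1 / k)
  1 - 2 * (1 - r^(k + 1)) / ((k + 1) * (1 - r))
}

# Exhaustive pairwise AUROC oracle (Mann-Whitney with half ties).
bruteforce_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Threshold-enumeration AUPRC oracle (step-curve area).
bruteforce_auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0; r_prev <- 0
  for (th in ths) {
    called <- scores >= th
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / n1
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# Direct-count confusion-matrix oracle.
bruteforce_f1 <- function(dec, lab) {
  tp <- sum(dec == 1 & lab == 1); fp <- sum(dec == 1 & lab == 0)
  fn <- sum(dec == 0 & lab == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}
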