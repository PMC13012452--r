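#' Parameters of a synthetic forced-expiratory maneuver
#'
#' The curve family is piecewise in the volume domain: a linear rising limb
#' from zero flow to peak expiratory flow (PEF) at volume
#' `v_peak = v_peak_frac * fvc_true`, followed by a power-law descending
#' limb `PEF * ((FVC - v) / (FVC - v_peak))^shape_k`. The exponent
#' `shape_k` directly parameterises descending-limb morphology:
#' `k > 1` gives the concave ("scooped") limb characteristic of airflow
#' obstruction, `k = 1` a straight limb, `k < 1` a convex limb. This family
#' admits closed-form spirometric indices, which the test-suite oracles
#' exploit.
#'
#' @param fvc_true true forced vital capacity (L), > 0.
#' @param pef_true true peak expiratory flow (L/s), > 0.
#' @param v_peak_frac fraction of FVC at which peak flow occurs, in (0, 1).
#' @param shape_k descending-limb exponent, > 0.
#' @param noise_sd additive Gaussian flow noise (L/s), >= 0.
#' @param dt sampling interval (s), > 0.
#' @param end_flow_threshold flow (L/s) below which the maneuver is
#'   truncated (standard end-of-test flow criterion); >= 0. Needed because
#'   `k >= 1` curves approach FVC only asymptotically.
#' @return an object of class `spiro_curve_params`.
#' @export
#' @examples
#' p <- spiro_curve_params(fvc_true = 4.5, pef_true = 8, shape_k = 1)
#' flow_at_volume(p, 2)
spiro_curve_params <- function(fvc_true, pef_true, v_peak_frac = 0.2,
                               shape_k = 1, noise_sd = 0, dt = 0.01,
                               end_flow_threshold = 0.025) {
  stopifnot(is.numeric(fvc_true), fvc_true > 0,
            is.numeric(pef_true), pef_true > 0,
            v_peak_frac > 0, v_peak_frac < 1,
            shape_k > 0, noise_sd >= 0, dt > 0, end_flow_threshold >= 0)
  structure(list(fvc_true = fvc_true, pef_true = pef_true,
                 v_peak_frac = v_peak_frac, shape_k = shape_k,
                 noise_sd = noise_sd, dt = dt,
                 end_flow_threshold = end_flow_threshold),
            class = "spiro_curve_params")
}

#' @export
print.spiro_curve_params <- function(x, ...) {
  cat(sprintf(
    "<spiro_curve_params> FVC %.2f L, PEF %.2f L/s, peak at %.0f%% FVC, k = %.2f\n",
    x$fvc_true, x$pef_true, 100 * x$v_peak_frac, x$shape_k))
  invisible(x)
}

#' Instantaneous flow at a given exhaled volume
#'
#' Evaluates the noiseless flow-volume relationship of the piecewise curve
#' family: `PEF * v / v_peak` on the rising limb and
#' `PEF * ((FVC - v) / (FVC - v_peak))^k` on the descending limb.
#'
#' @param params a [spiro_curve_params()] object.
#' @param v exhaled volume (L); vectorised. Must lie in `[0, fvc_true]`.
#' @return flow (L/s), same length as `v`.
#' @export
flow_at_volume <- function(params, v) {
  stopifnot(inherits(params, "spiro_curve_params"), is.numeric(v))
  if (any(v < 0 | v > params$fvc_true)) {
    abort_spk(sprintf("volume outside [0, %.6g] L", params$fvc_true),
              "spirokit_domain_error")
  }
  v_peak <- params$v_peak_frac * params$fvc_true
  u_pk <- params$fvc_true - v_peak
  ifelse(v < v_peak,
         params$pef_true * v / v_peak,
         params$pef_true * ((params$fvc_true - v) / u_pk)^params$shape_k)
}

#' A sampled expiratory flow curve
#'
#' @param flow numeric vector of flow samples (L/s) at uniform spacing.
#' @param dt sampling interval (s).
#' @param blow_id integer blow index within a test session (>= 1).
#' @return an object of class `spiro_curve`.
#' @export
spiro_curve <- function(flow, dt, blow_id = 1L) {
  stopifnot(is.numeric(flow), length(flow) >= 2L, all(is.finite(flow)),
            is.numeric(dt), dt > 0, blow_id >= 1L)
  structure(list(flow = as.numeric(flow), dt = dt,
                 blow_id = as.integer(blow_id)),
            class = "spiro_curve")
}

#' @export
print.spiro_curve <- function(x, ...) {
  cat(sprintf("<spiro_curve> %d samples at dt = %g s (%.2f s), PEF %.2f L/s\n",
              length(x$flow), x$dt, (length(x$flow) - 1) * x$dt, max(x$flow)))
  invisible(x)
}

#' Synthesize a sampled expiratory maneuver
#'
#' Integrates `dv/dt = flow_at_volume(v)` by forward Euler with step `dt`.
#' Because `v = 0` is a fixed point of the rising limb (flow is
#' proportional to `v`), integration is seeded with a small ignition volume
#' `v0 = min(pef_true * dt, v_peak / 100)` (well under 1\% of FVC); the
#' emitted series starts at that sample. Gaussian noise of sd `noise_sd` is added to the recorded flow;
#' truncation (when the noiseless flow on the descending limb drops below
#' `end_flow_threshold`) is decided on the noiseless signal so curve length
#' is noise-independent.
#'
#' @param params a [spiro_curve_params()] object.
#' @param seed integer seed making the noise reproducible, or `NULL`.
#' @param blow_id blow index stored on the curve.
#' @param max_duration hard cap on maneuver duration (s) to guarantee
#'   termination when `end_flow_threshold = 0`.
#' @return a [spiro_curve()].
#' @export
synthesize_curve <- function(params, seed = NULL, blow_id = 1L,
                             max_duration = 30) {
  stopifnot(inherits(params, "spiro_curve_params"))
  dt <- params$dt
  v_peak <- params$v_peak_frac * params$fvc_true
  v0 <- min(params$pef_true * dt, v_peak / 100)
  n_max <- ceiling(max_duration / dt)
  flow <- numeric(n_max)
  v <- v0
  n <- 0L
  past_peak <- FALSE
  repeat {
    f <- flow_at_volume(params, min(v, params$fvc_true))
    if (!past_peak && v >= v_peak) past_peak <- TRUE
    if (!past_peak && f <= 0) {
      abort_spk("integration stalled before peak flow (flow <= 0)",
                "spirokit_generation_error")
    }
    if (past_peak && f < params$end_flow_threshold) break
    n <- n + 1L
    flow[n] <- f
    if (n >= n_max) break
    v <- min(v + dt * f, params$fvc_true)
    if (v >= params$fvc_true) {
      # k < 1 limbs hit FVC in finite time; emit the terminal zero-flow sample
      n <- n + 1L
      flow[n] <- 0
      break
    }
  }
  if (n < 2L) {
    abort_spk("maneuver truncated before 2 samples; lower end_flow_threshold",
              "spirokit_generation_error")
  }
  flow <- flow[seq_len(n)]
  if (params$noise_sd > 0) {
    flow <- with_seed(seed, flow + stats::rnorm(n, sd = params$noise_sd))
  }
  spiro_curve(flow, dt, blow_id = blow_id)
}

#' Sample synthetic demographics
#'
#' Draws age (uniform), height (sex-specific normal), sex, and smoking
#' status from configurable distributions. Defaults emulate a middle-aged
#' general-population screening cohort.
#'
#' @param n number of subjects (>= 0).
#' @param seed integer seed or `NULL`.
#' @param config list with elements `age_range` (years), `height_mean`
#'   (named c(male=, female=), cm), `height_sd` (cm), `p_male`,
#'   `smoking_probs` (named probabilities for never/former/current).
#' @return a data.frame with columns age, sex, height, smoking.
#' @export
sample_demographics <- function(n, seed = NULL, config = list()) {
  stopifnot(n >= 0)
  cfg <- utils::modifyList(list(
    age_range = c(40, 70),
    height_mean = c(male = 176, female = 163),
    height_sd = 7,
    p_male = 0.5,
    smoking_probs = c(never = 0.45, former = 0.35, current = 0.20)
  ), config)
  if (n == 0) {
    return(data.frame(age = numeric(0), sex = character(0),
                      height = numeric(0), smoking = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    height <- stats::rnorm(n, mean = cfg$height_mean[sex], sd = cfg$height_sd)
    height <- pmax(height, 120)
    smoking <- sample(names(cfg$smoking_probs), n, replace = TRUE,
                      prob = cfg$smoking_probs)
    data.frame(age = age, sex = sex, height = height, smoking = smoking,
               stringsAsFactors = FALSE)
  })
}

#' Default cohort effect configuration
#'
#' Controls how COPD status maps onto curve parameters. Controls draw the
#' descending-limb exponent near 1 (straight/convex limb); cases draw it
#' above the obstructive threshold (concave limb) and get multiplicative
#' depression of peak flow and vital capacity, the synthetic analogue of
#' airflow limitation. `blow_jitter_sd` is the sd of the multiplicative
#' between-blow FVC jitter used to exercise repeatability filters;
#' `label_noise` is the probability that a subject's diagnosis label (and
#' codes) contradict their physiology.
#'
#' @param control_k_range,case_k_range ranges of `shape_k` per class.
#' @param case_pef_scale,case_fvc_scale ranges of the multiplicative
#'   depression applied to case PEF and FVC.
#' @param blow_jitter_sd between-blow multiplicative FVC jitter sd.
#' @param n_blows blows per subject (>= 2).
#' @param label_noise label-flip probability in [0, 1).
#' @param noise_sd additive flow noise (L/s) on every curve.
#' @param dt sampling interval (s).
#' @return a list of class `spiro_effect_config`.
#' @export
effect_config <- function(control_k_range = c(0.7, 1.3),
                          case_k_range = c(2.0, 4.0),
                          case_pef_scale = c(0.55, 0.8),
                          case_fvc_scale = c(0.72, 0.92),
                          blow_jitter_sd = 0.03,
                          n_blows = 2L,
                          label_noise = 0,
                          noise_sd = 0.05,
                          dt = 0.01) {
  stopifnot(n_blows >= 1L, label_noise >= 0, label_noise < 1)
  structure(list(control_k_range = control_k_range,
                 case_k_range = case_k_range,
                 case_pef_scale = case_pef_scale,
                 case_fvc_scale = case_fvc_scale,
                 blow_jitter_sd = blow_jitter_sd,
                 n_blows = as.integer(n_blows),
                 label_noise = label_noise,
                 noise_sd = noise_sd,
                 dt = dt),
            class = "spiro_effect_config")
}

#' Separable synthetic classification benchmark
#'
#' Noiseless curves whose only class-linked property is descending-limb
#' morphology: class 0 draws `shape_k = 0.8` (convex limb), class 1
#' `shape_k = 3` (strongly scooped limb); FVC, PEF and peak position are
#' drawn from common ranges so amplitude and duration carry minimal label
#' information. Used to verify that the encoder can recover a clean
#' morphological signal.
#'
#' @param n total curves (half per class).
#' @param seed integer seed.
#' @param k_classes length-2 vector of exponents for class 0 / class 1.
#' @param dt sampling interval (s).
#' @return list with `curves`, `labels`.
#' @export
separable_benchmark <- function(n = 400L, seed = 1L,
                                k_classes = c(0.8, 3), dt = 0.01) {
  with_seed(seed, {
    labels <- rep(c(0L, 1L), length.out = n)
    curves <- lapply(seq_len(n), function(i) {
      p <- spiro_curve_params(
        fvc_true = stats::runif(1, 3, 6),
        pef_true = stats::runif(1, 5, 9),
        v_peak_frac = stats::runif(1, 0.15, 0.28),
        shape_k = k_classes[labels[i] + 1L],
        noise_sd = 0, dt = dt)
      synthesize_curve(p, blow_id = 1L)
    })
    list(curves = curves, labels = labels)
  })
}

# ICD-10-style and self-report codes used for synthetic diagnoses.
copd_code_pool <- c("J430", "J439", "J440", "J441", "J449")
copd_self_report_pool <- c("SR-COPD", "SR-EMPHYSEMA")
noncopd_code_pool <- c("J45", "I10", "E11", "")

#' Generate a synthetic labelled cohort
#'
#' Builds `n` subject records: demographics drive expected lung volumes
#' through the synthetic LMS reference table (subject FVC is the predicted
#' value perturbed on the LMS z scale), disease status (Bernoulli with the
#' given prevalence) drives curve morphology through [effect_config()], and
#' diagnosis codes are sampled to match the label (or to contradict the
#' physiology for the `label_noise` fraction). Each subject contributes
#' `n_blows` repeated maneuvers with multiplicative FVC jitter.
#'
#' @param n number of subjects.
#' @param prevalence COPD prevalence in [0, 1].
#' @param config an [effect_config()].
#' @param seed integer seed or `NULL`.
#' @param demo_config passed to [sample_demographics()].
#' @param coeffs LMS table (see [lms_synthetic_table()]) used to map
#'   demographics to expected FVC.
#' @return a list of records, each with fields `subject_id`, `curves`
#'   (list of [spiro_curve()]), `demographics` (one-row data.frame),
#'   `diagnosis_codes`, `label`, and `params` (the per-subject true curve
#'   parameters, retained for oracle checks).
#' @export
generate_cohort <- function(n, prevalence = 0.5, config = effect_config(),
                            seed = NULL, demo_config = list(),
                            coeffs = lms_synthetic_table()) {
  stopifnot(n >= 0, prevalence >= 0, prevalence <= 1,
            inherits(config, "spiro_effect_config"))
  demo <- sample_demographics(n, seed = seed, demo_config)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    labels <- as.integer(stats::runif(n) < prevalence)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      d <- demo[i, , drop = FALSE]
      pred_fvc <- lms_predicted(coeffs, d, "FVC")$M
      z_i <- stats::rnorm(1, sd = 0.8)
      fvc_i <- pred_fvc * exp(z_i * 0.1)
      diseased <- labels[i] == 1L
      if (diseased) {
        k_i <- stats::runif(1, config$case_k_range[1], config$case_k_range[2])
        fvc_i <- fvc_i * stats::runif(1, config$case_fvc_scale[1],
                                      config$case_fvc_scale[2])
        pef_i <- fvc_i * stats::runif(1, 1.7, 2.2) *
          stats::runif(1, config$case_pef_scale[1], config$case_pef_scale[2])
      } else {
        k_i <- stats::runif(1, config$control_k_range[1],
                            config$control_k_range[2])
        pef_i <- fvc_i * stats::runif(1, 1.7, 2.2)
      }
      vpf_i <- stats::runif(1, 0.15, 0.28)
      blows <- vector("list", config$n_blows)
      for (b in seq_len(config$n_blows)) {
        jit <- if (config$blow_jitter_sd > 0)
          exp(stats::rnorm(1, sd = config$blow_jitter_sd)) else 1
        p_b <- spiro_curve_params(
          fvc_true = fvc_i * jit, pef_true = pef_i,
          v_peak_frac = vpf_i, shape_k = k_i,
          noise_sd = config$noise_sd, dt = config$dt)
        blows[[b]] <- synthesize_curve(
          p_b, seed = stats::runif(1, 1, 2^30), blow_id = b)
      }
      lab <- labels[i]
      if (config$label_noise > 0 && stats::runif(1) < config$label_noise) {
        lab <- 1L - lab
      }
      codes <- if (lab == 1L) {
        sample(c(copd_code_pool, copd_self_report_pool), 1)
      } else {
        code <- sample(noncopd_code_pool, 1)
        if (nzchar(code)) code else character(0)
      }
      records[[i]] <- list(
        subject_id = sprintf("S%05d", i),
        curves = blows,
        demographics = d,
        diagnosis_codes = codes,
        label = lab,
        params = spiro_curve_params(fvc_i, pef_i, v_peak_frac = vpf_i,
                                    shape_k = k_i, noise_sd = config$noise_sd,
                                    dt = config$dt))
    }
    records
  })
}
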