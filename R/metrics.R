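#' Cumulative exhaled volume of a curve
#'
#' Trapezoidal cumulative integral of flow over time; the first element is
#' zero by construction.
#'
#' @param curve a [spiro_curve()].
#' @return numeric vector of volumes (L), same length as `curve$flow`.
#' @export
compute_volume <- function(curve) {
  stopifnot(inherits(curve, "spiro_curve"))
  f <- curve$flow
  if (length(f) < 2L) abort_spk("curve needs >= 2 samples",
                                "spirokit_input_error")
  c(0, cumsum((f[-length(f)] + f[-1]) / 2 * curve$dt))
}

# Linear interpolation of y over uniform time grid at time t (seconds from
# first sample). Assumes t within range.
interp_at_time <- function(y, dt, t) {
  i <- t / dt
  i0 <- floor(i)
  frac <- i - i0
  i0 <- as.integer(i0) + 1L  # 1-based
  if (i0 >= length(y)) return(y[length(y)])
  y[i0] * (1 - frac) + y[i0 + 1L] * frac
}

# First time (seconds from first sample) at which the piecewise-linear
# cumulative volume crosses `target`.
time_at_volume <- function(vol, dt, target) {
  idx <- which(vol >= target)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(0)
  v0 <- vol[idx - 1L]; v1 <- vol[idx]
  (idx - 2L + (target - v0) / (v1 - v0)) * dt
}

#' Measured spirometric indices of one maneuver
#'
#' Computes FVC, FEV1, FEV1/FVC, PEF, FEF25-75 and FEF75 from a sampled
#' expiratory flow curve. Time zero defaults to the first sample whose flow
#' reaches 5\% of the eventual peak flow; the standard back-extrapolated
#' time zero (tangent through the peak projected to zero volume) is
#' available via `time_zero = "back_extrapolation"`. All volumes and times
#' are referenced to time zero; PEF is the raw maximum of the sampled flow.
#' FEF25-75 is `0.5 * FVC / (t75 - t25)`; FEF75 is the instantaneous
#' (interpolated) flow at 75\% of FVC exhaled.
#'
#' A curve shorter than 1 s after time zero yields `FEV1 = NA` with a
#' warning. Curves whose cumulative volume dips more than 1\% of the final
#' volume below its running maximum (substantial negative flow, beyond
#' sensor-noise level) are rejected as invalid.
#'
#' @param curve a [spiro_curve()].
#' @param time_zero `"threshold"` (default) or `"back_extrapolation"`.
#' @return an object of class `pft_result`: list with `indices` (data.frame
#'   `name, measured, predicted, lln, z_score, pct_predicted`), `t25`,
#'   `t75` (seconds from time zero).
#' @export
compute_indices <- function(curve, time_zero = c("threshold",
                                                 "back_extrapolation")) {
  time_zero <- match.arg(time_zero)
  stopifnot(inherits(curve, "spiro_curve"))
  f <- curve$flow
  dt <- curve$dt
  vol <- compute_volume(curve)
  v_final <- vol[length(vol)]
  if (v_final <= 0 || max(f) <= 0) {
    abort_spk("curve has no positive net exhaled volume",
              "spirokit_validity_error")
  }
  dip <- max(cummax(vol) - vol)
  if (dip > 0.01 * v_final) {
    abort_spk("cumulative volume is non-monotone beyond noise level",
              "spirokit_validity_error")
  }
  pef <- max(f)
  i_pef <- which.max(f)
  if (time_zero == "threshold") {
    i0 <- which(f >= 0.05 * pef)[1]
    t0 <- (i0 - 1L) * dt
    v_t0 <- vol[i0]
  } else {
    t_pef <- (i_pef - 1L) * dt
    t0 <- max(0, t_pef - vol[i_pef] / pef)
    v_t0 <- interp_at_time(vol, dt, t0)
  }
  fvc <- v_final - v_t0
  if (fvc <= 0) abort_spk("no volume exhaled after time zero",
                          "spirokit_validity_error")
  t_end <- (length(f) - 1L) * dt
  fev1 <- if (t_end - t0 >= 1) {
    interp_at_time(vol, dt, t0 + 1) - v_t0
  } else {
    warning("maneuver shorter than 1 s after time zero; FEV1 missing")
    NA_real_
  }
  t25 <- time_at_volume(vol, dt, v_t0 + 0.25 * fvc) - t0
  t75 <- time_at_volume(vol, dt, v_t0 + 0.75 * fvc) - t0
  fef2575 <- 0.5 * fvc / (t75 - t25)
  fef75 <- interp_at_time(f, dt, t75 + t0)
  idx <- data.frame(
    name = c("FVC", "FEV1", "FEV1_FVC", "PEF", "FEF25_75", "FEF75"),
    measured = c(fvc, fev1, fev1 / fvc, pef, fef2575, fef75),
    predicted = NA_real_, lln = NA_real_, z_score = NA_real_,
    pct_predicted = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(indices = idx, t25 = t25, t75 = t75), class = "pft_result")
}

#' @export
print.pft_result <- function(x, digits = 3, ...) {
  cat("<pft_result>\n")
  print(format(x$indices, digits = digits), row.names = FALSE)
  cat(sprintf("t25 = %.3f s, t75 = %.3f s\n", x$t25, x$t75))
  invisible(x)
}

#' Measured, predicted, LLN and z-score for every index
#'
#' Combines [compute_indices()] with LMS reference values: for each index
#' with a (sex, index) row in the table, fills in the predicted value (M),
#' the lower limit of normal, the z-score, and percent predicted
#' (`100 * measured / predicted`). FEV1/FVC uses its own LMS entry.
#' Indices without a table row are emitted measured-only with a warning.
#'
#' @param curve a [spiro_curve()].
#' @param demo one-row data.frame with age, sex, height.
#' @param coeffs a [lms_table()].
#' @param time_zero passed to [compute_indices()].
#' @return a `pft_result` with reference columns filled.
#' @export
full_pft <- function(curve, demo, coeffs, time_zero = "threshold") {
  res <- compute_indices(curve, time_zero = time_zero)
  idx <- res$indices
  missing_rows <- character(0)
  for (i in seq_len(nrow(idx))) {
    p <- lms_predicted(coeffs, demo, idx$name[i])
    if (is.null(p)) {
      missing_rows <- c(missing_rows, idx$name[i])
      next
    }
    idx$predicted[i] <- p$M
    idx$lln[i] <- lln(p$M, p$S, p$L)
    if (is.finite(idx$measured[i]) && idx$measured[i] > 0) {
      idx$z_score[i] <- z_score(idx$measured[i], p$M, p$S, p$L)
      idx$pct_predicted[i] <- 100 * idx$measured[i] / p$M
    }
  }
  if (length(missing_rows) > 0) {
    warning(sprintf("no LMS coefficients for: %s (measured-only)",
                    paste(missing_rows, collapse = ", ")))
  }
  res$indices <- idx
  res
}

# Convenience accessor: one field of one index from a pft_result.
pft_value <- function(pft, name, field = "measured") {
  pft$indices[[field]][pft$indices$name == name]
}
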