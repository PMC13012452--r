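#' LMS reference-coefficient tables
#'
#' The LMS method summarises a reference distribution by its skewness (L),
#' median (M) and coefficient of variation (S). For a spirometric index and
#' sex, the median and scatter follow
#' `M = exp(a0 + a1*log(height) + a2*log(age) + Mspline(age))` and
#' `S = exp(b0 + b1*log(age) + Sspline(age))`, with L constant and the
#' age-indexed spline offsets linearly interpolated from a lookup table.
#'
#' `lms_table()` assembles a table from its two data.frames;
#' `read_lms_csv()` / `write_lms_csv()` handle the on-disk CSV pair
#' (`coefficients.csv`: sex,index,a0,a1,a2,b0,b1,L and `splines.csv`:
#' sex,index,age,m_spline,s_spline). Official reference tables are not
#' bundled; [lms_synthetic_table()] provides a synthetic table with
#' plausible magnitudes for simulation and tests.
#'
#' @param coef data.frame with columns sex, index, a0, a1, a2, b0, b1, L.
#' @param spline data.frame with columns sex, index, age, m_spline,
#'   s_spline.
#' @return an object of class `spiro_lms`.
#' @export
lms_table <- function(coef, spline) {
  need_c <- c("sex", "index", "a0", "a1", "a2", "b0", "b1", "L")
  need_s <- c("sex", "index", "age", "m_spline", "s_spline")
  stopifnot(all(need_c %in% names(coef)), all(need_s %in% names(spline)))
  structure(list(coef = coef, spline = spline), class = "spiro_lms")
}

#' @export
print.spiro_lms <- function(x, ...) {
  cat(sprintf("<spiro_lms> %d (sex, index) rows, age range [%g, %g] years\n",
              nrow(x$coef), min(x$spline$age), max(x$spline$age)))
  invisible(x)
}

#' Synthetic LMS reference table
#'
#' A synthetic stand-in for a published reference-coefficient table, with
#' coefficients chosen so predicted values have physiologically plausible
#' magnitudes (e.g. FVC about 5.2 L for a 50-year-old, 177 cm male) and
#' mild sinusoidal age-spline offsets so interpolation paths are exercised.
#' It is not derived from, and must not be mistaken for, any official
#' reference equation set.
#'
#' @param age_grid ages (years) at which spline offsets are tabulated.
#' @return a [lms_table()].
#' @export
lms_synthetic_table <- function(age_grid = seq(25, 85, by = 5)) {
  base <- data.frame(
    index = c("FVC", "FEV1", "FEV1_FVC", "PEF", "FEF25_75", "FEF75"),
    a0 = c(-8.634, -8.457, 0.166, -5.122, -7.006, -5.684),
    a1 = c(2.10, 2.05, 0.00, 1.50, 1.90, 1.60),
    a2 = c(-0.15, -0.19, -0.087, -0.10, -0.35, -0.50),
    b0 = c(-2.433, -2.433, -2.737, -2.303, -1.966, -1.772),
    b1 = c(0.08, 0.08, 0.02, 0.05, 0.05, 0.05),
    L = c(0.9, 0.9, 1.2, 1.0, 0.8, 0.7),
    stringsAsFactors = FALSE)
  male <- cbind(sex = "male", base, stringsAsFactors = FALSE)
  female <- cbind(sex = "female", base, stringsAsFactors = FALSE)
  # women have smaller volumes at equal height; ratio is sex-neutral here
  vol_idx <- female$index != "FEV1_FVC"
  female$a0[vol_idx] <- female$a0[vol_idx] + log(0.90)
  coef <- rbind(male, female)
  spl <- do.call(rbind, lapply(seq_len(nrow(coef)), function(i) {
    data.frame(sex = coef$sex[i], index = coef$index[i], age = age_grid,
               m_spline = 0.02 * sin(age_grid / 12),
               s_spline = 0.015 * cos(age_grid / 15),
               stringsAsFactors = FALSE)
  }))
  lms_table(coef, spl)
}

#' Write / read an LMS table as a CSV pair
#'
#' @param table a [lms_table()].
#' @param dir directory receiving (or holding) `coefficients.csv` and
#'   `splines.csv`.
#' @return `write_lms_csv` returns `dir` invisibly; `read_lms_csv` returns
#'   a [lms_table()].
#' @export
write_lms_csv <- function(table, dir) {
  stopifnot(inherits(table, "spiro_lms"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table$coef, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(table$spline, file.path(dir, "splines.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_lms_csv
#' @export
read_lms_csv <- function(dir) {
  cf <- utils::read.csv(file.path(dir, "coefficients.csv"),
                        stringsAsFactors = FALSE)
  sp <- utils::read.csv(file.path(dir, "splines.csv"),
                        stringsAsFactors = FALSE)
  lms_table(cf, sp)
}

#' Predicted median, scatter and skewness for one index
#'
#' @param coeffs a [lms_table()].
#' @param demo one-row data.frame with `age` (years), `sex`, `height` (cm).
#' @param index_name one of the index names present in the table.
#' @return list with elements `M`, `S`, `L`, or `NULL` if the table has no
#'   row for this (sex, index) pair.
#' @export
lms_predicted <- function(coeffs, demo, index_name) {
  stopifnot(inherits(coeffs, "spiro_lms"))
  age <- demo$age[1]; sex <- demo$sex[1]; height <- demo$height[1]
  row <- coeffs$coef[coeffs$coef$sex == sex & coeffs$coef$index == index_name, ]
  if (nrow(row) == 0) return(NULL)
  sp <- coeffs$spline[coeffs$spline$sex == sex &
                        coeffs$spline$index == index_name, ]
  if (nrow(sp) >= 2) {
    rng <- range(sp$age)
    if (age < rng[1] || age > rng[2]) {
      abort_spk(sprintf(
        "age %.1f outside reference table range [%.0f, %.0f] years",
        age, rng[1], rng[2]), "spirokit_range_error")
    }
    msp <- stats::approx(sp$age, sp$m_spline, xout = age)$y
    ssp <- stats::approx(sp$age, sp$s_spline, xout = age)$y
  } else {
    msp <- 0; ssp <- 0
  }
  M <- exp(row$a0 + row$a1 * log(height) + row$a2 * log(age) + msp)
  S <- exp(row$b0 + row$b1 * log(age) + ssp)
  list(M = M, S = S, L = row$L)
}

#' LMS z-score of a measured value
#'
#' `z = ((y/M)^L - 1) / (L*S)`, with the log-limit `z = log(y/M)/S` when
#' `|L|` is numerically zero.
#'
#' @param measured measured value (> 0), vectorised.
#' @param M,S,L LMS parameters (M > 0, S > 0).
#' @return z-score(s).
#' @export
z_score <- function(measured, M, S, L) {
  if (any(measured <= 0) || M <= 0 || S <= 0) {
    abort_spk("z_score requires positive measured, M and S",
              "spirokit_domain_error")
  }
  if (abs(L) < 1e-6) log(measured / M) / S
  else ((measured / M)^L - 1) / (L * S)
}

#' Value attaining a given z-score (inverse of [z_score()])
#'
#' @param z z-score, vectorised.
#' @inheritParams z_score
#' @return the measured value whose z-score is `z`.
#' @export
value_at_z <- function(z, M, S, L) {
  stopifnot(M > 0, S > 0)
  if (abs(L) < 1e-6) return(M * exp(z * S))
  arg <- 1 + L * S * z
  if (any(arg <= 0)) {
    abort_spk("value_at_z: 1 + L*S*z must be positive",
              "spirokit_domain_error")
  }
  M * arg^(1 / L)
}

#' Lower limit of normal (5th centile)
#'
#' The value whose z-score is -1.645, the conventional lower limit of
#' normal of a reference distribution.
#'
#' @inheritParams z_score
#' @return the LLN in the units of M.
#' @export
lln <- function(M, S, L) value_at_z(-1.645, M, S, L)
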