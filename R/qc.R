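exclusion_df <- function(ids, stage, reason) {
  data.frame(subject_id = as.character(ids),
             stage = rep_len(stage, length(ids)),
             reason = rep_len(as.character(reason), length(ids)),
             stringsAsFactors = FALSE)
}

#' Case definition from diagnosis codes
#'
#' A record is a case iff any of its diagnosis codes starts with one of the
#' ICD-style prefixes or equals one of the self-reported illness codes.
#' Defaults follow the conventional COPD definition (emphysema J43, other
#' chronic obstructive pulmonary disease J44, plus self-report codes as
#' used by the synthetic cohort generator).
#'
#' @param icd_prefixes character vector of code prefixes.
#' @param self_report_codes character vector of exact-match codes.
#' @return an object of class `case_definition`.
#' @export
case_definition <- function(icd_prefixes = c("J43", "J44"),
                            self_report_codes = c("SR-COPD",
                                                  "SR-EMPHYSEMA")) {
  stopifnot(length(icd_prefixes) + length(self_report_codes) > 0)
  structure(list(icd_prefixes = icd_prefixes,
                 self_report_codes = self_report_codes),
            class = "case_definition")
}

#' @rdname case_definition
#' @param record a cohort record (list with `diagnosis_codes`).
#' @param case_def a [case_definition()].
#' @return `assign_label` returns 0 or 1.
#' @export
assign_label <- function(record, case_def = case_definition()) {
  codes <- record$diagnosis_codes
  if (length(codes) == 0) return(0L)
  hit_icd <- any(vapply(codes, function(cd)
    any(startsWith(cd, case_def$icd_prefixes)), logical(1)))
  hit_sr <- any(codes %in% case_def$self_report_codes)
  as.integer(hit_icd || hit_sr)
}

#' Quality-control configuration
#'
#' @param tail_fraction proportion trimmed per tail of each metric
#'   distribution (default 0.005, i.e. top/bottom 0.5\%).
#' @param max_blow_rel_diff maximum tolerated relative difference between
#'   the two best blows (default 0.10).
#' @param metrics_for_trimming index names whose outliers are trimmed.
#' @param consistency_metric index used by the blow-consistency filter.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(tail_fraction = 0.005, max_blow_rel_diff = 0.10,
                      metrics_for_trimming = c("FVC", "FEV1", "PEF"),
                      consistency_metric = "FVC") {
  stopifnot(tail_fraction >= 0, tail_fraction < 0.5,
            max_blow_rel_diff > 0, max_blow_rel_diff < 1)
  structure(list(tail_fraction = tail_fraction,
                 max_blow_rel_diff = max_blow_rel_diff,
                 metrics_for_trimming = metrics_for_trimming,
                 consistency_metric = consistency_metric),
            class = "qc_config")
}

#' Attach PFT results to cohort records
#'
#' Computes measured indices for every blow and a full (reference-equipped)
#' PFT for the best blow (largest FVC). Invalid blows are dropped with a
#' reason; records with no valid blow get `pft = NULL`.
#'
#' @param records list of cohort records.
#' @param coeffs a [lms_table()].
#' @param time_zero passed to [compute_indices()].
#' @return the records, each augmented with `blow_metrics` (data.frame
#'   `blow_id, FVC, FEV1, PEF`) and `pft` (best-blow `pft_result`).
#' @export
compute_record_pft <- function(records, coeffs = lms_synthetic_table(),
                               time_zero = "threshold") {
  lapply(records, function(rec) {
    rows <- list(); pfts <- list()
    for (cur in rec$curves) {
      m <- tryCatch(suppressWarnings(compute_indices(cur, time_zero)),
                    spirokit_validity_error = function(e) NULL)
      if (is.null(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        blow_id = cur$blow_id,
        FVC = pft_value(m, "FVC"), FEV1 = pft_value(m, "FEV1"),
        PEF = pft_value(m, "PEF"))
      pfts[[length(pfts) + 1L]] <- list(curve = cur)
    }
    if (length(rows) == 0) {
      rec$blow_metrics <- NULL
      rec$pft <- NULL
      return(rec)
    }
    bm <- do.call(rbind, rows)
    rec$blow_metrics <- bm
    best <- which.max(bm$FVC)
    rec$pft <- suppressWarnings(
      full_pft(pfts[[best]]$curve, rec$demographics, coeffs,
               time_zero = time_zero))
    rec$best_blow_id <- bm$blow_id[best]
    rec
  })
}

#' Trim statistical outliers in key pulmonary function metrics
#'
#' Excludes records for which any configured metric falls strictly below
#' the `tail_fraction` percentile or strictly above the
#' `1 - tail_fraction` percentile of the cohort distribution (percentiles
#' by linear interpolation, `stats::quantile` type 7).
#'
#' @param records records with `pft` attached ([compute_record_pft()]).
#' @param qc a [qc_config()].
#' @return list with `records` (survivors) and `exclusions` (data.frame
#'   `subject_id, stage, reason`).
#' @export
trim_outliers <- function(records, qc = qc_config()) {
  if (length(records) == 0) abort_spk("empty cohort", "spirokit_input_error")
  metrics <- qc$metrics_for_trimming
  vals <- sapply(metrics, function(m)
    vapply(records, function(r)
      if (is.null(r$pft)) NA_real_ else pft_value(r$pft, m), numeric(1)))
  vals <- matrix(vals, nrow = length(records),
                 dimnames = list(NULL, metrics))
  keep <- rep(TRUE, length(records))
  reason <- rep(NA_character_, length(records))
  for (m in metrics) {
    x <- vals[, m]
    lo <- stats::quantile(x, qc$tail_fraction, na.rm = TRUE, names = FALSE)
    hi <- stats::quantile(x, 1 - qc$tail_fraction, na.rm = TRUE,
                          names = FALSE)
    bad <- !is.na(x) & (x < lo | x > hi)
    reason[bad & keep] <- sprintf("%s outside [P%.3g, P%.3g]", m,
                                  100 * qc$tail_fraction,
                                  100 * (1 - qc$tail_fraction))
    keep <- keep & !bad
  }
  list(records = records[keep],
       exclusions = exclusion_df(
         vapply(records[!keep], `[[`, "", "subject_id"),
         "trim_outliers", reason[!keep]))
}

#' Repeated-blow consistency filter
#'
#' Takes the two best blows (largest values of the configured consistency
#' metric, FVC by default) and computes their relative difference
#' `|a - b| / max(a, b)`; the record is excluded iff it exceeds
#' `max_blow_rel_diff`. Single-blow records are kept with a warning.
#'
#' @param record one record with `blow_metrics` attached.
#' @param qc a [qc_config()].
#' @return `"keep"` or `"exclude"`.
#' @export
blow_consistency_filter <- function(record, qc = qc_config()) {
  bm <- record$blow_metrics
  if (is.null(bm) || nrow(bm) == 0) return("exclude")
  x <- sort(bm[[qc$consistency_metric]], decreasing = TRUE)
  if (length(x) < 2) {
    warning(sprintf("record %s has a single valid blow; kept",
                    record$subject_id))
    return("keep")
  }
  rel <- abs(x[1] - x[2]) / max(x[1], x[2])
  if (rel > qc$max_blow_rel_diff) "exclude" else "keep"
}

#' Balance a cohort by downsampling controls
#'
#' Keeps every case (label 1) and samples controls without replacement down
#' to the case count; deterministic given `seed`.
#'
#' @param records labelled records.
#' @param seed integer seed.
#' @return the balanced record list (cases first, then sampled controls).
#' @export
balance_downsample <- function(records, seed = NULL) {
  labels <- vapply(records, `[[`, integer(1), "label")
  cases <- which(labels == 1L)
  controls <- which(labels == 0L)
  if (length(controls) < length(cases)) {
    abort_spk(sprintf("cannot balance: %d controls < %d cases",
                      length(controls), length(cases)),
              "spirokit_balance_error")
  }
  pick <- with_seed(seed, sample(controls, length(cases)))
  records[c(cases, sort(pick))]
}

#' Screen labels against physiological evidence
#'
#' Delegates each record to a pluggable consistency checker; flagged
#' records are excluded. The default deterministic rule flags a
#' contradiction when a case has an FEV1/FVC z-score of +1 or more (clearly
#' supranormal airflow for a diagnosed obstructive disease) or a control
#' has an FEV1/FVC z-score of -3 or less (severe obstruction without a
#' diagnosis). A checker that throws leaves the record retained and logged.
#'
#' @param records records with `pft` attached.
#' @param checker function(record) -> TRUE to flag (exclude); defaults to
#'   the rule above.
#' @return list with `records`, `exclusions` (data.frame), and
#'   `checker_failures` (subject ids whose checker call errored).
#' @export
label_consistency_screen <- function(records, checker = NULL) {
  if (is.null(checker)) checker <- default_label_checker
  flagged <- logical(length(records))
  failed <- character(0)
  for (i in seq_along(records)) {
    flagged[i] <- tryCatch(isTRUE(checker(records[[i]])),
                           error = function(e) {
                             failed <<- c(failed, records[[i]]$subject_id)
                             FALSE
                           })
  }
  list(records = records[!flagged],
       exclusions = exclusion_df(
         vapply(records[flagged], `[[`, "", "subject_id"),
         "label_consistency_screen",
         "label contradicts FEV1/FVC z-score"),
       checker_failures = failed)
}

#' @rdname label_consistency_screen
#' @param record one record.
#' @export
default_label_checker <- function(record) {
  if (is.null(record$pft)) return(FALSE)
  z <- pft_value(record$pft, "FEV1_FVC", "z_score")
  if (!is.finite(z)) return(FALSE)
  (record$label == 1L && z >= 1) || (record$label == 0L && z <= -3)
}

#' Stratified train/validation/test split
#'
#' Per class, the validation and test sets each receive
#' `ceiling(ratio * n_class)` records (ratios normalised to sum 1) and the
#' training set the remainder; membership is random given `seed`. This
#' per-stratum ceiling rule keeps class proportions within one subject of
#' the stratum-exact allocation in every subset.
#'
#' @param records labelled records.
#' @param ratios length-3 numeric train/val/test weights (default 8:1:1).
#' @param seed integer seed.
#' @return data.frame `subject_id, split` with split in
#'   train/val/test.
#' @export
stratified_split <- function(records, ratios = c(8, 1, 1), seed = NULL) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  labels <- vapply(records, `[[`, integer(1), "label")
  ids <- vapply(records, `[[`, "", "subject_id")
  if (length(unique(labels)) < 2) {
    abort_spk("both classes must be present to stratify",
              "spirokit_split_error")
  }
  r <- ratios / sum(ratios)
  out <- vector("list", 2)
  for (ci in c(0L, 1L)) {
    idx <- which(labels == ci)
    n <- length(idx)
    if (n < 3) abort_spk(sprintf("class %d has %d < 3 records", ci, n),
                         "spirokit_split_error")
    n_val <- ceiling(r[2] * n)
    n_test <- ceiling(r[3] * n)
    if (n_val + n_test > n) {
      abort_spk("hold-out ratios leave no training data",
                "spirokit_split_error")
    }
    perm <- with_seed(if (is.null(seed)) NULL else seed + ci, sample(idx))
    split <- rep("train", n)
    if (n_val > 0) split[seq_len(n_val)] <- "val"
    if (n_test > 0) split[n_val + seq_len(n_test)] <- "test"
    out[[ci + 1L]] <- data.frame(subject_id = ids[perm], split = split,
                                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(match(res$subject_id, ids)), , drop = FALSE]
}

#' Run the full cohort quality-control pipeline
#'
#' Fixed stage order: label assignment (from diagnosis codes), blow
#' validity (records with no valid blow are excluded), outlier trimming,
#' blow-consistency filtering, class balancing, and the label-consistency
#' screen. Every exclusion carries a machine-readable stage and reason.
#'
#' @param records raw cohort records.
#' @param case_def a [case_definition()].
#' @param qc a [qc_config()].
#' @param coeffs a [lms_table()].
#' @param seed integer seed (balancing).
#' @param checker passed to [label_consistency_screen()].
#' @return list with `records` (survivors, labels assigned, PFT attached),
#'   `exclusions` (data.frame `subject_id, stage, reason`), and `log`
#'   (per-stage data.frame `stage, n_in, n_out, n_excluded`).
#' @export
qc_pipeline <- function(records, case_def = case_definition(),
                        qc = qc_config(), coeffs = lms_synthetic_table(),
                        seed = NULL, checker = NULL) {
  excl <- list()
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      n_excluded = n_in - n_out, stringsAsFactors = FALSE)
  }

  n0 <- length(records)
  records <- lapply(records, function(r) {
    r$label <- assign_label(r, case_def)
    r
  })
  note("assign_label", n0, length(records))

  records <- compute_record_pft(records, coeffs)
  valid <- vapply(records, function(r) !is.null(r$pft), logical(1))
  excl[[length(excl) + 1L]] <- exclusion_df(
    vapply(records[!valid], `[[`, "", "subject_id"),
    "validity", "no valid blow")
  note("validity", length(records), sum(valid))
  records <- records[valid]

  tr <- trim_outliers(records, qc)
  excl[[length(excl) + 1L]] <- tr$exclusions
  note("trim_outliers", length(records), length(tr$records))
  records <- tr$records

  keep <- vapply(records, function(r)
    suppressWarnings(blow_consistency_filter(r, qc)) == "keep", logical(1))
  excl[[length(excl) + 1L]] <- exclusion_df(
    vapply(records[!keep], `[[`, "", "subject_id"),
    "blow_consistency",
    sprintf("blow relative difference > %g", qc$max_blow_rel_diff))
  note("blow_consistency", length(records), sum(keep))
  records <- records[keep]

  n_before <- length(records)
  balanced <- balance_downsample(records, seed = seed)
  dropped <- setdiff(vapply(records, `[[`, "", "subject_id"),
                     vapply(balanced, `[[`, "", "subject_id"))
  excl[[length(excl) + 1L]] <- exclusion_df(dropped, "balance",
                                            "control downsampled")
  note("balance", n_before, length(balanced))
  records <- balanced

  sc <- label_consistency_screen(records, checker)
  excl[[length(excl) + 1L]] <- sc$exclusions
  note("label_consistency_screen", length(records), length(sc$records))

  list(records = sc$records,
       exclusions = do.call(rbind, excl),
       log = do.call(rbind, log))
}
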