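# Evaluation harness: six-dimension judged report quality, score
# normalization, diagnosis extraction, classification metrics with
# bootstrap confidence intervals, and the input-masking robustness
# experiment.

judge_dimensions <- c("factual_accuracy", "completeness", "logic_evidence",
                      "terminology", "safety", "curve_description")

#' Normalize a 1-5 judge score to the 0-100 scale
#'
#' Affine map `(raw - 1) / 4 * 100`: 1 maps to 0, 5 maps to 100.
#'
#' @param raw score(s) in 1..5.
#' @return value(s) in 0..100.
#' @export
normalize_score <- function(raw) {
  if (any(!is.finite(raw) | raw < 1 | raw > 5)) {
    abort_spk("raw judge scores must lie in [1, 5]",
              "spirokit_domain_error")
  }
  (raw - 1) / 4 * 100
}

extract_numbers <- function(text) {
  m <- gregexpr("-?[0-9]+\\.?[0-9]*", text)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, gregexpr("-?[0-9]+\\.?[0-9]*", text))[[1]]
}

score_to_1_5 <- function(frac) as.integer(pmin(5, pmax(1, 1 + round(4 * frac))))

# Deterministic rubric proxies for the six dimensions, computed from the
# candidate and gold reports (section coverage, numeric agreement,
# terminology checklist, contradiction flags).
rubric_judge <- function(report, gold) {
  rs <- report$sections; gs <- gold$sections
  r_all <- render_report(report); g_all <- render_report(gold)

  gold_nums <- unique(extract_numbers(paste(gs$findings, gs$impression)))
  rep_nums <- unique(extract_numbers(paste(rs$findings, rs$impression)))
  num_frac <- if (length(gold_nums) == 0) 1 else
    mean(gold_nums %in% rep_nums)
  dx_match <- identical(report$diagnosis, gold$diagnosis) &&
    !is.na(gold$diagnosis)
  factual <- score_to_1_5(num_frac)
  if (!dx_match && !is.na(gold$diagnosis)) factual <- min(factual, 2L)

  nonempty <- vapply(rs, function(s) nzchar(trimws(s)), logical(1))
  completeness <- score_to_1_5(mean(nonempty))

  lln_cited <- grepl("LLN", rs$impression, fixed = TRUE)
  logic <- if (lln_cited && dx_match) 5L else if (lln_cited) 3L else 1L

  checklist <- c("FEV1", "FVC", "LLN", "z-score", "predicted")
  hits <- mean(vapply(checklist, grepl, logical(1), x = r_all,
                      fixed = TRUE))
  terminology <- score_to_1_5(hits)

  safety <- 5L
  if (!is.na(gold$diagnosis) && !dx_match) safety <- 2L
  if (grepl("non-fully reversible", r_all, fixed = TRUE)) {
    safety <- min(safety, 3L)
  }

  curve <- if (!nzchar(trimws(rs$morphology))) 1L else {
    g_tags <- c(concave = grepl("concave", gs$morphology),
                convex = grepl("convex", gs$morphology),
                linear = grepl("linear", gs$morphology))
    r_tags <- c(concave = grepl("concave", rs$morphology),
                convex = grepl("convex", rs$morphology),
                linear = grepl("linear", rs$morphology))
    if (identical(g_tags, r_tags)) 5L else 3L
  }

  c(factual_accuracy = factual, completeness = completeness,
    logic_evidence = logic, terminology = terminology, safety = safety,
    curve_description = curve)
}

#' Judge a generated report against its gold standard
#'
#' The default fallback computes deterministic rubric proxies (section
#' coverage, numeric agreement with the gold report, an LLN-citation logic
#' check, a terminology checklist, contradiction and unsafe-phrase flags,
#' and morphology-tag agreement) mapped onto the 1-5 scale. A pluggable
#' judge adapter may be supplied instead; it must return a named list of
#' the six raw scores and is retried once on failure, after which the
#' result is invalid (all-NA) with a warning.
#'
#' @param report,gold `spiro_report` objects (non-empty).
#' @param judge optional adapter `function(report, gold)`.
#' @return object of class `judge_scores`: list with `raw` (named 1-5
#'   vector) and `normalized` (0-100).
#' @export
judge_report <- function(report, gold, judge = NULL) {
  stopifnot(inherits(report, "spiro_report"), inherits(gold, "spiro_report"))
  raw <- if (is.null(judge)) {
    rubric_judge(report, gold)
  } else {
    parse_once <- function() {
      out <- judge(report, gold)
      out <- unlist(out)[judge_dimensions]
      stopifnot(all(is.finite(out)), all(out >= 1 & out <= 5))
      out
    }
    tryCatch(parse_once(), error = function(e1) {
      tryCatch(parse_once(), error = function(e2) {
        warning("judge adapter failed twice; scores invalid")
        stats::setNames(rep(NA_real_, 6), judge_dimensions)
      })
    })
  }
  structure(list(raw = raw,
                 normalized = if (all(is.finite(raw)))
                   normalize_score(raw) else raw * NA),
            class = "judge_scores")
}

#' Extract the diagnostic decision from a report
#'
#' The rule fallback parses the structured impression for
#' `Diagnosis code: 0|1` and `Confidence: x`; text without a parseable
#' impression (including refusals and inconclusive impressions) is
#' `invalid`, which counts against the valid-response rate. A pluggable
#' extractor adapter may be supplied; its errors also yield `invalid`.
#'
#' @param report a `spiro_report` or free text.
#' @param extractor optional adapter `function(text)` returning
#'   `list(decision =, confidence =)`.
#' @return object of class `diagnosis_extraction`: list with `decision`
#'   (0, 1, or `"invalid"`) and `confidence` (in [0,1] or NA).
#' @export
extract_diagnosis <- function(report, extractor = NULL) {
  text <- if (inherits(report, "spiro_report")) {
    report$sections$impression
  } else {
    as.character(report)
  }
  invalid <- structure(list(decision = "invalid", confidence = NA_real_),
                       class = "diagnosis_extraction")
  if (!is.null(extractor)) {
    out <- tryCatch(extractor(text), error = function(e) NULL)
    if (is.null(out) || !out$decision %in% c(0, 1)) return(invalid)
    return(structure(list(decision = as.integer(out$decision),
                          confidence = as.numeric(out$confidence)),
                     class = "diagnosis_extraction"))
  }
  m <- regmatches(text, regexec("Diagnosis code: ([01])", text))[[1]]
  if (length(m) < 2) return(invalid)
  cm <- regmatches(text,
                   regexec("Confidence: ([0-9]*\\.?[0-9]+)", text))[[1]]
  conf <- if (length(cm) >= 2) as.numeric(cm[2]) else NA_real_
  if (is.finite(conf) && (conf < 0 || conf > 1)) conf <- NA_real_
  structure(list(decision = as.integer(m[2]), confidence = conf),
            class = "diagnosis_extraction")
}

#' AUROC by the Mann-Whitney statistic (ties count one half)
#'
#' @param scores numeric scores, higher meaning more likely positive.
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1], or NA if a class is absent.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall step curve
#'
#' Thresholds sweep the distinct score values from high to low; at each
#' threshold all items with a score at or above it are called positive.
#' The area is the step integral `sum((R_i - R_{i-1}) * P_i)` over the
#' resulting (recall, precision) points.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1], or NA if no positives.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || length(scores) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

confusion_stats <- function(decisions, labels) {
  tp <- sum(decisions == 1 & labels == 1)
  fp <- sum(decisions == 1 & labels == 0)
  fn <- sum(decisions == 0 & labels == 1)
  tn <- sum(decisions == 0 & labels == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else if (tp == 0 && (fp > 0 || fn > 0)) 0 else NA_real_
  list(f1 = f1, sensitivity = sens, specificity = spec)
}

#' Classification metrics from diagnosis extractions
#'
#' Invalid extractions are excluded from the threshold metrics and counted
#' against the valid-response rate. AUROC is the Mann-Whitney statistic of
#' the confidences (ties one half); AUPRC the precision-recall step-curve
#' area; F1, sensitivity and specificity come from the binary decisions.
#'
#' @param extractions list of `diagnosis_extraction` objects.
#' @param labels 0/1 truth labels, same length.
#' @return object of class `metrics_summary`: list with `auroc`, `auprc`,
#'   `f1`, `sensitivity`, `specificity`, `valid_response_rate`, `n_valid`,
#'   `flags`.
#' @export
classification_metrics <- function(extractions, labels) {
  stopifnot(length(extractions) == length(labels))
  valid <- vapply(extractions, function(e) e$decision %in% c(0L, 1L),
                  logical(1))
  vrr <- mean(valid)
  flags <- character(0)
  if (!any(valid)) {
    return(structure(list(auroc = NA_real_, auprc = NA_real_,
                          f1 = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_,
                          valid_response_rate = vrr, n_valid = 0L,
                          flags = "no valid extractions"),
                     class = "metrics_summary"))
  }
  dec <- vapply(extractions[valid], function(e) as.integer(e$decision),
                integer(1))
  conf <- vapply(extractions[valid], function(e) e$confidence, numeric(1))
  lab <- labels[valid]
  if (length(unique(lab)) < 2) {
    flags <- c(flags, "single-class labels: rank metrics undefined")
  }
  has_conf <- is.finite(conf)
  au <- if (all(has_conf)) auroc(conf, lab) else {
    flags <- c(flags, "missing confidences: rank metrics on subset")
    auroc(conf[has_conf], lab[has_conf])
  }
  ap <- if (all(has_conf)) auprc(conf, lab) else
    auprc(conf[has_conf], lab[has_conf])
  cs <- confusion_stats(dec, lab)
  structure(list(auroc = au, auprc = ap, f1 = cs$f1,
                 sensitivity = cs$sensitivity,
                 specificity = cs$specificity,
                 valid_response_rate = vrr, n_valid = sum(valid),
                 flags = flags),
            class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat(sprintf(
    "<metrics_summary> AUROC %.3f AUPRC %.3f F1 %.3f sens %.3f spec %.3f (valid %.0f%%)\n",
    x$auroc, x$auprc, x$f1, x$sensitivity, x$specificity,
    100 * x$valid_response_rate))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects with replacement, recomputes the metric, and reports
#' the percentile interval. Resamples on which the metric is undefined
#' (e.g. single-class) are redrawn up to `max_redraws` times, then dropped
#' with a log; if more than half the resamples are dropped the interval is
#' flagged unreliable. Deterministic by seed.
#'
#' @param metric_fn `function(indices)` returning a scalar (it receives a
#'   vector of resampled subject indices into the caller's data).
#' @param n number of subjects.
#' @param n_resamples bootstrap resamples (default 10000).
#' @param level confidence level.
#' @param seed integer seed.
#' @param max_redraws redraw cap per undefined resample.
#' @return list with `lower`, `upper`, `level`, `n_resamples`, `seed`,
#'   `n_dropped`, `unreliable`.
#' @export
bootstrap_ci <- function(metric_fn, n, n_resamples = 10000L, level = 0.95,
                         seed = 1L, max_redraws = 5L) {
  stopifnot(n_resamples >= 1, n >= 1)
  with_seed(seed, {
    vals <- numeric(n_resamples)
    dropped <- 0L
    for (i in seq_len(n_resamples)) {
      v <- NA_real_
      for (att in seq_len(max_redraws + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        v <- metric_fn(idx)
        if (is.finite(v)) break
      }
      vals[i] <- v
      if (!is.finite(v)) dropped <- dropped + 1L
    }
    ok <- vals[is.finite(vals)]
    if (dropped > 0) {
      message(sprintf("bootstrap_ci: %d/%d resamples dropped (undefined)",
                      dropped, n_resamples))
    }
    if (length(ok) == 0) {
      return(list(lower = NA_real_, upper = NA_real_, level = level,
                  n_resamples = n_resamples, seed = seed,
                  n_dropped = dropped, unreliable = TRUE))
    }
    alpha <- (1 - level) / 2
    q <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
    list(lower = q[1], upper = q[2], level = level,
         n_resamples = n_resamples, seed = seed, n_dropped = dropped,
         unreliable = dropped > n_resamples / 2)
  })
}

#' Classification metrics with bootstrap confidence intervals
#'
#' @inheritParams classification_metrics
#' @param n_resamples,level,seed passed to [bootstrap_ci()]; resampling is
#'   at the subject (extraction) level.
#' @return a `metrics_summary` with an added `ci` list (per metric).
#' @export
metrics_with_ci <- function(extractions, labels, n_resamples = 1000L,
                            level = 0.95, seed = 1L) {
  ms <- classification_metrics(extractions, labels)
  n <- length(extractions)
  mk <- function(metric) {
    force(metric)
    bootstrap_ci(function(idx) {
      classification_metrics(extractions[idx], labels[idx])[[metric]]
    }, n, n_resamples = n_resamples, level = level,
    seed = derive_seed(seed, metric))
  }
  ms$ci <- list(auroc = mk("auroc"), auprc = mk("auprc"), f1 = mk("f1"))
  ms
}

#' Input-masking robustness experiment
#'
#' Runs the prompt -> report -> extraction -> metrics chain twice over the
#' same records in identical order — once with full PFT text, once with the
#' PFT block masked — and reports the paired summaries. The rule-based
#' pipeline has two variants: without a curve channel, masking leaves the
#' diagnostic engine nothing to work from, so impressions become
#' inconclusive and the valid-response rate collapses; with the curve
#' channel enabled, indices are recomputed from the raw curve and the
#' pipeline keeps answering.
#'
#' @param records QC'd records with `pft` attached.
#' @param coeffs a [lms_table()] (for curve-channel recomputation).
#' @param kb knowledge base (list of snippets).
#' @param use_curve_channel recompute PFT from the raw curve when masked.
#' @param judge optional judge adapter.
#' @return list with `masked` and `unmasked`, each holding `metrics`
#'   (a `metrics_summary`) and `judge_mean` (named mean normalized scores
#'   against the unmasked gold reports), plus `paired` (per-record
#'   data.frame of decisions).
#' @export
masking_experiment <- function(records, coeffs = lms_synthetic_table(),
                               kb = default_kb(), use_curve_channel = FALSE,
                               judge = NULL) {
  labels <- vapply(records, `[[`, integer(1), "label")
  run_mode <- function(masked) {
    lapply(records, function(rec) {
      pft <- if (!masked) {
        rec$pft
      } else if (use_curve_channel) {
        # visual channel: re-derive quantitative indices from the curve
        ids <- vapply(rec$curves, `[[`, integer(1), "blow_id")
        bi <- match(rec$best_blow_id, ids, nomatch = 1L)
        suppressWarnings(full_pft(rec$curves[[bi]], rec$demographics,
                                  coeffs))
      } else {
        NULL
      }
      morph <- describe_morphology(rec$curves[[1]])
      sn <- retrieve_snippets(paste(morph$text, "airflow obstruction"),
                              kb, k = 2)
      generate_report(rec, pft = pft, morphology = morph, snippets = sn)
    })
  }
  gold <- run_mode(masked = FALSE)
  masked_reports <- run_mode(masked = TRUE)
  summarize <- function(reports) {
    ex <- lapply(reports, extract_diagnosis)
    js <- mapply(function(r, g) judge_report(r, g, judge)$normalized,
                 reports, gold)
    list(metrics = classification_metrics(ex, labels),
         judge_mean = rowMeans(matrix(unlist(js), nrow = 6,
                                      dimnames = list(judge_dimensions))),
         extractions = ex)
  }
  um <- summarize(gold)
  mk <- summarize(masked_reports)
  list(unmasked = um, masked = mk,
       paired = data.frame(
         subject_id = vapply(records, `[[`, "", "subject_id"),
         label = labels,
         unmasked_decision = vapply(um$extractions, function(e)
           as.character(e$decision), character(1)),
         masked_decision = vapply(mk$extractions, function(e)
           as.character(e$decision), character(1)),
         stringsAsFactors = FALSE))
}
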