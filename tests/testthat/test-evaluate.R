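test_that("score normalization is the exact affine map", {
  expect_equal(normalize_score(5), 100)
  expect_equal(normalize_score(1), 0)
  expect_equal(normalize_score(3), 50)
  expect_equal(normalize_score(1:5), c(0, 25, 50, 75, 100))
  expect_error(normalize_score(0), class = "spirokit_domain_error")
  expect_error(normalize_score(6), class = "spirokit_domain_error")
})

make_report_pair <- function() {
  cu <- synthesize_curve(spiro_curve_params(3.2, 4.8, 0.2, 2.8,
                                            dt = 0.01), seed = 4)
  rec <- list(subject_id = "S1", curves = list(cu),
              demographics = demo_row(age = 61),
              diagnosis_codes = "J449", label = 1L)
  pft <- full_pft(cu, rec$demographics, lms_synthetic_table())
  morph <- describe_morphology(cu)
  sn <- retrieve_snippets("airflow obstruction severity", default_kb(), 2)
  generate_report(rec, pft, morph, sn)
}

test_that("the rubric judge rewards fidelity and flags gaps", {
  gold <- make_report_pair()
  js <- judge_report(gold, gold)
  expect_equal(unname(js$raw["factual_accuracy"]), 5L)
  expect_equal(unname(js$raw["completeness"]), 5L)
  expect_equal(unname(js$normalized["factual_accuracy"]), 100)
  expect_true(all(js$raw >= 1 & js$raw <= 5))

  # empty morphology section caps curve description
  hollow <- gold
  hollow$sections$morphology <- ""
  jh <- judge_report(hollow, gold)
  expect_lte(unname(jh$raw["curve_description"]), 2L)

  # deterministic
  expect_identical(judge_report(gold, gold)$raw, js$raw)

  # the discouraged reversibility phrasing costs safety points
  risky <- gold
  risky$sections$impression <- paste(risky$sections$impression,
                                     "non-fully reversible obstruction")
  expect_lte(unname(judge_report(risky, gold)$raw["safety"]), 3L)

  # adapter contract: one retry, then invalid
  attempts <- 0
  flaky <- function(r, g) {
    attempts <<- attempts + 1
    stop("parse error")
  }
  expect_warning(ji <- judge_report(gold, gold, judge = flaky), "twice")
  expect_equal(attempts, 2)
  expect_true(all(is.na(ji$raw)))
})

test_that("diagnosis extraction parses structured impressions only", {
  rep <- make_report_pair()
  ex <- extract_diagnosis(rep)
  expect_equal(ex$decision, 1L)
  expect_true(ex$confidence > 0 && ex$confidence <= 1)
  expect_equal(extract_diagnosis("complete gibberish")$decision,
               "invalid")
  expect_equal(extract_diagnosis(
    "I cannot assess this case without the measurements.")$decision,
    "invalid")
  # adapter path
  ok <- extract_diagnosis("x", extractor = function(t)
    list(decision = 0, confidence = 0.2))
  expect_equal(ok$decision, 0L)
  bad <- extract_diagnosis("x", extractor = function(t) stop("no"))
  expect_equal(bad$decision, "invalid")
})

test_that("rank metrics equal exhaustive oracles on all small inputs", {
  set.seed(77)
  score_pools <- list(runif(8), rep(c(0.3, 0.7), 4),
                      c(0.1, 0.1, 0.5, 0.5, 0.5, 0.9, 0.9, 0.2))
  for (n in 2:8) {
    for (labels_int in 0:(2^n - 1)) {
      labels <- as.integer(intToBits(labels_int))[1:n]
      if (length(unique(labels)) < 2) next
      for (pool in score_pools) {
        s <- pool[1:n]
        expect_equal(auroc(s, labels), bruteforce_auroc(s, labels),
                     tolerance = 1e-12)
        expect_equal(auprc(s, labels), bruteforce_auprc(s, labels),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rank metrics agree with an independent reference", {
  set.seed(15)
  s <- runif(60)
  y <- rbinom(60, 1, 0.4)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("confusion metrics match direct-count oracles", {
  expect_equal(
    classification_metrics(
      lapply(c(0.2, 0.8), function(cc)
        structure(list(decision = as.integer(cc > 0.5), confidence = cc),
                  class = "diagnosis_extraction")),
      c(0, 1))$auroc, 1)
  # labels [0,1,1,0], confidences [.1,.4,.35,.8] -> AUROC 0.5
  ex <- Map(function(d, cc) structure(list(decision = d, confidence = cc),
                                      class = "diagnosis_extraction"),
            c(0L, 1L, 1L, 0L), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(classification_metrics(ex, c(0, 1, 1, 0))$auroc, 0.5)
  # decisions [1,1,0] vs labels [1,0,0] -> F1 = 2/3
  ex2 <- Map(function(d) structure(list(decision = d, confidence = 0.5),
                                   class = "diagnosis_extraction"),
             c(1L, 1L, 0L))
  ms <- classification_metrics(ex2, c(1, 0, 0))
  expect_equal(ms$f1, 2 / 3)
  expect_equal(ms$sensitivity, 1)
  expect_equal(ms$specificity, 0.5)
  set.seed(99)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    dec <- rbinom(n, 1, 0.5); lab <- rbinom(n, 1, 0.5)
    ex3 <- lapply(dec, function(d)
      structure(list(decision = as.integer(d), confidence = 0.5),
                class = "diagnosis_extraction"))
    got <- classification_metrics(ex3, lab)$f1
    want <- bruteforce_f1(dec, lab)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("invalid extractions lower the valid-response rate", {
  ex <- list(
    structure(list(decision = 1L, confidence = 0.9),
              class = "diagnosis_extraction"),
    structure(list(decision = "invalid", confidence = NA_real_),
              class = "diagnosis_extraction"),
    structure(list(decision = 0L, confidence = 0.2),
              class = "diagnosis_extraction"))
  ms <- classification_metrics(ex, c(1, 1, 0))
  expect_equal(ms$valid_response_rate, 2 / 3)
  expect_equal(ms$n_valid, 2L)
  # all invalid
  allinv <- classification_metrics(ex[c(2, 2)], c(0, 1))
  expect_equal(allinv$valid_response_rate, 0)
  expect_true(is.na(allinv$auroc))
  # single-class flag
  ms1 <- classification_metrics(ex[c(1, 3)], c(1, 1))
  expect_match(paste(ms1$flags, collapse = " "), "single-class")
})

test_that("bootstrap intervals are seeded, nested and honest", {
  x <- rnorm(80, mean = 2)
  ci <- bootstrap_ci(function(idx) mean(x[idx]), length(x),
                     n_resamples = 500, seed = 3)
  ci2 <- bootstrap_ci(function(idx) mean(x[idx]), length(x),
                      n_resamples = 500, seed = 3)
  expect_identical(ci, ci2)
  expect_lte(ci$lower, mean(x))
  expect_gte(ci$upper, mean(x))
  # constant metric: zero width
  cz <- bootstrap_ci(function(idx) 1.5, 10, n_resamples = 50, seed = 1)
  expect_equal(cz$lower, cz$upper)
  # interval widens as the sample shrinks
  set.seed(5)
  big <- rnorm(500); small <- big[1:50]
  ci_big <- bootstrap_ci(function(idx) mean(big[idx]), 500,
                         n_resamples = 400, seed = 7)
  ci_small <- bootstrap_ci(function(idx) mean(small[idx]), 50,
                           n_resamples = 400, seed = 7)
  expect_gt(ci_small$upper - ci_small$lower,
            ci_big$upper - ci_big$lower)
  # chronically undefined metric: flagged unreliable
  suppressMessages(
    cu <- bootstrap_ci(function(idx) NA_real_, 10, n_resamples = 20,
                       seed = 2, max_redraws = 1))
  expect_true(cu$unreliable)
})

test_that("masking collapses the text-only pipeline but not the
           curve-channel variant", {
  cfg <- effect_config(noise_sd = 0.03)
  recs <- generate_cohort(24, prevalence = 0.5, config = cfg, seed = 31)
  recs <- compute_record_pft(recs)
  res <- masking_experiment(recs, use_curve_channel = FALSE)
  expect_equal(res$unmasked$metrics$valid_response_rate, 1)
  expect_lt(res$masked$metrics$valid_response_rate,
            res$unmasked$metrics$valid_response_rate)
  # identical record order in both arms
  expect_identical(res$paired$subject_id,
                   vapply(recs, `[[`, "", "subject_id"))
  # unmasked judge scores are high for self-consistent reports
  expect_gt(res$unmasked$judge_mean[["factual_accuracy"]], 90)

  res2 <- masking_experiment(recs, use_curve_channel = TRUE)
  expect_equal(res2$masked$metrics$valid_response_rate, 1)
  # curve-channel decisions under masking track the unmasked decisions
  agree <- mean(res2$paired$masked_decision ==
                  res2$paired$unmasked_decision)
  expect_gt(agree, 0.9)
})
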