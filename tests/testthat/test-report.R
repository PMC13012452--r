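test_that("concavity index matches its closed forms", {
  # straight limb: index 0
  cu1 <- synthesize_curve(spiro_curve_params(4.5, 8, 0.2, 1,
                                             dt = 0.001))
  expect_equal(concavity_index(cu1), 0, tolerance = 1e-2)
  # convex limb k = 1/3 reaches zero flow in finite time: (k-1)/(k+1)
  cu_cv <- synthesize_curve(spiro_curve_params(4.5, 8, 0.2, 1 / 3,
                                               dt = 0.001))
  expect_equal(concavity_index(cu_cv), -0.5, tolerance = 1e-2)
  # scooped limb k = 3: sampled near-untruncated (tiny end-flow
  # threshold, long watch window) to approach the asymptotic closed
  # form 0.5
  cu3 <- synthesize_curve(spiro_curve_params(
    4.5, 8, 0.2, 3, dt = 0.01, end_flow_threshold = 3e-5),
    max_duration = 1200)
  expect_lt(abs(concavity_index(cu3) - 0.5), 1e-2)
  # at the default end-of-test threshold the truncated closed form holds
  cu3t <- synthesize_curve(spiro_curve_params(4.5, 8, 0.2, 3,
                                              dt = 0.001))
  expect_equal(concavity_index(cu3t),
               analytic_truncated_concavity(3, 8, 0.025),
               tolerance = 1e-2)
  # no descending limb -> error
  rising <- spiro_curve(c(0.5, 1, 2, 3), 0.01)
  expect_error(concavity_index(rising), class = "spirokit_domain_error")
})

test_that("morphology text tracks the concavity index", {
  scooped <- synthesize_curve(spiro_curve_params(4.5, 8, 0.2, 3,
                                                 dt = 0.005))
  m <- describe_morphology(scooped)
  expect_match(m$text, "concave|scooped")
  expect_gt(m$concavity_index, 0.1)

  straight <- synthesize_curve(spiro_curve_params(4.5, 8, 0.2, 1,
                                                  dt = 0.005))
  ml <- describe_morphology(straight)
  expect_match(ml$text, "linear")
  expect_false(grepl("concave", ml$text))

  expect_identical(describe_morphology(scooped)$text, m$text)

  # adapter failure falls back to the rule text with a warning
  expect_warning(
    mf <- describe_morphology(scooped, describer = function(...)
      stop("vlm down")), "fallback")
  expect_identical(mf$text, m$text)
})

test_that("lexical retrieval ranks by relevance with stable ties", {
  kb <- list(
    knowledge_snippet("a", "airflow obstruction severity is graded",
                      tags = "severity"),
    knowledge_snippet("b", "smoking cessation advice for patients",
                      tags = "treatment"),
    knowledge_snippet("c", "airflow limitation appears on curves",
                      tags = "diagnosis"))
  out <- retrieve_snippets("airflow obstruction severity", kb, k = 3)
  expect_equal(out$id[1], "a")  # two query terms beat one
  expect_gt(out$score[1], out$score[2])

  # verbatim snippet query ranks that snippet first
  out2 <- retrieve_snippets(kb[[2]]$text, kb, k = 1)
  expect_equal(out2$id, "b")

  # k larger than the kb returns everything
  expect_equal(nrow(retrieve_snippets("airflow", kb, k = 10)), 3)

  # permutation invariance up to tie-break
  perm <- retrieve_snippets("airflow obstruction severity",
                            kb[c(3, 1, 2)], k = 3)
  expect_equal(perm$id, out$id)
  expect_equal(perm$score, out$score)

  expect_warning(empty <- retrieve_snippets("", kb, k = 2), "empty")
  expect_equal(nrow(empty), 0)

  # shipped knowledge base loads and retrieves
  kb0 <- default_kb()
  expect_gte(length(kb0), 5)
  hit <- retrieve_snippets("severity grading FEV1 percent predicted",
                           kb0, k = 1)
  expect_equal(hit$id, "sev-grades")
})

test_that("diagnosis follows the LLN-first hierarchy", {
  # ratio above LLN but FEV1 below predicted: non-COPD, ratio cited first
  pft <- fake_pft(list())
  idx <- pft$indices
  idx[idx$name == "FEV1_FVC", c("measured", "lln")] <- c(0.75, 0.70)
  idx[idx$name == "FEV1", "pct_predicted"] <- 72
  pft$indices <- idx
  dx <- diagnose(pft)
  expect_equal(dx$diagnosis, 0L)
  expect_match(dx$rationale[1], "LLN")
  expect_match(dx$rationale[1], "no airflow obstruction")
  expect_true(is.na(dx$grade))
  expect_lt(dx$confidence, 0.5)

  # below LLN with FEV1 55% predicted: obstructed, grade 2
  idx[idx$name == "FEV1_FVC", c("measured", "lln")] <- c(0.55, 0.70)
  idx[idx$name == "FEV1", "pct_predicted"] <- 55
  pft$indices <- idx
  dx2 <- diagnose(pft)
  expect_equal(dx2$diagnosis, 1L)
  expect_equal(dx2$grade, 2L)
  expect_match(dx2$rationale[1], "below its LLN")
  expect_gt(dx2$confidence, 0.5)

  # grade boundaries
  for (case in list(c(85, 1), c(80, 1), c(79.9, 2), c(50, 2),
                    c(49, 3), c(30, 3), c(29, 4))) {
    idx[idx$name == "FEV1", "pct_predicted"] <- case[1]
    pft$indices <- idx
    expect_equal(diagnose(pft)$grade, as.integer(case[2]),
                 label = sprintf("FEV1 %%pred %.1f", case[1]))
  }

  # exactly at the LLN: strict inequality, not obstructed
  idx[idx$name == "FEV1_FVC", c("measured", "lln")] <- c(0.70, 0.70)
  pft$indices <- idx
  expect_equal(diagnose(pft)$diagnosis, 0L)

  # missing LLN: inconclusive, never a guess
  idx[idx$name == "FEV1_FVC", "lln"] <- NA_real_
  pft$indices <- idx
  dx3 <- diagnose(pft)
  expect_true(is.na(dx3$diagnosis))
  expect_match(dx3$rationale[1], "inconclusive")
})

test_that("report templates integrate diagnosis, morphology, knowledge", {
  cu <- synthesize_curve(spiro_curve_params(3.1, 4.5, 0.2, 3,
                                            dt = 0.01), seed = 2)
  rec <- list(subject_id = "S1", curves = list(cu),
              demographics = demo_row(age = 62),
              diagnosis_codes = "J440", label = 1L)
  pft <- full_pft(cu, rec$demographics, lms_synthetic_table())
  morph <- describe_morphology(cu)
  sn <- retrieve_snippets("airflow obstruction severity", default_kb(), 2)
  rep <- generate_report(rec, pft, morph, sn)
  txt <- render_report(rep)
  expect_match(rep$sections$impression, "LLN")
  expect_match(txt, "concave")
  expect_true(any(vapply(sn$text, grepl, logical(1), x = txt,
                         fixed = TRUE)))
  expect_identical(render_report(generate_report(rec, pft, morph, sn)),
                   txt)
  # diagnosis consistent with the rule engine, and parseable
  dx <- diagnose(pft)
  expect_equal(rep$diagnosis, dx$diagnosis)
  expect_match(rep$sections$impression,
               sprintf("Diagnosis code: %d", dx$diagnosis))

  # failed adapter falls back with a warning
  expect_warning(
    repf <- generate_report(rec, pft, morph, sn,
                            generator = function(...) stop("llm down")),
    "fallback")
  expect_identical(render_report(repf), txt)

  # non-obstructed fixture: impression states non-COPD and cites LLN
  cun <- synthesize_curve(spiro_curve_params(5.2, 9, 0.2, 0.9,
                                             dt = 0.01), seed = 3)
  pftn <- full_pft(cun, demo_row(age = 48, height = 180),
                   lms_synthetic_table())
  repn <- generate_report(rec, pftn, describe_morphology(cun), sn)
  expect_equal(repn$diagnosis, 0L)
  expect_match(repn$sections$impression, "LLN")
  expect_match(repn$sections$impression, "not supported")

  # masked inputs without a curve channel: inconclusive, no decision
  repm <- generate_report(rec, pft = NULL, morphology = morph,
                          snippets = sn)
  expect_true(is.na(repm$diagnosis))
  expect_match(repm$sections$impression, "inconclusive")
  expect_false(grepl("Diagnosis code", repm$sections$impression))
})
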