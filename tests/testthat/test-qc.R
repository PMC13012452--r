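test_that("case definition matches ICD prefixes and self-report codes", {
  cd <- case_definition()
  expect_equal(assign_label(list(diagnosis_codes = "J449"), cd), 1L)
  expect_equal(assign_label(list(diagnosis_codes = "J430"), cd), 1L)
  expect_equal(assign_label(list(diagnosis_codes = character(0)), cd), 0L)
  expect_equal(assign_label(list(diagnosis_codes = "J45"), cd), 0L)  # asthma
  expect_equal(assign_label(list(diagnosis_codes = c("I10", "SR-COPD")),
                            cd), 1L)
})

test_that("outlier trimming removes exactly the configured tails", {
  recs <- lapply(1:1000, function(i)
    fake_record(sprintf("S%04d", i), FVC = i, FEV1 = 3, PEF = 8))
  out <- trim_outliers(recs, qc_config(tail_fraction = 0.005,
                                       metrics_for_trimming = "FVC"))
  expect_length(out$records, 990)
  expect_equal(nrow(out$exclusions), 10)
  expect_true(all(out$exclusions$stage == "trim_outliers"))

  none <- trim_outliers(recs, qc_config(tail_fraction = 0,
                                        metrics_for_trimming = "FVC"))
  expect_length(none$records, 1000)

  same <- lapply(1:50, function(i) fake_record(paste0("T", i), FVC = 4))
  kept <- trim_outliers(same, qc_config(metrics_for_trimming = "FVC"))
  expect_length(kept$records, 50)

  expect_error(trim_outliers(list(), qc_config()),
               class = "spirokit_input_error")
})

test_that("blow-consistency uses the two best blows and a 10% bound", {
  mk <- function(fvcs) {
    list(subject_id = "X",
         blow_metrics = data.frame(blow_id = seq_along(fvcs), FVC = fvcs,
                                   FEV1 = NA, PEF = NA))
  }
  expect_equal(blow_consistency_filter(mk(c(3.0, 3.4))), "exclude")
  expect_equal(blow_consistency_filter(mk(c(3.0, 3.2))), "keep")
  expect_equal(blow_consistency_filter(mk(c(3.1, 3.1))), "keep")
  # three blows: the two best (3.4, 3.3) agree even though 2.0 is junk
  expect_equal(blow_consistency_filter(mk(c(2.0, 3.4, 3.3))), "keep")
  expect_warning(res <- blow_consistency_filter(mk(3.0)), "single")
  expect_equal(res, "keep")
})

test_that("balancing keeps all cases and equalises class counts", {
  recs <- c(lapply(1:40, function(i) fake_record(paste0("P", i), label = 1)),
            lapply(1:100, function(i) fake_record(paste0("N", i), label = 0)))
  bal <- balance_downsample(recs, seed = 4)
  labs <- vapply(bal, `[[`, integer(1), "label")
  expect_equal(sum(labs == 1), 40)
  expect_equal(sum(labs == 0), 40)
  bal2 <- balance_downsample(recs, seed = 4)
  expect_identical(vapply(bal2, `[[`, "", "subject_id"),
                   vapply(bal, `[[`, "", "subject_id"))
  expect_error(balance_downsample(
    c(lapply(1:2, function(i) fake_record(paste0("P", i), label = 1)),
      list(fake_record("N1", label = 0))), seed = 1),
    class = "spirokit_balance_error")
})

test_that("label screen flags physiology-contradicting labels", {
  recs <- list(fake_record("A", label = 1, z_ratio = 1.5),
               fake_record("B", label = 1, z_ratio = -2.5),
               fake_record("C", label = 0, z_ratio = -3.5),
               fake_record("D", label = 0, z_ratio = 0.2))
  out <- label_consistency_screen(recs)
  expect_setequal(vapply(out$records, `[[`, "", "subject_id"), c("B", "D"))
  expect_setequal(out$exclusions$subject_id, c("A", "C"))

  passthrough <- label_consistency_screen(recs, checker = function(r) FALSE)
  expect_length(passthrough$records, 4)

  failing <- label_consistency_screen(recs, checker = function(r)
    stop("boom"))
  expect_length(failing$records, 4)  # retained on checker failure
  expect_length(failing$checker_failures, 4)
})

test_that("stratified split follows the per-class ceiling rule", {
  recs <- c(lapply(1:5, function(i) fake_record(paste0("P", i), label = 1)),
            lapply(1:5, function(i) fake_record(paste0("N", i), label = 0)))
  sp <- stratified_split(recs, seed = 2)
  expect_equal(sum(sp$split == "val"), 2)
  expect_equal(sum(sp$split == "test"), 2)
  expect_equal(sum(sp$split == "train"), 6)
  # disjoint + exhaustive
  expect_setequal(sp$subject_id, vapply(recs, `[[`, "", "subject_id"))
  expect_equal(anyDuplicated(sp$subject_id), 0)
  # per-class ceiling in each split
  labs <- setNames(vapply(recs, `[[`, integer(1), "label"),
                   vapply(recs, `[[`, "", "subject_id"))
  for (cl in 0:1) {
    ids <- names(labs)[labs == cl]
    expect_equal(sum(sp$split[sp$subject_id %in% ids] == "val"), 1)
    expect_equal(sum(sp$split[sp$subject_id %in% ids] == "test"), 1)
  }
  expect_identical(stratified_split(recs, seed = 2), sp)
  all_train <- stratified_split(recs, ratios = c(1, 0, 0), seed = 2)
  expect_true(all(all_train$split == "train"))
  expect_error(stratified_split(recs[c(1, 6, 7, 8)], seed = 1),
               class = "spirokit_split_error")
})

test_that("split sizes reproduce the printed cohort arithmetic", {
  # 8,245 cases + 10,171 controls at 8:1:1 -> 14,730 / 1,843 / 1,843
  recs <- c(lapply(1:8245, function(i) list(subject_id = paste0("P", i),
                                            label = 1L)),
            lapply(1:10171, function(i) list(subject_id = paste0("N", i),
                                             label = 0L)))
  sp <- stratified_split(recs, ratios = c(8, 1, 1), seed = 1)
  expect_equal(unname(table(sp$split)["train"]), 14730)
  expect_equal(unname(table(sp$split)["val"]), 1843)
  expect_equal(unname(table(sp$split)["test"]), 1843)
})

test_that("the QC pipeline conserves records and logs exclusions", {
  cfg <- effect_config(noise_sd = 0.05, label_noise = 0.05,
                       blow_jitter_sd = 0.05)
  recs <- generate_cohort(80, prevalence = 0.45, config = cfg, seed = 12)
  res <- qc_pipeline(recs, seed = 9)
  # conservation at every stage
  for (i in seq_len(nrow(res$log))) {
    expect_equal(res$log$n_in[i],
                 res$log$n_out[i] + res$log$n_excluded[i])
  }
  # chained: stage i+1 input equals stage i output
  expect_true(all(res$log$n_in[-1] == res$log$n_out[-nrow(res$log)]))
  # every exclusion has a stage and reason
  expect_true(all(nzchar(res$exclusions$stage)))
  expect_true(all(nzchar(res$exclusions$reason)))
  # balanced before screening
  bal_row <- res$log[res$log$stage == "balance", ]
  expect_true(bal_row$n_out %% 2 == 0)
  # survivors carry labels and full PFTs
  expect_true(all(vapply(res$records, function(r)
    r$label %in% c(0L, 1L) && !is.null(r$pft), logical(1))))
})
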