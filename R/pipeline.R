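# End-to-end pipeline: simulate/ingest -> metrics + QC -> split -> train
# encoder -> prompts -> reports -> evaluation, with per-stage artifacts,
# config-hash skipping, and a structured run log.

#' Pipeline configuration
#'
#' All randomness flows from `seed` through [derive_seed()], so each stage
#' is independently reproducible. Defaults run a desk-scale cohort in a
#' few minutes on one CPU.
#'
#' @param out_dir artifact directory.
#' @param n cohort size for simulation (ignored when `manifest` given).
#' @param prevalence simulated COPD prevalence.
#' @param manifest optional existing cohort manifest to ingest instead of
#'   simulating.
#' @param seed root seed.
#' @param effect an [effect_config()].
#' @param qc a [qc_config()].
#' @param encoder an [encoder_config()].
#' @param epochs,batch_size,lr encoder training settings.
#' @param split_ratios train/val/test weights.
#' @param n_boot bootstrap resamples for the evaluation CIs.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n = 120L, prevalence = 0.35,
                            manifest = NULL, seed = 1L,
                            effect = effect_config(),
                            qc = qc_config(),
                            encoder = encoder_config(
                              conv_channels = c(8L, 16L),
                              kernels = c(7L, 5L),
                              lstm_hidden = 16L),
                            epochs = 4L, batch_size = 16L, lr = 3e-3,
                            split_ratios = c(8, 1, 1), n_boot = 200L,
                            log_level = "info") {
  structure(list(out_dir = out_dir, n = as.integer(n),
                 prevalence = prevalence, manifest = manifest,
                 seed = as.integer(seed), effect = effect, qc = qc,
                 encoder = encoder, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 split_ratios = split_ratios, n_boot = as.integer(n_boot),
                 log_level = log_level),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$log_level <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

runlog_append <- function(path, event) {
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, metrics + quality control, stratified split,
#' encoder training, prompt assembly, report generation, and evaluation in
#' order, writing each stage's artifact under `config$out_dir`. A stage is
#' skipped when its artifact already exists and the stored config hash
#' matches. Any stage failure halts with the stage name; artifacts of
#' completed stages are preserved. A JSONL run log records per-stage input
#' and output counts, exclusions, wall time, and the config hash.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the evaluation summary, the run-log path,
#'   and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hashes_path <- file.path(out, "stage_hashes.json")
  hashes <- if (file.exists(hashes_path)) {
    jsonlite::read_json(hashes_path, simplifyVector = TRUE)
  } else list()
  log_path <- file.path(out, "runlog.jsonl")
  info <- function(...) {
    if (identical(config$log_level, "info")) message(sprintf(...))
  }
  stage <- function(name, artifact, run_fn) {
    t0 <- proc.time()[["elapsed"]]
    arts <- file.path(out, artifact)
    if (all(file.exists(arts)) && identical(hashes[[name]], hash)) {
      info("stage %s: artifact up to date, skipped", name)
      runlog_append(log_path, list(stage = name, skipped = TRUE,
                                   config_hash = hash))
      return(NULL)
    }
    res <- tryCatch(run_fn(), error = function(e) {
      abort_spk(sprintf("pipeline halted at stage '%s': %s", name,
                        conditionMessage(e)), "spirokit_stage_error")
    })
    hashes[[name]] <<- hash
    jsonlite::write_json(hashes, hashes_path, auto_unbox = TRUE)
    runlog_append(log_path, list(
      stage = name, skipped = FALSE, n_in = res$n_in, n_out = res$n_out,
      n_excluded = res$n_in - res$n_out,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      config_hash = hash))
    info("stage %s: %d -> %d (%.1fs)", name, res$n_in, res$n_out,
         proc.time()[["elapsed"]] - t0)
    res$value
  }

  coeffs <- lms_synthetic_table()
  kb <- default_kb()

  # --- simulate / ingest ---------------------------------------------------
  manifest <- file.path(out, "cohort", "manifest.jsonl")
  stage("simulate", file.path("cohort", "manifest.jsonl"),
        function() {
    if (!is.null(config$manifest)) {
      recs <- read_cohort(config$manifest)
      write_cohort(recs, file.path(out, "cohort"))
    } else {
      recs <- generate_cohort(config$n, config$prevalence, config$effect,
                              seed = derive_seed(config$seed, "simulate"),
                              coeffs = coeffs)
      write_cohort(recs, file.path(out, "cohort"))
    }
    list(n_in = length(recs), n_out = length(recs), value = NULL)
  })
  records <- read_cohort(manifest)

  # --- metrics + QC --------------------------------------------------------
  qc_res <- NULL
  stage("qc", c("exclusions.csv", "pft.csv"), function() {
    qc_res <<- qc_pipeline(records, qc = config$qc, coeffs = coeffs,
                           seed = derive_seed(config$seed, "qc"))
    utils::write.csv(qc_res$exclusions, file.path(out, "exclusions.csv"),
                     row.names = FALSE)
    pft_rows <- do.call(rbind, lapply(qc_res$records, function(r) {
      idx <- r$pft$indices
      data.frame(subject_id = r$subject_id, name = idx$name,
                 measured = idx$measured, predicted = idx$predicted,
                 lln = idx$lln, z_score = idx$z_score)
    }))
    utils::write.csv(pft_rows, file.path(out, "pft.csv"),
                     row.names = FALSE)
    list(n_in = length(records), n_out = length(qc_res$records),
         value = NULL)
  })
  if (is.null(qc_res)) {
    qc_res <- qc_pipeline(records, qc = config$qc, coeffs = coeffs,
                          seed = derive_seed(config$seed, "qc"))
  }
  recs <- qc_res$records

  # --- split ---------------------------------------------------------------
  split_path <- file.path(out, "split.csv")
  stage("split", "split.csv", function() {
    sp <- stratified_split(recs, ratios = config$split_ratios,
                           seed = derive_seed(config$seed, "split"))
    utils::write.csv(sp, split_path, row.names = FALSE)
    list(n_in = length(recs), n_out = nrow(sp), value = NULL)
  })
  split <- utils::read.csv(split_path, stringsAsFactors = FALSE)

  pick <- function(which_split) {
    ids <- split$subject_id[split$split == which_split]
    recs[vapply(recs, `[[`, "", "subject_id") %in% ids]
  }
  first_curves <- function(rr) lapply(rr, function(r) r$curves[[1]])
  labs <- function(rr) vapply(rr, `[[`, integer(1), "label")

  # --- encoder training ----------------------------------------------------
  ckpt <- file.path(out, "encoder.ckpt.json")
  stage("train_encoder", "encoder.ckpt.json", function() {
    tr <- pick("train"); va <- pick("val")
    cfg <- config$encoder
    cfg$seed <- derive_seed(config$seed, "train_encoder")
    model <- train_encoder(first_curves(tr), labs(tr),
                           first_curves(va), labs(va),
                           config = cfg, epochs = config$epochs,
                           batch_size = config$batch_size, lr = config$lr)
    save_encoder(model, ckpt)
    utils::write.csv(model$history, file.path(out, "history.csv"),
                     row.names = FALSE)
    list(n_in = length(tr), n_out = length(tr), value = NULL)
  })
  model <- load_encoder(ckpt)

  # --- prompts -------------------------------------------------------------
  te <- pick("test")
  stage("prompts", "prompts.jsonl", function() {
    probs <- classify_curves(first_curves(te), model)
    con <- file(file.path(out, "prompts.jsonl"), "w")
    on.exit(close(con))
    for (i in seq_along(te)) {
      pb <- build_prompt(te[[i]], te[[i]]$pft, copd_prob = probs[i])
      writeLines(jsonlite::toJSON(list(subject_id = te[[i]]$subject_id,
                                       text = pb$text),
                                  auto_unbox = TRUE), con)
    }
    list(n_in = length(te), n_out = length(te), value = NULL)
  })

  # --- reports -------------------------------------------------------------
  stage("reports", "reports.jsonl", function() {
    con <- file(file.path(out, "reports.jsonl"), "w")
    on.exit(close(con))
    for (rec in te) {
      morph <- describe_morphology(rec$curves[[1]])
      sn <- retrieve_snippets(paste(morph$text, "airflow obstruction"),
                              kb, k = 2)
      rep <- generate_report(rec, rec$pft, morph, sn)
      writeLines(jsonlite::toJSON(list(
        subject_id = rec$subject_id, label = rec$label,
        diagnosis = rep$diagnosis, confidence = rep$confidence,
        markdown = render_report(rep)), auto_unbox = TRUE, null = "null"),
        con)
    }
    list(n_in = length(te), n_out = length(te), value = NULL)
  })

  # --- evaluation ----------------------------------------------------------
  eval_path <- file.path(out, "evaluation.json")
  stage("evaluate", "evaluation.json", function() {
    reports <- lapply(te, function(rec) {
      morph <- describe_morphology(rec$curves[[1]])
      sn <- retrieve_snippets(paste(morph$text, "airflow obstruction"),
                              kb, k = 2)
      generate_report(rec, rec$pft, morph, sn)
    })
    ex <- lapply(reports, extract_diagnosis)
    ms <- metrics_with_ci(ex, labs(te), n_resamples = config$n_boot,
                          seed = derive_seed(config$seed, "evaluate"))
    summary <- list(
      n_test = length(te),
      auroc = ms$auroc, auprc = ms$auprc, f1 = ms$f1,
      sensitivity = ms$sensitivity, specificity = ms$specificity,
      valid_response_rate = ms$valid_response_rate,
      ci = lapply(ms$ci, function(ci) ci[c("lower", "upper", "level")]))
    jsonlite::write_json(summary, eval_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    list(n_in = length(te), n_out = length(te), value = summary)
  })
  evaluation <- jsonlite::read_json(eval_path, simplifyVector = TRUE)

  invisible(list(evaluation = evaluation, runlog = log_path,
                 artifacts = list(
                   manifest = manifest, split = split_path,
                   checkpoint = ckpt, evaluation = eval_path)))
}
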