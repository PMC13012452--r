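# Gold-standard report drafting: curve-morphology description, lexical
# knowledge retrieval, the hierarchical diagnostic rule (ratio-vs-LLN
# first, severity grading second), and deterministic template synthesis
# with pluggable LLM/VLM adapters.

#' Concavity index of the descending limb
#'
#' Resamples flow on the volume axis and compares the area under the
#' descending limb with the area under the straight chord from the peak
#' `(v_peak, PEF)` to the curve end `(FVC, 0)`:
#' `index = 1 - area(limb) / area(chord)`. Positive values indicate a
#' concave ("scooped") limb, zero a straight limb, negative a convex limb.
#' For the power-law curve family with exponent `k` the index is exactly
#' `(k - 1) / (k + 1)`.
#'
#' @param curve a [spiro_curve()].
#' @return dimensionless index.
#' @export
concavity_index <- function(curve) {
  stopifnot(inherits(curve, "spiro_curve"))
  f <- curve$flow
  vol <- compute_volume(curve)
  i_pef <- which.max(f)
  if (i_pef >= length(f)) {
    abort_spk("peak flow at final sample: no descending limb",
              "spirokit_domain_error")
  }
  idx <- i_pef:length(f)
  v <- vol[idx]; fl <- f[idx]
  pef <- f[i_pef]
  v_span <- v[length(v)] - v[1]
  if (v_span <= 0) {
    abort_spk("no volume exhaled on descending limb",
              "spirokit_domain_error")
  }
  area <- sum(diff(v) * (fl[-1] + fl[-length(fl)]) / 2)
  chord <- 0.5 * pef * v_span
  1 - area / chord
}

#' Describe flow-volume curve morphology
#'
#' The rule fallback maps the [concavity_index()] and the position of peak
#' flow to templated text: the limb is called concave ("scooped") above
#' `threshold`, linear within `±threshold`, convex below. A pluggable
#' describer (e.g. a vision-language-model adapter receiving a rendered
#' flow-volume plot) may replace the rule; on adapter failure the rule
#' fallback is used and a warning logged.
#'
#' @param curve a [spiro_curve()].
#' @param describer optional function(curve, concavity) returning text.
#' @param threshold concavity magnitude separating concave/linear/convex.
#' @return object of class `morphology_description`: list with
#'   `concavity_index`, `pef_sharpness`, `text`.
#' @export
describe_morphology <- function(curve, describer = NULL, threshold = 0.1) {
  ci <- concavity_index(curve)
  vol <- compute_volume(curve)
  v_frac <- vol[which.max(curve$flow)] / vol[length(vol)]
  sharp <- if (v_frac < 0.3) "early sharp peak" else "rounded peak"
  limb <- if (ci > threshold) {
    paste("The descending limb is concave, showing the scooped",
          "configuration associated with airflow obstruction.")
  } else if (ci < -threshold) {
    "The descending limb is convex, with flow sustained late in exhalation."
  } else {
    "The descending limb is approximately linear."
  }
  text <- sprintf(
    "The flow-volume curve shows an %s reaching %.1f L/s. %s (concavity index %.2f)",
    sharp, max(curve$flow), limb, ci)
  if (!is.null(describer)) {
    text <- tryCatch(describer(curve, ci), error = function(e) {
      warning("morphology describer failed; using rule fallback: ",
              conditionMessage(e))
      text
    })
  }
  structure(list(concavity_index = ci, pef_sharpness = sharp, text = text),
            class = "morphology_description")
}

#' Knowledge snippets and their JSONL loader
#'
#' Snippets carry an id, free text, topical tags (diagnosis / severity /
#' treatment), and a source label. [default_kb()] ships a small set of
#' original paraphrase snippets on obstructive-disease diagnosis, severity
#' grading and management; user knowledge bases load from JSONL (one
#' snippet object per line).
#'
#' @param id unique snippet id.
#' @param text snippet text (non-empty).
#' @param tags character vector of tags.
#' @param source source label.
#' @return a `knowledge_snippet`.
#' @export
knowledge_snippet <- function(id, text, tags = character(0),
                              source = "user") {
  stopifnot(nzchar(text))
  structure(list(id = id, text = text, tags = tags, source = source),
            class = "knowledge_snippet")
}

#' @rdname knowledge_snippet
#' @param path JSONL file of snippets.
#' @export
read_kb_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln)
    knowledge_snippet(o$id, o$text, as.character(o$tags),
                      if (is.null(o$source)) "user" else o$source)
  })
}

#' @rdname knowledge_snippet
#' @param kb list of snippets.
#' @export
write_kb_jsonl <- function(kb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in kb) {
    writeLines(jsonlite::toJSON(unclass(sn), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname knowledge_snippet
#' @export
default_kb <- function() {
  path <- system.file("extdata", "kb_copd.jsonl", package = "spirokit")
  read_kb_jsonl(path)
}

tokenize_terms <- function(text) {
  toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(text)), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Retrieve the most relevant knowledge snippets
#'
#' Lexical BM25-style scoring over snippet text and tags: each query term
#' contributes `idf(term) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len/avglen))`
#' with `k1 = 1.2`, `b = 0.75` and a smoothed inverse document frequency.
#' Results are sorted by descending score, ties broken by snippet id; the
#' score set is invariant to knowledge-base order.
#'
#' @param query query text.
#' @param kb list of [knowledge_snippet()] objects.
#' @param k number of snippets to return (capped at the kb size).
#' @return data.frame `id, score, text` of the top-k snippets.
#' @export
retrieve_snippets <- function(query, kb, k = 3L) {
  stopifnot(k >= 1, length(kb) >= 1)
  q <- unique(tokenize_terms(query))
  if (length(q) == 0) {
    warning("empty query; no snippets retrieved")
    return(data.frame(id = character(0), score = numeric(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  docs <- lapply(kb, function(sn)
    tokenize_terms(paste(sn$text, paste(sn$tags, collapse = " "))))
  N <- length(docs)
  lens <- vapply(docs, length, integer(1))
  avglen <- mean(lens)
  k1 <- 1.2; b <- 0.75
  df <- vapply(q, function(term)
    sum(vapply(docs, function(d) term %in% d, logical(1))), numeric(1))
  idf <- log(1 + (N - df + 0.5) / (df + 0.5))
  scores <- vapply(seq_len(N), function(i) {
    tf <- vapply(q, function(term) sum(docs[[i]] == term), numeric(1))
    denom <- tf + k1 * (1 - b + b * lens[i] / avglen)
    sum(ifelse(tf > 0, idf * tf * (k1 + 1) / denom, 0))
  }, numeric(1))
  ids <- vapply(kb, `[[`, "", "id")
  ord <- order(-scores, ids)
  top <- utils::head(ord, min(k, N))
  data.frame(id = ids[top], score = scores[top],
             text = vapply(kb[top], `[[`, "", "text"),
             stringsAsFactors = FALSE)
}

#' Hierarchical spirometric diagnosis
#'
#' Applies the diagnostic hierarchy in fixed order: (1) airflow
#' obstruction is present iff the measured FEV1/FVC ratio is strictly
#' below its lower limit of normal; (2) only if obstructed, the severity
#' grade follows FEV1 percent predicted (>= 80 grade 1, 50-79 grade 2,
#' 30-49 grade 3, < 30 grade 4). The rationale chain records the ordered
#' checks with the LLN comparison always first. A missing ratio LLN yields
#' an inconclusive result, never a guess. The COPD confidence is a
#' logistic function of the ratio's relative distance from the LLN.
#'
#' @param pft a `pft_result` with reference values filled ([full_pft()]).
#' @return list with `diagnosis` (0/1/NA), `grade` (1-4 or NA),
#'   `confidence` (P(COPD) in (0,1), NA if inconclusive), `rationale`
#'   (ordered character vector).
#' @export
diagnose <- function(pft) {
  ratio <- pft_value(pft, "FEV1_FVC", "measured")
  ratio_lln <- pft_value(pft, "FEV1_FVC", "lln")
  fev1_pct <- pft_value(pft, "FEV1", "pct_predicted")
  if (!is.finite(ratio) || !is.finite(ratio_lln)) {
    return(list(diagnosis = NA_integer_, grade = NA_integer_,
                confidence = NA_real_,
                rationale = "FEV1/FVC ratio or its LLN unavailable; inconclusive"))
  }
  margin <- (ratio_lln - ratio) / ratio_lln
  confidence <- as.numeric(stats::plogis(12 * margin))
  if (ratio >= ratio_lln) {
    return(list(
      diagnosis = 0L, grade = NA_integer_, confidence = confidence,
      rationale = c(sprintf(
        "FEV1/FVC %.3f is at or above its LLN %.3f: no airflow obstruction",
        ratio, ratio_lln),
        "secondary indices not used to overturn the primary criterion")))
  }
  rationale <- sprintf(
    "FEV1/FVC %.3f is below its LLN %.3f: airflow obstruction present",
    ratio, ratio_lln)
  if (!is.finite(fev1_pct)) {
    return(list(diagnosis = 1L, grade = NA_integer_,
                confidence = confidence,
                rationale = c(rationale,
                              "FEV1 percent predicted unavailable; grade not assigned")))
  }
  grade <- if (fev1_pct >= 80) 1L else if (fev1_pct >= 50) 2L
  else if (fev1_pct >= 30) 3L else 4L
  list(diagnosis = 1L, grade = grade, confidence = confidence,
       rationale = c(rationale,
                     sprintf("FEV1 %.0f%% predicted: severity grade %d",
                             fev1_pct, grade)))
}

#' Generate a structured diagnostic report
#'
#' The deterministic template fallback renders four sections — findings
#' (PFT values), curve morphology, impression (diagnosis, grade and the
#' ordered rationale, always citing the FEV1/FVC-vs-LLN comparison first),
#' and recommendations (retrieved knowledge snippets). A pluggable
#' generator adapter may synthesise the sections instead; on adapter
#' failure the fallback is used and a warning logged. With `pft = NULL`
#' (masked inputs and no curve channel) the impression is inconclusive and
#' carries no machine-readable decision.
#'
#' @param record a cohort record.
#' @param pft a `pft_result` with references, or `NULL`.
#' @param morphology a `morphology_description`, or `NULL`.
#' @param snippets data.frame from [retrieve_snippets()], or `NULL`.
#' @param generator optional adapter `function(inputs)` returning a list
#'   with element `sections`.
#' @return object of class `spiro_report`: list with `sections`,
#'   `diagnosis`, `grade`, `confidence`.
#' @export
generate_report <- function(record, pft = NULL, morphology = NULL,
                            snippets = NULL, generator = NULL) {
  dx <- if (is.null(pft)) {
    list(diagnosis = NA_integer_, grade = NA_integer_,
         confidence = NA_real_,
         rationale = "required quantitative indices unavailable")
  } else {
    diagnose(pft)
  }
  findings <- if (is.null(pft)) {
    "Quantitative pulmonary function values were not available."
  } else {
    paste(prompt_pft_lines(pft), collapse = "\n")
  }
  morph_text <- if (is.null(morphology)) "" else morphology$text
  impression <- if (is.na(dx$diagnosis)) {
    paste("Impression: inconclusive -", dx$rationale[1])
  } else {
    paste0(
      "Impression: ", if (dx$diagnosis == 1L) {
        sprintf("airflow obstruction consistent with COPD%s.",
                if (is.finite(dx$grade))
                  sprintf(", severity grade %d", dx$grade) else "")
      } else "no airflow obstruction; COPD not supported.",
      "\n", paste(paste0("- ", dx$rationale), collapse = "\n"),
      sprintf("\nDiagnosis code: %d. Confidence: %.3f.",
              dx$diagnosis, dx$confidence))
  }
  recommendations <- if (is.null(snippets) || nrow(snippets) == 0) {
    "No guideline snippets retrieved."
  } else {
    paste(paste0("- ", snippets$text), collapse = "\n")
  }
  sections <- list(findings = findings, morphology = morph_text,
                   impression = impression,
                   recommendations = recommendations)
  if (!is.null(generator)) {
    sections <- tryCatch({
      out <- generator(list(record = record, pft = pft,
                            morphology = morphology, snippets = snippets,
                            diagnosis = dx))
      stopifnot(is.list(out$sections))
      out$sections
    }, error = function(e) {
      warning("report generator adapter failed; using template fallback: ",
              conditionMessage(e))
      sections
    })
  }
  structure(list(sections = sections, diagnosis = dx$diagnosis,
                 grade = dx$grade, confidence = dx$confidence),
            class = "spiro_report")
}

#' Render a report as Markdown text
#'
#' @param report a `spiro_report`.
#' @return single Markdown string.
#' @export
render_report <- function(report) {
  s <- report$sections
  paste(c("# Spirometry diagnostic report", "",
          "## Findings", s$findings, "",
          "## Curve morphology", s$morphology, "",
          "## Impression", s$impression, "",
          "## Recommendations", s$recommendations),
        collapse = "\n")
}

#' @export
print.spiro_report <- function(x, ...) {
  cat(render_report(x), "\n")
  invisible(x)
}
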