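# Multimodal prompt assembly: a structured text prompt (demographics
# block, PFT block, COPD-probability line) with optional projected
# embeddings and PFT masking for robustness experiments.

fmt_num <- function(x, digits = 2) {
  ifelse(is.finite(x), formatC(x, format = "f", digits = digits), "n/a")
}

prompt_pft_lines <- function(pft) {
  rows <- pft$indices[pft$indices$name %in%
                        c("FEV1", "FVC", "FEV1_FVC", "PEF", "FEF25_75"), ]
  units <- c(FEV1 = "L", FVC = "L", FEV1_FVC = "", PEF = "L/s",
             FEF25_75 = "L/s")
  vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    u <- units[[r$name]]
    sprintf("- %s: measured %s %s, predicted %s %s, LLN %s %s, z-score %s",
            sub("FEV1_FVC", "FEV1/FVC", sub("FEF25_75", "FEF25-75", r$name)),
            fmt_num(r$measured), u, fmt_num(r$predicted), u,
            fmt_num(r$lln), u, fmt_num(r$z_score))
  }, character(1))
}

#' Assemble a multimodal prompt bundle
#'
#' Renders the three prompt blocks: patient demographics, the PFT block
#' (measured / predicted / LLN / z-score for FEV1, FVC, FEV1/FVC, PEF and
#' FEF25-75), and the encoder's COPD-probability line, plus an embedding
#' placeholder span when projected embeddings are attached. With
#' `mask_pft = TRUE` every numeric PFT token is withheld while the section
#' header is preserved, emulating the input-masking robustness experiment.
#'
#' @param record a cohort record (for demographics).
#' @param pft a `pft_result`, or `NULL` when `mask_pft = TRUE`.
#' @param copd_prob encoder COPD probability, or `NA` to omit the line.
#' @param projected optional projected embedding matrix (`L x d_llm`).
#' @param mask_pft withhold all numeric PFT values.
#' @return an object of class `prompt_bundle`: list with `text`,
#'   `embeddings` (matrix or `NULL`), and `mask_flags`.
#' @export
build_prompt <- function(record, pft = NULL, copd_prob = NA,
                         projected = NULL, mask_pft = FALSE) {
  if (is.null(pft) && !mask_pft) {
    abort_spk("pft must be supplied unless mask_pft = TRUE",
              "spirokit_input_error")
  }
  d <- record$demographics
  demo_block <- c(
    "## Patient information",
    sprintf("Age: %.0f years", d$age),
    sprintf("Sex: %s", d$sex),
    sprintf("Height: %.0f cm", d$height),
    sprintf("Smoking history: %s", d$smoking))
  pft_block <- c("## Pulmonary function results",
                 if (mask_pft) "[quantitative values withheld]"
                 else prompt_pft_lines(pft))
  prob_block <- if (is.finite(copd_prob)) {
    sprintf("## Signal model\nCOPD probability from curve encoder: %.3f",
            copd_prob)
  } else NULL
  emb_block <- if (!is.null(projected)) {
    sprintf("## Curve embedding\n<spiro_embedding %d x %d>",
            nrow(projected), ncol(projected))
  } else NULL
  text <- paste(c(paste(demo_block, collapse = "\n"),
                  paste(pft_block, collapse = "\n"),
                  prob_block, emb_block), collapse = "\n\n")
  structure(list(text = text, embeddings = projected,
                 mask_flags = list(pft = mask_pft)),
            class = "prompt_bundle")
}

#' Mask the PFT block of an existing prompt bundle
#'
#' Replaces every digit-bearing line of the pulmonary-function section with
#' a withheld marker, keeping the section header. Idempotent: masking a
#' masked bundle changes nothing.
#'
#' @param bundle a `prompt_bundle`.
#' @return the masked `prompt_bundle`.
#' @export
mask_prompt <- function(bundle) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  lines <- strsplit(bundle$text, "\n", fixed = TRUE)[[1]]
  sec_starts <- grep("^## ", lines)
  pft_start <- grep("^## Pulmonary function results", lines)
  if (length(pft_start) == 1) {
    nxt <- sec_starts[sec_starts > pft_start]
    pft_end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    body <- seq(pft_start + 1L, pft_end)
    body <- body[grepl("[0-9]", lines[body])]
    if (length(body)) {
      lines <- lines[-body]
      lines <- append(lines, "[quantitative values withheld]",
                      after = pft_start)
    }
  }
  bundle$text <- paste(lines, collapse = "\n")
  bundle$mask_flags$pft <- TRUE
  bundle
}

#' Serialize / restore a prompt bundle as JSON
#'
#' @param bundle a `prompt_bundle`.
#' @param path JSON path.
#' @return `write_prompt_json` returns `path` invisibly;
#'   `read_prompt_json` a `prompt_bundle`.
#' @export
write_prompt_json <- function(bundle, path) {
  obj <- list(text = bundle$text, mask_flags = bundle$mask_flags,
              embeddings = if (is.null(bundle$embeddings)) NULL else
                list(dim = dim(bundle$embeddings),
                     data = as.numeric(bundle$embeddings)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_prompt_json
#' @export
read_prompt_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  emb <- if (!is.null(obj$embeddings) && length(obj$embeddings)) {
    array(as.numeric(unlist(obj$embeddings$data)),
          as.integer(unlist(obj$embeddings$dim)))
  } else NULL
  structure(list(text = obj$text, embeddings = emb,
                 mask_flags = as.list(obj$mask_flags)),
            class = "prompt_bundle")
}
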