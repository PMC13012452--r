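# Curve and cohort serialization. Two curve dialects are supported:
# "timeseries" (CSV with header time_s,flow_lps) and "flowpoints" (a
# dt= header line followed by one comma-separated row of flow values,
# for instrument-style exports).

#' Read / write a sampled curve
#'
#' @param path file path.
#' @param dialect `"timeseries"` or `"flowpoints"`.
#' @param blow_id blow index to attach on read.
#' @return `read_curve` returns a [spiro_curve()]; `write_curve` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path, dialect = c("timeseries", "flowpoints"),
                       blow_id = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_spk(sprintf("no such file: %s", path), "spirokit_parse_error")
  }
  if (dialect == "timeseries") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) {
                     abort_spk(sprintf("cannot parse %s: %s", path,
                                       conditionMessage(e)),
                               "spirokit_parse_error")
                   })
    if (!all(c("time_s", "flow_lps") %in% names(df))) {
      abort_spk("expected columns time_s,flow_lps", "spirokit_parse_error")
    }
    tm <- suppressWarnings(as.numeric(df$time_s))
    fl <- suppressWarnings(as.numeric(df$flow_lps))
    bad <- which(!is.finite(tm) | !is.finite(fl))
    if (length(bad)) {
      abort_spk(sprintf("non-numeric field at line %d of %s",
                        bad[1] + 1L, path), "spirokit_parse_error")
    }
    if (length(tm) < 2) abort_spk("curve needs >= 2 samples",
                                  "spirokit_parse_error")
    dts <- diff(tm)
    if (max(dts) - min(dts) > 1e-6) {
      abort_spk(sprintf("non-uniform sampling interval in %s", path),
                "spirokit_parse_error")
    }
    spiro_curve(fl, mean(dts), blow_id = blow_id)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 2 || !grepl("^dt=", lines[1])) {
      abort_spk("flowpoints dialect needs a 'dt=' header line",
                "spirokit_parse_error")
    }
    dt <- suppressWarnings(as.numeric(sub("^dt=", "", lines[1])))
    if (!is.finite(dt) || dt <= 0) {
      abort_spk("invalid dt header", "spirokit_parse_error")
    }
    fl <- suppressWarnings(as.numeric(strsplit(lines[2], ",")[[1]]))
    bad <- which(!is.finite(fl))
    if (length(bad)) {
      abort_spk(sprintf("non-numeric flow value at position %d", bad[1]),
                "spirokit_parse_error")
    }
    spiro_curve(fl, dt, blow_id = blow_id)
  }
}

#' @rdname read_curve
#' @param curve a [spiro_curve()].
#' @export
write_curve <- function(curve, path, dialect = c("timeseries",
                                                 "flowpoints")) {
  dialect <- match.arg(dialect)
  if (dialect == "timeseries") {
    df <- data.frame(time_s = (seq_along(curve$flow) - 1L) * curve$dt,
                     flow_lps = curve$flow)
    utils::write.table(format(df, digits = 12, scientific = FALSE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    writeLines(c(sprintf("dt=%.12g", curve$dt),
                 paste(formatC(curve$flow, format = "g", digits = 12),
                       collapse = ",")), path)
  }
  invisible(path)
}

#' Write / read a cohort manifest
#'
#' A cohort is stored as a JSONL manifest (one record per line) plus one
#' curve CSV per blow under `curves/`, referenced by relative path.
#'
#' @param records list of cohort records.
#' @param dir output directory.
#' @return `write_cohort` returns the manifest path invisibly;
#'   `read_cohort` returns the record list.
#' @export
write_cohort <- function(records, dir) {
  dir.create(file.path(dir, "curves"), showWarnings = FALSE,
             recursive = TRUE)
  manifest <- file.path(dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (rec in records) {
    rels <- character(length(rec$curves))
    for (i in seq_along(rec$curves)) {
      cu <- rec$curves[[i]]
      rels[i] <- file.path("curves",
                           sprintf("%s_%d.csv", rec$subject_id, cu$blow_id))
      write_curve(cu, file.path(dir, rels[i]))
    }
    obj <- list(subject_id = rec$subject_id, curves = rels,
                demographics = as.list(rec$demographics),
                diagnosis_codes = as.list(rec$diagnosis_codes),
                label = rec$label)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(manifest)
}

#' @rdname write_cohort
#' @param manifest_path path to `manifest.jsonl`.
#' @export
read_cohort <- function(manifest_path) {
  base <- dirname(manifest_path)
  lines <- readLines(manifest_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    o <- tryCatch(jsonlite::fromJSON(ln), error = function(e) {
      abort_spk(sprintf("corrupt manifest line: %s",
                        conditionMessage(e)), "spirokit_parse_error")
    })
    curves <- lapply(seq_along(o$curves), function(i)
      read_curve(file.path(base, o$curves[[i]]), blow_id = i))
    list(subject_id = o$subject_id, curves = curves,
         demographics = as.data.frame(o$demographics,
                                      stringsAsFactors = FALSE),
         diagnosis_codes = as.character(unlist(o$diagnosis_codes)),
         label = if (is.null(o$label)) NA_integer_ else
           as.integer(o$label))
  })
}
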