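# Patient records: timestamped typed variable assignments with explicit
# missingness (absence of a var_id means missing), plus raw value
# normalization at the ingestion boundary.

#' Create a patient record
#'
#' @param patient_id identifier.
#' @param values named list `var_id -> typed value` (logical for boolean
#'   variables, numeric for numeric, character for categorical/ordinal).
#'   A variable absent from the list is missing; `NULL` entries are dropped.
#' @param series list of [rc_series()] with the patient's longitudinal data.
#' @param timestamps optional named list `var_id -> ISO timestamp` recording
#'   when each value was observed.
#' @param group optional target-group label carried by the record; when
#'   present, rules for other groups are filtered out at trigger time.
#' @return list of class `rc_patient`.
#' @export
patient_record <- function(patient_id, values = list(), series = list(),
                           timestamps = list(), group = NULL) {
  values <- values[!vapply(values, is.null, TRUE)]
  structure(list(patient_id = patient_id, values = values, series = series,
                 timestamps = timestamps, group = group),
            class = "rc_patient")
}

#' @export
print.rc_patient <- function(x, ...) {
  cat(sprintf("<patient %s> %d known variables, %d series\n",
              x$patient_id, length(x$values), length(x$series)))
  invisible(x)
}

ingestion_error <- function(variable, raw, why) {
  stop(structure(
    class = c("rc_ingestion_error", "error", "condition"),
    list(message = sprintf("cannot normalize value '%s' for variable '%s': %s",
                           raw, variable, why),
         call = NULL, variable = variable, raw = raw)))
}

#' Normalize a raw value against a variable definition
#'
#' The ingestion boundary: trims whitespace; numeric values must parse as
#' plain decimals; booleans accept true/false, yes/no and 1/0
#' case-insensitively; categorical and ordinal values are matched
#' case-insensitively against the allowed values and the canonical label is
#' returned (so `"Asthma "` normalizes to `"asthma"`). An unparseable value
#' raises a typed ingestion error naming the variable and the raw text —
#' never a silent missing.
#'
#' @param variable a [kb_variable()].
#' @param raw raw value (character, or already typed).
#' @return typed value matching the variable's kind.
#' @export
normalize_value <- function(variable, raw) {
  if (length(raw) != 1L) ingestion_error(variable$var_id, paste(raw, collapse = ","),
                                         "expected a single value")
  if (is.na(raw)) ingestion_error(variable$var_id, "NA", "value is NA")
  s <- if (is.character(raw)) trimws(raw) else raw
  switch(variable$kind,
    boolean = {
      if (is.logical(s)) return(s)
      key <- tolower(as.character(s))
      if (key %in% c("true", "yes", "1")) return(TRUE)
      if (key %in% c("false", "no", "0")) return(FALSE)
      ingestion_error(variable$var_id, as.character(raw), "not a boolean literal")
    },
    numeric = {
      if (is.numeric(s)) return(as.numeric(s))
      if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", s)) {
        ingestion_error(variable$var_id, as.character(raw), "not a plain decimal number")
      }
      as.numeric(s)
    },
    categorical = ,
    ordinal = {
      s <- trimws(as.character(s))
      hit <- which(tolower(variable$allowed_values) == tolower(s))
      if (!length(hit)) {
        ingestion_error(variable$var_id, as.character(raw),
                        paste0("not among allowed values (",
                               paste(variable$allowed_values, collapse = ", "), ")"))
      }
      variable$allowed_values[hit[1]]
    },
    timeseries = ingestion_error(variable$var_id, as.character(raw),
                                 "time-series variables are ingested as series, not scalars"),
    ingestion_error(variable$var_id, as.character(raw),
                    paste0("unknown variable kind '", variable$kind, "'"))
  )
}

patient_to_plain <- function(p) {
  drop_null(list(
    patient_id = p$patient_id,
    group = p$group,
    values = p$values[order(names(p$values), method = "radix")],
    timestamps = if (length(p$timestamps)) p$timestamps else NULL,
    series = if (length(p$series)) {
      lapply(p$series, function(s) {
        list(var_id = s$var_id, time = format(s$time, "%Y-%m-%d"),
             value = s$value)
      })
    } else {
      NULL
    }
  ))
}

#' Write a patient record to a JSON file
#'
#' @param patient a [patient_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_patient <- function(patient, path) {
  json <- jsonlite::toJSON(patient_to_plain(patient), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a patient record from a JSON file
#'
#' Raw scalar values are normalized against the KB's variable registry when
#' a KB is supplied; normalization failures abort with the ingestion error.
#'
#' @param path path to a patient JSON file.
#' @param kb optional knowledge base used to normalize values.
#' @return a [patient_record()].
#' @export
load_patient <- function(path, kb = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  values <- raw$values %||% list()
  if (!is.null(kb)) {
    for (v in names(values)) {
      vdef <- kb$variables[[v]]
      if (is.null(vdef)) stop("patient file references undeclared variable '", v, "'")
      values[[v]] <- normalize_value(vdef, unlist(values[[v]]))
    }
  } else {
    values <- lapply(values, unlist)
  }
  series <- lapply(raw$series %||% list(), function(s) {
    rc_series(s$var_id, unlist(s$time), unlist(s$value))
  })
  patient_record(raw$patient_id, values = values, series = series,
                 timestamps = lapply(raw$timestamps %||% list(), unlist),
                 group = raw$group %||% NULL)
}
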