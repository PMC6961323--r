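#' Construct an encounter table from event data frames
#'
#' The core container for encounter-level EMR events: one row per
#' (encounter, drug) medication event and one per (encounter, diagnosis)
#' event. Codes are whitespace-trimmed, case-preserved opaque strings.
#' Duplicate (encounter, code) rows are permitted on input; accessors and
#' all downstream statistics operate on the deduplicated view. Events
#' referencing an encounter absent from the encounter index are dropped and
#' counted in the validation summary.
#'
#' @param drug_events data.frame with columns `encounter_id`, `drug_code`
#'   (optionally `atc_code`).
#' @param diagnosis_events data.frame with columns `encounter_id`,
#'   `diagnosis_code` (optionally `icd10_code`).
#' @param encounter_ids optional character vector defining the encounter
#'   index; defaults to the union of encounter ids seen in either event
#'   table.
#' @return an object of class `encounter_table`: a list with deduplicated
#'   `drug_events` and `diagnosis_events` data frames, the `encounters`
#'   index, optional `atc_map` / `icd10_map` side tables, and a
#'   `validation` summary (rows in, rows kept, rows dropped per stream).
#' @export
encounter_table <- function(drug_events, diagnosis_events,
                            encounter_ids = NULL) {
  drug_events <- validate_events(drug_events, "drug_code")
  diagnosis_events <- validate_events(diagnosis_events, "diagnosis_code")

  if (is.null(encounter_ids)) {
    encounter_ids <- sort(unique(c(drug_events$encounter_id,
                                   diagnosis_events$encounter_id)))
  } else {
    encounter_ids <- unique(normalize_codes(encounter_ids))
  }

  clean <- function(ev, code_col) {
    n_in <- nrow(ev)
    ok <- nzchar(ev[[code_col]]) & nzchar(ev$encounter_id) &
      ev$encounter_id %in% encounter_ids
    ev <- ev[ok, , drop = FALSE]
    n_valid <- nrow(ev)
    ev <- ev[!duplicated(ev[, c("encounter_id", code_col)]), , drop = FALSE]
    rownames(ev) <- NULL
    list(events = ev, n_in = n_in, n_dropped = n_in - n_valid,
         n_dedup = n_valid - nrow(ev))
  }

  atc_map <- extract_code_map(drug_events, "drug_code", "atc_code")
  icd10_map <- extract_code_map(diagnosis_events, "diagnosis_code", "icd10_code")

  d <- clean(drug_events[, c("encounter_id", "drug_code")], "drug_code")
  g <- clean(diagnosis_events[, c("encounter_id", "diagnosis_code")],
             "diagnosis_code")

  structure(list(
    encounters = encounter_ids,
    drug_events = d$events,
    diagnosis_events = g$events,
    atc_map = atc_map,
    icd10_map = icd10_map,
    validation = data.frame(
      stream = c("drug", "diagnosis"),
      rows_in = c(d$n_in, g$n_in),
      rows_dropped = c(d$n_dropped, g$n_dropped),
      rows_deduplicated = c(d$n_dedup, g$n_dedup),
      rows_kept = c(nrow(d$events), nrow(g$events))
    )
  ), class = "encounter_table")
}

validate_events <- function(ev, code_col) {
  if (!is.data.frame(ev)) stop("event input must be a data.frame")
  for (col in c("encounter_id", code_col)) {
    if (!col %in% names(ev)) {
      stop(sprintf("missing mandatory column '%s'", col))
    }
  }
  ev$encounter_id <- normalize_codes(ev$encounter_id)
  ev[[code_col]] <- normalize_codes(ev[[code_col]])
  ev
}

extract_code_map <- function(ev, code_col, map_col) {
  if (!map_col %in% names(ev)) return(NULL)
  m <- unique(ev[, c(code_col, map_col)])
  m <- m[nzchar(normalize_codes(m[[map_col]])), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' @export
print.encounter_table <- function(x, ...) {
  cat("encounter_table:", length(x$encounters), "encounters,",
      length(unique(x$drug_events$drug_code)), "distinct drugs,",
      length(unique(x$diagnosis_events$diagnosis_code)),
      "distinct diagnoses\n")
  cat("events (deduplicated):", nrow(x$drug_events), "medication,",
      nrow(x$diagnosis_events), "diagnosis\n")
  dropped <- sum(x$validation$rows_dropped)
  if (dropped > 0) cat("validation dropped", dropped, "rows\n")
  invisible(x)
}

#' Read encounter-level events from delimited text files
#'
#' Accepts either two files (medications and diagnoses) or one long file
#' with an `event_type` column taking values `"drug"` and `"diagnosis"`
#' and a single `code` column. The delimiter (comma or tab) is
#' auto-detected from the header line unless given.
#'
#' @param medications path to the medication events file
#'   (`encounter_id,drug_code[,atc_code]`), or to the single long file when
#'   `diagnoses` is `NULL`.
#' @param diagnoses path to the diagnosis events file
#'   (`encounter_id,diagnosis_code[,icd10_code]`), or `NULL` for
#'   long-format input.
#' @param sep field delimiter; `NULL` auto-detects comma vs tab.
#' @return an [encounter_table()].
#' @export
read_encounters <- function(medications, diagnoses = NULL, sep = NULL) {
  med <- read_delim_file(medications, sep)
  if (is.null(diagnoses)) {
    if (!all(c("event_type", "code") %in% names(med))) {
      stop("long-format input requires columns 'event_type' and 'code'")
    }
    drug <- med[med$event_type == "drug", c("encounter_id", "code")]
    names(drug)[2] <- "drug_code"
    dx <- med[med$event_type == "diagnosis", c("encounter_id", "code")]
    names(dx)[2] <- "diagnosis_code"
  } else {
    drug <- med
    dx <- read_delim_file(diagnoses, sep)
  }
  encounter_table(drug, dx)
}

read_delim_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop(sprintf("empty input file: %s", path))
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L && ncol(df) == 0L) {
    stop(sprintf("empty input file: %s", path))
  }
  df
}

#' Read a pediatric drug-label table
#'
#' Each row carries a drug code plus either a structured labeling statement
#' class or a free-text pediatric age statement from which the minimum
#' labeled age is parsed. Recognised classes: `preterm`,
#' `full_term_newborn`, `infant_toddler`, `child`, `child_no_age`,
#' `adolescent`, `not_established`, `no_pediatric_labeling`,
#' `contraindicated`. Free text such as "children 6 to 17 years" is parsed
#' to the first age mention; unparseable statements fall back to
#' `not_established` and are reported via the `unparsed` attribute. Empty
#' statements map to `no_pediatric_labeling`.
#'
#' @param path delimited file with columns `drug_code`,
#'   `statement_class_or_text` and optionally `min_age_value`,
#'   `min_age_unit` (`days`, `months` or `years`).
#' @param sep field delimiter; `NULL` auto-detects.
#' @return a `drug_label_table` data.frame with columns `drug_code`,
#'   `label_statement_class`, `min_age_value`, `min_age_unit`.
#' @export
read_drug_labels <- function(path, sep = NULL) {
  df <- read_delim_file(path, sep)
  if (!"drug_code" %in% names(df)) stop("missing mandatory column 'drug_code'")
  stmt_col <- intersect(c("statement_class_or_text", "statement", "label"),
                        names(df))[1]
  if (is.na(stmt_col)) {
    stop("missing mandatory column 'statement_class_or_text'")
  }
  drug_label_table(data.frame(
    drug_code = df$drug_code,
    statement = df[[stmt_col]],
    min_age_value = if ("min_age_value" %in% names(df))
      suppressWarnings(as.numeric(df$min_age_value)) else NA_real_,
    min_age_unit = if ("min_age_unit" %in% names(df))
      df$min_age_unit else NA_character_,
    stringsAsFactors = FALSE
  ))
}

label_classes <- c("preterm", "full_term_newborn", "infant_toddler",
                   "child", "child_no_age", "adolescent", "not_established",
                   "no_pediatric_labeling", "contraindicated")

#' Build a drug-label table from structured rows
#'
#' @param df data.frame with columns `drug_code`, `statement` (class name or
#'   free text) and optionally `min_age_value`, `min_age_unit`.
#' @return validated `drug_label_table`; duplicate drug codes with
#'   conflicting classes raise an error naming the codes.
#' @export
drug_label_table <- function(df) {
  df$drug_code <- normalize_codes(df$drug_code)
  stmt <- normalize_codes(df$statement)
  cls <- character(nrow(df))
  age_val <- if ("min_age_value" %in% names(df)) df$min_age_value else
    rep(NA_real_, nrow(df))
  age_unit <- if ("min_age_unit" %in% names(df)) df$min_age_unit else
    rep(NA_character_, nrow(df))
  unparsed <- character(0)

  for (i in seq_len(nrow(df))) {
    s <- stmt[i]
    if (!nzchar(s)) {
      cls[i] <- "no_pediatric_labeling"
    } else if (tolower(s) %in% label_classes) {
      cls[i] <- tolower(s)
    } else {
      parsed <- parse_age_statement(s)
      if (is.null(parsed)) {
        cls[i] <- "not_established"
        unparsed <- c(unparsed, df$drug_code[i])
      } else {
        cls[i] <- parsed$class
        if (is.na(age_val[i])) {
          age_val[i] <- parsed$value
          age_unit[i] <- parsed$unit
        }
      }
    }
  }

  out <- data.frame(drug_code = df$drug_code,
                    label_statement_class = cls,
                    min_age_value = age_val,
                    min_age_unit = age_unit,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  dup <- unique(out$drug_code[duplicated(out$drug_code)])
  if (length(dup) > 0) {
    stop(sprintf("conflicting label statements for drug code(s): %s",
                 paste(dup, collapse = ", ")))
  }
  # classes defined by an age band need a resolvable age
  needs_age <- out$label_statement_class %in%
    c("child", "adolescent", "infant_toddler")
  defaults <- c(child = 2, adolescent = 12, infant_toddler = 29 / 365.25)
  miss <- needs_age & is.na(out$min_age_value)
  out$min_age_value[miss] <- defaults[out$label_statement_class[miss]]
  out$min_age_unit[miss] <- "years"
  attr(out, "unparsed") <- unparsed
  class(out) <- c("drug_label_table", "data.frame")
  out
}

# Pull "6 to 17 years", "from 28 days", "2 years and older" style minimum
# ages out of free-text pediatric labeling statements.
parse_age_statement <- function(s) {
  sl <- tolower(s)
  if (grepl("preterm|premature", sl)) {
    return(list(class = "preterm", value = -1, unit = "days"))
  }
  if (grepl("contraindicat|not applicable", sl)) {
    return(list(class = "contraindicated", value = NA_real_,
                unit = NA_character_))
  }
  if (grepl("not (been )?established", sl)) {
    return(list(class = "not_established", value = NA_real_,
                unit = NA_character_))
  }
  # "6 to 17 years" style ranges: the minimum age is the first number
  range_pat <- "([0-9]+(\\.[0-9]+)?)\\s*(to|-|through)\\s*[0-9]+(\\.[0-9]+)?\\s*(day|week|month|year)"
  m <- regmatches(sl, regexpr(range_pat, sl))
  if (length(m) == 0L) {
    m <- regmatches(sl, regexpr("([0-9]+(\\.[0-9]+)?)\\s*(day|week|month|year)",
                                sl))
  }
  if (length(m) == 1L) {
    value <- as.numeric(sub("^([0-9]+(\\.[0-9]+)?).*$", "\\1", m))
    unit <- sub("^.*(day|week|month|year).*$", "\\1", m)
    if (unit == "week") {
      value <- value * 7
      unit <- "day"
    }
    unit <- paste0(unit, "s")
    return(list(class = class_for_age(value, unit), value = value,
                unit = unit))
  }
  if (grepl("newborn|neonate", sl)) {
    return(list(class = "full_term_newborn", value = 0, unit = "days"))
  }
  if (grepl("infant|toddler", sl)) {
    return(list(class = "infant_toddler", value = 29, unit = "days"))
  }
  if (grepl("adolescent", sl)) {
    return(list(class = "adolescent", value = 12, unit = "years"))
  }
  if (grepl("child|pediatric|paediatric", sl)) {
    return(list(class = "child_no_age", value = NA_real_,
                unit = NA_character_))
  }
  NULL
}

class_for_age <- function(value, unit) {
  yrs <- age_in_years(value, unit)
  if (yrs < 0) "preterm"
  else if (yrs <= 28 / 365.25) "full_term_newborn"
  else if (yrs < 2) "infant_toddler"
  else if (yrs < 12) "child"
  else if (yrs <= 18) "adolescent"
  else "no_pediatric_labeling"
}

age_in_years <- function(value, unit) {
  switch(tolower(unit),
         days = value / 365.25,
         day = value / 365.25,
         months = value / 12,
         month = value / 12,
         years = value,
         year = value,
         stop(sprintf("unknown age unit '%s'", unit)))
}

#' Write a pipeline table as delimited text
#'
#' Writes any tabular pipeline artifact (association tables, partition
#' tables, alignment tables) or a matrix. Matrices are written as a square
#' table with the row index in the first column, or optionally as
#' long-format `(row_id, col_id, value)` triplets.
#'
#' @param table data.frame or matrix.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @param long for matrices, write long-format triplets instead of a square
#'   table.
#' @return the path, invisibly.
#' @export
write_table <- function(table, path, sep = "\t", long = FALSE) {
  if (is.matrix(table)) {
    if (long) {
      idx <- which(!is.na(table), arr.ind = TRUE)
      table <- data.frame(row_id = rownames(table)[idx[, 1]],
                          col_id = colnames(table)[idx[, 2]],
                          value = table[idx])
    } else {
      table <- data.frame(row_id = rownames(table),
                          as.data.frame(table, check.names = FALSE),
                          check.names = FALSE)
    }
  }
  ok <- tryCatch({
    utils::write.table(table, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write to '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}
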