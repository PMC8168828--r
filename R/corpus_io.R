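RECORD_FIELDS <- c("record_id", "title", "abstract", "label", "study_id", "year")
MANDATORY_FIELDS <- c("record_id", "title", "abstract")

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "tsv", "jsonl")))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         csv = "csv", tsv = "tsv", jsonl = "jsonl", ndjson = "jsonl",
         stop_format("cannot infer format from extension '.", ext,
                     "'; pass format = \"csv\", \"tsv\" or \"jsonl\""))
}

validate_records <- function(rec) {
  dup <- unique(rec$record_id[duplicated(rec$record_id)])
  if (length(dup) > 0L)
    stop_validation("duplicate record_id: ",
                    paste(utils::head(dup, 10L), collapse = ", "))
  bad <- !is.na(rec$label) & !(rec$label %in% c(0L, 1L))
  if (any(bad))
    stop_validation("label must be 0 or 1; offending record_id: ",
                    paste(utils::head(rec$record_id[bad], 10L), collapse = ", "))
  bad_year <- !is.na(rec$year) & (rec$year < 1000L | rec$year > 9999L)
  if (any(bad_year))
    stop_validation("year must be a 4-digit integer; offending record_id: ",
                    paste(utils::head(rec$record_id[bad_year], 10L),
                          collapse = ", "))
  rec
}

as_record_frame <- function(rec) {
  rec$record_id <- as.character(rec$record_id)
  rec$title <- as.character(rec$title)
  rec$abstract <- as.character(rec$abstract)
  rec$label <- if (is.null(rec$label)) NA_integer_ else {
    lab <- rec$label
    lab[!is.na(lab) & lab == ""] <- NA
    as.integer(lab)
  }
  rec$study_id <- if (is.null(rec$study_id)) NA_character_ else {
    sid <- as.character(rec$study_id)
    sid[!is.na(sid) & sid == ""] <- NA_character_
    sid
  }
  rec$year <- if (is.null(rec$year)) NA_integer_ else {
    yr <- rec$year
    yr[!is.na(yr) & yr == ""] <- NA
    as.integer(yr)
  }
  out <- data.frame(record_id = rec$record_id, title = rec$title,
                    abstract = rec$abstract, label = rec$label,
                    study_id = rec$study_id, year = rec$year,
                    stringsAsFactors = FALSE)
  validate_records(out)
}

#' Read a collection of title-abstract records
#'
#' Reads bibliographic records from CSV, TSV or JSONL (one JSON object per
#' line). The file must provide `record_id`, `title` and `abstract`;
#' `label` (0/1), `study_id` and `year` are optional and map to `NA` when
#' absent. Text fields are preserved verbatim (no trimming); files are read
#' as UTF-8.
#'
#' @param path file to read.
#' @param format `"csv"`, `"tsv"` or `"jsonl"`; inferred from the file
#'   extension when `NULL`.
#' @return a `data.frame` with columns `record_id`, `title`, `abstract`,
#'   `label`, `study_id`, `year`, one row per record.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("record_id,title,abstract,label",
#'              'r1,"A trial","Some text",1'), f)
#' read_records(f)
read_records <- function(path, format = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  format <- infer_format(path, format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    for (k in seq_along(objs)) {
      missing <- setdiff(MANDATORY_FIELDS, names(objs[[k]]))
      if (length(missing) > 0L)
        stop_format("jsonl line ", k, " lacks mandatory field(s): ",
                    paste(missing, collapse = ", "))
    }
    grab <- function(field, default) {
      vapply(objs, function(o) {
        v <- o[[field]]
        if (is.null(v) || length(v) == 0L || is.na(v)) default else as.character(v)
      }, character(1))
    }
    rec <- list(record_id = grab("record_id", NA_character_),
                title = grab("title", ""),
                abstract = grab("abstract", ""),
                label = grab("label", NA_character_),
                study_id = grab("study_id", NA_character_),
                year = grab("year", NA_character_))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.csv(path, sep = sep, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = character(0), fileEncoding = "UTF-8")
    missing <- setdiff(MANDATORY_FIELDS, names(df))
    if (length(missing) > 0L)
      stop_format("missing mandatory column(s): ",
                  paste(missing, collapse = ", "))
    rec <- as.list(df[intersect(RECORD_FIELDS, names(df))])
  }
  as_record_frame(rec)
}

#' Write a collection of records
#'
#' Inverse of [read_records()]: absent optional values are written as empty
#' fields (CSV/TSV) or omitted keys (JSONL), never as 0, so that a
#' write-then-read round trip reproduces every field exactly.
#'
#' @param records record `data.frame` as returned by [read_records()].
#' @param path output file.
#' @inheritParams read_records
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = NULL) {
  records <- as_record_frame(as.list(records))
  format <- infer_format(path, format)
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (k in seq_len(nrow(records))) {
      obj <- list(record_id = records$record_id[k], title = records$title[k],
                  abstract = records$abstract[k])
      if (!is.na(records$label[k])) obj$label <- records$label[k]
      if (!is.na(records$study_id[k])) obj$study_id <- records$study_id[k]
      if (!is.na(records$year[k])) obj$year <- records$year[k]
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con,
                 useBytes = TRUE)
    }
  } else {
    out <- records
    out$label <- ifelse(is.na(out$label), "", as.character(out$label))
    out$study_id <- ifelse(is.na(out$study_id), "", out$study_id)
    out$year <- ifelse(is.na(out$year), "", as.character(out$year))
    sep <- if (format == "csv") "," else "\t"
    # standard quoting keeps embedded separators/newlines round-trippable
    utils::write.table(out, path, sep = sep, row.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}

#' Write per-record predictions
#'
#' Writes one row per record, in the input order, with the calibrated
#' probability (6 decimal places), the binary class call and the
#' machine/manual routing decision. Records and predictions must align
#' one-to-one by `record_id`.
#'
#' @param records record `data.frame`.
#' @param predictions prediction `data.frame` from [classify_records()].
#' @param path output file.
#' @inheritParams read_records
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, predictions, path, format = NULL) {
  format <- infer_format(path, format)
  if (nrow(records) != nrow(predictions))
    stop_validation("records (", nrow(records), ") and predictions (",
                    nrow(predictions), ") differ in length")
  if (nrow(records) > 0L &&
      !all(records$record_id == predictions$record_id))
    stop_validation("record_id mismatch between records and predictions")
  out <- data.frame(
    record_id = as.character(records$record_id),
    probability = ifelse(is.na(predictions$probability), "",
                         sprintf("%.6f", predictions$probability)),
    is_rct = ifelse(is.na(predictions$is_rct), "",
                    as.integer(predictions$is_rct)),
    route = as.character(predictions$route),
    stringsAsFactors = FALSE)
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (k in seq_len(nrow(out))) {
      obj <- list(record_id = out$record_id[k], route = out$route[k])
      if (nzchar(out$probability[k])) {
        obj$probability <- as.numeric(out$probability[k])
        obj$is_rct <- as.integer(out$is_rct[k])
      }
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6), con,
                 useBytes = TRUE)
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       qmethod = "double", fileEncoding = "UTF-8")
  }
  invisible(path)
}
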