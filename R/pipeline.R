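# Automated verify -> clean -> link -> group pipeline and extraction with
# snapshot marking: the "linkage as a service" surface. Because the central
# map is used by every future linkage, the cost of an operator mistake is
# high; every run is atomic (a failed stage leaves the event log untouched)
# and every extraction is reproducible from its snapshot.

#' Declare a dataset schema
#'
#' @param dataset_id Dataset identifier.
#' @param columns Data frame (or list of lists) with `name`, `type`
#'   (`"text"`, `"date"`, `"code"`), `required` (logical).
#' @param source_id_column Column holding the custodian's record key; must be
#'   declared and required.
#' @param cleaning_rules Named list: per-column character vector of rule ids
#'   among `"trim"`, `"casefold"`, `"strip_punct"`, `"squash_ws"`.
#' @param date_formats Formats tried in order when parsing `date` columns
#'   (R `strptime` syntax).
#' @param null_tokens Values (after trimming/case-folding) treated as
#'   missing.
#' @return A `dataset_schema` object.
#' @export
dataset_schema <- function(dataset_id, columns, source_id_column,
                           cleaning_rules = list(),
                           date_formats = c("%Y-%m-%d", "%d/%m/%Y"),
                           null_tokens = c("", "UNKNOWN", "UNK", "N/A", "NA", "NULL", "MISSING")) {
  if (is.list(columns) && !is.data.frame(columns)) {
    columns <- do.call(rbind, lapply(columns, function(cl) {
      data.frame(name = cl$name, type = cl$type %||% "text",
                 required = isTRUE(cl$required), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("name", "type", "required") %in% names(columns)))
  if (!source_id_column %in% columns$name ||
      !columns$required[columns$name == source_id_column]) {
    ongolink_stop("source_id_column must be a declared, required column",
                  "ongolink_config_error")
  }
  unknown <- setdiff(names(cleaning_rules), columns$name)
  if (length(unknown)) {
    ongolink_stop(paste0("cleaning rules reference unknown columns: ",
                         paste(unknown, collapse = ", ")),
                  "ongolink_config_error")
  }
  structure(list(dataset_id = dataset_id, columns = columns,
                 source_id_column = source_id_column,
                 cleaning_rules = cleaning_rules,
                 date_formats = date_formats,
                 null_tokens = null_tokens),
            class = "dataset_schema")
}

#' Bundled default schema for person records
#'
#' Columns `source_id`, `given_name`, `surname`, `sex`, `dob`, `address`,
#' with trim/case-fold/punctuation-stripping rules on text fields and
#' day-first date parsing on `dob`. Matches [default_linkage_config()].
#'
#' @param dataset_id Dataset identifier.
#' @return A [dataset_schema()].
#' @export
default_schema <- function(dataset_id = "dataset") {
  txt <- c("trim", "squash_ws", "casefold", "strip_punct")
  dataset_schema(
    dataset_id = dataset_id,
    columns = data.frame(
      name = c("source_id", "given_name", "surname", "sex", "dob", "address"),
      type = c("text", "text", "text", "code", "date", "text"),
      required = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    source_id_column = "source_id",
    cleaning_rules = list(given_name = txt, surname = txt, sex = txt,
                          address = txt)
  )
}

apply_cleaning_rule <- function(x, rule) {
  switch(rule,
    trim = trimws(x),
    casefold = toupper(x),
    strip_punct = gsub("[^[:alnum:] ]+", "", x),
    squash_ws = gsub("[[:space:]]+", " ", x),
    stop("unknown cleaning rule: ", rule)
  )
}

parse_date_multi <- function(x, formats) {
  out <- rep(NA_character_, length(x))
  todo <- !is.na(x)
  for (f in formats) {
    if (!any(todo)) break
    d <- as.Date(x[todo], format = f)
    # reject format-coincidence parses that drop information (e.g. %Y-%m-%d
    # applied to 03/02/1980): require round-trip equality
    ok <- !is.na(d) & format(d, f) == x[todo]
    out[which(todo)[ok]] <- format(d[ok], "%Y-%m-%d")
    todo[which(todo)[ok]] <- FALSE
  }
  out
}

#' Verify a delimited file against its schema
#'
#' Checks the header matches the schema, required columns are non-empty,
#' source ids are unique within the file, and dates are parseable. Every
#' violation is listed with the offending row numbers; any violation means
#' the file fails verification.
#'
#' @param path CSV file path (RFC-4180 quoting, UTF-8, header row).
#' @param schema A [dataset_schema()].
#' @return A list of class `verification_report`: `ok` (logical),
#'   `violations` (data.frame `check`, `column`, `rows`, `detail`), `n_rows`.
#' @export
verify_file <- function(path, schema) {
  viol <- data.frame(check = character(0), column = character(0),
                     rows = character(0), detail = character(0),
                     stringsAsFactors = FALSE)
  add_viol <- function(check, column, rows, detail) {
    rbind(viol, data.frame(check = check, column = column,
                           rows = paste(rows, collapse = ","),
                           detail = detail, stringsAsFactors = FALSE))
  }
  if (!file.exists(path) || dir.exists(path)) {
    viol <- add_viol("readable", "", "", "file does not exist")
    return(structure(list(ok = FALSE, violations = viol, n_rows = 0L),
                     class = "verification_report"))
  }
  rows <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) NULL)
  if (is.null(rows) || nrow(rows) == 0L) {
    viol <- add_viol("readable", "", "", "file empty or unparseable")
    return(structure(list(ok = FALSE, violations = viol, n_rows = 0L),
                     class = "verification_report"))
  }
  declared <- schema$columns$name
  missing_cols <- setdiff(declared, names(rows))
  for (mc in missing_cols) viol <- add_viol("header", mc, "", "declared column absent")
  extra <- setdiff(setdiff(names(rows), declared), "_action")
  for (ec in extra) viol <- add_viol("header", ec, "", "undeclared column present")
  present <- intersect(declared, names(rows))
  for (cn in present) {
    req <- schema$columns$required[schema$columns$name == cn]
    v <- trimws(rows[[cn]])
    if (req) {
      bad <- which(is.na(v) | v == "")
      if (length(bad)) viol <- add_viol("required", cn, bad, "required column empty")
    }
    if (schema$columns$type[schema$columns$name == cn] == "date") {
      nonmiss <- which(!(is.na(v) | toupper(v) %in% toupper(schema$null_tokens)))
      if (length(nonmiss)) {
        parsed <- parse_date_multi(v[nonmiss], schema$date_formats)
        bad <- nonmiss[is.na(parsed)]
        if (length(bad)) viol <- add_viol("date", cn, bad, "unparseable under declared formats")
      }
    }
  }
  sid <- schema$source_id_column
  if (sid %in% names(rows)) {
    dup_vals <- unique(rows[[sid]][duplicated(rows[[sid]])])
    for (dv in dup_vals) {
      viol <- add_viol("unique_source_id", sid, which(rows[[sid]] == dv),
                       sprintf("duplicated source id '%s'", dv))
    }
  }
  structure(list(ok = nrow(viol) == 0L, violations = viol, n_rows = nrow(rows)),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %s, %d rows, %d violation(s)\n",
              if (x$ok) "ok" else "FAILED", x$n_rows, nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Clean and standardise verified rows
#'
#' Deterministic, idempotent application of the schema's per-column rules:
#' text rules in declared order, null tokens to missing, dates normalised to
#' ISO `YYYY-MM-DD` (a date unparseable under all declared formats becomes
#' missing, counted as a warning). The count of changed cells per rule is
#' recorded in the `"cleaning_log"` attribute.
#'
#' @param rows Data frame of raw rows (character columns).
#' @param schema A [dataset_schema()].
#' @return Data frame with `dataset_id`, `source_record_id` and the cleaned
#'   field columns (plus `_action` when present in the input).
#' @export
clean_standardise <- function(rows, schema) {
  log <- list()
  note <- function(col, rule, n) {
    if (n > 0) log[[length(log) + 1L]] <<- data.frame(
      column = col, rule = rule, cells_changed = n, stringsAsFactors = FALSE)
  }
  out <- rows
  for (cn in intersect(schema$columns$name, names(out))) {
    v <- as.character(out[[cn]])
    for (rule in schema$cleaning_rules[[cn]] %||% character(0)) {
      nv <- apply_cleaning_rule(v, rule)
      note(cn, rule, sum(nv != v, na.rm = TRUE))
      v <- nv
    }
    vt <- toupper(trimws(v))
    is_null <- !is.na(vt) & vt %in% toupper(schema$null_tokens)
    note(cn, "null_token", sum(is_null))
    v[is_null] <- NA_character_
    if (schema$columns$type[schema$columns$name == cn] == "date") {
      nonmiss <- !is.na(v)
      parsed <- v
      parsed[nonmiss] <- parse_date_multi(v[nonmiss], schema$date_formats)
      note(cn, "date_parse_failed", sum(nonmiss & is.na(parsed)))
      note(cn, "date_normalised", sum(nonmiss & !is.na(parsed) & parsed != v, na.rm = TRUE))
      v <- parsed
    }
    out[[cn]] <- v
  }
  cleaned <- data.frame(dataset_id = schema$dataset_id,
                        source_record_id = out[[schema$source_id_column]],
                        stringsAsFactors = FALSE)
  for (cn in setdiff(schema$columns$name, schema$source_id_column)) {
    cleaned[[cn]] <- if (cn %in% names(out)) out[[cn]] else NA_character_
  }
  if ("_action" %in% names(rows)) cleaned[["_action"]] <- rows[["_action"]]
  attr(cleaned, "cleaning_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(column = character(0), rule = character(0),
               cells_changed = integer(0), stringsAsFactors = FALSE)
  cleaned
}

#' Run the automated verify / clean / link / group pipeline on a file
#'
#' Executes the stages in order and, on full success, dispatches to the
#' requested scenario's engine operation. A failed stage forces all later
#' stages to be skipped, and the map log is untouched by any failed run.
#'
#' @param path CSV file path.
#' @param schema A [dataset_schema()].
#' @param config A [linkage_config()].
#' @param map A [linkage_map()] (ignored for `mode = "project"`).
#' @param mode `"ongoing"` (ingest into the map), `"project"` (isolated
#'   once-off linkage), `"byo"` (read-only cohort keys), or `"reconcile"`
#'   (open-records batch of adds/amends/deletes).
#' @param run_id Label for the run.
#' @param stop_after Optional manual override: stop after `"verify"`,
#'   `"clean"`, or `"link"` (the remaining stages are skipped, nothing is
#'   grouped into the map).
#' @return A `pipeline_run` list: `run_id`, `mode`, `stages` (named outcomes
#'   `ok`/`failed`/`skipped`), `verification`, `report` (mode-specific),
#'   `keys` (for project/byo), `ok`.
#' @export
run_pipeline <- function(path, schema, config, map = NULL,
                         mode = c("ongoing", "project", "byo", "reconcile"),
                         run_id = basename(path),
                         stop_after = NULL) {
  mode <- match.arg(mode)
  stages <- c(verify = "skipped", clean = "skipped", link = "skipped",
              group = "skipped")
  run <- function(ok) {
    structure(list(run_id = run_id, mode = mode, stages = stages,
                   verification = verification, report = report, keys = keys,
                   ok = ok), class = "pipeline_run")
  }
  verification <- NULL; report <- NULL; keys <- NULL
  verification <- verify_file(path, schema)
  stages["verify"] <- if (verification$ok) "ok" else "failed"
  if (!verification$ok) return(run(FALSE))
  if (identical(stop_after, "verify")) return(run(TRUE))

  rows <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  cleaned <- tryCatch(clean_standardise(rows, schema), error = function(e) e)
  if (inherits(cleaned, "error")) {
    stages["clean"] <- "failed"
    return(run(FALSE))
  }
  stages["clean"] <- "ok"
  if (identical(stop_after, "clean")) return(run(TRUE))

  outcome <- tryCatch({
    switch(mode,
      ongoing = {
        report <- ingest_batch(map, cleaned, config, batch_id = run_id)
      },
      reconcile = {
        report <- reconcile_open_batch(map, cleaned, config, batch_id = run_id)
      },
      project = {
        res <- project_link(cleaned, config, project_id = run_id)
        report <- res$report; keys <- res$keys
      },
      byo = {
        keys <- byo_link(cleaned, map, config, extraction_id = run_id)
      })
    TRUE
  }, error = function(e) e)
  if (inherits(outcome, "error")) {
    stages["link"] <- "failed"
    return(run(FALSE))
  }
  stages["link"] <- "ok"
  stages["group"] <- if (identical(stop_after, "link")) "skipped" else "ok"
  run(TRUE)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run %s> mode=%s %s\n", x$run_id, x$mode,
              if (x$ok) "ok" else "FAILED"))
  cat(sprintf("  stages: %s\n",
              paste(sprintf("%s=%s", names(x$stages), x$stages), collapse = " ")))
  invisible(x)
}

run_report_json <- function(run) {
  jsonlite::toJSON(list(
    run_id = run$run_id, mode = run$mode, ok = run$ok,
    stages = as.list(run$stages),
    n_violations = if (!is.null(run$verification)) nrow(run$verification$violations) else 0L
  ), auto_unbox = TRUE, pretty = TRUE)
}

next_extraction_id <- function(map, project_id) {
  prior <- map$state$snapshots$extraction_id
  n <- sum(grepl(paste0("^", project_id, "-e\\d+$"), prior))
  paste0(project_id, "-e", n + 1L)
}

#' Extract linkage keys for a project, with snapshot marking
#'
#' Marks a snapshot, writes the keys of the matching live records at that
#' sequence number, and records the extraction in the log. A later
#' re-extraction with `as_of` set to a previous extraction id reproduces the
#' earlier key file bit-identically, answering researcher queries about how
#' records were linked at the time of their extraction.
#'
#' @param map A [linkage_map()].
#' @param project_id Project label; extraction ids are
#'   `<project_id>-e1`, `-e2`, ...
#' @param datasets Optional character vector restricting the extraction to
#'   these dataset ids.
#' @param path Optional path: the key file is written there as CSV.
#' @param as_of Optional prior extraction id: reproduce that extraction
#'   instead of marking a new snapshot.
#' @return A list: `keys` (data frame `dataset_id`, `source_record_id`,
#'   `group_id`, `extraction_id`), `snapshot` (a `snapshot_ref`).
#' @export
extract_keys <- function(map, project_id, datasets = NULL, path = NULL,
                         as_of = NULL) {
  if (!is.null(as_of)) {
    snaps <- map$state$snapshots
    i <- which(snaps$extraction_id == as_of)
    if (!length(i)) {
      ongolink_stop(sprintf("unknown extraction id: %s", as_of),
                    "ongolink_not_found_error")
    }
    ref <- structure(list(extraction_id = as_of, seq = snaps$seq[i],
                          created = NA_character_), class = "snapshot_ref")
    st <- state_at(map, ref$seq)
    keys <- group_membership(st)
    keys$extraction_id <- as_of
  } else {
    ref <- mark_snapshot(map, next_extraction_id(map, project_id))
    keys <- group_membership(map)
    keys$extraction_id <- ref$extraction_id
  }
  if (!is.null(datasets)) {
    keys <- keys[keys$dataset_id %in% datasets, , drop = FALSE]
  }
  rownames(keys) <- NULL
  if (!is.null(path)) write_key_file(keys, path)
  list(keys = keys, snapshot = ref)
}

#' Write / read a key file
#'
#' CSV with columns `dataset_id`, `source_record_id`, `group_id`,
#' `extraction_id`, rows in byte-order, so that repeated extractions of the
#' same state are byte-identical.
#'
#' @param keys Key data frame.
#' @param path File path.
#' @export
write_key_file <- function(keys, path) {
  keys <- keys[c_order(keys$dataset_id, keys$source_record_id), , drop = FALSE]
  utils::write.csv(keys, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_key_file
#' @export
read_key_file <- function(path) {
  utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
}

#' Export a snapshot of group membership at a sequence number
#'
#' CSV of `(dataset_id, source_record_id, group_id)` at the given event
#' sequence number (e.g. a snapshot mark's `seq`).
#'
#' @param map A [linkage_map()].
#' @param seq Event sequence number.
#' @param path File path.
#' @export
export_snapshot <- function(map, seq, path) {
  st <- state_at(map, seq)
  keys <- group_membership(st)
  utils::write.csv(keys, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
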