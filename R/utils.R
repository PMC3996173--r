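`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#' @noRd
ongolink_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ongolink_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Canonical partition representation
#'
#' Reduces a grouping to a canonical form that is independent of group
#' identifiers and of the order in which records arrived, so that two linkage
#' runs can be compared for *partition* equality. Members are identified by
#' `dataset_id` and `source_record_id` (the custodian key), never by internal
#' record uids, which differ between runs.
#'
#' @param keys A data frame with columns `dataset_id`, `source_record_id`,
#'   `group_id` (a key file, or the output of [group_membership()]).
#' @return A list of character vectors (one per group, members sorted), the
#'   list itself sorted by first member; suitable for `identical()` comparison.
#' @export
canonical_partition <- function(keys) {
  stopifnot(all(c("dataset_id", "source_record_id", "group_id") %in% names(keys)))
  if (nrow(keys) == 0L) return(list())
  member <- paste(keys$dataset_id, keys$source_record_id, sep = "\r")
  parts <- split(member, keys$group_id)
  parts <- lapply(parts, function(m) sort(unique(m)))
  parts <- unname(parts[order(vapply(parts, `[`, "", 1L))])
  parts
}

# numeric suffix of ids like "r12" / "g7"; used only for deterministic ordering
id_num <- function(x) as.integer(sub("^[a-z]+", "", x))

new_counter_id <- function(prefix, n) paste0(prefix, n)

# stable row ordering for output files: byte-wise (C locale) sorting so that
# extractions are reproducible across platforms and locales
c_order <- function(...) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(...)
}
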