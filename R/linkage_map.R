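# Event-sourced linkage map. The append-only event log is the source of
# truth; the current group state is a pure fold of the log, cached on the map
# handle and recomputable at any historical sequence number. This is the
# "full history stored within the linkage map" design: every change of group
# membership is an event carrying a reason, so the map can always explain how
# a group came together and roll back to the state at any extraction.

EVENT_KINDS <- c("RECORD_ADDED", "PAIR_ACCEPTED", "GROUP_CREATED",
                 "RECORD_JOINED_GROUP", "GROUPS_MERGED", "RECORD_REMOVED",
                 "GROUP_RECONSTITUTED", "RECORD_AMENDED", "SNAPSHOT_MARK")

#' Construct a linkage-map event
#'
#' @param seq Strictly increasing positive integer sequence number.
#' @param kind One of the event kinds (see Details).
#' @param payload Kind-specific named list (record uids, group ids, pair
#'   references).
#' @param reason Free-text reason recorded in the history.
#' @return A `map_event` list.
#' @details Event kinds: `RECORD_ADDED`, `PAIR_ACCEPTED`, `GROUP_CREATED`,
#'   `RECORD_JOINED_GROUP`, `GROUPS_MERGED`, `RECORD_REMOVED`,
#'   `GROUP_RECONSTITUTED`, `RECORD_AMENDED`, `SNAPSHOT_MARK`.
#' @export
map_event <- function(seq, kind, payload = list(), reason = "") {
  kind <- match.arg(kind, EVENT_KINDS)
  structure(list(seq = as.integer(seq), kind = kind, payload = payload,
                 reason = reason,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
            class = "map_event")
}

empty_state <- function() {
  list(
    seq = 0L,
    records = data.frame(record_uid = character(0), dataset_id = character(0),
                         source_record_id = character(0), version_no = integer(0),
                         status = character(0), added_seq = integer(0),
                         group_id = character(0), stringsAsFactors = FALSE),
    fields = NULL,  # data.frame record_uid + field columns, created lazily
    groups = list(),
    group_meta = data.frame(group_id = character(0), created_seq = integer(0),
                            closed_seq = integer(0), stringsAsFactors = FALSE),
    pairs = data.frame(uid_a = character(0), uid_b = character(0),
                       weight = numeric(0), n_agree = integer(0),
                       classification = character(0), suppressed = logical(0),
                       active = logical(0), created_seq = integer(0),
                       stringsAsFactors = FALSE),
    snapshots = data.frame(extraction_id = character(0), seq = integer(0),
                           stringsAsFactors = FALSE)
  )
}

# field values for the given uids, one row per uid, in order
state_fields <- function(state, uids) {
  state$fields[match(uids, state$fields$record_uid), -1L, drop = FALSE]
}

close_group <- function(state, gid, seq) {
  state$groups[[gid]] <- NULL
  state$group_meta$closed_seq[state$group_meta$group_id == gid] <- seq
  state
}

open_group <- function(state, gid, members, seq) {
  state$groups[[gid]] <- members
  state$group_meta <- rbind(state$group_meta,
                            data.frame(group_id = gid, created_seq = seq,
                                       closed_seq = NA_integer_,
                                       stringsAsFactors = FALSE))
  state$records$group_id[state$records$record_uid %in% members] <- gid
  state
}

#' Apply one event to a group state (pure fold step)
#'
#' @param state A group state as produced by [empty_state()] or previous
#'   applications.
#' @param event A [map_event()].
#' @return The updated state. Never mutates its input.
#' @keywords internal
apply_event <- function(state, event) {
  p <- event$payload
  seq <- event$seq
  state$seq <- seq
  switch(event$kind,
    RECORD_ADDED = {
      state$records <- rbind(state$records, data.frame(
        record_uid = p$record_uid, dataset_id = p$dataset_id,
        source_record_id = p$source_record_id,
        version_no = as.integer(p$version_no), status = "live",
        added_seq = seq, group_id = NA_character_, stringsAsFactors = FALSE))
      vals <- lapply(p$fields, function(v) if (is.null(v)) NA_character_ else as.character(v))
      row <- as.data.frame(c(list(record_uid = p$record_uid), vals),
                           stringsAsFactors = FALSE)
      state$fields <- if (is.null(state$fields)) row else rbind(state$fields, row)
      state
    },
    PAIR_ACCEPTED = {
      state$pairs <- rbind(state$pairs, data.frame(
        uid_a = p$uid_a, uid_b = p$uid_b, weight = as.numeric(p$weight),
        n_agree = as.integer(p$n_agree), classification = p$classification,
        suppressed = isTRUE(p$suppressed), active = TRUE, created_seq = seq,
        stringsAsFactors = FALSE))
      state
    },
    GROUP_CREATED = open_group(state, p$group_id, as.character(p$members), seq),
    RECORD_JOINED_GROUP = {
      state$groups[[p$group_id]] <- c(state$groups[[p$group_id]], p$record_uid)
      state$records$group_id[state$records$record_uid == p$record_uid] <- p$group_id
      state
    },
    GROUPS_MERGED = {
      for (gid in as.character(p$merged_group_ids)) state <- close_group(state, gid, seq)
      open_group(state, p$group_id, as.character(p$members), seq)
    },
    RECORD_REMOVED = {
      uid <- p$record_uid
      i <- state$records$record_uid == uid
      state$records$status[i] <- p$new_status %||% "deleted"
      gid <- state$records$group_id[i]
      state$records$group_id[i] <- NA_character_
      if (!is.na(gid) && !is.null(state$groups[[gid]])) {
        remaining <- setdiff(state$groups[[gid]], uid)
        if (length(remaining)) state$groups[[gid]] <- remaining
        else state <- close_group(state, gid, seq)
      }
      touches <- state$pairs$uid_a == uid | state$pairs$uid_b == uid
      state$pairs$active[touches] <- FALSE
      state
    },
    GROUP_RECONSTITUTED = {
      state <- close_group(state, p$old_group_id, seq)
      for (g in p$new_groups) {
        state <- open_group(state, g$group_id, as.character(g$members), seq)
      }
      state
    },
    RECORD_AMENDED = state,  # the paired REMOVED/ADDED events carry the change
    SNAPSHOT_MARK = {
      state$snapshots <- rbind(state$snapshots, data.frame(
        extraction_id = p$extraction_id, seq = seq, stringsAsFactors = FALSE))
      state
    },
    stop("unknown event kind: ", event$kind)
  )
}

#' Create an empty linkage map
#'
#' A linkage map is a mutable handle (environment) holding the append-only
#' event log and a cached current state. All mutation goes through
#' [append_event()]; the cached state is always equal to the fold of the log.
#'
#' @return An object of class `linkage_map`.
#' @export
linkage_map <- function() {
  map <- new.env(parent = emptyenv())
  map$log <- list()
  map$state <- empty_state()
  class(map) <- "linkage_map"
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  st <- x$state
  cat("<linkage_map>\n")
  cat(sprintf("  events: %d\n", length(x$log)))
  cat(sprintf("  live records: %d in %d groups\n",
              sum(st$records$status == "live"), length(st$groups)))
  cat(sprintf("  stored match pairs: %d (%d active)\n",
              nrow(st$pairs), sum(st$pairs$active)))
  cat(sprintf("  snapshots: %d\n", nrow(st$snapshots)))
  invisible(x)
}

#' Append an event to the map's log
#'
#' The log is append-only: events are never modified or removed, and sequence
#' numbers must be contiguous.
#'
#' @param map A [linkage_map()].
#' @param event A [map_event()] with `seq` equal to the last seq + 1.
#' @return The map, invisibly.
#' @export
append_event <- function(map, event) {
  expected <- length(map$log) + 1L
  if (event$seq != expected) {
    ongolink_stop(sprintf("out-of-order event: seq %d, expected %d",
                          event$seq, expected), "ongolink_integrity_error")
  }
  map$log[[expected]] <- event
  map$state <- apply_event(map$state, event)
  invisible(map)
}

next_seq <- function(map) length(map$log) + 1L

next_record_uid <- function(state) {
  n <- if (nrow(state$records)) max(id_num(state$records$record_uid)) else 0L
  paste0("r", n + 1L)
}

next_group_id <- function(state) {
  n <- if (nrow(state$group_meta)) max(id_num(state$group_meta$group_id)) else 0L
  paste0("g", n + 1L)
}

# run expr; on error restore the map's log and state (all-or-nothing)
with_map_transaction <- function(map, expr) {
  old_log <- map$log
  old_state <- map$state
  tryCatch(expr, error = function(e) {
    map$log <- old_log
    map$state <- old_state
    stop(e)
  })
}

#' Group state at a historical point
#'
#' Deterministic fold of events `1..seq`; `state_at(map, length(map$log))` is
#' the current state. This is the roll-back primitive: researchers' queries
#' about an earlier extraction are answered from the state at that
#' extraction's sequence number.
#'
#' @param map A [linkage_map()].
#' @param seq Event sequence number, `0 <= seq <= ` log length.
#' @return A group state list (`records`, `fields`, `groups`, `pairs`,
#'   `snapshots`, ...).
#' @export
state_at <- function(map, seq) {
  if (seq < 0L || seq > length(map$log)) {
    ongolink_stop(sprintf("seq %d outside log range [0, %d]", seq, length(map$log)),
                  "ongolink_range_error")
  }
  st <- empty_state()
  for (i in seq_len(seq)) st <- apply_event(st, map$log[[i]])
  st
}

#' Reconstitute a member set into groups from match pairs
#'
#' Connected components of the graph whose vertices are `members` and whose
#' edges are the given match pairs: the primitive behind unwinding a group
#' after a member record is deleted or amended, revealing how the groups
#' would have looked had that record never entered the system.
#'
#' @param members Character vector of record uids.
#' @param pairs Data frame or two-column matrix with the pair endpoints
#'   (`uid_a`, `uid_b`); every endpoint must be in `members`.
#' @return A list of character vectors (components, each sorted; singletons
#'   allowed), ordered by first member.
#' @export
reconstitute <- function(members, pairs) {
  members <- unique(as.character(members))
  if (is.data.frame(pairs)) pairs <- cbind(pairs$uid_a, pairs$uid_b)
  if (!is.matrix(pairs)) pairs <- matrix(character(0), ncol = 2L)
  if (nrow(pairs) && !all(c(pairs) %in% members)) {
    ongolink_stop("pair endpoint not in member set", "ongolink_integrity_error")
  }
  parent <- stats::setNames(seq_along(members), members)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(match(pairs[k, 1L], members))
    rb <- find(match(pairs[k, 2L], members))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(members), find, integer(1))
  comps <- split(members, roots)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1L))])
}

#' Full event history of one source record
#'
#' All events whose payload references any version of the record (additions,
#' accepted pairs, group joins/merges/reconstitutions, removal, amendment),
#' in sequence order, with their reasons.
#'
#' @param map A [linkage_map()].
#' @param dataset_id,source_record_id The custodian key of the record.
#' @return A list of [map_event()]s.
#' @export
record_history <- function(map, dataset_id, source_record_id) {
  rec <- map$state$records
  uids <- rec$record_uid[rec$dataset_id == dataset_id &
                         rec$source_record_id == source_record_id]
  if (!length(uids)) {
    ongolink_stop(sprintf("unknown record %s/%s", dataset_id, source_record_id),
                  "ongolink_not_found_error")
  }
  refs <- function(ev) {
    p <- ev$payload
    any(c(p$record_uid, p$uid_a, p$uid_b, p$old_record_uid, p$new_record_uid,
          unlist(p$members),
          unlist(lapply(p$new_groups, function(g) g$members))) %in% uids)
  }
  Filter(refs, map$log)
}

#' Mark a snapshot for an extraction
#'
#' Appends a `SNAPSHOT_MARK` event; the returned reference resolves through
#' [state_at()] so the exact map state at the moment of extraction remains
#' reproducible forever.
#'
#' @param map A [linkage_map()].
#' @param extraction_id Unused extraction identifier.
#' @return A `snapshot_ref` list (`extraction_id`, `seq`, `created`).
#' @export
mark_snapshot <- function(map, extraction_id) {
  if (extraction_id %in% map$state$snapshots$extraction_id) {
    ongolink_stop(sprintf("extraction id already used: %s", extraction_id),
                  "ongolink_conflict_error")
  }
  ev <- map_event(next_seq(map), "SNAPSHOT_MARK",
                  list(extraction_id = extraction_id),
                  reason = sprintf("snapshot for extraction %s", extraction_id))
  append_event(map, ev)
  structure(list(extraction_id = extraction_id, seq = ev$seq,
                 created = ev$timestamp), class = "snapshot_ref")
}

#' Live group membership as a key table
#'
#' @param state_or_map A group state or a [linkage_map()] (current state).
#' @return Data frame `dataset_id`, `source_record_id`, `group_id` for every
#'   live record, sorted for reproducible output.
#' @export
group_membership <- function(state_or_map) {
  st <- if (inherits(state_or_map, "linkage_map")) state_or_map$state else state_or_map
  rec <- st$records[st$records$status == "live",
                    c("dataset_id", "source_record_id", "group_id")]
  rec <- rec[c_order(rec$dataset_id, rec$source_record_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# ---- persistence: JSON-lines event log ----

event_to_json <- function(ev) {
  jsonlite::toJSON(unclass(ev), auto_unbox = TRUE, null = "null", na = "null",
                   digits = I(17))
}

#' Serialise / load the event log
#'
#' The log is stored as JSON-lines, one event per line, with stable field
#' names (`seq`, `kind`, `payload`, `reason`, `timestamp`). Reading replays
#' the log, so the loaded map's state is exactly the fold of the file.
#'
#' @param map A [linkage_map()].
#' @param path File path.
#' @return `write_map_log()`: `path`, invisibly. `read_map_log()`: a
#'   [linkage_map()]. `map_log_json()`: character vector of JSON lines (a
#'   pure function of the log, usable as a content fingerprint).
#' @export
write_map_log <- function(map, path) {
  writeLines(map_log_json(map), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_map_log
#' @export
map_log_json <- function(map) {
  vapply(map$log, function(ev) as.character(event_to_json(ev)), "")
}

#' @rdname write_map_log
#' @export
read_map_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  map <- linkage_map()
  for (ln in lines) {
    raw <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    payload <- lapply(raw$payload, function(v) {
      if (is.list(v)) v else if (is.null(v)) NA_character_ else v
    })
    ev <- map_event(raw$seq, raw$kind, payload, raw$reason %||% "")
    ev$timestamp <- raw$timestamp %||% ev$timestamp
    append_event(map, ev)
  }
  map
}

# ---- consistency checks (used by tests and after public operations) ----

validate_state <- function(state, strategy = "merge_allowed") {
  rec <- state$records[state$records$status == "live", , drop = FALSE]
  in_groups <- unlist(state$groups, use.names = FALSE)
  if (anyDuplicated(in_groups)) stop("record in more than one group")
  if (!setequal(rec$record_uid, in_groups)) {
    stop("live records and group members differ")
  }
  if (!all(rec$group_id[match(in_groups, rec$record_uid)] ==
           rep(names(state$groups), lengths(state$groups)))) {
    stop("group index out of step with membership")
  }
  live_one_version <- stats::aggregate(
    status ~ dataset_id + source_record_id, data = state$records,
    FUN = function(s) sum(s == "live"))
  if (any(live_one_version$status > 1L)) stop("more than one live version of a record")
  if (strategy == "merge_allowed") {
    act <- state$pairs[state$pairs$active & !state$pairs$suppressed, , drop = FALSE]
    ga <- rec$group_id[match(act$uid_a, rec$record_uid)]
    gb <- rec$group_id[match(act$uid_b, rec$record_uid)]
    ok <- is.na(ga) | is.na(gb) | ga == gb
    if (!all(ok)) stop("active match pair spans two groups under merge_allowed")
  }
  invisible(TRUE)
}
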