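# Deleted, amended and "open" record handling. Deletion never simply drops a
# record from its group: the group is unwound using the stored match-pair
# information, so the map looks as if the deleted record (or the previous
# version of an amended record) had never entered the system. All mutations
# are pure log appends; the old state remains queryable via state_at().

live_record_row <- function(map, dataset_id, source_record_id) {
  rec <- map$state$records
  i <- which(rec$dataset_id == dataset_id &
             rec$source_record_id == source_record_id & rec$status == "live")
  if (!length(i)) {
    ongolink_stop(sprintf("no live record %s/%s", dataset_id, source_record_id),
                  "ongolink_not_found_error")
  }
  rec[i, ]
}

# unwind the group a record is being removed from: emit RECORD_REMOVED, then
# reconstitute the remaining members into the connected components of the
# remaining active (non-suppressed) match pairs
remove_and_unwind <- function(map, uid, new_status, reason) {
  gid <- current_group(map, uid)
  members_before <- if (!is.na(gid)) map$state$groups[[gid]] else character(0)
  append_event(map, map_event(next_seq(map), "RECORD_REMOVED",
    list(record_uid = uid, new_status = new_status), reason = reason))
  remaining <- setdiff(members_before, uid)
  if (length(remaining) >= 2L) {
    pr <- map$state$pairs
    pr <- pr[pr$active & !pr$suppressed &
             pr$uid_a %in% remaining & pr$uid_b %in% remaining, , drop = FALSE]
    comps <- reconstitute(remaining, pr)
    if (length(comps) > 1L) {
      new_groups <- lapply(comps, function(m) {
        list(group_id = NA_character_, members = m)
      })
      # ids assigned in component order, deterministically
      for (i in seq_along(new_groups)) {
        new_groups[[i]]$group_id <- paste0("g",
          max(id_num(map$state$group_meta$group_id)) + i)
      }
      append_event(map, map_event(next_seq(map), "GROUP_RECONSTITUTED",
        list(old_group_id = gid, new_groups = new_groups),
        reason = sprintf("group %s unwound after removal of %s: split into %d",
                         gid, uid, length(comps))))
    }
  }
  invisible(list(former_group = gid, former_comembers = remaining))
}

#' Delete a record and unwind its group
#'
#' Marks the record's live version deleted, deactivates its match pairs, and
#' reconstitutes its former group into the connected components of the
#' remaining members over the remaining pairs — possibly splitting the group
#' where the deleted record was the only bridge. Other groups are untouched.
#'
#' @param map A [linkage_map()].
#' @param dataset_id,source_record_id Custodian key of the live record.
#' @param reason Non-empty reason recorded in the history.
#' @return The events appended, invisibly.
#' @export
delete_record <- function(map, dataset_id, source_record_id, reason) {
  stopifnot(is_string(reason), nzchar(reason))
  row <- live_record_row(map, dataset_id, source_record_id)
  with_map_transaction(map, {
    first <- next_seq(map)
    remove_and_unwind(map, row$record_uid, "deleted", reason)
    validate_state(map$state)
    invisible(map$log[seq(first, length(map$log))])
  })
}

#' Amend a record: supersede, unwind, and re-link the new version
#'
#' The old version is superseded and unwound exactly as a deletion; the new
#' version (version_no + 1) is then ingested through the standard
#' candidate/score/group path, compared against (at minimum) all former
#' co-group members and all blocking-key candidates of the amended values. A
#' `RECORD_AMENDED` event links the two versions. An amendment identical to
#' the current fields is a logged no-op.
#'
#' @param map A [linkage_map()].
#' @param dataset_id,source_record_id Custodian key of the live record.
#' @param new_fields Named list or one-row data frame of cleaned field
#'   values.
#' @param config A [linkage_config()].
#' @param reason Reason recorded in the history.
#' @return The events appended, invisibly.
#' @export
amend_record <- function(map, dataset_id, source_record_id, new_fields, config,
                         reason = "record amended") {
  row <- live_record_row(map, dataset_id, source_record_id)
  fn <- config_field_names(config)
  norm <- function(v) {
    v <- as.character(v %||% NA_character_)
    if (length(v) != 1L || is.na(v) || v == "") NA_character_ else v
  }
  new_vals <- lapply(stats::setNames(fn, fn), function(f) norm(new_fields[[f]]))
  old_vals <- lapply(stats::setNames(fn, fn),
                     function(f) norm(state_fields(map$state, row$record_uid)[[f]]))
  with_map_transaction(map, {
    first <- next_seq(map)
    if (identical(new_vals, old_vals)) {
      append_event(map, map_event(next_seq(map), "RECORD_AMENDED",
        list(old_record_uid = row$record_uid, new_record_uid = NA_character_,
             noop = TRUE),
        reason = sprintf("%s (no field changed; no-op)", reason)))
      return(invisible(map$log[seq(first, length(map$log))]))
    }
    unwound <- remove_and_unwind(map, row$record_uid, "superseded", reason)
    new_uid <- next_record_uid(map$state)
    append_event(map, map_event(next_seq(map), "RECORD_ADDED", list(
      record_uid = new_uid, dataset_id = dataset_id,
      source_record_id = source_record_id,
      version_no = row$version_no + 1L, fields = new_vals
    ), reason = sprintf("%s: new version of %s", reason, row$record_uid)))
    append_event(map, map_event(next_seq(map), "RECORD_AMENDED",
      list(old_record_uid = row$record_uid, new_record_uid = new_uid,
           noop = FALSE), reason = reason))
    # candidate set: blocking candidates of the amended values, plus all
    # former co-group members (so prior links are re-evaluated)
    cand <- generate_candidates(new_uid, map$state, config)
    live_co <- unwound$former_comembers[
      unwound$former_comembers %in%
        map$state$records$record_uid[map$state$records$status == "live"]]
    if (length(live_co)) {
      extra <- cbind(uid_a = rep(new_uid, length(live_co)), uid_b = live_co)
      swap <- id_num(extra[, 1L]) > id_num(extra[, 2L])
      extra[swap, ] <- extra[swap, c(2L, 1L), drop = FALSE]
      cand <- unique(rbind(cand, extra))
    }
    scored <- score_candidates(cand, map$state, config)
    link_and_group(map, scored, new_uid, config,
                   reason_prefix = sprintf("amend %s/%s", dataset_id, source_record_id))
    validate_state(map$state, config$grouping_strategy)
    invisible(map$log[seq(first, length(map$log))])
  })
}

#' Reconcile an "open records" batch of additions, amendments and deletions
#'
#' Accepts a batch whose rows are flagged by an `_action` column
#' (`add`/`amend`/`delete`), or, when the column is absent, infers the diff
#' against the stored live versions: unknown custodian keys are additions,
#' known keys with changed fields are amendments, unchanged rows produce no
#' events (deletions are always explicit). Deletions are applied first, then
#' amendments, then additions, as one contiguous batch; on any row-level
#' error the whole batch is rejected before any map mutation.
#'
#' @param map A [linkage_map()].
#' @param batch Data frame with `dataset_id`, `source_record_id`, field
#'   columns, and optionally `_action`.
#' @param config A [linkage_config()].
#' @param batch_id Label for reasons and the report.
#' @return A list of class `batch_diff`: `additions`, `amendments`,
#'   `deletions` (data frames), `batch_id`, `report` (the additions'
#'   [ingest_batch()] report or `NULL`), `first_seq`, `last_seq`.
#' @export
reconcile_open_batch <- function(map, batch, config, batch_id = "open-batch") {
  rec <- map$state$records
  live_key <- paste(rec$dataset_id, rec$source_record_id, sep = "\r")[rec$status == "live"]
  key <- paste(batch$dataset_id, batch$source_record_id, sep = "\r")
  if (anyDuplicated(key)) {
    ongolink_stop("duplicate custodian key within batch", "ongolink_validation_error")
  }
  if ("_action" %in% names(batch)) {
    action <- batch[["_action"]]
    bad <- !action %in% c("add", "amend", "delete")
    if (any(bad)) {
      ongolink_stop(sprintf("invalid _action values at rows: %s",
                            paste(which(bad), collapse = ", ")),
                    "ongolink_validation_error")
    }
  } else {
    known <- key %in% live_key
    fn <- intersect(config_field_names(config), names(batch))
    changed <- vapply(seq_len(nrow(batch)), function(i) {
      if (!known[i]) return(TRUE)
      cur <- state_fields(map$state,
        rec$record_uid[rec$status == "live" &
                       paste(rec$dataset_id, rec$source_record_id, sep = "\r") == key[i]])
      any(vapply(fn, function(f) {
        a <- as.character(batch[[f]][i]); b <- as.character(cur[[f]])
        a[isTRUE(a == "")] <- NA; b[isTRUE(b == "")] <- NA
        !identical(is.na(a), is.na(b)) || (!is.na(a) && a != b)
      }, TRUE))
    }, TRUE)
    action <- ifelse(!known, "add", ifelse(changed, "amend", "none"))
  }
  # row-level validation before any mutation
  errs <- character(0)
  for (i in seq_len(nrow(batch))) {
    if (action[i] %in% c("amend", "delete") && !key[i] %in% live_key) {
      errs <- c(errs, sprintf("row %d: %s of unknown record %s/%s", i, action[i],
                              batch$dataset_id[i], batch$source_record_id[i]))
    }
    if (action[i] == "add" && key[i] %in% live_key) {
      errs <- c(errs, sprintf("row %d: add of already-live record %s/%s", i,
                              batch$dataset_id[i], batch$source_record_id[i]))
    }
  }
  if (length(errs)) {
    ongolink_stop(paste(c("batch rejected:", errs), collapse = "\n  "),
                  "ongolink_validation_error")
  }
  with_map_transaction(map, {
    first <- next_seq(map)
    dels <- batch[action == "delete", , drop = FALSE]
    amds <- batch[action == "amend", , drop = FALSE]
    adds <- batch[action == "add", , drop = FALSE]
    for (i in seq_len(nrow(dels))) {
      delete_record(map, dels$dataset_id[i], dels$source_record_id[i],
                    reason = sprintf("batch %s: custodian deletion", batch_id))
    }
    for (i in seq_len(nrow(amds))) {
      amend_record(map, amds$dataset_id[i], amds$source_record_id[i],
                   amds[i, , drop = FALSE], config,
                   reason = sprintf("batch %s: custodian amendment", batch_id))
    }
    report <- NULL
    if (nrow(adds)) report <- ingest_batch(map, adds, config, batch_id = batch_id)
    validate_state(map$state, config$grouping_strategy)
    structure(list(additions = adds, amendments = amds, deletions = dels,
                   batch_id = batch_id, report = report,
                   first_seq = first, last_seq = next_seq(map) - 1L),
              class = "batch_diff")
  })
}
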