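# Incremental linkage engine: batch ingestion, grouping strategies
# (transitive-closure merging vs best-link), and the project-based and
# bring-your-own linkage scenarios.

restrict_to_config_fields <- function(batch, config) {
  fn <- config_field_names(config)
  missing_cols <- setdiff(fn, names(batch))
  for (mc in missing_cols) batch[[mc]] <- NA_character_
  batch[fn]
}

# deterministic processing order for scored pairs
pair_order <- function(scored) {
  order(-scored$weight,
        pmin(id_num(scored$uid_a), id_num(scored$uid_b)),
        pmax(id_num(scored$uid_a), id_num(scored$uid_b)))
}

agreement_payload <- function(agreement_row) as.list(agreement_row)

accept_pair_event <- function(map, row, agreement, suppressed, config, reason) {
  append_event(map, map_event(next_seq(map), "PAIR_ACCEPTED", list(
    uid_a = row$uid_a, uid_b = row$uid_b, weight = row$weight,
    n_agree = row$n_agree, classification = row$classification,
    suppressed = suppressed, agreement = agreement_payload(agreement)
  ), reason = reason))
}

current_group <- function(map, uid) {
  map$state$records$group_id[map$state$records$record_uid == uid]
}

# ---- merge_allowed grouping: groups are the transitive closure of links ----
group_merge_allowed <- function(map, scored, new_uids, config, reason_prefix) {
  counts <- c(created = 0L, joined = 0L, merged = 0L)
  keep <- is_effective_match(scored$classification, config)
  em <- scored[keep, , drop = FALSE]
  agree <- attr(scored, "agreement")[keep, , drop = FALSE]
  ord <- pair_order(em)
  em <- em[ord, , drop = FALSE]; agree <- agree[ord, , drop = FALSE]
  for (i in seq_len(nrow(em))) {
    row <- em[i, ]
    accept_pair_event(map, row, agree[i, ], suppressed = FALSE, config,
                      reason = sprintf("%s: pair weight %.4g (%s)",
                                       reason_prefix, row$weight, row$classification))
    ga <- current_group(map, row$uid_a)
    gb <- current_group(map, row$uid_b)
    pair_txt <- sprintf("pair %s~%s (weight %.4g)", row$uid_a, row$uid_b, row$weight)
    if (is.na(ga) && is.na(gb)) {
      gid <- next_group_id(map$state)
      append_event(map, map_event(next_seq(map), "GROUP_CREATED",
        list(group_id = gid, members = c(row$uid_a, row$uid_b)),
        reason = sprintf("%s: new group from %s", reason_prefix, pair_txt)))
      counts["created"] <- counts["created"] + 1L
    } else if (is.na(ga) || is.na(gb)) {
      joiner <- if (is.na(ga)) row$uid_a else row$uid_b
      gid <- if (is.na(ga)) gb else ga
      append_event(map, map_event(next_seq(map), "RECORD_JOINED_GROUP",
        list(group_id = gid, record_uid = joiner),
        reason = sprintf("%s: %s joined via %s", reason_prefix, joiner, pair_txt)))
      counts["joined"] <- counts["joined"] + 1L
    } else if (ga != gb) {
      gid <- next_group_id(map$state)
      members <- c(map$state$groups[[ga]], map$state$groups[[gb]])
      append_event(map, map_event(next_seq(map), "GROUPS_MERGED",
        list(group_id = gid, merged_group_ids = c(ga, gb), members = members,
             via_pair = c(row$uid_a, row$uid_b)),
        reason = sprintf("%s: groups %s+%s merged via %s",
                         reason_prefix, ga, gb, pair_txt)))
      counts["merged"] <- counts["merged"] + 1L
    }  # same group: pair stored, no group change
  }
  for (u in new_uids) {
    if (is.na(current_group(map, u))) {
      gid <- next_group_id(map$state)
      append_event(map, map_event(next_seq(map), "GROUP_CREATED",
        list(group_id = gid, members = u),
        reason = sprintf("%s: singleton for %s", reason_prefix, u)))
      counts["created"] <- counts["created"] + 1L
    }
  }
  counts
}

# ---- best_link grouping ------------------------------------------------
# Incoming records are processed strictly in batch order; each joins the
# group of its single highest-weight match pair among records already placed
# (existing groups and earlier incoming records). Ties: more agreeing fields,
# then the group created earliest. An incoming record can therefore never
# merge two groups already in the system; match pairs pointing at other
# groups are stored flagged suppressed_by_best_link.
group_best_link <- function(map, scored, new_uids, config, reason_prefix) {
  counts <- c(created = 0L, joined = 0L, merged = 0L)
  keep <- is_effective_match(scored$classification, config)
  em <- scored[keep, , drop = FALSE]
  agree <- attr(scored, "agreement")[keep, , drop = FALSE]
  for (u in new_uids) {
    touches <- em$uid_a == u | em$uid_b == u
    other <- ifelse(em$uid_a == u, em$uid_b, em$uid_a)
    placed <- !is.na(vapply(other, function(v) current_group(map, v), ""))
    # only pairs whose other endpoint already sits in a group are usable now;
    # a pair to a later batch record is handled at that record's turn
    idx <- which(touches & placed)
    if (length(idx)) {
      other_gid <- vapply(other[idx], function(v) current_group(map, v), "")
      gseq <- map$state$group_meta$created_seq[match(other_gid, map$state$group_meta$group_id)]
      ord <- order(-em$weight[idx], -em$n_agree[idx], gseq, id_num(other[idx]))
      idx <- idx[ord]; other_gid <- other_gid[ord]
      best_gid <- other_gid[1L]
      for (k in seq_along(idx)) {
        i <- idx[k]
        row <- em[i, ]
        suppressed <- other_gid[k] != best_gid
        accept_pair_event(map, row, agree[i, ], suppressed = suppressed, config,
          reason = if (suppressed) {
            sprintf("%s: pair weight %.4g suppressed_by_best_link (best is group %s)",
                    reason_prefix, row$weight, best_gid)
          } else {
            sprintf("%s: pair weight %.4g (%s)", reason_prefix, row$weight,
                    row$classification)
          })
      }
      append_event(map, map_event(next_seq(map), "RECORD_JOINED_GROUP",
        list(group_id = best_gid, record_uid = u),
        reason = sprintf("%s: best link for %s is group %s (weight %.4g)",
                         reason_prefix, u, best_gid, em$weight[idx[1L]])))
      counts["joined"] <- counts["joined"] + 1L
    } else {
      gid <- next_group_id(map$state)
      append_event(map, map_event(next_seq(map), "GROUP_CREATED",
        list(group_id = gid, members = u),
        reason = sprintf("%s: singleton for %s", reason_prefix, u)))
      counts["created"] <- counts["created"] + 1L
    }
  }
  counts
}

link_and_group <- function(map, scored, new_uids, config, reason_prefix) {
  if (config$grouping_strategy == "merge_allowed") {
    group_merge_allowed(map, scored, new_uids, config, reason_prefix)
  } else {
    group_best_link(map, scored, new_uids, config, reason_prefix)
  }
}

new_ingest_report <- function(batch_id, n_added, scored, counts, first_seq, last_seq) {
  structure(list(
    batch_id = batch_id,
    n_records_added = n_added,
    n_candidates = nrow(scored),
    n_match = sum(scored$classification == "match"),
    n_possible = sum(scored$classification == "possible"),
    n_non_match = sum(scored$classification == "non_match"),
    n_groups_created = unname(counts["created"]),
    n_groups_joined = unname(counts["joined"]),
    n_groups_merged = unname(counts["merged"]),
    first_seq = first_seq, last_seq = last_seq
  ), class = "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat(sprintf("<ingest_report %s>\n", x$batch_id))
  cat(sprintf("  records added: %d\n", x$n_records_added))
  cat(sprintf("  candidates: %d (match %d / possible %d / non-match %d)\n",
              x$n_candidates, x$n_match, x$n_possible, x$n_non_match))
  cat(sprintf("  groups created %d, joined %d, merged %d\n",
              x$n_groups_created, x$n_groups_joined, x$n_groups_merged))
  cat(sprintf("  seq range: %s..%s\n", x$first_seq, x$last_seq))
  invisible(x)
}

#' Ingest a batch of new records into the on-going linkage map
#'
#' Every batch record is added, candidate pairs are generated (internally and
#' against existing records, per blocking and candidate scope), scored,
#' classified, match pairs stored, and groups updated per the configured
#' grouping strategy. Singletons get their own group. All changes are logged
#' with reasons; on any error the map is untouched.
#'
#' @param map A [linkage_map()].
#' @param batch Data frame of verified, cleaned records: columns
#'   `dataset_id`, `source_record_id`, plus the config field columns. Source
#'   ids must not already be live (amendments go through [amend_record()]).
#' @param config A [linkage_config()].
#' @param batch_id Label recorded in event reasons and the report.
#' @return An `ingest_report` (invisible map mutation).
#' @export
ingest_batch <- function(map, batch, config, batch_id = "batch") {
  stopifnot(is.data.frame(batch),
            all(c("dataset_id", "source_record_id") %in% names(batch)) || nrow(batch) == 0L)
  if (nrow(batch) == 0L) {
    return(new_ingest_report(batch_id, 0L,
                             score_candidates(generate_candidates(character(0), map$state, config),
                                              map$state, config),
                             c(created = 0L, joined = 0L, merged = 0L),
                             next_seq(map), next_seq(map) - 1L))
  }
  key <- paste(batch$dataset_id, batch$source_record_id, sep = "\r")
  if (anyDuplicated(key)) {
    ongolink_stop("duplicate (dataset_id, source_record_id) within batch",
                  "ongolink_validation_error")
  }
  rec <- map$state$records
  live_key <- paste(rec$dataset_id, rec$source_record_id, sep = "\r")[rec$status == "live"]
  dup <- key %in% live_key
  if (any(dup)) {
    ongolink_stop(sprintf("source ids already live in map: %s",
                          paste(batch$source_record_id[dup], collapse = ", ")),
                  "ongolink_validation_error")
  }
  with_map_transaction(map, {
    first_seq <- next_seq(map)
    fields <- restrict_to_config_fields(batch, config)
    new_uids <- character(nrow(batch))
    for (i in seq_len(nrow(batch))) {
      uid <- next_record_uid(map$state)
      new_uids[i] <- uid
      vals <- lapply(fields[i, , drop = FALSE], function(v) {
        v <- as.character(v)
        if (is.na(v) || v == "") NA_character_ else v
      })
      append_event(map, map_event(next_seq(map), "RECORD_ADDED", list(
        record_uid = uid, dataset_id = batch$dataset_id[i],
        source_record_id = batch$source_record_id[i], version_no = 1L,
        fields = vals
      ), reason = sprintf("batch %s: record added", batch_id)))
    }
    cand <- generate_candidates(new_uids, map$state, config)
    scored <- score_candidates(cand, map$state, config)
    counts <- link_and_group(map, scored, new_uids, config,
                             reason_prefix = sprintf("batch %s", batch_id))
    validate_state(map$state, config$grouping_strategy)
    new_ingest_report(batch_id, nrow(batch), scored, counts,
                      first_seq, next_seq(map) - 1L)
  })
}

#' Project-based (once-off) linkage in an isolated map
#'
#' Runs a full linkage over the supplied datasets in a fresh map namespace
#' unconnected to any on-going map, and returns the keys. The isolated map is
#' deletable as a unit, matching the create-and-destroy project scenario.
#'
#' @param records Data frame of cleaned records (`dataset_id`,
#'   `source_record_id`, field columns), or a list of such data frames.
#' @param config A [linkage_config()].
#' @param project_id Label used in the key file.
#' @return A list with elements `map` (the isolated [linkage_map()]), `keys`
#'   (data frame `dataset_id`, `source_record_id`, `group_id`,
#'   `extraction_id`), and `report`.
#' @export
project_link <- function(records, config, project_id = "project") {
  if (is.data.frame(records)) records <- list(records)
  records <- do.call(rbind, records)
  map <- linkage_map()
  report <- ingest_batch(map, records, config, batch_id = project_id)
  keys <- group_membership(map)
  keys$extraction_id <- project_id
  list(map = map, keys = keys, report = report)
}

#' Bring-your-own cohort linkage (read-only)
#'
#' Links a researcher's cohort against the on-going map without adding it:
#' each cohort record is assigned the group key of its best effective match
#' among existing records; unmatched cohort records are clustered among
#' themselves (if `internal = TRUE`) and given fresh ephemeral keys. No
#' events are appended; the map is unchanged.
#'
#' @param cohort Data frame of cleaned cohort records (`dataset_id`,
#'   `source_record_id`, field columns).
#' @param map A [linkage_map()]; read-only for this operation.
#' @param config A [linkage_config()].
#' @param internal Also link cohort records to each other?
#' @param extraction_id Label for the key file.
#' @return Key file data frame (`dataset_id`, `source_record_id`,
#'   `group_id`, `extraction_id`).
#' @export
byo_link <- function(cohort, map, config, internal = TRUE,
                     extraction_id = "byo") {
  empty <- data.frame(dataset_id = character(0), source_record_id = character(0),
                      group_id = character(0), extraction_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L) return(empty)
  # score against a scratch copy of the state; the real map is never touched
  scratch <- linkage_map()
  scratch$log <- map$log
  scratch$state <- map$state
  n_before <- length(map$log)
  ingest <- cohort
  report <- NULL
  # add cohort records to the scratch state only (no grouping yet)
  fields <- restrict_to_config_fields(cohort, config)
  new_uids <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    uid <- next_record_uid(scratch$state)
    new_uids[i] <- uid
    vals <- lapply(fields[i, , drop = FALSE], function(v) {
      v <- as.character(v)
      if (is.na(v) || v == "") NA_character_ else v
    })
    append_event(scratch, map_event(next_seq(scratch), "RECORD_ADDED", list(
      record_uid = uid, dataset_id = cohort$dataset_id[i],
      source_record_id = cohort$source_record_id[i], version_no = 1L,
      fields = vals), reason = "byo scratch"))
  }
  cand <- generate_candidates(new_uids, scratch$state, config)
  scored <- score_candidates(cand, scratch$state, config)
  em <- scored[is_effective_match(scored$classification, config), , drop = FALSE]
  existing_rec <- map$state$records
  group_of_existing <- function(uid) {
    existing_rec$group_id[existing_rec$record_uid == uid]
  }
  is_cohort <- function(uid) uid %in% new_uids
  keys <- rep(NA_character_, length(new_uids))
  for (i in seq_along(new_uids)) {
    u <- new_uids[i]
    touches <- (em$uid_a == u | em$uid_b == u)
    other <- ifelse(em$uid_a == u, em$uid_b, em$uid_a)
    ext <- touches & !vapply(other, is_cohort, TRUE)
    if (any(ext)) {
      idx <- which(ext)
      ord <- order(-em$weight[idx], -em$n_agree[idx], id_num(other[idx]))
      keys[i] <- group_of_existing(other[idx[ord[1L]]])
    }
  }
  if (internal && any(is.na(keys))) {
    un <- new_uids[is.na(keys)]
    internal_pairs <- em[em$uid_a %in% un & em$uid_b %in% un, , drop = FALSE]
    comps <- reconstitute(un, internal_pairs)
    for (ci in seq_along(comps)) {
      keys[match(comps[[ci]], new_uids)] <- paste0("byo", ci)
    }
  } else if (any(is.na(keys))) {
    un <- which(is.na(keys))
    keys[un] <- paste0("byo", seq_along(un))
  }
  stopifnot(length(map$log) == n_before)  # read-only contract
  out <- data.frame(dataset_id = cohort$dataset_id,
                    source_record_id = cohort$source_record_id,
                    group_id = keys, extraction_id = extraction_id,
                    stringsAsFactors = FALSE)
  out[c_order(out$dataset_id, out$source_record_id), , drop = FALSE]
}
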