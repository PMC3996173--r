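# Probabilistic matching substrate: blocking-key derivation, candidate pair
# generation, field comparison, Fellegi-Sunter log2 likelihood-ratio
# weighting, and threshold classification.

NO_KEY <- NA_character_  # sentinel: a record with no usable key joins no block

apply_transform <- function(values, tr) {
  op <- tr$op %||% "full"
  switch(op,
    constant = rep("1", length(values)),
    full = values,
    initial = substr(values, 1L, 1L),
    prefix = substr(values, 1L, as.integer(tr$k %||% 1L)),
    year = substr(values, 1L, 4L),  # ISO dates: leading YYYY
    stop("unknown blocking transform op: ", op)
  )
}

#' Derive blocking keys for records
#'
#' One key string per blocking pass per record. A pass whose every component
#' is missing yields the no-key sentinel (`NA`), which never matches any key,
#' so the record enters no candidate pair from that pass.
#'
#' @param fields A named list (one record) or data frame (one record per row)
#'   of field values; missing values as `NA` or `""`.
#' @param config A [linkage_config()].
#' @return For a single record, a character vector of keys (one per pass);
#'   for a data frame, a character matrix (records x passes).
#' @export
derive_blocking_keys <- function(fields, config) {
  single <- !is.data.frame(fields)
  if (single) fields <- as.data.frame(lapply(fields, as.character),
                                      stringsAsFactors = FALSE)
  n <- nrow(fields)
  keys <- matrix(NA_character_, nrow = n, ncol = length(config$blocking_passes))
  for (p in seq_along(config$blocking_passes)) {
    pass <- config$blocking_passes[[p]]
    parts <- matrix("", nrow = n, ncol = length(pass))
    any_present <- rep(FALSE, n)
    for (ci in seq_along(pass)) {
      tr <- pass[[ci]]
      op <- tr$op %||% "full"
      if (op == "constant") {
        v <- rep("1", n)
      } else {
        if (!tr$field %in% names(fields)) {
          ongolink_stop(paste0("blocking transform references unknown field: ", tr$field),
                        "ongolink_config_error")
        }
        v <- as.character(fields[[tr$field]])
        v[!is.na(v) & v == ""] <- NA_character_
        v <- apply_transform(v, tr)
      }
      present <- !is.na(v)
      any_present <- any_present | present
      parts[, ci] <- ifelse(present, v, "")
    }
    key <- apply(parts, 1L, paste0, collapse = "|")
    key[!any_present] <- NO_KEY
    keys[, p] <- key
  }
  if (single) keys[1L, ] else keys
}

# pairs of row indices sharing at least one non-sentinel blocking key, within
# a single pool of records (used for incoming x incoming)
pairs_within <- function(keys) {
  out <- list()
  for (p in seq_len(ncol(keys))) {
    k <- keys[, p]
    ok <- which(!is.na(k))
    if (length(ok) < 2L) next
    blocks <- split(ok, k[ok])
    for (b in blocks) {
      if (length(b) < 2L) next
      cmb <- utils::combn(sort(b), 2L)
      out[[length(out) + 1L]] <- cbind(cmb[1L, ], cmb[2L, ])
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, out)
  unique(m)
}

# pairs (i in keys_a) x (j in keys_b) sharing at least one key
pairs_between <- function(keys_a, keys_b) {
  out <- list()
  for (p in seq_len(ncol(keys_a))) {
    ka <- keys_a[, p]; kb <- keys_b[, p]
    ia <- which(!is.na(ka)); ib <- which(!is.na(kb))
    if (!length(ia) || !length(ib)) next
    shared <- intersect(ka[ia], kb[ib])
    for (key in shared) {
      ai <- ia[ka[ia] == key]; bi <- ib[kb[ib] == key]
      out[[length(out) + 1L]] <- cbind(rep(ai, each = length(bi)),
                                       rep(bi, times = length(ai)))
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2L))
  unique(do.call(rbind, out))
}

#' Generate candidate record pairs for an incoming batch
#'
#' Returns the union of (a) incoming x incoming pairs sharing at least one
#' blocking key and (b) incoming x existing pairs sharing at least one key.
#' Under `candidate_scope = "most_recent_per_group"` the existing side is
#' restricted to the most recently added live record of each group.
#'
#' @param incoming_uids Record uids of the incoming batch (must be present in
#'   `state`).
#' @param state A group state (see [state_at()]).
#' @param config A [linkage_config()].
#' @return A two-column character matrix of record uid pairs (`uid_a` <
#'   `uid_b` by numeric id, no duplicates, no self-pairs).
#' @export
generate_candidates <- function(incoming_uids, state, config) {
  empty <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("uid_a", "uid_b")))
  if (!length(incoming_uids)) return(empty)
  inc_fields <- state_fields(state, incoming_uids)
  inc_keys <- derive_blocking_keys(inc_fields, config)
  if (!is.matrix(inc_keys)) inc_keys <- matrix(inc_keys, nrow = 1L)

  within <- pairs_within(inc_keys)
  pairs <- cbind(incoming_uids[within[, 1L]], incoming_uids[within[, 2L]])

  existing <- existing_candidate_uids(state, config)
  existing <- setdiff(existing, incoming_uids)
  if (length(existing)) {
    ex_fields <- state_fields(state, existing)
    ex_keys <- derive_blocking_keys(ex_fields, config)
    if (!is.matrix(ex_keys)) ex_keys <- matrix(ex_keys, nrow = 1L)
    between <- pairs_between(inc_keys, ex_keys)
    if (nrow(between)) {
      pairs <- rbind(pairs, cbind(incoming_uids[between[, 1L]],
                                  existing[between[, 2L]]))
    }
  }
  if (!nrow(pairs)) return(empty)
  # canonical orientation + dedupe
  swap <- id_num(pairs[, 1L]) > id_num(pairs[, 2L])
  pairs[swap, ] <- pairs[swap, c(2L, 1L), drop = FALSE]
  pairs <- unique(pairs)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  colnames(pairs) <- c("uid_a", "uid_b")
  pairs
}

# live records eligible as the "existing" side of candidate generation
existing_candidate_uids <- function(state, config) {
  live <- state$records$record_uid[state$records$status == "live"]
  if (config$candidate_scope == "all_records" || !length(live)) return(live)
  # most recent live record per group, by RECORD_ADDED seq
  rec <- state$records[state$records$status == "live", , drop = FALSE]
  rec <- rec[order(rec$added_seq, decreasing = TRUE), , drop = FALSE]
  rec$record_uid[!duplicated(rec$group_id)]
}

#' Compare two records field by field
#'
#' @param a,b Named lists or one-row data frames of field values.
#' @param config A [linkage_config()].
#' @return A named character vector over `{"agree", "disagree", "missing"}`,
#'   covering exactly the config fields, in order. Symmetric in `a`, `b`; a
#'   field is missing if either side is missing.
#' @export
compare_records <- function(a, b, config) {
  out <- vapply(config$fields, function(f) {
    compare_field(a[[f$name]] %||% NA_character_,
                  b[[f$name]] %||% NA_character_, f)
  }, character(1))
  names(out) <- config_field_names(config)
  out
}

# vectorised comparison over many pairs: returns pairs x fields matrix
compare_pair_matrix <- function(fields_a, fields_b, config) {
  fn <- config_field_names(config)
  m <- matrix(NA_character_, nrow = nrow(fields_a), ncol = length(fn),
              dimnames = list(NULL, fn))
  for (f in config$fields) {
    m[, f$name] <- compare_field(fields_a[[f$name]], fields_b[[f$name]], f)
  }
  m
}

#' Fellegi-Sunter pair weight from an agreement vector
#'
#' `weight = sum over fields of log2(m/u)` for agreements,
#' `log2((1-m)/(1-u))` for disagreements, and 0 for missing comparisons.
#'
#' @param agreement A named character vector as returned by
#'   [compare_records()], or a pairs x fields character matrix.
#' @param config A [linkage_config()].
#' @return Numeric weight(s) in log2 units.
#' @export
score_agreement <- function(agreement, config) {
  if (!is.matrix(agreement)) agreement <- matrix(agreement, nrow = 1L,
                                                 dimnames = list(NULL, names(agreement)))
  w <- numeric(nrow(agreement))
  for (f in config$fields) {
    a <- agreement[, f$name]
    w <- w + ifelse(a == "agree", log2(f$m_prob / f$u_prob),
             ifelse(a == "disagree", log2((1 - f$m_prob) / (1 - f$u_prob)), 0))
  }
  unname(w)
}

#' Classify a pair weight against the configured thresholds
#'
#' Weight at or above the upper threshold: match. Strictly below the lower
#' threshold: non-match. Otherwise: possible (resolved by the configured
#' `possible_policy` before grouping; there is no clerical review).
#'
#' @param weight Numeric vector of log2 pair weights.
#' @param config A [linkage_config()].
#' @return Character vector over `{"match", "possible", "non_match"}`.
#' @export
classify_weight <- function(weight, config) {
  ifelse(weight >= config$upper_threshold, "match",
  ifelse(weight < config$lower_threshold, "non_match", "possible"))
}

#' Score and classify a set of candidate pairs
#'
#' @param pairs Two-column matrix of record uids (as from
#'   [generate_candidates()]).
#' @param state Group state holding the records' fields.
#' @param config A [linkage_config()].
#' @return A data frame with columns `uid_a`, `uid_b`, `weight`, `n_agree`,
#'   `classification`, and an attached `"agreement"` attribute (pairs x
#'   fields character matrix).
#' @export
score_candidates <- function(pairs, state, config) {
  if (!nrow(pairs)) {
    out <- data.frame(uid_a = character(0), uid_b = character(0),
                      weight = numeric(0), n_agree = integer(0),
                      classification = character(0), stringsAsFactors = FALSE)
    attr(out, "agreement") <- matrix(character(0), ncol = length(config$fields),
                                     dimnames = list(NULL, config_field_names(config)))
    return(out)
  }
  fa <- state_fields(state, pairs[, 1L])
  fb <- state_fields(state, pairs[, 2L])
  agree <- compare_pair_matrix(fa, fb, config)
  w <- score_agreement(agree, config)
  out <- data.frame(uid_a = pairs[, 1L], uid_b = pairs[, 2L],
                    weight = w,
                    n_agree = rowSums(agree == "agree"),
                    classification = classify_weight(w, config),
                    stringsAsFactors = FALSE)
  attr(out, "agreement") <- agree
  out
}

# does this classification count as a link, under the configured policy?
is_effective_match <- function(classification, config) {
  classification == "match" |
    (classification == "possible" & config$possible_policy == "treat_as_match")
}
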