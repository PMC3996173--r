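# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (exhaustive enumeration, repeated set expansion) and
# independent of the package's algorithms.

# two exact fields, m = 0.9 / u = 0.1 each, complete (constant-key) blocking;
# weights: agree +log2(9), disagree -log2(9); both agree = 6.3399 classifies
# as a match, one of each = 0 classifies as a non-match
hand_config <- function(upper = 6, lower = 1,
                        grouping_strategy = "merge_allowed",
                        candidate_scope = "all_records",
                        possible_policy = "treat_as_nonmatch") {
  linkage_config(
    fields = list(
      field_spec("a", "exact", m_prob = 0.9, u_prob = 0.1),
      field_spec("b", "exact", m_prob = 0.9, u_prob = 0.1)
    ),
    blocking_passes = list(blocking_pass(list(op = "constant"))),
    upper_threshold = upper, lower_threshold = lower,
    candidate_scope = candidate_scope,
    grouping_strategy = grouping_strategy,
    possible_policy = possible_policy
  )
}

# records for hand_config(): value pairs chosen per person
hand_records <- function(a, b, dataset_id = "ds", ids = NULL) {
  n <- max(length(a), length(b))
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(n))
  data.frame(dataset_id = rep_len(dataset_id, n), source_record_id = ids,
             a = rep_len(a, n), b = rep_len(b, n), stringsAsFactors = FALSE)
}

# default-config person rows, cleaned form
person_row <- function(sid, given, surname, sex, dob, address,
                       dataset_id = "ds") {
  data.frame(dataset_id = dataset_id, source_record_id = sid,
             given_name = given, surname = surname, sex = sex, dob = dob,
             address = address, stringsAsFactors = FALSE)
}

# independent connected-components oracle: repeated set expansion
brute_components <- function(members, pairs) {
  if (is.data.frame(pairs)) pairs <- cbind(pairs$uid_a, pairs$uid_b)
  comps <- lapply(members, identity)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (k in seq_len(nrow(pairs))) {
      ia <- which(vapply(comps, function(cm) pairs[k, 1] %in% cm, TRUE))
      ib <- which(vapply(comps, function(cm) pairs[k, 2] %in% cm, TRUE))
      if (ia != ib) {
        comps[[ia]] <- c(comps[[ia]], comps[[ib]])
        comps[[ib]] <- NULL
        changed <- TRUE
      }
    }
  }
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1))])
}

# independent pairwise precision/recall oracle: literal double loop
brute_eval <- function(keys, truth) {
  id <- paste(keys$dataset_id, keys$source_record_id)
  tid <- paste(truth$dataset_id, truth$source_record_id)
  person <- truth$person_id[match(id, tid)]
  n <- nrow(keys)
  tp <- fp <- fn <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    same_g <- keys$group_id[i] == keys$group_id[j]
    same_p <- person[i] == person[j]
    if (same_g && same_p) tp <- tp + 1
    if (same_g && !same_p) fp <- fp + 1
    if (!same_g && same_p) fn <- fn + 1
  }
  list(precision = if (tp + fp == 0) 1.0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1.0 else tp / (tp + fn))
}

# ingest a cleaned data frame in k sequential batches
ingest_in_batches <- function(map, records, config, k) {
  if (nrow(records) == 0L) return(invisible(map))
  idx <- split(seq_len(nrow(records)),
               cut(seq_len(nrow(records)), k, labels = FALSE))
  for (b in seq_along(idx)) {
    ingest_batch(map, records[idx[[b]], , drop = FALSE], config,
                 batch_id = sprintf("b%d", b))
  }
  invisible(map)
}

# synthetic cleaned records for the default config
synth_cleaned <- function(n_persons, seed, corruption = corruption_model(seed = seed),
                          dataset_id = "ds1", records_per_person = 2L) {
  pop <- generate_population(n_persons, seed = seed)
  em <- emit_records(pop, dataset_id, corruption,
                     records_per_person = records_per_person)
  list(cleaned = clean_standardise(em$rows, default_schema(dataset_id)),
       truth = em$truth, population = pop)
}

write_rows_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}
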