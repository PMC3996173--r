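test_that("empty batches are no-ops with all-zero reports", {
  cfg <- hand_config()
  map <- linkage_map()
  rep <- ingest_batch(map, hand_records(a = character(0), b = character(0)), cfg)
  expect_equal(rep$n_records_added, 0L)
  expect_equal(rep$n_candidates, 0L)
  expect_length(map$log, 0L)
})

test_that("two records of one person form a single group of two", {
  # both fields agree: weight 2*log2(9) = 6.34 >= upper 6 by hand
  cfg <- hand_config(upper = 6, lower = 1)
  map <- linkage_map()
  rep <- ingest_batch(map, hand_records(a = c("x", "x"), b = c("1", "1")), cfg)
  expect_equal(length(map$state$groups), 1L)
  expect_equal(lengths(map$state$groups)[[1]], 2L)
  expect_equal(rep$n_match, 1L)
  expect_equal(rep$n_groups_created, 1L)
})

test_that("a batch record matching an existing group joins it", {
  cfg <- hand_config()
  map <- linkage_map()
  ingest_batch(map, hand_records(a = c("x", "x"), b = c("1", "1")), cfg)
  rep <- ingest_batch(map, hand_records(a = "x", b = "1", ids = "n1"), cfg)
  expect_equal(rep$n_groups_joined, 1L)
  expect_equal(length(map$state$groups), 1L)
  expect_equal(lengths(map$state$groups)[[1]], 3L)
  joined <- Filter(function(e) e$kind == "RECORD_JOINED_GROUP", map$log)
  expect_length(joined, 1L)
})

test_that("ingest reports partition candidates into the three classes", {
  dat <- synth_cleaned(25, seed = 9,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 9))
  map <- linkage_map()
  rep <- ingest_batch(map, dat$cleaned, default_linkage_config())
  expect_equal(rep$n_match + rep$n_possible + rep$n_non_match, rep$n_candidates)
  expect_gte(rep$n_candidates, 0L)
  expect_equal(rep$n_records_added, nrow(dat$cleaned))
})

test_that("duplicate live source ids are rejected before any map mutation", {
  cfg <- hand_config()
  map <- linkage_map()
  ingest_batch(map, hand_records(a = "x", b = "1", ids = "A"), cfg)
  len <- length(map$log)
  expect_error(ingest_batch(map, hand_records(a = c("y", "z"), b = c("2", "3"),
                                              ids = c("B", "A")), cfg),
               class = "ongolink_validation_error")
  expect_length(map$log, len)
  expect_error(ingest_batch(map, hand_records(a = c("y", "y"), b = c("2", "2"),
                                              ids = c("B", "B")), cfg),
               class = "ongolink_validation_error")
  expect_length(map$log, len)
})

test_that("merge_allowed groups equal the components of the stored pairs", {
  dat <- synth_cleaned(20, seed = 61,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 61))
  cfg <- default_linkage_config()
  map <- linkage_map()
  ingest_in_batches(map, dat$cleaned, cfg, 3)
  live <- map$state$records$record_uid[map$state$records$status == "live"]
  act <- map$state$pairs[map$state$pairs$active, c("uid_a", "uid_b")]
  oracle <- brute_components(live, act)
  got <- lapply(unname(map$state$groups), sort)
  got <- got[order(vapply(got, `[`, "", 1))]
  expect_equal(got, oracle)
  # an internal pair (both endpoints already co-grouped) changes nothing
  n_groups <- length(map$state$groups)
  expect_equal(length(brute_components(live, act)), n_groups)
})

test_that("a merge event names the triggering pair and closes both groups", {
  cfgd <- default_linkage_config()
  split_pair <- rbind(
    person_row("A", "MARGARET", "WILSON", "F", "1955-03-09", "10 HIGH ST"),
    person_row("B", "MARGARET", "CAMPBELL", "F", "1955-03-09", "12 OCEAN PDE"))
  bridge <- person_row("C", "MARGARET", "WILSON", "F", "1955-03-09",
                       "12 OCEAN PDE")
  map <- linkage_map()
  ingest_batch(map, split_pair, cfgd)
  g_before <- names(map$state$groups)
  ingest_batch(map, bridge, cfgd)
  merge_ev <- Filter(function(e) e$kind == "GROUPS_MERGED", map$log)
  expect_length(merge_ev, 1L)
  p <- merge_ev[[1]]$payload
  expect_length(p$via_pair, 2L)
  expect_true(any(g_before %in% p$merged_group_ids))
  expect_false(any(p$merged_group_ids %in% names(map$state$groups)))
  expect_equal(length(map$state$groups), 1L)
})

test_that("best link joins only the highest-weight group and never merges", {
  cfgd <- default_linkage_config(grouping_strategy = "best_link")
  # the same person split over two spine groups (surname change): the bridge
  # matches WILSON-side at higher weight than CAMPBELL-side
  spine <- rbind(
    person_row("A", "MARGARET", "WILSON", "F", "1955-03-09", "10 HIGH ST"),
    person_row("B", "MARGARET", "CAMPBELL", "F", "1955-03-09", "12 OCEAN PDE"))
  bridge <- person_row("C", "MARGARET", "WILSON", "F", "1955-03-09",
                       "12 OCEAN PDE")
  map <- linkage_map()
  ingest_batch(map, spine, cfgd)
  expect_equal(length(map$state$groups), 2L)
  rep <- ingest_batch(map, bridge, cfgd)
  # both pre-existing groups persist; the bridge joined exactly one of them
  expect_equal(length(map$state$groups), 2L)
  expect_equal(rep$n_groups_merged, 0L)
  expect_equal(rep$n_match, 2L)
  expect_length(Filter(function(e) e$kind == "GROUPS_MERGED", map$log), 0L)
  # the suppressed pair is flagged and the used pair is not
  expect_setequal(map$state$pairs$suppressed, c(TRUE, FALSE))
  # the bridge sits with the higher-weight (same-surname) record A
  part <- canonical_partition(group_membership(map))
  expect_true(list(sort(c("ds\rA", "ds\rC"))) %in% part ||
              any(vapply(part, function(g) setequal(g, c("ds\rA", "ds\rC")), TRUE)))

  # identical scenario under merge_allowed: the two groups merge
  cfgm <- default_linkage_config()
  map2 <- linkage_map()
  ingest_batch(map2, spine, cfgm)
  ingest_batch(map2, bridge, cfgm)
  expect_equal(length(map2$state$groups), 1L)
})

test_that("best link gives unmatched incoming records singleton groups", {
  cfgd <- default_linkage_config(grouping_strategy = "best_link")
  map <- linkage_map()
  rep <- ingest_batch(map, person_row("A", "JOHN", "SMITH", "M", "1980-02-03",
                                      "1 HIGH ST"), cfgd)
  expect_equal(rep$n_groups_created, 1L)
  expect_equal(length(map$state$groups), 1L)
})

test_that("under best link the pre-existing group count never decreases", {
  dat <- synth_cleaned(30, seed = 13,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 13))
  cfg <- default_linkage_config(grouping_strategy = "best_link")
  map <- linkage_map()
  idx <- split(seq_len(nrow(dat$cleaned)), cut(seq_len(nrow(dat$cleaned)), 4, labels = FALSE))
  for (b in seq_along(idx)) {
    pre <- names(map$state$groups)
    ingest_batch(map, dat$cleaned[idx[[b]], ], cfg)
    expect_true(all(pre %in% names(map$state$groups)))
  }
})

test_that("arrival order does not change merge_allowed groupings", {
  dat <- synth_cleaned(25, seed = 31,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 31))
  cfg <- default_linkage_config()
  parts <- lapply(1:4, function(s) {
    set.seed(s)
    sh <- dat$cleaned[sample.int(nrow(dat$cleaned)), ]
    map <- linkage_map()
    ingest_in_batches(map, sh, cfg, 3)
    canonical_partition(group_membership(map))
  })
  for (k in 2:4) expect_identical(parts[[k]], parts[[1]])
})

test_that("incremental ingestion equals one-shot linkage under complete blocking", {
  dat <- synth_cleaned(20, seed = 17,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 17))
  cfg <- default_linkage_config()
  cfg$blocking_passes <- list(blocking_pass(list(op = "constant")))
  map <- linkage_map()
  ingest_in_batches(map, dat$cleaned, cfg, 4)
  pr <- project_link(dat$cleaned, cfg, "oneshot")
  expect_identical(canonical_partition(group_membership(map)),
                   canonical_partition(pr$keys))
})

test_that("project linkage is deterministic and isolated", {
  dat <- synth_cleaned(10, seed = 23)
  cfg <- default_linkage_config()
  r1 <- project_link(dat$cleaned, cfg, "projA")
  r2 <- project_link(dat$cleaned, cfg, "projA")
  expect_identical(canonical_partition(r1$keys), canonical_partition(r2$keys))
  expect_equal(unique(r1$keys$extraction_id), "projA")

  # running a project leaves an on-going map byte-identical
  ongoing <- linkage_map()
  ingest_batch(ongoing, dat$cleaned[1:4, ], cfg)
  before <- map_log_json(ongoing)
  invisible(project_link(dat$cleaned, cfg, "projB"))
  expect_identical(map_log_json(ongoing), before)
})

test_that("two toy datasets with one shared person give five project groups", {
  cfg <- hand_config()
  d1 <- hand_records(a = c("p1", "p2", "p3"), b = c("1", "2", "3"),
                     dataset_id = "d1", ids = c("x1", "x2", "x3"))
  d2 <- hand_records(a = c("p3", "p4", "p5"), b = c("3", "4", "5"),
                     dataset_id = "d2", ids = c("y1", "y2", "y3"))
  res <- project_link(list(d1, d2), cfg, "toy")
  expect_equal(length(unique(res$keys$group_id)), 5L)
})

test_that("bring-your-own linkage writes keys without touching the map", {
  dat <- synth_cleaned(15, seed = 41)
  cfg <- default_linkage_config()
  map <- linkage_map()
  ingest_batch(map, dat$cleaned, cfg)
  log_before <- map_log_json(map)
  state_before <- map$state

  # cohort = corrupted re-emissions of the first 5 persons + 1 stranger
  cohort <- dat$cleaned[c(1, 3, 5, 7, 9), ]
  cohort$dataset_id <- "cohort"
  cohort$source_record_id <- paste0("c", 1:5)
  stranger <- person_row("c6", "ZEBEDEE", "QUIRKE", "M", "2001-12-31",
                         "99 ZAMIA CT", dataset_id = "cohort")
  keys <- byo_link(rbind(cohort, stranger), map, cfg)
  expect_identical(map_log_json(map), log_before)
  expect_identical(map$state, state_before)
  expect_equal(nrow(keys), 6L)
  matched <- keys[keys$source_record_id != "c6", ]
  expect_true(all(matched$group_id %in% names(map$state$groups)))
  expect_match(keys$group_id[keys$source_record_id == "c6"], "^byo")
  expect_equal(nrow(byo_link(cohort[0, ], map, cfg)), 0L)
})
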