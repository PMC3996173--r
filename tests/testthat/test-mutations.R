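test_that("deleting a singleton dissolves its group and nothing else", {
  cfg <- hand_config()
  map <- linkage_map()
  ingest_batch(map, hand_records(a = c("x", "y"), b = c("1", "2"),
                                 ids = c("A", "B")), cfg)
  expect_equal(length(map$state$groups), 2L)
  delete_record(map, "ds", "A", "withdrawn by custodian")
  expect_equal(length(map$state$groups), 1L)
  expect_equal(unname(unlist(lapply(map$state$groups, length))), 1L)
  rec <- map$state$records
  expect_equal(rec$status[rec$source_record_id == "A"], "deleted")
  expect_error(delete_record(map, "ds", "A", "again"),
               class = "ongolink_not_found_error")
  expect_error(delete_record(map, "ds", "nope", "x"),
               class = "ongolink_not_found_error")
})

test_that("deleting a bridge record splits its group; a triangle survives", {
  # three exact fields; with upper=3 a pair agreeing on two of three fields
  # (weight log2(9) = 3.17) is a match, one agreement (weight <= 0) is not,
  # so A-B-C is a chain held together only through B
  cfg3 <- linkage_config(
    fields = list(field_spec("a", "exact", m_prob = .9, u_prob = .1),
                  field_spec("b", "exact", m_prob = .9, u_prob = .1),
                  field_spec("c", "exact", m_prob = .9, u_prob = .1)),
    blocking_passes = list(blocking_pass(list(op = "constant"))),
    upper_threshold = 3, lower_threshold = 0)
  recs <- data.frame(dataset_id = "ds", source_record_id = c("A", "B", "C"),
                     a = c("p", "p", "z"), b = c("1", "1", "1"),
                     c = c("m", "n", "n"), stringsAsFactors = FALSE)
  map3 <- linkage_map()
  ingest_batch(map3, recs, cfg3)
  expect_equal(length(map3$state$groups), 1L)  # A-B-C chained through B
  delete_record(map3, "ds", "B", "bridge removed")
  part <- canonical_partition(group_membership(map3))
  expect_equal(part, list("ds\rA", "ds\rC"))

  # triangle: all three pairwise matches; deleting B keeps {A,C}
  tri <- data.frame(dataset_id = "ds", source_record_id = c("A", "B", "C"),
                    a = "p", b = "1", c = "m", stringsAsFactors = FALSE)
  map4 <- linkage_map()
  ingest_batch(map4, tri, cfg3)
  expect_equal(length(map4$state$groups), 1L)
  delete_record(map4, "ds", "B", "redundant member removed")
  part4 <- canonical_partition(group_membership(map4))
  expect_equal(part4, list(sort(c("ds\rA", "ds\rC"))))
  # no reconstitution event was needed: the group survived intact
  expect_length(Filter(function(e) e$kind == "GROUP_RECONSTITUTED", map4$log), 0L)
})

test_that("add-then-delete equals never-present (random scenarios)", {
  cfg <- default_linkage_config()
  for (seed in c(101, 102, 103)) {
    dat <- synth_cleaned(15, seed = seed,
                         corruption = corruption_model(0.05, 0.02, 0.02, seed = seed))
    cl <- dat$cleaned
    set.seed(seed)
    victim <- sample(cl$source_record_id, 1)
    mapA <- linkage_map()
    ingest_in_batches(mapA, cl, cfg, 2)
    delete_record(mapA, "ds1", victim, "equivalence check")
    mapB <- linkage_map()
    ingest_in_batches(mapB, cl[cl$source_record_id != victim, ], cfg, 2)
    expect_identical(canonical_partition(group_membership(mapA)),
                     canonical_partition(group_membership(mapB)))
  }
})

test_that("deletion never alters groups disjoint from the victim's group", {
  dat <- synth_cleaned(20, seed = 71,
                       corruption = corruption_model(0.05, 0.02, 0.02, seed = 71))
  cfg <- default_linkage_config()
  map <- linkage_map()
  ingest_in_batches(map, dat$cleaned, cfg, 2)
  victim_sid <- dat$cleaned$source_record_id[5]
  rec <- map$state$records
  victim_uid <- rec$record_uid[rec$source_record_id == victim_sid & rec$status == "live"]
  victim_gid <- rec$group_id[rec$record_uid == victim_uid]
  others_before <- map$state$groups[names(map$state$groups) != victim_gid]
  delete_record(map, "ds1", victim_sid, "locality check")
  others_after <- map$state$groups[names(others_before)]
  expect_identical(others_before, others_after)
})

test_that("an amendment that changes nothing relevant is a logged no-op", {
  cfg <- hand_config()
  map <- linkage_map()
  ingest_batch(map, hand_records(a = "x", b = "1", ids = "A"), cfg)
  len <- length(map$log)
  evs <- amend_record(map, "ds", "A", list(a = "x", b = "1"), cfg)
  expect_length(map$log, len + 1L)
  expect_equal(map$log[[len + 1L]]$kind, "RECORD_AMENDED")
  expect_true(map$log[[len + 1L]]$payload$noop)
  rec <- map$state$records
  expect_equal(sum(rec$status == "live"), 1L)
  expect_equal(rec$version_no[rec$status == "live"], 1L)
})

test_that("a surname correction that breaks the only match isolates the record", {
  cfgd <- default_linkage_config()
  map <- linkage_map()
  pair <- rbind(
    person_row("A", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"),
    person_row("B", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"))
  ingest_batch(map, pair, cfgd)
  expect_equal(length(map$state$groups), 1L)
  amend_record(map, "ds", "B",
               list(given_name = "GERTRUDE", surname = "ZELLWEGER", sex = "F",
                    dob = "1931-11-20", address = "9 EDEN CLOSE"), cfgd,
               reason = "identity correction")
  part <- canonical_partition(group_membership(map))
  expect_equal(part, list("ds\rA", "ds\rB"))
  rec <- map$state$records
  expect_equal(rec$version_no[rec$source_record_id == "B" & rec$status == "live"], 2L)
  expect_equal(rec$status[rec$source_record_id == "B" & rec$version_no == 1L],
               "superseded")
})

test_that("an amendment can move a record to a different group, with reasons", {
  cfgd <- default_linkage_config()
  map <- linkage_map()
  recs <- rbind(
    person_row("A1", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"),
    person_row("A2", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"),
    person_row("B1", "GERTRUDE", "ZELLWEGER", "F", "1931-11-20", "9 EDEN CLOSE"))
  ingest_batch(map, recs, cfgd)
  expect_equal(length(map$state$groups), 2L)
  amend_record(map, "ds", "A2",
               list(given_name = "GERTRUDE", surname = "ZELLWEGER", sex = "F",
                    dob = "1931-11-20", address = "9 EDEN CLOSE"), cfgd,
               reason = "misattributed record")
  part <- canonical_partition(group_membership(map))
  expect_equal(part, list("ds\rA1", sort(c("ds\rA2", "ds\rB1"))))
  h <- record_history(map, "ds", "A2")
  kinds <- vapply(h, function(e) e$kind, "")
  expect_true("RECORD_AMENDED" %in% kinds)
  expect_true(all(nzchar(vapply(h, function(e) e$reason, ""))))
})

test_that("add-then-amend equals adding the amended version (random scenarios)", {
  cfg <- default_linkage_config()
  for (seed in c(201, 202, 203)) {
    dat <- synth_cleaned(15, seed = seed,
                         corruption = corruption_model(0.05, 0.02, 0.02, seed = seed))
    cl <- dat$cleaned
    set.seed(seed)
    i <- sample(nrow(cl), 1)
    amended <- cl[i, ]
    amended$surname <- "QUILLFEATHER"   # not in the name pools
    mapA <- linkage_map()
    ingest_in_batches(mapA, cl, cfg, 2)
    amend_record(mapA, "ds1", cl$source_record_id[i], amended, cfg)
    clB <- cl; clB[i, ] <- amended
    mapB <- linkage_map()
    ingest_in_batches(mapB, clB, cfg, 2)
    expect_identical(canonical_partition(group_membership(mapA)),
                     canonical_partition(group_membership(mapB)))
  }
})

test_that("mutation history remains fully queryable after unwinding", {
  cfg <- hand_config()
  map <- linkage_map()
  ingest_batch(map, hand_records(a = c("x", "x"), b = c("1", "1"),
                                 ids = c("A", "B")), cfg)
  seq_before <- length(map$log)
  delete_record(map, "ds", "A", "history retention check")
  st <- state_at(map, seq_before)
  expect_equal(sum(st$records$status == "live"), 2L)
  expect_equal(length(st$groups), 1L)
})

test_that("reconcile applies deletions, then amendments, then additions", {
  cfgd <- default_linkage_config()
  base <- rbind(
    person_row("A", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"),
    person_row("B", "BORIS", "KHAN", "M", "1982-09-12", "7 HIGH ST"),
    person_row("C", "CLARA", "NGUYEN", "F", "1990-01-30", "2 OCEAN PDE"))
  map <- linkage_map()
  ingest_batch(map, base, cfgd)

  batch <- rbind(
    cbind(person_row("B", "", "", "", "", ""), `_action` = "delete"),
    cbind(person_row("C", "CLARA", "NGUYEN", "F", "1990-01-30",
                     "5 STATION ST"), `_action` = "amend"),
    cbind(person_row("D", "DENZEL", "MURRAY", "M", "1975-07-07",
                     "8 PALM TCE"), `_action` = "add"))
  diff <- reconcile_open_batch(map, batch, cfgd, "month-02")
  expect_s3_class(diff, "batch_diff")
  expect_equal(nrow(diff$deletions), 1L)
  expect_equal(nrow(diff$amendments), 1L)
  expect_equal(nrow(diff$additions), 1L)

  # equals the same operations applied individually in the stated order
  map2 <- linkage_map()
  ingest_batch(map2, base, cfgd)
  delete_record(map2, "ds", "B", "individual")
  amend_record(map2, "ds", "C",
               list(given_name = "CLARA", surname = "NGUYEN", sex = "F",
                    dob = "1990-01-30", address = "5 STATION ST"), cfgd)
  ingest_batch(map2, person_row("D", "DENZEL", "MURRAY", "M", "1975-07-07",
                                "8 PALM TCE"), cfgd)
  expect_identical(canonical_partition(group_membership(map)),
                   canonical_partition(group_membership(map2)))
})

test_that("reconcile infers a diff when no action column is present", {
  cfgd <- default_linkage_config()
  base <- rbind(
    person_row("A", "ALICE", "THOMPSON", "F", "1970-05-05", "3 YORK ST"),
    person_row("B", "BORIS", "KHAN", "M", "1982-09-12", "7 HIGH ST"))
  map <- linkage_map()
  ingest_batch(map, base, cfgd)
  len <- length(map$log)

  resend <- rbind(
    base[1, ],                                                     # unchanged
    person_row("B", "BORIS", "KHAN", "M", "1982-09-12", "1 NEW ST"), # changed
    person_row("E", "ERICA", "WATSON", "F", "1999-03-03", "4 MULGA ST")) # new
  diff <- reconcile_open_batch(map, resend, cfgd, "inferred")
  expect_equal(nrow(diff$deletions), 0L)
  expect_equal(nrow(diff$amendments), 1L)
  expect_equal(diff$amendments$source_record_id, "B")
  expect_equal(nrow(diff$additions), 1L)
  # the unchanged resend produced no events at all
  touching_A <- Filter(function(e) e$seq > len, record_history(map, "ds", "A"))
  expect_length(touching_A, 0L)
})

test_that("a bad row rejects the whole reconcile batch before any mutation", {
  cfgd <- default_linkage_config()
  map <- linkage_map()
  ingest_batch(map, person_row("A", "ALICE", "THOMPSON", "F", "1970-05-05",
                               "3 YORK ST"), cfgd)
  len <- length(map$log)
  batch <- rbind(
    cbind(person_row("A", "", "", "", "", ""), `_action` = "delete"),
    cbind(person_row("GHOST", "", "", "", "", ""), `_action` = "delete"))
  expect_error(reconcile_open_batch(map, batch, cfgd),
               class = "ongolink_validation_error")
  expect_length(map$log, len)
  rec <- map$state$records
  expect_equal(rec$status[rec$source_record_id == "A"], "live")
})
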