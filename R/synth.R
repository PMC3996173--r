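# Synthetic population, record, and scenario generator with ground truth.
# Emulates a population of persons who each generate records in one or more
# datasets over time, with field corruption (typos, missing values, day/month
# and name-field transpositions) and legitimate changes (surname and address
# changes), plus batch scripts of additions, amendments and deletions. Every
# emitted record carries a truth identifier, enabling pairwise precision and
# recall evaluation of any linkage run without real data.

pool_path <- function(file) system.file("extdata", file, package = "ongolink")

load_pool <- function(file) {
  utils::read.csv(pool_path(file), colClasses = "character")
}

#' Corruption model for synthetic records
#'
#' @param typo_rate Per-field probability of a single-character edit
#'   (substitute / insert / delete / transpose, uniformly chosen).
#' @param missing_rate Per-field probability the value is blanked.
#' @param transposition_rate Per-record probability of a structural swap:
#'   day/month of the date of birth, or given name/surname.
#' @param seed Integer seed; every generator operation is deterministic
#'   given the model's seed.
#' @return A `corruption_model` list.
#' @export
corruption_model <- function(typo_rate = 0, missing_rate = 0,
                             transposition_rate = 0, seed = 1L) {
  stopifnot(typo_rate >= 0, typo_rate <= 1, missing_rate >= 0,
            missing_rate <= 1, transposition_rate >= 0, transposition_rate <= 1)
  structure(list(typo_rate = typo_rate, missing_rate = missing_rate,
                 transposition_rate = transposition_rate,
                 seed = as.integer(seed)),
            class = "corruption_model")
}

typo_once <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(x)
  op <- sample(c("substitute", "insert", "delete", "transpose"), 1L)
  pos <- sample.int(n, 1L)
  alphabet <- LETTERS
  out <- switch(op,
    substitute = { chars[pos] <- sample(setdiff(alphabet, chars[pos]), 1L); chars },
    insert = append(chars, sample(alphabet, 1L), after = pos),
    delete = if (n > 1L) chars[-pos] else chars,
    transpose = {
      if (n > 1L) {
        p <- min(pos, n - 1L)
        tmp <- chars[p]; chars[p] <- chars[p + 1L]; chars[p + 1L] <- tmp
      }
      chars
    })
  paste0(out, collapse = "")
}

random_dob <- function(n) {
  format(as.Date("1920-01-01") + sample.int(31000L, n, replace = TRUE) - 1L,
         "%Y-%m-%d")
}

random_address <- function(n, streets) {
  paste(sample.int(200L, n, replace = TRUE),
        sample(streets, n, replace = TRUE))
}

# would these two identities be confusable under the default comparators?
# (same surname, agreeing date of birth, similar given name)
confusable <- function(given_a, surname_a, dob_a, given_b, surname_b, dob_b) {
  surname_a == surname_b &&
    isTRUE(date_parts_agree(dob_a, dob_b)) &&
    jaro_winkler(given_a, given_b) >= 0.85
}

#' Generate a synthetic population with ground truth
#'
#' Names and addresses are drawn from small bundled frequency lists. A
#' configurable fraction of persons share a surname or date of birth with an
#' earlier person, creating plausible near-matches; identities are kept
#' distinct (no two persons are confusable under the bundled default
#' comparators), so with zero corruption the truth partition is recoverable.
#' A fraction of persons carry life events (surname or address changes) that
#' scenario amendments can apply.
#'
#' @param n Number of persons.
#' @param seed Integer seed; the population is deterministic given the seed.
#' @param shared_surname_frac Fraction of persons reusing an earlier person's
#'   surname.
#' @param shared_dob_frac Fraction reusing an earlier person's date of birth.
#' @param surname_change_prob,address_change_prob Probability a person
#'   carries that life event.
#' @return A data frame of class `synthetic_population` with columns
#'   `person_id`, `given_name`, `surname`, `sex`, `dob`, `address`, and a
#'   `"life_events"` attribute (named list person_id -> ordered list of
#'   `(type, value)` changes).
#' @export
generate_population <- function(n, seed = 1L,
                                shared_surname_frac = 0.15,
                                shared_dob_frac = 0.05,
                                surname_change_prob = 0.2,
                                address_change_prob = 0.3) {
  stopifnot(n >= 0)
  set.seed(seed)
  givens <- load_pool("given_names.csv")
  surnames <- load_pool("surnames.csv")
  streets <- load_pool("streets.csv")$name
  out <- data.frame(person_id = character(0), given_name = character(0),
                    surname = character(0), sex = character(0),
                    dob = character(0), address = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(out, "life_events") <- list()
    class(out) <- c("synthetic_population", class(out))
    return(out)
  }
  pg <- as.numeric(givens$freq); ps <- as.numeric(surnames$freq)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      surname <- if (i > 1L && stats::runif(1) < shared_surname_frac) {
        rows[[sample.int(i - 1L, 1L)]]$surname
      } else sample(surnames$name, 1L, prob = ps)
      dob <- if (i > 1L && stats::runif(1) < shared_dob_frac) {
        rows[[sample.int(i - 1L, 1L)]]$dob
      } else random_dob(1L)
      given <- sample(givens$name, 1L, prob = pg)
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        if (confusable(given, surname, dob,
                       rows[[j]]$given_name, rows[[j]]$surname, rows[[j]]$dob)) {
          clash <- TRUE; break
        }
      }
      if (!clash) break
    }
    repeat {
      address <- random_address(1L, streets)
      if (!address %in% vapply(rows[seq_len(i - 1L)],
                               function(r) r$address, "")) break
    }
    rows[[i]] <- list(person_id = sprintf("p%04d", i), given_name = given,
                      surname = surname, sex = sample(c("M", "F"), 1L),
                      dob = dob, address = address)
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  life <- stats::setNames(vector("list", n), out$person_id)
  for (i in seq_len(n)) {
    ev <- list()
    if (stats::runif(1) < surname_change_prob) {
      new_surname <- sample(surnames$name, 1L, prob = ps)
      ev[[length(ev) + 1L]] <- list(type = "surname", value = new_surname)
    }
    if (stats::runif(1) < address_change_prob) {
      repeat {
        new_address <- random_address(1L, streets)
        if (!new_address %in% out$address) break
      }
      ev[[length(ev) + 1L]] <- list(type = "address", value = new_address)
    }
    life[[i]] <- ev
  }
  attr(out, "life_events") <- life
  class(out) <- c("synthetic_population", class(out))
  out
}

corrupt_record <- function(row, model) {
  fields <- c("given_name", "surname", "sex", "dob", "address")
  if (stats::runif(1) < model$transposition_rate) {
    if (stats::runif(1) < 0.5) {
      p <- date_parts_split(row$dob)
      row$dob <- paste(p[1], p[3], p[2], sep = "-")
    } else {
      tmp <- row$given_name; row$given_name <- row$surname; row$surname <- tmp
    }
  }
  for (f in fields) {
    if (stats::runif(1) < model$typo_rate) {
      if (f == "dob") {
        # digit typo in one date component
        d <- strsplit(row$dob, "", fixed = TRUE)[[1]]
        pos <- sample(setdiff(seq_along(d), c(5L, 8L)), 1L)
        d[pos] <- sample(setdiff(as.character(0:9), d[pos]), 1L)
        row$dob <- paste0(d, collapse = "")
      } else {
        row[[f]] <- typo_once(row[[f]])
      }
    }
  }
  for (f in fields) {
    if (stats::runif(1) < model$missing_rate) row[[f]] <- ""
  }
  row
}

#' Emit corrupted records for a dataset, with a truth map
#'
#' Each covered person emits `records_per_person` records with fields
#' corrupted per the model. Output rows use the same CSV dialect the
#' pipeline ingests (columns `source_id`, `given_name`, `surname`, `sex`,
#' `dob`, `address`); the truth map gives the generating person of every
#' emitted record. Deterministic given the model's seed.
#'
#' @param population A [generate_population()] result.
#' @param dataset_id Dataset identifier (also prefixes source ids).
#' @param corruption A [corruption_model()].
#' @param coverage Probability each person appears in this dataset.
#' @param records_per_person Records emitted per covered person.
#' @return A list: `rows` (raw CSV-dialect data frame), `truth` (data frame
#'   `dataset_id`, `source_record_id`, `person_id`).
#' @export
emit_records <- function(population, dataset_id, corruption = corruption_model(),
                         coverage = 1, records_per_person = 1L) {
  set.seed(corruption$seed + 1000L * nchar(dataset_id) +
             sum(utf8ToInt(dataset_id)))
  rows <- list(); truth <- list()
  k <- 0L
  for (i in seq_len(nrow(population))) {
    if (stats::runif(1) >= coverage) next
    for (r in seq_len(records_per_person)) {
      k <- k + 1L
      base <- as.list(population[i, c("given_name", "surname", "sex", "dob", "address")])
      rec <- corrupt_record(base, corruption)
      sid <- sprintf("%s-%05d", dataset_id, k)
      rows[[k]] <- data.frame(source_id = sid, given_name = rec$given_name,
                              surname = rec$surname, sex = rec$sex,
                              dob = rec$dob, address = rec$address,
                              stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(dataset_id = dataset_id, source_record_id = sid,
                               person_id = population$person_id[i],
                               stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(list(rows = data.frame(source_id = character(0), given_name = character(0),
                                  surname = character(0), sex = character(0),
                                  dob = character(0), address = character(0),
                                  stringsAsFactors = FALSE),
                truth = data.frame(dataset_id = character(0),
                                   source_record_id = character(0),
                                   person_id = character(0), stringsAsFactors = FALSE)))
  }
  list(rows = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Script a multi-batch scenario of additions, amendments and deletions
#'
#' Partitions the population's records over ordered batches: batch 1 is pure
#' additions; later batches mix additions of remaining persons with
#' amendments (applying a person's next life event, or re-emitting corrected
#' fields) and deletions of previously emitted records. Batch files carry an
#' `_action` column and use the pipeline's CSV dialect. Replaying with the
#' same seed yields identical batches.
#'
#' @param population A [generate_population()] result.
#' @param n_batches Number of batches (>= 1).
#' @param dataset_id Dataset identifier.
#' @param p_amend,p_delete Per-batch fraction of previously live records
#'   amended / deleted (batches after the first).
#' @param corruption A [corruption_model()]; its seed drives the script.
#' @return A list of class `scenario_script`: `batches` (list of data
#'   frames, each with `_action`), `truth` (record-level truth map),
#'   `dataset_id`.
#' @export
script_scenario <- function(population, n_batches, dataset_id = "ds1",
                            p_amend = 0.1, p_delete = 0.05,
                            corruption = corruption_model()) {
  stopifnot(n_batches >= 1L)
  if (n_batches == 1L && p_delete > 0) {
    ongolink_stop("deletions require at least one prior batch",
                  "ongolink_spec_error")
  }
  set.seed(corruption$seed)
  n <- nrow(population)
  batch_of <- sort(rep_len(seq_len(n_batches), n))
  life <- attr(population, "life_events")
  life_cursor <- stats::setNames(rep(1L, n), population$person_id)
  live <- data.frame(source_record_id = character(0), person_id = character(0),
                     given_name = character(0), surname = character(0),
                     sex = character(0), dob = character(0),
                     address = character(0), stringsAsFactors = FALSE)
  batches <- list(); truth <- list()
  k <- 0L
  emit_row <- function(person_row, sid, action) {
    rec <- corrupt_record(as.list(person_row[c("given_name", "surname", "sex",
                                               "dob", "address")]), corruption)
    data.frame(source_id = sid, given_name = rec$given_name,
               surname = rec$surname, sex = rec$sex, dob = rec$dob,
               address = rec$address, `_action` = action,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (b in seq_len(n_batches)) {
    rows <- list()
    # deletions and amendments of previously emitted records
    if (b > 1L && nrow(live)) {
      n_del <- min(nrow(live), round(p_delete * nrow(live)))
      del_idx <- if (n_del) sample.int(nrow(live), n_del) else integer(0)
      for (di in del_idx) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = live$source_record_id[di], given_name = "", surname = "",
          sex = "", dob = "", address = "", `_action` = "delete",
          stringsAsFactors = FALSE, check.names = FALSE)
      }
      keep <- setdiff(seq_len(nrow(live)), del_idx)
      n_amd <- min(length(keep), round(p_amend * nrow(live)))
      amd_idx <- if (n_amd) sample(keep, n_amd) else integer(0)
      for (ai in amd_idx) {
        pid <- live$person_id[ai]
        pe <- life[[pid]]
        cur <- live[ai, ]
        if (length(pe) >= life_cursor[pid]) {
          change <- pe[[life_cursor[pid]]]
          life_cursor[pid] <- life_cursor[pid] + 1L
          if (change$type == "surname") cur$surname <- change$value
          if (change$type == "address") cur$address <- change$value
        } else {
          # correction: re-emit the person's true current fields
          base <- population[population$person_id == pid, ]
          cur$given_name <- base$given_name; cur$sex <- base$sex
          cur$dob <- base$dob
        }
        live[ai, c("given_name", "surname", "sex", "dob", "address")] <-
          cur[c("given_name", "surname", "sex", "dob", "address")]
        rows[[length(rows) + 1L]] <- emit_row(cur, cur$source_record_id, "amend")
      }
      if (length(del_idx)) live <- live[-del_idx, , drop = FALSE]
    }
    # additions of this batch's persons
    for (i in which(batch_of == b)) {
      k <- k + 1L
      sid <- sprintf("%s-%05d", dataset_id, k)
      p <- population[i, ]
      rows[[length(rows) + 1L]] <- emit_row(p, sid, "add")
      live <- rbind(live, data.frame(
        source_record_id = sid, person_id = p$person_id,
        given_name = p$given_name, surname = p$surname, sex = p$sex,
        dob = p$dob, address = p$address, stringsAsFactors = FALSE))
      truth[[k]] <- data.frame(dataset_id = dataset_id, source_record_id = sid,
                               person_id = p$person_id, stringsAsFactors = FALSE)
    }
    batches[[b]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source_id = character(0), given_name = character(0),
                 surname = character(0), sex = character(0),
                 dob = character(0), address = character(0),
                 `_action` = character(0), stringsAsFactors = FALSE,
                 check.names = FALSE)
  }
  structure(list(batches = batches,
                 truth = do.call(rbind, truth),
                 dataset_id = dataset_id),
            class = "scenario_script")
}

#' Pairwise precision, recall and F1 against ground truth
#'
#' Computes record-pair precision (pairs grouped together that are truly the
#' same person, over all pairs grouped together) and recall (over all true
#' same-person pairs among the evaluated records). With zero predicted pairs
#' precision is reported as 1.0 with an explicit `zero_predicted` flag
#' (likewise recall with zero truth pairs).
#'
#' @param keys Data frame `dataset_id`, `source_record_id`, `group_id` (a
#'   key file or [group_membership()] output).
#' @param truth Data frame `dataset_id`, `source_record_id`, `person_id`.
#' @return A list: `precision`, `recall`, `f1`, `n_predicted_pairs`,
#'   `n_truth_pairs`, `n_true_positive`, `zero_predicted`, `zero_truth`.
#' @export
evaluate_linkage <- function(keys, truth) {
  key_id <- paste(keys$dataset_id, keys$source_record_id, sep = "\r")
  truth_id <- paste(truth$dataset_id, truth$source_record_id, sep = "\r")
  unknown <- setdiff(key_id, truth_id)
  if (length(unknown)) {
    ongolink_stop(paste0("records absent from truth map: ",
                         paste(gsub("\r", "/", unknown), collapse = ", ")),
                  "ongolink_not_found_error")
  }
  person <- truth$person_id[match(key_id, truth_id)]
  choose2 <- function(x) sum(x * (x - 1) / 2)
  p_pairs <- choose2(table(keys$group_id))
  t_pairs <- choose2(table(person))
  tp <- choose2(table(paste(keys$group_id, person, sep = "\r")))
  zero_p <- p_pairs == 0; zero_t <- t_pairs == 0
  precision <- if (zero_p) 1.0 else tp / p_pairs
  recall <- if (zero_t) 1.0 else tp / t_pairs
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_predicted_pairs = unname(p_pairs), n_truth_pairs = unname(t_pairs),
       n_true_positive = unname(tp),
       zero_predicted = zero_p, zero_truth = zero_t)
}
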