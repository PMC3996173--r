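# Linkage configuration: field comparator specs, m/u probabilities, blocking
# passes, thresholds and strategy flags. A config is an ordinary list with
# class "linkage_config" so it serialises cleanly to YAML.

#' Declare one identifying field for probabilistic comparison
#'
#' @param name Field name; must match a column of the cleaned dataset schema.
#' @param comparator One of `"exact"`, `"truncated"`, `"approximate"`,
#'   `"date_parts"`.
#' @param m_prob Probability the field agrees among true matches (the
#'   Fellegi-Sunter m probability), in (0, 1).
#' @param u_prob Probability the field agrees among non-matches (u
#'   probability), in (0, 1). Must satisfy `u_prob < m_prob`.
#' @param k Truncation length for the `truncated` comparator (>= 1).
#' @param sim_threshold Similarity threshold in \[0, 1\] for the
#'   `approximate` comparator.
#' @param method String-similarity function for the `approximate` comparator:
#'   `"jaro_winkler"` or `"levenshtein"`.
#' @param missing_policy How a missing comparison contributes to the pair
#'   weight; only `"zero_weight"` is defined.
#' @return A `field_spec` list.
#' @export
field_spec <- function(name,
                       comparator = c("exact", "truncated", "approximate", "date_parts"),
                       m_prob, u_prob,
                       k = NULL, sim_threshold = NULL,
                       method = "jaro_winkler",
                       missing_policy = "zero_weight") {
  comparator <- match.arg(comparator)
  stopifnot(is_string(name))
  if (!(is.numeric(m_prob) && is.numeric(u_prob) &&
        u_prob > 0 && m_prob < 1 && u_prob < m_prob)) {
    ongolink_stop(
      sprintf("field '%s': require 0 < u_prob < m_prob < 1", name),
      "ongolink_config_error"
    )
  }
  cmp <- list(type = comparator)
  if (comparator == "truncated") {
    if (is.null(k) || k < 1) {
      ongolink_stop(sprintf("field '%s': truncated comparator requires k >= 1", name),
                    "ongolink_config_error")
    }
    cmp$k <- as.integer(k)
  }
  if (comparator == "approximate") {
    if (is.null(sim_threshold) || sim_threshold < 0 || sim_threshold > 1) {
      ongolink_stop(
        sprintf("field '%s': approximate comparator requires sim_threshold in [0,1]", name),
        "ongolink_config_error"
      )
    }
    cmp$sim_threshold <- sim_threshold
    cmp$method <- match.arg(method, c("jaro_winkler", "levenshtein"))
  }
  structure(
    list(name = name, comparator = cmp,
         m_prob = m_prob, u_prob = u_prob,
         missing_policy = match.arg(missing_policy, "zero_weight")),
    class = "field_spec"
  )
}

#' Declare one blocking pass
#'
#' A blocking pass derives one key string per record from an ordered list of
#' field transforms; only record pairs sharing a key in at least one pass are
#' compared. A pass whose components are all missing yields a no-key sentinel
#' that never matches any key.
#'
#' @param ... Transforms, each a list with elements `field` (name), `op`
#'   (`"full"`, `"prefix"`, `"initial"`, `"year"`, or `"constant"`), and for
#'   `prefix` an integer `k`.
#' @return A `blocking_pass` list of transforms.
#' @export
blocking_pass <- function(...) {
  transforms <- list(...)
  stopifnot(length(transforms) >= 1L)
  for (tr in transforms) {
    op <- tr$op %||% "full"
    if (!op %in% c("full", "prefix", "initial", "year", "constant")) {
      ongolink_stop(paste0("unknown blocking transform op: ", op),
                    "ongolink_config_error")
    }
    if (op != "constant" && !is_string(tr$field)) {
      ongolink_stop("blocking transform requires a field name",
                    "ongolink_config_error")
    }
  }
  structure(transforms, class = "blocking_pass")
}

#' Assemble a linkage configuration
#'
#' @param fields List of [field_spec()]s (at least one).
#' @param blocking_passes List of [blocking_pass()]es (at least one).
#' @param upper_threshold Pair weight (log2 units) at or above which a pair is
#'   classified a match.
#' @param lower_threshold Pair weight below which a pair is a non-match;
#'   weights in `[lower, upper)` are "possible" matches.
#' @param candidate_scope `"all_records"` (compare incoming records against
#'   every live record sharing a blocking key) or `"most_recent_per_group"`
#'   (only against the most recently added live record of each group).
#' @param grouping_strategy `"merge_allowed"` (groups are the transitive
#'   closure of accepted pairs; accepting a pair may merge two groups) or
#'   `"best_link"` (an incoming record joins only its single best-matching
#'   group and can never merge two existing groups).
#' @param possible_policy How "possible" pairs are resolved in the absence of
#'   clerical review: `"treat_as_nonmatch"` (default) or `"treat_as_match"`.
#' @return A `linkage_config` object.
#' @export
linkage_config <- function(fields, blocking_passes,
                           upper_threshold, lower_threshold,
                           candidate_scope = c("all_records", "most_recent_per_group"),
                           grouping_strategy = c("merge_allowed", "best_link"),
                           possible_policy = c("treat_as_nonmatch", "treat_as_match")) {
  if (length(fields) < 1L || length(blocking_passes) < 1L) {
    ongolink_stop("config requires at least one field and one blocking pass",
                  "ongolink_config_error")
  }
  if (lower_threshold > upper_threshold) {
    ongolink_stop("lower_threshold must be <= upper_threshold",
                  "ongolink_config_error")
  }
  field_names <- vapply(fields, function(f) f$name, "")
  if (anyDuplicated(field_names)) {
    ongolink_stop("duplicate field names in config", "ongolink_config_error")
  }
  for (bp in blocking_passes) {
    for (tr in bp) {
      if ((tr$op %||% "full") != "constant" && !tr$field %in% field_names) {
        ongolink_stop(paste0("blocking transform references unknown field: ", tr$field),
                      "ongolink_config_error")
      }
    }
  }
  structure(
    list(
      fields = fields,
      blocking_passes = blocking_passes,
      upper_threshold = upper_threshold,
      lower_threshold = lower_threshold,
      candidate_scope = match.arg(candidate_scope),
      grouping_strategy = match.arg(grouping_strategy),
      possible_policy = match.arg(possible_policy)
    ),
    class = "linkage_config"
  )
}

config_field_names <- function(config) vapply(config$fields, function(f) f$name, "")

#' @export
print.linkage_config <- function(x, ...) {
  cat("<linkage_config>\n")
  cat(sprintf("  fields: %s\n", paste(config_field_names(x), collapse = ", ")))
  cat(sprintf("  blocking passes: %d\n", length(x$blocking_passes)))
  cat(sprintf("  thresholds (log2): lower %.3g / upper %.3g\n",
              x$lower_threshold, x$upper_threshold))
  cat(sprintf("  strategy: %s, scope: %s, possible: %s\n",
              x$grouping_strategy, x$candidate_scope, x$possible_policy))
  invisible(x)
}

#' Read / write a linkage configuration as YAML
#'
#' @param path File path.
#' @return `read_linkage_config()` returns a [linkage_config()];
#'   `write_linkage_config()` returns `path` invisibly.
#' @export
read_linkage_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fields <- lapply(raw$fields, function(f) {
    field_spec(
      name = f$name,
      comparator = f$comparator,
      m_prob = f$m_prob, u_prob = f$u_prob,
      k = f$k, sim_threshold = f$sim_threshold,
      method = f$method %||% "jaro_winkler",
      missing_policy = f$missing_policy %||% "zero_weight"
    )
  })
  passes <- lapply(raw$blocking_passes, function(p) do.call(blocking_pass, p))
  linkage_config(
    fields = fields, blocking_passes = passes,
    upper_threshold = raw$upper_threshold,
    lower_threshold = raw$lower_threshold,
    candidate_scope = raw$candidate_scope %||% "all_records",
    grouping_strategy = raw$grouping_strategy %||% "merge_allowed",
    possible_policy = raw$possible_policy %||% "treat_as_nonmatch"
  )
}

#' @rdname read_linkage_config
#' @param config A [linkage_config()].
#' @export
write_linkage_config <- function(config, path) {
  raw <- list(
    fields = lapply(config$fields, function(f) {
      out <- list(name = f$name, comparator = f$comparator$type,
                  m_prob = f$m_prob, u_prob = f$u_prob)
      out$k <- f$comparator$k
      out$sim_threshold <- f$comparator$sim_threshold
      out$method <- f$comparator$method
      out$missing_policy <- f$missing_policy
      out[!vapply(out, is.null, TRUE)]
    }),
    blocking_passes = lapply(config$blocking_passes, function(p) {
      lapply(unclass(p), function(tr) tr[!vapply(tr, is.null, TRUE)])
    }),
    upper_threshold = config$upper_threshold,
    lower_threshold = config$lower_threshold,
    candidate_scope = config$candidate_scope,
    grouping_strategy = config$grouping_strategy,
    possible_policy = config$possible_policy
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Bundled default linkage configuration
#'
#' The configuration used throughout the package's examples and the synthetic
#' study conditions: Jaro-Winkler comparators on names, component-wise date
#' comparison on date of birth, exact comparison on sex and address, five
#' blocking passes (surname prefix + birth year, full date of birth, given
#' name prefix + birth year, surname prefix + given prefix, full address),
#' and log2 thresholds 12 (match) / 6 (possible). Every high-weight field
#' features in at least one pass, so a true-match pair only evades
#' comparison when several fields are corrupted at once.
#'
#' @param grouping_strategy,candidate_scope,possible_policy Overrides passed
#'   to [linkage_config()].
#' @return A [linkage_config()].
#' @export
default_linkage_config <- function(grouping_strategy = "merge_allowed",
                                   candidate_scope = "all_records",
                                   possible_policy = "treat_as_nonmatch") {
  linkage_config(
    fields = list(
      field_spec("given_name", "approximate", m_prob = 0.92, u_prob = 0.04,
                 sim_threshold = 0.85, method = "jaro_winkler"),
      field_spec("surname", "approximate", m_prob = 0.95, u_prob = 0.02,
                 sim_threshold = 0.88, method = "jaro_winkler"),
      field_spec("dob", "date_parts", m_prob = 0.97, u_prob = 0.004),
      field_spec("sex", "exact", m_prob = 0.98, u_prob = 0.5),
      field_spec("address", "exact", m_prob = 0.75, u_prob = 0.01)
    ),
    blocking_passes = list(
      blocking_pass(list(field = "surname", op = "prefix", k = 2L),
                    list(field = "dob", op = "year")),
      blocking_pass(list(field = "dob", op = "full")),
      blocking_pass(list(field = "given_name", op = "prefix", k = 2L),
                    list(field = "dob", op = "year")),
      blocking_pass(list(field = "surname", op = "prefix", k = 2L),
                    list(field = "given_name", op = "prefix", k = 2L)),
      blocking_pass(list(field = "address", op = "full"))
    ),
    upper_threshold = 12, lower_threshold = 6,
    candidate_scope = candidate_scope,
    grouping_strategy = grouping_strategy,
    possible_policy = possible_policy
  )
}
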