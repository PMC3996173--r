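# Field comparators: the primitives that turn a pair of field values into
# agree / disagree / missing. All comparators treat NA on either side as
# missing; the weight of a missing comparison is decided by the scoring
# step (zero under the `zero_weight` policy).

#' Jaro similarity between two strings
#'
#' @param a,b Character scalars.
#' @return Similarity in \[0, 1\]; 1 for identical strings, 0 when either is
#'   empty or no characters match.
#' @keywords internal
jaro_similarity <- function(a, b) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(sa); lb <- length(sb)
  if (la == 0L || lb == 0L) return(0)
  window <- max(0L, max(la, lb) %/% 2L - 1L)
  matched_b <- logical(lb)
  ma <- integer(0)   # indices into sa of matched chars, in order of sa
  mb_for_a <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!matched_b[j] && sa[i] == sb[j]) {
        matched_b[j] <- TRUE
        ma <- c(ma, i)
        break
      }
    }
  }
  m <- length(ma)
  if (m == 0L) return(0)
  # transpositions: compare matched characters in order of each string
  t_half <- sum(sa[ma] != sb[which(matched_b)]) / 2
  (m / la + m / lb + (m - t_half) / m) / 3
}

#' Jaro-Winkler similarity
#'
#' The standard name comparator in probabilistic record linkage: the Jaro
#' similarity boosted for a shared prefix of up to four characters.
#'
#' @param a,b Character vectors (recycled to common length).
#' @param prefix_scale Winkler prefix scaling factor, default 0.1.
#' @return Numeric vector of similarities in \[0, 1\]; `NA` where either
#'   input is `NA`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")   # 0.9611...
#' jaro_winkler("DIXON", "DICKSONX")  # 0.8133...
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    if (is.na(a[i]) || is.na(b[i])) return(NA_real_)
    j <- jaro_similarity(a[i], b[i])
    sa <- strsplit(a[i], "", fixed = TRUE)[[1]]
    sb <- strsplit(b[i], "", fixed = TRUE)[[1]]
    l <- 0L
    for (k in seq_len(min(4L, length(sa), length(sb)))) {
      if (sa[k] == sb[k]) l <- l + 1L else break
    }
    j + l * prefix_scale * (1 - j)
  }, numeric(1))
}

#' Normalised Levenshtein similarity
#'
#' `1 - edit_distance / max(nchar)`, with the edit distance computed by
#' [utils::adist()].
#'
#' @param a,b Character vectors.
#' @return Numeric vector of similarities in \[0, 1\]; `NA` where either
#'   input is `NA`.
#' @export
levenshtein_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(a) & !is.na(b)
  if (any(ok)) {
    d <- mapply(function(x, y) utils::adist(x, y)[1, 1], a[ok], b[ok])
    denom <- pmax(nchar(a[ok]), nchar(b[ok]), 1L)
    out[ok] <- 1 - d / denom
  }
  out
}

string_similarity <- function(a, b, method = c("jaro_winkler", "levenshtein")) {
  method <- match.arg(method)
  switch(method,
    jaro_winkler = jaro_winkler(a, b),
    levenshtein  = levenshtein_similarity(a, b)
  )
}

# split ISO "YYYY-MM-DD" into its parts; non-conforming values yield NAs
date_parts_split <- function(x) {
  m <- regmatches(x, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", x))
  t(vapply(m, function(g) {
    if (length(g) == 4L) g[2:4] else rep(NA_character_, 3L)
  }, character(3)))
}

#' Date-parts agreement
#'
#' Compares two ISO dates component-wise: the pair agrees when at least two of
#' \{year, month, day\} are equal, or when the year is equal and day and month
#' are transposed. This tolerates single-component typos and day/month swaps,
#' the dominant error modes in recorded dates of birth.
#'
#' @param a,b Character vectors of ISO `YYYY-MM-DD` dates.
#' @return Logical vector; `NA` where either side is `NA` or unparseable.
#' @export
date_parts_agree <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  pa <- date_parts_split(a); pb <- date_parts_split(b)
  bad <- is.na(pa[, 1]) | is.na(pb[, 1])
  eq <- (pa == pb)
  n_eq <- rowSums(eq)
  swapped <- eq[, 1] & pa[, 2] == pb[, 3] & pa[, 3] == pb[, 2]
  out <- n_eq >= 2 | swapped
  out[bad] <- NA
  out
}

#' Compare one field across a vectorised set of value pairs
#'
#' @param va,vb Character vectors of field values for the two sides of each
#'   pair.
#' @param spec A [field_spec()].
#' @return Character vector over `{"agree", "disagree", "missing"}`.
#' @keywords internal
compare_field <- function(va, vb, spec) {
  n <- max(length(va), length(vb))
  va <- rep_len(as.character(va), n); vb <- rep_len(as.character(vb), n)
  miss <- is.na(va) | is.na(vb) | va == "" | vb == ""
  agree <- rep(FALSE, n)
  cmp <- spec$comparator
  ok <- !miss
  if (any(ok)) {
    agree[ok] <- switch(cmp$type,
      exact = va[ok] == vb[ok],
      truncated = substr(va[ok], 1L, cmp$k) == substr(vb[ok], 1L, cmp$k),
      approximate = {
        s <- string_similarity(va[ok], vb[ok], cmp$method)
        !is.na(s) & s >= cmp$sim_threshold
      },
      date_parts = {
        g <- date_parts_agree(va[ok], vb[ok])
        miss[ok][is.na(g)] <- TRUE
        isTRUE_v <- !is.na(g) & g
        isTRUE_v
      },
      stop("unknown comparator type: ", cmp$type)
    )
  }
  out <- ifelse(miss, "missing", ifelse(agree, "agree", "disagree"))
  out
}
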