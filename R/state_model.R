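# Core domain vocabulary: health states, age-group scheme, record and
# matrix-set containers with their file formats.

# Death is the absorbing state appended after the six morbidity states.
DEATH_STATE <- 7L
SEXES <- c("female", "male")

#' Labels of the six health states plus death
#'
#' The state space is a six-category aggregation of the Clinical Risk
#' Groups (CRG) health-status classification, plus death as a final
#' absorbing state (code 7). Codes 1..6 order the states from healthy to
#' dominant/metastatic malignancies.
#'
#' @return Character vector of length 7, names `"1"`..`"7"`.
#' @export
#' @examples
#' health_state_labels()[1]
health_state_labels <- function() {
  c("1" = "Healthy",
    "2" = "Significant acute disease",
    "3" = "Minor chronic disease",
    "4" = "Significant chronic disease in one or two organ systems",
    "5" = "Significant chronic disease in three or more organ systems - Catastrophic conditions",
    "6" = "Dominant and metastatic malignancies",
    "7" = "Death")
}

#' Labels of the nine original CRG health-status categories
#'
#' @return Character vector of length 9, names `"1"`..`"9"`.
#' @export
crg9_labels <- function() {
  c("1" = "Healthy",
    "2" = "History of significant acute disease",
    "3" = "Single minor chronic disease",
    "4" = "Minor chronic disease in multiple organ systems",
    "5" = "Single dominant or moderate chronic disease",
    "6" = "Significant chronic disease in multiple organ systems",
    "7" = "Dominant chronic disease in three or more organ systems",
    "8" = "Dominant and metastatic malignancies",
    "9" = "Catastrophic conditions")
}

#' Default CRG 9-category to 6-state cross-walk
#'
#' The label-consistent mapping of the nine CRG health-status categories
#' onto the six aggregated states: categories 3 and 4 (single/multiple
#' minor chronic disease) fold into state 3, categories 5 and 6 into
#' state 4, categories 7 and 9 (dominant chronic in three or more organ
#' systems, catastrophic conditions) into the composite state 5, and
#' category 8 (dominant and metastatic malignancies) stands alone as
#' state 6.
#'
#' @return Integer vector of length 9; position k holds the aggregated
#'   state for CRG category k.
#' @export
default_crg_map <- function() {
  c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 5L)
}

#' Aggregate raw CRG status codes to the six-state scheme
#'
#' @param crg9 Integer vector of CRG health-status categories in 1..9.
#' @param map Integer vector of length 9 mapping each category to a
#'   state in 1..6; the default is [default_crg_map()]. Alternative
#'   cross-walks can be supplied, but must be total on 1..9 and
#'   surjective onto 1..6.
#' @return Integer vector of aggregated state codes in 1..6.
#' @export
#' @examples
#' aggregate_crg_status(c(1, 4, 8))
aggregate_crg_status <- function(crg9, map = default_crg_map()) {
  if (length(map) != 9L || !all(map %in% 1:6) || !all(1:6 %in% map)) {
    stop_validation("'map' must map categories 1..9 onto all states 1..6")
  }
  crg9 <- as_integerish(crg9, "crg9")
  bad <- which(is.na(crg9) | crg9 < 1L | crg9 > 9L)
  if (length(bad)) {
    stop_validation(sprintf(
      "CRG status code(s) outside 1..9: %s (position %s)",
      paste(crg9[bad], collapse = ", "), paste(bad, collapse = ", ")))
  }
  as.integer(map)[crg9]
}

#' Age-group scheme
#'
#' Half-open integer age intervals with one representative (midpoint)
#' age per group, used both to stratify transition counts and as the
#' interpolation knots when expanding group matrices to single years of
#' age. The default is the ten-group scheme <1, 1-14, 15-24, ...,
#' 75-84, >=85, with the open-ended last group pinned at age 90.
#'
#' @param breaks Increasing integer lower bounds of the groups; group g
#'   is `[breaks[g], breaks[g+1])` and the last group is open-ended.
#' @param midpoints Strictly increasing representative age per group, in
#'   years; `midpoints[g]` must lie inside group g.
#' @return An object of class `age_group_scheme`.
#' @export
#' @examples
#' sch <- age_group_scheme()
#' sch$labels
age_group_scheme <- function(breaks = c(0, 1, 15, 25, 35, 45, 55, 65, 75, 85),
                             midpoints = c(0.5, 8, 20, 30, 40, 50, 60, 70, 80, 90)) {
  if (length(breaks) != length(midpoints)) {
    stop_validation("'breaks' and 'midpoints' must have the same length")
  }
  if (is.unsorted(breaks, strictly = TRUE) || breaks[1] != 0) {
    stop_validation("'breaks' must be strictly increasing and start at 0")
  }
  if (is.unsorted(midpoints, strictly = TRUE)) {
    stop_validation("'midpoints' must be strictly increasing")
  }
  upper <- c(breaks[-1], Inf)
  if (any(midpoints < breaks)) {
    stop_validation("each midpoint must lie inside its group")
  }
  n <- length(breaks)
  labels <- sprintf("[%s,%s)", breaks, c(breaks[-1], "Inf"))
  structure(
    list(breaks = as.numeric(breaks), midpoints = as.numeric(midpoints),
         upper = upper, labels = labels, n_groups = n),
    class = "age_group_scheme")
}

#' Map integer ages to age-group indices
#'
#' @param age Integer vector of ages in years (>= 0).
#' @param scheme An [age_group_scheme()].
#' @return Integer group indices in `1..scheme$n_groups`.
#' @export
age_group_index <- function(age, scheme = age_group_scheme()) {
  age <- as_integerish(age, "age")
  if (any(is.na(age) | age < 0L)) stop_validation("ages must be nonnegative integers")
  findInterval(age, scheme$breaks)
}

#' @export
print.age_group_scheme <- function(x, ...) {
  cat("Age-group scheme:", x$n_groups, "groups\n")
  cat(" ", paste(sprintf("%s@%g", x$labels, x$midpoints), collapse = " "), "\n")
  invisible(x)
}

# ---- individual records ----------------------------------------------------

RECORD_COLUMNS <- c("person_id", "sex", "age", "state_t", "state_t1")

#' Validate individual two-year observation records
#'
#' A record holds one person's paired-year observation: sex, integer age
#' at baseline, health state at baseline (1..6) and state or death at
#' follow-up (1..7). Invalid rows are separated out with a per-row
#' diagnostic, never silently dropped.
#'
#' @param df A data.frame with columns `person_id`, `sex`, `age`,
#'   `state_t`, `state_t1`.
#' @return A list with `records` (the valid rows, types normalised) and
#'   `rejects` (data.frame of `row`, `reason`).
#' @export
validate_records <- function(df) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_validation(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(df)
  reason <- character(n)
  sex <- tolower(trimws(as.character(df$sex)))
  sex[sex %in% c("f", "female")] <- "female"
  sex[sex %in% c("m", "male")] <- "male"
  age <- suppressWarnings(as.numeric(df$age))
  state_t <- suppressWarnings(as.numeric(df$state_t))
  state_t1 <- suppressWarnings(as.numeric(df$state_t1))

  flag <- function(cond, msg) {
    idx <- which(cond & !nzchar(reason))
    reason[idx] <<- msg
  }
  flag(!sex %in% SEXES, "sex not 'female'/'male'")
  flag(is.na(age) | age < 0 | age != floor(age), "unparseable or negative age")
  flag(is.na(state_t) | !state_t %in% 1:6,
       "state_t outside 1..6 (baseline records cannot be dead)")
  flag(is.na(state_t1) | !state_t1 %in% 1:7, "state_t1 outside 1..7")

  keep <- !nzchar(reason)
  records <- data.frame(
    person_id = as.character(df$person_id)[keep],
    sex = sex[keep],
    age = as.integer(age[keep]),
    state_t = as.integer(state_t[keep]),
    state_t1 = as.integer(state_t1[keep]),
    stringsAsFactors = FALSE)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Read individual records from delimited text
#'
#' Expects a header row naming the five fields `person_id`, `sex`,
#' `age`, `state_t`, `state_t1` (any column order). Rows violating the
#' record invariants are rejected with a warning listing their row
#' numbers; the call fails only if no valid row remains in a non-empty
#' file.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default comma).
#' @return Data.frame of valid records, with attribute `"rejects"`
#'   holding the per-row diagnostics.
#' @export
read_records <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = TRUE)
  if (nrow(df) == 0L) {
    warning("no data rows in '", path, "': returning an empty record set")
    v <- validate_records(df[RECORD_COLUMNS[RECORD_COLUMNS %in% names(df)]][0, , drop = FALSE])
    return(structure(v$records, rejects = v$rejects))
  }
  v <- validate_records(df)
  if (nrow(v$rejects)) {
    warning(sprintf("rejected %d row(s): %s", nrow(v$rejects),
                    paste(sprintf("row %d (%s)", v$rejects$row, v$rejects$reason),
                          collapse = "; ")))
  }
  if (nrow(v$records) == 0L) {
    stop_validation(paste0("no valid rows in '", path, "'"))
  }
  structure(v$records, rejects = v$rejects)
}

#' Write individual records to delimited text
#'
#' @param records Data.frame of records (see [validate_records()]).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  utils::write.table(records[RECORD_COLUMNS], path, sep = delim,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- transition matrix sets ------------------------------------------------

#' Construct a set of annual transition matrices
#'
#' A matrix set holds one 7x7 row-stochastic matrix of annual transition
#' probabilities per (sex, age index), where the age index is either an
#' age-group number (`index_kind = "age_group"`) or a single year of age
#' (`index_kind = "single_year"`). Row 7 (death) is absorbing in every
#' matrix.
#'
#' @param matrices Nested list: `matrices[[sex]][[as.character(index)]]`
#'   is a 7x7 numeric matrix; sexes `"female"` and `"male"`.
#' @param index_kind `"age_group"` or `"single_year"`.
#' @param midpoints For `"age_group"` sets, the representative age of
#'   each group (used as interpolation knots); otherwise `NULL`.
#' @param states State labels (length 7).
#' @return An object of class `transition_matrix_set`.
#' @export
transition_matrix_set <- function(matrices, index_kind = c("age_group", "single_year"),
                                  midpoints = NULL, states = health_state_labels()) {
  index_kind <- match.arg(index_kind)
  x <- structure(
    list(index_kind = index_kind, states = unname(states),
         midpoints = midpoints, matrices = matrices),
    class = "transition_matrix_set")
  validate_matrix_set(x)
  x
}

#' Validate a transition matrix set
#'
#' Checks that every matrix is 7x7 with entries in \[0,1\], rows summing
#' to 1 within `tol`, and an absorbing death row.
#'
#' @param x A `transition_matrix_set`.
#' @param tol Row-sum tolerance (default 1e-9).
#' @return `x`, invisibly; errors name the first offending matrix/row.
#' @export
validate_matrix_set <- function(x, tol = 1e-9) {
  if (!all(names(x$matrices) %in% SEXES)) {
    stop_validation("matrix set sexes must be 'female'/'male'")
  }
  absorbing <- c(rep(0, 6), 1)
  for (sex in names(x$matrices)) {
    for (key in names(x$matrices[[sex]])) {
      m <- x$matrices[[sex]][[key]]
      where <- sprintf("(%s, age index %s)", sex, key)
      if (!is.matrix(m) || !all(dim(m) == c(7L, 7L))) {
        stop_validation(paste("matrix", where, "is not 7x7"))
      }
      if (any(m < 0 | m > 1)) {
        stop_validation(paste("matrix", where, "has entries outside [0,1]"))
      }
      rs <- rowSums(m)
      bad <- which(abs(rs - 1) > tol)
      if (length(bad)) {
        stop_validation(sprintf("matrix %s row %d sums to %.6g, not 1",
                                where, bad[1], rs[bad[1]]))
      }
      if (any(abs(m[7, ] - absorbing) > tol)) {
        stop_validation(paste("matrix", where, "death row is not absorbing"))
      }
    }
  }
  invisible(x)
}

#' Ages or group indices present in a matrix set
#'
#' @param x A `transition_matrix_set`.
#' @return Sorted integer indices common layout checks rely on.
#' @export
matrix_set_indices <- function(x) {
  sort(unique(as.integer(unlist(lapply(x$matrices, names)))))
}

#' @export
print.transition_matrix_set <- function(x, ...) {
  n <- sum(vapply(x$matrices, length, 1L))
  idx <- matrix_set_indices(x)
  cat(sprintf("Transition matrix set (%s): %d matrices, sexes {%s}, indices %d..%d\n",
              x$index_kind, n, paste(names(x$matrices), collapse = ", "),
              min(idx), max(idx)))
  invisible(x)
}

#' Write a transition matrix set to a structured-text file
#'
#' The file is a self-describing JSON document recording `index_kind`,
#' state labels, midpoints (for group sets) and one entry per (sex, age
#' index). Probabilities are written with 17 significant digits so that
#' a write/read round trip reproduces every entry bit-exactly.
#'
#' @param x A `transition_matrix_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_set <- function(x, path) {
  validate_matrix_set(x)
  entries <- list()
  for (sex in names(x$matrices)) {
    keys <- names(x$matrices[[sex]])
    keys <- keys[order(as.integer(keys))]
    for (key in keys) {
      entries[[length(entries) + 1L]] <- list(
        sex = sex, age_index = as.integer(key),
        matrix = unname(x$matrices[[sex]][[key]]))
    }
  }
  doc <- list(format = "transition-matrix-set", version = 1L,
              index_kind = x$index_kind, states = x$states,
              midpoints = x$midpoints, entries = entries)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a transition matrix set from file
#'
#' Every matrix is re-validated on read; a malformed file fails naming
#' the first offending entry and row.
#'
#' @param path Path written by [write_matrix_set()].
#' @return A `transition_matrix_set`.
#' @export
read_matrix_set <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(doc$format) || doc$format != "transition-matrix-set") {
    stop_validation(paste0("'", path, "' is not a transition-matrix-set file"))
  }
  matrices <- list()
  for (e in doc$entries) {
    m <- e$matrix
    if (is.list(m)) m <- do.call(rbind, m)
    matrices[[e$sex]][[as.character(e$age_index)]] <- m
  }
  transition_matrix_set(matrices, index_kind = doc$index_kind,
                        midpoints = doc$midpoints,
                        states = unlist(doc$states))
}

# ---- shared internals ------------------------------------------------------

# Validation failures get their own condition class so the CLI can map
# them to exit code 2.
stop_validation <- function(msg) {
  stop(structure(class = c("hlemms_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

as_integerish <- function(x, what) {
  x <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & x != floor(x))) {
    stop_validation(paste0("'", what, "' must be integer-valued"))
  }
  as.integer(x)
}

# Inverse-CDF draw: smallest state whose cumulative probability exceeds
# u, with ties at cumulative boundaries resolved upward. `cum` is the
# cumulative vector over states 1..k (cum[k] == 1); returns values 1..k.
inv_cdf_state <- function(u, cum) {
  findInterval(u, cum[-length(cum)]) + 1L
}
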