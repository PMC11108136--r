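# Maximum-likelihood estimation of group-centred annual transition
# matrices from paired-year records: p_ij = s_ij / s_i, the count-based
# MLE for a stationary Markov chain observed over one pair of years.

#' Tally observed transitions by sex, age group and state pair
#'
#' Each record increments exactly one `(sex, group, state_t, state_t1)`
#' cell; the age group is assigned from the baseline age, consistent
#' with conditioning on the state at the earlier year. Duplicate person
#' identifiers are counted (with a warning): the estimator works on
#' observations, not persons.
#'
#' @param records Validated records (see [validate_records()]).
#' @param scheme An [age_group_scheme()].
#' @return An object of class `transition_counts`: list with `s_ij`
#'   (array `[sex x group x 6 x 7]`), `s_i` (array `[sex x group x 6]`)
#'   and the scheme.
#' @export
count_transitions <- function(records, scheme = age_group_scheme()) {
  G <- scheme$n_groups
  s_ij <- array(0L, dim = c(2L, G, 6L, 7L),
                dimnames = list(SEXES, scheme$labels, NULL, NULL))
  if (nrow(records)) {
    if (anyDuplicated(records$person_id)) {
      warning("duplicate person_id values present; all rows are counted")
    }
    sex_i <- match(records$sex, SEXES)
    if (anyNA(sex_i)) stop_validation("records contain sex values outside 'female'/'male'")
    g <- age_group_index(records$age, scheme)
    lin <- (((records$state_t1 - 1L) * 6L + (records$state_t - 1L)) * G +
              (g - 1L)) * 2L + sex_i
    tab <- tabulate(lin, nbins = 2L * G * 6L * 7L)
    s_ij[] <- tab  # dims (sex, group, i, j): sex varies fastest, matching lin
  }
  s_i <- apply(s_ij, c(1, 2, 3), sum)
  structure(list(s_ij = s_ij, s_i = s_i, scheme = scheme),
            class = "transition_counts")
}

#' Estimate group-centred transition matrices
#'
#' For each (sex, age group), row i of the matrix is the observed
#' frequency vector `s_ij / s_i` over follow-up states j = 1..7; row 7
#' is the absorbing death row. Rows with zero exposure are completed by
#' a stated policy and flagged, never silently.
#'
#' @param counts A `transition_counts` object.
#' @param min_cell Diagnostic threshold: every `(sex, group, state)`
#'   with exposure below `min_cell` is listed in the diagnostics
#'   (default 30). No pooling is applied automatically.
#' @param zero_exposure Policy for rows with `s_i = 0`:
#'   `"borrow_nearest"` (default) copies the row estimated for the
#'   nearest age group with exposure for the same (sex, state), ties
#'   resolved toward the younger group; `"identity"` keeps the state
#'   with probability 1 and zero mortality. Either way the row is
#'   flagged in the diagnostics.
#' @return List with `set` (an age-group `transition_matrix_set`) and
#'   `diagnostics` (data.frame of `sex`, `group`, `state`, `exposure`,
#'   `action`).
#' @export
estimate_group_matrices <- function(counts, min_cell = 30L,
                                    zero_exposure = c("borrow_nearest", "identity")) {
  stopifnot(inherits(counts, "transition_counts"))
  zero_exposure <- match.arg(zero_exposure)
  scheme <- counts$scheme
  G <- scheme$n_groups
  diagnostics <- list()
  note <- function(sex, g, i, exposure, action) {
    diagnostics[[length(diagnostics) + 1L]] <<- data.frame(
      sex = sex, group = scheme$labels[g], state = i,
      exposure = exposure, action = action, stringsAsFactors = FALSE)
  }

  raw_row <- function(s, g, i) {
    si <- counts$s_i[s, g, i]
    if (si > 0) counts$s_ij[s, g, i, ] / si else NULL
  }
  matrices <- list()
  for (s in 1:2) {
    sex <- SEXES[s]
    for (g in seq_len(G)) {
      m <- matrix(0, 7, 7)
      for (i in 1:6) {
        si <- counts$s_i[s, g, i]
        if (si > 0) {
          m[i, ] <- counts$s_ij[s, g, i, ] / si
          if (si < min_cell) note(sex, g, i, si, "low_exposure")
        } else if (zero_exposure == "borrow_nearest") {
          cand <- which(counts$s_i[s, , i] > 0)
          if (length(cand)) {
            donor <- cand[order(abs(cand - g), cand)][1]
            m[i, ] <- raw_row(s, donor, i)
            note(sex, g, i, 0L, paste0("borrowed_from_", scheme$labels[donor]))
          } else {
            m[i, i] <- 1
            note(sex, g, i, 0L, "identity_fallback")
          }
        } else {
          m[i, i] <- 1
          note(sex, g, i, 0L, "identity_fallback")
        }
      }
      m[7, 7] <- 1
      matrices[[sex]][[as.character(g)]] <- m
    }
  }
  diagnostics <- if (length(diagnostics)) do.call(rbind, diagnostics) else
    data.frame(sex = character(), group = character(), state = integer(),
               exposure = integer(), action = character(), stringsAsFactors = FALSE)
  set <- transition_matrix_set(matrices, "age_group", midpoints = scheme$midpoints)
  list(set = set, diagnostics = diagnostics)
}
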