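# Expansion of group-centred matrices to single years of age. Each
# matrix entry is interpolated entrywise across the group midpoints with
# a natural cubic spline, then rows are clipped to [0,1] and
# renormalized to restore row-stochasticity.

#' Spline evaluation age under the tail-closure policy
#'
#' Ages beyond the last group midpoint evaluate the spline at the last
#' midpoint (constant extrapolation); ages below the first interpolated
#' midpoint rely on the spline's natural boundary behaviour.
#'
#' @param age Integer age(s).
#' @param midpoints Group midpoints used as knots.
#' @return Evaluation age(s).
#' @export
interpolation_age <- function(age, midpoints) {
  pmin(age, max(midpoints))
}

#' Expand group-centred matrices to single-year-of-age matrices
#'
#' Age 0 takes the first group's (`[0,1)`) matrix verbatim — the infant
#' group is excluded from interpolation. For ages `1..max_age`, each of
#' the 42 live-row entries (states 1..6 by 1..7) is interpolated as a
#' natural cubic spline through the remaining group midpoints evaluated
#' at integer ages (constant beyond the last midpoint), clipped to
#' \[0,1\]; each live row is then renormalized to sum 1 and the death
#' row forced absorbing. With the default ten-group scheme and
#' `max_age = 90` the output holds 91 matrices per sex, 182 in total.
#'
#' Rows whose pre-repair sum deviates from 1 by more than 1e-3 are
#' recorded in the attribute `"renormalization_log"` of the result.
#'
#' @param groups An age-group `transition_matrix_set` covering both
#'   sexes and all groups of `scheme`.
#' @param scheme The [age_group_scheme()] whose midpoints are the knots.
#' @param max_age Last single year of age (default 90, standing for the
#'   open-ended ">= 90" terminal age).
#' @return A single-year `transition_matrix_set` with ages `0..max_age`
#'   per sex.
#' @export
interpolate_yearly <- function(groups, scheme = age_group_scheme(), max_age = 90L) {
  stopifnot(inherits(groups, "transition_matrix_set"))
  if (groups$index_kind != "age_group") {
    stop_validation("'groups' must be an age_group matrix set")
  }
  G <- scheme$n_groups
  if (max_age < max(scheme$midpoints)) {
    stop_validation("'max_age' must be at least the last group midpoint")
  }
  for (sex in SEXES) {
    have <- names(groups$matrices[[sex]])
    missing <- setdiff(as.character(seq_len(G)), have)
    if (length(missing)) {
      stop_validation(sprintf("missing group matrix: (%s, group %s)",
                              sex, missing[1]))
    }
  }
  knots <- scheme$midpoints[-1]          # infant group excluded
  ages <- 1:max_age
  eval_at <- interpolation_age(ages, knots)
  renorm_log <- list()
  matrices <- list()
  for (sex in SEXES) {
    gm <- groups$matrices[[sex]]
    # raw[age, i, j]: splined entries before repair
    raw <- array(0, dim = c(length(ages), 6L, 7L))
    for (i in 1:6) {
      for (j in 1:7) {
        vals <- vapply(2:G, function(g) gm[[as.character(g)]][i, j], 0)
        f <- stats::splinefun(knots, vals, method = "natural")
        raw[, i, j] <- f(eval_at)
      }
    }
    matrices[[sex]][["0"]] <- gm[["1"]]
    for (a in ages) {
      m <- matrix(0, 7, 7)
      block <- raw[a, , ]
      pre_sums <- rowSums(block)
      block <- pmin(pmax(block, 0), 1)
      sums <- rowSums(block)
      if (any(sums == 0)) {
        stop_validation(sprintf(
          "interpolated row has zero total mass: (%s, age %d, state %d)",
          sex, a, which(sums == 0)[1]))
      }
      off <- which(abs(pre_sums - 1) > 1e-3)
      for (i in off) {
        renorm_log[[length(renorm_log) + 1L]] <- data.frame(
          sex = sex, age = a, state = i, row_sum = pre_sums[i],
          stringsAsFactors = FALSE)
      }
      m[1:6, ] <- block / sums
      m[7, 7] <- 1
      matrices[[sex]][[as.character(a)]] <- m
    }
  }
  out <- transition_matrix_set(matrices, "single_year")
  attr(out, "renormalization_log") <- if (length(renorm_log))
    do.call(rbind, renorm_log) else NULL
  if (length(renorm_log)) {
    message(length(renorm_log),
            " interpolated row(s) needed renormalization by more than 1e-3")
  }
  out
}
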