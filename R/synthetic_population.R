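# Synthetic two-year panels with known ground-truth dynamics. The
# generator stands in for a morbidity/mortality registry so that the
# estimation -> interpolation -> simulation pipeline can be validated by
# parameter recovery against a known truth.

#' Specify a synthetic population
#'
#' @param counts Integer matrix `[sex x group]` (rownames `"female"`,
#'   `"male"`) of persons per cell.
#' @param baseline_state_mix Numeric array `[sex x group x 6]`; each
#'   `(sex, group)` slice is a probability vector over baseline states
#'   1..6 (sums to 1 within 1e-9).
#' @param truth A `transition_matrix_set` of kind `"age_group"` holding
#'   the ground-truth annual transition probabilities.
#' @param scheme The [age_group_scheme()] the cells refer to.
#' @param seed Integer seed; the panel is fully reproducible from the spec.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(counts, baseline_state_mix, truth,
                            scheme = age_group_scheme(), seed = 1L) {
  G <- scheme$n_groups
  if (!is.matrix(counts) || !identical(rownames(counts), SEXES) || ncol(counts) != G) {
    stop_validation("'counts' must be a [female,male] x group matrix")
  }
  if (any(counts < 0)) stop_validation("'counts' must be nonnegative")
  if (!identical(dim(baseline_state_mix), c(2L, G, 6L))) {
    stop_validation("'baseline_state_mix' must be a 2 x n_groups x 6 array")
  }
  sums <- apply(baseline_state_mix, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop_validation("each baseline state mix must sum to 1")
  }
  if (any(baseline_state_mix < 0)) {
    stop_validation("baseline state mixes must be nonnegative")
  }
  if (!inherits(truth, "transition_matrix_set") || truth$index_kind != "age_group") {
    stop_validation("'truth' must be an age_group transition_matrix_set")
  }
  validate_matrix_set(truth)
  structure(list(counts = counts, baseline_state_mix = baseline_state_mix,
                 truth = truth, scheme = scheme, seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Synthetic population spec: %d persons (%d female, %d male), %d age groups, seed %d\n",
              sum(x$counts), sum(x$counts["female", ]), sum(x$counts["male", ]),
              x$scheme$n_groups, x$seed))
  invisible(x)
}

#' Study-like synthetic population specification
#'
#' A documented fixture spec whose total size scales to about 87,850
#' persons at `scale = 1`, with a general-population age/sex structure,
#' morbidity prevalence increasing with age and annual mortality rising
#' steeply after age 75 (overall crude mortality just under 1% per
#' year). All numbers are fixture choices for validation; they are not
#' calibrated to any registry.
#'
#' @param scale Positive multiplier on the population size.
#' @param seed Seed stored in the spec (drives [generate_panel()]).
#' @return A `population_spec`.
#' @export
#' @examples
#' sp <- default_study_like_spec(scale = 0.01)
#' sum(sp$counts)
default_study_like_spec <- function(scale = 1, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop_validation("'scale' must be a positive number")
  }
  scheme <- age_group_scheme()
  G <- scheme$n_groups
  # age structure (fractions of total population per group)
  age_frac <- c(0.008, 0.140, 0.090, 0.110, 0.150, 0.150, 0.130, 0.110, 0.075, 0.037)
  # share of each group that is female (older groups skew female)
  female_share <- c(0.49, 0.49, 0.49, 0.50, 0.50, 0.50, 0.51, 0.52, 0.55, 0.62)
  total <- 87850 * scale
  counts <- rbind(female = round(total * age_frac * female_share),
                  male = round(total * age_frac * (1 - female_share)))
  storage.mode(counts) <- "integer"

  # baseline morbidity mix: healthy share declines with age, residual
  # mass shifts from acute/minor-chronic toward multi-system disease
  healthy <- c(0.93, 0.90, 0.85, 0.78, 0.68, 0.55, 0.42, 0.28, 0.16, 0.09)
  mix <- array(0, dim = c(2L, G, 6L))
  for (g in seq_len(G)) {
    w <- c(0, 0.30, 0.40, 0.22, 0.06, 0.02) +
      (g / G) * c(0, -0.20, -0.25, 0.25, 0.16, 0.04)
    w[1] <- 0
    w <- pmax(w, 0); w <- w / sum(w)
    row <- c(healthy[g], (1 - healthy[g]) * w[-1])
    row <- row / sum(row)
    mix[1, g, ] <- row
    mix[2, g, ] <- row
  }
  truth <- study_like_truth(scheme)
  population_spec(counts, mix, truth, scheme, seed = seed)
}

# Ground-truth age-group matrices for the study-like spec: annual death
# probability rises with age and with state severity; survivors mostly
# persist in their state, with some recovery toward health and
# progression toward more severe states that strengthens with age.
study_like_truth <- function(scheme = age_group_scheme()) {
  G <- scheme$n_groups
  # annual death probability of the healthy, per group; state-severity
  # multipliers lift it so the morbidity-mix-weighted crude mortality
  # stays near 1% per year with realistic old-age levels (~5% at 75-84,
  # ~14% at 85+)
  base_q <- c(0.0020, 0.0002, 0.0004, 0.0006, 0.0010, 0.0020,
              0.0050, 0.0100, 0.0250, 0.0700)
  state_mult <- c(1, 1.1, 1.3, 1.8, 3.0, 4.0)
  sex_mult <- c(female = 0.85, male = 1.15)
  matrices <- list()
  for (sex in SEXES) {
    for (g in seq_len(G)) {
      m <- matrix(0, 7, 7)
      # annual persistence: healthy mostly stays healthy, acute disease
      # is transient, established chronic states are sticky
      stay_by_state <- c(0.90, 0.50, 0.80, 0.85, 0.90, 0.90)
      for (i in 1:6) {
        q <- min(0.85, base_q[g] * state_mult[i] * sex_mult[[sex]])
        stay <- stay_by_state[i]
        move <- exp(-0.9 * abs((1:6) - i))
        move[i] <- 0
        # progression bias grows with age
        move[(1:6) > i] <- move[(1:6) > i] * (1 + 0.25 * g)
        move <- move / sum(move)
        m[i, 1:6] <- (1 - q) * (stay * (1:6 == i) + (1 - stay) * move)
        m[i, 7] <- q
      }
      m[7, 7] <- 1
      matrices[[sex]][[as.character(g)]] <- m
    }
  }
  transition_matrix_set(matrices, "age_group", midpoints = scheme$midpoints)
}

#' Generate a synthetic two-year panel
#'
#' Draws one record per person: baseline age uniform over the integer
#' ages of the person's group (the open-ended last group uses ages
#' 85..99), baseline state from the cell's state mix, follow-up state
#' from the ground-truth transition row. A single seeded pseudo-random
#' stream is used, with three draws consumed per record in record order
#' (cells ordered female then male, youngest group first), so a given
#' spec always yields a bit-identical panel.
#'
#' @param spec A [population_spec()].
#' @return Data.frame of individual records (see [validate_records()]),
#'   ordered by cell.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  scheme <- spec$scheme
  G <- scheme$n_groups
  n_total <- sum(spec$counts)
  if (n_total == 0L) {
    warning("population spec has zero total count: returning an empty panel")
    return(data.frame(person_id = character(), sex = character(),
                      age = integer(), state_t = integer(), state_t1 = integer(),
                      stringsAsFactors = FALSE))
  }
  cells <- expand.grid(group = seq_len(G), sex = SEXES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$sex, SEXES), cells$group), ]
  n_cell <- spec$counts[cbind(match(cells$sex, SEXES), cells$group)]
  sex <- rep(cells$sex, n_cell)
  group <- rep(cells$group, n_cell)

  set.seed(spec$seed)
  # byrow = TRUE: record r consumes stream draws 3r-2, 3r-1, 3r
  u <- matrix(stats::runif(3L * n_total), ncol = 3L, byrow = TRUE)

  lo <- scheme$breaks[group]
  hi <- ifelse(is.finite(scheme$upper[group]), scheme$upper[group],
               scheme$breaks[group] + 15)
  age <- as.integer(pmin(lo + floor(u[, 1] * (hi - lo)), hi - 1))

  state_t <- integer(n_total)
  state_t1 <- integer(n_total)
  sex_i <- match(sex, SEXES)
  for (s in 1:2) {
    for (g in seq_len(G)) {
      idx <- which(sex_i == s & group == g)
      if (!length(idx)) next
      state_t[idx] <- inv_cdf_state(u[idx, 2], cumsum(spec$baseline_state_mix[s, g, ]))
      tm <- spec$truth$matrices[[SEXES[s]]][[as.character(g)]]
      for (i in 1:6) {
        ii <- idx[state_t[idx] == i]
        if (length(ii)) {
          state_t1[ii] <- inv_cdf_state(u[ii, 3], cumsum(tm[i, ]))
        }
      }
    }
  }
  data.frame(person_id = paste0("p", seq_len(n_total)), sex = sex,
             age = age, state_t = state_t, state_t1 = state_t1,
             stringsAsFactors = FALSE)
}
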