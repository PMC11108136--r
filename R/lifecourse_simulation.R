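# Monte Carlo generation of lifetime state trajectories from yearly
# transition matrices, and the analytic absorbing-chain calculator used
# as its deterministic oracle.
#
# Person-year convention: a person alive at exact age x contributes one
# full year in the state occupied at x, including the year in which
# they die (years lived = age_at_death + 1). Trajectories store only
# living states; death terminates the sequence.

#' Initial state distribution of the under-1 group
#'
#' Empirical baseline state frequencies of the `[0,1)` age group, per
#' sex — the composition a simulated birth cohort is started from.
#'
#' @param x Either a validated records data.frame or a
#'   [population_spec()] (whose under-1 baseline mix is returned).
#' @param scheme An [age_group_scheme()].
#' @return Numeric matrix `[2 x 6]`, rownames `"female"`/`"male"`; each
#'   row sums to 1.
#' @export
initial_state_distribution <- function(x, scheme = age_group_scheme()) {
  if (inherits(x, "population_spec")) {
    init <- rbind(female = x$baseline_state_mix[1, 1, ],
                  male = x$baseline_state_mix[2, 1, ])
    return(init)
  }
  under1 <- x[age_group_index(x$age, scheme) == 1L, , drop = FALSE]
  init <- matrix(0, 2, 6, dimnames = list(SEXES, NULL))
  for (sex in SEXES) {
    st <- under1$state_t[under1$sex == sex]
    if (!length(st)) {
      stop_validation(paste0(
        "no under-1 individuals for sex '", sex,
        "': supply an explicit initial state vector instead"))
    }
    init[sex, ] <- tabulate(st, nbins = 6L) / length(st)
  }
  init
}

# Per-sex arrays of cumulative transition rows for fast inverse-CDF
# draws: C[[sex]][i, j, a+1] = P(next state <= j | state i, age a), with
# the constant tail reused for ages beyond the set's last age.
cumulative_rows <- function(yearly, max_attained_age) {
  idx <- matrix_set_indices(yearly)
  lapply(stats::setNames(SEXES, SEXES), function(sex) {
    C <- array(0, dim = c(6L, 7L, max_attained_age + 1L))
    for (a in 0:max_attained_age) {
      key <- as.character(min(a, max(idx)))
      m <- yearly$matrices[[sex]][[key]]
      if (is.null(m)) {
        stop_validation(sprintf("yearly set has no matrix for (%s, age %s)", sex, key))
      }
      C[, , a + 1L] <- t(apply(m[1:6, , drop = FALSE], 1, cumsum))
    }
    C
  })
}

#' Simulate lifetime health trajectories
#'
#' Each trajectory starts at age 0 in a state drawn from the initial
#' distribution, then advances one year per cycle, drawing the next
#' state by inverse-CDF comparison of a pseudo-random number with the
#' cumulative transition probabilities of the current (sex, age) matrix
#' row (states ordered 1..7, ties at cumulative boundaries resolved
#' upward). A trajectory ends when death is drawn or at
#' `max_attained_age` (censoring, flagged). One pseudo-random stream is
#' used per sex, seeded `seed` (females) and `seed + 1` (males), with a
#' fixed block of draws consumed trajectory by trajectory.
#'
#' @param yearly A single-year `transition_matrix_set`; ages beyond its
#'   last age reuse the last matrix (constant tail).
#' @param init Initial state matrix as from
#'   [initial_state_distribution()].
#' @param n_per_sex Trajectories per sex (default 10000).
#' @param seed Integer seed.
#' @param max_attained_age Censoring age (default 110).
#' @return An object of class `trajectory_sample`: list with `sex`,
#'   `states` (integer matrix, one row per trajectory, column `a + 1` =
#'   state at age a, `NA` after death), `age_at_death` (`NA` when
#'   censored), `censored`, `seed`, `max_attained_age`.
#' @export
simulate_trajectories <- function(yearly, init, n_per_sex = 10000L, seed = 1L,
                                  max_attained_age = 110L) {
  stopifnot(inherits(yearly, "transition_matrix_set"))
  if (yearly$index_kind != "single_year") {
    stop_validation("'yearly' must be a single_year matrix set")
  }
  if (!is.matrix(init) || ncol(init) != 6L ||
      any(abs(rowSums(init) - 1) > 1e-9) || any(init < 0)) {
    stop_validation("'init' must be a [sex x 6] matrix of probability vectors")
  }
  C <- cumulative_rows(yearly, max_attained_age)
  n_ages <- max_attained_age + 1L
  states <- list(); aad <- list(); cens <- list()
  for (s in 1:2) {
    sex <- SEXES[s]
    n <- n_per_sex
    set.seed(seed + (s - 1L))
    # byrow = TRUE: trajectory r consumes draws (r-1)*(n_ages) + 1 .. r*n_ages
    u <- matrix(stats::runif(n * n_ages), nrow = n, byrow = TRUE)
    st_mat <- matrix(NA_integer_, n, n_ages)
    cur <- inv_cdf_state(u[, 1], cumsum(init[sex, ]))
    st_mat[, 1] <- cur
    alive <- rep(TRUE, n)
    death_age <- rep(NA_integer_, n)
    for (a in 0:(max_attained_age - 1L)) {
      live <- which(alive)
      if (!length(live)) break
      nxt <- integer(length(live))
      cura <- cur[live]
      for (i in 1:6) {
        ii <- which(cura == i)
        if (length(ii)) {
          nxt[ii] <- inv_cdf_state(u[live[ii], a + 2L], C[[sex]][i, , a + 1L])
        }
      }
      died <- nxt == DEATH_STATE
      death_age[live[died]] <- a
      alive[live[died]] <- FALSE
      surv <- live[!died]
      if (length(surv)) {
        cur[surv] <- nxt[!died]
        st_mat[cbind(surv, a + 2L)] <- cur[surv]
      }
    }
    states[[sex]] <- st_mat
    aad[[sex]] <- death_age
    cens[[sex]] <- is.na(death_age)
  }
  out <- structure(
    list(sex = rep(SEXES, each = n_per_sex),
         states = rbind(states$female, states$male),
         age_at_death = c(aad$female, aad$male),
         censored = c(cens$female, cens$male),
         seed = as.integer(seed), max_attained_age = as.integer(max_attained_age),
         n_per_sex = as.integer(n_per_sex)),
    class = "trajectory_sample")
  frac_cens <- mean(out$censored)
  if (frac_cens > 0.01) {
    warning(sprintf(
      "%.1f%% of trajectories were censored at age %d: the constant-tail closure may be inadequate",
      100 * frac_cens, max_attained_age))
  }
  out
}

#' @export
print.trajectory_sample <- function(x, ...) {
  cat(sprintf("Trajectory sample: %d trajectories (%d per sex), seed %d, %d censored at age %d\n",
              length(x$sex), x$n_per_sex, x$seed, sum(x$censored), x$max_attained_age))
  invisible(x)
}

#' Analytic expectancies of the absorbing chain
#'
#' Deterministic counterpart of the Monte Carlo engine: state-occupancy
#' probabilities are propagated age by age with matrix-vector products,
#' and expectancies are computed with the same person-years formula the
#' sample estimator uses, `e_{x,j} = sum_{y >= x} L_{y,j} / l_x`, where
#' `L_{y,j}` is the probability mass alive at exact age y in state j
#' (whole-year credit) and `l_x` the probability of being alive at exact
#' age x. Occupancy is truncated at `max_attained_age`, matching the
#' simulator's censoring.
#'
#' @inheritParams simulate_trajectories
#' @return An expectancy table (see [expectancies_from_sample()]) with
#'   `lx` on the probability scale.
#' @export
analytic_expectancies <- function(yearly, init, max_attained_age = 110L) {
  stopifnot(inherits(yearly, "transition_matrix_set"))
  tabs <- lapply(SEXES, function(sex) {
    occ <- state_occupancy(yearly, init[sex, ], sex, max_attained_age)
    expectancy_rows(sex, occ$L, occ$lx)
  })
  as_expectancy_table(do.call(rbind, tabs), convention = "whole_year",
                      kind = "analytic")
}

# Occupancy propagation: L[a+1, j] = P(alive at exact age a in state j),
# lx[a+1] = P(alive at exact age a). Ages 0..max_attained_age.
state_occupancy <- function(yearly, init_vec, sex, max_attained_age) {
  idx <- matrix_set_indices(yearly)
  n_ages <- max_attained_age + 1L
  L <- matrix(0, n_ages, 6L)
  v <- init_vec
  for (a in 0:max_attained_age) {
    L[a + 1L, ] <- v
    if (a < max_attained_age) {
      m <- yearly$matrices[[sex]][[as.character(min(a, max(idx)))]]
      v <- as.numeric(v %*% m[1:6, 1:6])
    }
  }
  list(L = L, lx = rowSums(L))
}

#' Chain-implied sampling dispersion of expectancy estimates
#'
#' For each sex, age x and state j (plus the total), computes the
#' standard deviation across individuals of remaining person-years in
#' state j from age x, conditional on being alive at x, implied by the
#' chain itself (backward second-moment recursion, truncated at
#' `max_attained_age` like the simulator). Dividing by `sqrt(l_x)` of a
#' trajectory sample gives the exact Monte Carlo standard error of the
#' corresponding expectancy estimate — well defined even where a finite
#' sample happens to show no variation.
#'
#' @inheritParams analytic_expectancies
#' @return Data.frame with columns `sex`, `age`, `sd_ex`,
#'   `sd_ex_s1`..`sd_ex_s6`.
#' @export
mc_sampling_sd <- function(yearly, init, max_attained_age = 110L) {
  idx <- matrix_set_indices(yearly)
  out <- lapply(SEXES, function(sex) {
    occ <- state_occupancy(yearly, init[sex, ], sex, max_attained_age)
    n_ages <- max_attained_age + 1L
    # m1[s, k], m2[s, k]: first/second moments of remaining years in
    # target k (k = 1..6 states, 7 = total) starting alive at x in s
    m1 <- matrix(0, 6, 7); m2 <- matrix(0, 6, 7)
    sds <- matrix(NA_real_, n_ages, 7L)
    for (x in max_attained_age:0) {
      cvec <- cbind(diag(6), 1)  # indicator credit of this year, per target
      if (x == max_attained_age) {
        m1 <- cvec
        m2 <- cvec
      } else {
        P <- yearly$matrices[[sex]][[as.character(min(x, max(idx)))]][1:6, 1:6]
        mu <- P %*% m1
        s2 <- P %*% m2
        m2 <- cvec^2 + 2 * cvec * mu + s2
        m1 <- cvec + mu
      }
      lx <- occ$lx[x + 1L]
      if (lx > 0) {
        w <- occ$L[x + 1L, ] / lx
        e1 <- colSums(w * m1)
        e2 <- colSums(w * m2)
        sds[x + 1L, ] <- sqrt(pmax(e2 - e1^2, 0))
      }
    }
    keep <- !is.na(sds[, 7])
    df <- data.frame(sex = sex, age = which(keep) - 1L,
                     sd_ex = sds[keep, 7], stringsAsFactors = FALSE)
    sj <- sds[keep, 1:6, drop = FALSE]
    colnames(sj) <- paste0("sd_ex_s", 1:6)
    cbind(df, sj)
  })
  do.call(rbind, out)
}
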