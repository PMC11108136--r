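# Programmatic fixtures shared across test files.

# One 7x7 matrix: every living state stays with prob 1 - q and dies
# with prob q.
stay_or_die_matrix <- function(q) {
  m <- diag(7) * (1 - q)
  m[, 7] <- q
  m[7, ] <- c(rep(0, 6), 1)
  m
}

# Random row-stochastic 7x7 with absorbing death; death probability
# around q_death.
random_transition_matrix <- function(q_death = 0.05) {
  m <- matrix(0, 7, 7)
  for (i in 1:6) {
    w <- stats::rgamma(6, shape = 1)
    q <- min(0.95, stats::rbeta(1, 2, 2) * 2 * q_death)
    m[i, 1:6] <- (1 - q) * w / sum(w)
    m[i, 7] <- q
  }
  m[7, 7] <- 1
  m
}

# Age-group set with the same matrix everywhere.
constant_group_set <- function(m, scheme = age_group_scheme()) {
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in seq_len(scheme$n_groups)) {
      mats[[sex]][[as.character(g)]] <- m
    }
  }
  transition_matrix_set(mats, "age_group", midpoints = scheme$midpoints)
}

# Single-year set 0..max_age with one matrix per age from `maker(age)`.
yearly_set_from <- function(maker, max_age = 90) {
  mats <- list()
  for (sex in c("female", "male")) {
    for (a in 0:max_age) {
      mats[[sex]][[as.character(a)]] <- maker(a)
    }
  }
  transition_matrix_set(mats, "single_year")
}

# Randomized stationary chain with mortality rising in age, so that
# nearly all trajectories die before age 110.
random_yearly_set <- function(seed, max_age = 90) {
  set.seed(seed)
  yearly_set_from(function(a) {
    random_transition_matrix(q_death = min(0.95, 0.01 * exp(0.055 * a)))
  }, max_age = max_age)
}

random_init <- function(seed) {
  set.seed(seed)
  init <- rbind(female = stats::rgamma(6, 1), male = stats::rgamma(6, 1))
  init / rowSums(init)
}

# Hand-built trajectory sample: `traj` is a list of integer state
# sequences (living states only); censored when the sequence reaches
# max_attained_age + 1 years.
manual_sample <- function(traj, sex = rep("female", length(traj)),
                          max_attained_age = 10L) {
  st <- matrix(NA_integer_, length(traj), max_attained_age + 1L)
  for (r in seq_along(traj)) st[r, seq_along(traj[[r]])] <- traj[[r]]
  yrs <- lengths(traj)
  censored <- yrs == max_attained_age + 1L
  structure(
    list(sex = sex, states = st,
         age_at_death = ifelse(censored, NA_integer_, yrs - 1L),
         censored = censored, seed = NA_integer_,
         max_attained_age = max_attained_age,
         n_per_sex = sum(sex == "female")),
    class = "trajectory_sample")
}

records_df <- function(sex, age, state_t, state_t1) {
  n <- max(length(sex), length(age), length(state_t), length(state_t1))
  data.frame(person_id = if (n) paste0("p", seq_len(n)) else character(),
             sex = sex, age = age,
             state_t = state_t, state_t1 = state_t1, stringsAsFactors = FALSE)
}
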