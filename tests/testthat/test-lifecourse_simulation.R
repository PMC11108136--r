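# Monte Carlo trajectory engine and the analytic absorbing-chain
# calculator.

test_that("initial state distribution is the under-1 composition per sex", {
  rec <- rbind(records_df(rep("female", 3), 0, 1, 1),
               records_df(rep("male", 10), 0, c(rep(1, 8), 2, 2), 1),
               records_df("female", 30, 5, 5))
  rec$person_id <- paste0("r", seq_len(nrow(rec)))
  init <- initial_state_distribution(rec)
  expect_identical(init["female", ], c(1, 0, 0, 0, 0, 0))
  expect_identical(init["male", ], c(0.8, 0.2, 0, 0, 0, 0))
  # independent recount
  males0 <- rec[rec$sex == "male" & rec$age == 0, ]
  expect_identical(as.numeric(init["male", 2]), sum(males0$state_t == 2) / nrow(males0))

  expect_error(initial_state_distribution(records_df("male", 0, 1, 1)),
               "no under-1.*female")
})

test_that("forced absorption gives one-year lifespans; zero mortality censors everyone", {
  all_die <- yearly_set_from(function(a) stay_or_die_matrix(1))
  init <- rbind(female = c(1, 0, 0, 0, 0, 0), male = c(0, 0, 1, 0, 0, 0))
  s <- suppressWarnings(
    simulate_trajectories(all_die, init, n_per_sex = 50, seed = 2,
                          max_attained_age = 20))
  expect_true(all(s$age_at_death == 0L))
  expect_true(all(rowSums(!is.na(s$states)) == 1L))

  ident <- yearly_set_from(function(a) diag(7))
  s <- suppressWarnings(
    simulate_trajectories(ident, init, n_per_sex = 50, seed = 2,
                          max_attained_age = 20))
  expect_true(all(s$censored))
  expect_true(all(s$states[s$sex == "female", ] == 1L))
  expect_true(all(s$states[s$sex == "male", ] == 3L))
})

test_that("no trajectory contains a state after death and samples are reproducible", {
  yearly <- random_yearly_set(21)
  init <- random_init(22)
  s1 <- simulate_trajectories(yearly, init, n_per_sex = 300, seed = 9)
  s2 <- simulate_trajectories(yearly, init, n_per_sex = 300, seed = 9)
  expect_identical(s1, s2)
  dead <- which(!s1$censored)
  for (r in dead[1:25]) {
    seqr <- s1$states[r, ]
    lived <- which(!is.na(seqr))
    expect_identical(lived, seq_len(s1$age_at_death[r] + 1L))
    expect_true(all(seqr[lived] %in% 1:6))
  }
  # years lived match the death ages under whole-year crediting
  expect_identical(rowSums(!is.na(s1$states))[dead],
                   as.numeric(s1$age_at_death[dead] + 1L))
})

test_that("constant mortality reproduces the geometric survival expectation", {
  q <- 0.5
  flat <- yearly_set_from(function(a) stay_or_die_matrix(q), max_age = 10)
  init <- rbind(female = c(1, 0, 0, 0, 0, 0), male = c(1, 0, 0, 0, 0, 0))
  n <- 50000
  s <- suppressWarnings(
    simulate_trajectories(flat, init, n_per_sex = n, seed = 17,
                          max_attained_age = 80))
  yrs <- rowSums(!is.na(s$states))
  # closed form: E[years] = 1/q, sd = sqrt(1-q)/q
  se <- sqrt(1 - q) / q / sqrt(2 * n)
  expect_lt(abs(mean(yrs) - 1 / q), 3 * se)
})

test_that("analytic expectancies partition and handle forced absorption", {
  all_die <- yearly_set_from(function(a) stay_or_die_matrix(1), max_age = 5)
  init <- rbind(female = c(0.5, 0.5, 0, 0, 0, 0), male = c(1, 0, 0, 0, 0, 0))
  an <- analytic_expectancies(all_die, init, max_attained_age = 10)
  # everyone dies in the first cycle with full-year credit for it
  expect_identical(nrow(an[an$sex == "female", ]), 1L)
  expect_equal(an$ex[an$sex == "female"], 1, tolerance = 1e-12)
  expect_equal(an$ex_s1[an$sex == "female"], 0.5, tolerance = 1e-12)

  yearly <- random_yearly_set(33)
  an <- analytic_expectancies(yearly, random_init(34))
  state_sum <- rowSums(as.matrix(an[paste0("ex_s", 1:6)]))
  expect_lt(max(abs(state_sum - an$ex)), 1e-9)
  expect_true(all(diff(an$lx[an$sex == "male"]) <= 0))
})

test_that("Monte Carlo expectancies agree with the analytic chain on a small run", {
  yearly <- random_yearly_set(55)
  init <- random_init(56)
  s <- simulate_trajectories(yearly, init, n_per_sex = 4000, seed = 57)
  mc <- expectancies_from_sample(s)
  an <- analytic_expectancies(yearly, init)
  sds <- mc_sampling_sd(yearly, init)
  for (sex in c("female", "male")) {
    m <- mc[mc$sex == sex & mc$age == 0, ]
    a <- an[an$sex == sex & an$age == 0, ]
    sd0 <- sds[sds$sex == sex & sds$age == 0, ]
    expect_lt(abs(m$ex - a$ex), 3 * sd0$sd_ex / sqrt(m$lx) + 1e-9)
    expect_lt(abs(m$ex_s1 - a$ex_s1), 3 * sd0$sd_ex_s1 / sqrt(m$lx) + 1e-9)
  }
})
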