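# Natural-spline expansion of group matrices to single years of age.

test_that("constant group matrices interpolate to themselves, 91 per sex", {
  m <- stay_or_die_matrix(0.2)
  yearly <- interpolate_yearly(constant_group_set(m))
  expect_identical(sum(lengths(yearly$matrices)), 182L)
  expect_identical(length(yearly$matrices$female), 91L)
  expect_identical(sort(matrix_set_indices(yearly)), 0:90)
  for (a in c(0, 1, 37, 90)) {
    expect_equal(yearly$matrices$male[[as.character(a)]], m, tolerance = 1e-12)
  }
})

test_that("the interpolant passes through the group values at midpoints", {
  set.seed(12)
  sch <- age_group_scheme()
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:10) mats[[sex]][[as.character(g)]] <- random_transition_matrix(0.1)
  }
  groups <- transition_matrix_set(mats, "age_group", midpoints = sch$midpoints)
  yearly <- interpolate_yearly(groups, sch)
  # integer midpoints of interpolated groups: ages 8, 20, ..., 90
  for (g in 2:10) {
    a <- as.character(sch$midpoints[g])
    expect_equal(yearly$matrices$female[[a]][1:6, ],
                 mats$female[[as.character(g)]][1:6, ], tolerance = 1e-9)
  }
  # age 0 is the infant group verbatim, excluded from interpolation
  expect_identical(yearly$matrices$female[["0"]], mats$female[["1"]])
})

test_that("splined entries match an independent natural-spline oracle", {
  set.seed(13)
  sch <- age_group_scheme()
  knots <- sch$midpoints[-1]
  # two-state design keeps rows stochastic at every age, so the repair
  # step is a no-op and the production entries are the raw spline values
  y <- runif(9, 0.1, 0.9)
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:10) {
      m <- diag(7)
      if (g > 1) {
        m[1, 1] <- 1 - y[g - 1]
        m[1, 2] <- y[g - 1]
      }
      mats[[sex]][[as.character(g)]] <- m
    }
  }
  groups <- transition_matrix_set(mats, "age_group", midpoints = sch$midpoints)
  yearly <- interpolate_yearly(groups, sch)
  ages <- 1:90
  oracle <- natural_spline_oracle(knots, y, interpolation_age(ages, knots))
  oracle <- pmin(pmax(oracle, 0), 1)
  got <- vapply(ages, function(a) yearly$matrices$male[[as.character(a)]][1, 2], 0)
  expect_equal(got, oracle, tolerance = 1e-9)

  # an entry varying linearly across midpoints stays linear in age
  lin <- (knots - knots[1]) / (knots[9] - knots[1]) * 0.5
  for (sex in c("female", "male")) {
    for (g in 2:10) {
      m <- diag(7)
      m[1, 1] <- 1 - lin[g - 1]; m[1, 7] <- lin[g - 1]
      mats[[sex]][[as.character(g)]] <- m
    }
  }
  groups <- transition_matrix_set(mats, "age_group", midpoints = sch$midpoints)
  yearly <- interpolate_yearly(groups, sch)
  got <- vapply(8:90, function(a) yearly$matrices$female[[as.character(a)]][1, 7], 0)
  expect_equal(got, (8:90 - 8) / 82 * 0.5, tolerance = 1e-9)
})

test_that("tail closure is constant beyond the last midpoint", {
  expect_identical(interpolation_age(100, c(8, 90)), 90)
  expect_identical(interpolation_age(55, c(8, 90)), 55)
  set.seed(14)
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:10) mats[[sex]][[as.character(g)]] <- random_transition_matrix(0.2)
  }
  groups <- transition_matrix_set(mats, "age_group",
                                  midpoints = age_group_scheme()$midpoints)
  yearly <- interpolate_yearly(groups, max_age = 100)
  expect_identical(length(yearly$matrices$female), 101L)
  expect_identical(yearly$matrices$female[["95"]], yearly$matrices$female[["90"]])
  expect_identical(yearly$matrices$male[["100"]], yearly$matrices$male[["90"]])
})

test_that("output sets are valid row-stochastic matrices with absorbing death", {
  set.seed(15)
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:10) mats[[sex]][[as.character(g)]] <- random_transition_matrix(0.3)
  }
  groups <- transition_matrix_set(mats, "age_group",
                                  midpoints = age_group_scheme()$midpoints)
  yearly <- interpolate_yearly(groups)
  # constructor already validates; assert the invariants explicitly
  for (sex in c("female", "male")) {
    for (a in as.character(0:90)) {
      m <- yearly$matrices[[sex]][[a]]
      expect_true(all(m >= 0 & m <= 1))
      expect_true(all(abs(rowSums(m) - 1) <= 1e-9))
      expect_identical(m[7, ], c(0, 0, 0, 0, 0, 0, 1))
    }
  }
})

test_that("incomplete group sets fail naming the missing matrix", {
  m <- stay_or_die_matrix(0.1)
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:9) mats[[sex]][[as.character(g)]] <- m
  }
  mats$male[["10"]] <- m
  groups <- transition_matrix_set(mats, "age_group",
                                  midpoints = age_group_scheme()$midpoints)
  expect_error(interpolate_yearly(groups), "female, group 10")
})
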