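# Count-based MLE of group-centred matrices.

test_that("a single record increments exactly one cell", {
  rec <- records_df("female", 40, 1, 1)
  counts <- count_transitions(rec)
  expect_identical(counts$s_ij[1, 5, 1, 1], 1L)  # (female, [35,45), 1 -> 1)
  expect_identical(sum(counts$s_ij), 1L)
  expect_identical(counts$s_i[1, 5, 1], 1L)
})

test_that("duplicate person identifiers are counted with a warning; empty input is all-zero", {
  rec <- records_df(c("male", "male"), c(20, 21), c(2, 2), c(2, 7))
  rec$person_id <- c("dup", "dup")
  expect_warning(counts <- count_transitions(rec), "duplicate")
  expect_identical(sum(counts$s_ij), 2L)

  counts0 <- count_transitions(records_df(character(), integer(), integer(), integer()))
  expect_identical(sum(counts0$s_ij), 0L)
  expect_identical(sum(counts0$s_i), 0L)
})

test_that("estimated rows are the observed frequencies and sum to one", {
  # 10 baseline-healthy females aged 35-44: 4 stay, 3 to minor chronic, 3 die
  rec <- records_df(rep("female", 10), rep(40, 10), rep(1, 10),
                    c(1, 1, 1, 1, 3, 3, 3, 7, 7, 7))
  est <- estimate_group_matrices(count_transitions(rec))
  row <- est$set$matrices$female[["5"]][1, ]
  expect_identical(row, c(0.4, 0, 0.3, 0, 0, 0, 0.3))
  expect_identical(sum(row), 1)  # rational arithmetic: 4/10 + 3/10 + 3/10
  # the ten-group two-sex scheme always yields 20 matrices
  expect_identical(sum(lengths(est$set$matrices)), 20L)
})

test_that("identity panels give identity blocks with absorbing death", {
  set.seed(2)
  truth <- constant_group_set(diag(7))
  panel <- generate_panel(population_spec(
    matrix(30L, 2, 10, dimnames = list(c("female", "male"), NULL)),
    array(1 / 6, dim = c(2, 10, 6)), truth, seed = 4))
  est <- estimate_group_matrices(count_transitions(panel))
  for (sex in c("female", "male")) {
    for (g in as.character(1:10)) {
      m <- est$set$matrices[[sex]][[g]]
      expect_identical(m[cbind(1:7, 1:7)], rep(1, 7))
    }
  }
})

test_that("the estimator agrees with a brute-force tally on a random panel", {
  set.seed(31)
  truth <- constant_group_set(random_transition_matrix(0.1))
  spec <- population_spec(
    matrix(200L, 2, 10, dimnames = list(c("female", "male"), NULL)),
    array(1 / 6, dim = c(2, 10, 6)), truth, seed = 8)
  panel <- generate_panel(spec)
  est <- estimate_group_matrices(count_transitions(panel))
  for (case in list(c(1, 3, 1, 1), c(2, 10, 5, 7), c(1, 7, 2, 3), c(2, 1, 6, 6))) {
    sex <- c("female", "male")[case[1]]
    oracle <- brute_force_phat(panel, sex, case[2], case[3], case[4])
    got <- est$set$matrices[[sex]][[as.character(case[2])]][case[3], case[4]]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("zero-exposure rows follow the stated policy and are flagged", {
  # no baseline state-6 males anywhere except group 5
  rec <- rbind(records_df(rep("male", 60), rep(c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90), 6),
                          rep(c(1, 2, 3, 4, 5), 12), 1),
               records_df("male", 37, 6, 7),  # the only state-6 exposure: group 5
               records_df(rep("female", 10), seq(0, 90, 10), rep(1:5, 2), 2))
  rec$person_id <- paste0("q", seq_len(nrow(rec)))
  counts <- count_transitions(rec)
  est <- estimate_group_matrices(counts)
  # group 7 borrowed the state-6 row from the nearest group with exposure (5)
  expect_identical(est$set$matrices$male[["7"]][6, ],
                   est$set$matrices$male[["5"]][6, ])
  expect_true(any(grepl("borrowed_from", est$diagnostics$action)))
  expect_true(all(c("low_exposure") %in% est$diagnostics$action))

  est2 <- estimate_group_matrices(counts, zero_exposure = "identity")
  expect_identical(est2$set$matrices$male[["7"]][6, ],
                   c(0, 0, 0, 0, 0, 1, 0))
  # zero-exposure handling is never silent
  expect_true(all(
    est2$diagnostics$action[est2$diagnostics$exposure == 0] == "identity_fallback"))
})

test_that("min_cell threshold is diagnostic only", {
  rec <- records_df(rep("female", 5), rep(30, 5), rep(1, 5), rep(1, 5))
  est <- estimate_group_matrices(count_transitions(rec), min_cell = 30)
  d <- est$diagnostics
  expect_true(any(d$exposure == 5 & d$action == "low_exposure"))
  # the estimate itself is untouched
  expect_identical(est$set$matrices$female[["4"]][1, 1], 1)
})
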