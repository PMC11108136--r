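# Domain types, CRG aggregation, record and matrix-set I/O.

test_that("CRG aggregation is total on 1..9, surjective onto 1..6, and label-consistent", {
  mapped <- aggregate_crg_status(1:9)
  expect_length(mapped, 9)
  expect_true(all(mapped %in% 1:6))
  expect_setequal(unique(mapped), 1:6)
  # label-anchored cases: identical labels map across, minor chronic folds in
  expect_identical(aggregate_crg_status(1), 1L)
  expect_identical(aggregate_crg_status(8), 6L)
  expect_identical(aggregate_crg_status(4), 3L)
  # composite state 5 receives both dominant-3+-organ and catastrophic
  expect_identical(aggregate_crg_status(c(7, 9)), c(5L, 5L))
})

test_that("CRG codes outside 1..9 are rejected naming the offender", {
  expect_error(aggregate_crg_status(10), "10")
  expect_error(aggregate_crg_status(c(2, 0)), "0")
  expect_error(aggregate_crg_status(3, map = rep(1L, 9)), "surjective|onto|map")
})

test_that("every integer age maps to exactly one default age group", {
  sch <- age_group_scheme()
  expect_identical(sch$n_groups, 10L)
  expect_identical(sch$labels[1], "[0,1)")
  expect_identical(sch$labels[10], "[85,Inf)")
  g <- age_group_index(0:120, sch)
  expect_true(all(g %in% 1:10))
  # group boundaries land where the scheme says
  expect_identical(age_group_index(c(0, 1, 14, 15, 84, 85, 120)),
                   c(1L, 2L, 2L, 3L, 9L, 10L, 10L))
  expect_true(all(diff(sch$midpoints) > 0))
  expect_error(age_group_index(-1), "nonnegative")
})

test_that("record reading validates rows and reports rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,sex,age,state_t,state_t1",
               "a,female,30,1,1", "b,male,64,3,7", "c,F,0,2,2"), path)
  rec <- read_records(path)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$sex, c("female", "male", "female"))

  # baseline death is impossible; the row is rejected, others kept
  writeLines(c("person_id,sex,age,state_t,state_t1",
               "a,female,30,7,7", "b,male,64,3,2"), path)
  expect_warning(rec <- read_records(path), "row 1")
  expect_identical(nrow(rec), 1L)
  expect_identical(attr(rec, "rejects")$row, 1L)

  # empty file with header: empty collection plus warning
  writeLines("person_id,sex,age,state_t,state_t1", path)
  expect_warning(rec <- read_records(path), "empty|no data")
  expect_identical(nrow(rec), 0L)

  # missing column fails, zero valid rows fails
  writeLines(c("person_id,sex,age,state_t", "a,female,30,1"), path)
  expect_error(read_records(path), "state_t1")
  writeLines(c("person_id,sex,age,state_t,state_t1", "a,female,-3,1,1"), path)
  expect_warning(expect_error(read_records(path), "no valid rows"))
})

test_that("matrix-set serialization round-trips bit-exactly for both kinds", {
  set.seed(41)
  sch <- age_group_scheme()
  mats <- list()
  for (sex in c("female", "male")) {
    for (g in 1:10) mats[[sex]][[as.character(g)]] <- random_transition_matrix()
  }
  groups <- transition_matrix_set(mats, "age_group", midpoints = sch$midpoints)
  path <- withr::local_tempfile(fileext = ".json")
  write_matrix_set(groups, path)
  back <- read_matrix_set(path)
  expect_identical(back$index_kind, "age_group")
  expect_identical(back$midpoints, groups$midpoints)
  for (sex in c("female", "male")) {
    for (g in 1:10) {
      expect_identical(back$matrices[[sex]][[as.character(g)]],
                       unname(mats[[sex]][[as.character(g)]]))
    }
  }

  set.seed(42)
  yearly <- yearly_set_from(function(a) random_transition_matrix(0.02))
  expect_identical(sum(lengths(yearly$matrices)), 182L)
  write_matrix_set(yearly, path)
  back <- read_matrix_set(path)
  expect_identical(back$matrices, yearly$matrices)
})

test_that("invalid matrices never survive construction or read", {
  m <- stay_or_die_matrix(0.1)
  bad <- m; bad[1, ] <- bad[1, ] * 0.8
  expect_error(
    transition_matrix_set(list(female = list(`1` = bad)), "age_group"),
    "row 1 sums to 0.8")
  nonabs <- m; nonabs[7, ] <- c(1, rep(0, 6))
  expect_error(
    transition_matrix_set(list(female = list(`1` = nonabs)), "age_group"),
    "absorbing")

  # tampered file is rejected on read, naming the offender
  ok <- transition_matrix_set(list(female = list(`3` = m)), "age_group")
  path <- withr::local_tempfile(fileext = ".json")
  write_matrix_set(ok, path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  doc$entries[[1]]$matrix[2, 2] <- 0.5
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  expect_error(read_matrix_set(path), "age index 3.*row 2|row 2.*age index 3")
})
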