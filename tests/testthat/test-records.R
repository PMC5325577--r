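test_that("age filter is inclusive at the 24-month boundary", {
  rec <- data.frame(animal = c("a", "b", "c"), age_months = c(23L, 24L, 30L))
  out <- suppressMessages(filter_records(rec))
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_dropped"), 1L)

  # all eligible -> identity
  rec2 <- data.frame(animal = letters[1:4], age_months = c(24L, 36L, 48L, 120L))
  expect_equal(nrow(filter_records(rec2)), 4L)

  # 10 records, 3 underage -> 7 retained
  rec3 <- data.frame(animal = paste0("d", 1:10),
                     age_months = c(12L, 18L, 23L, 24L, 25L, 30L, 40L,
                                    50L, 60L, 70L))
  expect_equal(nrow(suppressMessages(filter_records(rec3))), 7L)

  expect_error(suppressMessages(
    filter_records(data.frame(animal = "a", age_months = 12L))),
    "no records remain")
})

test_that("evaluation year derives from birth date plus age in months", {
  expect_equal(derive_eval_year("1990-01", 24), 1992L)
  expect_equal(derive_eval_year("1990-11", 26), 1993L)  # crosses year boundary
  expect_equal(derive_eval_year("2000-06", 0), 2000L)
  expect_equal(derive_eval_year("2000-06-15", 12), 2001L)
  expect_true(is.na(derive_eval_year(NA_character_, 24)))
  expect_true(is.na(derive_eval_year("june 1990", 24)))
})

test_that("input validation reports score-range and identity issues", {
  ped <- pedigree(animal = c("a", "b"), sire = c(NA, NA), dam = c(NA, NA))
  rec <- data.frame(animal = c("a", "b", "ghost"),
                    sex = "F", birth_date = "2000-01",
                    age_months = c(30L, 40L, 50L),
                    hip_score = c(8L, 2L, 1L),
                    elbow_score = c(4L, NA, 1L),
                    eval_year = 2003L)
  issues <- validate_inputs(ped, rec)
  expect_equal(sum(issues$severity == "error"), 2L)  # hip 8 + unknown animal
  expect_true(any(grepl("hip_score 8", issues$message)))
  expect_true(any(issues$animal == "ghost"))
  # elbow score 4 is valid: no issue mentions it
  expect_false(any(grepl("elbow_score 4", issues$message)))
})

test_that("records round-trip through the delimited format", {
  tr <- small_truth(seed = 3)
  ds <- simulate_dataset(tr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(ds$records, path)
  rec2 <- read_records(path)
  expect_equal(rec2$animal, ds$records$animal)
  expect_equal(rec2$hip_score, ds$records$hip_score)
  expect_equal(rec2$age_months, ds$records$age_months)
  expect_equal(rec2$eval_year, ds$records$eval_year)
  expect_equal(rec2$birth_date, ds$records$birth_date)
})
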