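# Schema, CSV reading, the Cleveland loader and the band discretizer.

test_that("read_csv_dataset parses the sample patient rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  sample_rows_csv(f)
  ds <- read_csv_dataset(f, sample_schema())
  expect_equal(n_instances(ds), 2L)
  expect_setequal(dataset_labels(ds), c("0", "1"))
  expect_equal(ds$data$chol, c(322, 261))
  expect_equal(ds$data$thall, c("7", "7"))
})

test_that("header-only CSV gives an empty dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("age,sex,cp,trestbps,chol,fbs,induced_angina,thalach,st,slope,ca,thall,class", f)
  ds <- read_csv_dataset(f, sample_schema())
  expect_equal(n_instances(ds), 0L)
})

test_that("'?' cells become missing values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex,cp,trestbps,chol,fbs,induced_angina,thalach,st,slope,ca,thall,class",
               "55,0,3,115,322,0,0,160,1.6,2,?,7,0"), f)
  ds <- read_csv_dataset(f, sample_schema())
  expect_true(is.na(ds$data$ca[1]))
  expect_false(anyNA(ds$data$age))
})

test_that("schema errors name the offending column; bad numerics are addressed", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,sex", "55,0"), f)
  expect_error(read_csv_dataset(f, sample_schema()), "missing column.*cp")
  writeLines(c("age,sex,extra", "55,0,1"), f)
  expect_error(read_csv_dataset(f, sample_schema()), "unexpected column.*extra")
  sample_rows_csv(f)
  txt <- readLines(f)
  txt[2] <- sub("322", "oops", txt[2])
  writeLines(txt, f)
  expect_error(read_csv_dataset(f, sample_schema()), "column 'chol', row 1.*oops")
})

test_that("CSV write/read round trip preserves values, labels and missingness", {
  ds <- make_cleveland_like(40, seed = 3)
  ds$data$ca[c(2, 9)] <- NA
  ds$data$thal[5] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, f)
  back <- read_csv_dataset(f, cleveland_schema())
  expect_equal(back$data, ds$data)
})

test_that("load_cleveland handles the headerless UCI layout and collapses the class", {
  f <- withr::local_tempfile(fileext = ".data")
  synthetic_uci_csv(f)
  ds <- load_cleveland(f)
  expect_equal(n_instances(ds), 5L)
  expect_true(all(dataset_labels(ds) %in% c("0", "1")))
  # raw codes 2 and 3 collapse to "1"
  expect_equal(dataset_labels(ds), c("0", "1", "0", "1", "1"))
  expect_true(is.na(ds$data$ca[3]))       # "?" preserved
  expect_equal(ds$data$thal, c("6", "3", "3", "3", "3"))  # "6.0" canonicalized
})

test_that("load_cleveland accepts a header-bearing CSV and rejects bad layouts", {
  ds <- make_cleveland_like(15, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, f)
  back <- load_cleveland(f)
  expect_equal(back$data, ds$data)
  writeLines(c("1,2,3", "4,5,6"), f)
  expect_error(load_cleveland(f), "schema error: expected 14 columns")
})

test_that("discretize follows printed band order, first match wins", {
  expect_equal(discretize("cholesterol", 322), "Very higher")
  expect_equal(discretize("bp", 115), "Lower")
  # 230 satisfies both the 188-250 and 217-307 intervals; first printed wins
  expect_equal(discretize("cholesterol", 230), "Medium")
  expect_equal(discretize("age", 42), "Middle")     # overlaps 40-58 too
  expect_equal(discretize("ecg", 0.4), "Abnormal")  # inclusive endpoints
  expect_equal(discretize("smoking", 10), "Lower")
  expect_equal(discretize("blood_sugar", 120), "Yes")
})

test_that("discretize is total: UNBANDED for gaps, NA for missing, never throws", {
  expect_equal(discretize("thallium", 4), "UNBANDED")
  expect_equal(discretize("chest_pain", 2.5), "UNBANDED")
  expect_true(is.na(discretize("cholesterol", NA)))
  expect_error(discretize("nope", 1), "unknown banded attribute")
  # attributes whose bands cover the real line never yield UNBANDED
  for (att in c("cholesterol", "bp", "blood_sugar", "ecg", "age",
                "smoking", "family_history", "medical_records")) {
    vals <- seq(-10, 700, by = 7.3)
    expect_false(any(discretize(att, vals) == "UNBANDED"), label = att)
  }
})

test_that("attribute and schema invariants are enforced", {
  expect_error(attribute_spec("x", "categorical"), "category")
  expect_error(attribute_spec("x", "numeric", categories = c("a")), "categories")
  expect_error(dataset_schema(list(attribute_spec("a", "numeric"),
                                   attribute_spec("a", "numeric")),
                              attribute_spec("y", "categorical", categories = "0")),
               "duplicate")
  expect_error(dataset_schema(list(attribute_spec("a", "numeric")),
                              attribute_spec("a", "categorical", categories = "0")),
               "duplicates a predictor")
  sch <- toy_schema()
  expect_error(new_dataset(sch, data.frame(x1 = 1, x2 = 1, x3 = 1, c1 = "z",
                                           class = "pos")),
               "not a declared category")
})
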