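# CSV readers/writers and the UCI Cleveland heart-disease loader.

#' Read a CSV file against a schema
#'
#' RFC-4180-style CSV with a header row. The header must contain exactly the
#' schema's predictor names (order-insensitive) and optionally the class
#' column. The token `"?"` (and the empty string) is the missing-value
#' marker and becomes NA.
#'
#' @param path Path to the CSV file.
#' @param schema An `rr_schema` describing the columns.
#' @return An `rr_dataset`.
#' @export
read_csv_dataset <- function(path, schema) {
  if (!file.exists(path)) stopf("I/O error: no such file: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, strip.white = TRUE)
  pn <- schema_names(schema)
  cn <- schema$class_attribute$name
  extra <- setdiff(names(df), c(pn, cn))
  if (length(extra)) {
    stopf("schema error: unexpected column(s): %s", paste(extra, collapse = ", "))
  }
  missing_cols <- setdiff(pn, names(df))
  if (length(missing_cols)) {
    stopf("schema error: missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  new_dataset(schema, df)
}

#' Write a dataset as CSV
#'
#' Inverse of [read_csv_dataset()]: NA values are written as `"?"` so that a
#' round trip preserves missingness.
#'
#' @param ds An `rr_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(ds, path) {
  df <- ds$data
  for (j in seq_along(df)) {
    col <- df[[j]]
    col <- if (is.numeric(col)) {
      ifelse(is.na(col), "?", fmt_num(col))
    } else {
      ifelse(is.na(col), "?", col)
    }
    df[[j]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shortest decimal representation that round-trips through as.numeric().
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  short <- sprintf("%g", x)
  ok <- !is.na(x) & suppressWarnings(as.numeric(short) == x)
  ok[is.na(ok)] <- FALSE
  out[ok] <- short[ok]
  out
}

#' The 13-predictor Cleveland heart-disease schema
#'
#' The standard processed UCI Cleveland layout: thirteen predictors plus a
#' binary diagnosis class (`"0"` healthy, `"1"` presence of heart disease).
#' Numeric ranges are the observed Cleveland ranges and drive the synthetic
#' generator only.
#'
#' @return An `rr_schema` with 13 predictor attributes and class `num`.
#' @export
cleveland_schema <- function() {
  dataset_schema(
    attributes = list(
      attribute_spec("age", "numeric", range = c(29, 77), discrete = TRUE,
                     description = "age in years"),
      attribute_spec("sex", "categorical", categories = c("0", "1"),
                     description = "1 = male, 0 = female"),
      attribute_spec("cp", "categorical", categories = c("1", "2", "3", "4"),
                     description = paste("chest pain type: 1 typical angina,",
                                         "2 atypical angina, 3 non-anginal, 4 asymptomatic")),
      attribute_spec("trestbps", "numeric", range = c(94, 200), discrete = TRUE,
                     description = "resting blood pressure (mm Hg)"),
      attribute_spec("chol", "numeric", range = c(126, 564), discrete = TRUE,
                     description = "serum cholesterol (mg/dl)"),
      attribute_spec("fbs", "categorical", categories = c("0", "1"),
                     description = "fasting blood sugar > 120 mg/dl"),
      attribute_spec("restecg", "categorical", categories = c("0", "1", "2"),
                     description = "resting ECG: 0 normal, 1 ST-T abnormality, 2 LV hypertrophy"),
      attribute_spec("thalach", "numeric", range = c(71, 202), discrete = TRUE,
                     description = "maximum heart rate achieved"),
      attribute_spec("exang", "categorical", categories = c("0", "1"),
                     description = "exercise-induced angina: 0 no, 1 yes"),
      attribute_spec("oldpeak", "numeric", range = c(0, 6.2),
                     description = "ST depression induced by exercise relative to rest"),
      attribute_spec("slope", "categorical", categories = c("1", "2", "3"),
                     description = "slope of peak exercise ST segment"),
      attribute_spec("ca", "numeric", range = c(0, 3), discrete = TRUE,
                     description = "major vessels colored by fluoroscopy (0-3)"),
      attribute_spec("thal", "categorical", categories = c("3", "6", "7"),
                     description = "thallium scan: 3 normal, 6 fixed defect, 7 reversible defect")
    ),
    class_attribute = attribute_spec("num", "categorical",
                                     categories = c("0", "1"),
                                     description = "0 healthy, 1 presence of heart disease")
  )
}

#' Load a Cleveland heart-disease file
#'
#' Accepts either the raw UCI `processed.cleveland.data` comma layout (14
#' headerless columns in the fixed UCI order) or a header-bearing CSV using
#' the [cleveland_schema()] names. The multi-level diagnosis (0-4) is
#' collapsed to binary: any value > 0 becomes `"1"`. Missing markers `"?"`
#' are preserved as NA.
#'
#' @param path Path to the data file.
#' @return An `rr_dataset` with the Cleveland schema.
#' @export
load_cleveland <- function(path) {
  if (!file.exists(path)) stopf("I/O error: no such file: %s", path)
  schema <- cleveland_schema()
  pn <- schema_names(schema)
  first <- readLines(path, n = 1L)
  toks <- trimws(strsplit(first, ",", fixed = TRUE)[[1]])
  has_header <- all(pn %in% toks)
  if (has_header) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, strip.white = TRUE)
    if (!(schema$class_attribute$name %in% names(df))) {
      stopf("schema error: missing class column '%s'", schema$class_attribute$name)
    }
  } else {
    df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          na.strings = NULL, strip.white = TRUE)
    if (ncol(df) != 14L) {
      stopf("schema error: expected 14 columns in headerless Cleveland file, got %d", ncol(df))
    }
    names(df) <- c(pn, schema$class_attribute$name)
  }
  # The raw UCI file writes integer codes as "3.0", "0.0", ...; canonicalize
  # categorical codes before schema validation, and collapse the class.
  for (nm in c("sex", "cp", "fbs", "restecg", "exang", "slope", "thal")) {
    df[[nm]] <- strip_dot_zero(df[[nm]])
  }
  cls <- strip_dot_zero(df[[schema$class_attribute$name]])
  cls[cls %in% c("?", "")] <- NA_character_
  num <- suppressWarnings(as.numeric(cls))
  cls[!is.na(num) & num > 0] <- "1"
  cls[!is.na(num) & num == 0] <- "0"
  df[[schema$class_attribute$name]] <- cls
  new_dataset(schema, df)
}

strip_dot_zero <- function(x) sub("\\.0+$", "", x)
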