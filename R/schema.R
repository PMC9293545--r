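# Dataset schemas and the tabular container used throughout the package.
#
# A dataset is a light S3 object: a schema (ordered attribute specs plus a
# categorical class attribute) and a data.frame holding one row per
# instance. Numeric attributes are numeric columns; categorical attributes
# are character columns restricted to their declared categories. Missing
# values are NA everywhere (the CSV reader maps the "?" token to NA).

#' Declare a predictor or class attribute
#'
#' @param name Attribute name (unique within a schema).
#' @param kind `"numeric"` or `"categorical"`.
#' @param categories Ordered character vector of admissible values
#'   (categorical attributes only; at least one).
#' @param range Length-2 numeric vector giving the plausible value range.
#'   Used only by the synthetic generator; numeric attributes only.
#' @param discrete If `TRUE`, the synthetic generator samples integers from
#'   `range` instead of continuous values (e.g. a fluoroscopy vessel count).
#' @param description Free-text description.
#' @return An `rr_attribute` object.
#' @export
attribute_spec <- function(name, kind = c("numeric", "categorical"),
                           categories = NULL, range = c(0, 1),
                           discrete = FALSE, description = "") {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("attribute name must be a non-empty string")
  }
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 1L) {
      stopf("categorical attribute '%s' needs >= 1 category", name)
    }
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      stopf("duplicate categories for attribute '%s'", name)
    }
  } else if (!is.null(categories)) {
    stopf("numeric attribute '%s' must not declare categories", name)
  }
  structure(
    list(name = name, kind = kind, categories = categories,
         range = as.numeric(range), discrete = isTRUE(discrete),
         description = description),
    class = "rr_attribute"
  )
}

#' Assemble a dataset schema
#'
#' @param attributes List of predictor [attribute_spec()] objects, in column
#'   order.
#' @param class_attribute A categorical [attribute_spec()] naming the class
#'   column; must not duplicate a predictor name.
#' @return An `rr_schema` object.
#' @export
dataset_schema <- function(attributes, class_attribute) {
  stopifnot(is.list(attributes), length(attributes) >= 1L)
  for (a in attributes) {
    if (!inherits(a, "rr_attribute")) stopf("attributes must be attribute_spec objects")
  }
  if (!inherits(class_attribute, "rr_attribute") ||
      class_attribute$kind != "categorical") {
    stopf("class attribute must be a categorical attribute_spec")
  }
  nms <- vapply(attributes, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate attribute names in schema")
  if (class_attribute$name %in% nms) {
    stopf("class attribute '%s' duplicates a predictor", class_attribute$name)
  }
  structure(
    list(attributes = attributes, class_attribute = class_attribute),
    class = "rr_schema"
  )
}

schema_names <- function(schema) vapply(schema$attributes, `[[`, "", "name")

schema_attr <- function(schema, name) {
  for (a in schema$attributes) if (a$name == name) return(a)
  if (schema$class_attribute$name == name) return(schema$class_attribute)
  stopf("unknown attribute '%s'", name)
}

#' Construct a dataset from a data.frame
#'
#' Columns are coerced to the schema's types and validated: categorical
#' values must be declared categories (or NA), numeric columns numeric. The
#' class column is optional (unlabeled data).
#'
#' @param schema An `rr_schema`.
#' @param df A data.frame with one column per predictor (schema names) and
#'   optionally the class column.
#' @return An `rr_dataset`.
#' @export
new_dataset <- function(schema, df) {
  pn <- schema_names(schema)
  cn <- schema$class_attribute$name
  missing_cols <- setdiff(pn, names(df))
  if (length(missing_cols)) {
    stopf("schema error: missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  has_class <- cn %in% names(df)
  out <- df[, c(pn, if (has_class) cn), drop = FALSE]
  for (a in schema$attributes) {
    out[[a$name]] <- coerce_column(out[[a$name]], a, a$name)
  }
  if (has_class) {
    out[[cn]] <- coerce_column(out[[cn]], schema$class_attribute, cn)
  }
  rownames(out) <- NULL
  structure(list(schema = schema, data = out), class = "rr_dataset")
}

coerce_column <- function(x, spec, name) {
  if (spec$kind == "numeric") {
    if (is.character(x)) {
      x[x %in% c("?", "")] <- NA_character_
      bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad)) {
        stopf("unparseable numeric cell in column '%s', row %d: '%s'",
              name, which(bad)[1L], x[which(bad)[1L]])
      }
      x <- as.numeric(x)
    }
    if (!is.numeric(x)) stopf("column '%s' must be numeric", name)
    as.numeric(x)
  } else {
    x <- as.character(x)
    x[x %in% c("?", "")] <- NA_character_
    bad <- !is.na(x) & !(x %in% spec$categories)
    if (any(bad)) {
      stopf("value '%s' (row %d) not a declared category of '%s'",
            x[which(bad)[1L]], which(bad)[1L], name)
    }
    x
  }
}

#' @export
print.rr_dataset <- function(x, ...) {
  cat(sprintf("<rr_dataset> %d instances, %d predictors, class '%s'\n",
              n_instances(x), length(x$schema$attributes),
              x$schema$class_attribute$name))
  invisible(x)
}

#' Number of instances in a dataset
#' @param ds An `rr_dataset`.
#' @return Integer row count.
#' @export
n_instances <- function(ds) nrow(ds$data)

#' Class labels of a dataset
#' @param ds An `rr_dataset`.
#' @return Character vector of labels (NA where unlabeled), or NULL if the
#'   dataset carries no class column.
#' @export
dataset_labels <- function(ds) {
  cn <- ds$schema$class_attribute$name
  if (cn %in% names(ds$data)) ds$data[[cn]] else NULL
}

# Row-subset a dataset (keeps schema).
subset_dataset <- function(ds, idx) {
  d <- ds$data[idx, , drop = FALSE]
  rownames(d) <- NULL
  structure(list(schema = ds$schema, data = d), class = "rr_dataset")
}

# Bind two datasets sharing a schema.
rbind_dataset <- function(a, b) {
  structure(list(schema = a$schema, data = rbind(a$data, b$data)),
            class = "rr_dataset")
}
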