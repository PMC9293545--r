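# Conditions, rules and ordered rule sets (decision lists).
#
# A condition is attribute OP value with OP in {=, <=, >=}: equality on
# categorical attributes, thresholds on numeric ones. A rule is a
# conjunction of conditions with a class consequent; a rule set is an
# ordered decision list closed by a default class. Matching is first-match
# and a missing (NA) value fails every condition, so incomplete records
# fall through to later rules or the default.

#' Build a rule condition
#'
#' @param attribute Attribute name.
#' @param op `"="` (categorical equality), `"<="` or `">="` (numeric).
#' @param value Category token for `"="`; numeric threshold otherwise.
#' @return An `rr_condition`.
#' @export
condition <- function(attribute, op, value) {
  if (!op %in% c("=", "<=", ">=")) stopf("unknown operator '%s'", op)
  if (op == "=") {
    value <- as.character(value)
  } else {
    value <- as.numeric(value)
    if (is.na(value)) stopf("numeric condition on '%s' needs a numeric threshold", attribute)
  }
  structure(list(attribute = attribute, op = op, value = value),
            class = "rr_condition")
}

#' Build a rule
#'
#' @param conditions List of [condition()] objects (possibly empty). The
#'   antecedent may not contain duplicate (attribute, op, value) triples.
#' @param consequent Class token.
#' @return An `rr_rule`.
#' @export
rule <- function(conditions = list(), consequent) {
  keys <- vapply(conditions, function(cc) {
    paste(cc$attribute, cc$op, as.character(cc$value))
  }, character(1))
  if (anyDuplicated(keys)) stopf("duplicate condition in antecedent")
  structure(list(conditions = conditions, consequent = as.character(consequent)),
            class = "rr_rule")
}

#' Build a rule set (decision list)
#'
#' @param rules Ordered list of [rule()] objects.
#' @param default_class Class assigned when no rule matches (the implicit
#'   empty-antecedent default rule).
#' @return An `rr_ruleset`.
#' @export
ruleset <- function(rules = list(), default_class) {
  structure(list(rules = rules, default_class = as.character(default_class)),
            class = "rr_ruleset")
}

n_conditions <- function(r) length(r$conditions)

#' @export
format.rr_rule <- function(x, ...) {
  ant <- if (n_conditions(x) == 0L) "TRUE" else {
    paste(vapply(x$conditions, function(cc) {
      val <- if (cc$op == "=") cc$value else fmt_num(cc$value)
      paste(cc$attribute, cc$op, val)
    }, character(1)), collapse = " AND ")
  }
  sprintf("IF %s THEN %s", ant, x$consequent)
}

#' @export
print.rr_rule <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.rr_ruleset <- function(x, ...) {
  cat(serialize_ruleset(x), sep = "\n")
  invisible(x)
}

# Logical vector: which rows of the dataset satisfy every condition.
# NA values fail their condition (no-imputation policy).
rule_matches <- function(r, ds) {
  df <- ds$data
  m <- rep(TRUE, nrow(df))
  for (cc in r$conditions) {
    if (!cc$attribute %in% names(df)) {
      stopf("schema error: rule refers to unknown attribute '%s'", cc$attribute)
    }
    col <- df[[cc$attribute]]
    hit <- switch(cc$op,
      "="  = !is.na(col) & col == cc$value,
      "<=" = !is.na(col) & col <= cc$value,
      ">=" = !is.na(col) & col >= cc$value
    )
    m <- m & hit
    if (!any(m)) break
  }
  m
}

#' Does a rule match an instance?
#'
#' @param r An `rr_rule`.
#' @param instance A single-row data.frame or named list of values.
#' @param ds Optional `rr_dataset` the instance belongs to; when given,
#'   `instance` may be a row index.
#' @return Logical scalar; an empty antecedent matches everything.
#' @export
matches <- function(r, instance, ds = NULL) {
  if (!is.null(ds) && is.numeric(instance)) {
    return(rule_matches(r, subset_dataset(ds, instance)))
  }
  df <- as.data.frame(instance, stringsAsFactors = FALSE)
  rule_matches(r, structure(list(schema = NULL, data = df), class = "rr_dataset"))
}

#' Coverage counts of a rule over a dataset
#'
#' Counts positives (label equals `positive_class`) and negatives among the
#' instances the rule matches; these are the p and n of the pruning metric
#' and the cover/precision of the growth gain.
#'
#' @param r An `rr_rule`.
#' @param ds A labeled `rr_dataset`.
#' @param positive_class Class token counted as positive.
#' @return An `rr_coverage`: list with `p`, `n`, `cover` (= p) and `rt`
#'   (= p/(p+n), NA when the rule covers nothing).
#' @export
coverage <- function(r, ds, positive_class) {
  lab <- dataset_labels(ds)
  if (is.null(lab)) stopf("dataset has no class labels")
  m <- rule_matches(r, ds)
  p <- sum(m & !is.na(lab) & lab == positive_class)
  n <- sum(m) - p
  coverage_stats(p, n)
}

#' Assemble coverage counts directly
#'
#' @param p Positive instances covered.
#' @param n Negative instances covered.
#' @return An `rr_coverage`.
#' @export
coverage_stats <- function(p, n) {
  if (p < 0 || n < 0) stopf("coverage counts must be non-negative")
  structure(list(p = p, n = n, cover = p,
                 rt = if (p + n > 0) p / (p + n) else NA_real_),
            class = "rr_coverage")
}

#' Predict classes with a decision list
#'
#' First matching rule wins; instances matching no rule get the default
#' class.
#'
#' @param object An `rr_ruleset`.
#' @param ds An `rr_dataset` (labels, if present, are ignored).
#' @param ... Unused.
#' @return Character vector of predicted class tokens, one per instance.
#' @export
predict.rr_ruleset <- function(object, ds, ...) {
  n <- n_instances(ds)
  out <- rep(object$default_class, n)
  open <- rep(TRUE, n)
  for (r in object$rules) {
    if (!any(open)) break
    m <- open & rule_matches(r, ds)
    out[m] <- r$consequent
    open[m] <- FALSE
  }
  out
}

# --- serialization -----------------------------------------------------------
#
# Grammar (one rule per line, last line is the default rule):
#   ruleset  := meta* ruleline* defaultline
#   meta     := "#%" key "=" value
#   ruleline := "IF" antecedent "THEN" class
#   antecedent := "TRUE" | cond (" AND " cond)*
#   cond     := attribute (" = " token | " <= " number | " >= " number)
# Tokens (attributes, categories, classes) must be whitespace-free.

#' Serialize a rule set to its text grammar
#'
#' @param rs An `rr_ruleset`.
#' @param meta Named list of metadata strings written as `#%` header lines.
#' @return Character vector of lines.
#' @export
serialize_ruleset <- function(rs, meta = list()) {
  meta <- c(list(format = "ripperr-rules", version = "1"), meta)
  hdr <- sprintf("#%% %s=%s", names(meta), vapply(meta, as.character, ""))
  body <- vapply(rs$rules, format, character(1))
  c(hdr, body, sprintf("IF TRUE THEN %s", rs$default_class))
}

#' Parse a rule set from its text grammar
#'
#' @param lines Character vector of lines (or a single string with
#'   newlines).
#' @return An `rr_ruleset`; metadata header lines are attached as the
#'   `"meta"` attribute.
#' @export
parse_ruleset <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  meta <- list()
  rules <- list()
  default_class <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#%")) {
      kv <- sub("^#%\\s*", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
      next
    }
    if (startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^IF (.+) THEN (\\S+)$", ln))[[1]]
    if (length(m) != 3L) stopf("parse error at line %d: '%s'", i, ln)
    r <- rule(parse_antecedent(m[2], i), m[3])
    if (n_conditions(r) == 0L) {
      default_class <- r$consequent  # default rule; must be last
    } else {
      if (!is.null(default_class)) {
        stopf("parse error at line %d: rules after the default rule", i)
      }
      rules[[length(rules) + 1L]] <- r
    }
  }
  if (is.null(default_class)) stopf("parse error: no default (IF TRUE) rule found")
  out <- ruleset(rules, default_class)
  attr(out, "meta") <- meta
  out
}

parse_antecedent <- function(txt, lineno) {
  if (identical(trimws(txt), "TRUE")) return(list())
  parts <- strsplit(txt, " AND ", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\S+) (=|<=|>=) (\\S+)$", trimws(p)))[[1]]
    if (length(m) != 4L) stopf("parse error at line %d: bad condition '%s'", lineno, p)
    condition(m[2], m[3], m[4])
  })
}

#' Write / read a rule set file
#'
#' @param rs An `rr_ruleset`.
#' @param path File path.
#' @param meta Named list of metadata recorded in the header.
#' @return `path` invisibly (write); an `rr_ruleset` (read).
#' @export
write_ruleset <- function(rs, path, meta = list()) {
  writeLines(serialize_ruleset(rs, meta), path)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stopf("I/O error: no such file: %s", path)
  parse_ruleset(readLines(path))
}
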