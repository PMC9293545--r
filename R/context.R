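# Context-aware clinical screening: a static knowledge base of eleven
# ordered rules over banded patient attributes. The rules combine the
# thallium scan (code 3 "less"/normal vs 6 or 7 "higher"/defect), chest
# pain type, fluoroscopy vessel count (0 "less" vs >= 1 "higher"),
# exercise-induced angina, and history attributes (family history, medical
# records). Evaluation is first-match in printed order; the printed order
# makes rule 8 unreachable on complete records (rules 6-7 exhaust its
# premises), which is preserved and surfaced by the reachability report
# rather than repaired. Records matching no rule get the DEFAULT outcome
# no_heart_disease, flagged as such.

context_outcomes <- c("no_heart_disease", "presence", "presence_1", "presence_2")

#' The context screening rule set
#'
#' Eleven ordered rules over the derived (banded) patient attributes
#' `thallium` (less/higher), `chest_pain` (typical_angina, atypical_angina,
#' nonangina, asymptomatic), `vessel` (less/higher), `angina` (yes/no),
#' `family_history` (yes/no) and `medical_record` (yes/no).
#'
#' @return List of 11 `rr_rule` objects in evaluation order, each carrying
#'   an integer `"id"` attribute.
#' @export
load_context_ruleset <- function() {
  cr <- function(id, conds, outcome) {
    r <- rule(lapply(conds, function(kv) condition(kv[[1]], "=", kv[[2]])), outcome)
    attr(r, "id") <- id
    r
  }
  list(
    cr(1L, list(c("thallium", "less"), c("chest_pain", "typical_angina")), "no_heart_disease"),
    cr(2L, list(c("thallium", "less"), c("chest_pain", "atypical_angina")), "no_heart_disease"),
    cr(3L, list(c("thallium", "less"), c("chest_pain", "nonangina")), "no_heart_disease"),
    cr(4L, list(c("thallium", "less"), c("chest_pain", "asymptomatic"), c("vessel", "less")), "no_heart_disease"),
    cr(5L, list(c("thallium", "less"), c("chest_pain", "asymptomatic"), c("vessel", "higher")), "presence_2"),
    cr(6L, list(c("thallium", "higher"), c("vessel", "less"), c("angina", "no")), "no_heart_disease"),
    cr(7L, list(c("thallium", "higher"), c("vessel", "less"), c("angina", "yes")), "presence"),
    cr(8L, list(c("thallium", "higher"), c("vessel", "less")), "presence_2"),
    cr(9L, list(c("family_history", "yes")), "presence_1"),
    cr(10L, list(c("medical_record", "yes")), "presence_1"),
    cr(11L, list(c("family_history", "yes"), c("medical_record", "yes")), "presence_1")
  )
}

cp_labels <- c("typical_angina", "atypical_angina", "nonangina", "asymptomatic")

#' Build a validated patient record for context screening
#'
#' All fields optional (NA when unknown); coded fields are range-checked.
#'
#' @param chest_pain Chest pain type code 1-4.
#' @param cholesterol Serum cholesterol (mg/dl).
#' @param bp Resting blood pressure (mm Hg).
#' @param blood_sugar Fasting blood sugar (mg/dl).
#' @param ecg_st Exercise-induced ST depression.
#' @param thallium Thallium scan code: 3, 6 or 7.
#' @param age Age in years.
#' @param gender 1 male, 0 female.
#' @param smoking_years Years of smoking.
#' @param drinking 0 no, 1 yes.
#' @param family_history Count of relevant familial conditions (>= 1 reads
#'   as "yes").
#' @param medical_records Count of relevant prior conditions (>= 1 reads as
#'   "yes").
#' @param vessels Fluoroscopy vessel count 0-3.
#' @param induced_angina Exercise-induced angina: 0 no, 1 yes.
#' @return An `rr_patient` (named list).
#' @export
patient_record <- function(chest_pain = NA, cholesterol = NA, bp = NA,
                           blood_sugar = NA, ecg_st = NA, thallium = NA,
                           age = NA, gender = NA, smoking_years = NA,
                           drinking = NA, family_history = NA,
                           medical_records = NA, vessels = NA,
                           induced_angina = NA) {
  rec <- list(chest_pain = chest_pain, cholesterol = cholesterol, bp = bp,
              blood_sugar = blood_sugar, ecg_st = ecg_st, thallium = thallium,
              age = age, gender = gender, smoking_years = smoking_years,
              drinking = drinking, family_history = family_history,
              medical_records = medical_records, vessels = vessels,
              induced_angina = induced_angina)
  rec <- lapply(rec, function(x) suppressWarnings(as.numeric(x)))
  check_code <- function(field, allowed) {
    v <- rec[[field]]
    if (!is.na(v) && !(v %in% allowed)) {
      stopf("validation error: field '%s' has invalid code %s (allowed: %s)",
            field, format(v), paste(allowed, collapse = ", "))
    }
  }
  check_code("chest_pain", 1:4)
  check_code("thallium", c(3, 6, 7))
  check_code("gender", 0:1)
  check_code("drinking", 0:1)
  check_code("induced_angina", 0:1)
  check_code("vessels", 0:3)
  structure(rec, class = "rr_patient")
}

# Derived categorical view of a record, as used by the rule antecedents.
derive_context_features <- function(rec, vessel_threshold = 1) {
  list(
    thallium = if (is.na(rec$thallium)) NA_character_
               else if (rec$thallium == 3) "less" else "higher",
    chest_pain = if (is.na(rec$chest_pain)) NA_character_
                 else cp_labels[rec$chest_pain],
    vessel = if (is.na(rec$vessels)) NA_character_
             else if (rec$vessels < vessel_threshold) "less" else "higher",
    angina = if (is.na(rec$induced_angina)) NA_character_
             else if (rec$induced_angina == 1) "yes" else "no",
    family_history = if (is.na(rec$family_history)) NA_character_
                     else if (rec$family_history >= 1) "yes" else "no",
    medical_record = if (is.na(rec$medical_records)) NA_character_
                     else if (rec$medical_records >= 1) "yes" else "no"
  )
}

match_context <- function(features) {
  for (r in load_context_ruleset()) {
    hit <- TRUE
    for (cc in r$conditions) {
      v <- features[[cc$attribute]]
      if (is.na(v) || v != cc$value) { hit <- FALSE; break }
    }
    if (hit) return(list(id = attr(r, "id"), outcome = r$consequent))
  }
  list(id = NA_integer_, outcome = "no_heart_disease")  # DEFAULT
}

#' Assess a patient record with the context rule set
#'
#' Discretizes the banded fields (first-match, printed band order), derives
#' the rule attributes (thallium less/higher, vessel less/higher, ...), and
#' fires the first matching rule. A record matching no rule receives the
#' DEFAULT outcome `no_heart_disease` with `fired_rule = "DEFAULT"` so the
#' rule set's incompleteness stays visible.
#'
#' @param record An [patient_record()] (or a named list / single-row
#'   data.frame of its fields).
#' @param vessel_threshold Fluoroscopy count at or above which the vessel
#'   attribute reads "higher" (default 1).
#' @return An `rr_assessment`: list with `outcome`, `fired_rule` (rule id
#'   1-11 or `"DEFAULT"`), `features` and `band_trace` (data.frame of
#'   attribute, raw value, band).
#' @export
assess <- function(record, vessel_threshold = 1) {
  if (!inherits(record, "rr_patient")) {
    record <- do.call(patient_record, as.list(record)[names(formals(patient_record))[
      names(formals(patient_record)) %in% names(as.list(record))]])
  }
  feats <- derive_context_features(record, vessel_threshold)
  banded <- c(chest_pain = "chest_pain", cholesterol = "cholesterol", bp = "bp",
              blood_sugar = "blood_sugar", ecg_st = "ecg", thallium = "thallium",
              age = "age", gender = "gender", smoking_years = "smoking",
              drinking = "drinking", family_history = "family_history",
              medical_records = "medical_records")
  trace <- data.frame(
    attribute = names(banded),
    raw = vapply(names(banded), function(f) record[[f]], numeric(1)),
    band = vapply(names(banded), function(f) {
      v <- record[[f]]
      if (is.na(v)) NA_character_ else discretize(banded[[f]], v)
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  hit <- match_context(feats)
  structure(list(
    outcome = hit$outcome,
    fired_rule = if (is.na(hit$id)) "DEFAULT" else hit$id,
    features = feats,
    band_trace = trace
  ), class = "rr_assessment")
}

#' @export
print.rr_assessment <- function(x, ...) {
  cat(sprintf("outcome: %s (rule %s)\n", x$outcome, x$fired_rule))
  invisible(x)
}

#' Reachability and coverage audit of the context rule set
#'
#' Enumerates every combination of the derived rule attributes (complete
#' records, no missing values) and records which rule fires first. Under
#' the printed order rule 8 is shadowed by rules 6-7 and never fires.
#'
#' @return List with `grid` (one row per combination, with `fired_rule`),
#'   `reachable`, `unreachable` (rule ids), and `default_fraction` (share
#'   of combinations falling through to DEFAULT).
#' @export
context_reachability <- function() {
  grid <- expand.grid(
    thallium = c("less", "higher"), chest_pain = cp_labels,
    vessel = c("less", "higher"), angina = c("no", "yes"),
    family_history = c("no", "yes"), medical_record = c("no", "yes"),
    stringsAsFactors = FALSE
  )
  fired <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hit <- match_context(as.list(grid[i, ]))
    fired[i] <- if (is.na(hit$id)) 0L else hit$id
  }
  grid$fired_rule <- ifelse(fired == 0L, "DEFAULT", fired)
  ids <- seq_len(11L)
  list(
    grid = grid,
    reachable = ids[ids %in% fired],
    unreachable = ids[!ids %in% fired],
    default_fraction = mean(fired == 0L)
  )
}

#' Screen a table of patient records
#'
#' @param df Data.frame with [patient_record()] field names as columns
#'   (missing columns read as NA; `"?"` cells read as missing).
#' @param vessel_threshold See [assess()].
#' @return Data.frame with one row per input row: `outcome`, `fired_rule`,
#'   `band_trace` (compact `attr=band` string) and `error` (NA on success;
#'   invalid rows carry their validation message and empty outcome).
#' @export
screen_records <- function(df, vessel_threshold = 1) {
  fields <- names(formals(patient_record))
  n <- nrow(df)
  out <- data.frame(row = seq_len(n), outcome = rep(NA_character_, n),
                    fired_rule = rep(NA_character_, n),
                    band_trace = rep(NA_character_, n),
                    error = rep(NA_character_, n), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    args <- list()
    for (f in fields) {
      if (f %in% names(df)) {
        v <- df[[f]][i]
        if (is.character(v) && (is.na(v) || v %in% c("?", ""))) v <- NA
        args[[f]] <- v
      }
    }
    res <- tryCatch({
      a <- assess(do.call(patient_record, args), vessel_threshold)
      tr <- a$band_trace[!is.na(a$band_trace$band), , drop = FALSE]
      out$outcome[i] <- a$outcome
      out$fired_rule[i] <- as.character(a$fired_rule)
      out$band_trace[i] <- paste(sprintf("%s=%s", tr$attribute, tr$band), collapse = ";")
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) out$error[i] <- res
  }
  out
}

#' Export the context rule set in the rule text grammar
#'
#' @return Character vector of lines (one `IF ... THEN ...` rule per line
#'   plus the DEFAULT rule).
#' @export
serialize_context_ruleset <- function() {
  serialize_ruleset(ruleset(load_context_ruleset(), "no_heart_disease"),
                    meta = list(ruleset = "context-screening"))
}
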