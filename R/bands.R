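# Clinical attribute bands used by the context screening rules.
#
# Each banded attribute carries an ordered list of predicates over the raw
# value. Several printed intervals overlap (cholesterol 188-250 vs 217-307,
# age 35-45 vs 40-58); resolution is deliberately first-match in printed
# order, so the earlier band wins. Closed intervals include both endpoints;
# one-sided bands keep their printed strictness.

#' The clinical band table
#'
#' Ordered discretization bands for the attributes used by the context
#' screening rule set: chest pain type codes, serum cholesterol, resting
#' blood pressure, fasting blood sugar, exercise ST depression, thallium
#' scan codes, age, gender, smoking years, drinking, family history and
#' medical-record counts.
#'
#' @return Named list; each element is an ordered list of bands, a band
#'   being `list(label, type, a, b)` with `type` one of `"lt"`, `"gt"`,
#'   `"le"`, `"ge"`, `"eq"`, `"between"` (closed interval).
#' @export
band_table <- function() {
  b <- function(label, type, a, b = NA_real_) list(label = label, type = type, a = a, b = b)
  list(
    chest_pain = list(
      b("Typical angina", "eq", 1), b("Atypical angina", "eq", 2),
      b("Nonangina", "eq", 3), b("Asymptomatic", "eq", 4)
    ),
    cholesterol = list(
      b("Lower", "lt", 197), b("Medium", "between", 188, 250),
      b("Higher", "between", 217, 307), b("Very higher", "gt", 281)
    ),
    bp = list(
      b("Lower", "lt", 134), b("Medium", "between", 124, 153),
      b("Higher", "between", 142, 172), b("Very higher", "gt", 154)
    ),
    blood_sugar = list(b("No", "lt", 120), b("Yes", "ge", 120)),
    ecg = list(
      b("Normal", "lt", 0.4), b("Abnormal", "between", 0.4, 1.8),
      b("Hypertrophy", "gt", 1.8)
    ),
    thallium = list(
      b("Normal", "eq", 3), b("Fixed defect", "eq", 6),
      b("Reversible defect", "eq", 7)
    ),
    age = list(
      b("Younger", "lt", 35), b("Middle", "between", 35, 45),
      b("Older", "between", 40, 58), b("Very older", "gt", 58)
    ),
    gender = list(b("Male", "eq", 1), b("Female", "eq", 0)),
    smoking = list(b("Lower", "le", 10), b("Higher", "gt", 10)),
    drinking = list(b("No", "eq", 0), b("Yes", "eq", 1)),
    family_history = list(b("No", "lt", 1), b("Yes", "ge", 1)),
    medical_records = list(b("No", "lt", 1), b("Yes", "ge", 1))
  )
}

band_holds <- function(band, x) {
  switch(band$type,
    lt = x < band$a,
    gt = x > band$a,
    le = x <= band$a,
    ge = x >= band$a,
    eq = x == band$a,
    between = x >= band$a & x <= band$b,
    stopf("unknown band type '%s'", band$type)
  )
}

#' Discretize a raw value into its clinical band
#'
#' Returns the label of the first band (in printed order) whose predicate
#' holds. Attributes whose bands do not cover the whole real line can yield
#' the sentinel `"UNBANDED"`; a missing input yields NA.
#'
#' @param attribute Band-table attribute name (see [band_table()]).
#' @param raw_value Numeric raw value (a code for coded attributes).
#' @return Band label, `"UNBANDED"`, or NA for missing input.
#' @export
discretize <- function(attribute, raw_value) {
  tab <- band_table()
  if (!attribute %in% names(tab)) stopf("unknown banded attribute '%s'", attribute)
  vapply(as.numeric(raw_value), function(x) {
    if (is.na(x)) return(NA_character_)
    for (band in tab[[attribute]]) {
      if (isTRUE(band_holds(band, x))) return(band$label)
    }
    "UNBANDED"
  }, character(1))
}
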