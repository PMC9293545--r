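# Minimum-description-length accounting for rule sets.
#
# The rule-set score is theory bits (cost of transmitting the rules) plus
# data bits (cost of transmitting the exceptions the rules make on the
# training data). It drives three things: the stopping test during
# sequential covering, the final delete-if-shorter pass over the finished
# rule set, and the choice among original/replacement/revision variants
# during optimization. The coding scheme is the classical RIPPER one:
# rule cost discounted by a redundancy factor (default 0.5) and
# Quinlan-style exception coding that splits the expected errors between
# false positives and false negatives.

#' MDL parameters
#'
#' @param redundancy_factor Multiplier on rule (theory) bits accounting for
#'   redundancy among attribute choices; classical value 0.5.
#' @param expected_fp_over_err Expected share of the errors that are false
#'   positives, in `[0, 1]`; classical value 0.5.
#' @param dl_budget_bits Slack allowed over the best description length
#'   seen so far before sequential covering stops. Default 64 bits (the
#'   classical choice); 11 is available as an alternative preset.
#' @return An `rr_mdl_params`.
#' @export
mdl_params <- function(redundancy_factor = 0.5, expected_fp_over_err = 0.5,
                       dl_budget_bits = 64) {
  stopifnot(dl_budget_bits > 0,
            expected_fp_over_err >= 0, expected_fp_over_err <= 1,
            redundancy_factor > 0)
  structure(list(redundancy_factor = redundancy_factor,
                 expected_fp_over_err = expected_fp_over_err,
                 dl_budget_bits = dl_budget_bits),
            class = "rr_mdl_params")
}

#' Bits to transmit which k of n elements, at element probability p
#'
#' The standard coding cost `-k log2(p) - (n - k) log2(1 - p)` with the
#' `0 * log2(0) := 0` convention. An impossible code (k > 0 with p = 0, or
#' k < n with p = 1) yields `+Inf` rather than being silently dropped.
#'
#' @param n Number of elements.
#' @param k Number of marked elements, `0 <= k <= n`.
#' @param p Marking probability in `[0, 1]`.
#' @return Bits (non-negative, possibly `Inf`).
#' @export
subset_dl <- function(n, k, p) {
  stopifnot(is_count(n), is_count(k), k <= n, p >= 0, p <= 1)
  term1 <- if (k == 0) 0 else if (p == 0) Inf else -k * log2(p)
  term2 <- if (n - k == 0) 0 else if (p == 1) Inf else -(n - k) * log2(1 - p)
  term1 + term2
}

#' Theory bits of a single rule
#'
#' A rule with k conditions out of a pool of `total_candidate_conditions`
#' costs `log2(k) + 2 log2(log2(k)) [k > 1] + subset_dl(total, k, k/total)`
#' bits, discounted by the redundancy factor. The empty rule is free (it is
#' the default rule's job).
#'
#' @param r An `rr_rule`.
#' @param total_candidate_conditions Size of the candidate condition pool
#'   (see [count_candidate_conditions()]).
#' @param params [mdl_params()].
#' @return Bits.
#' @export
theory_dl <- function(r, total_candidate_conditions, params = mdl_params()) {
  k <- n_conditions(r)
  if (k == 0L) return(0)
  total <- total_candidate_conditions
  if (total <= 0) stopf("total_candidate_conditions must be positive when the rule is non-empty")
  if (k > total) total <- k  # degenerate pool; keep the cost finite
  bits <- log2(k) + (if (k > 1) 2 * log2(log2(k)) else 0) +
    subset_dl(total, k, k / total)
  params$redundancy_factor * bits
}

#' Exception (data) bits of a rule set's predictions
#'
#' `log2(cover + uncover + 1)` plus the bits to point out the false
#' positives among the covered instances and the false negatives among the
#' uncovered ones. The larger side is coded at the expected error rate
#' (`expected_fp_over_err * (fp + fn)` errors for the covered side, the
#' complement for the uncovered side); the smaller side at its empirical
#' rate.
#'
#' @param cover Instances covered by the rule set.
#' @param uncover Instances not covered.
#' @param fp False positives among the covered.
#' @param fn False negatives among the uncovered.
#' @param params [mdl_params()].
#' @return Bits.
#' @export
data_dl <- function(cover, uncover, fp, fn, params = mdl_params()) {
  stopifnot(is_count(cover), is_count(uncover), is_count(fp), is_count(fn))
  if (fp > cover) stopf("fp (%d) exceeds cover (%d)", fp, cover)
  if (fn > uncover) stopf("fn (%d) exceeds uncover (%d)", fn, uncover)
  total_bits <- log2(cover + uncover + 1)
  err <- fp + fn
  if (cover >= uncover) {
    exp_err <- params$expected_fp_over_err * err
    cover_bits <- if (cover > 0) subset_dl(cover, fp, min(1, exp_err / cover)) else 0
    uncover_bits <- if (uncover > 0) subset_dl(uncover, fn, fn / uncover) else 0
  } else {
    exp_err <- (1 - params$expected_fp_over_err) * err
    cover_bits <- if (cover > 0) subset_dl(cover, fp, fp / cover) else 0
    uncover_bits <- subset_dl(uncover, fn, min(1, exp_err / uncover))
  }
  total_bits + cover_bits + uncover_bits
}

#' Candidate-condition pool size for a dataset
#'
#' Sum over categorical predictors of their category counts, plus twice the
#' number of distinct observed values for each numeric predictor (a <= and
#' a >= threshold per value).
#'
#' @param ds An `rr_dataset` (typically the current grow set).
#' @return Integer pool size.
#' @export
count_candidate_conditions <- function(ds) {
  total <- 0L
  for (a in ds$schema$attributes) {
    if (a$kind == "categorical") {
      total <- total + length(a$categories)
    } else {
      v <- ds$data[[a$name]]
      total <- total + 2L * length(unique(v[!is.na(v)]))
    }
  }
  total
}

#' Description length of a rule set on labeled data
#'
#' Theory bits are summed over the rules; data bits are computed from the
#' decision-list predictions on the positives P and negatives N: an
#' instance is "covered" when some rule matches it (predicted positive),
#' false positives are covered negatives, false negatives uncovered
#' positives.
#'
#' @param rs An `rr_ruleset` whose rules all predict the positive class.
#' @param P,N `rr_dataset`s of positive and negative instances.
#' @param total_candidate_conditions Candidate pool size used for theory
#'   bits.
#' @param params [mdl_params()].
#' @return An `rr_dl`: list with `theory_bits`, `data_bits`, `total_bits`.
#' @export
ruleset_dl <- function(rs, P, N, total_candidate_conditions,
                       params = mdl_params()) {
  theory <- 0
  for (r in rs$rules) theory <- theory + theory_dl(r, total_candidate_conditions, params)
  cov_p <- covered_by_any(rs$rules, P)
  cov_n <- covered_by_any(rs$rules, N)
  cover <- sum(cov_p) + sum(cov_n)
  uncover <- (n_instances(P) - sum(cov_p)) + (n_instances(N) - sum(cov_n))
  fp <- sum(cov_n)
  fn <- n_instances(P) - sum(cov_p)
  data_bits <- data_dl(cover, uncover, fp, fn, params)
  structure(list(theory_bits = theory, data_bits = data_bits,
                 total_bits = theory + data_bits),
            class = "rr_dl")
}

covered_by_any <- function(rules, ds) {
  m <- rep(FALSE, n_instances(ds))
  for (r in rules) {
    if (all(m)) break
    m <- m | rule_matches(r, ds)
  }
  m
}
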