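# Fixtures and independent brute-force oracles. The oracles here are coded
# straight from the defining formulas / enumerations and never call the
# package's own implementation paths they check.

toy_schema <- function() {
  dataset_schema(
    attributes = list(
      attribute_spec("x1", "numeric", range = c(0, 100)),
      attribute_spec("x2", "numeric", range = c(0, 100)),
      attribute_spec("x3", "numeric", range = c(0, 100)),
      attribute_spec("c1", "categorical", categories = c("a", "b", "c"))
    ),
    class_attribute = attribute_spec("class", "categorical",
                                     categories = c("neg", "pos"))
  )
}

# Planted 2-rule concept over the toy schema (used for recovery tests).
toy_concept <- function(noise = 0) {
  planted_concept(ruleset(list(
    rule(list(condition("x1", "<=", 40), condition("c1", "=", "a")), "pos"),
    rule(list(condition("x2", ">=", 70)), "pos")
  ), "neg"), noise)
}

# A labeled toy dataset with fully random (pure-noise) labels.
pure_noise_dataset <- function(n, seed) {
  d <- generate_dataset(toy_schema(), planted_concept(ruleset(list(), "neg")), n, seed)
  lab <- withr::with_seed(1000L + seed, sample(c("pos", "neg"), n, replace = TRUE))
  d$data$class <- lab
  d
}

split_pn <- function(ds, pos_class = "pos") {
  lab <- dataset_labels(ds)
  list(P = subset_dataset(ds, which(lab == pos_class)),
       N = subset_dataset(ds, which(lab != pos_class)))
}

# The 12-predictor layout printed as the data sample (no resting-ECG
# column); used for the two sample patient rows.
sample_schema <- function() {
  dataset_schema(
    attributes = list(
      attribute_spec("age", "numeric", range = c(29, 77)),
      attribute_spec("sex", "categorical", categories = c("0", "1")),
      attribute_spec("cp", "categorical", categories = c("1", "2", "3", "4")),
      attribute_spec("trestbps", "numeric", range = c(94, 200)),
      attribute_spec("chol", "numeric", range = c(126, 564)),
      attribute_spec("fbs", "categorical", categories = c("0", "1")),
      attribute_spec("induced_angina", "categorical", categories = c("0", "1")),
      attribute_spec("thalach", "numeric", range = c(71, 202)),
      attribute_spec("st", "numeric", range = c(0, 6.2)),
      attribute_spec("slope", "categorical", categories = c("1", "2", "3")),
      attribute_spec("ca", "numeric", range = c(0, 3)),
      attribute_spec("thall", "categorical", categories = c("3", "6", "7"))
    ),
    class_attribute = attribute_spec("class", "categorical", categories = c("0", "1"))
  )
}

# The two printed sample patient rows.
sample_rows_csv <- function(path) {
  writeLines(c(
    "age,sex,cp,trestbps,chol,fbs,induced_angina,thalach,st,slope,ca,thall,class",
    "55,0,3,115,322,0,0,160,1.6,2,0,7,0",
    "74,1,2,124,261,0,0,141,0.3,1,0,7,1"
  ), path)
  path
}

# A tiny synthetic file in the headerless UCI Cleveland column layout
# (values written "3.0"-style as in the raw file; one "?" and multi-level
# diagnosis codes). Synthetic stand-in, not UCI data.
synthetic_uci_csv <- function(path) {
  writeLines(c(
    "63.0,1.0,1.0,145.0,233.0,1.0,2.0,150.0,0.0,2.3,3.0,0.0,6.0,0",
    "67.0,1.0,4.0,160.0,286.0,0.0,2.0,108.0,1.0,1.5,2.0,3.0,3.0,2",
    "41.0,0.0,2.0,130.0,204.0,0.0,2.0,172.0,0.0,1.4,1.0,?,3.0,0",
    "62.0,0.0,4.0,140.0,268.0,0.0,2.0,160.0,0.0,3.6,3.0,2.0,3.0,3",
    "57.0,0.0,4.0,120.0,354.0,0.0,0.0,163.0,1.0,0.6,1.0,0.0,3.0,1"
  ), path)
  path
}

# --- independent oracles -----------------------------------------------------

oracle_foil_gain <- function(p0, n0, p1, n1) {
  if (p1 == 0) return(-Inf)
  p1 * (log2(p1 / (p1 + n1)) - log2(p0 / (p0 + n0)))
}

oracle_prune_T <- function(p, n) if (p + n == 0) 0 else (p - n) / (p + n)

oracle_subset_dl <- function(n, k, p) {
  t1 <- if (k == 0) 0 else if (p == 0) Inf else -k * log2(p)
  t2 <- if (n - k == 0) 0 else if (p == 1) Inf else -(n - k) * log2(1 - p)
  t1 + t2
}

oracle_theory_dl <- function(k, total, rf = 0.5) {
  if (k == 0) return(0)
  rf * (log2(k) + (if (k > 1) 2 * log2(log2(k)) else 0) +
          oracle_subset_dl(total, k, k / total))
}

oracle_data_dl <- function(cover, uncover, fp, fn, exp_fp = 0.5) {
  bits <- log2(cover + uncover + 1)
  err <- fp + fn
  if (cover >= uncover) {
    cb <- if (cover > 0) oracle_subset_dl(cover, fp, min(1, exp_fp * err / cover)) else 0
    ub <- if (uncover > 0) oracle_subset_dl(uncover, fn, fn / uncover) else 0
  } else {
    cb <- if (cover > 0) oracle_subset_dl(cover, fp, fp / cover) else 0
    ub <- oracle_subset_dl(uncover, fn, min(1, (1 - exp_fp) * err / uncover))
  }
  bits + cb + ub
}

oracle_metrics <- function(tp, tn, fp, fn) {
  sd <- function(a, b) if (b > 0) a / b else NA_real_
  list(accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
       precision = sd(tp, tp + fp), recall = sd(tp, tp + fn),
       specificity = sd(tn, tn + fp), f_score = sd(2 * tp, 2 * tp + fp + fn))
}

# Row-by-row rule matching, independent of the vectorized path.
oracle_rule_matches_row <- function(r, row) {
  for (cc in r$conditions) {
    v <- row[[cc$attribute]]
    if (is.na(v)) return(FALSE)
    ok <- switch(cc$op,
                 "=" = v == cc$value,
                 "<=" = v <= cc$value,
                 ">=" = v >= cc$value)
    if (!ok) return(FALSE)
  }
  TRUE
}

oracle_coverage <- function(r, ds, positive_class) {
  lab <- dataset_labels(ds)
  p <- 0L; n <- 0L
  for (i in seq_len(n_instances(ds))) {
    if (oracle_rule_matches_row(r, ds$data[i, , drop = FALSE])) {
      if (!is.na(lab[i]) && lab[i] == positive_class) p <- p + 1L else n <- n + 1L
    }
  }
  list(p = p, n = n)
}

# Exhaustive trailing-suffix pruning oracle: evaluate every candidate
# (keep first j conditions, j = 1..k), maximize T, ties to shortest.
oracle_prune <- function(r, prune, positive_class) {
  k <- length(r$conditions)
  best_j <- 1L; best_t <- -Inf
  for (j in seq_len(k)) {
    cand <- rule(r$conditions[seq_len(j)], r$consequent)
    cov <- oracle_coverage(cand, prune, positive_class)
    tv <- oracle_prune_T(cov$p, cov$n)
    if (tv > best_t) { best_t <- tv; best_j <- j }
  }
  rule(r$conditions[seq_len(best_j)], r$consequent)
}

# Random small rule over the toy schema (for pruning-oracle sweeps).
random_toy_rule <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(1:4, 1)
    conds <- lapply(seq_len(k), function(i) {
      att <- sample(c("x1", "x2", "x3", "c1"), 1)
      if (att == "c1") condition("c1", "=", sample(c("a", "b", "c"), 1))
      else condition(att, sample(c("<=", ">="), 1), round(stats::runif(1, 5, 95), 1))
    })
    # drop accidental duplicate triples
    keys <- vapply(conds, function(cc) paste(cc$attribute, cc$op, cc$value), "")
    rule(conds[!duplicated(keys)], "pos")
  })
}
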