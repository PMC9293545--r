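# Confusion counts, derived screening metrics, and cross-validation.

#' Cross-tabulate truth against predictions
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive_class Token counted as positive. The positive-class
#'   convention is always explicit; nothing is inferred.
#' @return An `rr_confusion`: list with `Tpos`, `Tneg`, `Fpos`, `Fneg`.
#' @export
confusion_counts <- function(truth, predicted, positive_class) {
  if (length(truth) != length(predicted)) {
    stopf("truth (%d) and predicted (%d) differ in length", length(truth), length(predicted))
  }
  if (!length(truth)) stopf("need at least one (truth, predicted) pair")
  tp <- truth == positive_class
  pp <- predicted == positive_class
  structure(list(Tpos = sum(tp & pp), Tneg = sum(!tp & !pp),
                 Fpos = sum(!tp & pp), Fneg = sum(tp & !pp)),
            class = "rr_confusion")
}

#' Screening metrics from confusion counts
#'
#' Accuracy (percent), precision (positive predictive value), recall
#' (sensitivity), specificity and F-score (harmonic mean of precision and
#' recall, equal to `2 Tpos / (2 Tpos + Fpos + Fneg)`). A metric whose
#' denominator is zero is returned as NA (the NOT_DEFINED sentinel) rather
#' than silently coerced.
#'
#' @param cc An `rr_confusion` (or list with Tpos/Tneg/Fpos/Fneg).
#' @param f_as_printed If `TRUE`, compute the non-standard audit variant
#'   `2 Tpos / (2 Tpos + Fpos + Tneg)` instead of the F-score. It does not
#'   equal the harmonic mean of precision and recall; off by default.
#' @return An `rr_metrics`: list with `accuracy` (percent), `precision`,
#'   `recall`, `specificity`, `f_score` (fractions).
#' @export
compute_metrics <- function(cc, f_as_printed = FALSE) {
  tp <- cc$Tpos; tn <- cc$Tneg; fp <- cc$Fpos; fn <- cc$Fneg
  total <- tp + tn + fp + fn
  if (total <= 0) stopf("no evaluated instances")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  f_den <- if (f_as_printed) 2 * tp + fp + tn else 2 * tp + fp + fn
  structure(list(
    accuracy = 100 * (tp + tn) / total,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    f_score = safe_div(2 * tp, f_den)
  ), class = "rr_metrics")
}

#' @export
print.rr_metrics <- function(x, ...) {
  cat(sprintf("accuracy    %6.2f%%\n", x$accuracy))
  for (nm in c("precision", "recall", "specificity", "f_score")) {
    cat(sprintf("%-11s %6s\n", nm,
                ifelse(is.na(x[[nm]]), "ND", sprintf("%.4f", x[[nm]]))))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation of the rule learner
#'
#' Fold assignment is stratified by class and deterministic in the seed;
#' the model is retrained on each training split with [train_multiclass()].
#'
#' @param ds A labeled `rr_dataset`.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for fold assignment (training seeds derive from
#'   it).
#' @param params [optimization_params()].
#' @param positive_class Token treated as positive in the metrics.
#' @param stratified Stratify folds by class (default). Each class must
#'   then have at least `folds` members.
#' @return An `rr_cv`: list with `per_fold` (data.frame of the five metrics
#'   per fold), `mean`, `sd` and the fold assignment.
#' @export
cross_validate <- function(ds, folds = 5L, seed = 1L,
                           params = optimization_params(),
                           positive_class, stratified = TRUE) {
  if (folds < 2L) stopf("folds must be >= 2")
  lab <- dataset_labels(ds)
  if (is.null(lab) || anyNA(lab)) stopf("cross-validation needs fully labeled data")
  n <- n_instances(ds)
  if (folds > n) stopf("more folds (%d) than instances (%d)", folds, n)
  assign <- integer(n)
  if (stratified) {
    rare <- names(which(table(lab) < folds))
    if (length(rare)) {
      stopf("class '%s' has fewer members than folds; use stratified = FALSE", rare[1])
    }
    with_seed(seed, {
      for (cls in sort(unique(lab))) {
        idx <- which(lab == cls)
        idx <- if (length(idx) > 1L) sample(idx) else idx
        assign[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
  } else {
    with_seed(seed, {
      assign <- rep_len(seq_len(folds), n)[sample.int(n)]
    })
  }
  metric_names <- c("accuracy", "precision", "recall", "specificity", "f_score")
  per_fold <- matrix(NA_real_, nrow = folds, ncol = length(metric_names),
                     dimnames = list(NULL, metric_names))
  for (f in seq_len(folds)) {
    train <- subset_dataset(ds, which(assign != f))
    test <- subset_dataset(ds, which(assign == f))
    pf <- modify_params(params,
                        induction = modify_params(params$induction,
                                                  seed = derive_seed(seed, 40000L + f)))
    model <- train_multiclass(train, pf)
    pred <- predict(model, test)
    mm <- compute_metrics(confusion_counts(dataset_labels(test), pred, positive_class))
    per_fold[f, ] <- unlist(mm)[metric_names]
  }
  per_fold <- as.data.frame(per_fold)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold, na.rm = TRUE),
    sd = apply(per_fold, 2, stats::sd, na.rm = TRUE),
    folds = folds, seed = seed, assignment = assign
  ), class = "rr_cv")
}

#' @export
print.rr_cv <- function(x, ...) {
  cat(sprintf("<rr_cv> %d-fold cross-validation (seed %d)\n", x$folds, x$seed))
  print(round(x$per_fold, 4))
  cat("mean:\n"); print(round(x$mean, 4))
  cat("sd:\n"); print(round(x$sd, 4))
  invisible(x)
}
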