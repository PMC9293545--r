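# Rule-set optimization and the top-level trainers.
#
# Optimization revisits each rule in turn: with the rest of the rule set
# fixed, a replacement rule is grown from scratch and a revision rule is
# grown from the original antecedent, both on the instances the other rules
# leave uncovered; the variant (original / revision / replacement)
# minimizing the rule set's total description length is kept. A residual
# covering pass then restores completeness, and a reverse-order MDL
# deletion pass plus a monotonicity guard ensure a round never increases
# the description length.

#' Optimization parameters
#'
#' @param k Number of optimization rounds after initial covering
#'   (default 2).
#' @param induction [induction_params()] shared by covering and
#'   optimization.
#' @return An `rr_optimization_params`.
#' @export
optimization_params <- function(k = 2L, induction = induction_params()) {
  stopifnot(k >= 0)
  structure(list(k = as.integer(k), induction = induction),
            class = "rr_optimization_params")
}

#' One optimization pass over a rule set
#'
#' @param rs An `rr_ruleset` whose rules predict the positive class.
#' @param P,N Positive / negative `rr_dataset`s.
#' @param params [optimization_params()] or [induction_params()].
#' @return An `rr_ruleset` with total description length no greater than
#'   the input's.
#' @export
optimize_ruleset <- function(rs, P, N, params = optimization_params()) {
  ip <- if (inherits(params, "rr_optimization_params")) params$induction else params
  if (!length(rs$rules)) {
    # nothing to revise; a residual pass on an empty list is plain covering
    return(rs)
  }
  pos_class <- rs$rules[[1L]]$consequent
  total_cc <- count_candidate_conditions(rbind_dataset(P, N))
  mdlp <- ip$mdl
  dl_in <- ruleset_dl(rs, P, N, total_cc, mdlp)$total_bits
  cur <- rs$rules
  for (i in seq_along(cur)) {
    others <- cur[-i]
    upi <- which(!covered_by_any(others, P))
    uni <- which(!covered_by_any(others, N))
    if (!length(upi)) next
    UP <- subset_dataset(P, upi)
    UN <- subset_dataset(N, uni)
    U <- rbind_dataset(UP, UN)
    if (n_instances(U) < 2L) next
    sp <- split_grow_prune(U, modify_params(ip, seed = derive_seed(ip$seed, 5000L + i)))
    glab <- dataset_labels(sp$grow)
    if (!any(!is.na(glab) & glab == pos_class)) next
    rep_r <- grow_rule(sp$grow, pos_class, ip)
    if (n_conditions(rep_r) > 0L) rep_r <- prune_rule(rep_r, sp$prune, pos_class, ip)
    rev_r <- grow_rule(sp$grow, pos_class, ip, init = cur[[i]]$conditions)
    if (n_conditions(rev_r) > 0L) rev_r <- prune_rule(rev_r, sp$prune, pos_class, ip)
    variants <- list(cur[[i]], rev_r, rep_r)
    dls <- vapply(variants, function(v) {
      trial <- cur
      trial[[i]] <- v
      ruleset_dl(ruleset(trial, rs$default_class), P, N, total_cc, mdlp)$total_bits
    }, numeric(1))
    cur[[i]] <- variants[[which.min(dls)]]  # ties keep the original
  }
  # residual covering: positives orphaned by revision become a fresh
  # covering problem appended to the list
  up_left <- which(!covered_by_any(cur, P))
  if (length(up_left)) {
    res <- build_ruleset(subset_dataset(P, up_left), N,
                         modify_params(ip, seed = derive_seed(ip$seed, 7000L)))
    cur <- c(cur, res$rules)
  }
  cur <- dl_prune_rules(cur, P, N, total_cc, mdlp, rs$default_class)
  out <- ruleset(cur, rs$default_class)
  dl_out <- ruleset_dl(out, P, N, total_cc, mdlp)$total_bits
  if (dl_out > dl_in) return(rs)  # MDL monotonicity guard
  out
}

#' Induce and optimize a rule set for one positive class
#'
#' Sequential covering ([build_ruleset()]) followed by `k` rounds of
#' [optimize_ruleset()].
#'
#' @param P,N Positive / negative `rr_dataset`s.
#' @param params [optimization_params()].
#' @return An `rr_ruleset`.
#' @export
ripper <- function(P, N, params = optimization_params()) {
  ip <- params$induction
  rs <- build_ruleset(P, N, ip)
  if (params$k > 0L) {
    for (j in seq_len(params$k)) {
      ipj <- modify_params(ip, seed = derive_seed(ip$seed, 90000L + j))
      rs <- optimize_ruleset(rs, P, N, optimization_params(k = params$k, induction = ipj))
    }
  }
  rs
}

#' Train a multiclass decision list
#'
#' Classes are ordered by ascending training frequency (ties broken
#' lexicographically). For each of the first m - 1 classes a rule block is
#' learned with [ripper()] against all remaining instances, covered
#' instances are removed, and the last (most frequent) class becomes the
#' default.
#'
#' @param ds A labeled `rr_dataset`.
#' @param params [optimization_params()].
#' @return An `rr_ruleset` (the full decision list) carrying attributes
#'   `class_order` and `params`.
#' @export
train_multiclass <- function(ds, params = optimization_params()) {
  lab <- dataset_labels(ds)
  if (is.null(lab)) stopf("training data has no class labels")
  keep <- which(!is.na(lab))
  if (!length(keep)) stopf("training data has no labeled instances")
  ds <- subset_dataset(ds, keep)
  # canonical row order: training is invariant to how the rows arrived
  ds <- subset_dataset(ds, do.call(order, unname(as.list(ds$data))))
  lab <- dataset_labels(ds)
  freq <- table(lab)
  ord <- names(freq)[order(freq, names(freq))]  # ascending frequency, lexicographic ties
  all_rules <- list()
  remaining <- ds
  m <- length(ord)
  if (m > 1L) {
    for (ci in seq_len(m - 1L)) {
      cls <- ord[ci]
      rl <- dataset_labels(remaining)
      pidx <- which(!is.na(rl) & rl == cls)
      if (!length(pidx)) next
      P <- subset_dataset(remaining, pidx)
      N <- subset_dataset(remaining, setdiff(seq_len(n_instances(remaining)), pidx))
      ipc <- modify_params(params$induction,
                           seed = derive_seed(params$induction$seed, 300000L + ci))
      rs <- ripper(P, N, optimization_params(k = params$k, induction = ipc))
      all_rules <- c(all_rules, rs$rules)
      keep <- which(!covered_by_any(rs$rules, remaining))
      remaining <- subset_dataset(remaining, keep)
    }
  }
  out <- ruleset(all_rules, ord[m])
  attr(out, "class_order") <- ord
  attr(out, "params") <- params
  out
}
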