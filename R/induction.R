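# Sequential-covering rule induction: grow/prune split, FOIL-gain growth,
# reduced-error pruning, and rule-set construction under an MDL stop.

#' Induction parameters
#'
#' @param ratio Fraction of the data used for growing (the rest prunes);
#'   conventional 2/3.
#' @param seed Integer seed; every random choice in an induction run derives
#'   deterministically from it.
#' @param min_rule_coverage A candidate rule must cover at least this many
#'   not-yet-covered positives to be accepted ("too limited" rejection).
#' @param max_prune_error A candidate rule whose prune-set error rate
#'   reaches this value is rejected ("precision too poor").
#' @param resplit Re-draw the grow/prune split before each new rule
#'   (default) or keep a single static split for the whole run.
#' @param mdl [mdl_params()] controlling the description-length stop.
#' @return An `rr_induction_params`.
#' @export
induction_params <- function(ratio = 2 / 3, seed = 1L, min_rule_coverage = 1L,
                             max_prune_error = 0.5, resplit = TRUE,
                             mdl = mdl_params()) {
  stopifnot(ratio > 0, ratio < 1, max_prune_error > 0, max_prune_error <= 1,
            min_rule_coverage >= 0)
  structure(list(ratio = ratio, seed = as.integer(seed),
                 min_rule_coverage = min_rule_coverage,
                 max_prune_error = max_prune_error,
                 resplit = isTRUE(resplit), mdl = mdl),
            class = "rr_induction_params")
}

#' Split a dataset into grow and prune sets
#'
#' Stratified by class label where possible: per-class grow counts are
#' apportioned by largest remainder so the overall grow size is exactly
#' `round(ratio * n)`. Deterministic given the seed.
#'
#' @param ds An `rr_dataset` with at least 2 instances.
#' @param params [induction_params()] (supplies `ratio` and `seed`).
#' @return An `rr_split`: list with `grow` and `prune` datasets.
#' @export
split_grow_prune <- function(ds, params = induction_params()) {
  n <- n_instances(ds)
  if (n < 2L) stopf("need at least 2 instances to split, got %d", n)
  lab <- dataset_labels(ds)
  if (is.null(lab)) lab <- rep("", n)
  lab <- ifelse(is.na(lab), "<NA>", lab)
  strata <- sort(unique(lab))
  n_grow <- round(params$ratio * n)
  sizes <- vapply(strata, function(s) sum(lab == s), 0L)
  quota <- params$ratio * sizes
  base <- floor(quota)
  rem <- n_grow - sum(base)
  frac <- quota - base
  # hand the leftover grow slots to the strata with the largest remainders
  extra <- integer(length(strata))
  if (rem > 0) {
    ord <- order(-frac, strata)
    extra[ord[seq_len(min(rem, length(strata)))]] <- 1L
  }
  alloc <- pmin(base + extra, sizes)
  grow_idx <- integer(0)
  with_seed(params$seed, {
    for (j in seq_along(strata)) {
      idx <- which(lab == strata[j])
      idx <- if (length(idx) > 1L) sample(idx) else idx
      grow_idx <- c(grow_idx, idx[seq_len(alloc[j])])
    }
  })
  grow_idx <- sort(grow_idx)
  structure(list(grow = subset_dataset(ds, grow_idx),
                 prune = subset_dataset(ds, setdiff(seq_len(n), grow_idx)),
                 ratio = params$ratio, seed = params$seed),
            class = "rr_split")
}

#' FOIL information gain of a refinement
#'
#' `gain = p_after * (log2(rt_after) - log2(rt_before))` where `rt` is the
#' positive fraction of the instances the rule covers. A refinement that
#' covers no positives scores `-Inf` (candidate discarded).
#'
#' @param before,after `rr_coverage` (or `list(p=, n=)`) for the rule before
#'   and after adding the candidate condition.
#' @return Gain in bits, or `-Inf`.
#' @export
foil_gain <- function(before, after) {
  bp <- before$p; bn <- before$n
  ap <- after$p;  an <- after$n
  if (bp + bn <= 0 || bp == 0) {
    stopf("cannot grow from a rule covering no positives (before: p=%s, n=%s)", bp, bn)
  }
  if (ap == 0) return(-Inf)
  ap * (log2(ap / (ap + an)) - log2(bp / (bp + bn)))
}

# Best single condition to append, by FOIL gain, with deterministic
# tie-breaks: earlier attribute in schema order, then smaller threshold /
# earlier category, then "<=" before ">=". Returns NULL when no candidate
# has positive, finite gain. Vectorized per attribute via sorted cumulative
# counts, so growth is O(m log m) per attribute and step.
best_condition <- function(ds, covered, pos, rt0) {
  best <- NULL
  best_gain <- 0
  lg_rt0 <- log2(rt0)
  for (a in ds$schema$attributes) {
    x <- ds$data[[a$name]]
    cv <- covered & !is.na(x)
    if (!any(cv)) next
    if (a$kind == "categorical") {
      xs <- factor(x[cv], levels = a$categories)
      ps <- pos[cv]
      p1 <- tabulate(xs[ps], nbins = length(a$categories))
      t1 <- tabulate(xs, nbins = length(a$categories))
      n1 <- t1 - p1
      gain <- ifelse(p1 > 0, p1 * (log2(p1 / (p1 + n1)) - lg_rt0), -Inf)
      for (j in order(-gain)) {
        if (!is.finite(gain[j]) || gain[j] <= best_gain) break
        cand <- list(gain = gain[j], attribute = a$name, op = "=",
                     value = a$categories[j])
        best <- cand; best_gain <- gain[j]
        break
      }
    } else {
      xs <- x[cv]; ps <- pos[cv]
      o <- order(xs)
      sx <- xs[o]; sp <- ps[o]
      cp <- cumsum(sp); cn <- cumsum(!sp)
      u_pos <- which(c(sx[-1] != sx[-length(sx)], TRUE))  # last index of each unique value
      u <- sx[u_pos]
      p_le <- cp[u_pos]; n_le <- cn[u_pos]
      ptot <- cp[length(cp)]; ntot <- cn[length(cn)]
      p_ge <- ptot - c(0, p_le[-length(p_le)])
      n_ge <- ntot - c(0, n_le[-length(n_le)])
      g_le <- ifelse(p_le > 0, p_le * (log2(p_le / (p_le + n_le)) - lg_rt0), -Inf)
      g_ge <- ifelse(p_ge > 0, p_ge * (log2(p_ge / (p_ge + n_ge)) - lg_rt0), -Inf)
      gain <- c(g_le, g_ge)
      val <- c(u, u)
      opi <- rep(1:2, each = length(u))
      ord <- order(-gain, val, opi)
      j <- ord[1]
      if (is.finite(gain[j]) && gain[j] > best_gain) {
        best <- list(gain = gain[j], attribute = a$name,
                     op = c("<=", ">=")[opi[j]], value = val[j])
        best_gain <- gain[j]
      }
    }
  }
  best
}

#' Grow a rule by greedy FOIL-gain refinement
#'
#' Starting from `init` (empty by default), repeatedly appends the
#' condition with maximal FOIL gain until the rule covers no negative grow
#' instances or no candidate has positive gain.
#'
#' @param grow An `rr_dataset` (the grow set) containing at least one
#'   instance of `target_class`.
#' @param target_class Class token the rule predicts.
#' @param params [induction_params()] (unused knobs reserved).
#' @param init Optional list of [condition()]s seeding the antecedent (used
#'   to grow revision rules during optimization).
#' @return An `rr_rule` with consequent `target_class`.
#' @export
grow_rule <- function(grow, target_class, params = induction_params(),
                      init = list()) {
  lab <- dataset_labels(grow)
  if (is.null(lab)) stopf("grow set has no class labels")
  pos <- !is.na(lab) & lab == target_class
  if (!any(pos)) stopf("grow set contains no instance of class '%s'", target_class)
  conds <- init
  covered <- if (length(init)) {
    rule_matches(rule(init, target_class), grow)
  } else {
    rep(TRUE, n_instances(grow))
  }
  repeat {
    p0 <- sum(covered & pos)
    n0 <- sum(covered & !pos)
    if (n0 == 0L || p0 == 0L) break
    cand <- best_condition(grow, covered, pos, p0 / (p0 + n0))
    if (is.null(cand)) break
    cc <- condition(cand$attribute, cand$op, cand$value)
    conds[[length(conds) + 1L]] <- cc
    covered <- covered & rule_matches(rule(list(cc), target_class), grow)
  }
  rule(conds, target_class)
}

#' Prune a rule on held-out data
#'
#' Considers the candidates obtained by deleting trailing suffixes of the
#' antecedent (always retaining at least one condition) and keeps the one
#' maximizing the pruning metric `T = (p - n) / (p + n)` on the prune set
#' (`T := 0` when the candidate covers nothing). Ties go to the shortest
#' candidate.
#'
#' @param r An `rr_rule` with at least one condition.
#' @param prune An `rr_dataset` (the prune set).
#' @param target_class Positive class token.
#' @param params [induction_params()] (reserved).
#' @return The pruned `rr_rule`.
#' @export
prune_rule <- function(r, prune, target_class, params = induction_params()) {
  k <- n_conditions(r)
  if (k == 0L) return(r)
  lab <- dataset_labels(prune)
  pos <- !is.na(lab) & lab == target_class
  m <- rep(TRUE, n_instances(prune))
  tvals <- numeric(k)
  for (j in seq_len(k)) {
    m <- m & rule_matches(rule(r$conditions[j], target_class), prune)
    p <- sum(m & pos); n <- sum(m) - p
    tvals[j] <- if (p + n > 0) (p - n) / (p + n) else 0
  }
  best_j <- which.max(tvals)  # first max = shortest candidate on ties
  rule(r$conditions[seq_len(best_j)], r$consequent)
}

# Prune-set error rate of a rule (n / (p + n)); NA when it covers nothing.
prune_error <- function(r, prune, target_class) {
  cs <- coverage(r, prune, target_class)
  if (cs$p + cs$n == 0) NA_real_ else cs$n / (cs$p + cs$n)
}

#' Build a rule set by sequential covering
#'
#' Repeats split / grow / prune, accepting each rule unless its prune-set
#' error rate reaches `max_prune_error` or it covers fewer than
#' `min_rule_coverage` outstanding positives, removing covered instances
#' after each acceptance. Stops when the positives are exhausted, a rule is
#' rejected, or the rule set's description length exceeds the best seen so
#' far by more than the MDL budget. A final reverse-order pass deletes any
#' rule whose removal lowers the total description length.
#'
#' @param P An `rr_dataset` of positive instances (uniform label).
#' @param N An `rr_dataset` of negative instances.
#' @param params [induction_params()].
#' @return An `rr_ruleset` whose rules all predict the positive class; the
#'   default class is the majority label of `N` (fall-through).
#' @export
build_ruleset <- function(P, N, params = induction_params()) {
  neg_default <- negative_default(N)
  if (n_instances(P) == 0L) return(ruleset(list(), neg_default))
  pos_class <- unique(dataset_labels(P))
  pos_class <- pos_class[!is.na(pos_class)]
  if (length(pos_class) != 1L) stopf("P must carry a single class label")
  total_cc <- count_candidate_conditions(rbind_dataset(P, N))
  mdlp <- params$mdl
  rules <- list()
  curP <- P; curN <- N
  dl_best <- ruleset_dl(ruleset(rules, neg_default), P, N, total_cc, mdlp)$total_bits
  iter <- 0L
  static_seed <- params$seed
  while (n_instances(curP) > 0L && iter < 1000L) {
    iter <- iter + 1L
    cur <- rbind_dataset(curP, curN)
    if (n_instances(cur) < 2L) break
    sp_seed <- if (params$resplit) derive_seed(params$seed, iter) else static_seed
    sp <- split_grow_prune(cur, modify_params(params, seed = sp_seed))
    glab <- dataset_labels(sp$grow)
    if (!any(!is.na(glab) & glab == pos_class)) break
    r <- grow_rule(sp$grow, pos_class, params)
    if (n_conditions(r) > 0L) r <- prune_rule(r, sp$prune, pos_class, params)
    err <- prune_error(r, sp$prune, pos_class)
    if (!is.na(err) && err >= params$max_prune_error) break  # precision too poor
    covp <- coverage(r, curP, pos_class)
    if (covp$p < params$min_rule_coverage) break  # coverage too limited
    rules[[length(rules) + 1L]] <- r
    dl <- ruleset_dl(ruleset(rules, neg_default), P, N, total_cc, mdlp)$total_bits
    if (dl > dl_best + mdlp$dl_budget_bits) {
      rules <- rules[-length(rules)]
      break
    }
    dl_best <- min(dl_best, dl)
    keepP <- !rule_matches(r, curP)
    keepN <- !rule_matches(r, curN)
    curP <- subset_dataset(curP, which(keepP))
    curN <- subset_dataset(curN, which(keepN))
  }
  rules <- dl_prune_rules(rules, P, N, total_cc, mdlp, neg_default)
  ruleset(rules, neg_default)
}

#' Reverse-order MDL pruning of a rule set
#'
#' Walks the rules in reverse order and deletes each rule whose removal
#' lowers the total description length; the same pass that closes
#' [build_ruleset()] and [optimize_ruleset()]. Never increases the total
#' description length.
#'
#' @param rs An `rr_ruleset`.
#' @param P,N Positive / negative `rr_dataset`s.
#' @param total_candidate_conditions Candidate pool size for theory bits.
#' @param params [mdl_params()].
#' @return The pruned `rr_ruleset`.
#' @export
mdl_prune_ruleset <- function(rs, P, N, total_candidate_conditions,
                              params = mdl_params()) {
  ruleset(dl_prune_rules(rs$rules, P, N, total_candidate_conditions,
                         params, rs$default_class),
          rs$default_class)
}

# Reverse-order deletion of rules whose removal lowers total DL.
dl_prune_rules <- function(rules, P, N, total_cc, mdlp, default_class) {
  if (!length(rules)) return(rules)
  dl_cur <- ruleset_dl(ruleset(rules, default_class), P, N, total_cc, mdlp)$total_bits
  for (i in rev(seq_along(rules))) {
    cand <- rules[-i]
    dl_c <- ruleset_dl(ruleset(cand, default_class), P, N, total_cc, mdlp)$total_bits
    if (dl_c < dl_cur) {
      rules <- cand
      dl_cur <- dl_c
    }
  }
  rules
}

negative_default <- function(N) {
  lab <- dataset_labels(N)
  lab <- lab[!is.na(lab)]
  if (!length(lab)) return("")
  tt <- sort(table(lab), decreasing = TRUE)
  names(tt)[1L]
}

modify_params <- function(params, ...) {
  upd <- list(...)
  for (nm in names(upd)) params[[nm]] <- upd[[nm]]
  params
}
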