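# Rule-set optimization, the top-level learner and multiclass training.

test_that("ripper with k = 0 is exactly build_ruleset", {
  ds <- generate_dataset(toy_schema(), toy_concept(), 150, seed = 19)
  pn <- split_pn(ds)
  ip <- induction_params(seed = 4)
  rs0 <- build_ruleset(pn$P, pn$N, ip)
  rsk <- ripper(pn$P, pn$N, optimization_params(k = 0, induction = ip))
  expect_identical(serialize_ruleset(rsk), serialize_ruleset(rs0))
  # P empty -> empty rule list
  empty <- generate_dataset(toy_schema(), toy_concept(), 0, seed = 1)
  expect_length(ripper(empty, pn$N, optimization_params())$rules, 0)
})

test_that("optimize_ruleset never increases total description length", {
  sch <- toy_schema()
  for (s in 1:12) {
    ds <- generate_dataset(sch, toy_concept(0.05), 160, seed = 600 + s)
    pn <- split_pn(ds)
    ip <- induction_params(seed = s)
    rs <- build_ruleset(pn$P, pn$N, ip)
    tot <- count_candidate_conditions(ds)
    dl_in <- ruleset_dl(rs, pn$P, pn$N, tot)$total_bits
    opt <- optimize_ruleset(rs, pn$P, pn$N, optimization_params(induction = ip))
    dl_out <- ruleset_dl(opt, pn$P, pn$N, tot)$total_bits
    expect_lte(dl_out, dl_in + 1e-9)
  }
})

test_that("optimization discards a planted redundant antecedent", {
  sch <- toy_schema()
  concept <- planted_concept(ruleset(list(rule(list(condition("x1", "<=", 50)), "pos")), "neg"))
  ds <- generate_dataset(sch, concept, 200, seed = 23)
  pn <- split_pn(ds)
  # hand-built rule set carrying a redundant second condition
  bloated <- ruleset(list(rule(list(condition("x1", "<=", 50),
                                    condition("x2", "<=", 99.9)), "pos")), "neg")
  tot <- count_candidate_conditions(ds)
  dl_in <- ruleset_dl(bloated, pn$P, pn$N, tot)$total_bits
  opt <- optimize_ruleset(bloated, pn$P, pn$N, optimization_params(induction = induction_params(seed = 2)))
  dl_out <- ruleset_dl(opt, pn$P, pn$N, tot)$total_bits
  expect_lt(dl_out, dl_in)
  expect_equal(max(vapply(opt$rules, function(r) length(r$conditions), 0L)), 1L)
})

test_that("already-minimal ruleset on separable data is a fixed point", {
  sch <- toy_schema()
  concept <- planted_concept(ruleset(list(rule(list(condition("x1", "<=", 50)), "pos")), "neg"))
  ds <- generate_dataset(sch, concept, 200, seed = 29)
  pn <- split_pn(ds)
  ip <- induction_params(seed = 6)
  rs <- build_ruleset(pn$P, pn$N, ip)
  opt <- optimize_ruleset(rs, pn$P, pn$N, optimization_params(induction = ip))
  tot <- count_candidate_conditions(ds)
  expect_equal(ruleset_dl(opt, pn$P, pn$N, tot)$total_bits,
               ruleset_dl(rs, pn$P, pn$N, tot)$total_bits, tolerance = 1e-9)
})

test_that("train_multiclass orders classes by ascending frequency", {
  sch <- dataset_schema(
    list(attribute_spec("x", "numeric", range = c(0, 100))),
    attribute_spec("class", "categorical", categories = c("A", "B", "C")))
  df <- withr::with_seed(15, data.frame(
    x = c(stats::runif(10, 0, 10), stats::runif(30, 40, 60),
          stats::runif(60, 80, 100)),
    class = rep(c("A", "B", "C"), c(10, 30, 60))))
  ds <- new_dataset(sch, df)
  m <- train_multiclass(ds, optimization_params(induction = induction_params(seed = 8)))
  expect_equal(attr(m, "class_order"), c("A", "B", "C"))
  expect_equal(m$default_class, "C")
  # rule blocks appear in class order: all A rules precede all B rules
  cons <- vapply(m$rules, `[[`, "", "consequent")
  expect_true(all(sort(match(cons, c("A", "B"))) == match(cons, c("A", "B"))))
  expect_equal(mean(predict(m, ds) == df$class), 1)
})

test_that("single-class data trains to a default-only classifier", {
  sch <- toy_schema()
  ds <- generate_dataset(sch, planted_concept(ruleset(list(), "neg")), 30, seed = 3)
  m <- train_multiclass(ds)
  expect_length(m$rules, 0)
  expect_equal(m$default_class, "neg")
  expect_error(train_multiclass(subset_dataset(ds, integer(0))), "no labeled instances")
})

test_that("binary training learns the minority class over the majority default", {
  ds <- make_cleveland_like(300, seed = 11)
  m <- train_multiclass(ds, optimization_params(induction = induction_params(seed = 5)))
  freq <- table(dataset_labels(ds))
  expect_equal(m$default_class, names(freq)[which.max(freq)])
  minority <- names(freq)[which.min(freq)]
  expect_true(all(vapply(m$rules, `[[`, "", "consequent") == minority))
})

test_that("predictions are invariant to training row order at fixed seed", {
  ds <- generate_dataset(toy_schema(), toy_concept(0.05), 250, seed = 37)
  perm <- withr::with_seed(99, sample(n_instances(ds)))
  p <- optimization_params(induction = induction_params(seed = 12))
  m1 <- train_multiclass(ds, p)
  m2 <- train_multiclass(subset_dataset(ds, perm), p)
  expect_identical(serialize_ruleset(m1), serialize_ruleset(m2))
})

test_that("optimization (k >= 1) does not hurt training accuracy on planted data", {
  wins <- 0L
  for (s in 1:10) {
    ds <- generate_dataset(toy_schema(), toy_concept(0.05), 200, seed = 800 + s)
    pn <- split_pn(ds)
    ip <- induction_params(seed = s)
    rs0 <- ripper(pn$P, pn$N, optimization_params(k = 0, induction = ip))
    rs2 <- ripper(pn$P, pn$N, optimization_params(k = 2, induction = ip))
    acc <- function(rs) mean(predict(rs, ds) == dataset_labels(ds))
    if (acc(rs2) >= acc(rs0) - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 8L)  # allow rare DL-vs-accuracy tradeoffs
})
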