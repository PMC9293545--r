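# Synthetic planted-rule data: every learning and evaluation path is
# testable without external downloads. Attributes are sampled
# independently (numeric uniform over the declared range, categorical
# uniform over categories); the label is the planted rule set's
# decision-list prediction, optionally flipped by independent label noise.
# Noise is capped below 0.5 so the planted concept stays the Bayes
# classifier and noiseless recovery tests have a 100%-accuracy anchor.

#' Declare a planted concept
#'
#' @param rs An `rr_ruleset` acting as ground-truth labeler.
#' @param noise_rate Probability of flipping each generated label between
#'   the positive class and the default class; must lie in `[0, 0.5)`.
#' @return An `rr_concept`.
#' @export
planted_concept <- function(rs, noise_rate = 0) {
  stopifnot(inherits(rs, "rr_ruleset"), noise_rate >= 0, noise_rate < 0.5)
  structure(list(ruleset = rs, noise_rate = noise_rate), class = "rr_concept")
}

#' Generate a synthetic dataset from a planted concept
#'
#' @param schema An `rr_schema`; numeric attributes use their declared
#'   `range` (integers when `discrete`), categorical attributes sample
#'   uniformly over their categories.
#' @param concept A [planted_concept()].
#' @param n Number of instances (>= 0).
#' @param seed Integer seed; generation is fully deterministic in it.
#' @return A labeled `rr_dataset`. The noiseless planted labels are kept in
#'   the `"clean_labels"` attribute for auditing.
#' @export
generate_dataset <- function(schema, concept, n, seed = 1L) {
  stopifnot(is_count(n))
  cols <- list()
  with_seed(seed, {
    for (a in schema$attributes) {
      cols[[a$name]] <- if (a$kind == "categorical") {
        sample(a$categories, n, replace = TRUE)
      } else if (a$discrete) {
        as.numeric(sample(seq(a$range[1], a$range[2]), n, replace = TRUE))
      } else {
        stats::runif(n, a$range[1], a$range[2])
      }
    }
    df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    if (n == 0L) {
      df <- as.data.frame(stats::setNames(lapply(schema$attributes, function(a) {
        if (a$kind == "categorical") character(0) else numeric(0)
      }), schema_names(schema)), check.names = FALSE)
    }
    ds0 <- new_dataset(schema, df)
    clean <- predict(concept$ruleset, ds0)
    labels <- clean
    if (concept$noise_rate > 0 && n > 0L) {
      flip <- stats::runif(n) < concept$noise_rate
      classes <- schema$class_attribute$categories
      # flip between the label and the planted default / positive side
      labels[flip] <- vapply(labels[flip], function(l) {
        alt <- setdiff(classes, l)
        if (length(alt)) alt[1L] else l
      }, character(1))
    }
    df[[schema$class_attribute$name]] <- labels
    out <- new_dataset(schema, df)
    attr(out, "clean_labels") <- clean
    out
  })
}

#' The built-in Cleveland-like planted concept
#'
#' Two clinically shaped rules over the Cleveland schema: a reversible
#' thallium defect, or at least one fluoroscopy-colored vessel together
#' with asymptomatic chest pain, plants class "1"; everything else defaults
#' to "0".
#'
#' @param noise_rate Label-flip probability (see [planted_concept()]).
#' @return An `rr_concept` over [cleveland_schema()].
#' @export
cleveland_concept <- function(noise_rate = 0) {
  planted_concept(ruleset(list(
    rule(list(condition("thal", "=", "7")), "1"),
    rule(list(condition("ca", ">=", 1), condition("cp", "=", "4")), "1")
  ), default_class = "0"), noise_rate)
}

#' Generate a Cleveland-like synthetic dataset
#'
#' Schema and value ranges follow the 13-predictor Cleveland layout
#' (thallium codes 3/6/7, vessel counts 0-3, plausible physiological
#' ranges); labels come from [cleveland_concept()].
#'
#' @param n Number of instances.
#' @param seed Integer seed.
#' @param noise_rate Label-flip probability.
#' @return A labeled `rr_dataset` with 13 predictors and binary class.
#' @export
make_cleveland_like <- function(n, seed = 1L, noise_rate = 0) {
  generate_dataset(cleveland_schema(), cleveland_concept(noise_rate), n, seed)
}
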