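---
title: "Rule induction and clinical screening in ripperr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule induction and clinical screening in ripperr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripperr)
```

## The model

`ripperr` learns an *ordered decision list*: rules are tried top to
bottom, the first whose antecedent holds assigns its class, and a default
rule with an empty antecedent closes the list. This representation is the
reason to use a rule learner at all in clinical screening — every
prediction can be traced to one legible conjunction of conditions.

Learning follows the RIPPER scheme (repeated incremental pruning to
produce error reduction), which marries three ideas:

1. **Sequential covering.** Learn one rule for the current positive
   class, remove the instances it covers, repeat until the positives are
   exhausted or adding rules stops paying.
2. **Grow/prune separation.** Each rule is grown greedily on one part of
   the data and then pruned on a disjoint held-out part, so the
   conditions that survive justified themselves on data they were not
   fitted to.
3. **MDL accounting.** The rule set is charged for its own complexity
   (theory bits) and for the training errors it leaves (exception bits);
   the learner stops, prunes and selects among candidate rule sets by
   total description length.

Multiclass problems are reduced to a sequence of binary ones: classes are
sorted by ascending training frequency (ties broken lexicographically so
runs are reproducible), a rule block is learned for each of the first
m − 1 classes against everything not yet covered, and the most frequent
class becomes the default. On typical screening data this means the rare
(diseased) class gets explicit rules and the majority (healthy) class is
the fall-through — the clinically natural reading.

### Growth

Candidate conditions are `attr = v` over declared categories and
`attr ≤ t`, `attr ≥ t` over the distinct observed values of numeric
attributes. A candidate's score is the FOIL information gain

\[ IGN = p' \left( \log_2 rt' - \log_2 rt \right), \]

with `p'` the positives covered after adding the condition and `rt`,
`rt'` the positive fraction covered before/after. A candidate covering no
positives scores −∞ and is discarded. Growth stops when the rule covers
no negatives in the grow set or no candidate has strictly positive gain;
literal emptiness of the grow set is not the stopping event, since
growing never removes instances. Ties are broken deterministically:
earlier attribute in schema order, then smaller threshold, then `≤`
before `≥`. The threshold search is implemented with sorted cumulative
counts, so one growth step costs O(m log m) per numeric attribute.

### Pruning

Only trailing suffixes of the antecedent are candidates for deletion —
pruning starts with the condition added last, reflecting that later
conditions were fitted in the context of earlier ones. At least one
condition is always retained (an empty rule is the default rule's job).
The kept candidate maximizes `T = (p − n)/(p + n)` on the prune set, with
`T := 0` when a candidate covers nothing; exact ties go to the shortest
candidate.

### MDL coding

No single canonical "description length of a rule set" exists, so the
package fixes one precisely, bit for bit:

* `subset_dl(n, k, p) = −k log₂ p − (n−k) log₂(1−p)` with
  `0·log₂0 := 0`; an impossible code (k > 0 at p = 0) is reported as +∞,
  never dropped.
* Theory bits of a rule with k conditions from a pool of `total`
  candidates: `0.5 · [log₂ k + 2 log₂ log₂ k (k>1) + subset_dl(total, k,
  k/total)]`. The factor 0.5 is the classical redundancy discount.
* Exception (data) bits: `log₂(T+1)` plus `subset_dl` pointers to the
  false positives among covered and false negatives among uncovered
  instances; the larger side is coded at the expected error rate
  (`expected_fp_over_err = 0.5` splits the expected errors evenly), the
  smaller at its empirical rate.
* The candidate pool size is Σ category counts + 2 × Σ distinct numeric
  values — the number of distinct conditions growth could have chosen.

Covering stops when the total DL exceeds the best seen so far by more
than `dl_budget_bits`. The default is the classical 64; a much tighter
11-bit budget is exposed as a preset (`mdl_params(dl_budget_bits = 11)`)
because that constant circulates in descriptions of the algorithm, but 64
is the documented default. During covering, DL is evaluated against the
*full* positive and negative sets (not the shrinking remainder): this
keeps the data term comparable across iterations and makes the stopping
test monotone in what actually matters, total errors committed.

### Rule acceptance

A grown-and-pruned rule is rejected — and covering halts — when its
prune-set error rate reaches `max_prune_error` (default 0.5: worse than
guessing on held-out data) or it covers fewer than `min_rule_coverage`
(default 1) outstanding positives. Both thresholds are exposed because
"too poor" and "too limited" are inherently policy choices.

### Optimization

Each round revisits every rule with the rest of the list fixed: on the
instances the other rules leave uncovered, a *replacement* is grown from
scratch and a *revision* is grown onward from the current antecedent;
both are pruned, and the variant (original / revision / replacement)
minimizing the total DL is kept, ties favouring the original so separable
problems are fixed points. Revision can orphan positives, so a residual
covering pass appends rules for them, followed by the same reverse-order
DL deletion pass that closes covering. Finally a monotonicity guard
compares the result's DL with the input's and keeps the input if the
round did not pay: since DL is the selection criterion, a DL-increasing
round is by definition not an improvement. This makes "optimization never
increases description length" a property that holds by construction
rather than by hope; the residual pass is the only step that can add
bits, and the guard bounds its cost at zero.

`k = 2` rounds are the default; returns diminish quickly after that.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `ratio` | 2/3 | fraction | conventional grow share; prune set stays large enough to veto chance-pure rules |
| `k` | 2 | rounds | standard two-pass optimization |
| `min_rule_coverage` | 1 | instances | any accepted rule must make progress |
| `max_prune_error` | 0.5 | rate | held-out error at or beyond coin-flipping rejects the rule |
| `dl_budget_bits` | 64 | bits | classical slack; 11-bit preset available |
| `redundancy_factor` | 0.5 | — | classical theory-bit discount |
| `expected_fp_over_err` | 0.5 | — | errors split evenly between FP and FN a priori |
| `seed` | 1 | — | every random choice derives from this one integer |

The grow/prune split is re-drawn before each rule (`resplit = TRUE`),
which decorrelates successive rules; a single static split is available
for analyses that want the classical IREP setup.

## Determinism

One seed reproduces a whole run: split draws, optimization splits,
per-class and per-fold training seeds are all derived deterministically
from it. Training additionally sorts the instances into a canonical row
order first, so the learned model is invariant to how the rows happened
to be ordered on disk — a property the test suite asserts byte-for-byte
on the serialized model.

## The synthetic world

`generate_dataset()` samples attributes *independently* (numeric uniform
over a declared range, categorical uniform over categories) and labels by
a planted rule set, optionally flipping labels with probability
`noise_rate < 0.5` (so the planted concept remains the Bayes classifier
and noiseless recovery has a 100% ceiling). `make_cleveland_like()`
instantiates this over the 13-predictor heart-disease schema with
plausible physiological ranges and a two-rule planted concept over the
thallium, vessel-count and chest-pain attributes.

What a green recovery test establishes: the full grow/prune/MDL/optimize
pipeline can find a DNF structure that is genuinely there, under label
noise, reproducibly. What it does not establish: performance on real
clinical data, where attributes are correlated, classes overlap
intrinsically, and missingness is informative. The generator deliberately
has no correlation structure — that keeps every oracle analytic — so no
claim about real-data accuracy should be read off these tests.

## Numerical and degenerate-case choices

* Missing values are never imputed; a missing value fails every
  condition, so incomplete records fall through toward the default rule.
* Metrics with zero denominators return NA (a visible NOT_DEFINED
  sentinel), never 0 or NaN; accuracy is reported in percent, the other
  four as fractions.
* The F-score is the harmonic mean of precision and recall,
  `2Tpos/(2Tpos+Fpos+Fneg)`. A legacy variant replacing `Fneg` with
  `Tneg` circulates in some screening write-ups; it is available behind
  `f_as_printed = TRUE` strictly for auditing such outputs and is not a
  harmonic mean.
* Specificity is `Tneg/(Tneg+Fpos)` — true negatives over all actual
  negatives.
* `split_grow_prune` apportions per-class grow counts by largest
  remainder so the overall grow size is exactly `round(ratio · n)` while
  staying as stratified as rounding permits.
* Empty positive set ⇒ empty rule list; pure-positive grow set ⇒ empty
  antecedent (which the error-rate veto then rejects whenever negatives
  exist).

## The clinical band table and screening rules

The screening knowledge base discretizes raw physiology into labeled
bands (cholesterol, blood pressure, blood sugar, ST depression, age,
smoking years, and coded attributes). Several printed intervals
genuinely overlap (cholesterol "Medium" 188–250 vs "Higher" 217–307; age
"Middle" 35–45 vs "Older" 40–58). Resolution is first match in table
order — deterministic and faithful to the published band sequence —
with closed intervals including both endpoints and one-sided bands
keeping their strict inequalities. Values outside every band return the
sentinel `UNBANDED`; nothing throws.

The eleven screening rules run over derived dichotomies: thallium code 3
maps to "less" (normal), 6 and 7 to "higher" (fixed/reversible defect);
the vessel attribute has no published band rows, so fluoroscopy count 0
maps to "less" and ≥ 1 to "higher" (the threshold is configurable).
Under first-match order, rule 8 ("thallium higher and vessel less ⇒
presence_2") is fully shadowed by rules 6–7, which split the same
premises by angina; the package preserves the published order rather
than repairing it, and `context_reachability()` reports rule 8 (and the
similarly shadowed rule 11) as unreachable, together with the fraction
of attribute combinations that fall through to DEFAULT. Incompleteness
and shadowing are surfaced, never silently fixed.

## Known limitations

* On pure-noise labels the error-rate veto is the binding rejection, and
  a short rule can be chance-pure on a modest prune set: across seeded
  trials the learner accepts up to ~3 spurious rules (median ≤ 1) on
  n = 200 coin-flip data rather than always 0–1. Tightening
  `max_prune_error` or the DL budget trades this against recall on true
  structure.
* Numeric conditions are single thresholds (`≤`/`≥`); intervals arise
  only as conjunctions, and `<`/`>` are deliberately excluded to keep
  the candidate space finite over observed values.
* The learner offers no probabilistic outputs, rule weighting, or
  calibration; the context engine does no learning at all.
* Cross-validation retrains per fold but shares the band table and
  screening rules globally; they are static knowledge, not fitted
  objects.
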