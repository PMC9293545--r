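# ripperr

Interpretable rule induction for clinical risk screening in R.

`ripperr` is for biostatisticians and clinical-informatics researchers who
need disease-risk classifiers that a physician can read: ordered lists of
`IF ... THEN ...` rules over tabular patient data (the UCI Cleveland
heart-disease layout and anything like it), rather than opaque ensembles.
It implements the RIPPER family of sequential-covering learners together
with a static, context-aware clinical screening rule base, the usual
confusion-matrix metrics, a synthetic planted-rule data generator, and a
small CLI.

## The algorithm

Training learns an ordered decision list, one class at a time in ascending
class frequency, the most frequent class becoming the default rule. For
each class, rules are induced by sequential covering with four stages:

* **Growth.** The training data is split (stratified, default 2/3 : 1/3)
  into a grow set and a prune set. Starting from an empty antecedent,
  conditions (`attr = v` for categorical, `attr ≤ t` / `attr ≥ t` for
  numeric) are added greedily, each chosen to maximize FOIL information
  gain

  `IGN = p' · (log₂ rt' − log₂ rt)`,

  where `p'` is the positive count covered after adding the condition and
  `rt`, `rt'` are the positive fractions covered before and after. Growth
  stops when the rule covers no negative grow instances or no condition
  has positive gain.

* **Pruning.** Trailing condition suffixes are deleted to maximize
  `T = (p − n) / (p + n)` on the held-out prune set (reduced-error
  pruning).

* **MDL stopping and selection.** A rule set is scored in bits: theory
  bits per rule (redundancy factor 0.5) plus Quinlan-style exception bits
  for its training errors. Covering stops when the total description
  length exceeds the best seen so far by more than a budget (default 64
  bits; the 11-bit variant is available), a candidate rule is rejected
  when its prune-set error reaches 0.5 or it covers no new positives, and
  a final reverse-order pass deletes any rule whose removal shortens the
  description.

* **Optimization.** `k` rounds (default 2) revisit each rule, growing a
  *replacement* (from scratch) and a *revision* (from the current
  antecedent) on the instances the other rules leave uncovered, and keep
  whichever of original/revision/replacement minimizes the total
  description length; a residual covering pass then restores completeness.

Evaluation reports accuracy `(Tpos+Tneg)/total` (percent), precision
`Tpos/(Tpos+Fpos)`, recall `Tpos/(Tpos+Fneg)`, specificity
`Tneg/(Tneg+Fpos)` and F-score `2·prec·rec/(prec+rec)`, with stratified
cross-validation.

Separately from the learner, `assess()`/`screen_records()` apply a fixed
context-aware clinical rule base: eleven ordered screening rules over
banded attributes (thallium scan normal vs defect, fluoroscopy vessel
count, chest pain type, exercise-induced angina, family history, medical
records), with the band table (`band_table()`, `discretize()`) covering
cholesterol, blood pressure, blood sugar, ST depression, age, smoking and
more. First match wins; unmatched records are flagged `DEFAULT`.

## Worked example

```r
library(ripperr)

ds <- make_cleveland_like(300, seed = 1)   # synthetic, Cleveland-shaped
model <- train_multiclass(ds)
print(model)
#> #% format=ripperr-rules
#> #% version=1
#> IF thal = 7 THEN 1
#> IF cp = 4 AND ca >= 1 THEN 1
#> IF TRUE THEN 0

cm <- confusion_counts(dataset_labels(ds), predict(model, ds), positive_class = "1")
compute_metrics(cm)
#> accuracy    100.00%
#> precision   1.0000
#> recall      1.0000
#> specificity 1.0000
#> f_score     1.0000
```

The generator plants the concept "reversible thallium defect, or ≥ 1
colored vessel with asymptomatic chest pain ⇒ disease"; the learner
recovers exactly those two rules (class `"1"`), everything else falling to
the default `"0"` (healthy). The 100% metrics are the noiseless-recovery
sanity anchor, not a claim about real data — see the vignette for what
the synthetic world does and does not establish.

Context screening:

```r
assess(patient_record(thallium = 7, vessels = 0, induced_angina = 1, chest_pain = 4))
#> outcome: presence (rule 7)
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ripperr", package = "ripperr"))')
Rscript "$CLI" simulate --n 300 --seed 1 --out sim.csv
Rscript "$CLI" train    --data sim.csv --rules model.rules --seed 1
Rscript "$CLI" evaluate --data sim.csv --folds 5 --seed 1
Rscript "$CLI" screen   --data patients.csv --out assessments.csv
```

Subcommands: `train`, `predict`, `evaluate`, `screen`, `simulate`. Flags
mirror the parameter objects (`--seed`, `--k`, `--ratio`,
`--dl-budget`, `--folds`, `--positive-class`, ...); `--config file`
supplies `key=value` defaults that flags override. Exit codes: 0 success,
1 usage, 2 I/O, 3 schema/validation, 4 partial failure.

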