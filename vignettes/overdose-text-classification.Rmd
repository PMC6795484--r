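---
title: "Classifying drug overdose deaths from death-certificate free text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying drug overdose deaths from death-certificate free text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The surveillance problem

Drug overdose (OD) deaths are identified in mortality surveillance by the
ICD-10 underlying cause-of-death (UCOD) code on the coded death
certificate: an OD death is one whose UCOD falls in X40–X44 (unintentional
poisoning), X60–X64 (intentional self-poisoning), X85 (assault by
poisoning) or Y10–Y14 (poisoning of undetermined intent). Coding happens
at NCHS weeks after the death, but the certifier's free-text cause-of-death
statement is available almost immediately. `odcert` implements a
classifier that reads only that free text and predicts whether the coded
record will be an OD death, giving health departments provisional OD
counts months earlier.

The package treats the task as binary text classification under heavy
class imbalance: roughly 3% of deaths are ODs, the text is terse, fully
capitalized, rarely grammatical ("ACUTE COCAINE TOXICITY" / "ACCIDENTAL
OVERDOSE"), and the features are binary indicators of word, bigram and
trigram presence.

## The model

### Featureization

Each certificate contributes up to six free-text fields: the immediate
cause (line a), three "due to" lines, the "significant conditions
contributing" (SCC) section, and the description of injury. Two field
combinations are supported: `all_sections` uses everything;
`no_scc` drops the SCC section. The selected fields are concatenated in
certificate reading order, uppercased, punctuation is replaced by spaces,
and whitespace is collapsed (`combine_fields()`).

The combined string is tokenized into maximal alphanumeric runs of at
least two characters; stop words are removed; all contiguous 1-, 2- and
3-grams of the remaining tokens are enumerated; any n-gram occurring in
fewer than five training documents is discarded; the surviving n-grams,
ordered lexicographically, define the feature space. Feature $j$ of
document $i$ is $x_{ij} = \mathbf{1}[\text{n-gram } j \text{ occurs in
document } i]$ — presence, never counts. At deployment the training
vocabulary is frozen: test-year n-grams never seen in training contribute
nothing.

### Classifiers and the tuning protocol

Three families are implemented behind one fitting function, `od_train()`:
a linear support vector machine (`e1071`), a random forest (`ranger`) and
a single-hidden-layer perceptron (`nnet`). Hyperparameters (SVM cost;
forest depth, size and feature sampling; MLP hidden width and weight
decay) are tuned by 3-times-repeated, stratified 10-fold cross-validation
scored by the F-score,

$$F = \frac{2 \cdot \mathrm{PPV} \cdot \mathrm{Sens}}
           {\mathrm{PPV} + \mathrm{Sens}},$$

the harmonic mean of positive predictive value and sensitivity. F-score,
not accuracy, drives tuning because a majority-class classifier is 97%
accurate and useless. Stratification assigns each class to folds
round-robin after a seeded shuffle, so every fold's positive count is
within one of $n_{pos}/k$ — an invariant the test suite asserts directly.

Tuning is an iterative grid search: score a coarse grid, then re-search
around the winner (geometric neighbours for continuous hyperparameters,
arithmetic steps for integer ones; a winner at a grid edge widens the
grid outward), stopping when the winner is interior and the round-on-round
improvement falls below $10^{-3}$, or after five rounds. Exact F-score
ties go to the least complex candidate — lowest cost, shallowest forest,
smallest hidden layer, largest decay — a deterministic, regularization-
friendly convention. The chosen values are then refit on all training
rows.

### The rule-based baseline

The operational alternative is a curated list of overdose-indicative
words and bigrams: a certificate is positive iff any phrase occurs as a
contiguous token subsequence of its combined text. Matching is on token
boundaries, never substrings (the phrase "OD" must not fire inside
"METHOD"). The package ships a 37-phrase default list
(`default_phrase_list()`); it is a constructed stand-in, labelled
synthetic, and fully replaceable by a one-phrase-per-line file.

### Evaluation

`evaluation_report()` produces the confusion matrix and PPV, sensitivity,
specificity and F-score; undefined ratios (zero denominators) are
reported as `NA` with a warning, never silently as 0. Classifiers are
compared with the pooled-variance two-proportion z-test without
continuity correction,

$$z = \frac{\hat p_1 - \hat p_2}
       {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)}},
  \qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

one-tailed with the learned model as group 1 ("greater"). When published
comparison counts are unavailable, `count_from_proportion()` reconstructs
them from printed proportions (e.g. sensitivity 0.9243 of 912 true
positives → 843); this is explicitly approximate and only used to rebuild
comparison inputs from published tables. When the pooled proportion is 0
or 1 the statistic is degenerate; since both sample proportions are then
necessarily equal, the test returns $z = 0$, $p = 0.5$, with a warning.

## The synthetic certificate generator

Real death-certificate data is restricted, so the package generates
synthetic corpora (`simulate_certificates()`) with the statistical
structure the method assumes:

* **Prevalence** — each record is an OD with probability
  `od_prevalence = 0.03`, matching the ~3% rate in statewide data.
* **Text shape** — OD records draw from terse templates ("ACUTE {drug}
  TOXICITY", "{drug} OVERDOSE", "MIXED DRUG INTOXICATION", injury
  "ACCIDENTAL OVERDOSE"); non-OD records draw from natural- and
  external-cause templates ("ACUTE MYOCARDIAL INFARCTION" due to
  "CORONARY ARTERY DISEASE", …). UCOD codes are sampled consistently with
  the label, so generated labels always equal `label_from_ucod(ucod)`.
* **SCC confounding** — a fraction `scc_confounder_rate = 0.05` of
  non-OD records carry overdose-history phrases ("HISTORY OF DRUG
  OVERDOSE", "PREVIOUS HEROIN OVERDOSE") in the SCC section only. This is
  the documented failure mode of including SCC text: such phrases
  describe a prior, non-fatal event. It makes the field-combination
  comparison a testable property — excluding SCC cannot hurt precision on
  this generator.
* **Certifier noise** — with probability `template_noise = 0.05` a record
  has a word dropped, duplicated, or abbreviated (OVERDOSE → OD,
  INTOXICATION → INTOX, …), emulating non-grammatical certifier habits.
* **Year split** — `simulate_study()` produces a train-year/test-year
  pair in which the test year's substance lexicon gains a novel drug
  (CARFENTANIL by default) never seen in training, emulating the arrival
  of new substances between training and deployment. The default phrase
  list deliberately omits it, and one OD template ("COMPLICATIONS OF
  {drug} USE") carries no generic overdose keyword, so novel-drug deaths
  are invisible to the keyword list while the learned model can still
  recover them from contextual tokens.

The defaults above are the package's study conditions and are used
unchanged by the test suite and the acceptance script (5,000 train-year
and 2,000 test-year certificates).

What the generator does **not** emulate: the vocabulary breadth of real
certifier language (hundreds of features here versus ~10,000 on real
statewide data), misspellings, demographic fields, multi-jurisdiction
coding dialects, or any real decedent's record. Template text is far more
separable than real text — under the default conditions the tuned
pipeline reaches F-scores at or near 1.0 on held-out synthetic data,
comfortably above the 0.95 floor the generator is designed to guarantee,
whereas published results on real data sit near 0.97. Passing the
end-to-end tests therefore demonstrates that the pipeline is implemented
correctly and that its qualitative behaviour (SCC confounding direction,
keyword-list brittleness to novel substances) is as designed — it is not
a forecast of real-data performance.

## Numerical and design choices

Choices the method description leaves open, fixed here once:

* **Punctuation becomes a space**, not deleted: "FENTANYL/HEROIN" must
  yield two tokens, not one merged nonsense token.
* **Field order** is certificate reading order (line a, due-to lines,
  SCC, injury); n-grams may span field boundaries because the fields are
  merged into one string before tokenization. A consequence: dropping SCC
  can create new cause–injury boundary n-grams, so the `no_scc`
  vocabulary is not a strict subset of `all_sections` (unigrams are; the
  tests assert exactly that).
* **"Appearing less than five times"** is read as *document* frequency,
  the default semantics of the standard vectorizer family; total-count
  semantics are available via `vectorizer_config(count = "total")`.
* **Tokens are alphanumeric runs of length ≥ 2**; single characters are
  dropped (standard vectorizer default, configurable).
* **Stop words** are a fixed English list frozen in the package for
  reproducibility, overridable by file; n-grams form after stop-word
  removal, so previously non-adjacent words may join.
* **Vocabulary order** is C-locale lexicographic, for deterministic
  column indices and byte-identical persistence.
* **ICD-10 matching** is on the uppercased 3-character prefix; 4th
  characters and dots are ignored.
* **Class weights** are not used; imbalance is handled entirely by
  tuning on F-score. Decision thresholds are each family's native one
  (sign of the SVM margin, probability 0.5).
* **Seeding** — one integer seed drives fold assignment, forest and MLP
  fitting, and the generator; every pipeline stage is a deterministic
  function of (data, seed), which the suite verifies by re-running.
* **Degenerate inputs** — empty text yields an all-zero feature row and
  the model's constant-feature prediction, flagged `no_features` at
  deployment; a fold with no positives is a configuration error advising
  a smaller `k` rather than a silent NaN.

## Problem sizes used by the tests

Unit tests run on corpora of tens to hundreds of generated certificates
with reduced CV settings (k = 5, 1–2 repeats, small grids); the
end-to-end checks and `scripts/acceptance.R` use the full study
conditions — 5,000/2,000 certificates, the default grids and the full
3×10 protocol for the linear SVM. These sizes are the package's chosen
reference experiment; the generator scales to larger corpora if heavier
experiments are wanted.

## Limitations

* The shipped phrase list is a synthetic stand-in, not any
  jurisdiction's operational 37-term list; rule-baseline results on real
  data depend entirely on the operational list used.
* The MLP is single-hidden-layer (`nnet`); the default grid only uses
  single-layer sizes, so nothing is lost at the defaults, but deeper
  architectures are out of scope.
* No probability calibration, confidence intervals, or McNemar-style
  paired tests; the comparison statistic is the (unpaired) two-proportion
  z-test, matching standard surveillance practice for this task.
* Part-of-speech and parse-based features, regular-expression rules, and
  fuzzy matching are deliberately excluded; published experience found
  syntax features unhelpful on non-grammatical certificate text.
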