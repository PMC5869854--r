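---
title: "Detecting risk-of-bias reporting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting risk-of-bias reporting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robscreen)
```

## The detection model

`robscreen` treats "does this manuscript report X?" as a lexicon-matching
problem over three items: randomization of animals to groups, blinded
assessment of outcome, and sample size calculation. The model is
deliberately not statistical: a document is called positive for an item
iff at least one *inclusion* regular expression matches its normalized
text at a position not overlapped by any *exclusion* match. This buys
three properties that matter in review tooling and that machine-learned
classifiers give up: every call is auditable (the evidence span is
returned), the vocabulary is directly editable by the reviewer, and
behaviour is exactly reproducible.

The assumptions are correspondingly strong. Reporting is equated with the
presence of a phrase from a finite vocabulary; a paper that randomized but
described it in unusual words is missed (a false negative), and a paper
that mentions, say, a blinded protocol in its discussion of other work is
over-called unless an exclusion catches it. Published validations of this
approach on real stroke corpora show exactly these failure modes —
over-calling of randomization and blinding (low specificity) and
under-calling of sample size calculations (low sensitivity) — so the
shipped lexicon must be understood as a seed to be grown against each new
literature, not a finished vocabulary.

### Normalization

Matching happens on normalized text: lowercased, whitespace runs collapsed
to single spaces, and hyphen–newline pairs (`"-\n"`) joined, which repairs
words split across lines by PDF-to-text conversion. An offset map projects
every normalized position back to the original file, so evidence can be
located in the source document. Offsets are reported 1-based inclusive,
the `substring()` convention. No other cleanup is performed at this layer:
what the PDF converter produced is what is scanned.

### Exclusion semantics

An exclusion pattern suppresses an inclusion match iff their character
spans intersect. Span-overlap was chosen over alternatives (sentence
co-occurrence, fixed windows) because it needs no sentence segmenter, is
trivially explained to a reviewer, and admits an exact brute-force oracle
(enumerate all matches, subtract overlapped ones) that the test suite runs
against 500 generated texts. Two consequences are worth knowing: an
exclusion only works when it physically overlaps the trigger (so exclusion
entries are written to share a keyword with the inclusion they guard), and
adding inclusions can only flip calls false→true while adding exclusions
can only flip true→false — a monotonicity that is also property-tested.

### Patterns

Patterns use the portable regular-expression core (character classes,
alternation, bounded repetition; no backreferences) so configurations stay
engine-agnostic; they are compiled (as PCRE) when a configuration loads,
never at detection time. The whole document is scanned by default,
references included, because converted full texts carry no reliable
section structure; `strip_after()` (CLI `--strip-after`) can truncate at a
heading pattern when a corpus is known to have clean reference headings.

## Evaluation statistics

Validation against manual gold-standard annotation reports sensitivity,
specificity and accuracy per item. Zero-denominator cases (no gold
positives, or no gold negatives) are flagged undefined rather than coerced
to 0 or 1, because silent coercion corrupts aggregate tables. When all
terms are defined, accuracy = p·Se + (1 − p)·Sp holds exactly (p the gold
prevalence); the suite asserts this identity on every evaluated confusion
matrix.

All interval estimates are exact Clopper–Pearson intervals computed from
Beta quantiles (`qbeta`), the inversion of the binomial tails. They are
conservative — realised coverage is at least nominal — which is the
appropriate default for the small journal- and epoch-level denominators
this tool produces. The implementation is cross-checked against a
tail-bisection oracle to 1e-9 over the full grid 0 ≤ k ≤ n ≤ 50 at levels
0.90/0.95/0.99, and its simulated coverage (10,000 replicates, p ∈ {0.05,
0.5, 0.95}, n ∈ {10, 100}) is verified to stay at or above 95%.

`reconstruct_counts()` inverts a published summary row (n, prevalence, Se,
Sp) to integer counts by rounding expected cell counts to nearest. Because
published inputs are themselves rounded, recovered metrics carry an
uncertainty of about one unit in the last printed digit; checks against
printed accuracies therefore use a ±1 percentage-point band, and report
percentages are rounded half-up to integers to match the display precision
of published tables.

## Prevalence grouping and trend

Journal summaries follow the field's display convention: journals
contributing fewer than five manuscripts (the `min_group_size` default)
are pooled into an `"other"` row rather than dropped, so per-item counts
are conserved; ranked rows are ordered by proportion descending with ties
broken alphabetically, making output deterministic.

Two epoch modes exist because both appear in practice: fixed calendar
widths (default 6 months) counted back from an anchor date — natural for
plots against a search date — and date quantiles (default quartiles) —
natural for regression with balanced group sizes. Month arithmetic clamps
the day of month (Oct-31 minus 6 months is Apr-30), which is unambiguous
and testable. In quantile mode, documents sharing an identical date always
fall in one bin (the provisional bin of the date's first occurrence in
date order); bin sizes may then differ, which is preferred to splitting a
date across bins.

The trend model is unweighted ordinary least squares of epoch proportion
on a time-ascending epoch index, the literal reading of "least squares
linear regression" on grouped proportions; an `n`-weighted variant is
available as a sensitivity analysis. Per-document logistic regression was
deliberately not made the default, to keep the estimate interpretable as
"change in reported proportion per epoch". With fewer than three epochs
the fit is refused; with a constant response the slope is 0, r² is
reported as 0 and the p-value as `NA`, since the zero-slope test is
degenerate there. Note that the "slope within two standard errors"
recovery guarantee is itself a ~2σ event; the tests therefore assert its
frequency over 40 simulated series rather than any single draw.

## The synthetic benchmark

Real validation corpora of full-text PDFs cannot be redistributed, so the
package carries a generator whose output stands in for them. Each document
is six keyword-free methods-boilerplate sentences plus planted phrases:
gold-positive documents receive one phrase from the item's positive bank,
gold-negative documents receive, with probability `confounder_rate`, a
confounder phrase using the item's keywords in an irrelevant sense
("random hexamer primers", "high power fields", "spectral power
analysis"). Positive counts are exact by assignment
(`round(n_docs × prevalence)` sampled without replacement) rather than
Bernoulli draws, so prevalence targets are exactly testable at small n.
Journals follow a skewed deterministic allocation that always yields both
≥5-paper and <5-paper groups; dates are uniform over the configured range;
a single integer seed drives one stream and the caller's random state is
restored afterwards.

Hardness calibrates difficulty against the shipped lexicon: level 0 plants
verbatim lexicon phrases (detection is perfect by construction — this
validates the coupling, not the detector), level 1 plants paraphrases
sharing lexicon keywords of which one per ten-phrase bank deliberately
evades the patterns (expected sensitivity ≈ 0.9), and level 2 plants
paraphrases avoiding the keywords entirely (sensitivity collapses). The
shipped benchmark configuration — 200 documents, 50% prevalence per item,
hardness 1, confounder rate 0.3, seed 20161004 — mirrors the scale of a
small validation corpus and exercises both error directions while leaving
the 0.80 sensitivity/specificity usefulness bar clearly attainable by the
seed lexicon.

What passing the benchmark does *not* show: performance on real prose.
Synthetic documents are short, single-register, English-only, and their
positive statements come from the same curated phrase space the lexicon
was written against. Field performance on a new literature must be
established against a manual gold standard for that literature; the
benchmark's role is regression-testing the pipeline and quantifying the
relative cost of paraphrase and confounders.

## Problem sizes and runtime choices

The test suite runs its stochastic properties at deliberately modest
sizes — 500 generated texts for the detector oracle, the full k ≤ n ≤ 50
interval grid, 10,000-replicate coverage simulations, 40-replicate slope
recovery, 200-document benchmarks — chosen so the whole suite completes in
about a minute on one CPU while keeping each property's sampling error
well below its assertion margin.

## Limitations

The detector inherits every upstream conversion artifact except the two it
repairs (case, hyphenation); supplementary materials are not scanned;
negation is handled only through the exclusion lists; and the shipped
lexicon encodes English stroke-literature phrasing. The evaluation layer
assumes a single gold annotator; inter-rater disagreement is outside its
scope.
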