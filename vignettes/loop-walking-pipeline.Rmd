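---
title: "Prioritizing loop triple mutants: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing loop triple mutants: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopwalk)
```

## The problem

A loop-walking screen randomizes three consecutive loop residues of an
enzyme at once and assays each picked variant twice: enzymatic activity
without heat treatment and residual activity after a heat challenge
(60 °C for 30 min in the assays this package models). A screen of ~200
clones covers under 3 % of the 20³ = 8000 possible residue triples, so the
interesting question is inverse: given the screened fraction, which
*unscreened* triples are most likely to be strongly stabilized? `loopwalk`
answers it with a physicochemically encoded, sparsity-regularized
discrimination cascade.

## Response variable and screening arithmetic

The modeled response is the thermostability activity
`T = 100 * residual / initial`, a within-variant ratio. Working with the
ratio rather than either raw channel cancels variant-to-variant expression
differences, because both measurements come from the same lysate. Reporting
conventions follow screening practice: `T` is rounded to the nearest
integer percent, while residual activity relative to wild-type is rounded
to two significant figures (a mutant at 1076.9 % of wild-type residual
activity is reported as 1100 %).

Quadrant classification partitions variants at the wild-type point
(100 %, 100 %) of the (relative activity, relative residual activity)
plane. A variant exactly at 100 % on an axis is classed as *non-improved*
on that axis: equality with wild-type is not an improvement, and in
practice exact ties occur only for the wild-type itself.

Synergy of a triple mutation over its three constituent singles is scored
against a multiplicative null: if effects on a ratio-valued response were
independent, the triple's relative residual activity would equal the
product of the single-mutant fractions. The score is the log10 excess over
that null; zero means exact multiplicativity. The "sum of individual
effects" intuition is thereby made precise in the only scale where
ratio effects add.

## Encoding

Each residue is mapped to 13 physicochemical descriptor scales and the
three positions are concatenated position-major into 39 features. The
packaged descriptor table (`paper_descriptors()`) is a curated stand-in
for a deduplicated AAindex selection: scales we could transcribe with
confidence carry their best-match accession ids (isoelectric point
ZIMJ680104, van der Waals volume FAUJ880103, hydropathy KYTJ820101, turn
frequency CHOP780101, polarity ZIMJ680103); the remaining eight rows are
synthetic curated values, flagged `SYN*` in their ids and labelled
"synthetic best-match values" in the citation column. They reproduce the
qualitative structure of the named properties (the atom–atom potential
stability scale is highest for Phe/Trp/Tyr, the side-chain interaction
parameter for Lys/Pro/Gln/Glu/Asp, and so on), and — deliberately — the
13 rows are mutually only moderately correlated (max |r| ≈ 0.84, and
≤ 0.73 among any pair relevant to the default generator truth). A
descriptor set selected as one representative per correlation cluster
should not contain near-duplicates, and near-duplicate columns would also
make any sparse fit's support ill-determined.

`select_representative_descriptors()` exposes the deduplication operation
itself: average-linkage hierarchical clustering on `1 − |Pearson r|`
between scales, cut at a chosen number of clusters, with each cluster
represented by the member most correlated (in absolute value) with its
co-members. Absolute correlation is used because an anti-correlated scale
carries the same information as its negation. Zero-variance scales cannot
be correlated and are dropped with a warning before clustering. Ties in
the representative score resolve to the earlier input row.

## Stratification

Variants are ranked by `T` (descending) and split by ceil-quotas:
`ceiling(0.34 n)` into *high*, `ceiling(0.34 n)` into *low*, remainder
*medium*. At n = 214 this gives 73/68/73. Note that 34 % tails cannot give
73 + 73 + 72 at n = 214 (that sums to 218); the quota actually implied by
the arithmetic is surfaced in the `"counts"` attribute of the label vector
and in the run report rather than being adjusted to any expected split.
Ties in `T` are broken by stable input order (radix sort), so
stratification is deterministic and independent of every seed in the
pipeline.

## The discrimination cascade

The two binary models are L1-penalized logistic regressions (`glmnet`,
`alpha = 1`). The logistic link is the natural choice for a discrimination
model whose outputs must be *probabilities* — stage 2 ranks candidates by
P(high), and stage 1 thresholds P(improved) at 0.5. Features are
standardized before fitting (population mean/sd, stored in the model and
re-applied at prediction time) because the L1 penalty is scale-sensitive
and because standardized weights are comparable across descriptor scales
in the 13 × 3 weight table. Constant feature columns standardize to zero
and are flagged rather than dividing by zero.

The penalty strength λ is governed by a `lambda_policy()`:

* `"cv"` — inner 10-fold cross-validated binomial deviance, minimized over
  glmnet's path; fold assignment derives deterministically from the policy
  seed. This is the default when *fitting* a model.
* `"cv_once"` — the default *inside leave-one-out validation*: λ is chosen
  once by inner CV on the full training set, then held fixed across the n
  leave-one-out refits. Re-running the inner CV inside every fold is
  statistically slightly cleaner but costs n × (nfolds + 1) path fits per
  LOOCV; with the fixed-λ variant an n = 214 LOOCV is two orders of
  magnitude cheaper, and the held-out sample still never influences its
  own fold's coefficients. The per-fold variant remains available as
  `lambda_policy("cv")` for sensitivity analysis.
* `"fixed"` — a user-supplied λ (used heavily in tests, where analytic
  limits need a known penalty).

Leave-one-out folds whose training set would retain fewer than two members
of a class cannot support the penalized fit; such folds fall back to the
training majority class and are flagged in the report.

Stage 1 keeps a candidate iff P(improved) > 0.5 — with no stated selection
rule beyond "predicted improved", the Bayes threshold is the only
non-arbitrary choice. Stage 2 sorts survivors by P(high) descending; exact
probability ties are broken by lexicographic order in the fixed amino-acid
alphabet (A R N D C Q E G H I L K M F P S T W Y V — the AAindex value
order used throughout), which makes rankings reproducible byte for byte.
Candidate selection takes the top `n_high` entries and then the best
`n_medium` entries among those predicted medium (P(high) ≤ 0.5) that were
not already taken, so the two lists are disjoint for every input.

The wild-type triple receives no special treatment in enumeration: it is
excluded from the candidate list only if it was observed in the screen,
which is what makes the 8000 − 214 = 7786 arithmetic exact.

## The synthetic screen generator

Because real loop-walking datasets are rarely published, the generator
(`generative_config()`, `simulate_thermostability()`) is a first-class,
tested module. It emulates:

* a latent stability score `s = w · x̃ + b + ε`, sparse in the
  standardized features `x̃` (standardized against the full 8000-triple
  space, so the truth is a fixed function of sequence, not of the sample);
* a logistic link `retained = plogis(s)` mapping the score into (0, 1), as
  a physical retention fraction must be;
* an independent no-heat activity channel, log-normal around 1000 U/mL
  with 15 % coefficient of variation — a typical plate-assay error level —
  with residual activity as the product of the two. Apparent >100 %
  retention relative to wild-type can then arise through the activity
  channel, as it does in real screens, while the retention fraction itself
  stays physical.

The default truth has 5 nonzero weights, three in the position-1 block
(the hot-spot-like asymmetry where one residue dominates) and one each at
positions 2 and 3, with noise sd 0.5 — well under a quarter of the latent
signal spread, the regime in which a 214-variant screen carries enough
information for the cascade to be worth running. The five carrier
descriptors were chosen mutually weakly correlated so the planted truth is
*identifiable*: a recovery benchmark that plants opposed-sign weights on
two strongly correlated scales cannot distinguish failure of the fitter
from non-identifiability of the truth, because an L1 fit will represent
such a composite through either scale alone.

What the generator does **not** emulate: codon-level mutagenesis bias
(NNK vs NNN), expression artifacts, plate and batch effects, replicate
structure, or epistasis beyond the linear-in-descriptors model. Passing
recovery tests therefore show that the pipeline recovers structure *of the
kind it assumes*; they do not certify performance on real screens, where
the descriptor-linear assumption is itself the main approximation.

## Problem sizes and numerical conventions

The test suite and acceptance script run at the study's own sizes where
that is cheap (n = 214 screens, the full 8000-triple space, 20 seeded
recovery replicates) and at reduced sizes where an oracle is exponential
(brute-force linkage on ≤ 8 descriptors, 4-letter enumeration cross-checks
against nested loops). Standardization uses the population-sd convention
(divisor n), documented in `fit_scaler()`; `[1, 2, 3]` maps to
(−1.2247, 0, 1.2247). All randomness — library sampling, noise, activity
draws, inner-CV folds — flows from explicit integer seeds through a
save/restore wrapper, so no call disturbs the caller's RNG state and every
pipeline output is bit-reproducible for a fixed config.

## Known limitations

* The descriptor fixture is a curated stand-in, not the original
  supplementary accession list; analyses of *real* screens should load
  their own validated scales via `load_descriptor_table()` (CSV or
  AAindex1 flat-file).
* LOOCV accuracy on tertile-stratified data is optimistic near the class
  boundaries, where labels are determined by rank rather than by a margin;
  no significance testing is attached to hit rates or synergy scores.
* Duplicate triples in a screen abort the run rather than being merged:
  replicate-merging policy is assay-specific and left to the user.
* The linear-logistic cascade cannot represent within-loop epistasis
  beyond what the descriptor products encode; its value is ranking, not
  mechanistic truth.
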