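---
title: "Correlation-weight models from SMILES attributes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight models from SMILES attributes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwqsar)
```

## The model

`cwqsar` fits one-descriptor regressions of the form

$$\mathrm{endpoint} = C_0 + C_1 \cdot DCW(T, N), \qquad
  DCW(T,N) = \sum_k CW(S_k) + \sum_k CW(SS_k),$$

where the sums run over every occurrence of every SMILES attribute in a
compound's notation: single SMILES atoms $S_k$ (one character, or an
indivisible group such as `Cl`, `Br`, `@@`, a bracket-atom expression,
or a `%nn` ring closure) and unordered adjacent pairs $SS_k$.  The
modeling assumption is therefore purely additive and text-level: the
endpoint is (approximately) a linear function of counts of local
notation features.  No chemistry is perceived — no valence model, no
aromaticity, no 3D structure.  What the method "knows" about a compound
is exactly its token statistics, which is why canonical SMILES input
matters: two different notations of the same molecule have different
attributes.  Canonicalization is deliberately out of scope and should
happen upstream.

Two normalizations make the attribute space well-behaved:

* `)` is folded into `(`, so branching contributes a single attribute
  type rather than two artificially distinct ones;
* pairs are unordered, keyed with the higher-character-code token first
  (`(O,=)` and `(=,O)` are the same attribute).  This matches the
  conventional two-column attribute listings, every pair row of which
  is consistent with this ordering rule.

## The four-way split and the target functions

The data are partitioned into active training, passive training,
calibration and validation blocks, by default in equal quarters.  The
weights are driven by the active block; the passive block penalizes
solutions that only work there; the calibration block steers the model
through the TF1 terms; the validation block is untouched until final
reporting.

Monte Carlo optimization maximizes either

$$TF_0 = r_A + r_P - |r_A - r_P| \cdot 0.1$$

(signed Pearson correlations of observed endpoint vs. descriptor on
the two training blocks; the penalty term rewards *balanced*
correlations) or

$$TF_1 = TF_0 + (IIC_C + CII_C) \cdot 0.5,$$

which adds the index of ideality of correlation and the correlation
intensity index on the calibration block.  IIC is Pearson $r$ scaled
by $\min(MAE^-, MAE^+)/\max(MAE^-, MAE^+)$, the ratio of the one-sided
mean absolute residuals; it punishes models whose errors are
systematically one-sided.  Because that ratio depends on the residual
scale and sign, the package evaluates IIC against predictions from an
intercept/slope refit on the active block at every proposal.  CII is
$1 - \sum_k \max(0, R^2_{(k)} - R^2)$ over leave-one-out subsets; it
punishes correlations that are propped up by removable
"oppositionist" points.  CII depends only on correlations, so it is
evaluated directly against the descriptor.

Blocked attributes — those present in fewer than $T$ active-training
compounds — keep weight 0 throughout.  Rarity is counted per compound
(an attribute occurring five times in one compound counts once),
consistent with frequency tables whose counts are commensurate with
block sizes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `T` | 3 | rarity threshold, in active-training compounds; below it an attribute is blocked |
| `N` | 15 | optimization epochs; one epoch visits every non-blocked attribute once |
| `target_function` | TF1 | TF0 for training-set-only optimization |
| `step_magnitude` | 0.5 | half-width of the uniform weight perturbation, in weight units |
| `initial_weight` | 1.0 | starting weight of non-blocked attributes; at `N = 0` the descriptor is then a raw attribute count, a sensible baseline |
| `k` | 10 | Las Vegas candidates; more candidates only improve the selected split, at proportional cost |
| `probe_epochs` | 3 | epochs of the probe optimization used to score a candidate split |
| `min_frequency` | 10 | per-block compound count an attribute needs to be reported as a promoter |

The `T = 3`, `N = 15` regime is the standard practical setting for this
family of models, and the defaults reproduce it.

## The proposal move

The update scheme inside an epoch is the one genuinely open design
choice, and the package's choice is a *directional coordinate search*:
for each attribute (in seeded random order) draw a single step
$\delta \sim U(-s, +s)$; try $w + \delta$, and if that is rejected try
$w - \delta$; once a direction is accepted, keep stepping by the same
$\delta$ while the target function strictly improves, up to 20
sub-steps.  Acceptance of the first step is non-strict (ties accepted,
allowing plateau drift); continuation steps require strict improvement
so that ties cannot cause unbounded drift along a flat region.

The rationale: a single symmetric proposal per attribute per epoch
wastes half its proposals on the wrong sign and travels $O(s)$ per
epoch, which converges far too slowly to be useful inside the 15-epoch
regime — weights routinely need to move several units from their
uniform start.  The directional search keeps the defining contract
(seeded determinism; a perturbation is accepted iff the target function
does not decrease; the TF sequence over accepted moves is
non-decreasing; blocked weights never move) while converging within
the default epoch budget.

## Las Vegas split selection

`las_vegas_select()` draws `k` random partitions (candidate seeds
derived deterministically from the master seed), runs a short TF1 probe
optimization on each, and scores each candidate by the calibration-set
$IIC + CII$ of the probe.  The winner is the candidate with the best
score — by construction the maximum of the logged candidate scores,
which is also how the tests verify it.  The criterion is configurable
(`"r2"` scores the probe calibration $R^2$; `"overlap"` skips
optimization and scores the mean pairwise endpoint-distribution
overlap).  Overlap is measured as histogram intersection on shared
equal-width bins over the pooled endpoint range — a stand-in for
"percentage of matching distributions", whose exact published
definition is not available in the main text of the method literature.

## Applicability domain and interpretation

For each attribute, the statistical defect
$d_k = \sum_{\text{block pairs}} |P - P'|/(N + N')$ compares its
per-block occurrence probabilities (compound fractions) across the
active, passive and calibration blocks; terms with zero combined
frequency contribute 0.  A compound's defect $D_j$ sums $d_k$ over its
non-blocked attribute occurrences, and the compound is in-domain iff
$D_j < 2\bar{D}$ strictly, where $\bar{D}$ is the mean $D_j$ over the
active ∪ passive ∪ calibration population — the only population that
can define the reference, since those three blocks define the defects
themselves.  The degenerate case $\bar{D} = 0$ (perfectly uniform
attribute distributions) flags everything out by strictness; the
package warns rather than redefining the boundary.  The domain is
advisory: predictions are still produced for out-of-domain compounds,
flagged.

Promoter extraction classifies an attribute as an endpoint *increase*
promoter when its weight is strictly positive in every one of ≥ 3
independent optimization runs (all negative: *decrease*; any mixed or
zero: unstable, omitted), subject to a `min_frequency` cut in each of
the three training-type blocks so that interpretation rests on
well-populated attributes.

## The synthetic generator

`generate_dataset()` produces grammar-generated SMILES-like strings —
chains over a 9-token alphabet with optional one-atom branches, `=`
marks and at most one ring-digit pair, always balanced and always
tokenizable — and plants an endpoint that is exactly affine in the
descriptor of a chosen true weight table, plus Gaussian noise.  The
defaults (300 compounds, 10–30 tokens, noise SD 0.1, planted signs
with sulfur/cycles positive and oxygen/double-bond/nitrogen negative,
$C_0 = -0.5$, $C_1 = 0.4$) produce an endpoint span of several log
units, comparable to real pNOAEL collections, with planted magnitudes
from 0.05 up to 1.5 so that both blocked-scale and dominant attributes
are represented.

The generator emulates precisely the statistical structure the model
assumes, and nothing else.  Passing recovery benchmarks on it shows
that the optimizer, split search, metrics and diagnostics work as
specified; it does **not** show that real toxicity endpoints are
additive in SMILES attributes, that real data are this clean, or that
real chemical space is covered.  Real endpoints carry measurement
variability across studies, non-additive structure and duplicated
scaffolds that the generator deliberately omits.

## Numerical choices and degenerate inputs

* IIC with one empty residual side is 0 (the empty side's MAE is 0),
  except the all-zero-residual case, defined as $IIC = r$ — the
  continuous perfect-fit limit.
* CII leave-one-out correlations are computed incrementally from
  running sums in $O(n)$ per evaluation; deleted subsets with
  (numerically) zero variance contribute protest 0, with a warning in
  the exported function.  The incremental form is capped at
  $R^2_{(k)} \le 1$ to keep rounding from manufacturing protests on
  exact fits; tests verify agreement with a from-scratch oracle at
  $10^{-10}$.
* $Q^2$ refits only $C_0$/$C_1$ per deletion (weights frozen), via the
  closed-form PRESS of simple regression; leverage 1 is rejected as
  degenerate.
* $R^2$ is the squared Pearson correlation throughout, and CCC uses
  population ($1/n$) moments — the readings under which the published
  reporting arithmetic is reproducible.
* The final $C_0$/$C_1$ are fit on the active training block, the set
  whose correlation the weights were optimized against; the calibration
  block influences the model only through TF1.
* Proposals that make any needed correlation undefined (zero-variance
  descriptor on a block) are rejected outright; a degenerate *initial*
  state raises an error instead.
* Zero-variance endpoints in any training block, empty blocks, and
  dictionary/config `T` mismatches are configuration or numeric errors,
  never silent.
* Model files store 17 significant digits, enough for bit-exact
  round-trips of doubles through decimal text.

## Problem sizes

The bundled tests run the full pipeline at 300 compounds (the
recovery benchmark: Las Vegas over 10 candidates with 3 probe epochs,
then 15 epochs of TF1) in well under a minute, and the metric oracles
on 200 random series of up to 50 points.  These sizes were chosen as
the smallest at which the benchmark is statistically meaningful; the
implementation itself is vectorized per proposal and handles
thousand-compound tables comfortably, with cost linear in compounds ×
attributes × epochs.

## Known limitations

* Attribute kinds are limited to single atoms and adjacent pairs;
  the key/kind representation is extensible to longer n-grams, but no
  further kinds are implemented.
* The optimizer is a local, greedy stochastic search: different seeds
  give different weight tables of similar quality.  That is inherent to
  the method — promoter extraction exists precisely to separate the
  stable signal from run-to-run noise.
* Prediction quality is only as good as the attribute overlap between
  training and query compounds; unseen attributes contribute 0 to the
  descriptor and are surfaced in `n_unseen` rather than treated as
  errors.
* The linear endpoint model is fixed by design; nonlinear links are out
  of scope.
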