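---
title: "Degree-based topological indices and QSPR models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and QSPR models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqspr)
```

## The modelling problem

Quantitative structure–property relationship (QSPR) modelling predicts
physicochemical properties of molecules from numerical descriptors of their
structure. This package works with the cheapest useful family of
descriptors: *degree-based topological indices* of the hydrogen-suppressed
molecular graph, in which heavy atoms are vertices and bonds are edges
(bond order and stereochemistry are deliberately ignored). The study
packaged here covers 17 drugs used in bladder-cancer therapy, each with
seven tabulated properties — boiling point (BP), enthalpy of vaporization
(EV), flash point (FP), molar refractivity (MR), polar surface area (SA),
molar volume (MV) and polarizability (P) — in unspecified but internally
consistent units.

## Edge partitions as the sufficient statistic

Every degree-based index has the form
$$I(G) = \sum_{uv \in E(G)} f(d_u, d_v)$$
with a symmetric per-edge term $f$. The multiset of unordered endpoint
degree pairs — the *edge partition* $\{E_{(a,b)}\}$ — therefore determines
all such indices, and the package computes indices exclusively from
partitions. The ten registered terms are

| index | per-edge term |
|---|---|
| $M_1$ (first Zagreb) | $d_u + d_v$ |
| $M_2$ (second Zagreb) | $d_u d_v$ |
| $H$ (harmonic) | $2/(d_u + d_v)$ |
| $F$ (forgotten) | $d_u^2 + d_v^2$ |
| $SS$ | $\sqrt{d_u d_v/(d_u + d_v)}$ |
| $ABC$ (atom-bond connectivity) | $\sqrt{(d_u + d_v - 2)/(d_u d_v)}$ |
| $RI$ (Randić) | $1/\sqrt{d_u d_v}$ |
| $SC$ (sum-connectivity) | $1/\sqrt{d_u + d_v}$ |
| $GA$ (geometric–arithmetic) | $2\sqrt{d_u d_v}/(d_u + d_v)$ |
| $HZ$ (hyper-Zagreb) | $(d_u + d_v)^2$ |

Two remarks on fidelity. First, the descriptor named *SS* here is
implemented exactly as tabulated in the source study,
$\sum \sqrt{d_u d_v/(d_u+d_v)}$, although the name "symmetric division
degree" conventionally denotes $\sum (d_u^2+d_v^2)/(d_u d_v)$; the study's
own worked example uses the tabulated formula, and reproducing its
arithmetic takes precedence over nomenclature. Second, the identity
$HZ = F + 2M_2$ holds exactly (expand $(d_u+d_v)^2$), which makes it a
free data-integrity check: `validate_descriptor_table()` applies it to
every packaged row. The same identity means a descriptor *matrix* with all
ten columns has column rank at most 9 — exact collinearity, not a data
defect — which is why the synthetic generator's well-posedness check asks
for rank $\ge 9$ on the standardized matrix rather than full rank.

The `ABC` term vanishes on an edge between two degree-1 vertices
($d_u + d_v - 2 = 0$); no special-casing is needed, and degrees $\ge 1$
rule out division by zero everywhere.

## The packaged drug tables

`drug_properties()` and `drug_descriptors()` ship the study's two data
tables; `lenalidomide_partition()` ships the one fully worked edge
partition, $E_{(1,3)}=4$, $E_{(2,2)}=3$, $E_{(2,3)}=8$, $E_{(3,3)}=6$,
whose ten index values pin down every per-edge term implementation. The
printed descriptor table was transcribed using the $HZ$ identity as a
per-row cross-check. One cell (Axitinib's $F$) is absent from the printed
source; it is reconstructed as $HZ - 2M_2 = 362$ and flagged
`reconstructed` in the validation report rather than silently imputed. The
full molecular graphs of the 17 drugs are not published (only drawn), so
apart from Lenalidomide's partition the descriptor rows are taken as data,
not recomputed.

```{r}
validate_descriptor_table()[c(1, 6), ]
```

## Regression models

For each descriptor $x$ and property $y$, two ordinary-least-squares
models are fitted on all 17 drugs:
$$y = \beta_0 + \beta_1 x + \varepsilon \qquad\text{and}\qquad
  y = \beta_0 + \beta_1 x + \beta_2 x^2 + \beta_3 x^3 + \varepsilon .$$
Raw monomials are used, not orthogonal polynomials, so the coefficients
are directly comparable with published equations; the price is an
ill-conditioned design when $x$ ranges into the thousands (e.g. $HZ$),
which is harmless for the QR-based solver but is recorded as a condition
number on each fit. Rank deficiency proper (constant $x$, or fewer
distinct values than coefficients) is an error.

The statistics panel reported with each fit is
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$, $R = +\sqrt{R^2}$ (published
magnitudes are positive regardless of slope sign),
$F = (R^2/k)\big/((1-R^2)/(n-k-1))$ with $k$ the degree, and the
upper-tail $F(k, n-k-1)$ p-value. The residual dispersion is the residual
standard error $S_E = \sqrt{\mathrm{RSS}/(n-k-1)}$. The source study's
printed $S_E$ column is internally inconsistent (its cubic $S_E$ exceeds
its linear $S_E$ on the same data despite a higher $R^2$), so this package
standardizes on the definition above and does not attempt to reproduce
printed $S_E$ values. No train/test split is used anywhere: with $n = 17$
the study fits and reports in-sample, and all metrics in this package are
explicitly in-sample.

```{r}
d <- load_drug_table()
fit_polynomial(d$M1, d$BP, 1, "M1", "BP")
```

## The feedforward network

`ann_train()` implements a fully-connected network
$10 \to 32 \to 32 \to 1$ with ReLU hidden activations and a linear output,
trained by full-batch backpropagation on the mean squared error. Design
choices, with defaults in `ann_config()`:

* **Standardization** — inputs and target are z-scored (descriptor scales
  span orders of magnitude); predictions are inverse-transformed.
* **Optimizer** — adaptive-moment (Adam) updates, learning rate $10^{-3}$,
  $\beta_1 = 0.9$, $\beta_2 = 0.999$; full-batch, so the seed controls
  initialization only and training is bit-reproducible.
* **Initialization** — uniform $\pm\sqrt{6/(n_{in}+n_{out})}$ weights and
  zero biases, drawn from the configured seed; the documented seed set for
  capability checks is $\{0, \dots, 9\}$.
* **Stopping** — at most 20 000 epochs, stopping early once the best loss
  has not improved by more than $10^{-10}$ for 500 consecutive epochs; the
  returned weights are those of the best observed loss, so the reported
  trajectory is a running minimum and non-increasing by construction.
* **Divergence** — a non-finite loss aborts with advice to lower the
  learning rate rather than returning garbage weights.

`ann_gradients()` exposes the analytic backprop gradients so they can be
(and are, in the test suite) checked against central finite differences.
One subtlety worth recording: the check fixture perturbs biases away from
zero first, because a ReLU pre-activation of exactly zero sits on the kink
where a central difference is not a valid derivative estimate and the
comparison would be meaningless, not wrong.

With 17 samples and ~1 400 parameters the network can interpolate; the
interesting statement is not generalization (none is claimed) but
*capability*: the architecture recovers the tabulated in-sample fit
quality ($R^2 \ge 0.94$ for BP, $\ge 0.99$ for polarizability) under the
documented optimizer and seeds. The study's own per-drug predicted values
depend on its unstated optimizer state and are not exactly recoverable;
only metric panels recomputed from its printed prediction columns are
asserted.

## Exact Shapley attribution

`exact_shapley()` attributes a model prediction to the $d$ input features
by full enumeration of the $2^d$ coalitions:
$$\phi_i = \sum_{S \subseteq D \setminus \{i\}}
  \frac{|S|!\,(d-|S|-1)!}{d!}\,\bigl(v(S \cup \{i\}) - v(S)\bigr),$$
with the value function $v(S)$ defined as the model prediction on the
explained sample with features outside $S$ replaced by the background
per-feature mean. A single mean-imputation background (here: the 17-drug
descriptor table) keeps the cost at $2^{10} = 1024$ model calls per sample
— done in one batched call — and makes the attribution deterministic; it
is an approximation of interventional attribution that averages over
background rows. Enumeration was chosen over kernel-regression or
sampling estimators because it is exact, which turns the Shapley axioms
(local accuracy, symmetry, dummy, linearity) into directly testable
properties; a permutation-sampling estimator is kept in the test suite as
an independent oracle. Because the published figures print no attribution
values, rankings — not bar heights — are the only comparison surface
against the source study, and its qualitative rankings are treated as
non-binding (its background and estimator are unstated).

## The synthetic-data generator

`make_dataset()` emulates the study's data-generating situation with known
ground truth: connected simple graphs with degrees in $[1, 4]$ (the
organic heavy-atom valence range), built as a uniform-attachment random
spanning tree — each new vertex joins a uniformly chosen existing vertex
with spare valence, which guarantees connectivity — plus independent extra
edges accepted with probability 0.15 where both endpoints have spare
valence. Atom counts are drawn uniformly from 10–30 by default, bracketing
the 21-edge Lenalidomide example. The response is a polynomial of a single
chosen descriptor plus homoscedastic Gaussian noise,
$y = \beta_0 + \beta_1 x + \beta_2 x^2 + \beta_3 x^3 + \mathcal N(0, \sigma^2)$,
matching the assumptions of the OLS stage; a single master seed reproduces
the entire study.

What the generator does *not* emulate: real chemistry. There are no atom
types, no ring-statistics realism, no bond orders, and the response truly
is a polynomial of one descriptor. Passing tests on synthetic studies
therefore demonstrate *algorithmic correctness* (parameter recovery at
$\sigma = 0$, near-nominal confidence-interval coverage, model-mismatch
detection), not chemical validity of QSPR modelling on new compounds.

## Numerical choices and degenerate inputs

* Index values are carried at full double precision; comparisons against
  published values use the source's print precision (4 decimals for
  indices, 1 decimal for prediction tables).
* Empty edge partitions evaluate every index to 0 (empty sum).
* Disconnected graphs are accepted by `edge_partition()` with a message
  (indices are additive over components) since drug molecules are
  connected.
* Constant responses make $R^2$ undefined and raise an error; constant
  regressors are rank-deficient and raise an error.
* Degenerate synthetic draws (a descriptor column with fewer than 4
  distinct values, or standardized rank below 9) are re-drawn with a
  message, up to 20 attempts.
* p-values are kept at full precision internally; report files round to 4
  decimals, so very small p-values display as 0, as in the source tables.

## Problem sizes used in verification

The test suite runs oracle comparisons at these scales, chosen to complete
a full run in a few minutes while leaving the estimators' error bars far
smaller than the tolerances they are checked against: 500 random graphs
for the per-edge index oracle, 50 + 25 random instances for the
normal-equations OLS oracle, central-difference checks on 3-feature
networks, permutation-sampling Shapley comparisons with 4 000–5 000
permutations, 400 + 1000 replicates for confidence-interval coverage, and
network capability runs on the real 17-drug fixture under the documented
seed set.

## Known limitations

* Descriptor rows other than Lenalidomide's cannot be re-derived from
  structures (the study publishes no machine-readable graphs) and are
  trusted as printed, identity-checked only.
* All network metrics are in-sample by design; nothing here estimates
  predictive performance on unseen molecules.
* The mean-imputation Shapley value function ignores feature dependence in
  the background; with strongly collinear descriptors (recall
  $HZ = F + 2M_2$) attributions split credit among correlated features in
  a way no axiom pins down.
* Property units are unstated in the source and therefore unchecked.
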