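---
title: "Methods: fingerprint-driven proportion optimization of a multicomponent injection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-driven proportion optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saiopt)
```

## The problem

Sodium aescinate injection (SAI) is a multicomponent drug: a mixture of
escin isomers (labelled A--F) plus minor saponins (G--J), whose relative
proportions differ markedly between manufacturers. The individual
components differ in two opposing properties: some drive the product's
anti-inflammatory efficacy, others its vascular irritation. The question
the package addresses is *which proportion of components minimizes
irritation while preserving efficacy*, using only

1. an HPLC fingerprint per sample (a vector of peak areas for A--J),
2. an administered dose per sample (mg·kg⁻¹), and
3. two bioassay readouts per sample: Evans Blue optical density at
   590 nm in peritoneal lavage (absorbance; a vascular-permeability,
   i.e. irritation, readout) and the xylene ear-edema swelling ratio
   (left − right)/right × 100 % (an anti-inflammatory readout).

The workflow has four computational stages, each a module of this
package: peak-table arithmetic (`relative_areas`, `peak_doses`,
`mean_proportion`, `to_ten_point`), grey correlation analysis (`gca`),
a backpropagation surrogate (`fit_surrogate`, `holdout_validate`), and
an inverse Monte Carlo optimizer (`screen_candidates`,
`consensus_proportion`, `confirm_proportion`). `run_pipeline` chains
them with one seed and a manifest.

## Peak-table arithmetic

Each sample's administered dose is split over its components in
proportion to peak area: dose(s, c) = dose(s) · area(s, c)/total(s).
Row sums therefore reconstruct the administered dose exactly, and a
component absent from a sample receives zero dose.

Two rounding conventions matter when reproducing published tables:

* Relative areas are reported at 2 decimal places. Proportion vectors
  derived *from the published table* must therefore be computed from
  the 2-dp export, not from full precision — the bundled data reproduce
  the published commercial proportion (2.1192 : 1.6576 : 3.4811 :
  2.2931 : 0.2653 : 0.1837) only via that route, and
  `relative_areas(..., digits = 2)` exists for exactly this purpose.
  Internal computation always keeps full precision.
* Published ten-point proportions sum to exactly 10.0000 at 4 dp, which
  plain rounding does not guarantee (the residual lands on the largest
  entry). `round_proportion(..., preserve_sum = TRUE)` implements that
  largest-remainder convention; `to_ten_point` itself is exact and
  unrounded.

The bundled total-area row of the ten samples disagrees with the sum of
its own published 4-dp cells by up to 2×10⁻⁴ for some samples — an
artifact of the source table's rounding. `sample_totals` returns true
column sums; comparisons against the published row allow the propagated
rounding of ten 4-dp entries (2.5×10⁻⁴).

The stated doses of the knockout samples S6--S10 are taken as given
inputs; they are close to, but not exactly, 12.50 × total(Sᵢ)/total(S2),
and no attempt is made to recompute them.

## Grey correlation analysis

For a behavior sequence $x_0$ (a response over samples) and factor
sequences $x_i$ (one component's dosage over samples), all sequences are
first mean-normalized ($x \mapsto x/\bar x$), then the Deng relational
coefficient at position $k$ is

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_i(k) + \rho\,\Delta_{\max}},
  \qquad \Delta_i(k) = |x_0(k) - x_i(k)|,$$

with $\Delta_{\min}$ and $\Delta_{\max}$ taken over *all* factors and
positions (the two-level min-min / max-max operators) and the
distinguishing coefficient $\rho \in (0,1)$, default 0.5. The grey
correlation degree of a factor is the mean of its coefficients, and
components are ranked by degree.

Direction matters and is always explicit: a **descending** ranking
against the irritation readout puts the most irritation-associated
component first, while the effectiveness ranking uses **ascending**
degrees against the swelling readout — a component whose dosage pattern
is *least* associated with residual swelling is the one most plausibly
suppressing it. The direction flag is exposed rather than hard-coded
because the two published component orders are only jointly consistent
with the published degree tables under exactly this pairing (the tables'
captions appear to be swapped relative to the running text; the package
follows the text's orders).

Properties that follow from the construction, and are tested: scale
invariance (mean normalization cancels any positive scalar),
permutation equivariance over samples, monotonicity of every degree in
$\rho$, and exact agreement with a brute-force loop evaluation of the
definition on random small instances (10⁻¹² tolerance). All-zero factor
columns (a component absent from every sample, possible in knockout
subsets) cannot be normalized and are dropped from the ranking with a
warning. Ties are broken lexicographically for determinism.

## The backpropagation surrogate

The surrogate maps a 10-entry per-component dosage vector to the two
responses with a four-layer feed-forward network: 10 inputs, hidden
layers of 20 and 2 neurons with hyperbolic-tangent activation, and a
2-neuron identity output. Inputs and outputs are min-max scaled to
$[-1, 1]$ per feature; weights start uniform in $[-0.5, 0.5]$ from a
seeded generator; training is full-batch gradient descent on the mean
squared error of the scaled data, with the published settings as
defaults: at most 1000 epochs and an error goal of 10⁻⁴ ("trained 1000
times", "computing precision 0.0001" — read as 1000 epochs and an MSE
goal, the natural toolbox interpretation). The activation pairing and
scaling are the usual platform defaults for such toolboxes; the source
is silent on them, so they are fixed here explicitly for
reproducibility.

Two non-default mechanisms are available behind flags and off by
default: classical momentum, and an L2 weight penalty (`weight_decay`).
The step rule is backtracking gradient descent: a proposed step that
would increase the (penalized) loss is rejected and the learning rate
halved, otherwise it is accepted and the rate grown slightly (capped at
20× the initial rate). Consequently the recorded loss history is
non-increasing and divergence cannot occur silently; a non-finite loss
aborts with advice to lower the learning rate. Training is bit-for-bit
deterministic given the seed.

With only nine training rows (the holdout design: fit on nine samples,
validate on S5) the network has far more parameters than data; it can
drive the training error below the goal — and the tests show it can —
but that is interpolation. `holdout_validate` documents this: the
holdout record probes plausibility, not generalization. Genuine accuracy
claims are made only on synthetic data with known ground truth, where
held-out error can be compared to the noise floor.

### Recovery experiment design

The surrogate recovery test generates 60 samples from the template-free
fingerprint model (Dirichlet compositions, so dosages cover the
composition simplex at a constant 12.5 mg·kg⁻¹ administered dose),
simulates both responses from a linear ground truth with noise
σ = 0.01 per channel, fits on 50 rows and evaluates on 10, and pools the
squared held-out errors over 10 seeded replicates; the pooled per-channel
RMSE must stay within 3σ. Two design choices deserve a note:

* Effect sizes are set so both channels carry comparable signal-to-noise
  (response spans of roughly 0.5 units against σ = 0.01). A channel
  spanning, say, 12 % against σ = 0.01 % would demand 0.25 % relative
  generalization accuracy from an interpolating network — a test of
  channel scaling, not of recovery.
* The replicate-pooled RMSE is the assessed quantity. Individual
  replicates scatter around it (worst cases near 4--5σ), as expected for
  a flexible model on 50 points; pooling measures the method's error
  level rather than its worst draw.

The noiseless variant (40 simplex samples, zero σ) recovers the linear
map within 5 % relative error held out, using a small weight penalty
(10⁻⁴) to keep the network in its near-linear regime.

## Inverse optimization

Candidates are drawn independently and uniformly inside per-component
intervals (A 0.5--4, B 0.5--3, C 5--10, D 1.5--6.5, E 0.5--3.5,
F 0.5--3.5) — the published search box, which lowers the
irritation-leading components A and B and raises C--F. Uniform sampling
is the maximum-entropy choice for a plain box; the source does not state
its sampling scheme.

Each candidate is bridged into surrogate units by embedding: components
G--J are fixed at zero (flagged for elimination on account of low
abundance and unfavorable ranking), and the candidate is rescaled so its
embedded dosage total equals a reference administered dose (default
12.50 mg·kg⁻¹, the commercial-sample dose). The source never states this
unit bridge; it is a configuration value and is recorded in the manifest.

Screening accepts candidates whose predicted absorbance and swelling
fall *strictly* below the criteria (defaults 0.539 and 19.198 %,
presumably the normal-control readouts; they are configuration defaults,
not derived). Sampling continues until 50 candidates are accepted
(published choice) or the draw budget (default 10⁵) is exhausted; zero
acceptances raise an error that reports the surrogate's response range
over the box. The consensus is the component-wise median of the accepted
set by default ("median" in the published results section; "mean" is
available because the discussion uses it), is re-predicted through the
same surrogate for confirmation, and is converted to a ten-point
proportion. One trained network with repeated sampling is used, not
re-training per batch — the source's wording ("operated multiple times")
is ambiguous; this is the cheaper and statistically cleaner reading.

Aggregation concentrates: across seeds, the standard deviation of the
consensus per component is below the spread of single accepted
candidates, which is the checkable form of the published claim that the
accepted proportions "trend to a concentrated range".

## The synthetic generator

Since the per-sample bioassay readouts were published only as bar
charts, the generator emulates their *structure* with known ground
truth: each response is its baseline plus a linear combination of
per-component dosages plus Gaussian noise, absorbance floored at zero.
Ear masses are back-computed from the simulated swelling with the right
(untreated) ear fixed at 16 mg — a typical 8-mm mouse ear punch — so the
swelling-ratio formula round-trips exactly; the ratio is scale-invariant
in that reference mass.

Default coefficients follow the study's qualitative conclusions: A and B
irritation-dominant (absorbance 0.060 and 0.070 per mg·kg⁻¹ against a
0.10 baseline), C and D efficacy-dominant (swelling −1.8 and −2.0 % per
mg·kg⁻¹ against a 25 % baseline), E and F moderate contributors on both
axes, G--J mid-level irritants with little efficacy. Magnitudes are
invented configuration values — no synthetic setting claims to equal the
unpublished measurements. The baseline absorbance is set low relative to
the component effects so that, as in the real assay, the response
variance is dominated by composition differences; a generator whose
responses were mostly baseline would make every association analysis
insensitive, emulating nothing.

Fingerprints are generated either by resampling the bundled 10-sample
table with multiplicative lognormal jitter (mean 1, CV configurable;
CV 0.15 imitates batch-to-batch variation around real products) or,
template-free, as Dirichlet compositions times a lognormal total. The
template route preserves the real data's structure — including knockout
rows where most components are absent — and is used for end-to-end
realism; the Dirichlet route covers dose space evenly and is used where
coverage matters (surrogate recovery).

What passing synthetic tests does *not* show: that real dose–response
relations are linear or additive (a saturating Hill-type option exists
for sensitivity exploration), that the real noise is Gaussian or
homoscedastic, or that the published grade values are reproduced — those
require the unpublished per-sample readouts. What the tests do show is
that each stage recovers known structure under its stated conditions,
and that the chained pipeline improves the ground-truth responses of the
consensus over the commercial mean proportion.

## Numerical and reproducibility choices

* One global seed fans out to per-stage seeds (`derive_seed`), so stages
  are individually reproducible and mutually decoupled; all seeds stay
  within 32-bit range.
* Pipeline outputs print numbers via a fixed `%.10g` format, so a rerun
  with the same configuration and seed is byte-identical; the output
  directory is excluded from the configuration hash.
* Problem sizes in the tests and drivers — 60 synthetic samples for
  surrogate experiments, 10 or 20 for ranking replicates, 200 ranking
  replicates, 50 optimizer runs, up to 8000/20000 training epochs —
  were chosen as the smallest sizes at which the respective effects are
  stable, keeping a full run of the suite under a minute.
* Degenerate inputs have defined behavior: constant scaler columns map
  to 0; all factors identical to the behavior sequence yield
  coefficients 1 with a warning; an all-zero proportion vector, an
  all-zero sample row, and a non-positive sequence mean are errors.

## Known limitations

* Nine real training rows cannot validate the surrogate; only the
  synthetic recovery experiments quantify its error, and the box region
  explored by the optimizer partly extrapolates beyond the bundled
  samples' composition range (visible as a modest acceptance rate).
* The acceptance thresholds and the unit bridge for candidates are
  configuration values whose published provenance is unstated.
* Grey correlation degrees from the bundled data depend on the simulated
  responses; the published degree tables cannot be reproduced without
  the unpublished measurements, and only the ranking logic is checked
  against them.
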