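---
title: "Methods: the kick-out model, its simulator, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the kick-out model, its simulator, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kickout)
```

## The mechanism and its steady state

A dCas9–guide complex bound inside an open reading frame acts as a
roadblock for elongating RNA polymerase. Collisions resolve in one of two
ways: the polymerase stops (probability `P(stop)`), or it transcribes
through (probability `r = 1 − P(stop)`) and, in doing so, can eject dCas9
from the DNA (ejection frequency `delta`). The target is rebound at rate
`kon[dCas9]` and also leaves spontaneously at `koff`. Expression relative
to the unrepressed promoter is

$$\gamma^* \;=\; 1 - (1 - r)\,P(\mathrm{bound}), \qquad
P(\mathrm{bound}) = \frac{k_{on}[\mathrm{dCas9}]}
{k_{on}[\mathrm{dCas9}] + \delta\,r\,\gamma_0 + k_{off}},$$

or, with $\lambda = \delta\gamma_0/k_{on}[\mathrm{dCas9}]$ and
$\alpha = k_{off}/k_{on}[\mathrm{dCas9}]$,

$$\gamma^* = \frac{r + \lambda r + \alpha}{1 + \lambda r + \alpha} \in [r, 1].$$

Two regimes matter. At **saturation** ($\lambda, \alpha \to 0$),
$\gamma^* = r$: repression is set by the guide alone, independent of dCas9
level and promoter strength. Away from saturation, a stronger promoter
(larger $\gamma_0$, hence larger $\lambda$) ejects dCas9 more often, loses
occupancy, and is repressed *less* — the promoter-strength dependence that
identifies the mechanism.

Assumptions worth stating: collisions are instantaneous Bernoulli events
(no spatial RNAP translocation), rebinding after ejection is exponential at
`kon[dCas9]` (the data only require it to be fast at high dCas9), and
replication-fork displacement is not a separate event class — if the user
believes it matters it is absorbed into `koff`.

### Inference and bounds

`infer_lambda_r()` inverts the steady state for the product
$\lambda r$ — the product, not $\lambda$, is the primary inferred quantity,
because the two never appear separately in the steady state and dividing by
a small, uncertain $r$ manufactures spurious precision. $\lambda$ is formed
only inside `koff_upper_bound()`, where the bound
$k_{off} \le \alpha_{max}\,\delta\gamma_0/\lambda$ requires it.
`alpha_crossing()` finds the largest spontaneous-unbinding ratio compatible
with an observed expression bound by bisection; the prediction is strictly
decreasing in $\alpha$, so the root is unique. The search is confined to
the feasible range $\alpha < (\gamma^*_{ref} - r)/(1 - \gamma^*_{ref})$,
beyond which the inferred $\lambda r$ would be negative. What "significantly
lower" means (how many error bars) is not part of the model; the bound is
therefore an explicit argument.

`gene_copy_number()` implements the replication-overlap dosage
$n(\Phi) = 2^{(t_C(1-\Phi)+t_D)/t_d}$. With the default parameters
(`tC = 60`, `tD = 20`, `td = 30` min, `phi = 0.66`) it evaluates to 2.54,
not the "about 2" sometimes quoted for these conditions; the discrepancy is
documented rather than reconciled, no test asserts either value, and the
lifetime bound is reported for both conventions in the README.

### Uncertainty propagation

`propagate_uncertainty()` is Monte Carlo (default $10^5$ independent
Gaussian draws, mandatory seed), not a first-order delta method: near
saturation the prediction is strongly curved, and the delta method
understates the sd. Draws violating model preconditions (e.g. a reference
expression below the saturated floor) are rejected and resampled, so
moments refer to the admissible region; if more than half of all draws are
rejected the propagation is refused as ill posed rather than silently
conditioned on a thin slice of the input distribution.

## The stochastic simulator

`simulate_population()` runs an exact Gillespie simulation (no
tau-leaping; correctness at desk scale beats speed, and the inner loop is
compiled) of the joint (occupancy, mRNA, protein) system per cell:

| quantity | default | why |
|---|---|---|
| `gamma0` | 20 /min | strong model promoters initiate at ≲20/min |
| mRNA half-life | 5 min (`mrna_decay = ln 2/5`) | typical bacterial mRNA |
| `protein_per_mrna` | 2 /min per transcript | keeps counts realistic and the event budget tractable |
| `dilution_rate` | ln 2/30 /min | 30-min doubling, stable fluorophore |
| `delta` | 1 | conservative: every successful passage ejects |
| `koff` | 0 | full-complementarity complexes essentially never unbind |
| `rebinding_rate` | 2000 /min | saturating (≫ any `kout`) unless overridden |
| `extrinsic_cv` | 0.148 | calibrated: scale acts on transcription *and* translation, so protein $\propto s^2$ and the unrepressed population CV comes out at 0.30, the constitutive-gene noise plateau |
| `dcas9_cv` | 0.3 / 1.0 | see below |
| `t_end`, `burn_in` | 120, 60 min | see below |

Cells are initialized at the stationary expectation (occupancy Bernoulli,
counts Poisson at the stationary means), so ensemble means are exact from
$t=0$ and `burn_in` only needs to equilibrate variances (relaxation
$\sim 2/k_{dil}$). The reported `protein_level` is the **time average**
over the recording window rather than the end-point count: a stable
fluorophore integrates expression history, and the time average is both the
better proxy for imaged GFP concentration and a lower-variance estimator
with identical mean. Per-cell streams derive from the master seed by a
counter-based scheme, so populations are reproducible and cell $i$ does not
change when more cells are appended.

**Per-cell dCas9 variability.** The two tuning modes are not symmetric in
how noisy the dCas9 pool is. Complementarity tuning operates at full tet
induction, where expression noise is modest: CV 0.3, in line with the
constitutive plateau. Concentration tuning deliberately operates at
*sub-saturating* induction, and tet-family promoters at intermediate
inducer are well known to be strongly heterogeneous (near all-or-none);
a CV of 0.3 there would be unrealistically quiet — a deterministic mixture
calculation shows it caps the noise inflation at ~1.3×, below what the
distributions in this regime actually show. The concentration-mode default
is therefore `dcas9_cv = 1.0`. This is the package's own calibration
choice, made from that pre-implementation analysis and then frozen; both
defaults are overridable and echoed in all outputs.

**What a green noise test establishes.** With these choices the simulator
reproduces, qualitatively: flat population CV (≈0.3, within 20% relative)
across passage probabilities 0.026–1 at saturation; CV inflation ≥1.5× near
half-occupancy in concentration mode; invariance of the population mean to
halving the dCas9 level at saturation (the decoy experiment as a model
property); and the titration midpoint shifting to higher inducer with more
decoys. It does **not** reproduce instrument intensity scales, gating
artefacts, cell-cycle or division dynamics (dilution is a first-order
rate), or bursting beyond what the two-state occupancy process produces.
One caveat made explicit in the ledger: "saturating" must be read as
rebinding ≫ `kout`, not literally 100×; at exactly 100× the occupancy
deficit (~1%) moves detectably under a $10^4$-cell Monte Carlo when the
dCas9 level is halved, exactly as the model says it should.

## The auto-repressor feedback model

The repressor and the reporter sit in one operon, so at steady state the
repressor concentration is proportional to the normalized expression $g$.
CRISPRi multiplies the initiation rate by $r$, giving the fixed point

$$g = \frac{r\,\beta}{1 + (g/K)^n},$$

whose positive root is unique (the right side is strictly decreasing in
$g$) and found by bracketed root-finding on $[0, r\beta]$ at tolerance
$10^{-10}$. This functional form is a reconstruction: it reproduces the
qualitative behaviour the construct is used to demonstrate — repression
appears *weaker* under feedback, $g^*(r)/g^*(1) > r$ — and should not be
asserted to equal any particular published appendix parameterization. The
inducer (DAPG) is handled phenomenologically, as a separate $(K, n)$ fit
per condition, because the underlying monomer/dimer equilibrium is not
settled.

`fit_feedback()` minimizes weighted squared residuals on log expression
(multiplicative noise, positive data), multi-started from a fixed
log-spaced $K$ grid (× $n \in \{0.5, 1, 2, 4\}$ when $n$ is free) and
polished with L-BFGS-B; it is deterministic by construction (no random
starts). `compare_hill()` refits with each candidate $n$ fixed and ranks by
residual sum, ties toward the smaller $n$. At the reference design (4
passage probabilities, 3 replicates, 5% lognormal noise, $K = 0.3$,
$n = 2$) the recovery tolerances — $K$ within 15%, $n$ within 0.3 — hold in
the typical case ($K$: essentially always; $n$: ~77% of seeds, median error
~0.15), so the test suite asserts the median over ten fixed seeds rather
than pretending a per-seed guarantee.

## Cytometry statistics

- **Outlier rule**: single pass; mean and sd computed once on the full
  sample, points beyond 3 sd discarded. Not iterated, and therefore
  idempotent on its own output for the fixtures used.
- **Blank correction**: the noise is $\sigma/\mu$ with
  $\mu = \bar{x}_{sample} - \bar{x}_{blank}$. The sd correction is in
  **quadrature** by default ($\sigma^2 = \sigma_{sample}^2 -
  \sigma_{blank}^2$): autofluorescence is an independent additive noise
  source, and variances of independent sources add. Linear sd subtraction
  is dimensionally consistent but statistically wrong; it remains available
  behind `method = "linear"` for exact replication of that convention, and
  the choice is recorded in the output object.
- **Significance**: two-sided t-tests on natural logs of per-replicate
  means (never pooled cells), threshold $0.05/m$ Bonferroni-corrected.
  Zero-variance replicate groups make the t statistic undefined; the
  package defines p = 1 for identical groups and p = 0 for distinct
  constants.
- **Doubling time**: linear regression of log OD against time over a
  user-selected exponential window; a non-positive slope is a refusal
  (`kickout_no_growth`), not a number.

## Morphometrics

The major axis is total least squares (leading eigenvector of the vertex
covariance) — appropriate because both coordinates carry error. Width is
**twice** the mean perpendicular vertex distance to the axis, poles
excluded, so a capsule's width equals its diameter; the single-sided mean
is exposed as an attribute for anyone replicating the one-sided convention.
Pole exclusion is not standardized anywhere, so the rule is explicit: a
first-pass width $w_0$ from all vertices, then vertices within $w_0/2$ of
either axial extreme are dropped and the width recomputed once. Vertices
(not arc-length segments) are the averaging unit, matching discrete contour
input; generators sample vertices at equal arc length, so the two coincide
for fixtures. Near-isotropic contours (eigenvalue ratio < 1.05) trigger a
degenerate-axis warning and a longest-chord fallback. Jitter in
`gen_capsule_contour()` is applied in the body frame before rotation, so a
rotated contour with the same seed is the same noisy polygon rigidly
moved — making rotation invariance exactly testable.

## Synthetic data: the stated world

Fluorescence is lognormal (positive, right-skewed): per-cell value =
level × lognormal(extrinsic) × lognormal(intrinsic) + Gaussian
autofluorescence, truncated at zero. The generator defaults compose to a
total CV of 0.30 (`extrinsic_cv = 0.25`, `intrinsic_cv = 0.161`;
$(1+c_e^2)(1+c_i^2) - 1 = 0.09$); the split between the two components is a
free calibration knob — no measurement pins it down — and round-trip tests
depend only on the total. Two-color generation shares a configurable
fraction of the log-variance between channels, with the lognormal
closed-form correlation $(e^{fv}-1)/(e^{v}-1)$ as the analytic oracle.
Autofluorescence blanks mirror a no-reporter strain: additive Gaussian with
its own generator. Every generator is a pure function of (config, seed)
with counter-based sub-seeds.

## Numerical choices, in one place

- Root brackets: `alpha_crossing` on $[0, \min(10, \alpha_{sup})]$,
  tolerance $10^{-8}$; `steady_state` on $[0, r\beta]$, tolerance
  $10^{-10}$ (residual < $10^{-9}$ guaranteed by the unit slope bound).
- Monte-Carlo sizes: $10^5$ draws for uncertainty propagation; $10^4$
  cells where a 3-standard-error mean comparison is the claim; smaller
  (150–4000 cells) where only orderings or CV ratios are asserted, sized
  so the suite stays within minutes.
- Degenerate inputs are errors or flagged values, never silent: undefined
  occupancy (both rates zero), divergent inference ($\gamma^* \ge 1$),
  inconsistent observation (below the saturated floor), infinite lifetime
  (`koff_bound = 0` returns `Inf`), no growth, below background, negative
  corrected variance, too-short cell after pole exclusion.
- All rates are per minute; all expression values dimensionless fractions
  of the unrepressed level; configs are validated by the type
  constructors on read.

## Known limitations

- `P(stop)` is an input per guide; nothing predicts it from sequence.
- Promoter-region targeting (concentration-dependent, mechanistically
  different) is out of scope, as are temperature dependence (enters only
  through a user-supplied `r`), image segmentation, FCS binary parsing and
  spectral compensation.
- The feedback model is a steady-state reconstruction; kinetic (time-
  resolved) feedback behaviour is not modelled.
- The simulator's cell is a well-mixed point with first-order dilution; no
  explicit division, replication or partitioning noise.
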