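---
title: "Patient-wise glycemic health assessment: model, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-wise glycemic health assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycofit)
```

## The problem

A 5-point oral glucose tolerance test with insulinemia (OGTT-I) measures
blood glucose and insulin at 0, 30, 60, 90 and 120 min after a 75 g
glucose bolus — ten numbers per subject. Binary clinical rules on those
numbers (fasting thresholds, excursion caps, 2-h persistence) hide a
continuum of physiological states: two subjects with near-identical
glycemia curves can regulate glucose through very different mechanisms,
and subjects passing every threshold can still carry substantial
dysglycemia risk. `glycofit` turns the ten measurements into a
physiological description: per-subsystem rate parameters of a
compartmental model, dimensionless indices comparing subsystems across
subjects, diagnostic range labels, and a logistic risk probability.

## The compartmental model

Five states: glucose in the stomach $S$, jejunum $J$ and ileum $L$
(mmol), glycemia $G$ (mM) and insulinemia $I$ (pM):

$$
\begin{aligned}
\dot S &= -k_{js} S\\
\dot J &= k_{js} S - J/\tau - k_{gj} J\\
\dot L &= J/\tau - k_{lg} L\\
\dot G &= \eta\,(k_{gj} J + k_{lg} L) + P_0 - k_{xg} G - k_{xgi} G I
  + k_\lambda (G_b - G)_+ - \gamma (G - G_b)_+\\
\dot I &= \beta (G - G_b)_+ \bigl(1 + f_{gi}(J + L)\bigr) - k_{xi}(I - I_b)
\end{aligned}
$$

with $P_0 = k_{xg} G_b + k_{xgi} G_b I_b$ so that $(0,0,0,G_b,I_b)$ is an
exact basal equilibrium. The hinge terms $(\cdot)_+$ encode hepatic
buffering (release below basal, uptake above) and above-basal-only
pancreatic secretion, potentiated by the incretin signal proportional to
gut glucose $J+L$. The right-hand side (`gim_rhs`) is pluggable: any
function with the same signature can replace it without touching the
statistics downstream, which depend only on the parameter vector.

Units are fixed package-wide: mM for glycemia (180 mg/dL = 10 mM exactly,
i.e. divisor 18), pM for insulinemia (1 uU/mL = 6.945 pM), minutes for
time, mmol for gut glucose (75 g = 416.67 mmol by the same 0.18 g/mmol
factor). The diagnostic table and the risk coefficients only make numeric
sense on these scales.

Integration uses `deSolve::lsoda` with rtol 1e-8 / atol 1e-10 for
simulation and relaxed 1e-6 / 1e-8 inside the fitting loop; the hinges
are continuous but non-smooth, which the tight tolerances absorb.

## Dimensionless subsystem indices

With scale variables $G_b$, $I_b$, the dose $D$ and the glucose turnover
time $t_c = 1/(k_{xg} + k_{xgi} I_b)$, the default mapping is
$\Pi_S = k_{js}\tau$ (digestive motility), $\Pi_N = f_{gi} D$ (incretin
load), $\Pi_D = \eta D / G_b$ (glucose distribution),
$\Pi_B = k_{xgi} I_b / k_{xg}$ (basal uptake ratio),
$\Pi_X = k_{xgi} I_b t_c$ (insulin activity load),
$\Pi_I = \beta G_b t_c / I_b$ (pancreatic response) and
$\Pi_R = (k_\lambda + \gamma) t_c$ (hepatic response). Each is
dimensionless (the test suite checks invariance under a global change of
time units) and lands in the subsystem group the diagnostic table assigns
it. The mapping lives in a registry (`register_ndn_mapping`) so an
alternative derivation can be swapped in by name.

## Per-patient fitting and identifiability

`fit_patient` minimises the sum of squared residuals of $G$ and $I$ at
the sample times, each normalised by the subject's basal value so the mM
and pM scales weigh equally. $G_b$, $I_b$ are fixed at the measured basal
sample (directly observed; they anchor the equilibrium) and $D$ at the
recorded dose.

Ten measurements cannot determine twelve free rates. Two design choices
deal with this:

* The structural closures $k_{gj}$, $k_{xg}$, $k_\lambda$, $\gamma$ are
  held at canonical values by default (`default_fixed_parameters()`).
  These four are the least constrained by a 5-point record — the hepatic
  hinges act only near basal, and $k_{gj}$/$k_{xg}$ trade off almost
  perfectly against $k_{lg}$/$k_{xgi}$. Eight parameters against ten
  residuals remain.
* Even so, distinct parameter vectors can interpolate ten points almost
  exactly. A weak log-scale ridge penalty (`prior_weight`, default 1e-3)
  pulls the eight free parameters toward the centre of the physiological
  start box. The weight sits roughly two orders of magnitude below the
  data loss produced by typical assay noise, so well-identified
  parameters are essentially unbiased, while the degenerate directions
  resolve toward the physiological branch. The reported `loss` is the
  pure data term; the penalised `objective` is reported alongside.

The optimiser is multi-start bounded Levenberg-Marquardt
(`minpack.lm::nls.lm` on log-parameters): 24 Latin-hypercube starts in
the start box (healthy diagnostic ranges widened 4-fold), the best 6
polished briefly, the best 2 run to convergence, then up to 6
perturbation restarts around the incumbent while the data loss exceeds
1e-8. Everything is deterministic given `seed`. Hard box bounds span the
abnormal-to-healthy diagnostic ranges widened 10-fold on the log scale.

Three diagnostics report what the data did not determine:
`weakly_identified` (parameters whose ±0.3 log-unit perturbation moves
the data loss by less than 1e-3, i.e. under ~1% of curve),
`at_bounds`, and `repeat_fit_consistency` (coefficient of variation of
estimates across independent multi-start designs; default flag above
10%). The measurement-sensitivity protocol perturbs each of the ten
measurements ±10% and refits warm-started — 20 refits per subject — and
labels a parameter measurement-sensitive above 20% deviation; the
curve-shape sensitivity index is the normalised L2 change of the
basal-scaled $(G, I)$ curves under ±10% parameter perturbation, labelled
sensitive above 5% of the curve norm. The 10%/20%/5% values are exposed
configuration, not claims about any external dataset.

## Diagnostic ranges

For each index, log-logistic distributions (scale $\alpha$ = median,
shape $\beta$; location fixed at 0 since all indices are positive) are
fitted to the healthy and non-healthy cohorts by closed-form-likelihood
MLE. Construction per index:

1. KS test between cohorts; indices without a significant difference are
   marked *not discriminative* and excluded (BH-adjusted q-values are
   reported alongside raw p).
2. Direction of the non-healthy shift from the tail-occupancy test: the
   healthy cohort's 90% left/right tail regions are computed and the
   occupancy proportions compared by a two-sample t-test on the 0/1
   indicators. (A two-proportion z-test would be conventional; the
   t-test form is kept deliberately and documented.)
3. The equal-density threshold — the crossing of the two fitted
   densities, bracketed on a log grid between the medians and polished
   by bisection — separates *normal* from *undesirable*.
4. The healthy central 90% interval bounds the undesirable range on the
   non-healthy side; beyond it lies *abnormal*.

The ROC/Youden threshold (exhaustive midpoint enumeration, both
orientations, ties toward the healthy median) is reported per index as a
diagnostic — it should closely coincide with the equal-density crossing —
but does not define the ranges. Values exactly on a shared boundary take
the healthier label, matching the shared printed endpoints of the
packaged table. For two-sided shifts the construction follows the
one-sided schematic on the dominant tail and flags the case.

The packaged reference table (`load_reference_ranges()`) ships as JSON
with 14 rows; the `eta` row keeps its units string as printed ("L^-3")
without reinterpretation.

## Risk model

The fixed published coefficients define
$z = a_1\eta + a_2\Pi_X + a_3 G_b + a_4 I_b + a_5\tau + a_6 k_{xgi} + a_0$
and $P = e^z/(1+e^z)$, with non-healthy at $P \ge 0.60$ (boundary
inclusive). De-novo fitting uses `stats::glm` (IRLS) with Wald backward
elimination: repeatedly drop the largest-p predictor at or above
$\alpha = 0.05$ and refit; design builders add pairwise interactions
("full") or squared terms ("quadratic"). Classifier metrics include
sensitivity, specificity, DOR (with 0.5-cell Haldane correction flagged
when a confusion cell is empty), MCC and AIC $= 2k - 2\log L$. No
selection direction on AIC is hard-coded; smaller-is-better is the
conventional reading and the metrics are emitted for the caller to
compare.

## Synthetic cohorts: what they emulate and what they do not

The generator draws per-parameter heterogeneity from log-logistic laws.
For indices with a packaged diagnostic row, the healthy template centres
the law at the geometric midpoint of the healthy range with the shape set
so the central 90% of draws spans exactly that range; basal levels centre
at 4.8 mM / 30 pM (the healthy-cohort medians 86.4 mg/dL and 4.32 uU/mL).
The non-healthy template applies the characteristic shifts — slower
stomach emptying (×0.35), shorter jejunal transit time (×0.65), reduced
insulin-dependent consumption (×0.13), larger distribution factor (×1.5),
basal levels at the non-healthy medians (91.0 mg/dL, 8.30 uU/mL) — plus a
shared log-normal latent factor (sd 0.4, sized so the coupled
subsystems correlate above the graph cutoff |r| > 0.4) multiplying the
motility/secretion/uptake parameters, which induces the stronger
between-subsystem correlations expected in dysglycemia. Measurement noise
is multiplicative log-normal, default CV 3% (glycemia) and 7%
(insulinemia) — typical assay repeatability figures; the generating
methodology states no noise model, so these are engineering defaults and
configurable. Crossover studies share a subject baseline across arms,
apply named multiplicative dose effects (default: transit time +10/20/30%
and insulin sensitivity up to +30% across 60/120/180 mg arms) and an
independent between-visit log-normal jitter (CV 10%).

What passing tests on these cohorts shows: the pipeline recovers
parameters it can identify, constructs ranges that converge to the
analytic construction, and detects paired dose effects at the stated
power. What it does not show: agreement with any real cohort's joint
parameter distribution, assay artefacts (carry-over, detection limits),
or within-subject circadian variation — none of which the generator
models.

## Problem sizes and numerical choices

Default suite sizes were chosen so the full test run completes on a
single CPU: parameter recovery uses 20 synthetic subjects at 2% noise
plus one canonical noiseless subject; the dose-effect power check uses 20
replicate 36-subject crossover studies evaluated on the generating
parameters (re-fitting all 144 arms per replicate adds nothing to the
paired-test property being checked and is two orders of magnitude more
costly; single-record fitting accuracy is established separately). The
oracle-equivalence checks (Youden vs exhaustive enumeration, Louvain
modularity vs exhaustive partition search at 6-7 nodes, equal-density
crossing vs dense grid) are exact, not statistical.

Degenerate inputs are handled explicitly: a flat record converges with
its dose-response parameters flagged weakly identified; identical
density fits raise a degenerate-densities error; constant columns yield
NA correlations with a warning; zero confusion cells flag the Haldane
correction; complete separation and collinear designs raise errors
naming the problem.

## Known limitations

* The right-hand side and NDN mapping are reference forms chosen for the
  stated structural properties (basal equilibrium, subsystem grouping,
  dimensionlessness); both are pluggable by design.
* Parameters beyond the identifiable core inherit a pull toward the
  canonical centre from the ridge penalty; interpret `weakly_identified`
  flags before reading individual values.
* Ranges are cross-sectional; no longitudinal modelling.
* The published risk coefficients are taken as fixed constants; the
  package does not attempt to reproduce the cohort that produced them.
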