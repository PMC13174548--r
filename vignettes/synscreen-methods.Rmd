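---
title: "Methods behind synscreen: models, estimators and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind synscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synscreen)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generators do and do not emulate, the
numerical choices made where the design was genuinely open, and the
known limitations. Everything quantitative stated here is computed by
the test suite or the acceptance script; nothing is asserted beyond
what those runs measure.

## 1. Single-agent activity

### Normalization

Raw well luminescence is normalized per plate to the negative controls:

$$ \text{viability} = 100 \cdot \frac{\text{signal} - \overline{\text{empty}}}{\overline{\text{DMSO}} - \overline{\text{empty}}} $$

so DMSO wells average 100% and empty (cell-free) wells 0%. The
transformation is affine-invariant — rescaling all signals on a plate
by any positive constant leaves viability unchanged — which is why
plate-reader gain does not matter. Values are deliberately **not**
clipped to [0, 100]: noise pushes control-level wells above 100 and
strongly cytotoxic wells below 0, and clipping would bias the
library-wide Z statistics computed downstream. Clipping is available as
an explicit opt-in (`normalize_viability(clip = TRUE)`). A plate whose
mean DMSO signal does not exceed its mean empty signal is reported as
an error ("inverted controls") rather than producing sign-flipped
viabilities silently.

### The 4PL model

Dose-response curves follow the four-parameter logistic on dose $d$:

$$ y(d) = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + (d/\mathrm{EC}_{50})^{h}} $$

with plateaus in percent viability, $\mathrm{EC}_{50}$ in nM and Hill
slope $h$. `fit_4pl()` minimizes least squares by bounded
Levenberg–Marquardt (via minpack.lm) with $\log_{10} \mathrm{EC}_{50}$
as the free potency parameter. Numerical choices:

- **Starting values from the data**: top = max response, bottom = min
  response, EC50 = the dose whose response is nearest the half-range,
  $h = 1$.
- **Bounds**: $\log_{10} \mathrm{EC}_{50}$ one decade beyond the tested
  range (an EC50 outside that window is not identifiable from the
  design); $h \in [0.1, 10]$; plateaus one observed response-range
  beyond the observed extremes.
- **Degenerate inputs**: if the observed response range is below 5
  percentage points the curve carries no potency information; a flat
  sentinel (top = bottom = mean, EC50 = NA, `converged = FALSE`) is
  returned instead of an arbitrary fit.
- If the optimizer crosses the plateaus, they are swapped and the slope
  negated, keeping top ≥ bottom.

On noise-free 11-point data the generating parameters are recovered to
about $10^{-6}$ relative error; under 5% multiplicative noise the
median $|\log_{10} \mathrm{EC}_{50}|$ error across 50 replicate fits is
about 0.03 (the test asserts < 0.15).

### AUC and Z-AUC

The activity score is the **dose-averaged viability**: the trapezoidal
integral of viability over $\log_{10}$ dose divided by the log-dose
range. A curve flat at $v$% scores exactly $v$, which makes the scale
interpretable and design-independent; lower AUC = more active. Two
open choices were settled as follows:

- *Raw points vs fitted curve.* The default integrates the raw
  normalized points. Integrating the fitted 4PL instead is available
  (`compute_auc(curve = )`, `model_activity(from_fit = TRUE)`), but raw
  integration is the default because it is defined for every compound
  including non-converging and flat curves, and at 11 points the two
  differ by less than typical plate noise.
- *Duplicate doses* are averaged before integration.

Within each cell model the library's AUC vector is standardized
(Z-AUC, sample SD). Z-AUC is computed **within model first**, then
averaged across models per compound, then ranked ascending (rank 1 =
most active); ties break lexicographically by compound id so ranking is
deterministic. Compounds screened in only a subset of models are
averaged over the models they appear in; compounds in no model are
dropped with a warning.

## 2. Excess HSA synergy

A combination matrix is a factorial grid over two dose series, each
including dose 0 (the margins are the single-agent curves; the (0,0)
well is untreated). On the viability scale the Highest-Single-Agent
reference for an interior well is the stronger single agent at the
matching marginal doses:

$$ \mathrm{ref}(i,j) = \min\{v_A(d_i),\, v_B(d_j)\} $$

and the synergy score is the **sum** over interior wells (both doses
> 0) of observed minus reference:

$$ \text{Excess HSA} = \sum_{i,j > 0} \big( v_{\text{obs}}(i,j) - \mathrm{ref}(i,j) \big). $$

Design choices and their rationale:

- **Sum, not mean.** The −2000 hit threshold is only dimensionally
  consistent with a sum over the ~81 interior wells of a 10×10 design
  (mean excess −25 → −2025). The per-well mean and the interior well
  count are reported alongside so 7×7 designs can be compared, but the
  default hit rule applies to the raw sum.
- **Interior wells only.** Margin wells have zero excess by definition;
  including them would only add zeros while confusing well counts
  across designs.
- **Strict inequality** for hits: a score of exactly −2000 is not a
  hit. The threshold is configurable.
- **Scale duality.** Inhibition input (100 − viability) is converted
  internally; the score is identical, and the per-well surface on the
  inhibition scale (`hsa_surface()`, positive = synergy) is exactly the
  negated per-well viability excess.
- The score is symmetric under drug swap (matrix transpose), verified
  property-style, and matches a naive double-loop reference to
  $10^{-9}$ on 1,000 random matrices.

### Noise bias of the plug-in reference

The HSA reference is a minimum over two *noisy* margins, and
$E[\min(X, Y)] < \min(E[X], E[Y])$ whenever the margins are within a
few noise SDs of each other — which always happens near the top
plateau, where both agents leave viability ≈ 100. The plug-in Excess
HSA therefore carries a systematic **positive** (antagonism-side) bias
under noise even when the truth is exactly the HSA null: with 10%
multiplicative noise on 10×10 matrices the null distribution is centred
near +40 with an SD near 90 (measured over 500 simulated null pairs in
the test suite). Three consequences:

- The bias is far inside the −2000 hit threshold, so it does not
  create false synergy calls — the measured false-hit rate at −2000 is
  0/500. It is anti-conservative only for *antagonism* claims.
- A noise-free HSA-null matrix scores exactly 0 (asserted to
  $10^{-9}$).
- Because the bias is intrinsic to any min-over-noisy-margins
  statistic, the test suite asserts what is true (bias positive and
  small relative to the threshold) rather than a zero-mean null.

### Profiles, partners, time courses

A compound's combination profile is its vector of (model-averaged)
Excess HSA scores against every panel partner, the self pair excluded.
Profiles are compared by Pearson correlation over shared partners,
converted to the distance $1 - r$, and clustered agglomeratively —
average linkage by default, configurable, since the correlation but not
the linkage was a fixed requirement. Compounds with zero-variance
profiles have undefined correlations; they are flagged and appended
after the clustered leaves, never silently dropped. Partner ranking
sorts a compound's profile ascending (rank 1 = strongest synergy).
Time-course matrices are scored per time point; the trajectory and the
argmax-|score| time are reported.

## 3. Preranked enrichment

`preranked_es()` implements the weighted Kolmogorov–Smirnov running
sum: walking down the ranked list (descending score, ties broken by
item id for determinism), the sum rises by
$|s|^p / \sum_{\text{set}} |s|^p$ at set members and falls by
$1/(N - N_{\text{set}})$ elsewhere; the enrichment score is the signed
maximal deviation, always in $[-1, 1]$. $p = 1$ is the default weight;
$p = 0$ gives the unweighted statistic. When the positive and negative
extrema tie exactly in magnitude the earlier peak wins — an arbitrary
but fixed convention.

The null is an **explicit permutation null**: ES values of `n_perm`
uniformly random same-size member sets. When
$\binom{N}{N_{\text{set}}} \le 10{,}000$ the null is enumerated
exactly instead. This replaces adaptive multilevel p-value estimation
deliberately: the permutation null is transparent, testable, and
sufficient for directional conclusions; its resolution floor is
$1/(n_\text{perm}+1)$, flagged when hit. Conventions:

- $p$ is sign-stratified:
  $(1 + \#\{\text{same-sign } |ES_0| \ge |ES|\}) / (1 + \#\text{same-sign})$.
- $\mathrm{NES} = ES / \mathrm{mean}(|ES_0|\ \text{same sign})$, the
  classic normalization.
- BH FDR is applied over each result batch; significance at
  FDR < 0.05.
- Leading edge: members at or before the peak (positive ES) or at or
  after the trough (negative ES).

Calibration is verified empirically: for random sets the type-I error
at $\alpha = 0.05$ over 200 seeded runs falls in [0.02, 0.09] (the
$+1$ corrections make the test slightly conservative, ~0.03-0.05
observed).

Drug-target set enrichment (DSEA) reuses this machinery with compounds
as items, scored by $-\overline{\text{Z-AUC}}$ so the most active
compounds sit at the top with positive scores and "enriched at the
top" reads as "enriched among actives". Sets with fewer than 3
library members are skipped with a warning.

## 4. Proteomics differential abundance

Inputs are replicate-level log2 protein intensities (quantification and
normalization are assumed done upstream). Per protein:
$\log_2\mathrm{FC} = \overline{\text{treated}} - \overline{\text{control}}$;
the p-value comes from **Welch's** unequal-variance two-sample t-test —
the replicate comparison was otherwise unspecified, and Welch is the
safe default when arm variances are not assumed equal; this is a
documented reconstruction. The composite rank metric
$\log_2\mathrm{FC} \times (-\log_{10} p)$ feeds preranked GSEA; it is
odd in the fold change and monotone in significance, so strong, reliable
changes dominate both tails. Significance filters: $|\log_2\mathrm{FC}|
> 0.5$ and $p < 0.05$. Degenerate rows (zero variance in both arms) get
$p = 1$ for equal means or the smallest representable double otherwise,
with an explicit flag instead of a silent number.

Overlap analysis intersects per-condition significant sets per
direction and reports exclusive Venn regions keyed by membership
pattern. Combination-exclusive proteins are those significant (down,
by default) in the combination arm of *every* model but in *no*
single-agent arm of any model.

## 5. Signature and quartile metrics

The signature score is the sum of per-gene expression Z-scores over the
signature; missing genes are dropped and counted (identical arithmetic
to zero-imputation, but reported so cross-universe comparisons are made
knowingly). Quartile stratification ranks samples by driver expression
with stable first-occurrence ties and cuts ranks at
$\lfloor 4(r-1)/n \rfloor + 1$, so strata differ by at most one sample
and extras land in the lower strata first (9 samples → 3, 2, 2, 2).
Downstream rank tests (Kruskal–Wallis, post hoc comparisons, survival
models) are intentionally out of scope; the module emits tidy tables
any standard tool consumes. Tumor volumes use the caliper formula
$L W^2 / 2$ (length = longer dimension; swapped with a warning if
violated) and the endpoint ellipsoid $L W H \pi / 6$, both homogeneous
of degree 3. The apoptotic index divides caspase-positive counts by
percent confluence and normalizes to the 0-hour baseline.

## 6. What the simulators emulate — and what they do not

All generators are deterministic given a seed (a local RNG is used, so
the caller's RNG stream is untouched) and attach a ground-truth sidecar
(`sim_truth()`) for recovery tests.

**Plate screens** lay out each compound as an 11-point 1:3 dilution
series from 45,000 nM (terminal dose $45000/3^{10} \approx 0.76$ nM,
printing as 0.8 nM at one decimal) in 1536-well plates with DMSO and
empty negative controls and positive-control wells simulated at the
empty (fully cytotoxic) level — present for layout realism, unused by
normalization. Compound signal interpolates between the control means
by latent 4PL viability. **Noise is multiplicative log-normal** with
mean 1 and configurable CV (default 0.10): plate readers show
proportional error, and the magnitude — unstated in any source — is an
explicit artifact choice. Not emulated: edge/evaporation gradients,
dispense drift, plate-position effects, carryover.

**Combination matrices** build margins from each compound's latent 4PL
and interiors from one of three regimes: `hsa_null`
($\min(v_A, v_B)$), `independence` ($v_A v_B / 100$, which always sits
at or below the HSA reference — mild "synergy" by construction), and
`potency_shift` — the synergy mechanism — where each agent acts as if
its dose were multiplied by a shift factor whenever the partner is
present. Potency shift (dose equivalence) was chosen deliberately
because it guarantees sub-HSA responses *without encoding the Excess
HSA statistic itself* into the generator; a shift factor of 1 reduces
exactly to the null. Default shift factor 3, one dilution step of the
screen's 1:3 series.

**Time courses** scale all drug effects by a saturating onset ramp
$r(t) = 1 - e^{-(t - \text{onset})/\tau}$ (0 before onset), applied as
$v_t = 100 - r(t)(100 - v_\infty)$. Because the HSA reference commutes
with this monotone rescaling, the Excess HSA of the ramped matrix is
exactly $r(t)$ times the endpoint score in the noise-free case — zero
before onset, maximal at the last time point.

**Proteomics tables** draw per-protein baselines
($\mathcal{N}(20, 2^2)$ log2 units) with Gaussian replicate noise
(default $\sigma = 0.2$); treated replicates of affected-set members
are shifted by the set's log2 effect. Overlapping sets must agree on
the shift at shared proteins or the generator refuses. Not emulated:
missing values, intensity-dependent variance, batch structure, shared
reference channels.

**Cohorts** give the driver gene a standard normal across samples and
each signature gene $\rho \cdot \text{driver} + \sqrt{1-\rho^2} \cdot
\varepsilon$, so marginals stay standard normal and the coupling *is*
the driver-gene correlation. Background genes are independent. Not
emulated: gene-gene correlation beyond the driver, subtype structure,
non-Gaussian tails.

**Two-model screens** draw per-compound latent activities correlated
at $\rho$ across models ($\sqrt{\rho}\,\text{shared} +
\sqrt{1-\rho}\,\text{specific}$). Activity drives both the bottom
plateau (18 percentage points per SD, clamped to [0, 100]) and
$\log_{10} \mathrm{EC}_{50}$ (0.55 decades per SD, clamped one dilution
step inside the tested range), so active compounds are both more potent
and more cytotoxic and the AUC is close to affine in activity. The
observed between-model Pearson correlation of Z-AUC profiles therefore
recovers the latent $\rho$ up to mild plate-noise attenuation — a few
percent at CV 0.10 (measured ≈ 0.69 for $\rho = 0.72$); the latent
default is 0.72 and is *not* inflated to compensate, so the measured
value is expected to sit slightly below the latent one. Passing the
concordance test shows the pipeline preserves a known latent
correlation through normalization, integration and standardization; it
does not validate any biological claim about real cell models.

## 7. Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen to keep
Monte-Carlo error well inside the asserted margins: 1,000 random
matrices for the synergy oracle; 500 null matrices for false-hit
calibration; 100 seeds × 45 pairwise matrices for planted-partner
recovery; 50 replicate fits for EC50 recovery; 200 seeds × 200
permutations for enrichment calibration; 100 cohorts of 400 samples
for quartile recovery; 3,000 compounds for the two-model concordance
estimate. Every stochastic step takes an explicit integer seed, and
the acceptance script derives all of its seeds from a single `--seed`.

## 8. Known limitations

- The Excess HSA reconstruction (sum over interior wells on the
  viability scale) is validated by dimensional consistency with the
  −2000 threshold, not against an external reference implementation of
  the original metric.
- The plug-in HSA reference is positively biased under noise (Section
  2); comparisons of *antagonism* scores across noise regimes should
  account for it.
- Permutation p-values have resolution $1/(n_\text{perm}+1)$; deeply
  significant sets saturate at that floor rather than receiving
  multilevel-extrapolated values.
- Welch's test with n = 3 per arm has little power; the significance
  filters are threshold rules, not calibrated error control across the
  proteome.
- The 4PL fitter reports a convergence flag but no parameter
  uncertainties; profile-likelihood or bootstrap intervals are out of
  scope.
- Simulators model well-level noise only; systematic plate artifacts
  that real screens exhibit are absent, so passing recovery tests
  bounds estimator behavior under the stated noise model, not under
  arbitrary real-world artifacts.
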