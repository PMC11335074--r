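---
title: "Screening divalent-cation binding sites in ASIC1a: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening divalent-cation binding sites in ASIC1a: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casite)
```

Acid-sensing ion channel 1a (ASIC1a) is a trimeric proton-gated Na⁺
channel whose pH dependence is modulated by extracellular Ca²⁺ and Mg²⁺:
raising the divalent concentration shifts both activation and
steady-state desensitization (SSD) toward more acidic pH, consistent
with competition between protons and divalent cations for shared binding
sites. `casite` implements the two computational workflows used to
localize and quantify that modulation:

1. a **trajectory contact screen** that ranks acidic side chains (Asp/Glu)
   as candidate Ca²⁺-coordinating residues from ion-coordinate time
   series, and
2. an **electrophysiology analysis** that turns per-oocyte voltage-clamp
   peak-current tables into Hill midpoints (pH₅₀, pHD₅₀), inhibition
   IC₅₀s, exponential time constants, paired shifts, τ ratios and group
   statistics.

Both are paired with synthetic-data generators carrying known ground
truth, so the full pipeline runs — and is tested — without any external
download.

## The contact screen

The screen asks a deliberately coarse question: which carboxylate groups
keep a tagged Ca²⁺ ion in their vicinity for a meaningful part of the
simulation? It makes no attempt to characterize electronic coordination,
coordination numbers or chelation geometry.

The reference point of a residue is the unweighted midpoint of its two
side-chain carboxylate oxygens (`group_center()`). Screening proceeds in
two passes over each 100 ns segment:

* **Pre-screen.** Distances between every tagged ion and every group are
  sampled every 10 ns (`build_distance_table()`). Any (ion, group) pair
  with at least one distance strictly below 10 Å is retained
  (`screen_pairs()`). For the full study geometry — 2 channels × 18 ions
  × 183 acidic residues × 6 segments × 10 samples — this is 395 280
  distances (`count_screening_distances()`).
* **Refinement.** Retained pairs are re-measured every 0.4 ns. A group
  passes a segment when its distance to a retained ion is below 6 Å
  during at least 10 % of that segment's sampled frames; the
  below-cutoff frames need not be contiguous (`refine_candidates()`).

Several points were left open by the original description; the package
resolves them as follows, and each choice is visible in the output:

* **Strict inequalities** everywhere a threshold is applied ("smaller
  than 10 Å", "closer than 4 Å"): a distance of exactly 10 Å is not
  retained.
* **Sampling** at interval *k·Δ* picks the stored frame nearest each
  target time; there is no interpolation.
* **The 10 % criterion is evaluated per 100 ns segment**, and a group is
  an overall candidate when it passes in at least one segment. The
  per-segment flags are kept in the report (`per_segment` attribute)
  because a stricter whole-trajectory reading is also defensible; users
  can aggregate either way.
* The criterion's **denominator is the full simulated time** of the
  segment: frames excluded by the second-passage mask (below) still
  count in the denominator but can never count toward the numerator.
* The **residency criterion is evaluated per retained pair** and OR-ed
  over a group's pairs, whereas the reported occupancy fractions and
  capped mean distances use the distance to the *closest* ion whose home
  vestibule matches the group — each vestibule/group pairing contributes
  one data point, and spreads across subunit copies of the same residue
  are reported both as s.d. and s.e.m. (`residue_summary` attribute),
  since the convention is ambiguous in the source displays.

**Second-passage exclusion.** Ions occasionally leave the vestibule in
which they started. Once an ion has left, any later contact it makes
with *other* vestibules is a different binding event and is excluded, so
the statistics describe only the originally occupied site. "Leaving" is
operationalized as exceeding 25 Å from the home-vestibule centroid (the
mean of that vestibule's group centers at the first frame) continuously
for at least 5 ns (`detect_departures()`); the source never quantifies
the notion, and these values cleanly separate genuine escapes from
transient excursions at the simulated diffusivities. Contacts with the
ion's own home vestibule are never masked.

**Site classification.** Acidic-pocket ions are labelled `inner_AP` or
`outer_AP` by their first-frame distance to user-supplied anchor groups
(the E219/D409 homologs for the inner site, the E97 homolog for the
outer site); exact ties go to `inner_AP` so the labelling is
deterministic.

Coordinates are assumed pre-imaged and whole; the package does no
periodic-boundary handling. Units are Å and ns throughout, and the
readers convert nothing silently.

## The synthetic trajectory generator

`generate_bundle()` integrates overdamped (Brownian) dynamics for point
ions in a field of attractive Gaussian wells planted at chosen groups,

$$x_{t+\Delta} = x_t - \nabla U \, D \Delta + \sqrt{2 D \Delta}\,\eta,
\qquad U = \sum_w -d_w \exp\!\left(-\tfrac{|x - c_w|^2}{2 w_w^2}\right),$$

with well depths $d_w$ in units of kT (the factor kT/γ is absorbed into
the diffusion coefficient), a reflective sphere as the boundary, and
static groups. Defaults — D = 0.5 Å²/ns, timestep 0.1 ns, boundary 40 Å,
100 ns segments — were chosen so that a segment costs milliseconds while
binder and non-binder occupancy statistics are cleanly separated. The
`wt_like` preset mirrors the study's layout qualitatively: a 600 ns run
(six segments) with an inner and an outer well cluster in one acidic
pocket, wells in the central vestibule, and far-away non-binder groups;
`nonbinding` removes all wells; `escape` switches wells off at a known
time and applies a brief outward drift so the scheduled departure is
sharp on the trajectory's time scale (free diffusion at 0.5 Å²/ns would
take ~200 ns to clear the departure radius, blurring the ground truth).

The generator emulates only what the screen consumes: residence near
planted sites, diffusive exploration, and scripted escapes. It has no
electrostatics, hydration shells, force-field terms or protonation
dynamics, and the boundary is reflective rather than periodic. Passing
screens on these bundles therefore demonstrates that the *bookkeeping*
— sampling, thresholds, masking, per-segment logic — is correct, not
that the screen would rank residues correctly in any particular MD
force field.

## The electrophysiology model

All fitting works on magnitudes of normalized responses; peak currents
are stored signed (inward negative). Activation and SSD series are
normalized to the series maximum (so the normalized maximum is exactly
1); recovery and onset series are normalized to their designated control
response. For SSD the series maximum rather than the first record is
used as the reference — the two can differ under noise and the
convention is not stated in the source; the choice is visible in the
normalized output.

The fitted forms are

* activation / SSD: $I = I_{max} / (1 + (10^{-pH_{50}} / 10^{-pH})^{n_H})$,
  with the SSD branch reflected (response falls with conditioning
  acidity) and its midpoint reported as pHD₅₀;
* inhibition: $I = NonIn + (I_{max} - NonIn) / (1 + (x / IC_{50})^{n_H})$;
* recovery: $I = I_{max} (1 - e^{-t/\tau})$;
* onset: $I = NonDes + (I_{max} - NonDes) e^{-t/\tau}$.

Fits minimize unweighted least squares (Levenberg–Marquardt via
`minpack.lm`) with a five-point multistart grid on the midpoint
parameter, bounds pH₅₀ ∈ [3, 9], n_H ∈ (0, 10], IC₅₀ ∈ (10⁻⁴, 10³] mM,
and convergence tolerance 10⁻¹⁰. The original analysis names only the
software used; this scheme is the package's own and is exercised by
noiseless-identifiability tests (recovery of generating parameters to
10⁻⁶).

Midpoint-versus-concentration curves (pH₅₀ as a function of free Ca²⁺)
are fitted with the same inhibition form but a **fixed unit Hill slope**
(`fit_inhibition(..., fix_nH = 1)`): a single competing site implies a
hyperbolic dependence, and freeing the slope roughly doubles the
Monte-Carlo spread of the IC₅₀ estimate without changing its center.
Even with the slope fixed, the IC₅₀ from six mean points (20 oocytes per
concentration, between-oocyte s.d. 0.11) has a Monte-Carlo s.d. of about
0.56 mM (≈16 %); single-replicate IC₅₀ values should be read with that
precision in mind.

**Paired analyses.** The modulation measures — ΔpH₅₀, ΔpHD₅₀ and the τ
ratios — are computed per oocyte and then averaged, never as differences
or ratios of pooled fits, matching the paired recording design (both
divalent conditions measured in the same oocyte). Ratio orientation
follows the convention of each protocol: recovery reports
τ(low)/τ(high), onset τ(high)/τ(low), so both exceed 1 under divalent
modulation. Group comparisons use a two-sided paired t for two
conditions and one-way ANOVA with Dunnett (mutants vs control) or Tukey
(all pairs) single-step multivariate-t contrasts at α = 0.05. Arms with
all-zero paired differences return statistic 0, p = 1; constant non-zero
differences are degenerate for the t statistic and raise an error.

## The peak-series generator and its presets

`simulate_peak_series()` draws, per oocyte, the high-divalent midpoint
from a normal distribution and the *paired shift* from an independent
normal, sets the low-divalent midpoint to their sum, evaluates the protocol's
response equation on its stimulus grid, and applies
multiplicative measurement noise (σ = 0.03). This reproduces the
high-arm spread and the paired-shift spread exactly; the implied low-arm
marginal spread is slightly larger than the printed one, because the
joint between-arm structure of the recordings is not published. Kinetics
presets use independent mean-1 lognormal τ multipliers per arm with
CV = 0.4 — consequently the *ratio of mean τs* is reproduced, while the
published per-oocyte ratio means (8.3 for recovery, 17.3 for onset)
exceed the corresponding ratios of means, as expected for ratios of
noisy quantities; the oocyte-level correlation needed to match them
exactly is likewise unpublished.

Hill slopes are nowhere published for these curves; the presets assume
n_H = 1.5 for activation and 3 for SSD (SSD curves are visibly
steeper). The registry (`ephys_presets()`) encodes, as ground truth, the
WT Ca²⁺ values (pH₅₀ 6.50/6.75, pHD₅₀ 7.14/7.42), WT Mg²⁺
(6.59/6.72; 6.97 at 10 mM / 7.37 at 0.1 mM), WT kinetics (recovery τ
4.0/22.8 s, onset τ 63.6/3.9 s, NonDes 0.05), the pore-block curve
(IC₅₀ 9.6 mM, n_H 1, NonIn 0 — chosen so the analytic block at 10 mM
equals the printed 51 %), the modulation curve (floor 6.01, ceiling
6.78, IC₅₀ 3.5 mM, passing ≈6.50 at 2 mM), ASIC1b (6.13/6.33;
7.13/7.37), and the mutant shift presets (AP-Act 0.10, D409A 0.41,
AP-SSD 0.05, CV-SSD 0.13, ASIC1b CV-SSD −0.14).

## The three-state gating simulator

`gating_model()` implements a minimal closed/open/desensitized scheme in
which a proton-occupancy term gates activation and desensitization and
Ca²⁺ competes for the proton sites, shifting both apparent pK values by
$\log_{10}(1 + [\mathrm{Ca}] / K_{Ca})$. Because both sensors shift
equally, the simulated peak-response curve translates rigidly along the
pH axis when the Ca²⁺ concentration changes — the simulator's alkaline
shift between 2 mM and 100 nM matches the closed-form competition limit
$\log_{10}(1 + 2 / 3.5) \approx 0.196$ to better than 0.001 pH units,
which is exactly the property the tests assert. Rate constants are
illustrative (resting closed at pH 7.8, transient opening with
desensitization at acidic pH) and are not fitted to any recorded trace;
occupancies are integrated with `deSolve::lsoda` at rtol 10⁻⁸ and
conserve C + O + D = 1 to ~10⁻¹⁵.

## Numerical choices, problem sizes and degenerate inputs

* Distance oracle tests run on ≤5-frame, ≤3-ion, ≤5-group bundles and
  require exact agreement with a loop-based recomputation.
* The planted-binder check runs the full screen on ten 600 ns `wt_like`
  bundles (seeds 1–10) and requires precision = recall = 1; the whole
  test suite completes in about a minute on one core.
* Parameter-recovery checks use 20 simulated oocytes (10 for recovery
  kinetics, 8 for Mg²⁺ SSD, matching the recorded group sizes) at fixed
  seeds and accept within twice the Monte-Carlo standard error of each
  estimator, estimated once from 200 independent replicates of the full
  simulate-and-fit pipeline and frozen into the tests.
* Degenerate inputs fail loudly and specifically: empty bundles and
  tables, non-finite coordinates, zero control amplitudes, constant
  response series, fewer than four stimulus values, fewer than two
  complete pairs, non-positive τ.
* A capped mean with no qualifying frame is reported as a flagged
  "no-contact" sentinel, never as zero.

## Limitations

The generators are calibrated to published summary statistics, not raw
data: between-arm correlations, batch effects, rundown, leak and
series-resistance artefacts are absent, so passing recovery tests bounds
estimator bias under the stated noise model only. The contact screen
inherits whatever sampling quality its input trajectories have; the
package neither generates physical trajectories nor judges force-field
adequacy, and binary trajectory formats (XTC/DCD) must be converted to
the multi-model PDB or CSV dialect externally. The gating model is a
caricature for validating competition logic, not a quantitative kinetic
model of ASIC1a.
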