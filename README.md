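# casite

Screening of divalent-cation binding sites in acid-sensing ion channels
(ASICs), and quantification of Ca²⁺/Mg²⁺ modulation of their pH
dependence.

ASIC1a is a trimeric proton-gated Na⁺ channel. Extracellular Ca²⁺
competes with protons for binding sites on the channel: lowering the
free Ca²⁺ concentration shifts both the pH dependence of activation
(pH₅₀) and of steady-state desensitization (pHD₅₀) toward more alkaline
values. Locating the residues behind that competition combines two very
different analyses, and `casite` implements both as a tested, reusable
pipeline:

1. **Trajectory contact screen** (`traj_bundle`, `candidate_report`):
   ranks acidic side chains (Asp/Glu) as candidate Ca²⁺-coordinating
   residues from ion coordinate time series. A coarse pre-screen retains
   every (ion, residue) pair that ever comes within 10 Å at 10 ns
   sampling; retained pairs are re-measured at 0.4 ns, and a residue is
   a candidate when its carboxylate midpoint stays within 6 Å of a
   tagged ion during ≥ 10 % of a 100 ns segment. Ions that leave their
   starting vestibule have later foreign-vestibule contacts excluded
   (second-passage exclusion). Occupancy fractions (< 4, < 6, < 20 Å)
   and capped mean distances are reported per residue.
2. **Electrophysiology analysis** (`fit_hill`, `fit_inhibition`,
   `fit_recovery`, `fit_onset`, `paired_shift`, `tau_ratio`,
   `compare_groups`): per-oocyte Hill fits
   `I = Imax / (1 + (10^-pH50 / 10^-pH)^nH)` of activation and SSD
   curves, inhibition-curve fits
   `I = NonIn + (Imax − NonIn) / (1 + (x/IC50)^nH)`, single-exponential
   kinetics, per-oocyte paired shifts (ΔpH₅₀ = pH₅₀,low − pH₅₀,high) and
   τ ratios, paired t-tests and ANOVA with Dunnett/Tukey contrasts.

Synthetic generators with known ground truth drive both pipelines:
overdamped Langevin ions in planted Gaussian wells (`preset_bundle`,
`generate_bundle`), per-oocyte peak-current tables under all five
voltage-clamp protocols (`simulate_peak_series`, `ephys_presets`), and a
three-state closed/open/desensitized gating model with proton–Ca²⁺
competition (`gating_model`, `simulate_three_state_trace`).

## Worked example

Screen a synthetic 600 ns wild-type-like system (three tagged ions, an
inner and outer acidic-pocket site plus central-vestibule sites, and
far-away non-binder residues), then quantify Ca²⁺ modulation on 20
simulated oocytes:

```r
library(casite)

res <- run_traj_pipeline("wt_like", seed = 1)
subset(res$report, candidate,
       c(group_id, region, fraction_lt_4, fraction_lt_6,
         capped_mean_distance))
#>    group_id region fraction_lt_4 fraction_lt_6 capped_mean_distance
#>  1 GLU219.A AP             1             1                     1.29
#>  2 ASP409.A AP             0.991         1                     2.16
#>  3 ASP347.A AP             0.971         1                     2.43
#>  4 ASP351.A AP             0.983         1                     2.24
#>  5 GLU97.A  AP             0.936         0.944                 1.83
#>  6 GLU238.A AP             0.926         0.939                 2.37
#>  7 GLU242.A AP             0.928         0.950                 2.22
#>  8 GLU375.A CV             0.992         1                     1.46
#>  9 GLU413.A CV             0.938         0.995                 2.45
#> 10 GLU418.A CV             0.986         1                     2.13
```

Exactly the ten residues carrying planted attractive wells are flagged
(`fraction_lt_6` is the fraction of refined frames with the closest
matching ion under 6 Å; `capped_mean_distance` is the mean ion–residue
distance over frames ≤ 10 Å).

```r
ep <- run_ephys_pipeline("wt_ca", "activation", n_oocytes = 20, seed = 1)
ep$shift
#> <paired_shift> 0.2271 +/- 0.08706 (s.d.), n = 20
ep$stats
#> <stats_result:paired-t> statistic = 11.66, p = 4.18e-10
```

Each simulated oocyte is fitted in both Ca²⁺ arms (2 mM and 100 nM);
the per-oocyte alkaline shift of the activation midpoint averages
0.23 ± 0.09 pH units here, against a generating value of 0.25, and the
paired t-test confirms the arms differ. The analytic pore block at
10 mM Ca²⁺ from the wild-type inhibition parameters:

```r
reproduce("t6")
#>   target                                       quantity value n reference
#> 1     t6 percent block of maximal current at 10 mM Ca2+    51 1        51
```

A thin command-line wrapper ships in `inst/cli/casite`
(`simulate-traj`, `screen-traj`, `traj-report`, `simulate-ephys`,
`ephys-fit`, `reproduce`).

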