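---
title: "Methods: constraint-based analysis of cyanobacterial phototrophic metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based analysis of cyanobacterial phototrophic metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

This vignette documents the models and numerical procedures behind
`cyanoflux`: what is being optimized, which parameters matter and why they
have the defaults they have, what the synthetic data generators emulate
(and what they deliberately do not), and where genuinely open design
choices were resolved.

## 1. Flux balance analysis and its assumptions

All steady-state analyses solve

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,\; A v \lesseqgtr b,$$

where $S$ is the stoichiometric matrix, the bounds encode irreversibility
and exchange limits, and the extra rows $A v \lesseqgtr b$ carry flux-ratio
couplings. The central assumption of FBA — that intracellular fluxes
maximize biomass yield under the given constraints — is adopted for the
light phase; the dark phase instead maximizes ATP production (see §4),
since net growth in darkness is minimal.

**Degenerate optima.** The optimal face of an FBA problem is usually not a
single point. The package therefore distinguishes three objects:

- `solve_fba()` returns one optimal *vertex*, with no uniqueness claim;
- `flux_variability()` returns per-reaction flux ranges over the optimal
  face ("FVA"); every statement of the form "reaction X is inactive in
  every optimum" is made through an FVA maximum of zero, never from a
  vertex;
- `parsimonious_fba()` fixes the objective and minimizes total absolute
  flux. All *reported* flux maps use it, because plain vertices can carry
  arbitrary futile cycles (e.g. the anabolic/catabolic
  phosphoglycerate-kinase pair spinning against the transhydrogenase at
  the flux bound) that have no biological meaning and no effect on the
  objective.

**The LP solver.** The package ships a dense bounded-variable two-phase
revised simplex (C++/Armadillo): Dantzig pricing with a Bland's-rule
fallback for termination, largest-pivot tie-breaking in the ratio test for
numerical stability, an explicit basis inverse refactorised every 200
iterations, feasibility tolerance $10^{-9}$ and a reported-value comparison
tolerance of $10^{-6}$. Its results are cross-checked in the test suite
against an independent solver on random LPs and against exhaustive vertex
enumeration on every fixture with at most 8 reactions; on those fixtures
objective values and FVA ranges agree to $10^{-6}$.

## 2. The phototrophic reference scenario

`scenario_config()` carries every tunable constraint. Defaults (units
mmol gDW⁻¹ h⁻¹ unless noted):

| parameter | default | meaning |
|---|---|---|
| `growth_rate_target` | ln 2 / 24 ≈ 0.0289 h⁻¹ | 24 h doubling time under constant light |
| `carbon_source` | bicarbonate | carbon enters only as HCO₃⁻; CO₂ exchange is release-only |
| `maintenance_atp` | 0.15 | growth-independent ATP drain |
| `oxidase_fraction` | 0.10 | terminal-oxidase O₂ uptake = 10% of PSII O₂ evolution (equality) |
| `mehler_like_fraction` | 0.10 | flavodiiron (Mehler-like) O₂ uptake, same coupling |
| `ros_fraction` | 0.005 | superoxide at 0.5% of PSII and PSI electron flow |
| `oxygenase_min_ratio` | 0.03 | oxygenase ≥ 3% of carboxylase flux |
| `storage_flux` | 0.05 | required glycogen synthesis in the light |
| `light_limit` | calibrated | photon bound giving exactly the target growth rate |

Light is the limiting resource: when `light_limit` is unset it is
calibrated by bisection so the optimized growth rate equals the target.
The maintenance default (0.15, about 15% of the growth-associated ATP at
the reference rate) and the storage default (≈20% of fixed carbon routed
to glycogen) are drawn from the range used in cyanobacterial
genome-scale models; both are plain config fields and every analysis
records the values it used. The equality form of the respiration and ROS
couplings reflects that these are *assumed activities*, not capacities.

An alternative reading couples the Mehler-like flux to ~20% of
water-splitting electrons rather than 10% of O₂; that variant is available
by setting `mehler_like_fraction = 0.2` with the same machinery.

## 3. The synthetic core network

`build_core_model()` generates a ~100-reaction, two-compartment
(cytosol/extracellular) core model. It is a first-class, tested artifact,
not a fixture: every reaction is elementally balanced for C, N, O, P and S
and charge-neutral under a uniform neutral-protonation convention, and
`check_balance()` verifies this. Hydrogen is deliberately excluded from
the default check and flagged separately: proton bookkeeping depends on the
protonation-state convention, and intracellular pH itself varies over the
diurnal cycle.

Structure: photon uptake; PSII water splitting; plastoquinone,
cytochrome b₆f, plastocyanin and PSI; FNR (reversible); an ATP synthase
driven by a lumped proton-motive-force pseudo-metabolite (`pmf`, 4 charges
per ATP); proton-pumping NDH-1 (3 pmf per NADPH); terminal oxidase (8 pmf
per O₂); the CBB cycle with separate carboxylase and oxygenase; the full
photorespiratory salvage network with both glyoxylate fates (to glycine
via transaminase/glycine-cleavage, and to glycerate via carboligase); an
optional phosphoserine branch; lower glycolysis; optional phosphoketolase,
OPP and malic enzyme; all four TCA-closure variants as toggles; glycogen
synthesis/degradation; nitrate, sulfate, phosphate and acetate exchange;
and lumped, balanced synthesis reactions for seven biomass components
(protein, DNA, RNA, lipid, pigment, cell wall, ions) feeding a biomass
objective with 30 mmol ATP gDW⁻¹ growth-associated maintenance. The
biomass split is protein-dominant (5 mmol residue-equivalents per gDW);
the amino-acid composition of the protein equivalent (glu 0.40, ala 0.35,
gly 0.12, ser 0.10, cys 0.03 per residue) fixes the serine/glycine demand
that drives the photorespiration scenarios.

Three structural choices deserve emphasis because qualitative results
depend on them, and all three mirror the organism rather than convenience:

1. **No cytosolic carbonic anhydrase.** Bicarbonate is converted to CO₂
   only inside the carboxysomal fixation pool, one-way. Respired cytosolic
   CO₂ can leave but cannot be re-fixed. This reflects the cyanobacterial
   carbon-concentrating mechanism and is what makes the acetate + DCMU
   experiment discriminating: with re-fixation, acetate carbon could reach
   sugars through the CBB cycle regardless of the glyoxylate shunt.
2. **Nitrogen assimilation via GS/GOGAT only; GDH irreversible** (the
   deaminating direction). Besides being the canonical cyanobacterial
   route, this removes amination shortcuts that would otherwise make the
   two photorespiratory glyoxylate fates stoichiometrically unequal; with
   GS/GOGAT both fates cost exactly 2 ATP, 1 reduced-N and 1 NADPH per
   serine and release one CO₂, which is why FVA shows them as equivalent
   alternative optima.
3. **No non-pumping NADH dehydrogenase (NDH-2).** NADH is oxidized only by
   the transhydrogenase (if present) or by NDH-1 (if allowed NADH as a
   substrate). An NDH-2 would silently re-route NADH around the
   transhydrogenase and erase the dark-metabolism dichotomy; its omission
   follows the same logic by which GDH is kept irreversible.

One quantitative choice matters for the dark-phase ranking: NDH-1 is
assigned 3 pmf charges per NADPH. At 4 the complete OPP oxidation of a
glucosyl unit and the glycolysis + TCA route yield exactly 24 ATP each and
the dark routing becomes degenerate; at 3 the yields are 21 vs 22.5, so
cyclic TCA flux is strictly optimal whenever NADH can be converted
(transhydrogenase present or NDH-1 promiscuous) and the OPP is strictly
optimal when it cannot. One caveat is documented here rather than hidden:
even in the cyclic-TCA routings the *small* ribose-5-phosphate demand for
nucleotide synthesis is met through the OPP (it avoids a phosphofructokinase
ATP), so the OPP flux is a fraction of a percent of the cyclic flux rather
than exactly zero.

What the core model does **not** emulate: genome-scale reaction counts,
compartmental detail (thylakoid lumen, carboxysome and periplasm are
merged into the two compartments), quantum-yield absolute magnitudes,
cyanophycin/PHB storage, and fermentative secretion (acetate export is
closed). Passing tests on it therefore validate *relative and qualitative*
claims — yield orderings, activity/inactivity of pathways, flux-sign
patterns — not absolute genome-scale flux magnitudes.

## 4. Scenarios

- **Dark metabolism** (`dark_metabolism()`): photons zero, respiration
  couplings off, and the glycogen mobilisation cap set to
  $(1+\varepsilon)$ times the minimum needed for maintenance alone
  (found by a preliminary LP; $\varepsilon = 0.1$). The biomass objective
  then represents residual cellular turnover squeezed into the slack.
- **TCA variants** (`compare_tca_variants()`): one optimization per
  closure topology under otherwise identical constraints; the light bound
  or glycogen cap is computed once (on the open cycle) and reused so the
  comparison is between topologies only.
- **Photorespiration scenarios 1–3**
  (`photorespiration_analysis()`): (1) no phosphoserine pathway —
  serine/glycine/cysteine must come from glyoxylate, so a nonzero
  oxygenase flux *emerges* from yield optimization (5.3% of carboxylase
  flux with the default biomass composition); (2) phosphoserine pathway
  present — the oxygenase FVA maximum drops to zero; (3) phosphoserine
  pathway plus the 3% oxygenase floor — the bound binds exactly and FVA
  exposes the two equivalent glyoxylate fates. The photorespiration rate
  is defined as $100 \cdot v_{\mathrm{oxygenase}}/v_{\mathrm{carboxylase}}$;
  the alternative normalisation by total RuBisCO flux would read
  $100\,r/(1+r)$ and is trivially derived from the reported ratio.
- **Acetate + DCMU** (`acetate_dcmu_test()`): PSII fixed to zero (DCMU
  blocks water splitting but not PSI cyclic electron flow, which still
  makes ATP), bicarbonate closed to net uptake, acetate the sole carbon
  source. Growth is possible exactly when the glyoxylate shunt provides
  net C₄ synthesis from C₂ units.

## 5. The diurnal simulation

`run_diurnal()` implements the static-optimization flavour of dynamic FBA:
one LP per step plus an explicit storage-pool update; no optimization over
the whole horizon. Defaults: 48 steps of 30 min, 12 h light, triangular
light peaking at noon at five times the constant-light calibrated bound
(the daytime must deliver in 12 h what the reference delivers in 24, with
headroom for storage), transitions ramped over 4 steps (2 h).

The time-varying biomass objective is implemented as per-step synthesis
*requirements* (equality bounds on per-component demand reactions) rather
than objective weights: the weight vector of the schedule *is* the
required synthesis-rate vector. This choice — an extension of the rule
that DNA/ion synthesis is a fixed per-step flux rather than an objective
term — guarantees that dark steps still produce DNA and ions while
maximizing ATP, avoids the winner-takes-all degeneracy of multi-component
linear objectives, and makes the 24 h component totals match the daily
targets by construction (the step-count robustness checks then verify the
discretisation, not the normalisation). Daily totals default to the
amounts implied by one doubling at the reference composition
(ln 2 × BOF weight per component). The light-phase LP objective is net
glycogen accumulation (enabled after mid-day); the dark objective is ATP
production, with net O₂ uptake capped at `dark_respiration_fraction`
(default 0.1) of the peak-light oxidase level — that cap is what paces
glycogen consumption through the night. Growth-associated ATP beyond the
component syntheses' own costs is not charged in the diurnal mode.

The pigment window follows the rule "2 h before dawn to 2 h before dusk";
the alternative main-text-style variant (decline after noon) can be had
via `pigment_lead_h` and custom `daily_totals`. An infeasible step (for
example, maintenance demands exceeding what an exhausted glycogen pool can
support) truncates the trajectory with a diagnostic naming the step, time
and pool state.

Carbon closure over the cycle — net inorganic carbon uptake versus carbon
accumulated in components plus the glycogen pool change — holds to
numerical precision because each step is individually mass-balanced; the
1% acceptance band absorbs only LP tolerance, and the left-Riemann
discretisation cancels from both sides. Component totals change by far
less than 2% between 24, 48 and 96 steps.

## 6. Transcript-rhythm statistics

Sampling design: six unevenly spaced circadian times (CT 0.5, 5.5, 11.5,
12.5, 17.5, 23.5) × two replicates, treated as independent samples at
their recorded times. The oscillation statistic is the direct discrete
Fourier projection at 1/24 h⁻¹ of the mean-centered profile,
$p_d = |\sum_k x_k e^{-2\pi i t_k/24}|^2 / n$ — for centered data an
unnormalized single-frequency Lomb–Scargle. It is computed on
log-intensities by default. Significance comes from shuffling values over
times ($p = (1 + \#\{p_d^{perm} \ge p_d\})/(n_{perm}+1)$, positively
biased, hence never zero); the analysis default is $10^5$ permutations and
tests use $10^2$–$10^3$. Under the null the p-values are uniform on the
achievable grid, and the type-I error at $\alpha = 0.05$ sits inside the
99% binomial band over 2000 simulated null genes.

**Phase** is the CT of the fitted cosine's peak obtained by least-squares
harmonic regression at 1/24 h⁻¹. The raw argument of the Fourier sum is
*biased* on this uneven design (by ≈0.25 h at phase 0, over 1 h at phase
8) because the sampling grid aliases the conjugate frequency; the
least-squares fit is exact for noiseless cosines under any design and
recovers injected phases with a median error well under 2 h at
signal-to-noise 3 on the six-point design (≈0.4 h in the calibration run).

**Normalization.** The least-oscillating set (LOS) is selected on the raw
matrix as the genes with permutation $p >$ threshold (default 0.5), or as
the $k$ least-oscillating genes when a fixed-size reference set is wanted
— the latter is the robust choice when a global time-locked trend makes
every profile nominally rhythmic. Per array, the deviation of LOS
intensities from the LOS cross-array means is smoothed against the mean
intensity by local linear regression with tricube weights (`stats::loess`,
`degree = 1`, span 0.75 by default) and subtracted from all genes at their
observed intensity (clamped to the fitted range). A constant additive
array bias is removed essentially exactly; a smooth intensity-dependent
distortion is removed to the extent the span resolves its length scale
(the test uses span 0.3 against a sine distortion of period $2\pi$ on a
log-intensity range of ≈9, cutting its RMS by more than 80%). An empty LOS
is an error — normalization is undefined without reference genes.

**The expression generator** (`generate_expression()`) draws oscillators
as `baseline + A cos(2π(t − φ)/24)` plus Gaussian noise, with phases
uniform on \[0, 24), plus an optional additive array trend peaking during
the subjective day and an optional smooth intensity distortion — exactly
the technical structure the LOS normalization is designed to remove. It
does not emulate spot-level microarray artefacts, missing values,
count-like noise, or gene–gene correlation; calibration results on it
certify the statistics, not any particular microarray platform.

## 7. Problem sizes and numerical settings

Analyses in the documentation, tests and the acceptance script use the
synthetic core network (≈120 reactions), 48-step diurnal simulations
(with 24- and 96-step refinement checks), 2000 null genes at 999
permutations for test calibration, and 300-gene simulations for phase
recovery. These sizes make every result reproducible in minutes on a
single core while keeping all statistical bands meaningful. Solver
tolerances: feasibility $10^{-9}$; equality-coupling residuals are checked
at $10^{-8}$; cross-method comparisons at $10^{-6}$.

## 8. Known limitations

- The core network is a caricature by design; absolute fluxes, the
  genome-scale network counts and the exact 5% photorespiration figure of
  the full reconstruction are outside its scope (the scenario logic, not
  the numbers, transfers). The genome-scale checks run only when a
  published reconstruction SBML is supplied via
  `options(cyanoflux.dataset_s1 = ...)` together with a role mapping.
- Suboptimal "standby" flux states (e.g. residual OPP flux under light
  reported from isotope labelling) are not recovered by yield
  optimization, and no attempt is made to do so.
- The dFBA couples steps only through the glycogen pool; there is no
  circadian clock model, no cell-division model, and no cyanophycin/PHB
  pool.
- The simplex is dense; it is comfortable at core-network size and fine at
  a few thousand reactions, but it is not a sparse industrial LP code.
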