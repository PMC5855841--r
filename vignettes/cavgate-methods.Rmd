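---
title: "cavgate: models, presets and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cavgate: models, presets and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavgate)
```

`cavgate` simulates and analyses whole-cell voltage-clamp recordings of
CaV2.1 (P/Q-type) calcium channels under perturbed N-linked glycosylation,
and carries the two satellite analyses that accompany such a study: a
clinical stroke-like-episode (SLE) cohort summary and an N-glycosylation
sequon scan. This vignette documents the model, the defaults, and every
place where the design was genuinely open.

## 1. The gating model

Steady-state current density is Boltzmann-ohmic:

$$I(V) = G_{max}\,(V - V_{rev})\, \frac{1}{1 + e^{-(V - V_{1/2})/k}}$$

with $G_{max}$ the maximal conductance density (nS/pF), $V_{rev}$ the
extrapolated reversal potential, $V_{1/2}$ the half-activation voltage and
$k$ the slope factor (mV per e-fold change in the open-probability odds).
Activation is a single Hodgkin-Huxley gate ($m^1$); inactivation is a
single exponential with a non-inactivating pedestal:

$$I(t) = I_{ss}(V)\,\bigl(1 - e^{-t/\tau_{act}}\bigr)\,
        \bigl(r + (1 - r)\,e^{-t/\tau_{inact}}\bigr).$$

The pedestal is required by the data this emulates: measured degrees of
inactivation at the end of 3 s pulses are well below 100%, so a pure
exponential would be mis-specified. Accordingly the time-constant fit also
estimates an additive offset; a fit without offset would diverge from ours
whenever the pedestal is sizeable.

Useful closed form: the inward-current peak voltage $V^*$ satisfies
$(V_{rev} - V^*)(1 - m_\infty(V^*)) = k$, which the package uses both to
place $V_{1/2}$ from an observed peak voltage (`solve_v_half_for_peak()`)
and as an invariant test against a dense grid search.

## 2. Condition presets: what is anchored and what is assumed

Nine presets encode the experimental groups (vehicle/DMSO; tunicamycin at
0.2, 0.6 and 2 µg/mL; α2δ-1 omission; and the wild-type/N283Q mutagenesis
arm with its own vehicle/tunicamycin pair). Anchored quantities — group
sizes, mean peak current densities and their SEMs, activation-shift and
inactivation-difference magnitudes, and the peak-current voltages (+15 mV
control, +10 mV tunicamycin) — are taken as reported. Everything else is
an explicit assumption:

* **Absolute activation parameters.** Only shifts and peak voltages are
  reported, never absolute $V_{1/2}$, $k$ or $V_{rev}$. We fix
  $k = 4.5$ mV and $V_{rev} = +60$ mV (typical for heterologously
  expressed CaV2.1 in ~2.5 mM Ca²⁺) and *solve* the control $V_{1/2}$
  (≈ +5.11 mV) so the model peaks exactly at +15 mV. Treated presets shift
  $V_{1/2}$ by −3.5 / −5 / −4.5 mV as reported; $k$ and $V_{rev}$ are held
  fixed because no change in them was reported.
* **Absolute inactivation levels.** Only between-group differences are
  reported. Control degrees are set to 80% (+20 mV) and 75% (0 mV) and
  treated presets differ by the reported percentage points (tunicamycin
  0.6: −14/−16; N283Q: −22/−35). The tunicamycin 0.2 degrees are not
  reported at all; we set them halfway between vehicle and tunicamycin 0.6
  (the published traces show an intermediate, mostly non-significant
  effect) and likewise keep the N283Q+tunicamycin inactivation at the
  N283Q values. No acceptance-level quantity depends on these two choices.
* **Time constants.** Absolute $\tau_{inact}$ values are unreported;
  vehicle uses 300 ms (+20 mV) and 400 ms (0 mV), tunicamycin 0.6 ×1.5 and
  N283Q ×2, encoding "slower inactivation" qualitatively. $\tau_{act} =
  1$ ms, fast enough that the 20 ms peak approximates steady state.
* **Between-cell variability.** Peak-density SD is reconstructed as
  SEM·√n (e.g. vehicle 14.9·√27 ≈ 77 pA/pF) and sampled lognormally on the
  magnitude, which keeps conductances positive even for the near-abolished
  2 µg/mL group (CV ≈ 2.3). $V_{1/2}$ spread is 2 mV SD, degree spread 5
  points (truncated to [0, 100]), $\tau$ CV 0.3, capacitance lognormal
  around 12 pF (CV 0.3) — all plausible HEK293 values, none reported.
* **Noise.** Additive white Gaussian, SD 5 pA: small against vehicle-scale
  currents (~1.8 nA), clearly visible on the 2 µg/mL preset.

Presets serialize to a flat `name.field_with_units = value` config with 17
significant digits, so a written config re-reads bit-identically.

## 3. Protocols and the synthetic-data generator

The I–V protocol steps from −80 mV holding to −50…+60 mV in 5 mV
increments (20 ms, 20 kHz); the step list is not reported, so it was chosen
to cover both peak voltages and the reversal potential. Inactivation uses
3 s pulses to +20 and 0 mV at 1 kHz. Capacitive transients and leak are not
simulated (analyses of the real data are implicitly leak-subtracted); the
first 1 ms of every sweep is nevertheless treated as a blanking window by
the analysis side so that imported real traces with residual transients
remain usable.

Each cell's conductance is set so that its *noiseless steady-state* peak
density equals its sampled peak-density target; the analyzed 20 ms peak
then sits ~2% below the steady-state value because inactivation already
nibbles at the 20 ms peak. The pedestal $r$ is calibrated per cell so that
the *measured* degree of inactivation of a noiseless 3 s sweep — the
estimator of Section 4 — equals the cell's nominal degree exactly, making
noiseless simulation-followed-by-analysis an identity for this statistic.

Everything is seeded: per-cell and per-sweep seeds derive deterministically
from a group master seed, and regenerating a group writes byte-identical
sweep files.

**What a green test does not establish.** The generator emulates
steady-state gating, first-order kinetics and stationary white noise. It
does not emulate rundown, series-resistance error, leak, imperfect space
clamp, capacitive transients, or voltage-dependent time constants, so
agreement of recovered effects with the presets validates the analysis
pipeline and the stated variability model — not the biology of any real
recording.

## 4. Analysis pipeline and numerical choices

* **Peak detection** (20 ms sweeps): most negative raw sample after the
  blanking window, ties to the earliest sample; outward-only traces are
  returned with a `no_inward_current` flag rather than an error.
* **Degree of inactivation** (3 s sweeps): $100(1 - I_{end}/I_{peak})$
  with $I_{end}$ the mean over the final 50 ms and $I_{peak}$ the most
  negative value of a 50 ms *running mean*. The symmetric treatment is
  deliberate: a raw single-sample extremum over 3000 samples of a slowly
  decaying noisy trace overestimates $|I_{peak}|$ by roughly
  $\sigma\sqrt{2\ln n_{eff}}$, which for the smallest-current condition
  (N283Q at 0 mV, ~70–90 pA peaks) inflates the apparent degree by ~10
  percentage points and destroys the group differences the pipeline must
  recover. Window averaging is the in-package analogue of the bandwidth
  limiting every real acquisition applies; 50 ms stays an order of
  magnitude below the shortest default $\tau_{inact}$. Cells whose
  smoothed peak stays within 3× the estimated noise SD are reported as
  unmeasurable (`measurable = FALSE`) and excluded from group means, the
  in-silico analogue of not patching an untransfected cell.
* **Boltzmann I–V fit**: unweighted least squares on the *unnormalized*
  density curve ($V_{1/2}$, $k$, $V_{rev}$ are scale-invariant, and tests
  verify fits of normalized curves agree). $G_{max}$ is profiled out by
  linear least squares, and L-BFGS-B searches the three shape parameters
  with bounds $k \in [0.5, 20]$, $V_{rev} \in [20, 90]$,
  $V_{1/2} \in [-40, 30]$ mV; initialization takes $V_{rev}$ from the
  interpolated zero crossing beyond the peak (fallback +60), $V_{1/2}$
  from the half-peak voltage on the rising limb, $k = 5$ mV. `optim` was
  chosen over `nls` because the specification requires exact recovery on
  noiseless curves and `nls`'s relative-offset criterion fails on
  zero-residual data. Non-convergence is reported (`converged = FALSE`),
  never silent, and group shift summaries count excluded fits.
* **Inactivation τ fit**: $A e^{-(t - t_{peak})/\tau} + C$ from the raw
  peak sample to the pulse end; $A$ and $C$ are linear given $\tau$, so the
  fit is a coarse log-grid bracket plus golden-section refinement in one
  dimension. A dense independent log-grid search in the tests must agree
  with the optimizer RSS within 1%.
* **Statistics**: implemented from the defining formulas. Mann-Whitney U
  enumerates all $\binom{N}{n_x}$ labelings when $N \le 12$ and the data
  are tie-free (sizes where desk-scale exactness is possible), otherwise
  uses the tie-corrected normal approximation with a 0.5 continuity
  correction; two-group Kruskal-Wallis coincides with the uncorrected
  normal approximation, which the tests check to $10^{-6}$. Dunn's post
  hoc defaults to Bonferroni adjustment (no adjustment was named in the
  source analysis; unadjusted is available). Student's t is the classic
  pooled-variance form, matching its naming. Fisher's exact test sums
  hypergeometric point probabilities not exceeding the observed one (with
  $10^{-7}$ relative slack); degenerate zero-margin tables return p = 1
  with a flag. Null calibration (type-I error within [0.03, 0.07] at
  α = 0.05 over 2000 replicates) is part of the acceptance suite.

## 5. Clinical cohort and sequon scan

The packaged episode table mirrors the nine published SLE episodes
per-record; the two excluded candidates (a radiologically confirmed
ischemic stroke and a seizure at the onset of a CNS infection) were
described only narratively, so their rows are reconstructed stand-ins
(patient ids `X1`/`X2`). The SLE rule is explicit: at least one core
symptom (focal deficit, irritability, decreased consciousness), no
alternative diagnosis, no ischemic stroke on MRI, and not a seizure at the
onset of a CNS infection; exclusion reasons take precedence. Focal deficits
are encoded as presence of paresis (three of nine episodes), matching the
published count. One published summary cell is not reproducible from the
published per-episode values: the symptom-free-interval mean/SD row
("13.0/8.4 h", range "3–24 h") disagrees with the six printed interval
values (mean 7.7 h, minimum 1 h); `episode_summary()` recomputes from the
per-episode values.

Raw per-patient laboratory values of the comparison cohort were never
published — only group means/SDs and categorical counts — so the published
group p-values are out of reach. `make_synthetic_patients()` draws numeric
variables from the published moments (normal, truncated at zero for labs;
the unreported MVRD dispersion defaults to 0.1) and assigns categorical
flags deterministically to match the published counts, giving
`compare_cohort()` a realistic 7 + 32 (+ 4 early-death, excluded) table to
exercise; its p-values are checked for sanity, not against the paper.

The sequon scanner reports all, possibly overlapping, N-X-S/T motifs with
X ≠ P at 1-based asparagine positions. `X` in a sequence is tolerated as an
ambiguity code that satisfies no motif requirement except "not proline".
In alignment columns, gaps are skipped when reading the +1/+2 context,
because the sequon is a property of the ungapped protein. Verifying that
the full human α1A sequence yields the N283 site requires the external
UniProt O00555 record and is left as a documented optional check.

## 6. Known limitations

* Group-level acceptance quantities inherit the *reported* between-cell
  variability; at the original group sizes the vehicle mean density
  (n = 27, SD ≈ 77 pA/pF) has SEM ≈ 15 pA/pF, i.e. a single simulated
  cohort can legitimately land ~10% away from the preset mean.
* The kinetic model has voltage-independent time constants within each
  long-pulse branch and a single inactivation mechanism; it is not a
  Markov-state model and makes no claim about mode switching, Ca²⁺- vs
  voltage-dependent inactivation, or temperature effects.
* Surface-expression loss is represented purely as reduced conductance
  density; trafficking of α2δ-1 is not modelled.
* The 20 ms analyzed peak underestimates the steady-state current by ~2%
  by construction; fitted $V_{1/2}$ values carry a sub-0.1 mV bias from
  the voltage dependence of that factor, far below the between-cell
  spread.
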