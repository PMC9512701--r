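---
title: "Models and methods: locally generated NTPs for single-molecule kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: locally generated NTPs for single-molecule kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lagoon)
```

This vignette documents the models implemented in `lagoon`, the parameters
that matter, the choices made where the design was genuinely open, and what
the synthetic-data tests do and do not demonstrate about real data.

## 1. Uncaging chemistry

Free NTP concentration `A(x, t)` obeys

$$\frac{\partial A}{\partial t} = D\nabla^2 A + k_{unc}(x,t)\,C
  - \frac{V_{max} A}{K_m + A},$$

where `C` is the caged-nucleotide concentration, `k_unc` the first-order
photolysis rate constant and the last term Michaelis–Menten consumption by
the scavenger enzyme.

**Photolysis.** `k_unc = ln(10)·ε·Φ·I·λ/(N_A h c)`: the decadic molar
absorptivity ε (M⁻¹cm⁻¹) converted to a per-molecule cross-section, times
the photon flux at power density `I` (W cm⁻²) and wavelength λ, times the
photolysis quantum yield Φ. The rate is strictly linear in `I`, which is
the basis of using laser power as a concentration dial. ε and Φ of
nitrophenyl-type cages are not precisely transferable between buffers and
instruments, and in objective- or prism-type TIRF only a thin evanescent
layer is illuminated while the released nucleotide equilibrates over the
full chamber depth. The `photolysis_params()` defaults (ε = 4000 M⁻¹cm⁻¹,
Φ = 0.07) are therefore explicit placeholders, and an `efficiency` factor
absorbs the geometry. The package treats the pair as a single calibration
constant: `calibrate_photolysis()` sets `efficiency` so that a stated
operating point is met. Throughout the package that anchor is **40 µM
effective free ATP under continuous 5 W cm⁻² uncaging of a 2 mM caged-ATP
reservoir against 10 U ml⁻¹ hexokinase**, the operating point of the
continuous-uncaging titration assay.

**Scavenger.** One enzyme unit converts 1 µmol min⁻¹ at saturation, so
activity `a` (U ml⁻¹) gives `Vmax = 16.7·a` µM s⁻¹; `Km` defaults to
120 µM (hexokinase·ATP, glucose saturating at 10% w/v). A `linearized`
mode replaces the Michaelis–Menten term with `k_scav·A`,
`k_scav = Vmax/Km`, which admits closed forms used as test oracles:
steady state `A_ss = k_unc C / k_scav`, post-pulse decay `e^{-k_scav t}`,
and the spatial decay length `L = sqrt(D Km / Vmax)` outside a wide spot.

**Reservoir.** The caged pool (2–10 mM) exceeds the µM-scale free
nucleotide by three orders of magnitude, so depletion is negligible and the
default holds `C` constant. A closed mode (`reservoir = FALSE`) tracks
caged + free + consumed for mass-balance verification (relative tolerance
10⁻⁶ in the tests).

**Numerics.** Method of lines; second-order central differences in space;
`deSolve::lsoda` (adaptive, stiff-capable) in time, integrated piecewise
over constant-illumination segments so pulse edges are exact breakpoints
rather than stiff discontinuities. The outer spatial boundary is a
far-field sink (free NTP fixed at zero), with a reflecting option used to
verify that uniform illumination reproduces the well-mixed solution. Grid
pre-checks refuse spacings coarser than `L/10` and domains shorter than
five decay lengths beyond the spot. Pulsed 0-D runs must resolve the pulse
with at least 20 output points. Coordinates are spot-centred in µm with
the spot edge at ±width/2; units are µm, s, µM, W cm⁻² everywhere.

**Open question.** Whether the original simulations of this chemistry
included caged-compound diffusion or depletion is not documented; both are
omitted here (constant reservoir) and only the closed 0-D mode tracks
depletion. No claim of equation-level fidelity to any external code is
made.

## 2. Stochastic turnover

**Remodeler stepping.** Productive ATP binding is an inhomogeneous Poisson
process with rate `k_on·[A](t)`, *gated*: while a hydrolysis cycle is in
progress a further binding is non-productive and discarded. Each cycle
completes after a drawn hydrolysis time (default uniform on 0.2–0.6 s, the
reported range of mean hydrolysis times for the Chd1 remodeler;
exponential and fixed alternatives are selectable) and advances the FRET
state by one elementary step (default 0.1). A processivity cap (default 6
steps) ends the monotone FRET-increase phase, after which the acceptor
passes the donor in the real assay and analysis stops anyway. Sampling uses
batch thinning (candidates from the bounding homogeneous process, kept with
probability `λ(t)/λ_max`) followed by a gating walk, and is exactly
reproducible under a seed.

Gating is a modelling choice: it is the simplest mechanism consistent with
a bimodal first-step histogram, because it forbids bursts of arbitrarily
many near-simultaneous turnovers. Under gating and a ≥ 200 ms cycle time,
two completions can never fall into one camera frame at ordinary frame
rates; compound (double-size) steps instead arise when the residual ATP
left after a pulse supports a *second full cycle* whose completion lands
closer to the first than the detector's temporal resolution. Both routes
the data could reflect — same-frame merging and residual-ATP second cycles
— are thus present in the model, and the simulator merges same-frame
completions in its emitted state paths as well.

**`k_on` calibration.** The binding rate is not identifiable from printed
numbers, so it is calibrated: `calibrate_k_on()` bisects `k_on` until the
90-ms reference condition yields one completed turnover per pulse on
average, evaluated on the *first* pulse cycle (the processivity cap binds
later cycles). That is the operating definition of "processive with
predominantly single steps".

**Single-turnover study conditions** (`single_turnover_conditions()`):
100 W cm⁻² pulses on a 10 mM caged reservoir, 8-s period, 8 pulses, an 8-s
dark baseline before the first pulse (so the pre-step plateau is
observable, as in recorded traces), and scavenger activity 50 U ml⁻¹. The
activity is the one genuinely free condition: it is sized so that the free
ATP of a 90-ms pulse (~340 µM peak) is consumed within ≈ 0.4 s — one
hydrolysis time. That is the design point of the regime: ATP must persist
long enough to permit binding, but be gone before a second cycle can
start. Much weaker scavenging (e.g. the 1 U ml⁻¹ used for continuous
sliding assays) leaves ATP for longer than the pulse period and no
single-turnover regime exists at any pulse duration. Under these
conditions a 180-ms pulse doubles the dose, the residue outlives the first
cycle, and second cycles — hence compound steps — become frequent, while
90 ms and 30 ms stay predominantly single; this is the behaviour the
acceptance script quantifies.

**Helicase unwinding.** Each molecule waits exponentially for onset with
hazard `k_init·[A]/(Km+[A])`, then progresses at speed
`vmax·[A]/(Km+[A])` (fraction of duplex per second) times a per-molecule
log-normal factor with mean 1 (default CV 0.3, representing molecule-to-
molecule heterogeneity); completion loses the donor-labelled strand. At
`[A] = Km` the mean speed is `vmax/2`, which the tests verify against the
simulation.

## 3. Synthetic traces

The three-channel forward model per frame:

* `I_DD = γ_D (1−E) I_tot` (donor excitation, donor emission),
* `I_DA = E·I_tot + β·I_DD + α·I_AA` (sensitised acceptor emission plus
  donor bleedthrough β and direct excitation α),
* `I_AA` — direct-excitation acceptor signal, recorded every
  `aa_interleave` frames (default 10) and carried forward between
  measurements.

Photobleaching times are exponential with configurable half-lives
(defaults 180 s donor / 90 s acceptor, the values measured at 10 W cm⁻²
uncaging light). After donor bleach or donor-strand loss the donor-excited
channels fall to the noise floor while `I_AA` persists; after acceptor
bleach the donor de-quenches and both acceptor signals disappear. Noise is
additive Gaussian per channel — a deliberate simplification of EMCCD
statistics (no gain register, offset or shot-noise scaling), sufficient for
exercising detectors but not for photon-budget questions. Unwinding-type
traces interpolate FRET linearly from `E_high` to `E_low` over the
unwinding interval; the true trajectory shape in the real assay is not
established, so linearity is a declared stand-in. AFS traces are
`baseline − bp(t)·rise_per_bp + drift + noise` with elongation confined to
uncaging windows.

What passing tests show: the analysis stack inverts this forward model
exactly in the noiseless limit and recovers its parameters under noise.
What they cannot show: robustness to non-Gaussian camera noise, baseline
drift in FRET channels, triplet blinking, or heterogeneous labelling —
real-data effects outside the generator.

## 4. Trace analysis

**Corrections.** `acceptor' = I_DA − β I_DD − α I_AA`, `donor' = γ I_DD`,
`E = acceptor'/(acceptor'+donor')`, clamped to [−0.1, 1.1] with
out-of-range frames flagged; frames whose corrected total falls below a
noise floor (default a quarter of the median total) are masked, not
errored — that is how donor-strand loss is detected downstream.

**Step detection.** Greedy chi-square change-point placement: each round
adds the single split that most reduces the residual sum of squares
(ties → earliest index), subject to a minimum plateau of `min_size`
samples (default 3 — the detector's full temporal resolution; two true
steps closer than this merge into one detected step, which is precisely
how compound steps manifest). Candidate step counts `k` are scored by the
ratio of the chi-square of a *counter-fit* (change points at the plateaus'
midpoints, where genuine steps are least likely) to the fit's chi-square;
the best `k` is accepted when the ratio exceeds `acceptance_threshold`
(default 1.6, set so that flat Gaussian traces yield steps in < 5% of
cases — verified in the tests at lengths 150 and 600). Accepted steps are
then pruned weakest-first while any step is smaller than 3.5 standard
errors of the flanking plateau difference, which removes noise-ridden
spurious steps without touching genuine ones.

**First steps and the mixture.** Only the initial monotone FRET-increase
phase is analysed (each fit is truncated at its first negative step);
plateaus flanking a qualifying first step must span ≥ 5 frames — the
automated replacement for manual plateau selection. The first-step sample
is decomposed into two Gaussian components by maximum-likelihood EM
(default), with deterministic multi-starts (density peaks, k-means,
quartiles) plus random restarts, a width floor of one fifth of the sample
SD and rejection of low-weight spike solutions — the classical mixture
degeneracies. For the shorter-pulse conditions the second component's
centre and width are fixed to the reference (longest-pulse) fit and only
the weight is free. A histogram least-squares mode reproduces the
published form of such fits; EM on raw sizes is the package default.

**Rates and maps.** The unwinding rate is the reciprocal of the transit
from departure below `E_high − δ` (δ = 0.1, configurable) to donor-strand
loss, with the departure extrapolated back to the `E_high` crossing by the
local decay slope so the transit equals the unwinding interval for a
steady decay. Aggregates are unweighted means ± s.e.m. over molecules.
The power→concentration map matches rates by monotone interpolation on a
reference titration and refuses extrapolation. Unwound/intact
classification thresholds the late-window `mean(I_DA)/mean(I_AA)` ratio at
the Otsu point of the pooled log-ratios; the windows (first/last 20
frames) are a declared choice, as the original windows are unstated. AFS
traces are smoothed by a 10-s running median followed by Savitzky–Golay
(3-s window, order 3), and elongation rates are slopes over consecutive
6.25-s windows within ±30 s of each uncaging switch-on.

## 5. Problem sizes and runtimes

The test suite and the acceptance script run simulations sized for a
single CPU: 500 traces per pulse-duration condition (8 pulses, 72 s at
5 Hz), 200–1000 molecules per titration point, 2000 traces for bleaching
statistics, 100–400 staircases for detector scoring. These sizes give
Monte-Carlo standard errors comfortably inside the tolerances asserted and
keep a full run in tens of seconds; they are stated here as the package's
chosen study sizes.

## 6. Known limitations

* The photolysis constants are calibration parameters, not measurements;
  absolute concentrations inherit the anchor's uncertainty.
* The spatial solver has no flow and rectangular-spot illumination only;
  evanescent-field optics are outside scope.
* Gated binding is an assumption; real remodelers may queue or
  cooperatively bind nucleotide.
* The Gaussian-noise camera model understates heavy-tailed EMCCD noise.
* The step detector is a same-spirit re-implementation of iterative
  chi-square/counter-fit detection, not a bit-exact reproduction of any
  published code.
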