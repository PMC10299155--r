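---
title: "Methods: models, estimators and design choices in smg4"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in smg4}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the estimators applied to
it, the numerical choices, and the places where the design was genuinely
open and a decision had to be made. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The binding model and what the generator emulates

A surface-tethered G-quadruplex is visited by labeled protein; the
fluorescence at its diffraction-limited spot switches between a dark
unbound level and one or two bright bound levels. `binding_model()`
describes this as a continuous-time Markov chain (CTMC) with first-order
rate constants: for two states, unbound→bound at the observed association
rate `v_plus1` (s⁻¹, proportional to labeled-protein concentration) and
bound→unbound at `k_off` (s⁻¹, concentration independent). Dwell times in
each state are exponential.

`simulate_trajectory()` samples the CTMC exactly (exponential waiting
times), then imposes the observation process of a real experiment:

* **Pre-injection baseline.** The first `pre_frames` frames (default 300,
  i.e. 30 s at the default 100 ms frame interval) precede protein
  injection; the molecule is held unbound. Downstream QC removes these
  frames from the analysis segment, which is also where it estimates the
  baseline.
* **Camera integration.** A frame spanning a transition reports the
  occupancy-weighted average of the state intensities, not the state at
  the frame start. This deliberately produces single-frame intermediate
  values ("blur" frames) that QC and idealization must tolerate — it is
  the main way the generator stresses the estimators, and it has visible
  consequences (Section 3).
* **Noise.** Additive Gaussian read noise; the default SD is one fifth of
  the smallest state separation (signal-to-noise 5, a typical usable
  smTIRFM trace). Intensity units are arbitrary (default levels 100 and
  600 AU); no published trace SNR or AU scale exists, so these are
  conventions and fully configurable.
* **Photobleaching.** Optional exponential bleaching time (`bleach_rate`,
  default 0); after bleaching the trace reports baseline fluorescence.

The ground truth carries both the exact CTMC dwells and the
frame-discretized path (majority-occupancy state per frame), so
missed-event bias can be quantified: a dwell shorter than about half a
frame can vanish from the discretized path, merging its neighbours.

What the generator does **not** emulate: photon (Poisson/EMCCD) noise
statistics, evanescent-field depth, drift, spectral cross-talk in the
binding channel, or non-stationary rates. Passing tests therefore show
estimator correctness under Gaussian noise and ideal stationarity, not
robustness to every instrumental artifact of a real microscope.

`simulate_movie()` renders trajectories as pixel-integrated 2-D Gaussian
PSFs on a constant background with shot-like Gaussian noise (SD
proportional to the square root of the clean pixel value), for testing
spot detection and extraction; `simulate_fret_traces()`,
`simulate_mp_events()` and `simulate_emsa()` generate the companion
assays (Sections 5–7).

## 2. Trajectory selection (QC)

`qc_select()` applies the standard selection criteria for
injection-style binding experiments: no above-baseline excursion of at
least `min_event_frames` (default 3) frames before injection; a
post-injection baseline (median of sub-threshold frames) within
`drift_tolerance` (default 2) baseline SDs of the pre-injection median;
and at least `min_events` (default 2) events persisting
`min_event_frames` frames after injection. The event threshold is
`baseline_mean + event_sigmas * baseline_sd` with `event_sigmas = 3` by
default — the literature states only "above the baseline", so the
threshold is explicit, configurable and recorded in every report.
Frame indexing is 0-based with a half-open injection boundary: frames
`[0, pre_frames)` are pre-injection. All decisions are invariant to a
constant intensity offset (a property-tested guarantee).

## 3. Idealization: pooled Gaussian HMM

All QC-passing analysis segments of an experiment are fitted
*collectively* with a single Gaussian hidden Markov model: one set of
state means and SDs, one per-frame transition matrix. The original
hierarchical variational-Bayes machinery this stands in for also pools
all molecules of an experiment; whether it normalized intensities
per-molecule is not documented, so the global emission model is our
choice, documented rather than asserted. Per-molecule scaling is out of
scope.

Numerics: Baum–Welch EM to relative log-likelihood change `< 1e-6` or
500 iterations; 5 restarts (pooled-quantile initialization first, then
k-means centers), each run for a 15-iteration burn-in with only the best
restart continued to convergence — the standard cheap-multistart scheme.
Emission SDs are floored at `1e-6` of the pooled intensity range so
noiseless traces cannot collapse the likelihood; log-space emission
handling prevents underflow in Viterbi decoding. States are always
relabeled by ascending mean, so state 0 is unbound and state 1 bound. A
state carrying less than 0.1% of the pooled frames marks the fit
degenerate (warning plus flags, never silent). The per-iteration
log-likelihood trace is kept and tested for monotonicity.

**State-count selection.** `select_model()` scores candidates (2–4
states) by BIC on the pooled log-likelihood with
`p = (K−1) + K(K−1) + 2K` parameters. BIC alone, however, over-selects
under camera integration: the blur frames of Section 1 populate the
intensity range *between* true levels, and a spurious mid-level state
gains log-likelihood proportional to the number of frames, which beats
any `log N` penalty at ensemble sizes of interest. The selection is
therefore restricted to *resolvable* candidates: no degenerate state,
and every pair of adjacent means at least `min_separation` (default 3)
pooled emission SDs apart. Blur states sit within ~2.5 SD of their
neighbours and are rejected; genuine states in usable data (4–5 SD apart
at the default SNR) are kept. If no candidate is resolvable the best
score wins outright; ties break toward fewer states. All candidate
scores, separations and flags are returned for audit.

## 4. Dwell times and rate constants

`extract_dwells()` converts maximal constant-state runs into dwells; the
first and last run of each molecule are censored (their true length is
unknown) and are excluded from fits by default. The literature is silent
on this point, so it is a documented default with the flags retained for
sensitivity analysis; dropping censored dwells mildly favours shorter
dwells when lifetimes approach the observation window, which is one
reason the acceptance conditions use windows much longer than the dwells.

`fit_exponential()` offers two routes:

* **MLE (default).** Left-truncated exponential (mixture) likelihood:
  observed dwells are at least one frame long, and by memorylessness the
  truncated MLE reduces to fitting `duration − truncation`; for one
  component the estimate is `1/(mean − truncation)` with
  SE `rate/sqrt(n)`. The truncation removes the upward bias a naive fit
  suffers on frame-limited data (demonstrated by brute-force simulation
  in the tests at 5 s⁻¹, where the naive fit is ~30% low). Two-component
  mixtures are fitted by EM with a BFGS-Hessian for standard errors;
  reported weights are post-truncation weights.
* **Histogram least squares.** Bin counts (default one frame wide, up to
  the 95th-percentile dwell) fitted with `A e^{−kt}` or a two-term sum
  via `minpack.lm::nlsLM` — the GraphPad-style analysis, kept for
  comparability.

`choose_components()` compares 1- vs 2-phase fits with a
likelihood-ratio test (MLE route, χ² with 2 df — conservative at the
boundary, which correctly favours the single phase on pure data) or the
extra-sum-of-squares F-test (histogram route), at `alpha = 0.05`.

Kinetic constants follow by arithmetic with first-order (delta-method)
error propagation: `tau = 1/k_off`,
`k_on = v_plus1 / (concentration × labeling_efficiency)`,
`Kd = k_off/k_on`; the identities hold to machine precision by
construction. `aggregate_concentration_series()` computes `k_on` per
concentration and pools by inverse variance (matching the convention of
computing it "from respective v₊₁ values" rather than one regression),
pools `k_off` the same way, tests the required flatness of `k_off`
versus concentration (weighted regression; slope `p < 0.01` flags a
model violation) and checks that `v_plus1` grows monotonically. For
three-state selections a single bound-state `k_off/tau/Kd` is undefined
and is reported `NA`, association quantities only.

Reference values for four protein variants against three quadruplexes
ship in `g4p_reference_kinetics()`, including flags for the rows whose
printed `tau` and `Kd` reproduce the identities at printed precision
(two printed entries do not, consistent with rounding of unprinted
intermediates; consistency checks skip them).

## 5. smFRET histograms

`fret_efficiency()` corrects the acceptor channel for donor
bleed-through, `A' = A − leakage·D`, then computes `E = A'/(A'+D)`
clamped to `[0,1]`; frames with non-positive total are excluded and
counted, and the clamped fraction is reported as a QC metric. No
universal leakage value exists (it is an instrument property); the
default 0.10 is deliberate, mandatory to confirm in configs, and
recorded in outputs. The generator adds leakage before noise so the
correction inverts it exactly in the noiseless limit — a tested
identity. The histogram unit is the per-molecule mean efficiency
(matching per-molecule binning practice; per-frame pooling is
available), binned at exactly 0.01 on `[0,1]` (left-closed bins) and
fitted with a non-negative double Gaussian; a failed fit falls back to a
flagged single Gaussian, and a degenerate histogram (single occupied
bin) to a moment estimate. `compare_conditions()` reports component-mean
shifts with propagated SEs plus a two-sample KS test on per-molecule
means; "no change" requires shifts under 0.05 and KS `p > 0.01`, both
configurable and echoed in the result. Gamma correction and acceptor
direct excitation are out of scope (static population histograms only).

## 6. Mass photometry

`mp_calibrate()` fits the contrast→mass line through protein standards
(e.g. 56/112/224/670 kDa) by OLS and must round-trip its own standards.
`fit_mass_histogram()` bins events of the chosen sign at exactly 3 kDa
and fits a multi-Gaussian by least squares; the component count is fixed
or chosen by a BIC sweep evaluated on the *event-level* mixture
likelihood, so components that merely chase bin noise are penalized
away. Landing/departure events mirror each other by construction when
`include_negatives` is set; positives are analyzed by default and both
signs are available. `assign_stoichiometry()` searches integer
combinations `a·protein + b·DNA` (bounds 6 and 4, tolerance 4 kDa ≈ one
bin plus fit error); unassigned components are a valid outcome for
network-like species. Raw interferometric movie processing is instrument
software and out of scope — the pipeline starts at event lists.

## 7. EMSA and labeling efficiency

`fit_isotherm()` fits `f = [P]^n/(Kd^n + [P]^n)` by nonlinear least
squares (`n` fixed at 1 for the single-site hyperbola, free for the Hill
variant); a Kd outside the titration range is flagged as extrapolated.
Supershifted species are assumed pooled into "bound" upstream; gel
densitometry itself is out of scope, inputs begin at quantified
fractions. `labeling_efficiency()` is Beer–Lambert arithmetic with an
optional dye 280 nm correction factor (default 0, as the plain protocol
reads; ~0.08 is conventional for Cy3), path-length invariant by
construction. Extinction coefficients are required user inputs — none
are published for these protein variants.

## 8. Pipeline, reproducibility, problem sizes

`run_pipeline()` executes simulate → QC → idealize → dwell → kinetics
(plus the side assays) from one merged config; one global seed expands
into fixed per-stage, per-condition streams, every threshold appears in
the emitted `manifest.json`, and no timestamps are written, so identical
config + seed yields byte-identical outputs (a tested property). All
generators draw from a private RNG state (`withr`), leaving the caller's
stream untouched.

The test and acceptance problem sizes are the package's own choices,
balancing estimator variance against run time: 500 molecules × 3000
frames for the headline dissociation-rate recovery; 150 molecules per
concentration at 0.25/0.5/1 nM (the exact published series
concentrations are unspecified — "pM to low nM" — so the package picks
and records its own) for association-rate recovery; 20 seeded replicates
of 30 molecules × 600 frames for state-count selection; 12-point EMSA
titrations in triplicate lanes at 2% densitometry noise, reflecting
replicate-gel practice.

## 9. Known limitations

* No missed-event correction beyond the one-frame truncation; at rates
  approaching the frame rate, merged dwells bias rates low even with
  truncation.
* Global emission model: molecule-to-molecule brightness variation is
  not modeled and would broaden fitted state SDs.
* The resolvability criterion in model selection intentionally refuses
  states closer than ~3 SD; genuinely adjacent intensity states below
  that separation are not claimed.
* Gaussian noise throughout; no Poisson/EMCCD gain model.
* Dual-channel registration is a fixed supplied translation; no drift
  correction or colocalization.
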