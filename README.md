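# smg4 — single-molecule kinetics of protein binding to G-quadruplex DNA

`smg4` implements the full analysis chain of a single-molecule TIRF
microscopy (smTIRFM) binding experiment in which a fluorescently labeled
G-quadruplex recognition protein (G4P and its expanded variants) binds and
releases individual surface-tethered G4 DNA molecules. Because such raw
data are rarely deposited, the package pairs every analysis stage with a
synthetic-data generator of known ground truth, so the whole pipeline is
testable end to end and can be used to study estimator bias (camera
discretization, censoring, missed events) under controlled conditions.

It is aimed at single-molecule biophysicists who want a reproducible,
scriptable alternative to the usual chain of IDL spot finders, MATLAB
trace pickers, hFRET/KERA and GraphPad fits.

## The model

A molecule switches between discrete fluorescence states as a
continuous-time Markov chain. For the common two-state experiment,

- unbound → bound at the observed association rate *v*₊₁ (s⁻¹), which
  grows with protein concentration,
- bound → unbound at the dissociation rate constant *k*₋₁ = *k*_off (s⁻¹),
  which is concentration independent.

Dwell times in each state are exponential; fitting the bound-state dwell
distribution gives *k*_off and the bound-state lifetime τ = 1/*k*_off,
and the unbound-state distribution gives *v*₊₁. Because only labeled
protein is visible,

&nbsp;&nbsp;&nbsp;&nbsp;*k*_on = *v*₊₁ / ([P] · labeling efficiency),
&nbsp;&nbsp;&nbsp;&nbsp;*K*_d = *k*_off / *k*_on.

The trajectory is observed through a camera: state intensities are
integrated over 100 ms frames (fractional-occupancy weighting across
transitions), Gaussian read noise is added, and the first 300 frames
precede protein injection. Idealization is a pooled Gaussian hidden
Markov model fitted by Baum–Welch EM with BIC-based state-count selection
restricted to resolvable models, followed by Viterbi decoding. Dwell
fitting uses a left-truncated exponential MLE (dwells shorter than one
frame are unobservable) with a GraphPad-style binned least-squares route
and one- vs two-phase selection by likelihood-ratio or extra-sum-of-squares
F-test.

Companion modules cover the remaining quantitative assays of such a
study: smFRET population histograms with donor-leakage correction and
double-Gaussian fits, mass-photometry calibration / 3 kDa histograms /
mixture fits / stoichiometry assignment, EMSA binding isotherms, and
Beer–Lambert dye-labeling efficiency.

## Worked example

Simulate 100 molecules at the kinetics of a tight G4 binder
(*v*₊₁ = 0.5 s⁻¹ at 1 nM labeled protein, *k*_off = 0.61 s⁻¹), then run
QC → HMM → dwells → kinetics:

```r
library(smg4)

model <- binding_model(v_plus1 = 0.5, k_off = 0.61)
ens   <- simulate_ensemble(model, 100, seed = 42)
qc    <- qc_filter(ens$trajectories)
hmm   <- fit_hmm(qc$analysis, n_states = 2, seed = 43)
dwells  <- extract_dwells(decode_ensemble(qc$analysis, hmm))
bound   <- fit_exponential(dwells, state = 1)
unbound <- fit_exponential(dwells, state = 0)
print(bound)
#> <sm_expfit> 1-component exponential (mle), 6727 dwells, truncation 0.1 s
#>   rate 0.5937 +/- 0.00724 1/s  (tau 1.68 s, weight 1)

per_conc <- data.frame(concentration = 1e-9, labeling_efficiency = 0.55,
                       v_plus1 = unbound$rates, v_plus1_se = unbound$rate_se,
                       k_off = bound$rates, k_off_se = bound$rate_se)
aggregate_concentration_series(per_conc)
#> <sm_kinetic_result> (2 states)
#>   k_on  = 8.728e+08 +/- 1.1e+07 1/(M s)   [1 concentration(s)]
#>   k_off = 0.5937 +/- 0.0072 1/s
#>   tau   = 1.684 +/- 0.021 s
#>   Kd    = 0.6802 +/- 0.012 nM
```

The fitted `k_off` (0.594 s⁻¹) recovers the simulated 0.61 s⁻¹ within a
few percent; τ and *K*_d satisfy their defining identities exactly. The
mild downward pull is the expected missed-event effect of 100 ms frames:
sub-frame unbound gaps merge adjacent bound dwells.

A whole analysis can equivalently be driven from one YAML config via
`run_pipeline()` (see `default_config()`), which writes trace TSVs, dwell
CSVs, fitted-model JSON and a manifest recording every threshold and
seed. `inst/scripts/smg4.R` is a thin shell wrapper around it.

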