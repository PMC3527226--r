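---
title: "Methods: model, estimation, identifiability and sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, estimation, identifiability and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling and statistical choices behind
`stat1ple`: the pathway model and its assumptions, the parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical methods, and the main limitations. Code chunks are shown for
orientation and are not evaluated when the vignette is built; the package
test suite and `scripts/acceptance.R` contain the executable versions of
every claim made here.

## The pathway model

IFNγ stimulation is modelled as a delay differential equation (DDE) system
with eight states: the active receptor complex `IIr`; cytoplasmic and
nuclear unphosphorylated STAT1 (`STAT1Uc`, `STAT1Un`); cytoplasmic and
nuclear phosphorylated STAT1 (`STAT1Dc`, `STAT1Dn`); the mRNAs `mSTAT1` and
`mSOCS1`; and the SOCS1 protein. The phosphorylation flux

```
v = k_phos * IIr * STAT1Uc / (1 + k_inh * SOCS1)
```

carries the SOCS1 negative feedback as a non-competitive inhibition factor.
Transcription of `mSOCS1` and `mSTAT1` is driven by nuclear phosphorylated
STAT1 with constant lags `tau_socs` and `tau_stat`, representing the delay
between promoter occupancy and the appearance of mature transcript.

Modelling assumptions, stated explicitly:

- Mass-action kinetics everywhere except the inhibition factor; no
  saturable transport or Michaelis–Menten steps.
- Receptor activation is a two-state switch with capacity `R_tot`; ligand
  is not depleted (dose enters as a constant).
- Dimerization is not resolved: "phosphorylated STAT1" lumps monomer and
  dimer; import of phosphorylated STAT1 is first-order in `STAT1Dc`.
- Phosphorylated STAT1 leaves the cytoplasm only by nuclear import and
  leaves the nucleus only after dephosphorylation; there is no nuclear
  export of the phosphorylated form and no cytoplasmic phosphatase.
- STAT1 is degraded (`d_stat`) and resynthesized (translation from
  `mSTAT1`, with basal transcription `b_m_stat`), so total STAT1 is not
  conserved over the 9-hour window.
- For `t < 0` the system sits in the basal steady state obtained at dose 0;
  the delayed terms use that history. `consistent_initial_stat1()` places
  the free initial conditions `stat1_uc0`, `stat1_un0` on that steady
  state so simulations start from equilibrium.

## Parameters, units, defaults

Time is in minutes, the dose in ng/ml, concentrations in arbitrary units
(a.u.) — the natural scale of immunoblot data, which motivates the explicit
scaling factors. The 25 parameters of `pathway_parameters()`:

| Parameter | Unit | PSC_like | PC_like | Role |
|---|---|---|---|---|
| `k_act` | 1/(min·ng/ml) | 0.01 | 5e-4 | receptor activation |
| `k_inact` | 1/min | 0.01 | — | receptor inactivation |
| `R_tot` | a.u. | 1 | — | receptor capacity |
| `k_phos` | 1/(min·a.u.) | 1 | — | STAT1 phosphorylation |
| `k_inh` | 1/a.u. | 2 | — | SOCS1 inhibition strength |
| `k_impD` | 1/min | 0.05 | 0.004 | nuclear import, phospho-STAT1 |
| `k_impU` | 1/min | 0.01 | 0.02 | nuclear import, unphospho-STAT1 |
| `k_exp` | 1/min | 0.017 | 0.06 | nuclear export, unphospho-STAT1 |
| `k_deph` | 1/min | 0.05 | — | nuclear dephosphorylation |
| `k_tc_socs` | 1/min | 0.01 | — | SOCS1 transcription |
| `d_m_socs` | 1/min | 0.03 | — | mSOCS1 decay |
| `k_tl_socs` | 1/min | 0.05 | — | SOCS1 translation |
| `d_socs` | 1/min | 0.02 | — | SOCS1 decay |
| `b_m_stat` | a.u./min | 0.02 | — | basal STAT1 transcription |
| `k_tc_stat` | 1/min | 0.005 | — | induced STAT1 transcription |
| `d_m_stat` | 1/min | 0.02 | — | mSTAT1 decay |
| `k_tl_stat` | 1/min | 0.01 | — | STAT1 translation |
| `d_stat` | 1/min | 0.001 | — | STAT1 degradation |
| `tau_socs` | min | 20 | — | SOCS1 transcriptional delay |
| `tau_stat` | min | 60 | — | STAT1 transcriptional delay |
| `s_pstat`, `s_stat`, `s_socs` | — | 1 | — | readout scaling factors |
| `stat1_uc0`, `stat1_un0` | a.u. | derived | derived | basal initial STAT1 |

"—" means the `PC_like` preset inherits the `PSC_like` value. The presets
are package design choices, constructed so that the two regimes differ
where the biology says they should: receptor activation 20-fold and
phospho-STAT1 nuclear import 12.5-fold higher in the stellate-cell preset,
nuclear dephosphorylation balancing nuclear import in stellate cells
(`k_deph/k_impD = 1`), a peak total-STAT1 nuclear:cytoplasmic ratio of
about 3.5 in the stellate regime versus below 0.5 in the cancer regime,
and transcriptional delays of tens of minutes, consistent with the
timescale of measured SOCS1 induction. They are the default study
conditions of the generator and are deliberately never adjusted to make a
downstream statistic come out one way or another.

## What the synthetic-data generator emulates

`sampling_design()` + `generate_dataset()` emulate a sparse wet-lab
time-course campaign: a dozen time points over 0–540 min, five readouts
(phospho-STAT1 and total STAT1 immunoblot signals, SOCS1 qPCR, and the two
nuclear:cytoplasmic ratios from imaging), additive Gaussian noise with a
per-record standard deviation, and a sigma rule of 10% of the observable's
dynamic range with a floor of 5% when no explicit sigma is given. Ratios
are undefined where their denominator vanishes; the generator refuses
designs that sample an undefined ratio rather than silently dropping
records.

It does **not** emulate: blot saturation or background subtraction,
replicate-correlated (gel-level) errors, log-normal noise, cell-to-cell
heterogeneity, detection limits, or dose–response designs beyond a scalar
dose per record. Noise is independent across records by construction, which
is exactly the assumption behind the chi-squared cost.

## Estimation

`fit_model()` minimizes the chi-squared cost (sum of squared
sigma-normalized residuals) with a multistart hybrid: uniform starts in a
log10-bounded box, a simulated-annealing stage (Metropolis acceptance,
geometric cooling, bound-reflected Gaussian proposals) for the global
search, and `stats::nlminb()` for the local refinement. Positive rate
constants are optimized in log10 space because plausible ranges span
orders of magnitude; the delays are walked linearly (a delay of zero is
meaningful). Failed integrations contribute a large finite cost so a
restart survives excursions into non-integrable corners. All schedule
constants live in `fit_settings()`, not in code, and every restart derives
its random stream from the single settings seed, so fits are exactly
reproducible.

## Identifiability

`profile_likelihood()` re-minimizes all other free parameters at each value
of the profiled one, walking adaptively from the optimum: the step targets
a fixed chi-squared increment, is clamped per step, backs off when a single
step would overshoot the threshold, and warm-starts each re-minimization
from the neighbouring grid point with a small cold multistart as fallback.
If a better optimum is discovered along the way the profile re-anchors and
restarts. Confidence intervals are read off by linear interpolation of the
threshold crossing; a side that never crosses within the parameter bounds
is reported as the explored endpoint with an `unbounded` flag — never an
extrapolated number. Pointwise and simultaneous intervals differ only in
the chi-squared threshold (`ci_threshold(alpha, 1)` versus df = number of
free parameters). `classify_profile()` distinguishes identifiable,
practically nonidentifiable (rising profile, unbounded CI on at least one
side), and structurally nonidentifiable (profile flat to within 1% of the
threshold over the whole explored range); `profile_correlation()` exposes
parameter couplings along the profile, with slope −1 on the log-log scale
as the signature of a pure product redundancy.

## Overfitting and effective degrees of freedom

`overfit_samples()` draws datasets with the same design and noise model but
randomized values (parametric bootstrap per record), refits each, and
evaluates the refitted parameters against the *original* data; the excess
over the best-fit chi-squared is the overfitting statistic.
`effective_dof()` selects the chi-squared law closest to the empirical
distribution in Kolmogorov–Smirnov distance; ties resolve to the smaller
degrees of freedom and a distribution collapsed near zero is flagged as
degenerate. `confidence_level()` converts a threshold back into a realized
confidence level under the selected law.

## Sensitivity analysis

`mcc()` computes time-dependent metabolic control coefficients —
the relative state response to a relative parameter perturbation,
`C(t) = (Δx/x)/δ` with a one-sided −1% perturbation by default — masking
times where the reference value is numerically zero. Two independent
validations are built in: closed-form cases (a scaling factor has
coefficient exactly 1 for its own readout; a pure-decay subsystem has
`C(t) = −k·t`), and `forward_sensitivity_mcc()`, which integrates the
forward sensitivity DDEs (including the lagged channels) and must agree
with the finite differences wherever the coefficient is appreciable.
`mcc_band()` and `trajectory_band()` propagate profile-likelihood
uncertainty into envelopes over parameter sets spaced along the in-CI
portion of a profile. `inhibition_sim()` simulates finite (e.g. 50%)
parameter inhibition for comparison with the infinitesimal coefficients.

## Numerical choices

- Integration: `deSolve::dede` (`lsoda` by default) with `rtol = 1e-8`,
  `atol = 1e-10`; the constant-lag history is the basal steady state.
- Delay cross-check: a linear-chain approximation (`method = "linchain"`,
  default order 20) replaces each lag by a cascade of first-order stages —
  an independent discretization that bounds delay-handling errors.
- Small negative values from integrator roundoff (below `1e-8` of the
  state scale) are clamped to zero; anything larger aborts the simulation.
- Finite-difference gradients near an optimum are only as good as the
  integrator noise floor; workflows that need tight convergence (e.g.
  recovering a noise-free optimum) should pass
  `sim_args = list(rtol = 1e-10, atol = 1e-12)`.
- Serialization uses full precision (`digits = NA` JSON, `%.17g` CSV) so
  a rerun of `run_workflow()` with the same configuration produces
  bit-identical files, verified by MD5 hashes in the manifest.

## Design rationale

The estimation, profiling and overfitting machinery is generic over a
`prediction_model` interface rather than hard-wired to the pathway. This
keeps closed-form models (a line, a product) available as analytic
references for the statistical layer — the test suite exercises the same
code paths on models whose profiles and confidence intervals are known
exactly — and makes the pathway model one plug-in among several. Problem
sizes in the shipped examples (restart counts, profile step limits,
bootstrap sample counts) are chosen for desk-scale runtimes and are
arguments, not constants.

## Limitations

- Constant lags are a coarse model of transcriptional delay; distributed
  delays would change early mRNA kinetics.
- The observation model is linear in the states; saturating readouts are
  not represented.
- Profile-based bands explore one profiled parameter (plus its co-fitted
  partners) at a time; they are not joint credible bands.
- The overfitting analysis assumes the noise model used for randomization
  is the true one.
- With the shipped presets, nuclear import of phosphorylated STAT1 is
  rate-limiting in the `PC_like` regime, so the pathway output is
  sensitive to that parameter there; conclusions about import robustness
  are preset-dependent.
- Parameter estimation is frequentist throughout; no priors, no posterior.
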