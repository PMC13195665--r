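---
title: "Kinetics from time-resolved native MS: models, calibration and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics from time-resolved native MS: models, calibration and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetakin)
```

## The measurement this package models

Dual-channel ("theta") electrospray emitters mix two solutions at the
Taylor cone microseconds to seconds before ionisation, so each native mass
spectrum is a snapshot of a binding reaction at some unknown reaction time
("droplet lifetime"). Toggling the spray voltage produces *bursts* of
spectra whose mixing times drift from tens of seconds (partial premixing
at the tip) down toward sub-second, covering roughly 0–40 s in a couple of
minutes of acquisition.

Two problems stand between those spectra and rate constants:

1. **The mixing time of each spectrum is unknown.** It is calibrated with
   an internal-standard *timer*: a nanobody–epitope pair with
   independently known kinetics sprayed alongside the analyte. The
   observed bound fraction of the timer, placed on the timer's theoretical
   binding curve, dates the spectrum.
2. **The two channels need not mix 1:1.** A *mixing factor*
   $\alpha \in (0,1)$ gives the fraction of the droplet contributed by the
   protein channel, so post-mixing initial concentrations are
   $[P]_0 = \alpha\,[P]_\mathrm{total}$ and
   $[L]_0 = (1-\alpha)\,[L]_\mathrm{total}$. Ideal mixing is
   $\alpha = 0.5$; real emitters deviate, and deviate differently from
   burst to burst, so $\alpha$ is estimated per burst inside the fit.

## The 1:1 kinetic model

For a protein P binding one partner L,

$$\frac{d[PL]}{dt} = k_\mathrm{on}[P][L] - k_\mathrm{off}[PL],
\qquad K_D = \frac{k_\mathrm{off}}{k_\mathrm{on}},$$

with mass balance $[P] = [P]_0 - [PL]$, $[L] = [L]_0 - [PL]$ and
$[PL](0) = 0$. This Riccati equation has a closed-form solution: with
$r_1 \le r_2$ the roots of $C^2 - ([P]_0+[L]_0+K_D)\,C + [P]_0[L]_0$,

$$[PL](t) = \frac{r_1 r_2\left(1 - e^{-k t}\right)}
                 {r_2 - r_1 e^{-k t}},
\qquad k = k_\mathrm{on}(r_2 - r_1).$$

`closed_form_complex()` is the package's default evaluation path; it costs
one `exp` per point, which matters inside an iterative fit.
`integrate_ode()` (deSolve/lsoda) solves the same equation numerically and
is kept as an independent route and as the natural extension point for
multi-site models. Numerical choices:

* The quadratic roots are computed in the cancellation-free form
  $r_1 = [P]_0[L]_0 / r_2$.
* Irreversible binding is the $K_D = 0$ limit of the same expression. When
  additionally $|[P]_0 - [L]_0| < 10^{-9}\max([P]_0,[L]_0)$ the roots
  coalesce and the degenerate second-order branch
  $[PL](t) = [P]_0^2 k_\mathrm{on} t / (1 + [P]_0 k_\mathrm{on} t)$ is
  used to avoid catastrophic cancellation.
* The ODE state is integrated in units of $\min([P]_0, [L]_0)$ at
  rtol $10^{-10}$ / atol $10^{-12}$, so accuracy stays *relative* to the
  reachable concentration even for weakly bound systems; the two routes
  agree to ~$10^{-7}$ relative over wide random parameter draws.
* All concentrations are molar throughout; no unit inference is done on
  input files.

## Timer calibration and time inversion

`build_curve(timer, alpha)` produces the timer's bound-fraction curve
$f(t) = [PL](t)/[P]_0$ under a given $\alpha$; `invert_time()` maps an
observed timer fraction back to a droplet lifetime. Because the 1:1 curve
has an exact algebraic inverse, inversion is analytic (and vectorised) by
default; a bracketed root-finding route (geometric bracket expansion +
Brent) is provided for arbitrary monotone evaluators and doubles as an
independent cross-check in the test suite.

A spectrum whose timer fraction is within 1% of the equilibrium plateau
(`eps = 0.01`) has *equilibrated*: its time is unresolvable, and it is
excluded rather than assigned a capped time, which would bias fits toward
long times. `sensitivity_window()` reports where a timer is actually
informative — by default the times at which the curve passes 5% and 95% of
its plateau. Timers with unmeasurably slow dissociation (ALFA-tag-like)
are supported via `koff = 0`.

## The global fit

For burst $b$ with mixing factor $\alpha_b$ and spectrum $i$, the
objective is

$$\sum_{b}\sum_{i \in b}
  \left(f^\mathrm{obs}_{bi} -
        f^\mathrm{model}\!\left(t_{bi}(\alpha_b);\,
        k_\mathrm{on}, k_\mathrm{off}, \alpha_b\right)\right)^2,$$

where $f^\mathrm{obs}$ are analyte bound fractions and
$t_{bi}(\alpha_b)$ is re-inverted from the timer margin at the *current*
$\alpha_b$ on every objective evaluation — the mixing factor moves both
the calibration curve and the model's initial concentrations. Residuals
are on dimensionless fractions rather than concentrations, which removes
total-concentration scale errors from the objective.

Implementation choices:

* **Optimiser.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) over
  $(\log_{10} k_\mathrm{on}, \log_{10} k_\mathrm{off}, \alpha_1 \ldots)$,
  with bounds $k_\mathrm{on} \in [10^2, 10^{10}]$,
  $k_\mathrm{off} \in [10^{-6}, 10^3]$, $\alpha \in [0.05, 0.95]$.
* **Multi-start.** A deterministic $3 \times 2$ grid
  ($k_\mathrm{on} \in \{10^4, 10^5, 10^6\}$,
  $k_\mathrm{off} \in \{10^{-3}, 10^{-1}\}$, $\alpha = 0.5$); the best
  final RSS wins. Fits are exactly reproducible.
* **Equilibrated spectra** are screened once against the curve at the
  reference $\alpha = 0.5$ so the residual vector keeps a fixed length
  across iterations; inside the objective, timer fractions are capped just
  below the current-$\alpha$ plateau so the objective stays finite and
  continuous while $\alpha$ moves.
* **Uncertainties** per fit come from the Jacobian at the optimum
  (finite differences, $\sigma^2 (J^\top J)^{-1}$, delta method back to
  natural units). Headline uncertainties should instead come from
  replicate scatter via `summarize_replicates()`, which computes $K_D$ per
  replicate as that replicate's $k_\mathrm{off}/k_\mathrm{on}$ — never the
  ratio of averaged rates — and reports mean ± sample SD across emitters.
* **Irreversible ligands** (covalent inhibitors whose rate-limiting step
  is bond formation; encounter complex and adduct are isobaric) are fitted
  with `fit_irreversible()`, fixing $k_\mathrm{off} = 0$.

### Model selection and diagnostics

`compare_alpha_models()` fits one shared $\alpha$ and one $\alpha$ per
burst, seeds the larger model from the smaller one's optimum (so the
nested pair can never invert), and applies the extra-sum-of-squares
F-test

$$F = \frac{(RSS_r - RSS_f)/(p_f - p_r)}{RSS_f/(n - p_f)}$$

at the 0.05 level, reporting the statistically justified model.
`flag_outlier_bursts()` flags bursts whose RMS residual exceeds 3× the RMS
pooled over the *other* bursts. Leave-one-out pooling matters: with the
deviant burst included in the reference scale, one bad burst among five
mathematically cannot exceed $\sqrt{n/n_b} \approx 2.2$ times the pooled
RMS and would always escape a 3× rule. Flags are advisory; excluding a
burst and refitting is an explicit user action.

## Mole fractions and response factors

`mole_fractions()` turns deconvoluted per-species abundances into the
bound fractions the fit consumes, treating intensity as proportional to
concentration within a margin (reasonable when binding changes the mass by
<5%). In the *fusion* strategy one protein carries both the timer epitope
and the ligand site, so the ternary species counts as bound on both
margins. A single multiplicative *response factor* for the bound species
can correct unequal signal per mole; `estimate_response_factors()` fits it
from mixtures of known composition by least squares on
$f^\mathrm{obs} = r k / (r k + 1 - k)$. One shared factor (not
per-charge-state) is all the described calibration experiment can
identify.

## The synthetic-data generator

`simulation_config()` / `simulate_dataset()` implement the forward model:
latent times per spectrum, per-burst mixing factors, noise-free fractions
from the closed form, additive Gaussian noise clipped to
$[0, \mathrm{plateau}]$, and abundances emitted at a nominal intensity
scale. Defaults are the benchmark study conditions, chosen once:

| parameter | default | why |
|---|---|---|
| analyte $k_\mathrm{on}$, $k_\mathrm{off}$ | $1.3\times10^5$ M$^{-1}$s$^{-1}$, $1.3\times10^{-2}$ s$^{-1}$ | GFP–Nb15 benchmark regime |
| analyte channel totals | 1.6, 4 µM | 0.8 / 2 µM after ideal 2-fold dilution |
| timer | 1 µM epitope, 2 µM Nb, $3.6\times10^5$ / $9.4\times10^{-6}$ | benchmark timer pair |
| bursts × spectra | 5 × 15 | typical acquisition |
| latent times | log-uniform 0.1–40 s | observed 0–40 s span, density toward short times |
| $\alpha$ per burst | uniform 0.4–0.6 | observed departure from ideal mixing |
| noise σ | 0.02 (fractions) | typical deconvoluted-abundance scatter |

An alternative per-burst exponential-decay schedule
($t_s = t_\mathrm{max} e^{-s/\tau}$) mimics the within-burst decay of
mixing times qualitatively. The noise model is additive on fractions, not
counts — deconvoluted abundances are continuous and no counting model is
implied by the measurement. Clipping (rather than resampling) the noise at
the physical bounds puts a small point mass at the plateau; those spectra
are precisely the ones the equilibration filter removes.

What the generator does *not* emulate: raw m/z spectra, charge-state
envelopes, deconvolution artifacts, drift in spray conditions within a
burst, or mechanistic premixing at the tip. Passing recovery tests on
synthetic data therefore demonstrates the inference machinery, not the
upstream deconvolution.

## Known limitations

* **Per-burst $\alpha$ is weakly identified at realistic noise.** On
  noise-free data the fit recovers $\alpha$ exactly, but at fraction noise
  σ = 0.02 the objective is nearly flat in individual $\alpha_b$: in this
  concentration regime the timer→analyte fraction map depends on $\alpha$
  only at second order, so a burst's $\alpha$ can wander far (occasionally
  to its bounds) at negligible RSS cost. $k_\mathrm{on}$ is robust to
  this; $k_\mathrm{off}$ is partially confounded because both $\alpha$ and
  $K_D$ move the late-time plateau.
* **$k_\mathrm{off}$ carries most of the statistical risk.** With ~75
  spectra at σ = 0.02 and ligand excess $[L]_0/K_D \approx 20$ the plateau
  is high (~0.96) and weakly $K_D$-sensitive; single-dataset
  $k_\mathrm{off}$ errors of 10–30% are expected even with $\alpha$ known.
  This is why replicate-level mean ± SD, not single-fit Jacobian errors,
  is the headline uncertainty.
* **The F-test is mildly anticonservative under timer noise.** Noise in
  the timer margin becomes noise in the assigned times; its burst-level
  realisations act like small per-burst $\alpha$ perturbations that the
  full model can absorb, so the shared-$\alpha$ model is an incomplete
  null even when mixing is truly equal. With exact timer fractions the
  test holds its nominal size.
* Reaction acceleration in microdroplets, if present, cancels between
  timer and analyte only if both accelerate equally; the package inherits
  that assumption and cannot test it.

## Problem sizes used in the checks

The packaged checks run the recovery studies at 50 seeded datasets for the
reversible benchmark regime, 20 for the irreversible regime, and 200
null datasets for the F-test size, with 5 bursts × 15 spectra each —
small enough to run on a laptop in minutes, large enough for the rates
being estimated to have two meaningful digits.
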