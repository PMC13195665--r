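# thetakin

Kinetic inference for **time-resolved native mass spectrometry** with
dual-channel (theta) electrospray emitters.

## The problem

Native MS can resolve every ligand-bound state of a protein, but a
conventional emitter sprays an equilibrated solution — the kinetics are
gone before the first scan. A theta emitter mixes two solutions at the
Taylor cone so each spectrum catches the binding reaction mid-flight, at
an unknown reaction time somewhere between milliseconds and ~40 s. Two
things must then be inferred from the spectra themselves:

* the **mixing time** of each spectrum, calibrated with an
  internal-standard *timer* — a nanobody–epitope pair with independently
  known kinetics whose observed occupancy dates the droplet; and
* the **mixing factor** α of each burst of spectra — the fraction of the
  droplet contributed by the protein channel (α = 0.5 is ideal 1:1
  mixing), which sets the diluted initial concentrations
  [P]₀ = α[P]ₜₒₜ and [L]₀ = (1−α)[L]ₜₒₜ.

Given per-spectrum species abundances (from any deconvolution tool), the
package computes bound mole fractions, assigns each spectrum a time from
the timer margin, and globally fits the 1:1 model

  d[PL]/dt = k_on [P][L] − k_off [PL],  K_D = k_off / k_on

across all bursts at once, estimating k_on, k_off (or k_on alone for
irreversible/covalent ligands, k_off = 0) and one mixing factor per burst
or per emitter. A nested-model F-test decides whether per-burst mixing
factors are statistically justified; outlier bursts are flagged;
replicate fits are aggregated as mean ± SD with K_D computed per
replicate. A synthetic-data generator reproduces the whole experiment
with known ground truth so every stage is testable by parameter recovery.

## Worked example

Simulate the benchmark regime (GFP–Nb15-like analyte, k_on = 1.3×10⁵
M⁻¹s⁻¹, k_off = 1.3×10⁻² s⁻¹, timed by a NbAS-like pair), then fit:

```r
library(thetakin)

cfg <- simulation_config(seed = 2026)   # defaults = benchmark conditions
sim <- simulate_dataset(cfg)
fractions <- mole_fractions(sim$records)
fit <- fit_global(fractions, cfg$timer, p_total = 1.6e-6, l_total = 4e-6)
fit
#> Excluding 5 equilibrated spectrum/spectra (timer at plateau).
#> <kinetic_fit> model = per_burst_alpha
#>   kon  = 1.324e+05 M^-1 s^-1 (se 4.7e+03)
#>   koff = 0.01264 s^-1 (se 0.0031)
#>   KD   = 9.551e-08 M
#>   alphas: burst_01=0.604, burst_02=0.553, burst_03=0.444, burst_04=0.393, burst_05=0.529
#>   rss = 0.04026 over 70 spectra, 7 parameters
```

Five spectra were dropped because their timer margin had reached its
equilibrium plateau (no time information). The fitted constants recover
the simulation truth within a few percent for k_on and within the
expected single-dataset scatter for k_off; `K_D` here is 96 nM against a
truth of 100 nM. `tidy(fit)`, `glance(fit)` and `autoplot(fit)` give the
parameter table, one-row summary and the per-burst kinetic plot.

Model selection between shared and per-burst mixing factors:

```r
compare_alpha_models(fractions, cfg$timer, 1.6e-6, 4e-6)
#> <alpha_model_comparison>
#>   shared alpha   : rss 0.042531 (3 params)
#>   per-burst alpha: rss 0.04026 (7 params)
#>   F = 0.888 on (4, 63) df, p = 0.476 -> shared_alpha
```

(This dataset was generated with genuinely different per-burst α, but at
σ = 0.02 the F-test rightly declines to claim them from one emitter's
worth of data.)

Real data enters through the same path: a delimited table with columns
`emitter_id`, `burst_id`, `scan_index`, `species`, `abundance` read by
`read_species_table()`, plus a YAML config describing the timer and
analyte systems (`read_config()`). A thin command-line wrapper is
installed at `inst/cli/thetakin`:

```sh
thetakin simulate --config cfg.yaml --out runs/e1
thetakin fit --data runs/e1/dataset_species.tsv --config cfg.yaml \
             --model both --out runs/e1/fit
thetakin report runs/*/fit/fit_summary.yaml --out replicates.tsv
```

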