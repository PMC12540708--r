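# jnkdyn

Tools for studying how the temporal dynamics of JNK (c-Jun N-terminal
kinase) activity — sustained, transient, or pulsed — shape downstream gene
expression. The package is aimed at systems biologists analyzing
kinase-reporter imaging together with time-course RNA-seq, and at modelers
asking which gene-level parameters (mRNA stability, promoter affinity,
transcriptional delay) explain observed expression dynamics.

## What it implements

**The model.** A seven-species ODE model of the JNK → phospho-c-Jun (pJun)
→ target-gene axis with DUSP1 negative feedback, driven by a step stimulus
c(t) ∈ {0, 1}:

    d[cJun]/dt      = β_j·[cJun mRNA] − α_j·[cJun] − β_jp·[cJun]·JNK^n/(JNK^n + T^n)
    d[pJun]/dt      = β_jp·[cJun]·JNK^n/(JNK^n + T^n) − α_junp·[pJun]
    d[cJun mRNA]/dt = β_jmi + β_mj·[pJun] − α_jm·[cJun mRNA]
    d[Target]/dt    = β_t + β_tj·[pJun] − α_m·[Target]
    d[JNK]/dt       = β_jnkp·c − α_jnkp·[JNK] − α_djnkp·[JNK]·D^n/(D^n + Td^n)
    d[DUSP1 mRNA]/dt= β_md·[pJun] − α_dusp·[DUSP1 mRNA]
    d[DUSP1]/dt     = β_dusp·[DUSP1 mRNA] − α_dp·[DUSP1]

with a Hill-promoter variant replacing the target production by
β_tj·pJun^nt/(K^nt + pJun^nt) and delay variants using pJun(t − τ).

**The analyses.**

* `simulate_jnk()` — piecewise-exact integration under
  sustained/transient/pulsed stimulus programs (compiled RHS, adaptive
  solver, DDE variants), validated against an independent fixed-step
  Euler oracle;
* `sobol_indices()` — Saltelli-sampled global sensitivity analysis of
  target-gene output over the 20 documented parameter ranges;
* `scan_decay()`, `scan_decay_affinity()`, `scan_delay()`,
  `compare_models()`, `predict_cluster_halflife()` — grid-scan RMSE
  fitting of decay rates (200 values, 0.02–1.4 h⁻¹ ≙ half-lives 36 h to
  30 min), promoter affinities (200 values, 0.01–3 C_s) and delays
  (25 values, 0.01–1 h), with half-life conversion t½ = ln 2 / α_m;
* `detect_pulses()`, `activity_duration()`, `summarize_population()` —
  single-cell kinase-translocation-reporter (C/N ratio) quantification
  with the 50%-above-baseline threshold rule;
* `filter_degs()`, `cluster_genes()`, `choose_k()`, `cluster_overlap()`,
  `crossref_halflives()` — DEG filtering, min–max scaling, k-means
  clustering of expression time courses, and cross-referencing against
  published mRNA half-life tables;
* `gen_expression_profiles()`, `gen_cell_traces()`, `gen_deg_table()` —
  synthetic inputs with known ground truth for every stage.

See the methods vignette (`vignettes/jnk-dynamics-methods.Rmd`) for the
modeling assumptions, numerical choices and known limitations.

## Worked example

Simulate a short-lived target gene (30-min half-life) under pulsed
stimulation, then recover its decay rate from a noisy 5-timepoint
expression profile:

```r
library(jnkdyn)

traj <- simulate_jnk(jnk_params(alpha_m = log(2) / 0.5), make_stimulus("pulsed"))
pk <- count_peaks(traj$states[, "target_gene"], traj$times, min_prominence = 0.2)
pk$n_peaks
#> [1] 2
round(pk$peak_times, 2)
#> [1] 1.25 5.25

sp <- gen_expression_profiles("pulsed", alpha_m = log(2) / 0.5,
                              noise_sd = 0.03, seed = 7)
scan_decay(synthetic_profile(sp, 1))
#> fit surface (mass_action, 'pulsed' condition): rmse_min = 0.02617
#>   alpha_m_hat = 1.4 h^-1 (half-life 0.495 h)
```

The short-lived gene tracks both stimulus pulses (peaks near 1.25 h and
5.25 h), and the decay-rate scan recovers a half-life of 0.495 h against
the generating 0.5 h. Sensitivity analysis ranks the drivers of
target-gene variance:

```r
sobol_indices("pulsed", n_base = 250, seed = 1)
#> Sobol sensitivity of target-gene output ('pulsed' stimulus, n_base = 250)
#> summary indices (median over 16 timepoints), negative estimates clipped:
#>     parameter first_order total_order
#> 1     alpha_m     0.38102      0.3698
#> 2      beta_t     0.06234      0.1080
#> 3    alpha_jm     0.05945      0.1074
#> ...
```

The mRNA decay rate `alpha_m` carries by far the largest first-order
index: mRNA stability is the dominant determinant of expression dynamics
in this model.

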