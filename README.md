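# gspfinger

Systematic benchmarking of graph-signal-processing (GSP) features derived
from structural connectomes and regional fMRI time courses, with subject
fingerprinting as the primary yardstick.

## What it does

Treating regional brain activity as a signal on the structural connectome
graph, GSP decomposes it on *connectome harmonics* — eigenvectors of a graph
shift operator built from the connectome — and derives features that
quantify structure/function coupling. Which operator, which connectome edge
weighting, and which preprocessing to use are all unsettled choices. This
package implements a full comparative pipeline:

- **Operators & harmonics** — unnormalized (`L_U = D − A`), normalized
  (`L_N = D⁺ᐟ² L D⁺ᐟ²`) and random-walk (`L_RW = D⁺ L`) Laplacians, and the
  modularity matrix (`L_Q = A − kkᵀ/2M`), with ascending eigenvalues, a
  deterministic sign convention and a degree-weighted treatment of the
  non-symmetric `L_RW`.
- **Five feature types** over the full parameter grid — power spectral
  density `P_{t,k} = x̂²_{t,k}` and energy `E_{t,k} = λ_k x̂_{t,k}`
  (spectral domain, 128 parameter combinations each); alignment and
  liberality (low-/high-pass graph filtering `X_F = U H Uᵀ X`, the retained
  harmonics swept from 5% to 20% of R in 10 steps; 1280 combinations each);
  and the structural decoupling index `SDI = ‖X_L‖/‖X_A‖` with four cutoff
  schemes (512 combinations).
- **Six quality criteria** — robustness to acquisition settings (percentage
  of subjects whose same-day similarity falls below their across-day
  similarity, with the penalty Ω = Σ max(0, −ΔR)); head-motion sensitivity
  (variance explained by mean framewise displacement); reliability
  (ICC(A,1) from two-way ANOVA mean squares); fingerprinting accuracy
  (Hungarian one-to-one assignment on cross-session similarity);
  parsimony of the ICC-selected feature subset (selection on LR sessions,
  evaluation on the RL day pair, avoiding double dipping); and
  generalizability to parcellation changes. A min–max normalized consensus
  score ranks all candidate pipelines.
- **Pattern embedding** — cosine-distance adaptive Gaussian affinities
  between the feature vectors of all parameter combinations, averaged over
  scans and subjects and spectrally embedded into (u2, u3).
- **Synthetic cohort generator** — subject-specific connectomes around a
  community-structured group backbone (four edge-property variants of one
  latent topology), graph-smooth BOLD-like signals with subject-specific
  spectral signatures, 2-day × 2-phase-encoding session effects, and
  per-scan mean framewise displacement from a truncated normal
  (0.13 ± 0.02 mm in [0.08, 0.18]) coupled into the signals — so the whole
  benchmark runs without access-restricted data.

## Worked example

```r
library(gspfinger)

cfg <- cohort_config(seed = 7)        # 20 subjects, 60 regions, 200 frames
cohort <- generate_cohort(cfg)
print(cohort)
#> Synthetic GSP cohort: 20 subjects x 4 scans, R = 60 regions, T = 200
#>   mean FD: 0.126 +/- 0.021 mm (range 0.082-0.169)

combos <- enumerate_combinations("liberality", cfg$n_regions)
combo <- subset(combos, property == "NFD" & individuality == "individual" &
                  operator == "L_U" & zscore & !normalize & nH_pct == 0.20)
tab <- compute_feature_table(cohort, "liberality", combos = combo)
fingerprint_accuracy_pairs(tab, combo$combo_id)
#> $accuracy
#> [1] 100
#> $per_pair
#>  LR  RL
#> 100 100
```

All 20 subjects are correctly re-identified across days from their
high-frequency (structure-decoupled) signal content when subject-specific
connectomes are used; with `subject_signature_strength = 0` and
`subject_sc_jitter = 0` the same computation falls to chance (5%).

The numbered scripts under `analysis/` run the full narrative at desk scale
(6 subjects, 40 regions): `01_simulate.R` generates the cohort,
`02_features.R` sweeps all five feature grids over the three parcellation
variants, `03_embedding.R` maps combination similarity into two dimensions,
`04_quality.R` scores the six criteria, and `05_ranking.R` produces the
consensus ranking (tables under `results/analysis/`).

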