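# ssapdiv

Do the site-specific amino acid preferences (SSAP) of homologous proteins stay
put as sequences diverge, or do they drift with the genetic background? The
question decides how transferable site-specific substitution models are across
homologs — one model per fold, or one per family (or closer). `ssapdiv` is an
R package plus analysis workflow for answering it computationally, from
predicted stability effects alone: it turns per-site mutational stability
changes (ΔΔG, kcal/mol) into SSAP profiles under biophysical
stability-to-fitness models, detects per-site significant SSAP differences
between homologs with a replicate-aware exact permutation test under FDR
control, and relates those differences to structural deviation and residue
contact-network rewiring.

It is aimed at structural bioinformaticians and molecular evolution
researchers who have (or can simulate) ΔΔG tables — e.g. FoldX-style model
builds — and want a calibrated, reproducible site-level comparison of
preference profiles.

## The model in brief

For site *r* and amino acid *a*, the preference is

> π(r,a) = Pf(ΔΔG(r,a)) / Σⱼ Pf(ΔΔG(r,j))

where Pf is the folding probability under one of three models:
**threshold** Pf = e^(−ΔΔG/kT) / (1 + e^(−ΔΔG/kT)) (sigmoid, marginal
stability), **maximum** Pf = α·e^(−λΔΔG) (exponential, strong selection for
stability), **optimum** Pf = α·e^(−λΔΔG²) (Gaussian around the wildtype
stability).

Two profiles are compared site by site: replicates are simulated at a
calibrated Pearson correlation to each source profile (multinomial n = 100
plus Gaussian noise σ found by bisection), the per-site statistic is
RMSD_corrected = RMSD_between − RMSD_within of Jensen–Shannon distances
(√JSD, base 2) over replicate pairs, its null is the exact permutation
distribution over relabelings of the pooled replicates, and
Benjamini–Hochberg controls the FDR across sites at α = 0.05. On the
structural side, equivalent sites are Cα pairs within 3.5 Å after optimal
superposition; sRMSD is the mean paired Cα distance; contact rewiring at a
site is f_r = (gained + lost) / (gained + lost + conserved) contacts — one
minus the Jaccard index of its neighbor sets in the two homologs.

Everything runs at desk scale on synthetic inputs: the package ships a
generator for ΔΔG matrices with burial-dependent effect sizes, toy 3D
structures, and homolog pairs with tunable divergence, coordinate noise and
planted preference shifts, so every stage is testable without structure
databases or force-field runs.

## Worked example

```r
library(ssapdiv)

# a synthetic 56-site protein: ddG -> preferences under the threshold model
g    <- generate_ddg(synthetic_spec(n_sites = 56, seed = 1))
prof <- ddg_to_preferences(g$ddg, fitness_model_spec("threshold"))
round(prof$values[1:3, 1:6], 3)
#>          A     C     D     E     F     G
#> [1,] 0.080 0.043 0.031 0.065 0.033 0.055
#> [2,] 0.063 0.088 0.019 0.035 0.075 0.041
#> [3,] 0.066 0.078 0.082 0.007 0.029 0.024

# full pipeline on a synthetic homolog pair at 50% sequence divergence
cfg <- list(pair_id = "demo",
            synthetic = synthetic_spec(n_sites = 60, divergence_target = 0.5,
                                       coordinate_noise = 0.4),
            seed = 42)
res <- run_pair(cfg)
res
#> Pair 'demo': divergence 0.50, sRMSD 0.57 A, 9/60 sites significant (15.0%)
res$contacts
#> Contact comparison: 60 sites; totals G=60 L=30 C=106; pooled rewired fraction 0.459
```

Reading the output: at 50% sequence divergence, 9 of 60 equivalent sites
(15%) have significantly different preference profiles at a 5% FDR
(each with an exact permutation p and BH q in `res$comparison$results`), the
homolog backbones deviate by 0.57 Å on average over equivalent Cα pairs, and
46% of residue contacts were gained or lost between the homologs' contact
networks.

The numbered scripts under `analysis/` run the full study on synthetic
cohorts and write tables under `results/`: input simulation
(`01_simulate_inputs.R`), the three fitness models and burial-vs-entropy
(`02_preference_models.R`), null calibration of the test at replicate
correlation 0.60 (`03_null_calibration.R`), planted-signal power
(`04_planted_recovery.R`), the divergence-binned fraction of significant
sites with bootstrap CIs (`05_divergence_cohort.R`), and contact rewiring vs
coordinate perturbation plus network-proximity tests
(`06_contact_rewiring.R`).

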