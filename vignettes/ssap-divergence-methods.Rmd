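---
title: "Methods: stability-based amino acid preferences and their divergence between homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability-based amino acid preferences and their divergence between homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssapdiv)
```

## The problem

Site-specific amino acid preferences (SSAP) describe, for every site of a
protein, the normalized propensity of each of the 20 amino acids to occupy it.
Whether the SSAP of two homologous proteins stay essentially the same as their
sequences diverge — or drift with the changing genetic background (intragenic
epistasis) — matters directly for site-specific substitution models in
phylogenetics: conserved preferences would let one model serve a whole fold,
while background-dependent preferences demand finer-grained models and caution
when transferring experimentally derived preferences across homologs.

`ssapdiv` implements a purely computational route to this question. Starting
from tables of predicted stability effects of point mutations (ΔΔG, kcal/mol,
one value per site × amino acid, e.g. produced by a force field such as FoldX
from a crystal structure), it:

1. maps ΔΔG to a folding probability Pf under one of three biophysical
   stability-to-fitness models and normalizes per site into an SSAP profile;
2. simulates replicate profiles with a calibrated correlation to the source
   profile, standing in for experimental replicates;
3. tests each pair of equivalent sites of two homologs for a significant SSAP
   difference with a replicate-aware Jensen–Shannon / RMSD statistic and an
   exact permutation test, under Benjamini–Hochberg FDR control;
4. relates the per-site outcomes to structural deviation (sRMSD over
   equivalent Cα pairs) and to the rewiring of residue contact networks.

A synthetic-data generator produces every input class at desk scale, so the
entire pipeline is exercised and validated without any structure database,
force-field runs or sequencing data.

## Stability-to-fitness models

All three models map ΔΔG = ΔG(mutant) − ΔG(wildtype) to a folding probability
Pf, which serves as the fitness proxy; the per-site preference is the
normalization π(r,a) = Pf(ΔΔG(r,a)) / Σ_j Pf(ΔΔG(r,j)).

* **Threshold stability** (default): Pf = e^{−(ΔΔG+ΔG_wt)/kT} /
  (1 + e^{−(ΔΔG+ΔG_wt)/kT}). A sigmoid: above a critical stability mutations
  are nearly neutral, below it fitness falls off. ΔG_wt is the wildtype
  folding free energy; the common approximation ΔG_wt ≈ 0 is the default, but
  the parameter is exposed — varying it shifts the sigmoid midpoint by exactly
  −ΔG_wt, which is how its sensitivity can be probed.
* **Maximum stability**: Pf = α·e^{−λ·ΔΔG}. Every unit of stability helps;
  under the normalization the row is exactly the softmax of −λ·ΔΔG, and α
  cancels.
* **Optimum stability**: Pf = α·e^{−λ·ΔΔG²}. A Gaussian around the wildtype
  stability; deviations in either direction are unfavorable.

Parameters and defaults: `kT = 0.593` kcal/mol (≈298 K, matching the kcal/mol
scale on which force fields report ΔΔG; configurable), `lambda = 1` for both
power models (for the maximum model this is the well-calibrated choice under
the preference normalization; for the optimum model no calibrated value is
established, so the same default is used and flagged as an assumption),
`dg_wt = 0`, `alpha = 1` (cancels).

All rows are computed in log space with log-sum-exp: a site carrying one huge
destabilizing ΔΔG (hundreds of kcal/mol) must yield a valid probability row,
never underflow to zero.

```{r}
g <- generate_ddg(synthetic_spec(n_sites = 6, seed = 1))
prof <- ddg_to_preferences(g$ddg, fitness_model_spec("threshold"))
round(prof$values[1:3, 1:8], 3)
```

## Replicate simulation and σ calibration

Experimental SSAP profiles come with replicates; predicted profiles do not.
Replicates are therefore simulated: per site, a multinomial sample of size
`n = 100` is drawn around the site's preferences and converted to fractions;
Gaussian noise of scale σ is added per amino acid; negative entries are
clamped to zero (preferences are non-negative; the raw noise model can produce
negative values) and the row is renormalized over the site's 20 amino acids.
The per-site normalization is the only reading under which the output is a
valid preference row, so that is what is implemented.

The replicate-to-source Pearson correlation — computed over all L×20 entries
flattened, the convention used when replicate correlations of
mutational-scanning experiments are reported — decreases monotonically in σ,
so a target correlation is dialed in by bisection (`calibrate_sigma`). The
attainable ceiling is set by the multinomial sampling alone (σ = 0); for a
56-site profile it is ≈0.93, comfortably above the working target of 0.60.
The working target 0.60 is the replicate quality at which, under the null of
identical underlying profiles, the per-comparison error rate stays at or below
the 5% FDR level in essentially all runs, and it is of the same order as
replicate correlations reported for large-scale mutagenesis experiments.
"Average correlation" is interpreted as replicate-to-source (not
replicate-to-replicate) correlation averaged over simulated replicates; both
the interpretation and the flattening convention are configurable choices
documented here. An alternative replicate scheme — re-running the prediction
on coordinate-jittered structural models — is not implemented; the noise
route is cheaper and known to lead to the same conclusions.

## The per-site test

For a site r with replicate sets [π₁ᵃ..π_nᵃ] and [π₁ᵇ..π_mᵇ]:

* distances are the **Jensen–Shannon metric**, the square root of the JS
  divergence with base-2 logarithms — a true metric on the simplex, 0 iff the
  distributions are equal and exactly 1 for disjoint support;
* **RMSD_within(r)** is the root-mean-square of JS distances over all
  within-set replicate pairs, pooled from both sets (C(n,2) + C(m,2) pairs).
  Pooling (rather than averaging two per-set RMSDs) is a deliberate choice: a
  single measurement-error scale per site, estimated from all available
  within-set pairs;
* **RMSD_between(r)** is the RMS over all n×m cross-set pairs;
* **RMSD_corrected(r) = RMSD_between − RMSD_within** is the
  measurement-error-corrected distance;
* the null is the **exact permutation distribution**: every distinct
  relabeling of the pooled n+m replicates into groups of sizes n and m
  (enumerated exhaustively when C(n+m,n) ≤ `max_permutations`, otherwise
  uniformly subsampled with the identity labeling always included);
  p = fraction of relabelings with a statistic ≥ the observed one, ties
  counted (conservative), so p is never 0;
* **Benjamini–Hochberg** q-values control the FDR across the sites of one
  pairwise comparison (per-comparison scope: each homolog pair is reported
  separately), significance at q ≤ α = 0.05.

**Replicate count.** The default is 6 replicates per profile. The statistic is
invariant under swapping the two groups, so with an even n = m split every
relabeling ties exactly with its complement and the smallest attainable
p-value is 2/C(2n,n), not 1/C(2n,n). With 5+5 replicates that floor is
2/252 ≈ 0.0079; across 100 sites of which 10 carry signal, the best BH
q-value is then 0.079 and *nothing* can clear a 5% FDR even for maximal
(JS = 1) preference shifts. With 6+6 replicates the floor is 2/924 ≈ 0.0022
(best q ≈ 0.022 in the same scenario), which gives the test usable
granularity at a still-trivial computational cost. A 2+2 mode remains
available for data measured in actual replicate pairs, with the caveat that
its p-value floor is 1/3.

```{r}
g2 <- generate_ddg(synthetic_spec(n_sites = 40, seed = 2))
p0 <- ddg_to_preferences(g2$ddg)
set.seed(3)
cmp <- compare_profiles(p0, p0, target_r = 0.6)  # null self-comparison
cmp
```

## Structure: equivalent sites, sRMSD, contact rewiring

Two sites of two homologs are **equivalent** when their Cα atoms lie within
3.5 Å after optimal superposition. The internal `superpose` utility is a
least-squares (Kabsch) fit iterated with re-pairing by mutual nearest
neighbors under that threshold; it is a pragmatic stand-in for a dedicated
structural aligner, and externally produced alignment maps are accepted
everywhere as first-class input (that is the recommended route for real
structure pairs). Pairs whose alignment covers less than 95% of either
structure are skipped in cohort runs (insertions and deletions make
site-to-site comparison unreliable at lower coverage); the threshold is
configurable, and coverage is checked per structure.

**sRMSD** is the structural-deviation summary over equivalent sites. It is
computed as the arithmetic mean of the paired Cα distances, (1/n)Σdᵢ — note
that despite the conventional name this is a mean of distances, not a
root-mean-square; the definition is implemented exactly as stated and the
naming discrepancy is documented rather than silently "fixed".

**Contact networks** connect residues whose atoms approach within 3.5 Å under
one of two dialects: side-chain atoms only (backbone N, Cα, C, O, OXT
excluded; glycine contributes nothing) or all heavy atoms. Hydrogens are
always excluded (crystal structures generally lack them), and sequential
neighbors |i−j| ≤ 1 are included by default (no exclusion is part of the
definition; a switch drops them for conventions that do). Across an ensemble
of models, the edge weight E is the fraction of models in which the contact
occurs.

For an equivalent-site pair, each homolog's neighbor set is mapped into a
common index space and split into conserved (both homologs), lost (first
only) and gained (second only) contacts; the **rewired fraction**
f_r = (G+L)/(G+L+C) is one minus the Jaccard index of the two neighbor sets.
Contacts to unaligned sites have no image in the other homolog and are counted
as lost/gained by default (they are real contacts of one homolog absent from
the other); an "ignore" mode drops them instead. Worked check: totals of
(16 gained, 23 lost, 118 conserved) give a pooled rewired fraction of 24.8%
(≈25%), and (31, 36, 105) give 39.0%.

Network proximity of a query site set to anchor sites is tested with
shortest-path lengths (Dijkstra, via igraph): observed statistic = mean over
query sites of the hop distance to the nearest anchor (optionally weighted by
1−E), null = the same statistic for random equal-sized site sets drawn from
the non-anchor nodes, p = (#{null ≤ observed}+1)/(n_random+1).

Divergence-binned summaries use bins of width 0.1 over [0,1] by default (the
binning is a presentation choice, configurable) with percentile-bootstrap 95%
confidence intervals of the bin mean (n_boot = 10,000 by default; analyses
here scale it down where the bin populations are tiny).

## What the synthetic generator emulates — and what it does not

`generate_ddg` draws non-wildtype ΔΔG from a shifted gamma
(shift −0.5 kcal/mol, shape 2), scale 2.0 kcal/mol at buried sites vs 0.5 at
exposed sites. These are design choices: right-skewed, mostly destabilizing
effects, a burial fraction of 0.35, and the consequence — verified by test —
that buried sites yield lower-entropy (less tolerant) preferences than
exposed ones, with typical row entropies in the 1.5–4 bit range (non-uniform
but not degenerate). `generate_toy_structure` builds ideal-geometry folds
(helix with 1.5 Å rise, 100°/residue, 2.3 Å radius; an antiparallel two-helix
bundle; a compact random walk) with a single outward-pointing pseudo-side-chain
atom per residue — enough for the two contact dialects to be meaningfully
different at toy scale without rotamer modeling. `generate_homolog_pair`
derives a homolog by Gaussian coordinate jitter, an exact count of random
substitutions, ΔΔG perturbation whose scale grows with the local substitution
density (spatial neighbors within 8 Å), re-zeroing each row at the homolog's
wildtype, plus optional planted sites with independently redrawn rows.

What passing tests on these inputs show: the statistical machinery is
calibrated (null error rate within the FDR level), powerful against planted
signal, and the qualitative trends — more divergence → more significant SSAP
differences, more coordinate perturbation → more contact rewiring, buried →
less tolerant — emerge from the construction. What they do not show: anything
about force-field accuracy, real protein geometry (no rotamers, no backbone
physics), insertion/deletion handling, or the magnitudes observed on real
structure cohorts, which depend on curated structure sets and force-field
runs that are outside this package's scope.

## Numerical choices and edge cases

* Preference rows: log-space normalization (log-sum-exp); row sums within
  1e-9 by construction; profile reads renormalize rows within 1e-6 of 1 and
  reject anything farther.
* Wildtype self-ΔΔG is identically 0 by definition and is forced to 0 on
  ingestion (with a warning) if a file claims otherwise.
* Internal site indices are 1-based and dense (the R convention), with author
  residue numbers carried separately for reporting, so PDB numbering gaps
  can never corrupt matrix indexing.
* FoldX-style per-run energy tables are averaged by arithmetic mean (the
  aggregation is not standardized; mean is the documented assumption), with
  per-entry standard errors recorded when ≥2 runs exist.
* Altlocs resolve by highest occupancy, ties alphabetically; first model only
  for multi-model files; hydrogens and HETATM dropped.
* Replicate simulation: a site whose post-clamp row sums to zero has its
  noise resampled (bounded retries) rather than producing an invalid row.
* Permutation ties count as ≥ observed (conservative); the identity labeling
  is always included, so p > 0.
* Bootstrap CIs: a single-record bin reports a degenerate CI at its value;
  empty bins are reported as missing, never as errors.

## Problem sizes used in tests and analyses

Test and analysis problem sizes are chosen to exercise every code path at
desk scale: profiles of 40–200 sites, cohorts of ~20 pairs of 60 sites,
100-repetition null calibration on a 56-site profile (the size of a small
immunoglobulin-binding domain), bootstrap coverage at 1,000 trials. Headline
magnitudes reported for real structure cohorts (hundreds of pairs, full-size
domains, force-field ΔΔG) are expressly not reproduced here — only their
qualitative trends are, on synthetic cohorts.

## Known limitations

* The JS metric is blind to physicochemical similarity between amino acids: a
  shift toward a chemically similar residue counts as much as a shift toward
  a dissimilar one. Similarity-aware distances are out of scope.
* The superposition utility assumes mostly-corresponding residue order for
  its initial pairing and does not model insertions/deletions; real homolog
  pairs should come with externally computed alignments.
* Replicate simulation models measurement noise, not systematic error between
  structure determinations of the same protein.
* The optimum model's rate constant has no established calibration under the
  preference normalization; its default (1.0) is an assumption.
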