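---
title: "Methods: ensemble docking and multilabel screening of partially disordered proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble docking and multilabel screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and design
decisions behind ensdock, and states precisely what the synthetic
fixtures do and do not establish about real data.

## 1. Ensembles and reweighting

A partially disordered protein is represented as a
`structural_ensemble`: an ordered list of conformations with
non-negative statistical weights summing to one, approximating a
Boltzmann distribution over the conformational space. Enhanced-sampling
simulations (e.g. parallel-bias metadynamics) visit conformations with
a bias `V_i`; the unbiased distribution is recovered with
Torrie–Valleau weights

$$w_i \propto \exp\!\big(V_i / k_B T\big),$$

normalised over frames (`torrie_valleau_weights`). Two numerical
points: the maximum bias is subtracted before exponentiation, which
makes the computation overflow-safe and manifests the invariance of the
weights under a uniform bias shift; and `k_B` is the molar Boltzmann
constant (0.008314462618 kJ/mol/K), so bias energies are expected in
kJ/mol and temperatures in K.

All ensemble statistics (RMSF, SASA distributions, region ratios) use
the frame weights; uniform weights are the default when no bias trace
is supplied.

### RMSF

`residue_rmsf` reports, per residue, the square root of the weighted
mean squared deviation of the representative (CA) position about the
weighted mean position. Superposition onto the mean structure before
measuring fluctuations is exposed as an option but **off by default**:
for a chain that is mostly disordered, global reorientation and
expansion are part of the signal, and the nanometre-scale fluctuation
values used in the pocket-selection filter are only reached without
alignment. When enabled, superposition uses two passes of weighted
least-squares (Kabsch) fitting of every frame onto the weighted mean.

Units: coordinates are Angstrom internally; RMSF, radius of gyration
and distances are reported in nm. The pocket filter's default RMSF
cutoff is 4.1 in the units of the supplied RMSF vector; the
literature on this class of filters quotes both 4.1 and 4.5 (and mixes
nm/nm² notation), so the cutoff is a plain configuration value
(`filter_config(max_mean_rmsf = )`), not a constant.

### SASA

`sasa_atoms` implements sphere-point (Shrake–Rupley) sampling:
quasi-uniform points are placed on each atom's solvent-expanded sphere
(van der Waals radius + probe, Bondi radii, probe default 1.4 Å), and
the accessible fraction is the fraction of points outside all
neighbouring expanded spheres. The default 960 points per atom keeps
the two-sphere quadrature error below 1 % of the analytic overlap
area; tests verify this against both the closed-form spherical-cap
formula and an independent 10×-density implementation. Residue SASA is
the sum over the residue's atoms; `region_sasa_ratio` compares
weighted-mean region SASA between a ligand-bound (holo) and a free
(apo) ensemble, excluding (with a warning) regions whose apo SASA is
zero from the mean ratio.

## 2. Prediction-derived distance restraints

From an AlphaFold-style `prediction_bundle` (per-residue pLDDT scaled
to [0, 1], pairwise PAE, pairwise predicted distances), the package

* marks maximal runs of residues with pLDDT **strictly above** 0.75 as
  structured regions (`structured_regions`);
* keeps a residue pair (i < j) as a distance restraint when its
  symmetrised PAE is **strictly below** 4 Å, its sequence separation
  is at least 3, and the two residues are not both inside a structured
  region (`select_restraints`). Structured regions are excluded
  because, in the simulation protocols this feeds, they are restrained
  to the predicted structure directly by an RMSD potential and the
  coarse-grained prior is not trained for ordered segments.

PAE matrices are asymmetric; the pair value is `min(pae[i,j],
pae[j,i])` by default (lenient, reading "error lower than the cutoff"
as satisfiable by either direction), with `mean` as the documented
alternative. The minimum sequence separation of 3 reflects that
near-diagonal distances in such restraint sets start around 3 residues
apart; it is configurable.

### Metainference score

`metainference_energy` evaluates the restraint part of the
metainference energy for a set of replica conformations: with forward
model d_i(X_r) (CA–CA distance; the prior is a one-bead-per-residue
model), predicted distance d_i^AF and combined variance
σ²_{r,i} = (σ_i^SEM)² + (σ_{r,i}^B)²,

$$E_{\text{data}} = k_B T \sum_{r,i}
  \frac{\big(d_i(X_r) - d_i^{AF}\big)^2}{2\,\sigma^2_{r,i}}, \qquad
E_\sigma = k_B T \sum_{r,i}
  \Big(\log \sigma_{r,i} + \tfrac{1}{2}\log 2\pi\Big),$$

so that the total is k_B T times the full Gaussian negative
log-likelihood. The √(2π) normalisation constant is included to make
the score a true negative log-likelihood; it shifts the total by a
constant and does not affect any comparison at fixed σ. The
molecular-mechanics prior energy of a simulation engine is explicitly
**not** part of this score — the evaluator scores ensembles against
data; it does not run dynamics. σ values are inputs (the Gibbs
sampling of σ during a simulation belongs to the engine) and must lie
in the conventional sampling range [10⁻⁴, 10].

## 3. Pocket selection

Cavity detection itself is an external, grid-based geometric
computation; ensdock consumes its tabular report (`read_cavities_csv`,
or the `detect_cavities` adapter whose fixture backend injects known
cavities for testing). A cavity becomes a binding site iff **all** of:

| filter | default | comparison |
|---|---|---|
| lining residues | 5 | strict > |
| mean Eisenberg–Weiss hydropathy | 0 | ≤ |
| area (Å²) | [80, 2480] | inclusive |
| volume (Å³) | 120 | ≥ |
| residue RMSF statistic | 4.1 | strict < |

The clause tying the volume filter to "hydrophobic, relatively large"
cavities is read as: all filters apply conjunctively, selecting
hydrophobic, large cavities — there is no separate branch for
hydrophilic ones. The RMSF condition uses the **mean** over cavity
residues (max is a config alternative); low fluctuation is the proxy
for "sticky" residues whose interactions drive phase separation, which
is what makes these pockets functionally interesting targets.

Sites are clustered by residue sharing: an edge connects two sites
when their overlap exceeds the threshold (default 0.6, strict >), and
clusters are connected components (single linkage). The overlap
measure is the **overlap coefficient** |A∩B| / min(|A|, |B|), chosen
over Jaccard because transient pockets detected on different frames
are frequently nested versions of the same site with very different
sizes; Jaccard is available as a config alternative. Site ids are
assigned deterministically by (frame, detection order) so cluster
labels are reproducible.

Docking boxes are axis-aligned bounding boxes of the cavity residues'
CA coordinates padded by 5 Å per side — generous enough to let an
engine place ligands at shallow disordered pockets.

## 4. Docking adapter and mock engine

The engine contract is: five poses requested per (compound, site), the
lowest energy bookkept (`dock`). Engine failures become missing matrix
entries, not crashes, and missing entries are excluded from labelling
denominators. Energies are stored as reported (kcal/mol), without
rescoring.

The **mock scorer** exists so that every downstream stage — labelling,
training, screening, redocking, hit-rate analysis — has a
deterministic, planted-ground-truth test bed. Its energy for a
(compound, site, seed) key is N(−5, 1²) noise derived from a 64-bit
FNV-1a hash with an avalanche finalizer, minus a boost Δ when the
compound is a planted binder at that site. The avalanche step matters:
keys for the same compound at different sites differ only near the end
of the string, and a plain polynomial hash maps such keys to nearly
identical values, which would correlate a compound's energies across
all sites and corrupt the fixture's statistics. The hash is integer
arithmetic only, hence bit-reproducible across platforms.

## 5. Labels, fingerprints, classifier, screening rule

**Labels.** Per site, with n non-missing energies and percentile p
(default 5), the threshold is the (⌊np/100⌋+1)-th lowest energy and a
compound is active iff its energy is **strictly below** it. On
tie-free data with n divisible by 100/p this marks exactly np/100
actives; ties at the threshold are inactive. (The alternative reading
"threshold = the ⌊np/100⌋-th lowest with strict <" would mark one
fewer active than the percentile implies and is rejected by the
package's worked examples.)

**Fingerprints.** `featurize` computes hashed linear-path topological
fingerprints: all simple paths of 1–7 bonds in the heavy-atom graph,
labelled by their alternating element/bond-order string (taking the
lexicographically smaller reading direction), hashed and folded to
1412 bits. SMILES are canonicalised (OpenBabel) before parsing, and
the path-label set is a graph invariant, so equivalent SMILES yield
identical rows. Malformed SMILES are screened syntactically *before*
canonicalisation (the converter silently truncates bad input rather
than failing) and reported per row.

**Classifier.** A feed-forward multilabel network: configurable hidden
stack (default four layers of 1256 ReLU units), sigmoid outputs (one
per site), binary cross-entropy loss, Adam (lr 10⁻³ default),
inverted dropout (rate 0.2) on the first and last hidden layers.
Compounds are split 80/10/10 into train/validation/test — a stated
90/10/10 protocol sums to 110 % and is normalised here to 80/10/10 —
and the split is **stratified on multibinding activity** (inactive /
active at < half the sites / at ≥ half). Stratification is essential
rather than cosmetic: multibinders are rare (tens among thousands),
and an unstratified split leaves the validation set with no
multibinder at all in a few percent of seeds, making the
checkpoint criterion blind. The checkpoint is the epoch with the best
validation mean MCC, computed per site from confusion counts with
single-class sites excluded as undefined (not imputed); final metrics
are reported on the held-out test split. All randomness (init,
shuffling, dropout, splits, oversampling) flows from the config seed,
so a fixed seed reproduces training bit-for-bit on a given platform.

**Oversampling.** Compounds with ≥ 1 active label are duplicated with
replacement until the pool's mean per-site active fraction reaches a
target (default 0.25), originals always retained. When the target is
arithmetically unreachable (the actives' mean per-row active count is
below the target rate — the typical case when most actives are
single-site noise), each active row is duplicated once instead, which
doubles active representation without exploding the pool.

**Screening.** Predicted probabilities are binarised at 0.5 and a
compound is selected iff its active-site fraction is **strictly
greater** than the threshold (default 0.70): with 41 sites, 29 active
sites select (29/41 ≈ 0.707) and 28 do not. The multibinding hit
histogram likewise uses a strict "> min_sites" count.

## 6. Synthetic fixtures: what they emulate, and what they don't

The generator defaults define the package's standard synthetic study:

* a 60-residue CA chain, 50 frames, self-avoiding 3.8 Å virtual-bond
  walks with residues 15–46 pinned to a shared template (a structured
  domain surrogate: near-zero RMSF against wandering tails); bias
  energies N(10, 2²) kJ/mol at 298 K;
* 2000 training compounds against 20 sites, 25 planted multibinders
  boosted by Δ = 3 kcal/mol (three background standard deviations;
  background N(−5, 1²) kcal/mol) at 90 % of sites; a 500-compound
  screening library with 50 further planted binders;
* SMILES drawn from a combinatorial grammar (branched
  alkane/alcohol/amine chains; substituted benzenes) deduplicated
  after canonicalisation. Planted multibinders are exactly the
  aromatic-scaffold compounds, so activity is *learnable from
  structure* — without that coupling a fingerprint model could not
  beat chance and the screening stage would be untestable.

Replicated experiments (`enrichment_replicates`) regenerate planted
site subsets, energies and training seeds per replicate over a fixed
library, and compare the redocked screened set's multibinding hit rate
with the naive training set's. At the default conditions the screened
rate (~90 %) exceeds the naive rate (~1 %) in every replicate; the
sizes (2000 compounds, 20 sites, 100 replicates, a few minutes of CPU)
were chosen as the smallest study at which that comparison is stable.

What passing fixture tests **does not** show: that real docking
energies are as cleanly separable as planted Gaussians (real
energy–structure relationships are weaker and noisier); that real
pockets yield 41 sites or 26 clusters (those depend on the deposited
ensemble and an external detector); or anything about conformational
entropy or holo/apo SASA ratios of real MD ensembles, which require
study-scale trajectories. Those study-scale quantities are reachable
through `benchmark_deposited()` when the archived data are locally
available, and are otherwise reported as not reproducible at desk
scale.

## 7. Degenerate inputs and tie-breaking

* Weights that sum to zero, non-finite coordinates or bias energies,
  σ outside [10⁻⁴, 10], PAE cutoffs ≤ 0, thresholds outside (0, 1]:
  rejected with informative errors.
* Zero-padding docking boxes are flagged as degenerate with a warning.
* All-missing energy columns are rejected; partially missing columns
  label the missing compounds NA and shrink that site's denominator.
* MCC with a zero denominator factor is defined as 0 (the conventional
  completion); sites whose *truth* is single-class are reported as
  undefined and excluded from mean MCC.
* Duplicate (compound, site) docking results are rejected listing the
  offending ids — silent overwriting would mask engine bookkeeping
  bugs.

## 8. Known limitations

* The classifier trains dense matrices in memory; libraries in the
  millions need batching beyond the current `screen` chunking.
* The fingerprint is a fixed hashed-path scheme; count-based or
  circular fingerprints are not provided.
* The vina adapter shells out to an external binary and is exercised
  only by its argument-construction path in tests; pose parsing
  assumes the engine's standard table format.
* Fixture chemistry is a small grammar: molecules are drug-unlike
  fragments, adequate for separability tests, not for chemical-space
  claims.
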