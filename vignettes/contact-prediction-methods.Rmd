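---
title: "Contact prediction from decoy ensembles: models and methods"
author: "decoymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact prediction from decoy ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Ab initio structure prediction samples an energy function and returns many
candidate structures ("decoys"). Because native residue-residue contacts are
energetically favourable, they recur across low-energy decoys even when every
individual decoy has the wrong fold. decoymap turns this observation into a
contact predictor with three layers of information:

1. **Physicochemical, per contact.** Every contact observed in a low-energy
   decoy is described by the labelled graphs of its structural neighbourhood
   and scored by a calibrated SVM ensemble trained to distinguish native from
   non-native contact environments.
2. **Physicochemical, per ensemble.** The occurrence frequency
   $f_{ij} = n_{ij}/N$ of a contact across the $N$ selected decoys (the
   classical "Counting" predictor) summarises how persistently the energy
   function realises the contact.
3. **Evolutionary.** Coupling scores $g_{ij}$ from a co-evolution analysis of
   a deep multiple-sequence alignment (consumed as an external
   `i j score` file; any pseudo-likelihood or MI-based method can stand
   behind it).

The final score of a candidate pair is the linear combination

$$s_{ij} \;=\; S_{ij} \;+\; \alpha\, f_{ij} \;+\; \beta\, g_{ij},$$

where $S_{ij}$ is the mean ensemble-SVM probability of the pair over the
decoys that contain it, and $\beta$ switches between a shallow-alignment and
a deep-alignment value at a depth of $5L$ sequences ($L$ = protein length).
Contacts are reported in rank order (CASP RR dialect) and, optionally, as
non-penalising bounded-Lorentz distance restraints for folding engines.

Two residues are *in contact* when their C$\beta$ atoms (C$\alpha$ for
glycine) lie within 8 Å. Contacts are predicted only at sequence separations
$j - i \ge 12$; evaluation distinguishes medium-range (12-23) and long-range
($\ge 24$) contacts, the CASP convention.

## Decoy selection

Decoys arrive as PDB files plus a sidecar energy table (`decoy_id energy`),
deliberately decoupled from any particular folding program's output format.
`select_low_energy()` keeps the $\lceil q N \rceil$ lowest-energy decoys —
$q = 0.02$ for prediction ensembles (20 of 1000) and $q = 0.03$ for training
ensembles (6 of 200). Ties are broken by decoy identifier so selections are
deterministic and nested across fractions.

## Contact graphs

The structural context of a candidate contact $(i, j)$ is captured by two
graphs built on the decoy's full contact map (minimum separation 1: chain
neighbours count if they satisfy the distance rule):

* the **neighbourhood** $N_i$ of a residue: a sequential seed set (the
  residue and its neighbours up to two positions away; for helical residues
  the positions $i,\, i\pm3,\, i\pm4$ facing the same side on adjacent helix
  turns, from the 3.6-residue period) plus every residue in contact with a
  seed;
* the **shared neighbourhood graph** (SNG): the intersection of the node
  sets of $N_i$ and $N_j$;
* the **immediate neighbourhood graph** (ING): $\{i, j\}$ plus every
  residue in direct contact with either anchor.

Edges of the SNG/ING are the contacts *induced* among their node sets — the
only parameter-free edge rule consistent with taking subgraphs of the
contact graph. The helix seed offsets $\{-4, -3, 0, +3, +4\}$ are exposed in
`neighborhood_spec()` so the periodicity reading can be changed in one
place.

## The 238-input feature vector

Each candidate contact in each decoy is encoded by seven feature groups;
the five graph groups are evaluated on the SNG and the ING separately, so
each appears twice:

| group | inputs |
|---|---|
| pairwise | 49 |
| graph topology (×2) | 10 |
| graph spectrum (×2) | 5 |
| single node (×2) | 10 |
| node label statistics (×2) | 43 |
| edge label statistics (×2) | 12 |
| whole protein | 29 |

Total: $49 + 29 + 2(10+5+10+43+12) = 238$. `feature_schema()` names every
input in order. The exact decompositions inside each group (the named items
are fixed, the published sub-breakdowns are not) are pinned by this package
and versioned as schema `dm-238-v1`; all bin edges live in `dm_config()` so
they are stable across runs:

* APC-MI bins $(0, .05, .1, .2, .4, \infty)$; solvation bins at
  $(-0.5, 0, 0.5)$ kcal/mol; RSA bins at $(0.25, 0.6)$ with buried meaning
  RSA $< 0.25$; conservation bins at $(0.25, 0.5, 0.75)$; contact-potential
  bins at $(-2.2, -1.1)$ (the shipped table's terciles); sequence-separation
  bins $(<12, 12\text{-}23, 24\text{-}50, >50)$; length classes
  $(\le 50, 51\text{-}100, 101\text{-}150, 151\text{-}250, 251\text{-}400,
  >400)$.
* Centralities use standard $(n-1)$ normalisations per connected component;
  radius, diameter and eccentricity are computed on the largest component so
  disconnected graphs stay finite. Spectrum features count distinct
  adjacency eigenvalues at tolerance $10^{-8}$.
* Degenerate graphs are well-defined: a single-node graph contributes zeros
  except the node count, and its spectrum is $(0, 0, 1, 0, 0)$; a graph
  without edges has all-zero edge statistics.

### Structure annotations

External annotation programs are replaced by internal, testable rules:

* **Secondary structure**: dihedral windows (helix
  $\varphi \in [-90,-30]$, $\psi \in [-77,-17]$ in runs $\ge 4$; strand
  $\varphi \in [-170,-70]$, $\psi \in [90,180] \cup [-180,-170]$ in runs
  $\ge 3$, shorter strand stretches = isolated bridge), with $3_{10}$/π
  helix and turns assigned from $(i,i{+}3)$/$(i,i{+}5)$ backbone
  hydrogen-bond patterns.
* **Hydrogen bonds**: backbone N···O $\le 3.5$ Å at separation $\ge 2$.
* **Solvent accessibility**: Shrake-Rupley integration with a probe of
  1.4 Å and a deterministic 92-point golden-spiral sphere per atom; RSA
  normalises by Tien-style theoretical maxima and is clamped at 1.2. The
  92-point quadrature carries per-atom noise of order $1/\sqrt{n}$
  (roughly 3%); totals converge below 2% on doubling the point count, and
  the z-normalisation before the SVM makes this resolution immaterial
  downstream.
* **Solvation energy**: $\sum_\text{atoms} \sigma_\text{type} \cdot
  \text{SASA}$ with an Eisenberg-McLachlan-style coefficient table.
* **Contact potential**: a 20×20 quasi-chemical-style table. Both tables
  are *synthetic stand-ins* generated from documented formulas (see
  `inst/extdata/*_synthetic.tsv`) because the original parameter sets are
  not redistributable here; both are plain TSV and swappable.

### Alignment statistics

Conservation is $1 - H_c/\log 20$ with Henikoff position-based sequence
weights (normalised to sum to the depth) and a pseudocount of 1 added to
each *observed* residue's weighted count — restricting the pseudocount to
the observed support keeps perfectly conserved columns (and every column of
a depth-1 alignment) at exactly 1. Neighbourhood conservation is the mean
over a ±2-column window. Mutual information uses 21 symbols (20 residues +
gap) with a pseudocount of 0.05 per joint cell, and the average product
correction $\mathrm{APC}(a,b) = \mathrm{MI}(a,b) - \overline{\mathrm{MI}}_a
\overline{\mathrm{MI}}_b / \overline{\mathrm{MI}}$ removes background
covariation.

## The SVM ensemble

Contact classification is heavily imbalanced, so training combines random
undersampling with an ensemble: proteins are split at random into five
non-overlapping subsets; per protein, 50 native and 150 non-native contact
instances are drawn uniformly without replacement from its selected training
decoys (everything available, if fewer); and one soft-margin Gaussian-kernel
SVM is trained per subset. The undersample is applied *per protein* — the
reading consistent with subset sizes scaling with corpus size. Inputs are
z-normalised (mean/sd fitted on the union of subsets, sd floored at
$10^{-8}$).

Raw member outputs are signed decision values (margin distances), not
probabilities. Each member is calibrated by **percentile binning**: scores
between the 5th and 95th percentile are split into ten equal-width bins, the
bin probability is the native fraction inside it, scores outside clamp to
the extreme bins, and empty bins inherit the nearest non-empty bin's value.
Calibration scores come from an internal 5-fold cross-validation of the
member's own subset, so the bins reflect scores the member has not
memorised. The count-weighted mean of the bin probabilities equals the
calibration set's native fraction exactly — a conservation law the test
suite asserts to $10^{-12}$.

The ensemble probability of a feature vector is the mean of the five
calibrated member probabilities; the per-pair score $S_{ij}$ averages that
over the decoys containing the pair. Defaults $C = 10$,
$\gamma = 1/238$ apply when `tune_hyperparameters()` (protein-level
cross-validated grid search maximising long-range top-$L/5$ precision,
ties to the smallest $C$ then $\gamma$) is skipped.

## Combination and tuning

Coupling scores scale differently between methods and alignment depths, so
$g$ is min-max rescaled to $[0,1]$ per protein before weighting. Pairs with
a coupling score but no decoy occurrence are admitted with $S = 0$, $f = 0$
so that deep-alignment proteins are not capped by decoy coverage.
`tune_combination_weights()` grid-searches $(\alpha, \beta)$ by
protein-level cross-validation of long-range top-$L/5$ accuracy, separately
for the shallow ($\le 5L$) and deep ($> 5L$) strata; an empty stratum
inherits the other's $\beta$ with a warning, and ties prefer smaller
weights. Ranking breaks ties by descending $f$, then ascending $(i, j)$.

## Restraints

Predicted contacts convert to a bounded-Lorentz energy term:
$E(d) = -w$ for $lb \le d \le ub$, and
$E(d) = -w / (1 + ((d - ub)/hw)^2)$ beyond the upper bound (symmetrically
below the lower bound), with defaults $lb = 1.5$ Å, $ub = 8$ Å, $hw = 1$ Å,
$w = 1$. The term is continuous, equals $-w/2$ at one half-width of
violation, decays to zero for gross violations, and is never positive — a
wrong prediction is ignored, not penalised. The $d < lb$ branch cannot fire
at the default parameters but is kept for general bounds. The emitted
restraint count defaults to the top $L$ contacts; the optimum for any given
folding engine is left to the user (`--n-contacts`).

## Evaluation

$\mathrm{Acc} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ and
$\mathrm{Cov} = \mathrm{TP}_{\text{frac}}/\mathrm{TP}_{\text{total}}$ over
the top $\max(1, \lfloor L/k \rfloor)$ in-range predictions,
$k \in \{10, 5, 2\}$, with $\mathrm{TP}_{\text{total}}$ the number of
in-range native contacts (coverage is NA when there are none). Proteins
stratify by alignment depth into $(1, 1L]$, $(1L, 5L]$ and $> 5L$.

## The synthetic generator

`make_corpus()` builds fully seeded study systems so every stage trains and
tests without downloads:

* **Natives** are compact single-chain globules built residue-by-residue
  with the natural-extension (NeRF) rule from ideal dihedrals
  (helix $-57/-47$, strand $-120/130$, ω = 180); coil torsions are chosen
  greedily from a small candidate library to pull the chain back towards
  its centroid without C$\alpha$ clashes. This yields consecutive
  C$\alpha$-C$\alpha$ distances of 3.8 Å, helix rise 1.5 Å/residue, proper
  $(i, i{+}4)$ hydrogen-bond ladders and genuine medium/long-range contact
  networks. Sequences follow hydrophobic periodicity patterns (heptad-like
  in helices, alternating in strands).
* **Decoys** are the native plus a chain-correlated Gaussian displacement
  field (Ornstein-Uhlenbeck along the sequence, autocorrelation 0.9),
  cycling through three perturbation tiers
  $\sigma = (1.5, 2.5, 4.0)$ Å per coordinate — C$\alpha$-RMSD roughly
  2.5, 4.1 and 6.6 Å, i.e. "very close", "relatively close" and "far",
  emulating decoy sets of graded nativeness. Energies are synthetic,
  $E = 1 \cdot \mathrm{RMSD} + \mathcal{N}(0, 0.5)$: only the rank
  structure (low energy ↔ more native) matters to the pipeline.
* **Alignments** sample rows from per-column profiles centred on the query;
  a seeded half of the medium/long-range native contacts is planted as
  jointly mutating column pairs, and the coupling-score file is the APC-MI
  of the generated alignment, so planted pairs score far above background.

What the generator deliberately does **not** emulate: decoys with genuinely
different folds (perturbed natives keep more native contacts than real
ab initio decoys do, which makes the frequency baseline stronger here than
in practice), alignment gaps and phylogenetic tree structure, side chains
beyond C$\beta$, and physical energy functions. Green end-to-end tests
therefore demonstrate that the machinery learns and combines the intended
signals under controlled conditions — not field performance on real decoy
sets.

## Problem sizes and determinism

The packaged study corpus is 12 proteins of length 60 with 200 decoys and
depth-500 alignments each — large enough that the end-to-end properties
(held-out SVM AUC above the frequency baseline and a permuted-label
control; combined ranking at least as accurate as Counting) are stable
across seeds, small enough to run in about a minute. Unit fixtures are
smaller (10 proteins, L = 50, 100 decoys). All randomness flows from
explicit integer seeds: corpus generation, protein subset splits,
undersampling, calibration folds and the permutation control are exactly
reproducible.

## Known limitations

* The per-group feature sub-breakdowns match the published group totals and
  named items, not an exact historical input list; the schema version
  exists so a faithful replacement could be dropped in.
* The contact potential and solvation coefficients are synthetic stand-ins;
  swap `inst/extdata/*_synthetic.tsv` for measured tables where available.
* Secondary structure and SASA are fast approximations; they are
  *consistent* across decoys (which is what the classifier needs), not
  replicas of STRIDE or POPS output.
* Model files are serialised R objects (`saveRDS`); there is no
  cross-language model format.
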