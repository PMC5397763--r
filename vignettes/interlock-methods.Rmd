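---
title: "Methods: co-evolution, structure networks and interface analysis with interlock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-evolution, structure networks and interface analysis with interlock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interlock)
```

interlock studies how one protein domain locks another in an autoinhibited
two-domain complex, using three complementary signals: correlated mutations
between the domains' sequence alignments, communication paths on residue
interaction networks built from coordinate ensembles, and the composition and
persistence of the inter-domain interface. This vignette documents the model
behind each stage, the default parameters and why they are set where they are,
what the bundled synthetic generators do and do not emulate, and the main
numerical choices and limitations.

## Co-evolution from a concatenated alignment

Two per-domain alignments sharing the same ordered sequence identifiers are
gap-filtered and concatenated row-wise. Columns whose gap fraction is
*strictly* greater than `max_gap_fraction = 0.30` are removed, so a column with
exactly 30% gaps is retained; `X` counts as a gap because an unknown residue
carries no pair information.

For a column pair $(i, j)$ the observed joint frequency $P_{obs}(x_i, y_j)$ is
computed from rows ungapped at both columns (optionally with identity-cluster
sequence weights, `msa_weights()`). It is shrunk towards the product of the
per-column profiles $q$:

$$P_{PP}(x_i, y_j) = (1 - \tau)\,P_{obs}(x_i, y_j) + \tau\, q(x_i)\, q(y_j),
\qquad
\tau = \frac{1 + b}{e^{a\,N_{eff}(i,j)} + b},$$

where $N_{eff}(i,j)$ is the (weighted) number of sequences ungapped at both
columns. With the defaults $a = 0.05$, $b = 10$, $\tau = 1$ at zero depth (the
pair is fully shrunk to the independent product, contributing zero mutual
information rather than noise) and $\tau$ falls below 0.1 by roughly 90
effective sequences — the scale of a typical curated two-domain alignment, so
moderately deep alignments are dominated by their observed counts.

Mutual information is computed in nats over $P_{PP}$,
$MI = \sum_{x,y} P(x,y)\,\log\frac{P(x,y)}{P(x)P(y)}$, and corrected for
background and phylogenetic signal with the average-product correction

$$MI_p(i,j) = MI(i,j) - \frac{\overline{MI}(i,\cdot)\;\overline{MI}(\cdot,j)}
{\overline{MI}(\cdot,\cdot)},$$

with row means taken over off-diagonal entries. Pairs are ranked by $MI_p$
(ties broken by raw $MI$, then by column indices, so the ranking is
deterministic), classified as intra-domain or inter-domain against the domain
boundary, and intra-domain pairs closer than `min_separation = 5` columns are
suppressed because chain neighbours covary trivially. Reported positions are
always in original (pre-filter) column coordinates.

```{r coevolution-example}
gen <- generate_coupled_msa(
  n_seqs = 100, length_a = 60, length_b = 60,
  couplings = list(coupling_spec(10, 80, strength = 0.9)),
  gap_fraction = 0.05, seed = 1
)
res <- predict_coevolving_pairs(gen$msa_a, gen$msa_b, top_n = 5)
tidy(res)
```

## Protein structure networks and communication paths

Residues are nodes; the edge weight between residues $i, j$ is the percentage
interaction strength

$$I_{ij} = 100\,\frac{n_{ij}}{\sqrt{N_i N_j}},$$

with $n_{ij}$ the number of heavy-atom pairs within `contact_cutoff = 4.5` Å
and $N_i$ a per-residue-type normalization constant (`psn_normalization()`,
editable) that compensates for residue size. Intra-chain pairs separated by at
most `exclude_neighbors = 2` positions are excluded so edges reflect
non-covalent packing rather than the covalent backbone.

Edges are kept at strength $\ge I_{min}$. Instead of fixing $I_{min}$ blindly,
`largest_cluster_profile()` scans a grid (0–10% in 0.5 steps) and
`select_imin()` places the cutoff at the sharpest drop of the largest connected
component — the percolation-style transition where weak, non-specific contacts
stop bridging the network. When the profile has no transition the conventional
2.5% default is used.

Shortest communication paths are computed with Floyd–Warshall on hop counts
(or on costs $1/I_{ij}$ in weighted mode) and reconstructed deterministically:
among equally short continuations the smallest residue in canonical chain/resno
order is chosen. Over an ensemble, `ensemble_paths()` reports the per-frame
paths, their average hop length, the consensus nodes (present in at least 50%
of per-frame paths by default), and the path on the dynamically stable network
— the network of edges present in at least `stability = 0.5` of frames
(inclusive). Floyd–Warshall is implemented directly (vectorised over the
intermediate node) because the reconstruction rule needs the full distance
matrix; the test suite cross-checks it against an independent breadth-first
search.

## Interface composition, hydrogen bonds and pseudoenergies

Interface residues are those with any heavy atom within
`interface_cutoff = 5.0` Å of the partner chain. Hydrogen bonds are
donor–acceptor heavy-atom pairs (standard N/O roles by residue type) within
`da_cutoff = 3.5` Å; when hydrogens are present in the model, a hydrogen
attached to the donor must additionally make an H–D–A angle within 30°.
Occupancy over an ensemble is the fraction of frames in which a residue pair is
bonded, and a bond is *stable* only when occupancy is strictly above 50% — a
bond present in exactly half the frames is not stable.

Interface pseudoenergies are counting scores with distance thresholds, not a
force field: each hydrogen bond contributes `e_hbond = -1.5` kcal/mol, each
oppositely/likely charged residue pair within 6 Å contributes ∓1.0 kcal/mol
(formal charges on Asp/Glu carboxylate oxygens, Lys NZ and Arg guanidinium
nitrogens), and each cross-chain heavy-atom pair between 3 and 5 Å contributes
`e_vdw = -0.2` kcal/mol. The constants are calibrated stand-ins chosen so that
a well-formed interface lands near the −2 to −3 kcal/mol-per-residue range
reported for stable protein–protein complexes; they are configurable in
`energy_config()` and should not be interpreted as physical energies. Each
term's energy is split equally between its two residues, which conserves the
total exactly; a residue is a *hotspot* when its share is at or below
`hotspot_threshold = -2.0` kcal/mol.

## Conformational metrics

RMSD uses optimal least-squares (Kabsch) superposition over a selection
(backbone N, CA, C, O by default) before measuring deviations. The radius of
gyration is mass-weighted by default. RMSF is computed per Cα over a trailing
window (default the last 20% of frames) about the window-mean structure, with
two iterations of mean-structure refinement so the mean and the superposition
are self-consistent.

## What the synthetic generators emulate — and what they do not

`generate_coupled_msa()` draws every column i.i.d. from a per-column Dirichlet
profile and overwrites planted pairs: with probability `strength` the letter at
column $j$ is a fixed bijection of the letter at column $i$. Gaps are i.i.d.
per cell. This gives the co-evolution stage an exact ground truth — at
strength 1 and no gaps the planted pair's joint is a permutation matrix with
$MI = H(q_i)$ — but it deliberately does *not* emulate phylogeny: rows are
independent, so there is no tree-induced background covariation. The
average-product correction is therefore exercised on profile-composition bias
only.

`generate_toy_complex()` builds two straight Cα traces (3.8 Å spacing) 20 Å
apart and plants interactions in dedicated 12 Å-spaced slots: 3-atom
pseudo-side-chain clusters facing each other at ~3.0–3.1 Å across the
interface (contacts), a Lys NZ / Asp OD1 pair at exactly 3.0 Å (hydrogen
bonds), and the same cluster construction between consecutive members of a
planted path on the far side of a chain. The layout is deterministic, so every
planted geometry is exact and every non-planted cross-chain residue pair is at
least 8 Å away by construction. `generate_ensemble()` adds i.i.d. Gaussian
noise per atom and, in a contiguous final block of `round(broken_fraction *
n_frames)` frames, rigidly translates chain B 20 Å along the interface normal
— a caricature of interface rupture with an exact broken-frame ground truth.
These toys are validation scaffolds: they have no secondary structure, no
excluded volume and no realistic side chains.

Problem sizes throughout the package's examples and tests (around 100
sequences, 40–60 columns per domain, 12+12-residue complexes, 10-frame
ensembles) are chosen so the full pipeline runs in seconds on a laptop while
every stage still has a non-trivial planted truth.

## Numerical choices

- All-pairs MI uses per-column 20-state indicator matrices and one
  `crossprod()` per pair, so the inner loop is dense linear algebra rather
  than table construction.
- Floyd–Warshall is vectorised over the intermediate node
  (`d <- pmin(d, outer(d[, k], d[k, ])))` in effect), $O(L^3)$ but with
  matrix-level operations.
- Zero cells contribute nothing to MI (the $0 \log 0 = 0$ convention);
  distance comparisons against cutoffs include a $10^{-12}$ slack on squared
  distances so exact planted geometries are classified stably.
- Pipeline TSVs format doubles with `%.6g` and record an MD5 hash of the
  normalized configuration, making byte-identical reruns a testable property.

## Limitations

- The pseudoenergy model is a calibrated counting score; magnitudes are only
  comparable within the package.
- No phylogenetic correction beyond APC and optional identity weights; on real
  alignments with strong tree structure, MIp rankings inherit the usual MI
  caveats.
- Hydrogen-bond detection without explicit hydrogens reduces to a heavy-atom
  distance criterion.
- The I_min auto-selection assumes the largest-cluster profile has a visible
  transition; flat profiles fall back to 2.5%.
- The PDB reader supports single-topology multi-model files (trajectory-like
  ensembles); ensembles with varying atom counts are rejected by design.
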