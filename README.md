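# interlock

Co-evolution, residue-network and interface analysis of autoinhibited
two-domain protein complexes.

## The scientific problem

In many signalling proteins one domain *autoinhibits* another: an N-terminal
domain binds its partner domain's functional surface and keeps the protein
silent until the clamp is released. Characterising such a complex raises three
linked questions:

1. **Do the domains co-evolve?** Correlated mutations between columns of the
   two domains' alignments indicate an evolutionarily maintained interface.
2. **How is the clamp wired?** On a residue interaction network built from a
   structural ensemble, which residues carry the communication paths between
   functional sites?
3. **How strong and persistent is the interface?** Which residues form it,
   which hydrogen bonds survive over the ensemble, and which residues are
   energetic hotspots?

interlock implements all three stages plus synthetic generators with planted
ground truth, so every stage is testable end to end.

## Core method

**Co-evolution.** For columns $i, j$ of the concatenated two-domain alignment,
a pseudocount-corrected joint distribution

$$P_{PP}(x_i, y_j) = (1-\tau)\,P_{obs}(x_i,y_j) + \tau\,q(x_i)\,q(y_j),
\qquad \tau = \frac{1+b}{e^{a N_{eff}(i,j)} + b}$$

yields mutual information in nats, corrected for background signal by the
average-product correction
$MI_p(i,j) = MI(i,j) - \overline{MI}(i,\cdot)\,\overline{MI}(\cdot,j)/\overline{MI}(\cdot,\cdot)$.
Pairs are ranked by $MI_p$ and classified as intra- or inter-domain.

**Structure networks.** Residues are nodes; edges carry the percentage
interaction strength $I_{ij} = 100\, n_{ij} / \sqrt{N_i N_j}$ (heavy-atom
contacts within 4.5 Å, normalized per residue type) and are kept at
$I_{ij} \ge I_{min}$, with $I_{min}$ selected at the sharpest drop of the
largest-cluster-size profile. Shortest communication paths (Floyd–Warshall)
are summarised over the ensemble by average hop length, consensus nodes and
the path on the dynamically stable network (edges present in ≥ 50% of frames).

**Interface.** Interface residues at 5 Å; hydrogen bonds at a 3.5 Å
donor–acceptor cutoff with occupancy over frames (*stable* strictly above
50%); counting pseudoenergies (H-bond −1.5, electrostatic ∓1.0 within 6 Å,
van der Waals −0.2 per atom pair in 3–5 Å) with energy-conserving per-residue
attribution and hotspot calling at ≤ −2 kcal/mol. RMSD/Rg/RMSF complete the
picture.

## Worked example

Plant one inter-domain coupling (columns 10 and 80 of a 60+60-column
alignment, obeyed by 90% of 100 sequences, 5% gaps) and recover it:

```r
library(interlock)

gen <- generate_coupled_msa(
  n_seqs = 100, length_a = 60, length_b = 60,
  couplings = list(coupling_spec(10, 80, strength = 0.9)),
  gap_fraction = 0.05, seed = 1
)
res <- predict_coevolving_pairs(gen$msa_a, gen$msa_b, top_n = 5)
tidy(res)
#> # A tibble: 5 × 7
#>       i     j    MI   MIp  rank class    neff
#>   <int> <int> <dbl> <dbl> <int> <chr>   <dbl>
#> 1    10    80 1.79  1.15      1 inter      93
#> 2    83    97 0.889 0.163     2 intra_B    90
#> 3    47    98 0.800 0.155     3 inter      95
#> 4    17    25 0.859 0.154     4 intra_A    90
#> 5    54    64 0.861 0.137     5 inter      94
```

The planted pair ranks first with an $MI_p$ seven times the best background
pair. Now a toy two-chain complex with two planted interface contacts (one a
Lys–Asp hydrogen bond), a planted communication path 2→5→8→11 on chain A, and
a 10-frame ensemble whose final 2 frames have the interface broken:

```r
spec <- toy_complex_spec(12, 12, contact_pairs = list(c(3, 4), c(6, 7)),
                         hbond_pairs = list(c(3, 4)), path_chain = c(2, 5, 8, 11))
base <- generate_toy_complex(spec, seed = 1)
ens <- generate_ensemble(base, n_frames = 10, noise_sd = 0.05,
                         broken_fraction = 0.2, seed = 1)

ensemble_paths(ens, "A:2", "A:11")
#> <path_result> A:2 -> A:11: average length 3.00 over 10/10 frames
#> consensus: A:11, A:2, A:5, A:8

hbond_occupancy(ens)
#> # A tibble: 1 × 5
#>   donor_residue acceptor_residue n_frames_present occupancy stable
#> 1 A:3           B:4                             8       0.8 TRUE

interface_energies(base)
#> # A tibble: 1 × 6
#>   hbond_energy electrostatic_energy vdw_energy total_stabilizing
#> 1         -1.5                   -1       -3.6              -6.1
#> # n_interface_residues 4, normalized_per_residue -1.525

hotspots(base)
#> # A tibble: 4 × 6
#>   node_id chain resno resname energy hotspot
#> 1 A:3     A         3 LYS      -2.15 TRUE
#> 2 B:4     B         4 ASP      -2.15 TRUE
#> 3 A:6     A         6 ALA      -0.9  FALSE
#> 4 B:7     B         7 ALA      -0.9  FALSE
```

The interface separation in the last two frames is visible in the metrics
(backbone RMSD jumps from ~0.1 Å to ~10 Å, Rg from ~17 Å to ~24 Å):

```r
dplyr::left_join(rmsd_series(ens), rg_series(ens), by = c("frame", "time"))
#>    frame  time     rmsd    rg
#>  1     1     0 1.60e-14  16.9
#>  2     2  1000 1.09e- 1  16.9
#>  ...
#>  9     9  8000 1.00e+ 1  23.7
#> 10    10  9000 9.99e+ 0  23.7
```

The whole pipeline — simulate, coevolve, structure network, interface,
metrics, summary — runs from one configuration file:

```r
run_pipeline(system.file("extdata", "demo_config.ini", package = "interlock"),
             outdir = "interlock_out")
```

or from the command line via `inst/cli/interlock run --config cfg.ini`.
Outputs are TSV with a recorded config hash; the same config and seed produce
byte-identical files.

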