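# lipidsites

Protein–lipid interaction sites and residence-time kinetics from
coarse-grained membrane trajectories.

Ion channels and other membrane proteins are regulated by specific lipids —
phosphoinositides such as PIP2, anionic phospholipids such as PS,
cholesterol, gangliosides — that bind at defined sites on the protein
surface. In coarse-grained molecular-dynamics simulations of a protein in a
compositionally complex, asymmetric bilayer, those sites and their kinetics
have to be extracted from millions of bead coordinates. `lipidsites`
implements that analysis chain as a tidyverse-style R package:

- **Contacts.** A residue and a lipid interact in a frame when any bead of
  the residue lies within a cutoff of any headgroup bead of the lipid under
  periodic minimum-image distances (0.65 nm for phospho- and glycolipid
  headgroups; a conservative 1.0 nm for cholesterol). A compiled cell list
  makes this fast; an all-pairs reference path verifies it.
- **Hotspots.** Per-residue interaction frequencies, pooled over the
  monomers and copies of a multimeric protein, as percentages of all
  contacts of a species — with CSV export and a B-factor-coloured PDB for
  surface rendering.
- **Density.** Leaflet-resolved lateral (2-D) radial distribution functions
  g(r) of each species about the protein, and first-annular-shell
  enrichment ratios.
- **Interaction sites.** A residue co-interaction graph — nodes are
  residues, an edge gains weight 1 whenever two residues touch the *same
  lipid molecule in the same frame* — partitioned by weighted Louvain
  community detection (with seeded restarts and a deterministic local
  refinement), each community being one interaction site.
- **Residence times.** The normalised survival time-correlation function

      sigma(t) = (1/N_j) * (1/(T - t)) * sum_j sum_v rho_j(v, v + t),

  where `rho_j(v, v+t) = 1` iff lipid j is continuously bound from time v
  to v + t, normalised so sigma(0) = 1, then fitted with
  `A exp(-t/theta1) + B exp(-t/theta2)`; the larger time constant is the
  residence time, with the SD of the fitted parameter as its error.
- **Structure metrics.** Per-residue RMSF (averaged over time, copies and
  monomers) and residue-pair side-chain distance distributions.
- **Synthetic benchmark data.** A generator of bilayer + multimeric
  scaffold systems with plasma-membrane-like leaflet compositions (outer
  PC/PE/Sph/GM3/Chol 40:10:15:10:25, inner PC/PE/PS/PIP2/Chol
  10:40:15:10:25), planted binding sites and two-state Markov on/off
  kinetics, emitting GRO/PDB files plus exact ground truth — so every
  stage of the chain can be validated against known answers.

## Worked example

Generate a synthetic membrane system with a planted PIP2/PS competition
site, then recover the site and its occupancy statistics:

```r
library(lipidsites)

sys <- generate_system(synthetic_spec(n_frames = 300, seed = 42))
rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
interaction_frequency(rec)
#> # A tibble: 3 x 5
#>   resid resname pooled_key count percent
#>   <int> <chr>   <chr>      <int>   <dbl>
#> 1     2 ARG     ARG2         380    34.6
#> 2     1 ALA     ALA1         359    32.7
#> 3     3 ASN     ASN3         358    32.6

detect_sites(build_interaction_graph(rec), seed = 42)
#> # A tibble: 1 x 4
#>   site_id n_residues total_weight residues
#>     <int>      <int>        <dbl> <list>
#> 1       1          3          990 <chr [3]>
```

The three residues carrying ~100% of PIP2 contacts form a single detected
community — exactly the planted site (`ALA1`, `ARG2`, `ASN3`).

Residence times, from a two-population occupancy simulation (many brief
grazing encounters with a 5-ns mean, tight binding with a 50-ns mean):

```r
occ <- simulate_site_occupancy(300, 1500, k_on = 0.05,
                               k_off = 1 - exp(-1/50),
                               short_fraction = 10/11,
                               k_off_short = 1 - exp(-1/5), seed = 7)
fit_biexponential(survival_curve(occ))
#> <residence_fit> residence time 47.39 +/- 0.0248 ns
#>   A = 0.517, theta1 = 4.867 ns; B = 0.485, theta2 = 47.39 ns
#>   (fit over t <= 749.5 ns, n = 750)
```

Both planted time constants are recovered (4.9 vs 5 ns, 47.4 vs 50 ns);
the reported residence time is the long one. `tidy()`/`glance()` give
broom-style summaries, and `autoplot()` methods plot hotspot tables,
survival curves (with the fit overlay), RDF profiles and site partitions.

The whole chain runs in one call on a trajectory file:

```r
cfg <- run_config("system.gro", "results/", species = c("PIP2", "PS"),
                  monomers_per_copy = 4)
run_pipeline(cfg)   # hotspot/RDF/enrichment CSVs, site + residence JSON,
                    # B-factor PDBs, and a reproducible manifest
```

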