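---
title: "Detecting lipid interaction sites and residence times in coarse-grained membrane simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lipid interaction sites and residence times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsites)
```

# The analysis model

`lipidsites` analyses coarse-grained trajectories of a membrane protein in
a multi-species bilayer and answers three questions: *where* on the protein
surface does each lipid species interact, *how strongly is it enriched*
around the protein, and *how long* does it stay bound. The chain is built
from four statistics.

**Contacts.** A protein residue and a lipid molecule are in contact in a
frame when any bead of the residue (backbone and side chain) lies strictly
within a cutoff of any headgroup bead of the lipid, using minimum-image
distances in an orthorhombic periodic box. The headgroup is defined per
species: phosphate plus the choline/ethanolamine/serine moiety for
PC/PE/PS, the inositol ring with all its phosphates for PIP2, all sugar
beads for the ganglioside GM3, and the steroid core plus hydroxyl for
cholesterol. The default cutoff is 0.65 nm; cholesterol uses a deliberately
conservative 1.0 nm because it remains mobile even while associated with a
site. All residue beads are used on the protein side: interactions mediated
purely by a residue's backbone are documented in this class of data, so a
side-chain-only rule would miss real contacts. Contact counting treats
(frame, lipid) pairs as the unit — a residue touched by two lipids in one
frame counts twice — which is the natural normalisation for "share of all
headgroup interactions"; this is an interpretation choice, recorded here
because frequencies could alternatively count frames-with-any-contact.

**Hotspot tables** convert contacts into per-residue percentages of a
species' total interactions. For a symmetric multimer the counts of
equivalent residues (same name and within-monomer id) are pooled across
monomers and protein copies *before* percentages are taken; pooling is the
default for hotspot tables and off for site occupancy. A strict display
threshold (default 2.5%) selects residues for surface rendering; the PDB
writer places the percentage in the B-factor column.

**Interaction sites** are communities of the residue co-interaction graph:
residues are nodes, and each time two residues contact the *same lipid
molecule in the same frame* their edge weight increases by one. The graph
pools monomer-equivalent residues by default (one graph per species for the
whole system); a per-copy path plus Jaccard-matched consensus merging
(`merge_equivalent_sites()`, residue kept when present in at least half of
the matched sites, ties broken towards the lexicographically smallest
residue key) is available for asymmetric systems. The partition is found by
weighted Louvain modularity maximisation. Because the greedy multilevel
pass is vertex-order sensitive and can stall in local optima on small or
noisy graphs, `detect_sites()` runs a small number of seeded restarts with
shuffled vertex order and polishes each with a deterministic local
refinement — single-node moves, pairwise exchanges across communities,
two-way community splits (exhaustive up to 14 members, spectral above) and
whole-community merges, accepted only when modularity strictly increases —
then keeps the best partition. The result is deterministic given the seed
(default 42, recorded in the output). Raw co-occurrence counts are used as
weights; modularity is invariant to a global weight scale, so the
frame-normalised variant (`normalize = TRUE`) yields the same partition.
Resolution defaults to 1.0 and is exposed because community granularity is
the method's main tunable; edge pruning (`min_weight_fraction`) defaults to
0 — no pruning — and exists for noisy data.

**Residence times** come from the normalised survival time-correlation
function. For lipid $j$ let $\rho_j(v, v+t) = 1$ when the lipid is
continuously bound from time $v$ to $v+t$ inclusive. Then

$$\sigma(t) = \frac{1}{N_j}\,\frac{1}{T-t}\sum_j \sum_v \rho_j(v, v+t),$$

normalised by $\sigma(0)$ so that $\sigma(0) = 1$; $N_j$ counts only lipids
with nonzero interaction time. On a discrete grid the prefactor is
ambiguous (total time vs number of start frames); `lipidsites` resolves it
as the number of admissible start frames, $F - k$ at lag $k$ with $F$
frames, a convention fixed by enumeration (a single lipid bound for 4 of 11
frames has raw $\sigma(0) = 4/11$) and recorded in the curve's metadata.
Lags run to $(F-2)\,\Delta t$, strictly below the total time. With
`gap_tolerance = g` interruptions of at most $g$ unoccupied frames inside
a bound interval are bridged; the default 0 keeps the strict definition,
under which $\sigma$ is provably non-increasing (survival windows nest).

The curve is fitted with $A e^{-t/\theta_1} + B e^{-t/\theta_2}$,
$A,B \ge 0$, $\theta_i > 0$ — two populations: brief encounters in which
the lipid fails to engage the site, and tight binding. The *larger* time
constant is the reported residence time, and the parameter errors are the
standard deviations of the fitted estimates from the fit covariance.

# Numerical choices in the fit

Least squares is unweighted and restricted to $t \le T/2$ by default: the
$1/(T-t)$ prefactor makes long-lag values increasingly noisy. The
optimiser is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`).
Initialisation is deterministic: with $t_e$ the first lag where
$\sigma < 1/e$, the ladder starts at
$(A,B,\theta_1,\theta_2) = (0.5, 0.5, t_e/3, 3t_e)$ and falls back to
$(0.3, 0.7, t_e/2, t_e)$ and $(0.5, 0.5, t_e/5, 8t_e)$ only if the
optimiser fails to converge. Labels are reordered post-fit so
$\theta_1 \le \theta_2$.

Two degeneracies are handled explicitly. When the data are effectively
single-exponential, one amplitude converges to the zero bound and its time
constant becomes unconstrained; reporting "the larger $\theta$" would then
report noise. If one amplitude falls below $10^{-3}$ of the total, the
curve is refitted with a single exponential and returned with $A = 0$ and
$\theta_1 = \theta_2$ equal to the single time constant. Second, a fitted
time constant at or beyond the fit window cannot be resolved by the
trajectory — the fit only bounds it from below — and is flagged
`exceeds_window`.

# The synthetic data generator

Because real microsecond-scale trajectories are neither redistributable nor
recomputable at desk scale, the package ships a generator that emulates the
*geometry and kinetics* the analysis consumes while remaining fully
controlled:

- A static multimeric scaffold (default one copy of four monomers, twelve
  two-bead residues each) in a 30 × 30 nm patch. Planted-site residues are
  clustered at the headgroup plane of their leaflet; all other residues sit
  at the bilayer core, out of headgroup reach. Site anchors are spread so
  that instances of different sites stay outside each other's contact
  range.
- Lipids are minimal three-bead models (one headgroup, two tail beads) at
  fixed leaflet height, performing a lateral Gaussian random walk
  (default step 0.3 nm/frame) with periodic wrapping. Default leaflet
  compositions follow a mammalian plasma-membrane mixture: outer
  PC/PE/Sph/GM3/Chol 40:10:15:10:25, inner PC/PE/PS/PIP2/Chol
  10:40:15:10:25, at 150 lipids per leaflet (0.167 nm² per lipid of
  lateral box would be unphysical, so the generator rejects area per lipid
  below 0.4 nm²).
- Binding is a two-state Markov process per site instance: an unbound
  lipid of a species with affinity for the site binds with probability
  $k_{on}$ per frame while within the capture radius (default 1.8 nm), is
  then placed with its headgroup within $0.9 \times 0.65$ nm of a randomly
  chosen site residue, and unbinds with probability $k_{off}$ per frame,
  upon which it is displaced beyond 1.5× the cutoff. One lipid per site
  instance at a time (a non-exclusive mode exists). A lipid released in a
  frame does not rebind within the same frame, so realised dwell lengths
  are exactly geometric with mean $1/k_{off}$ frames. Unbound lipids are
  actively kept outside contact range of all site residues, which makes
  the ground-truth bound intervals *identical* to the contact-derived
  occupancy — the property the end-to-end tests assert exactly.
- The default scenario plants a two-species competition site (PIP2 with
  $k_{on}=0.5$, $k_{off}=0.02$ against PS with $k_{on}=0.2$,
  $k_{off}=0.1$) and a second PS-only site — a strong binder displacing a
  weak one at a shared site, with a separate secondary site, the
  qualitative situation the analysis is designed to resolve.

What the generator does **not** emulate: forces and excluded volume,
membrane elasticity and undulations, lipid tails with conformational
degrees of freedom, protein flexibility (the scaffold is static), and the
energetic origin of binding. Passing tests on generated data therefore
demonstrate that the *analysis* recovers planted geometry and kinetics
correctly — not that any particular force field produces them.

A second, occupancy-level tier (`simulate_site_occupancy()`) skips the
spatial layer and draws the per-lipid bound/unbound series directly, with
an optional short-lived event population (`short_fraction`,
`k_off_short`). It exists because residence-time recovery studies need
hundreds of binding events at long time constants, which would require
$10^4$-frame spatial simulations for no extra validity.

# The residence-time recovery study

The recovery experiments plant the two-population kinetics the
biexponential model assumes. A single geometric dwell population yields a
single-exponential survival curve, on which the four-parameter model is
unidentifiable: the redundant component chases correlated tail noise and
"report the larger $\theta$" then fails in a substantial fraction of
replicates at any data volume. The study conditions are therefore:
short-event time constant $\theta_s = \max(2, \theta/10)$ frames with
short-event fraction $f_s = (\theta/\theta_s)/(1+\theta/\theta_s)$ — the
equal-amplitude configuration, since a population's amplitude in
$\sigma(t)$ is proportional to its event fraction times its mean dwell —
500 lipids, $\max(600, 30\,\theta)$ frames (a fit window of 15–30
time constants), and $k_{on} = 0.05$ per frame, giving well over 500 long
events per replicate. These sizes were chosen from identifiability
considerations, and the suite asserts recovery of the long time constant
within 15% in at least 90% of 20 seeded replicates for
$\theta \in \{10, 50, 200\}$ ns.

# Density and structure statistics

The radial distribution is two-dimensional (lateral), matching bilayer
geometry: distances are xy-plane minimum-image distances from each protein
copy's lateral centre of geometry to each lipid's headgroup centre of
geometry, leaflet-resolved with leaflets re-assigned every frame from the
headgroup z relative to the global headgroup midplane (bilayer normal fixed
to z). Normalisation divides annulus counts by the uniform expectation
$\rho \cdot \pi (r_2^2 - r_1^2)$ with $\rho$ the species' leaflet count
over the lateral box area, so $g \to 1$ far from the protein; `r_max` may
not exceed half the smallest lateral box length. The reference-point
convention (centre of geometry, not centre of mass or protein surface) is
recorded in the profile's attributes rather than asserted against any
published curve. First-shell enrichment compares a species' share among
lipids within `shell_cutoff` of the nearest protein bead (default 1.0 nm —
"first annular shell" has no canonical definition, so the cutoff is
explicit and configurable) with its share of the whole leaflet, pooled
over frames.

RMSF is computed about the time-mean structure after per-frame, per-copy
centre-of-geometry removal only — no rotational superposition, because
membrane-embedded copies translate laterally but their orientation is
maintained by the bilayer; residue values average the residue's beads and
then pool copies and monomers. Residue-pair distances default to side-chain
centres of geometry (charged side chains reorient; the backbone-only
alternative is available via `bead_rule`), with a histogram, quantiles and
a sample bimodality coefficient reported descriptively.

# File formats and conventions

Coordinates are nm and times ns throughout (PDB Ångström converted on
read/write). GRO (fixed-column, 3-decimal) and multi-MODEL PDB are parsed
natively; binary formats plug in through a reader contract returning
`(time, positions, box)` per frame. Boxes must be orthorhombic — triclinic
input raises an explicit unsupported error. Frames are 0-based in all
outputs, residue ids 1-based (GRO/PDB convention); monomer equivalence is
declared by within-monomer residue id, not inferred from symmetry. Pipeline
outputs use fixed numeric formatting and a manifest without timestamps, so
identical configuration and inputs reproduce every artifact byte for byte.

# Known limitations

- Orthorhombic boxes only; no trajectory alignment or fitting.
- Leaflet assignment by global midplane is wrong for strongly undulating
  membranes; the generator produces flat bilayers, so this is untested
  against curvature.
- The survival estimator shares start windows across overlapping lags, so
  long-lag values are strongly correlated; the default $T/2$ fit window
  mitigates but does not remove this.
- Residence times at or beyond the observable window are lower bounds
  (flagged), not estimates.
- The exhaustive modularity oracle is limited to 13 nodes; community
  results on larger graphs are checked only against the refinement's
  monotonicity, not global optimality.
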