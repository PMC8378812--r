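---
title: "Detecting lipid binding sites from coarse-grained membrane trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lipid binding sites from coarse-grained membrane trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsites)
```

## The problem

Bacterial inner-membrane proteins are surrounded by a mixed bilayer —
predominantly PE, with anionic PG and cardiolipin (CDL) — and many of them
carry discrete surface sites that bind CDL specifically. Coarse-grained (CG)
molecular dynamics is the standard way to sample such protein–lipid
encounters on the microsecond timescale: each lipid is a handful of beads
(for CDL, a central glycerol `GL0` bridging two phosphates `PO1`/`PO2`,
plus tails), and each residue a backbone bead `BB` with optional side-chain
beads.

`lipidsites` implements the analysis layer of that workflow:

1. **Global contact statistics** — leaflet-resolved lipid *binding
   propensity*, z-profiles of lipid-contacting residues, and per-bead-type
   contact profiles.
2. **Site identification** — dual-cutoff (hysteretic) binding kinetics per
   lipid–residue pair, clustering of the residue co-binding network into
   discrete sites, and per-site occupancy/residence-time metrics with the
   standard filters.
3. **Site annotation and statistics** — adjacent-basic-residue geometry,
   composition flags, and occupancy stratification with two-tailed t-tests.
4. **A rule engine** that scores any candidate residue set on a
   membrane-oriented structure against the three-part heuristic for a
   high-affinity CDL site.
5. **A synthetic system generator** producing CG-like membranes with
   *planted* binding sites of known kinetics, so that every stage can be
   validated against ground truth without any simulation data.

## Models and statistics

### Binding propensity

A lipid counts as bound in a frame when any of its beads lies within the
contact cutoff (default 0.6 nm) of any protein bead. For a lipid type $t$
in leaflet $\ell$,

$$\mathrm{propensity}(t, \ell) =
  \frac{\text{share of } t \text{ among bound lipids in } \ell}
       {\text{share of } t \text{ among all lipids in } \ell}.$$

A propensity of 1 means binding proportional to abundance; if a type makes
up 20 % of the bound lipid but 10 % of the membrane its propensity is 2.
Bound counts are aggregated over all post-equilibration frames (the first
10 % of frames are discarded by default). Because the membrane may not
state whether the denominator should be per leaflet or whole-membrane, both
variants are available (`scope = "leaflet"`, the default and the one that
resolves leaflet asymmetry, or `scope = "membrane"`).

### Dual-cutoff binding kinetics

Contact state per (lipid, residue) pair is hysteretic: the pair becomes
bound when the headgroup–residue minimum distance drops below the lower
cutoff (0.55 nm) and unbinds only once it exceeds the upper cutoff
(1.0 nm). This suppresses flicker from thermal noise around a single
threshold. With `upper == lower` the rule degenerates to plain
thresholding, which is how it is unit-tested against a literal two-state
automaton.

### Site identification

Site detection uses only the CDL headgroup beads (`GL0`, `PO1`, `PO2`);
tail contacts are deliberately ignored. Residues that bind the same lipid
at the same time are linked in a *co-binding graph*: the edge weight
between residues $i$ and $j$ is the number of (lipid, frame) pairs bound to
both simultaneously, normalized by the smaller of the two residues' bound
counts. Edges below a retention threshold (default 0.3) are dropped — the
normalization and threshold are this package's choices, made so that
residues binding independently are never linked strongly enough to merge
two disjoint sites. Louvain modularity maximization (via `igraph`, with a
fixed seed for reproducibility) partitions the graph; isolated single
residues are discarded.

Per site:

* **occupancy** = frames with any lipid bound to ≥ 1 site residue / total
  frames;
* **events** = maximal runs of continuous binding per lipid (0-based frame
  indices in all serialized output);
* **residence time** = mean event duration by default. The field often fits
  a single-exponential to the event-survival curve instead; that estimator
  is available (`estimator = "survival"`, falling back to the mean below 20
  events), but the default matches the plain reading of residence as "the
  time the lipid is continuously in contact".

Two filters mirror standard practice: sites with residence time ≤ 10 ns are
dropped (shorter binding is indistinguishable from free diffusion; with the
generator's 1 ns frame spacing this is exactly 10 frames), and residues
contributing less than 10 % of the site occupancy are pruned, after which
metrics are recomputed. The filters are applied after community detection
and metric computation; whether historical pipelines pruned residues before
or after the residence filter is not documented anywhere we know of, and
the order chosen here (residence filter first) is the one that never lets a
pruned residue rescue a short-lived site.

### Annotation and stratification

Basic means Arg or Lys only — His is modeled neutral at membrane pH in the
CG force field and is grouped with the polar residues. Two basics are
*adjacent* when their backbone beads are within 0.8 nm in 3-D in the static
input model (not trajectory averages). Sites are stratified as: all / any
KR / no KR / exactly 1 KR / ≥ 2 KR / ≥ 2 adjacent / ≥ 3 adjacent, where
"≥ k adjacent" means the largest connected cluster of mutually adjacent
basics has ≥ k members. Composition contrasts (Gly, His, Pro, Ser, Thr
present vs absent among ≥ 2-adjacent sites) use Welch's two-tailed t-test
by default; a pooled-variance option exists, and no multiple-testing
correction is applied by default (raw p-values are reported;
Benjamini–Hochberg is available via `p_adjust = "BH"`). The mean basic
count is reported with both SD and SEM since either convention is common.

### The CDL-site rules

A high-affinity CDL site is operationalized as:

1. ≥ 2 basic residues pairwise within 0.8 nm, within 0.3 nm of each other
   on z, with mean |z| in a band of 1.8 ± 0.5 nm from the membrane center.
   The depth tolerance is this package's choice — "roughly 1.8 nm" has no
   canonical tolerance — and is configurable.
2. ≥ 1 polar residue (Ser, Thr or His).
3. ≥ 1 aromatic residue at least 0.2 nm deeper (toward z = 0) than the
   basic cluster's mean depth; "slightly deeper" likewise has no canonical
   number, and 0.2 nm is configurable. Aromatic = Phe/Trp/Tyr, with a flag
   to exclude Tyr. Gly content is reported as an annotation, not a rule.
4. Depths are measured on backbone beads, consistent with the adjacency
   analysis; whether a side-chain reference would be more faithful is an
   open question we resolve in favor of consistency.

`scan_structure()` enumerates all basic pairs/triples passing rule-1
geometry, expands each by residues within 1.0 nm, scores them, and returns
a deterministic ranking (rules passed, then cluster compactness, then
lowest residue id). Tightening any threshold can only shrink the passing
set, which is tested as a monotonicity property.

## The synthetic generator

The generator emulates the study conditions rather than membrane physics:

* two leaflets of POPE/POPG/CDL at 67/23/10 mol% (largest-remainder
  rounding converts fractions to counts deterministically);
* a static protein of residues on a cylinder (radius 1.5 nm) spanning the
  membrane — static so contact ground truth is unambiguous;
* background lipids performing a 2-D random walk (lateral diffusion
  0.05 nm²/ns, a typical CG value) with periodic wrapping;
* planted sites: a residue set plus a dedicated lipid following a two-state
  Markov chain with per-frame probabilities `p_on`/`p_off`; when bound the
  headgroup sits 0.35 nm from the site (inside the lower cutoff), when
  unbound it orbits beyond the upper cutoff, so the dual-cutoff rule
  recovers the planted state series *exactly*;
* frame spacing 1 ns, making the 10 ns residence filter exactly 10 frames.

Geometry is deliberately minimal: all lipid types carry beads at the same
two z-levels (head 2.0 nm, tail 1.2 nm) and all beads of one lipid are
laterally co-located, so every type presents an identical contact
cross-section and binding is composition-proportional when nothing is
planted — the null condition under which every propensity must be ≈ 1.
POPE/POPG are one phosphate plus one tail bead; CDL is `GL0`/`PO1`/`PO2`
plus four tail beads, the smallest bead set that exercises every
headgroup-bead analysis. The generator therefore does **not** reproduce
membrane packing, lipid–lipid interactions, protein flexibility, realistic
bead geometry or electrostatics; tests passing on generated data show the
*analysis* is correct, not that any physical prediction is.

Two practical switches matter for exact recovery tests:
`min_background_distance` keeps background lipids outside an excluded
cylinder around the protein (reflective walls in minimum-image
coordinates), guaranteeing that no background lipid ever crosses the lower
cutoff; and planted sites may name their residues (default cycle
ARG/LYS/SER, making planted sites basic-rich like their real
counterparts).

## Numerical choices

* Orthorhombic minimum-image convention throughout; triclinic boxes are
  rejected.
* The membrane frame puts the phosphate-bead center of mass at z = 0;
  imported systems are re-centered per frame and leaflets assigned from the
  phosphate z sign of frame 0 (warning when a lipid flips for > 50 % of
  frames).
* z-profiles use the backbone-bead position of the *final* frame for
  residues whose any-lipid contact probability exceeds 10 %, with 0.1 nm
  bins (no canonical bin width exists; 0.1 nm resolves the leaflet
  structure).
* The spatially indexed contact search is a periodic cell list with cell
  size ≥ cutoff; it is verified against an exhaustive all-pairs scan.
* Ties in the representative pose are broken deterministically (earliest
  event, then earliest frame, then lowest lipid id).
* Community detection is seeded; the same seed always yields the same
  partition.
* All internal units are nm and ns; Å is converted on PDB read/write.

## Problem sizes

The validation suite runs entirely on generated data: kinetics recovery
uses 20,000-frame trajectories (5 seeds × 3 kinetic regimes) on a 12-residue
protein with 10 lipids per leaflet; propensity calibration uses 5,000
frames with 30 lipids per leaflet; clustering and rule-engine properties
use 100 randomized fixtures each. These sizes were chosen as the smallest
at which the statistical tolerances (occupancy ± 0.05, dwell ± 20 %,
propensity ± 0.15) are comfortably resolved.

## Worked example

```{r example, eval = FALSE}
params <- generator_params(
  n_lipids_per_leaflet = 10, n_protein_residues = 12, n_frames = 20000,
  seed = 1, min_background_distance = 0.7,
  planted_sites = list(planted_site(c(3, 4, 5), p_on = 0.3, p_off = 0.1)))
sys <- generate_system(params)

sites <- find_binding_sites(sys$trajectory, sys$topology,
                            min_residence_ns = NULL)
sites
#> 1 binding site(s) [ CDL ]
#>   site 1: residues {3,4,5}  occupancy 0.745  residence 9.66 ns  1541 events

struct <- structure_from_topology(sys$topology, sys$trajectory)
annotate_sites(sites, struct)[, c("site_id", "n_basic",
                                  "has_adjacent_basics", "leaflet")]
```

The recovered occupancy (0.745 here) estimates the planted stationary
occupancy `p_on / (p_on + p_off) = 0.75`, and the residence time estimates
the geometric mean dwell `1/p_off = 10` frames = 10 ns.

## Limitations

* The generator validates the analysis chain, not membrane biophysics;
  real CG trajectories have correlated lipid motion, protein dynamics and
  non-trivial bead geometry that the toy model omits.
* Residence-time estimation from short trajectories is biased by censoring
  (events truncated at the trajectory ends are counted at their observed
  length); no correction is applied.
* koff / binding free-energy estimation via bootstrapped survival analysis
  is out of scope, as are force-field energetics of any kind.
* The rule engine audits geometry; it does not predict affinities.
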