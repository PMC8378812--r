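# lipidsites

Identification and characterization of lipid binding sites on membrane
proteins from coarse-grained (CG) trajectories, with a focus on cardiolipin
(CDL) binding to bacterial inner-membrane proteins.

Membrane proteins are surrounded by a mixed bilayer (here POPE/POPG/CDL at
67/23/10 mol%), and specific lipids bind at discrete surface sites. From a
CG trajectory this package computes:

* **Binding propensity**, per lipid type and leaflet:
  `propensity = (% of bound lipid) / (% of total lipid)`, with binding
  defined by any-bead contact within 0.6 nm. A value of 1 means binding
  proportional to abundance; e.g. a lipid making up 20 % of the
  protein-bound lipid but only 10 % of the membrane has propensity
  20/10 = 2.
* **z-profiles** of lipid-contacting residues (contact probability > 10 %),
  which resolve the leaflet asymmetry of basic residues, and per-bead-type
  contact profiles (which residues touch the CDL phosphates `PO1`/`PO2`,
  the central glycerol `GL0`, the tails).
* **Binding sites**: per (lipid, residue) pair a hysteretic dual-cutoff
  state series (bound below 0.55 nm, unbound only above 1.0 nm; headgroup
  beads only), a residue co-binding network clustered by Louvain community
  detection, and per-site occupancy (`frames_bound / frames_total`),
  binding events, and residence times — filtered at > 10 ns residence and
  pruning residues below 10 % of the site occupancy.
* **Annotations**: adjacent basic residues (Arg/Lys backbone beads within
  0.8 nm in 3-D), composition flags, and occupancy stratification with
  two-tailed t-tests.
* **A rule engine** scoring candidate sites against the three-part
  heuristic for a high-affinity CDL site: (1) 2–3 adjacent basics in the
  same membrane plane ~1.8 nm from the membrane center, (2) a polar
  residue (Ser/Thr/His), (3) a deeper aromatic.

A synthetic-system generator plants binding sites with two-state Markov
kinetics of chosen `p_on`/`p_off` in a toy CG membrane, so the entire
pipeline is testable against known ground truth — no simulation data
required.

## Worked example

```r
library(lipidsites)

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
#>   site_id n_basic has_adjacent_basics leaflet
#> 1       1       2                TRUE   inner
```

The planted site (residues 3–5, stationary occupancy
`p_on/(p_on + p_off) = 0.75`, mean dwell `1/p_off = 10` frames at 1
ns/frame) is recovered exactly as a residue set; the measured occupancy
(0.745) and residence time (9.66 ns) estimate the planted kinetics.
Scoring a membrane-oriented structure against the CDL-site rules:

```r
st <- generate_rule_structure(seed = 1)   # planted 3-rule site + decoys
rule_report_table(scan_structure(st))[1, c("residues", "overall")]
#>   residues overall
#> 1  1,2,3,4       3
```

A thin command-line wrapper over the same functions lives at
`inst/cli/lipidsites.R` (subcommands `generate`, `contacts`, `sites`,
`annotate`, `rules`, `run`; YAML configuration via `pipeline_config()`).

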