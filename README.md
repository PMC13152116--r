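# hydronet

Internal hydration-network analysis for class A GPCR structures and
trajectories.

Active-state class A G protein-coupled receptors carry ordered internal
water molecules that relay between the sodium-binding pocket (D^2.50,
S^3.39), the NPxxY motif (N^7.49...Y^7.53), the DRY motif (R^3.50) and
the bound Gα C-terminal helix. `hydronet` is for structural biologists and
simulation analysts who want to quantify that relay:

* **Static networks** — classify resolved waters into ligand-pocket (L),
  signalling (S, clusters 1–3) and G-protein-interface (G) regions from
  heavy-atom hydrogen-bond geometry, and test pathway connectivity.
* **Trajectory statistics** — hydrogen-bond episode lifetimes
  `t_avg = Σᵢ t_H-bond,i / N_H-bond`, the per-frame occupied-site count
  `N_Wat(t)`, and the sustained-threshold rehydration time of a depleted
  network.
* **Hydration cavities** — grid-based dual-probe (1.4 Å / 4.0 Å) cavity
  detection and volume measurement, assignment to the conserved (CWC:
  2.50/3.39/7.45), junctional (JWC: 7.53) and extended (EWC:
  3.50/5.58/5.61) water cavities, and classification of the position-5.58
  residue (small-polar vs bulky) that governs EWC hydration.
* **Conservation** — alignment-column residue frequencies and
  property-conservation fractions at the cavity-defining
  Ballesteros–Weinstein positions.
* **Synthetic data** — a seven-helix bundle fixture with a transcribed
  14-water inventory, two-state (bound/unbound) occupancy trajectories
  with exponential dwell times, alignments with injected column
  compositions, and rigid-plus-noise trajectories — every generator emits
  a ground-truth record consumed by recovery tests.

## Worked example

```r
library(hydronet)

## 1. the receptor-like fixture: 14 waters, mapping, site list, truth
d <- tempfile()
b <- make_bundle_structure(dir = d)

## 2. static network workflow: parse -> number -> H-bonds -> classify
res <- run_static_network(b$files$pdb, mapping_path = b$files$mapping,
                          site_names = b$site_names,
                          terminals = b$truth$terminals)
print(res$inventory)
#> hydronet_inventory: 14 water sites
#>          L          S          G unassigned
#>          5          8          1          0
#> S clusters:
#> 1 2 3
#> 2 2 4
res$connectivity$path
#> [1] TRUE
```

Five ligand-pocket waters, eight signalling waters in clusters 2/2/4
(sodium pocket, NPxxY, DRY) and one interface water, with a continuous
hydrogen-bond path from the sodium-pocket aspartate to the partner-chain
carbonyl.

```r
## 3. lifetime recovery on synthetic two-state kinetics
##    (mean bound duration 1.34 ns, dt = 10 ps, 9 sites, 1 us each)
tr <- make_occupancy_trajectory(tau_b = 1340, tau_u = 500, dt = 10,
                                n_frames = 1e5, n_sites = 9, seed = 1)
lt <- occupancy_lifetimes(occupancy_from_matrix(tr$presence, tr$dt))
head(lt, 3)
#>    site n_hbond t_avg_ns censored_n
#> 1 site1     548 1.340985          1
#> 2 site2     546 1.291648          2
#> 3 site3     540 1.352611          1
attr(lt, "pooled")$t_avg_ps / 1000
#> [1] 1.324  # pooled estimate vs injected 1.34 ns

## 4. cavity volume on an analytic fixture (sealed 10 A cube -> 1000 A^3)
sh <- make_shell_structure(inner_edge = 10, sealed = TRUE)
detect_cavities(sh$structure, spacing = 0.5)[[1]]
#> hydronet_cavity: unassigned, 1000.0 A^3, centroid (-0.1, -0.1, -0.1)
```

`t_avg_ns` is the mean duration of uninterrupted hydrogen-bond episodes
per site; `censored_n` counts episodes touching the trajectory
boundaries (included in the mean, reported so you can judge edge bias).
Cavity volumes are voxel counts times spacing³.

A command-line interface covering the three workflows plus the
generators (`network`, `trajstats`, `cavities`, `conservation`, `synth`)
is available through `hydronet_cli()` or the wrapper script
`inst/cli/hydronet.R`; all reports are TSV with a `#`-prefixed header
echoing every parameter used.

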