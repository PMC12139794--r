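# watsite

Hydration-site prediction and consensus water analysis from molecular
dynamics water density.

## The problem

Placing ordered water molecules into experimental density maps — cryo-EM in
particular — is hard: water peaks are faint, resolution-dependent, and easily
confused with noise or ions. A molecular dynamics simulation of the solvated,
fixed solute offers an independent, physics-based source of evidence: where
simulated water density is far above bulk, an ordered water belongs.

`watsite` implements that workflow for structural biologists and simulators:

1. **Site finding.** Water-oxygen observations within the first hydration
   shell (3.25 Å) of the solute are binned on a coarse 0.1 Å voxel grid. A
   sliding 10×10×10-voxel cube (1 Å edge) locates the regions holding the
   most water; cubes are accepted greedily, at least 2.25 Å apart from each
   other and from the solute. The mean position of the waters inside each
   cube is the predicted water position.
2. **Scoring.** Each site is scored by the excess chemical potential of
   water — the work to transfer (WT) a water molecule from bulk to that
   position:

   WT(x) = −kT · ln( ρ(x) / ρ(∞) ),    ρ(∞) = 0.033 Å⁻³.

   Around each site a 1 Å cube is divided into 8,000,000 fine voxels
   (a = 0.005 Å); WT is the Boltzmann average over the densest top 1 %
   (n = 80,000 voxels):

   WT(V) = −kT · ln( Σ exp(−WT(dV)/kT) / n )
         = −kT · ln( S / (n · n_frames · dV · ρ(∞)) ),

   with S the total water count in the selected voxels. Strongly negative
   WT (≈ −4 to −5 kcal/mol) marks positions whose local density exceeds bulk
   more than a thousand-fold.
3. **Consensus analysis.** Waters modelled in multiple experimental
   structures are superposed into one frame (Kabsch, Cα pairing), pooled
   within 4 Å of a reference protomer, clustered by single linkage
   (connected components under strictly-less-than-1 Å links), filtered to
   cluster means within 3.25 Å of the solute, and classified
   *high-consensus* (seen in ≥ 5 structures) or *lower-consensus* (1–4).
4. **Evaluation.** Predicted and experimental waters are matched one-to-one,
   greedily by ascending distance within 2.2 Å, giving precision
   TP/(TP+FP) and recall TP/(TP+FN), optionally as curves over WT
   thresholds or list depth.

A synthetic-data module (`synthetic_spec()`, `generate_trajectory()`,
`generate_pseudo_structures()`, analytic `expected_wt()`) generates systems
with known ground truth, so the whole pipeline is testable without external
data.

## Worked example

Five Gaussian hydration sites of known occupancy are planted in the first
shell of a small pseudo-solute over uniform bulk at 0.033 Å⁻³, and the
pipeline is asked to find them back:

```r
library(watsite)

spec <- default_synthetic_spec(n_frames = 5000, seed = 42)
traj <- generate_trajectory(spec)
traj
#> Water trajectory: 5000 frames, 306526 water-oxygen observations (mean 61.3/frame)

fit <- hydration_sites(traj, spec$solute, max_sites = 5)
fit
#> Hydration-site fit: 5 site(s) from 5000 frames (81292 first-shell observations)
#> WT range: [-4.797, -4.648] kcal/mol at T = 300 K
#> Top 5 sites:
#>   rank      x      y      z window_count     wt density_ratio
#> 1    1  4.297 -0.002 -0.001         5153 -4.797          3125
#> 2    2 -4.297 -0.001 -0.003         4884 -4.766          2962
#> 3    3  0.004  4.295 -0.007         4649 -4.737          2824
#> 4    4  0.006 -4.296  0.006         4320 -4.693          2624
#> 5    5  0.001  0.007  4.289         4004 -4.648          2434
```

The five planted centers (±4.3 Å along each axis) are recovered to within a
few hundredths of an Ångström; the WT values rank the sites exactly by their
planted occupancies (1.00 down to 0.80), and a WT of −4.8 kcal/mol
corresponds to a density ratio above 3000 (column `density_ratio`). Matching
the predictions against the ground truth:

```r
truth <- as.matrix(spec$sites[, c("x", "y", "z")])
match_waters(predict(fit), truth, cutoff = 2.2)
#> Water matching at 2.20 A: TP = 5, FP = 0, FN = 0
#>   precision = 1.000, recall = 1.000
```

`write_sites(fit, "sites.pdb")` exports the sites as water oxygens with WT
in the B-factor column for inspection in any molecular viewer.

For experimental structures, `read_structure()` ingests PDB/mmCIF files and
`consensus_waters()` runs the cross-structure clustering:

```r
recs <- lapply(paths, read_structure)          # nine depositions, say
cw <- consensus_waters(recs, reference = recs[[4]])
summary(cw)
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "watsite.R", package = "watsite"))') \
    predict --trajectory traj.xyz --solute solute.pdb --out run1
```

Subcommands: `predict`, `consensus`, `evaluate`, `simulate`; configuration
comes from a flat YAML file (`--config`) with per-flag overrides. Exit codes:
0 success, 2 validation error, 3 I/O or format error.

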