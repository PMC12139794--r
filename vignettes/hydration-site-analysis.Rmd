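---
title: "Hydration-site analysis by the excess chemical potential of water"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-site analysis by the excess chemical potential of water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watsite)
```

## The model

`watsite` treats ordered-water placement as a density-estimation problem on
a molecular dynamics trajectory of water around a *fixed* solute. Water
molecules are represented solely by their oxygen atom. The central quantity
is the excess chemical potential of water at a position $x$ — the reversible
work to transfer a water molecule from bulk to $x$:

$$\mathrm{WT}(x) \;=\; -kT \,\ln \frac{\rho(x)}{\rho(\infty)},$$

where $\rho(x)$ is the local water-oxygen number density and
$\rho(\infty) = 0.033\ \mathrm{Å^{-3}}$ the bulk density of liquid water
(the pure-liquid and the far-from-solute reference are treated as the same
bulk state). Strongly negative WT marks positions where water is far more
localized than bulk — exactly the positions experimentalists model as
ordered waters. WT is preferred over the protein–water interaction energy
because it balances solute attraction against the free energy of
interaction with the remaining solvent; interaction energy alone does not
separate reliably observed water positions from marginal ones.

Two assumptions are inherited from the simulation protocol the package
expects: the solute is rigid and fixed in the simulation frame (so density
can be accumulated without alignment per frame), and the trajectory is
pre-imaged with the solute whole (no periodic-boundary handling is done).

### Site finding

Candidate sites are the densest 1 Å cubes of first-shell water density:

1. every water-oxygen observation within `shell_predict = 3.25` Å of the
   solute is binned into half-open cubic voxels of edge
   `coarse_voxel = 0.1` Å on a grid spanning the solute bounding box plus
   `shell + 1` Å of padding;
2. a sliding cube of `window = 10` voxels per side (1 Å edge, stride 1) is
   summed exactly over the grid (implemented with a 3-D summed-area table,
   bit-identical to direct summation since all counts are integers);
3. windows are visited in descending count, ties broken by lexicographic
   lowest-corner index, and accepted when their geometric center is at
   least `min_separation = 2.25` Å from every accepted center and
   `min_solute_dist = 2.25` Å from every solute atom.

The *predicted water position* of a site is the arithmetic mean of all
member observations in its 1 Å cube (restricted to the first shell, the
same population the site was selected from); the *cube center* is the
reference position for scoring.

### Scoring

Around each reference position a cube extending 0.5 Å in each direction is
divided into fine voxels of edge `fine_voxel = 0.005` Å — $200^3 = 8\times
10^6$ voxels of volume $dV = a^3$. The per-voxel
$\mathrm{WT}(dV) = -kT\ln(\rho_{dV}/\rho_\infty)$ is Boltzmann-averaged
over the `top_fraction = 0.01` densest voxels ($n = 80{,}000$):

$$\mathrm{WT}(V) = -kT \ln \frac{\sum_{\text{selected}} e^{-\mathrm{WT}(dV)/kT}}{n}
 \;=\; -kT \ln \frac{S}{n\, N_{\text{frames}}\, dV\, \rho_\infty},$$

with $S$ the total count in the selection. The second, count-based form is
what the code evaluates; the test suite verifies it against an independent
enumerate–sort–sum implementation of the first form to $10^{-9}$.

## Parameters

| key | default | units | role |
|---|---|---|---|
| `shell_predict` | 3.25 | Å | first-hydration-shell cutoff (binning, site membership) |
| `shell_aggregate` | 4.0 | Å | pooling shell for experimental waters |
| `coarse_voxel` | 0.1 | Å | coarse voxel edge |
| `window` | 10 | voxels | sliding-cube side (1 Å cube) |
| `min_separation`, `min_solute_dist` | 2.25 | Å | site-acceptance filters |
| `fine_voxel` | 0.005 | Å | fine voxel edge |
| `half_extent` | 0.5 | Å | fine-grid half extent |
| `top_fraction` | 0.01 | — | Boltzmann-average selection (80,000 voxels) |
| `link_cutoff` | 1.0 | Å | single-linkage cutoff (strict `<`) |
| `first_shell` | 3.25 | Å | cluster-mean shell filter (inclusive `≤`) |
| `high_threshold` | 5 | structures | high-consensus class |
| `match_cutoff` | 2.2 | Å | predicted/experimental match distance (inclusive) |
| `temperature` | 300 | K | thermal energy, $kT = 0.59616$ kcal/mol |
| `rho_bulk` | 0.033 | Å⁻³ | bulk reference density |

$k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹. `rho_bulk` is user-overridable
because simulated water models equilibrate to bulk densities slightly
different from experiment; the density-*ratio* estimator only needs the
reference to match the trajectory's own bulk.

The 2.2 Å match cutoff reflects that two water oxygens closer than 2.2 Å
cannot be distinct molecules (the O–O interaction is strongly repulsive
there), so a prediction within 2.2 Å of an experimental water is "the same"
water.

## Numerical choices

* **Half-open voxels.** All binning uses $[o + i a,\, o + (i+1) a)$
  intervals, so every observation lands in exactly one voxel and repeated
  coordinates accumulate deterministically.
* **Boundary conventions.** Linkage is strict (`< 1.0` Å: a pair at exactly
  1.0 Å stays unconnected); shell filters are inclusive (`≤ 3.25` Å); the
  match cutoff is inclusive (`≤ 2.2` Å). These follow the natural reading
  of "less than 1 Å", "more than 3.25 Å … discarded" and "within 2.2 Å".
* **Tie-breaks.** Window selection and fine-voxel selection order ties by
  lexicographic index. Among equal counts the WT value is provably
  unaffected (equal counts contribute equally to $S$); the tie-break exists
  purely for bitwise reproducibility of site lists across platforms.
* **Zero-count voxels in the selection.** When fewer than $n$ fine voxels
  are occupied, zero-count voxels pad the selection and contribute zero to
  the exponential sum (the log of the average, not the average of the log),
  keeping WT finite. Consequently uniform bulk in the sparse regime scores
  $\mathrm{WT} \to -kT\ln\!\big(V_{\text{cube}}/(n\,dV)\big) = -kT\ln 100
  \approx -2.75$ kcal/mol rather than 0. The raw estimator is reported
  as-is; `boltzmann_wt(..., baseline_correction = TRUE)` optionally
  subtracts this baseline, clearly labelled as non-default behaviour.
* **Degenerate inputs.** An unvisited fine cube makes WT undefined: scoring
  drops such sites with a warning, and `boltzmann_wt()` raises a validation
  error. Superposition requires ≥ 3 paired atoms and rejects collinear
  selections (rank-deficient cross-covariance) as numerical errors.
* **Window "position".** The reference point of a 1 Å cube is its geometric
  center (lowest corner + 0.5 Å per axis); separation filters are measured
  center-to-center and center-to-atom. The sampling cube "extending 0.5 Å
  in x, y and z" is interpreted as ±0.5 Å — forced by the stated
  8-million-voxel count at $a = 0.005$ Å.
* **Count vs density sorting.** Fine voxels are uniform, so selecting by
  count equals selecting by density; counts avoid needless division.
* **Cluster size.** A consensus cluster's size is the number of *distinct*
  source structures, not its raw member count: one structure can contribute
  two waters under 1 Å apart, and with nine input structures the size range
  1–9 only holds under the distinct-structure convention.
* **Alternate locations.** Readers keep altloc blank or `A` only, and drop
  hydrogens and common ions from both solute and water sets.

## The synthetic generator

`synthetic_spec()` describes a box of uniform bulk (Poisson-distributed
uniform points at `bulk_density`, default 0.033 Å⁻³) plus localized sites:
per frame, each site emits one oxygen with probability `occupancy`,
displaced from its center by an isotropic Gaussian of width `sigma`.
`generate_pseudo_structures()` emulates independently determined
experimental structures: each true site is detected with probability
`detect_prob` and jittered by `jitter_sigma`.

The reference conditions (`default_synthetic_spec()`) are five sites with
occupancies 1.00–0.80 and widths 0.12–0.20 Å placed 2.8 Å from the
pseudo-solute (inside the 2.25–3.25 Å acceptance shell, > 4 Å apart),
bulk at 0.033 Å⁻³ in a 12 Å box, 20,000 frames. Occupancies near 1 and
widths of ~0.15 Å mimic well-ordered first-shell waters whose WT then
falls in the −4 to −5 kcal/mol range typical of high-consensus positions;
20,000 frames keep the full recovery test under a minute on one CPU while
holding the Monte-Carlo error of WT well below 0.05 kcal/mol.

`expected_wt()` supplies the analytic expectation of the estimator. In the
sparse regime (expected in-cube observations $M \ll n$), every observation
occupies its own selected voxel, so $E[S] = M = N_{\text{frames}}
(\text{occ} \cdot f_{\text{cube}} + \rho_{\text{bulk}} V_{\text{cube}})$
with $f_{\text{cube}}$ the Gaussian mass inside the cube (a product of 1-D
normal CDF differences), giving
$\mathrm{WT} = -kT \ln\!\big(M/(n N_{\text{frames}} dV \rho_\infty)\big)$.
Outside that regime the expected per-voxel intensities are enumerated on
the full fine grid and the top-$n$ selection applied to them; this ignores
fluctuations around the selection boundary and is documented as an
approximation. Desk-scale frame counts stay firmly in the sparse regime.

The generator intentionally omits several features of real MD water:
temporal autocorrelation (site occupancy is Bernoulli per frame — WT is a
per-frame density functional, so autocorrelation affects error bars, not
expectations), anisotropic and multi-modal site shapes, hydrogen positions,
solute flexibility, and density depletion immediately at the solute
surface. Passing recovery tests therefore demonstrate the correctness of
the *estimator and pipeline machinery*, not force-field accuracy or
real-data performance; on real trajectories the same code path applies
unchanged but accuracy is bounded by the simulation itself.

## Problem sizes and limitations

The package's own validation runs at desk scale: boxes ≤ 15 Å, trajectories
up to 20,000 frames, and coarse grids around $120^3$ voxels, chosen so the
complete test suite finishes in well under a minute of compute per stage on
a single CPU. Production-scale inputs (a full protein with a 100,000-frame
trajectory) are supported by the same code but note:

* the coarse grid is stored densely; a large solute at 0.1 Å resolution can
  require hundreds of millions of voxels — beyond `tabulate()`'s integer
  indexing the accumulator refuses and asks for a coarser grid or tighter
  padding. A chunked/sparse accumulator would be the natural extension.
* trajectory I/O via multi-model PDB or XYZ is text-based and therefore
  slow for very long trajectories; binary MD formats should be converted
  (or strided) upstream.
* matching is $O(n_p \times n_e)$ in memory; fine for the few hundred to a
  few thousand waters typical per protomer.
* single-linkage clustering materialises the pairwise distance matrix;
  adequate to a few thousand pooled waters, quadratic beyond.

Deliberate non-goals: free-energy-perturbation estimates of the insertion
free energy (the density-ratio route is the estimator), entropy/enthalpy
decompositions or orientational statistics of inhomogeneous-solvation
frameworks, kernel density smoothing, Hungarian-optimal matching (the
one-to-one matching is greedy by proximity, by design), and any cryo-EM map
processing — experimental inputs enter only as modelled water coordinates.

## Open design points, resolved

* Equal bulk references: the pure-liquid and far-from-solute free-energy
  references are treated as the same state, so only the density ratio is
  ever computed.
* The integration extent of the Boltzmann average is the 1 Å sampling cube
  itself.
* A site's member waters for the mean position are restricted to the first
  shell, because the site was selected from first-shell counts.
* Experimental waters are not deduplicated across alternate conformers
  beyond the altloc-A rule; the strict 1 Å linkage merges true duplicates
  at clustering time while the distinct-structure cluster size keeps the
  consensus count honest.
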