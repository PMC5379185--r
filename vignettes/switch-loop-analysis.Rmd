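---
title: "Characterising switch-loop conformational states with swiscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising switch-loop conformational states with swiscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swiscape)
```

## The problem

Small GTPases such as RhoA act as molecular switches: the Switch I loop
(residues 28–40 in RhoA numbering) adopts different conformations depending
on whether GDP or GTP is bound, and the GTP-bound loop itself interconverts
between an effector-competent state and a "GDP-like" state. Characterising
these sub-states from simulation data requires (i) low-dimensional
coordinates that separate the states, (ii) enhanced sampling to cross the
free-energy barriers between them, (iii) unsupervised clustering of the
loop's internal coordinates, and (iv) physical descriptors — solvation and
component-wise interaction energies — that explain why one state is
preferred over another. `swiscape` implements this pipeline as reusable,
testable R functions, exercised at desk scale on analytic landscapes and
synthetic loop ensembles with known ground truth.

## Two-reference collective variables

A single reference structure cannot resolve states that are both far from
it: RMSD-like quantities are degenerate. The package therefore projects
every conformation against *two* references, an inactive ("GDP-bound") and
an active ("GTP-bound") structure.

**DRMSD.** For an atom selection of size $N$ (by default all C$_\alpha$
atoms of the loop),
$$\mathrm{DRMSD}(X, X^{\mathrm{ref}}) = \sqrt{\frac{1}{P}
\sum_{i<j}\left[d(x_i,x_j) - d(x^{\mathrm{ref}}_i, x^{\mathrm{ref}}_j)
\right]^2},\qquad P = \binom{N}{2},$$
computed over internal pairwise distances, so no superposition is needed
and the value is exactly invariant under rigid motion. `drmsd_projection()`
returns the per-frame pair (DRMSD vs inactive, DRMSD vs active).

**Dihedral similarity $S$.** For backbone dihedrals
$\theta_i$ with reference values $\theta_i^{\mathrm{ref}}$,
$$S = \sum_i \tfrac12\left(1 + \cos(\theta_i - \theta_i^{\mathrm{ref}})
\right) \in [0, n_{\mathrm{angles}}],$$
maximal exactly when every angle matches its reference. A Gaussian-kernel
form $S = \sum_i \exp(-\Delta\theta_i^2 / 2\sigma^2)$ is also available,
with the angular difference always taken minimum-image on the circle.
The half-cosine form is the default: with the narrow kernel width of
2.3° that is natural for hill deposition, the Gaussian-kernel similarity
is almost everywhere zero and cannot produce broad, smoothly varying
basins in the $(S_{\mathrm{GDP}}, S_{\mathrm{GTP}})$ plane; the
half-cosine form is smooth (its gradient is analytic, which the biased
sampler exploits) and range-stable. The kernel form remains a
configuration switch for sensitivity analysis.

`s_projection()` maps an ensemble into the $(S_{\mathrm{inactive}},
S_{\mathrm{active}})$ plane; `map_structures()` places single structures
(e.g. crystal conformers) onto the same plane so they can be overlaid on a
free-energy surface.

## Well-tempered metadynamics at desk scale

The sampling engine is an overdamped Langevin integrator
($x \leftarrow x - (\Delta t/\gamma_f)\nabla U + \sqrt{2 k_BT \Delta t
/\gamma_f}\,\eta$) biased by Gaussian hills deposited every `stride` steps
along 1–2 collective variables. Hills are tempered:
$$h(t) = W\exp\!\big(-V(s,t)/((\gamma - 1)k_BT)\big),$$
so the accumulated bias converges to $-(1 - 1/\gamma) F(s)$ and
$$\hat F(s) = -\tfrac{\gamma}{\gamma-1} V(s, t_{\mathrm{final}}) + C.$$
A second, independent estimate comes from time-dependent reweighting: each
recorded frame receives weight $w(t) \propto \exp[(V(s(t),t) - c(t))/k_BT]$
with the running offset
$$c(t) = \tfrac{1}{\beta}\ln\frac{\sum_s e^{\beta\frac{\gamma}{\gamma-1}
V(s,t)}}{\sum_s e^{\beta\frac{1}{\gamma-1} V(s,t)}}$$
maintained on the bias grid and refreshed at every hill (initial $c = 0$).
The two estimators (`fes_from_bias()` and `reweight()`) must agree; their
gap is one of the package's standing cross-checks.

Defaults follow common practice for loop-scale CVs: initial hill height
$W = 0.1$ kcal/mol deposited every 2 ps of sampler time, $k_BT = 0.5962$
kcal/mol (300 K). The bias factor is not dictated by the problem; the
package uses $\gamma = 10$, a mid-range standard for dihedral-type CVs,
and exposes it in the configuration. Hill widths are specified in the CV's
own units; for angular CVs, degrees are accepted at the file interface and
converted. For a dimensionless similarity CV the width must be chosen
relative to the CV range — a width quoted in degrees for such a CV is
flagged rather than silently converted.

Because biasing an all-atom solvated protein is far outside desk scale,
the engine is validated on analytic potentials with independent oracles:

* `double_well_1d()` / `double_well_calibrated()` — a quartic double well
  whose basin free-energy difference (by quadrature of the Boltzmann
  weight on each side of the saddle) and energy barrier (by direct
  optimisation) can be prescribed exactly. The shipped validation uses
  $\Delta G = 2.0$ and barrier $= 4.0$ kcal/mol; both estimators must
  recover $\Delta G$ within 0.3 kcal/mol, the barrier within 0.5, and
  each other within 0.2.
* `mueller_like_2d()` — the classic three-basin 2-D benchmark, rescaled
  to a few kcal/mol.
* `dihedral_chain()` — independent per-angle double wells, so the $S$
  similarity itself can be the biased CV end to end.

**Numerical choices.** The in-run bias and its gradient live on a per-CV
grid (400 points by default) updated analytically at each hill and read
back by linear interpolation — $O(1)$ per step, which keeps a $10^6$-step
R-level run around ten seconds. Post-hoc surface evaluation
(`fes_from_bias()`, `bias_value()`) sums hills exactly. Surfaces are
masked where no hill centre lies within 3 hill widths, preventing
extrapolated artifacts at unexplored edges, and shifted so the unmasked
minimum is zero. Convergence of a desk run is judged by the basin
$\Delta G$ estimate changing by less than 0.05 kcal/mol over the last 20%
of hills.

## Basins and barriers

`find_basins_barriers()` implements a water-level flood fill: bins are
flooded in order of increasing free energy; a local minimum opens a basin,
and the level at which two basins first connect is their lowest separating
saddle (the minimax path height). Basins with persistence below
`min_depth` (default 0.5 kcal/mol; 1.0 for sampled surfaces, which are
noisier) are absorbed into their deeper neighbour. Reported quantities:
basin locations and values (labels A, B, C, … by increasing minimum),
pairwise barriers $\mathrm{saddle}(i,j) - F_i$, and
$\Delta G_{ij} = F_j - F_i$. The implementation is verified against an
exhaustive level-search oracle (BFS connectivity at every candidate
level) on 20×20 grids. Barrier estimates can only decrease as the grid is
refined — spurious saddles from coarse bins disappear, never appear.

## Sub-state discovery

Dihedral features are embedded as $(\sin\theta, \cos\theta)$ pairs before
k-means. The paper-style alternative — clustering raw angles — breaks at
the ±180° seam; the embedding makes Euclidean distance the chord length
$2|\sin(\Delta/2)|$, monotone in angular separation, with no seam. A
raw-angle mode is retained for fidelity comparisons. Clustering uses
k-means++ seeding followed by Lloyd iterations (`stats::kmeans`,
"Lloyd", ≤500 iterations, relative inertia tolerance $10^{-6}$), best of
`n_init` restarts, fully reproducible per seed. The cluster count defaults
to $k = 4$, matching the protocol the pipeline mirrors; silhouette-style
diagnostics can be computed but $k$ is never auto-selected. Populations
and label accuracies are only ever compared after optimal label matching
(`match_labels()`, exhaustive over the $k!$ permutations), because k-means
labels are arbitrary.

The default feature set is all loop-residue $\phi/\psi$ angles plus
$\chi_1$ of the two reporter side chains (Tyr34/Phe39 in RhoA numbering);
which residues count as "conserved" is configuration, not code. $\chi_1$
is defined by N–CA–CB–XG with XG from a per-residue-type table (Tyr: CG);
where a published analysis might have meant $\chi_2$, that is an explicit
config option rather than a guess.

Side-chain signature classification (`classify_frames()`) is rule-based:
closed if the minimum side-chain–partner heavy-atom distance is strictly
below 3.5 Å (hydrogen-bond range), open if strictly above 5.5 Å,
intermediate otherwise. Comparators are strict, so boundary frames fall
into `intermediate`; the rules are validated for mutual exclusivity and
coverage at construction time.

## Hydration and interaction energies

`water_count()` counts a water once if its oxygen lies within the cutoff
(default 4 Å) of any heavy atom of the residue — the oxygen-only
convention is the field standard when the criterion is unstated; any-atom
counting is a flag. `hydration_profile()` averages over frames and
attaches a block-averaged standard error (default block length 100
frames), which converges to the naive SE for independent frames and
exceeds it for positively correlated ones; the SE method is recorded in
the output. Residues are classed nonpolar
(Ala/Val/Leu/Ile/Phe/Pro/Met/Gly/Trp) or polar for the reporting split.

Interaction energies are plain pairwise sums with a distance cutoff
(default 10 Å = 1 nm), no periodic imaging and no Ewald — appropriate for
whole-molecule extracts: Coulomb $332.0636\, q_iq_j/r$ (kcal/mol, e, Å)
and Lennard-Jones in Rmin form
$\varepsilon_{ij}[(R_{ij}/r)^{12} - 2(R_{ij}/r)^6]$ with geometric-mean
$\varepsilon$ and $R_{ij} = R_i/2 + R_j/2$, the combination rules of the
CHARMM family. `delta_energy()` reports
$\Delta E_g = \langle E_g\rangle_{\mathrm{active}} -
\langle E_g\rangle_{\mathrm{inactive}}$ per partner group (protein, water,
nucleotide, ion) with block-averaged errors; a group absent from one
system is reported missing, never silently zero. Because the energy is a
pair sum, `residue_decomposition()` partitions the loop total exactly
(the per-residue focal sets tile the loop against fixed partner sets).
$\Delta E$ is a mean interaction-energy difference, not a free energy: no
entropic correction is attempted.

## What the synthetic generators emulate — and what they do not

Every pipeline input class has a seeded generator that emits its ground
truth alongside the data:

* `gen_loop_ensemble()` — mixtures of dihedral states: per frame a state
  is drawn by weight, $\phi/\psi$ are drawn from von Mises distributions
  (concentration $\kappa$, chosen over the wrapped normal for its
  closed-form density, which the distributional tests integrate), and 3-D
  coordinates are rebuilt by internal-coordinate chain extension (N–CA
  1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, ω fixed trans). The default loop
  has 13 residues numbered 28–40 so documented selections match Switch-I
  numbering. κ = 50 (angular SD ≈ 8°) is a realistic within-basin spread
  for a loop backbone.
* `gen_reference_pair()` — noise-free conformations at the state means,
  standing in for the inactive/active crystal references.
* `gen_solvated_frame()` — homogeneous Poisson oxygen sites at a given
  density (bulk water ≈ 0.0334 Å⁻³) in the solute's bounding box plus
  margin.
* `gen_toy_energetics()` — paired charged/LJ site systems constructed so
  the active system trades favourable solvation for stronger nucleotide
  interaction (Δwater > 0, Δnucleotide < 0, Δtotal < 0), verified by
  direct summation at generation time.

These emulate the *statistical structure* of the real problem — multi-state
dihedral mixtures, two distinguishable references, solvent at realistic
density, competing energy components — but not real protein geometry:
there are no side chains beyond an ideal CB, no excluded-volume
interactions between states, no solvent structure (Poisson, not liquid),
and no force-field realism. Passing tests therefore demonstrate that the
*machinery* (CVs, sampler, estimators, clustering, counting, energy sums)
is correct and internally consistent, not that any particular biological
conclusion is reproduced.

## Degenerate inputs and edge conventions

Collinear atom quadruples make a dihedral undefined and raise an error
rather than returning an arbitrary value. Angles are always wrapped to
(−π, π], with +π (trans) the canonical representative. Empty atom
selections are legal (they select nothing); overlapping focal/partner
groups are not. A reweighting bin that receives no weight is masked, not
reported as zero free energy. Frames exactly on a classification
threshold go to `intermediate` (strict comparators). k-means restarts
never replace a model with a worse-inertia one, and empty clusters cannot
occur with k-means++ seeding on ≥ k distinct rows (fewer distinct rows is
an error).

## Problem sizes

The shipped validation runs at sizes chosen to finish interactively on a
single core: $10^6$ Langevin steps for the double-well metadynamics
recovery, 4000 frames for the four-state clustering recovery, 50 solvated
frames (≈500 waters each) for the hydration statistics, 40-frame toy
systems for energetics, and a 150-frame demonstration pipeline. All are
stated in the configuration and scale up transparently.

## Known limitations

* The sampler is overdamped Langevin only; no inertial or thermostatted
  MD, no replicas, no adaptive hill widths.
* Two CVs at most; the FES tooling is 1-D/2-D.
* No periodic-boundary treatment anywhere: the package analyses
  whole-molecule extracts, and the toy systems are non-periodic by
  construction.
* The PDB writer emits a fixed single chain and standard columns only.
* Backbone reconstruction uses ideal geometry; it is a generator for
  synthetic ensembles and a round-trip test harness, not a model builder.

## A minimal session

```{r example, eval = FALSE}
spec <- two_state_loop_spec(n_res = 13, kappa = 50, weights = c(0.6, 0.4))
gen  <- gen_loop_ensemble(spec, n_frames = 200, seed = 1)
refs <- gen_reference_pair(spec)

proj <- s_projection(gen$ensemble, refs)      # (S_inactive, S_active)
plot(proj)

dh <- extract_dihedrals(gen$ensemble, 28:40, c("phi", "psi"))
km <- cluster_states(build_features(dh), k = 4, seed = 2)
population_table(km)

pot <- double_well_calibrated(delta_g = 2, barrier = 4)
run <- wt_metad(pot, cv_coordinate(1, range = c(-2.2, 2.2)),
                W = 0.1, widths = 0.1, stride = 400, bias_factor = 10,
                n_steps = 2e5, x0 = pot$reference$x_min[1], seed = 3)
fes <- find_basins_barriers(fes_from_bias(run$bias), min_depth = 1)
fes$basins
```
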