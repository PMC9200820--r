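---
title: "Characterizing conformational ensembles of predicted structure models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conformational ensembles of predicted structure models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confens)
```

## The problem

Deep-learning structure predictors can emit hundreds or thousands of
candidate models (decoys) for a single sequence. For proteins that
function through a conformational equilibrium — hinge-bending enzymes such
as adenylate kinase, lid-gated lysozymes, integrin I-domains — the decoy
set is interesting precisely because it may sample *several* functional
states, not just the single most populated crystal form. confens
implements the post-prediction half of that workflow: given the decoy
coordinates and an external per-model energy (e.g. a coarse-grained
force-field rescoring), it filters, clusters, and characterizes the
surviving ensemble, and compares its collective motions against a
reference ensemble such as an MD trajectory of the experimental
structure.

The package deliberately does **not** predict structures or compute
energies. Models come in as multi-model PDB files; energies come in as a
`model_id,energy_kcal_mol` CSV.

## The procedure

The pipeline (`run_pipeline()`) executes the stages in a fixed order:

1. **Mean-energy filter.** With energies $E_1,\dots,E_n$ the threshold is
   the arithmetic mean $\bar E$; every model with $E_i > \bar E$ is
   removed, models at exactly $\bar E$ are kept. The rule is applied once:
   re-filtering the kept subset would recompute a lower mean and keep
   shrinking the set, which is not the intent of a single triage pass.
2. **Pairwise RMSD matrix.** Entry $(i,j)$ is the backbone RMSD after an
   *independent* optimal (Kabsch) superposition of that pair. Because each
   pair is fitted separately the matrix is a dissimilarity, not a metric;
   we therefore never embed it in Euclidean space and do not offer
   Ward-type linkages.
3. **Hierarchical clustering with elbow-selected k.** Agglomerative
   clustering (average linkage by default) on the precomputed matrix. The
   within-partition dispersion is
   $W(k) = \sum_c \frac{n_c}{n}\,\overline{d^2_c}$, the size-weighted mean
   of each cluster's mean within-cluster squared RMSD. The elbow is
   formalized as the $k \in \{2,\dots,k_{max}-1\}$ maximizing the discrete
   second difference $W(k-1) - 2W(k) + W(k+1)$, ties to the smallest $k$;
   when $W(1)$ is already below a flatness floor (0.25 Å², i.e. a typical
   within-ensemble RMSD of 0.5 Å) the ensemble is called homogeneous and
   $k = 1$. A visual elbow is irreproducible; the second difference is the
   standard deterministic surrogate and recovers the visual answer exactly
   on well-separated ensembles.
4. **Centroids.** Each cluster's representative is its *lowest-energy*
   member (not a geometric average), ties to the smallest model index.
5. **Ensemble characterization.** The kept models are iteratively aligned
   to their mean; then per-residue RMSF (reported in nm), Cartesian PCA of
   the Cα coordinates, projection of both the models and the reference
   ensemble onto PC1, the overlap of the two projection densities, hinge
   descriptors (aperture angle, inter-domain distance), classification
   against labelled references with population fractions, and the ensemble
   spread ΔRMSD (the maximum pairwise backbone RMSD).

## Conventions and tunable parameters

* **Backbone** means N, CA, C, O; the carbonyl O can be excluded
  (`include_o = FALSE`) and a Cα-only selection is available, because
  "backbone RMSD" is reported both ways in the literature. Synthetic
  Cα-only chains degrade gracefully: the backbone selection then picks the
  Cα trace.
* **Superposition** is unweighted; a weights argument exists for
  extensions but no mass weighting is applied anywhere, and the SVD
  determinant correction forbids reflections.
* **Alignment** (`align_to_mean()`): tolerance 1e-6 Å on the mean shift,
  at most 10 iterations, first model as the initial reference. Two to
  five iterations typically suffice.
* **RMSF** uses the Cα atom per residue by default (`"backbone"` uses the
  backbone-atom centroid) and is reported in nm, the conventional
  trajectory-analysis unit, while all coordinates stay in Å.
* **PCA** is Cα by default. Components carry a sign convention (largest
  entry positive) so projections are reproducible. Projection of an
  external ensemble refits each model to the PC mean first; the fitting
  ensemble itself is projected without refitting (`refit = FALSE`), which
  makes the score variance equal the component variance identically.
* **Density overlap** uses Gaussian KDEs with Silverman bandwidths on a
  shared 512-point grid padded by three bandwidths; doubling the grid
  changes the value by less than 1e-3. A zero-variance series is treated
  as a point mass (overlap = fraction of the other series within one
  bandwidth).
* **Classification** margin (`intermediate_margin`): 0 by default, giving
  a strict nearest-reference rule and binary populations; a positive
  margin introduces an `"intermediate-like"` class for models nearly
  equidistant from two references, which some systems (e.g. I-domain
  surveys) need.
* **ΔRMSD** is read as the ensemble *diameter* (max pairwise RMSD). The
  alternative reading — the range of RMSDs to one reference — is available
  as `method = "reference_range"`.
* **Clustering linkage** defaults to average, the common robust choice for
  precomputed dissimilarities; complete and single are available because
  published pipelines differ and rarely state the linkage.

## The synthetic generator

Real decoy sets and MD trajectories are too heavy for unit testing and
carry no ground truth. The generator builds the smallest article that
exercises every operation:

* **Geometry**: a Cα-only chain (46 residues by default) of two straight
  20-residue arms at 3.8 Å spacing joined by a short hinge segment; "open"
  and "closed" endpoints subtend 130° and 60° at the hinge. By
  construction the aperture-angle descriptor of an endpoint equals its
  θ exactly, and the endpoint separation grows monotonically with
  Δθ.
* **Decoys**: each of 1000 models draws a state from a 30/70 open/closed
  mixture, a morph coordinate λ ~ N(state, 0.02) with 0 = open and
  1 = closed, and coordinates `(1-λ)·open + λ·closed` plus 0.2 Å per-axis
  noise. The defaults mirror the scale of a real decoy study (a thousand
  models, two states with a minority population near 30%, state
  separation two orders of magnitude above the noise).
* **Energies**: a double well
  $E(\lambda) = -E_0 + 16h\,\lambda^2(1-\lambda)^2 + c\lambda +
  \mathcal N(0, \sigma_E^2)$ with $E_0 = 700$, $h = 25$, $c = 0$,
  $\sigma_E = 5$ kcal/mol — wells near −700 kcal/mol as for a ~200-residue
  coarse-grained rescoring, a barrier far above the scoring noise, and
  $E(0.5) = -E_0 + h$ exactly. Note the quartic penalizes over-extension
  (λ outside [0, 1]) even more steeply than the barrier, so with a tight
  two-state λ distribution the filter mostly trims over-extended and
  unlucky-noise models; barrier-region enrichment among the removed
  models appears when λ actually spans the well-to-well domain.
* **Pseudo-trajectory**: a mean-reverting discrete walk
  $\lambda_{t+1} = \lambda_t + \kappa(\mu-\lambda_t)\Delta t +
  \sigma\sqrt{\Delta t}\,\xi_t$ reflected into [−0.2, 1.2], rendered
  through the same morph. The reflection bounds deliberately allow slight
  over-opening beyond the crystallographic endpoints, an amplitude excess
  predicted ensembles are known to show relative to MD. Defaults
  (κ = 1, Δt = 0.05, μ = 0.5, σ = 0.6, 500 frames) make the walk
  visit both wells.

Everything is a pure function of (spec, seed); the pipeline reseeds the
generator, the energy noise and the trajectory deterministically from one
master seed, so identical configs give byte-identical outputs.

**What passing tests do and do not show.** The generator has exactly one
collective degree of freedom, linear Cartesian geometry (mid-morph bond
lengths are distorted — acceptable for a geometric test article), no side
chains, no solvent and Gaussian noise. Recovery of k, populations, PC1
dominance and descriptor monotonicity on it validates the *machinery*,
not the biological claim that any particular predictor samples functional
states; on real data the PC1 variance fraction, overlaps and populations
are reported, never asserted.

## Numerical choices and degenerate inputs

* Cosines are clamped to [−1, 1] before `acos`; coincident region centers
  are an error, not NaN.
* A single-model ensemble has RMSF undefined (error) and spread 0.
* All-identical models give a degenerate PC model (zero variances,
  `variance_fraction = NA`, flagged) rather than dividing by zero.
* Cluster labels are renumbered by decreasing size with smallest-member
  tie-break, so permuting the input changes labels only by that rule,
  never the partition.
* Altlocs resolve to the highest-occupancy conformer (blank preferred on
  ties) at read time; insertion codes are rejected so residue keys stay
  integers.
* The elbow needs an interior point: with `k_max = 2` and a non-flat
  curve the only candidate, k = 2, is returned directly.

## Problem sizes

The shipped tests run the study conditions at their native scale where it
matters (population recovery at n = 1000 over ten seeds; cluster recovery
at n = 200 over twenty seeds; calibration of the density overlap at 1e5
samples; the stationary variance of the pseudo-trajectory at 1e5 frames)
and small toy articles everywhere a property is scale-free.

## Known limitations

* RMSD clustering operates on the whole selection; there is no flexible
  or partial superposition, and topologically different models cannot be
  compared (no sequence alignment).
* The aperture/distance descriptors require user-specified regions; real
  systems need their own domain definitions (an adenylate kinase example
  config ships in `inst/extdata/`).
* Side-chain orientation descriptors are out of scope — distinguishing
  rotameric states of individual residues is known to be beyond this kind
  of backbone clustering.
* mmCIF and binary trajectory formats are not read; convert to
  multi-model PDB first.
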