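---
title: "Multi-modal dynamic cross-correlation: models, parameters and design choices"
author: "mdccr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal dynamic cross-correlation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdccr)
```

## The problem

Dynamic cross-correlation (DCC) maps are a standard way to read correlated
motion out of a molecular-dynamics trajectory: for atoms $i$ and $j$,

$$\mathrm{DCC}(i,j) =
  \frac{\langle \Delta\mathbf{r}_i(t)\cdot\Delta\mathbf{r}_j(t)\rangle_t}
  {\sqrt{\langle\|\Delta\mathbf{r}_i(t)\|^2\rangle_t\,
         \langle\|\Delta\mathbf{r}_j(t)\|^2\rangle_t}},
  \qquad
  \Delta\mathbf{r}_i(t) = \mathbf{r}_i(t)-\langle\mathbf{r}_i(t)\rangle_t .$$

The mean position $\langle\mathbf{r}_i\rangle_t$ is a poor reference when an
atom's sampled distribution is multi-modal — a side chain flipping between
rotamers, a loop touching and leaving a binding partner.  Deviations are
then measured from a point the atom rarely visits (between the basins), and
a contact that is formed only part of the time averages away to a weak DCC
value even when the coupled motion inside the contact episodes is strong.

The multi-modal variant (mDCC) implemented here fixes both defects.  Each
atom's coordinate cloud is described by a Gaussian mixture; one mixture
component is a *mode* (one basin).  For mode $k$ of atom $i$ and mode $l$
of atom $j$,

$$\mathrm{mDCC}(i,j;k,l) =
  \frac{\langle w(t)\,(\Delta\mathbf{r}_{i,k}(t)\cdot\Delta\mathbf{r}_{j,l}(t))\rangle_t}
  {\sqrt{\langle w(t)\,\|\Delta\mathbf{r}_{i,k}(t)\|^2\rangle_t\,
         \langle w(t)\,\|\Delta\mathbf{r}_{j,l}(t)\|^2\rangle_t}},$$

with $\Delta\mathbf{r}_{i,k}(t) = \mathbf{r}_i(t) - \boldsymbol{\mu}_k$ the
deviation from the mode center and
$w(t) = p_k(\mathbf{r}_i(t))\,p_l(\mathbf{r}_j(t))$ the joint posterior
probability that both atoms occupy those modes at time $t$.  Frames where
the mode pair does not co-occur contribute (almost) nothing; deviations are
measured from the basin the atom is actually in.  By the weighted
Cauchy–Schwarz inequality the value lies in $[-1, 1]$, and when both atoms
are uni-modal ($K = 1$, $w \equiv 1$, $\boldsymbol{\mu}$ = the mean) the
expression collapses exactly to DCC — a reduction the test suite asserts to
$10^{-9}$ on a 50-atom system.

## Mode fitting

`fit_modes()` fits full-covariance 3-D Gaussian mixtures by
expectation–maximization.  Choices that matter:

* **Model selection.** $K$ is chosen by BIC over $K = 1..\texttt{max\_modes}$
  (default 6, comfortably above the mode counts seen in practice for single
  atoms).  BIC-EM is deterministic given the seed and easy to test; the
  criterion sits behind one function so it can be swapped.
* **Initialisation.** Each candidate $K$ gets `restarts = 5` seeded k-means
  initialisations.  Each restart runs a short EM (25 iterations); only the
  best short run is polished to convergence (relative log-likelihood change
  $< 10^{-6}$, cap 200 iterations).  This is the usual remedy for EM's local
  optima at a fraction of the cost of five full runs.
* **Regularization.** $10^{-6}\,\mathring{A}^2$ is added to covariance
  diagonals, so frozen or nearly frozen atoms produce a valid single mode
  instead of a singular fit.
* **Pruning.** Components with converged weight below 0.01 are dropped and
  the rest renormalised.  Real mode weights of interest are an order of
  magnitude above this floor, so pruning removes only numerical debris.
* **Ordering.** Modes are sorted by descending weight (ties broken by
  lexicographic center comparison) so reports are stable across runs.

EM monotonicity (the log-likelihood trace never decreases), weight
normalisation, and positive-definiteness of fitted covariances are asserted
in the tests; on planted two-component mixtures with $8\sigma$ separation
and $n = 10{,}000$ the fit recovers $K = 2$ with weights within $\pm 0.02$
in at least 95 of 100 seeded replicates, and on one fixture the fit is
cross-checked against an independent mixture implementation (mclust).

## Residue summary and the rare-pair filter

Residue-level values take the largest mode-pair mDCC over all heavy-atom
pairs of the two residues, after discarding *rare* mode pairs.  The rarity
condition is applied to the time-averaged joint probability
$\langle w\rangle_t \le 0.1$: a per-frame condition would either exclude
nothing (some frame always has $w > 0$ threshold) or everything, while the
time average matches the intuition that a mode pair occupied less than 10%
of the trajectory is not a reliable interaction.  Ties at the maximum are
broken toward larger mean joint probability, then smaller center distance —
the better-populated, contact-relevant candidate becomes the provenance of
the cell.  A companion DCC matrix stores the maximum atom-pair DCC per
residue pair, mirroring the mDCC summary, because the transient-edge rule
below needs a residue-level DCC and the max is the natural counterpart.
The per-cell minimum mDCC is kept for diagnostics; the summary itself is
the max, so strongly negative cells are visible in the companion minimum
rather than the headline matrix.

Self-pairs are defined as 1 for residues with any motion and excluded from
network building.  Residues whose atoms are all frozen yield missing cells
rather than silent zeros, and a frozen atom in a scalar `dcc()` call is an
explicit error.

## Network construction and betweenness

`build_network()` connects residue pairs with representative
$\mathrm{mDCC} \ge 0.5$ whose maximizing mode pair has center distance
$< 5\,\mathring{A}$ — correlated *and* in atomic contact.  An edge whose
conventional DCC is below 0.5 is flagged **transient**: the interaction
exists only during part of the trajectory and only the mode-resolved
correlation sees it.  Edge eligibility uses the maximizing (provenance)
mode pair by default; a flag (`any_mode_pair`) instead admits any mode pair
that jointly passes both thresholds, since the choice between the two
readings is genuinely open — they differ only when the best-correlated pair
is out of contact while a weaker-correlated pair is in contact.

Betweenness is the standard unweighted
$g(i) = \sum_{\{s,t\}} \sigma_{st}(i)/\sigma_{st}$ over unordered node
pairs within each connected component ($\sigma_{st}$ = number of shortest
paths, $\sigma_{st}(i)$ = those through $i$); pairs in different components
contribute nothing.  The ordered-pair reading would double every value
uniformly and leave rankings unchanged; the unordered convention is the
common one and matches the closed forms used in the tests (path $a\!-\!b\!-\!c$:
$g(b)=1$; 3-leaf star: center 3; 4-cycle: 0.5 per node).  Computation is
delegated to igraph (Brandes' algorithm) and verified in the tests against
an exhaustive shortest-path enumeration oracle on 100 random connected
graphs of up to 12 nodes.  Rankings (`top_betweenness()`) are reported per
molecule with ties broken by node order, so output is deterministic.

## Descriptors

* **Superposition** is the closed-form SVD (Kabsch) solution with the
  determinant correction, so reflections are never applied; fits with fewer
  than 3 atoms or collinear selections are refused.  Superposition is
  idempotent and preserves intra-frame distances to $10^{-8}\,\mathring{A}$.
* **RMSF** defaults to per-molecule superposition (each molecule fitted on
  its own backbone, other molecules ignored), which isolates internal
  fluctuations from inter-molecular tumbling; global and no-fit variants
  are flags.  The package leaves the superposition convention for the mDCC
  analysis itself to the caller — a pre-superposed trajectory is the input
  contract — because global and per-molecule conventions answer different
  questions and neither is universally right.
* **Cartesian PCA** eigendecomposes the population covariance
  ($1/n$ normalisation) of the flattened $3N$ coordinate vector.
  Contribution rates are ratios, so the normalisation choice is inert for
  them, but it is fixed to make eigenvalues reproducible.
* **Density clustering** of (PC1, PC2) score clouds uses kernel-density
  contouring (normal-reference bandwidth, grid 100×100, cells above 5% of
  the peak density, 8-connected region labelling).  Published cluster
  pictures of this kind are drawn by visual contouring; these defaults
  resolve three $\sigma = 0.1$ blobs 5 units apart and merge two blobs 0.1
  apart at $\sigma = 1$, which is the behaviour a reader of such figures
  expects.  Sub-threshold points are assigned the nearest labelled cell by
  default (`assign_all = FALSE` keeps them as noise).

## The synthetic benchmark

No public trajectory accompanies the method at the scale it is meant for
(microsecond protein–DNA simulations), so the package ships generators
whose outputs have known answers:

* `generate_unimodal_system()` — independent isotropic Gaussian jitter
  about fixed centers.  Closed forms: RMSF $= \sqrt{3}\,\sigma$, DCC $\to 0$.
* `generate_two_state_pair()` — two atoms share one latent two-state
  Markov switch (mean dwell 100 frames, the "repeatedly formed and
  disrupted" temporal texture of a transient contact, without kinetic
  realism) selecting each atom's active center; within-mode displacements
  are correlated with coefficient $\rho$.  With **anti-aligned**
  inter-center vectors and the default box ($\rho = 0.9$, $6\sigma$ center
  separation, occupancy 0.5) the switch contribution to the naive
  covariance opposes the jitter correlation: conventional DCC lands near
  $-0.5$ while the matched-mode mDCC stays near $\rho$.  This is the
  package's contract case — the scenario in which DCC is blind and mDCC is
  not — and the acceptance tests require mDCC $\ge 0.8$ with DCC $\le 0.3$
  in 10 of 10 seeds.
* `generate_allosteric_chain()` — molecules A, bridge, B whose residues
  form one coupling path: consecutive path residues share the switch, have
  jitter correlation $\rho = 0.9$ and sit 3.5 Å apart (both matched-mode
  center distances inside the 5 Å contact rule), while non-consecutive
  path residues are $\ge 7$ Å apart and decoy residues are uncoupled and
  far away.  Geometry alone therefore decides the intended edge set
  (consecutive pairs), and the middle bridge residue is the unique
  betweenness maximum.  The generator refuses parameter combinations whose
  intended edges are geometrically unrealisable.

Defaults were chosen once, as study conditions: jitter $\sigma$ 1 Å for
pairs (side-chain-scale fluctuation), 0.25 Å in the chain (tight contacts),
mode separation $6\sigma$ (clearly resolved basins), dwell 100 frames,
5,000-frame chains and 20,000-frame pairs — small enough to analyse in
minutes, large enough that mixture-fitting error is far below the margins
being tested.  Mean-occupancy checks use the iid (dwell $\le 1$) limit
where a binomial error bound applies; under Markov dwell the effective
sample size is smaller by roughly $2\times$dwell and the tests use a
correspondingly wider bound.

What the generators deliberately do **not** emulate: force-field energetics,
solvent, sequence-specific geometry, anisotropic or mode-dependent jitter,
and temporal correlation within modes.  Passing the synthetic benchmarks
therefore shows the estimators are correct and the pipeline is faithful —
not that any particular biological system will show transient interactions.

## Degenerate inputs and numerical conventions

Frozen atoms: single mode at the point, floor covariance, undefined
correlations reported as such.  All-identical score clouds: one cluster.
Empty edge sets are valid networks.  Mixture fits on fewer than 50 frames
warn.  Trajectories whose bounding box exceeds 1000 Å warn (likely
un-imaged periodic coordinates); the package performs no periodic-boundary
handling by design — input is expected pre-imaged.  All randomness is
seeded and every generator is bit-reproducible for a given seed.

## Known limitations

* Modes are purely spatial; a hidden-Markov treatment of mode kinetics is
  out of scope.
* No lagged correlations or mutual-information generalisations.
* XTC trajectories are not read (no installed reader); use DCD or
  multi-model PDB.
* The residue summary takes a max, so a cell dominated by one strong mode
  pair hides weaker, possibly negative, relationships (the recorded minimum
  is a partial diagnostic).
* Betweenness is computed on an unweighted, thresholded graph; correlation
  strength beyond the threshold does not influence rankings.

## Problem sizes used in the checks

The automated checks run at: 50 atoms × 2,000 frames (uni-modal collapse),
20 random 6-atom × 250-frame systems (range/symmetry), 10 × 20,000-frame
two-state pairs, 100 mixture replicates at $n = 10{,}000$, 100 random
graphs ≤ 12 nodes, 100,000-frame descriptor closed forms, and 5 seeded
19-atom × 5,000-frame allosteric chains — sizes chosen so the whole battery
completes on a laptop-class single core while keeping statistical margins
wide.
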