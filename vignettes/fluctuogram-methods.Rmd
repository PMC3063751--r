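---
title: "Fluctuograms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuograms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic generators do and do not emulate, and the
known limitations.

## The model

A protein trajectory is reduced to two coarse-grained sites per residue:
the backbone site pinned exactly at Cα, and a sidechain site at the
mass-weighted centre of the sidechain atoms (glycine contributes a single
site; a bound ion contributes one site). Site masses are the summed atom
masses; masses never enter the equal-time statistics (harmonic
equipartition in coordinates is mass-independent) but are carried for
completeness.

Each analysis window is represented by an elastic network: a harmonic
potential

$$U = \sum_{(i,j)} \tfrac12\, k_{ij}\, (d_{ij} - b_{ij})^2,$$

with rest lengths $b_{ij}$ (Å) and non-negative force constants $k_{ij}$
(kcal/mol/Å²). The ensemble this Hamiltonian defines at temperature $T$
is Gaussian with covariance $k_B T\, H^{+}$, where $H$ is the Hessian at
the rest geometry and $^{+}$ the pseudoinverse over non-rigid modes.
Because $b_{ij}$ is set to the window-mean distance of every bond, the
tangential curvature term vanishes and each bond contributes the standard
block $-k\,\hat e\,\hat e^{\mathsf T}$ to the Hessian.

**Bond pool.** Every site pair whose distance dips to 10 Å or below at
any point of the trajectory is a candidate bond. The matching result is
insensitive to this cutoff because redundant pairs are free to relax to
zero stiffness; 10 Å simply provides a basis large enough to express the
couplings present in the data.

## Fluctuation matching

For one window the targets are the mean distance $b_{ij}$ and the
population variance $\langle\delta d^2\rangle$ of every pool pair.
Matching starts from $k^{(0)}_{ij} = k_B T / \langle\delta
d^2\rangle_{ij}$ — the exact answer for an isolated bond — and iterates

$$k^{(m+1)}_{ij} = \max\!\Big(k^{(m)}_{ij} + \alpha\, k_B T\,
\big(1/\langle\delta d^2\rangle_{\text{target}} -
1/\langle\delta d^2\rangle_{\text{ENM}}\big),\, 0\Big),$$

where the predicted variances come from a fresh normal-mode analysis at
each step. Iteration stops when the RMS change of the force constants
drops below 0.005 kcal/mol/Å². A `variance_difference` rule
($k \leftarrow k - \alpha\,k_BT\,(\langle\delta d^2\rangle_{\text{ENM}} -
\langle\delta d^2\rangle_{\text{target}})/\langle\delta
d^2\rangle_{\text{target}}^2$, the first-order equivalent) is selectable;
both rules vanish identically when predicted and target variances agree,
so the truth is always a fixed point.

**Step constant.** For an isolated bond the iteration contracts for any
$\alpha < 2$. On a realistic dense pool, however, overlapping bonds
amplify the collective update and $\alpha = 0.5$ can enter a limit cycle;
$\alpha = 0.2$ (the default) was stable on every fixture we generated
while still converging in a few dozen iterations, comfortably inside the
method's typical 200-step budget. Clamped bonds stay in the pool: a bond
driven to zero can re-enter if later updates push it positive.

**Determinism.** Given the targets the matcher is exactly deterministic;
windows are independent and may be evaluated in any order.

## Windowing

Windows are `window_frames` frames long and advance by half a window, so
consecutive windows share exactly half their frames; the window count is
$\lfloor (n_\text{frames}-\Delta t)/(\Delta t/2)\rfloor + 1$. The window
length trades time resolution against estimation noise; the method's
conclusions are reported to be qualitatively stable between roughly half
and twice the default window, and the `stride` argument allows
non-overlapping windows for sensitivity checks.

## Residue-level metrics

With sites aggregated to residues, $k_{IJ}$ is the sum of the force
constants of all bonds joining residues $I$ and $J$, and
$k_I = \sum_{J \ne I} k_{IJ}$. Intra-residue (backbone–sidechain) bonds
report internal geometry, not inter-residue coupling, so they are
excluded from $k_I$, from $\delta k_I$ and from $\psi_I$; they do enter
$\Delta b_I$ through the activity rule below. Sequence-neighbour pairs
($|I-J| \le 3$) are *included* in $k_I$ by default — the selection
criteria filter them separately — and a `min_separation` argument
excludes them where wanted.

Between consecutive windows,

* $\delta k_I(t) = k_I(t) - k_I(t-1)$;
* $\Delta b_I(t)$ sums $|b_{ij}(t) - b_{ij}(t-1)|$ over bonds touching
  $I$ that carry a positive force constant in at least one of the two
  windows (geometry changes where no mechanical coupling exists are not
  interesting);
* $\psi_I(t)$ averages $\big(k_{ij}(t) - k_{ij}(t-1)\big) /
  \max\!\big(k_{ij}(t), k_{ij}(t-1)\big)$ over the same active bonds.
  Normalising by the larger of the two values is what bounds the metric
  in $[-1,1]$, with $+1$/$-1$ attained exactly when every bond of a
  residue appears/vanishes. A residue with no active bond has no defined
  value and is reported as `NA`, never as 0.

For two-state comparisons (e.g. ligand-bound vs apo),
$\Delta k_I(t) = k_I^{A}(t) - k_I^{B}(t)$; residues are classified by the
time average of $|\Delta k_I|$ (large above 20, significant 10–20,
medium/weak below 10 kcal/mol/Å²) and the top decile is flagged.

## Selection criteria and evaluation

All criteria screen pairs with sequence separation $|I-J| > 3$ (the
backbone makes closer pairs trivially coupled). Over the windows of a
fluctuogram each pair contributes its mean, population standard
deviation and maximum coupling.

* **A** (hubs): residue $I$ is selected when at least `n_cut` partners
  have mean coupling ≥ `k_cut` (defaults 10 and 2.5 kcal/mol/Å²).
* **B** (strong pairs): both ends of every pair with mean ≥ `k_b`
  (default 11; 17 suits less globular folds).
* **C** (strong and variable): both ends of pairs with maximum ≥ `k_c`
  (default 8) and normalised variation ≥ `s_c` (default 0.8). The
  variation is the coefficient of variation sd/mean by default; sd/max
  and absolute-sd modes are selectable because the dimensionless 0.8 is
  most naturally read as a CV. Raising any cutoff can only shrink a
  selection, which the tests assert over parameter grids.

A selected residue is a *hit* when it lies within ±1 of a reference
residue (truncated at the chain termini, hits counted once per
selection); a reference residue is *covered* when a selection lies
within ±1 of it. Hit rate = hits/selected, coverage =
covered/reference. Baselines pick the same number of residues uniformly
without replacement, 10,000 seeded rounds by default, and report mean ±
population sd of hits, coverage and their ratios. For sparse reference
sets the expected covered count has the hypergeometric closed form
$n_\text{ref}\,(1 - \binom{N-3}{p}/\binom{N}{p})$, which the test suite
checks the Monte Carlo against.

## Sequence arm (SCA)

Sequences with more than 100 gaps, or more than one gap in designated
loop columns, are dropped; redundant sequences (≥ 95 % identity over
mutually non-gap columns, single-linkage, pairs with under 50 % mutual
coverage treated as non-redundant) are reduced to their first-seen
representative.

Each column is binarised against its most prevalent amino acid (ties go
to the alphabetically first letter; gaps are never the consensus and
score 0). Conservation is the relative entropy (nats) of the regularised
consensus frequency $f' = (1-\lambda) f + \lambda q$ against the
background frequency $q$ of the consensus letter, with pseudocount
$\lambda = 0.01$ — without it the entropy gradient diverges at $f \in
\{0,1\}$. The background table is a built-in database-wide amino-acid
composition, overridable. The coupling matrix is
$\tilde C_{ij} = \phi_i \phi_j\, |\mathrm{cov}(x_i, x_j)|$ with
$\phi = |\partial D/\partial f|$ evaluated at $f'$.

**Significance.** Columns are permuted independently across sequences
(conservation preserved, correlations destroyed) and the coupling matrix
rebuilt. Because the matrix is entrywise non-negative its leading
eigenvalue is a conservation-dominated Perron mode that survives
permutation, so the null records each randomised matrix's largest
eigenvalue *beyond the first*, and observed eigenvalues (beyond the
first) exceeding the 95th percentile of that null are significant.
Recording the raw maximum instead would compare sector modes against the
null's Perron mode and mask them entirely.

**Sectors.** Positions whose distance from the origin in the
(eigenvector 2, eigenvector 3) plane reaches 0.07 are selected; selected
positions are clustered into three sectors by k-means on their angular
direction (each point mapped to the unit circle), seeded, labels ordered
by cluster size. Angular clustering was chosen because equal-strength
sectors appear as rays at roughly fixed angles whose absolute rotation
within the plane is arbitrary; a sign-quadrant rule would depend on that
arbitrary rotation. Matrix cleaning reconstructs
$\sum_{k \in \{2,3,4\}} \lambda_k v_k v_k^{\mathsf T}$ on the selected
positions, ordered by sector and, within a sector, by decreasing
distance to origin.

## Synthetic generators and what passing tests mean

The generators provide known-answer versions of the two inputs the
method normally takes from molecular dynamics and from sequence
databases.

**Toy networks.** `make_toy_network()` embeds a chain compactly (growth
biased toward the centroid under excluded volume) and adds 100 random
contacts drawn from pairs 3.5–9.5 Å apart, with force constants uniform
on 1–20 kcal/mol/Å². The density matters: a sparsely braced chain is
mechanically under-constrained, its soft collective modes acquire
thermal amplitudes comparable to the bond lengths, and the Euclidean
distance variance then departs grossly from the harmonic prediction. The
default is over-braced the way a protein interior is, keeping the
transverse correction $\mathcal O\big((\sigma_\perp^2/b)^2\big)$ at the
few-percent level — the regime the method assumes of real proteins.

**Gaussian sampling.** `sample_from_network()` draws exactly from the
model's Gaussian, with zero amplitude on rigid-body (and any residual
floppy) modes, so internal statistics need no superposition; a flag adds
random rigid placement per frame to exercise the fitting code. The
sampler is the independent oracle for the NMA variance prediction — the
two are compared on the linearised bond coordinate, where the agreement
is an exact theorem — and the recovery target for the matcher, which
works on true Euclidean distances and therefore also absorbs the small
anharmonic offset. Two-state trajectories concatenate seeded segments
from two networks and record the change points.

**Planted alignments.** `synth_alignment()` ties sector columns to a
per-sequence Bernoulli latent state (consensus emitted with probability
0.95 when active, 0.4 when inactive, state probability 0.5) and gives
every other column an independent conservation level drawn once from
0.3–0.95, the span of weakly to strongly conserved columns in real
alignments. The canonical fixture matches a real use case in size: 465
sequences by 274 positions with three 15-position sectors.

What the fixtures do *not* emulate: anharmonic and multi-well dynamics
within a window, time correlation between frames (samples are i.i.d.),
alignment gaps and phylogenetic relatedness, and any coupling between
the structural and sequence arms. Passing tests therefore demonstrate
correctness of the inference machinery under its own assumptions, not
that those assumptions hold for any particular protein.

**Problem sizes.** The validation suite uses 20-site networks with
4000-frame windows (where the matcher's recovery error is dominated by
sampling noise, shrinking roughly as $1/\sqrt{n_\text{frames}}$),
$10^5$-draw sampler comparisons, and the 465 × 274 alignment — sizes at
which every statistical margin asserted by the tests has been verified
to hold with room to spare while the whole suite runs in about a minute.

## Numerical choices

* $k_B = 0.0019872041$ kcal/mol/K; default $T = 300$ K.
* Zero modes: eigenvalues below $10^{-8}$ of the largest are zero. The
  expected rigid-body count follows the rank of the centred rest
  geometry (3 for a point, 5 for a collinear arrangement — the two-site
  dimer is the textbook case — 6 otherwise). Extra zero modes are
  tolerated when the positive-stiffness bond graph is connected (floppy
  modes change no bond length to first order, so bond statistics remain
  well defined); a disconnected graph is an error that lists the
  components; fewer zero modes than rigid motions is a geometry error.
* Superposition for RMSF/RMSD: unweighted least-squares (Kabsch) fits on
  all selected sites, iterating the mean structure for RMSF; collinear
  mean structures trigger a warning.
* Degenerate inputs: zero-variance bonds abort the inversion naming the
  bond; empty selections give an undefined (`NA`) hit rate and zero
  coverage; an empty sector selection is legal, a non-empty one smaller
  than the sector count is not.
* All ids — sites, residues, windows, alignment columns — are 1-based.

## Limitations

The harmonic window model cannot represent multi-well dynamics within a
window, only between windows; force constants from short windows carry
estimation noise that the selection statistics partially average out but
never remove; the SCA weighting follows the binary-approximation
construction and other conservation weightings would shift sector
boundaries; and the ±1 hit-rate convention makes all hit rates depend on
reference-set density, which is why every reported rate is paired with
its random baseline.
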