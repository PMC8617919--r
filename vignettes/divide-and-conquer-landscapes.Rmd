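---
title: "Divide-and-conquer free-energy landscapes: model and methods"
author: "felstitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer free-energy landscapes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A free-energy landscape (FEL) over a pair of collective variables (CVs),

$$F(v_1, v_2) = -k_B T \,\ln \rho(v_1, v_2) + \text{const},$$

summarises the thermodynamics of a large conformational change: basins are
metastable states, saddle heights are barriers.  Estimating $\rho$ for a
slow process by one long simulation is hopeless when the process is orders
of magnitude slower than the affordable simulation time.  The
divide-and-conquer strategy implemented here replaces the single long run
by many short, independent runs, each confined to a small rectangular
region of the CV plane by a flat-bottom restraint, and then stitches the
per-region statistics into one landscape.  Because the runs never need to
communicate, the scheme parallelises trivially.

# Collective variables

The CVs are projections onto principal components of a superposed
structure ensemble.  Every model is first superposed on a fixed
sub-structure of the first model (for a two-domain protein, the
C$\alpha$ atoms of one domain): with $Q$ the centroid of the model's fit
atoms and $P$ that of the reference's, the cross-covariance
$A_{ab} = \sum_\nu (r_\nu - Q)_a (s_\nu - P)_b$ determines the optimal
proper rotation.  `optimalRotation()` computes it by singular value
decomposition with a determinant correction, which coincides with the
closed form $(A^{t}A)^{1/2}A^{-1}$ whenever $\det A > 0$ but also handles
reflected and near-singular inputs.  The fitted coordinates
$r'_i = R\,(r_i - Q)$ feed the covariance
$\Lambda_{kl} = \langle (X'_k - \langle X'_k\rangle)(X'_l - \langle
X'_l\rangle)\rangle$ (ensemble-average convention, denominator $M$), whose
leading eigenvectors $c_1, c_2$ define
$v_n = c_n \cdot (X' - \langle X'\rangle)$.

Two conventions deserve note.  First, projections are mean-centred by
default (`centered = TRUE`); uncentred absolute axes differ only by a
constant offset and are available as an option, because centred axes make
region geometry portable between runs.  Second, eigenvector signs are
fixed by making each vector's largest-magnitude coordinate positive, so
the axes are reproducible across platforms; degenerate eigenvalues keep
their original order, and the axes are then basis-dependent.

# The restraint and its force

Sampling region $i$ is the rectangle
$[v_1^{min}, v_1^{max}] \times [v_2^{min}, v_2^{max}]$.  The restraint is
flat inside and harmonic outside,

$$\phi(v_m) = \tfrac{k}{2}(v_m^{min} - v_m)^2 \;[v_m < v_m^{min}], \quad
0 \;[\text{inside}], \quad \tfrac{k}{2}(v_m - v_m^{max})^2
\;[v_m > v_m^{max}],$$

summed over $m = 1, 2$: inside the box the dynamics is exactly unbiased.
The Cartesian force needs $\partial v_m / \partial r_i$ *including* the
dependence of $R$ and $Q$ on the fit atoms.  Rather than transcribing a
chain-rule expression, `cvGradient()` differentiates the stationarity
condition of the optimal rotation ($RA$ symmetric): a perturbation $dA$
yields $dR = \Omega R$ with skew $\Omega$ solving
$\Omega M + M \Omega = dA^{t}R^{t} - R\,dA$, diagonal in the basis of
$A$'s right singular vectors with denominators $\hat\sigma_i +
\hat\sigma_j$ (last singular value sign-corrected).  The result is exact:
the test suite checks agreement with central finite differences to
$10^{-5}$ on randomized configurations, and the gradient rows sum to zero
because the fitted projection is translation-invariant.  Collinear fit
atoms make the rotation non-unique and raise an error instead of
returning garbage.

Units throughout: Angstrom, kcal/mol, with
$k_B = 0.0019872041\ \mathrm{kcal\,mol^{-1}K^{-1}}$ (so $k_B T \approx
0.6$ kcal/mol at 300 K).  The default spring constant for protein-scale
CV amplitudes is $k = 0.048\ \mathrm{kcal\,mol^{-1}\,\mathring{A}^{-2}}$;
the toy demonstration uses $k = 1$ because its CV amplitudes are an order
of magnitude smaller.

# Region geometry, weights, multiplicity

The CV domain is tiled by disjoint *small areas*; each is grown by a
margin on every edge interior to the domain to give the overlapping
*sampling region* actually simulated (adjacent regions overlap by twice
the margin, diagonal neighbours share a corner square).  Samples outside
a run's sampling rectangle — where the restraint energy is non-zero — are
excluded from all statistics, so no reweighting factor is ever needed.

Each region knows $\rho$ only up to a factor.  For adjacent regions the
factor ratio comes from the overlap strip: with $N_i$, $N_j$ the two
runs' retained sample counts inside the geometric intersection of their
rectangles, matching the weighted densities requires
$e^{W_i} N_i = e^{W_j} N_j$, i.e. $W_j - W_i = \ln(N_i / N_j)$.  This
*density-matching* sign convention is the package default; the opposite
sign ($\log N_j - \log N_i$) is retained as the documented `"counts"`
option.  The density-matching form is the one under which the toy
pipeline reproduces its reference landscape — the discriminating test of
the convention — and per-region sample totals $L_i$ never enter: the
overlap counts already absorb them.

Weights are propagated breadth-first from a seed region (the one with the
most usable overlap edges; $W_{seed} = 0$) across all edges with positive
counts on both sides, including diagonal edges, so each populated region
is assigned exactly once.  With noisy counts the result is mildly
path-dependent; `method = "leastsq"` solves all edges simultaneously in
the least-squares sense (exact on cycle-consistent inputs) as a
documented extension.  A disconnected overlap graph is an error that
lists the components.  Adding a constant to every $W_i$ does not change
the landscape (gauge freedom).

The assembled density in bin $b$ is

$$\hat\rho(b) \propto \sum_i e^{W_i} \sum_{t \in b} \frac{1}{M(v_t)},$$

where the multiplicity $M(v)$ is the number of sampling rectangles
covering $v$: a point in a two-region overlap is counted by both runs and
must be down-weighted by $1/2$, a four-corner point by $1/4$.  Finally
$F = -k_B T \ln \hat\rho$, shifted so the lowest populated bin is zero;
empty bins are masked, never imputed.  The negative sign is deliberate:
high-population regions are *basins* (low $F$).

# The synthetic sampler and what it does (not) show

The per-region simulations are stood in for by a bead-chain model with a
known equilibrium distribution, sampled by overdamped Langevin dynamics
(Euler–Maruyama, $dx = F\,dt/\gamma + \sqrt{2 k_B T\,dt/\gamma}\,dW$,
R-seeded, fully reproducible).  The model emulates hinged two-domain
motion:

* 10 beads, harmonic bonds ($k = 5$, $b_0 = 3.8$ Å — a C$\alpha$ virtual
  bond);
* two stiff lobes (angle-harmonic bending, $k_\theta = 150$ kcal/mol,
  preferred joint angle 160°) around one free hinge joint at the middle
  bead;
* a quartic double well on the end-to-end distance $q$ with minima at
  $q_0 \pm w = 12$ and $20$ Å and a 1.8 kcal/mol (≈ 3 $k_B T$) barrier —
  the closed and open hinge arrangements;
* a z-scaffold (each bead tethered to a corrugated resting height,
  $k = 10$): it confines the hinge swing to a plane, removing the
  azimuthal degeneracy of the motion, while keeping the resting geometry
  three-dimensional so the superposition is well-conditioned;
* a weak chiral joint term (2 kcal/mol on the normalised $z$ cross
  product) that prefers one in-plane turn direction, as protein geometry
  does: without it the two mirror-image swing branches are degenerate and
  the landscape doubles.

With this geometry the hinge double well is fully resolved within the
first two principal components (the well coordinate correlates > 0.8
with one of them; the other is the orthogonal soft swing), which is the
property the divide-and-conquer construction needs.  The ground truth is
a long *unbiased* run of the same integrator, Boltzmann-inverted on the
same bin grid (`referenceFelOracle()`); because estimator and reference
share the integrator, time-step bias cancels and the comparison isolates
the stitching machinery.  Quadrature over the analytic well coordinate
provides an additional closed-form check of basin offsets
(`modeBasinDeltaF()`), and with the mode, bending, scaffold and chiral
terms switched off the Boltzmann density factorises over bond vectors,
giving an exact bond-length law the sampler must reproduce.

What passing these tests does *not* show: the toy has no explicit
solvent, no rugged orthogonal degrees of freedom, and its region-level
equilibration is fast; on a real protein the within-region runs, not the
stitching arithmetic, dominate the error budget.

Two integrator safeguards deserve mention because they could in principle
touch the physics: beyond 5 Å outside the restraint box the wall
continues with constant force (harmonic-then-linear), and the
deterministic drift per coordinate per step is clamped at 0.5 Å.  Both
act only in far-from-equilibrium transients — equilibrium drift is about
0.05 Å per step, and configurations beyond the wall are excluded from
every statistic by the exclusion rule — so neither affects the sampled
distribution that enters the landscape.

# The demonstration pipeline and its numerical choices

`runDemoPipeline()` chains everything: an unbiased reference run
(4 × 10^5 steps) supplies the ensemble for the PCA basis and the CV
domain; the domain is split 3 × 3 with a margin of 0.2 of the small-area
width; each region is sampled by four independent restrained runs of
5 × 10^5 steps each ($dt = 0.005$, samples every 20 steps, the first 10%
of every run discarded as equilibration), pooled before the exclusion
rule.  Each run starts from a different reference-ensemble frame drawn
inside the region — genuine equilibrium draws, so the pooled samples
stratify over whatever slow coordinates the CV pair does not resolve —
and regions the reference run never visited are skipped, as one skips
areas containing no experimental structure.  Two choices here came out
of explicit convergence diagnostics.  First, the basis superposes on
*all* beads: fitting only the first lobe leaves a lever-amplified
frame-orientation wobble in the distal coordinates that dominates the
leading components, decorrelates them from the hinge coordinate, and
leaves each region box internally slow to mix; the all-bead fit removes
it and the stitched-minus-reference error drops by almost an order of
magnitude.  Second, starting a region from a structure dragged in from
far away through the wall can strand the run in a deformed metastable
state, which is why starts are restricted to frames already inside the
region.  Three replicas with distinct seeds mirror the repeated
independent runs one would use for error bars; the landscape spread
across replicas is the reported precision.  Bin edges adapt so the
median occupied-bin count is at least 20, between 12 × 10 and 36 × 28
bins.  The reference landscape uses 1.2 × 10^7 unbiased steps.  These
sizes make a full validation run in a few minutes on one CPU core while
leaving the statistical error of the comparison (~0.05–0.1 kcal/mol)
well below the 0.3 kcal/mol bound the tests assert.

Comparing two landscapes requires fixing the gauge (each is only defined
up to a constant): `compareFel()` subtracts the mean difference over the
mutually well-sampled bins (both unmasked, both with at least 100
effective counts) and reports the mean and maximum absolute residual.

Barrier analysis (`barrierDeltaDeltaF()`) finds basin minima inside two
query rectangles and the minimax saddle over 4-connected paths of
unmasked bins — implemented by flooding bins in order of increasing $F$
with a union-find, so the saddle is exact on the grid; masked bins are
impassable.  One-dimensional profiles (`marginalFel()`) are arithmetic
means of unmasked $F$ across the transverse extent of a rectangle,
matching how stitched landscapes are usually compared against long
conventional runs.

# Design decisions that were genuinely open

* **Sign of $\omega$ and of $F$.**  Printed forms of both exist with
  either sign in the literature; here both are fixed by the recovery
  property on the toy model (density matching for $\omega$, wells-down
  for $F$), with the alternatives retained as options or documented.
* **$L_i$ normalisation.**  No per-region division by $L_i$ beyond what
  the overlap counts absorb; verified by the term-by-term oracle test.
* **Hydrogens and hetero-atoms in contacts.**  The contact definition
  ("any atom closer than 4.5 Å, strictly") uses every atom present in
  the file by default; a heavy-atom-only switch exists for
  hydrogen-free models.  `min_seq_sep = 1` excludes only self-contacts;
  inter-domain analyses should filter by residue range instead.
* **Contact-group semantics.**  A structure "has" a group when *any* of
  the group's pairs is formed (default), since partially formed groups
  are the interesting intermediate states; `mode = "all"` is available.
* **Alternate locations, chains.**  First altloc wins; the first chain
  is read by default.  Both are deterministic, configurable choices.
* **Representative structures.**  The RMSD centroid (smallest summed
  best-fit C$\alpha$ RMSD to all other members), ties to the lowest
  index.

# Known limitations

The pairwise overlap scheme is not a self-consistent histogram solver:
with very noisy overlaps a full WHAM-type iteration would pool
information better than the spanning-tree or least-squares weights.
Landscape errors concentrate where regions are internally slow to
equilibrate (boxes straddling a barrier); making the small areas smaller
along the slow axis is the intended remedy, at the price of more
regions.  The toy sampler's Euler–Maruyama integrator has O($dt$)
equilibrium bias; it cancels in the stitched-vs-reference comparison but
would matter if the toy were used as an absolute standard.  Region
layouts are axis-aligned rectangles only.
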