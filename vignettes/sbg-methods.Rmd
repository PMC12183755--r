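---
title: "Structure-based Gaussian expansion: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based Gaussian expansion: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgx)
```

## The model

`sbgx` computes vibrational eigenstates of a molecule (or an abstract
D-dimensional system) by expanding the nuclear wavefunction in $L$
space-fixed multivariate Gaussians,

$$\chi(\mathbf{Q}) = \sum_{i=1}^{L} c_i\, G_i(\mathbf{Q}), \qquad
G_i(\mathbf{Q}) = \exp\!\left[-(\mathbf{Q}-\mathbf{Q}_i)^{\mathsf T}
\boldsymbol\alpha_i (\mathbf{Q}-\mathbf{Q}_i) + \zeta_i\right],$$

where $\mathbf{Q}$ collects mass-weighted Cartesian coordinates. All
internal arithmetic is in Hartree atomic units ($\hbar = 1$, lengths in
$\sqrt{m_e}\,a_0$), which removes every $\hbar$ from the matrix-element
formulas; I/O uses Angstrom, amu and cm$^{-1}$ with the CODATA factors
$1\,\mathrm{amu} = 1822.888486\,m_e$,
$1\,\text{\AA} = 1.8897261255\,a_0$ and
$1\,E_h = 219474.6313705\,\mathrm{cm}^{-1}$.

The width matrix of each basis is taken from the local curvature,
$\boldsymbol\alpha_i = \tfrac12\sqrt{\mathbf{V}''(\mathbf{Q}_i)}$
(principal matrix square root), i.e. each Gaussian is the ground state of
the local harmonic oscillator. Because a molecular Hessian has six
near-zero eigenvalues (rigid translations and rotations) and can have
negative ones away from stationary points, the Hessian is
positive-definitized first: eigenvalues with magnitude below `zero_tol`
are replaced by $\omega_c^2$, where $\omega_c$ corresponds to
`v_const_wavenumber`, and negative eigenvalues have their signs flipped so
that the width still follows the steep local shape of the wavefunction in
concave regions. The raw (unregularized) Hessian is used in the potential
matrix elements; regularization affects only the basis widths. Rationale:
the regularized curvature is a statement about the basis function shape,
while the potential element should approximate the true operator.

**Tunable parameters of this step.**

* `v_const_wavenumber` (cm$^{-1}$): the replacement frequency for zero
  modes. It should sit somewhat below the harmonic frequency of the mode
  of interest; the package default is 1500 cm$^{-1}$, appropriate for the
  bundled double-well fixture whose well frequency is about
  3100 cm$^{-1}$. There is no universal value; choose per system.
* `zero_tol` (a.u. of $\omega^2$): what counts as "zero". The default is
  $(10\,\mathrm{cm}^{-1})^2$ in atomic units, which cleanly separates
  translation/rotation nullspace noise from genuine soft modes in the
  systems we target. For molecular systems an alternative route projects
  the Hessian with $1 - \hat O_\mathrm{tra} - \hat O_\mathrm{rot}$ before
  eigendecomposition (`proj` argument of `regularize_hessian()`), which is
  more robust when rigid-body contamination is larger than `zero_tol`.

## Matrix elements

With $A = \boldsymbol\alpha_1 + \boldsymbol\alpha_2$ and
$\mathbf d = \mathbf Q_1 - \mathbf Q_2$, the product of two normalized
Gaussians is a Gaussian with centre
$\mathbf{Q}_{12} = A^{-1}(\boldsymbol\alpha_1\mathbf{Q}_1 +
\boldsymbol\alpha_2\mathbf{Q}_2)$ and precision $2A$, so every element is
a Gaussian moment:

* overlap: $S_{12} = e^{\zeta_1+\zeta_2}\,\pi^{D/2}\,(\det A)^{-1/2}
  \exp(-\mathbf d^{\mathsf T} B\,\mathbf d)$ with
  $B = \boldsymbol\alpha_1 A^{-1} \boldsymbol\alpha_2$;
* momentum moments: $M_{ab} = \langle G_1|\hat P_a \hat P_b|G_2\rangle$,
  $M = \left[2B - 4 (B\mathbf d)(B\mathbf d)^{\mathsf T}\right] S_{12}$;
* kinetic energy: $T = \tfrac12\,\mathrm{Tr}(O\,M)$, where $O$ is the
  identity for abstract systems and
  $1 - \hat O_\mathrm{tra} - \hat O_\mathrm{rot}$ for molecules. The
  projection operators are built once from a single reference geometry
  (by default the transition-state frame of the path), keeping the
  vibrational kinetic matrix a fixed Hermitian matrix;
* potential (local harmonic approximation, LHA):
  $V_{12} = \left\{V(\mathbf Q_{12}) + \tfrac14\mathrm{Tr}\left[A^{-1}
  \mathbf V''(\mathbf Q_{12})\right]\right\} S_{12}$. The linear term of
  the Taylor expansion vanishes because $\mathbf Q_{12}$ is the product
  centre. The LHA is exact for potentials up to quadratic.

All closed forms were re-derived for this package and are gated by
quadrature oracles in the test suite: a Gauss–Hermite rule in a reference
frame twice as broad as the pair product reproduces them to $10^{-10}$
relative for $D \le 3$.

## Solving the generalized eigenproblem

The spectrum solves
$\mathbf S^{-1}(\mathbf T_\mathrm{vib} + \mathbf V)\,\mathbf c = E\,\mathbf c$
by canonical orthogonalization: eigendecompose $\mathbf S$, discard
eigenvalues below `s_tol` times the largest, and solve the symmetric
problem in the retained subspace.

`s_tol` deserves attention. The LHA potential matrix is not the projection
of a single operator onto the basis: each element carries an independent
truncation error whose leading term is the fourth cumulant
$\tfrac18 V''''\sigma^4$ of the pair product (for the bundled quartic
double well this is of order $10^{-4}$ hartree per element). The
generalized eigenproblem is therefore *not variational*: an overlap
eigenvalue $s$ smaller than the relative element inconsistency admits a
combination whose energy error is amplified by $1/s$, and retained
near-null modes produce spurious, arbitrarily low eigenvalues. The package
default `s_tol = 1e-3` is matched to that error scale and keeps the
working subspace consistent; lowering it is appropriate only for exactly
quadratic potentials (where the LHA is exact and the classical
`1e-8`-style cutoff applies). The same mechanism sets the accuracy
envelope of the method itself: on the bundled 1D double well the
tunneling doublet from a well-conditioned nine-basis path set agrees with
the sinc-DVR oracle at the ten-percent level, not better, and adding
bases does not converge it further — the bottleneck is the LHA element
error, not basis completeness (the same nine Gaussians with exact quartic
matrix elements reproduce the DVR splitting to better than 1%).

Consecutive levels are labelled a tunneling doublet when their gap is
below 20% of the gap to the next level (`doublet_gap_factor`); parity
labels are the sign of $\langle\chi|\hat\sigma|\chi\rangle$, evaluated in
closed form by mirroring every basis through a supplied symmetry
operation.

## Automatic basis construction

Bases are first placed equally spaced in arc length along the reaction
path, endpoints included. The path itself either comes from a multi-frame
XYZ file (aligned by mass-weighted sequential superposition, which removes
linear and angular momentum from frame-to-frame shifts) or, for model
potentials, from `synthetic_irc()` (normalized-gradient steepest descent
from the saddle, finished by Newton iterations onto each minimum).

Additional bases follow a principal component analysis of the path:
the covariance of the mean-centred structures (plain sum of outer
products, as only variance *ratios* matter) is diagonalized, components
with $\lambda_n/\lambda_1 \ge$ `pc_ratio_threshold` (default $10^{-3}$)
are selected, and candidate centres are generated at
$\mathbf Q_i \pm d_{i,n}\,\mathrm{PC}n$ (first order) and
$\mathbf Q_i \pm (d_{i,n}\,\mathrm{PC}n \pm d_{i,n'}\,\mathrm{PC}n')$ for
distinct pairs $n<n'$ (second order; no $\pm 2d$ single-component shifts
— the two-index formula involves two distinct components). The shift
distance $d_{i,n}$ makes the overlap of the existing basis with an
equal-width copy shifted along $\mathrm{PC}n$ equal `target_overlap`
(default 0.75, the middle of the useful 0.7–0.8 window; solved by
bisection, with the closed form
$d = \sqrt{-2\ln t/(\mathbf u^{\mathsf T}\boldsymbol\alpha\,\mathbf u)}$
as a test oracle). Optionally each component is orthogonalized against
the local path tangent first (`orthogonalize_to_tangent`).

Candidate widths are then recomputed from the Hessian at each candidate
centre, and candidates are pruned greedily in a deterministic order
(centre index, then component order, then sign pattern): a candidate
survives iff its maximum overlap with the path bases and all previously
kept candidates is at most `prune_overlap_max` (default 0.9). Greedy
deterministic pruning makes rebuilds byte-identical; its one side effect
is that the final set is only approximately mirror-symmetric for
symmetric problems, because the visit order runs from one end of the path.
Exact symmetric layouts (the plain IRC placement) are used wherever exact
orbit accounting matters.

Before the PCA the path is resampled to uniform arc length with at least
`resample_factor` (default 20) times the number of path bases, so the
variances are independent of the sampler's step density.

A reference "all local normal modes" construction
(`local_normal_mode_shifts()`) uses the eigenvectors of each centre's
regularized Hessian instead of the global components; it reproduces the
same shift combinatorics per centre and is the expensive baseline that
component selection is meant to undercut.

## Counting potential evaluations

Assembling the Hamiltonian needs potential information (energy and
Hessian) at every pair midpoint — up to $L(L+1)/2$ points. A symmetry
operation that permutes the basis centres partitions the unordered pairs
into orbits; `count_unique_evaluations()` counts those orbits (and centre
orbits in GPR mode), and `assemble_hamiltonian()` serves symmetry-image
requests by transporting stored information
($E \to E$, $\mathbf g \to M\mathbf g$,
$\mathbf H \to M\mathbf H M^{\mathsf T}$) instead of calling the provider.
For five equally spaced bases on a reflection-symmetric path this reduces
15 pair evaluations to 9; coincidences (self-symmetric pair midpoints
landing on a basis centre) can reduce the served requests further.

## GPR interpolation of potential information

With GPR enabled, the provider is called only at the $L$ basis centres;
the $L(L-1)/2$ midpoints are interpolated. One multi-output model covers
the energy and the upper triangle of the Hessian
($1 + D(D+1)/2$ columns) with the squared-exponential kernel
$k(\mathbf Q,\mathbf Q') = \tau^2
\exp(-\lVert\mathbf Q-\mathbf Q'\rVert^2/2\beta^2)$ shared across
columns. Choices the data forced:

* **Target scaling.** Energies and Hessian elements differ by orders of
  magnitude, so each column is centred and scaled to unit variance before
  fitting and de-scaled after; $\tau$ then acts on unit-variance targets
  and its default grid is $\{0.3, 1, 3\}$. The $\beta$ grid defaults to
  the 10/25/50/75/90th percentiles of the pairwise training distances.
* **Hyperparameter selection.** $(\tau,\beta)$ minimize the summed squared
  leave-one-out error of the scalar
  $V(\mathbf Q_i) + \tfrac14\mathrm{Tr}[(2\boldsymbol\alpha_i)^{-1}
  \mathbf V''(\mathbf Q_i)]$ — the diagonal bracket of the potential
  element, which is the quantity the spectrum actually consumes. LOO
  residuals come from the closed-form inverse-Gram identity
  $e_i = [\mathbf K^{-1}\mathbf y]_i/[\mathbf K^{-1}]_{ii}$; the test
  suite verifies they equal explicit $n$-fold refits.
* **Regularization.** Training data are deterministic, so $\sigma$ is a
  conditioning device, not a noise model:
  $\sigma^2 = \texttt{sigma2\_rel}\cdot\tau^2$ with default
  $10^{-8}$.
* **Symmetry.** When a symmetry operation is configured, training rows for
  image centres are generated by transporting stored information rather
  than new provider calls, which is what makes the centre-orbit accounting
  the true provider cost.

On the bundled two-dimensional double well, swapping the direct provider
for the GPR source moves the lowest levels by a few tenths of a percent
(the end-to-end test asserts below 1%), while the provider call count
drops from the pair count to the centre count.

## The synthetic study systems

`fixture_double_well()` is the package's standard testbed: a quartic
double well $V_0(Q_1^2-a^2)^2/a^4$ with $V_0 = 1.6\times10^{-2}$ hartree
and $a = 25\,\sqrt{m_e}a_0$, optionally one transverse harmonic mode
($\omega_t = 4\times10^{-3}$ a.u. $\approx 878$ cm$^{-1}$) with a weak
$c\,Q_1^2$ coupling that bends the reaction path. These values put the
ground doublet splitting at about 1.4% of the well frequency — the
tunneling-dominated regime of umbrella-type inversions — while keeping
every oracle (sinc-DVR on a few hundred grid points, quadrature,
closed-form ladders) computable in seconds. What the fixture does *not*
emulate: rotational-vibrational coupling of a real molecule, Hessian
noise from electronic-structure convergence, anharmonic transverse modes,
and dimensionalities beyond a few — passing tests demonstrate the
machinery and its documented error envelope, not chemical accuracy for
any real system.

`pseudo_triatomic()` supplies the molecular test bed for the projection
operators: a bent three-atom molecule whose potential is quadratic in two
bond stretches and the bend, mapped to mass-weighted Cartesians through
the Wilson B matrix, so its Hessian has exactly six zero eigenvalues and
its spectrum is known in closed form ($\tfrac12\sum\omega_k$). Rigid
translation of all basis centres leaves its SBG spectrum unchanged to
$10^{-8}$, which pins the projection algebra.

The sinc-DVR oracle uses the standard uniform-grid kinetic matrix in one
and two dimensions; grids in the tests are 161–301 points per dimension
for 1D and about $100\times49$ for 2D, converged to well below the
tolerances they guard.

## Degenerate inputs and tie-breaks

Duplicate basis centres are removed before pruning (distance
$<10^{-8}$ a.u.); duplicated bases in a solve are absorbed by the overlap
truncation (rank drops, spectrum unchanged); a symmetry operation that
fails to permute the centres within $10^{-6}$ a.u. is rejected rather
than silently ignored; collinear references drop the zero-norm rotation
vector and return a rank-2 rotational projector; eigenvector sign
ambiguity in the path generator is fixed by orienting the downhill
eigenvector's largest component positive, making branch order
reproducible.

## Known limitations

* The LHA element error sets a floor on spectral accuracy that basis
  enrichment cannot cross; quantities that survive error cancellation
  (splittings, level patterns) fare better than absolute ZPEs.
* The eigenproblem is not variational; energies can undershoot, and
  `s_tol` governs the trade between completeness and stability.
* Rotational projection uses one global reference frame; for strongly
  bent paths a per-centre treatment might differ (the operators are
  exposed, so this is testable externally).
* The tabulated potential store is JSON; at the target problem sizes
  (tens of centres, $D \lesssim 100$) file size and parse time are
  negligible.
* GPR accuracy is data-limited by the centre count; for sparse 1D
  layouts the interpolation error at midpoints can reach tens of
  cm$^{-1}$, which the estimation report (`gpr_estimation_report()`)
  quantifies per run.
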