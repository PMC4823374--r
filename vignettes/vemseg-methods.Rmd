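---
title: "vemseg: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vemseg: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`vemseg` segments cellular structures — here mitochondria and synaptic
junctions — in stacks of serial-section electron microscopy images
(FIB/SEM, SBFSEM).  These stacks are usually *anisotropic*: the section
thickness along Z (often 20 nm) is several times the in-plane pixel size.
The package quantifies this with the anisotropy factor

$$\rho = \frac{s_z}{s_x},$$

the ratio of the Z voxel size to the in-plane voxel size, and every stage
that mixes information across sections is corrected by it.

The pipeline has four stages:

1. **Feature extraction** — multiscale, rotationally invariant Gaussian
   derivative features per voxel;
2. **Classification** — a PCA-reduced Gaussian Bayes classifier trained on
   sparse user scribbles, producing per-voxel posterior probabilities;
3. **Regularization** — a conditional random field (CRF) over the voxel
   grid, minimized exactly by a graph cut for two labels and by
   alpha-beta swap for three or more, optionally in overlapping tiles;
4. **Smoothing** (optional, visualization only) — a constrained
   minimum-curvature implicit surface per label, triangulated at its zero
   level set.

A synthetic phantom generator produces EM-like stacks with dense ground
truth so the entire system is testable without any acquisition.

# Feature extraction

At a scale $\sigma$ (pixels) the image is convolved with the Gaussian and
its derivatives, with each derivative order $d$ scaled by $\sigma^d$ so that
responses are comparable across scales.  The per-slice extractor (**F2D**)
treats every section independently — the right choice for anisotropic
stacks — and produces, per scale, the four rotation-invariant components

$$\left\{\, s_{00},\ \sqrt{s_{10}^2 + s_{01}^2},\ \lambda_1,\ \lambda_2 \,\right\}:$$

the smoothed intensity, the gradient magnitude, and the eigenvalues of the
Hessian $\begin{pmatrix} s_{20} & s_{11} \\ s_{11} & s_{02}\end{pmatrix}$,
computed in closed form as

$$\lambda_{1,2} = \tfrac12\left(s_{20}+s_{02} \pm
  \sqrt{(s_{20}-s_{02})^2 + 4 s_{11}^2}\right),$$

ordered $\lambda_1 \ge \lambda_2$.  Dark sheet-like structures (synaptic
junctions) and blob-like structures (mitochondria) separate well in this
eigenvalue space.  The volumetric extractor (**F3D**) is the direct 3D
generalization (gradient magnitude and three ordered eigenvalues of the
3×3 Hessian, computed by the trigonometric closed form for symmetric
matrices); it is intended for near-isotropic stacks and the package warns
when it is applied at $\rho > 1.5$.  With `extractor = "auto"` the package
picks F3D when $\rho \le 1.5$ and F2D otherwise.

Scales form a half-octave geometric sequence $\sigma_i = 2^{i/2}\sigma_0$,
$i = 0..n-1$.  Only the base scale $\sigma_0$ is normally chosen by the
user; the default number of scales is $n = 4$ (e.g. $\sigma_0 = 4$ gives
scales 4, 5.66, 8, 11.31 px and a 16-dimensional F2D vector).  $\sigma_0$
should match the smallest structures of interest; the cross-validation grid
(below) selects it quantitatively.

Numerical choices: convolutions are separable with mirror (reflect)
boundary handling, which avoids spurious gradients at slice borders;
kernels are truncated at $4\sigma$; sampled derivative kernels are
calibrated so their discrete moments are exact (zero sum and unit first
moment for first derivatives; zero sum, zero first and second moment 2 for
second derivatives), making responses on constant and polynomial images
exact to rounding.

# Classification

Labels $y$ follow Bayes' rule per voxel,

$$P(y \mid f(x)) \propto p(f(x) \mid y)\, P(y),$$

with a multivariate Gaussian class-conditional $p(f \mid y) =
\mathcal{N}(f; \mu_y, \Sigma_y)$ and priors $P(y)$ estimated as
labeled-voxel frequencies.  Because high-dimensional feature clouds from
small scribble sets often span a proper subspace, features are first
projected onto a PCA basis retaining 99 % of the variance, fitted on the
whole feature cloud of the training stack (subsampled uniformly at random
to at most $10^6$ vectors under a fixed seed).  The retained dimension is
the smallest count of leading axes whose cumulative variance fraction
reaches the target.

Per label, $\mu_y$ and $\Sigma_y$ are the sample mean and covariance of the
projected features.  $\Sigma_y$ is regularized as $\Sigma_y +
\varepsilon\,\mathrm{tr}(\Sigma_y)/k'\, I$ with $\varepsilon = 10^{-6}$
(and a plain $\varepsilon I$ floor when the trace is zero, i.e. a class
whose features are all identical), so a Cholesky factor always exists.
Densities are evaluated in log space through the cached Cholesky factor and
normalized with log-sum-exp, so posteriors remain finite and normalized
arbitrarily far from the class means (exercised in the tests at
$10^3\sigma$).  Ties in the maximum-posterior labeling break toward the
lowest label id, making every stage deterministic.

# CRF regularization

Voxel-independent classification produces speckle: isolated voxels, small
holes, jagged boundaries.  The CRF couples 6-connected neighbors through
the energy

$$E(Y) = \sum_{i \in V} \phi_i(y_i, x)
 + \theta_{XY} \sum_{(i,j) \in E_{XY}} \phi_{ij}(y_i, y_j)
 + \theta_{Z} \sum_{(i,j) \in E_{Z}} \phi_{ij}(y_i, y_j),$$

with unaries $\phi_i(y_i, x) = -\log P(y_i \mid f_i(x))$ (posteriors
floored at $10^{-12}$) and pairwise terms $\phi_{ij}(a, b) = D[a, b]$ from
a symmetric, zero-diagonal label distance matrix.  The 6-neighborhood is
split into in-plane edges $E_{XY}$ and across-section edges $E_Z$; since
sections are $\rho$ times farther apart, the default coupling across
sections is $\theta_Z = \theta_{XY} / \rho$ (both independently
overridable).  The default distance matrix for (bg, syn, mit) penalizes any
label change by 1 and forbids synapse–mitochondrion contact with an
$\infty$ entry — organelle-level prior knowledge expressed in one matrix.

For two labels with submodular pairwise terms
($\phi(a,a) + \phi(b,b) \le \phi(a,b) + \phi(b,a)$, checked before
solving), the exact global minimizer is found by a single max-flow/min-cut
computation.  The package implements the Boykov–Kolmogorov augmenting-path
algorithm in C++ (two search trees grown from source and sink with orphan
adoption), which is near-linear in practice on image grids; its optimality
is verified in the test suite against exhaustive enumeration of all $2^n$
labelings on hundreds of randomized small grids.

With three or more labels the problem is NP-hard and the package uses
**alpha-beta swap**: starting from the maximum-posterior labeling, for each
label pair $(\alpha, \beta)$ in ascending lexicographic order the voxels
currently labeled $\alpha$ or $\beta$ are re-assigned by one exact binary
cut (interactions with fixed-label neighbors folded into the unaries); a
move is accepted only if it strictly lowers the energy, and sweeps repeat
until a full pass makes no progress.  The energy trace is therefore
strictly decreasing and the procedure is deterministic.

$\infty$ entries are represented by the finite surrogate
$10^6 (\max_i \max_y \phi_i(y) + \theta_{XY} + \theta_Z)$, which exceeds
any achievable labeling energy at the problem sizes the package targets;
after solving, the returned energy is asserted to be below the surrogate,
otherwise an infeasibility error is raised.

**Tiling.** Graph cuts hold the whole residual graph in memory, so large
stacks are regularized in disjoint tiles (default 256×256×64 voxels), each
extended by a margin (default 10 voxels) in every direction; the CRF is
minimized on the extended tile and only core voxels are written.  The
margin gives the CRF context across tile boundaries; the tests verify that
tiled and untiled results agree exactly when objects keep at least 12
voxels from the cuts.  The in-plane neighborhood is 4-connected (plus the
two Z neighbors), the minimal structure consistent with the
$E_{XY}$/$E_Z$ split; connected-component analysis uses the same
6-connectivity by default so counting and regularization agree.

# Constrained smoothing

The hard segmentation is kept untouched for all quantitative outputs;
smoothing only affects extracted surfaces.  For one object label, define
$v_i = +1$ inside, $-1$ outside, and margins $m_i = 0$ on boundary voxels
(those with a 6-neighbor of opposite sign), $1$ elsewhere.  The implicit
field $f$ minimizes the anisotropy-weighted sum of squared axial second
differences

$$\sum_i \left(f_{N_x(i)} + f_{N_{-x}(i)} - 2f_i\right)^2
       + \left(f_{N_y(i)} + f_{N_{-y}(i)} - 2f_i\right)^2
       + \frac{\left(f_{N_z(i)} + f_{N_{-z}(i)} - 2f_i\right)^2}{\rho^4}$$

subject to $v_i f_i \ge m_i$ for all $i$.  The $\rho^4$ divisor accounts
for the squared second difference across sections that are $\rho$ times
farther apart.  Boundaries are natural (free): stencils are accumulated
only where both axial neighbors exist, so constant fields and linear ramps
— the exact solutions for empty volumes and half-space objects — have
exactly zero energy.

This convex quadratic program is solved by damped Jacobi iteration
(damping $\omega = 2/3$, a standard stable choice for fourth-order
stencils) initialized at $f = v$, with a projection after every sweep that
resets violated coordinates to $v_i m_i$ — so the constraints hold exactly
at every iterate, including the output.  Iteration stops when the largest
per-voxel update falls below `tol` ($10^{-4}$ by default) or after
`max_iter` sweeps (1000); non-convergence is reported in a flag, never as
an error.  Because the constraint $v_i f_i \ge m_i$ is a per-coordinate
bound, the tests can cross-check the attained objective against an
independent bound-constrained solver (L-BFGS-B) on instances up to 200
unknowns; they agree to $10^{-4}$.

The zero level set is triangulated by marching tetrahedra (each grid cell
split into six tetrahedra around its main diagonal), a marching-cubes
variant that needs no case table and produces watertight, consistently
outward-oriented meshes wherever the object stays inside the volume;
vertices on shared cell edges are merged.  Vertex coordinates are in nm,
with Z scaled by the section thickness.  Meshes export to PLY (binary
little-endian or ASCII) and STL.

# Evaluation and counting

One-vs-rest voxel metrics: TPR $=$ TP/(TP+FN), FPR $=$ FP/(FP+TN),
ACC $=$ (TP+TN)/total, JAC $=$ TP/(TP+FP+FN) and the volume error
VOE $=$ |FP−FN|/(TP+FN) (a fraction internally; the CLI prints it as a
percentage).  Undefined ratios (empty foreground) are reported as `NA`,
never as errors.

Structure counts are connected components (6-connectivity, configurable to
26) of a label with at least $t$ voxels; sweeping $t$ over a range
(default 10..2000) and averaging $|\#CC_{[\mathrm{size} \ge t]} -
\mathrm{GT}|$ over the range summarizes counting robustness in one number —
a good segmentation keeps the estimate near the truth across a wide
threshold band.

Parameter selection uses k-fold cross-validation (default $k = 5$) over a
grid of $(\sigma_0, \theta_{XY})$.  Folds are **contiguous Z slice
blocks**, not random voxel splits: consecutive sections are strongly
correlated, and block folds prevent that correlation from leaking between
training and test.  Each fold trains on the labeled voxels of the other
blocks and evaluates the regularized prediction on the held-out block,
one-vs-rest per structure.

# The phantom generator

The phantom emulates the image statistics the pipeline actually relies on,
at EM-plausible geometry (default 128×128×32 voxels at 10×10×20 nm,
$\rho = 2$): a bright background (mean 0.70) crossed by faint dark
membrane curves (0.45); mitochondria as randomly oriented dark ellipsoids
(semi-axes 8–14 px, mean 0.35) with darker internal stripes (0.25)
mimicking cristae texture; synaptic junctions as thin curved sheets (2 px
thick, lateral radius 12–20 px, 0.28 with a darker 0.22 rim); and additive
Gaussian noise ($\sigma = 0.06$).  The class means were chosen once so the
classes overlap through the noise — the classifier must work for the
pipeline to succeed, but cannot be trivially perfect.  Geometry is
generated in nm space and sampled at the voxel grid, so anisotropy enters
exactly as in acquisition.  Objects keep a 2-voxel clearance from each
other and the border (placement retries bounded, then an error), which
also enforces the synapse–mitochondrion exclusion in the ground truth.
All randomness flows through one seeded generator: identical spec and seed
give bit-identical stacks.

Scribble training data is emulated by keeping a random per-class fraction
of the dense labels (`make_training_scribbles`), deterministic under its
seed.

What the phantom does **not** emulate: membrane-bounded neurites and
vesicles, shot/scan noise structure, section-to-section registration
errors, charging and staining gradients, or anisotropic point-spread blur.
Passing the phantom suite therefore demonstrates that the machinery is
correct and the pipeline recovers known structures under EM-like contrast
and anisotropy — not that any particular accuracy will transfer to real
tissue.

# Test problem sizes and reproducibility

The test suite verifies graph-cut optimality by exhaustive enumeration on
grids up to 3×3×2 voxels (hundreds of seeded instances), swap-move
properties on 4×4×2 three-label instances, smoothing against the
bound-constrained oracle at up to 200 unknowns, and the full pipeline on
the default 128×128×32 phantom: training scribbles (5 % per class) drawn
only from the first half of the sections, prediction and regularization on
the whole stack, requiring Jaccard at least 0.8 for mitochondria and 0.6
for synaptic sheets, with regularization never decreasing either.  These
sizes were chosen to keep the default suite fast while still exercising
every code path; all seeds are fixed in the tests, so results are
bit-reproducible.

# Design decisions and limitations

- **Eigenvalues, not formulas with mixed conventions:** the Hessian
  eigenvalues are computed by the closed forms above, which satisfy the
  trace/determinant identities by construction; the tests check them
  against a general symmetric eigensolver.
- **Intensity normalization** to $[0, 1]$ at load time makes
  $\sigma$-scaled derivative magnitudes comparable across 8- and 16-bit
  sources; it is a per-stack min-max rescale, so absolute gray levels are
  not preserved across stacks.
- **Priors from scribble frequencies**: the prior $P(y)$ is estimated from
  the user-provided labeled voxels.  Scribble proportions rarely match
  true volume fractions; the CRF largely compensates, but strongly skewed
  scribbles will bias the argmax labeling.
- **No learned pairwise terms**: the distance matrix is fixed prior
  knowledge, not trained.  Alpha-beta swap returns a strong local optimum,
  not the global one, for 3+ labels.
- **Jacobi smoothing** converges slowly on large flat regions (it is a
  fourth-order problem); for visualization-quality surfaces the default
  iteration cap is usually sufficient, and the convergence flag reports
  when it is not.
- **Memory**: the tiled regularizer bounds peak memory by tile size;
  feature stacks are held densely in memory (4n or 5n doubles per voxel),
  which is the practical limit for very large stacks.
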