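---
title: "Moment-based rotationally invariant metrics for cryo-EM structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based rotationally invariant metrics for cryo-EM structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kammetrics)
```

## The problem

Single-particle cryo-EM produces large stacks of noisy tomographic
projection images of a molecule at unknown orientations. Two recurring
questions are (i) how similar are two solved 3D structures, without the
expensive step of rotationally aligning them, and (ii) which structure in a
library best explains a raw image stack, without performing a 3D
reconstruction. Kam's method of moments supplies a common language for
both: the first and second moments of the images' Fourier transforms are
simple functionals of the underlying 3D structure and of the distribution
of viewing directions, and low-order moments can be estimated from images
in a single streaming pass.

`kammetrics` implements two metrics built on these moments:

* a **volume metric** `d_volume()` between the moments two structures
  would produce under a *uniform* distribution of viewing directions, and
* an **image metric** `d_image()` between empirical moments estimated from
  a particle stack and the moments a candidate structure would produce
  under the *best-fitting admissible* distribution of viewing directions,
  which is eliminated in closed form.

Both are invariant to 3D rotation of the structures, so no alignment is
ever computed.

## Model and notation

Let $\phi$ be the molecule's electrostatic potential and
$F(\mathbf k)=\int \phi(\mathbf x)\,e^{-2\pi i \mathbf k\cdot\mathbf x}\,
d\mathbf x$ its Fourier transform (this sign/scale convention is used
throughout and is unit-tested against the closed-form Gaussian pair). On
spheres of radius $k$, $F$ is expanded in complex orthonormal spherical
harmonics with Condon–Shortley phase,
$$ F(k\mathbf u) \;=\; \sum_{\ell=0}^{L}\sum_{m=-\ell}^{\ell} (-i)^\ell\,
   A_{\ell m}(k)\, Y_\ell^m(\mathbf u), $$
where $L$ is the volume bandlimit. The $(-i)^\ell$ phase is folded into
the stored coefficient, under which a real volume satisfies
$A_{\ell,-m} = (-1)^m \overline{A_{\ell m}}$.

By the Fourier-slice theorem, an image of the particle at rotation $R$
has Fourier transform $\widehat I(k,\varphi) = F(R\,\mathbf c_\varphi)$
with $\mathbf c_\varphi = k(\cos\varphi,\sin\varphi,0)$. With viewing
directions drawn from a density $\rho$ (assumed invariant to in-plane
rotation and reflection, hence an even-degree harmonic expansion
$\rho=\sum_{p\ \mathrm{even}\le P} \sum_u B_{pu} Y_p^u$ on the projective
sphere, with $B_{00}=1/\sqrt{4\pi}$ fixed by normalisation), the moments
$$ m_1(k) = \mathbb E\,\widehat I(k,\varphi), \qquad
   m_2(k_1,k_2,\Delta\varphi) = \mathbb E\,\widehat I(k_1,\varphi+\Delta\varphi)\,
   \overline{\widehat I(k_2,\varphi)} $$
depend only on the shown arguments and are **affine in the free
coefficients of $\rho$**. That linearity is the hinge of the image metric.

## How the moments are computed

`expand_volume()` obtains $A_{\ell m}(k)$ from a voxel volume through the
plane-wave (spherical Bessel) identity: treating the voxel volume as a
weighted point set, the projection of its nonuniform Fourier transform
onto harmonics at radius $k$ is
$A_{\ell m}(k) = 4\pi h^3 \sum_{\mathbf x} v(\mathbf x)\,
j_\ell(2\pi k r_{\mathbf x})\,\overline{Y_\ell^m}(\hat{\mathbf x})$.
Binning voxels by their few hundred distinct radii turns this into two
small dense products per degree; the result is exact for the voxel data —
no gridding, no interpolation, no angular quadrature — and the conjugate
symmetry above holds to machine precision.

`analytic_moments()` and `moment_design()` evaluate the moment
expectations by a quadrature that is *exact*, not approximate, for a
bandlimited expansion: the in-plane average is a discrete circular mean
(the slice is a trigonometric polynomial of degree $\le L$ in $\varphi$,
and products have degree $\le 2L < n_\varphi$), and the integral over
viewing directions uses Gauss–Legendre (polar) × uniform (azimuth) nodes
sized for the degree-$(2L+P)$ integrand. `moment_design()` assembles the
affine map $b \mapsto (m_1, m_2)$ from the free density coefficients by
evaluating the same node table against each real basis function of the
admissible set.

Tests verify the analytic moments against a Monte-Carlo oracle (plain
averaging over Haar-random rotations) to within sampling error, and the
design against rejection-sampled rotations from a known bandlimited
density.

## The two metrics

The moments live on a polar grid: radial nodes $k_j$ (by default the
volume's natural frequency ladder $j/\text{side length}$, up to half the
Nyquist frequency; Gauss–Legendre nodes are available) and $n_\varphi$
uniform angles. The discrete norms weight $m_1$ entries by $k$ and $m_2$
entries by $k_1 k_2$, times the radial quadrature weights and the angular
step, approximating the continuous polar measures. Both metrics use
$$ d = \sqrt{\;\|\Delta m_1\|^2 + \lambda\,\|\Delta m_2\|^2\;}, $$
with $\lambda = 1$ by default. The square-root form was chosen (over the
sum of the two residuals) because it makes $d$ a genuine norm of
differences, so symmetry and the triangle inequality hold exactly —
properties the test suite asserts on random triples.

`d_volume()` compares two structures' uniform-density moments.
`d_image()` minimises the same weighted residual over the free density
coefficients: because the moments are affine in $b$, this is a small
linear least-squares problem (5 unknowns at the default $P=2$), solved by
SVD; a rank-deficient system falls back to the minimum-norm solution with
a condition-number note. The returned object carries the distance, the
fitted viewing density, the per-moment residuals, and the residual at the
pinned uniform density (an upper bound for the minimised distance —
asserted for every fit in the tests).

Positivity of $\rho$ is deliberately **not** enforced; `density_min()`
reports the most negative value of a fitted density as a diagnostic.

## Empirical moments from images

`empirical_moments()` evaluates each image's Fourier transform directly
on the polar grid with a precomputed nonuniform DFT matrix — exact for
the pixel data. Images are grouped by CTF; within a group, the moments
average in one streaming pass (chunking never changes the result), and
the white-noise contribution to the second moment is subtracted in closed
form: for noise variance $\sigma^2$ per pixel, the noise covariance of
the polar samples is $\sigma^2 E E^H$ with $E$ the fixed transform
matrix. Across groups the underlying moments are recovered by a per-entry
weighted least squares,
$m_2 \propto \sum_g n_g H_g(k_1)H_g(k_2)\,\hat m_{2,g} \big/
\sum_g n_g (H_g(k_1)H_g(k_2))^2$,
which never divides by CTF zeros. `estimate_noise_variance()` supplies
$\sigma^2$ from the corner annulus outside the particle.

`preprocess_stack()` covers the practical steps used on deposited data:
Fourier-crop downsampling, phase-ramp centering with deposited shifts
(in ångström; the recorded shift is undone), and a circular binary mask.
`fit_moment_scale()` resolves global intensity ambiguities by a
closed-form least-squares scale between second-moment diagonals; the
scale multiplies $m_2$, with $\sqrt{c}$ applied to $m_1$.

## The simulator and what it does (not) emulate

`simulate_dataset()` composes pose sampling → central-slice projection →
radial CTF → white noise. Defaults mirror the synthetic protocol the
package targets: 25000 images, viewing directions from a three-component
von Mises–Fisher mixture, 100 unique radial CTFs, SNR 0.1 with the SNR
defined as mean squared clean-pixel intensity over noise variance.
Parameters the protocol leaves open were fixed once as field-typical
values: mixture means uniform on the sphere, Dirichlet(1) weights,
concentrations uniform in $[4, 16]$; CTF defocus uniform in 1–3 μm at
300 kV, $C_s$ = 2 mm, 7% amplitude contrast.

Clean images are generated from the structure's $L$-bandlimited
expansion: the central slice is evaluated exactly on the image frequency
grid and inverse-transformed. This makes the simulated images *exactly*
the bandlimited image-formation model whose analytic moments the metrics
use, so empirical-vs-analytic comparisons converge at the Monte-Carlo
$n^{-1/2}$ rate with no interpolation floor (measured residual bias
$\sim 10^{-5}$ relative, against $\sim 10^{-2}$ sampling error at
$n=10^4$).

Deliberately **not** modelled (matching the method's stated scope):
structural heterogeneity, junk particles, non-white noise, astigmatic
CTFs, B-factors and solvent effects. Passing the synthetic recovery
experiments therefore demonstrates the statistical machinery, not
robustness to those real-data effects.

## Database search

`build_db()` precomputes each library structure's expansion, uniform
moments and design operators; `rank_by_volume()` and `rank_by_images()`
are then a few small linear-algebra operations per entry, which is what
makes the search scalable to large structure libraries.
`recovery_experiment()` packages the end-to-end study: a library of 20
mutually distinct Gaussian-blob phantoms (rejection sampling keeps every
pairwise volume distance above 15% of the running median), one
2000-image query stack per structure at SNR 0.1 with a 10-CTF bank, and
ranking of every stack against the whole library. `ndcg()` scores
ranking agreement (linear gain over a log2 discount, with a pluggable
rank-based relevance transform).

## Numerical choices and limitations

* **Grid sizes.** Default experiments use $N=32$ voxel grids at 2 Å,
  $L=8$, $P=2$, $n_k=8$ radial nodes up to half Nyquist, $n_\varphi=36$.
  These keep the full test suite and the acceptance script within
  minutes on one CPU while leaving the phantoms' frequency content
  essentially inside the bandlimit (blob centres within 14% of the box,
  widths ≥ 3.5 Å).
* **Phantom scale.** The library stands in for a PDB-scale database; 20
  structures is the desk-scale analogue, and recovery rates on it are
  not directly comparable to full-database experiments.
* **Bandlimit truncation.** Comparisons between the expansion route and
  direct voxel-space operations (projection vs. axis sums,
  trilinear-rotated volumes) agree to $10^{-3}$–$10^{-2}$ relative,
  limited by $L$-truncation and interpolation, and the tests use
  tolerances of that order; all expansion-internal identities
  (rotation invariance, conjugate symmetry, shell energies) hold to
  $10^{-10}$ or better.
* **Seeds.** Every stochastic component takes an explicit seed and
  restores the caller's RNG state, so experiments are reproducible and
  composable.
* **Atomic models.** The potential generator uses one isotropic Gaussian
  per element (amplitude ∝ atomic number, tabulated widths). The table
  is an argument of `atomic_model_to_volume()`, so a multi-Gaussian
  electron scattering parameterisation can be swapped in without
  touching the rest of the pipeline.

## A worked example

```{r example, eval = FALSE}
library(kammetrics)

cfg <- default_metric_config()              # N = 32, 2 A, L = 8, P = 2
lib <- make_phantom_library(6, seed = 2)
db  <- build_db(lib, cfg)

# volume query: a rotated copy ranks first at numerically zero distance
e3  <- expand_volume(lib[["ph03"]], cfg$L, cfg$grid$k)
R   <- random_rotations(1)[, , 1]
mq  <- analytic_moments_uniform(rotate_expansion(e3, R), cfg$grid)
rank_by_volume(mq, db, query_id = "ph03-rotated")

# image query: simulate a noisy nonuniform-pose stack and match it back
qm  <- simulate_query_moments(lib[["ph05"]], cfg, n_images = 2000,
                              snr = 0.1, n_ctf = 10, seed = 7)
rank_by_images(qm$moments, db, query_id = "ph05-images")
```
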