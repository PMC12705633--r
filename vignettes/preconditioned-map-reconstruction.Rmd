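---
title: "Preconditioned MAP PET reconstruction: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preconditioned MAP PET reconstruction: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The reconstruction problem

PET data are Poisson counts per line of response (LOR):
$y_i \sim \mathrm{Poisson}(\bar y_i)$ with the affine forward model
$\bar y_i = \sum_j a_i c_{ij} \lambda_j + b_i$, where $\lambda$ is the voxel
activity, $c_{ij}$ the geometric detection probability, $a_i \in (0,1]$ the
attenuation factor of the LOR, and $b_i \ge 0$ the expected scatter+randoms
background. The MAP estimate minimizes
$\Phi(\lambda) = -L(\lambda) + \beta R(\lambda)$ with
$-L(\lambda) = \sum_i \bar y_i - y_i \log \bar y_i$.

The Hessian of $-L$ is $\sum_i a_i^2 (y_i/\bar y_i^2)\, c_{ij} c_{i\xi}$. Its
diagonal spans several orders of magnitude (attenuation enters squared, and
$1/\bar y_i$ varies between body-crossing and background LORs), which makes
plain gradient methods very slow. This package implements a reconstruction
strategy built on three ingredients:

1. an *unconstrained* formulation whose gradient stays well defined for
   negative activity values,
2. a smooth relative difference prior with analytic derivatives, and
3. a frozen *mixed diagonal–circulant preconditioner* inside a conjugate
   gradient loop with a quadratic step size.

# The unconstrained likelihood gradient

Instead of constraining $\lambda \ge 0$, the gradient denominator is clamped
at the background:
$$\partial_j(-L) = \sum_i a_i c_{ij}\,\frac{\bar y_i - y_i}{\max(\bar y_i, b_i)}.$$
Inside the object $\bar y_i \gg b_i$, so this is bit-identical to the exact
Poisson gradient; in background LORs it keeps the *expected* curvature
$1/\max(\bar y_i, b_i)$ of the exact likelihood while letting voxel values
fluctuate around zero, so cold regions converge without the positivity bias
of multiplicative algorithms. The clamp must use $b_i$ itself — deflating it
(e.g. $\alpha b_i$, $\alpha<1$) changes the expected curvature and biases the
solution. The objective *value* is only used for monitoring; when iterates
drive $\bar y \le 0$ in background bins, `neg_loglik()` clamps at a tiny
floor ($10^{-12}\,\overline b$) to stay finite.

# The smooth relative difference prior

The pairwise penalty implemented is
$$M_{j\xi} = k_j k_\xi\,
\frac{(\lambda_j-\lambda_\xi)^2}
     {\sqrt{\lambda_j^2+\lambda_\xi^2+\gamma^2(\lambda_j-\lambda_\xi)^2+\varepsilon^2}},
\qquad R = \sum_j \sum_{\xi \in N_j} M_{j\xi},$$
a smooth variant of the relative difference prior that is well defined for
negative values. The square root in the denominator is what makes the
analytic gradient carry a $D^{3/2}$ power and the Hessian a $D^{5/2}$ power;
differentiating the pair term symbolically reproduces those closed forms
exactly, and the package's derivatives (implemented for general $\gamma$) are
verified against finite differences of the value in the test suite. For
$|\lambda| \gg \varepsilon$ the penalty scales as activity times the squared
*relative* difference — the defining RDP behavior: hot regions are not
over-smoothed, and edges with contrast above about $\gamma$ are preserved.

Parameters, with defaults:

* `beta` — global strength; the benchmark driver picks a mid level by a pilot
  rule (prior curvature trace $\approx$ 10% of the likelihood curvature trace
  at the initialization) and sweeps low = mid/3 and high = 3·mid.
* `gamma = 2` — edge preservation, the value for which the closed forms were
  cross-checked against an independent transcription.
* `eps` — smoothing scale in activity units. Default
  $10^{-3}\times$ mean initialization activity inside the object mask: small
  enough not to regularize real activity levels, large enough to keep the
  penalty twice differentiable around zero.
* `k_weights` — per-voxel factor hook (all 1 by default); position-dependent
  weighting schemes can be plugged in without touching the kernels.
* neighborhood — 8 in-plane + 2 axial offsets; the double sum runs over
  ordered pairs, so each unordered pair contributes twice.

The prior is non-convex: individual Hessian diagonal entries and the
curvature $\langle s|H_{\mathrm{rdp}}|s\rangle$ along a direction can be
negative. The step size guards for this (below).

# The preconditioner

The objective's Hessian is approximated as $D^{-1} C D^{-1}$ with $D$
diagonal and $C$ circulant per slice, giving the applied operator
$$s = D\,F^{-1}\,T\,F\,D\,g, \qquad D = \mathrm{diag}(\eta^{-1/2}),$$
computed **once** at the initialization and frozen (the Poisson Hessian is
approximately constant given a reasonable start).

**Diagonal.** $\eta_j = \sum_i a_i^2 c_{ij}/\max(\bar y_i, b_i) +
\beta\,\partial^2 R/\partial\lambda_j^2$, evaluated at the OSEM
initialization. Two approximations make it a single back-projection: the
geometric footprint is treated as near-binary ($\sum a^2 c^2 \approx
\sum a^2 c$, exact for a nearest-bin projector, which the oracle tests use),
and $y/\bar y^2$ is replaced by its expectation $1/\bar y$ — making $\eta$ a
smooth, low-frequency image even at low counts. Because $\eta$ from the
back-projection is nearly zero outside the scanned object, it is floored at
its 1st percentile over the support mask before inversion; equivalently
$D$ is capped, keeping the operator bounded and invertible.

**Circulant.** The response $\sum_i c_{ij}c_{i\xi}$ of a 2D tomograph is the
$1/r$ blur of backprojection, so its approximate inverse is a ramp ($|f|$)
filter. The filter is built by a fixed recipe: band-limited Ram-Lak impulse
response ($h[0]=1/(4\Delta^2)$, $h[n\ \mathrm{odd}]=-1/(\pi n\Delta)^2$,
length the next power of two $\ge 2 n_{\mathrm{radial}}$); optional
multiplication by the TOF kernel $\exp(-x^2/4\sigma^2)$ in the spatial
domain (good TOF timing localizes emissions, so less ramp is needed — the
kernel flattens the low-frequency end); Fourier transform; Hamming
apodization with cutoff at the Nyquist frequency; radial interpolation onto
the 2D FFT grid of a slice (linear in $|f|$ by default, spline available),
zero beyond the Nyquist disc; the same filter for all slices. The Hamming
window is the standard $0.54-0.46\cos(\cdot)$ taken over the symmetric
frequency axis, i.e. $0.54+0.46\cos(\pi f/f_{\max})$ on $[0,f_{\max}]$ —
1 at DC, 0.08 at Nyquist. The filter's overall scale is deliberately left
unnormalized: the quadratic step size absorbs any global scaling of the
search direction.

The operator is linear, symmetric and positive semidefinite ($T \ge 0$,
$D > 0$) — properties the test suite asserts on random vectors. It is *not*
positive definite: the response is exactly zero beyond the Nyquist disc and
very small at DC (the band-limited ramp), so gradient components at those
frequencies are followed only through conjugation. This is visible in
practice as a whole-image RMSE plateau over a few iterations while VOI means
keep converging, and it is why the monitored gradient norm of the filtered
variants levels off at a small but nonzero fraction of its initial value
rather than decaying indefinitely.

# The optimizer loop

All gradient variants minimize $\Phi$ under one sign convention
($g = \nabla\Phi$, update $\lambda \leftarrow \lambda - \alpha s$):

1. $g_k = \nabla(-L) + \beta\nabla R$ (one back projection);
2. $s_k = D F^{-1} T F D g_k$ (PCG/PG) or $D D g_k$ (DCG/DG);
3. Polak–Ribière conjugation (PCG/DCG, $k>0$):
   $\gamma_k = \max(\langle s_k | g_k - g_{k-1}\rangle /
   \langle z_{k-1} | g_{k-1}\rangle, 0)$ with $z_{k-1}$ the *previous
   preconditioned gradient* (the standard preconditioned-PR form; the
   alternative — previous conjugate direction — is a symbol-overloading
   ambiguity, and the preconditioned-gradient form guarantees a positive
   denominator for a PSD preconditioner), then
   $d_k = s_k + \gamma_k d_{k-1}$; a non-descent $d_k$ falls back to $s_k$;
4. $f_k = $ forward projection of $d_k$ (the only forward projection);
5. quadratic step
   $\alpha_k = \langle d_k|g_k\rangle\,/\,
   (\langle f_k|\tfrac{1}{\max(\bar y, b)}|f_k\rangle +
   \beta\langle d_k|H_{\mathrm{rdp}}|d_k\rangle)$; if the full denominator is
   nonpositive (RDP non-convexity) the likelihood-only curvature is used;
6. $\lambda_{k+1} = \lambda_k - \alpha_k d_k$,
   $\bar y_{k+1} = \bar y_k - \alpha_k f_k$ (incremental — no extra
   projection), with a full forward refresh every 20 iterations to bound
   floating-point drift (the refresh shows up in the projection counters,
   which the tests use to verify the 1 forward + 1 back budget per
   iteration).

Initialization is 14 OSEM sub-iterations over 2 angle-interleaved subsets
from a uniform image. With `constrain_nonneg = TRUE`, negatives are truncated
to zero after each update and $\bar y$ is recomputed (one extra forward
projection per iteration). Truncation is only stable combined with the
diagonal-preconditioned gradient (DG) — the comparator used for the
constrained-vs-unconstrained experiments; combined with the circulant filter
the truncation re-injects mass that the long filtered steps remove, and the
iteration can ratchet upward, so the filtered constrained combination should
be avoided.

**BSREM comparator.** Relaxed subset-gradient steps preconditioned by
$\max(\lambda,\tau)/\mathrm{sensitivity}$, with small values reset to the
threshold $\tau = 10^{-6}\times$ mean initialization activity after each
sub-iteration (which is what makes it a constrained algorithm). Relaxation
$\alpha_n = 1/(1+0.1\,n)$ over epochs; 5–9 subsets. Epoch accounting: one
full-data gradient iteration = 1 epoch; one BSREM sub-iteration =
$1/n_{\mathrm{subsets}}$ epoch.

**Reference reconstructions.** Convergence metrics need a converged image at
the same $\beta$. The package generates it with a long run of the fastest
converger (PCG, 600 iterations, gradient-norm monitored): all variants
descend the same objective toward the same optimum, and on desk-scale
problems the diagonal-only variants are still far from it after thousands of
iterations — the slow convergence that motivates preconditioning in the
first place — so a long DG run would be a worse reference, not a more
neutral one. The 10 mm sphere VOI of the reference is stable at the 0.3–0.5%
level over the second half of the run, which bounds the resolution of
VOI-error statements made against it.

# The synthetic data generator

The generator is the package's own study design, not a fixture:

* `nema_like` — image-quality phantom: uniform background cylinder (water
  attenuation, 0.0096/mm) with six spheres of 10, 13, 17, 22, 28 and 37 mm
  diameter at 10:1 contrast (4:1 and cold variants configurable).
* `brain_like` — procedural cortical-ribbon pattern at 4:1 gray:white
  contrast with cold ventricle-like inserts.
* `thorax_like` — body ellipse with low-attenuation lungs (0.0024/mm), a
  bone-like spine (0.0172/mm) and an irregular hot lesion; its attenuation
  factors span over two orders of magnitude across LORs, the regime in which
  the Hessian diagonal is most ill-conditioned.

Acquisition simulation scales the noiseless attenuated projection so that
trues carry $(1-\mathrm{sf})\times$ `total_counts` and a spatially uniform
background sinogram carries the rest ($\mathrm{sf}$ = `scatter_fraction`),
then draws seeded Poisson counts. Defaults for the benchmark problem:
128×128 single slice at 2 mm pixels, 128 radial bins, 96 view angles
(matching the ~0.75 views-per-radial-bin ratio of clinical scanners),
$5\times10^6$ prompts, scatter fraction 0.2. Low-count variants use exact
binomial thinning. VOI masks are eroded by one voxel from each insert.

What the generator does *not* emulate: 3D oblique LORs (direct planes only,
consistent with the per-slice 2D filter), nonuniform smooth scatter,
detector normalization and gaps, randoms structure, resolution modeling, and
real anthropomorphic textures. Passing tests therefore demonstrate the
optimization behavior of the algorithms under controlled Poisson statistics,
not clinical image quality.

A note on scale: a single 2 mm slice at $5\times10^6$ prompts is far noisier
per voxel than a clinical 3D acquisition. Two consequences are visible in
the shipped experiments and are properties of the regime, not of the
algorithms: the early iterations show a transient over/undershoot of the
smallest-sphere VOI mean (a ~9-voxel region) before it settles, and the
converged unconstrained image differs from its negativity-truncated
counterpart by tens of percent RMSE, because background voxels fluctuate
with an amplitude comparable to the object mean and truncation removes half
of that fluctuation. At clinical statistics both effects shrink by an order
of magnitude.

# Numerical choices

* Projector: Joseph's method (ray-driven linear interpolation) assembled
  once per geometry as a sparse matrix; backprojection is the exact
  transpose, so the adjoint identity holds to machine precision. A
  nearest-bin binary-footprint variant exists for oracle tests.
* TOF: bin width = FWHM of the Gaussian kernel, 3σ truncation, weights
  renormalized per sample so TOF bins partition the non-TOF line integral
  exactly; samples outside every truncated kernel go to the nearest bin.
* Degenerate inputs: `max(ȳ, b) = 0` with $y>0$ is an error; with $y=0$ the
  bin carries weight 0. Zero-sensitivity voxels are left untouched by OSEM.
  A nonpositive step-size denominator after the likelihood-only fallback is
  an error rather than a silent clamp.
* Determinism: the only random element is the seeded Poisson/binomial
  sampling in the generator; reconstructions are deterministic given the
  data.

# Limitations

* The circulant part is per-slice 2D and ignores axial blur; the filter
  cutoff is not adapted to $\beta$.
* The filter suppresses DC and everything beyond the Nyquist disc, so the
  gradient norm of filtered variants plateaus; convergence statements are
  therefore made on VOI means and RMSE against a converged reference, not on
  gradient norms.
* The frozen $\eta$ inherits the OSEM initialization's bias inside small hot
  structures, which contributes to the early VOI transient at desk scale.
* The constrained (truncated) variant is only supported in combination with
  the diagonal preconditioner.
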