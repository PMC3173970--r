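---
title: "Multiresolution transforms for medical image segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiresolution transforms for medical image segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mraseg)
```

# The problem and the approach

Measuring the size of a small structure — a lesion in a clinical CT slice,
or a spherical insert in a quality-assurance phantom — is limited less by
resolution than by noise: acquisition noise blurs the boundary that a
threshold has to find, and a threshold chosen to suppress noise also erodes
the structure. Multiresolution analysis addresses this by moving the
denoising step into a transform domain in which the structure is sparse
(few large coefficients) while white noise stays spread out (many small
coefficients), so that hard thresholding separates the two.

The package composes three such transforms into one segmentation pipeline:

1. an **intensity pre-threshold** that removes gross scanner artefacts;
2. a **transform-domain hard threshold** (wavelet, ridgelet or curvelet)
   that removes noise while preserving edges;
3. an **intensity post-threshold** that clears the residual noise floor;
4. **4-connected component labelling** with region measurement.

Which transform is appropriate depends on the geometry of the features:
wavelets capture point singularities but only three orientations
(horizontal, vertical, diagonal); ridgelets capture straight-line
singularities; curvelets capture curved edges, which is what organ and
lesion boundaries predominantly are. The package implements all three so
that the comparison can be made on equal terms.

# The wavelet transform

The 1D analysis step is the orthonormal filter-bank recursion

$$a_j(n) = \sum_i l(i)\, a_{j-1}(2n - i), \qquad
  d_j(n) = \sum_i h(i)\, a_{j-1}(2n - i),$$

with periodic (circular) index arithmetic and the quadrature-mirror
high-pass $h(i) = (-1)^i\, l(L-1-i)$. Two filters are registered: Haar
(averages and differences) and the 4-tap Daubechies filter db2. The 2D
transform applies one row pass then one column pass per level and recurses
on the LL band only (the Mallat, or nonstandard, decomposition).

**Boundary policy.** Periodic extension is chosen because it keeps the
analysis matrix exactly orthogonal: Parseval's identity and perfect
reconstruction then hold to machine precision, which is the property the
test suite pins down. Symmetric extension would reduce edge artefacts
slightly but destroys exact orthogonality.

**Odd lengths.** A dimension of odd length cannot be halved by a critically
sampled filter bank. The policy here processes the even part circularly and
carries the final sample into the approximation scaled by $\sqrt 2$. The
scaling makes a constant signal produce a constant approximation and
exactly zero details at every level, so coefficient thresholding can never
shift the DC level of a block; the price is that energy is no longer
exactly preserved in that single carried coordinate. Subband sizes then
halve by ceiling division and the total coefficient count always equals the
pixel count.

**Thresholding** zeroes detail coefficients with $|c| < t$ and never
touches the approximation band: the approximation carries the foreground
intensity that the later segmentation thresholds rely on.

# The finite Radon and ridgelet transforms

On a prime-sized block ($p \times p$), the finite Radon transform sums the
image along the $p+1$ families of modular-arithmetic lines of $Z_p^2$,

$$r_k[l] = \frac{1}{\sqrt p} \sum_{(i,j)\,:\, j = k i + l \ (\mathrm{mod}\ p)} f(i,j),
  \quad k = 0, \dots, p-1,$$

plus the family of lines of constant first index ($k = p$). Each family
partitions the grid, so all per-direction totals are equal — an invariant
the tests check exactly. Any two distinct points share exactly one line,
which gives a closed-form exact inverse: summing the $p+1$ projections
through a point counts that point $p+1$ times and every other point once.

The $1/\sqrt p$ normalisation (rather than $1/p$) is used so that white
pixel noise keeps its standard deviation in the projection domain, making a
single $3\sigma$ threshold meaningful across transforms.

The ridgelet transform is a 3-level 1D wavelet decomposition of each
projection (depth capped at $\lfloor \log_2 p \rfloor$): a line singularity
in the block becomes a point singularity along one projection, which the 1D
wavelet concentrates into few coefficients. Images are processed in
non-overlapping $p \times p$ tiles, padded to a multiple of $p$ by
symmetric edge replication — zero padding would manufacture artificial
edges at the image border that the transform would then "detect". Blockwise
processing is visible as mild tiling artefacts in the output, which is
inherent to the method rather than a defect of the implementation.

# The curvelet transform via wrapping

The curvelet system is built from a pair of Meyer-type windows using the
smooth step $\nu(t) = t^4(35 - 84t + 70t^2 - 20t^3)$, which satisfies
$\nu(t) + \nu(1-t) = 1$:

* a **radial window** $W$ with $\sum_j W^2(2^j r) = 1$ for all $r > 0$,
  realised as the square root of the difference of two low-pass profiles an
  octave apart;
* an **angular window** $V$ with $\sum_l V^2(t - l) = 1$, flat on
  $|t| \le 1/4$ with complementary sine/cosine transitions of half-width
  $1/4$ (the `angularOverlap` parameter).

A wedge at scale $j$ and orientation $l$ is the product
$U_{j,l}(\rho, \theta) = \Psi_j(\rho) V\!\big((\theta - \theta_l)/\Delta_j\big)$
sampled on the centred frequency grid, with the coarsest scale a single
nondirectional low-pass band and the finest annulus extended to the corners
of the square spectrum. Because the angular windows sum to one around every
circle and the radial windows telescope to one, the squared wedge masks sum
to **exactly one at every frequency sample**. That partition of unity is
the load-bearing property: it makes the transform a tight frame, so

* total coefficient energy equals image energy (Parseval), and
* the adjoint of the analysis operator is an exact inverse.

Both identities hold to ~1e-14 in the tests, comfortably inside the 1e-6
tolerance asserted.

The forward transform is the standard four-step wrapping algorithm: 2D FFT
(unitary), multiplication by each wedge mask, wrapping of the supported
data into the wedge's rectangle by periodic index folding, and inverse FFT
per wedge. **Wrapping rectangle:** the rectangle is sized to the wedge
support's bounding box on the centred grid, which makes the periodic
folding collision-free and the book-keeping exact for every orientation,
including wedges straddling the diagonal; the overall redundancy is about
3× at the default plan. The rectangles elongate toward fine scales in
accordance with the parabolic scaling law (width ≈ length²): the angle
count doubles every other scale while the radial extent doubles every
scale.

**Plan defaults.** The depth rule is
$J = \lceil \log_2 \min(M, N) \rceil - 4$ (minimum 2), counting the
nondirectional coarse band as a level; it yields 5 scales for a 512 × 512 image. The conventional alternative that does not
count the coarse band would give 6; the rule here is deliberate and can be
overridden via `nscales`. The second-coarsest scale uses 16 angles
(the constraint is at least 8 and a multiple of 4), doubling every other
scale toward fine. Odd image dimensions ≥ 32 are accepted; the grid
geometry handles the asymmetric Nyquist row of even sizes without special
cases because reconstruction only requires the partition of unity,
not mask symmetry.

**Real output.** Thresholding modifies opposite wedges independently, so
the accumulated spectrum may lose exact Hermitian symmetry; the inverse
re-imposes it explicitly before the final inverse FFT and checks that the
residual imaginary part is at floating-point level.

**Per-band thresholds.** A coefficient in band $(j, l)$ of a white-noise
image has standard deviation $\sigma \sqrt{\sum U_{j,l}^2 / (R_1 R_2)}$,
which differs between bands. `thresholdCurvelet(..., perBandNoise = TRUE)`
scales the user threshold by this gain so a single $t = k\sigma$ treats all
orientations equitably; the coarsest band is never thresholded, for the
same DC-preservation reason as the wavelet LL band.

# The synthetic phantom and what it does (not) emulate

The generator renders the equatorial slice of a body phantom: an elliptical
water cavity (default semi-axes 150 × 115 mm) holding six disc inserts of
diameters 10, 13, 17, 22, 28, 37 mm, angularly equispaced on a 57 mm ring,
on a 128 × 128 grid of 4.6875 mm pixels. The physical phantom is
three-dimensional; the per-slice statistics all refer to the equatorial
plane where the spherical inserts present their maximal diameter, so a 2D
rendering is the faithful evaluation target. Pixel membership uses a
centre-point test by default; `supersample = 4` switches to 4 × 4
area-fraction antialiasing for smoother edges.

Intensity levels default to background 0, cavity 20, insert 200 on the
8-bit scale. The cavity level is set *below* the standard pre-threshold of
35: in the acquisitions this phantom emulates, the water background is
faint relative to the hot inserts and the pre-threshold removes it, leaving
the six inserts as separate components. (A cavity brighter than the
pre-threshold would remain fused with the inserts into one connected
component and no border- or size-based rule could separate them — nested
same-intensity structures are outside what a global threshold pipeline can
do.) All levels are configurable for data with different contrast.

The noise model adds i.i.d. zero-mean Gaussian noise with
σ = `sigmaFraction` × max(image), default 20%, without clipping — metrics
and transforms operate on real-valued arrays, and clamping happens only
when writing integer image files. What the generator does **not** emulate:
correlated (reconstruction-kernel) noise, partial-volume averaging from
finite slice thickness, scanner point-spread blur, and intensity
inhomogeneity. Passing tests on the phantom therefore demonstrate that the
algorithms are correct and well-conditioned, not that the specific error
percentages transfer to any particular scanner.

The slice-level summary statistic is the spheres-to-background ratio,
$\mathrm{SBR} = 100\, S / (A - S)$ with $S = \pi \sum (d/2)^2$ the total
insert cross-section and $A = M N p^2$ the slice area; the default geometry
gives $S = 2509.17\ \mathrm{mm}^2$, $A = 360000\ \mathrm{mm}^2$ and
SBR = 0.702%.

# Segmentation and measurement choices

* **Connectivity** is 4-connected, the conservative choice: diagonal noise
  bridges between adjacent structures do not merge them. Components smaller
  than `minRoiPixels` (default 4) are discarded.
* **Background exclusion**: components touching the image border are
  treated as surviving background and dropped by default (`excludeBorder`);
  dropping the single largest component is available (`excludeLargest`) but
  off by default, since on insert phantoms the largest valid region is
  simply the largest insert.
* **Diameter estimate**: the equivalent-circle diameter
  $2\sqrt{\mathrm{area}/\pi}$ from the pixel count, which is robust to
  boundary raggedness; a maximum-Feret (caliper) diameter is reported
  alongside for comparison but does not enter the error statistics.
* **Region-to-insert matching** accepts the nearest insert centre within
  half the minimal inter-centre distance; everything else is flagged
  spurious (region with no insert) or missed (insert with no region).
* **Error statistics**: signed diameter error
  $100 (\mathrm{measured} - \mathrm{actual}) / \mathrm{actual}$ (negative =
  underestimation) and area accuracy
  $100 (1 - |\mathrm{measured} - \mathrm{ref}| / \mathrm{ref})$ floored at
  zero. The evaluation report's data-loss flag is "High" when the
  denoised-vs-clean MSE exceeds a configurable bound — a deliberate
  operationalisation of a qualitative notion.
* **SNR convention**: the package reports
  $10 \log_{10}\big(\sum s^2 / \sum (y - s)^2\big)$ — clean reference
  energy over residual energy. Other conventions exist (e.g. regional mean
  over standard deviation); published SNR tables are not comparable across
  conventions, so the definition is stated here once and used everywhere.

# Numerical choices and problem sizes

* Thresholds: the pipeline defaults $t_{\mathrm{pre}} = 35$ and
  $t_{\mathrm{post}} = 7$ are interpreted on the 8-bit scale;
  `intensityScale` maps them onto wider scales (257 for 16-bit).
  Coefficient thresholds for denoising use $t = 3\sigma$ with the true
  simulation σ — standard universal-threshold practice; when σ is unknown a
  robust estimate from the finest subband can be substituted.
* The denoising comparison uses the 128 × 128 phantom grid with five noise
  realisations and reports medians; the pipeline-recovery check renders
  the phantom at 512 × 512 (1.17 mm pixels) where rasterisation error of
  the smallest (10 mm) insert is well below one pixel width. These sizes
  make the entire suite run in seconds while leaving every tolerance at
  machine-precision headroom.
* Tolerances asserted: 1e-8 absolute for wavelet/ridgelet round trips,
  1e-6 relative for curvelet round trip and energy, 1e-10 for window
  admissibility and the partition of unity; all are met with 6–8 orders of
  magnitude to spare.
* Tie-breaks and degenerate inputs: `t = 0` thresholds are exact
  identities (strict `< t` comparison); empty images segment to an empty
  region table rather than an error; PSNR of identical images is reported
  as `Inf` and serialised as the string `"Inf"` in JSON reports.

# Known limitations

* The ridgelet path operates on one block size at a time; multiscale block
  combinations are not implemented.
* The curvelet finest scale is directional (curvelets all the way out); a
  wavelet-type finest scale is a known variant and not provided.
* DICOM input is not supported; convert single slices to 16-bit PNG/TIFF.
* 3D volumes are out of scope throughout; the phantom is the 2D equatorial
  slice, so effects of slice thickness (partial volume) are absent by
  construction.
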