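# mraseg

Multiresolution transform-based segmentation of 2D grayscale medical
images.

Delineating a region of interest (a hot lesion, a phantom insert) in CT or
PET slices is hard when the structure is embedded in scanner noise and
surrounded by soft tissue of overlapping gray level. A classical remedy is
to denoise in a transform domain whose basis elements match the geometry of
the structures — wavelets for point-like features, ridgelets for straight
edges, curvelets for curved edges — and only then threshold and measure.
`mraseg` implements that whole chain for radiology-style evaluation work,
with every transform written from first principles so its conventions are
explicit and testable:

* **2D discrete wavelet transform** — the orthonormal filter-bank recursion
  `a_j(n) = Σ_i l(i) a_{j-1}(2n − i)` (and the mirrored high-pass) with
  periodic extension, Haar and Daubechies-4 (db2) filters, multilevel Mallat
  decomposition with exact reconstruction.
* **Finite Radon / finite ridgelet transform** — on a prime p × p block,
  projections `r_k[l] = p^{-1/2} Σ_{(i,j): j = k i + l (mod p)} f(i, j)`
  over the p+1 line directions of Z_p², inverted exactly in closed form by
  back-projection; the ridgelet transform is a 1D wavelet decomposition of
  each projection, applied blockwise over the image.
* **Fast discrete curvelet transform (wrapping)** — Meyer-type radial
  windows `W` with `Σ_j W²(2^j r) = 1` and angular windows `V` with
  `Σ_l V²(t − l) = 1` form frequency wedges `U_{j,l}(r, θ)` obeying the
  parabolic scaling law (width ≈ length²). Because `Σ_{j,l} U²_{j,l} = 1`
  at every frequency sample, the transform (FFT → wedge windowing →
  wrapping into a rectangle → inverse FFT per wedge) is a tight frame:
  coefficient energy equals image energy and the adjoint is an exact
  inverse.
* **Segmentation pipeline** — intensity pre-threshold (t = 35 on the 8-bit
  scale), transform-domain hard-threshold denoising, intensity
  post-threshold (t = 7), 4-connected component labelling, and
  equivalent-circle diameter measurement with signed error percentages
  `100 (measured − actual) / actual`.
* **Synthetic body phantom** — the equatorial slice of a NEMA-IEC-style
  phantom (elliptical cavity, six disc inserts of 10, 13, 17, 22, 28,
  37 mm on a ring) rendered on a configurable grid, plus a Gaussian noise
  model (σ as a fraction of maximum intensity), so the full chain is
  evaluable without scanner data. The spheres-to-background ratio
  `SBR = 100 S / (A − S)` with `S = π Σ (d/2)²` and `A = M N (pixel size)²`
  is provided as the slice-level summary statistic.

## Worked example

Segment a noise-free 512 × 512 rendering of the default phantom and compare
each region's equivalent diameter against the known insert diameters:

```r
library(mraseg)

spec <- PhantomSpec(grid = c(512L, 512L), pixelSizeMm = 4.6875 / 4)
img  <- generatePhantom(spec)
res  <- segmentImage(img, SegmentationConfig())
m    <- matchRoisToSpheres(res$rois, spec)
m$matches[order(m$matches$actualDiameterMm), ]
```

```
 sphere actualDiameterMm measuredDiameterMm    errorPct areaAccuracyPct
      1               10           10.07048  0.70484040        98.58535
      2               13           13.09029  0.69456597        98.60604
      3               17           16.98550 -0.08529753        99.82948
      4               22           21.88828 -0.50781945        98.98694
      5               28           28.05063  0.18081818        99.63804
      6               37           37.00132  0.00357038        99.99286
```

All six inserts are recovered; every measured diameter is within one pixel
width (1.17 mm) of truth, and the signed error percentages stay below 1%.
Curvelet denoising of the same phantom contaminated with Gaussian noise at
σ = 20% of the maximum intensity:

```r
clean <- generatePhantom(PhantomSpec())
noisy <- addGaussianNoise(clean, sigmaFraction = 0.2, seed = 1)
den   <- denoiseCurvelet(noisy, t = 3 * 40)   # threshold 3 sigma
evaluateDenoising(clean, noisy, den)$psnrGainDb
```

raises PSNR from 16.07 dB to 27.72 dB (an 11.65 dB gain); wavelet and
ridgelet denoising at the same 3σ threshold reach about 25.7 and 20.6 dB,
reproducing the expected quality ordering curvelet > wavelet > ridgelet.

A command-line front end covering phantom generation, forward/inverse
transforms, denoising, segmentation and evaluation is installed at
`inst/cli/mraseg`:

```sh
Rscript inst/cli/mraseg phantom --sigma 0.2 --seed 1 --out run/
Rscript inst/cli/mraseg segment --input run/phantom.png --out run/seg/
```

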