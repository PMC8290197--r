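---
title: "msilazy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msilazy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

msilazy implements the computational core of an interactive mass
spectrometry imaging (MSI) workstation as a library plus a thin command
line: lazy imzML access, one-pass image initialization, per-spectrum
signal processing, peak analysis, ion-image generation,
continuous-centroid export, PCA / delegated t-SNE, and slice-to-slice
registration for 3D stack reconstruction. Everything is testable against
a deterministic synthetic phantom, so no external dataset is required.

## Lazy data model

An MSI acquisition stores one spectrum per pixel. For datasets of tens of
gigabytes, the package never loads spectra wholesale. Instead:

* `parse_imzml_metadata()` streams the `.imzML` XML in fixed-size text
  chunks, extracting one access record per `<spectrum>` element (pixel
  position plus byte offsets into the `.ibd` binary). No DOM is built;
  memory scales with the number of spectra. The binary UUID is always
  checked against the first 16 bytes of the `.ibd`; MD5 verification is
  opt-in because hashing a large binary defeats lazy access.
* `read_spectrum()` seeks and decodes exactly one spectrum
  (little-endian; dtypes from the CV params; 64-bit m/z with 32-bit
  intensities on write by default, the common vendor convention).
* `iterate_spectra_chunked()` splits the ordinal range into contiguous,
  equal chunks (remainder to the last worker — this keeps each worker's
  I/O sequential), folds per-spectrum results with a user reducer, and
  discards spectrum data immediately. For associative, commutative
  reducers the result is independent of the worker count.

The retained memory after initialization is the closed form implemented
by `estimate_memory()`: four rasters over the |I| pixels (ion image and
normalization map as doubles, spectrum-index map as int, validity mask as
short) plus three overview spectra of the spectral depth |S| and one
|S|-length buffer per worker thread,

    E = |I| (2 d_double + d_int + d_short) + (3 + T) |S| d_double.

`initialize_artefacts()` builds these in a single chunked pass: the
skyline (element-wise maximum), sum and mean overview spectra, the
per-pixel normalization factors, the spectrum-index raster (−1 at empty
pixels) and the mask. Empty pixels hold 0 in the value rasters;
consumers gate on the mask. Two spectra mapping to one pixel is an
integrity error. For processed (per-spectrum axis) data there is no
canonical overview axis of fixed depth, so the caller must supply
explicit bin edges; we deliberately do not guess a resampling rule.

## Signal chain

Processing order is fixed: normalization, then smoothing, then baseline
correction — the order in which these steps are conventionally applied.

* **Normalization** divides a spectrum by a scalar f: the total ion
  count (TIC), the intensity median, an in-file per-spectrum factor, or
  1 when disabled. In-file factors are carried as a spectrum-level
  `userParam` ("normalization factor") because imzML has no standard CV
  term for them; selecting in-file normalization without a stored factor
  is an explicit error rather than a silent fallback to 1. An all-zero
  spectrum makes TIC/median degenerate and errors out.
* **Smoothing** is Savitzky–Golay (delegated to `signal::sgolayfilt`):
  each point is replaced by the centre value of a least-squares
  polynomial over an odd window; edges use the polynomial of the first
  or last full window. Defaults (window 9, order 2) are package
  configuration, not values taken from any reference workflow.
* **Baseline** estimation is a morphological opening (top-hat: erosion
  then dilation with a flat structuring element of width
  `2*halfwidth + 1`) or a running median of the same width with
  shrinking edge windows. Widths are in array elements, which keeps them
  resolution-agnostic. The corrected signal is clipped at zero since
  downstream peak picking assumes non-negative intensities. The opening
  uses edge-clipped symmetric windows, which preserves the
  anti-extensivity and idempotence of a proper opening.

One practical consequence, visible in the tests: averaging per-pixel
top-hat residuals leaves a positive noise-rectification pedestal in the
mean spectrum. For mean-spectrum peak picking the package therefore
normalizes per spectrum but smooths and baseline-corrects the *mean
spectrum itself* — this is also the cheaper computation.

## Peak analysis

Noise is the median absolute deviation scaled by 1.4826 (consistency
with the Gaussian standard deviation; the scale choice is ours). A peak
is an index whose intensity equals the maximum of its sliding window
(half-width in elements), strictly exceeds `snr * noise`, dominates at
least one sample in the window (so flat stretches yield nothing), and is
the leftmost member of any plateau of equal maxima — determinism under
ties.

`bin_peaks()` pools lists, sorts, and starts a new bin whenever the gap
to the previous peak exceeds the tolerance (greedy single linkage). Bin
centres are intensity-weighted means — robust against low-intensity
stragglers — and bin intensity/SNR come from the strongest member.
Member sets always partition the input.

`poisson_monoisotopic()` resolves isotope envelopes: for each candidate
charge z it chains peaks spaced `1.00235 / z` Da (±0.01 Da default) and
scores the chain's intensities against Poisson weights
`p_k = e^{-λ} λ^k / k!` with `λ = 0.000594 · (monoisotopic m/z)` — an
averagine-style rate — using the cosine (normalized dot product). The
acceptance threshold is 0.95: a charge-2 envelope misread at charge 1
(every other member, which aliases exactly onto the charge-1 spacing)
scores ≈ 0.93 on the exact model, while correct chains with realistic
intensity noise stay above 0.98, so 0.95 separates the two. λ is keyed
to the monoisotopic m/z rather than the neutral mass for the same
reason: it makes the wrong-charge subsampled chain distinguishable.
Unchained peaks pass through as monoisotopic singletons.

`sample_at_peaks()` takes the windowed maximum around each common peak
(0 on an empty window) and backs the continuous-centroid export.

## Ion images and dimensionality reduction

`generate_ion_image()` treats "m/z ± tol" as a closed interval, loads
each masked pixel's spectrum lazily, applies the signal chain, and
reduces the in-window intensities with mean, max, sum or median. Empty
windows at a pixel give 0, not missing. Useful identities (tested): the
sum image equals the mean image times the in-window sample count, the
max image is monotone under window nesting, and toggling TIC
normalization rescales pixels exactly by the normalization map.

`pca_images()` centres columns (unit-variance scaling optional, off by
default) and uses the SVD; scores map back to raster geometry and
variance ratios are reported. t-SNE is deliberately not re-implemented:
`tsne_images()` delegates to a pluggable backend function (Rtsne when
installed) and raises a capability error otherwise; embeddings are
min–max normalized per channel for display.

## Registration and 3D reconstruction

Rasters are matrices (rows = y) with physical pixel spacing in µm;
transforms are pull maps (fixed-space point → moving-space sample
position). The rigid (Euler) transform rotates about the image centre
and translates in physical units; chains apply in list order and
resample in a single composed interpolation pass, with out-of-domain
pixels set to 0 and nearest-neighbour interpolation keeping masks
binary.

`register_rigid()` maximizes Mattes-style mutual information (joint
histogram, dense sampling) or mean squares under a 3-level Gaussian
pyramid with downsampling factors 4, 2, 1 and a 250-evaluation budget
per level. Numerical choices that mattered:

* **Background fill in the metric.** Out-of-domain moving samples count
  as background (0) rather than being dropped: plug-in MI estimates are
  biased upwards on smaller samples, so excluding pixels would make
  "shrink the overlap" look like an alignment gain.
* **Sample-adaptive bins.** The histogram bin count per level is capped
  at roughly sqrt(pixels/4): 32² bins over a 12×12 coarse level is
  meaningless.
* **Initialization and search.** The coarsest level is scanned
  exhaustively over rotation (±16°, 2° steps) and translation (±12 px,
  coarse-pixel steps); the best few grid candidates are each refined by
  Nelder–Mead and re-ranked at the next level before committing. We use
  a derivative-free simplex rather than gradient descent because the
  dense-histogram MI surface is piecewise-smooth at best; with the grid
  initialization this recovers |θ| ≤ 15°, |t| ≤ 10 px transforms to
  within 0.5° / 0.5 px in ≥ 95% of seeded trials. Dense sampling keeps
  the whole procedure deterministic without a sampling RNG.

`register_deformable()` refines a rigid result with a cubic B-spline
displacement grid (default final spacing 0.8 mm on the original
resolution) optimized by gradient-free coordinate search under a
750-evaluation budget, with a mild quadratic penalty on control
displacements so the zero field is stable when the metric is flat. An
external registration engine can replace the built-in stage via the
`backend` argument (parameter files are the backend's concern); the
built-in exists so the test suite needs no binary downloads.

`reconstruct_stack()` starts at a reference slice (identity chain) and
registers each slice to the already-aligned neighbour, outwards in both
directions. Spectra are never resampled — chains apply to ion images
only, and transform parameters can be serialized
(`write_chains_json()`) for use with the unmodified spectral data. For
mono-modal serial sections the mean-squares metric is preferable: the
reference image is itself interpolated, and MI's histogram bias against
smoothed copies costs accuracy there, while MI remains the right choice
across modalities. `landmark_error()` maps moving-space points into
fixed space through the chain inverse (analytic for rigid steps,
fixed-point iteration for B-spline fields) and reports mean, population
SD and per-point Euclidean distances in physical units.

## The phantom generator

`make_phantom()` emulates what the pipeline needs from real MALDI data:
per-pixel profile spectra that are a sum of region-specific analytes
(Gaussian peaks of configurable width carrying Poisson isotope
envelopes on a 1.00235 Da spacing), a smooth exponential baseline,
Gaussian noise, and a per-pixel multiplicative intensity factor
(uniform in 0.7–1.3 by default) emulating matrix inhomogeneity — the
situation TIC normalization exists to correct. Files are written
through the package's own writer and are byte-identical for a fixed
seed. Ground truth (region masks, analyte masses, per-pixel factors) is
returned alongside.

Defaults describe a 128×128 px image at 20 µm with a 2,000-sample axis
over m/z 600–1,800 and three circular regions of five analytes each.
The test-suite instances are smaller and finer where the check demands
it: most phantom-based tests use 40×40 px with a 1,600-sample axis over
m/z 600–1,000 (0.25 Da steps, so the 1.2 Da peak shapes are well
sampled), registration properties use 48×48 px anatomy rasters, and the
lazy-access check writes a deliberately large 8,192-spectrum ×
32,768-sample file (≈1 GiB) with integer-valued intensities so chunked
sums are exact under any association. `make_slice_stack()` adds serial
sections: a smooth radial scale drift (≤ 2%, so consecutive-section
realism exists without defeating rigid recovery) composed with known
rigid transforms, plus per-slice landmark sets transformed consistently
— 10 slices × 7 landmarks by default.

What the phantom does *not* emulate: matrix cluster ions, detector
saturation, mass-dependent resolution, chemical noise correlated across
pixels. Passing tests therefore demonstrate correctness of the
computations, not robustness to every artefact of real acquisitions.

## Known limitations

* Processed-centroid overviews require user-supplied bin edges.
* The built-in deformable stage is intentionally minimal (small grids,
  coordinate search); production deformable work should plug in an
  external engine.
* t-SNE requires an installed backend.
* Checksummed streaming writes and vendor raw formats are out of scope.
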