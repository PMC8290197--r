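# msilazy

Memory-efficient analysis of 2D/3D mass spectrometry imaging (MSI) data
in R.

MSI acquisitions store one full mass spectrum per image pixel, and modern
datasets reach tens of gigabytes — far beyond what can be loaded into
memory for interactive work. msilazy is built around *lazy access*: the
imzML XML metadata is streamed (never parsed into a DOM), spectra are
decoded from the `.ibd` binary one at a time on demand, and every
whole-image computation is a chunked reduction that discards spectral
data immediately. The memory retained for a loaded image is the closed
form

    E = |I| (2 δ_double + δ_int + δ_short) + (3 + T) |S| δ_double

for |I| pixels, spectral depth |S| and T worker threads: four rasters
(ion image, normalization map, spectrum index, validity mask) plus three
overview spectra (skyline, sum, mean) plus one spectrum buffer per
worker — O(|I| + |S|) instead of the O(|I|·|S|) footprint of the raw
data.

On top of the data model the package provides the standard MSI
processing chain, each step implemented as practitioners expect it:

* per-spectrum normalization `S(j) = S_old(j) / f` with f the total ion
  count (TIC), the intensity median, or an in-file factor;
* Savitzky–Golay smoothing and top-hat (morphological opening) or
  running-median baseline correction;
* peak picking as sliding-window local maxima above `snr × noise`, with
  noise the median absolute deviation (`1.4826 · MAD`);
* peak binning across images and Poisson monoisotopic harvesting
  (isotope chains at 1.00235/z Da spacing scored against
  `p_k = e^{-λ} λ^k / k!`, λ proportional to the monoisotopic m/z);
* ion images (`m/z ± tol` windows reduced by mean/max/sum/median),
  continuous-centroid imzML export at a common peak list;
* PCA score images and delegated t-SNE embeddings;
* rigid (Euler) and B-spline registration under a 3-level multiresolution
  pyramid with Mattes mutual information or mean squares, bidirectional
  stack reconstruction from a reference slice, and landmark-error
  quantification in µm.

A deterministic phantom generator (`make_phantom()`,
`make_slice_stack()`) produces imzML files with known region masks,
analyte masses, per-pixel intensity factors and slice transforms, so the
whole pipeline is testable without any download.

Intended users: MSI method developers and analysts who need scriptable,
memory-bounded building blocks (or a reference implementation) rather
than a GUI workstation.

## Worked example

```r
library(msilazy)

spec <- phantom_spec(width = 40, height = 40, mz_range = c(600, 1000),
                     axis_depth = 1600, seed = 101)
ph   <- make_phantom(spec, tempfile("demo"))
meta <- parse_imzml_metadata(ph$imzml)
meta
#> msi_dataset:phantom.imzML
#>  geometry  : 40x40x1 px (20/20/1 um)
#>  dialect   : continuous-profile
#>  spectra   : 1600 (depth 1600)
#>  est. memory (1 thread): 86,400 bytes

# one chunked pass: overview spectra + normalization/index/mask rasters
art <- initialize_artefacts(meta, signal_params(normalization = "tic"),
                            n_workers = 2)

# pick on the processed mean spectrum
mean_spec <- apply_signal_chain(
  list(index = 0, mz = art$overview$mz_axis,
       intensity = art$overview$mean),
  signal_params(sg_window = 9, sg_order = 2, baseline = "tophat",
                baseline_halfwidth = 60))
peaks <- poisson_monoisotopic(
  pick_peaks(mean_spec, snr_threshold = 10, halfwindow = 8), charges = 1)
sum(peaks$is_monoisotopic)
#> [1] 16
head(peaks[peaks$is_monoisotopic, c("mz", "intensity", "snr")], 3)
#>         mz    intensity       snr
#> 1 600.0000 3.650296e-05  26.82976
#> 2 624.5153 3.481982e-04 255.92640
#> 3 648.7805 2.815900e-04 206.96925

# ion image of the first analyte of region 1, thresholded at half max
img <- generate_ion_image(meta, ph$masses[[1]][1], tolerance = 2,
                          reducer = "max",
                          signal_params(normalization = "tic"))
seg <- img >= max(img) / 2
sum(seg & ph$region_masks[[1]]) / sum(seg | ph$region_masks[[1]])
#> [1] 1
```

The phantom plants 15 analytes in three circular regions; the picked
monoisotopic list recovers all 15 (the m/z 600.00 entry is a boundary
artefact of the axis start — 1 false discovery in 16 calls), peak m/z
values sit within ~0.5 Da of the planted masses (the apex of a merged
isotope envelope is slightly heavier than the monoisotopic mass), and
the half-max segmentation of the ion image reproduces the true region
mask exactly (Jaccard 1.0).

A thin command line covering the same operations installs to
`exec/msilazy` (subcommands `info`, `init`, `ion`, `pick`,
`export-centroid`, `synth`, `recon3d`, `dr`).

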