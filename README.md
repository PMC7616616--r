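# selfnav3d

Navigator-free ("self-navigated") 3D multi-slab diffusion MRI in R:
extended-CAIPI sampling design, structured low-rank phase-map estimation,
and phase-corrected multi-shot reconstruction, with a synthetic-data module
so the whole pipeline runs and is benchmarked without scanner data.

## The problem

3D multi-slab diffusion imaging encodes each thin slab as a small 3D
k-space over several EPI shots. Motion during diffusion encoding gives
every shot a different smooth 2D phase ψ_j; uncorrected, the shot
combination is severely corrupted. The conventional fix — an extra 2D
navigator echo per shot — costs TR, SAR and SNR efficiency. The
self-navigated approach removes the navigator:

- **Sampling.** Each shot's kz trajectory is a periodic triangle of width
  `w = floor(Nkz/2) + 1`, so every shot crosses the central (DC) kz plane;
  the crossings are *self-navigation points*. One non-blipped shot
  traverses the central plane entirely. The multi-shot pattern is
  optimized by a greedy exhaustive search over the per-shot shifts
  `(s_ky, s_kz, s_p)`, minimizing `o_i + g_i + d_i` (overlap + 3×3 k-space
  gaps + self-navigation distance) subject to `d_i <= dmax`.
- **Phase estimation.** The central-plane k-space of all shots is
  reconstructed jointly from the self-navigation points by an ADMM that
  combines data fidelity, SPIRiT self-consistency `λ1‖(G−I)x̂‖²`, a
  low-rank penalty on the multi-shot multi-coil block-Hankel matrix
  `H(x̂)` (singular-value hard thresholding), and a magnitude constraint
  anchored to the traversal shot's image `m′`. Unit-magnitude phase maps
  φ_j follow by conjugate-sensitivity combination.
- **Reconstruction.** The corrected slab k-space solves
  `min_X Σ_j ‖M_j F φ_j F⁻¹ X − y_j‖² + λ4‖(G_slab−I)X‖²` by CG,
  decoupled along x; the image is the coil sum-of-squares.

See `vignettes/selfnav3d-methods.Rmd` for the models, the numerical
choices and the limitations of the synthetic study.

## Worked example

Design the published 1.22 mm sampling (180×12 grid, 12 shots, R_y = 3):

```r
library(selfnav3d)
cfg  <- sampling_config(Ny = 180, Nkz = 12, Nshot = 12, Ry = 3, dmax = 15)
pats <- greedy_optimize(cfg)
attr(pats, "metrics")
#> # A tibble: 12 x 4
#>     shot     o     g     d
#>    <int> <int> <int> <dbl>
#>  1     1     0  2008     0
#>  2     2     0  1603     1
#>  3     3     0  1273     2
#>  4     4     0   973     8
#>  5     5     0   716     7
#>  6     6     0   552    11
#>  7     7     0   414     7
#>  8     8     0   348    14
#>  9     9     5   277    15
#> 10    10    15   249     0
#> 11    11    15   231     4
#> 12    12    20   208     6
masks <- sampling_masks(pats, cfg)
gap_metric(masks)                            # 0: no empty 3x3 window remains
overlap_metric(masks) / sum(masks$combined)  # 0.0278: <3% of samples overlap
selfnav_acceleration(pats[[1]], cfg)         # 3: the kz0 traversal shot
```

Each optimized shot keeps a self-navigation point within 15 lines of the
k-space center (`d` column; the `g` column counts the full-convolution
gaps the optimizer penalizes, including windows beyond the grid edge),
the final pattern has no interior 3×3 gap, and under 3% of acquired
points are duplicates.

Run the full synthetic benchmark at desk scale (64×64×12 slab, 8 coils,
12 shots, R_y = 3, 2-rad shot phases, noiseless; a few minutes of
compute):

```r
bench <- run_benchmark(run_config(seed = 1))
bench$phase
#> # A tibble: 1 x 3
#>   variant   mae mae_filtered
#>   <chr>   <dbl>        <dbl>
#> 1 full    0.0740       0.0820
bench$recon
#> # A tibble: 3 x 2
#>   method      nrmse
#>   <chr>       <dbl>
#> 1 uncorrected 0.598
#> 2 truth       0.173
#> 3 slr         0.210
```

The estimated phase maps agree with the generating motion phases to
0.074 rad mean absolute error inside the object, and the phase-corrected
reconstruction (`slr`) approaches the accuracy of correction with the
true phases (`truth`, ratio 1.21), while skipping the correction leaves
roughly three times that error.

## Command line

A thin CLI over the package functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/selfnav3d.R", package="selfnav3d"))') \
    design --ny 180 --nkz 12 --nshot 12 --ry 3 --dmax 15 --out pattern.rds
```

Subcommands: `design`, `simulate`, `benchmark`.
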