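# imri: real-time interventional MRI reconstruction

`imri` reconstructs dynamic image series from heavily undersampled
golden-angle radial k-space, for the setting where the images guide an
intervention in real time: a needle or electrode advancing through
brain tissue while the scanner acquires a handful of spokes per frame.
It is aimed at researchers prototyping reconstruction methods for
interventional MRI and at anyone who needs a self-contained, fully
simulated test bed for group-wise dynamic reconstruction.

## The model

Frames are reconstructed jointly in groups of `fpg` frames x `spf`
spokes. A group `x` is decomposed into a low-rank background plus a
sparse dynamic component, `x = L + S`, by solving the LSFP model

    min over L, S of
      1/2 || E(L + S) - d ||_2^2  +  lambda_L ||L||_*
      + lambda_s ||D_t S||_1
      + lambda_L^psi ||psi L||_1  +  lambda_S^psi ||psi S||_1

with `E = Omega F C` the multi-coil radial encoding operator, `||.||_*`
the nuclear norm of the pixels-by-frames (Casorati) matrix of `L`,
`D_t` the temporal forward difference, and `psi` a tight-frame framelet
applied to both components. The solver is a primal-dual fixed-point
(PDFP) iteration with exact singular-value thresholding; an unrolled
network variant replaces the framelet with learned 3D-convolutional
transform pairs and trains all thresholds and step sizes per block with
Adam. A synthetic brain-intervention generator (ellipse head phantom,
constant-speed needle, simulated coil maps, NUFFT acquisition) supplies
training and evaluation data entirely in software.

Alongside the solver there are the classical L + S baseline, the
acquisition arithmetic of golden-angle radial protocols (Nyquist spoke
counts, acceleration factors, frame/group timing), stack-of-stars
slice detangling, an HDF5 k-space container, NIfTI image I/O, PSNR and
SSIM, and automatic needle-tip depth tracking.

## Worked example

Simulate a needle insertion, acquire 20-spokes-per-frame radial
k-space with 8 coils, reconstruct with LSFP, and track the tip:

```r
library(imri)

spec <- phantom_spec(matrix_size = 128, pixel_mm = 1, n_coils = 8, seed = 1)
scen <- intervention_scenario("unilateral-left", n_frames = 10,
                              speed_mm_per_frame = 1.525, matrix_mm = 128)
sim  <- simulate_intervention(spec, scen)
acq  <- acquire(sim$frames, spec, group_scheme(spf = 20, fpg = 5))

rec <- lsfp_reconstruct(acq$kspace[[1]], acq$op, lsfp_params())
rep <- eval_report(abs(acq$truth[[1]]$frames), abs(rec$x$frames))
round(c(psnr = rep$mean_psnr, ssim = rep$mean_ssim), 3)
#>   psnr   ssim
#> 21.675  0.607

# baseline: the pre-insertion background, acquired and reconstructed
# with the same protocol (the trajectory repeats every group, so the
# frame-wise aliasing cancels in the difference image)
bg_frames <- array(rep(sim$background, 5), c(128, 128, 5))
acq0 <- acquire(bg_frames, spec, group_scheme(20, 5))
baseline <- abs(lsfp_reconstruct(acq0$kspace[[1]], acq0$op, lsfp_params())$x$frames)
depth <- track_tip(abs(rec$x$frames), baseline,
                   scen$entry_point_mm, scen$target_point_mm)
rbind(measured = round(depth, 3), programmed = needle_depth_mm(scen, 1:5))
#>             [,1]  [,2]  [,3]  [,4]  [,5]
#> measured   2.306 3.295 5.158 6.004 7.917
#> programmed 1.525 3.050 4.575 6.100 7.625
```

The mean PSNR/SSIM quantify fidelity to the noiseless ground truth at
acceleration R = 10 (20 of the 201 Nyquist spokes per frame); the
depth rows show the tip position recovered from the reconstructions
against the programmed constant-speed insertion (1.525 mm per frame),
agreeing within about a pixel.

The same pipeline is scriptable from a shell through the thin CLI at
`system.file("cli", "imri", package = "imri")` (subcommands `timing`,
`simulate`, `recon`, `eval`, `run`), e.g.

    imri timing --tr-ms 4 --spf 20 --fpg 5 --groups 100 --matrix 128
    # temporal resolution: 80.0 ms/frame
    # group duration:      0.4 s
    # total acquisition:   40 s (100 groups)
    # acceleration R:      10 (matrix 128, 20 spokes/frame)

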