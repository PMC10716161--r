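test_that("simulated coil maps are normalized, smooth, and reduce to a unit map", {
  for (nc in c(1L, 8L, 11L)) {
    maps <- simulate_coilmaps(nc, 32)
    sos <- apply(abs(maps)^2, c(1, 2), sum)
    expect_lt(max(abs(sos - 1)), 1e-6)
  }
  expect_equal(abs(simulate_coilmaps(1, 16)[, , 1]), matrix(1, 16, 16))
  # spatial smoothness: finite differences of an 11-coil map stay small
  maps <- simulate_coilmaps(11, 128)
  g <- abs(diff(maps[, , 1]))
  expect_lt(max(g), 0.06)
})

test_that("fast NUFFT forward matches the brute-force non-uniform DFT", {
  set.seed(42)
  for (N in c(16, 32)) {
    tr <- make_trajectory(trajectory_config(N), group_scheme(5, 2))
    pl <- nufft_plan(tr$kcoords, N)
    img <- rand_cplx(c(N, N))
    y_fast <- nufft_forward(pl, img)
    y_ref <- nudft_forward(img, traj_kc(tr))
    expect_lt(max(abs(y_fast - y_ref)), 1e-4)
  }
})

test_that("point source at the matrix center yields flat-magnitude k-space", {
  N <- 32
  tr <- make_trajectory(trajectory_config(N), group_scheme(6, 1))
  pl <- nufft_plan(tr$kcoords, N)
  img <- matrix(0i, N, N)
  img[N %/% 2 + 1, N %/% 2 + 1] <- 1
  y <- nufft_forward(pl, img)
  expect_lt(max(abs(abs(y) - 1 / N)), 1e-4)
})

test_that("encoding operator passes the adjoint dot-product test across configurations", {
  set.seed(7)
  cases <- list(list(N = 16, spf = 4, fpg = 3, nc = 1),
                list(N = 16, spf = 2, fpg = 5, nc = 4),
                list(N = 32, spf = 8, fpg = 2, nc = 3),
                list(N = 64, spf = 5, fpg = 2, nc = 2),
                list(N = 128, spf = 4, fpg = 1, nc = 2))
  for (cs in cases) {
    tr <- make_trajectory(trajectory_config(cs$N), group_scheme(cs$spf, cs$fpg))
    op <- encoding_operator(simulate_coilmaps(cs$nc, cs$N), tr)
    x <- rand_cplx(c(cs$N, cs$N, cs$fpg))
    d <- rand_cplx(c(cs$nc, cs$spf * cs$fpg, cs$N))
    lhs <- sum(Conj(d) * enc_forward(op, x)$data)
    rhs <- sum(Conj(enc_adjoint(op, d)$frames) * x)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("encoding is linear and encodes frames independently", {
  set.seed(8)
  p <- toy_problem(N = 16, spf = 3, fpg = 3, n_coils = 2, seed = 8)
  x <- rand_cplx(c(16, 16, 3)); y <- rand_cplx(c(16, 16, 3))
  a <- 1.3 - 0.4i; b <- -0.7 + 2i
  lin <- enc_forward(p$op, a * x + b * y)$data
  sep <- a * enc_forward(p$op, x)$data + b * enc_forward(p$op, y)$data
  expect_lt(max(abs(lin - sep)) / max(abs(sep)), 1e-10)

  # zero image maps to zero k-space
  expect_equal(max(abs(enc_forward(p$op, x * 0)$data)), 0)

  # zeroing frame 2 changes only spokes 4..6 (frame 2 of 3, spf 3)
  x2 <- x; x2[, , 2] <- 0
  dd <- enc_forward(p$op, x)$data - enc_forward(p$op, x2)$data
  changed <- apply(abs(dd), 2, max) > 1e-12
  expect_equal(which(changed), 4:6)
})

test_that("density-compensated adjoint of a fully sampled acquisition recovers the image", {
  # 402 spokes at 256 matrix is the fully sampled single-frame protocol;
  # run the geometry at 128/201 to keep the check quick
  N <- 128
  spf <- full_spoke_count(N)
  tr <- make_trajectory(trajectory_config(N), group_scheme(spf, 1))
  op <- encoding_operator(simulate_coilmaps(1, N), tr)
  spec <- phantom_spec(matrix_size = N, n_coils = 1, seed = 3)
  img <- make_background(spec) + 0i
  dim(img) <- c(N, N, 1)
  rec <- enc_adjoint(op, enc_forward(op, img), density_compensated = TRUE)$frames
  # regression pin: one-shot ramp regridding of full sampling carries
  # some low-frequency shading but reproduces the anatomy
  expect_gt(psnr(img, rec), 14)
  # and the plain (non-compensated) adjoint is far blurrier
  plain <- enc_adjoint(op, enc_forward(op, img))$frames
  expect_gt(psnr(img, rec), psnr(img, plain / max(abs(plain))))
})

test_that("stack-of-stars detangling is unitary and handles the degenerate cases", {
  set.seed(9)
  k4 <- rand_cplx(c(2, 6, 8, 4))
  sl <- detangle_stack_of_stars(k4)
  expect_length(sl, 4)
  e_in <- sum(abs(k4)^2)
  e_out <- sum(vapply(sl, function(s) sum(abs(s)^2), numeric(1)))
  expect_lt(abs(e_in - e_out) / e_in, 1e-10)

  # partitions = 1: identity
  k1 <- rand_cplx(c(2, 6, 8, 1))
  expect_equal(detangle_stack_of_stars(k1)[[1]], k1[, , , 1])

  # energy only in partition-frequency 0 (constant along z): slices
  # identical up to the 1/sqrt(Np) DC scaling
  kc <- array(0i, dim = c(2, 6, 8, 4))
  base <- rand_cplx(c(2, 6, 8))
  for (s in 1:4) kc[, , , s] <- base
  out <- detangle_stack_of_stars(kc)
  for (s in 1:4) {
    ref <- if (s == 3) base * sqrt(4) else base * 0  # DC lands at slice Np/2+1
    expect_lt(max(abs(out[[s]] - ref)), 1e-12)
  }
})

test_that("k-space HDF5 container round-trips and fails informatively", {
  set.seed(10)
  p <- toy_problem(N = 16, spf = 4, fpg = 2, n_coils = 2, seed = 10)
  kg <- p$d
  kg$timing <- acquisition_timing(4, 1, 1)
  kg$noise_sd <- 0.01
  f <- tempfile(fileext = ".h5")
  write_kspace(kg, f, pixel_mm = 1.5)
  back <- read_kspace(f)
  expect_equal(back$data, kg$data)
  expect_equal(back$trajectory$kcoords, kg$trajectory$kcoords, tolerance = 1e-7)
  expect_equal(back$scheme$spf, 4L)
  expect_equal(back$noise_sd, 0.01)
  expect_equal(attr(back, "pixel_mm"), 1.5)
  expect_equal(back$timing$tr_ms, 4)

  # missing trajectory dataset is named in the error
  f2 <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(f2)
  rhdf5::h5createGroup(f2, "kdata")
  rhdf5::h5write(Re(kg$data), f2, "kdata/re")
  rhdf5::h5write(Im(kg$data), f2, "kdata/im")
  expect_error(read_kspace(f2), "ktraj")

  # legacy file without noise_sd: default 0 with a warning
  f3 <- tempfile(fileext = ".h5")
  write_kspace(kg, f3)
  fid <- rhdf5::H5Fopen(f3)
  oid <- rhdf5::H5Gopen(fid, "kdata")
  rhdf5::H5Adelete(oid, "noise_sd")
  rhdf5::H5Gclose(oid); rhdf5::H5Fclose(fid)
  expect_warning(b3 <- read_kspace(f3), "noise_sd")
  expect_equal(b3$noise_sd, 0)
})

test_that("NIfTI image round-trip preserves magnitude, phase and pixel size", {
  set.seed(11)
  x <- image_group(rand_cplx(c(16, 16, 3)), pixel_mm = 2)
  f <- tempfile(fileext = ".nii")
  write_image_nifti(x, f, phase = TRUE)
  back <- read_image_nifti(f, phase_path = sub("\\.nii$", "_phase.nii", f))
  expect_equal(abs(back$frames), abs(x$frames), tolerance = 1e-6)
  expect_equal(Arg(back$frames), Arg(x$frames), tolerance = 1e-5)
  expect_equal(back$pixel_mm, 2)
})
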