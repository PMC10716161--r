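test_that("background phantom is deterministic, bounded and seed-varies only in texture", {
  spec <- phantom_spec(matrix_size = 64, texture_sd = 0, seed = 1)
  bg1 <- make_background(spec)
  bg2 <- make_background(spec)
  expect_identical(bg1, bg2)
  expect_true(all(bg1 >= 0 & bg1 <= 1))

  # piecewise-constant with zero texture: few distinct values
  expect_lte(length(unique(as.vector(bg1))), 8)

  sA <- phantom_spec(matrix_size = 64, texture_sd = 0.05, seed = 1)
  sB <- phantom_spec(matrix_size = 64, texture_sd = 0.05, seed = 2)
  tA <- make_background(sA); tB <- make_background(sB)
  expect_gt(max(abs(tA - tB)), 0)          # textures differ
  outside <- bg1 == 0                       # ellipse geometry identical
  expect_identical(tA == 0, outside)
  expect_identical(tB == 0, outside)
})

test_that("needle advances linearly and only at the tip between frames", {
  spec <- phantom_spec(matrix_size = 64, texture_sd = 0, n_coils = 1, seed = 2)
  scen <- intervention_scenario("unilateral-left", n_frames = 10,
                                speed_mm_per_frame = 2, matrix_mm = 64)
  sim <- simulate_intervention(spec, scen)
  expect_equal(dim(sim$frames), c(64, 64, 10))
  expect_equal(needle_depth_mm(scen), pmin(2 * (1:10), 45))

  # depth-0 needle leaves the background untouched
  scen0 <- scen; scen0$speed_mm_per_frame <- 1e-9
  sim0 <- simulate_intervention(spec, scen0)
  expect_lt(max(abs(sim0$frames[, , 1] - sim$background)), 1e-12)

  # frame-to-frame differences confined to the advancing tip segment
  entry <- scen$entry_point_mm
  for (t in 2:5) {
    dmask <- abs(sim$frames[, , t] - sim$frames[, , t - 1]) > 0
    if (!any(dmask)) next
    px <- (which(dmask, arr.ind = TRUE) - 0.5)
    depth_along <- px[, 1] - entry[1]  # insertion is along the row axis
    expect_gte(min(depth_along), 2 * (t - 1) - scen$needle_width_mm - 1)
    expect_lte(max(depth_along), 2 * t + scen$needle_width_mm + 1)
  }

  # bilateral setups modify both hemispheres symmetrically
  scB <- intervention_scenario("bilateral-A", n_frames = 5, matrix_mm = 64,
                               speed_mm_per_frame = 3)
  simB <- simulate_intervention(spec, scB)
  dm <- abs(simB$frames[, , 5] - simB$background) > 0
  cols <- which(dm, arr.ind = TRUE)[, 2]
  expect_true(any(cols < 32) && any(cols > 32))

  # a path leaving the support is rejected
  bad <- intervention_scenario("unilateral-left", n_frames = 5,
                               entry_point_mm = c(2, 10),
                               target_point_mm = c(-20, 10), matrix_mm = 64)
  expect_error(simulate_intervention(spec, bad), "support")
})

test_that("DBS-style sequences group five frames per slice and accept the 402/512 protocol", {
  spec <- phantom_spec(matrix_size = 32, texture_sd = 0, n_coils = 1, seed = 3)
  scen <- intervention_scenario("unilateral-right", n_frames = 5,
                                needle_contrast = 1.8, matrix_mm = 32,
                                speed_mm_per_frame = 2)
  dbs <- simulate_dbs_sequence(spec, scen)
  expect_equal(dbs$frames_per_slice, 5L)
  expect_equal(dim(dbs$frames)[3], 5L)

  # zero-length electrode leaves the background
  scen0 <- scen; scen0$speed_mm_per_frame <- 1e-9
  dbs0 <- simulate_dbs_sequence(spec, scen0)
  expect_lt(max(abs(dbs0$frames[, , 1] - dbs0$background)), 1e-9)

  # the DBS radial protocol (402 spokes, 512 readout) is a valid config
  cfg <- trajectory_config(512, readout_points = 512)
  tr <- make_trajectory(cfg, group_scheme(402, 1))
  expect_equal(dim(tr$kcoords), c(402, 512, 2))
})

test_that("acquisition splits frames into groups, is deterministic, and writes paired files", {
  spec <- phantom_spec(matrix_size = 32, n_coils = 2, noise_sd = 0.01, seed = 4)
  scen <- intervention_scenario("unilateral-left", n_frames = 10,
                                matrix_mm = 32, speed_mm_per_frame = 1)
  sim <- simulate_intervention(spec, scen)
  sch <- group_scheme(4, 5)
  out <- tempfile("acq")
  a1 <- acquire(sim$frames, spec, sch, out_dir = out)
  expect_length(a1$kspace, 2)     # 10 frames / fpg 5
  expect_length(a1$truth, 2)
  a2 <- acquire(sim$frames, spec, sch)
  expect_identical(a1$kspace[[1]]$data, a2$kspace[[1]]$data)  # same seed

  expect_true(all(file.exists(file.path(out, c("kspace_g001.h5", "kspace_g002.h5",
                                               "truth_g001.nii", "manifest.json")))))
  back <- read_kspace(file.path(out, "kspace_g001.h5"))
  expect_equal(back$data, a1$kspace[[1]]$data, tolerance = 1e-12)

  # indivisible frame counts are rejected
  expect_error(acquire(sim$frames, spec, group_scheme(4, 3)), "divisible")
})

test_that("single-coil k-space of a real zero-phase image obeys conjugate symmetry", {
  spec <- phantom_spec(matrix_size = 32, n_coils = 1, texture_sd = 0, seed = 5)
  scen <- intervention_scenario("unilateral-left", n_frames = 2,
                                matrix_mm = 32, speed_mm_per_frame = 2)
  sim <- simulate_intervention(spec, scen)
  acq <- acquire(sim$frames, spec, group_scheme(3, 2))
  kg <- acq$kspace[[1]]
  nr <- dim(kg$data)[3]
  # within a spoke, sample j and sample 2*ctr-j sit at +/-k
  ctr <- nr %/% 2 + 1
  j <- (ctr + 1):(nr - 1)
  jm <- 2 * ctr - j
  for (sp in 1:3) {
    a <- kg$data[1, sp, j]
    b <- kg$data[1, sp, jm]
    expect_lt(max(Mod(a - Conj(b))), 1e-4 * max(Mod(a)))
  }
})

test_that("train/test scenario seeds can be split disjointly", {
  train_seeds <- 1:8
  test_seeds <- 101:102
  expect_length(intersect(train_seeds, test_seeds), 0)
  s1 <- intervention_scenario("unilateral-left", seed = 1, matrix_mm = 32,
                              n_frames = 2)
  s2 <- intervention_scenario("unilateral-left", seed = 101, matrix_mm = 32,
                              n_frames = 2)
  expect_false(s1$seed == s2$seed)
})
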