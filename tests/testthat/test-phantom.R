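# shared noiseless fixtures (built once; building is fast but not free)
spec0 <- phantom_spec()
static0 <- build_static_phantom(spec0)

test_that("static phantom reproduces the piecewise-constant construction", {
  spec <- phantom_spec(psf_fwhm = 0)
  vol <- build_static_phantom(spec)
  # centre voxel of the 37 mm sphere is exactly 4 x background
  ctr <- c(spec$sphere_ring_radius * cos(300 * pi / 180),
           spec$sphere_ring_radius * sin(300 * pi / 180), 0)
  expect_equal(suv_max(vol, list(center = ctr, diameter = 8)), 4)
  # grid centre is background, far corner is air
  mid <- (dim(vol$data) + 1) / 2
  expect_equal(vol$data[mid[1], mid[2], mid[3]], 1)
  expect_equal(vol$data[1, 1, 1], 0)
  # linearity: doubling background activity doubles every voxel
  vol2 <- build_static_phantom(phantom_spec(psf_fwhm = 0,
                                            background_activity = 2))
  expect_equal(vol2$data, 2 * vol$data)
})

test_that("geometry validation rejects impossible phantoms", {
  expect_error(build_static_phantom(phantom_spec(sphere_ring_radius = 140)),
               "outside")
  expect_error(build_static_phantom(phantom_spec(voxel_size = 6)),
               "voxel size")
  expect_error(phantom_spec(contrast_ratio = 1), "contrast_ratio")
  expect_error(phantom_spec(sphere_diameters = c(10, 9)), "ascending")
  expect_error(phantom_spec(motion_axis = c(1, 1, 0) / sqrt(2)), "aligned")
})

test_that("PSF blur conserves the activity of interior structures", {
  # compact blob well inside the grid: total activity must survive smoothing
  arr <- array(0, dim = c(41, 41, 41))
  arr[18:24, 18:24, 18:24] <- 5
  vol <- image_volume(arr, 2.7)
  sm <- smooth_volume(vol, 5)
  expect_lt(abs(sum(sm$data) / sum(arr) - 1), 1e-3)
  expect_equal(smooth_volume(vol, 0)$data, arr)
})

test_that("residual displacement distributions narrow under gating", {
  flat <- respiratory_trace(seq(0, 20, 0.04), rep(0, 501))
  pdf_static <- residual_displacement_pdf(flat)
  expect_equal(sum(pdf_static$prob), 1)
  expect_equal(pdf_static$sd, 0)
  expect_equal(pdf_static$mids[pdf_static$prob > 0], 0)

  sc <- sim_scan(jitter = 0, seed = 13, duration = 60, rate = 500)
  ungated <- residual_displacement_pdf(sc$trace)
  # raised-cosine breathing spans [0, 2 x amplitude]
  support <- range(ungated$mids[ungated$prob > 0])
  expect_lt(abs(support[2] - 30), 2)
  m1 <- gate_method1_qpg(sc$cycles, sc$events)
  gated <- residual_displacement_pdf(sc$trace, m1)
  expect_lt(gated$sd, ungated$sd)
})

test_that("motion blur is the identity for delta kernels and lowers maxima", {
  flat <- respiratory_trace(seq(0, 20, 0.04), rep(0, 501))
  d0 <- residual_displacement_pdf(flat)
  same <- apply_motion_blur(static0, d0, spec0$motion_axis)
  expect_equal(same$data, static0$data)

  # a delta off the origin is recentred away: still the identity
  shifted <- respiratory_trace(seq(0, 20, 0.04), rep(7.3, 501))
  d7 <- residual_displacement_pdf(shifted)
  expect_equal(apply_motion_blur(static0, d7, spec0$motion_axis)$data,
               static0$data)

  sc <- sim_scan(jitter = 0, seed = 14, duration = 60, rate = 500)
  wide <- residual_displacement_pdf(sc$trace, bin_width = spec0$voxel_size / 2)
  moved <- apply_motion_blur(static0, wide, spec0$motion_axis)
  rois <- sphere_rois(static0, spec0)
  for (j in seq_along(rois$sphere_mm)) {
    expect_lt(max(moved$data[rois$sphere[[j]]]),
              max(static0$data[rois$sphere[[j]]]))
  }
  # unnormalised pdf is rejected
  bad <- wide
  bad$prob <- bad$prob * 0.9
  expect_error(apply_motion_blur(static0, bad), "normalised")
})

test_that("count noise is unbiased and scales as 1/sqrt(counts)", {
  arm_hi <- recon_arm("hi", count_budget = 1, counts_per_unit = 1e5)
  hi <- apply_count_noise(static0, arm_hi, seed = 1)
  expect_lt(max(abs(hi$data - static0$data) / pmax(static0$data, 0.05)), 0.05)

  # background ROI relative SD doubles budget -> sqrt(2) change
  rois <- sphere_rois(static0, spec0)
  rel_sd <- function(budget, seed) {
    v <- apply_count_noise(static0, recon_arm("x", budget), seed = seed)
    mean(measure_iq(v, spec0, rois = rois)$BV)
  }
  r_half <- mean(vapply(1:10, function(s) rel_sd(0.5, 400 + s), numeric(1)))
  r_full <- mean(vapply(1:10, function(s) rel_sd(1, 500 + s), numeric(1)))
  expect_lt(abs(r_half / r_full - sqrt(2)), 0.15 * sqrt(2))

  # mean over seeds approaches the noiseless volume
  stack <- Reduce(`+`, lapply(1:15, function(s) {
    apply_count_noise(static0, recon_arm("x", 1), seed = 600 + s)$data
  })) / 15
  inside <- static0$data > 0.5
  expect_lt(abs(mean(stack[inside] - static0$data[inside])), 1e-3)
})

test_that("the arm pipeline orders contrast: static >= gated >= ungated moving", {
  sc <- sim_scan(jitter = 0.3, seed = 15, duration = 120, rate = 1000)
  m1 <- gate_method1_qpg(sc$cycles, sc$events)
  m2 <- gate_method2_adaptive(sc$cycles, sc$trace, sc$events)
  v_static <- simulate_arm(spec0, sc$trace, recon_arm("s", apply_motion = FALSE),
                           noiseless = TRUE, static_volume = static0)
  v_ungated <- simulate_arm(spec0, sc$trace, recon_arm("u"),
                            noiseless = TRUE, static_volume = static0)
  v_m1 <- simulate_arm(spec0, sc$trace, recon_arm("g1", gate_mask = m1),
                       noiseless = TRUE, static_volume = static0)
  v_m2 <- simulate_arm(spec0, sc$trace, recon_arm("g2", gate_mask = m2),
                       noiseless = TRUE, static_volume = static0)
  rois <- sphere_rois(static0, spec0)
  cr10 <- function(v) measure_iq(v, spec0, rois = rois)$CR[1]
  expect_gte(cr10(v_static), cr10(v_m1))
  expect_gte(cr10(v_static), cr10(v_m2))
  expect_gte(cr10(v_m1), cr10(v_ungated))
  expect_gte(cr10(v_m2), cr10(v_ungated))
  # gated SUVmax of every sphere sits between ungated-moving and static
  for (j in seq_along(rois$sphere_mm)) {
    mx <- c(max(v_static$data[rois$sphere[[j]]]),
            max(v_m1$data[rois$sphere[[j]]]),
            max(v_ungated$data[rois$sphere[[j]]]))
    expect_true(mx[1] >= mx[2] && mx[2] >= mx[3])
  }
})

test_that("NIfTI round-trip preserves the volume", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(static0, path)
  back <- read_volume_nifti(path)
  expect_equal(back$voxel_size, static0$voxel_size, tolerance = 1e-6)
  expect_equal(back$data, static0$data, tolerance = 1e-6)
})
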