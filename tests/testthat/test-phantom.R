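# phantom: anatomy, territories, centerlines, input function, simulation,
# perturbations

test_that("generated anatomy satisfies its construction invariants", {
  tr <- small_truth()
  lv <- tr$masks$lv$data; rv <- tr$masks$rv$data; epi <- tr$masks$epi$data
  expect_false(any(lv & rv))
  expect_true(all(lv <= epi))
  expect_true(all(rv <= epi))
  myo <- myocardium_mask(tr$masks)
  expect_gt(sum(myo$data), 0)
  # single connected shell
  lab <- label_components(myo)
  expect_equal(max(lab), 1L)
  # every myocardial voxel labelled and carrying a flow value
  terr <- tr$territory$data
  expect_true(all(terr[myo$data > 0] %in% 1:3))
  expect_true(all(tr$flow$rest$data[myo$data > 0] > 0))
  expect_true(all(tr$flow$stress$data[myo$data > 0] > 0))
  expect_true(all(tr$flow$rest$data[myo$data == 0] == 0))
})

test_that("same spec and seed give bit-identical anatomy", {
  a <- generate_anatomy(small_spec())
  b <- generate_anatomy(small_spec())
  expect_identical(a$masks$epi$data, b$masks$epi$data)
  expect_identical(a$territory$data, b$territory$data)
})

test_that("wall thickness matches the spec by a brute-force distance oracle", {
  spec <- small_spec(wall_thickness = 10, voxel_size = 2, grid_shape = 72)
  tr <- generate_anatomy(spec)
  myo <- myocardium_mask(tr$masks)
  d <- dim(myo$data)
  # LV-wall voxels only (within the wall of the LV, away from RV)
  dl <- distance_transform(tr$masks$lv)
  wall_lin <- which(myo$data > 0 & dl <= 10 + 1e-9)
  out_lin <- which(tr$masks$epi$data == 0)
  lv_lin <- which(tr$masks$lv$data > 0)
  set.seed(11)
  samp <- sample(wall_lin, 150)
  xyz <- voxel_to_world(myo, arrayInd(samp, d))
  lv_xyz <- voxel_to_world(myo, arrayInd(lv_lin, d))
  out_xyz <- voxel_to_world(myo, arrayInd(out_lin, d))
  thick <- brute_min_dist(xyz, lv_xyz) + brute_min_dist(xyz, out_xyz)
  # slab property: inner + outer distance ~ wall thickness, within one voxel
  expect_lt(abs(mean(thick) - 10), 2)
})

test_that("phantom geometry that cannot fit the grid errors", {
  expect_error(phantom_spec(grid_shape = 4), "grid too small")
  expect_error(generate_anatomy(phantom_spec(grid_shape = c(32, 32, 32))),
               "does not fit")
})

test_that("centerlines run base to apex on the epicardial surface", {
  tr <- default_truth()
  epi <- tr$masks$epi
  d <- dim(epi$data)
  # surface voxels for the oracle: epi voxels bordering the outside
  out_xyz <- voxel_to_world(epi, arrayInd(which(epi$data > 0), d))
  for (v in c("LAD", "LCX", "rPDA")) {
    cl <- generate_centerline(tr, v)
    expect_true(all(diff(cl$arc) > 0))
    expect_equal(cl$arc[1], 0)
    # base at high z, apex at low z in the phantom frame
    expect_gt(cl$points[1, 3], cl$points[nrow(cl$points), 3])
    # surface-distance oracle: within ~1 voxel of the epicardium
    dmin <- brute_min_dist(cl$points, out_xyz)
    expect_lt(max(dmin), 2 * max(epi$voxel_size))
  }
  expect_error(generate_centerline(tr, "LED"), "should be one of|arg")
})

test_that("two-point centerlines and reversal behave as arc-length says", {
  p <- rbind(c(0, 0, 0), c(3, 4, 0))
  cl <- centerline(p, "LAD")
  expect_equal(arc_length(cl), 5)
  cl3 <- centerline(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0)), "LCX")
  rev3 <- centerline(cl3$points[3:1, ], "LCX")
  expect_equal(rev3$arc, max(cl3$arc) - rev(cl3$arc))
  expect_error(centerline(rbind(c(0, 0, 0), c(0, 0, 0)), "LAD"),
               "strictly increasing")
})

test_that("gamma-variate input function has the stated analytic shape", {
  prm <- input_function_params(t0 = 10, alpha = 3, beta = 8,
                               tail_fraction = 0)
  tt <- seq(0, 300, by = 0.01)
  ca <- simulate_input_function(prm, tt)
  expect_true(all(ca >= 0))
  expect_true(all(ca[tt <= 10] == 0))
  # peak at t0 + alpha * beta = 34 s (set dCa/dt = 0 analytically)
  expect_lt(abs(tt[which.max(ca)] - 34), 0.05)
  # linearity in amplitude
  prm2 <- input_function_params(amplitude = 2 * prm$amplitude, t0 = 10,
                                alpha = 3, beta = 8, tail_fraction = 0)
  expect_equal(simulate_input_function(prm2, tt), 2 * ca)
  expect_error(input_function_params(alpha = -1), "> 0")
  expect_error(input_function_params(beta = 0), "> 0")
  expect_error(simulate_input_function(prm, c(3, 2, 1)), "increasing")
})

test_that("noise-free simulation equals the frame-averaged model curves", {
  tr <- small_truth()
  sched <- make_schedule("SMC_CNUH")
  inp <- input_function_params()
  ser <- simulate_dynamic_pet(tr, inp, sched, state = "rest", noise_scale = 0)
  expect_true(all(ser$data >= 0))

  # blood-pool voxel equals frame-averaged Ca
  lv_lin <- which(tr$masks$lv$data > 0)
  v1 <- lv_lin[1]
  tt <- seq(0, 360, by = 0.5)
  ca <- simulate_input_function(inp, tt)
  ca_frames <- vapply(seq_len(27), function(f) {
    sel <- tt >= sched$start[f] & tt <= sched$start[f] + sched$duration[f]
    v <- ca[sel]
    (sum(v) - (v[1] + v[length(v)]) / 2) / (sum(sel) - 1)
  }, numeric(1))
  expect_equal(ser$data[v1 + (seq_len(27) - 1) * prod(dim(tr$masks$lv$data))],
               ca_frames, tolerance = 1e-10)

  # myocardial voxel equals the frame-averaged model TAC for its truth flow
  myo_lin <- which(myocardium_mask(tr$masks)$data > 0)
  v2 <- myo_lin[100]
  K1 <- tr$flow$rest$data[v2]
  spec <- tr$spec
  m <- model_tissue_tac(kinetic_params(K1, spec$k2, spec$k3, spec$blood_fraction),
                        inp, sched)
  expect_equal(ser$data[v2 + (seq_len(27) - 1) * prod(dim(tr$masks$lv$data))],
               m$activity, tolerance = 1e-10)

  # outside the epicardium: zero
  out_lin <- which(tr$masks$epi$data == 0)
  expect_true(all(ser$data[out_lin[1] + (seq_len(27) - 1) *
                             prod(dim(tr$masks$lv$data))] == 0))
})

test_that("simulation is a pure function of inputs and seed", {
  tr <- small_truth()
  sched <- make_schedule("SMC_CNUH")
  a <- simulate_dynamic_pet(tr, schedule = sched, state = "stress", seed = 5L)
  b <- simulate_dynamic_pet(tr, schedule = sched, state = "stress", seed = 5L)
  expect_identical(a$data, b$data)
  c3 <- simulate_dynamic_pet(tr, schedule = sched, state = "stress", seed = 6L)
  expect_false(identical(a$data, c3$data))
})

test_that("zero perturbation leaves masks bit-identical", {
  tr <- small_truth()
  out <- perturb_masks(tr$masks, perturbation_spec())
  expect_identical(out$lv$data, tr$masks$lv$data)
  expect_identical(out$rv$data, tr$masks$rv$data)
  expect_identical(out$epi$data, tr$masks$epi$data)
})

test_that("apex truncation removes exactly the stated short-axis slices", {
  tr <- small_truth()
  n_slices <- sum(apply(tr$masks$epi$data, 3, sum) > 0)
  out <- perturb_masks(tr$masks, perturbation_spec(apex_truncation_slices = 3L))
  expect_equal(sum(apply(out$epi$data, 3, sum) > 0), n_slices - 3L)
  expect_error(perturb_masks(tr$masks,
                             perturbation_spec(apex_truncation_slices = 500L)),
               "exceeds")
})

test_that("RV dilation grows the RV strictly outward", {
  tr <- small_truth()
  out <- perturb_masks(tr$masks, perturbation_spec(rv_dilation_mm = 4))
  expect_gt(sum(out$rv$data), sum(tr$masks$rv$data))
  # outward only: no voxel inside the original epicardium changed
  inside <- tr$masks$epi$data > 0
  expect_identical(out$rv$data[inside], tr$masks$rv$data[inside])
})

test_that("perturbation severity is monotone in symmetric-difference volume", {
  tr <- small_truth()
  specs <- list(
    perturbation_spec(1L, 0, 0.5, seed = 3L),
    perturbation_spec(2L, 3, 1.0, seed = 3L),
    perturbation_spec(4L, 6, 1.5, seed = 3L))
  symdiff <- vapply(specs, function(s) {
    out <- perturb_masks(tr$masks, s)
    sum(out$epi$data != tr$masks$epi$data) + sum(out$rv$data != tr$masks$rv$data)
  }, numeric(1))
  expect_true(all(diff(symdiff) >= 0))
  # determinism
  o1 <- perturb_masks(tr$masks, specs[[2]])
  o2 <- perturb_masks(tr$masks, specs[[2]])
  expect_identical(o1$epi$data, o2$epi$data)
})

test_that("lesions reduce stress flow over the targeted arc interval only", {
  tr <- generate_anatomy(small_spec())
  cl <- generate_centerline(tr, "LAD")
  les <- apply_lesion(tr, cl, 20, 40, factor = 0.5)
  changed <- les$flow$stress$data != tr$flow$stress$data
  expect_gt(sum(changed), 0)
  expect_true(all(les$flow$stress$data[changed] ==
                    0.5 * tr$flow$stress$data[changed]))
  expect_identical(les$flow$rest$data, tr$flow$rest$data)
  # only LAD-territory voxels affected
  expect_true(all(tr$territory$data[changed] == 1L))
})
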