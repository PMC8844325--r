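# fusion: transforms, PET LV segmentation, rigid + MI registration

test_that("rigid transforms satisfy the group identities", {
  tf <- rigid_transform(c(12, -7, 4), c(10, -6, 4))
  R <- rotation_matrix(tf)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
  expect_lt(abs(det(R) - 1), 1e-8)
  idc <- compose_transforms(tf, invert_transform(tf))
  expect_lt(max(abs(rotation_matrix(idc) - diag(3))), 1e-8)
  expect_lt(max(abs(idc$translation_mm)), 1e-8)
  # angle round trip through the matrix form
  tf2 <- transform_from_matrix(R, tf$translation_mm)
  expect_equal(tf2$angles_deg, tf$angles_deg, tolerance = 1e-8)
})

test_that("transform application is rigid and composes correctly", {
  set.seed(2)
  pts <- matrix(stats::rnorm(30, sd = 40), ncol = 3)
  a <- rigid_transform(c(5, 10, -3), c(4, -2, 7))
  b <- rigid_transform(c(-8, 2, 6), c(-1, 3, 2))
  pd <- as.matrix(stats::dist(pts))
  pd2 <- as.matrix(stats::dist(transform_points(a, pts)))
  expect_lt(max(abs(pd - pd2)) / max(pd), 1e-9)
  expect_equal(transform_points(compose_transforms(a, b), pts),
               transform_points(a, transform_points(b, pts)),
               tolerance = 1e-9)
})

test_that("transform JSON sidecars round-trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  tf <- rigid_transform(c(1.25, -3.5, 0.75), c(10.1, -6.2, 4.3))
  write_transform(tf, tmp)
  tf2 <- read_transform(tmp)
  expect_equal(tf2$angles_deg, tf$angles_deg)
  expect_equal(tf2$translation_mm, tf$translation_mm)
})

test_that("transformed centerlines preserve arc length and shift rigidly", {
  cl <- centerline(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 5)), "LAD")
  idc <- rigid_transform()
  expect_equal(transform_centerline(cl, idc)$points, cl$points)
  sh <- rigid_transform(c(0, 0, 0), c(3, -2, 1))
  cls <- transform_centerline(cl, sh)
  expect_equal(cls$points, sweep(cl$points, 2, c(3, -2, 1), "+"))
  rot <- rigid_transform(c(30, 10, -20), c(5, 5, 5))
  expect_equal(transform_centerline(cl, rot)$arc, cl$arc, tolerance = 1e-9)
})

test_that("segment_lv_from_pet thresholds, picks one component, fills holes", {
  tr <- default_truth()
  ser <- default_series("stress")
  ps <- pet_sum(ser)
  seg <- segment_lv_from_pet(ps, 0.5)
  blob <- (tr$masks$lv$data > 0) | (myocardium_mask(tr$masks)$data > 0)
  dice <- 2 * sum(seg$data > 0 & blob) / (sum(seg$data) + sum(blob))
  expect_gte(dice, 0.7)

  # threshold 0 keeps the whole positive support (one component here)
  seg0 <- segment_lv_from_pet(ps, 0)
  expect_equal(sum(seg0$data), sum(ps$data > 0))

  # two equal blobs: deterministic tie-break toward the lowest voxel index
  two <- array(0, c(10, 10, 10))
  two[2:3, 2:3, 2:3] <- 1
  two[7:8, 7:8, 7:8] <- 1
  v <- volume(two, 1)
  picked <- segment_lv_from_pet(v, 0.5)
  expect_equal(sum(picked$data), 8)
  expect_equal(picked$data[2, 2, 2], 1)
  expect_equal(picked$data[7, 7, 7], 0)

  expect_error(segment_lv_from_pet(volume(array(0, c(4, 4, 4)), 1)), "positive")
})

test_that("register_rigid_lv recovers identity, shifts and rotations", {
  tr <- small_truth()
  lv <- tr$masks$lv
  expect_error(register_rigid_lv(lv, volume(array(c(1, rep(0, 7)), c(2, 2, 2)), 1)),
               "degenerate")

  tf_id <- register_rigid_lv(lv, lv)
  expect_lt(max(abs(tf_id$translation_mm)), 3)
  expect_lt(rotation_angle_between_t(tf_id, rigid_transform()), 3)

  # known shift: move the PET-side mask by (10, -6, 4) mm
  shifted <- volume(lv$data, lv$voxel_size, lv$origin + c(10, -6, 4),
                    lv$direction)
  tf <- register_rigid_lv(shifted, lv)
  expect_lt(max(abs(tf$translation_mm - c(10, -6, 4))), max(lv$voxel_size))

  # known 10 deg rotation about the long axis (use the full biventricular
  # envelope, whose cross-section is rotationally asymmetric)
  blob <- volume((tr$masks$epi$data > 0) + 0, lv$voxel_size, lv$origin)
  ctr <- colMeans(voxel_to_world(blob, arrayInd(which(blob$data > 0), dim(blob$data))))
  tf_true <- make_centered(c(10, 0, 0), c(0, 0, 0), ctr)
  rot_dat <- resample_by_transform(blob, tf_true)
  tf_rec <- register_rigid_lv(rot_dat, blob)
  expect_lt(rotation_angle_between_t(tf_rec, tf_true), 2)
})

test_that("MI refinement is a fixed point at truth and never degrades the metric", {
  tr <- small_truth()
  ser <- simulate_dynamic_pet(tr, schedule = make_schedule("SMC_CNUH"),
                              state = "stress", noise_scale = 0)
  ps <- pet_sum(ser)
  idt <- rigid_transform()
  tf <- refine_mutual_information(ps, tr$masks, idt)
  expect_lt(rotation_angle_between_t(tf, idt), 1)
  expect_lt(max(abs(tf$translation_mm)), max(ps$voxel_size) / 2 + 1e-9)
})
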