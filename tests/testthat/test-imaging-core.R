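# imaging core: schedules, PET_sum, reorientation, resampling, I/O

test_that("schedule presets reproduce the clinical binning schemes", {
  snuh <- make_schedule("SNUH")
  expect_equal(nrow(snuh), 21L)
  expect_equal(schedule_total(snuh), 600)
  expect_equal(snuh$duration, c(rep(10, 12), rep(30, 6), rep(60, 2), 180))

  smc <- make_schedule("SMC_CNUH")
  expect_equal(nrow(smc), 27L)
  expect_equal(schedule_total(smc), 360)

  expect_error(make_schedule("NOPE"), "unknown")
  expect_error(make_schedule(frames = cbind(c(0, 20), c(10, 10))), "contiguous")
  expect_error(make_schedule(frames = cbind(c(0, 5), c(10, 10))), "contiguous")
  expect_error(make_schedule(frames = cbind(0, -1)), "> 0")
  expect_error(make_schedule(frames = cbind(5, 10)), "start at 0")
})

test_that("pet_sum selects second-half frames, weights by duration, is linear", {
  sched <- make_schedule("SNUH")
  d <- c(4, 4, 4)
  set.seed(7)
  arr <- array(stats::runif(prod(d) * 21), c(d, 21))
  ser <- dynamic_series(arr, sched, voxel_size = 2)
  ps <- pet_sum(ser)
  # exactly the 2 x 60 s and 1 x 180 s frames (starts 300/360/420 >= 300)
  manual <- arr[, , , 19] * 60 + arr[, , , 20] * 60 + arr[, , , 21] * 180
  expect_equal(ps$data, manual)

  zero <- dynamic_series(array(0, c(d, 21)), sched, voxel_size = 2)
  expect_true(all(pet_sum(zero)$data == 0))

  ser2 <- dynamic_series(2 * arr, sched, voxel_size = 2)
  expect_equal(pet_sum(ser2)$data, 2 * ps$data)

  # storage-order invariance given the schedule: permuting frames together
  # with their schedule rows cannot change the sum; emulate by summing the
  # qualifying frames directly in another order
  manual_rev <- arr[, , , 21] * 180 + arr[, , , 20] * 60 + arr[, , , 19] * 60
  expect_equal(ps$data, manual_rev)
})

test_that("series frame count must match the schedule", {
  sched <- make_schedule("SNUH")
  expect_error(dynamic_series(array(0, c(4, 4, 4, 20)), sched, 2), "frame count")
})

test_that("reorient_short_axis preserves world coordinates", {
  v <- asym_volume()
  expect_equal(reorient_short_axis(v, c(1, 2, 3)), v)

  m <- c(3, -1, -2)
  w <- reorient_short_axis(v, m)
  expect_equal(sort(unique(as.vector(w$data))), sort(unique(as.vector(v$data))))
  # index-arithmetic oracle: the voxel at old (i,j,k) must sit at the mapped
  # new index, and both must have identical world coordinates
  d <- dim(v$data)
  for (idx in list(c(1, 1, 1), c(2, 3, 4), c(3, 4, 5), c(1, 4, 2))) {
    val <- v$data[idx[1], idx[2], idx[3]]
    newd <- dim(w$data)
    nidx <- vapply(1:3, function(a) {
      o <- abs(m[a])
      if (m[a] > 0) idx[o] else d[o] - idx[o] + 1L
    }, numeric(1))
    expect_equal(w$data[nidx[1], nidx[2], nidx[3]], val)
    expect_equal(voxel_to_world(w, matrix(nidx, 1)),
                 voxel_to_world(v, matrix(idx, 1)))
  }
  # group property: applying the inverse mapping restores the volume
  inv <- integer(3)
  for (a in 1:3) inv[abs(m[a])] <- a * sign(m[a])
  expect_equal(reorient_short_axis(w, inv), v)

  expect_error(reorient_short_axis(v, c(1, 1, 3)), "permutation")
})

test_that("resample block-averages intensities and majority-votes masks", {
  v <- asym_volume(c(4, 4, 4))
  expect_identical(resample(v, 1), v)

  const <- volume(array(3.5, c(8, 8, 8)), 1)
  r <- resample(const, 2)
  expect_true(all(r$data == 3.5))
  expect_equal(r$voxel_size, c(2, 2, 2))

  # hand-computed block mean for a 4 x 4 plane collapsed in-plane
  plane <- volume(array(1:16, c(4, 4, 1)), 1)
  r4 <- resample(plane, c(4, 4, 1))
  expect_equal(as.vector(r4$data), mean(1:16))

  mask <- volume(array(c(1, 1, 1, 0, 0, 0, 0, 0), c(2, 2, 2)), 1)
  rm1 <- resample(mask, 2)
  expect_equal(as.vector(rm1$data), 0)   # 3/8 foreground -> background

  # composability of voxel sizes
  big <- volume(array(stats::rnorm(16^3), c(16, 16, 16)), 1)
  expect_equal(resample(resample(big, 2), 2)$voxel_size,
               resample(big, 4)$voxel_size)
  expect_error(resample(v, 10), "exceeds")
})

test_that("NIfTI volumes and series round-trip losslessly", {
  tmp <- withr::local_tempdir()
  v <- asym_volume()
  p <- file.path(tmp, "vol.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$data, v$data)
  expect_equal(v2$voxel_size, v$voxel_size)
  expect_equal(v2$origin, v$origin)

  # uncompressed too
  p3 <- file.path(tmp, "vol.nii")
  write_volume(v, p3)
  expect_equal(read_volume(p3)$data, v$data)

  # masks with non-binary values are rejected on load
  bad <- volume(array(2, c(2, 2, 2)), 1)
  pb <- file.path(tmp, "bad.nii")
  write_volume(bad, pb)
  expect_error(read_volume(pb, mask = TRUE), "non-binary")

  sched <- make_schedule("SMC_CNUH")
  arr <- array(stats::rnorm(3 * 3 * 3 * 27), c(3, 3, 3, 27))
  ser <- dynamic_series(arr, sched, voxel_size = c(1, 2, 3), state = "stress")
  ps <- file.path(tmp, "dyn.nii.gz")
  write_series(ser, ps)
  ser2 <- read_series(ps, state = "stress")
  expect_equal(ser2$data, ser$data)
  expect_equal(ser2$schedule$start, ser$schedule$start)

  # frame-count / schedule mismatch rejected
  utils::write.csv(data.frame(start_s = 0, duration_s = 10),
                   file.path(tmp, "dyn_schedule.csv"), row.names = FALSE)
  expect_error(read_series(ps), "frame count")
})

test_that("anatomy mask invariants are enforced on construction", {
  d <- c(6, 6, 6)
  lv <- array(0, d); lv[2:3, 2:3, 2:3] <- 1
  rv <- array(0, d); rv[5, 5, 5] <- 1
  epi <- array(0, d); epi[1:6, 1:6, 1:6] <- 1
  mk <- function(a) volume(a, 1)
  expect_s3_class(anatomy_masks(mk(lv), mk(rv), mk(epi)), "mbf_masks")

  overlap <- lv; overlap[5, 5, 5] <- 1
  expect_error(anatomy_masks(mk(overlap), mk(rv), mk(epi)), "overlap")
  small_epi <- array(0, d); small_epi[2:3, 2:3, 2:3] <- 1
  expect_error(anatomy_masks(mk(lv), mk(rv), mk(small_epi)), "EPI")
  expect_error(anatomy_masks(mk(lv), mk(rv), mk(lv)), "myocardium|EPI")
})
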