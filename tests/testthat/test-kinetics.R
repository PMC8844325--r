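# kinetics: forward model, fitting, profiles, interpolation

test_that("model TAC collapses to v_b * Ca when K1 = 0", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  m <- model_tissue_tac(kinetic_params(0, 0.4, 0.1, 0.3), inp, sched)
  tt <- mbfvs:::fine_times(sched, 0.5)
  ca_frames <- mbfvs:::frame_average_fine(simulate_input_function(inp, tt),
                                          0.5, sched)
  expect_equal(m$activity, 0.3 * ca_frames, tolerance = 1e-12)
})

test_that("one-tissue special case matches an independent convolution oracle", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params(tail_fraction = 0)
  K1 <- 0.5; k2 <- 0.3
  m <- model_tissue_tac(kinetic_params(K1, k2, 0, 0), inp, sched, dt_s = 0.1)
  # independent oracle: closed form K1 * int Ca(s) exp(-k2 (t-s)) ds computed
  # by direct Riemann convolution on a fine grid, then trapezoid-averaged
  dt <- 0.02
  tt <- seq(0, 600, by = dt)
  ca <- simulate_input_function(inp, tt)
  conv <- K1 / 60 * dt * (stats::convolve(ca, rev(exp(-k2 * tt / 60)),
                                          type = "open")[seq_along(tt)])
  oracle <- vapply(seq_len(nrow(sched)), function(f) {
    sel <- which(tt >= sched$start[f] - 1e-9 &
                   tt <= sched$start[f] + sched$duration[f] + 1e-9)
    v <- conv[sel]
    (sum(v) - (v[1] + v[length(v)]) / 2) / (length(sel) - 1)
  }, numeric(1))
  expect_lt(max(abs(m$activity - oracle)) / max(oracle), 0.01)
})

test_that("the model is linear in the input function", {
  sched <- make_schedule("SMC_CNUH")
  inp1 <- input_function_params()
  inp2 <- input_function_params(amplitude = 3 * inp1$amplitude)
  p <- kinetic_params(1.2, 0.5, 0.15, 0.25)
  m1 <- model_tissue_tac(p, inp1, sched)
  m2 <- model_tissue_tac(p, inp2, sched)
  expect_equal(m2$activity, 3 * m1$activity, tolerance = 1e-10)
})

test_that("noise-free fits recover truth parameters", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  truth <- kinetic_params(0.9, 0.4, 0.1, 0.3)
  m <- model_tissue_tac(truth, inp, sched)
  f <- fit_kinetics(m, inp)
  expect_true(f$converged)
  expect_lt(abs(f$params$K1 - 0.9) / 0.9, 1e-3)
  expect_lt(abs(f$params$v_b - 0.3), 0.01)
})

test_that("forward/inverse consistency holds over a parameter grid", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  for (K1 in c(0.5, 1.5, 3)) {
    for (k3 in c(0.05, 0.2)) {
      truth <- kinetic_params(K1, 0.4, k3, 0.3)
      f <- fit_kinetics(model_tissue_tac(truth, inp, sched), inp)
      expect_lt(abs(f$params$K1 - K1) / K1, 1e-3)
    }
  }
})

test_that("doubling truth K1 doubles fitted K1 (flow linearity probe)", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  f1 <- fit_kinetics(model_tissue_tac(kinetic_params(1, 0.4, 0.1, 0.3), inp, sched), inp)
  f2 <- fit_kinetics(model_tissue_tac(kinetic_params(2, 0.4, 0.1, 0.3), inp, sched), inp)
  expect_lt(abs(f2$params$K1 / f1$params$K1 - 2), 0.02)
})

test_that("an all-zero TAC fits K1 = 0 at the bound", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  z <- tac(sched$mid, sched$duration, rep(0, nrow(sched)))
  f <- fit_kinetics(z, inp)
  expect_equal(f$params$K1, 0, tolerance = 1e-6)
})

test_that("fits are deterministic given identical inputs", {
  sched <- make_schedule("SNUH")
  inp <- input_function_params()
  truth <- kinetic_params(1.1, 0.5, 0.12, 0.28)
  m <- model_tissue_tac(truth, inp, sched)
  noisy <- tac(m$mid_s, m$duration_s,
               m$activity + with_fixed_seed(3L, stats::rnorm(21, 0, 1)))
  f1 <- fit_kinetics(noisy, inp)
  f2 <- fit_kinetics(noisy, inp)
  expect_identical(unlist(f1$params), unlist(f2$params))
})

test_that("interpolated profiles pass through ROI values and stay monotone-safe", {
  prof <- flow_profile(data.frame(position = c(2, 6, 10, 14),
                                  mbf = c(1.0, 2.0, 2.0, 0.8)),
                       vessel = "LAD", state = "stress")
  cur <- interpolate_profile(prof, step_mm = 2)
  at_roi <- cur$value[match(prof$position, cur$position)]
  expect_equal(at_roi, prof$mbf)
  # monotone interpolant stays inside the bracketing values
  between <- cur$value[cur$position > 2 & cur$position < 6]
  expect_true(all(between > 1 & between < 2))
  const <- flow_profile(data.frame(position = c(0, 4, 8), mbf = rep(1.5, 3)),
                        vessel = "LAD", state = "rest")
  expect_true(all(interpolate_profile(const, 1)$value == 1.5))
  single <- flow_profile(data.frame(position = 1, mbf = 1), "LAD", "rest")
  expect_error(interpolate_profile(single), ">= 2")
})

test_that("profile fits are independent of ROI processing order", {
  tr <- small_truth()
  ser <- simulate_dynamic_pet(tr, schedule = make_schedule("SMC_CNUH"),
                              state = "stress")
  cl <- generate_centerline(tr, "LAD")
  rs <- subtended_rois(cl, tr$masks)
  ca <- arterial_input_tac(ser, tr$masks)
  p1 <- vessel_flow_profile(rs, ser, ca, polish = FALSE, dt_s = 1)
  rs_rev <- rs
  rs_rev$rois <- rev(rs$rois)
  p2 <- vessel_flow_profile(rs_rev, ser, ca, polish = FALSE, dt_s = 1)
  expect_equal(p1$mbf, p2$mbf)
  expect_equal(p1$position, p2$position)
})
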