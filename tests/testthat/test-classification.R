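# classification, Dice agreement, pooling, t tests

mk_class <- function(labels, vessel = "LAD", state = "stress",
                     positions = seq_along(labels) * 4 - 2) {
  structure(data.frame(position = positions, mbf = 1, lower = 1,
                       label = labels),
            class = c("mbf_classification", "data.frame"),
            vessel = vessel, state = state, provenance = "M")
}

test_that("normal ranges are the mean +/- k SD band, clipped at zero", {
  mk_prof <- function(vals) flow_profile(
    data.frame(position = c(0, 4, 8), mbf = vals), "LAD", "stress")
  p1 <- mk_prof(c(1, 1, 1)); p2 <- mk_prof(c(3, 3, 3))
  r <- build_normal_range(list(p1, p2), k_sd = 1)
  expect_equal(r$lower, rep(2 - sqrt(2), 3))   # SD of {1, 3} = sqrt(2)
  expect_equal(r$upper, rep(2 + sqrt(2), 3))

  r0 <- build_normal_range(list(p1, p2), k_sd = 0)
  expect_equal(r0$lower, r0$upper)
  expect_equal(r0$lower, rep(2, 3))

  same <- build_normal_range(list(p1, p1), k_sd = 2)
  expect_equal(same$lower, same$upper)

  # large k: the band is clipped below at zero
  rbig <- build_normal_range(list(p1, p2), k_sd = 10)
  expect_true(all(rbig$lower == 0))

  p3 <- flow_profile(data.frame(position = c(0, 4, 8), mbf = c(1, 1, 1)),
                     "LCX", "stress")
  expect_error(build_normal_range(list(p1, p3)), "mix")
  expect_error(build_normal_range(list(p1)), ">= 2")
})

test_that("classification uses the inclusive below-the-range rule", {
  range <- structure(data.frame(vessel = "LAD", state = "stress",
                                position = c(0, 20), lower = c(1.5, 1.5),
                                upper = c(3, 3)),
                     class = c("mbf_normal_range", "data.frame"))
  prof <- flow_profile(data.frame(position = c(2, 10, 18),
                                  mbf = c(2.0, 1.0, 2.0)), "LAD", "stress")
  cls <- classify_profile(prof, range)
  expect_equal(cls$label, c("normal", "abnormal", "normal"))

  # exactly at the lower bound: normal ("within the range" is inclusive);
  # above the upper bound: still normal (only "below the range" is abnormal)
  prof2 <- flow_profile(data.frame(position = c(2, 10), mbf = c(1.5, 5)),
                        "LAD", "stress")
  expect_equal(classify_profile(prof2, range)$label, c("normal", "normal"))

  # no extrapolation outside the range span
  prof3 <- flow_profile(data.frame(position = c(2, 30), mbf = c(2, 2)),
                        "LAD", "stress")
  expect_error(classify_profile(prof3, range), "outside")

  # monotonicity: decreasing any value never flips abnormal -> normal
  for (i in seq_len(nrow(prof))) {
    lowered <- prof
    lowered$mbf[i] <- lowered$mbf[i] - 0.75
    cl2 <- classify_profile(flow_profile(lowered, "LAD", "stress"), range)
    was_abn <- cls$label == "abnormal"
    expect_true(all(cl2$label[was_abn] == "abnormal"))
  }
})

test_that("dice_agreement matches hand-worked examples in both modes", {
  a <- mk_class(c("normal", "normal", "abnormal", "abnormal", "abnormal"))
  b <- mk_class(c("normal", "abnormal", "abnormal", "abnormal", "normal"))
  mf <- dice_agreement(a, b, "matched-fraction")
  expect_equal(mf$dc, 3 / 5)
  ab <- dice_agreement(a, b, "abnormal-set")
  expect_equal(ab$dc, 2 * 2 / (3 + 3))

  expect_equal(dice_agreement(a, a)$dc, 1)
  expect_equal(dice_agreement(a, a, "abnormal-set")$dc, 1)

  flip <- mk_class(rev(c("normal", "normal", "abnormal", "abnormal", "abnormal")))
  expect_equal(dice_agreement(a, flip)$dc, 1 / 5)  # only the middle matches

  # both all-normal: abnormal-set Dice defined as 1
  n5 <- mk_class(rep("normal", 5))
  expect_equal(dice_agreement(n5, n5, "abnormal-set")$dc, 1)

  # symmetry
  expect_equal(dice_agreement(a, b)$dc, dice_agreement(b, a)$dc)
  expect_equal(dice_agreement(a, b, "abnormal-set")$dc,
               dice_agreement(b, a, "abnormal-set")$dc)

  expect_error(dice_agreement(a, mk_class(rep("normal", 4))), "length")
  expect_error(dice_agreement(a, mk_class(b$label, vessel = "LCX")), "mix")
})

test_that("pooling recomputes DC over concatenated samples", {
  # vessel1: 4/5 matched; vessel2: 6/10 matched -> pooled 10/15
  v1a <- mk_class(c(rep("normal", 4), "abnormal"))
  v1b <- mk_class(c(rep("normal", 4), "normal"))
  lab2a <- rep(c("abnormal", "normal"), 5)
  lab2b <- c(lab2a[1:6], rev(lab2a[7:10]))
  stopifnot(sum(lab2a == lab2b) == 6)
  v2a <- mk_class(lab2a, vessel = "LCX")
  v2b <- mk_class(lab2b, vessel = "LCX")
  pooled <- pool_agreement(list(list(a = v1a, b = v1b), list(a = v2a, b = v2b)))
  g <- pooled[pooled$group == "global", ]
  expect_equal(g$n, 15)
  expect_equal(g$dc, 10 / 15)
  expect_equal(pooled$dc[pooled$group == "LAD"], 4 / 5)
  expect_equal(pooled$dc[pooled$group == "LCX"], 6 / 10)
  # pooled DC lies between the per-vessel matched fractions
  expect_true(g$dc >= 6 / 10 && g$dc <= 4 / 5)

  one <- pool_agreement(list(list(a = v1a, b = v1b)))
  expect_equal(one$dc[one$group == "global"], 4 / 5)
})

test_that("compare_dc_groups matches the textbook pooled-variance t test", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  res <- compare_dc_groups(a, b, paired = FALSE)
  # closed-form oracle
  sp2 <- (3 * stats::var(a) + 3 * stats::var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 6)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)

  # scale invariance of t
  res2 <- compare_dc_groups(10 * a, 10 * b, paired = FALSE)
  expect_equal(res2$t, res$t, tolerance = 1e-12)

  # identical paired samples: t = 0, p = 1
  resp <- compare_dc_groups(a, a, paired = TRUE)
  expect_equal(resp$t, 0)
  expect_equal(resp$p, 1)

  # zero variance, unequal means: flagged degenerate
  resd <- compare_dc_groups(c(1, 1, 1), c(2, 2, 2), paired = FALSE)
  expect_true(resd$degenerate)

  expect_error(compare_dc_groups(1, c(1, 2)), "n >= 2")
  expect_error(compare_dc_groups(c(1, 2), c(1, 2, 3), paired = TRUE), "equal-length")
})
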