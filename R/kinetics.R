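# Two-tissue irreversible compartment model for 13N-ammonia:
#   dC1/dt = K1 Ca(t) - (k2 + k3) C1,   dC2/dt = k3 C1,
#   measured(t) = (1 - v_b) (C1 + C2) + v_b Ca(t)
# with K1 reported as MBF (mL/min/g), k2/k3 in 1/min, activities in kBq/mL.
# The ODEs are solved on a fine uniform grid with an exponential integrator
# that is exact for piecewise-linear Ca, then duration-averaged per frame.

#' Kinetic parameter set
#'
#' @param K1 uptake rate, mL/min/g (reported as MBF).
#' @param k2 washout rate, 1/min.
#' @param k3 trapping rate, 1/min (no k4: irreversible trapping).
#' @param v_b fractional blood volume, [0, 1).
#' @return An object of class `mbf_kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, v_b) {
  if (any(c(K1, k2, k3, v_b) < 0) || v_b >= 1)
    stop("rates must be >= 0 and v_b in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, v_b = v_b),
            class = "mbf_kinetic_params")
}

#' @export
print.mbf_kinetic_params <- function(x, ...) {
  cat(sprintf("<mbf_kinetic_params> K1 = %.4g mL/min/g, k2 = %.4g, k3 = %.4g /min, v_b = %.3g\n",
              x$K1, x$k2, x$k3, x$v_b))
  invisible(x)
}

# fine-grid tissue curve; ca sampled at 0, dt, 2 dt, ... seconds.
# Exponential-integrator recursion (exact for piecewise-linear Ca), run in
# C++ — this is the innermost loop of every kinetic fit.
two_tissue_fine <- function(K1, k2, k3, v_b, ca, dt_s) {
  .cpp_two_tissue(ca, dt_s / 60, K1, k2, k3, v_b)
}

# accept an input function object, a bare function of t (s), or a measured
# arterial TAC (linearly interpolated through its frame mid-times, pinned to
# zero at t = 0); returns Ca on the fine grid
input_on_grid <- function(input, times) {
  if (is_input_function(input)) return(eval_input_function(input, times))
  if (is.function(input)) return(pmax(input(times), 0))
  if (is_tac(input)) {
    xs <- c(0, input$mid_s)
    ys <- c(0, input$activity)
    return(pmax(stats::approx(xs, ys, xout = times, rule = 2)$y, 0))
  }
  stop("unsupported input-function type: ", class(input)[1])
}

#' Frame-averaged tissue curve predicted by the model
#'
#' @param params an `mbf_kinetic_params`.
#' @param input arterial input: an `mbf_input_function`, a function of time
#'   (s), or a measured arterial `mbf_tac`.
#' @param schedule an `mbf_schedule`.
#' @param dt_s fine integration step, s.
#' @return An `mbf_tac` with source `"model"`.
#' @export
model_tissue_tac <- function(params, input, schedule, dt_s = 0.5) {
  if (!inherits(params, "mbf_kinetic_params")) stop("expected `mbf_kinetic_params`")
  stopifnot_schedule(schedule)
  tt <- fine_times(schedule, dt_s)
  ca <- input_on_grid(input, tt)
  ct <- two_tissue_fine(params$K1, params$k2, params$k3, params$v_b, ca, dt_s)
  tac_from_schedule(schedule, frame_average_fine(ct, dt_s, schedule),
                    source = "model")
}

#' Default fitting bounds and initial values
#'
#' Physiological envelope used by [fit_kinetics()]: K1 in [0, 6] mL/min/g,
#' k2 and k3 in [0, 3] /min, v_b in [0, 0.6]; initial values
#' (0.8, 0.3, 0.1, 0.3). Fixed constants so fits are deterministic.
#' @export
kinetic_fit_defaults <- function() {
  list(lower = c(K1 = 0, k2 = 0, k3 = 0, v_b = 0),
       upper = c(K1 = 6, k2 = 3, k3 = 3, v_b = 0.6),
       init = c(K1 = 0.8, k2 = 0.3, k3 = 0.1, v_b = 0.3))
}

# trapezoid frame-average operator: nframes x npts matrix so that
# frame_means = W %*% fine_curve (hot path for fitting)
frame_average_matrix <- function(schedule, dt_s, npts) {
  W <- matrix(0, nrow(schedule), npts)
  for (f in seq_len(nrow(schedule))) {
    i0 <- round(schedule$start[f] / dt_s) + 1L
    i1 <- min(round((schedule$start[f] + schedule$duration[f]) / dt_s) + 1L, npts)
    w <- rep(1, i1 - i0 + 1L)
    w[c(1L, length(w))] <- 0.5
    W[f, i0:i1] <- w / (i1 - i0)
  }
  W
}

#' Fit the two-tissue model to a measured TAC
#'
#' Bounded weighted least squares: minimizes
#' `sum(w_i (tac_i - model_i)^2)` over (K1, k2, k3, v_b) with L-BFGS-B,
#' optionally polished by Nelder-Mead. Default weights are proportional to
#' frame duration. Deterministic given data, init and bounds.
#' Non-convergence is flagged in the result, never silently dropped.
#'
#' @param roi_tac measured `mbf_tac`.
#' @param input arterial input (see [model_tissue_tac()]).
#' @param weights per-frame weights; default frame durations.
#' @param bounds list with `lower`/`upper` (see [kinetic_fit_defaults()]).
#' @param init named initial parameter vector.
#' @param fit_vb fit the blood fraction (default) or freeze it at its init.
#' @param polish run a Nelder-Mead polish after L-BFGS-B (tightest
#'   accuracy; disable for bulk profile fitting where L-BFGS-B alone is
#'   well within tolerance).
#' @param dt_s fine integration step, s.
#' @return A list of class `mbf_kinetic_fit`: `params`
#'   (`mbf_kinetic_params`), `residual_norm`, `converged`, `message`.
#' @export
fit_kinetics <- function(roi_tac, input, weights = NULL, bounds = NULL,
                         init = NULL, fit_vb = TRUE, polish = TRUE,
                         dt_s = 0.5) {
  if (!is_tac(roi_tac)) stop("expected `mbf_tac`")
  defs <- kinetic_fit_defaults()
  if (is.null(bounds)) bounds <- defs[c("lower", "upper")]
  if (is.null(init)) init <- defs$init
  if (is.null(weights)) weights <- roi_tac$duration_s
  if (length(weights) != length(roi_tac$activity))
    stop("weights must match the number of frames")
  schedule <- make_schedule(frames = cbind(roi_tac$mid_s - roi_tac$duration_s / 2,
                                           roi_tac$duration_s))
  tt <- fine_times(schedule, dt_s)
  ca <- input_on_grid(input, tt)
  y <- roi_tac$activity
  w <- weights / mean(weights)
  W <- frame_average_matrix(schedule, dt_s, length(tt))

  pred <- function(p) drop(W %*% two_tissue_fine(p[1], p[2], p[3], p[4], ca, dt_s))
  obj <- if (fit_vb) {
    function(p) sum(w * (y - pred(p))^2)
  } else {
    function(p3) sum(w * (y - pred(c(p3, init[["v_b"]])))^2)
  }
  lo <- bounds$lower
  hi <- bounds$upper
  p0 <- init
  if (!fit_vb) { lo <- lo[1:3]; hi <- hi[1:3]; p0 <- p0[1:3] }

  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  if (polish) {
    # gradient-free polish; L-BFGS-B can stall on the flat tail of the surface
    pol <- stats::optim(fit$par, function(p) {
      if (any(p < lo) || any(p > hi)) return(1e12)
      obj(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 600, reltol = 1e-14))
    if (pol$value < fit$value) fit <- pol
  }

  par <- pmin(pmax(fit$par, lo), hi)
  if (!fit_vb) par <- c(par, v_b = unname(init[["v_b"]]))
  params <- kinetic_params(par[[1]], par[[2]], par[[3]], par[[4]])
  structure(list(params = params,
                 residual_norm = sqrt(fit$value),
                 converged = fit$convergence == 0,
                 message = if (fit$convergence == 0) "converged" else
                   paste0("optimizer code ", fit$convergence)),
            class = "mbf_kinetic_fit")
}

#' Flow profile along a vessel
#'
#' Fits the kinetic model to every ROI TAC of a vessel ROI set and assembles
#' the MBF-vs profile: fitted K1 per ROI, ordered base to apex at the ROI
#' arc-length positions. ROI fits are independent; per-ROI failures are
#' flagged in the profile, the operation never aborts.
#'
#' @param roiset an `mbf_roiset` from [subtended_rois()].
#' @param series the dynamic series the TACs are read from.
#' @param input arterial input (typically [arterial_input_tac()] output).
#' @param ... passed to [fit_kinetics()].
#' @return A data.frame of class `mbf_flow_profile` with columns `position`,
#'   `mbf`, `k2`, `k3`, `v_b`, `residual`, `converged`, and attributes
#'   `vessel` and `state`.
#' @export
vessel_flow_profile <- function(roiset, series, input, ...) {
  if (!inherits(roiset, "mbf_roiset")) stop("expected `mbf_roiset`")
  if (!is_series(series)) stop("expected `mbf_series`")
  rows <- lapply(roiset$rois, function(roi) {
    f <- fit_kinetics(extract_tac(series, roi$voxels), input, ...)
    data.frame(position = roi$position, mbf = f$params$K1, k2 = f$params$k2,
               k3 = f$params$k3, v_b = f$params$v_b,
               residual = f$residual_norm, converged = f$converged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]   # base-to-apex regardless of processing order
  rownames(out) <- NULL
  flow_profile(out, vessel = roiset$vessel, state = series$state)
}

#' Construct a flow profile from its table
#'
#' @param df data.frame with at least `position` and `mbf`.
#' @param vessel,state profile labels.
#' @return A `mbf_flow_profile`.
#' @export
flow_profile <- function(df, vessel, state) {
  if (any(diff(df$position) <= 0)) stop("profile positions must be strictly increasing")
  if (any(df$mbf < 0)) stop("MBF values must be >= 0")
  structure(df, class = c("mbf_flow_profile", "data.frame"),
            vessel = vessel, state = state)
}

#' Interpolate a flow profile to a fine position grid
#'
#' Monotone-preserving piecewise-cubic (Fritsch-Carlson) interpolation
#' through the ROI values — the "continuous curve" drawn through the
#' per-ROI markers. Passes exactly through the ROI values.
#'
#' @param profile an `mbf_flow_profile` with >= 2 ROIs.
#' @param step_mm sampling step, mm.
#' @return data.frame with `position`, `value`.
#' @export
interpolate_profile <- function(profile, step_mm = 1) {
  if (nrow(profile) < 2L) stop("need >= 2 ROI values to interpolate")
  f <- stats::splinefun(profile$position, profile$mbf, method = "monoH.FC")
  pos <- seq(min(profile$position), max(profile$position), by = step_mm)
  if (pos[length(pos)] < max(profile$position))
    pos <- c(pos, max(profile$position))
  data.frame(position = pos, value = f(pos))
}
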