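#' Gamma-variate arterial input function
#'
#' Parameterizes the arterial blood concentration driving the kinetic model:
#' a gamma variate `Ca(t) = A (t - t0)^alpha exp(-(t - t0)/beta)` for
#' `t > t0` (zero before the bolus arrival `t0`), optionally with a slow
#' recirculation tail. The gamma part peaks at `t0 + alpha * beta`.
#'
#' @param amplitude scale `A`; units chosen so the curve is in kBq/mL. The
#'   default is set so the noise-free peak is 100 kBq/mL.
#' @param t0 bolus arrival delay, s.
#' @param alpha shape (> 0), unitless.
#' @param beta scale (> 0), s.
#' @param tail_fraction recirculation tail amplitude as a fraction of the
#'   bolus peak, in [0, 1).
#' @return An object of class `mbf_input_function`.
#' @export
input_function_params <- function(amplitude = NULL, t0 = 10, alpha = 3,
                                  beta = 8, tail_fraction = 0.15) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be > 0")
  if (tail_fraction < 0 || tail_fraction >= 1)
    stop("`tail_fraction` must be in [0, 1)")
  peak_raw <- (alpha * beta)^alpha * exp(-alpha)
  if (is.null(amplitude)) amplitude <- 100 / peak_raw  # 100 kBq/mL peak
  if (amplitude <= 0) stop("`amplitude` must be > 0")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta,
                 tail_fraction = tail_fraction),
            class = "mbf_input_function")
}

is_input_function <- function(x) inherits(x, "mbf_input_function")

#' Evaluate an arterial input function
#'
#' @param params an `mbf_input_function`.
#' @param times non-negative, increasing times, s.
#' @return Numeric vector `Ca(times)` in kBq/mL (zero for `t <= t0`).
#' @export
simulate_input_function <- function(params, times) {
  if (!is_input_function(params)) stop("expected `mbf_input_function`")
  times <- as.numeric(times)
  if (any(times < 0)) stop("`times` must be non-negative")
  if (any(diff(times) <= 0)) stop("`times` must be increasing")
  eval_input_function(params, times)
}

# vectorized evaluation without argument policing (internal hot path)
eval_input_function <- function(params, t) {
  u <- t - params$t0
  ca <- numeric(length(t))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    bolus <- params$amplitude * up^params$alpha * exp(-up / params$beta)
    if (params$tail_fraction > 0) {
      peak <- params$amplitude * (params$alpha * params$beta)^params$alpha *
        exp(-params$alpha)
      rise <- params$alpha * params$beta          # tail rises on the bolus scale
      tail <- params$tail_fraction * peak * (1 - exp(-up / rise)) *
        exp(-up / 1200)                           # slow clearance, ~20 min
      bolus <- bolus + tail
    }
    ca[pos] <- bolus
  }
  ca
}
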