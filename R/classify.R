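# Normal/abnormal classification of flow profiles against low-risk ranges
# and Dice-coefficient agreement between segmentation pipelines.

#' Build a per-position normal flow range from low-risk profiles
#'
#' Resamples each profile onto a common position grid (monotone cubic
#' interpolation) and takes `mean +/- k_sd * SD` per position, clipped below
#' at zero: the conventional band construction for a low-risk cohort.
#'
#' @param profiles list of `mbf_flow_profile`s, all with the same vessel and
#'   state labels.
#' @param k_sd band half-width in SD units (default 2).
#' @param step_mm common position grid step, mm.
#' @return A data.frame of class `mbf_normal_range` with columns `vessel`,
#'   `state`, `position`, `lower`, `upper`.
#' @export
build_normal_range <- function(profiles, k_sd = 2, step_mm = 4) {
  if (length(profiles) < 2L) stop("need >= 2 low-risk profiles")
  vessels <- vapply(profiles, function(p) attr(p, "vessel"), "")
  states <- vapply(profiles, function(p) attr(p, "state"), "")
  if (length(unique(vessels)) != 1L || length(unique(states)) != 1L)
    stop("profiles mix vessels or states: ",
         paste(unique(paste(vessels, states)), collapse = ", "))
  lo <- max(vapply(profiles, function(p) min(p$position), 0))
  hi <- min(vapply(profiles, function(p) max(p$position), 0))
  if (hi <= lo) stop("profiles share no common position span")
  pos <- seq(lo, hi, by = step_mm)
  vals <- vapply(profiles, function(p) {
    stats::splinefun(p$position, p$mbf, method = "monoH.FC")(pos)
  }, numeric(length(pos)))
  vals <- matrix(vals, nrow = length(pos))
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, stats::sd)
  structure(
    data.frame(vessel = vessels[1], state = states[1], position = pos,
               lower = pmax(mu - k_sd * sdv, 0), upper = mu + k_sd * sdv),
    class = c("mbf_normal_range", "data.frame"))
}

#' Read / write normal ranges as CSV
#'
#' Columns `vessel, state, position_mm, lower, upper`.
#' @param ranges one `mbf_normal_range` or a list of them (rbound on write).
#' @param path CSV path.
#' @export
write_normal_range <- function(ranges, path) {
  if (inherits(ranges, "mbf_normal_range")) ranges <- list(ranges)
  df <- do.call(rbind, lapply(ranges, function(r)
    data.frame(vessel = r$vessel, state = r$state, position_mm = r$position,
               lower = r$lower, upper = r$upper)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normal_range
#' @return A list of `mbf_normal_range`, one per vessel/state present.
#' @export
read_normal_range <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("vessel", "state", "position_mm", "lower", "upper")
  if (!all(need %in% names(tab)))
    stop("normal-range CSV needs columns ", paste(need, collapse = ","), ": ", path)
  split_tab <- split(tab, paste(tab$vessel, tab$state))
  lapply(split_tab, function(s) {
    s <- s[order(s$position_mm), ]
    if (any(s$lower > s$upper)) stop("normal range with lower > upper: ", path)
    structure(
      data.frame(vessel = s$vessel[1], state = s$state[1],
                 position = s$position_mm, lower = s$lower, upper = s$upper),
      class = c("mbf_normal_range", "data.frame"))
  })
}

#' Classify a flow profile against a normal range
#'
#' A ROI value is `abnormal` iff it falls strictly below the range's lower
#' bound at its position (bounds linearly interpolated between range
#' positions); values at the bound or above — including above the upper
#' bound — are `normal`. No extrapolation: profile positions outside the
#' range span are an error.
#'
#' @param profile an `mbf_flow_profile`.
#' @param range an `mbf_normal_range` for the same vessel and state.
#' @param provenance mask pedigree tag carried into the result.
#' @return A data.frame of class `mbf_classification` with `position`,
#'   `mbf`, `lower`, `label`; attributes `vessel`, `state`, `provenance`.
#' @export
classify_profile <- function(profile, range, provenance = "M") {
  if (!inherits(profile, "mbf_flow_profile")) stop("expected `mbf_flow_profile`")
  if (!inherits(range, "mbf_normal_range")) stop("expected `mbf_normal_range`")
  tol <- 1e-9
  if (min(profile$position) < min(range$position) - tol ||
      max(profile$position) > max(range$position) + tol)
    stop(sprintf("profile positions [%.1f, %.1f] mm outside the normal-range span [%.1f, %.1f] mm",
                 min(profile$position), max(profile$position),
                 min(range$position), max(range$position)))
  lower <- stats::approx(range$position, range$lower, xout = profile$position,
                         rule = 2)$y
  label <- ifelse(profile$mbf < lower - tol, "abnormal", "normal")
  structure(
    data.frame(position = profile$position, mbf = profile$mbf, lower = lower,
               label = label),
    class = c("mbf_classification", "data.frame"),
    vessel = attr(profile, "vessel"), state = attr(profile, "state"),
    provenance = provenance)
}

#' Dice agreement between two classification vectors
#'
#' Two readings of the Dice coefficient over normal/abnormal labels are
#' provided. `"matched-fraction"` (default): `DC = 2 m / (n_a + n_b)` where
#' `m` is the number of positions with identical labels — with equal
#' lengths this is the matched fraction `m / n`. `"abnormal-set"`:
#' classical set Dice over the abnormal index sets,
#' `2 |A and B| / (|A| + |B|)`, defined as 1 when both sets are empty.
#'
#' @param a,b `mbf_classification`s of equal length at matched positions,
#'   same vessel and state.
#' @param mode Dice variant.
#' @return A list of class `mbf_agreement`: `dc`, `n`, `matched`,
#'   `mismatched`, `n_abnormal_a`, `n_abnormal_b`, `mode`, `grouping`.
#' @export
dice_agreement <- function(a, b, mode = c("matched-fraction", "abnormal-set")) {
  mode <- match.arg(mode)
  for (x in list(a, b)) if (!inherits(x, "mbf_classification"))
    stop("expected `mbf_classification`")
  if (nrow(a) != nrow(b)) stop("classification vectors differ in length")
  if (max(abs(a$position - b$position)) > 1e-6)
    stop("classification vectors have mismatched positions")
  if (!identical(attr(a, "vessel"), attr(b, "vessel")) ||
      !identical(attr(a, "state"), attr(b, "state")))
    stop("classification vectors mix vessels or states")
  dc_from_labels(a$label, b$label, mode,
                 grouping = c(attr(a, "vessel"), attr(a, "state")))
}

# the arithmetic core, shared with pooling
dc_from_labels <- function(la, lb, mode, grouping = "global") {
  n <- length(la)
  m <- sum(la == lb)
  dc <- if (mode == "matched-fraction") {
    2 * m / (n + n)
  } else {
    A <- which(la == "abnormal")
    B <- which(lb == "abnormal")
    if (length(A) == 0L && length(B) == 0L) 1
    else 2 * length(intersect(A, B)) / (length(A) + length(B))
  }
  structure(list(dc = min(max(dc, 0), 1), n = n, matched = m,
                 mismatched = n - m,
                 n_abnormal_a = sum(la == "abnormal"),
                 n_abnormal_b = sum(lb == "abnormal"),
                 mode = mode, grouping = paste(grouping, collapse = "/")),
            class = "mbf_agreement")
}

#' @export
print.mbf_agreement <- function(x, ...) {
  cat(sprintf("<mbf_agreement> [%s, %s] DC = %.3f (n = %d, matched %d)\n",
              x$grouping, x$mode, x$dc, x$n, x$matched))
  invisible(x)
}

#' Pool classification agreement globally and per territory
#'
#' Recomputes the Dice coefficient over the concatenated ROI samples (never
#' a mean of per-vessel DCs): globally, and per vessel, with rest and
#' stress pooled separately.
#'
#' @param pairs list of classification pairs, each `list(a = , b = )` from
#'   [classify_profile()].
#' @param mode Dice variant, see [dice_agreement()].
#' @return data.frame with `group`, `state`, `n`, `dc`.
#' @export
pool_agreement <- function(pairs, mode = c("matched-fraction", "abnormal-set")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("no agreement results to pool")
  samples <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(vessel = attr(p$a, "vessel"), state = attr(p$a, "state"),
               la = p$a$label, lb = p$b$label)
  }))
  out <- list()
  for (st in unique(samples$state)) {
    sub <- samples[samples$state == st, ]
    out[[length(out) + 1L]] <- data.frame(
      group = "global", state = st, n = nrow(sub),
      dc = dc_from_labels(sub$la, sub$lb, mode)$dc)
    for (v in unique(sub$vessel)) {
      vs <- sub[sub$vessel == v, ]
      if (nrow(vs) == 0L) { warning("empty group ", v, "/", st); next }
      out[[length(out) + 1L]] <- data.frame(
        group = v, state = st, n = nrow(vs),
        dc = dc_from_labels(vs$la, vs$lb, mode)$dc)
    }
  }
  do.call(rbind, out)
}

#' Student's t test between two groups of Dice coefficients
#'
#' Two-sided; paired when the same vessels underlie both groups (e.g. the
#' two-user corrected-mask comparison), unpaired pooled-variance otherwise.
#' Degenerate inputs are handled explicitly: zero variance everywhere with
#' equal means reports `t = 0, p = 1`; zero variance with unequal means is
#' flagged.
#'
#' @param dc_a,dc_b numeric vectors of per-vessel DCs.
#' @param paired logical.
#' @return list with `t`, `p`, `paired`, `degenerate`.
#' @export
compare_dc_groups <- function(dc_a, dc_b, paired = FALSE) {
  dc_a <- as.numeric(dc_a)
  dc_b <- as.numeric(dc_b)
  if (length(dc_a) < 2L || length(dc_b) < 2L) stop("need n >= 2 per group")
  if (paired && length(dc_a) != length(dc_b))
    stop("paired comparison needs equal-length, vessel-matched groups")
  degenerate_var <- if (paired) stats::var(dc_a - dc_b) == 0 else
    (stats::var(dc_a) == 0 && stats::var(dc_b) == 0)
  if (degenerate_var) {
    equal <- if (paired) all(dc_a == dc_b) else mean(dc_a) == mean(dc_b)
    if (equal)
      return(list(t = 0, p = 1, paired = paired, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, paired = paired, degenerate = TRUE))
  }
  ht <- if (paired) stats::t.test(dc_a, dc_b, paired = TRUE) else
    stats::t.test(dc_a, dc_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, paired = paired,
       degenerate = FALSE)
}
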