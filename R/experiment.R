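# End-to-end mask-robustness experiment: simulate phantoms, fuse the dynamic
# PET with truth (M-role), automated-defect (FA-role) and corrected-defect
# (C-role) masks, extract per-vessel flow profiles, classify against
# low-risk ranges, and score agreement with Dice coefficients.

#' Experiment configuration
#'
#' Collects every knob of the mask-comparison experiment; fully
#' serializable, and re-running a stored config reproduces outputs
#' bit-identically.
#'
#' @param phantom an `mbf_phantom_spec`.
#' @param schedule_preset `"SNUH"` or `"SMC_CNUH"`.
#' @param input_fn an `mbf_input_function`.
#' @param n_phantoms simulated cases per arm.
#' @param n_lowrisk low-risk phantoms used to build the normal ranges
#'   (ignored when `normal_range` is supplied); 15 mirrors the low-risk
#'   cohort size behind the clinical ranges.
#' @param flow_cv between-phantom coefficient of variation of territory
#'   flows (population variability), unitless.
#' @param fa_spec,c_spec,c2_spec `mbf_perturbation_spec`s for the FA, C and
#'   (optional) second-user C masks.
#' @param vessels vessels to analyze.
#' @param roi_length_mm ROI edge/step, mm.
#' @param dc_mode Dice variant, see [dice_agreement()].
#' @param register run LV-to-LV rigid registration per arm; `mi_refine`
#'   adds the mutual-information stage.
#' @param mi_refine logical, see above.
#' @param k_sd normal-range half width, SD units.
#' @param normal_range optional precomputed list of `mbf_normal_range`
#'   (named `"<vessel> <state>"`), e.g. from a previous run.
#' @param lesion optional list(vessel, from_mm, to_mm, factor, state)
#'   applied to every main phantom.
#' @param seed master seed; all per-phantom seeds derive from it.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return list of class `mbf_experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              schedule_preset = "SNUH",
                              input_fn = input_function_params(),
                              n_phantoms = 10L, n_lowrisk = 15L,
                              flow_cv = 0.15,
                              fa_spec = perturbation_spec(apex_truncation_slices = 2L,
                                                          rv_dilation_mm = 6),
                              c_spec = perturbation_spec(apex_truncation_slices = 1L),
                              c2_spec = NULL,
                              vessels = c("LAD", "LCX", "rPDA"),
                              roi_length_mm = 4, dc_mode = "matched-fraction",
                              register = TRUE, mi_refine = FALSE,
                              k_sd = 2, normal_range = NULL, lesion = NULL,
                              seed = 1L, output_dir = NULL) {
  structure(list(phantom = phantom, schedule_preset = schedule_preset,
                 input_fn = input_fn, n_phantoms = as.integer(n_phantoms),
                 n_lowrisk = as.integer(n_lowrisk), flow_cv = flow_cv,
                 fa_spec = fa_spec, c_spec = c_spec, c2_spec = c2_spec,
                 vessels = vessels, roi_length_mm = roi_length_mm,
                 dc_mode = dc_mode, register = register,
                 mi_refine = mi_refine, k_sd = k_sd,
                 normal_range = normal_range, lesion = lesion,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "mbf_experiment_config")
}

identity_transform <- function() rigid_transform()

is_identity_transform <- function(tf) {
  max(abs(tf$angles_deg)) < 1e-9 && max(abs(tf$translation_mm)) < 1e-9
}

# nearest-neighbour mapping of CT-space masks into the PET grid under tf
transform_masks <- function(masks, tf, ref) {
  if (is_identity_transform(tf) && same_grid(masks$epi, ref)) return(masks)
  fixed_xyz <- all_voxel_world(ref)
  map1 <- function(m) {
    volume(array(render_mask(m, ref, tf, fixed_xyz), dim(ref$data)),
           ref$voxel_size, ref$origin, ref$direction)
  }
  anatomy_masks(map1(masks$lv), map1(masks$rv), map1(masks$epi),
                provenance = masks$provenance)
}

# scale per-territory truth flows by named multipliers (population spread)
scale_truth_flows <- function(truth, mult) {
  terr <- truth$territory$data
  for (st in names(truth$flow)) {
    fv <- truth$flow[[st]]$data
    for (i in seq_along(TERRITORIES))
      fv[terr == i] <- fv[terr == i] * mult[[TERRITORIES[i]]]
    truth$flow[[st]] <- volume(fv, truth$flow[[st]]$voxel_size,
                               truth$flow[[st]]$origin,
                               truth$flow[[st]]$direction)
  }
  truth
}

# one vessel's flow profile for one arm: fuse (optional), transform the
# centerline and masks, discretize, fit
arm_profile <- function(series, arm_masks, cl, config, tf) {
  cl_t <- transform_centerline(cl, tf)
  ref <- series_frame(series, 1L)
  masks_t <- transform_masks(arm_masks, tf, ref)
  ca <- arterial_input_tac(series, masks_t, erosion_mm = 4)
  roiset <- subtended_rois(cl_t, masks_t, roi_length_mm = config$roi_length_mm,
                           on_empty = "truncate")
  # bulk fitting: L-BFGS-B without polish at 1 s integration step is well
  # inside the per-ROI tolerance and ~5x faster
  vessel_flow_profile(roiset, series, ca, polish = FALSE, dt_s = 1)
}

# classification restricted to the positions covered by the range
classify_in_span <- function(profile, range, provenance) {
  keep <- profile$position >= min(range$position) - 1e-9 &
    profile$position <= max(range$position) + 1e-9
  classify_profile(flow_profile(profile[keep, , drop = FALSE],
                                attr(profile, "vessel"), attr(profile, "state")),
                   range, provenance = provenance)
}

align_classifications <- function(a, b) {
  common <- intersect(round(a$position, 6), round(b$position, 6))
  ia <- match(common, round(a$position, 6))
  ib <- match(common, round(b$position, 6))
  list(a = structure(a[ia, , drop = FALSE], class = class(a),
                     vessel = attr(a, "vessel"), state = attr(a, "state"),
                     provenance = attr(a, "provenance")),
       b = structure(b[ib, , drop = FALSE], class = class(b),
                     vessel = attr(b, "vessel"), state = attr(b, "state"),
                     provenance = attr(b, "provenance")))
}

#' Build normal ranges from simulated low-risk phantoms
#'
#' Simulates `n_lowrisk` lesion-free phantoms (territory flows jittered by
#' `flow_cv` around the spec values), extracts their flow profiles with
#' truth masks, and builds per-vessel/state `mean +/- k_sd SD` bands.
#'
#' @param config an `mbf_experiment_config`.
#' @return named list of `mbf_normal_range` (`"<vessel> <state>"`).
#' @export
build_lowrisk_ranges <- function(config) {
  schedule <- make_schedule(config$schedule_preset)
  truth0 <- generate_anatomy(config$phantom)
  cls <- lapply(config$vessels, function(v) generate_centerline(truth0, v))
  names(cls) <- config$vessels
  seeds <- with_seed(config$seed * 7L + 1L,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       config$n_lowrisk * 3L),
                            ncol = 3L))
  profiles <- list()
  for (i in seq_len(config$n_lowrisk)) {
    mult <- with_seed(seeds[i, 1],
                      pmax(stats::rnorm(3, 1, config$flow_cv), 0.3))
    names(mult) <- TERRITORIES
    truth <- scale_truth_flows(truth0, mult)
    for (st in c("rest", "stress")) {
      series <- simulate_dynamic_pet(truth, config$input_fn, schedule,
                                     state = st,
                                     seed = seeds[i, if (st == "rest") 2L else 3L])
      for (v in config$vessels) {
        pr <- arm_profile(series, truth$masks, cls[[v]], config,
                          identity_transform())
        profiles[[paste(v, st)]] <- c(profiles[[paste(v, st)]], list(pr))
      }
    }
  }
  lapply(profiles, build_normal_range, k_sd = config$k_sd,
         step_mm = config$roi_length_mm)
}

#' Run the mask-comparison experiment
#'
#' For each simulated phantom and state, fuses the dynamic PET with truth
#' masks (M role) and with FA-, C- (and optionally second-user C2-)
#' perturbed masks, extracts per-vessel MBF profiles, classifies them
#' against the low-risk ranges and scores agreement with Dice
#' coefficients — globally, per territory and per state — plus the paired
#' t-test comparisons. Fully reproducible from the config seed.
#'
#' @param config an `mbf_experiment_config`.
#' @return list of class `mbf_experiment_report`: `per_vessel` (data.frame:
#'   phantom, vessel, state, pair, dc, n), `pooled` (per pair), `tests`,
#'   `failures`, `normal_range`, `config`.
#' @export
run_mask_comparison_experiment <- function(config) {
  if (!inherits(config, "mbf_experiment_config"))
    stop("expected `mbf_experiment_config`")
  schedule <- make_schedule(config$schedule_preset)
  truth0 <- generate_anatomy(config$phantom)
  cls <- lapply(config$vessels, function(v) generate_centerline(truth0, v))
  names(cls) <- config$vessels

  ranges <- config$normal_range
  if (is.null(ranges)) ranges <- build_lowrisk_ranges(config)

  arms <- c("FA", "C", if (!is.null(config$c2_spec)) "C2")
  seeds <- with_seed(config$seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       config$n_phantoms * 6L),
                            ncol = 6L))
  per_vessel <- list()
  samples <- list()
  failures <- list()

  for (i in seq_len(config$n_phantoms)) {
    mult <- with_seed(seeds[i, 1],
                      pmax(stats::rnorm(3, 1, config$flow_cv), 0.3))
    names(mult) <- TERRITORIES
    truth <- scale_truth_flows(truth0, mult)
    if (!is.null(config$lesion)) {
      le <- config$lesion
      truth <- apply_lesion(truth, cls[[le$vessel]], le$from_mm, le$to_mm,
                            le$factor, state = le$state %||% "stress")
    }
    arm_masks <- list(M = truth$masks)
    pspec <- config$fa_spec
    pspec$seed <- seeds[i, 4]
    arm_masks$FA <- perturb_masks(truth$masks, pspec, provenance = "FA")
    pspec <- config$c_spec
    pspec$seed <- seeds[i, 5]
    arm_masks$C <- perturb_masks(truth$masks, pspec, provenance = "C")
    if (!is.null(config$c2_spec)) {
      pspec <- config$c2_spec
      pspec$seed <- seeds[i, 6]
      arm_masks$C2 <- perturb_masks(truth$masks, pspec, provenance = "C")
    }

    for (st in c("rest", "stress")) {
      series <- simulate_dynamic_pet(truth, config$input_fn, schedule,
                                     state = st,
                                     seed = seeds[i, if (st == "rest") 2L else 3L])
      psum <- if (config$register) pet_sum(series) else NULL
      lv_pet <- if (config$register) segment_lv_from_pet(psum) else NULL
      tfs <- lapply(arm_masks, function(m) {
        if (!config$register) return(identity_transform())
        tf <- register_rigid_lv(lv_pet, fill_holes(m$epi))
        if (config$mi_refine) tf <- refine_mutual_information(psum, m, tf)
        tf
      })
      for (v in config$vessels) {
        res <- tryCatch({
          cl_m <- lapply(names(arm_masks), function(a)
            classify_in_span(arm_profile(series, arm_masks[[a]], cls[[v]],
                                         config, tfs[[a]]),
                             ranges[[paste(v, st)]], provenance = a))
          names(cl_m) <- names(arm_masks)
          cl_m
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(phantom = i, vessel = v, state = st,
                       message = conditionMessage(res))
          next
        }
        for (arm in arms) {
          al <- align_classifications(res$M, res[[arm]])
          ag <- dice_agreement(al$a, al$b, mode = config$dc_mode)
          per_vessel[[length(per_vessel) + 1L]] <-
            data.frame(phantom = i, vessel = v, state = st, pair = arm,
                       dc = ag$dc, n = ag$n)
          samples[[length(samples) + 1L]] <-
            data.frame(phantom = i, vessel = v, state = st, pair = arm,
                       la = al$a$label, lb = al$b$label)
        }
      }
    }
  }

  per_vessel <- if (length(per_vessel)) do.call(rbind, per_vessel) else
    data.frame(phantom = integer(), vessel = character(), state = character(),
               pair = character(), dc = numeric(), n = integer())
  samples <- if (length(samples)) do.call(rbind, samples) else NULL

  pooled <- NULL
  if (!is.null(samples)) {
    pooled <- do.call(rbind, lapply(split(samples, samples$pair), function(sub) {
      rows <- lapply(split(sub, sub$state), function(ss) {
        g <- data.frame(pair = ss$pair[1], group = "global", state = ss$state[1],
                        n = nrow(ss),
                        dc = dc_from_labels(ss$la, ss$lb, config$dc_mode)$dc)
        pv <- do.call(rbind, lapply(split(ss, ss$vessel), function(sv)
          data.frame(pair = sv$pair[1], group = sv$vessel[1], state = sv$state[1],
                     n = nrow(sv),
                     dc = dc_from_labels(sv$la, sv$lb, config$dc_mode)$dc)))
        rbind(g, pv)
      })
      do.call(rbind, rows)
    }))
    rownames(pooled) <- NULL
  }

  tests <- list()
  fa <- per_vessel[per_vessel$pair == "FA", ]
  cc <- per_vessel[per_vessel$pair == "C", ]
  key <- function(df) paste(df$phantom, df$vessel, df$state)
  common <- intersect(key(fa), key(cc))
  if (length(common) >= 2L)
    tests$fa_vs_c <- compare_dc_groups(fa$dc[match(common, key(fa))],
                                       cc$dc[match(common, key(cc))],
                                       paired = TRUE)
  if (!is.null(config$c2_spec)) {
    c2 <- per_vessel[per_vessel$pair == "C2", ]
    common2 <- intersect(key(cc), key(c2))
    if (length(common2) >= 2L)
      tests$c1_vs_c2 <- compare_dc_groups(cc$dc[match(common2, key(cc))],
                                          c2$dc[match(common2, key(c2))],
                                          paired = TRUE)
  }

  report <- structure(list(per_vessel = per_vessel, pooled = pooled,
                           tests = tests,
                           failures = if (length(failures))
                             do.call(rbind, failures) else NULL,
                           normal_range = ranges, config = config),
                      class = "mbf_experiment_report")
  if (!is.null(config$output_dir)) write_experiment_report(report, config$output_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mbf_experiment_report <- function(x, ...) {
  cat("<mbf_experiment_report>\n")
  if (!is.null(x$pooled)) {
    cat("pooled Dice coefficients:\n")
    print(x$pooled, row.names = FALSE)
  }
  if (!is.null(x$failures))
    cat(nrow(x$failures), "vessel analyses failed\n")
  invisible(x)
}

# stage to a temp dir, then rename: no partial output trees on failure
write_experiment_report <- function(report, output_dir) {
  stage <- paste0(output_dir, ".staging")
  if (dir.exists(stage)) unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  utils::write.csv(report$per_vessel, file.path(stage, "per_vessel_dc.csv"),
                   row.names = FALSE)
  if (!is.null(report$pooled))
    utils::write.csv(report$pooled, file.path(stage, "pooled_dc.csv"),
                     row.names = FALSE)
  write_normal_range(report$normal_range, file.path(stage, "normal_ranges.csv"))
  jsonlite::write_json(
    list(tests = report$tests,
         seed = report$config$seed,
         n_phantoms = report$config$n_phantoms,
         failures = if (is.null(report$failures)) 0L else nrow(report$failures)),
    file.path(stage, "summary.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(serialize_config(report$config), file.path(stage, "config.yaml"))
  if (dir.exists(output_dir)) unlink(output_dir, recursive = TRUE)
  file.rename(stage, output_dir)
  invisible(output_dir)
}

# plain-list view of a config for YAML round-trips (named vectors become
# maps, otherwise yaml drops their names)
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (!is.null(names(x))) return(as.list(x))
    x
  }
  strip(config[setdiff(names(config), "normal_range")])
}

#' Load an experiment config from YAML
#'
#' Reconstructs an `mbf_experiment_config` from the file written alongside
#' experiment outputs (or hand-written with the same keys).
#' @param path YAML path.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  spec <- phantom_spec(grid_shape = unlist(ph$grid_shape),
                       voxel_size = ph$voxel_size, lv_radius = ph$lv_radius,
                       rv_radius = ph$rv_radius,
                       wall_thickness = ph$wall_thickness,
                       apex_extent = ph$apex_extent,
                       flow_rest = unlist(ph$flow_rest),
                       flow_stress = unlist(ph$flow_stress),
                       k2 = ph$k2, k3 = ph$k3,
                       blood_fraction = ph$blood_fraction,
                       noise_scale = ph$noise_scale, seed = ph$seed)
  mk_pspec <- function(p) if (is.null(p)) NULL else
    perturbation_spec(p$apex_truncation_slices, p$rv_dilation_mm,
                      p$boundary_jitter_mm, p$septal_merge, p$seed)
  inp <- y$input_fn
  experiment_config(
    phantom = spec, schedule_preset = y$schedule_preset,
    input_fn = input_function_params(inp$amplitude, inp$t0, inp$alpha,
                                     inp$beta, inp$tail_fraction),
    n_phantoms = y$n_phantoms, n_lowrisk = y$n_lowrisk, flow_cv = y$flow_cv,
    fa_spec = mk_pspec(y$fa_spec), c_spec = mk_pspec(y$c_spec),
    c2_spec = mk_pspec(y$c2_spec), vessels = unlist(y$vessels),
    roi_length_mm = y$roi_length_mm, dc_mode = y$dc_mode,
    register = y$register, mi_refine = y$mi_refine, k_sd = y$k_sd,
    lesion = y$lesion, seed = y$seed, output_dir = y$output_dir)
}
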