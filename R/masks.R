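#' Biventricular anatomy masks
#'
#' Bundles the three co-registered binary volumes that define the heart
#' anatomy: LV blood pool, RV blood pool and the biventricular epicardial
#' envelope (EPI). The myocardium is EPI minus the blood pools. Invariants
#' (binary values, LV/RV disjoint, blood pools contained in EPI, non-empty
#' myocardium, shared grid) are checked on construction — and therefore on
#' load — not assumed.
#'
#' @param lv,rv,epi binary `mbf_volume`s on one shared grid.
#' @param provenance mask pedigree tag: `"M"` (manual / phantom truth),
#'   `"FA"` (fully automated) or `"C"` (corrected automated).
#' @return An object of class `mbf_masks`.
#' @export
anatomy_masks <- function(lv, rv, epi, provenance = c("M", "FA", "C")) {
  provenance <- match.arg(provenance)
  for (m in list(lv, rv, epi)) {
    stopifnot_volume(m)
    if (!is_binary_data(m$data)) stop("masks must be strictly 0/1")
  }
  if (!same_grid(lv, rv) || !same_grid(lv, epi))
    stop("LV, RV and EPI masks must share one grid")
  if (any(lv$data & rv$data)) stop("LV and RV masks overlap")
  if (any(lv$data & !epi$data)) stop("LV mask not contained in EPI")
  if (any(rv$data & !epi$data)) stop("RV mask not contained in EPI")
  if (!any(epi$data & !lv$data & !rv$data)) stop("myocardium (EPI \\ blood pools) is empty")
  structure(list(lv = lv, rv = rv, epi = epi, provenance = provenance),
            class = "mbf_masks")
}

is_masks <- function(x) inherits(x, "mbf_masks")

#' @export
print.mbf_masks <- function(x, ...) {
  cat(sprintf("<mbf_masks> [%s] LV %d, RV %d, EPI %d voxels (myocardium %d)\n",
              x$provenance, sum(x$lv$data), sum(x$rv$data), sum(x$epi$data),
              sum(myocardium_mask(x)$data)))
  invisible(x)
}

#' Myocardium mask (EPI minus blood pools)
#'
#' @param masks an `mbf_masks`.
#' @return A binary `mbf_volume`.
#' @export
myocardium_mask <- function(masks) {
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  volume((masks$epi$data & !masks$lv$data & !masks$rv$data) + 0,
         masks$epi$voxel_size, masks$epi$origin, masks$epi$direction)
}
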