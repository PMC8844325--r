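# Minimal NIfTI-1 I/O. No NIfTI reader ships with the supported R stack, so
# the format is handled directly: single-file .nii / .nii.gz, little- or
# big-endian on read, datatypes uint8/int16/int32/float32/float64, sform (or
# pixdim fallback) geometry restricted to signed-permutation orientations in
# line with the volume model. Written files are little-endian float32
# (intensity) or uint8 (masks) with sform_code 1.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3D (or 4D) NIfTI-1 volume
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask logical; validate strict 0/1 voxel values after load.
#' @return An `mbf_volume`, or a plain list(data = 4D array, voxel_size,
#'   origin, direction) when the file has 4 dimensions.
#' @export
read_volume <- function(path, mask = FALSE) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    if (sz == 1543503872L) endian <- "big"  # 348 with swapped byte order
    else stop("not a NIfTI-1 file (sizeof_hdr = ", sz, "): ", path)
  }
  hdr_rest <- readBin(con, "raw", 344L)
  rd <- function(what, n, size, off) {
    # offset relative to full header start; we already consumed 4 bytes
    readBin(hdr_rest[(off - 4 + 1):length(hdr_rest)], what, n, size = size,
            endian = endian)
  }
  dims <- rd("integer", 8L, 2L, 40L)
  ndim <- dims[1]
  if (!(ndim %in% c(3L, 4L))) stop("unsupported NIfTI dimensionality (dim[0] = ", ndim, "): ", path)
  datatype <- rd("integer", 1L, 2L, 70L)
  pixdim <- rd("numeric", 8L, 4L, 76L)
  vox_offset <- rd("numeric", 1L, 4L, 108L)
  scl_slope <- rd("numeric", 1L, 4L, 112L)
  scl_inter <- rd("numeric", 1L, 4L, 116L)
  sform_code <- rd("integer", 1L, 2L, 254L)
  srow <- rbind(rd("numeric", 4L, 4L, 280L), rd("numeric", 4L, 4L, 296L),
                rd("numeric", 4L, 4L, 312L))
  nxyz <- dims[2:4]
  nt <- if (ndim == 4L) dims[5] else 1L
  nvox <- prod(nxyz) * nt
  skip <- vox_offset - 348   # 348 header bytes consumed so far
  if (skip > 0) readBin(con, "raw", skip)
  reader <- switch(as.character(datatype),
    "2" = function(n) as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian)),
    "4" = function(n) as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "8" = function(n) as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16" = function(n) readBin(con, "numeric", n, size = 4L, endian = endian),
    "64" = function(n) readBin(con, "numeric", n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, ": ", path))
  vals <- reader(nvox)
  if (length(vals) != nvox) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (sform_code > 0L) {
    voxel_size <- sqrt(colSums(srow[, 1:3]^2))
    if (any(voxel_size <= 0)) stop("invalid sform voxel sizes: ", path)
    direction <- sweep(srow[, 1:3], 2L, voxel_size, "/")
    direction <- tryCatch(check_direction(direction),
      error = function(e) stop("oblique NIfTI orientation unsupported (field srow): ", path))
    origin <- srow[, 4]
  } else {
    voxel_size <- pixdim[2:4]
    if (any(voxel_size <= 0)) stop("invalid pixdim voxel sizes (field pixdim): ", path)
    direction <- diag(3)
    origin <- c(0, 0, 0)
  }
  if (ndim == 4L) {
    arr <- array(vals, c(nxyz, nt))
    return(list(data = arr, voxel_size = voxel_size, origin = origin,
                direction = direction))
  }
  arr <- array(vals, nxyz)
  if (mask && !is_binary_data(arr))
    stop("mask volume contains non-binary values: ", path)
  volume(arr, voxel_size, origin, direction)
}

write_nifti_raw <- function(path, arr, voxel_size, origin, direction, datatype) {
  dims <- dim(arr)
  ndim <- length(dims)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer") writeBin(x, con, size = size, endian = "little")
  dimfield <- integer(8L)
  dimfield[1] <- ndim
  dimfield[1 + seq_along(dims)] <- dims
  dimfield[dimfield == 0L] <- 1L
  bitpix <- c("2" = 8L, "4" = 16L, "8" = 32L, "16" = 32L, "64" = 64L)[as.character(datatype)]
  pixdim <- c(1, voxel_size, if (ndim == 4L) 1 else numeric(0))
  pixdim <- c(pixdim, rep(0, 8 - length(pixdim)))
  srow <- cbind(direction %*% diag(voxel_size), origin)

  w(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                       # data_type..dim_info (10+18+4+2+1+1)
  w(as.integer(dimfield), 2L)                   # dim[8]
  writeBin(raw(14L), con)                       # intent_p1..intent_code
  w(as.integer(datatype), 2L)                   # datatype
  w(bitpix, 2L)                                 # bitpix
  w(0L, 2L)                                     # slice_start
  writeBin(as.numeric(pixdim), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(352, 1, 0)), con, size = 4L, endian = "little") # vox_offset, scl_slope, scl_inter
  writeBin(raw(4L), con)                        # slice_end(2) slice_code(1) xyzt_units(1)
  writeBin(raw(128L), con)                      # cal_max..glmin (24), descrip (80), aux_file (24)
  w(0L, 2L)                                     # qform_code
  w(1L, 2L)                                     # sform_code
  writeBin(as.numeric(rep(0, 6)), con, size = 4L, endian = "little") # quatern b,c,d + qoffset x,y,z
  writeBin(as.numeric(t(srow)), con, size = 4L, endian = "little")   # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                        # extension flag
  vals <- as.numeric(arr)
  if (datatype == NIFTI_DT$uint8) {
    writeBin(as.integer(vals), con, size = 1L, endian = "little")
  } else if (datatype == NIFTI_DT$float32) {
    writeBin(vals, con, size = 4L, endian = "little")
  } else if (datatype == NIFTI_DT$float64) {
    writeBin(vals, con, size = 8L, endian = "little")
  } else stop("unsupported write datatype ", datatype)
  invisible(path)
}

#' Write a volume as NIfTI-1
#'
#' Binary masks are stored as uint8, everything else as float64 so values
#' round-trip losslessly.
#'
#' @param vol an `mbf_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  dt <- if (is_binary_data(vol$data)) NIFTI_DT$uint8 else NIFTI_DT$float64
  write_nifti_raw(path, vol$data, vol$voxel_size, vol$origin, vol$direction, dt)
  invisible(path)
}

#' Read / write a dynamic series (4D NIfTI + schedule CSV)
#'
#' The schedule travels in a sidecar CSV with columns `start_s,duration_s`;
#' frame count must match the 4th NIfTI dimension.
#'
#' @param path 4D NIfTI path.
#' @param schedule_path sidecar CSV path; defaults to `path` with the NIfTI
#'   extension replaced by `_schedule.csv`.
#' @param state `"rest"` or `"stress"`.
#' @return An `mbf_series`.
#' @export
read_series <- function(path, schedule_path = NULL, state = c("rest", "stress")) {
  state <- match.arg(state)
  if (is.null(schedule_path))
    schedule_path <- sub("\\.nii(\\.gz)?$", "_schedule.csv", path)
  raw <- read_volume(path)
  if (is_volume(raw)) stop("expected a 4D NIfTI series, got a 3D volume: ", path)
  tab <- utils::read.csv(schedule_path)
  if (!all(c("start_s", "duration_s") %in% names(tab)))
    stop("schedule CSV needs columns start_s,duration_s: ", schedule_path)
  sched <- make_schedule(frames = tab[, c("start_s", "duration_s")])
  dynamic_series(raw$data, sched, raw$voxel_size, raw$origin, raw$direction,
                 state = state)
}

#' @rdname read_series
#' @param series an `mbf_series` to write.
#' @export
write_series <- function(series, path, schedule_path = NULL) {
  if (!is_series(series)) stop("expected an `mbf_series`")
  if (is.null(schedule_path))
    schedule_path <- sub("\\.nii(\\.gz)?$", "_schedule.csv", path)
  write_nifti_raw(path, series$data, series$voxel_size, series$origin,
                  series$direction, NIFTI_DT$float64)
  utils::write.csv(
    data.frame(start_s = series$schedule$start,
               duration_s = series$schedule$duration),
    schedule_path, row.names = FALSE)
  invisible(path)
}

#' Read / write anatomy masks as three NIfTI files
#'
#' @param lv_path,rv_path,epi_path per-structure NIfTI paths.
#' @param provenance mask pedigree tag, see [anatomy_masks()].
#' @return An `mbf_masks` (invariants validated on load).
#' @export
read_masks <- function(lv_path, rv_path, epi_path, provenance = "M") {
  anatomy_masks(read_volume(lv_path, mask = TRUE),
                read_volume(rv_path, mask = TRUE),
                read_volume(epi_path, mask = TRUE),
                provenance = provenance)
}

#' @rdname read_masks
#' @param masks an `mbf_masks` to write.
#' @export
write_masks <- function(masks, lv_path, rv_path, epi_path) {
  if (!is_masks(masks)) stop("expected `mbf_masks`")
  write_volume(masks$lv, lv_path)
  write_volume(masks$rv, rv_path)
  write_volume(masks$epi, epi_path)
  invisible(NULL)
}
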