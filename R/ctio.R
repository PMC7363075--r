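#' @useDynLib nctstroke, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Containers ------------------------------------------------------------
#
# Volumes are plain 3D arrays indexed (z, y, x), z ascending, wrapped in
# light S3 objects that carry per-axis spacing in millimetres.  Masks share
# their volume's grid.

#' Construct a CT volume
#'
#' Wraps a 3D array of Hounsfield-unit values indexed `(z, y, x)` together
#' with voxel spacing and a subject identifier.
#'
#' @param voxels 3D numeric array of HU values, dimension `(nz, ny, nx)`.
#' @param spacing Numeric length-3 vector, mm per axis `(z, y, x)`.  The z
#'   entry may instead be a vector of per-slice thicknesses (mixed-thickness
#'   scans), given as the `z_thickness` attribute; see `assemble_volume()`.
#' @param subject_id Character subject identifier.
#' @param z_thickness Optional numeric vector of per-slice thicknesses (mm),
#'   length `nz`.  Defaults to `rep(spacing[1], nz)`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, subject_id = "subject",
                      z_thickness = NULL) {
  stopifnot(length(dim(voxels)) == 3)
  if (any(spacing <= 0)) stop("spacing entries must be > 0")
  if (any(!is.finite(voxels))) stop("all voxel values must be finite")
  if (is.null(z_thickness)) z_thickness <- rep(spacing[1], dim(voxels)[1])
  if (any(z_thickness <= 0)) stop("slice thicknesses must be > 0")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 z_thickness = as.numeric(z_thickness),
                 subject_id = subject_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume %s: %d x %d x %d (z,y,x), spacing %s mm, HU [%.0f, %.0f]>\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a normalized volume
#'
#' Unitless intensities in `[0, 1]` with a provenance link to the source
#' CT volume (subject id and spacing are inherited).
#'
#' @param voxels 3D numeric array with values in `[0, 1]`.
#' @param source A `ct_volume` the values derive from.
#' @return An object of class `normalized_volume`.
#' @export
normalized_volume <- function(voxels, source) {
  if (min(voxels) < 0 || max(voxels) > 1)
    stop("normalized values must lie in [0, 1]")
  structure(list(voxels = voxels, spacing = source$spacing,
                 z_thickness = source$z_thickness,
                 subject_id = source$subject_id),
            class = "normalized_volume")
}

#' Construct a segmentation mask
#'
#' Binary grid aligned to a volume (cavity, proposal, or lesion ground
#' truth).
#'
#' @param voxels 3D array coercible to 0/1.
#' @param spacing mm per axis `(z, y, x)`.
#' @param z_thickness Optional per-slice thickness vector.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, spacing, z_thickness = NULL) {
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (is.null(z_thickness)) z_thickness <- rep(spacing[1], dim(v)[1])
  structure(list(voxels = v, spacing = as.numeric(spacing),
                 z_thickness = as.numeric(z_thickness)),
            class = "seg_mask")
}

mask_like <- function(vol, voxels) seg_mask(voxels, vol$spacing, vol$z_thickness)

# Assembly ---------------------------------------------------------------

#' Assemble axial slices into a CT volume
#'
#' Slices are sorted by ascending z position; per-slice thickness is derived
#' from consecutive z gaps (scans mixing e.g. 3 mm and 6 mm slices keep the
#' per-slice values).  The last slice inherits the final gap; a single slice
#' takes `default_thickness`.
#'
#' @param slices List of equally shaped 2D matrices of HU values `(y, x)`.
#' @param z_positions Numeric vector of slice z coordinates (mm), one per
#'   slice, distinct.
#' @param spacing_yx In-plane spacing (mm), length 2.
#' @param subject_id Subject identifier.
#' @param default_thickness Thickness used when only one slice is given.
#' @return A `ct_volume` with slices in ascending z order.
#' @export
assemble_volume <- function(slices, z_positions, spacing_yx = c(1, 1),
                            subject_id = "subject", default_thickness = 5) {
  if (length(slices) != length(z_positions))
    stop("one z position per slice is required")
  if (anyDuplicated(z_positions)) stop("duplicate z positions")
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stop("inconsistent in-plane shapes")
  ord <- order(z_positions)
  z <- z_positions[ord]
  vox <- array(0, c(length(slices), shp[1], shp[2]))
  for (i in seq_along(ord)) vox[i, , ] <- slices[[ord[i]]]
  if (length(z) > 1) {
    gaps <- diff(z)
    thick <- c(gaps, gaps[length(gaps)])
  } else thick <- default_thickness
  ct_volume(vox, c(stats::median(thick), spacing_yx), subject_id,
            z_thickness = thick)
}

# Windowing --------------------------------------------------------------

#' Clip and normalize Hounsfield units
#'
#' Applies the 0--80 HU stroke window: values are clamped to `[0, 80]` and
#' divided by 80, giving unitless intensities in `[0, 1]`.
#'
#' @param volume A `ct_volume` (or bare numeric array of HU values).
#' @param hu_min,hu_max Window limits in HU.
#' @return A `normalized_volume` (or bare array if the input was bare).
#' @export
clip_normalize <- function(volume, hu_min = 0, hu_max = 80) {
  f <- function(v) pmin(pmax(v, hu_min), hu_max) / hu_max
  if (inherits(volume, "ct_volume")) {
    v <- volume$voxels
    out <- array(f(v), dim = dim(v))
    normalized_volume(out, volume)
  } else {
    array(f(volume), dim = dim(volume))
  }
}

# Midline alignment ------------------------------------------------------

rotate_volume_inplane <- function(vox, angle, bilinear = TRUE, fill = 0) {
  out <- vox
  for (z in seq_len(dim(vox)[1]))
    out[z, , ] <- cpp_rotate2d(vox[z, , ], angle, as.integer(bilinear), fill)
  out
}

mirror_dice <- function(mask_vox) {
  m <- mask_vox
  flipped <- m[, , rev(seq_len(dim(m)[3]))]
  s <- sum(m) + sum(flipped)
  if (s == 0) return(1)
  2 * sum(m & flipped) / s
}

#' Estimate and apply midline alignment
#'
#' Estimates a single in-plane rotation that makes the head left-right
#' symmetric and applies it to the volume and the cavity mask.  The angle is
#' found by grid search over `angle_range` at `step` degrees, maximising the
#' Dice overlap between the rotated cavity mask and its horizontal mirror;
#' ties break toward the smaller absolute angle.  Intensities are rotated
#' with bilinear interpolation, masks with nearest neighbour, each applied
#' once to the original grid.
#'
#' @param volume A `ct_volume` or `normalized_volume`.
#' @param cavity A non-empty `seg_mask` aligned with `volume`.
#' @param angle_range Search interval in degrees.
#' @param step Grid step in degrees.
#' @param fill Fill value for intensities sampled outside the grid
#'   (defaults to air after windowing: 0).
#' @return List with `volume`, `cavity` (both rotated) and `angle`, the
#'   applied correction in degrees.
#' @export
align_midline <- function(volume, cavity, angle_range = c(-30, 30),
                          step = 0.5, fill = 0) {
  if (sum(cavity$voxels) == 0) stop("cavity mask is empty; cannot align")
  angles <- seq(angle_range[1], angle_range[2], by = step)
  # prefer smaller |angle| on ties: evaluate in order of |angle|
  angles <- angles[order(abs(angles), angles)]
  # score the symmetry objective on a central slab (up to 8 slices); the
  # chosen rotation is applied to the full volume
  nz <- dim(cavity$voxels)[1]
  zsel <- if (nz > 8) round(seq(nz * 0.25, nz * 0.75, length.out = 8)) else
    seq_len(nz)
  slab <- cavity$voxels[zsel, , , drop = FALSE]
  best <- -Inf; best_a <- 0
  for (a in angles) {
    rot <- rotate_volume_inplane(slab, a, bilinear = FALSE)
    d <- mirror_dice(rot)
    if (d > best + 1e-12) { best <- d; best_a <- a }
  }
  vox <- rotate_volume_inplane(volume$voxels, best_a, bilinear = TRUE,
                               fill = fill)
  cav <- rotate_volume_inplane(cavity$voxels, best_a, bilinear = FALSE)
  out_vol <- volume
  out_vol$voxels <- vox
  out_cav <- cavity
  out_cav$voxels <- array(as.integer(cav != 0), dim(cav))
  list(volume = out_vol, cavity = out_cav, angle = best_a)
}

# Cropping ---------------------------------------------------------------

#' Crop air background around the cranial cavity
#'
#' Returns the tightest axis-aligned box containing the cavity mask, expanded
#' in-plane by `margin` voxels (clamped to the grid), together with the
#' offset mapping cropped coordinates back to the original grid.
#'
#' @param volume A `ct_volume` or `normalized_volume`.
#' @param cavity Non-empty `seg_mask`.
#' @param masks Optional named list of further `seg_mask` objects cropped
#'   identically.
#' @param margin In-plane margin in voxels (z margin is 0).
#' @return List with `volume`, `cavity`, `masks`, and `offset` (0-based
#'   `(z, y, x)` of the crop origin in the original grid).
#' @export
crop_background <- function(volume, cavity, masks = list(), margin = 2) {
  cv <- cavity$voxels
  if (sum(cv) == 0) stop("cavity mask is empty; cannot crop")
  idx <- which(cv != 0, arr.ind = TRUE)
  d <- dim(cv)
  z0 <- min(idx[, 1]); z1 <- max(idx[, 1])
  y0 <- max(1, min(idx[, 2]) - margin); y1 <- min(d[2], max(idx[, 2]) + margin)
  x0 <- max(1, min(idx[, 3]) - margin); x1 <- min(d[3], max(idx[, 3]) + margin)
  crop <- function(v) v[z0:z1, y0:y1, x0:x1, drop = FALSE]
  out_vol <- volume
  out_vol$voxels <- crop(volume$voxels)
  if (!is.null(volume$z_thickness)) out_vol$z_thickness <- volume$z_thickness[z0:z1]
  out_cav <- cavity
  out_cav$voxels <- crop(cavity$voxels)
  out_cav$z_thickness <- cavity$z_thickness[z0:z1]
  out_masks <- lapply(masks, function(m) {
    m$voxels <- crop(m$voxels); m$z_thickness <- m$z_thickness[z0:z1]; m
  })
  list(volume = out_vol, cavity = out_cav, masks = out_masks,
       offset = c(z0, y0, x0) - 1L)
}

# NIfTI IO ---------------------------------------------------------------
# Internally (z, y, x); NIfTI stores (x, y, z), so axes are permuted on the
# way in and out.  Spacing travels in pixdim.

#' Write a volume or mask to NIfTI
#'
#' @param x A `ct_volume`, `normalized_volume`, or `seg_mask`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  vox <- aperm(x$voxels, c(3, 2, 1))  # (x, y, z)
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- c(x$spacing[3], x$spacing[2], x$spacing[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file path.
#' @param subject_id Subject identifier for the returned volume.
#' @param as_mask Return a `seg_mask` instead of a `ct_volume`.
#' @return A `ct_volume` or `seg_mask` with `(z, y, x)` axis order.
#' @export
read_nifti_volume <- function(path, subject_id = "subject", as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  vox <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 2, 1))
  spacing <- c(sp[3], sp[2], sp[1])
  if (as_mask) seg_mask(vox, spacing)
  else ct_volume(vox, spacing, subject_id)
}

#' Read an axial DICOM series as a CT volume
#'
#' Minimal geometry/intensity reader: slices are sorted by the z component
#' of the patient-position tag, pixel data are rescaled to HU with the
#' slope/intercept tags, and per-slice thickness is derived from z gaps.
#' Requires the `oro.dicom` package only if used; phantom-driven workflows
#' never touch it.
#'
#' @param dir Directory containing one DICOM series.
#' @param subject_id Subject identifier.
#' @return A `ct_volume`.
#' @export
read_dicom_series <- function(dir, subject_id = "subject") {
  if (!requireNamespace("oro.dicom", quietly = TRUE))
    stop("reading DICOM requires the 'oro.dicom' package")
  dd <- oro.dicom::readDICOM(dir)
  hdrs <- dd$hdr
  zpos <- vapply(hdrs, function(h) {
    ipp <- h$value[h$name == "ImagePositionPatient"][1]
    as.numeric(strsplit(ipp, " ")[[1]])[3]
  }, numeric(1))
  slices <- lapply(seq_along(dd$img), function(i) {
    h <- hdrs[[i]]
    slope <- suppressWarnings(as.numeric(h$value[h$name == "RescaleSlope"][1]))
    inter <- suppressWarnings(as.numeric(h$value[h$name == "RescaleIntercept"][1]))
    if (!is.finite(slope)) slope <- 1
    if (!is.finite(inter)) inter <- 0
    dd$img[[i]] * slope + inter
  })
  ps <- strsplit(hdrs[[1]]$value[hdrs[[1]]$name == "PixelSpacing"][1], " ")[[1]]
  assemble_volume(slices, zpos, spacing_yx = as.numeric(ps),
                  subject_id = subject_id)
}
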