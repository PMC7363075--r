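# Synthetic head-CT phantom generator.
#
# Stylized axial head: a bright skull shell (ellipsoid ring, slice-varying
# radii), soft-tissue cavity with Gaussian parenchyma texture, paired
# near-midline hypodense ventricles scaled with age, optional hypodense
# lesions (ellipsoids fully inside the cavity), an optional patient-table
# slab outside the head, additive HU noise followed by a per-scanner
# Gaussian reconstruction kernel, and optional in-plane head rotation.

#' Phantom generation parameters
#'
#' @param shape Grid `(slices, rows, cols)`.
#' @param spacing mm per axis `(z, y, x)`.
#' @param skull_hu Skull shell HU level.
#' @param parenchyma_hu,parenchyma_sd Brain tissue mean HU and texture sd.
#' @param ventricle_hu Ventricle (CSF) mean HU; a hypodense confounder.
#' @param lesion_hu Lesion mean HU; must be below 32 (hypodense infarct
#'   profile) and below `parenchyma_hu`.
#' @param lesion_count_range Integer range of lesions per stroke subject.
#' @param lesion_radius_mm Range of lesion radii in mm.
#' @param table_artifact Add a patient-table slab below the head.
#' @param rotation_deg Range of in-plane head rotation (degrees);
#'   `c(0, 0)` disables rotation.
#' @param scanner One of the profiles in `scanner_profiles()`; controls the
#'   reconstruction smoothing kernel width and noise sd.
#' @param age Age in years; scales the ventricle size (atrophy).
#' @param seed Integer seed; fully determines the sample.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(24, 96, 96), spacing = c(5, 2, 2),
                           skull_hu = 700, parenchyma_hu = 35,
                           parenchyma_sd = 5, ventricle_hu = 8,
                           lesion_hu = 22, lesion_count_range = c(1, 3),
                           lesion_radius_mm = c(8, 16),
                           table_artifact = TRUE, rotation_deg = c(0, 0),
                           scanner = "A", age = 65, seed = 1L) {
  if (lesion_hu >= 32)
    stop("lesion_hu must be < 32 (hypodense infarct profile)")
  if (lesion_hu >= parenchyma_hu)
    stop("lesion_hu must be below parenchyma_hu")
  if (any(lesion_radius_mm <= 0)) stop("lesion radii must be > 0")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (!scanner %in% names(scanner_profiles()))
    stop("unknown scanner profile: ", scanner)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 skull_hu = skull_hu, parenchyma_hu = parenchyma_hu,
                 parenchyma_sd = parenchyma_sd, ventricle_hu = ventricle_hu,
                 lesion_hu = lesion_hu,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_mm = lesion_radius_mm,
                 table_artifact = isTRUE(table_artifact),
                 rotation_deg = rotation_deg, scanner = scanner,
                 age = age, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Scanner texture profiles
#'
#' Each profile emulates a reconstruction kernel: a Gaussian smoothing width
#' (pixels) and an additive HU noise sd applied before smoothing.
#'
#' @return Named list of profiles with `sigma` and `noise_sd`.
#' @export
scanner_profiles <- function() {
  list(A = list(sigma = 0.6, noise_sd = 5),
       B = list(sigma = 1.4, noise_sd = 7))
}

# Ellipsoid helper: TRUE inside the (cy, cx, ry, rx) ellipse on a grid.
ellipse_mask <- function(ny, nx, cy, cx, ry, rx) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

head_geometry <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zc <- (nz + 1) / 2
  zr <- nz / 2 + 0.5
  s <- sqrt(pmax(0, 1 - ((seq_len(nz) - zc) / zr)^2))
  s <- pmax(s, 0.4)
  list(cy = (ny + 1) / 2, cx = (nx + 1) / 2,
       ry = 0.42 * ny, rx = 0.34 * nx, zscale = s)
}

#' Generate one synthetic head-CT sample
#'
#' @param params A `phantom_params` object.
#' @param subject_id Subject identifier recorded on the volume.
#' @param n_lesions Optional fixed lesion count (overrides
#'   `lesion_count_range`); used by `generate_cohort()` to force healthy
#'   samples to zero lesions.
#' @return A list of class `phantom_sample` with elements `volume`
#'   (`ct_volume`), `cavity` and `lesions` (`seg_mask`), `record`
#'   (one-row data.frame: subject_id, age, scanner_model, label) and
#'   `angle`, the true in-plane rotation in degrees.
#' @export
generate_phantom <- function(params, subject_id = "subject",
                             n_lesions = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    shp <- params$shape
    nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
    geo <- head_geometry(shp)
    prof <- scanner_profiles()[[params$scanner]]

    vol <- array(-1000, shp)       # air
    cavity <- array(0L, shp)
    vent <- array(0L, shp)

    # skull shell and cavity, slice-varying radii
    for (z in seq_len(nz)) {
      s <- geo$zscale[z]
      outer_m <- ellipse_mask(ny, nx, geo$cy, geo$cx, geo$ry * s * 1.10,
                              geo$rx * s * 1.10)
      inner_m <- ellipse_mask(ny, nx, geo$cy, geo$cx, geo$ry * s * 0.93,
                              geo$rx * s * 0.93)
      sl <- vol[z, , ]
      sl[outer_m] <- params$skull_hu
      sl[inner_m] <- params$parenchyma_hu
      vol[z, , ] <- sl
      cavity[z, , ] <- as.integer(inner_m)
    }

    # parenchyma texture
    ncav <- sum(cavity)
    vol[cavity == 1] <- vol[cavity == 1] +
      stats::rnorm(ncav, 0, params$parenchyma_sd)

    # paired near-midline ventricles, age-scaled
    vscale <- 0.75 + 0.005 * params$age
    vz <- round(nz / 2) + (-1:1)
    vz <- vz[vz >= 1 & vz <= nz]
    for (z in vz) {
      for (side in c(-1, 1)) {
        vm <- ellipse_mask(ny, nx, geo$cy - 0.04 * ny,
                           geo$cx + side * 0.07 * nx,
                           0.11 * ny * vscale, 0.05 * nx * vscale)
        vm <- vm & (cavity[z, , ] == 1)
        sl <- vol[z, , ]
        sl[vm] <- params$ventricle_hu + stats::rnorm(sum(vm), 0, 2)
        vol[z, , ] <- sl
        vv <- vent[z, , ]; vv[vm] <- 1L; vent[z, , ] <- vv
      }
    }

    # lesions: hypodense ellipsoids fully inside the cavity, off-ventricle
    lesions <- array(0L, shp)
    n_les <- if (!is.null(n_lesions)) n_lesions else {
      r <- params$lesion_count_range
      if (r[2] <= r[1]) r[1] else sample(r[1]:r[2], 1)
    }
    if (n_les > 0) {
      max_r_vox <- max(params$lesion_radius_mm) / min(params$spacing[2:3])
      if (2 * max_r_vox > min(geo$ry, geo$rx) * 0.93 * 2)
        stop("lesion radius too large to fit inside the cavity")
      placed <- 0
      attempts <- 0
      while (placed < n_les && attempts < 500) {
        attempts <- attempts + 1
        r_mm <- stats::runif(1, params$lesion_radius_mm[1],
                             params$lesion_radius_mm[2])
        rz <- max(1, r_mm / params$spacing[1])
        ry <- r_mm / params$spacing[2]
        rx <- r_mm / params$spacing[3]
        cz <- stats::runif(1, 1 + rz, nz - rz)
        # sample an in-plane centre well inside the cavity of slice round(cz)
        zc <- round(cz)
        sshrink <- geo$zscale[zc] * 0.93
        u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
        cy <- geo$cy + sqrt(u) * (geo$ry * sshrink - ry - 2) * sin(th)
        cx <- geo$cx + sqrt(u) * (geo$rx * sshrink - rx - 2) * cos(th)
        cand <- array(0L, shp)
        zs <- max(1, floor(cz - rz)):min(nz, ceiling(cz + rz))
        for (z in zs) {
          fz <- 1 - ((z - cz) / rz)^2
          if (fz <= 0) next
          m <- ellipse_mask(ny, nx, cy, cx, ry * sqrt(fz), rx * sqrt(fz))
          cand[z, , ] <- as.integer(m)
        }
        ok <- sum(cand) > 0 && all(cavity[cand == 1] == 1) &&
          !any(vent[cand == 1] == 1)
        if (!ok) next
        vol[cand == 1] <- params$lesion_hu +
          stats::rnorm(sum(cand), 0, 2)
        lesions[cand == 1] <- 1L
        placed <- placed + 1
      }
      if (placed < n_les)
        stop("lesion radius too large to fit inside cavity (placement failed)")
    }

    # patient table: bright slab outside/below the skull
    if (params$table_artifact) {
      ytab <- min(ny - 2, round(geo$cy + geo$ry * 1.10) + 4)
      vol[, ytab:min(ny, ytab + 2), ] <- 300
    }

    # noise + per-scanner reconstruction kernel
    vol <- vol + array(stats::rnorm(length(vol), 0, prof$noise_sd), dim(vol))
    for (z in seq_len(nz)) vol[z, , ] <- cpp_gauss2d(vol[z, , ], prof$sigma)

    # optional in-plane head rotation
    angle <- 0
    rr <- params$rotation_deg
    if (any(rr != 0)) {
      angle <- stats::runif(1, rr[1], rr[2])
      vol <- rotate_volume_inplane(vol, angle, bilinear = TRUE, fill = -1000)
      cavity <- array(as.integer(
        rotate_volume_inplane(cavity, angle, bilinear = FALSE) != 0), shp)
      lesions <- array(as.integer(
        rotate_volume_inplane(lesions, angle, bilinear = FALSE) != 0), shp)
      lesions <- lesions * cavity
    }

    v <- ct_volume(vol, params$spacing, subject_id)
    rec <- data.frame(subject_id = subject_id, age = params$age,
                      scanner_model = params$scanner,
                      label = as.integer(sum(lesions) > 0),
                      stringsAsFactors = FALSE)
    structure(list(volume = v,
                   cavity = mask_like(v, cavity),
                   lesions = mask_like(v, lesions),
                   record = rec, angle = angle),
              class = "phantom_sample")
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n` phantoms of which `round(n * stroke_fraction)` carry at least
#' one lesion (label "stroke"); ages are drawn uniformly from `age_range`
#' and scanner profiles uniformly from `scanners`.  Subjects are assigned
#' train/val/test split tags by the given fractions.  Everything is
#' reproducible from `seed`.
#'
#' @param n Number of subjects (> 0).
#' @param stroke_fraction Proportion of stroke subjects in `[0, 1]`.
#' @param template A `phantom_params` template; per-subject seed, age and
#'   scanner are filled in.
#' @param seed Integer cohort seed.
#' @param split_fractions Named numeric vector over train/val/test summing
#'   to 1.
#' @param age_range Age range (years) for the uniform age draw.
#' @param scanners Scanner profile ids sampled per subject.
#' @return List with `samples` (list of `phantom_sample`) and `cohort`
#'   (data.frame: subject_id, age, scanner_model, label, split).
#' @export
generate_cohort <- function(n, stroke_fraction, template = phantom_params(),
                            seed = 1L,
                            split_fractions = c(train = 0.5, val = 0.1,
                                                test = 0.4),
                            age_range = c(40, 90),
                            scanners = names(scanner_profiles())) {
  if (n <= 0) stop("n must be > 0")
  if (stroke_fraction < 0 || stroke_fraction > 1)
    stop("stroke_fraction must lie in [0, 1]")
  n_stroke <- round(n * stroke_fraction)
  with_seed(seed, {
    label <- sample(c(rep(1L, n_stroke), rep(0L, n - n_stroke)))
    ages <- round(stats::runif(n, age_range[1], age_range[2]))
    scan <- sample(scanners, n, replace = TRUE)
    n_split <- round(n * split_fractions)
    n_split[1] <- n - sum(n_split[-1])
    split <- sample(rep(names(split_fractions), n_split))
    seeds <- sample.int(2^31 - 2, n)
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      p <- template
      p$seed <- seeds[i]
      p$age <- ages[i]
      p$scanner <- scan[i]
      samples[[i]] <- generate_phantom(
        p, subject_id = sprintf("subj%03d", i),
        n_lesions = if (label[i] == 0) 0L else NULL)
    }
    cohort <- do.call(rbind, lapply(samples, `[[`, "record"))
    cohort$split <- split
    list(samples = samples, cohort = cohort)
  })
}

#' Write a cohort to disk
#'
#' Volumes and masks as NIfTI (one file per subject per role), cohort
#' metadata as CSV with columns subject_id, age, scanner_model, label,
#' split.
#'
#' @param cohort Result of `generate_cohort()`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$samples) {
    id <- s$record$subject_id
    write_nifti_volume(s$volume, file.path(dir, paste0(id, "_ct.nii.gz")))
    write_nifti_volume(s$cavity, file.path(dir, paste0(id, "_cavity.nii.gz")))
    write_nifti_volume(s$lesions, file.path(dir, paste0(id, "_lesion.nii.gz")))
  }
  utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
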