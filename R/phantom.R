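# Synthetic paired PET/CT phantom generator.  Emulates the salient
# properties of clinical head-and-neck PET/CT: two co-registered but
# differently gridded modalities (CT near 1.1 x 1.1 x 2.7 mm voxels, PET
# near 3.9 x 3.9 x 3.7 mm), CT anatomy in Hounsfield units with air, soft
# tissue and bone compartments, an FDG-avid tumor whose full extent is
# visible on PET but only partially visible on CT, and a slight
# field-of-view/origin mismatch between the grids.

#' Specification of a synthetic PET/CT phantom case
#'
#' @param grid_shape_ct,grid_shape_pet Integer length-3, voxels per axis.
#' @param spacing_ct,spacing_pet Numeric length-3, mm per axis (> 0).
#' @param origin_offset_pet PET origin minus CT origin, mm per axis.
#' @param tumor_center Tumor center in world mm (defaults to the CT grid
#'   center).
#' @param tumor_radii Ellipsoid semi-axes in mm (>= 0); all-zero radii give
#'   an empty tumor.
#' @param ct_tumor_contrast HU offset of the CT-visible tumor core over the
#'   soft-tissue background.
#' @param ct_visible_fraction Fraction of the tumor radii that shows
#'   contrast on CT; the full extent is always visible on PET, so CT alone
#'   carries only a partial boundary.
#' @param pet_tumor_uptake Hot-spot intensity as a multiple of the PET
#'   soft-tissue background.
#' @param pet_background Baseline PET uptake inside the body (arbitrary
#'   units).
#' @param noise_sd_ct,noise_sd_pet Gaussian noise standard deviations (HU
#'   and uptake units).
#' @param edge_sigma_mm Smoothing length for the CT tumor boundary; 0
#'   gives hard edges.
#' @param pet_edge_sigma_mm Smoothing length for the PET hot-spot
#'   boundary, emulating the scanner point-spread function (partial-volume
#'   blur); the PET boundary is intrinsically fuzzier than the CT one.
#' @param bone TRUE to include an 800 HU bone rod (exercises the upper
#'   clipping bound downstream).
#' @param seed Integer RNG seed; the same spec reproduces identical voxel
#'   values.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape_ct = c(64, 64, 28),
                         spacing_ct = c(1.1, 1.1, 2.7),
                         grid_shape_pet = c(18, 18, 20),
                         spacing_pet = c(3.9, 3.9, 3.7),
                         origin_offset_pet = c(1.3, -1.7, 2.1),
                         tumor_center = NULL,
                         tumor_radii = c(10, 9, 11),
                         ct_tumor_contrast = 40,
                         ct_visible_fraction = 0.8,
                         pet_tumor_uptake = 5,
                         pet_background = 1,
                         noise_sd_ct = 20,
                         noise_sd_pet = 0.15,
                         edge_sigma_mm = 0.5,
                         pet_edge_sigma_mm = 1.5,
                         bone = TRUE,
                         seed = 1L) {
  spec <- list(grid_shape_ct = as.integer(grid_shape_ct),
               spacing_ct = as.numeric(spacing_ct),
               grid_shape_pet = as.integer(grid_shape_pet),
               spacing_pet = as.numeric(spacing_pet),
               origin_offset_pet = as.numeric(origin_offset_pet),
               tumor_center = if (is.null(tumor_center)) NULL
                              else as.numeric(tumor_center),
               tumor_radii = as.numeric(tumor_radii),
               ct_tumor_contrast = ct_tumor_contrast,
               ct_visible_fraction = ct_visible_fraction,
               pet_tumor_uptake = pet_tumor_uptake,
               pet_background = pet_background,
               noise_sd_ct = noise_sd_ct,
               noise_sd_pet = noise_sd_pet,
               edge_sigma_mm = edge_sigma_mm,
               pet_edge_sigma_mm = pet_edge_sigma_mm,
               bone = isTRUE(bone),
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  if (is.null(spec$tumor_center))
    spec$tumor_center <- (spec$grid_shape_ct - 1) * spec$spacing_ct / 2
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$spacing_ct <= 0) || any(spec$spacing_pet <= 0))
    stop("invalid phantom spec: spacings must be positive")
  if (any(spec$grid_shape_ct < 1) || any(spec$grid_shape_pet < 1))
    stop("invalid phantom spec: grid shapes must be >= 1 per axis")
  if (any(spec$tumor_radii < 0))
    stop("invalid phantom spec: tumor radii must be >= 0")
  invisible(spec)
}

# Signed ellipsoid coordinate: < 1 inside, > 1 outside, on a world grid.
ellipsoid_field <- function(wx, wy, wz, center, radii) {
  r <- pmax(radii, 1e-12)
  gx <- ((wx - center[1]) / r[1])^2
  gy <- ((wy - center[2]) / r[2])^2
  gz <- ((wz - center[3]) / r[3])^2
  outer3_sum(gx, gy, gz)
}

# outer sum a[i] + b[j] + c[k] as a 3D array
outer3_sum <- function(a, b, c) {
  na <- length(a); nb <- length(b); nc <- length(c)
  array(a, c(na, nb, nc)) +
    array(rep(b, each = na), c(na, nb, nc)) +
    array(rep(c, each = na * nb), c(na, nb, nc))
}

# Soft (smoothed) indicator of the ellipsoid interior.  The transition is
# localized around the boundary with physical width ~ sigma_mm.
soft_ellipsoid <- function(wx, wy, wz, center, radii, sigma_mm) {
  if (all(radii <= 0)) {
    return(array(0, c(length(wx), length(wy), length(wz))))
  }
  q <- sqrt(pmax(ellipsoid_field(wx, wy, wz, center, radii), 0))
  if (sigma_mm <= 0) return((q <= 1) * 1)
  # convert the dimensionless boundary distance to ~mm via the mean radius
  scale <- mean(radii[radii > 0]) / sigma_mm
  1 / (1 + exp(pmin(pmax((q - 1) * scale, -40), 40)))
}

#' Generate one synthetic PET/CT phantom case
#'
#' Builds a layered CT volume (air shell near -1000 HU, soft-tissue body
#' near 40 HU, optional 800 HU bone rod) with a partially CT-visible tumor,
#' a PET volume with low background and a hot tumor covering the full tumor
#' extent, and a binary ground-truth mask on the CT grid (voxel center
#' inside the ellipsoid).  Identical specs reproduce identical voxels.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_case` with elements `ct`
#'   (`image_volume`, HU), `pet` (`image_volume`, uptake units), `label`
#'   (`label_volume` on the CT grid) and `spec`.
#' @export
generate_case <- function(spec) {
  validate_phantom_spec(spec)
  if (is.null(spec$tumor_center))
    spec$tumor_center <- (spec$grid_shape_ct - 1) * spec$spacing_ct / 2

  ct_lo <- rep(0, 3)
  ct_hi <- (spec$grid_shape_ct - 1) * spec$spacing_ct
  if (any(spec$tumor_radii > 0)) {
    if (any(spec$tumor_center - spec$tumor_radii < ct_lo) ||
        any(spec$tumor_center + spec$tumor_radii > ct_hi))
      stop("tumor extends outside the CT grid")
  }

  set.seed(spec$seed)

  # --- CT grid -----------------------------------------------------------
  dims <- spec$grid_shape_ct
  wx <- axis_world(dims[1], spec$spacing_ct[1], 0)
  wy <- axis_world(dims[2], spec$spacing_ct[2], 0)
  wz <- axis_world(dims[3], spec$spacing_ct[3], 0)
  center <- (ct_hi - ct_lo) / 2
  body_radii <- (ct_hi - ct_lo) / 2 * 0.92 + spec$spacing_ct
  body <- soft_ellipsoid(wx, wy, wz, center, body_radii, 2)

  # smooth low-frequency soft-tissue texture
  tex <- outer3_sum(20 * sin(wx / 17), 15 * cos(wy / 23), 10 * sin(wz / 31))
  ct <- -1000 * (1 - body) + body * (40 + tex)

  if (spec$bone) {
    # bone rod along z, offset from the tumor
    rod_center <- center + c(-0.25, 0.25, 0) * (ct_hi - ct_lo)
    rod_r <- 0.06 * mean(ct_hi[1:2] - ct_lo[1:2]) + mean(spec$spacing_ct[1:2])
    d2 <- outer3_sum(((wx - rod_center[1]) / rod_r)^2,
                     ((wy - rod_center[2]) / rod_r)^2, 0 * wz)
    ct <- ct + body * (d2 <= 1) * 760
  }

  core <- soft_ellipsoid(wx, wy, wz, spec$tumor_center,
                         spec$tumor_radii * spec$ct_visible_fraction,
                         spec$edge_sigma_mm)
  ct <- ct + spec$ct_tumor_contrast * core
  ct <- ct + array(rnorm(prod(dims), sd = spec$noise_sd_ct), dims)
  ct <- pmin(pmax(ct, -1100), 1100)

  lab <- (ellipsoid_field(wx, wy, wz, spec$tumor_center,
                          spec$tumor_radii) <= 1) * 1
  if (all(spec$tumor_radii <= 0)) lab[] <- 0

  # --- PET grid (different spacing and origin) ---------------------------
  pdims <- spec$grid_shape_pet
  po <- spec$origin_offset_pet
  pwx <- axis_world(pdims[1], spec$spacing_pet[1], po[1])
  pwy <- axis_world(pdims[2], spec$spacing_pet[2], po[2])
  pwz <- axis_world(pdims[3], spec$spacing_pet[3], po[3])
  pbody <- soft_ellipsoid(pwx, pwy, pwz, center, body_radii, 4)
  hot <- soft_ellipsoid(pwx, pwy, pwz, spec$tumor_center,
                        spec$tumor_radii, spec$pet_edge_sigma_mm)
  pet <- spec$pet_background * (0.05 + 0.95 * pbody) +
    spec$pet_background * (spec$pet_tumor_uptake - 1) * hot
  pet <- pet + array(rnorm(prod(pdims), sd = spec$noise_sd_pet), pdims)

  structure(list(
    ct = image_volume(ct, spec$spacing_ct, c(0, 0, 0), "CT"),
    pet = image_volume(pet, spec$spacing_pet, po, "PET"),
    label = label_volume(lab, spec$spacing_ct, c(0, 0, 0)),
    spec = spec), class = "phantom_case")
}

#' Generate a cohort of phantom cases with jittered tumors
#'
#' Each case perturbs the tumor center and semi-axes of the base spec with
#' independent Gaussian jitter, then draws fresh noise, all derived
#' deterministically from `seed`.
#'
#' @param spec Base [phantom_spec()].
#' @param n_cases Number of cases (>= 1).
#' @param seed Integer seed for the cohort.
#' @param jitter List with elements `center_sd` (mm) and `radius_sd` (mm);
#'   either may be 0.
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(spec, n_cases, seed = spec$seed,
                            jitter = list(center_sd = 2, radius_sd = 1)) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  validate_phantom_spec(spec)
  if (is.null(spec$tumor_center))
    spec$tumor_center <- (spec$grid_shape_ct - 1) * spec$spacing_ct / 2
  set.seed(as.integer(seed))
  lapply(seq_len(n_cases), function(i) {
    s <- spec
    s$tumor_center <- spec$tumor_center +
      rnorm(3, sd = jitter$center_sd %||% 0)
    s$tumor_radii <- pmax(spec$tumor_radii +
                            rnorm(3, sd = jitter$radius_sd %||% 0), 0.5)
    # per-case noise seed, kept within 32-bit integer range
    s$seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    generate_case(s)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom case as three NIfTI files
#'
#' @param case A `phantom_case`.
#' @param directory Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of file paths (`ct`, `pet`, `label`).
#' @export
write_case <- function(case, directory, prefix = "case") {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create output directory")
  paths <- c(ct = file.path(directory, paste0(prefix, "_ct.nii.gz")),
             pet = file.path(directory, paste0(prefix, "_pet.nii.gz")),
             label = file.path(directory, paste0(prefix, "_label.nii.gz")))
  write_volume(case$ct, paths["ct"])
  write_volume(case$pet, paths["pet"])
  write_volume(case$label, paths["label"])
  paths
}

#' Read a phantom case written by [write_case()]
#'
#' @param paths Named character vector with entries `ct`, `pet`, `label`.
#' @return A `phantom_case` (without the generating spec).
#' @export
read_case <- function(paths) {
  structure(list(ct = read_volume(paths[["ct"]], "image", "CT"),
                 pet = read_volume(paths[["pet"]], "image", "PET"),
                 label = read_volume(paths[["label"]], "label"),
                 spec = NULL), class = "phantom_case")
}
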