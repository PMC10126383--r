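# CT/PET fusion preprocessing: Hounsfield clipping, per-image
# z-normalization, isotropic resampling by linear interpolation, cropping
# to the overlapping field-of-view, and channel concatenation.

# Trilinear (or nearest) sampling of a 3D array at continuous 0-based voxel
# coordinates.  Coordinate arrays sx/sy/sz share a common shape; values are
# clamped to the grid so queries at the boundary are well defined.
sample_grid <- function(values, sx, sy, sz, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(values)
  sx <- pmin(pmax(sx, 0), d[1] - 1)
  sy <- pmin(pmax(sy, 0), d[2] - 1)
  sz <- pmin(pmax(sz, 0), d[3] - 1)
  if (mode == "nearest") {
    idx <- 1 + round(sx) + d[1] * (round(sy) + d[2] * round(sz))
    out <- values[idx]
  } else {
    x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
    fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
    x1 <- pmin(x0 + 1, d[1] - 1)
    y1 <- pmin(y0 + 1, d[2] - 1)
    z1 <- pmin(z0 + 1, d[3] - 1)
    lin <- function(ix, iy, iz) values[1 + ix + d[1] * (iy + d[2] * iz)]
    out <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
      lin(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
      lin(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
      lin(x1, y1, z0) * fx * fy * (1 - fz) +
      lin(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
      lin(x1, y0, z1) * fx * (1 - fy) * fz +
      lin(x0, y1, z1) * (1 - fx) * fy * fz +
      lin(x1, y1, z1) * fx * fy * fz
  }
  dm <- dim(sx)
  if (is.null(dm)) dm <- length(sx)
  array(out, dm)
}

# Expand per-axis continuous coordinates into full 3D coordinate arrays.
coord_arrays <- function(cx, cy, cz) {
  n <- c(length(cx), length(cy), length(cz))
  list(sx = array(cx, n),
       sy = array(rep(cy, each = n[1]), n),
       sz = array(rep(cz, each = n[1] * n[2]), n))
}

#' Clip a CT volume to the soft-tissue Hounsfield window
#'
#' Values are clamped to \[-1000, 600\] HU; in-range values pass through
#' unchanged.
#'
#' @param volume An `image_volume` with modality `"CT"`.
#' @param lower,upper Window bounds in HU.
#' @return The clipped `image_volume`.
#' @export
clip_ct <- function(volume, lower = -1000, upper = 600) {
  stopifnot(inherits(volume, "image_volume"))
  if (volume$modality != "CT") stop("clip_ct expects a CT volume")
  volume$values[] <- pmin(pmax(volume$values, lower), upper)
  volume
}

#' Z-normalize a volume
#'
#' Subtracts the whole-volume mean and divides by the whole-volume
#' (population) standard deviation.
#'
#' @param volume An `image_volume`.
#' @return The normalized `image_volume` (mean 0, SD 1).
#' @export
znormalize <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$values
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s < 1e-12) stop("cannot z-normalize a constant volume (SD = 0)")
  volume$values[] <- (v - m) / s
  volume
}

#' Resample a volume to isotropic spacing
#'
#' Output axis length is `round(n_in * spacing_in / target)`; voxel centers
#' sit at `origin + index * target`, so the origin is preserved and the
#' physical extent is conserved to within one target voxel.  Images use
#' trilinear interpolation, labels nearest-neighbor (so they stay binary).
#'
#' @param volume An `image_volume` or `label_volume`.
#' @param target_spacing Target spacing in mm (scalar, > 0).
#' @param mode `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   labels and `"linear"` otherwise.
#' @return Volume of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(volume, target_spacing = 1, mode = NULL) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1 ||
      target_spacing <= 0)
    stop("target_spacing must be a positive scalar (mm)")
  is_label <- inherits(volume, "label_volume")
  if (is.null(mode)) mode <- if (is_label) "nearest" else "linear"
  mode <- match.arg(mode, c("linear", "nearest"))
  d <- dim(volume$values)
  n_out <- pmax(1L, as.integer(round(d * volume$spacing / target_spacing)))
  if (all(n_out == d) && all(abs(volume$spacing - target_spacing) < 1e-12))
    return(volume)
  # continuous source index of each target voxel center
  cc <- lapply(1:3, function(a)
    (seq_len(n_out[a]) - 1) * target_spacing / volume$spacing[a])
  co <- coord_arrays(cc[[1]], cc[[2]], cc[[3]])
  out <- sample_grid(volume$values, co$sx, co$sy, co$sz, mode)
  if (is_label)
    label_volume(out, rep(target_spacing, 3), volume$origin)
  else
    image_volume(out, rep(target_spacing, 3), volume$origin,
                 volume$modality)
}

# Per-image crop of the physical interval [lo, hi]: start index is the
# first voxel center >= lo, stop index the last center <= hi.
crop_indices <- function(origin, spacing, n, lo, hi) {
  start <- ceiling((lo - origin) / spacing - 1e-9)
  stop <- floor((hi - origin) / spacing + 1e-9)
  start <- pmax(start, 0); stop <- pmin(stop, n - 1)
  if (any(stop < start)) stop("grids have no physical overlap")
  list(start = start, stop = stop)
}

#' Crop two same-spacing volumes to their overlapping field of view
#'
#' The physical intersection of the two bounding boxes is computed in
#' continuous world coordinates and snapped to each grid; the outputs share
#' one grid (shape, spacing, origin).  If the two grids are shifted by a
#' sub-voxel offset, the second volume is shifted onto the first volume's
#' grid by linear interpolation.
#'
#' @param ct,pet `image_volume`s at identical (isotropic) spacing.
#' @return List with cropped `ct` and `pet` on a common grid, plus the CT
#'   crop `start` (0-based voxel index into the input CT grid).
#' @export
crop_to_overlap <- function(ct, pet) {
  if (any(abs(ct$spacing - pet$spacing) > 1e-9))
    stop("crop_to_overlap requires identical spacing")
  sp <- ct$spacing
  ect <- volume_extent(ct); epet <- volume_extent(pet)
  lo <- pmax(ect$lo, epet$lo)
  hi <- pmin(ect$hi, epet$hi)
  if (any(hi < lo)) stop("grids have no physical overlap")
  ic <- crop_indices(ct$origin, sp, dim(ct$values), lo, hi)
  ip <- crop_indices(pet$origin, sp, dim(pet$values), lo, hi)
  n <- pmin(ic$stop - ic$start, ip$stop - ip$start) + 1
  sub <- function(v, s, n)
    v$values[s[1] + seq_len(n[1]), s[2] + seq_len(n[2]),
             s[3] + seq_len(n[3]), drop = FALSE]
  ct_vals <- sub(ct, ic$start, n)
  new_origin <- ct$origin + ic$start * sp
  pet_origin <- pet$origin + ip$start * sp
  shift <- (new_origin - pet$origin) / sp   # continuous PET index of start
  if (all(abs(pet_origin - new_origin) < 1e-9)) {
    pet_vals <- sub(pet, ip$start, n)
  } else {
    # sub-voxel misalignment: sample PET on the CT crop grid
    cc <- lapply(1:3, function(a) shift[a] + (seq_len(n[a]) - 1))
    co <- coord_arrays(cc[[1]], cc[[2]], cc[[3]])
    pet_vals <- sample_grid(pet$values, co$sx, co$sy, co$sz, "linear")
  }
  list(ct = image_volume(ct_vals, sp, new_origin, "CT"),
       pet = image_volume(pet_vals, sp, new_origin, "PET"),
       start = ic$start)
}

#' Full CT/PET fusion preprocessing for one case
#'
#' Pipeline order: clip CT to \[-1000, 600\] HU, z-normalize each modality
#' (PET is normalized without prior clipping), resample both to the target
#' isotropic spacing by linear interpolation, crop to the overlapping
#' field of view, and concatenate into a two-channel fused volume.  The
#' label, when given, is carried onto the same grid with nearest-neighbor
#' interpolation.
#'
#' @param ct,pet `image_volume`s (CT in HU, PET in uptake units).
#' @param label Optional `label_volume` on the CT grid.
#' @param target_spacing Isotropic grid spacing in mm (default 1).
#' @return List with `fused` (a `fused_volume`) and `label` (a
#'   `label_volume` on the fused grid, or `NULL`).
#' @export
preprocess_case <- function(ct, pet, label = NULL, target_spacing = 1) {
  stopifnot(inherits(ct, "image_volume"), inherits(pet, "image_volume"))
  ct_n <- znormalize(clip_ct(ct))
  pet_n <- znormalize(pet)
  ct_r <- resample_isotropic(ct_n, target_spacing, "linear")
  pet_r <- resample_isotropic(pet_n, target_spacing, "linear")
  cr <- crop_to_overlap(ct_r, pet_r)
  out_label <- NULL
  if (!is.null(label)) {
    stopifnot(inherits(label, "label_volume"))
    lab_r <- resample_isotropic(label, target_spacing, "nearest")
    n <- dim(cr$ct$values)
    s <- cr$start
    lv <- lab_r$values[s[1] + seq_len(n[1]), s[2] + seq_len(n[2]),
                       s[3] + seq_len(n[3]), drop = FALSE]
    out_label <- label_volume(lv, cr$ct$spacing, cr$ct$origin)
  }
  fused <- fused_volume(cr$ct$values, cr$pet$values, cr$ct$spacing,
                        cr$ct$origin)
  list(fused = fused, label = out_label)
}
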