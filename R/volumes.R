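#' @useDynLib petctseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile pnorm
NULL

# Coordinate convention used throughout the package: 0-based voxel indices,
# half-open index ranges, world position = origin + index * spacing (mm).
# Array axis 1 is the left-right (x) axis, axes (1,2) span the axial plane.

#' Construct a single-modality image volume
#'
#' An `image_volume` couples a 3D scalar grid with its physical geometry:
#' voxel spacing in mm per axis and the world position (mm) of the center of
#' voxel (0,0,0). World position of voxel index `i` (0-based) is
#' `origin + i * spacing`.
#'
#' @param values 3D numeric array of voxel values (HU for CT, uptake units
#'   for PET).
#' @param spacing Numeric length-3, mm per axis; all entries must be > 0.
#' @param origin Numeric length-3, mm; world coordinates of the first voxel
#'   center.
#' @param modality `"CT"` or `"PET"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "PET")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (any(!is.finite(values))) stop("`values` must be finite")
  structure(list(values = values, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' Construct a binary label volume
#'
#' @param values 3D array containing only 0 and 1 (logical arrays are
#'   coerced).
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (is.logical(values)) values <- array(as.numeric(values), dim(values))
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(values %in% c(0, 1))) stop("label values must be 0 or 1")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' Construct a fused two-channel (CT, PET) volume
#'
#' The network input: both modalities resampled onto one shared grid and
#' stacked along a trailing channel axis (channel 1 = CT, channel 2 = PET).
#' A channel whose availability flag is `FALSE` is identically zero.
#'
#' @param ct,pet 3D arrays on the shared grid (same shape).
#' @param spacing,origin Shared grid geometry (mm).
#' @param availability Named logical vector `c(CT=, PET=)`; a dropped
#'   channel must be all-zero.
#' @return An object of class `fused_volume` whose `channels` element is a
#'   4D array of dim `c(dim(ct), 2)`.
#' @export
fused_volume <- function(ct, pet, spacing, origin = c(0, 0, 0),
                         availability = c(CT = TRUE, PET = TRUE)) {
  ct <- as.array(ct); pet <- as.array(pet)
  if (!identical(dim(ct), dim(pet))) stop("CT and PET grids must match")
  if (length(dim(ct)) != 3L) stop("channels must be 3D arrays")
  availability <- as.logical(availability)
  names(availability) <- c("CT", "PET")
  ch <- array(c(ct, pet), dim = c(dim(ct), 2L))
  for (i in 1:2) if (!availability[i] && any(ch[, , , i] != 0))
    stop("a channel flagged unavailable must be identically zero")
  structure(list(channels = ch, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), availability = availability),
            class = "fused_volume")
}

#' Construct a per-voxel foreground probability map
#'
#' @param values 3D array with all values in \[0, 1\].
#' @inheritParams image_volume
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  values[] <- pmin(pmax(values, 0), 1)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "probability_map")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels @ %s mm, origin (%s) mm\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

#' @export
print.fused_volume <- function(x, ...) {
  cat(sprintf("<fused_volume> %s voxels @ %s mm, CT %s, PET %s\n",
              paste(dim(x$channels)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              ifelse(x$availability["CT"], "present", "dropped"),
              ifelse(x$availability["PET"], "present", "dropped")))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s voxels @ %s mm, range [%.3f, %.3f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

# World coordinates (mm) of each voxel center along one axis (0-based).
axis_world <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

# Physical extent: world coordinates of first and last voxel centers.
volume_extent <- function(v) {
  d <- dim(v$values)
  list(lo = v$origin, hi = v$origin + (d - 1) * v$spacing)
}

#' Write a volume to a NIfTI-1 file
#'
#' Spacing and origin are stored in the qform/sform (code 2) so that a
#' read-back reproduces the grid geometry exactly.
#'
#' @param volume An `image_volume`, `label_volume`, or `probability_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @param type `"image"`, `"label"`, or `"probability"`.
#' @param modality Modality tag for `type = "image"`.
#' @return The corresponding volume object.
#' @export
read_volume <- function(path, type = c("image", "label", "probability"),
                        modality = c("CT", "PET")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  vals <- as.array(img)
  switch(type,
         image = image_volume(vals, spacing, origin, match.arg(modality)),
         label = label_volume(vals, spacing, origin),
         probability = probability_map(vals, spacing, origin))
}
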