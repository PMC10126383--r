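# Training-patch extraction with foreground oversampling and the
# stochastic augmentation schedule: left-right flip, isotropic spatial
# zoom, brightness, contrast, Gaussian noise, and in-plane rotation, each
# applied independently with its configured probability to an enlarged
# patch that is center-cropped afterwards so interpolation artifacts never
# reach the network input.

#' Augmentation configuration
#'
#' Defaults follow the training schedule for head-and-neck PET/CT patches:
#' left-right flip 50% of the time (the head and neck are anatomically
#' symmetric along the left-right direction), isotropic zoom 20% of the
#' time with a factor in \[0.7, 1.4\], brightness and contrast 15% of the
#' time each with factors in \[0.75, 1.25\], additive Gaussian noise 10% of
#' the time, and in-plane rotation up to +/-30 degrees 20% of the time.
#'
#' Brightness multiplies the normalized intensities by its factor;
#' contrast scales them about the channel mean and clips back to the
#' pre-transform value range.  Noise SD is drawn uniformly from
#' `noise_sd_range` (normalized-intensity units).
#'
#' @param p_flip,p_scale,p_brightness,p_contrast,p_noise,p_rotate
#'   Per-transform application probabilities in \[0, 1\].
#' @param scale_range,brightness_range,contrast_range Factor ranges.
#' @param noise_sd_range Range the additive-noise SD is drawn from.
#' @param max_rotation_deg Rotation limit in degrees (axial plane).
#' @param margin Extra voxels per side for the enlarged pre-crop patch;
#'   `NULL` derives it from `scale_range` and the rotation support so the
#'   final center crop never sees padding.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_flip = 0.5,
                           p_scale = 0.2, scale_range = c(0.7, 1.4),
                           p_brightness = 0.15,
                           brightness_range = c(0.75, 1.25),
                           p_contrast = 0.15, contrast_range = c(0.75, 1.25),
                           p_noise = 0.1, noise_sd_range = c(0, 0.1),
                           p_rotate = 0.2, max_rotation_deg = 30,
                           margin = NULL) {
  p <- c(p_flip, p_scale, p_brightness, p_contrast, p_noise, p_rotate)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  for (r in list(scale_range, brightness_range, contrast_range,
                 noise_sd_range))
    if (length(r) != 2 || r[1] > r[2]) stop("ranges must be ordered pairs")
  if (!is.null(margin) && any(margin < 0)) stop("margin must be >= 0")
  structure(list(p_flip = p_flip, p_scale = p_scale,
                 scale_range = scale_range, p_brightness = p_brightness,
                 brightness_range = brightness_range,
                 p_contrast = p_contrast, contrast_range = contrast_range,
                 p_noise = p_noise, noise_sd_range = noise_sd_range,
                 p_rotate = p_rotate, max_rotation_deg = max_rotation_deg,
                 margin = margin),
            class = "augment_config")
}

# Margin (voxels per side) covering the largest zoom-out plus in-plane
# rotation support for a given final patch size.
augment_margin <- function(cfg, target_size) {
  if (!is.null(cfg$margin)) return(rep(cfg$margin, length.out = 3))
  zoom <- ceiling(target_size * (1 / cfg$scale_range[1] - 1) / 2)
  rot <- ceiling(target_size * (sqrt(2) - 1) / 2)
  m <- zoom
  m[1:2] <- m[1:2] + rot[1:2]  # rotation is in the (x, y) plane
  m
}

# Symmetric zero-pad of a 3D/4D array to at least `size` on the first three
# axes; returns the padded array and the pad offset (voxels).
pad_to_size <- function(a, size) {
  d <- dim(a)
  need <- pmax(size - d[1:3], 0)
  lo <- floor(need / 2)
  if (all(need == 0)) return(list(values = a, offset = c(0L, 0L, 0L)))
  nd <- d
  nd[1:3] <- d[1:3] + need
  out <- array(0, nd)
  idx <- lapply(1:3, function(i) lo[i] + seq_len(d[i]))
  if (length(d) == 3) out[idx[[1]], idx[[2]], idx[[3]]] <- a
  else out[idx[[1]], idx[[2]], idx[[3]], ] <- a
  list(values = out, offset = as.integer(lo))
}

#' Sample a training patch with foreground oversampling
#'
#' With probability `fg_prob` the patch is centered on a uniformly chosen
#' tumor voxel (clamped so the patch stays inside the padded source);
#' otherwise the position is uniform.  Sources smaller than the patch are
#' zero-padded symmetrically.  Uses the R session RNG.
#'
#' @param fused A `fused_volume`.
#' @param label A `label_volume` on the same grid.
#' @param size Patch edge length in voxels (scalar or length-3).
#' @param fg_prob Probability of forcing a tumor-centered patch.
#' @return A list of class `patch` with `channels` (4D), `label` (3D) and
#'   `source_offset` (0-based crop start in the padded source grid).
#' @export
sample_patch <- function(fused, label, size, fg_prob = 0.5) {
  stopifnot(inherits(fused, "fused_volume"), inherits(label, "label_volume"))
  size <- rep(as.integer(size), length.out = 3)
  if (fg_prob < 0 || fg_prob > 1) stop("fg_prob must be in [0, 1]")
  pc <- pad_to_size(fused$channels, size)
  pl <- pad_to_size(label$values, size)
  d <- dim(pl$values)
  fg <- NULL
  force_fg <- runif(1) < fg_prob
  if (force_fg) {
    fg <- which(pl$values > 0)
    if (length(fg) == 0) {
      warning("fg_prob requested a tumor patch but the label is empty; ",
              "falling back to uniform placement")
      force_fg <- FALSE
    }
  }
  if (force_fg) {
    v <- fg[sample.int(length(fg), 1L)] - 1L
    ctr <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
    start <- pmin(pmax(ctr - size %/% 2, 0), d - size)
  } else {
    start <- vapply(1:3, function(a)
      if (d[a] > size[a]) sample.int(d[a] - size[a] + 1L, 1L) - 1L else 0L,
      numeric(1))
  }
  idx <- lapply(1:3, function(a) start[a] + seq_len(size[a]))
  structure(list(
    channels = pc$values[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE],
    label = pl$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
    source_offset = as.integer(start)), class = "patch")
}

# In-plane rotation + isotropic zoom resampling about the patch center.
# Returns continuous source coordinates for every target voxel.
spatial_coords <- function(d, zoom = 1, theta = 0) {
  ctr <- (d - 1) / 2
  cx <- (seq_len(d[1]) - 1 - ctr[1])
  cy <- (seq_len(d[2]) - 1 - ctr[2])
  cz <- (seq_len(d[3]) - 1 - ctr[3])
  co <- coord_arrays(cx, cy, cz)
  # inverse map: target -> source
  ct <- cos(-theta); st <- sin(-theta)
  sx <- (co$sx * ct - co$sy * st) / zoom + ctr[1]
  sy <- (co$sx * st + co$sy * ct) / zoom + ctr[2]
  sz <- co$sz / zoom + ctr[3]
  list(sx = sx, sy = sy, sz = sz)
}

apply_spatial <- function(patch, zoom = 1, theta = 0) {
  d <- dim(patch$label)
  co <- spatial_coords(d, zoom, theta)
  nch <- dim(patch$channels)[4]
  for (c in seq_len(nch))
    patch$channels[, , , c] <- sample_grid(patch$channels[, , , c],
                                           co$sx, co$sy, co$sz, "linear")
  patch$label[] <- sample_grid(patch$label, co$sx, co$sy, co$sz, "nearest")
  patch
}

center_crop_patch <- function(patch, target) {
  d <- dim(patch$label)
  target <- rep(as.integer(target), length.out = 3)
  if (any(target > d)) stop("target crop larger than patch")
  start <- (d - target) %/% 2
  idx <- lapply(1:3, function(a) start[a] + seq_len(target[a]))
  patch$channels <- patch$channels[idx[[1]], idx[[2]], idx[[3]], ,
                                   drop = FALSE]
  patch$label <- patch$label[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  patch
}

#' Augment a training patch and center-crop to the network size
#'
#' Transforms are applied independently with their configured
#' probabilities in the fixed order flip, zoom, brightness, contrast,
#' noise, rotation; the label undergoes the same spatial transforms with
#' nearest-neighbor interpolation and is untouched by intensity
#' transforms.  The result is the center crop at `target_size`.
#'
#' @param patch A `patch` (enlarged; see [augment_margin()]).
#' @param cfg An [augment_config()].
#' @param target_size Final patch edge length (scalar or length-3).
#' @param force Optional character vector of transform names
#'   (`"flip"`, `"scale"`, `"brightness"`, `"contrast"`, `"noise"`,
#'   `"rotate"`) applied with probability 1; transforms not listed are
#'   skipped.  Used for deterministic testing.
#' @return The augmented, cropped `patch`.
#' @export
augment <- function(patch, cfg, target_size, force = NULL) {
  stopifnot(inherits(patch, "patch"), inherits(cfg, "augment_config"))
  target_size <- rep(as.integer(target_size), length.out = 3)
  if (any(target_size > dim(patch$label))) stop("target larger than patch")
  on_ <- function(name, p) {
    if (!is.null(force)) return(name %in% force)
    runif(1) < p
  }
  if (on_("flip", cfg$p_flip)) {
    patch$channels <- patch$channels[dim(patch$channels)[1]:1, , , ,
                                     drop = FALSE]
    patch$label <- patch$label[dim(patch$label)[1]:1, , , drop = FALSE]
  }
  if (on_("scale", cfg$p_scale)) {
    f <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
    patch <- apply_spatial(patch, zoom = f)
  }
  if (on_("brightness", cfg$p_brightness)) {
    f <- runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    patch$channels <- patch$channels * f
  }
  if (on_("contrast", cfg$p_contrast)) {
    f <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    for (c in seq_len(dim(patch$channels)[4])) {
      v <- patch$channels[, , , c]
      rng <- range(v)
      v <- mean(v) + f * (v - mean(v))
      patch$channels[, , , c] <- pmin(pmax(v, rng[1]), rng[2])
    }
  }
  if (on_("noise", cfg$p_noise)) {
    sdv <- runif(1, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
    patch$channels <- patch$channels +
      array(rnorm(length(patch$channels), sd = sdv), dim(patch$channels))
  }
  if (on_("rotate", cfg$p_rotate)) {
    th <- runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg) * pi / 180
    patch <- apply_spatial(patch, theta = th)
  }
  center_crop_patch(patch, target_size)
}

#' Downsample a binary label to a deep-supervision pyramid
#'
#' Level `i` keeps every `2^(i-1)`-th voxel starting at the grid corner
#' (stride sampling), so each level stays binary.
#'
#' @param label 3D binary array (or `label_volume`).
#' @param n_scales Number of levels (full resolution first).
#' @return List of `n_scales` binary arrays at full, 1/2, 1/4, ...
#'   resolution.
#' @export
downsample_labels <- function(label, n_scales) {
  if (inherits(label, "label_volume")) label <- label$values
  d <- dim(label)
  if (n_scales < 1) stop("n_scales must be >= 1")
  if (any(d %% 2^(n_scales - 1) != 0))
    stop("label shape must be divisible by 2^(n_scales - 1)")
  lapply(seq_len(n_scales), function(i) {
    s <- 2^(i - 1)
    label[seq(1, d[1], by = s), seq(1, d[2], by = s), seq(1, d[3], by = s),
          drop = FALSE]
  })
}
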