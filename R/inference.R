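# Whole-volume prediction: overlapping sliding windows with uniform
# overlap averaging, optional left-right flip test-time averaging,
# thresholding, back-resampling to the native grid, and probability-map
# ensembling.

#' Inference configuration
#'
#' @param window Sliding-window edge length in voxels (the training patch
#'   size); scalar or length-3.
#' @param stride_fraction Stride as a fraction of the window (default 1/4,
#'   i.e. windows overlap by three quarters).
#' @param flip_tta Average predictions over the left-right flipped copy of
#'   each window.
#' @param threshold Probability threshold for the binary mask (ties go to
#'   foreground).
#' @param availability Channels supplied at deployment: `"both"`,
#'   `"CT-only"`, or `"PET-only"` (the missing one is zero-filled).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(window, stride_fraction = 0.25,
                             flip_tta = TRUE, threshold = 0.5,
                             availability = c("both", "CT-only",
                                              "PET-only")) {
  if (stride_fraction <= 0 || stride_fraction > 1)
    stop("stride_fraction must be in (0, 1]")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  structure(list(window = rep(as.integer(window), length.out = 3),
                 stride_fraction = stride_fraction,
                 flip_tta = isTRUE(flip_tta), threshold = threshold,
                 availability = match.arg(availability)),
            class = "inference_config")
}

#' Sliding-window start positions along one axis
#'
#' Positions start at 0, advance by `stride`, and always include a final
#' position flush with the far edge, so the union of windows covers the
#' whole extent.
#'
#' @param extent Axis length in voxels.
#' @param window Window length (<= extent).
#' @param stride Step in voxels (>= 1).
#' @return Integer vector of 0-based start indices.
#' @export
sliding_window_positions <- function(extent, window, stride) {
  if (window > extent) stop("window exceeds the (padded) extent")
  if (stride < 1) stop("stride must be >= 1")
  last <- extent - window
  pos <- seq(0L, last, by = as.integer(stride))
  if (pos[length(pos)] != last) pos <- c(pos, as.integer(last))
  as.integer(pos)
}

flip_lr <- function(a) {
  if (length(dim(a)) == 4) a[dim(a)[1]:1, , , , drop = FALSE]
  else a[dim(a)[1]:1, , , drop = FALSE]
}

#' Sliding-window whole-volume prediction
#'
#' Extracts overlapping windows (stride = `stride_fraction` x window,
#' final window flush with the edge), predicts each with the network's
#' finest deep-supervision head, and averages overlapping predictions
#' uniformly.  With `flip_tta` each window is additionally evaluated
#' left-right flipped, un-flipped, and averaged 50/50 with the direct
#' prediction.  Volumes smaller than the window are zero-padded
#' symmetrically and un-padded after reassembly.  Inference is
#' deterministic.
#'
#' @param network A `segnet` or a mock prediction function (see
#'   [predict_patch()]).
#' @param fused A preprocessed `fused_volume`.
#' @param cfg An [inference_config()].
#' @return A `probability_map` on the fused grid.
#' @export
predict_volume <- function(network, fused, cfg) {
  stopifnot(inherits(fused, "fused_volume"),
            inherits(cfg, "inference_config"))
  fused <- simulate_missing(fused, cfg$availability)
  x <- fused$channels
  if (inherits(network, "segnet")) {
    if (network$cfg$modality == "CT" && !fused$availability["CT"])
      stop("CT-only network cannot run without the CT channel")
    if (network$cfg$modality == "PET" && !fused$availability["PET"])
      stop("PET-only network cannot run without the PET channel")
    x <- select_channels(x, network$cfg$modality)
  }
  d0 <- dim(x)[1:3]
  pd <- pad_to_size(x, cfg$window)
  x <- pd$values
  d <- dim(x)[1:3]
  stride <- pmax(1L, as.integer(round(cfg$window * cfg$stride_fraction)))
  pos <- lapply(1:3, function(a)
    sliding_window_positions(d[a], cfg$window[a], stride[a]))
  acc <- array(0, d)
  cnt <- array(0, d)
  for (p3 in pos[[3]]) for (p2 in pos[[2]]) for (p1 in pos[[1]]) {
    i1 <- p1 + seq_len(cfg$window[1])
    i2 <- p2 + seq_len(cfg$window[2])
    i3 <- p3 + seq_len(cfg$window[3])
    sub <- x[i1, i2, i3, , drop = FALSE]
    p <- predict_patch(network, sub)
    if (cfg$flip_tta) {
      pf <- predict_patch(network, flip_lr(sub))
      p <- (p + pf[dim(pf)[1]:1, , , drop = FALSE]) / 2
    }
    acc[i1, i2, i3] <- acc[i1, i2, i3] + p
    cnt[i1, i2, i3] <- cnt[i1, i2, i3] + 1
  }
  out <- acc / cnt
  off <- pd$offset
  out <- out[off[1] + seq_len(d0[1]), off[2] + seq_len(d0[2]),
             off[3] + seq_len(d0[3]), drop = FALSE]
  probability_map(out, fused$spacing, fused$origin)
}

#' Threshold a probability map into a binary mask
#'
#' Voxels with probability greater than or equal to the threshold become
#' foreground (the tie at exactly `threshold` is foreground).
#'
#' @param prob A `probability_map`.
#' @param threshold Threshold in (0, 1), default 0.5.
#' @return A `label_volume` on the same grid.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "probability_map"))
  label_volume((prob$values >= threshold) * 1, prob$spacing, prob$origin)
}

#' Resample a prediction back to the native grid of the input image
#'
#' By default the probability map is resampled linearly onto the reference
#' grid and thresholded there; `mask_resample = "nearest"` instead
#' thresholds first and carries the binary mask over with nearest-neighbor
#' interpolation.
#'
#' @param prob A `probability_map` (model output grid).
#' @param reference An `image_volume` whose grid/spacing/origin the output
#'   mask should match.
#' @param threshold Binarization threshold.
#' @param mask_resample `"linear"` (resample probabilities, then
#'   threshold) or `"nearest"` (threshold, then resample the mask).
#' @return A `label_volume` on the reference grid.
#' @export
resample_to_original <- function(prob, reference, threshold = 0.5,
                                 mask_resample = c("linear", "nearest")) {
  stopifnot(inherits(prob, "probability_map"),
            inherits(reference, "image_volume"))
  mask_resample <- match.arg(mask_resample)
  dp <- dim(prob$values); dr <- dim(reference$values)
  # overlap check in world coordinates
  plo <- prob$origin; phi <- prob$origin + (dp - 1) * prob$spacing
  rlo <- reference$origin
  rhi <- reference$origin + (dr - 1) * reference$spacing
  if (any(pmin(phi, rhi) < pmax(plo, rlo)))
    stop("prediction and reference grids do not overlap")
  cc <- lapply(1:3, function(a)
    (rlo[a] + (seq_len(dr[a]) - 1) * reference$spacing[a] - plo[a]) /
      prob$spacing[a])
  co <- coord_arrays(cc[[1]], cc[[2]], cc[[3]])
  if (mask_resample == "linear") {
    v <- sample_grid(prob$values, co$sx, co$sy, co$sz, "linear")
    out <- (v >= threshold) * 1
  } else {
    m <- (prob$values >= threshold) * 1
    out <- sample_grid(m, co$sx, co$sy, co$sz, "nearest")
  }
  label_volume(out, reference$spacing, reference$origin)
}

#' Average probability maps of several models
#'
#' Voxelwise arithmetic mean; all maps must live on the identical grid.
#'
#' @param maps List of `probability_map`s.
#' @return The mean `probability_map`.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) < 1) stop("need at least one probability map")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        any(abs(m$spacing - ref$spacing) > 1e-9) ||
        any(abs(m$origin - ref$origin) > 1e-9))
      stop("probability maps must share one grid")
  }
  avg <- Reduce(`+`, lapply(maps, function(m) m$values)) / length(maps)
  probability_map(avg, ref$spacing, ref$origin)
}
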