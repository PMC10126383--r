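# Segmentation evaluation: Dice similarity coefficient, Hausdorff
# distance in physical mm, two-way volume intraclass correlation with
# bootstrap dispersion, and two-sample z comparisons between models.

mask_values <- function(m) {
  if (inherits(m, "label_volume")) m$values else as.array(m)
}

#' Dice similarity coefficient
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)` where X is the ground truth and Y the
#' predicted mask.  When both masks are empty the overlap is vacuously
#' perfect and 1 is returned with a warning.
#'
#' @param x Ground-truth binary mask (`label_volume` or array).
#' @param y Predicted binary mask on the same grid.
#' @return DSC in \[0, 1\].
#' @export
dsc <- function(x, y) {
  xv <- mask_values(x); yv <- mask_values(y)
  if (!identical(dim(xv), dim(yv))) stop("masks must share one grid")
  sx <- sum(xv); sy <- sum(yv)
  if (sx + sy == 0) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(xv * yv) / (sx + sy)
}

# Boundary voxels: foreground voxels with at least one 6-neighbor that is
# background (volume edges count as background).  Returns an n x 3 matrix
# of physical coordinates (mm).
boundary_points <- function(vals, spacing) {
  d <- dim(vals)
  fg <- vals > 0
  inner <- array(TRUE, d)
  shift_and <- function(acc, ax, dir) {
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) { idx_dst[[ax]] <- seq_len(d[ax] - 1)
                   idx_src[[ax]] <- 2:d[ax] }
    else { idx_dst[[ax]] <- 2:d[ax]
           idx_src[[ax]] <- seq_len(d[ax] - 1) }
    nb <- array(FALSE, d)  # out-of-volume neighbors are background
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      fg[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1)) inner <- shift_and(inner, ax, dir)
  bnd <- which(fg & !inner, arr.ind = TRUE)
  sweep(bnd - 1, 2, spacing, "*")
}

# Directed distances: for each row of A, distance to the nearest row of B.
nearest_distances <- function(A, B) {
  nb <- nrow(B)
  b2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  chunk <- max(1L, floor(2e6 / nb))
  for (s in seq(1, nrow(A), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(A))
    Ac <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, "+") - 2 * Ac %*% t(B)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Hausdorff distance between two masks (mm)
#'
#' Symmetric Hausdorff distance over boundary voxel centers in physical
#' coordinates: the larger of the two directed maximum nearest-neighbor
#' distances.  `percentile < 100` gives the corresponding percentile
#' variant (e.g. 95 for HD95).
#'
#' @param x,y Binary masks (`label_volume`s on the same grid, or arrays).
#' @param spacing Voxel spacing in mm (taken from `x` when it is a
#'   `label_volume`).
#' @param percentile Percentile of the directed distance distributions
#'   (default 100 = maximum).
#' @return Distance in mm.
#' @export
hausdorff <- function(x, y, spacing = NULL, percentile = 100) {
  if (inherits(x, "label_volume") && is.null(spacing)) spacing <- x$spacing
  if (is.null(spacing)) stop("spacing required when masks are plain arrays")
  xv <- mask_values(x); yv <- mask_values(y)
  if (!identical(dim(xv), dim(yv))) stop("masks must share one grid")
  if (sum(xv) == 0 || sum(yv) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  A <- boundary_points(xv, spacing)
  B <- boundary_points(yv, spacing)
  dab <- nearest_distances(A, B)
  dba <- nearest_distances(B, A)
  if (percentile >= 100) max(max(dab), max(dba))
  else max(quantile(dab, percentile / 100, names = FALSE),
           quantile(dba, percentile / 100, names = FALSE))
}

# Two-way ANOVA mean squares for an n x k ratings table.
icc_mean_squares <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  rm_ <- rowMeans(tab); cm_ <- colMeans(tab)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  res <- sweep(sweep(tab, 1, rm_, "-"), 2, cm_, "-") + grand
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Two-way intraclass correlation of tumor volumes
#'
#' Single-measure ICC from the two-way ANOVA decomposition with cases as
#' rows and the two raters (ground truth, prediction) as columns.
#' `type = "consistency"` is ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE);
#' `type = "agreement"` is ICC(A,1), which additionally charges the
#' rater-mean difference.
#'
#' @param v_true,v_pred Volumes (mm^3) per case, equal lengths, n >= 3.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return ICC in \[-1, 1\].
#' @export
volume_icc <- function(v_true, v_pred,
                       type = c("consistency", "agreement")) {
  type <- match.arg(type)
  if (length(v_true) != length(v_pred)) stop("volume vectors must match")
  if (length(v_true) < 3) stop("volume ICC needs at least 3 cases")
  tab <- cbind(v_true, v_pred)
  ms <- icc_mean_squares(tab)
  if (abs(ms$msr) < 1e-300 && abs(ms$mse) < 1e-300)
    stop("degenerate volume table: no between-case variance")
  if (type == "consistency") {
    (ms$msr - ms$mse) / (ms$msr + (ms$k - 1) * ms$mse)
  } else {
    (ms$msr - ms$mse) /
      (ms$msr + (ms$k - 1) * ms$mse +
         ms$k / ms$n * (ms$msc - ms$mse))
  }
}

#' Bootstrap standard deviation of the volume ICC
#'
#' Resamples cases with replacement `n_boot` times, recomputes the ICC on
#' each resample, and returns the SD across replicates.  Replicates with
#' no between-case variance are skipped (their count is reported in a
#' warning).
#'
#' @inheritParams volume_icc
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Bootstrap SD of the ICC.
#' @export
bootstrap_sd <- function(v_true, v_pred, n_boot = 1000, seed = 1L,
                         type = c("consistency", "agreement")) {
  type <- match.arg(type)
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- length(v_true)
  set.seed(as.integer(seed))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vt <- v_true[idx]; vp <- v_pred[idx]
    ok <- tryCatch({
      vals[b] <- volume_icc(vt, vp, type); TRUE
    }, error = function(e) FALSE)
  }
  skipped <- sum(is.na(vals))
  if (skipped > 0)
    warning(sprintf("%d degenerate bootstrap replicate(s) skipped",
                    skipped))
  sd(vals, na.rm = TRUE)
}

#' Two-sample z test on summary statistics
#'
#' Unpooled (Welch-style) z statistic
#' `z = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with a two-sided p
#' value from the standard normal.
#'
#' @param mean1,sd1,n1 Summary statistics of sample 1.
#' @param mean2,sd2,n2 Summary statistics of sample 2.
#' @return List with `z` and `p`.
#' @export
two_sample_z <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both samples need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  if (se == 0) {
    if (mean1 == mean2) return(list(z = 0, p = 1))
    return(list(z = sign(mean1 - mean2) * Inf, p = 0))
  }
  z <- (mean1 - mean2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Evaluate one model's predictions against ground truth
#'
#' Computes per-case DSC, Hausdorff distance (mm) and mask volumes
#' (mm^3), aggregates means and SDs across cases, and the two-way volume
#' ICC with its bootstrap SD.  Cases with an empty mask have no defined
#' Hausdorff distance and are excluded from the HD aggregate with a
#' warning.
#'
#' @param predictions,truths Lists of `label_volume`s, matched per case
#'   and pairwise on identical grids.
#' @param hd_percentile Hausdorff percentile (default 100 = maximum).
#' @param icc_type ICC flavor, see [volume_icc()].
#' @param n_boot Bootstrap replicates for the ICC SD.
#' @param seed Seed for the bootstrap.
#' @return An object of class `metrics_report`: `per_case` data frame,
#'   `aggregate` list (`dsc_mean`, `dsc_sd`, `hd_mean`, `hd_sd`, `n`),
#'   and `icc` list (`value`, `sd`).
#' @export
evaluate_model <- function(predictions, truths, hd_percentile = 100,
                           icc_type = "consistency", n_boot = 1000,
                           seed = 1L) {
  if (length(predictions) != length(truths))
    stop("prediction and truth case lists must match")
  n <- length(truths)
  per <- data.frame(case = seq_len(n), dsc = NA_real_, hd = NA_real_,
                    vol_true = NA_real_, vol_pred = NA_real_)
  for (i in seq_len(n)) {
    tr <- truths[[i]]; pr <- predictions[[i]]
    if (!identical(dim(tr$values), dim(pr$values)))
      stop("case ", i, ": prediction and truth grids differ")
    vox <- prod(tr$spacing)
    per$dsc[i] <- dsc(tr, pr)
    per$vol_true[i] <- sum(tr$values) * vox
    per$vol_pred[i] <- sum(pr$values) * vox
    if (sum(tr$values) > 0 && sum(pr$values) > 0)
      per$hd[i] <- hausdorff(tr, pr, percentile = hd_percentile)
  }
  if (anyNA(per$hd))
    warning(sprintf("%d case(s) with an empty mask excluded from HD",
                    sum(is.na(per$hd))))
  agg <- list(dsc_mean = mean(per$dsc),
              dsc_sd = if (n > 1) sd(per$dsc) else NA_real_,
              hd_mean = mean(per$hd, na.rm = TRUE),
              hd_sd = if (sum(!is.na(per$hd)) > 1)
                sd(per$hd, na.rm = TRUE) else NA_real_,
              n = n)
  icc <- list(value = NA_real_, sd = NA_real_)
  if (n >= 3) {
    icc$value <- tryCatch(
      volume_icc(per$vol_true, per$vol_pred, icc_type),
      error = function(e) NA_real_)
    if (!is.na(icc$value))
      icc$sd <- suppressWarnings(
        bootstrap_sd(per$vol_true, per$vol_pred, n_boot, seed, icc_type))
  }
  structure(list(per_case = per, aggregate = agg, icc = icc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<metrics_report> n = %d cases\n", a$n))
  cat(sprintf("  DSC %.3f (%.3f)   HD %.2f (%.2f) mm   ICC %.3f (%.3f)\n",
              a$dsc_mean, a$dsc_sd %||% NA, a$hd_mean, a$hd_sd %||% NA,
              x$icc$value, x$icc$sd))
  invisible(x)
}
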