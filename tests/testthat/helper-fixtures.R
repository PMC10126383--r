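# Shared fixtures and independent oracles used across test files.

# Small phantom spec on a coarse grid; fast to generate and preprocess.
tiny_phantom_spec <- function(seed = 1L, ...) {
  args <- list(grid_shape_ct = c(24, 24, 12), spacing_ct = c(2, 2, 4),
               grid_shape_pet = c(12, 12, 12), spacing_pet = c(4, 4, 4),
               origin_offset_pet = c(2, -2, 2), tumor_radii = c(8, 7, 9),
               seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# A fused volume with deterministic synthetic contents on an n^3 grid.
make_fused <- function(n = 12, spacing = 1, seed = 1) {
  set.seed(seed)
  ct <- array(rnorm(n^3), c(n, n, n))
  pet <- array(rnorm(n^3), c(n, n, n))
  fused_volume(ct, pet, rep(spacing, 3))
}

# Ball label centered in an n^3 grid.
make_ball_label <- function(n = 12, r = 3, spacing = 1) {
  idx <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(idx^2, idx^2, "+"), idx^2, "+")
  label_volume((d2 <= r^2) * 1, rep(spacing, 3))
}

# O(n^2) brute-force symmetric Hausdorff distance over boundary voxels
# (explicit double loop; independent of the implementation's chunked
# vectorized path).
hausdorff_bruteforce <- function(x, y, spacing) {
  pts <- function(v) {
    d <- dim(v)
    fg <- which(v > 0, arr.ind = TRUE)
    keep <- logical(nrow(fg))
    for (i in seq_len(nrow(fg))) {
      p <- fg[i, ]
      edge <- FALSE
      for (ax in 1:3) for (dr in c(-1L, 1L)) {
        q <- p; q[ax] <- q[ax] + dr
        if (q[ax] < 1 || q[ax] > d[ax] || v[q[1], q[2], q[3]] == 0)
          edge <- TRUE
      }
      keep[i] <- edge
    }
    sweep(fg[keep, , drop = FALSE] - 1, 2, spacing, "*")
  }
  A <- pts(x); B <- pts(y)
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        dd <- sqrt(sum((P[i, ] - Q[j, ])^2))
        if (dd < best) best <- dd
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

# Two-way single-measure consistency ICC via base R aov() mean squares --
# the independent route for checking the closed-form implementation.
icc_aov_oracle <- function(v1, v2) {
  n <- length(v1)
  df <- data.frame(y = c(v1, v2),
                   case = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ case + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + mse)
}

# Mock networks for inference tests: plain functions over 4D patches.
mock_constant_net <- function(p) function(x) array(p, dim(x)[1:3])
# exactly left-right flip-equivariant: depends on |x - flipped x| pattern
mock_equivariant_net <- function(x) {
  v <- x[, , , 1] + if (dim(x)[4] > 1) x[, , , 2] else 0
  1 / (1 + exp(-(v + v[dim(v)[1]:1, , ])))
}
# a non-equivariant net whose output depends on left-right position
mock_asymmetric_net <- function(x) {
  d <- dim(x)[1:3]
  ramp <- array(seq(0, 1, length.out = d[1]), d)
  pmin(pmax(1 / (1 + exp(-x[, , , 1])) * ramp, 0), 1)
}
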