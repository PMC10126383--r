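test_that("sliding-window positions tile the extent flush to the edge", {
  expect_identical(sliding_window_positions(128, 128, 32), 0L)
  expect_identical(sliding_window_positions(160, 128, 32), c(0L, 32L))
  expect_identical(sliding_window_positions(150, 128, 32), c(0L, 22L))
  expect_error(sliding_window_positions(100, 128, 32), "extent")
  expect_error(sliding_window_positions(128, 64, 0), "stride")

  # coverage oracle on random configurations
  set.seed(1)
  for (i in 1:30) {
    extent <- sample(20:200, 1)
    window <- sample(5:extent, 1)
    stride <- sample(1:window, 1)
    pos <- sliding_window_positions(extent, window, stride)
    covered <- logical(extent)
    for (p in pos) covered[p + seq_len(window)] <- TRUE
    expect_true(all(covered))
    expect_equal(pos[length(pos)], extent - window)
    expect_true(all(diff(pos) <= stride))
  }
})

test_that("constant mock networks reconstruct exactly constant maps", {
  for (cfgdim in list(c(16, 16, 16), c(20, 16, 24), c(19, 21, 17),
                      c(30, 30, 30), c(13, 13, 13))) {
    set.seed(2)
    f <- fused_volume(array(rnorm(prod(cfgdim)), cfgdim),
                      array(rnorm(prod(cfgdim)), cfgdim), c(1, 1, 1))
    icfg <- inference_config(window = 16, stride_fraction = 0.25,
                             flip_tta = FALSE)
    out <- predict_volume(mock_constant_net(0.37), f, icfg)
    expect_identical(dim(out$values), as.integer(cfgdim))
    expect_true(all(abs(out$values - 0.37) < 1e-12))
  }
})

test_that("sliding-window reassembly reproduces a linear mock exactly", {
  # mock that returns its CT channel (affinely squashed into [0,1]):
  # overlap averaging of identical window contents must reproduce the
  # squashed volume exactly, voxel for voxel
  set.seed(3)
  d <- c(24, 20, 18)
  ctv <- array(runif(prod(d)), d)
  f <- fused_volume(ctv, array(0, d), c(1, 1, 1))
  mock <- function(x) (x[, , , 1] + 1) / 3
  icfg <- inference_config(window = 8, stride_fraction = 0.25,
                           flip_tta = FALSE)
  out <- predict_volume(mock, f, icfg)
  expect_equal(out$values, (ctv + 1) / 3, tolerance = 1e-12)
})

test_that("flip averaging is exact for an equivariant mock", {
  set.seed(4)
  d <- c(20, 16, 16)
  f <- fused_volume(array(rnorm(prod(d)), d), array(rnorm(prod(d)), d),
                    c(1, 1, 1))
  base <- inference_config(window = 16, flip_tta = FALSE)
  tta <- inference_config(window = 16, flip_tta = TRUE)
  a <- predict_volume(mock_equivariant_net, f, base)
  b <- predict_volume(mock_equivariant_net, f, tta)
  expect_lt(max(abs(a$values - b$values)), 1e-6)

  # for an asymmetric mock the two differ, and mirroring the whole input
  # mirrors the non-TTA output exactly
  a2 <- predict_volume(mock_asymmetric_net, f, base)
  b2 <- predict_volume(mock_asymmetric_net, f, tta)
  expect_gt(max(abs(a2$values - b2$values)), 1e-6)
  fm <- fused_volume(f$channels[d[1]:1, , , 1], f$channels[d[1]:1, , , 2],
                     c(1, 1, 1))
  m1 <- predict_volume(mock_asymmetric_net, fm, base)
  # mirrored input -> output of the mirrored mock; compare via the mock's
  # own equivariance-breaking ramp: predict on mirrored input then mirror
  mock_mirror <- function(x) {
    out <- mock_asymmetric_net(x[dim(x)[1]:1, , , , drop = FALSE])
    out[dim(out)[1]:1, , ]
  }
  m2 <- predict_volume(mock_mirror, f, base)
  expect_equal(m1$values[d[1]:1, , ], m2$values, tolerance = 1e-12)

  # probabilities stay in [0, 1]
  expect_true(all(b$values >= 0 & b$values <= 1))
})

test_that("trained-net inference respects availability settings", {
  f <- make_fused(n = 16, seed = 5)
  cfg <- network_config(n_levels = 2, base_filters = 4, in_channels = 1,
                        modality = "CT")
  net <- build_network(cfg, seed = 6)
  icfg_ok <- inference_config(window = 8, availability = "CT-only",
                              flip_tta = FALSE)
  out <- predict_volume(net, f, icfg_ok)
  expect_true(all(out$values >= 0 & out$values <= 1))
  icfg_bad <- inference_config(window = 8, availability = "PET-only")
  expect_error(predict_volume(net, f, icfg_bad), "CT-only network")
})

test_that("binarization thresholds with ties going to foreground", {
  p <- probability_map(array(c(1, 0, 0.5, 0.4999, 0.5001, 0.2),
                             c(6, 1, 1)), c(1, 1, 1))
  m <- binarize(p)
  expect_equal(as.vector(m$values), c(1, 0, 1, 0, 1, 0))
  expect_true(all(binarize(probability_map(array(1, c(2, 2, 2)),
                                           c(1, 1, 1)))$values == 1))
  expect_true(all(binarize(probability_map(array(0, c(2, 2, 2)),
                                           c(1, 1, 1)))$values == 0))
})

test_that("back-resampling to the native grid preserves geometry and volume", {
  set.seed(7)
  # a large uniform-interior blob on a 1 mm grid
  n <- 30
  idx <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(idx^2, idx^2, "+"), idx^2, "+")
  probv <- 1 / (1 + exp((sqrt(d2) - 10)))
  prob <- probability_map(array(probv, c(n, n, n)), c(1, 1, 1))

  ref_same <- image_volume(array(0, c(n, n, n)), c(1, 1, 1),
                           modality = "CT")
  m0 <- resample_to_original(prob, ref_same)
  expect_identical(m0$values, binarize(prob)$values)

  ref <- image_volume(array(0, c(n, n, 6)), c(1, 1, 5), modality = "CT")
  m1 <- resample_to_original(prob, ref)
  expect_equal(m1$spacing, c(1, 1, 5))
  expect_identical(dim(m1$values), c(30L, 30L, 6L))
  v_nat <- sum(binarize(prob)$values) * 1
  v_ref <- sum(m1$values) * 5
  expect_lt(abs(v_ref - v_nat) / v_nat, 0.1)

  # literal mask-then-resample mode stays binary and close to linear mode
  m2 <- resample_to_original(prob, ref, mask_resample = "nearest")
  expect_true(all(m2$values %in% c(0, 1)))

  far <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1), c(500, 500, 500),
                      modality = "CT")
  expect_error(resample_to_original(prob, far), "overlap")
})

test_that("ensemble averaging is the order-invariant voxel mean", {
  set.seed(8)
  mk <- function() probability_map(array(runif(4^3), c(4, 4, 4)),
                                   c(1, 1, 1))
  a <- mk(); b <- mk(); c_ <- mk()
  expect_equal(ensemble_average(list(a, a))$values, a$values)
  z <- probability_map(array(0, c(4, 4, 4)), c(1, 1, 1))
  o <- probability_map(array(1, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(ensemble_average(list(z, o))$values == 0.5))
  expect_equal(ensemble_average(list(a, b, c_))$values,
               ensemble_average(list(c_, a, b))$values)
  bad <- probability_map(array(0.5, c(5, 5, 5)), c(1, 1, 1))
  expect_error(ensemble_average(list(a, bad)), "grid")
})
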