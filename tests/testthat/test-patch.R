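make_case_for_patches <- function(seed = 1L) {
  spec <- tiny_phantom_spec(seed = seed)
  case <- generate_case(spec)
  preprocess_case(case$ct, case$pet, case$label, target_spacing = 2)
}

test_that("foreground oversampling guarantees tumor voxels when forced", {
  pc <- make_case_for_patches()
  set.seed(1)
  for (i in 1:25) {
    p <- sample_patch(pc$fused, pc$label, 8, fg_prob = 1)
    expect_gt(sum(p$label), 0)
  }
  # tumor occupying the whole grid is hit regardless of fg_prob
  full <- label_volume(array(1, dim(pc$label$values)), pc$label$spacing,
                       pc$label$origin)
  p <- sample_patch(pc$fused, full, 8, fg_prob = 0)
  expect_gt(sum(p$label), 0)
  # empty label with forced foreground falls back with a warning
  empty <- label_volume(array(0, dim(pc$label$values)), pc$label$spacing,
                        pc$label$origin)
  expect_warning(sample_patch(pc$fused, empty, 8, fg_prob = 1),
                 "empty")
})

test_that("tumor-containing patch fraction respects the oversampling rate", {
  pc <- make_case_for_patches()
  set.seed(7)
  hits <- vapply(seq_len(1000), function(i)
    sum(sample_patch(pc$fused, pc$label, 8, fg_prob = 0.5)$label) > 0,
    logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("patches smaller than the source are padded symmetrically", {
  pc <- make_case_for_patches()
  big <- dim(pc$label$values) + 6L
  set.seed(2)
  p <- sample_patch(pc$fused, pc$label, big, fg_prob = 0)
  expect_identical(dim(p$label), big)
  expect_identical(dim(p$channels)[1:3], big)
})

test_that("augmentation with all probabilities zero is a center crop", {
  pc <- make_case_for_patches()
  set.seed(3)
  p <- sample_patch(pc$fused, pc$label, 16, fg_prob = 1)
  cfg <- augment_config(p_flip = 0, p_scale = 0, p_brightness = 0,
                        p_contrast = 0, p_noise = 0, p_rotate = 0)
  out <- augment(p, cfg, 8)
  start <- (dim(p$label) - 8L) %/% 2L
  idx <- lapply(1:3, function(a) start[a] + seq_len(8))
  expect_identical(out$label, p$label[idx[[1]], idx[[2]], idx[[3]]])
  expect_identical(out$channels[, , , 1],
                   p$channels[idx[[1]], idx[[2]], idx[[3]], 1])
  expect_error(augment(p, cfg, 20), "larger")
})

test_that("two forced flips cancel; flip commutes with the label pairing", {
  pc <- make_case_for_patches()
  set.seed(4)
  p <- sample_patch(pc$fused, pc$label, 12, fg_prob = 1)
  cfg <- augment_config()
  once <- augment(p, cfg, 8, force = "flip")
  none <- augment(p, cfg, 8, force = character(0))
  twice <- augment(augment(p, cfg, 12, force = "flip"), cfg, 8,
                   force = "flip")
  expect_equal(twice$channels, none$channels)
  expect_equal(twice$label, none$label)
  # spatial transform commutes with channel/label pairing
  expect_equal(once$label, none$label[8:1, , ])
  expect_equal(once$channels[, , , 2], none$channels[8:1, , , 2])
})

test_that("brightness and contrast follow their documented elementwise rules", {
  pc <- make_case_for_patches()
  set.seed(5)
  p <- sample_patch(pc$fused, pc$label, 10, fg_prob = 1)
  cfg <- augment_config()

  set.seed(11)
  out <- augment(p, cfg, 8, force = "brightness")
  f <- withr::with_seed(11, runif(1, 0.75, 1.25))
  ref <- augment(p, cfg, 8, force = character(0))
  expect_equal(out$channels, ref$channels * f, tolerance = 1e-12)
  expect_identical(out$label, ref$label)

  set.seed(12)
  out <- augment(p, cfg, 8, force = "contrast")
  f <- withr::with_seed(12, runif(1, 0.75, 1.25))
  exp_ch <- p$channels
  for (c in 1:2) {
    v <- p$channels[, , , c]
    rng <- range(v)
    exp_ch[, , , c] <- pmin(pmax(mean(v) + f * (v - mean(v)), rng[1]),
                            rng[2])
  }
  start <- (dim(p$label) - 8L) %/% 2L
  idx <- lapply(1:3, function(a) start[a] + seq_len(8))
  expect_equal(out$channels, exp_ch[idx[[1]], idx[[2]], idx[[3]], ,
                                    drop = FALSE],
               tolerance = 1e-12)
})

test_that("augmentation keeps labels binary and is seed-deterministic", {
  pc <- make_case_for_patches()
  cfg <- augment_config()
  set.seed(6)
  for (i in 1:15) {
    p <- sample_patch(pc$fused, pc$label, 14, fg_prob = 0.5)
    out <- augment(p, cfg, 8)
    expect_true(all(out$label %in% c(0, 1)))
  }
  run <- function() {
    set.seed(99)
    p <- sample_patch(pc$fused, pc$label, 14, fg_prob = 0.5)
    augment(p, cfg, 8)
  }
  a <- run(); b <- run()
  expect_identical(a$channels, b$channels)
  expect_identical(a$label, b$label)
})

test_that("in-plane rotation by 90 degrees maps label like channels", {
  # noiseless synthetic patch: an off-center box
  ch <- array(0, c(9, 9, 5, 2))
  lab <- array(0, c(9, 9, 5))
  ch[6:8, 4:6, 2:4, ] <- 1
  lab[6:8, 4:6, 2:4] <- 1
  p <- structure(list(channels = ch, label = lab,
                      source_offset = c(0L, 0L, 0L)), class = "patch")
  rot <- petctseg:::apply_spatial(p, theta = pi / 2)
  # the tumor of the rotated channels equals the rotated label
  expect_equal((rot$channels[, , , 1] > 0.5) * 1, rot$label)
  expect_equal(sum(rot$label), sum(lab))
})

test_that("label pyramids stride-sample and stay binary", {
  lab <- array(1, c(8, 8, 8))
  pyr <- downsample_labels(lab, 3)
  expect_identical(vapply(pyr, function(x) dim(x)[1], integer(1)),
                   c(8L, 4L, 2L))
  expect_true(all(vapply(pyr, function(x) all(x == 1), logical(1))))

  set.seed(8)
  lab <- array((runif(16^3) > 0.5) * 1, c(16, 16, 16))
  pyr <- downsample_labels(lab, 2)
  expect_identical(pyr[[1]], lab)
  expect_identical(pyr[[2]],
                   lab[seq(1, 16, 2), seq(1, 16, 2), seq(1, 16, 2)])
  expect_error(downsample_labels(array(0, c(6, 6, 6)), 3), "divisible")
})
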