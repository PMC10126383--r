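test_that("CT clipping honors the soft-tissue window bounds", {
  v <- image_volume(array(c(700, -1500, 0, 599.5, 600.2, -1000.5),
                          c(6, 1, 1)), c(1, 1, 1), modality = "CT")
  out <- clip_ct(v)
  expect_equal(as.vector(out$values),
               c(600, -1000, 0, 599.5, 600, -1000))
  pet <- image_volume(array(1, c(2, 2, 2)), c(1, 1, 1), modality = "PET")
  expect_error(clip_ct(pet), "CT")
})

test_that("z-normalization uses whole-volume population statistics", {
  v <- image_volume(array(c(0, 0, 2, 2), c(4, 1, 1)), c(1, 1, 1),
                    modality = "PET")
  out <- znormalize(v)
  expect_equal(as.vector(out$values), c(-1, -1, 1, 1))

  set.seed(1)
  r <- image_volume(array(rnorm(4^3, 50, 9), c(4, 4, 4)), c(1, 1, 1),
                    modality = "CT")
  out <- znormalize(r)
  expect_lt(abs(mean(out$values)), 1e-6)
  expect_lt(abs(sqrt(mean((out$values - mean(out$values))^2)) - 1), 1e-6)

  const <- image_volume(array(5, c(3, 3, 3)), c(1, 1, 1), modality = "CT")
  expect_error(znormalize(const), "constant")
})

test_that("isotropic resampling follows the extent convention", {
  set.seed(2)
  v <- image_volume(array(rnorm(50 * 8 * 8), c(50, 8, 8)), c(2, 2, 2),
                    modality = "CT")
  out <- resample_isotropic(v, 1)
  expect_equal(out$spacing, c(1, 1, 1))
  expect_lte(abs(dim(out$values)[1] - 100), 1)
  expect_equal(out$origin, v$origin)

  # already at target -> identity
  iso <- image_volume(array(rnorm(5^3), c(5, 5, 5)), c(1, 1, 1),
                      modality = "PET")
  expect_identical(resample_isotropic(iso, 1)$values, iso$values)

  expect_error(resample_isotropic(iso, -1), "positive")
})

test_that("resampling conserves physical extent and label volume", {
  set.seed(3)
  for (i in 1:5) {
    sp <- runif(3, 0.8, 3.5)
    d <- sample(8:20, 3, replace = TRUE)
    v <- image_volume(array(rnorm(prod(d)), d), sp, modality = "CT")
    tgt <- runif(1, 0.8, 2)
    out <- resample_isotropic(v, tgt)
    in_extent <- d * sp
    out_extent <- dim(out$values) * tgt
    expect_true(all(abs(in_extent - out_extent) <= tgt + 1e-9))
  }
  lab <- make_ball_label(n = 20, r = 6, spacing = 2)
  out <- resample_isotropic(lab, 1)
  expect_true(all(out$values %in% c(0, 1)))
  v_in <- sum(lab$values) * 8
  v_out <- sum(out$values) * 1
  expect_lt(abs(v_out - v_in) / v_in, 0.1)
})

test_that("crop_to_overlap matches the interval-intersection oracle", {
  mk <- function(d, org, sp = 1)
    image_volume(array(rnorm(prod(d)), d), rep(sp, 3), org,
                 modality = "CT")
  set.seed(4)
  # the canonical nested case: one grid strictly inside the other
  ct <- mk(c(40, 40, 40), c(0, 0, 0))
  pet <- mk(c(30, 30, 30), c(5, 5, 5))
  pet$modality <- "PET"
  out <- crop_to_overlap(ct, pet)
  expect_equal(dim(out$ct$values), c(30L, 30L, 30L))
  expect_equal(out$ct$origin, c(5, 5, 5))
  expect_equal(out$pet$origin, out$ct$origin)
  expect_identical(out$pet$values, pet$values)

  # identical grids are unchanged
  same <- crop_to_overlap(ct, ct)
  expect_identical(same$ct$values, ct$values)

  # random integer-offset configurations against the oracle
  for (i in 1:20) {
    d1 <- sample(10:30, 3, TRUE); d2 <- sample(10:30, 3, TRUE)
    o1 <- sample(-5:5, 3, TRUE); o2 <- sample(-5:5, 3, TRUE)
    a <- mk(d1, o1); b <- mk(d2, o2); b$modality <- "PET"
    lo <- pmax(o1, o2); hi <- pmin(o1 + d1 - 1, o2 + d2 - 1)
    if (any(hi < lo)) {
      expect_error(crop_to_overlap(a, b), "overlap")
    } else {
      out <- crop_to_overlap(a, b)
      expect_equal(dim(out$ct$values), as.integer(hi - lo + 1))
      expect_equal(out$ct$origin, as.numeric(lo))
      expect_equal(dim(out$pet$values), dim(out$ct$values))
      # idempotence
      again <- crop_to_overlap(out$ct, out$pet)
      expect_identical(again$ct$values, out$ct$values)
      expect_identical(again$pet$values, out$pet$values)
    }
  }

  far <- mk(c(10, 10, 10), c(100, 100, 100))
  far$modality <- "PET"
  expect_error(crop_to_overlap(ct, far), "overlap")
})

test_that("sub-voxel origin offsets are resolved onto the CT grid", {
  set.seed(5)
  ct <- image_volume(array(rnorm(20^3), c(20, 20, 20)), c(1, 1, 1),
                     c(0, 0, 0), "CT")
  pet <- image_volume(array(rnorm(20^3), c(20, 20, 20)), c(1, 1, 1),
                      c(0.4, -0.3, 0.6), "PET")
  out <- crop_to_overlap(ct, pet)
  expect_equal(out$ct$origin, out$pet$origin)
  expect_identical(dim(out$ct$values), dim(out$pet$values))
})

test_that("preprocess_case fuses, clips before normalizing, keeps volume", {
  spec <- tiny_phantom_spec(seed = 6L)
  case <- generate_case(spec)
  out <- preprocess_case(case$ct, case$pet, case$label, target_spacing = 2)
  f <- out$fused
  expect_s3_class(f, "fused_volume")
  expect_equal(f$spacing, c(2, 2, 2))
  expect_identical(dim(f$channels)[1:3], dim(out$label$values))
  expect_true(all(f$availability))

  # clip-before-normalize: CT channel bounded by the normalized clip bound
  ct_clipped <- clip_ct(case$ct)
  m <- mean(ct_clipped$values)
  s <- sqrt(mean((ct_clipped$values - m)^2))
  expect_gte(min(f$channels[, , , 1]), (-1000 - m) / s - 1e-9)

  # label volume in mm^3 preserved across the grid change
  v_in <- sum(case$label$values) * prod(case$ct$spacing)
  v_out <- sum(out$label$values) * prod(f$spacing)
  expect_lt(abs(v_out - v_in) / v_in, 0.1)

  # order in which modalities are read does not change the result
  out2 <- preprocess_case(clip_ct(case$ct), case$pet, case$label,
                          target_spacing = 2)
  expect_equal(out2$fused$channels, f$channels)
})
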