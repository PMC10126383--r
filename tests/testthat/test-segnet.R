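test_that("deep-supervision head shapes follow the halving bookkeeping", {
  # resolution oracle: head i lives at input_size / 2^(i-1)
  cfg5 <- network_config(n_levels = 5, base_filters = 2, in_channels = 2,
                         filter_cap = 8)
  net5 <- build_network(cfg5, seed = 1)
  x <- array(rnorm(32^3 * 2), c(32, 32, 32, 2))
  heads <- petctseg:::net_forward(net5, x)$heads
  expect_length(heads, 4)
  expect_identical(lapply(heads, dim),
                   lapply(0:3, function(i) rep(as.integer(32 / 2^i), 3)))

  cfg3 <- network_config(n_levels = 3, base_filters = 4, in_channels = 2)
  net3 <- build_network(cfg3, seed = 2)
  heads <- petctseg:::net_forward(net3, x)$heads
  expect_identical(lapply(heads, dim), list(rep(32L, 3), rep(16L, 3)))

  # single- versus dual-input nets differ only in the first layer arity
  cfg1 <- network_config(n_levels = 3, base_filters = 4, in_channels = 1,
                         modality = "PET")
  net1 <- build_network(cfg1, seed = 3)
  h1 <- petctseg:::net_forward(net1, x[, , , 2, drop = FALSE])$heads
  expect_identical(lapply(h1, dim), lapply(heads, dim))

  # probabilities in [0, 1]
  expect_true(all(vapply(heads, function(h)
    all(h >= 0 & h <= 1), logical(1))))

  # indivisible input is rejected
  bad <- array(0, c(30, 32, 32, 2))
  expect_error(petctseg:::net_forward(net3, bad), "divisible")
})

test_that("dilated mode preserves shapes while enlarging receptive field", {
  cfg <- network_config(n_levels = 3, base_filters = 4, in_channels = 2,
                        conv_mode = "dilated")
  net <- build_network(cfg, seed = 4)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2))
  heads <- petctseg:::net_forward(net, x)$heads
  expect_identical(lapply(heads, dim), list(rep(16L, 3), rep(8L, 3)))
})

test_that("supervision weights halve and normalize", {
  expect_equal(supervision_weights(1), 1)
  expect_equal(supervision_weights(2), c(2, 1) / 3)
  expect_equal(supervision_weights(4), c(8, 4, 2, 1) / 15)
  for (n in 1:6) {
    w <- supervision_weights(n)
    expect_equal(sum(w), 1)
    if (n > 1) expect_true(all(diff(w) < 0))
  }
  expect_error(supervision_weights(0), "n_heads")
})

test_that("head loss matches its defining formulas", {
  set.seed(5)
  y <- (array(runif(6^3), c(6, 6, 6)) > 0.5) * 1
  o <- array(runif(6^3), c(6, 6, 6))
  # direct recomputation with independent arithmetic
  s <- 1e-5; eps <- 1e-7
  oc <- pmin(pmax(o, eps), 1 - eps)
  ce <- -sum(y * log(oc) + (1 - y) * log(1 - oc)) / length(o)
  d <- -(2 * sum(oc * y) + s) / (sum(oc) + sum(y) + s)
  expect_equal(head_loss(o, y), ce + d, tolerance = 1e-12)

  # perfect agreement drives the loss to -1 (up to clamping)
  expect_equal(head_loss(y, y), -1, tolerance = 1e-3)

  # uniform 0.5 prediction on a half-foreground label: CE = log 2
  y2 <- array(rep(c(0, 1), 32), c(4, 4, 4))
  o2 <- array(0.5, c(4, 4, 4))
  l <- head_loss(o2, y2)
  d2 <- -(2 * sum(0.5 * y2) + s) / (sum(o2) + sum(y2) + s)
  expect_equal(l - d2, log(2), tolerance = 1e-9)

  # disjoint supports: Dice term vanishes
  ya <- array(0, c(4, 4, 4)); ya[1:2, , ] <- 1
  ob <- array(eps, c(4, 4, 4)); ob[3:4, , ] <- 1 - eps
  dd <- -(2 * sum(pmin(pmax(ob, eps), 1 - eps) * ya) + s) /
    (sum(ob) + sum(ya) + s)
  expect_lt(abs(dd), 1e-3)

  # voxel permutation invariance
  perm <- sample(length(o))
  expect_equal(head_loss(array(o[perm], dim(o)), array(y[perm], dim(y))),
               head_loss(o, y))
  expect_error(head_loss(o, y[1:10]), "match")
})

test_that("composite loss is the normalized weighted head sum", {
  set.seed(6)
  outs <- lapply(c(8, 4), function(n) array(runif(n^3), rep(n, 3)))
  labs <- lapply(c(8, 4), function(n)
    (array(runif(n^3), rep(n, 3)) > 0.5) * 1)
  w <- supervision_weights(2)
  total <- composite_loss(list(outputs = outs, labels = labs, weights = w))
  per_head <- vapply(1:2, function(i) head_loss(outs[[i]], labs[[i]]),
                     numeric(1))
  expect_equal(total, sum(w * per_head), tolerance = 1e-12)
  # one head: total equals that head's loss
  expect_equal(composite_loss(list(outputs = outs[1], labels = labs[1],
                                   weights = 1)), per_head[1])
  expect_error(composite_loss(list(outputs = outs, labels = labs,
                                   weights = c(1))), "length")
  expect_error(composite_loss(list(outputs = outs, labels = labs,
                                   weights = c(0.9, 0.2))), "sum to 1")
})

test_that("polynomial decay starts at lr0 and reaches zero", {
  cfg <- train_config(total_iterations = 1000, lr0 = 0.01,
                      poly_exponent = 0.9)
  expect_equal(poly_lr(0, cfg), 0.01)
  expect_equal(poly_lr(1000, cfg), 0)
  expect_equal(poly_lr(500, cfg), 0.01 * 0.5^0.9)
  lrs <- vapply(0:1000, poly_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(poly_lr(1001, cfg), "iteration")
})

test_that("analytic gradients match central differences everywhere", {
  for (mode in c("conventional", "dilated")) {
    cfg <- network_config(n_levels = 2, base_filters = 4, in_channels = 2,
                          conv_mode = mode)
    net <- build_network(cfg, seed = 7)
    set.seed(8)
    x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
    y <- (array(runif(6 * 6 * 4), c(6, 6, 4)) > 0.5) * 1
    wts <- supervision_weights(1)
    lossfn <- function(nn) {
      fw <- petctseg:::net_forward(nn, x)
      composite_loss(list(outputs = fw$heads, labels = list(y),
                          weights = wts))
    }
    fw <- petctseg:::net_forward(net, x, keep_cache = TRUE)
    gz <- list(wts[1] *
                 petctseg:::head_loss_grad_z(fw$heads[[1]], y))
    grads <- petctseg:::net_backward(net, fw$cache, gz)
    set.seed(9)
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      for (j in sample(seq_along(p), min(3, length(p)))) {
        eps <- 1e-5
        n1 <- net; n1$params[[nm]][j] <- p[j] + eps
        n2 <- net; n2$params[[nm]][j] <- p[j] - eps
        num <- (lossfn(n1) - lossfn(n2)) / (2 * eps)
        expect_equal(grads[[nm]][j], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (%s)", nm, j, mode))
      }
    }
  }
})

test_that("channel dropout keeps one channel bit-exact, zeros the other", {
  f <- make_fused(n = 8, seed = 10)
  out <- channel_dropout(f, enabled = FALSE)
  expect_identical(out$channels, f$channels)

  # force each branch by scanning seeds
  seen <- character(0)
  for (s in 1:50) {
    set.seed(s)
    out <- channel_dropout(f, p_keep_both = 0.5)
    br <- attr(out, "branch")
    seen <- union(seen, br)
    if (br == "both") {
      expect_identical(out$channels, f$channels)
    } else if (br == "CT") {
      expect_true(all(out$channels[, , , 2] == 0))
      expect_identical(out$channels[, , , 1], f$channels[, , , 1])
      expect_false(out$availability[["PET"]])
    } else {
      expect_true(all(out$channels[, , , 1] == 0))
      expect_identical(out$channels[, , , 2], f$channels[, , , 2])
      expect_false(out$availability[["CT"]])
    }
    if (length(seen) == 3) break
  }
  expect_setequal(seen, c("both", "CT", "PET"))

  set.seed(1)
  dropped <- channel_dropout(f, p_keep_both = 0)
  expect_error(channel_dropout(dropped), "complete")
})

test_that("training runs, records dropout branches, and zero iterations is a no-op", {
  spec <- tiny_phantom_spec(seed = 11L)
  case <- generate_case(spec)
  pc <- preprocess_case(case$ct, case$pet, case$label, target_spacing = 2)
  cfg <- network_config(n_levels = 2, base_filters = 4, in_channels = 2)
  net <- build_network(cfg, seed = 12)

  t0 <- train_config(total_iterations = 0, patch_size = 8)
  fit0 <- train_network(net, list(pc), t0)
  expect_identical(fit0$network$params, net$params)
  expect_length(fit0$trace, 0)

  t1 <- train_config(total_iterations = 25, patch_size = 8,
                     channel_dropout_enabled = TRUE, seed = 13)
  fit1 <- train_network(net, list(pc), t1)
  expect_length(fit1$trace, 25)
  expect_true(all(is.finite(fit1$trace)))
  expect_true(all(fit1$dropout_log %in% c("both", "CT", "PET")))
  # deterministic under the same seed
  fit2 <- train_network(net, list(pc), t1)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$network$params, fit2$network$params)
})
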