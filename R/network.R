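# 3D encoder-decoder segmentation network (conventional and dilated
# variants) with deep-supervision heads.  Convolutions run in compiled
# kernels (src/conv3d.cpp); normalization, activations, transposed
# convolutions and the heads are vectorized R.  The backward pass is
# written out explicitly per layer, so training has no external autodiff
# dependency.

#' Network architecture configuration
#'
#' The encoder halves the spatial resolution `n_levels - 1` times (stride-2
#' convolutions); the decoder mirrors it with 2x2x2 transposed convolutions
#' and skip connections to same-resolution encoder outputs.  Every
#' convolution is followed by instance normalization and a leaky ReLU.
#' Each of the `n_ds_heads` finest decoder blocks carries a 1x1x1
#' convolution head emitting a per-voxel foreground probability.  In
#' dilated mode all stride-1 convolutions use the configured dilation
#' factor with unchanged kernel size.
#'
#' @param n_levels Encoder/decoder depth (>= 2); 5 for the full-scale
#'   configuration.
#' @param base_filters Filters at the finest level, doubling per level.
#' @param filter_cap Upper bound on filters per level.
#' @param conv_mode `"conventional"` or `"dilated"`.
#' @param dilation Dilation factor used in dilated mode (default 2).
#' @param kernel Convolution kernel size (odd; default 3).
#' @param in_channels 1 (single-modality) or 2 (CT + PET).
#' @param modality Which channel(s) the network consumes: `"both"`,
#'   `"CT"`, or `"PET"`; must agree with `in_channels`.
#' @param negative_slope Leaky-ReLU slope (default 0.01).
#' @param n_ds_heads Number of deep-supervision heads (default
#'   `n_levels - 1`, i.e. every decoder block).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_levels = 5, base_filters = 32,
                           filter_cap = 320,
                           conv_mode = c("conventional", "dilated"),
                           dilation = 2, kernel = 3, in_channels = 2,
                           modality = c("both", "CT", "PET"),
                           negative_slope = 0.01,
                           n_ds_heads = n_levels - 1) {
  conv_mode <- match.arg(conv_mode)
  modality <- match.arg(modality)
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (kernel %% 2 != 1) stop("kernel size must be odd")
  if (dilation < 1) stop("dilation must be >= 1")
  if (!in_channels %in% c(1L, 2L)) stop("in_channels must be 1 or 2")
  if ((modality == "both") != (in_channels == 2))
    stop("modality 'both' requires in_channels = 2 and vice versa")
  if (n_ds_heads < 1 || n_ds_heads > n_levels - 1)
    stop("n_ds_heads must be between 1 and n_levels - 1")
  structure(list(n_levels = as.integer(n_levels),
                 base_filters = as.integer(base_filters),
                 filter_cap = as.integer(filter_cap),
                 conv_mode = conv_mode, dilation = as.integer(dilation),
                 kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 modality = modality,
                 negative_slope = negative_slope,
                 n_ds_heads = as.integer(n_ds_heads)),
            class = "network_config")
}

level_filters <- function(cfg)
  pmin(cfg$base_filters * 2^(seq_len(cfg$n_levels) - 1), cfg$filter_cap)

he_init <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

#' Build an untrained segmentation network
#'
#' Weights use He initialization; instance-norm gains start at 1 and
#' biases at 0.
#'
#' @param cfg A [network_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `segnet` (configuration + parameter list).
#' @export
build_network <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- level_filters(cfg)
  k <- cfg$kernel
  p <- list()
  add_conv <- function(p, name, cin, cout) {
    p[[paste0(name, ".W")]] <- he_init(k, cin, cout)
    p[[paste0(name, ".b")]] <- numeric(cout)
    p[[paste0(name, ".g")]] <- rep(1, cout)
    p[[paste0(name, ".be")]] <- numeric(cout)
    p
  }
  for (l in seq_len(cfg$n_levels)) {
    cin <- if (l == 1) cfg$in_channels else f[l - 1]
    p <- add_conv(p, sprintf("enc%d.c1", l), cin, f[l])
    p <- add_conv(p, sprintf("enc%d.c2", l), f[l], f[l])
  }
  for (l in seq_len(cfg$n_levels - 1)) {
    p[[sprintf("dec%d.up.W", l)]] <-
      array(rnorm(8 * f[l + 1] * f[l], sd = sqrt(2 / (8 * f[l + 1]))),
            dim = c(2, 2, 2, f[l + 1], f[l]))
    p[[sprintf("dec%d.up.b", l)]] <- numeric(f[l])
    p <- add_conv(p, sprintf("dec%d.c1", l), 2 * f[l], f[l])
    p <- add_conv(p, sprintf("dec%d.c2", l), f[l], f[l])
    if (l <= cfg$n_ds_heads) {
      p[[sprintf("dec%d.head.W", l)]] <-
        matrix(rnorm(f[l], sd = sqrt(1 / f[l])), f[l], 1)
      p[[sprintf("dec%d.head.b", l)]] <- 0
    }
  }
  structure(list(cfg = cfg, params = p), class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<segnet> %d levels, %s convolution, %d input channel(s), %d heads, %d parameters\n",
    x$cfg$n_levels, x$cfg$conv_mode, x$cfg$in_channels, x$cfg$n_ds_heads,
    np))
  invisible(x)
}

# ---- layer primitives --------------------------------------------------

conv_fwd <- function(x, W, b, stride, dil) {
  k <- dim(W)[1]
  pad <- if (stride == 1) dil * (k - 1) / 2 else (k - 1) %/% 2
  y <- if (stride == 1)
    .conv3d_fwd_same(x, W, b, as.integer(dil))
  else
    .conv3d_fwd(x, W, b, as.integer(stride), as.integer(pad),
                as.integer(dil))
  list(y = y, cache = list(x = x, stride = as.integer(stride),
                           pad = as.integer(pad), dil = as.integer(dil)))
}

conv_bwd <- function(cache, W, gy) {
  r <- if (cache$stride == 1)
    .conv3d_bwd_same(cache$x, W, gy, cache$dil)
  else
    .conv3d_bwd(cache$x, W, gy, cache$stride, cache$pad, cache$dil)
  list(gx = r$gx, gW = r$gw, gb = r$gb)
}

inorm_fwd <- function(x, g, be, eps = 1e-5) {
  d <- dim(x); C <- d[4]; N <- prod(d[1:3])
  xm <- matrix(x, N, C)
  mu <- .colMeans(xm, N, C)
  xc <- xm - rep(mu, each = N)
  v <- .colMeans(xc * xc, N, C)
  sdinv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(sdinv, each = N)
  out <- xhat * rep(g, each = N) + rep(be, each = N)
  dim(out) <- d
  list(y = out, cache = list(xhat = xhat, sdinv = sdinv, d = d))
}

inorm_bwd <- function(cache, g, gy) {
  d <- cache$d; C <- d[4]; N <- prod(d[1:3])
  gm <- matrix(gy, N, C)
  xhat <- cache$xhat
  dgamma <- .colSums(gm * xhat, N, C)
  dbeta <- .colSums(gm, N, C)
  dxhat <- gm * rep(g, each = N)
  s1 <- .colSums(dxhat, N, C)
  s2 <- .colSums(dxhat * xhat, N, C)
  dz <- (dxhat - rep(s1 / N, each = N) - xhat * rep(s2 / N, each = N)) *
    rep(cache$sdinv, each = N)
  dim(dz) <- d
  list(gx = dz, gg = dgamma, gbe = dbeta)
}

lrelu_fwd <- function(x, slope) {
  m <- (x > 0) + slope * (x <= 0)
  list(y = x * m, cache = m)
}

# conv -> instance norm -> leaky ReLU
block_fwd <- function(net, x, name, stride, dil) {
  p <- net$params
  cv <- conv_fwd(x, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]],
                 stride, dil)
  nm <- inorm_fwd(cv$y, p[[paste0(name, ".g")]], p[[paste0(name, ".be")]])
  ac <- lrelu_fwd(nm$y, net$cfg$negative_slope)
  list(y = ac$y, cache = list(conv = cv$cache, norm = nm$cache,
                              act = ac$cache, name = name))
}

block_bwd <- function(net, cache, gy, grads) {
  p <- net$params
  name <- cache$name
  gy <- gy * cache$act
  nb <- inorm_bwd(cache$norm, p[[paste0(name, ".g")]], gy)
  grads[[paste0(name, ".g")]] <- grads[[paste0(name, ".g")]] + nb$gg
  grads[[paste0(name, ".be")]] <- grads[[paste0(name, ".be")]] + nb$gbe
  cb <- conv_bwd(cache$conv, p[[paste0(name, ".W")]], nb$gx)
  grads[[paste0(name, ".W")]] <- grads[[paste0(name, ".W")]] + cb$gW
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + cb$gb
  list(gx = cb$gx, grads = grads)
}

# 2x2x2 stride-2 transposed convolution, expressed per kernel corner as a
# dense matrix product followed by an interleaved scatter.
upconv_fwd <- function(x, W, b) {
  d <- dim(x); cin <- d[4]; cout <- dim(W)[5]
  N <- prod(d[1:3])
  xm <- matrix(x, N, cin)
  od <- c(2 * d[1:3], cout)
  y <- array(0, od)
  for (a3 in 0:1) for (a2 in 0:1) for (a1 in 0:1) {
    Wc <- matrix(W[a1 + 1, a2 + 1, a3 + 1, , ], cin, cout)
    yc <- array(xm %*% Wc, c(d[1:3], cout))
    y[seq(1 + a1, od[1], 2), seq(1 + a2, od[2], 2),
      seq(1 + a3, od[3], 2), ] <- yc
  }
  y <- y + rep(b, each = prod(od[1:3]))
  list(y = y, cache = list(xm = xm, d = d))
}

upconv_bwd <- function(cache, W, gy) {
  d <- cache$d; cin <- d[4]; cout <- dim(W)[5]
  od <- dim(gy)
  gx <- matrix(0, nrow(cache$xm), cin)
  gW <- array(0, dim(W))
  for (a3 in 0:1) for (a2 in 0:1) for (a1 in 0:1) {
    gsub <- matrix(gy[seq(1 + a1, od[1], 2), seq(1 + a2, od[2], 2),
                      seq(1 + a3, od[3], 2), ], ncol = cout)
    Wc <- matrix(W[a1 + 1, a2 + 1, a3 + 1, , ], cin, cout)
    gx <- gx + gsub %*% t(Wc)
    gW[a1 + 1, a2 + 1, a3 + 1, , ] <- crossprod(cache$xm, gsub)
  }
  gb <- colSums(matrix(gy, ncol = cout))
  list(gx = array(gx, d), gW = gW, gb = gb)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- whole-network forward / backward ----------------------------------

# Forward pass.  Returns deep-supervision head probabilities finest-first;
# with keep_cache = TRUE also every intermediate needed by net_backward.
net_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$cfg
  if (length(dim(x)) != 4 || dim(x)[4] != cfg$in_channels)
    stop("input must be a 4D array with ", cfg$in_channels, " channel(s)")
  div <- 2^(cfg$n_levels - 1)
  if (any(dim(x)[1:3] %% div != 0))
    stop("input spatial dims must be divisible by ", div)
  dil <- if (cfg$conv_mode == "dilated") cfg$dilation else 1L
  L <- cfg$n_levels
  enc_out <- vector("list", L)
  cache <- list(enc = vector("list", L), dec = vector("list", L - 1),
                head = vector("list", cfg$n_ds_heads))
  cur <- x
  for (l in seq_len(L)) {
    # downsampling (stride-2) convolutions keep dilation 1; dilated mode
    # applies to the stride-1 convolutions
    b1 <- block_fwd(net, cur, sprintf("enc%d.c1", l),
                    stride = if (l == 1) 1L else 2L,
                    dil = if (l == 1) dil else 1L)
    b2 <- block_fwd(net, b1$y, sprintf("enc%d.c2", l), 1L, dil)
    enc_out[[l]] <- b2$y
    cache$enc[[l]] <- list(c1 = b1$cache, c2 = b2$cache)
    cur <- b2$y
  }
  heads <- vector("list", cfg$n_ds_heads)
  for (l in rev(seq_len(L - 1))) {
    up <- upconv_fwd(cur, net$params[[sprintf("dec%d.up.W", l)]],
                     net$params[[sprintf("dec%d.up.b", l)]])
    skip <- enc_out[[l]]
    cat4 <- array(c(up$y, skip), dim = dim(up$y) + c(0, 0, 0, dim(skip)[4]))
    b1 <- block_fwd(net, cat4, sprintf("dec%d.c1", l), 1L, dil)
    b2 <- block_fwd(net, b1$y, sprintf("dec%d.c2", l), 1L, dil)
    hc <- NULL
    if (l <= cfg$n_ds_heads) {
      fm <- matrix(b2$y, ncol = dim(b2$y)[4])
      z <- fm %*% net$params[[sprintf("dec%d.head.W", l)]] +
        net$params[[sprintf("dec%d.head.b", l)]]
      heads[[l]] <- array(sigmoid(z), dim(b2$y)[1:3])
      hc <- list(fm = fm, prob = heads[[l]])
    }
    cache$dec[[l]] <- list(up = up$cache, c1 = b1$cache, c2 = b2$cache,
                           up_nch = dim(up$y)[4], dim = dim(b2$y))
    if (l <= cfg$n_ds_heads) cache$head[[l]] <- hc
    cur <- b2$y
  }
  out <- list(heads = heads)
  if (keep_cache) out$cache <- cache
  out
}

# Backward pass.  head_gz: list (finest-first) of gradients of the loss
# with respect to each head's pre-sigmoid logits.  Returns parameter
# gradients as a flat named list congruent with net$params.
net_backward <- function(net, cache, head_gz) {
  cfg <- net$cfg
  L <- cfg$n_levels
  grads <- lapply(net$params, function(p) p * 0)
  # gradient flowing into each decoder block's output feature map
  gdec <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- cache$dec[[l]]
    g <- array(0, dc$dim)
    if (!is.null(gdec[[l]])) g <- g + gdec[[l]]
    if (l <= cfg$n_ds_heads) {
      hname <- sprintf("dec%d.head", l)
      gz <- matrix(head_gz[[l]], ncol = 1)
      fm <- cache$head[[l]]$fm
      grads[[paste0(hname, ".W")]] <- grads[[paste0(hname, ".W")]] +
        crossprod(fm, gz)
      grads[[paste0(hname, ".b")]] <- grads[[paste0(hname, ".b")]] +
        sum(gz)
      g <- g + array(gz %*% t(net$params[[paste0(hname, ".W")]]), dc$dim)
    }
    r <- block_bwd(net, dc$c2, g, grads); grads <- r$grads
    r <- block_bwd(net, dc$c1, r$gx, grads); grads <- r$grads
    # split concat gradient: transposed-conv half then the skip half
    nu <- dc$up_nch
    gup <- r$gx[, , , seq_len(nu), drop = FALSE]
    gskip <- r$gx[, , , nu + seq_len(dim(r$gx)[4] - nu), drop = FALSE]
    ub <- upconv_bwd(dc$up, net$params[[sprintf("dec%d.up.W", l)]], gup)
    grads[[sprintf("dec%d.up.W", l)]] <-
      grads[[sprintf("dec%d.up.W", l)]] + ub$gW
    grads[[sprintf("dec%d.up.b", l)]] <-
      grads[[sprintf("dec%d.up.b", l)]] + ub$gb
    # the transposed conv consumed the feature one level deeper
    tgt <- l + 1
    deeper <- ub$gx
    if (tgt == L) {
      gdec[[L]] <- if (is.null(gdec[[L]])) deeper else gdec[[L]] + deeper
    } else {
      gdec[[tgt]] <- if (is.null(gdec[[tgt]])) deeper
                     else gdec[[tgt]] + deeper
    }
    # stash skip gradient for the encoder sweep
    cache$enc[[l]]$gskip <- gskip
  }
  # encoder sweep, deepest first; level L receives the bottleneck gradient
  gin <- gdec[[L]]
  for (l in rev(seq_len(L))) {
    g <- if (l == L) gin else gin + cache$enc[[l]]$gskip
    r <- block_bwd(net, cache$enc[[l]]$c2, g, grads); grads <- r$grads
    r <- block_bwd(net, cache$enc[[l]]$c1, r$gx, grads); grads <- r$grads
    gin <- r$gx
  }
  grads
}

#' Predict a single patch
#'
#' Generic over network representations: a trained `segnet` returns its
#' finest deep-supervision head; a plain function is treated as a mock
#' network mapping a 4D patch to a 3D probability array (used in inference
#' tests).
#'
#' @param network A `segnet` or a function.
#' @param x 4D array (x, y, z, channel).
#' @return 3D array of foreground probabilities.
#' @export
predict_patch <- function(network, x) UseMethod("predict_patch")

#' @export
predict_patch.segnet <- function(network, x) {
  net_forward(network, x)$heads[[1]]
}

#' @export
predict_patch.function <- function(network, x) network(x)
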