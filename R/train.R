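# SGD training loop: sample patch -> augment -> channel dropout ->
# forward -> deep-supervision loss -> Nesterov-momentum step at a
# polynomially decaying learning rate.  One iteration = one training
# patch (batch size 1).

#' Training configuration
#'
#' @param total_iterations Number of training patches (one iteration
#'   trains on one patch).
#' @param lr0 Initial learning rate for SGD (default 0.01).
#' @param poly_exponent Exponent of the polynomial decay (default 0.9).
#' @param momentum Nesterov momentum (default 0.99).
#' @param batch_size Patches per step (the training scheme uses 1).
#' @param channel_dropout_enabled Apply input-channel dropout when forming
#'   each two-channel input.
#' @param p_keep_both Channel-dropout probability of keeping both
#'   modalities (default 0.5).
#' @param patch_size Network input patch edge length in voxels.
#' @param fg_prob Foreground-oversampling probability for patch selection
#'   (default 0.5: at least half of training patches contain tumor).
#' @param seed Integer RNG seed for the whole run.
#' @return An object of class `train_config`.
#' @export
train_config <- function(total_iterations, lr0 = 0.01, poly_exponent = 0.9,
                         momentum = 0.99, batch_size = 1,
                         channel_dropout_enabled = FALSE,
                         p_keep_both = 0.5, patch_size = 128,
                         fg_prob = 0.5, seed = 1L) {
  if (total_iterations < 0) stop("total_iterations must be >= 0")
  if (p_keep_both < 0 || p_keep_both > 1)
    stop("p_keep_both must be in [0, 1]")
  structure(list(total_iterations = as.integer(total_iterations),
                 lr0 = lr0, poly_exponent = poly_exponent,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 channel_dropout_enabled = isTRUE(channel_dropout_enabled),
                 p_keep_both = p_keep_both,
                 patch_size = as.integer(patch_size),
                 fg_prob = fg_prob, seed = as.integer(seed)),
            class = "train_config")
}

# Select the channel(s) a network consumes from a two-channel patch array.
select_channels <- function(channels, modality) {
  switch(modality,
         both = channels,
         CT = channels[, , , 1, drop = FALSE],
         PET = channels[, , , 2, drop = FALSE])
}

#' Train a segmentation network on preprocessed cases
#'
#' Per iteration: draw a case uniformly, sample an enlarged patch with
#' foreground oversampling, augment and center-crop it, optionally apply
#' channel dropout, run the forward pass, compute the weighted
#' deep-supervision Dice + cross-entropy loss, and take one SGD step at
#' the polynomially decayed learning rate.  Deterministic for a fixed
#' `cfg$seed` (up to floating-point reduction order).
#'
#' @param network A `segnet` from [build_network()].
#' @param cases List of preprocessed cases, each a list with `fused` (a
#'   `fused_volume`) and `label` (a `label_volume` on the same grid).
#' @param cfg A [train_config()].
#' @param aug_cfg An [augment_config()].
#' @param verbose Print progress every `verbose` iterations (0 = silent).
#' @return List with `network` (trained), `trace` (per-iteration loss),
#'   and `dropout_log` (per-iteration kept-modality branch).
#' @export
train_network <- function(network, cases, cfg,
                          aug_cfg = augment_config(), verbose = 0) {
  stopifnot(inherits(network, "segnet"), inherits(cfg, "train_config"))
  if (length(cases) == 0) stop("training cohort is empty")
  total <- cfg$total_iterations
  trace <- numeric(total)
  dropout_log <- character(total)
  if (total == 0)
    return(list(network = network, trace = trace,
                dropout_log = dropout_log))
  set.seed(cfg$seed)
  modality <- network$cfg$modality
  n_heads <- network$cfg$n_ds_heads
  wts <- supervision_weights(n_heads)
  margin <- augment_margin(aug_cfg, rep(cfg$patch_size, 3))
  big <- cfg$patch_size + 2 * margin
  # Pre-pad every case by the augmentation margin so the enlarged
  # pre-crop patch can center anywhere in the volume (edges included);
  # the zero borders match the padding sliding-window inference uses.
  padded <- lapply(cases, function(cs) {
    d <- dim(cs$label$values) + 2 * margin
    fch <- pad_to_size(cs$fused$channels, d)$values
    lab <- pad_to_size(cs$label$values, d)$values
    list(fused = fused_volume(fch[, , , 1], fch[, , , 2],
                              cs$fused$spacing,
                              cs$fused$origin - margin * cs$fused$spacing),
         label = label_volume(lab, cs$label$spacing,
                              cs$label$origin - margin * cs$label$spacing))
  })
  vel <- lapply(network$params, function(p) p * 0)
  mu <- cfg$momentum
  for (it in seq_len(total)) {
    cs <- padded[[sample.int(length(padded), 1L)]]
    patch <- sample_patch(cs$fused, cs$label, big, cfg$fg_prob)
    patch <- augment(patch, aug_cfg, cfg$patch_size)
    branch <- "both"
    if (modality == "both" && cfg$channel_dropout_enabled) {
      branch <- dropout_branch(cfg$p_keep_both)
      if (branch == "CT") patch$channels[, , , 2] <- 0
      if (branch == "PET") patch$channels[, , , 1] <- 0
    }
    x <- select_channels(patch$channels, modality)
    labs <- downsample_labels(patch$label, n_heads)
    fw <- net_forward(network, x, keep_cache = TRUE)
    loss <- composite_loss(list(outputs = fw$heads, labels = labs,
                                weights = wts))
    if (!is.finite(loss))
      stop(sprintf("training diverged at iteration %d (loss = %s)",
                   it, format(loss)))
    head_gz <- lapply(seq_len(n_heads), function(i)
      wts[i] * head_loss_grad_z(fw$heads[[i]], labs[[i]]))
    grads <- net_backward(network, fw$cache, head_gz)
    lr <- poly_lr(it - 1, cfg)
    for (nm in names(network$params)) {
      vel[[nm]] <- mu * vel[[nm]] + grads[[nm]]
      network$params[[nm]] <- network$params[[nm]] -
        lr * (grads[[nm]] + mu * vel[[nm]])
    }
    trace[it] <- loss
    dropout_log[it] <- branch
    if (verbose > 0 && it %% verbose == 0)
      message(sprintf("iter %6d  lr %.5f  loss %8.4f  [%s]",
                      it, lr, loss, branch))
  }
  list(network = network, trace = trace, dropout_log = dropout_log)
}
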