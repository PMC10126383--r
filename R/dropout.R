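# Input-channel dropout: during training, a complete CT+PET input is, with
# probability 1 - p_keep_both, reduced to a single modality by replacing
# the other channel with an all-zero array (uniform choice of which).  No
# new values are introduced, so the kept channel is bit-identical and the
# network cannot extract information from the dropped one.

# One dropout draw: "both", "CT" (PET dropped) or "PET" (CT dropped).
dropout_branch <- function(p_keep_both = 0.5) {
  if (runif(1) < p_keep_both) return("both")
  if (runif(1) < 0.5) "CT" else "PET"
}

#' Randomly drop one modality channel of a fused volume
#'
#' With probability `p_keep_both` the input passes through unchanged;
#' otherwise exactly one channel (CT or PET, chosen uniformly) is replaced
#' by zeros and its availability flag cleared.  Applies only to complete
#' two-channel inputs.  Uses the R session RNG.
#'
#' @param fused A `fused_volume` with both channels present.
#' @param enabled If `FALSE`, identity.
#' @param p_keep_both Probability of keeping both modalities.
#' @return The (possibly) modified `fused_volume`, with an attribute
#'   `"branch"` recording the draw (`"both"`, `"CT"`, or `"PET"` -- the
#'   kept modality).
#' @export
channel_dropout <- function(fused, enabled = TRUE, p_keep_both = 0.5) {
  stopifnot(inherits(fused, "fused_volume"))
  if (!enabled) return(structure(fused, branch = "both"))
  if (!all(fused$availability))
    stop("channel dropout applies to complete two-channel inputs only")
  branch <- dropout_branch(p_keep_both)
  if (branch == "CT") {
    fused$channels[, , , 2] <- 0
    fused$availability["PET"] <- FALSE
  } else if (branch == "PET") {
    fused$channels[, , , 1] <- 0
    fused$availability["CT"] <- FALSE
  }
  structure(fused, branch = branch)
}

#' Simulate a missing modality at deployment
#'
#' The missing modality is replaced by a background image with zero at
#' every voxel, exactly as during channel-dropout training.
#'
#' @param fused A `fused_volume` with both channels present.
#' @param setting `"both"`, `"CT-only"`, or `"PET-only"`.
#' @return The `fused_volume` with the requested channel(s) retained.
#' @export
simulate_missing <- function(fused,
                             setting = c("both", "CT-only", "PET-only")) {
  stopifnot(inherits(fused, "fused_volume"))
  setting <- match.arg(setting)
  if (setting == "both") return(fused)
  if (all(!fused$availability))
    warning("both channels already dropped; input is degenerate")
  if (setting == "CT-only") {
    fused$channels[, , , 2] <- 0
    fused$availability["PET"] <- FALSE
  } else {
    fused$channels[, , , 1] <- 0
    fused$availability["CT"] <- FALSE
  }
  if (all(!fused$availability))
    warning("simulate_missing produced an all-zero input")
  fused
}
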