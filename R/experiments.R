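# Configuration-driven ablation runner: single-modality models, dual-input
# models with and without channel dropout, conventional versus dilated
# convolution, and probability-map ensembles, each evaluated under
# CT-only / PET-only / CT+PET deployment on a held-out phantom test split.

#' The eight-model ablation grid
#'
#' Rows 1-6 are trainable models (single-modality CT and PET, then the
#' four dual-input combinations of channel dropout x convolution type);
#' the two ensembles average the probability maps of their member models
#' under CT+PET deployment.
#'
#' @param models Optional subset of model ids (1-6) to include.
#' @param ensembles Optional list of ensembles, each
#'   `list(id =, members =)`; members must be included models.  `NULL`
#'   keeps the default pair (3+5 and 4+6) restricted to included models.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(models = 1:6, ensembles = NULL) {
  all_models <- data.frame(
    id = 1:6,
    modality = c("CT", "PET", "both", "both", "both", "both"),
    dropout = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    conv_mode = c("conventional", "conventional", "conventional",
                  "conventional", "dilated", "dilated"),
    stringsAsFactors = FALSE)
  if (!all(models %in% 1:6)) stop("model ids must be in 1..6")
  tab <- all_models[all_models$id %in% models, , drop = FALSE]
  if (is.null(ensembles)) {
    ensembles <- list(list(id = "Ensemble 1", members = c(3, 5)),
                      list(id = "Ensemble 2", members = c(4, 6)))
    ensembles <- Filter(function(e) all(e$members %in% tab$id), ensembles)
  } else {
    for (e in ensembles)
      if (!all(e$members %in% tab$id))
        stop("ensemble members must be included models")
  }
  structure(list(models = tab, ensembles = ensembles,
                 eval_settings = c("CT-only", "PET-only", "both")),
            class = "experiment_grid")
}

# Evaluation settings a model row participates in (single-modality models
# are scored only on their own modality; ensembles only on CT+PET).
applicable_settings <- function(modality) {
  switch(modality,
         CT = "CT-only",
         PET = "PET-only",
         both = c("CT-only", "PET-only", "both"))
}

#' Desk-scale phantom specification for grid experiments
#'
#' A reduced-size variant of the default phantom (64 mm field of view, CT
#' 2 x 2 x 4 mm, PET 4 mm isotropic, slight origin offset) sized so that a
#' full ablation run trains in minutes on one CPU while preserving the
#' qualitative structure of clinical data: PET carries most of the tumor
#' signal, CT shows only a partial boundary.
#'
#' @param ... Overrides forwarded to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
desk_phantom_spec <- function(...) {
  phantom_spec(grid_shape_ct = c(32, 32, 16), spacing_ct = c(2, 2, 4),
               grid_shape_pet = c(16, 16, 16), spacing_pet = c(4, 4, 4),
               origin_offset_pet = c(2, -2, 2),
               tumor_radii = c(10, 9, 11), ...)
}

format_cell <- function(m, s) {
  if (is.na(m)) return("-")
  if (is.na(s)) sprintf("%.3f", m) else sprintf("%.3f (%.3f)", m, s)
}

#' Run the ablation grid on a synthetic phantom cohort
#'
#' Generates a phantom cohort, preprocesses every case, splits it into
#' training and test sets (seeded), trains each model of the grid, scores
#' every applicable (model, availability) cell on the test split, averages
#' member probability maps for the ensembles, and writes ablation-table
#' and z-test reports (CSV + JSON) to `out_dir`.  Re-running with existing
#' checkpoints in `out_dir` skips training and reproduces the evaluation.
#'
#' @param grid An [experiment_grid()].
#' @param out_dir Output directory for checkpoints and reports.
#' @param phantom Base [phantom_spec()] for the cohort.
#' @param n_cases Cohort size.
#' @param train_frac Fraction of cases used for training (default 0.8).
#' @param target_spacing Isotropic preprocessing grid (mm).
#' @param patch_size Training patch and inference window edge (voxels).
#' @param n_levels,base_filters Network size.
#' @param iterations Training iterations per model.
#' @param seed Master seed (cohort, split, per-model training).
#' @param flip_tta Left-right flip averaging at inference.
#' @param n_boot Bootstrap replicates for volume-ICC dispersion.
#' @param resume Reuse existing checkpoints in `out_dir`.
#' @param verbose Progress printing interval for training (0 = silent).
#' @return Invisibly, a list with `cells` (per model x setting metrics),
#'   `table` (ablation-style data frame), `ztests`, `split`, and `traces`
#'   (per-model loss traces).
#' @export
run_grid <- function(grid, out_dir, phantom = desk_phantom_spec(),
                     n_cases = 20, train_frac = 0.8, target_spacing = 2,
                     patch_size = 16, n_levels = 3, base_filters = 8,
                     iterations = 2000, seed = 1L, flip_tta = TRUE,
                     n_boot = 200, resume = TRUE, verbose = 0) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  cohort <- generate_cohort(phantom, n_cases, seed = seed)
  cases <- lapply(cohort, function(cs)
    preprocess_case(cs$ct, cs$pet, cs$label, target_spacing))
  set.seed(seed + 1L)
  perm <- sample.int(n_cases)
  n_train <- max(1L, round(train_frac * n_cases))
  split <- list(train = sort(perm[seq_len(n_train)]),
                test = sort(perm[-seq_len(n_train)]))
  train_cases <- cases[split$train]
  test_cases <- cases[split$test]

  traces <- list(); nets <- list()
  for (r in seq_len(nrow(grid$models))) {
    row <- grid$models[r, ]
    ckpt <- file.path(out_dir, sprintf("model%d.rds", row$id))
    if (resume && file.exists(ckpt)) {
      saved <- readRDS(ckpt)
      nets[[as.character(row$id)]] <- saved$network
      traces[[as.character(row$id)]] <- saved$trace
      next
    }
    ncfg <- network_config(
      n_levels = n_levels, base_filters = base_filters,
      conv_mode = row$conv_mode,
      in_channels = if (row$modality == "both") 2L else 1L,
      modality = row$modality)
    net <- build_network(ncfg, seed = seed + 100L * row$id)
    tcfg <- train_config(total_iterations = iterations,
                         channel_dropout_enabled = row$dropout,
                         patch_size = patch_size,
                         seed = seed + 1000L * row$id)
    if (verbose > 0)
      message(sprintf("training model %d (%s, dropout=%s, %s)", row$id,
                      row$modality, row$dropout, row$conv_mode))
    fit <- train_network(net, train_cases, tcfg, verbose = verbose)
    nets[[as.character(row$id)]] <- fit$network
    traces[[as.character(row$id)]] <- fit$trace
    saveRDS(list(network = fit$network, trace = fit$trace,
                 config = list(row = row, train = tcfg)), ckpt)
    utils::write.csv(
      data.frame(iteration = seq_len(iterations),
                 lr = vapply(seq_len(iterations) - 1, poly_lr,
                             numeric(1), cfg = tcfg),
                 loss = fit$trace),
      file.path(out_dir, sprintf("model%d_trainlog.csv", row$id)),
      row.names = FALSE)
  }

  # ---- evaluation -------------------------------------------------------
  cells <- list(); prob_store <- list()
  truths <- lapply(test_cases, function(cs) cs$label)
  for (r in seq_len(nrow(grid$models))) {
    row <- grid$models[r, ]
    net <- nets[[as.character(row$id)]]
    for (setting in applicable_settings(row$modality)) {
      icfg <- inference_config(window = patch_size, flip_tta = flip_tta,
                               availability = setting)
      probs <- lapply(test_cases, function(cs)
        predict_volume(net, cs$fused, icfg))
      preds <- lapply(probs, binarize)
      rep_ <- suppressWarnings(
        evaluate_model(preds, truths, n_boot = n_boot,
                       seed = seed + 7L))
      key <- sprintf("Model %d|%s", row$id, setting)
      cells[[key]] <- rep_
      if (setting == "both")
        prob_store[[as.character(row$id)]] <- probs
    }
  }
  for (e in grid$ensembles) {
    members <- lapply(as.character(e$members), function(id)
      prob_store[[id]])
    if (any(vapply(members, is.null, logical(1)))) next
    probs <- lapply(seq_along(test_cases), function(i)
      ensemble_average(lapply(members, `[[`, i)))
    preds <- lapply(probs, binarize)
    cells[[sprintf("%s|both", e$id)]] <- suppressWarnings(
      evaluate_model(preds, truths, n_boot = n_boot, seed = seed + 7L))
  }

  # ---- ablation-style table --------------------------------------------
  row_ids <- c(sprintf("Model %d", grid$models$id),
               vapply(grid$ensembles, `[[`, character(1), "id"))
  settings <- grid$eval_settings
  tab <- data.frame(model = row_ids, stringsAsFactors = FALSE)
  for (s in settings) for (met in c("DSC", "HD", "ICC")) {
    col <- vapply(row_ids, function(id) {
      cell <- cells[[sprintf("%s|%s", id, s)]]
      if (is.null(cell)) return("-")
      a <- cell$aggregate
      switch(met,
             DSC = format_cell(a$dsc_mean, a$dsc_sd),
             HD = format_cell(a$hd_mean, a$hd_sd),
             ICC = format_cell(cell$icc$value, cell$icc$sd))
    }, character(1))
    tab[[sprintf("%s_%s", gsub("[^A-Za-z0-9]", "", s), met)]] <- col
  }

  # ---- pairwise z tests (dropout vs no dropout per convolution) --------
  zrows <- list()
  pairs <- list(conventional = c(3, 4), dilated = c(5, 6))
  for (cv in names(pairs)) {
    ids <- pairs[[cv]]
    if (!all(ids %in% grid$models$id)) next
    for (s in settings) {
      c1 <- cells[[sprintf("Model %d|%s", ids[1], s)]]
      c2 <- cells[[sprintf("Model %d|%s", ids[2], s)]]
      if (is.null(c1) || is.null(c2)) next
      for (met in c("DSC", "HD")) {
        a1 <- c1$aggregate; a2 <- c2$aggregate
        st <- if (met == "DSC")
          two_sample_z(a1$dsc_mean, a1$dsc_sd, a1$n,
                       a2$dsc_mean, a2$dsc_sd, a2$n)
        else two_sample_z(a1$hd_mean, a1$hd_sd, sum(!is.na(c1$per_case$hd)),
                          a2$hd_mean, a2$hd_sd, sum(!is.na(c2$per_case$hd)))
        zrows[[length(zrows) + 1]] <- data.frame(
          convolution = cv, setting = s, metric = met,
          z = st$z, p = st$p, stringsAsFactors = FALSE)
      }
      # ICC compared with bootstrap SDs as standard errors
      if (!is.na(c1$icc$value) && !is.na(c2$icc$value) &&
          !is.na(c1$icc$sd) && !is.na(c2$icc$sd) &&
          (c1$icc$sd > 0 || c2$icc$sd > 0)) {
        se <- sqrt(c1$icc$sd^2 + c2$icc$sd^2)
        z <- (c1$icc$value - c2$icc$value) / se
        zrows[[length(zrows) + 1]] <- data.frame(
          convolution = cv, setting = s, metric = "ICC",
          z = z, p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
      }
    }
  }
  ztests <- if (length(zrows)) do.call(rbind, zrows) else NULL

  utils::write.csv(tab, file.path(out_dir, "ablation_table.csv"),
                   row.names = FALSE)
  if (!is.null(ztests))
    utils::write.csv(ztests, file.path(out_dir, "ztests.csv"),
                     row.names = FALSE)
  cell_json <- lapply(cells, function(cc)
    list(aggregate = cc$aggregate, icc = cc$icc))
  jsonlite::write_json(
    list(seed = seed, split = split, cells = cell_json),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(cells = cells, table = tab, ztests = ztests,
                 split = split, traces = traces, nets = nets))
}
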