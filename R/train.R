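#' Training configuration
#'
#' The pipeline's optimization schedule: 25 epochs,
#' batch size 512, Adam with initial learning rate 0.001 lowered by 20% after
#' every fifth epoch, batch-level soft-dice loss, five folds. Adam moment
#' parameters are the conventional defaults.
#'
#' @param epochs number of passes over the sampled voxels (default 25).
#' @param batch_size voxels per batch (default 512).
#' @param lr0 initial learning rate (default 0.001).
#' @param lr_decay multiplicative factor applied every `lr_decay_every`
#'   epochs (default 0.8).
#' @param lr_decay_every epochs per decay step (default 5).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param tumor_frac,healthy_frac voxel sampling fractions (defaults 0.5 and
#'   0.01).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer.
#' @param dice_eps soft-dice stabilizer.
#' @return An object of class `mvseg_train_config`.
#' @export
train_config <- function(epochs = 25L, batch_size = 512L, lr0 = 0.001,
                         lr_decay = 0.8, lr_decay_every = 5L, folds = 5L,
                         seed = 1L, tumor_frac = 0.5, healthy_frac = 0.01,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, dice_eps = 1e-7) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (!(lr_decay > 0 && lr_decay <= 1)) stop("lr_decay must lie in (0, 1]")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, lr_decay_every = as.integer(lr_decay_every),
                 folds = as.integer(folds), seed = as.integer(seed),
                 tumor_frac = tumor_frac, healthy_frac = healthy_frac,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, dice_eps = dice_eps),
            class = "mvseg_train_config")
}

#' Learning-rate schedule
#'
#' Piecewise-constant schedule: `lr0 * lr_decay ^ floor(epoch / every)` with
#' 0-based epochs, i.e. 0.001 for epochs 0-4, 0.0008 for 5-9, and so on with
#' the defaults.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < cfg$epochs`.
#' @param cfg an [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  if (any(epoch >= cfg$epochs)) stop("epoch must be < cfg$epochs")
  cfg$lr0 * cfg$lr_decay^(epoch %/% cfg$lr_decay_every)
}

#' Stratified cross-validation folds
#'
#' Assigns cases to `k` folds, balancing the joint strata of tumor-volume
#' group (V1-V4 from the reference volume) and location: within each stratum
#' cases are shuffled and dealt round-robin, with a rotating starting fold so
#' stratum remainders spread evenly. This stands in for the manual
#' quality control of fold balance.
#'
#' @param cases list of [multiseq_case()] objects, or a data.frame with
#'   columns `case_id`, `ref_volume_cm3`, `location`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `mvseg_fold_split`: data.frame with `case_id`,
#'   `fold` (0-based), `volume_group`, `location`.
#' @export
make_folds <- function(cases, k = 5L, seed = 1L) {
  if (is.data.frame(cases)) {
    df <- cases
    stopifnot(all(c("case_id", "ref_volume_cm3", "location") %in% names(df)))
  } else {
    df <- data.frame(
      case_id = vapply(cases, function(cs) cs$case_id, character(1)),
      ref_volume_cm3 = vapply(cases, function(cs)
        predicted_volume_cm3(cs$reference), numeric(1)),
      location = vapply(cases, function(cs) cs$location, character(1)),
      stringsAsFactors = FALSE)
  }
  n <- nrow(df)
  if (k > n) stop("more folds than cases")
  df$volume_group <- vapply(df$ref_volume_cm3, volume_group, character(1))
  set.seed(seed)
  df$fold <- NA_integer_
  start <- 0L
  strata <- split(seq_len(n), paste(df$volume_group, df$location))
  for (s in strata) {
    s <- s[sample.int(length(s))]
    df$fold[s] <- (start + seq_along(s) - 1L) %% k
    start <- (start + length(s)) %% k
  }
  out <- df[, c("case_id", "fold", "volume_group", "location")]
  class(out) <- c("mvseg_fold_split", "data.frame")
  out
}

#' Train the network on one fold's cases
#'
#' Samples training voxels once per case (dataset construction, not per
#' epoch), then runs `cfg$epochs` passes over the pooled samples in shuffled
#' batches (final partial batch kept), optimizing the batch soft-dice loss
#' with Adam under the learning-rate schedule. Fully reproducible under the
#' config seed.
#'
#' @param train_cases list of [prepare_case()] results (standard space,
#'   normalized, padded).
#' @param cfg an [train_config()].
#' @param model_cfg an [model_config()].
#' @param body_mask [label_mask()] defining the healthy stratum for sampling
#'   (the template occupancy mask).
#' @param samples optional precomputed sample data.frame; when `NULL`,
#'   sampled here with per-case seeds derived from `cfg$seed`.
#' @return List with `params` (trained `mvseg_params`), `history` (mean
#'   loss per epoch), and `samples`.
#' @export
train_fold <- function(train_cases, cfg, model_cfg = model_config(),
                       body_mask, samples = NULL) {
  stopifnot(inherits(cfg, "mvseg_train_config"))
  if (length(train_cases) == 0L) stop("empty training set")
  if (is.null(samples)) {
    samples <- do.call(rbind, lapply(seq_along(train_cases), function(ci) {
      pc <- train_cases[[ci]]
      sample_voxels(pc$reference, body_mask, cfg$tumor_frac, cfg$healthy_frac,
                    seed = cfg$seed + 1000L * ci, case_id = pc$case_id)
    }))
  }
  ids <- vapply(train_cases, function(pc) pc$case_id, character(1))
  ci <- match(samples$case_id, ids)
  if (anyNA(ci)) stop("samples refer to cases not in the training set")
  smat <- cbind(ci - 1L, samples$i, samples$j, samples$k, samples$label)
  storage.mode(smat) <- "integer"
  params <- build_model(model_cfg, seed = cfg$seed)
  vols <- lapply(train_cases, function(pc) pc$vols)
  opt <- list(epochs = cfg$epochs, batch_size = cfg$batch_size, lr0 = cfg$lr0,
              lr_decay = cfg$lr_decay, lr_decay_every = cfg$lr_decay_every,
              epoch_offset = 0L, adam_beta1 = cfg$adam_beta1,
              adam_beta2 = cfg$adam_beta2, adam_eps = cfg$adam_eps,
              dice_eps = cfg$dice_eps, seed = as.double(cfg$seed),
              shuffle = TRUE)
  res <- cpp_mvcnn_train(vols, smat, unclass_params(params),
                         attr(params, "config"), opt, NULL)
  out <- res$params
  attr(out, "config") <- attr(params, "config")
  class(out) <- "mvseg_params"
  list(params = out, history = as.numeric(res$history), samples = samples)
}

#' Five-fold cross-validated training
#'
#' Builds a stratified fold split, then for each fold trains on all other
#' cases and records the held-out case ids, so every case is evaluated
#' exactly once by a model that never saw it.
#'
#' @param prepared_cases list of [prepare_case()] results.
#' @param cfg an [train_config()] (its `folds` and `seed` drive the split).
#' @param model_cfg an [model_config()].
#' @param body_mask sampling/inference mask ([label_mask()]).
#' @param fold_split optional precomputed [make_folds()] result.
#' @return List with `folds` (the split) and `models`: per fold a list with
#'   `params`, `history`, `heldout` (case ids).
#' @export
cross_validate <- function(prepared_cases, cfg, model_cfg = model_config(),
                           body_mask, fold_split = NULL) {
  ids <- vapply(prepared_cases, function(pc) pc$case_id, character(1))
  if (is.null(fold_split)) {
    df <- data.frame(
      case_id = ids,
      ref_volume_cm3 = vapply(prepared_cases, function(pc)
        predicted_volume_cm3(pc$reference), numeric(1)),
      location = vapply(prepared_cases, function(pc) pc$location, character(1)),
      stringsAsFactors = FALSE)
    fold_split <- make_folds(df, k = cfg$folds, seed = cfg$seed)
  }
  models <- lapply(sort(unique(fold_split$fold)), function(f) {
    held <- fold_split$case_id[fold_split$fold == f]
    tr <- prepared_cases[!(ids %in% held)]
    fcfg <- cfg
    fcfg$seed <- cfg$seed + f
    fit <- train_fold(tr, fcfg, model_cfg, body_mask)
    list(fold = f, params = fit$params, history = fit$history, heldout = held)
  })
  list(folds = fold_split, models = models)
}
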