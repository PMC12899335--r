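# prepare normalized padded tensors + per-frame broadcast labels for a list
# of records
prepare_tensors <- function(records, stats, max_len) {
  seqs <- lapply(records, function(r) normalize(r$positions, stats))
  pm <- pad_and_mask(seqs, max_len)
  labels <- vapply(records, function(r) as.numeric(isTRUE(r$is_drone)),
                   numeric(1))
  y <- matrix(labels, nrow = length(records), ncol = max_len)
  list(x = pm$x, mask = pm$mask, y = y, labels = labels)
}

#' Train the trajectory classifier
#'
#' Full training pipeline: load (or, if the directory is empty, first
#' generate) the labeled JSON dataset, downsample every trajectory to at
#' most `max_len` frames, split it stratified by class, compute the
#' normalization statistics on the training subset only, broadcast each
#' sequence label to all its valid frames, and run `epochs` epochs of Adam
#' on the masked binary cross-entropy. After each epoch the validation AUC
#' of the sequence-level probabilities (masked per-frame means) is computed
#' and the best-AUC weights are checkpointed. Deterministic given
#' `config$seed`.
#'
#' @param data Either a directory of trajectory JSON files or a list of
#'   [trajectory_record()] objects.
#' @param config A [classifier_config()].
#' @param n_generate Trajectories per class to generate when `data` is an
#'   empty or missing directory.
#' @param verbose Print one line per epoch (loss, validation AUC).
#' @return An object of class `trained_model`: best-AUC weights (`params`),
#'   final-epoch weights (`final_params`), normalization statistics,
#'   config, per-epoch `loss_history` and `auc_history`, and `best_epoch`.
#' @export
train_classifier <- function(data, config = classifier_config(),
                             n_generate = 200, verbose = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  if (is.character(data)) {
    records <- if (dir.exists(data)) load_dataset(data) else list()
    if (length(records) == 0) {
      generate_dataset(n_generate, data, seed = config$seed)
      records <- load_dataset(data)
    }
  } else {
    records <- data
  }
  labels <- vapply(records, function(r) isTRUE(r$is_drone), logical(1))
  if (all(labels) || all(!labels)) stop("dataset must contain both classes")

  records <- lapply(records, downsample, target_len = config$max_len)
  split <- split_dataset(records, config$split_fraction, config$seed)
  stats <- compute_stats(split$train)
  train <- prepare_tensors(split$train, stats, config$max_len)
  test <- prepare_tensors(split$test, stats, config$max_len)

  set.seed(config$seed)
  params <- rnn_init_params(config$cell, config$input_dim, config$hidden)
  opt <- adam_init(params)
  n_train <- dim(train$x)[1]
  h2 <- 2 * config$hidden

  loss_history <- numeric(config$epochs)
  auc_history <- numeric(config$epochs)
  best_auc <- -Inf
  best_epoch <- NA_integer_
  best_params <- params

  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(n_train)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    tot_loss <- 0
    tot_frames <- 0
    for (idx in batches) {
      xb <- train$x[idx, , , drop = FALSE]
      yb <- train$y[idx, , drop = FALSE]
      mb <- train$mask[idx, , drop = FALSE]
      dm <- NULL
      if (config$dropout > 0) {
        keep <- array(runif(length(idx) * config$max_len * h2) >=
                        config$dropout,
                      dim = c(length(idx), config$max_len, h2))
        dm <- keep / (1 - config$dropout)
      }
      res <- rnn_train_step(params, xb, yb, mb, dm, config$cell)
      upd <- adam_update(params, res$grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$state
      frames <- sum(mb)
      tot_loss <- tot_loss + res$loss * frames
      tot_frames <- tot_frames + frames
    }
    loss_history[epoch] <- tot_loss / tot_frames

    probs <- rnn_forward_eval(params, test$x, config$cell)
    seq_p <- sequence_probability(probs, test$mask)
    auc_history[epoch] <- auc_score(seq_p, test$labels)
    if (auc_history[epoch] > best_auc) {
      best_auc <- auc_history[epoch]
      best_epoch <- epoch
      best_params <- params
    }
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  val AUC %.4f", epoch,
                      loss_history[epoch], auc_history[epoch]))
  }

  structure(list(params = best_params, final_params = params,
                 stats = stats, config = config,
                 loss_history = loss_history, auc_history = auc_history,
                 best_epoch = best_epoch,
                 n_train = n_train, n_test = dim(test$x)[1]),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(paste0("<trained_model> %s, %d epochs, best val AUC %.4f ",
                     "(epoch %d), final loss %.4f\n"),
              toupper(x$config$cell), length(x$loss_history),
              max(x$auc_history), x$best_epoch,
              tail(x$loss_history, 1)))
  invisible(x)
}

#' Sequence-level drone probabilities for a list of records
#'
#' Downsamples, normalizes with the model's stored statistics, pads,
#' forward-passes in evaluation mode and aggregates per-frame probabilities
#' with the masked mean.
#'
#' @param model A [train_classifier()] result.
#' @param records List of [trajectory_record()] objects.
#' @return Numeric vector of drone probabilities, one per record.
#' @export
predict_records <- function(model, records) {
  stopifnot(inherits(model, "trained_model"))
  records <- lapply(records, downsample, target_len = model$config$max_len)
  seqs <- lapply(records, function(r) normalize(r$positions, model$stats))
  pm <- pad_and_mask(seqs, model$config$max_len)
  probs <- rnn_forward_eval(model$params, pm$x, model$config$cell)
  sequence_probability(probs, pm$mask)
}

#' Validation AUC of a model on labeled records
#'
#' @param model A [train_classifier()] result.
#' @param records Labeled records, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(model, records) {
  labels <- vapply(records, function(r) isTRUE(r$is_drone), logical(1))
  if (all(labels) || all(!labels)) stop("both classes must be present")
  auc_score(predict_records(model, records), labels)
}

#' Per-frame drone probabilities for a trajectory file
#'
#' Reads `movement_history` from the JSON file (a class label is not
#' required; auxiliary keys are ignored), normalizes with the model's stored
#' statistics, pads or truncates to the model's maximum length, runs an
#' evaluation-mode forward pass and trims the output to the observed frames.
#'
#' @param model A [train_classifier()] result or the path of a model saved
#'   with [save_model()].
#' @param json_path Trajectory JSON file.
#' @return A list with `per_frame` (length `min(T, max_len)` probabilities),
#'   `sequence_probability` and the thresholded `is_drone` decision.
#' @export
predict_file <- function(model, json_path) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "trained_model"))
  rec <- read_trajectory_json(json_path, require_label = FALSE)
  xn <- normalize(rec$positions, model$stats)
  pm <- pad_and_mask(list(xn), model$config$max_len)
  probs <- rnn_forward_eval(model$params, pm$x, model$config$cell)
  t_keep <- min(nrow(rec$positions), model$config$max_len)
  per_frame <- probs[1, seq_len(t_keep)]
  list(per_frame = per_frame,
       sequence_probability = mean(per_frame),
       is_drone = mean(per_frame) > 0.5)
}

#' Save / load a trained model
#'
#' Persists weights, normalization statistics, configuration and training
#' histories as a single JSON file (17 significant digits, enough to
#' reconstruct every double exactly), so prediction needs no access to the
#' training set.
#'
#' @param model A [train_classifier()] result.
#' @param path Output / input path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  obj <- list(cell = model$config$cell,
              config = unclass(model$config),
              stats = unclass(model$stats),
              params = model$params,
              final_params = model$final_params,
              loss_history = model$loss_history,
              auc_history = model$auc_history,
              best_epoch = model$best_epoch,
              n_train = model$n_train, n_test = model$n_test)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config,
                 obj$config[c("hidden", "layers", "dropout", "max_len",
                              "learning_rate", "epochs", "batch_size",
                              "split_fraction", "seed", "cell")])
  fix <- function(p) {
    p$head_W <- as.numeric(p$head_W)
    p$head_b <- as.numeric(p$head_b)
    p
  }
  structure(list(params = fix(obj$params),
                 final_params = fix(obj$final_params),
                 stats = structure(list(mu = obj$stats$mu,
                                        sigma = obj$stats$sigma),
                                   class = "normalization_stats"),
                 config = cfg,
                 loss_history = obj$loss_history,
                 auc_history = obj$auc_history,
                 best_epoch = obj$best_epoch,
                 n_train = obj$n_train, n_test = obj$n_test),
            class = "trained_model")
}

#' Plot the training loss curve
#'
#' Writes a PNG with the per-epoch training loss and validation AUC.
#'
#' @param model A [train_classifier()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_loss_history <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op), add = TRUE)
  ep <- seq_along(model$loss_history)
  graphics::plot(ep, model$loss_history, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "masked BCE training loss",
                 main = sprintf("%s training", toupper(model$config$cell)))
  graphics::par(new = TRUE)
  graphics::plot(ep, model$auc_history, type = "l", lty = 2, col = "blue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("validation AUC", side = 4, line = 2.5, col = "blue")
  invisible(path)
}
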