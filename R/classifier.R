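#' Classifier configuration
#'
#' Architecture and optimization settings for the bidirectional recurrent
#' sequence classifier: 3 input features (x, y, z), 64 hidden units per
#' direction, 2 stacked layers, bidirectional, dropout 0.2 between the
#' recurrent layers, a 128-to-1 linear head with a logistic output, masked
#' binary cross-entropy, Adam at learning rate 1e-3 for 35 epochs, sequences
#' padded/truncated to 100 frames.
#'
#' @param hidden Hidden units per direction.
#' @param layers Number of stacked recurrent layers (fixed at 2).
#' @param dropout Dropout probability between the recurrent layers.
#' @param max_len Maximum sequence length (padding/truncation target).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param split_fraction Training fraction of the stratified split.
#' @param seed Integer seed controlling the split, initialization, batch
#'   order and dropout.
#' @param cell `"lstm"` or `"gru"`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(hidden = 64, layers = 2, dropout = 0.2,
                              max_len = 100, learning_rate = 1e-3,
                              epochs = 35, batch_size = 16,
                              split_fraction = 0.8, seed = 1L,
                              cell = c("lstm", "gru")) {
  cell <- match.arg(cell)
  if (layers != 2) stop("only the two-layer architecture is implemented")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (max_len < 2) stop("max_len must be at least 2")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  structure(list(input_dim = 3L, hidden = as.integer(hidden), layers = 2L,
                 bidirectional = TRUE, dropout = dropout,
                 max_len = as.integer(max_len),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_fraction = split_fraction, seed = as.integer(seed),
                 cell = cell),
            class = "classifier_config")
}

#' Stratified train/test split
#'
#' Disjoint split preserving the class distribution, deterministic given the
#' seed.
#'
#' @param records List of [trajectory_record()] objects (both classes
#'   present, at least two records per class).
#' @param split_fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(records, split_fraction = 0.8, seed = 1L) {
  labels <- vapply(records, function(r) isTRUE(r$is_drone), logical(1))
  if (all(labels) || all(!labels))
    stop("both classes must be present")
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least two records per class")
  set.seed(seed)
  train_idx <- integer(0)
  for (cls in c(FALSE, TRUE)) {
    idx <- which(labels == cls)
    n_train <- round(split_fraction * length(idx))
    n_train <- min(max(n_train, 1), length(idx) - 1)
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = records[train_idx], test = records[-train_idx])
}

#' Per-feature normalization statistics
#'
#' Mean and population standard deviation of each input feature (x, y, z)
#' pooled over all frames of all training records; the standard deviation is
#' floored at 1e-8 to guard degenerate features. Computed from the training
#' subset only.
#'
#' @param records Non-empty list of [trajectory_record()] objects.
#' @return An object of class `normalization_stats` with fields `mu` and
#'   `sigma` (length-3 vectors).
#' @export
compute_stats <- function(records) {
  if (length(records) == 0) stop("records must be non-empty")
  pooled <- do.call(rbind, lapply(records, function(r) r$positions))
  mu <- colMeans(pooled)
  sigma <- sqrt(colMeans(sweep(pooled, 2, mu)^2)) # population std
  sigma <- pmax(sigma, 1e-8)
  structure(list(mu = mu, sigma = sigma), class = "normalization_stats")
}

#' Normalize / denormalize a position sequence
#'
#' Feature-wise affine standardization `(X - mu) / sigma`; exactly inverted
#' by [denormalize()].
#'
#' @param x A `T x 3` numeric matrix.
#' @param stats A [compute_stats()] result.
#' @return A `T x 3` matrix.
#' @export
normalize <- function(x, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  x <- matrix(as.numeric(x), ncol = 3)
  sweep(sweep(x, 2, stats$mu), 2, stats$sigma, "/")
}

#' @rdname normalize
#' @export
denormalize <- function(x, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  x <- matrix(as.numeric(x), ncol = 3)
  sweep(sweep(x, 2, stats$sigma, "*"), 2, stats$mu, "+")
}

#' Pad and mask a batch of variable-length sequences
#'
#' Right-pads each `T_i x 3` sequence with zeros to `max_len` frames
#' (truncating longer sequences to their first `max_len` frames) and builds
#' the binary validity mask.
#'
#' @param seqs List of `T_i x 3` numeric matrices, each with at least one
#'   row.
#' @param max_len Padded length.
#' @return A list with `x` (`B x max_len x 3` array) and `mask`
#'   (`B x max_len` binary matrix).
#' @export
pad_and_mask <- function(seqs, max_len = 100) {
  b <- length(seqs)
  if (b == 0) stop("empty batch")
  x <- array(0, dim = c(b, max_len, 3))
  mask <- matrix(0, nrow = b, ncol = max_len)
  for (i in seq_len(b)) {
    s <- matrix(as.numeric(seqs[[i]]), ncol = 3)
    if (nrow(s) < 1) stop("empty sequence at position ", i)
    t_i <- min(nrow(s), max_len)
    x[i, seq_len(t_i), ] <- s[seq_len(t_i), ]
    mask[i, seq_len(t_i)] <- 1
  }
  list(x = x, mask = mask)
}

#' Masked binary cross-entropy
#'
#' Mean element-wise cross-entropy over valid (mask = 1) frames only, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`. Padded frames provably do
#' not contribute.
#'
#' @param p Per-frame probabilities (vector or matrix).
#' @param y Per-frame labels in `{0, 1}`, same shape.
#' @param mask Binary validity mask, same shape; must not be all zero.
#' @return Scalar loss.
#' @export
masked_bce <- function(p, y, mask) {
  if (sum(mask) == 0) stop("mask must select at least one frame")
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -(y * log(pc) + (1 - y) * log(1 - pc))
  sum(mask * bce) / sum(mask)
}

#' Sequence-level probability
#'
#' Masked mean of per-frame probabilities; the overall drone probability of
#' a trajectory (decision threshold 0.5).
#'
#' @param p Per-frame probabilities: a vector (one sequence) or a
#'   `B x T` matrix.
#' @param mask Binary mask of the same shape.
#' @return A scalar, or a length-B vector for matrix input.
#' @export
sequence_probability <- function(p, mask) {
  if (is.matrix(p)) {
    ms <- rowSums(mask)
    if (any(ms == 0)) stop("each sequence needs at least one valid frame")
    return(rowSums(p * mask) / ms)
  }
  if (sum(mask) == 0) stop("mask must select at least one frame")
  sum(p * mask) / sum(mask)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie handling: the probability that a randomly chosen positive is
#' scored above a randomly chosen negative.
#'
#' @param scores Numeric scores.
#' @param labels Logical or 0/1 labels (`TRUE`/1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---------------------------------------------------------------------------
# network parameters, forward pass, Adam
# ---------------------------------------------------------------------------

# uniform(-1/sqrt(hidden), 1/sqrt(hidden)) initialization for the recurrent
# stack, uniform(-1/sqrt(2 hidden), .) for the head (fan-in scaling)
rnn_init_params <- function(cell = "lstm", input_dim = 3, hidden = 64) {
  gate_mult <- if (cell == "gru") 3 else 4
  k <- 1 / sqrt(hidden)
  u <- function(n) runif(n, -k, k)
  dir_par <- function(in_dim) {
    p <- list(Wx = matrix(u(in_dim * gate_mult * hidden), in_dim),
              Wh = matrix(u(hidden * gate_mult * hidden), hidden))
    if (cell == "gru") {
      p$bi <- u(gate_mult * hidden)
      p$bh <- u(gate_mult * hidden)
    } else {
      p$b <- u(gate_mult * hidden)
    }
    p
  }
  params <- list()
  for (layer in 1:2) {
    in_dim <- if (layer == 1) input_dim else 2 * hidden
    for (d in c("f", "b")) {
      pre <- paste0("l", layer, d)
      dp <- dir_par(in_dim)
      for (nm in names(dp)) params[[paste0(pre, "_", nm)]] <- dp[[nm]]
    }
  }
  kh <- 1 / sqrt(2 * hidden)
  params$head_W <- runif(2 * hidden, -kh, kh)
  params$head_b <- runif(1, -kh, kh)
  params
}

# forward pass in evaluation mode (dropout off); x is B x T x 3
rnn_forward_eval <- function(params, x, cell) {
  cpp_rnn_predict(params, aperm(x, c(1, 3, 2)), cell)
}

# forward + backward for one training batch; dropmask is B x T x 2H scaled
# by 1/(1-p), or NULL
rnn_train_step <- function(params, x, y, mask, dropmask, cell) {
  dm <- if (is.null(dropmask)) numeric(0) else aperm(dropmask, c(1, 3, 2))
  cpp_rnn_run(params, aperm(x, c(1, 3, 2)), y, mask, dm, cell,
              training = !is.null(dropmask), want_grad = TRUE)
}

#' Per-frame probabilities for a padded batch
#'
#' Evaluation-mode forward pass through the bidirectional recurrent stack
#' and logistic head. Output has the same `B x max_len` shape as the mask;
#' probabilities at padded positions are meaningless and should be dropped
#' via the mask.
#'
#' @param model A [train_classifier()] result.
#' @param x A `B x max_len x 3` array of normalized, padded sequences.
#' @param mask The `B x max_len` validity mask (returned untouched alongside
#'   the probabilities' interpretation; the recurrent stack itself runs over
#'   the full padded length).
#' @return A `B x max_len` matrix of probabilities in (0, 1).
#' @export
forward <- function(model, x, mask = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (length(dim(x)) != 3 || dim(x)[3] != 3)
    stop("x must be a B x T x 3 array")
  rnn_forward_eval(model$params, x, model$config$cell)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
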