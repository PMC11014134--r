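#' Network architecture configuration
#'
#' Describes the dual-task parallel CNN+LSTM model: four parallel branches of
#' four conv(3x3, `conv_channels`, same padding) -> batch-norm -> ReLU ->
#' 2x2 max-pool blocks with dropout after the last pool; a motion head
#' (concatenated flattened branch maps -> FC `motion_fc1` -> FC 6 ->
#' softmax); and a fatigue head (per branch, two stacked LSTM layers with a
#' linear inter-layer connection, last-step hidden states concatenated ->
#' FC `fatigue_fc_dims[1]` -> FC 3 -> softmax).
#'
#' Two published-table inconsistencies are resolved here (and surfaced by
#' [model_shapes()]): the fatigue head's fully connected pair is
#' `4096 -> 512 -> 3` (the printed `FC1: 4096 -> 1024` cannot compose with
#' `FC2: 512 -> 3`), and the fatigue LSTMs default to per-branch sequences
#' over feature-map rows (`rows_as_steps`: 16 steps x 320 features at the
#' full scale) rather than one flat 20,480-vector step
#' (`flat_single_step`, also available).
#'
#' @param n_branches Parallel CNN branches = images per example (default 4,
#'   one per sEMG channel).
#' @param input_shape `(height, width, channels)` of each image; height and
#'   width must be divisible by 16 (default `c(256, 256, 3)`).
#' @param conv_channels Feature channels in every conv layer (default 20).
#' @param conv_kernel,pool_kernel Kernel sizes (fixed at 3 and 2; retained
#'   for the architecture record).
#' @param dropout_rate Dropout after the last pooling layer (default 0.3).
#' @param motion_classes,fatigue_classes Output sizes (6 and 3).
#' @param motion_fc1 Hidden width of the motion head (default 2048).
#' @param lstm_hidden LSTM hidden size (default 1024).
#' @param lstm_layers Stacked LSTM layers (fixed at 2).
#' @param lstm_sequence_layout `"rows_as_steps"` or `"flat_single_step"`.
#' @param fatigue_fc_dims Hidden and output sizes of the fatigue FC pair
#'   (default `c(512, 3)`).
#' @param seed Parameter-initialization seed.
#' @return Object of class `fessemg_modelconfig`.
#' @export
model_config <- function(n_branches = 4, input_shape = c(256, 256, 3),
                         conv_channels = 20, conv_kernel = 3, pool_kernel = 2,
                         dropout_rate = 0.3, motion_classes = 6,
                         fatigue_classes = 3, motion_fc1 = 2048,
                         lstm_hidden = 1024, lstm_layers = 2,
                         lstm_sequence_layout = c("rows_as_steps", "flat_single_step"),
                         fatigue_fc_dims = c(512, 3), seed = 1L) {
  lstm_sequence_layout <- match.arg(lstm_sequence_layout)
  if (conv_kernel != 3 || pool_kernel != 2)
    stop_input("only conv_kernel = 3 and pool_kernel = 2 are implemented")
  if (lstm_layers != 2)
    stop_input("only lstm_layers = 2 is implemented")
  if (input_shape[1] %% 16 != 0 || input_shape[2] %% 16 != 0)
    stop_input("input height/width must be divisible by 16 ",
               "(four stride-2 poolings)")
  if (fatigue_fc_dims[2] != fatigue_classes)
    stop_input("fatigue_fc_dims[2] must equal fatigue_classes")
  structure(list(n_branches = as.integer(n_branches),
                 input_shape = as.integer(input_shape),
                 conv_channels = as.integer(conv_channels),
                 dropout_rate = dropout_rate,
                 motion_classes = as.integer(motion_classes),
                 fatigue_classes = as.integer(fatigue_classes),
                 motion_fc1 = as.integer(motion_fc1),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_sequence_layout = lstm_sequence_layout,
                 fatigue_fc_dims = as.integer(fatigue_fc_dims),
                 seed = as.integer(seed)),
            class = "fessemg_modelconfig")
}

#' Layer-by-layer shape table of the configured model
#'
#' The architecture contract: input/output sizes of every layer, computed
#' from the configuration by the same arithmetic the builder uses. At the
#' default full-scale configuration this reproduces the published parameter
#' table (concatenated feature dimension `16*16*20*4 = 20480`, motion head
#' `20480 -> 2048 -> 6`, fatigue head `4*1024 = 4096 -> 512 -> 3` after the
#' documented dimension corrections).
#'
#' @param config A [model_config()].
#' @return Data frame with columns module, layer, input, output.
#' @export
model_shapes <- function(config) {
  stopifnot(inherits(config, "fessemg_modelconfig"))
  H <- config$input_shape[1]; W <- config$input_shape[2]
  Cin <- config$input_shape[3]; K <- config$conv_channels
  B <- config$n_branches
  rows <- list()
  h <- H; w <- W; cin <- Cin
  for (l in 1:4) {
    rows[[length(rows) + 1]] <- data.frame(
      module = "feature_extraction", layer = paste0("Conv", l),
      input = sprintf("%d x %d x %d", h, w, cin),
      output = sprintf("%d x %d x %d", h, w, K))
    rows[[length(rows) + 1]] <- data.frame(
      module = "feature_extraction", layer = paste0("Pool", l),
      input = sprintf("%d x %d x %d", h, w, K),
      output = sprintf("%d x %d x %d", h / 2, w / 2, K))
    h <- h / 2; w <- w / 2; cin <- K
  }
  concat <- h * w * K * B
  rows[[length(rows) + 1]] <- data.frame(
    module = "motion", layer = "Concatenate",
    input = sprintf("%d x %d x %d x %d", h, w, K, B),
    output = as.character(concat))
  rows[[length(rows) + 1]] <- data.frame(
    module = "motion", layer = "FC1", input = as.character(concat),
    output = as.character(config$motion_fc1))
  rows[[length(rows) + 1]] <- data.frame(
    module = "motion", layer = "FC2", input = as.character(config$motion_fc1),
    output = as.character(config$motion_classes))
  if (config$lstm_sequence_layout == "rows_as_steps") {
    seq_in <- sprintf("%d steps x %d", h, w * K)
    stacks <- B
  } else {
    seq_in <- sprintf("1 step x %d", concat)
    stacks <- 1L
  }
  rows[[length(rows) + 1]] <- data.frame(
    module = "fatigue", layer = "LSTM1", input = seq_in,
    output = as.character(config$lstm_hidden))
  rows[[length(rows) + 1]] <- data.frame(
    module = "fatigue", layer = "LSTM2",
    input = as.character(config$lstm_hidden),
    output = as.character(config$lstm_hidden))
  fat_in <- stacks * config$lstm_hidden
  rows[[length(rows) + 1]] <- data.frame(
    module = "fatigue", layer = "Concatenate",
    input = sprintf("%d x %d", config$lstm_hidden, stacks),
    output = as.character(fat_in))
  rows[[length(rows) + 1]] <- data.frame(
    module = "fatigue", layer = "FC1", input = as.character(fat_in),
    output = as.character(config$fatigue_fc_dims[1]))
  rows[[length(rows) + 1]] <- data.frame(
    module = "fatigue", layer = "FC2",
    input = as.character(config$fatigue_fc_dims[1]),
    output = as.character(config$fatigue_fc_dims[2]))
  out <- do.call(rbind, rows)
  attr(out, "concat_dim") <- concat
  attr(out, "fatigue_concat_dim") <- fat_in
  out
}

#' Build the dual-task network
#'
#' Allocates and seed-initializes all parameters. Construction errors name
#' the offending constraint (e.g. input size not divisible by 16).
#'
#' @param config A [model_config()].
#' @return Object of class `fessemg_net` (external pointer + config).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "fessemg_modelconfig"))
  cpp_cfg <- list(n_branches = config$n_branches,
                  in_channels = config$input_shape[3],
                  height = config$input_shape[1],
                  width = config$input_shape[2],
                  conv_channels = config$conv_channels,
                  motion_fc1 = config$motion_fc1,
                  motion_classes = config$motion_classes,
                  lstm_hidden = config$lstm_hidden,
                  fatigue_fc1 = config$fatigue_fc_dims[1],
                  fatigue_classes = config$fatigue_classes,
                  dropout = config$dropout_rate,
                  lstm_sequence_layout = config$lstm_sequence_layout)
  ptr <- .net_create(cpp_cfg, config$seed)
  structure(list(ptr = ptr, config = config, cpp_config = cpp_cfg),
            class = "fessemg_net")
}

#' @export
print.fessemg_net <- function(x, ...) {
  cat("<fessemg_net> ", x$config$n_branches, " branches, input ",
      paste(x$config$input_shape, collapse = "x"), ", ",
      format(.net_n_params(x$ptr), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `fessemg_net`.
#' @return Numeric count.
#' @export
n_parameters <- function(model) .net_n_params(model$ptr)

#' Training configuration
#'
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 50).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param split Train/validation/test fractions, summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed Seed for the split and the training-time RNG.
#' @return Object of class `fessemg_trainconfig`.
#' @export
train_config <- function(epochs = 100, batch_size = 50, learning_rate = 0.001,
                         split = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8) stop_input("split fractions must sum to 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 split = split, seed = as.integer(seed)),
            class = "fessemg_trainconfig")
}

#' Bundle per-channel images into one labeled example
#'
#' @param images List of `n_branches` images (`fessemg_tfimage` or plain
#'   `H x W x 3` arrays), one per sEMG channel.
#' @param motion_label,fatigue_label Labels of the underlying time window.
#' @return Object of class `fessemg_example`.
#' @export
labeled_example <- function(images, motion_label, fatigue_label) {
  check_motion(motion_label)
  check_fatigue(fatigue_label)
  px <- lapply(images, function(im)
    if (inherits(im, "fessemg_tfimage")) im$pixels else im)
  structure(list(images = px, motion_label = motion_label,
                 fatigue_label = fatigue_label),
            class = "fessemg_example")
}

# Pack a list of fessemg_example into the column-per-example matrix layout
# the C++ model consumes, plus 0-based integer labels.
pack_examples <- function(examples, config) {
  H <- config$input_shape[1]; W <- config$input_shape[2]
  Cin <- config$input_shape[3]; B <- config$n_branches
  n <- length(examples)
  X <- matrix(0, nrow = B * Cin * H * W, ncol = n)
  ml <- integer(n); fl <- integer(n)
  img_len <- H * W * Cin
  for (e in seq_len(n)) {
    ex <- examples[[e]]
    if (length(ex$images) != B)
      stop_input("example ", e, " has ", length(ex$images),
                 " images; model expects ", B)
    for (b in seq_len(B)) {
      im <- ex$images[[b]]
      if (!all(dim(im) == c(H, W, Cin)))
        stop_input("example ", e, " branch ", b, " image is ",
                   paste(dim(im), collapse = "x"), "; expected ",
                   paste(c(H, W, Cin), collapse = "x"))
      X[((b - 1) * img_len + 1):(b * img_len), e] <- as.vector(im)
    }
    ml[e] <- match(ex$motion_label, MOTION_LABELS) - 1L
    fl[e] <- match(ex$fatigue_label, FATIGUE_LABELS) - 1L
  }
  if (anyNA(ml) || anyNA(fl)) stop_input("examples carry unknown labels")
  list(X = X, motion = ml, fatigue = fl)
}

#' Dual-task cross-entropy loss
#'
#' `loss = CE(motion) + CE(fatigue)`, the summed per-task cross-entropies
#' the network is trained on. Zero iff both predictions are one-hot on the
#' correct classes; `log(6) + log(3)` for uniform predictions.
#'
#' @param motion_probs Probability vector over motions (or matrix, one row
#'   per example).
#' @param motion_label Motion label(s): names from [motion_labels()] or
#'   1-based indices.
#' @param fatigue_probs,fatigue_label Same for the fatigue task.
#' @return Numeric vector of per-example losses.
#' @export
dual_loss <- function(motion_probs, motion_label, fatigue_probs, fatigue_label) {
  ce(motion_probs, motion_label, MOTION_LABELS) +
    ce(fatigue_probs, fatigue_label, FATIGUE_LABELS)
}

ce <- function(probs, label, label_set) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  idx <- if (is.character(label)) match(label, label_set) else as.integer(label)
  if (anyNA(idx) || any(idx < 1) || any(idx > ncol(probs)))
    stop_input("label out of range")
  if (length(idx) == 1) idx <- rep(idx, nrow(probs))
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  -log(pmax(p, .Machine$double.xmin))
}

#' Stratified train/validation/test split
#'
#' Seeded shuffle stratified by the (motion, fatigue) pair; global set sizes
#' follow the largest-remainder rule on `fractions` (so 100 examples at
#' 0.8/0.1/0.1 give exactly 80/10/10). Strata with fewer than 3 examples
#' trigger a warning and an unstratified split.
#'
#' @param examples List of `fessemg_example` (or anything with
#'   `motion_label`/`fatigue_label` fields).
#' @param fractions Length-3 nonnegative fractions summing to 1.
#' @param seed Shuffle seed.
#' @return List with `train`, `val`, `test` (disjoint, exhaustive) and
#'   `indices` (the per-set indices into `examples`).
#' @export
split_dataset <- function(examples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_input("fractions must sum to 1")
  n <- length(examples)
  strata <- vapply(examples, function(ex)
    paste(ex$motion_label, ex$fatigue_label, sep = "|"), character(1))
  targets <- largest_remainder(n * fractions)
  with_seed(seed, {
    groups <- split(seq_len(n), strata)
    if (any(vapply(groups, length, integer(1)) < 3)) {
      warning("stratum with < 3 examples; falling back to unstratified split",
              call. = FALSE)
      groups <- list(sample(n))
    } else {
      groups <- lapply(groups, sample)
    }
    assign_set <- integer(n)
    for (g in groups) {
      cnt <- largest_remainder(length(g) * fractions)
      assign_set[g] <- rep(1:3, times = cnt)
    }
    # correct per-stratum rounding drift so global sizes match exactly
    for (s in 1:3) {
      excess <- sum(assign_set == s) - targets[s]
      while (excess > 0) {
        deficit <- which(tabulate(assign_set, 3) < targets)[1]
        pool <- which(assign_set == s)
        assign_set[pool[sample.int(length(pool), 1)]] <- deficit
        excess <- excess - 1
      }
    }
  })
  idx <- lapply(1:3, function(s) which(assign_set == s))
  list(train = examples[idx[[1]]], val = examples[idx[[2]]],
       test = examples[idx[[3]]],
       indices = list(train = idx[[1]], val = idx[[2]], test = idx[[3]]))
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x) - sum(fl)))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Train the dual-task network
#'
#' Mini-batch Adam on the summed dual cross-entropy; per-epoch training
#' loss, validation loss and both-task validation accuracies are recorded,
#' and the best-validation-loss parameters are restored at the end.
#' Deterministic given the model seed and `config$seed`.
#'
#' @param model A `fessemg_net` from [build_model()] (updated in place).
#' @param train_examples,val_examples Lists of `fessemg_example`.
#' @param config A [train_config()].
#' @return The model, invisibly, with a `history` data frame attached
#'   (epoch, train_loss, val_loss, val_motion_acc, val_fatigue_acc).
#' @export
train_model <- function(model, train_examples, val_examples = list(),
                        config = train_config()) {
  stopifnot(inherits(model, "fessemg_net"), inherits(config, "fessemg_trainconfig"))
  if (length(train_examples) == 0) stop_input("empty training set")
  tr <- pack_examples(train_examples, model$config)
  va <- if (length(val_examples))
    pack_examples(val_examples, model$config)
  else list(X = matrix(0, nrow(tr$X), 0), motion = integer(0), fatigue = integer(0))
  h <- .net_train(model$ptr, tr$X, tr$motion, tr$fatigue,
                  va$X, va$motion, va$fatigue,
                  config$epochs, config$batch_size, config$learning_rate)
  model$history <- data.frame(epoch = seq_along(h$train_loss),
                              train_loss = h$train_loss,
                              val_loss = h$val_loss,
                              val_motion_acc = h$val_motion_acc,
                              val_fatigue_acc = h$val_fatigue_acc)
  model$best_val_loss <- h$best_val_loss
  invisible(model)
}

#' Predict motion and fatigue for labeled examples
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch-norm on
#' running statistics).
#'
#' @param object A `fessemg_net`.
#' @param examples List of `fessemg_example`.
#' @param ... Unused.
#' @return List with `motion_probs` (n x 6), `fatigue_probs` (n x 3), and
#'   argmax labels `motion` and `fatigue`.
#' @export
predict.fessemg_net <- function(object, examples, ...) {
  pk <- pack_examples(examples, object$config)
  out <- .net_predict(object$ptr, pk$X)
  colnames(out$motion_probs) <- MOTION_LABELS[seq_len(ncol(out$motion_probs))]
  colnames(out$fatigue_probs) <- FATIGUE_LABELS[seq_len(ncol(out$fatigue_probs))]
  list(motion_probs = out$motion_probs,
       fatigue_probs = out$fatigue_probs,
       motion = MOTION_LABELS[apply(out$motion_probs, 1, which.max)],
       fatigue = FATIGUE_LABELS[apply(out$fatigue_probs, 1, which.max)])
}

#' Save / load model weights
#'
#' Runtime checkpointing of parameters, batch-norm statistics and the
#' configuration (RDS container).
#'
#' @param model A `fessemg_net`.
#' @param path Checkpoint file path.
#' @return `load_model` returns a rebuilt `fessemg_net`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config,
               params = .net_get_params(model$ptr),
               state = .net_get_state(model$ptr),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config)
  .net_set_params(model$ptr, obj$params)
  .net_set_state(model$ptr, obj$state)
  model$history <- obj$history
  model
}

#' Desk-scale model and training profile
#'
#' A reduced-capacity profile of the same architecture for single-CPU use:
#' 32 x 32 inputs, 8 conv channels, LSTM hidden 32, motion FC 64, fatigue
#' FC 16, trained 30 epochs with batch 15 at learning rate 0.002, on 150
#' windows per motion class with STFT spectrogram images. The full-scale
#' defaults of [model_config()] / [train_config()] reproduce the published
#' architecture; this profile keeps every structural element (4 branches,
#' 4 conv/pool blocks, dual heads, dual loss) at a small fraction of the
#' compute so a full pipeline run takes minutes on one CPU.
#'
#' @param seed Seed applied to both configurations.
#' @return List with `model` ([model_config()]), `train` ([train_config()]),
#'   `image_size`, `method` and `n_windows_per_class`.
#' @export
desk_profile <- function(seed = 1L) {
  list(model = model_config(input_shape = c(32, 32, 3), conv_channels = 8,
                            motion_fc1 = 64, lstm_hidden = 32,
                            fatigue_fc_dims = c(16, 3), seed = seed),
       train = train_config(epochs = 30, batch_size = 15,
                            learning_rate = 0.002, seed = seed),
       image_size = c(32L, 32L),
       method = "STFT",
       n_windows_per_class = 150L)
}
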