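# Training protocol and evaluation battery: chronological splits, the
# Adam + halving learning-rate schedule, per-subject (personalized) model
# training, cross-subject MSE matrices, learning curves and the FNO-vs-CNN
# comparison.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, batch 32, 200 epochs, learning
#' rate starting at 0.001 and halved every 50 epochs, MSE loss, 6:2:2
#' chronological split.
#'
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 200; tests and desk-scale runs
#'   use far fewer).
#' @param initial_lr Initial Adam learning rate (default 0.001).
#' @param lr_halving_period Epochs between halvings (default 50).
#' @param split_ratio Train/validation/test fractions, summing to 1
#'   (default 0.6/0.2/0.2).
#' @param seed Integer seed controlling batching (and any model
#'   initialisation derived from it).
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, epochs = 200L,
                            initial_lr = 0.001, lr_halving_period = 50L,
                            split_ratio = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 0, initial_lr > 0,
            lr_halving_period >= 1, length(split_ratio) == 3,
            abs(sum(split_ratio) - 1) < 1e-8, all(split_ratio > 0))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 split_ratio = split_ratio, seed = as.integer(seed)),
            class = "training_config")
}

#' Learning rate at a given epoch
#'
#' `initial_lr * 0.5 ^ floor(epoch / lr_halving_period)` with 0-based
#' epochs: 0.001 at epoch 0, 0.0005 at epoch 50, 0.000125 at epoch 199
#' under the defaults.
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [training_config()].
#' @export
lr_schedule <- function(epoch, cfg = training_config()) {
  stopifnot(all(epoch >= 0))
  cfg$initial_lr * 0.5^(epoch %/% cfg$lr_halving_period)
}

#' Chronological train/validation/test split
#'
#' Contiguous split of sample indices 1..n: the first 60% train, the next
#' 20% validation, the last 20% test (floor-allocated, remainder to
#' train), so 3600 samples give 2160/720/720. Because consecutive sliding
#' windows share frames, samples whose input+target span crosses a
#' partition boundary can leak training frames into validation/test;
#' passing the span length purges them from validation and test (counts
#' reported in `dropped`).
#'
#' @param n Number of samples, or an `rp_dataset`.
#' @param cfg A [training_config()] (source of the ratios).
#' @param span Frames covered by one sample (T + T_hat); when given,
#'   boundary-crossing validation/test samples are dropped. Defaults to
#'   the dataset's span when `n` is an `rp_dataset`, else no purge.
#' @return List with integer index vectors `train`, `validation`, `test`
#'   and a named `dropped` count.
#' @export
split_dataset <- function(n, cfg = training_config(), span = NULL) {
  if (inherits(n, "rp_dataset")) {
    if (is.null(span)) span <- n$cfg$input_steps + n$cfg$horizon
    n <- n$n_samples
  }
  n <- as.integer(n)
  if (n < 10L) stop("need at least 10 samples to split", call. = FALSE)
  n_val <- floor(n * cfg$split_ratio[2])
  n_test <- floor(n * cfg$split_ratio[3])
  n_train <- n - n_val - n_test
  train <- seq_len(n_train)
  validation <- seq.int(n_train + 1L, n_train + n_val)
  test <- seq.int(n_train + n_val + 1L, n)
  dropped <- c(validation = 0L, test = 0L)
  if (!is.null(span) && span > 1L) {
    keep_v <- validation > n_train + span - 1L
    dropped["validation"] <- sum(!keep_v)
    validation <- validation[keep_v]
    keep_t <- test > n_train + n_val + span - 1L
    dropped["test"] <- sum(!keep_t)
    test <- test[keep_t]
  }
  list(train = train, validation = validation, test = test,
       dropped = dropped)
}

# Gather a batch of normalised input/target stacks from a dataset, in the
# internal (M, M, B, frames) layout.
#' @noRd
gather_batch <- function(ds, idx, scale) {
  M <- ds$M; T <- ds$cfg$input_steps; H <- ds$cfg$horizon
  idx <- ds$starts[idx]
  fi <- as.vector(outer(idx, seq.int(0L, T - 1L), "+"))
  x <- ds$frames[, , fi, drop = FALSE] / scale
  dim(x) <- c(M, M, length(idx), T)
  ft <- as.vector(outer(idx + T, seq.int(0L, H - 1L), "+"))
  y <- ds$frames[, , ft, drop = FALSE] / scale
  dim(y) <- c(M, M, length(idx), H)
  list(x = x, y = y)
}

#' Train a forecasting model (FNO or CNN baseline)
#'
#' Minimises the MSE between predicted and target frame stacks with Adam
#' under the halving learning-rate schedule, recording train and
#' validation MSE every epoch. Frames are normalised by the training
#' split's recurrence-plot maximum; the normalizer and encoding
#' configuration are stored in the returned model so inference is fully
#' determined by the checkpoint. Deterministic given `cfg$seed` (and
#' single-threaded BLAS).
#'
#' @param model An `fno_model` or `cnn_model`.
#' @param ds An `rp_dataset`.
#' @param train_idx,val_idx Sample indices (see [split_dataset()]).
#' @param cfg A [training_config()].
#' @return List with `model` (trained) and `curves` (data frame: epoch,
#'   train_mse, val_mse; empty when `epochs = 0`).
#' @export
train_model <- function(model, ds, train_idx, val_idx = integer(0),
                        cfg = training_config()) {
  stopifnot(inherits(ds, "rp_dataset"))
  if (length(train_idx) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(model$normalizer))
    model$normalizer <- fit_rp_normalizer(ds, train_idx)
  model$encoding <- ds$cfg
  sc <- model$normalizer$scale
  opt <- adam_init(model$params)
  curves <- data.frame(epoch = integer(0), train_mse = numeric(0),
                       val_mse = numeric(0))
  if (cfg$epochs == 0L) return(list(model = model, curves = curves))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_schedule(ep - 1L, cfg)
      perm <- sample(train_idx)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        g <- gather_batch(ds, bi, sc)
        if (inherits(model, "fno_model")) {
          # fused C++ step: forward, loss and backward in one call
          st <- cpp_fno_step(g$x, g$y, dft_restricted(ds$M, model$cfg$modes),
                             model$params, ds$M, length(bi),
                             model$cfg$input_steps, model$cfg$horizon,
                             model$cfg$num_layers, model$cfg$width)
          loss <- st$loss
          grads <- st$grads
        } else {
          fp <- forward_pass(model, g$x, keep_cache = TRUE)
          diff <- fp$out - g$y
          loss <- mean(diff^2)
          grads <- backward_pass(model, fp$cache, 2 * diff / length(diff))
        }
        if (!is.finite(loss))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
               call. = FALSE)
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params; opt <- upd$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      val <- if (length(val_idx))
        evaluate_mse(model, ds, val_idx) else NA_real_
      curves <- rbind(curves,
                      data.frame(epoch = ep,
                                 train_mse = ep_loss / length(train_idx),
                                 val_mse = val))
    }
  })
  list(model = model, curves = curves)
}

#' Mean squared forecast error of a model on a set of samples
#'
#' Computed on the model's normalised recurrence-plot scale (the scale the
#' loss was trained on), averaging over all frame entries. Invariant to
#' the order of the samples.
#'
#' @param model Trained `fno_model` or `cnn_model`.
#' @param ds An `rp_dataset`.
#' @param idx Sample indices to evaluate.
#' @param chunk Samples per forward pass.
#' @export
evaluate_mse <- function(model, ds, idx, chunk = 64L) {
  stopifnot(!is.null(model$normalizer))
  sc <- model$normalizer$scale
  tot <- 0; nel <- 0
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    g <- gather_batch(ds, part, sc)
    diff <- forward_pass(model, g$x)$out - g$y
    tot <- tot + sum(diff^2); nel <- nel + length(diff)
  }
  tot / nel
}

#' Cross-subject MSE matrix
#'
#' Entry (i, j) is the MSE of subject i's model evaluated on subject j's
#' test samples: a personalized model shows a small diagonal (its own
#' held-out data) and larger off-diagonal entries (other subjects).
#'
#' Normalization is part of each recording's preprocessing: subject j's
#' frames are always divided by subject j's stored training maximum (the
#' normalizer of the model trained on subject j), whichever model then
#' consumes them, so the matrix compares forecasting mismatch rather than
#' amplitude differences between subjects.
#'
#' @param models List of trained models, one per subject (in the same
#'   order as `datasets`).
#' @param datasets List of `rp_dataset`s, one per subject.
#' @param test_idx List of test-sample index vectors, one per subject.
#' @param chunk Samples per forward pass.
#' @return An `eval_report`: list with `mse_matrix` (S x S, rows = model's
#'   subject, columns = test subject).
#' @export
cross_subject_mse_matrix <- function(models, datasets, test_idx,
                                     chunk = 128L) {
  S <- length(models)
  if (length(datasets) != S || length(test_idx) != S)
    stop("models, datasets and test_idx must have one entry per subject",
         call. = FALSE)
  ids <- vapply(datasets, function(d) d$subject_id, character(1))
  mat <- matrix(NA_real_, S, S, dimnames = list(model = ids, test = ids))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    mi <- models[[i]]
    mi$normalizer <- models[[j]]$normalizer
    mat[i, j] <- evaluate_mse(mi, datasets[[j]], test_idx[[j]], chunk)
  }
  structure(list(mse_matrix = mat), class = "eval_report")
}

#' Compare FNO and CNN evaluation reports
#'
#' Per-subject ratio of diagonal (own-test) MSEs, CNN / FNO, and a flag for
#' "the FNO is no worse than the CNN on every subject's own test set".
#'
#' @param report_fno,report_cnn `eval_report`s of matching shape.
#' @return List with `ratio` (per-subject CNN/FNO diagonal ratios) and
#'   `fno_never_worse` (logical).
#' @export
compare_models <- function(report_fno, report_cnn) {
  a <- diag(report_fno$mse_matrix)
  b <- diag(report_cnn$mse_matrix)
  if (length(a) != length(b))
    stop("reports have different numbers of subjects", call. = FALSE)
  list(ratio = b / a, fno_never_worse = all(a <= b))
}
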