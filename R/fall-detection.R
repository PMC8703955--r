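# Energy-score fall early warning.
#
# A two-layer activity classifier is trained on FNO-*predicted* frame
# stacks to separate the normal motions (walking vs running). At run time
# the energy statistic E = -log sum_i exp(logit_i) of the classifier's
# logits serves as an out-of-distribution score: familiar motion yields a
# confident logit and a low energy, while motion unlike anything in
# training (a fall) yields high energy. A threshold calibrated as an
# upper quantile of energies on normal training data turns the score into
# a normal / potential-fall decision; because the classifier sees frames
# the forecaster predicts ahead of time, the alert can precede the
# verdict an observed-frame detector reaches.

#' Energy score of a logit vector
#'
#' `E = -log sum_i exp(logit_i)`, computed with an overflow-safe
#' log-sum-exp. Adding a constant c to every logit subtracts c from the
#' energy. Low energy = in-distribution (confident classifier), high
#' energy = out-of-distribution.
#'
#' @param logits Numeric vector of logits, or a matrix with one logit
#'   vector per row.
#' @return Scalar energy, or one energy per row for a matrix.
#' @examples
#' energy_score(c(0, 0))   # -log(2)
#' energy_score(c(2, 1))   # -2.3133
#' @export
energy_score <- function(logits) {
  if (is.matrix(logits)) {
    if (ncol(logits) < 1L) stop("empty logits", call. = FALSE)
    if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
    return(-apply(logits, 1, log_sum_exp))
  }
  if (length(logits) < 1L) stop("empty logits", call. = FALSE)
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  -log_sum_exp(logits)
}

#' Calibrate the energy threshold on normal training data
#'
#' The threshold is the empirical `quantile` (default 0.95, linear
#' interpolation convention) of the energies of normal training windows:
#' falls are never used for calibration (one-class calibration), and by
#' construction about 5% of in-distribution windows exceed the default
#' threshold.
#'
#' @param training_energies Energies of normal training windows.
#' @param quantile Calibration quantile in (0, 1).
#' @return The threshold tau.
#' @export
calibrate_threshold <- function(training_energies, quantile = 0.95) {
  if (length(training_energies) == 0L)
    stop("no training energies supplied", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be in (0, 1)", call. = FALSE)
  unname(stats::quantile(training_energies, quantile, type = 7))
}

#' Initialise the two-layer activity classifier
#'
#' Maps a flattened predicted frame stack (T_hat * M^2 entries) through one
#' hidden layer to per-class logits.
#'
#' @param input_dim Flattened stack length (T_hat * M^2).
#' @param hidden Hidden width (default 32).
#' @param classes Character vector of class labels (default walking,
#'   running).
#' @param seed Integer seed.
#' @param activation Hidden activation, `"sigmoid"` (default) or
#'   `"relu"`. The bounded sigmoid keeps hidden features saturated for
#'   inputs far outside the training range, so out-of-distribution
#'   windows cannot earn arbitrarily confident (low-energy) logits the
#'   way they can under an unbounded piecewise-linear hidden layer.
#' @return Object of class `activity_classifier`.
#' @export
classifier_init <- function(input_dim, hidden = 32L,
                            classes = c("walking", "running"), seed = 1L,
                            activation = c("sigmoid", "relu")) {
  stopifnot(input_dim >= 1, hidden >= 1, length(classes) >= 2)
  activation <- match.arg(activation)
  with_seed(seed, {
    f1 <- init_linear(input_dim, hidden)
    f2 <- init_linear(hidden, length(classes))
    structure(list(params = list(W1 = f1$W, b1 = f1$b,
                                 W2 = f2$W, b2 = f2$b),
                   classes = classes, input_dim = as.integer(input_dim),
                   hidden = as.integer(hidden), seed = as.integer(seed),
                   activation = activation),
              class = "activity_classifier")
  })
}

#' Logits of the activity classifier
#'
#' @param clf An `activity_classifier`.
#' @param X Matrix (n x input_dim) of flattened frame stacks.
#' @return Matrix (n x classes) of logits.
#' @export
classifier_logits <- function(clf, X) {
  stopifnot(inherits(clf, "activity_classifier"))
  if (ncol(X) != clf$input_dim)
    stop(sprintf("classifier expects %d features, got %d",
                 clf$input_dim, ncol(X)), call. = FALSE)
  act <- if (identical(clf$activation, "relu")) relu else sigmoid
  h <- act(sweep(X %*% clf$params$W1, 2L, clf$params$b1, "+"))
  sweep(h %*% clf$params$W2, 2L, clf$params$b2, "+")
}

#' Flatten FNO-predicted frame stacks into classifier features
#'
#' Runs the forecaster on the given samples and flattens each predicted
#' T_hat-frame stack into one feature row, exactly what the classifier is
#' trained on and scored with.
#'
#' @param fno A trained `fno_model`.
#' @param ds An `rp_dataset` encoded compatibly with the model.
#' @param idx Sample indices.
#' @param chunk Samples per forward pass.
#' @return Matrix (length(idx) x T_hat * M^2).
#' @export
predicted_stack_features <- function(fno, ds, idx, chunk = 64L) {
  sc <- fno$normalizer$scale
  out <- matrix(0, length(idx), ds$M^2 * ds$cfg$horizon)
  pos <- 1L
  for (part in split(idx, ceiling(seq_along(idx) / chunk))) {
    g <- gather_batch(ds, part, sc)
    pred <- forward_pass(fno, g$x)$out            # (M, M, B, T_hat)
    out[pos:(pos + length(part) - 1L), ] <-
      matrix(aperm(pred, c(3, 1, 2, 4)), nrow = length(part))
    pos <- pos + length(part)
  }
  out
}

#' Train the activity classifier on predicted frame stacks
#'
#' Softmax cross-entropy with Adam under the halving learning-rate
#' schedule; deterministic given `cfg$seed`. At least two classes must be
#' present.
#'
#' @param X Feature matrix from [predicted_stack_features()] (rows =
#'   windows).
#' @param labels Class label per row (character or factor).
#' @param hidden Hidden width.
#' @param cfg A [training_config()] (batch size, epochs, schedule, seed).
#' @param activation Hidden activation (see [classifier_init()]).
#' @return A trained `activity_classifier` with attribute
#'   `training_accuracy`.
#' @export
train_activity_classifier <- function(X, labels, hidden = 32L,
                                      cfg = training_config(),
                                      activation = c("sigmoid", "relu")) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least two activity classes to train the classifier",
         call. = FALSE)
  y <- match(labels, classes)
  clf <- classifier_init(ncol(X), hidden, classes, seed = cfg$seed,
                         activation = activation)
  opt <- adam_init(clf$params)
  n <- nrow(X)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_schedule(ep - 1L, cfg)
      perm <- sample(n)
      for (bi in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
        Xb <- X[bi, , drop = FALSE]
        h_pre <- sweep(Xb %*% clf$params$W1, 2L, clf$params$b1, "+")
        h <- if (identical(clf$activation, "relu")) relu(h_pre)
             else sigmoid(h_pre)
        z <- sweep(h %*% clf$params$W2, 2L, clf$params$b2, "+")
        zmax <- apply(z, 1, max)
        p <- exp(z - zmax)
        p <- p / rowSums(p)
        dz <- p
        dz[cbind(seq_along(bi), y[bi])] <-
          dz[cbind(seq_along(bi), y[bi])] - 1
        dz <- dz / length(bi)
        grads <- list(W2 = crossprod(h, dz), b2 = colSums(dz))
        dact <- if (identical(clf$activation, "relu")) (h_pre > 0)
                else h * (1 - h)
        dh <- (dz %*% t(clf$params$W2)) * dact
        grads$W1 <- crossprod(Xb, dh); grads$b1 <- colSums(dh)
        upd <- adam_step(clf$params, grads, opt, lr)
        clf$params <- upd$params; opt <- upd$state
      }
    }
  })
  pred <- max.col(classifier_logits(clf, X))
  attr(clf, "training_accuracy") <- mean(pred == y)
  clf
}

#' Slide the energy-score fall detector over a stream
#'
#' At each anchor frame a (stepping by `step`) two energies are computed
#' from data available at that moment: the energy of the classifier on the
#' FNO-*predicted* next T_hat frames (forecast score), and the energy on
#' the T_hat most recently *observed* frames (the conventional detector,
#' which necessarily lags the forecast by the horizon). An anchor whose
#' forecast energy exceeds tau raises a potential-fall alert; the event is
#' confirmed when actual fall data arrives after the risk signal — at the
#' first anchor strictly after the first alert whose observed energy also
#' exceeds tau — and `alert_lead` is the gap (in samples) between
#' confirmation and the first alert. The alert therefore precedes its own
#' confirmation by construction; no stronger earliness claim is made.
#'
#' @param stream A gyroscope [sensor_stream()].
#' @param fno Trained `fno_model` (supplies the normalizer and encoding).
#' @param classifier Trained `activity_classifier`.
#' @param tau Energy threshold from [calibrate_threshold()].
#' @param step Anchor stride in frames (default 1).
#' @param chunk Anchors per forward pass.
#' @return Data frame with one row per anchor: `frame_index` (end sample
#'   of the anchor frame), `energy` (forecast score), `energy_observed`
#'   (NA until T_hat observed frames exist), `decision`. Attributes
#'   `first_alert`, `confirmed_onset` (sample indices, NA if never
#'   triggered) and `alert_lead` (samples).
#' @export
detect_falls <- function(stream, fno, classifier, tau, step = 1L,
                         chunk = 64L) {
  stopifnot(inherits(fno, "fno_model"), !is.null(fno$normalizer),
            inherits(classifier, "activity_classifier"))
  cfg <- fno$encoding %||% encoding_config(input_steps = fno$cfg$input_steps,
                                           horizon = fno$cfg$horizon)
  enc <- encode_stream(stream, cfg)
  frames <- enc$frames / fno$normalizer$scale
  M <- enc$M; Tn <- cfg$input_steps; H <- cfg$horizon
  nf <- dim(frames)[3]
  if (nf < Tn + 1L) stop("stream too short for one input window", call. = FALSE)
  anchors <- seq.int(Tn, nf, by = step)
  e_pred <- rep(NA_real_, length(anchors))
  for (part in split(seq_along(anchors),
                     ceiling(seq_along(anchors) / chunk))) {
    fi <- as.vector(outer(anchors[part] - Tn + 1L, seq.int(0L, Tn - 1L), "+"))
    x <- frames[, , fi, drop = FALSE]
    dim(x) <- c(M, M, length(part), Tn)
    pred <- forward_pass(fno, x)$out
    feats <- matrix(aperm(pred, c(3, 1, 2, 4)), nrow = length(part))
    e_pred[part] <- energy_score(classifier_logits(classifier, feats))
  }
  e_obs <- rep(NA_real_, length(anchors))
  ok <- anchors >= H
  if (any(ok)) {
    which_ok <- which(ok)
    for (part in split(which_ok, ceiling(seq_along(which_ok) / chunk))) {
      fi <- as.vector(outer(anchors[part] - H + 1L, seq.int(0L, H - 1L), "+"))
      obs <- frames[, , fi, drop = FALSE]
      dim(obs) <- c(M, M, length(part), H)
      feats <- matrix(aperm(obs, c(3, 1, 2, 4)), nrow = length(part))
      e_obs[part] <- energy_score(classifier_logits(classifier, feats))
    }
  }
  t_anchor <- enc$t_index[anchors]
  decision <- ifelse(e_pred > tau, "potential_fall", "normal")
  alert_pos <- which(e_pred > tau)[1]
  first_alert <- if (!is.na(alert_pos)) t_anchor[alert_pos] else NA_integer_
  confirmed <- NA_integer_
  if (!is.na(alert_pos)) {
    later <- which(seq_along(anchors) > alert_pos & !is.na(e_obs) &
                     e_obs > tau)[1]
    if (!is.na(later)) confirmed <- t_anchor[later]
  }
  out <- data.frame(frame_index = t_anchor, energy = e_pred,
                    energy_observed = e_obs, decision = decision)
  attr(out, "tau") <- tau
  attr(out, "first_alert") <- first_alert
  attr(out, "confirmed_onset") <- confirmed
  attr(out, "alert_lead") <- if (is.na(first_alert) || is.na(confirmed))
    NA_integer_ else confirmed - first_alert
  out
}

#' Area under the ROC curve for energy separation
#'
#' Rank-statistic (Mann-Whitney) AUC of the energies of fall windows
#' against normal windows: 1 means every fall window scores higher than
#' every normal window.
#'
#' @param energies Numeric energy scores.
#' @param is_fall Logical, TRUE for fall windows.
#' @export
energy_auc <- function(energies, is_fall) {
  stopifnot(length(energies) == length(is_fall))
  pos <- energies[is_fall]; neg <- energies[!is_fall]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("need both fall and normal windows", call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
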