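# Desk-scale experiments shared by the acceptance tests. Each artifact is
# trained once per test session and cached; every seed is fixed so the
# whole battery is reproducible. The problem sizes (20 s streams, width-8
# operator, stride-2 training windows, constant learning rate over the
# short runs) are the package's desk-scale study conditions, described in
# the methods vignette.

.experiment_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.experiment_cache[[name]]))
    .experiment_cache[[name]] <- builder()
  .experiment_cache[[name]]
}

desk_fno_config <- function() fno_config(width = 8L)

desk_training_config <- function(epochs, seed)
  training_config(epochs = epochs, lr_halving_period = 1000L, seed = seed)

# 6 personalized walking forecasters + cross-subject MSE matrix
personalization_experiment <- function() cached("personalization", function() {
  enc <- encoding_config()
  cohort <- make_subject_cohort(6, "walking", seed = 1)
  dss <- lapply(cohort, function(p)
    encode_dataset(generate_motion_stream(p, 20, 30), enc,
                   subject_id = p$subject_id, motion = "walking"))
  splits <- lapply(dss, split_dataset)
  models <- vector("list", 6)
  curves1 <- NULL
  for (i in 1:6) {
    tr <- splits[[i]]$train
    tr <- tr[seq(1, length(tr), by = 2)]
    m <- fno_init(desk_fno_config(), seed = 100 + i)
    r <- train_model(m, dss[[i]], tr,
                     if (i == 1) splits[[i]]$validation else integer(0),
                     desk_training_config(150L, seed = 500 + i))
    models[[i]] <- r$model
    if (i == 1) curves1 <- r$curves
  }
  report <- cross_subject_mse_matrix(models, dss,
                                     lapply(splits, `[[`, "test"))
  list(cohort = cohort, datasets = dss, splits = splits, models = models,
       mse_matrix = report$mse_matrix, curves1 = curves1)
})

# decoder trained on subject 1's true frame/signal pairs
decoder_experiment <- function() cached("decoder", function() {
  pe <- personalization_experiment()
  ds <- pe$datasets[[1]]
  sp <- pe$splits[[1]]
  tr <- sp$train[seq(1, length(sp$train), by = 2)]
  dm <- decoder_init(decoder_config(hidden = 64L, head = 32L), M = ds$M,
                     seed = 11)
  r <- train_decoder(dm, ds, tr, integer(0),
                     desk_training_config(40L, seed = 12))
  te <- sp$test[seq(1, length(sp$test), by = 4)]
  preds <- NULL; trues <- NULL
  for (i in te) {
    sm <- get_sample(ds, i)
    seg <- decode_sequence(sm$target_frames, r$model)
    preds <- cbind(preds, seg$samples)
    trues <- cbind(trues, sm$target_signal)
  }
  corr <- vapply(1:3, function(a) stats::cor(preds[a, ], trues[a, ]),
                 numeric(1))
  list(model = r$model, correlations = corr)
})

# pooled walking+running forecaster, activity classifier, threshold, and
# detection runs on held-out normal and fall streams
fall_experiment <- function() cached("fall", function() {
  enc <- encoding_config()
  pe <- personalization_experiment()
  walk_p <- pe$cohort[[1]]
  run_p <- make_subject_profile("s1run", "running", seed = 21)
  dsw <- encode_dataset(generate_motion_stream(walk_p, 20, 30), enc,
                        subject_id = "s1", motion = "walking")
  dsr <- encode_dataset(generate_motion_stream(run_p, 20, 30), enc,
                        subject_id = "s1", motion = "running")
  spw <- split_dataset(dsw)
  spr <- split_dataset(dsr)
  pooled <- concat_datasets(list(
    subset_dataset(dsw, min(spw$train), max(spw$train)),
    subset_dataset(dsr, min(spr$train), max(spr$train))))
  tr <- seq(1, pooled$n_samples, by = 2)
  m <- fno_init(desk_fno_config(), seed = 31)
  m <- train_model(m, pooled, tr, integer(0),
                   desk_training_config(60L, seed = 32))$model
  feats <- predicted_stack_features(m, pooled, tr)
  clf <- train_activity_classifier(feats, pooled$sample_motion[tr],
                                   hidden = 32L,
                                   training_config(epochs = 30L, seed = 33))
  tau <- calibrate_threshold(
    energy_score(classifier_logits(clf, feats)), 0.95)
  normal_stream <- generate_motion_stream(walk_p, 20, 30, realization = 2)
  det_normal <- detect_falls(normal_stream, m, clf, tau, step = 2)
  fall_base <- generate_motion_stream(walk_p, 20, 30, realization = 3)
  fall <- inject_fall(fall_base, onset_s = 16, seed = 7)
  det_fall <- detect_falls(fall$stream, m, clf, tau, step = 1)
  list(fno = m, classifier = clf, tau = tau,
       det_normal = det_normal, det_fall = det_fall,
       annotation = fall$annotation)
})

# FNO and CNN baselines trained at an identical small budget
comparison_experiment <- function() cached("comparison", function() {
  pe <- personalization_experiment()
  ds <- pe$datasets[[1]]
  sp <- pe$splits[[1]]
  tr <- sp$train[seq(1, length(sp$train), by = 3)]
  cfg <- training_config(epochs = 6L, seed = 61)
  fno <- train_model(fno_init(desk_fno_config(), seed = 62), ds, tr,
                     integer(0), cfg)$model
  cnn <- train_model(cnn_init(cnn_config(channels = 8L), M = ds$M,
                              seed = 63), ds, tr, integer(0), cfg)$model
  mse_fno <- evaluate_mse(fno, ds, sp$test)
  mse_cnn <- evaluate_mse(cnn, ds, sp$test)
  list(fno = fno, cnn = cnn, mse_fno = mse_fno, mse_cnn = mse_cnn)
})
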