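test_that("energy score matches the log-sum-exp closed forms", {
  expect_equal(energy_score(c(0, 0)), -log(2))
  expect_equal(energy_score(5), -5)
  expect_equal(energy_score(c(2, 1)), -(2 + log1p(exp(-1))))
  expect_equal(energy_score(c(2, 1)), -2.3133, tolerance = 1e-4)
  # overflow-safe for extreme logits
  expect_equal(energy_score(c(1000, 999)), -(1000 + log1p(exp(-1))))
  # shifting all logits by c shifts the energy by -c
  l <- rnorm(4)
  expect_equal(energy_score(l + 3), energy_score(l) - 3)
  # matrix form scores rows
  m <- rbind(c(0, 0), c(2, 1))
  expect_equal(energy_score(m), c(-log(2), energy_score(c(2, 1))))
  expect_error(energy_score(numeric(0)), "empty")
  expect_error(energy_score(c(1, NA)), "non-finite")
})

test_that("threshold calibration uses the linear-interpolation quantile", {
  expect_equal(calibrate_threshold(rep(4.2, 10)), 4.2)
  expect_equal(calibrate_threshold(1:100, 0.95), 95.05)
  expect_error(calibrate_threshold(numeric(0)), "no training energies")
  expect_error(calibrate_threshold(1:10, 1.2), "quantile")
})

test_that("classifier produces two logits and learns separable classes", {
  clf <- classifier_init(50, hidden = 8, seed = 1)
  X <- matrix(rnorm(10 * 50), 10, 50)
  lg <- classifier_logits(clf, X)
  expect_equal(dim(lg), c(10, 2))
  # a zeroed classifier yields uniform logits: energy = -log 2 everywhere
  clf0 <- clf
  for (nm in names(clf0$params)) clf0$params[[nm]][] <- 0
  expect_all_close(energy_score(classifier_logits(clf0, X)),
                   rep(-log(2), 10), 1e-12)
  # clearly separated gaussian classes are learned to high accuracy
  set.seed(2)
  n <- 120
  Xa <- matrix(rnorm(n * 20, mean = 0), n, 20)
  Xb <- matrix(rnorm(n * 20, mean = 1.5), n, 20)
  clf2 <- train_activity_classifier(rbind(Xa, Xb),
                                    rep(c("walking", "running"), each = n),
                                    hidden = 8,
                                    training_config(epochs = 20, seed = 5))
  expect_gt(attr(clf2, "training_accuracy"), 0.95)
  expect_error(train_activity_classifier(Xa, rep("walking", n)),
               "at least two")
})

test_that("verdicts follow the threshold and are monotone in it", {
  fe <- fall_experiment()
  det <- fe$det_fall
  expect_identical(det$decision == "potential_fall",
                   det$energy > fe$tau)
  # raising tau never creates new alerts
  for (dt in c(0.2, 1, 5))
    expect_true(all(which(det$energy > fe$tau + dt) %in%
                      which(det$energy > fe$tau)))
})

test_that("energy AUC is the Mann-Whitney rank statistic", {
  e <- c(1, 2, 3, 10, 11)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(energy_auc(e, lab), 1)
  expect_equal(energy_auc(-e, lab), 0)
  set.seed(4)
  en <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
  w <- stats::wilcox.test(en[lb], en[!lb])$statistic
  expect_equal(energy_auc(en, lb), unname(w) / (20 * 20))
})
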