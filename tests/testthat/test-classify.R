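# build a labelled observation frame directly (bypassing signals)
toy_obs <- function(n_per_class = 10, sep = 4, sd = 0.5, seed = 1,
                    levels = c("nonseizure", "seizure")) {
  set.seed(seed)
  data.frame(
    subject = sprintf("s%02d", seq_len(2 * n_per_class)),
    class = factor(rep(levels, each = n_per_class), levels = levels),
    value = c(rnorm(n_per_class, 0, sd), rnorm(n_per_class, sep, sd)))
}

test_that("observations are per-subject medians per scheme", {
  tab <- toy_feature_table(n_subj = 4, effect = 0.5, seed = 3)
  # inject a known median for one subject's seizure epochs
  sel <- tab$subject == "s01" & tab$channel == "C4-P4" &
    tab$period == "seizure" & tab$feature == "envelope"
  tab$value[sel] <- rep(c(1, 2, 9), length.out = sum(sel))
  obs <- make_observations(tab, "envelope", scheme = 1)
  expect_equal(obs$value[obs$subject == "s01" & obs$class == "seizure"], 2)

  # scheme 3 never uses nonseizure epochs: removing them changes nothing
  obs3a <- make_observations(tab, "envelope", scheme = 3)
  obs3b <- make_observations(tab[tab$period != "nonseizure", ],
                             "envelope", scheme = 3)
  expect_equal(obs3a, obs3b)
  expect_setequal(levels(obs3a$class), c("S1", "S3"))

  # empty class errors
  expect_error(make_observations(tab[tab$period == "seizure", ],
                                 "envelope", scheme = 1), "empty")
})

test_that("a separable feature gives perfect metrics for all classifiers", {
  obs <- toy_obs(n_per_class = 10, sep = 8, sd = 0.3, seed = 11)
  rep <- evaluate_classifiers(obs, c("svm", "knn", "lr", "nb"), seed = 5)
  for (r in rep$results) {
    expect_equal(r$auc, 1.0)
    expect_equal(r$accuracy, 1.0)
    expect_equal(r$sensitivity, 1.0)
    expect_equal(r$specificity, 1.0)
  }
})

test_that("AUC equals the trapezoidal area of its own ROC curve", {
  obs <- toy_obs(n_per_class = 12, sep = 1.2, sd = 1, seed = 13)
  rep <- evaluate_classifiers(obs, c("lr", "nb"), seed = 7)
  for (r in rep$results) {
    roc <- r$roc
    o <- order(roc$fpr, roc$tpr)
    auc_trap <- sum(diff(roc$fpr[o]) *
                      (head(roc$tpr[o], -1) + tail(roc$tpr[o], -1)) / 2)
    expect_equal(r$auc, auc_trap, tolerance = 1e-9)
    expect_true(all(diff(roc$tpr[o]) >= -1e-12))
  }
})

test_that("AUC is invariant to monotone transforms, flips with labels", {
  obs <- toy_obs(n_per_class = 12, sep = 1.2, sd = 1.5, seed = 17)
  auc_of <- function(o) evaluate_classifiers(o, "lr",
                                             seed = 3)$results$lr$auc
  a1 <- auc_of(obs)
  mono <- obs; mono$value <- exp(mono$value / 2)     # strictly increasing
  expect_equal(auc_of(mono), a1, tolerance = 1e-9)

  # fixed-orientation ROC: relabelling the truth mirrors the AUC
  set.seed(18)
  score <- rnorm(24)
  truth <- obs$class
  a <- neowave:::.roc_auc(truth, score, levels(truth))$auc
  flipped <- factor(ifelse(truth == levels(truth)[1], levels(truth)[2],
                           levels(truth)[1]), levels = levels(truth))
  b <- neowave:::.roc_auc(flipped, score, levels(truth))$auc
  expect_equal(b, 1 - a, tolerance = 1e-9)
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(19)
  aucs <- replicate(60, {
    obs <- toy_obs(n_per_class = 10, sep = 0, sd = 1,
                   seed = sample.int(1e6, 1))
    evaluate_classifiers(obs, "lr", seed = sample.int(1e6, 1))$results$lr$auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("calibration bins predicted against observed rates", {
  obs <- toy_obs(n_per_class = 20, sep = 2, sd = 1, seed = 23)
  rep <- evaluate_classifiers(obs, "lr", seed = 9, train_frac = 0.6,
                              calibration_bins = 3)
  cal <- rep$results$lr$calibration
  expect_true(all(cal$predicted >= 0 & cal$predicted <= 1, na.rm = TRUE))
  expect_true(all(cal$observed >= 0 & cal$observed <= 1, na.rm = TRUE))
  expect_equal(sum(cal$n), rep$n_test)
})

test_that("scatter clusters separate seizure from nonseizure centroids", {
  tabs <- lapply(1:8, function(i) {
    out <- generate_recording(synth_config(n_channels = 3, duration = 60,
      seizure_intervals = list(c(15, 45)),
      channel_labels = c("C4-P4", "Cz-Pz", "C3-P3"), seed = 700 + i))
    feature_table(preprocess(out$recording), out$annotations,
                  sprintf("s%d", i), fusion_levels = 3)
  })
  sc <- scatter_clusters(do.call(rbind, tabs), scheme = 1)
  expect_length(sc$contacts, 2)
  pts <- sc$points
  cen <- function(cls) colMeans(pts[pts$class == cls,
                                    c("envelope", "sharpness", "don")])
  expect_true(all(cen("seizure") > cen("nonseizure")))
})
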