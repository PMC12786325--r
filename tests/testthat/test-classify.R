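make_specs <- function(classes, n_rec = 2, n_electrodes = 4, duration_s = 30,
                       seed0 = 0) {
  specs <- list()
  for (cls in classes) {
    for (i in seq_len(n_rec)) {
      sp <- tiny_spec(n_electrodes = n_electrodes, duration_s = duration_s,
                      n_active = n_electrodes %/% 2,
                      seed = derive_seed(seed0, paste0(cls, i)))
      rec <- generate_recording(sp, condition_profile(cls))
      specs <- c(specs, list(compute_power_density(rec)))
    }
  }
  specs
}

test_that("feature construction has deterministic shape and ordering", {
  fs <- 1250
  set.seed(1)
  rec <- new_recording(matrix(rnorm(20 * fs * 120), 20), fs = fs,
                       condition = "CTL")
  ps <- compute_power_density(rec)
  fm <- build_features(ps, selected_electrodes = 0:19, bin_hz = 1)
  expect_equal(dim(fm$x), c(12, 20 * 300)) # 12 fragments x 6000 features
  expect_equal(colnames(fm$x)[1:2], c("e0_f0", "e0_f1"))
  expect_equal(colnames(fm$x)[301], "e1_f0")
  expect_false(anyNA(fm$x))
  expect_equal(as.character(fm$labels), rep("CTL", 12))

  # bin_hz = 0.1 keeps the raw 0.1 Hz bins
  fm_raw <- build_features(ps, selected_electrodes = 0:1, bin_hz = 0.1)
  expect_equal(ncol(fm_raw$x), 2 * 2999)
  expect_equal(unname(fm_raw$x[1, 1:2999]), unname(ps$power[[1]][1, ]))

  # permuting the electrode storage order leaves the matrix unchanged
  perm <- c(5:20, 1:4)
  rec_p <- new_recording(rec$data[perm, ], fs = fs,
                         electrode_ids = (0:19)[perm], condition = "CTL")
  fm_p <- build_features(compute_power_density(rec_p),
                         selected_electrodes = 0:19, bin_hz = 1)
  expect_equal(fm_p$x, fm$x)

  # mean pooling preserves total power
  counts <- as.vector(table(pmin(floor(ps$freqs - 1e-9), 299)))
  expect_equal(as.vector(fm$x[, 1:300] %*% counts),
               unname(rowSums(ps$power[[1]])))

  expect_error(build_features(ps, selected_electrodes = 99), "electrode")
})

test_that("classifier separates separable toys and not permuted nulls", {
  # perfectly separable one-feature two-class toy
  set.seed(3)
  x <- cbind(c(runif(40, 0, 1), runif(40, 2, 3)))
  fm <- toy_features(x, rep(c("A", "B"), each = 40))
  fit <- train_condition_classifier(fm, seed = 5, ntree = 100)
  expect_equal(fit$report$accuracy, 1.0)
  expect_true(all(fit$report$cv_scores == 1))

  # label-permuted noise: accuracy within the binomial 95% CI of 1/k
  set.seed(4)
  xn <- matrix(rnorm(240 * 20), 240)
  fmn <- toy_features(xn, sample(rep(c("A", "B", "C"), each = 80)))
  fitn <- train_condition_classifier(fmn, seed = 6, ntree = 150)
  n_test <- fitn$report$n_test
  expect_lt(abs(fitn$report$accuracy - 1 / 3),
            1.96 * sqrt((1 / 3) * (2 / 3) / n_test))

  # report invariants
  rep3 <- fitn$report
  expect_equal(unname(rowSums(rep3$class_repartition)), rep(1, 3))
  expect_gte(rep3$cup, 1 / 3)
  expect_lte(rep3$cup, 1)
  expect_equal(rep3$chi2$A$dof, 2)
  expect_length(rep3$cv_scores, 5)

  expect_error(train_condition_classifier(
    toy_features(x, rep("A", 80))), "two classes")
  expect_error(train_condition_classifier(
    toy_features(x[1:42, , drop = FALSE],
                 c(rep("A", 40), "B", "B"))), "fewer fragments")
})

test_that("training is reproducible and honors the split protocol", {
  specs <- make_specs(c("CTL", "EV"), n_rec = 3)
  fm <- build_features(specs, selected_electrodes = 0:3)
  f1 <- train_condition_classifier(fm, seed = 11, ntree = 100, n_folds = 3)
  f2 <- train_condition_classifier(fm, seed = 11, ntree = 100, n_folds = 3)
  expect_identical(f1$train_idx, f2$train_idx)
  expect_equal(f1$report$accuracy, f2$report$accuracy)
  expect_equal(f1$report$cv_scores, f2$report$cv_scores)
  expect_equal(f1$report$class_repartition, f2$report$class_repartition)
  expect_equal(f1$report$cup, f2$report$cup)

  # stratified 70/30: class balance holds on both sides
  tab_all <- table(fm$labels)
  tab_tr <- table(fm$labels[f1$train_idx])
  expect_equal(as.vector(tab_tr), as.vector(round(0.7 * tab_all)))

  # group split keeps each recording on one side
  fg <- train_condition_classifier(fm, seed = 11, ntree = 50, n_folds = 2,
                                   group_by_recording = TRUE)
  sides <- vapply(split(seq_along(fm$groups) %in% fg$train_idx, fm$groups),
                  function(s) length(unique(s)), 0L)
  expect_true(all(sides == 1))
})

test_that("repartition prediction recovers the generating class", {
  specs <- make_specs(c("CTL", "EV", "GW"), n_rec = 3)
  fm <- build_features(specs, selected_electrodes = 0:3)
  fit <- train_condition_classifier(fm, seed = 21, ntree = 200)

  # fragments from a trained class's own generator map back to it
  sp <- tiny_spec(n_electrodes = 4, duration_s = 30, n_active = 2,
                  seed = 999)
  rec <- generate_recording(sp, condition_profile("EV"))
  fm_ev <- build_features(compute_power_density(rec), 0:3)
  rep_ev <- predict_repartition(fit, fm_ev)
  expect_equal(names(which.max(rep_ev$repartition)), "EV")
  expect_equal(sum(rep_ev$repartition), 1)
  expect_gte(rep_ev$cup, 1 / 3)
  expect_equal(rep_ev$chi2$dof, 2)

  # feature mismatch is rejected
  bad <- fm_ev
  colnames(bad$x) <- rev(colnames(bad$x))
  expect_error(predict_repartition(fit, bad), "feature columns")
})

test_that("confidence upon prediction grows with class separation", {
  run_cup <- function(mid_gain) {
    specs <- list()
    for (cls in c("A", "B")) {
      for (i in 1:3) {
        gains <- if (cls == "B") {
          data.frame(lo = 13, hi = 30, gain = mid_gain)
        } else empty_gains
        sp <- tiny_spec(n_electrodes = 2, duration_s = 60, n_active = 1,
                        seed = derive_seed(77, paste0(cls, i, mid_gain)))
        rec <- generate_recording(
          sp, condition_profile("CTL", band_gains = gains))
        rec$condition <- cls
        ps <- compute_power_density(rec)
        ps$condition <- cls
        specs <- c(specs, list(ps))
      }
    }
    fm <- build_features(specs, selected_electrodes = 0:1)
    train_condition_classifier(fm, seed = 31, ntree = 150)$report$cup
  }
  empty_gains <- data.frame(lo = numeric(0), hi = numeric(0),
                            gain = numeric(0))
  cups <- vapply(c(1.0, 1.3, 2.0), run_cup, 0)
  expect_true(all(diff(cups) > 0))
})

test_that("chi-square against random assignment matches hand computation", {
  # exact null: equal counts
  null3 <- chi_square_vs_random(c(100, 100, 100))
  expect_equal(null3$statistic, 0)
  expect_equal(null3$p_value, 1)
  expect_equal(null3$dof, 2)

  # hand-computed: (30^2 + 0 + 30^2) / 60 = 30
  ct <- chi_square_vs_random(c(90, 60, 30))
  expect_equal(ct$statistic, 30)
  expect_equal(ct$dof, 2)
  expect_equal(ct$p_value, pchisq(30, 2, lower.tail = FALSE))

  # the null expectation generalizes with the number of classes
  expect_equal(chi_square_vs_random(c(10, 20))$expected_percent, 50)
  expect_equal(chi_square_vs_random(c(5, 5, 5, 5))$expected_percent, 25)

  expect_warning(chi_square_vs_random(c(1, 0, 1)), "unreliable")
  expect_error(chi_square_vs_random(c(0, 0)), "positive sum")
})
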