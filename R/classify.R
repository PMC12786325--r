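#' Build a fragment-level feature matrix from power spectrograms
#'
#' Each (recording, fragment) pair becomes one row; the columns are the
#' per-selected-electrode power densities, mean-pooled into `bin_hz`-wide
#' frequency bins over the spectrogram grid (0.2-300 Hz by default). Column
#' order is deterministic: electrode-major in the order of
#' `selected_electrodes`, frequency-minor. At `bin_hz = 0.1` the columns are
#' the raw 0.1-Hz bins.
#'
#' @param specs a `power_spectrogram` or a list of them (one per recording),
#'   all sharing a frequency grid; each carries its condition label.
#' @param selected_electrodes electrode ids to use, typically from
#'   [select_active_electrodes()].
#' @param bin_hz pooled bin width in Hz.
#' @return an object of class `lfp_features`: a list with the numeric matrix
#'   `x` (rows = fragments), factor `labels`, integer `groups` (source
#'   recording), and the column metadata.
#' @export
build_features <- function(specs, selected_electrodes, bin_hz = 1) {
  if (inherits(specs, "power_spectrogram")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "power_spectrogram")))
  check_finite_scalar(bin_hz, "bin_hz", min = 0, strict_min = TRUE)
  freqs <- specs[[1]]$freqs
  for (s in specs) {
    if (!isTRUE(all.equal(s$freqs, freqs))) {
      stop_bad_arg("specs", "spectrograms have inconsistent frequency grids")
    }
    if (!all(selected_electrodes %in% s$electrode_ids)) {
      stop_bad_arg("selected_electrodes",
                   "electrode missing from a spectrogram")
    }
  }
  bin_of <- pmin(floor(freqs / bin_hz - 1e-9), ceiling(max(freqs) / bin_hz) - 1)
  bins <- sort(unique(bin_of))
  bin_lo <- bins * bin_hz
  col_names <- as.vector(t(outer(selected_electrodes, bin_lo,
                                 function(e, f) sprintf("e%d_f%g", e, f))))
  pool <- function(mat) { # fragments x freqs -> fragments x bins, mean pool
    t(rowsum(t(mat), group = bin_of) / as.vector(table(bin_of)))
  }
  rows <- list()
  labels <- character(0)
  groups <- integer(0)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    blocks <- lapply(as.character(selected_electrodes),
                     function(e) pool(s$power[[e]]))
    rows[[i]] <- do.call(cbind, blocks)
    n_frag <- nrow(rows[[i]])
    lab <- if (is.null(s$condition)) NA_character_ else s$condition
    labels <- c(labels, rep(lab, n_frag))
    groups <- c(groups, rep(i, n_frag))
  }
  x <- do.call(rbind, rows)
  colnames(x) <- col_names
  rownames(x) <- sprintf("rec%d_frag%d", groups,
                         unlist(lapply(rows, function(r) seq_len(nrow(r)))))
  if (anyNA(x)) stop_bad_arg("specs", "features contain missing values")
  structure(list(x = x,
                 labels = factor(labels),
                 groups = groups,
                 electrodes = as.integer(selected_electrodes),
                 bin_hz = bin_hz, bin_lo = bin_lo),
            class = "lfp_features")
}

#' @export
print.lfp_features <- function(x, ...) {
  cat(sprintf(
    "LFP feature matrix: %d fragments x %d features (%d electrodes x %d bins)\n",
    nrow(x$x), ncol(x$x), length(x$electrodes), length(x$bin_lo)))
  if (!all(is.na(x$labels))) print(table(condition = x$labels))
  invisible(x)
}

# Stratified index split; returns indices of the training portion.
stratified_split <- function(labels, train_frac) {
  train <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_tr <- round(train_frac * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Stratified fold assignment for cross-validation.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Train the random-forest condition classifier
#'
#' Fits the LFP condition classifier: a stratified, seeded split of the
#' fragments into train (70%) and held-out test (30%) sets, a five-fold
#' cross-validation on the training portion as an overfitting check, and a
#' random forest (500 trees by default) fitted on the training set. The
#' returned report carries the held-out accuracy, the fold accuracies, the
#' per-condition class repartition on the held-out set, the confidence upon
#' prediction (CUP; the mean predicted probability of the winning class) and
#' a chi-square test of each condition's repartition against uniform random
#' assignment.
#'
#' @param fm an [build_features()] feature matrix with at least two classes
#'   and `n_folds` fragments per class.
#' @param train_frac training fraction of the stratified split.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed governing split, folds and forest.
#' @param ntree number of trees.
#' @param mtry features sampled per split; default `sqrt(p)`.
#' @param group_by_recording if `TRUE`, the split is performed over source
#'   recordings rather than fragments, preventing fragments of one recording
#'   from straddling the split (the stricter protocol; default `FALSE`
#'   follows the fragment-level protocol).
#' @return an object of class `condition_rfc` with components `forest`,
#'   `report` (class `classification_report`), `train_idx`, `test_idx`,
#'   `levels`, `seed` and the hyperparameters.
#' @export
train_condition_classifier <- function(fm, train_frac = 0.7, n_folds = 5,
                                       seed = 1L, ntree = 500, mtry = NULL,
                                       group_by_recording = FALSE) {
  stopifnot(inherits(fm, "lfp_features"))
  labels <- droplevels(fm$labels)
  if (anyNA(labels)) stop_bad_arg("fm", "has unlabeled fragments")
  if (nlevels(labels) < 2L) stop_bad_arg("fm", "needs at least two classes")
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stop_bad_arg("fm", sprintf(
      "class '%s' has fewer fragments (%d) than n_folds (%d)",
      names(tab)[which.min(tab)], min(tab), n_folds))
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(fm$x))))

  with_seed(derive_seed(seed, "split"), {
    if (group_by_recording) {
      grps <- sort(unique(fm$groups))
      grp_lab <- factor(vapply(grps, function(g) {
        as.character(labels[fm$groups == g][1])
      }, ""), levels = levels(labels))
      grp_train <- grps[stratified_split(grp_lab, train_frac)]
      train_idx <- which(fm$groups %in% grp_train)
    } else {
      train_idx <- stratified_split(labels, train_frac)
    }
  })
  test_idx <- setdiff(seq_along(labels), train_idx)

  x_tr <- fm$x[train_idx, , drop = FALSE]
  y_tr <- labels[train_idx]

  cv_scores <- numeric(n_folds)
  with_seed(derive_seed(seed, "cv"), {
    fold <- stratified_folds(y_tr, n_folds)
    for (f in seq_len(n_folds)) {
      fit <- randomForest::randomForest(
        x_tr[fold != f, , drop = FALSE], droplevels(y_tr[fold != f]),
        ntree = ntree, mtry = mtry)
      pred <- predict(fit, x_tr[fold == f, , drop = FALSE])
      cv_scores[f] <- mean(as.character(pred) ==
                             as.character(y_tr[fold == f]))
    }
  })

  forest <- with_seed(derive_seed(seed, "forest"),
                      randomForest::randomForest(x_tr, y_tr, ntree = ntree,
                                                 mtry = mtry))

  x_te <- fm$x[test_idx, , drop = FALSE]
  y_te <- labels[test_idx]
  prob <- predict(forest, x_te, type = "prob")
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = levels(y_te))
  accuracy <- mean(pred == y_te)
  cup <- mean(apply(prob, 1, max))

  repartition <- t(vapply(levels(y_te), function(lv) {
    sel <- y_te == lv
    as.vector(prop.table(table(pred[sel])))
  }, numeric(nlevels(y_te))))
  dimnames(repartition) <- list(tested = levels(y_te),
                                predicted = levels(y_te))
  cup_by_class <- vapply(levels(y_te), function(lv) {
    mean(apply(prob[y_te == lv, , drop = FALSE], 1, max))
  }, 0)
  chi2 <- lapply(levels(y_te), function(lv) {
    chi_square_vs_random(table(pred[y_te == lv]))
  })
  names(chi2) <- levels(y_te)

  report <- structure(
    list(accuracy = accuracy, cv_scores = cv_scores,
         class_repartition = repartition, cup = cup,
         cup_by_class = cup_by_class, chi2 = chi2,
         n_train = length(train_idx), n_test = length(test_idx),
         seed = seed,
         hyperparameters = list(ntree = ntree, mtry = mtry,
                                train_frac = train_frac, n_folds = n_folds,
                                group_by_recording = group_by_recording)),
    class = "classification_report")

  structure(list(forest = forest, report = report,
                 train_idx = train_idx, test_idx = test_idx,
                 levels = levels(y_tr), feature_names = colnames(fm$x),
                 seed = seed),
            class = "condition_rfc")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Held-out accuracy: %.1f%% (n = %d)\n", 100 * x$accuracy,
              x$n_test))
  cat(sprintf("5-fold CV accuracy: %s (mean %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$cv_scores), collapse = ", "),
              100 * mean(x$cv_scores)))
  cat(sprintf("Confidence upon prediction (CUP): %.3f\n", x$cup))
  cat("Class repartition (rows = tested condition):\n")
  print(round(x$class_repartition, 3))
  invisible(x)
}

#' @export
print.condition_rfc <- function(x, ...) {
  cat(sprintf("Random-forest LFP condition classifier (%d classes: %s)\n",
              length(x$levels), paste(x$levels, collapse = ", ")))
  cat(sprintf("  %d features, %d trees, seed %d\n",
              length(x$feature_names),
              x$report$hyperparameters$ntree, x$seed))
  print(x$report)
  invisible(x)
}

#' @export
summary.condition_rfc <- function(object, ...) {
  print(object)
  invisible(object$report)
}

#' @export
predict.condition_rfc <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "lfp_features")) newdata$x else newdata
  if (!identical(colnames(x), object$feature_names)) {
    stop_bad_arg("newdata", "feature columns do not match the training set")
  }
  predict(object$forest, x, type = type)
}

#' Class repartition of a tested condition
#'
#' Classifies held-out fragments (typically of a condition the model was not
#' trained on, e.g. a co-treatment) and reports the fraction assigned to each
#' trained class, the confidence upon prediction, and the chi-square test of
#' the assignment counts against the uniform random-assignment null.
#'
#' @param model a [train_condition_classifier()] fit.
#' @param fm_test an [build_features()] matrix of test fragments.
#' @param tested_condition optional label for the tested condition.
#' @return an object of class `class_repartition`: list with `repartition`
#'   (fractions over trained classes, summing to 1), `counts`, `cup`, `chi2`,
#'   `n` and `condition`.
#' @export
predict_repartition <- function(model, fm_test, tested_condition = NULL) {
  stopifnot(inherits(model, "condition_rfc"))
  prob <- predict(model, fm_test, type = "prob")
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = model$levels)
  counts <- table(pred)
  repartition <- as.vector(prop.table(counts))
  names(repartition) <- model$levels
  if (is.null(tested_condition) && inherits(fm_test, "lfp_features") &&
      nlevels(fm_test$labels) == 1L) {
    tested_condition <- levels(fm_test$labels)
  }
  structure(list(condition = tested_condition, repartition = repartition,
                 counts = as.vector(counts), cup = mean(apply(prob, 1, max)),
                 chi2 = chi_square_vs_random(counts), n = nrow(prob)),
            class = "class_repartition")
}

#' @export
print.class_repartition <- function(x, ...) {
  cat(sprintf("Class repartition%s (n = %d fragments):\n",
              if (is.null(x$condition)) "" else
                paste0(" of condition ", x$condition), x$n))
  print(round(100 * x$repartition, 1))
  cat(sprintf("CUP %.3f; chi-square %.1f (df %d), p = %.3g vs %.1f%% per class\n",
              x$cup, x$chi2$statistic, x$chi2$dof, x$chi2$p_value,
              x$chi2$expected_percent))
  invisible(x)
}

#' Chi-square test against random assignment
#'
#' Goodness-of-fit of classifier assignment counts against the uniform
#' random-assignment null: with `k` trained classes the expectation is
#' `total/k` per class (33.3% per class for three), `k - 1` degrees of
#' freedom, upper-tail p-value.
#'
#' @param counts per-class assignment counts.
#' @return list with `statistic`, `dof`, `p_value` and `expected_percent`
#'   (the null percentage per class).
#' @export
#' @examples
#' chi_square_vs_random(c(90, 60, 30))$statistic # 30
chi_square_vs_random <- function(counts) {
  counts <- as.vector(counts)
  if (length(counts) < 2L || any(counts < 0) || sum(counts) <= 0) {
    stop_bad_arg("counts", "need >= 2 non-negative counts with positive sum")
  }
  k <- length(counts)
  if (sum(counts) / k < 1) {
    warning("expected count per class below 1; chi-square unreliable",
            call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, p = rep(1 / k, k)))
  list(statistic = unname(ct$statistic), dof = unname(ct$parameter),
       p_value = unname(ct$p.value), expected_percent = 100 / k)
}
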