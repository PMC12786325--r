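#' Write / read a recording as CSV
#'
#' The CSV dialect of the recording layout: one column per electrode, header
#' row of electrode ids (`e0`, `e1`, ...), one row per sample. CSV carries no
#' sampling rate, so `read_recording()` requires `fs` from the caller or
#' configuration.
#'
#' @param rec an [new_recording()] object.
#' @param path file path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  df <- as.data.frame(lapply(seq_len(nrow(rec$data)), function(i) {
    formatC(rec$data[i, ], format = "g", digits = 17) # round-trip exact
  }))
  names(df) <- paste0("e", rec$electrode_ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param fs sampling rate in Hz (mandatory for CSV, which does not carry it).
#' @param condition optional condition label to attach.
#' @param t0 recording start time (s).
#' @export
read_recording <- function(path, fs = NULL, condition = NULL, t0 = 0) {
  if (!file.exists(path)) {
    stop(sprintf("recording file not found: %s", path), call. = FALSE)
  }
  if (is.null(fs)) {
    stop("CSV recordings carry no sampling rate; supply `fs`", call. = FALSE)
  }
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || !all(grepl("^e[0-9]+$", names(df)))) {
    stop(sprintf(
      "malformed recording CSV '%s': header must be electrode ids e0, e1, ...",
      path), call. = FALSE)
  }
  mat <- t(as.matrix(df))
  dimnames(mat) <- NULL
  if (anyNA(mat)) {
    stop(sprintf("recording CSV '%s' contains missing samples", path),
         call. = FALSE)
  }
  new_recording(mat, fs = fs,
                electrode_ids = as.integer(sub("^e", "", names(df))),
                condition = condition, t0 = t0)
}

#' Write / read an abundance table as TSV
#'
#' The abundance TSV has a first column `protein_id` and one column per
#' sample; missing values are empty cells. A companion two-column TSV
#' (`sample_id`, `condition`) carries the condition map.
#'
#' @param tab an [abundance_table()].
#' @param path abundance TSV path.
#' @param conditions_path companion condition TSV path; defaults to
#'   `<path>.conditions.tsv`.
#' @return `write_abundance_table()` returns `path` invisibly;
#'   `read_abundance_table()` returns an `abundance_table`.
#' @export
write_abundance_table <- function(tab, path,
                                  conditions_path = paste0(path, ".conditions.tsv")) {
  stopifnot(inherits(tab, "abundance_table"))
  df <- data.frame(protein_id = tab$protein_ids, tab$abundance,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  write.table(data.frame(sample_id = colnames(tab$abundance),
                         condition = as.character(tab$conditions)),
              conditions_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path,
                                 conditions_path = paste0(path, ".conditions.tsv")) {
  for (p in c(path, conditions_path)) {
    if (!file.exists(p)) {
      stop(sprintf("file not found: %s", p), call. = FALSE)
    }
  }
  df <- read.delim(path, check.names = FALSE, na.strings = "")
  if (names(df)[1] != "protein_id") {
    stop(sprintf("malformed abundance TSV '%s': first column must be protein_id",
                 path), call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$protein_id
  cond <- read.delim(conditions_path)
  if (!all(c("sample_id", "condition") %in% names(cond))) {
    stop(sprintf("malformed condition TSV '%s'", conditions_path),
         call. = FALSE)
  }
  abundance_table(mat, conditions = stats::setNames(cond$condition,
                                                    cond$sample_id))
}

#' Write a ranked protein list in RNK format
#'
#' Two-column tab-separated rank file (id, score) consumable by gene-set
#' enrichment tools; the score is the negated condition mean rank so that
#' larger means more abundant.
#'
#' @param ranks a [rank_proteins()] result.
#' @param condition condition name.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranks, condition, path) {
  stopifnot(inherits(ranks, "rank_table"))
  mr <- ranks$cond_mean[, condition]
  ord <- order(mr, ranks$protein_ids)
  write.table(data.frame(id = ranks$protein_ids[ord], score = -mr[ord]),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

pipeline_defaults <- function() {
  list(
    seed = 1L,
    synth = list(classes = c("CTL", "GW", "EV"),
                 n_recordings_per_class = 4L,
                 duration_s = 60, n_electrodes = 24L, n_active = 12L,
                 fs = 2500, noise_sd = 10, one_over_f_exponent = 1),
    mixture = NULL, # e.g. list(profile = "GW_EV", n_recordings = 4L)
    classify = list(n_selected = 20L, bin_hz = 1, train_frac = 0.7,
                    n_folds = 5L, ntree = 500L, group_by_recording = FALSE),
    out_dir = NULL)
}

merge_config <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown %s key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration and merges it over the pipeline defaults.
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file path.
#' @return the resolved configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  merge_config(pipeline_defaults(), yaml::read_yaml(path))
}

# Special-case: the mixture block may omit defaults.
mixture_defaults <- function(user) {
  merge_config(list(profile = "GW_EV", n_recordings = 4L), user,
               path = "config$mixture")
}

#' Run the record-analyze-classify pipeline end to end
#'
#' Chains the synthetic generator, electrode selection, fragment-wise power
#' densities, feature construction and the random-forest condition
#' classifier into one seeded, reproducible run; optionally classifies a
#' composite mixture condition against the trained classes. All randomness
#' derives from the single top-level seed via named per-stage sub-streams
#' ([derive_seed()]), so rerunning the same configuration reproduces the
#' report bit for bit. Recordings are processed one at a time (generated,
#' reduced to spectrograms, discarded), keeping memory flat in the number of
#' recordings.
#'
#' @param config a configuration list (merged over [pipeline_defaults()]) or
#'   the path of a YAML file; see `pipeline_defaults()` for the block
#'   structure. Unknown keys are rejected.
#' @return a report bundle: list with the `classification_report`, the
#'   fitted `condition_rfc` model, `selected_electrodes`, the mixture
#'   `class_repartition` (if requested) and its generator truth proportions,
#'   and the resolved `config`. If `config$out_dir` is set, the report
#'   (JSON), the repartition table (CSV) and the resolved configuration
#'   (YAML) are written there.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(list(seed = 7, synth = list(
#'   n_recordings_per_class = 2L, duration_s = 20, n_electrodes = 6L,
#'   n_active = 3L, fs = 2500), classify = list(n_selected = 4L,
#'   ntree = 100L)))
#' bundle$report$accuracy
#' }
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- merge_config(pipeline_defaults(), config)
  if (!is.null(config$mixture)) {
    config$mixture <- mixture_defaults(config$mixture)
  }
  seed <- as.integer(config$seed)
  sy <- config$synth
  cl <- config$classify

  gen_spectrograms <- function(profile, n_rec, tag) {
    lapply(seq_len(n_rec), function(i) {
      spec <- recording_spec(
        n_electrodes = sy$n_electrodes, fs = sy$fs,
        duration_s = sy$duration_s, n_active = sy$n_active,
        noise_sd = sy$noise_sd,
        one_over_f_exponent = sy$one_over_f_exponent,
        seed = derive_seed(seed, sprintf("%s_%d", tag, i)))
      rec <- if (is.null(profile$mixture_weights)) {
        generate_recording(spec, profile)
      } else {
        generate_mixture_recording(
          spec, lapply(names(profile$mixture_weights), condition_profile),
          weights = unname(profile$mixture_weights))
      }
      ps <- compute_power_density(rec)
      attr(ps, "electrode_sd") <- apply(rec$data, 1, sd)
      attr(ps, "fragment_labels") <- attr(rec, "fragment_labels")
      ps
    })
  }

  specs <- list()
  for (cls in sy$classes) {
    specs <- c(specs, gen_spectrograms(condition_profile(cls),
                                       sy$n_recordings_per_class,
                                       paste0("synth_", cls)))
  }

  # top electrodes by mean full-trace SD across the training recordings
  sds <- rowMeans(vapply(specs, attr, numeric(sy$n_electrodes),
                         "electrode_sd"))
  ids <- specs[[1]]$electrode_ids
  selected <- ids[order(-sds, ids)][seq_len(cl$n_selected)]

  fm <- build_features(specs, selected, bin_hz = cl$bin_hz)
  model <- train_condition_classifier(
    fm, train_frac = cl$train_frac, n_folds = cl$n_folds,
    seed = derive_seed(seed, "classify"), ntree = cl$ntree,
    group_by_recording = cl$group_by_recording)

  mixture <- NULL
  mixture_truth <- NULL
  if (!is.null(config$mixture)) {
    mix_specs <- gen_spectrograms(condition_profile(config$mixture$profile),
                                  config$mixture$n_recordings, "mixture")
    fm_mix <- build_features(mix_specs, selected, bin_hz = cl$bin_hz)
    mixture <- predict_repartition(model, fm_mix,
                                   tested_condition = config$mixture$profile)
    truth <- unlist(lapply(mix_specs, attr, "fragment_labels"))
    mixture_truth <- prop.table(table(truth))
  }

  bundle <- list(report = model$report, model = model,
                 selected_electrodes = selected,
                 mixture = mixture, mixture_truth = mixture_truth,
                 config = config, seed = seed)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    rep <- model$report
    out <- list(
      accuracy = rep$accuracy, cv_scores = rep$cv_scores, cup = rep$cup,
      cup_by_class = as.list(rep$cup_by_class),
      class_repartition = as.data.frame(rep$class_repartition),
      chi2 = rep$chi2, seed = seed, hyperparameters = rep$hyperparameters,
      selected_electrodes = selected)
    if (!is.null(mixture)) {
      out$mixture <- list(condition = mixture$condition,
                          repartition = as.list(mixture$repartition),
                          cup = mixture$cup, chi2 = mixture$chi2,
                          n = mixture$n)
    }
    jsonlite::write_json(out, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(as.data.frame(rep$class_repartition),
              file.path(config$out_dir, "class_repartition.csv"))
    yaml::write_yaml(config, file.path(config$out_dir,
                                       "resolved_config.yaml"))
  }
  bundle
}
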