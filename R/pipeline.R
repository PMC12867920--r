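# Orchestration: simulate -> preprocess -> label -> (optional WOA) -> train
# -> evaluate, from one schema-validated configuration, with manifests and
# deterministic reruns.

run_config_schema <- function() {
  list(
    seed = NA, out_dir = NA,
    synth = list(n_sequences = NA, frames_per_seq = NA, fps = NA,
                 genre_count = NA, noise_sd = NA, n_informative = NA),
    preprocess = list(target_frames = NA, smooth_window = NA,
                      smooth_sigma = NA,
                      augment = list(temporal_scale_pct = NA,
                                     spatial_noise_pct = NA,
                                     angle_jitter_deg = NA)),
    label = list(standardize = NA),
    tcn = list(kernel_size = NA, dilations = NA, channels = NA, out_dim = NA),
    enc = list(layers = NA, heads = NA, model_dim = NA, ffn_dim = NA,
               dropout = NA, positional = NA),
    woa = list(enabled = NA, population = NA, max_iter = NA, n_select = NA,
               lambda = NA, explore_prob = NA, alpha = NA),
    train = list(lr = NA, weight_decay = NA, batch = NA, epochs = NA,
                 patience = NA, high_threshold = NA, high_weight = NA),
    eval = list(tau = NA)
  )
}

#' Default pipeline run configuration
#'
#' A complete configuration at reference scale (full model widths). Override
#' any subset of keys by passing a partial list to [run_pipeline()]; unknown
#' keys are rejected by name.
#'
#' @return A nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L, out_dir = NULL,
    synth = list(n_sequences = 100L, frames_per_seq = 100L, fps = 25,
                 genre_count = 10L, noise_sd = 0.002, n_informative = 40L),
    preprocess = list(target_frames = 100L, smooth_window = 5L,
                      smooth_sigma = 0.8, augment = NULL),
    label = list(standardize = FALSE),
    tcn = list(kernel_size = 2L, dilations = c(1L, 2L, 4L, 8L, 16L),
               channels = 128L, out_dim = 256L),
    enc = list(layers = 3L, heads = 8L, model_dim = 512L, ffn_dim = 2048L,
               dropout = 0.1, positional = TRUE),
    woa = list(enabled = FALSE, population = 30L, max_iter = 50L,
               n_select = 300L, lambda = 10, explore_prob = 0.1, alpha = 0.7),
    train = list(lr = 1e-4, weight_decay = 1e-4, batch = 32L, epochs = 100L,
                 patience = 5L, high_threshold = 70, high_weight = 1.5),
    eval = list(tau = 0.1)
  )
}

#' Validate a run configuration
#'
#' Recursively checks the configuration against the known schema and errors
#' on the first unknown key, naming it.
#'
#' @param config A nested configuration list.
#' @return The merged (defaults + overrides) configuration, invisibly
#'   validated.
#' @export
validate_run_config <- function(config) {
  check <- function(cfg, schema, path) {
    for (key in names(cfg)) {
      if (!(key %in% names(schema))) {
        stop(sprintf("unknown configuration key: %s%s",
                     if (nzchar(path)) paste0(path, ".") else "", key),
             call. = FALSE)
      }
      if (is.list(schema[[key]]) && is.list(cfg[[key]])) {
        check(cfg[[key]], schema[[key]],
              paste0(if (nzchar(path)) paste0(path, ".") else "", key))
      }
    }
  }
  check(config, run_config_schema(), "")
  merge_config(default_run_config(), config)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return The validated, default-merged configuration list.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("configuration must be YAML or JSON", call. = FALSE)
  }
  validate_run_config(cfg)
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> label -> (optional feature search) ->
#' train -> evaluate from one configuration. All stage seeds derive from the
#' global seed, so rerunning an identical configuration reproduces identical
#' reports. When `out_dir` is set, the run directory receives the dataset,
#' label table, fitted history, evaluation report and a manifest stamped
#' with the configuration hash and seed.
#'
#' @param config Partial or complete configuration list (see
#'   [default_run_config()]) or a path to a YAML/JSON file.
#' @param out_dir Optional output directory (overrides `config$out_dir`).
#' @param verbose Print stage progress.
#' @return A list of class `cogload_run`: `report` (test-split
#'   [evaluate_scores()]), `fit`, `dataset`, `labels`, `selected_features`,
#'   `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  cfg <- validate_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  seeds <- derive_seeds(cfg$seed, 4L)
  say <- function(...) if (verbose) message(sprintf(...))

  # -- simulate
  say("simulate: %d sequences", cfg$synth$n_sequences)
  gcfg <- gen_config(n_sequences = cfg$synth$n_sequences,
                     frames_per_seq = cfg$synth$frames_per_seq,
                     fps = cfg$synth$fps, genre_count = cfg$synth$genre_count,
                     noise_sd = cfg$synth$noise_sd,
                     n_informative = cfg$synth$n_informative,
                     seed = seeds[1])
  dataset <- generate_dataset(gcfg)

  # -- label (objective labels from the raw coordinates)
  labels <- build_labels(dataset$sequences, standardize = cfg$label$standardize)
  y <- labels$y

  # -- preprocess: smooth in metres (reconstruction view), then normalize
  # with training-split stats (model view)
  say("preprocess: smoothing + normalization")
  pp <- cfg$preprocess
  smoothed <- lapply(dataset$sequences, function(s) {
    out <- standardize_length(s, pp$target_frames)[[1]]
    gaussian_smooth(out, pp$smooth_window, pp$smooth_sigma)
  })
  if (!is.null(pp$augment)) {
    aug_seeds <- derive_seeds(seeds[2], length(smoothed))
    smoothed <- lapply(seq_along(smoothed), function(i)
      augment(smoothed[[i]],
              augment_spec(temporal_scale_pct = pp$augment$temporal_scale_pct %||% 10,
                           spatial_noise_pct = pp$augment$spatial_noise_pct %||% 5,
                           angle_jitter_deg = pp$augment$angle_jitter_deg %||% 3,
                           seed = aug_seeds[i])))
  }
  stats <- pose_stats(smoothed[dataset$splits$train])
  topo <- default_skeleton()
  inputs <- lapply(smoothed, function(s)
    branch_features(minmax_normalize(s, stats), topo))

  # -- optional dual feature search on the global feature slots
  selected <- NULL
  if (isTRUE(cfg$woa$enabled)) {
    say("optimize: WOA feature search (%d x %d)",
        cfg$woa$population, cfg$woa$max_iter)
    wres <- woa_select_features(
      dataset$features[dataset$splits$train, , drop = FALSE],
      y[dataset$splits$train],
      woa_config(population = cfg$woa$population, max_iter = cfg$woa$max_iter,
                 explore_prob = cfg$woa$explore_prob, alpha = cfg$woa$alpha,
                 seed = seeds[3]),
      n_select = cfg$woa$n_select, lambda = cfg$woa$lambda)
    selected <- wres$best$decoded$features
  }

  # -- train
  say("train: up to %d epochs", cfg$train$epochs)
  tcn_c <- tcn_config(kernel_size = cfg$tcn$kernel_size,
                      dilations = cfg$tcn$dilations,
                      channels = cfg$tcn$channels, out_dim = cfg$tcn$out_dim)
  enc_c <- encoder_config(n_layers = cfg$enc$layers, heads = cfg$enc$heads,
                          model_dim = cfg$enc$model_dim,
                          ffn_dim = cfg$enc$ffn_dim,
                          input_dim = cfg$tcn$out_dim,
                          dropout = cfg$enc$dropout,
                          positional = cfg$enc$positional)
  feature_idx <- if (!is.null(selected) && cfg$enc$model_dim == 512L) selected else NULL
  model <- cogload_model(tcn_c, enc_c, feature_idx = feature_idx,
                         seed = seeds[4])
  tr_c <- train_config(lr = cfg$train$lr, weight_decay = cfg$train$weight_decay,
                       batch = cfg$train$batch, epochs = cfg$train$epochs,
                       patience = cfg$train$patience,
                       high_threshold = cfg$train$high_threshold,
                       high_weight = cfg$train$high_weight, seed = seeds[4])
  fit <- train_model(model, inputs, y, dataset$splits$train,
                     dataset$splits$val, tr_c, verbose = verbose)

  # -- evaluate on the test split
  say("evaluate: test split")
  test <- dataset$splits$test
  pred <- vapply(test, function(i)
    model_fwd(fit$model, inputs[[i]], training = FALSE)$score, numeric(1))
  frc_cols <- selected %||% seq_len(min(300L, ncol(dataset$features)))
  report <- evaluate_scores(
    pred, y[test],
    pred_poses = lapply(smoothed[test], as_coords),
    gt_poses = lapply(dataset$sequences[test], as_coords),
    features = dataset$features[, frc_cols, drop = FALSE],
    tau = cfg$eval$tau)

  run <- structure(list(report = report, fit = fit, dataset = dataset,
                        labels = labels, selected_features = selected,
                        config = cfg),
                   class = "cogload_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Persist a run directory: dataset, labels, history, report, manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(run$dataset, file.path(out_dir, "dataset"))
  utils::write.csv(run$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(run$fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  write_report(run$report, file.path(out_dir, "report"))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(run$config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = run$config$seed,
    selected_features = run$selected_features,
    best_epoch = run$fit$best_epoch,
    artifacts = c("dataset", "labels.csv", "history.csv", "report.json",
                  "report.csv", "config.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cogload_run <- function(x, ...) {
  cat(sprintf("<cogload_run> %d sequences | best epoch %d\n",
              length(x$dataset$sequences), x$fit$best_epoch))
  print(x$report)
  invisible(x)
}
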