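# Plain-text interchange: the flat per-frame CSV dialect (frame, j00_x ...
# j24_z), JSON manifests and sidecars, label tables and reports.

pose_csv_header <- function() {
  axes <- c("x", "y", "z")
  cols <- as.vector(t(outer(sprintf("j%02d", 0:24), axes, paste, sep = "_")))
  c("frame", cols)
}

#' Write a pose sequence as flat CSV
#'
#' One row per frame with columns `frame, j00_x ... j24_z` (0-based frame
#' index, metres).
#'
#' @param seq A [pose_sequence()].
#' @param path Output file path.
#' @export
write_pose_csv <- function(seq, path) {
  flat <- flatten_coords(as_coords(seq))
  df <- data.frame(frame = seq_len(nrow(flat)) - 1L, flat)
  names(df) <- pose_csv_header()
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose sequence from flat CSV
#'
#' @param path A CSV written by [write_pose_csv()].
#' @param ... Metadata fields passed on to [pose_sequence()] (fps, genre,
#'   difficulty, lfhf, delta_alpha, beat_frames).
#' @return A [pose_sequence()].
#' @export
read_pose_csv <- function(path, ...) {
  df <- read.csv(path)
  stop_if(!identical(names(df), pose_csv_header()),
          "unexpected pose CSV columns")
  pose_sequence(unflatten_coords(as.matrix(df[, -1])), ...)
}

#' Write a dataset to a directory
#'
#' One CSV per sequence plus a JSON manifest carrying the per-sequence
#' metadata, the label table, the splits, the informative-slot ground truth
#' and the generator configuration.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$sequences))
  for (i in seq_along(dataset$sequences)) {
    files[i] <- sprintf("seq_%04d.csv", i)
    write_pose_csv(dataset$sequences[[i]], file.path(dir, files[i]))
  }
  meta <- lapply(dataset$sequences, function(s)
    list(fps = s$fps, genre = s$genre, difficulty = s$difficulty,
         lfhf = s$lfhf, delta_alpha = s$delta_alpha,
         beat_frames = s$beat_frames))
  manifest <- list(generator = "cogload synthetic pose generator",
                   version = as.character(utils::packageVersion("cogload")),
                   cfg = unclass(dataset$cfg), files = files,
                   sequences = meta, labels = dataset$labels,
                   informative_ids = dataset$informative_ids,
                   splits = dataset$splits)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(dataset$features),
                   file.path(dir, "feature_slots.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `pose_dataset` (without the generator RNG state; coordinates
#'   round-trip at CSV precision).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- length(manifest$files)
  sequences <- vector("list", n)
  for (i in seq_len(n)) {
    m <- manifest$sequences[i, ]
    sequences[[i]] <- read_pose_csv(
      file.path(dir, manifest$files[i]), fps = m$fps, genre = m$genre,
      difficulty = m$difficulty, lfhf = m$lfhf, delta_alpha = m$delta_alpha,
      beat_frames = unlist(m$beat_frames))
  }
  feats <- as.matrix(utils::read.csv(file.path(dir, "feature_slots.csv")))
  dimnames(feats) <- NULL
  cfg <- do.call(gen_config, manifest$cfg[c("n_sequences", "frames_per_seq",
                                            "fps", "genre_count", "noise_sd",
                                            "n_informative", "seed")])
  structure(list(sequences = sequences, labels = manifest$labels,
                 features = feats,
                 informative_ids = as.integer(manifest$informative_ids),
                 splits = lapply(manifest$splits, as.integer), cfg = cfg),
            class = "pose_dataset")
}

#' Write normalization statistics as a JSON sidecar
#'
#' @param stats A [pose_stats()] result.
#' @param path Output JSON path.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(list(x_min = stats$x_min, x_max = stats$x_max), path,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read normalization statistics from JSON
#'
#' @param path A JSON file written by [write_stats()].
#' @return A `normalization_stats`.
#' @export
read_stats <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(x_min = matrix(as.numeric(s$x_min), 25L, 3L),
                 x_max = matrix(as.numeric(s$x_max), 25L, 3L)),
            class = "normalization_stats")
}

#' Write an evaluation report as JSON and CSV
#'
#' @param report An [evaluate_scores()] report.
#' @param path Output path without extension (writes `path.json` and
#'   `path.csv`).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(unclass(report)), paste0(path, ".csv"),
                   row.names = FALSE)
  invisible(path)
}
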