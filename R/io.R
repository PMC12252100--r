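# Dataset container I/O (float64 binary matrix + JSON sidecar, versioned),
# CSV export, and run configuration loading/merging.

DATASET_FORMAT_VERSION <- 1L

#' Write a beat dataset to disk
#'
#' Features go to `<path>` as raw little-endian float64 (row-major, one beat
#' per row); labels, split tags, provenance and metadata go to
#' `<path>.json`. The round-trip is lossless.
#'
#' @param ds a [beat_dataset()].
#' @param path output path for the binary feature file (sidecar written next
#'   to it).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(ds$features)), con, size = 8L, endian = "little")
  close(con)
  sidecar <- list(
    format = "kanbeat-dataset", version = DATASET_FORMAT_VERSION,
    n = nrow(ds$features), segment_len = ncol(ds$features), fs = ds$fs,
    labels = as.character(ds$labels), split = as.character(ds$split),
    record_id = ds$record_id, r_index = ds$r_index, meta = ds$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a beat dataset written by [write_dataset()]
#' @param path path of the binary feature file.
#' @return a [beat_dataset()].
#' @export
read_dataset <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stopf("sidecar not found: %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(sc$format, "kanbeat-dataset")) stopf("not a kanbeat dataset: %s", path)
  if (!identical(as.integer(sc$version), DATASET_FORMAT_VERSION)) {
    stopf("dataset format version %s; this build reads version %d",
          sc$version, DATASET_FORMAT_VERSION)
  }
  n <- as.integer(sc$n)
  len <- as.integer(sc$segment_len)
  feats <- if (n > 0) {
    v <- readBin(path, "numeric", n = n * len, size = 8L, endian = "little")
    matrix(v, nrow = n, byrow = TRUE)
  } else {
    matrix(0, 0, len)
  }
  labels <- as.character(sc$labels)
  beat_dataset(feats, labels,
               split = if (n > 0) as.character(sc$split) else NULL,
               record_id = if (n > 0) as.character(sc$record_id) else NULL,
               r_index = if (n > 0) sc$r_index else NULL,
               fs = sc$fs, meta = as.list(sc$meta))
}

#' Export a beat dataset as CSV (for inspection)
#' @param ds a [beat_dataset()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_dataset_csv <- function(ds, path) {
  df <- data.frame(label = as.character(ds$labels),
                   split = as.character(ds$split),
                   record_id = ds$record_id, r_index = ds$r_index)
  feat <- as.data.frame(ds$features)
  names(feat) <- paste0("s", seq_len(ncol(feat)) - 1L)
  utils::write.csv(cbind(df, feat), path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' Nested defaults for every pipeline stage; configuration files may
#' override any subset, unknown keys are rejected.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    preprocess = list(half_width = 150L, wavelet_name = "db4", level = 3L,
                      threshold_rule = "soft",
                      fractions = c(0.6, 0.2, 0.2), stratified = FALSE),
    imbalance = list(strategy = "none", gamma = 2.0, alpha = 1.0,
                     k_neighbors = 5L),
    model = list(input_len = 300L, stem_channels = c(16L, 32L, 64L, 128L),
                 ms_kernels = c(3L, 11L, 21L, 31L), ms_out_channels = 128L,
                 dropout = 0.3, partial_ratio = 0.25, eca_gamma = 2,
                 eca_b = 1, gru_hidden = 256L, gru_layers = 2L,
                 kan_hidden = 571L, kan_grid = 5L, kan_order = 3L,
                 variant = "full"),
    train = list(batch_size = 64L, learning_rate = 5e-4, epochs = 60L,
                 loss = "ce"),
    synth = list(counts = c(N = 2475L, S = 83L, V = 199L, F = 22L, Q = 222L),
                 segment_len = 300L, separability = 1),
    paths = list(out_dir = ".")
  ), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) stopf("unknown configuration key: %s", key)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      v <- override[[nm]]
      if (!is.null(names(base[[nm]])) && is.list(v)) v <- unlist(v)
      base[[nm]] <- v
    }
  }
  base
}

#' Load a run configuration file (YAML or JSON) over the defaults
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (e.g. parsed CLI
#'   flags).
#' @return a `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    parsed <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    cfg <- merge_config(cfg, parsed)
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

run_config_model <- function(cfg, input_len = NULL) {
  m <- cfg$model
  model_config(input_len = input_len %||% m$input_len,
               stem_channels = m$stem_channels, ms_kernels = m$ms_kernels,
               ms_out_channels = m$ms_out_channels, dropout = m$dropout,
               partial_ratio = m$partial_ratio, eca_gamma = m$eca_gamma,
               eca_b = m$eca_b, gru_hidden = m$gru_hidden,
               gru_layers = m$gru_layers, kan_hidden = m$kan_hidden,
               kan_grid = m$kan_grid, kan_order = m$kan_order,
               seed = cfg$seed)
}

run_config_train <- function(cfg) {
  train_config(batch_size = cfg$train$batch_size,
               learning_rate = cfg$train$learning_rate,
               epochs = cfg$train$epochs, loss = cfg$train$loss,
               focal = focal_config(cfg$imbalance$gamma,
                                    rep_len(cfg$imbalance$alpha, 5)),
               seed = cfg$seed)
}
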