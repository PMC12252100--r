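#' Beat dataset container
#'
#' The unit every pipeline stage consumes: a numeric matrix of fixed-length
#' beat windows plus aligned labels, optional train/val/test split tags, and
#' per-row provenance (source record and R-peak sample index).
#'
#' @param features numeric matrix, one row per beat, one column per sample.
#' @param labels character or factor of AAMI classes (`N`, `S`, `V`, `F`, `Q`).
#' @param split optional character/factor of `"train"`, `"val"`, `"test"` (or
#'   `NA` before splitting).
#' @param record_id optional character vector of source record identifiers.
#' @param r_index optional integer vector of 0-based R-peak sample indices in
#'   the source record.
#' @param fs sampling frequency in Hz.
#' @param meta named list of provenance metadata (seed, config hash, ...).
#' @return an object of class `beat_dataset`.
#' @export
beat_dataset <- function(features, labels, split = NULL, record_id = NULL,
                         r_index = NULL, fs = 360, meta = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  labels <- factor(as.character(labels), levels = AAMI_CLASSES)
  if (anyNA(labels)) stopf("labels must all be one of %s", paste(AAMI_CLASSES, collapse = ", "))
  if (length(labels) != n) stopf("features has %d rows but labels has length %d", n, length(labels))
  if (is.null(split)) split <- rep(NA_character_, n)
  split <- factor(as.character(split), levels = c("train", "val", "test"))
  if (length(split) != n) stopf("split tags must have length %d", n)
  if (is.null(record_id)) record_id <- rep(NA_character_, n)
  if (is.null(r_index)) r_index <- rep(NA_integer_, n)
  structure(
    list(features = features, labels = labels, split = split,
         record_id = as.character(record_id), r_index = as.integer(r_index),
         fs = fs, meta = meta),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples @ %g Hz\n",
              nrow(x$features), ncol(x$features), x$fs))
  cat("  classes:", paste(sprintf("%s=%d", AAMI_CLASSES, tabulate(x$labels, 5L)),
                          collapse = " "), "\n")
  if (!all(is.na(x$split))) {
    cat("  splits: ", paste(sprintf("%s=%d", levels(x$split), tabulate(x$split, 3L)),
                            collapse = " "), "\n")
  }
  invisible(x)
}

#' Subset a beat dataset by row
#' @param x a `beat_dataset`.
#' @param i row index (integer or logical).
#' @param ... unused.
#' @return a `beat_dataset` with the selected rows.
#' @export
`[.beat_dataset` <- function(x, i, ...) {
  beat_dataset(x$features[i, , drop = FALSE], x$labels[i], x$split[i],
               x$record_id[i], x$r_index[i], fs = x$fs, meta = x$meta)
}

#' Number of beats in a dataset
#' @param ds a `beat_dataset`.
#' @return integer count.
#' @export
n_beats <- function(ds) nrow(ds$features)

#' Extract one split of a dataset
#' @param ds a `beat_dataset` with split tags.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return a `beat_dataset` with only the requested rows.
#' @export
dataset_split <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (all(is.na(ds$split))) stopf("dataset has no split tags; call split_dataset() first")
  ds[!is.na(ds$split) & ds$split == which]
}
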