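# Preprocessing: MIT-BIH symbol -> AAMI class consolidation, R-peak
# windowing, per-segment min-max normalization, and the train/val/test split.

#' AAMI class map for MIT-BIH beat symbols
#'
#' The standard consolidation of the 15 MIT-BIH beat annotation codes into
#' the five AAMI categories: N (normal, LBBB, RBBB), S (atrial premature,
#' aberrated atrial premature, nodal premature, supraventricular premature,
#' atrial escape, nodal escape), V (PVC, ventricular escape), F (fusion of
#' ventricular and normal), Q (paced, unclassifiable, fusion of paced and
#' normal).
#'
#' @return named character vector mapping symbol to class.
#' @export
aami_class_map <- function() {
  c(N = "N", L = "N", R = "N",
    A = "S", a = "S", J = "S", S = "S", e = "S", j = "S",
    V = "V", E = "V",
    F = "F",
    "/" = "Q", Q = "Q", f = "Q")
}

#' Map one MIT-BIH beat symbol to its AAMI class
#'
#' @param symbol MIT-BIH beat annotation code (e.g. `"L"`, `"A"`, `"/"`).
#' @param class_map mapping as returned by [aami_class_map()].
#' @return one of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @export
map_symbol <- function(symbol, class_map = aami_class_map()) {
  out <- unname(class_map[symbol])
  if (anyNA(out)) {
    stopf("unknown beat symbol(s): %s",
          paste(unique(symbol[is.na(out)]), collapse = ", "))
  }
  out
}

#' Window a record into fixed-length beat segments
#'
#' Extracts `half_width` samples on either side of each annotated R peak:
#' the half-open window `[r - half_width, r + half_width)` (0-based), i.e.
#' exactly `2 * half_width` samples with the R sample at index `half_width`.
#' Beats whose window crosses either record edge are dropped and counted in
#' the `dropped` attribute.
#'
#' @param record an `ecg_record` (see [synth_record()] / [read_wfdb()]).
#' @param half_width samples on either side of the R peak.
#' @return a [beat_dataset()] of raw segments with attribute `dropped`.
#' @export
segment_record <- function(record, half_width = 150) {
  if (half_width < 1) stopf("half_width must be >= 1")
  ann <- record$ann
  len <- length(record$signal)
  seg_len <- 2L * as.integer(half_width)
  if (nrow(ann) == 0L) {
    out <- beat_dataset(matrix(0, 0, seg_len), character(0), fs = record$fs)
    attr(out, "dropped") <- 0L
    return(out)
  }
  if (is.unsorted(ann$r_index, strictly = TRUE)) {
    stopf("annotations must be sorted by strictly increasing r_index")
  }
  lo <- ann$r_index - half_width           # 0-based inclusive start
  keep <- lo >= 0 & (lo + seg_len) <= len  # half-open end must fit
  feats <- t(vapply(which(keep), function(i) {
    record$signal[(lo[i] + 1L):(lo[i] + seg_len)]
  }, numeric(seg_len)))
  if (sum(keep) == 0L) feats <- matrix(0, 0, seg_len)
  labels <- map_symbol(ann$symbol[keep])
  out <- beat_dataset(feats, labels, record_id = rep(record$record_id, sum(keep)),
                      r_index = ann$r_index[keep], fs = record$fs)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Min-max normalize a segment to the unit interval
#'
#' Rescales `x` to `(x - min) / (max - min)`, so the minimum maps exactly to
#' 0 and the maximum to 1. A constant segment has no amplitude information
#' and raises an error; callers drop the beat and log it.
#'
#' @param x numeric vector (one segment) or matrix (one segment per row).
#' @return object of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (is.matrix(x)) {
    return(t(apply(x, 1L, minmax_normalize)))
  }
  if (length(x) == 0L) stopf("segment is empty")
  rng <- range(x)
  if (rng[1] == rng[2]) stopf("degenerate segment: max equals min, no amplitude to rescale")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Split specification
#'
#' @param fractions length-3 numeric `(train, val, test)` summing to 1.
#' @param seed integer seed for the shuffle.
#' @param stratified currently only `FALSE` (beat-level random split).
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.6, val = 0.2, test = 0.2),
                       seed = 1, stratified = FALSE) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stopf("fractions must be three values in (0,1) summing to 1")
  }
  if (isTRUE(stratified)) stopf("stratified splitting is not implemented")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = FALSE),
            class = "split_spec")
}

#' Tag a dataset with train/validation/test splits
#'
#' Sizes follow the ceiling rule calibrated to the published intra-patient
#' split: `val = ceiling(f_val * n)`, `test = ceiling(f_test * n)`,
#' `train = n - val - test` (so n = 109,447 gives 65,667 / 21,890 / 21,890).
#' Rows are shuffled with the spec's seed before assignment; tags are
#' disjoint and exhaustive.
#'
#' @param ds a [beat_dataset()].
#' @param spec a [split_spec()].
#' @return the dataset with `split` tags filled in.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  n <- n_beats(ds)
  sizes <- split_sizes(n, spec$fractions)
  perm <- with_seed(spec$seed, sample.int(n))
  tags <- rep(c("train", "val", "test"), times = sizes)
  ds$split <- factor(rep(NA_character_, n), levels = c("train", "val", "test"))
  ds$split[perm] <- factor(tags, levels = c("train", "val", "test"))
  ds$meta$split_seed <- spec$seed
  ds
}

#' Split sizes under the ceiling rule
#' @param n total number of beats (must be >= 5).
#' @param fractions length-3 `(train, val, test)` fractions.
#' @return named integer vector `(train, val, test)`.
#' @export
split_sizes <- function(n, fractions = c(0.6, 0.2, 0.2)) {
  if (n < 5) stopf("need at least 5 beats to split, got %d", n)
  val <- as.integer(ceiling(fractions[2] * n))
  test <- as.integer(ceiling(fractions[3] * n))
  train <- as.integer(n) - val - test
  if (train < 1) stopf("split leaves no training beats")
  c(train = train, val = val, test = test)
}

#' Full preprocessing pipeline for a raw beat dataset
#'
#' Wavelet-denoises each segment, min-max normalizes it, drops degenerate
#' (constant) segments, and assigns split tags.
#'
#' @param ds a raw [beat_dataset()].
#' @param wavelet a [wavelet_spec()] or `NULL` to skip denoising.
#' @param split a [split_spec()] or `NULL` to skip splitting.
#' @return a preprocessed `beat_dataset`.
#' @export
prepare_dataset <- function(ds, wavelet = wavelet_spec(), split = split_spec()) {
  feats <- ds$features
  if (!is.null(wavelet)) {
    feats <- t(apply(feats, 1L, dwt_denoise, spec = wavelet))
  }
  degenerate <- apply(feats, 1L, function(r) diff(range(r)) == 0)
  if (any(degenerate)) {
    warnf("dropping %d degenerate (constant) segment(s)", sum(degenerate))
    ds <- ds[!degenerate]
    feats <- feats[!degenerate, , drop = FALSE]
  }
  ds$features <- minmax_normalize(feats)
  if (!is.null(split)) ds <- split_dataset(ds, split)
  ds
}
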