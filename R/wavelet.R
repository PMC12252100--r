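# Periodized discrete wavelet transform (Daubechies filters) and
# soft/hard-threshold denoising. Written against the standard periodization
# convention (coefficient length ceil(n/2) per level, perfect reconstruction
# for even lengths), since no wavelet library ships with R here.

# Daubechies-4 decomposition low-pass filter (8 taps)
DB4_DEC_LO <- c(-0.010597401785069032, 0.032883011666885197,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.63088076792985892,
                0.71484657055291567, 0.23037781330889651)

wavelet_filters <- function(wavelet_name) {
  lo <- switch(wavelet_name,
    db4 = DB4_DEC_LO,
    haar = ,
    db1 = c(sqrt(0.5), sqrt(0.5)),
    stopf("unsupported wavelet '%s' (available: db1/haar, db4)", wavelet_name)
  )
  m <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(m)           # QMF: g[k] = (-1)^(k+1) h[m-1-k]
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

# circular (periodized) single-level analysis: approx + detail, each of
# length ceil(n/2); odd lengths are padded by repeating the last sample
dwt_level <- function(x, f) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  m <- length(f$dec_lo)
  half <- n %/% 2L
  cA <- numeric(half)
  cD <- numeric(half)
  shift <- m %/% 2L - 1L  # aligns phases with the usual periodization
  for (i in seq_len(half)) {
    pos <- ((2L * i - seq_len(m) + shift) %% n) + 1L
    seg <- x[pos]
    cA[i] <- sum(f$dec_lo * seg)
    cD[i] <- sum(f$dec_hi * seg)
  }
  list(cA = cA, cD = cD)
}

idwt_level <- function(cA, cD, f, out_len = 2L * length(cA)) {
  half <- length(cA)
  n <- 2L * half
  m <- length(f$dec_lo)
  y <- numeric(n)
  shift <- m %/% 2L - 1L
  for (i in seq_len(half)) {
    pos <- ((2L * i - seq_len(m) + shift) %% n) + 1L
    y[pos] <- y[pos] + f$dec_lo * cA[i] + f$dec_hi * cD[i]
  }
  y[seq_len(out_len)]
}

#' Maximum feasible decomposition level
#' @param n signal length.
#' @param wavelet_name wavelet family (`"db4"` or `"db1"`/`"haar"`).
#' @return integer, the deepest level for which the approximation still has
#'   at least as many samples as the filter length.
#' @export
dwt_max_level <- function(n, wavelet_name = "db4") {
  m <- length(wavelet_filters(wavelet_name)$dec_lo)
  if (n < m) return(0L)
  as.integer(floor(log2(n / (m - 1))))
}

#' Multi-level periodized DWT
#' @param x numeric vector.
#' @param wavelet_name wavelet family.
#' @param level decomposition depth.
#' @return list with `cA` (deepest approximation) and `cD` (list of detail
#'   vectors, level 1 first).
#' @export
dwt_decompose <- function(x, wavelet_name = "db4", level = 3) {
  maxl <- dwt_max_level(length(x), wavelet_name)
  if (level < 1 || level > maxl) {
    stopf("level %d infeasible for length %d with %s (maximum feasible level is %d)",
          level, length(x), wavelet_name, maxl)
  }
  f <- wavelet_filters(wavelet_name)
  lens <- integer(level)
  cD <- vector("list", level)
  cur <- x
  for (l in seq_len(level)) {
    lens[l] <- length(cur)
    s <- dwt_level(cur, f)
    cD[[l]] <- s$cD
    cur <- s$cA
  }
  list(cA = cur, cD = cD, lens = lens, wavelet = wavelet_name)
}

#' Inverse multi-level periodized DWT
#' @param dec a decomposition from [dwt_decompose()].
#' @return reconstructed numeric vector.
#' @export
dwt_reconstruct <- function(dec) {
  f <- wavelet_filters(dec$wavelet)
  cur <- dec$cA
  for (l in rev(seq_along(dec$cD))) {
    cur <- idwt_level(cur, dec$cD[[l]], f, out_len = dec$lens[l])
  }
  cur
}

#' Wavelet denoising specification
#'
#' Defaults are the standard ECG-denoising choices: db4, level 3, soft
#' thresholding with the universal threshold `sigma * sqrt(2 log n)`, sigma
#' estimated as `MAD(level-1 detail) / 0.6745`.
#'
#' @param wavelet_name wavelet family.
#' @param level decomposition depth (>= 1).
#' @param threshold_rule `"soft"` or `"hard"`.
#' @param sigma_estimator currently only `"mad_level1"`.
#' @return an object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelet_name = "db4", level = 3,
                         threshold_rule = c("soft", "hard"),
                         sigma_estimator = "mad_level1") {
  threshold_rule <- match.arg(threshold_rule)
  sigma_estimator <- match.arg(sigma_estimator, "mad_level1")
  if (level < 1) stopf("level must be >= 1")
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 threshold_rule = threshold_rule,
                 sigma_estimator = sigma_estimator),
            class = "wavelet_spec")
}

#' Denoise a segment by wavelet thresholding
#'
#' Decomposes with the periodized DWT, thresholds only the detail
#' coefficients (approximation untouched), and reconstructs. Output length
#' equals input length.
#'
#' @param x numeric vector (one segment).
#' @param spec a [wavelet_spec()].
#' @param threshold optional fixed threshold; by default the universal
#'   threshold with MAD-estimated sigma. `threshold = 0` reproduces the
#'   input to numerical precision.
#' @return denoised numeric vector.
#' @export
dwt_denoise <- function(x, spec = wavelet_spec(), threshold = NULL) {
  dec <- dwt_decompose(x, spec$wavelet_name, spec$level)
  if (is.null(threshold)) {
    sigma <- stats::mad(dec$cD[[1]], center = 0, constant = 1) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  dec$cD <- lapply(dec$cD, function(d) {
    if (spec$threshold_rule == "soft") {
      sign(d) * pmax(abs(d) - threshold, 0)
    } else {
      d * (abs(d) > threshold)
    }
  })
  dwt_reconstruct(dec)
}
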