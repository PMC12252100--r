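# Minimal WFDB-format codec: .hea headers, .dat signals (format 16 written;
# formats 16 and 212 read), and .atr annotations in the MIT binary codec
# (including SKIP/NUM/SUB/CHN/AUX pseudo-annotations on read). Covers the
# subset needed to exchange single-lead annotated records; amplitudes
# round-trip to ADC resolution (1/gain mV).

# MIT annotation code <-> symbol table (beat and common non-beat codes)
WFDB_CODES <- c("1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V",
                "6" = "F", "7" = "J", "8" = "A", "9" = "S", "10" = "E",
                "11" = "j", "12" = "/", "13" = "Q", "14" = "~", "16" = "|",
                "22" = "\"", "28" = "+", "31" = "!", "34" = "e", "37" = "x",
                "38" = "f", "41" = "r")

# the 15 MIT-BIH beat codes consolidated into the AAMI classes
WFDB_BEAT_SYMBOLS <- c("N", "L", "R", "A", "a", "J", "S", "e", "j",
                       "V", "E", "F", "/", "Q", "f")

symbol_to_code <- function(symbol) {
  code <- as.integer(names(WFDB_CODES))[match(symbol, WFDB_CODES)]
  if (anyNA(code)) {
    stopf("no annotation code for symbol(s): %s",
          paste(unique(symbol[is.na(code)]), collapse = ", "))
  }
  code
}

#' Write a record in WFDB format
#'
#' Emits `<record_id>.hea`, `<record_id>.dat` (format 16, single channel,
#' configurable gain) and `<record_id>.atr` (MIT annotation codec, long
#' gaps encoded with SKIP words).
#'
#' @param record an `ecg_record`.
#' @param dir output directory.
#' @param gain ADC units per mV.
#' @param channel_name signal description written to the header.
#' @return the record path (directory + record id), invisibly.
#' @export
write_wfdb <- function(record, dir = ".", gain = 4000, channel_name = "MLII") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  adc <- as.integer(round(record$signal * gain))
  if (any(abs(adc) > 32767)) stopf("signal exceeds the 16-bit ADC range at gain %g", gain)
  checksum <- sum(adc) %% 65536L
  if (checksum > 32767L) checksum <- checksum - 65536L
  writeLines(c(
    sprintf("%s 1 %g %d", record$record_id, record$fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s", record$record_id, gain,
            adc[1], checksum, channel_name)
  ), paste0(base, ".hea"))
  writeBin(adc, paste0(base, ".dat"), size = 2L, endian = "little")
  write_atr(record$ann, paste0(base, ".atr"))
  invisible(base)
}

write_atr <- function(ann, path) {
  codes <- symbol_to_code(ann$symbol)
  words <- integer(0)
  last <- 0L
  for (i in seq_along(codes)) {
    delta <- ann$r_index[i] - last
    if (delta < 0) stopf("annotation times must be non-decreasing")
    if (delta >= 1024L) {
      # SKIP pseudo-annotation: 4-byte interval, high 16 bits first
      words <- c(words, bitwShiftL(59L, 10L),
                 delta %/% 65536L, delta %% 65536L)
      delta <- 0L
    }
    words <- c(words, bitwShiftL(codes[i], 10L) + delta)
    last <- ann$r_index[i]
  }
  words <- c(words, 0L) # EOF word
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(words), con, size = 2L, endian = "little")
}

read_atr <- function(path) {
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
                 signed = FALSE, endian = "little")
  r_index <- integer(0)
  symbol <- character(0)
  t <- 0L
  i <- 1L
  while (i <= length(raw)) {
    word <- raw[i]
    code <- word %/% 1024L
    delta <- word %% 1024L
    if (word == 0L) break
    if (code == 59L) { # SKIP: next two words hold a 4-byte interval
      t <- t + raw[i + 1L] * 65536L + raw[i + 2L]
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN: no time advance
      i <- i + 1L
      next
    }
    if (code == 63L) { # AUX: delta is a byte count, padded to even
      i <- i + 1L + (delta + delta %% 2L) %/% 2L
      next
    }
    t <- t + delta
    sym <- WFDB_CODES[as.character(code)]
    if (is.na(sym)) stopf("unknown annotation code %d in %s", code, path)
    r_index <- c(r_index, t)
    symbol <- c(symbol, unname(sym))
    i <- i + 1L
  }
  data.frame(r_index = r_index, symbol = symbol, stringsAsFactors = FALSE)
}

parse_header <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(seq_len(n_sig), function(i) {
    tok <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_tok <- tok[3]
    baseline <- if (grepl("\\(", gain_tok)) as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_tok)) else 0
    gain <- as.numeric(sub("[(/].*", "", gain_tok))
    if (is.na(gain) || gain == 0) gain <- 200
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], format = sub("x.*|:.*|\\+.*", "", tok[2]),
         gain = gain, baseline = baseline, desc = desc)
  })
  list(record = rec[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

read_dat_16 <- function(path, n_sig, n_samp) {
  v <- readBin(path, "integer", n = file.size(path) %/% 2L, size = 2L,
               signed = TRUE, endian = "little")
  matrix(v, nrow = n_sig) # samples interleaved across signals
}

read_dat_212 <- function(path, n_sig, n_samp) {
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  n3 <- (length(b) %/% 3L) * 3L
  b0 <- b[seq(1L, n3, 3L)]; b1 <- b[seq(2L, n3, 3L)]; b2 <- b[seq(3L, n3, 3L)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 15L), 8L)
  s2 <- b2 + bitwShiftL(bitwAnd(b1, 240L), 4L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  matrix(v[seq_len(n_sig * (length(v) %/% n_sig))], nrow = n_sig)
}

#' Read a WFDB record
#'
#' Reads `<path>.hea`, `<path>.dat` (format 16 or 212) and `<path>.atr`,
#' selects the MLII channel when one is described (first channel with a
#' warning otherwise), converts to mV, and keeps beat annotations only
#' (original MIT-BIH symbols preserved; rhythm/artifact/aux annotations are
#' filtered out).
#'
#' @param path record path without extension.
#' @param annotator annotation file extension.
#' @return an `ecg_record`.
#' @export
read_wfdb <- function(path, annotator = "atr") {
  hea <- paste0(path, ".hea")
  atr <- paste0(path, ".", annotator)
  if (!file.exists(hea)) stopf("header file not found: %s", hea)
  if (!file.exists(atr)) stopf("annotation file not found: %s", atr)
  h <- parse_header(hea)
  if (h$fs != 360) warnf("sampling rate is %g Hz, not 360 Hz; no resampling applied", h$fs)
  dat <- file.path(dirname(hea), h$signals[[1]]$file)
  fmt <- h$signals[[1]]$format
  sig_mat <- switch(fmt,
    "16" = read_dat_16(dat, h$n_sig, h$n_samp),
    "212" = read_dat_212(dat, h$n_sig, h$n_samp),
    stopf("unsupported signal format '%s' (supported: 16, 212)", fmt)
  )
  descs <- vapply(h$signals, `[[`, character(1), "desc")
  ch <- match("MLII", descs)
  if (is.na(ch)) {
    ch <- 1L
    warnf("no MLII channel in %s (channels: %s); using channel 1",
          path, paste(descs, collapse = ", "))
  }
  s <- h$signals[[ch]]
  signal <- (sig_mat[ch, ] - s$baseline) / s$gain
  if (!is.na(h$n_samp) && length(signal) > h$n_samp) signal <- signal[seq_len(h$n_samp)]
  ann <- read_atr(atr)
  keep <- ann$symbol %in% WFDB_BEAT_SYMBOLS
  ann <- ann[keep, , drop = FALSE]
  ann$aami <- map_symbol(ann$symbol)
  rownames(ann) <- NULL
  structure(list(record_id = basename(path), signal = signal, fs = h$fs,
                 ann = ann),
            class = "ecg_record")
}
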