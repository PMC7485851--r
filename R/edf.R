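# Minimal EDF (European Data Format) reader/writer for continuous 16-bit
# records.  Covers the subset the package needs: a standard 256-byte header
# plus per-signal headers, equal sampling rate across the selected channels,
# contiguous data records of little-endian int16 with linear scaling from
# the digital to the physical range.  Written by hand because no EDF package
# is available to this package's dependency set.

.readAscii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a two-channel RIP record from an EDF file
#'
#' Channels are selected by their EDF labels via `channelMap`; both must
#' share the same sampling rate, which becomes the record's `fs` unless
#' overridden.
#'
#' @param path EDF file path.
#' @param channelMap named character vector `c(rcg = "<label>",
#'   abd = "<label>")`.
#' @param fs optional sampling-rate override in Hz.
#' @return A [RIPRecord-class].
#' @export
readEdfRecord <- function(path, channelMap = c(rcg = "RCG", abd = "ABD"),
                          fs = NULL) {
  if (!file.exists(path)) aureaIOError("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .readAscii(con, 8)
  if (version != "0") aureaIOError("%s: not an EDF file", path)
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))  # patient/recording/date/time
  headerBytes <- as.integer(.readAscii(con, 8))
  invisible(readBin(con, "raw", 44))               # reserved
  nRecords <- as.integer(.readAscii(con, 8))
  recDuration <- as.numeric(.readAscii(con, 8))
  ns <- as.integer(.readAscii(con, 4))
  if (is.na(ns) || ns < 1) aureaIOError("%s: malformed EDF header", path)
  field <- function(width) vapply(seq_len(ns), function(i)
    .readAscii(con, width), character(1))
  labels <- field(16)
  invisible(field(80)); invisible(field(8))        # transducer, dimension
  physMin <- as.numeric(field(8)); physMax <- as.numeric(field(8))
  digMin <- as.numeric(field(8)); digMax <- as.numeric(field(8))
  invisible(field(80))                             # prefiltering
  nsamp <- as.integer(field(8))
  invisible(field(32))                             # reserved
  seek(con, headerBytes)

  sel <- match(channelMap, labels)
  missing_ <- channelMap[is.na(sel)]
  if (length(missing_))
    aureaIOError("channel(s) not found in %s: %s", path,
                 paste(missing_, collapse = ", "))
  if (length(unique(nsamp[sel])) != 1L)
    aureaIOError("%s: selected channels have different sampling rates", path)
  data <- vector("list", length(sel))
  names(data) <- names(channelMap)
  for (nm in names(data)) data[[nm]] <- numeric(0)
  perRec <- sum(nsamp)
  for (r in seq_len(nRecords)) {
    block <- readBin(con, "integer", n = perRec, size = 2, signed = TRUE,
                     endian = "little")
    if (length(block) < perRec)
      aureaIOError("%s: truncated data record %d", path, r)
    offs <- cumsum(c(0L, nsamp))
    for (k in seq_along(sel)) {
      i <- sel[k]
      dig <- block[(offs[i] + 1L):(offs[i] + nsamp[i])]
      gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      data[[names(channelMap)[k]]] <-
        c(data[[names(channelMap)[k]]], physMin[i] + (dig - digMin[i]) * gain)
    }
  }
  if (is.null(fs)) {
    if (recDuration <= 0)
      aureaIOError("%s: cannot infer sampling rate; supply fs", path)
    fs <- nsamp[sel[1L]] / recDuration
  }
  RIPRecord(data$rcg, data$abd, fs)
}

.padAscii <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  sprintf("%-*s", n, s)
}

#' Write a RIP record to a minimal EDF file
#'
#' Emits a two-signal EDF with 1-second data records and linear 16-bit
#' scaling over each channel's observed range.  Primarily for fixtures and
#' interoperability checks; samples round-trip to 16-bit precision.
#'
#' @param record a [RIPRecord-class] whose sample count is a multiple of
#'   `fs` (whole seconds).
#' @param path destination path.
#' @param labels channel labels to embed, default `c("RCG", "ABD")`.
#' @return `path`, invisibly.
#' @export
writeEdfRecord <- function(record, path, labels = c("RCG", "ABD")) {
  fs <- record@fs
  n <- length(record@rcg)
  if (abs(fs - round(fs)) > 1e-9 || n %% round(fs) != 0)
    aureaIOError("EDF writer needs whole-second records at an integer rate")
  fs <- as.integer(round(fs))
  nRecords <- n %/% fs
  sig <- list(record@rcg, record@abd)
  physMin <- vapply(sig, min, numeric(1))
  physMax <- vapply(sig, max, numeric(1))
  physMax <- ifelse(physMax > physMin, physMax, physMin + 1)
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  ns <- 2L
  headerBytes <- 256L + 256L * ns
  writeChar(paste0(
    .padAscii("0", 8), .padAscii("synthetic", 80), .padAscii("aurea", 80),
    .padAscii("01.01.26", 8), .padAscii("00.00.00", 8),
    .padAscii(headerBytes, 8), .padAscii("", 44),
    .padAscii(nRecords, 8), .padAscii("1", 8), .padAscii(ns, 4),
    paste(vapply(labels, .padAscii, character(1), n = 16), collapse = ""),
    paste(rep(.padAscii("RIP belt", 80), ns), collapse = ""),
    paste(rep(.padAscii("au", 8), ns), collapse = ""),
    paste(vapply(physMin, function(v) .padAscii(sprintf("%.6g", v), 8),
                 character(1)), collapse = ""),
    paste(vapply(physMax, function(v) .padAscii(sprintf("%.6g", v), 8),
                 character(1)), collapse = ""),
    paste(rep(.padAscii(digMin, 8), ns), collapse = ""),
    paste(rep(.padAscii(digMax, 8), ns), collapse = ""),
    paste(rep(.padAscii("", 80), ns), collapse = ""),
    paste(rep(.padAscii(fs, 8), ns), collapse = ""),
    paste(rep(.padAscii("", 32), ns), collapse = "")), con, eos = NULL)
  dig <- lapply(seq_len(ns), function(i) {
    gain <- (digMax - digMin) / (physMax[i] - physMin[i])
    as.integer(round(digMin + (sig[[i]] - physMin[i]) * gain))
  })
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}
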