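# Readers for the two acquisition formats used with this kind of
# recording setup. Both are implemented directly on the documented file
# layouts: BrainVision is a text header (.vhdr) + text markers (.vmrk) +
# raw binary data (.eeg); EDF is a fixed-layout text header followed by
# 16-bit little-endian data records.

parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording triplet
#'
#' Reads the `.vhdr` header, the binary `.eeg` payload (IEEE float32 or
#' signed 16-bit with per-channel resolution, multiplexed or vectorized
#' orientation) and, when present, the `.vmrk` markers. Channel units
#' are taken from the header (microvolts by default).
#'
#' @param vhdr path to the `.vhdr` header file
#' @return a [new_recording()] with one `eeg` matrix channel; markers (if
#'   any) are stored in `meta$markers`
#' @export
read_brainvision <- function(vhdr) {
  ini <- parse_ini(readLines(vhdr, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)   # header is in microseconds
  fmt <- if (is.null(bi$BinaryFormat)) "IEEE_FLOAT_32" else bi$BinaryFormat
  orient <- if (is.null(ci$DataOrientation)) "MULTIPLEXED"
  else toupper(ci$DataOrientation)
  labs <- character(n_ch); res <- rep(1, n_ch); units <- character(n_ch)
  for (k in seq_len(n_ch)) {
    parts <- strsplit(ini[["Channel Infos"]][[sprintf("Ch%d", k)]],
                      ",")[[1]]
    labs[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      res[k] <- as.numeric(parts[3])
    units[k] <- if (length(parts) >= 4 && nzchar(parts[4])) parts[4]
    else "µV"
  }
  datafile <- file.path(dirname(vhdr), ci$DataFile)
  sz <- file.size(datafile)
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (toupper(fmt) == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (toupper(fmt) == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  ns <- length(raw) / n_ch
  x <- if (orient == "MULTIPLEXED")
    t(matrix(raw, nrow = n_ch))
  else matrix(raw, ncol = n_ch)
  x <- sweep(x, 2, res, `*`)
  colnames(x) <- labs
  markers <- NULL
  if (!is.null(ci$MarkerFile)) {
    mf <- file.path(dirname(vhdr), ci$MarkerFile)
    if (file.exists(mf)) {
      mini <- parse_ini(readLines(mf, warn = FALSE))
      mk <- mini[["Marker Infos"]]
      if (length(mk))
        markers <- do.call(rbind, lapply(mk, function(v) {
          p <- strsplit(v, ",")[[1]]
          data.frame(type = p[1], description = p[2],
                     position = as.integer(p[3]))
        }))
    }
  }
  new_recording(
    channels = list(eeg = list(data = x, rate = fs,
                               units = units[1])),
    blocks = data.frame(label = "all", start = 0, end = ns / fs),
    meta = list(markers = markers, source = "brainvision"))
}

#' Read an EDF (European Data Format) recording
#'
#' Minimal reader for classic continuous 16-bit EDF: parses the fixed
#' ASCII header, reads the data records, applies the per-signal
#' digital-to-physical scaling, and preserves each signal's native rate.
#'
#' @param path `.edf` file
#' @return a [new_recording()] with one channel per EDF signal (matrix
#'   `eeg` grouping is not attempted; labels are taken verbatim)
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)           # version, ids, dates
  rd(8)                                          # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8))
  fld(32)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmin_ - gain * dmin_
  store <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
      store[[i]] <- c(store[[i]], gain[i] * v + off[i])
    }
  }
  channels <- list()
  for (i in seq_len(ns)) {
    nm <- labels[i]
    channels[[nm]] <- list(data = store[[i]],
                           rate = nsamp[i] / rec_dur,
                           units = units[i])
  }
  new_recording(channels,
                blocks = data.frame(label = "all", start = 0,
                                    end = n_rec * rec_dur),
                meta = list(source = "edf"))
}
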