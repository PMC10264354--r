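#' Multi-rate recording container
#'
#' A `gw_recording` bundles named channels sampled at (possibly different)
#' rates with block annotations. EEG is stored as a samples x channels
#' matrix with 10-20 labels as column names; the peripheral channels
#' (`ecg`, `egg`, `scr`, `stetho`) are numeric vectors. This mirrors the
#' acquisition layout of the capsule experiments: a 31-channel EEG + ECG
#' amplifier and a separate 1000 Hz polygraph for EGG/ECG/SCR/stethoscope.
#'
#' @param channels named list; each element is `list(data=, rate=, units=)`.
#'   `data` is a numeric vector or a samples x channels matrix.
#' @param blocks data.frame with columns `label`, `start`, `end` (seconds);
#'   block labels are typically `baseline`, `normal`, `enhanced`.
#' @param meta optional named list carried along verbatim (e.g. clock
#'   offsets for cross-device synchronization, subject id).
#' @return an object of class `gw_recording`.
#' @export
new_recording <- function(channels, blocks, meta = list()) {
  stopifnot(is.list(channels), length(names(channels)) == length(channels))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(c("data", "rate", "units") %in% names(ch)))
      stop("channel '", nm, "' must have data, rate, units")
    if (ch$rate <= 0) stop("channel '", nm, "' has non-positive rate")
  }
  stopifnot(is.data.frame(blocks),
            all(c("label", "start", "end") %in% names(blocks)))
  if (any(blocks$end <= blocks$start)) stop("blocks must have end > start")
  structure(list(channels = channels, blocks = blocks, meta = meta),
            class = "gw_recording")
}

#' @export
print.gw_recording <- function(x, ...) {
  cat("<gw_recording>\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    n <- if (is.matrix(ch$data)) nrow(ch$data) else length(ch$data)
    k <- if (is.matrix(ch$data)) ncol(ch$data) else 1L
    cat(sprintf("  %-8s %8d samples x %2d @ %g Hz [%s]\n",
                nm, n, k, ch$rate, ch$units))
  }
  cat("  blocks:", paste(sprintf("%s[%g,%g]", x$blocks$label,
                                 x$blocks$start, x$blocks$end),
                         collapse = " "), "\n")
  invisible(x)
}

#' Extract one channel
#' @param rec a [new_recording()] object
#' @param name channel name
#' @return `list(data, rate, units)`
#' @export
get_channel <- function(rec, name) {
  stopifnot(inherits(rec, "gw_recording"))
  ch <- rec$channels[[name]]
  if (is.null(ch)) stop("no channel named '", name, "'")
  ch
}

#' Duration of a recording in seconds (longest channel)
#' @param rec recording
#' @export
recording_duration <- function(rec) {
  max(vapply(rec$channels, function(ch) {
    n <- if (is.matrix(ch$data)) nrow(ch$data) else length(ch$data)
    n / ch$rate
  }, 0))
}

#' Span (start, end) of a named block
#' @param rec recording
#' @param label block label
#' @return numeric length-2 vector `c(start, end)` in seconds
#' @export
block_span <- function(rec, label) {
  b <- rec$blocks[rec$blocks$label == label, , drop = FALSE]
  if (nrow(b) == 0) stop("no block labelled '", label, "'")
  c(b$start[1], b$end[1])
}

# full-precision number formatting so that write -> read round-trips are
# bit exact (%.17g is sufficient for IEEE doubles)
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a session directory
#'
#' Serializes a recording (plus optional events / button presses / ground
#' truth) as one directory of plain-text files: `channels/<name>.csv` with
#' full-precision samples, `meta.json` with rates, units and block
#' annotations, `events.csv`, `presses.csv` and `ground_truth.json`.
#' Round-trips through [read_recording()] are bit exact.
#'
#' @param rec recording
#' @param path directory to create
#' @param events optional event data.frame (see [simulate_session()])
#' @param presses optional `list(press_times=, release_times=)`
#' @param truth optional ground-truth list (stored as JSON)
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, events = NULL, presses = NULL,
                            truth = NULL) {
  stopifnot(inherits(rec, "gw_recording"))
  dir.create(file.path(path, "channels"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- list(
    blocks = rec$blocks,
    meta = rec$meta,
    channels = lapply(rec$channels, function(ch)
      list(rate = ch$rate, units = ch$units,
           ncol = if (is.matrix(ch$data)) ncol(ch$data) else 1L,
           labels = if (is.matrix(ch$data)) colnames(ch$data) else NULL))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(rec$channels)) {
    d <- rec$channels[[nm]]$data
    f <- file.path(path, "channels", paste0(nm, ".csv"))
    if (is.matrix(d)) {
      txt <- apply(d, 1, function(r) paste(fmt_full(r), collapse = ","))
      writeLines(c(paste(colnames(d), collapse = ","), txt), f)
    } else {
      writeLines(c(nm, fmt_full(d)), f)
    }
  }
  if (!is.null(events))
    write.csv(events, file.path(path, "events.csv"), row.names = FALSE)
  if (!is.null(presses))
    write.csv(data.frame(press = presses$press_times,
                         release = presses$release_times),
              file.path(path, "presses.csv"), row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording
#'
#' Reads one of the supported on-disk formats into a unified
#' [new_recording()] object with native rates preserved and units taken
#' from the file headers.
#'
#' @param path session directory (`format = "dir"`), BrainVision `.vhdr`
#'   header, or `.edf` file
#' @param format one of `"dir"` (the package's text container),
#'   `"brainvision"`, `"edf"`; guessed from `path` when `NULL`
#' @return a `gw_recording`
#' @export
read_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "dir"
    else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
    else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else stop("cannot guess format of ", path)
  }
  switch(format,
         dir = read_recording_dir(path),
         brainvision = read_brainvision(path),
         edf = read_edf(path),
         stop("unknown format '", format, "'"))
}

read_recording_dir <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  channels <- list()
  for (nm in names(meta$channels)) {
    info <- meta$channels[[nm]]
    f <- file.path(path, "channels", paste0(nm, ".csv"))
    if (!is.null(info$ncol) && info$ncol > 1) {
      d <- as.matrix(read.csv(f, check.names = FALSE))
      storage.mode(d) <- "double"
    } else {
      d <- as.numeric(readLines(f)[-1])
    }
    channels[[nm]] <- list(data = d, rate = info$rate, units = info$units)
  }
  blocks <- as.data.frame(meta$blocks)
  new_recording(channels, blocks,
                meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Read events / presses written next to a session directory
#' @param path session directory
#' @return data.frame of events
#' @export
read_events <- function(path) read.csv(file.path(path, "events.csv"))

#' @rdname read_events
#' @return for `read_presses`, `list(press_times, release_times)`
#' @export
read_presses <- function(path) {
  d <- read.csv(file.path(path, "presses.csv"))
  list(press_times = d$press, release_times = d$release)
}
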