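#' Recording container for dual-channel sensillum tip-recordings
#'
#' A `ssr_recording` holds the two channels of a tip-recording: the
#' unfiltered DC trace carrying the transepithelial (sensillum) potential,
#' and the high-pass filtered AC trace emphasising action potentials. Both
#' are millivolt sample vectors of equal length at a common sampling rate
#' (20 kHz by default, matching typical acquisition settings).
#'
#' @param dc numeric vector, unfiltered channel (mV).
#' @param ac numeric vector, high-pass filtered channel (mV); if `NULL` it
#'   is derived from `dc` with [derive_ac()].
#' @param sampling_rate samples per second (Hz), > 0.
#' @param stimulus_onsets stimulus valve-opening times in seconds from the
#'   start of the recording, strictly increasing, within `[0, duration)`.
#' @param meta named list of metadata. Recognised fields: `animal_id`,
#'   `condition`, `zt_window` (e.g. `"ZT1-3"` or `"ZT9-11"`), `day`,
#'   `stimulus_duration` (s). Extra fields are preserved.
#' @return an object of class `ssr_recording`.
#' @export
ssr_recording <- function(dc, ac = NULL, sampling_rate = 20000,
                          stimulus_onsets = numeric(0), meta = list()) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  dc <- as.numeric(dc)
  if (is.null(ac)) ac <- derive_ac(dc, sampling_rate)
  ac <- as.numeric(ac)
  if (length(dc) != length(ac)) stop("dc and ac must have the same length")
  stimulus_onsets <- as.numeric(stimulus_onsets)
  duration <- length(dc) / sampling_rate
  if (length(stimulus_onsets)) {
    if (any(diff(stimulus_onsets) <= 0)) {
      stop("stimulus_onsets must be strictly increasing")
    }
    if (any(stimulus_onsets < 0) || any(stimulus_onsets >= duration)) {
      stop("stimulus_onsets must lie within [0, duration)")
    }
  }
  structure(
    list(dc = dc, ac = ac, sampling_rate = sampling_rate,
         stimulus_onsets = stimulus_onsets, meta = meta),
    class = "ssr_recording"
  )
}

#' @export
print.ssr_recording <- function(x, ...) {
  cat(sprintf("<ssr_recording> %.3f s @ %g Hz, %d stimuli\n",
              length(x$dc) / x$sampling_rate, x$sampling_rate,
              length(x$stimulus_onsets)))
  if (!is.null(x$meta$animal_id)) {
    cat(sprintf("  animal %s | condition %s | %s\n",
                x$meta$animal_id, x$meta$condition %||% "?",
                x$meta$zt_window %||% ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive the AC channel from the DC channel
#'
#' Zero-phase high-pass filter with the magnitude response of an order-4
#' Butterworth filter applied forward and backward (the standard zero-phase
#' scheme). Implemented in the frequency domain on a mirror-extended copy of
#' the trace, which is exactly linear, exactly zero phase (spike timing is
#' preserved for latency measurements), and length preserving.
#'
#' @param dc numeric sample vector (mV).
#' @param sampling_rate Hz.
#' @param cutoff high-pass cutoff frequency in Hz, must be below Nyquist.
#' @param order Butterworth order of each pass (default 4).
#' @return numeric vector of the same length as `dc`.
#' @export
derive_ac <- function(dc, sampling_rate, cutoff = 150, order = 4L) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  n <- length(dc)
  if (n == 0) return(numeric(0))
  # even (mirror) extension avoids wrap-around edge artifacts
  ext <- c(dc, rev(dc))
  m <- length(ext)
  k <- seq_len(m) - 1
  f <- k / m * sampling_rate
  f <- pmin(f, sampling_rate - f) # fold to [0, fs/2]
  # two-pass (forward-backward) Butterworth high-pass power response
  gain <- ifelse(f == 0, 0, 1 / (1 + (cutoff / f)^(2 * order)))
  out <- Re(stats::fft(stats::fft(ext) * gain, inverse = TRUE)) / m
  out[seq_len(n)]
}

# ---------------------------------------------------------------------------
# Recording container I/O.  Two formats behind one pair of functions:
#   *.h5          HDF5 with datasets /dc, /ac and root attributes (random
#                 access friendly for hours-long traces)
#   *.csv         text fallback for small fixtures: '#meta <json>' header
#                 line followed by a dc,ac sample table
# ---------------------------------------------------------------------------

REQUIRED_REC_FIELDS <- c("sampling_rate", "stimulus_onsets")

#' Write / read a recording container
#'
#' `write_recording()` stores a recording either as HDF5 (`.h5`, datasets
#' `/dc` and `/ac` plus root attributes) or as a plain-text CSV container
#' (any other extension) whose first line is `#meta <json>`. A round-trip
#' reproduces samples exactly and metadata field-for-field.
#'
#' @param rec an [ssr_recording()].
#' @param path output file; extension `.h5`/`.hdf5` selects HDF5.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [ssr_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ssr_recording"))
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    write_recording_h5(rec, path)
  } else {
    write_recording_csv(rec, path)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE)) {
    read_recording_h5(path)
  } else {
    read_recording_csv(path)
  }
}

rec_header <- function(rec) {
  list(sampling_rate = rec$sampling_rate,
       stimulus_onsets = as.numeric(rec$stimulus_onsets),
       meta = rec$meta)
}

check_rec_header <- function(hdr) {
  for (f in REQUIRED_REC_FIELDS) {
    if (is.null(hdr[[f]])) {
      stop("recording container is missing required field '", f, "'")
    }
  }
  hdr
}

write_recording_csv <- function(rec, path) {
  hdr <- jsonlite::toJSON(rec_header(rec), digits = NA, auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", hdr), con)
  writeLines("dc,ac", con)
  writeLines(paste(format(rec$dc, digits = 17, trim = TRUE, scientific = TRUE),
                   format(rec$ac, digits = 17, trim = TRUE, scientific = TRUE),
                   sep = ","), con)
}

read_recording_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#meta ")) {
    stop("not a recording container (missing '#meta' header): ", path)
  }
  hdr <- jsonlite::fromJSON(sub("^#meta ", "", first), simplifyVector = TRUE)
  check_rec_header(hdr)
  hdr$stimulus_onsets <- as.numeric(unlist(hdr$stimulus_onsets))
  dat <- utils::read.csv(path, comment.char = "#")
  ssr_recording(dc = dat$dc, ac = dat$ac,
                sampling_rate = hdr$sampling_rate,
                stimulus_onsets = hdr$stimulus_onsets,
                meta = as.list(hdr$meta))
}

write_recording_h5 <- function(rec, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 containers")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$dc, path, "dc")
  rhdf5::h5write(rec$ac, path, "ac")
  rhdf5::h5write(rec$sampling_rate, path, "sampling_rate")
  rhdf5::h5write(as.numeric(rec$stimulus_onsets), path, "stimulus_onsets")
  rhdf5::h5write(as.character(jsonlite::toJSON(rec$meta, digits = NA,
                                               auto_unbox = TRUE)),
                 path, "meta_json")
  rhdf5::h5closeAll()
  invisible(path)
}

read_recording_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("the rhdf5 package is required for HDF5 containers")
  }
  present <- rhdf5::h5ls(path)$name
  hdr <- list(
    sampling_rate = if ("sampling_rate" %in% present)
      as.numeric(rhdf5::h5read(path, "sampling_rate")) else NULL,
    stimulus_onsets = if ("stimulus_onsets" %in% present)
      as.numeric(rhdf5::h5read(path, "stimulus_onsets")) else NULL
  )
  check_rec_header(hdr)
  meta <- if ("meta_json" %in% present) {
    jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta_json")),
                       simplifyVector = TRUE)
  } else list()
  rec <- ssr_recording(dc = as.numeric(rhdf5::h5read(path, "dc")),
                       ac = as.numeric(rhdf5::h5read(path, "ac")),
                       sampling_rate = hdr$sampling_rate,
                       stimulus_onsets = hdr$stimulus_onsets,
                       meta = as.list(meta))
  rhdf5::h5closeAll()
  rec
}

# ---------------------------------------------------------------------------
# Per-stimulus feature tables and deposited-layout sheets
# ---------------------------------------------------------------------------

FEATURE_COLS <- c("latency_ms", "f6ap_hz", "spa_mv", "n_aps_early", "n_aps_llpr")

# header synonyms for the deposited sheets; matched case-insensitively after
# stripping non-alphanumerics
FEATURE_COL_SYNONYMS <- list(
  experiment_id   = c("experimentid", "experiment", "id", "animal", "animalid"),
  condition       = c("condition", "treatment", "group"),
  zt              = c("zt", "ztwindow", "zeitgeber", "zeitgebertime"),
  stimulation_time_min = c("stimulationtimemin", "stimulationtime", "timemin",
                           "time", "stimtime"),
  latency_ms      = c("latencyms", "latency"),
  f6ap_hz         = c("f6aphz", "f6ap", "fap6", "phasicfrequency"),
  spa_mv          = c("spamv", "spa", "sensillumpotentialamplitude"),
  n_aps_early     = c("napsearly", "apsearly", "napsearlycount", "napearly",
                      "naps1s", "naps100ms", "spikesearly"),
  n_aps_llpr      = c("napsllpr", "apsllpr", "llpr", "napllpr", "spikesllpr")
)

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

match_headers <- function(headers, wanted = names(FEATURE_COL_SYNONYMS)) {
  norm <- normalize_header(headers)
  out <- stats::setNames(rep(NA_integer_, length(wanted)), wanted)
  for (w in wanted) {
    hit <- which(norm %in% FEATURE_COL_SYNONYMS[[w]])
    if (length(hit)) out[[w]] <- hit[1]
  }
  out
}

#' Write a per-stimulus feature table
#'
#' Long-format CSV with one row per (experiment, stimulation). Missing
#' values are written as the literal string `"NaN"`, following the
#' convention of deposited trial tables where unextractable parameters are
#' marked `NaN` rather than dropped.
#'
#' @param ft data.frame with columns `experiment_id`,
#'   `stimulation_time_min`, and the five response parameters
#'   `latency_ms`, `f6ap_hz`, `spa_mv`, `n_aps_early`, `n_aps_llpr`
#'   (plus optional `condition`, `zt`).
#' @param path output CSV path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(is.data.frame(ft))
  out <- ft
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      v <- format(out[[cn]], digits = 17, trim = TRUE)
      v[is.na(out[[cn]])] <- "NaN"
      out[[cn]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-stimulus feature table
#'
#' Accepts the long CSV dialect written by [write_feature_table()] or the
#' deposited "raw sheet" dialect (first column = stimulation time in
#' minutes, remaining columns = one experiment each, for a single
#' parameter). `"NaN"` cells become `NA`. Column headers are matched
#' case-insensitively against known synonyms; the mapping actually used is
#' attached as attribute `"matched_headers"`.
#'
#' @param path CSV (or XLS/XLSX, if `readxl` is installed) file.
#' @param dialect `"long"` or `"raw"`; `"auto"` inspects the header.
#' @param parameter for the raw dialect: which of the five feature columns
#'   the sheet holds (e.g. `"f6ap_hz"`).
#' @param sheet sheet name/index for Excel inputs.
#' @return data.frame in long format; stimulation times in minutes.
#' @export
read_feature_table <- function(path, dialect = c("auto", "long", "raw"),
                               parameter = NULL, sheet = 1) {
  dialect <- match.arg(dialect)
  dat <- read_table_any(path, sheet)
  hm <- match_headers(names(dat))
  if (dialect == "auto") {
    dialect <- if (!is.na(hm[["latency_ms"]]) || !is.na(hm[["experiment_id"]]))
      "long" else "raw"
  }
  if (dialect == "long") {
    need <- c("experiment_id", "stimulation_time_min")
    if (any(is.na(hm[need]))) {
      stop("unrecognized feature-table layout; recognized layouts: ",
           "'long' (experiment_id + stimulation_time_min + parameter ",
           "columns) or 'raw' (stimulation time column followed by one ",
           "column per experiment). Headers seen: ",
           paste(names(dat), collapse = ", "))
    }
    out <- data.frame(
      experiment_id = as.character(dat[[hm[["experiment_id"]]]]),
      stimulation_time_min = to_num(dat[[hm[["stimulation_time_min"]]]]),
      stringsAsFactors = FALSE
    )
    for (opt in c("condition", "zt")) {
      if (!is.na(hm[[opt]])) out[[opt]] <- as.character(dat[[hm[[opt]]]])
    }
    for (fc in FEATURE_COLS) {
      if (!is.na(hm[[fc]])) out[[fc]] <- to_num(dat[[hm[[fc]]]])
    }
    attr(out, "matched_headers") <- hm[!is.na(hm)]
    attr(out, "dialect") <- "long"
  } else {
    if (is.null(parameter)) {
      stop("raw-sheet dialect needs `parameter` (one of: ",
           paste(FEATURE_COLS, collapse = ", "), ")")
    }
    parameter <- match.arg(parameter, FEATURE_COLS)
    tcol <- if (!is.na(hm[["stimulation_time_min"]]))
      hm[["stimulation_time_min"]] else 1L
    ids <- names(dat)[-tcol]
    out <- do.call(rbind, lapply(ids, function(id) {
      data.frame(experiment_id = id,
                 stimulation_time_min = to_num(dat[[tcol]]),
                 value = to_num(dat[[id]]),
                 stringsAsFactors = FALSE)
    }))
    names(out)[names(out) == "value"] <- parameter
    attr(out, "dialect") <- "raw"
  }
  if (any(out$stimulation_time_min < 0, na.rm = TRUE)) {
    stop("stimulation times must be non-negative")
  }
  out
}

to_num <- function(x) {
  if (!is.numeric(x)) {
    x <- trimws(as.character(x))
    x[x %in% c("NaN", "nan", "NA", "")] <- NA
    x <- suppressWarnings(as.numeric(x))
  }
  x <- as.numeric(x)
  x[is.nan(x)] <- NA # "NaN" cells are missing values
  x
}

read_table_any <- function(path, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading Excel sheets requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Read a deposited-layout slope sheet
#'
#' The slope sheet of the deposited tables has one row per experiment:
#' experiment ID, condition, then one fitted-slope column per response
#' parameter (an optional ZT column separates the two zeitgeber datasets).
#'
#' @inheritParams read_feature_table
#' @return data.frame with `experiment_id`, `condition`, optional `zt`, and
#'   slope columns named after the feature columns; attribute
#'   `"matched_headers"` reports the header mapping used.
#' @export
read_slope_sheet <- function(path, sheet = 1) {
  dat <- read_table_any(path, sheet)
  hm <- match_headers(names(dat))
  if (is.na(hm[["experiment_id"]]) || is.na(hm[["condition"]])) {
    stop("unrecognized slope-sheet layout (need experiment ID and ",
         "condition columns). Headers seen: ",
         paste(names(dat), collapse = ", "))
  }
  out <- data.frame(
    experiment_id = as.character(dat[[hm[["experiment_id"]]]]),
    condition = as.character(dat[[hm[["condition"]]]]),
    stringsAsFactors = FALSE
  )
  if (!is.na(hm[["zt"]])) out$zt <- as.character(dat[[hm[["zt"]]]])
  for (fc in FEATURE_COLS) {
    if (!is.na(hm[[fc]])) out[[fc]] <- to_num(dat[[hm[[fc]]]])
  }
  if (!any(FEATURE_COLS %in% names(out))) {
    stop("slope sheet contains no recognized parameter columns")
  }
  attr(out, "matched_headers") <- hm[!is.na(hm)]
  out
}
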