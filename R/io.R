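pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE, scientific = FALSE, digits = 8), width)

#' Write an EEG recording to EDF or BDF
#'
#' Minimal European Data Format writer (16-bit EDF, 24-bit BDF), one
#' data-record per second. Voltages are stored in microvolts with per-channel
#' physical ranges spanning the data; a trailing partial second is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param bdf Write 24-bit BDF instead of 16-bit EDF.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, bdf = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer requires an integer sampling rate.")
  fs <- as.integer(round(fs))
  n_ch <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) abort("Recording shorter than one 1-s data record.")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  rng <- apply(abs(data), 1, max)
  rng <- pmax(rng, 1)                     # avoid degenerate physical ranges
  # physical-range header fields hold 8 ASCII chars; round the range up to
  # two decimals so the written field is exact and always covers the data
  rng <- ceiling(rng * 100) / 100
  phys_max <- rng
  phys_min <- -rng
  dig_max <- if (bdf) 8388607 else 32767
  dig_min <- if (bdf) -8388608 else -32768
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # fixed header (256 bytes)
  if (bdf) {
    writeBin(as.raw(255L), con)
    writeChar(pad_field("BIOSEMI", 7), con, 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, 8, eos = NULL)
  }
  writeChar(pad_field("X X X X", 80), con, 80, eos = NULL)     # patient id
  writeChar(pad_field("Startdate X X X X", 80), con, 80, eos = NULL)
  writeChar(pad_field("01.01.00", 8), con, 8, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, 8, eos = NULL)
  writeChar(num_field(256L * (1L + n_ch), 8), con, 8, eos = NULL)
  writeChar(pad_field(if (bdf) "24BIT" else "EDF", 44), con, 44, eos = NULL)
  writeChar(num_field(n_rec, 8), con, 8, eos = NULL)
  writeChar(num_field(1L, 8), con, 8, eos = NULL)               # record duration s
  writeChar(num_field(n_ch, 4), con, 4, eos = NULL)
  # per-signal header fields
  for (nm in rec$channel_names) writeChar(pad_field(nm, 16), con, 16, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("", 80), con, 80, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("uV", 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(phys_min[i], 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(phys_max[i], 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(dig_min, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(dig_max, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("", 80), con, 80, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num_field(fs, 8), con, 8, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_field("", 32), con, 32, eos = NULL)
  # records: per record, channel-blocked samples
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(n_ch)) {
      dig <- round((data[i, idx] - phys_min[i]) * scale[i] + dig_min)
      dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
      if (bdf) {
        b <- integer(3L * fs)
        v <- ifelse(dig < 0, dig + 16777216, dig)
        b[seq(1, by = 3, length.out = fs)] <- v %% 256
        b[seq(2, by = 3, length.out = fs)] <- (v %/% 256) %% 256
        b[seq(3, by = 3, length.out = fs)] <- (v %/% 65536) %% 256
        writeBin(as.raw(b), con)
      } else {
        writeBin(dig, con, size = 2L, endian = "little")
      }
    }
  }
  invisible(path)
}

read_edf_impl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 8L)
  bdf <- magic[1] == as.raw(255L)
  rd_str <- function(n) {
    vapply(n, function(w) trimws(rawToChar(readBin(con, "raw", w))), character(1))
  }
  rd_num <- function(w) as.numeric(rd_str(w))
  invisible(rd_str(c(80L, 80L, 8L, 8L)))                 # ids, date, time
  invisible(rd_num(8L))                                  # header bytes
  invisible(rd_str(44L))                                 # reserved
  n_rec <- rd_num(8L)
  rec_dur <- rd_num(8L)
  n_ch <- as.integer(rd_num(4L))
  if (is.na(n_ch) || n_ch < 1L) abort(sprintf("Cannot parse EDF header of '%s'.", path))
  labels <- rd_str(rep(16L, n_ch))
  invisible(rd_str(rep(80L, n_ch)))
  units <- rd_str(rep(8L, n_ch))
  phys_min <- rd_num(rep(8L, n_ch))
  phys_max <- rd_num(rep(8L, n_ch))
  dig_min <- rd_num(rep(8L, n_ch))
  dig_max <- rd_num(rep(8L, n_ch))
  invisible(rd_str(rep(80L, n_ch)))
  spr <- as.integer(rd_num(rep(8L, n_ch)))               # samples per record
  invisible(rd_str(rep(32L, n_ch)))
  if (length(unique(spr)) != 1L) {
    abort("EDF files with per-channel sampling rates are not supported.")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      if (bdf) {
        b <- as.integer(readBin(con, "raw", 3L * spr[i]))
        v <- b[seq(1, by = 3, length.out = spr[i])] +
          256 * b[seq(2, by = 3, length.out = spr[i])] +
          65536 * b[seq(3, by = 3, length.out = spr[i])]
        dig <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                       endian = "little")
      }
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      out[i, idx] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
    }
  }
  # convert to microvolts when the unit says otherwise
  mv <- grepl("^mV$", units, ignore.case = TRUE)
  out[mv, ] <- out[mv, ] * 1000
  list(data = out, fs = fs, channel_names = labels)
}

#' Write an EEG recording to the plain-text matrix container
#'
#' The container is a pair of files sharing a stem: `<stem>.eeg.tsv`, a
#' tab-separated channels x samples voltage matrix (microvolts, one row per
#' channel, no header), and `<stem>.json`, a sidecar holding `fs`,
#' `channel_names`, unit-sphere `positions` and the `reference`.
#'
#' @param rec An [eeg_recording()].
#' @param stem Path stem (without extension).
#' @return The stem, invisibly.
#' @export
write_eeg_container <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  readr::write_tsv(
    as.data.frame(rec$data), paste0(stem, ".eeg.tsv"),
    col_names = FALSE, progress = FALSE
  )
  jsonlite::write_json(
    list(
      fs = rec$fs, channel_names = rec$channel_names,
      positions = rec$positions, reference = rec$reference
    ),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' Read EEG from disk
#'
#' Supported formats: EDF/BDF (`.edf`, `.bdf`) and the package's plain-text
#' matrix container (pass the `<stem>.eeg.tsv` file or the bare stem). When a
#' format carries no sensor positions a generic spherical montage is
#' substituted with a warning.
#'
#' @param path File path.
#' @param format_hint One of `"auto"`, `"edf"`, `"bdf"`, `"container"`.
#'
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format_hint = c("auto", "edf", "bdf", "container")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.eeg\\.tsv$", ".tsv", path)))
    format_hint <- if (ext %in% c("", "tsv", "json")) {
      "container"
    } else if (ext %in% c("edf", "bdf")) {
      ext
    } else if (ext == "set") {
      abort("EEGLAB .set files are not supported; export to EDF or the text container.")
    } else {
      abort(sprintf("Unrecognized EEG format '%s'.", ext))
    }
  }
  if (format_hint %in% c("edf", "bdf")) {
    if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
    raw <- read_edf_impl(path)
    return(eeg_recording(raw$data, raw$fs, channel_names = raw$channel_names,
                         positions = NULL, reference = "common"))
  }
  stem <- sub("\\.eeg\\.tsv$", "", path)
  stem <- sub("\\.json$", "", stem)
  tsv <- paste0(stem, ".eeg.tsv")
  sidecar <- paste0(stem, ".json")
  if (!file.exists(tsv)) abort(sprintf("Container data file not found: '%s'.", tsv))
  data <- as.matrix(suppressMessages(
    readr::read_tsv(tsv, col_names = FALSE, progress = FALSE,
                    show_col_types = FALSE)
  ))
  dimnames(data) <- NULL
  if (!file.exists(sidecar)) abort(sprintf("Container sidecar not found: '%s'.", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(meta$channel_names) != nrow(data)) {
    abort(sprintf(
      "Sidecar lists %d channels but the data matrix has %d rows.",
      length(meta$channel_names), nrow(data)
    ))
  }
  positions <- if (!is.null(meta$positions)) as.matrix(meta$positions) else NULL
  eeg_recording(data, meta$fs, channel_names = meta$channel_names,
                positions = positions,
                reference = if (identical(meta$reference, "average")) "average" else "common")
}

feature_cols <- c("subject", "cohort", "visit", "age_months", "sex",
                  "retained_segments", "class", "feature", "value")

validate_features <- function(table) {
  missing <- setdiff(feature_cols, names(table))
  if (length(missing)) {
    abort(paste0("Feature table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(table)) {
    if (any(table$age_months <= 0)) abort("Feature table has non-positive ages.")
    if (any(table$retained_segments < 0)) abort("Feature table has negative segment counts.")
    dup <- table |>
      dplyr::count(.data$subject, .data$visit, .data$class, .data$feature) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup)) {
      abort(sprintf(
        "Duplicate (subject, visit, class, feature) keys in feature table (%d), e.g. %s/%s/%s/%s.",
        nrow(dup), dup$subject[1], dup$visit[1], dup$class[1], dup$feature[1]
      ))
    }
  }
  invisible(table)
}

#' Persist a long-format feature table to CSV
#'
#' Columns: `subject,cohort,visit,age_months,sex,retained_segments,class,feature,value`
#' with one value per (subject, visit, class, feature) key.
#'
#' @param table A feature tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
persist_features <- function(table, path) {
  validate_features(table)
  readr::write_csv(table[feature_cols], path, progress = FALSE)
  invisible(path)
}

#' Load a feature table written by [persist_features()]
#' @param path CSV path.
#' @return A validated feature tibble.
#' @export
load_features <- function(path) {
  table <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      subject = readr::col_character(), cohort = readr::col_character(),
      visit = readr::col_integer(), age_months = readr::col_double(),
      sex = readr::col_integer(), retained_segments = readr::col_integer(),
      class = readr::col_character(), feature = readr::col_character(),
      value = readr::col_double()
    )
  )
  validate_features(tibble::as_tibble(table))
}
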