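#' Multichannel iEEG recording container
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector of unique channel names.
#' @param patient_id Patient identifier.
#' @return Object of class `hfo_recording`.
#' @export
hfo_recording <- function(signal, sampling_rate, channel_names = NULL,
                          patient_id = "unknown") {
  signal <- as.matrix(signal)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nrow(signal)))
  assert_that(sampling_rate > 0, "sampling_rate must be positive")
  assert_that(length(channel_names) == nrow(signal),
              "channel_names must match the number of signal rows")
  assert_that(!anyDuplicated(channel_names), "channel names must be unique")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 patient_id = patient_id,
                 duration_minutes = ncol(signal) / sampling_rate / 60),
            class = "hfo_recording")
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf("<hfo_recording> patient %s: %d channels x %d samples @ %g Hz (%.2f min)\n",
              x$patient_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              x$duration_minutes))
  invisible(x)
}

#' Read a recording from disk
#'
#' Two container formats are supported: `"raw+json"`, a JSON header next to a
#' little-endian binary payload (float64 by default, hence a lossless round
#' trip), and `"edf"`, the 16-bit European Data Format.
#'
#' @param path Path to the `.json` header (raw+json) or `.edf` file.
#' @param format `"raw+json"` or `"edf"`; inferred from the extension when
#'   missing.
#' @return An [hfo_recording].
#' @export
read_recording <- function(path, format = c("auto", "raw+json", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "raw+json"
  }
  assert_that(file.exists(path), paste("file not found:", path))
  if (format == "edf") return(read_edf(path))
  hdr <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_epihfo("unparseable JSON header",
                                                  "epihfo_corrupt_input"))
  req <- c("sampling_rate", "channel_names", "n_samples", "dtype", "data_file")
  missing <- setdiff(req, names(hdr))
  assert_that(length(missing) == 0,
              paste("missing header field(s):", paste(missing, collapse = ", ")),
              class = "epihfo_corrupt_input")
  bin <- file.path(dirname(path), hdr$data_file)
  assert_that(file.exists(bin), "binary payload missing", class = "epihfo_corrupt_input")
  nch <- length(hdr$channel_names)
  n <- hdr$n_samples
  size <- if (hdr$dtype == "float32") 4L else 8L
  con <- file(bin, "rb"); on.exit(close(con))
  vals <- readBin(con, "double", n = nch * n, size = size, endian = "little")
  assert_that(length(vals) == nch * n, "binary payload has wrong length",
              class = "epihfo_corrupt_input")
  sig <- matrix(vals, nrow = nch, byrow = TRUE)
  hfo_recording(sig, as.numeric(hdr$sampling_rate), hdr$channel_names,
                if (!is.null(hdr$patient_id)) hdr$patient_id else "unknown")
}

#' Write a recording to disk
#'
#' @param rec An [hfo_recording].
#' @param path Output path (`.json` header for raw+json; `.edf` for EDF).
#' @param format Container format; see [read_recording()].
#' @param dtype `"float64"` (lossless) or `"float32"` for the raw container.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = c("auto", "raw+json", "edf"),
                            dtype = "float64") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "raw+json"
  }
  if (format == "edf") return(write_edf(rec, path))
  data_file <- paste0(sub("\\.json$", "", basename(path)), ".bin")
  hdr <- list(sampling_rate = rec$sampling_rate, channel_names = rec$channel_names,
              n_samples = ncol(rec$signal), dtype = dtype, data_file = data_file,
              patient_id = rec$patient_id)
  jsonlite::write_json(hdr, path, auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dirname(path), data_file), "wb"); on.exit(close(con))
  size <- if (dtype == "float32") 4L else 8L
  writeBin(as.numeric(t(rec$signal)), con, size = size, endian = "little")
  invisible(path)
}

# --- minimal continuous EDF reader/writer (16-bit, one data record per second)

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  assert_that(fs == round(fs), "EDF writer requires an integer sampling rate")
  nch <- nrow(rec$signal)
  n <- ncol(rec$signal)
  n_rec <- floor(n / fs)
  assert_that(n_rec >= 1, "recording shorter than one EDF data record")
  n_use <- n_rec * fs
  pmin_ <- apply(rec$signal[, seq_len(n_use), drop = FALSE], 1, min)
  pmax_ <- apply(rec$signal[, seq_len(n_use), drop = FALSE], 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(rec$patient_id, 80), edf_pad("epihfo", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nch, 8), edf_pad("", 44), edf_pad(n_rec, 8),
    edf_pad("1", 8), edf_pad(nch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste0(edf_pad(vals, width), collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", nch), 80)               # transducer
  field(rep("uV", nch), 8)              # physical dimension
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep("-32768", nch), 8)
  field(rep("32767", nch), 8)
  field(rep("", nch), 80)               # prefiltering
  field(rep(fs, nch), 8)                # samples per record
  field(rep("", nch), 32)               # reserved
  gain <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((rec$signal[ch, idx] - pmin_[ch]) / gain[ch]) - 32768
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(width) {
    b <- readBin(con, "raw", n = width)
    assert_that(length(b) == width, "truncated EDF header",
                class = "epihfo_corrupt_input")
    trimws(rawToChar(b[b != as.raw(0)]))
  }
  rd(8)                      # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  assert_that(!is.na(nch) && nch >= 1, "corrupt EDF channel count",
              class = "epihfo_corrupt_input")
  rdv <- function(width) sapply(seq_len(nch), function(i) rd(width))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  assert_that(all(!is.na(c(pmin_, pmax_, dmin, dmax, spr))), "corrupt EDF signal header",
              class = "epihfo_corrupt_input")
  sig <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch]) + pmin_[ch]
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  hfo_recording(sig, spr[1] / dur, labels, patient)
}

#' Apply a customized average reference
#'
#' Subtracts, at every sample, the mean of the channels not flagged
#' `excluded` from every channel.  Excluded channels are re-referenced too but
#' do not contribute to the mean, so the mean across included channels is 0 at
#' every sample afterwards.
#'
#' @param rec An [hfo_recording].
#' @param meta Channel metadata data frame with columns `channel` and
#'   `excluded` (0/1); rows are matched to `rec$channel_names`.
#' @return A re-referenced [hfo_recording].
#' @export
apply_average_reference <- function(rec, meta = NULL) {
  excl <- rep(FALSE, nrow(rec$signal))
  if (!is.null(meta)) {
    m <- match(rec$channel_names, meta$channel)
    assert_that(!anyNA(m), "metadata does not cover all channels")
    excl <- meta$excluded[m] > 0
  }
  incl <- which(!excl)
  assert_that(length(incl) >= 2, "need at least two channels in the reference",
              class = "epihfo_invalid_montage")
  ref <- colMeans(rec$signal[incl, , drop = FALSE])
  out <- rec
  out$signal <- sweep(rec$signal, 2, ref)
  out
}

event_table_required <- c("patient", "channel", "start_sample", "end_sample")

#' Read or write an event table
#'
#' Event tables are UTF-8 CSVs with a header row and at least the columns
#' `patient`, `channel`, `start_sample`, `end_sample`; extra columns (peak
#' counts, classes, probabilities) round-trip unchanged.  Sample indices are
#' 1-based with half-open `[start, end)` intervals.
#'
#' @param path CSV path.
#' @param events Data frame to write (for `write_event_table`).
#' @return `read_event_table` returns the data frame.
#' @export
read_event_table <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(event_table_required, names(df))
  assert_that(length(missing) == 0,
              paste("event table missing column(s):", paste(missing, collapse = ", ")),
              class = "epihfo_schema_error")
  df
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  missing <- setdiff(event_table_required, names(events))
  assert_that(length(missing) == 0,
              paste("event table missing column(s):", paste(missing, collapse = ", ")),
              class = "epihfo_schema_error")
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' One recording container per patient plus `channels.csv`, `outcomes.csv` and
#' `ground_truth.csv`.
#'
#' @param cohort An `hfo_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format Recording container format (see [write_recording()]).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, format = "raw+json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    ext <- if (format == "edf") ".edf" else ".json"
    write_recording(rec, file.path(dir, paste0(rec$patient_id, ext)), format)
  }
  utils::write.csv(cohort$channels, file.path(dir, "channels.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(cohort$events, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
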