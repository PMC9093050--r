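#' Read an EEG recording from disk
#'
#' Supports BrainVision triplets (`.vhdr` header + binary `.eeg`), EDF, and a
#' plain matrix-text format (one header row of labels, one row per sample,
#' tab-separated). The returned recording has a single continuity segment
#' spanning all samples; labels come from the file header. When the labels are
#' a subset of the packaged 59-channel montage, channels are re-ordered to the
#' montage's canonical order so downstream matrices always agree on order.
#'
#' @param path file path (`.vhdr` for BrainVision).
#' @param format `"brainvision"`, `"edf"`, `"matrix_text"`, or `"auto"`
#'   (by extension).
#' @param fs sampling rate in Hz, required for `matrix_text`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf", "matrix_text"),
                           fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vhdr = "brainvision",
                     edf = "edf",
                     txt = , tsv = "matrix_text",
                     stop("cannot infer format from extension: ", ext))
  }
  rec <- switch(format,
                brainvision = read_brainvision(path),
                edf = read_edf(path),
                matrix_text = read_matrix_text(path, fs))
  canonicalize_order(rec)
}

canonicalize_order <- function(rec) {
  canon <- tryCatch(default_montage()$labels, error = function(e) NULL)
  if (!is.null(canon) && all(rec$labels %in% canon) &&
      !identical(rec$labels, canon[canon %in% rec$labels])) {
    ord <- canon[canon %in% rec$labels]
    rec$data <- rec$data[ord, , drop = FALSE]
    rec$labels <- ord
  }
  rec
}

read_matrix_text <- function(path, fs) {
  if (is.null(fs)) stop("`fs` must be given for matrix_text recordings")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  m <- matrix(scan(path, what = double(), skip = 1L, quiet = TRUE),
              ncol = length(header), byrow = TRUE)
  if (anyDuplicated(header)) stop("duplicate channel labels in header")
  eeg_recording(t(m), fs = fs, labels = header)
}

#' Write a recording in matrix-text format
#'
#' Values are written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$labels, collapse = "\t"), con)
  m <- t(rec$data)
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, con)
  invisible(path)
}

# --- BrainVision ------------------------------------------------------------
# Minimal reader for the public BrainVision Core format: INI-style .vhdr
# naming a binary .eeg (multiplexed IEEE_FLOAT_32 or INT_16 with per-channel
# resolution in µV).
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  section <- ""
  kv <- list(); channels <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1)); val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (section == "Channel Infos") channels[[key]] <- val
    else kv[[paste(section, key, sep = ".")]] <- val
  }
  need <- function(k) {
    if (is.null(kv[[k]])) stop("BrainVision header missing ", k)
    kv[[k]]
  }
  if (toupper(need("Common Infos.DataFormat")) != "BINARY")
    stop("only BINARY BrainVision data supported")
  orientation <- toupper(need("Common Infos.DataOrientation"))
  n_ch <- as.integer(need("Common Infos.NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("Common Infos.SamplingInterval"))
  fmt <- toupper(kv[["Binary Infos.BinaryFormat"]] %||% "IEEE_FLOAT_32")
  ch <- t(vapply(paste0("Ch", seq_len(n_ch)), function(k) {
    if (is.null(channels[[k]])) stop("BrainVision header missing ", k)
    parts <- strsplit(channels[[k]], ",", fixed = TRUE)[[1]]
    c(parts[1], if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "1")
  }, character(2)))
  labels <- ch[, 1]; resolution <- as.numeric(ch[, 2])
  if (anyDuplicated(labels)) stop("duplicate channel labels in BrainVision header")
  data_file <- file.path(dirname(vhdr_path), need("Common Infos.DataFile"))
  sz <- file.info(data_file)$size
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(data_file, what = "numeric", size = 4L,
                   n = as.integer(sz / 4), endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(data_file, what = "integer", size = 2L, signed = TRUE,
                   n = as.integer(sz / 2), endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  if (length(raw) %% n_ch != 0) stop("BrainVision data length not a multiple of channel count")
  n_s <- length(raw) %/% n_ch
  data <- if (orientation == "MULTIPLEXED") matrix(raw, nrow = n_ch)
          else matrix(raw, nrow = n_ch, byrow = TRUE)
  data <- data * resolution
  eeg_recording(data, fs = fs, labels = labels)
}

# --- EDF --------------------------------------------------------------------
# Minimal EDF (European Data Format) reader: fixed 256-byte header, ns
# per-channel 256-byte headers, int16 data records scaled to physical units.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  ascii(8); ascii(80); ascii(80); ascii(8); ascii(8)  # version, patient, rec, date, time
  header_bytes <- as.integer(ascii(8))
  ascii(44)
  n_records <- as.integer(ascii(8))
  record_dur <- as.numeric(ascii(8))
  ns <- as.integer(ascii(4))
  field <- function(w) vapply(seq_len(ns), function(i) ascii(w), character(1))
  labels <- field(16)
  field(80); field(8)                       # transducer, physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                                 # prefiltering
  n_samp <- as.integer(field(8))
  field(32)                                 # reserved
  if (anyDuplicated(labels)) stop("duplicate channel labels in EDF header")
  if (length(unique(n_samp)) != 1L)
    stop("EDF with differing per-channel sampling rates not supported")
  expected <- header_bytes + n_records * sum(n_samp) * 2
  if (file.info(path)$size < expected) stop("EDF data shorter than header declares")
  fs <- n_samp[1] / record_dur
  data <- matrix(0, nrow = ns, ncol = n_records * n_samp[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  for (r in seq_len(n_records)) {
    for (c_i in seq_len(ns)) {
      x <- readBin(con, "integer", size = 2L, signed = TRUE, n = n_samp[c_i],
                   endian = "little")
      data[c_i, ((r - 1) * n_samp[1] + 1):(r * n_samp[1])] <- gain[c_i] * x + offset[c_i]
    }
  }
  eeg_recording(data, fs = fs, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
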