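#' Multichannel broadband recording
#'
#' Container for a raw multichannel time series plus per-channel metadata.
#' Metadata columns beyond `label` are optional: 3-D contact positions in mm
#' (`x_mm`, `y_mm`, `z_mm`), a parcel assignment (`parcel`), a gray-matter
#' proximity index (`gmpi`, 0 = white/gray boundary, 1 = pial surface) and the
#' label of the reference contact (`reference_label`) under a bipolar /
#' closest-white-matter referencing scheme.
#'
#' @param samples numeric matrix, channels x time
#' @param srate sampling rate in Hz
#' @param meta data.frame with at least a `label` column (unique labels);
#'   defaults to labels `ch1..chN`
#' @return an object of class `bb_recording`
#' @export
bb_recording <- function(samples, srate, meta = NULL) {
  samples <- as.matrix(samples)
  stop_if_not(is.numeric(samples) && all(is.finite(samples)),
              "all sample values must be finite numerics")
  stop_if_not(is.numeric(srate) && length(srate) == 1L && srate > 0,
              "sampling_rate must be a single positive number")
  if (is.null(meta)) {
    meta <- data.frame(label = paste0("ch", seq_len(nrow(samples))),
                       stringsAsFactors = FALSE)
  }
  stop_if_not("label" %in% names(meta), "meta must have a 'label' column")
  stop_if_not(nrow(meta) == nrow(samples),
              "meta must have one row per channel")
  stop_if_not(!anyDuplicated(meta$label), "channel labels must be unique")
  rownames(samples) <- meta$label
  structure(list(samples = samples, srate = srate, meta = meta),
            class = "bb_recording")
}

#' @export
print.bb_recording <- function(x, ...) {
  cat(sprintf("<bb_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$srate,
              ncol(x$samples) / x$srate))
  extras <- setdiff(names(x$meta), "label")
  if (length(extras)) cat("  metadata:", paste(extras, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bb_recording <- function(x) dim(x$samples)

#' Read a raw binary matrix recording
#'
#' Reads a recording stored as a little-endian float32/float64 matrix with a
#' JSON header (`n_channels`, `n_samples`, `rate`, optional `dtype`) and an
#' optional channel-metadata TSV (columns `label`, `x_mm`, `y_mm`, `z_mm`,
#' `parcel`, `gmpi`, `reference_label`; only `label` is required).
#'
#' @param bin_path path to the binary matrix (channel-major: channel 1's
#'   samples first)
#' @param header_path path to the JSON header; default `<bin_path>.json`
#' @param meta_path optional path to the metadata TSV
#' @return a [bb_recording]
#' @export
read_raw_recording <- function(bin_path,
                               header_path = paste0(bin_path, ".json"),
                               meta_path = NULL) {
  hd <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  stop_if_not(all(c("n_channels", "n_samples", "rate") %in% names(hd)),
              "header must contain n_channels, n_samples, rate")
  dtype <- if (is.null(hd$dtype)) "float64" else hd$dtype
  size <- switch(dtype, float32 = 4L, float64 = 8L,
                 stop("unsupported dtype: ", dtype))
  n <- as.integer(hd$n_channels) * as.integer(hd$n_samples)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = size, endian = "little")
  stop_if_not(length(x) == n, "binary file shorter than header promises")
  samples <- matrix(x, nrow = hd$n_channels, ncol = hd$n_samples, byrow = TRUE)
  meta <- if (!is.null(meta_path)) {
    read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  bb_recording(samples, hd$rate, meta)
}

#' Write a recording in the raw-matrix interchange format
#'
#' @param rec a [bb_recording]
#' @param bin_path output path for the float64 matrix; the JSON header goes to
#'   `<bin_path>.json` and the metadata TSV to `meta_path`
#' @param meta_path optional TSV output path for the channel metadata
#' @return `bin_path`, invisibly
#' @export
write_raw_recording <- function(rec, bin_path, meta_path = NULL) {
  con <- file(bin_path, "wb")
  writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
         rate = rec$srate, dtype = "float64"),
    paste0(bin_path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(meta_path)) {
    write.table(rec$meta, meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(bin_path)
}

#' Read a continuous EDF recording
#'
#' Minimal reader for the plain (continuous, 16-bit) European Data Format.
#' Per-channel digital-to-physical scaling is applied; physical dimensions are
#' passed through unchecked. EDF+ annotation channels are not supported.
#'
#' @param path path to the EDF file
#' @return a [bb_recording]
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                         # version
  rd(80); rd(80)                # patient / recording id
  rd(8); rd(8)                  # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)                        # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  stop_if_not(n_rec >= 1 && ns >= 1, "empty or corrupt EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80) # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  seek(con, header_bytes)
  stop_if_not(length(unique(nsamp)) == 1L,
              "channels with differing record sample counts are not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, nrow = ns, ncol = n_rec * nsamp[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
      out[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <-
        d * gain[i] + offset[i]
    }
  }
  srate <- nsamp[1] / rec_dur
  bb_recording(out, srate, data.frame(label = labels,
                                      stringsAsFactors = FALSE))
}

#' Write a continuous EDF recording
#'
#' Counterpart of [read_edf()]; quantizes to 16 bits over each channel's
#' observed range.
#'
#' @param rec a [bb_recording]; sampling rate and record length must give an
#'   integer number of samples per 1-s data record
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$srate))    # 1-s records
  stop_if_not(ncol(rec$samples) %% spr == 0,
              "signal length must be a whole number of 1-s records")
  n_rec <- ncol(rec$samples) %/% spr
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- substr(sprintf("%-*s", n, x), 1, n)
    writeChar(s, con, nchars = n, eos = NULL)
  }
  header_bytes <- 256L + 256L * ns
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(header_bytes, 8); pad("", 44)
  pad(n_rec, 8); pad("1", 8); pad(ns, 4)
  plo <- apply(rec$samples, 1, min)
  phi <- apply(rec$samples, 1, max)
  phi <- ifelse(phi > plo, phi, plo + 1)
  for (l in rec$meta$label) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("a.u.", 8)
  for (v in plo) pad(formatC(v, digits = 6, width = 8), 8)
  for (v in phi) pad(formatC(v, digits = 6, width = 8), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(spr, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (phi - plo) / 65535
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- rec$samples[i, ((r - 1) * spr + 1):(r * spr)]
      d <- as.integer(round((seg - plo[i]) / gain[i]) - 32768)
      writeBin(pmin(pmax(d, -32768L), 32767L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
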