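#' Read an ECG record from disk
#'
#' Supports two on-disk forms. `"csv"` is a plain-text dialect: an optional
#' first comment line `# fs=<Hz>`, a `sample_mv` header, then one value per
#' line; the sampling rate must come from the comment line or the `fs`
#' argument. `"wfdb"` reads a WFDB header/signal pair (`.hea` + `.dat`) in
#' signal formats 212 or 16 — the formats used by the MIT-BIH arrhythmia
#' database — and converts raw ADC units to physical mV as
#' `(adc - baseline) / gain`.
#'
#' @param path path to the CSV file or to the WFDB record (with or without
#'   the `.hea` extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param channel 1-based signal index to extract (WFDB records may be
#'   multi-channel).
#' @param fs sampling rate in Hz for CSV files lacking an `# fs=` line.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), channel = 1L, fs = NULL) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path, fs = fs) else read_record_wfdb(path, channel)
}

#' Write an ECG record as CSV
#'
#' Writes the dialect read by [read_record()]: an `# fs=` comment line, a
#' `sample_mv` header, one sample per line with full double precision, so
#' `read_record(write_record(x))` reproduces `x` exactly.
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(is_ecg_record(record))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", record$fs), "sample_mv",
               sprintf("%.17g", record$samples)), con)
  invisible(path)
}

read_record_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) && grepl("^#\\s*fs\\s*=", lines[1])) {
    fs_file <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", lines[1]))
    if (is.null(fs)) fs <- fs_file
    lines <- lines[-1]
  }
  if (is.null(fs)) {
    stop("sampling rate unknown: supply 'fs' or include an '# fs=' line", call. = FALSE)
  }
  if (length(lines) && trimws(lines[1]) == "sample_mv") lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  samples <- suppressWarnings(as.numeric(lines))
  if (anyNA(samples)) {
    stop(sprintf("non-numeric sample at line %d", which(is.na(samples))[1]), call. = FALSE)
  }
  ecg_record(samples, fs = fs,
             id = sub("\\.[^.]*$", "", basename(path)))
}

# --- WFDB ------------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  rec <- strsplit(lines[1], "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(lines[1 + i], "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2]))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- NA_real_
    bm <- regmatches(gain_field, regexpr("\\(-?[0-9]+\\)", gain_field))
    if (length(bm)) baseline <- as.numeric(gsub("[()]", "", bm))
    adczero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else sprintf("sig%d", i)
    list(file = f[1], format = fmt, gain = gain, baseline = baseline, desc = desc)
  })
  list(name = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

decode_wfdb_212 <- function(bytes) {
  n3 <- floor(length(bytes) / 3L) * 3L
  if (n3 < 3L) stop("format-212 signal file holds no complete sample pair", call. = FALSE)
  b <- as.integer(bytes[1:n3])
  b0 <- b[seq(1, n3, by = 3)]
  b1 <- b[seq(2, n3, by = 3)]
  b2 <- b[seq(3, n3, by = 3)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b1, 0x0FL), 8L), b0)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b1, 0xF0L), 4L), b2)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.vector(rbind(s1, s2))
}

read_record_wfdb <- function(path, channel = 1L) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("WFDB header not found: %s", hea), call. = FALSE)
  hdr <- parse_wfdb_header(hea)
  if (channel < 1L || channel > hdr$nsig) {
    stop(sprintf("channel %d out of range (record has %d signals)", channel, hdr$nsig),
         call. = FALSE)
  }
  sig <- hdr$signals[[channel]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop(sprintf("WFDB signal file not found: %s", dat), call. = FALSE)
  # all signals of MIT-BIH-style records share one interleaved .dat file
  same_file <- vapply(hdr$signals, function(s) identical(s$file, sig$file), logical(1))
  nsig_here <- sum(same_file)
  slot <- cumsum(same_file)[channel]
  raw_bytes <- readBin(dat, "raw", n = file.size(dat))
  if (sig$format == 212) {
    all_samples <- decode_wfdb_212(raw_bytes)
  } else if (sig$format == 16) {
    all_samples <- readBin(dat, "integer", n = floor(length(raw_bytes) / 2L),
                           size = 2L, signed = TRUE, endian = "little")
  } else {
    stop(sprintf("unsupported WFDB signal format %d (only 212 and 16 are read)",
                 sig$format), call. = FALSE)
  }
  total <- floor(length(all_samples) / nsig_here) * nsig_here
  if (total < nsig_here) stop("signal file shorter than one frame", call. = FALSE)
  mat <- matrix(all_samples[1:total], nrow = nsig_here)
  raw_adc <- mat[slot, ]
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0 && hdr$nsamp < length(raw_adc)) {
    raw_adc <- raw_adc[1:hdr$nsamp]
  }
  ecg_record((raw_adc - sig$baseline) / sig$gain, fs = hdr$fs,
             id = hdr$name, lead = sig$desc)
}

# --- annotations -----------------------------------------------------------

#' Write and read QRS annotations as CSV
#'
#' The annotation CSV has columns
#' `r_index,q_index,s_index,qrs_interval_s,rr_to_next_s`. Indices are written
#' 0-based (the convention of WFDB-centric tooling) and converted back to
#' this package's 1-based in-memory indices on read; intervals are written
#' with 9 decimal places so round trips preserve them to well below 1e-6 s.
#' The final beat's `rr_to_next_s` is empty.
#'
#' @param annotation a [qrs_annotation()].
#' @param path file path.
#' @return `read_annotation()` returns a [qrs_annotation()];
#'   `write_annotation()` returns `path` invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "qrs_annotation"))
  n <- length(annotation$r)
  df <- data.frame(
    r_index = annotation$r - 1L,
    q_index = annotation$q - 1L,
    s_index = annotation$s - 1L,
    qrs_interval_s = ifelse(is.na(annotation$qrs), NA, sprintf("%.9f", annotation$qrs)),
    rr_to_next_s = c(sprintf("%.9f", annotation$rr), if (n) NA),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(qrs_annotation(integer(0), integer(0), integer(0),
                          qrs = numeric(0), rr = numeric(0)))
  }
  rr <- as.numeric(df$rr_to_next_s)
  rr <- rr[seq_len(nrow(df) - 1L)]
  qrs_annotation(r = df$r_index + 1L,
                 q = df$q_index + 1L,
                 s = df$s_index + 1L,
                 qrs = as.numeric(df$qrs_interval_s),
                 rr = rr)
}
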