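#' Minimal WFDB record I/O
#'
#' Reads and writes the common single-segment WFDB layout: a text header
#' (`<record>.hea`) plus one binary signal file in format 16 (interleaved
#' little-endian 16-bit integers). Signals are converted between ADC units and
#' mV with the per-channel gain stored in the header; lead names are taken
#' from the channel description field (falling back to `sig0`, `sig1`, ... if
#' absent) and normalized case-insensitively. This is deliberately a small
#' subset of the format -- multi-segment records, non-16 storage formats and
#' multi-file layouts are not supported.
#'
#' @param path path to the record: either the `.hea` file or the bare record
#'   name (header path minus extension).
#' @param ... passed to [ecg_record()] (sex, age_years, ...).
#' @return an `ecg_record`.
#' @export
read_wfdb <- function(path, ...) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("no such file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("parse error: WFDB header too short: ", hea)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) stop("parse error: malformed WFDB record line")
  record_name <- rec[1]
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig_lines <- lines[2:(1 + n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("x.*$", "", f[2])  # strip samples-per-frame qualifier
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("\\(.*", "", sub("/.*$", "", gain_field)))
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, "", "fmt"))
  if (!identical(fmts, "16"))
    stop("unsupported WFDB signal format(s): ", paste(fmts, collapse = ", "),
         " (only format 16 is supported)")
  dat_files <- unique(vapply(sigs, `[[`, "", "file"))
  if (length(dat_files) != 1)
    stop("unsupported WFDB layout: all signals must share one .dat file")
  dat <- file.path(dirname(hea), dat_files)
  if (!file.exists(dat)) stop("no such file: ", dat)
  raw_n <- file.size(dat) / 2L
  vals <- readBin(dat, "integer", n = raw_n, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) %% n_sig != 0)
    stop("parse error: signal file length not a multiple of channel count")
  mat <- matrix(vals, nrow = n_sig)  # interleaved: channel-major within frame
  if (!is.na(n_samp) && ncol(mat) != n_samp)
    warning("header sample count (", n_samp, ") differs from file (", ncol(mat), ")")
  gains <- vapply(sigs, `[[`, 0, "gain")
  bases <- vapply(sigs, `[[`, 0, "baseline")
  mv <- (mat - bases) / gains
  descs <- vapply(sigs, `[[`, "", "desc")
  descs[is.na(descs)] <- paste0("sig", which(is.na(descs)) - 1L)
  rownames(mv) <- normalize_lead_names(descs)
  ecg_record(mv, sampling_rate_hz = fs, record_id = record_name, ...)
}

#' @rdname read_wfdb
#' @param record an `ecg_record` to write.
#' @param dir output directory.
#' @param gain ADC units per mV (default 1000; signals are quantized to
#'   1/gain mV).
#' @return the header path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_sig <- nrow(record$signals)
  n_samp <- ncol(record$signals)
  adc <- round(record$signals * gain)
  if (any(abs(adc) > 32767))
    stop("signal exceeds int16 range at gain ", gain, " ADU/mV")
  storage.mode(adc) <- "integer"
  name <- record$record_id
  dat_name <- paste0(name, ".dat")
  # 16-bit two's-complement checksum of each channel's samples
  chks <- apply(adc, 1, function(v) {
    s <- sum(v) %% 65536
    if (s >= 32768) s - 65536 else s
  })
  hdr <- c(
    sprintf("%s %d %g %d", name, n_sig, record$sampling_rate_hz, n_samp),
    sprintf("%s 16 %d/mV 16 0 %d %d 0 %s",
            dat_name, gain, adc[, 1], chks, rownames(adc))
  )
  writeLines(hdr, file.path(dir, paste0(name, ".hea")))
  writeBin(as.integer(adc), file.path(dir, dat_name), size = 2L,
           endian = "little")
  invisible(file.path(dir, paste0(name, ".hea")))
}
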