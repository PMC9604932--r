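#' Minimal WFDB format-16 record I/O
#'
#' Writes and reads physiologic signal records in the WFDB conventions:
#' a text header `<record>.hea` and an interleaved 16-bit little-endian
#' sample file `<record>.dat` (format 16), with per-signal gain in ADC
#' units per millivolt. Only the subset needed to interchange the records
#' this package produces is implemented. R-peak ground-truth annotations
#' are written as a plain-text `<record>.ann.csv` (columns `sample,label`)
#' rather than the binary WFDB annotation format.
#'
#' @param rec an [ecg_record()].
#' @param record_name record name (file stem).
#' @param dir directory.
#' @param gain ADC units per mV (default 200).
#' @return `write_wfdb()` returns the header path invisibly;
#'   `read_wfdb()` returns an [ecg_record()].
#' @export
write_wfdb <- function(rec, record_name, dir = ".", gain = 200) {
  stopifnot(inherits(rec, "ecg_record"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  dat <- paste0(record_name, ".dat")
  adu <- round(rec$samples * gain)
  adu[adu > 32767] <- 32767
  adu[adu < -32768] <- -32768
  hea <- c(sprintf("%s %d %g %d", record_name, ns, rec$fs, n),
           sprintf("%s 16 %g 16 0 %d 0 0 %s", dat, gain, adu[, 1],
                   rec$lead_names))
  writeLines(hea, file.path(dir, paste0(record_name, ".hea")))
  con <- file(file.path(dir, dat), "wb")
  writeBin(as.integer(adu), con, size = 2, endian = "little")
  close(con)
  if (nrow(rec$annotations) > 0) {
    utils::write.csv(as.data.frame(rec$annotations),
                     file.path(dir, paste0(record_name, ".ann.csv")),
                     row.names = FALSE)
  }
  invisible(file.path(dir, paste0(record_name, ".hea")))
}

#' @rdname write_wfdb
#' @export
read_wfdb <- function(record_name, dir = ".") {
  hea <- readLines(file.path(dir, paste0(record_name, ".hea")))
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  ns <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  lines <- lapply(1 + seq_len(ns), function(i) strsplit(trimws(hea[i]), "\\s+")[[1]])
  gains <- vapply(lines, function(x) as.numeric(x[3]), numeric(1))
  leads <- vapply(lines, function(x) x[length(x)], character(1))
  dat <- lines[[1]][1]
  con <- file(file.path(dir, dat), "rb")
  adu <- readBin(con, "integer", n * ns, size = 2, endian = "little",
                 signed = TRUE)
  close(con)
  samples <- matrix(adu, nrow = ns) / gains
  ann_path <- file.path(dir, paste0(record_name, ".ann.csv"))
  ann <- if (file.exists(ann_path)) {
    tibble::as_tibble(utils::read.csv(ann_path))
  } else NULL
  ecg_record(samples, fs = fs, lead_names = leads, annotations = ann)
}
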