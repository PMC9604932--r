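#' Multichannel ECG record
#'
#' An `ecg_record` is a lightweight container for a multichannel ECG signal:
#' a lead-by-sample matrix in millivolts, a sampling rate, ordered lead
#' names, and an optional annotation table of sample marks (e.g. R-peak
#' ground truth).
#'
#' @param samples numeric matrix, leads in rows, samples in columns (mV).
#' @param fs sampling rate in Hz.
#' @param lead_names character vector of lead labels, one per row.
#' @param annotations optional tibble with columns `sample` (1-based index)
#'   and `label` (character).
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, lead_names = rownames(samples),
                       annotations = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), is.numeric(fs), length(fs) == 1, fs > 0)
  if (is.null(lead_names)) {
    lead_names <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(lead_names) == nrow(samples))
  rownames(samples) <- lead_names
  if (is.null(annotations)) {
    annotations <- tibble::tibble(sample = integer(), label = character())
  } else {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("sample", "label") %in% names(annotations)))
  }
  structure(
    list(samples = samples, fs = fs, lead_names = lead_names,
         annotations = annotations),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = " "), "\n")
  if (nrow(x$annotations) > 0) {
    cat(sprintf("  annotations: %d (%s)\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
as_tibble.ecg_record <- function(x, ...) {
  n <- ncol(x$samples)
  out <- tibble::as_tibble(t(x$samples))
  dplyr::bind_cols(tibble::tibble(time = (seq_len(n) - 1) / x$fs), out)
}

n_samples <- function(rec) ncol(rec$samples)

duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' Read / write an ECG record as CSV
#'
#' The CSV layout is one column per lead with a header row of lead names;
#' the sampling rate is stored in a `# fs=<Hz>` comment on the first line.
#' Annotations, if present, are written alongside as `<path>.ann.csv` with
#' columns `sample,label`.
#'
#' @param rec an [ecg_record()].
#' @param path file path.
#' @return `write_ecg_csv()` returns `path` invisibly; `read_ecg_csv()`
#'   returns an [ecg_record()].
#' @export
write_ecg_csv <- function(rec, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%g", rec$fs), con)
  utils::write.csv(as.data.frame(t(rec$samples)), con, row.names = FALSE)
  close(con)
  if (nrow(rec$annotations) > 0) {
    utils::write.csv(as.data.frame(rec$annotations),
                     paste0(path, ".ann.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  first <- readLines(path, n = 1)
  fs <- 500
  skip <- 0
  if (grepl("^# fs=", first)) {
    fs <- as.numeric(sub("^# fs=", "", first))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  ann_path <- paste0(path, ".ann.csv")
  ann <- NULL
  if (file.exists(ann_path)) {
    ann <- tibble::as_tibble(utils::read.csv(ann_path))
  }
  ecg_record(t(as.matrix(df)), fs = fs, lead_names = names(df),
             annotations = ann)
}
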