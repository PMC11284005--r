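# Minimal WFDB-compatible record I/O: text header (.hea) + 16-bit
# little-endian sample-interleaved signal file (.dat), format 16, fixed gain
# in adu/mV.  Beat annotations and ground truth travel in plain-text
# sidecars (<record>_ann.csv, <record>_gt.json) rather than the binary MIT
# annotation format.

#' Write a recording as a WFDB record plus plain-text sidecars
#'
#' @param rec a `vt_recording`.
#' @param dir output directory (created if needed).
#' @param gain ADC gain, analogue-to-digital units per mV.
#' @return The record path (sans extension), invisibly.
#' @export
write_wfdb <- function(rec, dir, gain = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- rec$recording_id
  n_sig <- ncol(rec$signal); n_samp <- nrow(rec$signal)
  dat <- paste0(name, ".dat")
  hdr <- c(
    sprintf("%s %d %g %d", name, n_sig, rec$fs, n_samp),
    sprintf("%s 16 %g/mV 16 0 0 0 0 lead%d", dat, gain, seq_len(n_sig)),
    sprintf("# patient_id: %s", rec$patient_id),
    sprintf("# class_label: %s", rec$class_label),
    sprintf("# age: %g", rec$pi$age),
    sprintf("# sex: %s", rec$pi$sex),
    sprintf("# bmi: %g", rec$pi$bmi),
    sprintf("# smoking: %s", rec$pi$smoking))
  writeLines(hdr, file.path(dir, paste0(name, ".hea")))
  adu <- as.integer(clip(round(t(rec$signal) * gain), -32768, 32767))
  con <- file(file.path(dir, dat), "wb")
  writeBin(adu, con, size = 2L, endian = "little")
  close(con)
  if (!is.null(rec$annotations))
    utils::write.csv(rec$annotations, file.path(dir, paste0(name, "_ann.csv")),
                     row.names = FALSE)
  gt <- rec$gt
  side <- list(vt_events = rec$vt_events)
  if (!is.null(gt))
    side <- c(side, list(rr_ms = gt$rr_ms, beat_labels = gt$beat_labels,
                         realized_pvc_fraction = gt$realized_pvc_fraction,
                         vt_runs = gt$vt_runs, duration_s = gt$duration_s))
  jsonlite::write_json(side, file.path(dir, paste0(name, "_gt.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, name))
}

read_wfdb <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  top <- strsplit(trimws(hea[1L]), "\\s+")[[1L]]
  n_sig <- as.integer(top[2L]); fs <- as.numeric(top[3L])
  n_samp <- as.integer(top[4L])
  sig_lines <- hea[1L + seq_len(n_sig)]
  gains <- vapply(sig_lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1L]]
    as.numeric(sub("/.*$", "", f[3L]))
  }, numeric(1), USE.NAMES = FALSE)
  meta <- list()
  for (l in grep("^# ", hea, value = TRUE)) {
    kv <- strsplit(sub("^# ", "", l), ": ")[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  con <- file(paste0(path, ".dat"), "rb")
  adu <- readBin(con, "integer", n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  close(con)
  sig <- t(matrix(adu, nrow = n_sig)) / rep(gains, each = n_samp)

  ann <- NULL
  annf <- paste0(path, "_ann.csv")
  if (file.exists(annf))
    ann <- utils::read.csv(annf, stringsAsFactors = FALSE)
  gtf <- paste0(path, "_gt.json")
  side <- if (file.exists(gtf)) jsonlite::read_json(gtf, simplifyVector = TRUE)
          else list()
  vt_events <- side$vt_events
  vt_events <- if (is.null(vt_events) || length(vt_events) == 0) list()
               else lapply(seq_len(nrow(as.matrix(vt_events))),
                           function(i) as.numeric(as.matrix(vt_events)[i, ]))
  structure(list(
    patient_id = meta$patient_id %||% basename(path),
    recording_id = basename(path),
    signal = sig, fs = fs,
    class_label = meta$class_label %||% NA_character_,
    pi = list(age = as.numeric(meta$age %||% NA),
              sex = meta$sex %||% NA_character_,
              bmi = as.numeric(meta$bmi %||% NA),
              smoking = isTRUE(as.logical(meta$smoking %||% NA))),
    vt_events = vt_events, annotations = ann,
    gt = if (length(side) > 1L) side else NULL), class = "vt_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_recording_csv <- function(rec, file) {
  df <- data.frame(time_s = (seq_len(nrow(rec$signal)) - 1L) / rec$fs)
  for (k in seq_len(ncol(rec$signal))) df[[paste0("lead", k)]] <- rec$signal[, k]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

read_recording_csv <- function(file) {
  df <- utils::read.csv(file)
  if (!"time_s" %in% names(df))
    vt_abort("CSV recording must contain a 'time_s' column (sampling rate carrier)")
  leads <- grep("^lead", names(df), value = TRUE)
  if (!length(leads)) vt_abort("CSV recording has no leadK columns")
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(
    patient_id = sub("\\.csv$", "", basename(file)),
    recording_id = sub("\\.csv$", "", basename(file)),
    signal = as.matrix(df[leads]), fs = fs, class_label = NA_character_,
    pi = list(age = NA_real_, sex = NA_character_, bmi = NA_real_,
              smoking = NA),
    vt_events = list(), annotations = NULL, gt = NULL),
    class = "vt_recording")
}

#' Load a recording from disk
#'
#' @param path WFDB record path (without extension) or a CSV file.
#' @param format `"wfdb"` or `"csv"`.
#' @return A `vt_recording`.
#' @export
load_recording <- function(path, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  switch(format,
    wfdb = {
      if (!file.exists(paste0(path, ".hea")))
        vt_abort("no WFDB header at ", path, ".hea")
      read_wfdb(path)
    },
    csv = {
      if (!file.exists(path)) vt_abort("no such file: ", path)
      read_recording_csv(path)
    })
}
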