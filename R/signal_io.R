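#' Construct a PPG recording
#'
#' Container for a single-channel photoplethysmogram plus an optional
#' per-beat noninvasive reference blood-pressure channel. All timestamps
#' are seconds from record start; sample 1 is time 0.
#'
#' @param ppg Numeric vector of PPG samples (arbitrary units, finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param subject Optional subject identifier (scalar, coerced to character).
#' @param ref_bp Optional reference blood pressure: a data frame with
#'   columns `time` (s), `sbp`, `dbp` (mmHg), one row per beat (or per
#'   second); must satisfy `sbp > dbp` row-wise.
#' @return An object of class `ppg_recording`.
#' @export
ppg_recording <- function(ppg, fs, subject = NULL, ref_bp = NULL) {
  if (!is.numeric(ppg) || length(ppg) == 0)
    stop("`ppg` must be a non-empty numeric vector")
  if (any(!is.finite(ppg)))
    stop("`ppg` contains non-finite samples (first at index ",
         which(!is.finite(ppg))[1], ")")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (!is.null(ref_bp)) {
    ref_bp <- as.data.frame(ref_bp)
    need <- c("time", "sbp", "dbp")
    if (!all(need %in% names(ref_bp)))
      stop("`ref_bp` must have columns time, sbp, dbp")
    ref_bp <- ref_bp[, need]
    if (any(ref_bp$sbp <= ref_bp$dbp))
      stop("`ref_bp` must satisfy sbp > dbp for every row")
  }
  structure(list(ppg = as.numeric(ppg), fs = fs,
                 subject = if (is.null(subject)) NA_character_ else as.character(subject),
                 ref_bp = ref_bp),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording> subject=%s  %d samples @ %g Hz (%.1f s)%s\n",
              x$subject, length(x$ppg), x$fs, length(x$ppg) / x$fs,
              if (is.null(x$ref_bp)) "" else
                sprintf("  ref BP: %d rows", nrow(x$ref_bp))))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `ppg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$ppg) / rec$fs

# full-precision decimal rendering that survives a text round trip
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a recording to delimited text
#'
#' Plain comma-separated text with `# key=value` header lines (keys:
#' `fs`, `subject`, `channels`). Waveform channels are one column each;
#' the optional reference BP channel is stored as `ref_time`, `ref_sbp`,
#' `ref_dbp` columns padded with empty fields (the reference is per beat,
#' so it is shorter than the waveform). Values are written with enough
#' digits that `read_recording()` reproduces them bit-exactly.
#'
#' @param rec A `ppg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (length(rec$ppg) == 0) stop("refusing to write an empty recording")
  if (any(!is.finite(rec$ppg))) stop("refusing to write non-finite samples")
  n <- length(rec$ppg)
  cols <- list(ppg = .fmt_num(rec$ppg))
  channels <- "ppg"
  if (!is.null(rec$ref_bp)) {
    m <- nrow(rec$ref_bp)
    if (m > n) stop("reference BP has more rows than the waveform")
    pad <- function(v) c(.fmt_num(v), rep("", n - m))
    cols$ref_time <- pad(rec$ref_bp$time)
    cols$ref_sbp  <- pad(rec$ref_bp$sbp)
    cols$ref_dbp  <- pad(rec$ref_bp$dbp)
    channels <- c(channels, "ref_time", "ref_sbp", "ref_dbp")
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%s", .fmt_num(rec$fs)),
               sprintf("# subject=%s", rec$subject),
               sprintf("# channels=%s", paste(channels, collapse = ","))), con)
  writeLines(paste(channels, collapse = ","), con)
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Input file path. The header must declare the sampling
#'   rate as a `# fs=<Hz>` line; non-numeric waveform fields are
#'   reported with their 1-based line numbers.
#' @return A `ppg_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$fs))
    stop("format error: header does not declare the sampling rate (`# fs=...`)")
  fs <- suppressWarnings(as.numeric(kv$fs))
  if (is.na(fs)) stop("format error: non-numeric fs in header")
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) < 2) stop("format error: no data rows")
  channels <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  rows <- strsplit(lines[body_idx[-1]], ",", fixed = TRUE)
  nr <- length(rows)
  mat <- matrix(NA_character_, nrow = nr, ncol = length(channels))
  for (i in seq_len(nr)) {
    r <- rows[[i]]
    length(r) <- length(channels)
    mat[i, ] <- r
  }
  num <- function(col, name, required) {
    raw <- mat[, col]
    blank <- is.na(raw) | raw == ""
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!blank & is.na(v))
    if (length(bad) > 0)
      stop(sprintf("format error: non-numeric value %s in column '%s' at line %d",
                   dQuote(raw[bad[1]]), name, body_idx[1] + bad[1]))
    if (required && any(blank))
      stop(sprintf("format error: missing value in column '%s' at line %d",
                   name, body_idx[1] + which(blank)[1]))
    v
  }
  if (!"ppg" %in% channels) stop("format error: no 'ppg' channel")
  ppg <- num(match("ppg", channels), "ppg", required = TRUE)
  ref_bp <- NULL
  if (all(c("ref_time", "ref_sbp", "ref_dbp") %in% channels)) {
    rt <- num(match("ref_time", channels), "ref_time", FALSE)
    keep <- !is.na(rt)
    ref_bp <- data.frame(time = rt[keep],
                         sbp = num(match("ref_sbp", channels), "ref_sbp", FALSE)[keep],
                         dbp = num(match("ref_dbp", channels), "ref_dbp", FALSE)[keep])
  }
  ppg_recording(ppg, fs, subject = kv$subject, ref_bp = ref_bp)
}

#' Read / write a run configuration file
#'
#' YAML key/value file holding the tunables of every stage; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a validated [run_config()] list.
#' @seealso [run_config()]
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()] list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
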