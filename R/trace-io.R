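#' Construct a uniformly sampled time-series trace
#'
#' The basic container for a single recorded channel. Voltage traces are in
#' mV, current traces in pA, extracellular traces in arbitrary units; time is
#' in seconds throughout the package.
#'
#' @param samples numeric vector of samples (mV, pA or a.u. depending on
#'   `signal_kind`).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param signal_kind one of `"voltage"`, `"current"`, `"extracellular"`.
#' @param start_time time of the first sample in seconds.
#' @return an object of class `ts_trace` with fields `samples`,
#'   `sampling_rate`, `signal_kind`, `start_time`.
#' @examples
#' tr <- ts_trace(sin(seq(0, 1, by = 1e-3)), 1000)
#' trace_duration(tr)
#' @export
ts_trace <- function(samples, sampling_rate,
                     signal_kind = c("voltage", "current", "extracellular"),
                     start_time = 0) {
  signal_kind <- match.arg(signal_kind)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(start_time, "start_time")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         signal_kind = signal_kind, start_time = start_time),
    class = "ts_trace")
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("<ts_trace> %s, %d samples @ %g Hz (%.4g s)\n",
              x$signal_kind, length(x$samples), x$sampling_rate,
              trace_duration(x)))
  invisible(x)
}

#' Duration and time axis of a trace
#' @param trace a [ts_trace()].
#' @return `trace_duration`: duration in seconds; `trace_times`: vector of
#'   sample times in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate

#' @rdname trace_duration
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1L) / trace$sampling_rate
}

#' Define a current-step stimulation protocol
#'
#' Describes an episodic protocol: each sweep holds the cell at
#' `holding_potential` and injects one square current step. Successive sweeps
#' use the amplitudes in `amplitudes` (for instance 0 to 800 pA in 50 pA
#' increments for the evoked-firing protocol, or -100 and -50 pA steps for
#' input-resistance estimation).
#'
#' @param amplitudes vector of step amplitudes in pA, one per sweep,
#'   strictly increasing.
#' @param onset step onset within the sweep, seconds.
#' @param duration step duration, seconds (> 0).
#' @param holding_potential holding potential in mV.
#' @param tail post-step recording time, seconds.
#' @return an object of class `step_protocol`.
#' @examples
#' step_protocol(seq(0, 800, by = 50))
#' @export
step_protocol <- function(amplitudes, onset = 0.1, duration = 1,
                          holding_potential = -80, tail = 0.2) {
  amplitudes <- as.numeric(amplitudes)
  if (!length(amplitudes) || anyNA(amplitudes))
    stop("'amplitudes' must be a non-empty numeric vector")
  if (is.unsorted(amplitudes, strictly = TRUE))
    stop("step amplitudes must be strictly increasing across sweeps")
  assert_scalar_num(onset, "onset", nonneg = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(tail, "tail", nonneg = TRUE)
  structure(
    list(amplitudes = amplitudes, onset = onset, duration = duration,
         holding_potential = holding_potential, tail = tail,
         sweep_count = length(amplitudes)),
    class = "step_protocol")
}

#' Bundle voltage sweeps with their stimulus protocol
#'
#' @param sweeps list of [ts_trace()] objects, one per sweep, all sharing a
#'   sampling rate, ordered by injected current.
#' @param injected_current numeric vector of injected currents in pA,
#'   parallel to `sweeps`.
#' @param protocol the [step_protocol()] that generated the sweeps.
#' @param junction_corrected has the liquid junction potential already been
#'   subtracted?
#' @return an object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, injected_current, protocol,
                      junction_corrected = FALSE) {
  if (!is.list(sweeps) || !length(sweeps))
    stop("'sweeps' must be a non-empty list of ts_trace objects")
  if (!all(vapply(sweeps, inherits, logical(1L), "ts_trace")))
    stop("every sweep must be a ts_trace")
  rates <- vapply(sweeps, `[[`, numeric(1L), "sampling_rate")
  if (length(unique(rates)) != 1L)
    stop("all sweeps must share one sampling rate")
  if (length(injected_current) != length(sweeps))
    stop("one injected current per sweep is required")
  if (is.unsorted(injected_current, strictly = TRUE))
    stop("sweeps must be ordered by strictly increasing injected current")
  if (!is_flag(junction_corrected))
    stop("'junction_corrected' must be TRUE or FALSE")
  structure(
    list(sweeps = sweeps, injected_current = as.numeric(injected_current),
         protocol = protocol, junction_corrected = junction_corrected,
         sampling_rate = rates[1L]),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %d sweeps @ %g Hz, currents %g..%g pA, junction_corrected=%s\n",
    length(x$sweeps), x$sampling_rate, min(x$injected_current),
    max(x$injected_current), x$junction_corrected))
  invisible(x)
}

#' Subtract the liquid junction potential from a sweep set
#'
#' Whole-cell voltages are offset by the liquid junction potential between
#' pipette and bath solutions; for the solutions used in the source
#' recordings this was previously calculated to be 10 mV. All reported
#' voltages in this package are post-correction. The operation is guarded
#' against double application.
#'
#' @param sweeps a [sweep_set()] with `junction_corrected = FALSE`.
#' @param jp junction potential in mV (default 10); every voltage sample is
#'   shifted by `-jp`.
#' @return the corrected `sweep_set` with `junction_corrected = TRUE`.
#' @export
correct_junction_potential <- function(sweeps, jp = 10) {
  if (!inherits(sweeps, "sweep_set")) stop("'sweeps' must be a sweep_set")
  assert_scalar_num(jp, "jp")
  if (isTRUE(sweeps$junction_corrected))
    stop("junction potential already corrected; refusing to apply twice")
  sweeps$sweeps <- lapply(sweeps$sweeps, function(tr) {
    if (tr$signal_kind == "voltage") tr$samples <- tr$samples - jp
    tr
  })
  if (!is.null(sweeps$protocol))
    sweeps$protocol$holding_potential <-
      sweeps$protocol$holding_potential - jp
  sweeps$junction_corrected <- TRUE
  sweeps
}

# ---------------------------------------------------------------------------
# Delimited sweep format: '#'-prefixed header lines carry metadata, then a
# header row and one time column plus one column per sweep. Units are s, mV
# (or pA / a.u.), pA for injected currents.

#' Write a sweep set to disk
#'
#' Two formats are supported: `"delimited"`, a plain-text dialect with
#' `#`-prefixed header lines carrying the sampling rate and injected
#' currents, a first column of time in seconds and one column per sweep; and
#' `"rds"`, a lossless binary container (serialized R object).
#'
#' @param sweeps a [sweep_set()].
#' @param path output file path.
#' @param format `"delimited"` or `"rds"`.
#' @return `path`, invisibly.
#' @seealso [read_sweeps()]
#' @export
write_sweeps <- function(sweeps, path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  if (!inherits(sweeps, "sweep_set")) stop("'sweeps' must be a sweep_set")
  if (format == "rds") {
    saveRDS(sweeps, path)
    return(invisible(path))
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot open '%s' for writing", path))
  on.exit(close(con))
  kinds <- vapply(sweeps$sweeps, `[[`, character(1L), "signal_kind")
  writeLines(c(
    sprintf("# sampling_rate_hz: %.15g", sweeps$sampling_rate),
    sprintf("# injected_current_pa: %s",
            paste(format(sweeps$injected_current, digits = 15),
                  collapse = " ")),
    sprintf("# signal_kind: %s", kinds[1L]),
    sprintf("# junction_corrected: %s", sweeps$junction_corrected),
    sprintf("# holding_potential_mv: %.15g",
            sweeps$protocol$holding_potential),
    sprintf("# step_onset_s: %.15g", sweeps$protocol$onset),
    sprintf("# step_duration_s: %.15g", sweeps$protocol$duration)
  ), con)
  mat <- vapply(sweeps$sweeps, `[[`, numeric(length(sweeps$sweeps[[1L]]$samples)),
                "samples")
  mat <- cbind(time = trace_times(sweeps$sweeps[[1L]]), mat)
  colnames(mat) <- c("time_s", sprintf("sweep%02d", seq_along(sweeps$sweeps)))
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sweep set from disk
#'
#' @param path input file path.
#' @param format `"delimited"` or `"rds"` (see [write_sweeps()]). ABF
#'   (Axon Binary Format) files must be converted to one of these formats
#'   first; requesting `"abf"` raises an informative error.
#' @return a [sweep_set()].
#' @export
read_sweeps <- function(path, format = c("delimited", "rds", "abf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "abf")
    stop("ABF reading is not available; supported formats: ",
         "'delimited', 'rds'. Convert ABF files to the delimited dialect ",
         "with an external tool first.")
  if (format == "rds") {
    obj <- readRDS(path)
    if (!inherits(obj, "sweep_set"))
      stop(sprintf("'%s' does not contain a sweep_set", path))
    return(obj)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("missing header field '%s' in '%s'", key, path))
    trimws(sub(paste0("^# ", key, ":"), "", m[1L]))
  }
  fs <- as.numeric(get_field("sampling_rate_hz"))
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in header")
  currents <- as.numeric(strsplit(get_field("injected_current_pa"), "\\s+")[[1L]])
  kind <- get_field("signal_kind")
  jc <- as.logical(get_field("junction_corrected"))
  hold <- as.numeric(get_field("holding_potential_mv"))
  onset <- as.numeric(get_field("step_onset_s"))
  dur <- as.numeric(get_field("step_duration_s"))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop(sprintf("truncated sweep file: '%s'", path))
  ncol_expect <- length(strsplit(body[1L], "\t")[[1L]])
  dat <- utils::read.table(text = body[-1L], sep = "\t",
                           colClasses = "numeric")
  if (ncol(dat) != ncol_expect || ncol(dat) != length(currents) + 1L)
    stop(sprintf("corrupt sweep file '%s': column count mismatch", path))
  if (anyNA(dat)) stop(sprintf("corrupt sweep file '%s': non-numeric data", path))
  tt <- dat[[1L]]
  if (length(tt) > 2L) {
    dts <- diff(tt)
    if (max(abs(dts - dts[1L])) > 1e-6 * dts[1L])
      stop("non-uniform sampling detected; only uniformly sampled sweeps are supported")
  }
  n_tail <- max(0, length(tt) / fs - onset - dur)
  proto <- step_protocol(currents, onset = onset, duration = dur,
                         holding_potential = hold, tail = n_tail)
  sweeps <- lapply(seq_along(currents), function(i) {
    ts_trace(dat[[i + 1L]], fs, signal_kind = kind, start_time = tt[1L])
  })
  sweep_set(sweeps, currents, proto, junction_corrected = jc)
}
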