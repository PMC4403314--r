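#' Read and write spike-train files
#'
#' The plain-text spike-train format: `#` starts a comment line, a header
#' comment `# T_ms=<float>` carries the window duration, and every other line
#' is one spike train given as whitespace-separated times in ms (an empty
#' line is an empty train).  When the header is absent, `T` is the maximum
#' time rounded up to the next integer.
#'
#' @param path file path.
#' @return `read_spike_trains()` returns a [trial_set()].
#' @export
read_spike_trains <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  T <- NA_real_
  m <- regmatches(lines, regexpr("^#\\s*T_ms\\s*=\\s*([0-9.eE+-]+)", lines))
  if (length(m)) T <- as.numeric(sub("^#\\s*T_ms\\s*=\\s*", "", m[[1]]))
  body <- which(!grepl("^#", lines))
  trains <- vector("list", length(body))
  for (k in seq_along(body)) {
    i <- body[k]
    txt <- trimws(lines[i])
    times <- if (nzchar(txt)) as.numeric(strsplit(txt, "\\s+")[[1]]) else numeric(0)
    if (anyNA(times))
      stopf("line %d: non-numeric spike time", i)
    if (any(times < 0))
      stopf("line %d: negative spike time", i)
    if (is.unsorted(times))
      stopf("line %d: spike times not sorted ascending", i)
    trains[[k]] <- times
  }
  if (is.na(T)) {
    mx <- suppressWarnings(max(c(0, unlist(trains))))
    T <- ceiling(mx)
  }
  trial_set(lapply(trains, spike_train, T = T), stimulus_id = basename(path))
}

#' @rdname read_spike_trains
#' @param trials a [trial_set()] or single [spike_train()].
#' @export
write_spike_trains <- function(trials, path) {
  if (is_spike_train(trials)) trials <- trial_set(list(trials))
  stopifnot(inherits(trials, "trial_set"))
  lines <- c(sprintf("# T_ms=%.10f", trials$T),
             vapply(trials$trains, function(tr)
               paste(sprintf("%.10f", tr$times), collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write sampled traces as two-column CSV
#'
#' Format: header `t_ms,value`, then one row per sample.  The time column
#' must be uniformly spaced.
#'
#' @param path file path.
#' @param unit unit label attached on read.
#' @return `read_trace()` returns a [sampled_trace()].
#' @export
read_trace <- function(path, unit = "") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.csv(path)
  if (ncol(d) < 2) stopf("trace file needs columns t_ms,value: %s", path)
  t <- d[[1]]; v <- d[[2]]
  if (length(t) < 2) stopf("trace too short: %s", path)
  dts <- diff(t)
  if (diff(range(dts)) > 1e-6 * mean(dts)) stopf("trace time grid is not uniform: %s", path)
  sampled_trace(v, dt = mean(dts), t0 = t[1], unit = unit)
}

#' @rdname read_trace
#' @param x a [sampled_trace()].
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "sampled_trace"))
  d <- data.frame(t_ms = trace_times(x), value = x$values)
  write.csv(format(d, digits = 12, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# delimited matrix files for spectrograms and STRFs:
# rows = frequency bands (low -> high), columns = time/lag bins (first bin
# first), `#` header lines carry the bin width and band edges.

write_matrix_file <- function(values, path, bin_ms, band_edges, kind) {
  lines <- c(sprintf("# kind=%s", kind),
             sprintf("# bin_ms=%.10g", bin_ms),
             sprintf("# band_edges_hz=%s", paste(sprintf("%.10g", band_edges), collapse = ",")),
             apply(values, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  get <- function(key) {
    m <- hdr[grepl(paste0("^#\\s*", key, "\\s*="), hdr)]
    if (!length(m)) return(NULL)
    sub(paste0("^#\\s*", key, "\\s*="), "", m[[1]])
  }
  values <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  list(values = values,
       bin_ms = as.numeric(get("bin_ms") %||% "1"),
       band_edges = as.numeric(strsplit(get("band_edges_hz") %||% "", ",")[[1]]),
       kind = get("kind"))
}

#' Read and write spectrogram and STRF matrix files
#'
#' Delimited text: rows are frequency bands (low to high), columns time or
#' lag bins (lag 0 first); `#` header lines carry the bin width and band
#' edges.
#'
#' @param path file path.
#' @return [spectrogram()] or [strf_kernel()] objects respectively.
#' @export
read_spectrogram <- function(path) {
  m <- read_matrix_file(path)
  spectrogram(m$values, bin_ms = m$bin_ms, band_edges = m$band_edges)
}

#' @rdname read_spectrogram
#' @param s a [spectrogram()].
#' @export
write_spectrogram <- function(s, path) {
  write_matrix_file(s$values, path, s$bin_ms, s$band_edges, "spectrogram")
}

#' @rdname read_spectrogram
#' @export
read_strf <- function(path) {
  m <- read_matrix_file(path)
  strf_kernel(m$values, lag_ms = m$bin_ms, band_edges = m$band_edges)
}

#' @rdname read_spectrogram
#' @param h a [strf_kernel()].
#' @export
write_strf <- function(h, path) {
  write_matrix_file(h$values, path, h$lag_ms, h$band_edges, "strf")
}

#' Read and write neuron parameter sets as YAML
#'
#' @param path file path.
#' @return `read_parameter_set()` returns a [parameter_set()].
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(parameter_set, c(list(model = y$model), y$parameters))
}

#' @rdname read_parameter_set
#' @param ps a [parameter_set()].
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  yaml::write_yaml(list(model = ps$model, parameters = as.list(ps$values)), path)
  invisible(path)
}
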