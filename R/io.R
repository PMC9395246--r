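#' Parameter presets
#'
#' `preset_s1()` ships the calibrated defaults for awake mouse
#' somatosensory cortex (delta band [2, 4] Hz, 42.2-ms smoothing,
#' alpha = 2.87). `preset_v1()` adapts them to mouse visual cortex /
#' Neuropixels sessions, where the delta oscillation sits higher: delta
#' band [4, 8] Hz, 30-ms smoothing, alpha = 3.07.
#'
#' @return A list with elements `plfp` ([plfp_params()]) and `nsi`
#'   ([nsi_params()]).
#' @export
preset_s1 <- function() {
  list(plfp = plfp_params(), nsi = nsi_params())
}

#' @rdname preset_s1
#' @export
preset_v1 <- function() {
  list(plfp = plfp_params(T_smoothing = 0.030),
       nsi = nsi_params(alpha = 3.07, delta_band = c(4, 8)))
}

infer_units <- function(colname, default = "uV") {
  m <- regmatches(colname, regexpr("_[A-Za-z]+$", colname))
  if (length(m) == 1L && nzchar(m)) sub("^_", "", m) else default
}

#' Read a time series from disk
#'
#' Supported formats: two-column delimited text (`t_s`, `value_<units>`;
#' comma-separated, header row, times in seconds) and a flat little-endian
#' float64 binary array with a `<path>.yaml` sidecar holding `rate`, `t0`,
#' `units` and `n`. The sampling rate of a CSV is inferred from the time
#' column, which must be uniform to within 1e-6 relative jitter. NWB
#' container reading is not supported in this build and raises a
#' descriptive error.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"bin"` or `"nwb"`.
#' @param units Unit label override; by default parsed from the value
#'   column's `_<units>` suffix (CSV) or the sidecar (binary).
#' @return An [timeseries()].
#' @export
read_timeseries <- function(path, format = c("auto", "csv", "bin", "nwb"),
                            units = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "csv", bin = "bin", dat = "bin",
                     nwb = "nwb",
                     stop("unknown format for extension '", ext, "'",
                          call. = FALSE))
  }
  if (format == "nwb")
    stop("NWB reading is not supported in this build; convert the LFP ",
         "electrical series to CSV or flat binary + sidecar upstream",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "csv") {
    d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    if (ncol(d) < 2L) stop("expected two columns (time, value)",
                           call. = FALSE)
    tcol <- d[[1]]
    if (length(tcol) < 2L) stop("need at least two samples", call. = FALSE)
    dt <- diff(tcol)
    dt0 <- stats::median(dt)
    if (max(abs(dt - dt0)) > 1e-6 * dt0 + 1e-12)
      stop("non-uniform timestamps (relative jitter beyond 1e-6)",
           call. = FALSE)
    timeseries(d[[2]], rate = 1 / dt0, t0 = tcol[1],
               units = units %||% infer_units(names(d)[2]))
  } else {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("missing sidecar metadata file: ", sidecar, call. = FALSE)
    meta <- yaml::read_yaml(sidecar)
    for (k in c("n", "rate")) if (is.null(meta[[k]]))
      stop("sidecar missing required field '", k, "'", call. = FALSE)
    v <- readBin(path, what = "double", n = meta$n, size = 8,
                 endian = "little")
    timeseries(v, rate = meta$rate, t0 = meta$t0 %||% 0,
               units = units %||% meta$units %||% "uV")
  }
}

#' Write a time series to disk
#'
#' @param x An [timeseries()].
#' @param path Destination; `.csv` gives two-column text with a `t_s` and a
#'   `value_<units>` column, anything else a flat float64 binary array with
#'   a `<path>.yaml` sidecar.
#' @param format `"auto"`, `"csv"` or `"bin"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, format = c("auto", "csv", "bin")) {
  stopifnot(inherits(x, "nsi_ts"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) %in% c("csv", "tsv"))
      "csv" else "bin"
  if (format == "csv") {
    d <- tibble::tibble(t_s = ts_times(x), value = x$samples)
    names(d)[2] <- paste0("value_", x$units)
    readr::write_csv(d, path)
  } else {
    writeBin(as.double(x$samples), path, size = 8, endian = "little")
    yaml::write_yaml(list(n = length(x$samples), rate = x$rate, t0 = x$t0,
                          units = x$units), paste0(path, ".yaml"))
  }
  invisible(path)
}

params_provenance <- function(...) {
  ps <- list(...)
  lines <- character()
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (is.null(p)) next
    if (inherits(p, c("plfp_params", "nsi_params"))) p <- unclass(p)
    if (is.list(p)) {
      for (k in names(p)) {
        v <- p[[k]]
        if (is.null(v)) v <- "default(p0)"
        lines <- c(lines, sprintf("# %s.%s: %s", nm, k,
                                  paste(format(v), collapse = " ")))
      }
    } else lines <- c(lines, sprintf("# %s: %s", nm, format(p)))
  }
  lines
}

#' Write / read an episode table as TSV
#'
#' Tab-separated columns `t_center_s`, `nsi_<units>`, `label`, `validated`,
#' preceded by a `#`-commented provenance block holding the parameters and
#' noise floor that produced the table.
#'
#' @param episodes An [validate_episodes()] table.
#' @param path Destination TSV path.
#' @return `path` invisibly (writer); an `nsi_episodes` tibble (reader).
#' @export
write_episodes <- function(episodes, path) {
  units <- attr(episodes, "units") %||% "uV"
  hdr <- params_provenance(nsi = attr(episodes, "params"),
                           p0 = attr(episodes, "p0"),
                           recording_id = attr(episodes, "recording_id"))
  body <- paste(sprintf("%.6f", episodes$t_center),
                ifelse(is.na(episodes$nsi), "NA",
                       sprintf("%.9g", episodes$nsi)),
                episodes$label, episodes$validated, sep = "\t")
  writeLines(c(hdr,
               paste(c("t_center_s", paste0("nsi_", units), "label",
                       "validated"), collapse = "\t"),
               body), path)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  d <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  units <- infer_units(names(d)[2], default = "uV")
  out <- tibble::tibble(t_center = d[[1]], nsi = d[[2]],
                        label = d[[3]], validated = as.logical(d[[4]]))
  attr(out, "units") <- units
  class(out) <- c("nsi_episodes", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
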