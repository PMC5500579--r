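#' Uniformly sampled position time series
#'
#' The container all estimators consume: an ordered vector of positions with
#' a single sampling interval `dt` and a unit label. Values must be finite
#' and at least two samples long.
#'
#' @param values numeric vector of positions.
#' @param dt sampling interval (seconds, or simulation time units).
#' @param unit one of `"sim-unit"`, `"volt"`, `"metre"`.
#' @param meta free-form provenance list (seed, source file, model, ...).
#' @return An object of class `ot_timeseries` with fields `values`, `dt`,
#'   `n`, `unit`, `meta`.
#' @export
time_series <- function(values, dt, unit = c("sim-unit", "volt", "metre"),
                        meta = list()) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  stopifnot(is.numeric(dt), length(dt) == 1L)
  if (!is.finite(dt) || dt <= 0) stop("dt must be a single positive number")
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("all values must be finite")
  structure(list(values = values, dt = dt, n = length(values),
                 unit = unit, meta = meta),
            class = "ot_timeseries")
}

#' @export
print.ot_timeseries <- function(x, ...) {
  cat(sprintf("Time series: %d samples at dt = %g (%s), mean %.4g, sd %.4g\n",
              x$n, x$dt, x$unit, mean(x$values), sd(x$values)))
  if (!is.null(x$meta$seed)) cat(sprintf("  seed: %d\n", x$meta$seed))
  invisible(x)
}

#' Write a time series to disk
#'
#' Two on-disk forms are supported:
#' * `"text"`: one value per line, preceded by `#`-prefixed header lines
#'   carrying `dt`, `unit` and, when present, the generator seed;
#' * `"binary"`: raw little-endian 64-bit floats, with the same header
#'   written to a plain-text sidecar file `<path>.hdr`.
#'
#' Both forms round-trip values, `dt` and `unit` exactly.
#'
#' @param ts a [time_series()].
#' @param path output file path.
#' @param format `"text"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, format = c("text", "binary")) {
  stopifnot(inherits(ts, "ot_timeseries"))
  format <- match.arg(format)
  hdr <- c(sprintf("# dt=%.17g", ts$dt), sprintf("# unit=%s", ts$unit))
  if (!is.null(ts$meta$seed)) hdr <- c(hdr, sprintf("# seed=%d", ts$meta$seed))
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g", ts$values), con)
  } else {
    writeBin(ts$values, path, size = 8, endian = "little")
    writeLines(c(hdr, sprintf("# n=%d", ts$n)), paste0(path, ".hdr"))
  }
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  kv <- strsplit(kv, "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2L) out[[trimws(p[1])]] <- trimws(p[2])
  out
}

#' Read a time series from disk
#'
#' Accepts the two formats written by [write_timeseries()] plus two-column
#' delimited text `(time, value)`, for which the time column must be
#' uniformly spaced to a relative tolerance of `1e-6` (otherwise the read is
#' rejected and the measured jitter reported). A `dt` given both in the file
#' header and as an argument must agree; conflicting declarations are an
#' error rather than silently resolved.
#'
#' @param path input file.
#' @param format `"auto"` (binary when `<path>.hdr` exists, else text),
#'   `"text"` or `"binary"`.
#' @param dt sampling interval; required when the file does not declare one.
#' @param unit unit label; overrides nothing, used when the file has none.
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, format = c("auto", "text", "binary"),
                            dt = NULL, unit = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(paste0(path, ".hdr"))) "binary" else "text"
  if (format == "binary") {
    hdr <- .parse_header(readLines(paste0(path, ".hdr")))
    nbytes <- file.size(path)
    values <- readBin(path, "double", n = nbytes %/% 8, size = 8,
                      endian = "little")
    t_col <- NULL
  } else {
    lines <- readLines(path)
    is_hdr <- startsWith(lines, "#")
    hdr <- .parse_header(lines[is_hdr])
    body <- lines[!is_hdr & nzchar(trimws(lines))]
    fields <- strsplit(trimws(body), "[,;[:space:]]+")
    ncol <- lengths(fields)
    if (any(ncol != ncol[1]))
      stop(sprintf("malformed row at line %d: expected %d column(s)",
                   which(!is_hdr & nzchar(trimws(lines)))[which(ncol != ncol[1])[1]],
                   ncol[1]))
    num <- suppressWarnings(lapply(fields, as.numeric))
    bad <- vapply(num, function(v) any(is.na(v)), logical(1))
    if (any(bad))
      stop(sprintf("malformed row at line %d: non-numeric field",
                   which(!is_hdr & nzchar(trimws(lines)))[which(bad)[1]]))
    mat <- do.call(rbind, num)
    if (ncol[1] == 1L) {
      values <- mat[, 1]; t_col <- NULL
    } else if (ncol[1] == 2L) {
      t_col <- mat[, 1]; values <- mat[, 2]
    } else stop("expected one or two columns, got ", ncol[1])
  }
  hdr_dt <- if (!is.null(hdr$dt)) as.numeric(hdr$dt) else NULL
  if (!is.null(t_col)) {
    steps <- diff(t_col)
    jitter <- (max(steps) - min(steps)) / median(steps)
    if (!is.finite(jitter) || jitter > 1e-6)
      stop(sprintf("time column is not uniformly spaced: relative jitter %.3g (tolerance 1e-6)",
                   jitter))
    t_dt <- median(steps)
    if (!is.null(hdr_dt) && abs(hdr_dt - t_dt) > 1e-6 * t_dt)
      stop("header dt conflicts with the time column spacing")
    hdr_dt <- t_dt
  }
  if (!is.null(hdr_dt) && !is.null(dt) && abs(hdr_dt - dt) > 1e-9 * hdr_dt)
    stop(sprintf("dt declared in file (%g) conflicts with dt argument (%g); resolve explicitly",
                 hdr_dt, dt))
  dt <- if (!is.null(hdr_dt)) hdr_dt else dt
  if (is.null(dt)) stop("no dt declared in file; pass dt explicitly")
  unit <- if (!is.null(hdr$unit)) hdr$unit else if (!is.null(unit)) unit else "sim-unit"
  meta <- list(source = path)
  if (!is.null(hdr$seed)) meta$seed <- as.integer(hdr$seed)
  time_series(values, dt = dt, unit = unit, meta = meta)
}
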