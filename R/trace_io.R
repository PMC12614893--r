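#' Read and write dipolar traces
#'
#' Two on-disk dialects are supported. `"ascii"` is whitespace-delimited
#' columns `time_ns real [imag]` with `#` comment lines and an optional JSON
#' sidecar `<path>.json` holding acquisition metadata and the condition
#' label. `"bruker"` is a BES3T descriptor/data pair (`.DSC` text descriptor
#' plus `.DTA` big-endian float64 data, real or interleaved complex), the
#' format written by ELEXSYS spectrometers.
#'
#' @param path File path. For the Bruker dialect either member of the
#'   `.DSC`/`.DTA` pair may be given.
#' @param dialect `"ascii"` or `"bruker"`.
#' @return A [dipolar_trace()].
#' @export
load_trace <- function(path, dialect = c("ascii", "bruker")) {
  dialect <- match.arg(dialect)
  if (dialect == "ascii") load_trace_ascii(path) else load_trace_bruker(path)
}

load_trace_ascii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least two columns (time_ns, real)")
  acq <- NULL; label <- ""
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    label <- meta$label %||% ""
    if (!is.null(meta$acq)) acq <- do.call(acquisition_params, meta$acq)
  }
  dipolar_trace(tab[[1]], tab[[2]],
                imag = if (ncol(tab) >= 3) tab[[3]],
                acq = acq, label = label, normalise = FALSE)
}

#' @rdname load_trace
#' @param trace A [dipolar_trace()].
#' @param digits Significant digits written (ASCII dialect).
#' @export
write_trace <- function(trace, path, dialect = c("ascii", "bruker"),
                        digits = 10) {
  stopifnot(inherits(trace, "dipolar_trace"))
  dialect <- match.arg(dialect)
  if (dialect == "ascii") {
    cols <- cbind(trace$time, trace$real)
    if (!is.null(trace$imag)) cols <- cbind(cols, trace$imag)
    hdr <- c("# dipolar trace: time_ns real" ,
             if (!is.null(trace$imag)) "# third column: imag")
    writeLines(c(hdr, apply(signif(cols, digits), 1, paste, collapse = " ")),
               path)
    meta <- list(label = trace$label, acq = unclass(trace$acq))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_trace_bruker(trace, path)
  }
  invisible(path)
}

bruker_pair <- function(path) {
  base <- sub("\\.(DSC|DTA|dsc|dta)$", "", path)
  list(dsc = paste0(base, ".DSC"), dta = paste0(base, ".DTA"))
}

write_trace_bruker <- function(trace, path) {
  pair <- bruker_pair(path)
  cplx <- !is.null(trace$imag)
  n <- length(trace$time)
  dsc <- c(
    "#DESC	1.2 * DESCRIPTOR INFORMATION ***********************",
    "DSRC	EXP",
    "BSEQ	BIG",
    "IKKF	" %+% if (cplx) "CPLX" else "REAL",
    "XTYP	IDX",
    "IRFMT	D",
    if (cplx) "IIFMT	D",
    sprintf("XPTS	%d", n),
    sprintf("XMIN	%.6f", trace$time[1]),
    sprintf("XWID	%.6f", trace$time[n] - trace$time[1]),
    "XUNI	'ns'",
    sprintf("TITL	'%s'", trace$label))
  writeLines(dsc, pair$dsc)
  con <- file(pair$dta, "wb")
  on.exit(close(con))
  if (cplx) {
    inter <- as.vector(rbind(trace$real, trace$imag))
    writeBin(inter, con, size = 8, endian = "big")
  } else {
    writeBin(trace$real, con, size = 8, endian = "big")
  }
  invisible(path)
}

load_trace_bruker <- function(path) {
  pair <- bruker_pair(path)
  if (!file.exists(pair$dsc))
    stop("missing Bruker descriptor file: ", pair$dsc)
  if (!file.exists(pair$dta))
    stop("missing Bruker data file: ", pair$dta)
  lines <- readLines(pair$dsc, warn = FALSE)
  getkw <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^", key, "[ \t]+"), "", hit[1]))
  }
  npts <- as.integer(getkw("XPTS"))
  xmin <- as.numeric(getkw("XMIN", 0))
  xwid <- as.numeric(getkw("XWID"))
  cplx <- identical(getkw("IKKF", "REAL"), "CPLX")
  if (is.na(npts) || is.na(xwid)) stop("malformed BES3T descriptor")
  label <- gsub("'", "", getkw("TITL", ""))
  con <- file(pair$dta, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = npts * (1L + cplx), size = 8,
                  endian = "big")
  time <- xmin + xwid * (seq_len(npts) - 1) / (npts - 1)
  if (cplx) {
    dipolar_trace(time, vals[seq(1, 2 * npts, by = 2)],
                  imag = vals[seq(2, 2 * npts, by = 2)],
                  label = label, normalise = FALSE)
  } else {
    dipolar_trace(time, vals, label = label, normalise = FALSE)
  }
}

`%+%` <- function(a, b) paste0(a, b)
`%||%` <- function(a, b) if (is.null(a)) b else a
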