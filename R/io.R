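#' Read and write kinetic traces as annotated delimited text
#'
#' The on-disk format is two whitespace-delimited columns (`time_s`,
#' `signal`) preceded by `#`-prefixed `key: value` metadata lines
#' (`temperature_K`, `co_atm`, `co_molar`, `phi`, `protein_molar`, `mode`,
#' `sigma`, ...).  Unknown metadata keys are preserved verbatim on read
#' (with a warning), so headers round-trip losslessly.
#'
#' @param path file path.
#' @return `read_trace()` returns a [kinetic_trace()] with a `conditions`
#'   attribute rebuilt from the header (when the header carries one);
#'   `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  dat <- utils::read.table(text = body, col.names = c("time", "signal"),
                           colClasses = "numeric")
  bad <- which(diff(dat$time) <= 0)
  if (length(bad))
    stop(sprintf("non-monotonic time column at data line %d of %s",
                 bad[1] + 1L, path))
  known <- c("temperature_K", "co_atm", "co_molar", "phi", "protein_molar",
             "mode", "pseudo_first_order", "sigma", "henry_molar_per_atm",
             "seed")
  extra <- setdiff(names(meta), known)
  if (length(extra))
    warning("unknown metadata keys preserved: ", paste(extra, collapse = ", "))
  cond <- NULL
  if (!is.null(meta$mode)) {
    cond <- conditions(
      temperature_K = as.numeric(meta$temperature_K %||% 293.15),
      co_molar = if (is.null(meta$co_molar)) NULL else as.numeric(meta$co_molar),
      co_atm = if (is.null(meta$co_molar) && !is.null(meta$co_atm))
        as.numeric(meta$co_atm) else NULL,
      phi = as.numeric(meta$phi %||% 1),
      protein_molar = as.numeric(meta$protein_molar %||% 50e-6),
      mode = meta$mode,
      pseudo_first_order = if (is.null(meta$pseudo_first_order)) NULL
        else as.logical(meta$pseudo_first_order))
    if (!is.null(meta$co_atm)) cond$co_atm <- as.numeric(meta$co_atm)
  }
  tr <- kinetic_trace(dat$time, dat$signal, conditions = cond,
                      sigma = if (is.null(meta$sigma)) NULL
                              else as.numeric(meta$sigma))
  attr(tr, "meta") <- meta
  tr
}

#' @rdname read_trace
#' @param trace a [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  cond <- attr(trace, "conditions")
  meta <- attr(trace, "meta")
  hdr <- character()
  if (!is.null(cond)) {
    hdr <- c(hdr,
      sprintf("# temperature_K: %.10g", cond$temperature_K),
      if (!is.null(cond$co_atm)) sprintf("# co_atm: %.10g", cond$co_atm),
      sprintf("# co_molar: %.10g", cond$co_molar),
      sprintf("# phi: %.10g", cond$phi),
      sprintf("# protein_molar: %.10g", cond$protein_molar),
      sprintf("# mode: %s", cond$mode),
      sprintf("# pseudo_first_order: %s", cond$pseudo_first_order))
  }
  if (!is.null(attr(trace, "sigma")))
    hdr <- c(hdr, sprintf("# sigma: %.10g", attr(trace, "sigma")))
  if (!is.null(meta)) {
    covered <- c("temperature_K", "co_atm", "co_molar", "phi",
                 "protein_molar", "mode", "pseudo_first_order", "sigma")
    for (nm in setdiff(names(meta), covered))
      hdr <- c(hdr, sprintf("# %s: %s", nm, meta[[nm]]))
  }
  body <- sprintf("%.17g %.17g", trace$time, trace$signal)
  writeLines(c(hdr, body), path)
  invisible(path)
}

parse_meta <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed metadata header line: ", lines[bad][1])
  stats::setNames(lapply(kv, `[`, 3L), trimws(vapply(kv, `[`, "", 2L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write difference-spectra matrices
#'
#' Delimited text layout: optional `#` metadata header; first data row
#' holds the delays (s) preceded by a placeholder 0; each subsequent row is
#' a wavelength (nm) followed by the difference absorbances at every delay.
#'
#' @param path file path.
#' @return `read_spectra()` returns a [spectra_set()]; `write_spectra()`
#'   returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- parse_meta(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  m <- as.matrix(utils::read.table(text = body))
  delays <- as.numeric(m[1, -1])
  wavelengths <- as.numeric(m[-1, 1])
  dA <- unname(m[-1, -1, drop = FALSE])
  spectra_set(wavelengths, delays, dA,
              sigma = if (is.null(meta$sigma)) NULL
                      else as.numeric(meta$sigma))
}

#' @rdname read_spectra
#' @param spectra a [spectra_set()].
#' @export
write_spectra <- function(spectra, path) {
  hdr <- character()
  if (!is.null(spectra$sigma))
    hdr <- sprintf("# sigma: %.10g", spectra$sigma)
  top <- paste(c("0", sprintf("%.17g", spectra$delays)), collapse = " ")
  rows <- vapply(seq_along(spectra$wavelengths), function(i) {
    paste(c(sprintf("%.6f", spectra$wavelengths[i]),
            sprintf("%.17g", spectra$dA[i, ])), collapse = " ")
  }, "")
  writeLines(c(hdr, top, rows), path)
  invisible(path)
}
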