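# Columnar text I/O for spectrum sets.
#
# Format: a plain TSV with comment headers. Each Q block starts with a line
# `# q=<value>`; data lines carry `energy_meV  intensity  sigma`. Optional
# file-level headers: `# label: <text>` and
# `# resolution: gaussian fwhm_meV=<value>`. Human-readable and diff-able.

#' Write a spectrum set to a TSV file
#'
#' @param spectra a [as_qens_spectra()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(spectra, path) {
  spectra <- as_qens_spectra(spectra)
  res <- attr(spectra, "resolution")
  lab <- attr(spectra, "label")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# qenscell spectrum set", con)
  if (!is.null(lab)) writeLines(paste0("# label: ", lab), con)
  if (!is.null(res) && res$kind == "gaussian") {
    writeLines(sprintf("# resolution: gaussian fwhm_meV=%.10g", res$fwhm_meV), con)
  }
  for (qv in spectra_q_values(spectra)) {
    sl <- spectra[spectra$q == qv, ]
    writeLines(sprintf("# q=%.10g", qv), con)
    writeLines(sprintf("%.10g\t%.10g\t%.10g",
                       sl$energy_meV, sl$intensity, sl$sigma), con)
  }
  invisible(path)
}

#' Read a spectrum set from a TSV file
#'
#' Parses the block format written by [write_spectrum_set()]: `# q=<value>`
#' headers followed by `energy_meV intensity sigma` rows. Every slice is
#' validated (strictly increasing common grid, positive uncertainties);
#' malformed rows raise an error naming the line.
#'
#' @param path input file.
#' @param resolution the instrument resolution to attach: a
#'   `qens_resolution`, a single number (Gaussian FWHM in meV), or `NULL` to
#'   use a `# resolution:` header found in the file.
#' @return a [as_qens_spectra()] tibble.
#' @export
read_spectrum_set <- function(path, resolution = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (is.numeric(resolution)) resolution <- resolution_gaussian(resolution)

  label <- NULL
  q_cur <- NA_real_
  rows <- vector("list", length(lines))
  nrows <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl("^q\\s*=", body)) {
        q_cur <- suppressWarnings(as.numeric(sub("^q\\s*=\\s*", "", body)))
        if (!is.finite(q_cur)) abort(sprintf("line %d: unparseable q header.", i))
      } else if (grepl("^label:", body)) {
        label <- trimws(sub("^label:", "", body))
      } else if (grepl("^resolution:", body) && is.null(resolution)) {
        m <- regmatches(body, regexec("fwhm_meV=([0-9.eE+-]+)", body))[[1]]
        if (length(m) == 2) resolution <- resolution_gaussian(as.numeric(m[2]))
      }
      next
    }
    if (!is.finite(q_cur)) {
      abort(sprintf("line %d: data before any '# q=' header.", i))
    }
    parts <- strsplit(ln, "[\t ]+")[[1]]
    if (length(parts) != 3) {
      abort(sprintf("line %d: expected 3 columns (energy, intensity, sigma), got %d.",
                    i, length(parts)))
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (any(!is.finite(vals))) abort(sprintf("line %d: non-numeric value.", i))
    if (vals[3] <= 0) abort(sprintf("line %d: sigma must be positive.", i))
    if (vals[2] < 0) abort(sprintf("line %d: intensity must be non-negative.", i))
    nrows <- nrows + 1L
    rows[[nrows]] <- c(q_cur, vals)
  }
  if (!nrows) abort("No data rows found.")
  m <- do.call(rbind, rows[seq_len(nrows)])
  out <- tibble(q = m[, 1], energy_meV = m[, 2], intensity = m[, 3], sigma = m[, 4])
  as_qens_spectra(out, resolution = resolution, label = label)
}

#' Read a tabulated resolution curve
#'
#' Two-column TSV (energy in meV, density); comment lines starting with `#`
#' are skipped. The curve is renormalized to unit area.
#'
#' @param path input file.
#' @return a [resolution_tabulated()] object.
#' @export
read_resolution_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("energy_meV", "density"))
  resolution_tabulated(df$energy_meV, df$density)
}
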