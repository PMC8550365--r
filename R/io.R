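## Text I/O for two-column traces (CSV/TSV) and JCAMP-DX spectra.

#' Read a two-column XY table (CSV/TSV) as a spectrum or diffractogram
#'
#' Accepts plain-text files with exactly two numeric columns (axis, value),
#' an optional single header line, `#` comment lines, and either comma, tab,
#' semicolon or whitespace delimiters (auto-detected unless given).  Files
#' stored in descending axis order are reversed on read; the original
#' direction is recorded.
#'
#' @param path File path.
#' @param kind `"spectrum"` (wavenumber/intensity) or `"diffractogram"`
#'   (two_theta/counts).
#' @param delim Field delimiter; `NULL` auto-detects among `","`, `"\t"`,
#'   `";"` and whitespace.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param ... Passed to [raman_spectrum()] or [xrd_diffractogram()]
#'   (e.g. `probe`, `state`, `replicate`).
#'
#' @return A spectra or diffractogram table carrying an
#'   `"source_direction"` attribute (`"ascending"` or `"descending"`).
#' @export
read_xy_table <- function(path, kind = c("spectrum", "diffractogram"),
                          delim = NULL, sample_id = NULL, ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("no data rows in %s.", path))

  if (is.null(delim)) {
    probe_line <- lines[[min(2, length(lines))]]
    delim <- if (grepl(",", probe_line)) "," else if (grepl("\t", probe_line)) "\t"
      else if (grepl(";", probe_line)) ";" else "[[:space:]]+"
  }
  fields <- strsplit(trimws(lines), delim)

  parse_row <- function(f) suppressWarnings(as.numeric(f))
  first <- parse_row(fields[[1]])
  start <- 1L
  if (all(is.na(first))) { # header line: every field non-numeric
    start <- 2L
    if (length(fields) < 2) abort(sprintf("no numeric rows in %s.", path))
  }
  rows <- fields[start:length(fields)]
  rownos <- lineno[start:length(fields)]
  n_fields <- lengths(rows)
  if (any(n_fields != 2)) {
    bad <- which(n_fields != 2)[1]
    abort(sprintf("expected exactly 2 columns in %s but found %d on line %d.",
                  path, n_fields[bad], rownos[bad]))
  }
  vals <- vapply(rows, parse_row, numeric(2))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[1]
    abort(sprintf("non-numeric value in %s on line %d: '%s'.",
                  path, rownos[bad], paste(rows[[bad]], collapse = delim)))
  }
  x <- vals[1, ]; y <- vals[2, ]
  if (length(x) < 2) abort(sprintf("fewer than 2 data rows in %s.", path))
  direction <- if (x[1] <= x[length(x)]) "ascending" else "descending"

  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  out <- if (kind == "spectrum") {
    raman_spectrum(x, y, sample_id = sample_id, ...)
  } else {
    xrd_diffractogram(x, y, sample_id = sample_id, ...)
  }
  attr(out, "source_direction") <- direction
  out
}

#' Write a trace to a two-column text file
#'
#' Values are written with 15 significant digits so that a read/write
#' round-trip reproduces the data exactly at printed precision.
#'
#' @param data A single-spectrum (or single-diffractogram) table.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @param header Write a header line naming the two columns?
#' @return `path`, invisibly.
#' @export
write_xy_table <- function(data, path, delim = ",", header = TRUE) {
  is_spec <- "wavenumber" %in% names(data)
  axis <- if (is_spec) "wavenumber" else "two_theta"
  value <- if (is_spec) "intensity" else "counts"
  if (!all(c(axis, value) %in% names(data))) {
    abort("data must contain wavenumber/intensity or two_theta/counts columns.")
  }
  if (length(split_spectra(data)) > 1) {
    abort("write_xy_table() writes a single trace; split multi-spectrum tables first.")
  }
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  body <- paste(fmt(data[[axis]]), fmt(data[[value]]), sep = delim)
  if (header) body <- c(paste(axis, value, sep = delim), body)
  writeLines(body, path)
  invisible(path)
}

#' Read a JCAMP-DX 4.24 spectrum (AFFN `(X++(Y..Y))` tables)
#'
#' Reconstructs the wavenumber axis from `##FIRSTX`/`##DELTAX`/`##XFACTOR`
#' and scales stored ordinates by `##YFACTOR`.  Compressed encodings
#' (DIFDUP/SQZ/PAC) are rejected with a clear message; only plain
#' space-separated AFFN numbers are supported.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to `##TITLE` or file name.
#' @param ... Passed to [raman_spectrum()].
#' @return A spectra table.
#' @export
read_jcampdx <- function(path, sample_id = NULL, ...) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  get_ldr <- function(label) {
    hit <- grep(sprintf("^##%s=", label), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  xy_start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(xy_start) == 0) abort(sprintf("%s: missing ##XYDATA record.", path))
  form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[xy_start[1]], ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    abort(sprintf("%s: unsupported XYDATA form '%s'; only (X++(Y..Y)) is supported.", path, form))
  }
  need <- function(label) {
    v <- get_ldr(label)
    if (is.null(v)) abort(sprintf("%s: missing required ##%s record.", path, label))
    suppressWarnings(as.numeric(v))
  }
  firstx <- need("FIRSTX"); deltax <- need("DELTAX")
  xfactor <- need("XFACTOR"); yfactor <- need("YFACTOR")
  if (anyNA(c(firstx, deltax, xfactor, yfactor))) {
    abort(sprintf("%s: non-numeric FIRSTX/DELTAX/XFACTOR/YFACTOR.", path))
  }

  end <- grep("^##", lines)
  end <- end[end > xy_start[1]]
  stop_at <- if (length(end)) min(end) - 1L else length(lines)
  body <- lines[seq(xy_start[1] + 1L, stop_at)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) abort(sprintf("%s: empty XYDATA table.", path))
  if (any(grepl("[A-DF-Za-df-z%@]", body))) {
    abort(sprintf("%s: compressed (SQZ/DIF/DUP) ordinates are not supported; use AFFN.", path))
  }

  ys <- list(); xs_check <- numeric(0); count <- 0L
  for (ln in body) {
    toks <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    if (anyNA(nums) || length(nums) < 2) {
      abort(sprintf("%s: unparseable XYDATA line '%s'.", path, ln))
    }
    x_line <- nums[1] * xfactor
    x_expected <- (firstx + count * deltax) * xfactor
    if (abs(x_line - x_expected) > abs(deltax * xfactor) / 2 + 1e-9) {
      abort(sprintf("%s: X-sequence check failed (line X %g, expected %g).",
                    path, x_line, x_expected))
    }
    ys[[length(ys) + 1L]] <- nums[-1]
    count <- count + length(nums) - 1L
  }
  y <- unlist(ys) * yfactor
  npts <- get_ldr("NPOINTS")
  if (!is.null(npts) && !is.na(as.numeric(npts)) && as.numeric(npts) != length(y)) {
    abort(sprintf("%s: NPOINTS=%s but %d ordinates read.", path, npts, length(y)))
  }
  x <- (firstx + (seq_along(y) - 1) * deltax) * xfactor
  if (is.null(sample_id)) {
    sample_id <- get_ldr("TITLE")
    if (is.null(sample_id) || !nzchar(sample_id)) {
      sample_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  raman_spectrum(x, y, sample_id = sample_id, ...)
}
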