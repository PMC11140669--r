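#' Read spectra from delimited text
#'
#' Two layouts are supported. `two_column`: one spectrum, column 1 holding
#' wavenumbers and column 2 intensities. `matrix_with_header`: a header row of
#' wavenumbers followed by one spectrum per row (a spectra stack).
#'
#' @param path Path to the text file.
#' @param mode `"two_column"` or `"matrix_with_header"`.
#' @param delimiter One of `","`, `"\t"`, `";"`, `""` (whitespace).
#' @return A `spectral_container` (kind `spectrum` or `spectra_stack`).
#' @export
read_spectra_text <- function(path, mode = c("two_column", "matrix_with_header"),
                              delimiter = ",") {
  mode <- match.arg(mode)
  if (!delimiter %in% c(",", "\t", ";", "")) {
    stop("delimiter must be comma, tab, semicolon or whitespace", call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty file", call. = FALSE)

  split_line <- function(ln) {
    if (delimiter == "") {
      strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    } else {
      trimws(strsplit(ln, delimiter, fixed = TRUE)[[1L]])
    }
  }
  cells <- lapply(lines, split_line)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row at line %d (%d fields, expected %d)",
                 bad, widths[bad], widths[1L]), call. = FALSE)
  }
  num <- lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell at line %d", i), call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, num)

  if (mode == "two_column") {
    if (ncol(m) != 2L) {
      stop(sprintf("two_column layout expects 2 columns, found %d", ncol(m)),
        call. = FALSE
      )
    }
    if (nrow(m) < 2L) stop("fewer than 2 bands", call. = FALSE)
    spectral_container(m[, 2L], m[, 1L])
  } else {
    if (nrow(m) < 2L) {
      stop("matrix_with_header layout needs a header plus >= 1 spectrum row",
        call. = FALSE
      )
    }
    if (ncol(m) < 2L) stop("fewer than 2 bands", call. = FALSE)
    spectral_container(m[-1L, , drop = FALSE], m[1L, ])
  }
}

#' Write spectra to delimited text
#'
#' Single spectra are written in the two-column layout, stacks in the
#' matrix-with-header layout. Numbers are printed with 17 significant digits
#' so text round trips reproduce values to double precision.
#'
#' @param x A `spectral_container` of kind `spectrum` or `spectra_stack`
#'   (images/volumes should be flattened first or saved natively).
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra_text <- function(x, path, delimiter = ",") {
  .assert_container(x)
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  if (x$kind == "spectrum") {
    lines <- paste(fmt(x$axis), fmt(x$intensities), sep = delimiter)
  } else if (x$kind == "spectra_stack") {
    m <- x$intensities
    lines <- c(
      paste(fmt(x$axis), collapse = delimiter),
      apply(m, 1L, function(r) paste(fmt(r), collapse = delimiter))
    )
  } else {
    stop("text output supports spectrum and spectra_stack kinds only",
      call. = FALSE
    )
  }
  writeLines(lines, path)
  invisible(path)
}
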