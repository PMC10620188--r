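# Text persistence: two-column delimited files per spectrum, wide matrices
# for sets, JSON for analysis reports. Metadata travels in "#" comment
# headers so the files stay loadable by generic tools.

meta_header <- function(meta) {
  keep <- !vapply(meta, function(v) is.null(v) || (length(v) == 1 && is.na(v)),
                  logical(1))
  sprintf("# %s: %s", names(meta)[keep],
          vapply(meta[keep], function(v) format(v, digits = 17), character(1)))
}

parse_meta_header <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write / read one spectrum as two-column delimited text
#'
#' Column 1 is the Raman shift (cm^-1), column 2 the intensity; metadata is
#' stored as `# key: value` header lines. Values round-trip at full double
#' precision.
#'
#' @param spectrum A `sers_spectrum`.
#' @param path File path.
#' @param sep Field separator (tab by default, use `","` for CSV).
#' @export
write_spectrum <- function(spectrum, path, sep = "\t") {
  stopifnot(inherits(spectrum, "sers_spectrum"))
  hdr <- meta_header(spectrum$meta)
  body <- paste(sprintf("%.17g", spectrum$axis$values),
                sprintf("%.17g", spectrum$intensity), sep = sep)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @return `read_spectrum()` returns a `sers_spectrum`. A file with a
#'   descending axis is re-sorted ascending with a warning; non-numeric rows
#'   raise a parse error naming the offending line.
#' @export
read_spectrum <- function(path, sep = "\t") {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  meta <- parse_meta_header(lines[is_hdr])
  body <- lines[!is_hdr & nzchar(lines)]
  body_no <- which(!is_hdr & nzchar(lines))
  parts <- strsplit(body, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0)
    stop("parse error at line ", body_no[bad[1]], " of ", path,
         ": expected two delimited fields")
  nu <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- which(is.na(nu) | is.na(y))
  if (length(bad) > 0)
    stop("parse error at line ", body_no[bad[1]], " of ", path,
         ": non-numeric value")
  if (is.unsorted(nu)) {
    if (all(diff(nu) < 0)) {
      warning("descending wavenumber axis in ", path, "; re-sorted ascending")
      o <- order(nu); nu <- nu[o]; y <- y[o]
    } else stop("non-monotone wavenumber axis in ", path)
  }
  ax <- axis_from_values(nu)
  new_spectrum(ax, y,
               trap_state = meta$trap_state %||% NA_character_,
               session_id = as.character(meta$session_id %||% "S1"),
               time_s = meta$time_s %||% NA_real_,
               integration_s = meta$integration_s %||% 1,
               label_truth = meta$label_truth %||% NA_character_)
}

#' Write / read a spectrum set as a wide delimited matrix
#'
#' First column is the shared wavenumber axis, then one intensity column per
#' spectrum. Per-spectrum metadata (including ground-truth labels from the
#' simulator) goes to a sidecar CSV when `meta_path` is given.
#'
#' @param set A `sers_set`.
#' @param path Matrix file path.
#' @param meta_path Optional sidecar CSV path for the metadata table.
#' @param sep Field separator.
#' @export
write_spectrum_set <- function(set, path, meta_path = NULL, sep = "\t") {
  stopifnot(inherits(set, "sers_set"))
  n <- n_spectra(set)
  hdr <- c(sprintf("# n_spectra: %d", n),
           paste(c("wavenumber_cm1", sprintf("spec%04d", seq_len(n))),
                 collapse = sep))
  rows <- apply(cbind(set$axis$values, set$intensities), 1, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(c(hdr, rows), path)
  if (!is.null(meta_path))
    utils::write.csv(set$meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_set
#' @export
read_spectrum_set <- function(path, meta_path = NULL, sep = "\t") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  parts <- strsplit(lines[-1], sep, fixed = TRUE)
  ncols <- length(header)
  bad <- which(vapply(parts, length, integer(1)) != ncols)
  if (length(bad) > 0)
    stop("ragged matrix at data line ", bad[1], " of ", path,
         ": expected ", ncols, " fields")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = ncols, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("parse error at data line ", bad, " of ", path, ": non-numeric value")
  }
  nu <- m[, 1]
  if (all(diff(nu) < 0)) {
    warning("descending wavenumber axis in ", path, "; re-sorted ascending")
    o <- order(nu); m <- m[o, , drop = FALSE]; nu <- nu[o]
  }
  ax <- axis_from_values(nu)
  meta <- if (!is.null(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE,
                    colClasses = c(trap_state = "character",
                                   session_id = "character",
                                   label_truth = "character"))
  else NULL
  new_spectrum_set(ax, m[, -1, drop = FALSE], meta)
}

#' Write / read an analysis report as JSON
#'
#' @param report Any list-like report object.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
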