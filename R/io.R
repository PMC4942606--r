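# File dialects: whitespace-delimited ASCII matrices (the text export of SPM
# software), delimited spectra tables with an explicit wavenumber column, and
# the dataset manifest CSV. All readers are total on their writers' output.

detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  " "
}

#' Read a whitespace-delimited ASCII matrix file
#'
#' Parses the plain-text matrix dialect exported by SPM software: one matrix
#' row per line, whitespace-separated numeric fields, optional leading
#' `#`-prefixed header/comment lines (skipped).
#'
#' @param path path to the text file.
#' @return A numeric matrix.
#' @export
read_matrix_text <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) == 0L) stop_format("empty matrix file: ", path)
  fields <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield != nfield[1])) {
    bad <- which(nfield != nfield[1])[1]
    stop_format("ragged row in ", path, ": line ", line_no[bad], " has ",
                nfield[bad], " fields, expected ", nfield[1])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad_row <- line_no[ceiling(which(is.na(vals))[1] / nfield[1])]
    stop_format("non-numeric field in ", path, " at line ", bad_row)
  }
  matrix(vals, nrow = length(body), ncol = nfield[1], byrow = TRUE)
}

#' Write a matrix as whitespace-delimited ASCII
#'
#' @param matrix numeric matrix, non-empty and finite.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_text <- function(matrix, path) {
  m <- as.matrix(matrix)
  if (length(m) == 0L) stop_validation("cannot write an empty matrix")
  if (!all(is.finite(m))) {
    stop_validation("matrix contains non-finite values; refusing to write")
  }
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a spectral dataset as a delimited table
#'
#' Layout: first column is the wavenumber (or spatial) axis; each remaining
#' column is one sample. The first header row carries sample ids, the second
#' (`class`) row maps each sample to its class label.
#'
#' @param dataset a [spectral_dataset()].
#' @param path output path.
#' @param sep field separator (`","`, `"\t"`, or `" "`).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  header <- paste(c("wavenumber", dataset$sample_ids), collapse = sep)
  labels <- paste(c("class", dataset$class_labels), collapse = sep)
  body <- vapply(seq_along(dataset$variables_axis), function(j) {
    paste(sprintf("%.17g", c(dataset$variables_axis[j], dataset$intensities[, j])),
          collapse = sep)
  }, character(1))
  writeLines(c(header, labels, body), path)
  invisible(path)
}

#' Read a delimited spectra table
#'
#' Accepts comma-, tab- or whitespace-delimited tables in the layout written
#' by [write_spectra_table()]. A descending wavenumber axis is re-sorted to
#' ascending (with a notice); duplicate wavenumbers are an error.
#'
#' @param path input path.
#' @return A [spectral_dataset()].
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop_format("spectra table too short: ", path)
  sep <- detect_delimiter(lines[1])
  split1 <- function(x) {
    if (sep == " ") strsplit(trimws(x), "\\s+")[[1]] else strsplit(x, sep, fixed = TRUE)[[1]]
  }
  header <- split1(lines[1])
  label_row <- split1(lines[2])
  if (length(label_row) != length(header) ||
      tolower(label_row[1]) != "class") {
    stop_format("spectra table is missing the 'class' label row: ", path)
  }
  sample_ids <- header[-1]
  class_labels <- label_row[-1]
  body <- lapply(lines[-(1:2)], split1)
  nf <- lengths(body)
  if (any(nf != length(header))) {
    stop_format("row with wrong field count in ", path)
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(body)), nrow = length(body), byrow = TRUE)
  )
  if (anyNA(num)) stop_format("non-numeric value in spectra table: ", path)
  axis <- num[, 1]
  if (anyDuplicated(axis)) {
    stop_format("duplicate wavenumbers in spectra table: ", path)
  }
  intensities <- t(num[, -1, drop = FALSE])
  if (is.unsorted(axis)) {
    message("spectra axis not ascending; sorting to ascending wavenumber")
    ord <- order(axis)
    axis <- axis[ord]
    intensities <- intensities[, ord, drop = FALSE]
  }
  spectral_dataset(axis, intensities, class_labels, sample_ids)
}

#' Read and validate a dataset manifest
#'
#' The manifest is a delimited table with columns `file_path`, `cell_id`,
#' `class_label`, `biomarker`, `wavelength_um`, `replicate_id`. Validation
#' enforces: unique (cell_id, biomarker, replicate_id) triples, biomarker
#' names drawn from the canonical set, and (optionally) existence of every
#' referenced image file relative to the manifest's directory.
#'
#' @param path manifest path.
#' @param check_files verify that every referenced matrix file exists.
#' @return A validated manifest data frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- detect_delimiter(first)
  man <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("file_path", "cell_id", "class_label", "biomarker",
                "wavelength_um", "replicate_id")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    stop_format("manifest is missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  bad_bm <- setdiff(unique(man$biomarker), snom_biomarkers())
  if (length(bad_bm) > 0) {
    stop_validation("unknown biomarker name(s) ",
                    paste(sQuote(bad_bm), collapse = ", "),
                    "; allowed: {", paste(snom_biomarkers(), collapse = ", "), "}")
  }
  key <- paste(man$cell_id, man$biomarker, man$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_validation("duplicate (cell_id, biomarker, replicate_id) in manifest: ",
                    gsub("\r", " / ", dup, fixed = TRUE))
  }
  if (check_files) {
    paths <- file.path(dirname(path), man$file_path)
    missing <- man$file_path[!file.exists(paths)]
    if (length(missing) > 0) {
      stop_validation("manifest references missing file(s): ",
                      paste(missing, collapse = ", "))
    }
  }
  man
}

#' Load every image referenced by a manifest
#'
#' @param path manifest path (image paths are resolved relative to it).
#' @return A list with `images` (list of [transmission_image()]) and the
#'   validated `manifest`.
#' @param scan_size_um physical scan extent recorded in each image.
#' @export
read_snom_dataset <- function(path, scan_size_um = 400) {
  man <- read_manifest(path, check_files = TRUE)
  base <- dirname(path)
  images <- lapply(seq_len(nrow(man)), function(i) {
    transmission_image(
      read_matrix_text(file.path(base, man$file_path[i])),
      wavelength_um = man$wavelength_um[i],
      biomarker = man$biomarker[i],
      cell_id = man$cell_id[i],
      class_label = man$class_label[i],
      scan_size_um = scan_size_um
    )
  })
  list(images = images, manifest = man)
}
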