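#' Write a table as TSV with metadata header lines
#'
#' All pipeline outputs share one dialect: `#`-prefixed `key: value`
#' metadata lines (run seed, configuration hash, package version),
#' then a tab-separated table with a header row.
#'
#' @param x data frame.
#' @param path output path.
#' @param meta named list written as `#key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("normdev ", pkg_version())), meta)
  lines <- sprintf("#%s: %s", names(meta),
                   vapply(meta, function(v) paste(format(v), collapse = ","),
                          character(1)))
  writeLines(lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("normdev"))
}

#' Read a TSV written by the pipeline
#'
#' Skips `#` metadata lines (returned as an attribute) and parses
#' `NA`, empty fields, `nan` and `NaN` as missing.
#'
#' @param path file path.
#' @return tibble with attribute `meta`.
#' @export
read_tsv_meta <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  while (length(l <- readLines(con, 1)) && startsWith(l, "#")) {
    hdr <- c(hdr, sub("^#", "", l))
  }
  close(con)
  on.exit(NULL)
  x <- readr::read_tsv(path, comment = "#",
                       na = c("NA", "", "nan", "NaN"),
                       show_col_types = FALSE, progress = FALSE)
  meta <- strsplit(hdr, ": ", fixed = TRUE)
  attr(x, "meta") <- setNames(
    vapply(meta, function(m) paste(m[-1], collapse = ": "), character(1)),
    vapply(meta, `[[`, character(1), 1))
  x
}

#' Load a cohort table
#'
#' Reads a cohort TSV/CSV with the documented header; mandatory columns
#' are `subject_id`, `group`, `sex`, `age`, `schedule`. Unknown columns
#' are preserved.
#'
#' @param path file path (TSV; `.csv` files are read as CSV).
#' @return typed tibble.
#' @export
load_cohort <- function(path) {
  x <- if (grepl("\\.csv$", path)) {
    readr::read_csv(path, comment = "#", na = c("NA", "", "nan", "NaN"),
                    show_col_types = FALSE, progress = FALSE)
  } else {
    read_tsv_meta(path)
  }
  mandatory <- c("subject_id", "group", "sex", "age", "schedule")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$subject_id)) {
    abort("duplicate subject_id values in cohort file")
  }
  # all-missing numeric columns are type-ambiguous in the file; keep the
  # documented types
  numeric_cols <- c("age", "iq", "quality_surrogate", "adi_social",
                    "adi_communication", "adi_rrb", "ados_total",
                    "ados_social", "ados_rrb")
  for (cl in intersect(numeric_cols, names(x))) {
    if (is.logical(x[[cl]])) x[[cl]] <- as.numeric(x[[cl]])
  }
  x
}

#' Write / load a subjects-by-vertices measurement matrix
#'
#' The TSV has a `subject_id` column followed by one column per vertex
#' (`v0`, `v1`, ...).
#'
#' @param m a [measure_matrix()] or numeric matrix.
#' @param path file path.
#' @param meta metadata for [write_tsv_meta()].
#' @return `path` (write) or a `measure_matrix` (load).
#' @export
write_measure_matrix <- function(m, path, meta = list()) {
  values <- if (inherits(m, "measure_matrix")) m$values else as.matrix(m)
  measure <- if (inherits(m, "measure_matrix")) m$measure else "thickness"
  df <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(values)),
                         tibble::as_tibble(values))
  write_tsv_meta(df, path, c(meta, list(measure = measure)))
}

#' @rdname write_measure_matrix
#' @export
load_measure_matrix <- function(path) {
  x <- read_tsv_meta(path)
  if (!"subject_id" %in% names(x)) {
    abort("measurement file is missing the subject_id column")
  }
  values <- as.matrix(x[, setdiff(names(x), "subject_id")])
  measure <- attr(x, "meta")[["measure"]] %||% "thickness"
  measure_matrix(values, x$subject_id, measure)
}

#' Write / load a vertex parcellation table
#'
#' @param parcellation tibble (`vertex`, `region`).
#' @param path file path.
#' @param meta metadata lines.
#' @export
write_parcellation <- function(parcellation, path, meta = list()) {
  write_tsv_meta(parcellation, path, meta)
}

#' @rdname write_parcellation
#' @export
load_parcellation <- function(path) {
  x <- read_tsv_meta(path)
  if (!all(c("vertex", "region") %in% names(x))) {
    abort("parcellation file needs vertex and region columns")
  }
  x
}
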