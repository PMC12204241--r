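# Readers and writers for the plain-text formats the pipeline exchanges:
# TSV tables, MatrixMarket sparse counts with row/column sidecars, BED
# intervals (0-based half-open), JSON truth files and YAML configs.

#' Write / read a tab-separated table
#'
#' Thin readr wrappers pinned to the package's conventions (tab separator,
#' no row names, `NA` encoded literally).
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_file()` returns a tibble.
#' @export
write_tsv_file <- function(x, path) {
  x <- as_tibble(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], function(col) {
    vapply(col, function(el) paste(el, collapse = ";"), character(1))
  })
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read composition counts as MatrixMarket with sidecars
#'
#' Counts go to `<stem>.mtx` (1-based indices per the MatrixMarket
#' standard), sample metadata to `<stem>.samples.tsv`, and subcluster
#' labels to `<stem>.subclusters.tsv`.
#'
#' @param composition Composition tibble (see [generate_composition()]).
#' @param stem Path stem (no extension).
#' @return `read_composition()` returns the composition tibble.
#' @export
write_composition <- function(composition, stem) {
  id_cols <- intersect(c("sample_id", "donor_id", "region", "total"),
                       names(composition))
  subs <- setdiff(names(composition), id_cols)
  m <- Matrix::Matrix(as.matrix(composition[subs]), sparse = TRUE)
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  write_tsv_file(composition[id_cols], paste0(stem, ".samples.tsv"))
  write_tsv_file(tibble(subcluster = subs), paste0(stem, ".subclusters.tsv"))
  invisible(stem)
}

#' @rdname write_composition
#' @export
read_composition <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  samples <- read_tsv_file(paste0(stem, ".samples.tsv"))
  subs <- read_tsv_file(paste0(stem, ".subclusters.tsv"))$subcluster
  colnames(m) <- subs
  storage.mode(m) <- "integer"
  dplyr::bind_cols(samples, as_tibble(m))
}

#' Write / read BED intervals
#'
#' BED is 0-based, half-open; columns beyond `chrom`, `start`, `end` are
#' written as the name field.
#'
#' @param bed Tibble with `chrom`, `start`, `end` and optionally a name
#'   column (any fourth column).
#' @param path File path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end`,
#'   `name`.
#' @export
write_bed <- function(bed, path) {
  bed <- as_tibble(bed)
  nm_col <- setdiff(names(bed), c("chrom", "start", "end"))[1]
  out <- tibble(chrom = bed$chrom, start = as.integer(bed$start),
                end = as.integer(bed$end))
  if (!is.na(nm_col)) out$name <- bed[[nm_col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  cols <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)
  names(cols)[1:3] <- c("chrom", "start", "end")
  if (ncol(cols) >= 4) names(cols)[4] <- "name"
  if (any(cols$start >= cols$end) || any(cols$start < 0)) {
    abort(sprintf("Malformed BED `%s`: need 0 <= start < end.", path))
  }
  cols
}

#' Write / read JSON (e.g. simulation truth files)
#' @param x List or data frame.
#' @param path File path.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_file
#' @export
read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a YAML pipeline configuration
#'
#' Reads the YAML and fills unspecified fields from [default_config()].
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user %||% list())
}
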