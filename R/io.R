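# File dialects consumed and emitted by the pipeline. All writers go through
# an atomic write-to-temp-then-rename so a failed stage never leaves a
# truncated report behind.

write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a count matrix with its library sidecar
#'
#' The count file is TSV with a `transcript` column followed by one column
#' per library; the sidecar maps library names to the design with columns
#' `library`, `genotype`, `tissue`, `replicate`.
#'
#' @param counts_path,design_path File paths.
#' @return List with `counts` (integer matrix) and `design`.
#' @export
read_count_matrix <- function(counts_path, design_path) {
  x <- utils::read.delim(counts_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(x)[1] != "transcript") {
    stop("first column of the count file must be 'transcript'")
  }
  counts <- as.matrix(x[, -1, drop = FALSE])
  rownames(counts) <- x$transcript
  storage.mode(counts) <- "integer"
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  check_design(design, counts)
  list(counts = counts, design = design)
}

#' Write a count matrix and sidecar
#' @param counts Integer matrix with dimnames.
#' @param design Library design.
#' @param counts_path,design_path Output paths.
#' @export
write_count_matrix <- function(counts, design, counts_path, design_path) {
  df <- data.frame(transcript = rownames(counts), counts,
                   check.names = FALSE)
  write_tsv_atomic(df, counts_path)
  write_tsv_atomic(design, design_path)
  invisible(counts_path)
}

#' Read per-replicate variant evidence
#' @param path TSV with columns `transcript`, `pos`, `ref`, `alt`,
#'   `genotype`, `tissue`, `replicate`, `alt_reads`, `depth`.
#' @return data.frame validated against the evidence contract.
#' @export
read_variant_evidence <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_evidence(x)
  x
}

#' Read a species map
#' @param path TSV with columns `id`, `species`.
#' @return Named character vector id -> species.
#' @export
read_species_map <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(x$species, x$id)
}

#' Read GO annotations
#' @param path TSV with columns `transcript`, `term` (optional `name`).
#' @return data.frame of assignments.
#' @export
read_go_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
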