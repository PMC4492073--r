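#' The six atlas tissues
#'
#' Default tissue panel of the atlas: leaf, flower, elongating stem internode
#' (ES), post-elongation stem internode (PES), root and nitrogen-fixing
#' nodule. PES internodes are the lignifying stem segments; nodules are the
#' rhizobial symbiotic organs.
#'
#' @return Character vector of the six tissue labels.
#' @export
msgi_tissues <- function() {
  c("Leaf", "Flower", "ES", "PES", "Root", "Nodule")
}

#' Build a library design table
#'
#' One sequencing library per (genotype, tissue, replicate) triple. The
#' default reproduces the atlas layout: two genotypes (B47, the ssp. sativa
#' clone; F56, the ssp. falcata clone) times six tissues times three
#' biological replicates, 36 libraries in total.
#'
#' @param genotypes Character vector of genotype labels.
#' @param tissues Character vector of tissue labels.
#' @param replicates Number of biological replicates per (genotype, tissue).
#' @return A data.frame with columns `library`, `genotype`, `tissue`,
#'   `replicate`. Library ids are `<genotype>.<tissue>.<replicate>`.
#' @examples
#' d <- atlas_design()
#' nrow(d)  # 36
#' @export
atlas_design <- function(genotypes = c("B47", "F56"),
                         tissues = msgi_tissues(),
                         replicates = 3) {
  stopifnot(length(genotypes) >= 1, length(tissues) >= 1, replicates >= 1)
  if (anyDuplicated(genotypes) || anyDuplicated(tissues)) {
    stop("genotype and tissue labels must be unique")
  }
  d <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                   genotype = genotypes, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("genotype", "tissue", "replicate")]
  d$library <- paste(d$genotype, d$tissue, d$replicate, sep = ".")
  rownames(d) <- NULL
  d[, c("library", "genotype", "tissue", "replicate")]
}

# Validate a design data.frame, optionally against the columns of a matrix.
# Enforces unique (genotype, tissue, replicate) triples and a uniform
# replicate count per (genotype, tissue).
check_design <- function(design, mat = NULL) {
  need <- c("library", "genotype", "tissue", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design))) {
    stop("design must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  key <- paste(design$genotype, design$tissue, design$replicate)
  if (anyDuplicated(key) || anyDuplicated(design$library)) {
    stop("design has duplicated libraries")
  }
  reps <- table(paste(design$genotype, design$tissue))
  if (length(unique(as.integer(reps))) != 1L) {
    stop("replicate count is not uniform across (genotype, tissue) groups")
  }
  if (!is.null(mat)) {
    if (is.null(colnames(mat)) || !setequal(colnames(mat), design$library)) {
      stop("matrix columns do not match design libraries")
    }
  }
  invisible(design)
}

# Library ids for a genotype and/or tissue, in design order.
libs_for <- function(design, genotype = NULL, tissue = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) {
    if (!genotype %in% design$genotype) stop("unknown genotype: ", genotype)
    keep <- keep & design$genotype == genotype
  }
  if (!is.null(tissue)) {
    if (!tissue %in% design$tissue) stop("unknown tissue: ", tissue)
    keep <- keep & design$tissue == tissue
  }
  design$library[keep]
}
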