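#' Per-replicate SNP candidate filter
#'
#' Keeps variant evidence rows whose alternate-allele read support reaches
#' `min_alt_reads` in that replicate (the atlas rule: SNPs represented by at
#' least 10 reads per biological replicate). "Reads" is interpreted as reads
#' supporting the variant allele, not total depth; an optional minimum
#' alternate-allele fraction can be layered on top.
#'
#' @param evidence data.frame of per-replicate variant evidence with columns
#'   `transcript`, `pos` (0-based), `ref`, `alt`, `genotype`, `tissue`,
#'   `replicate`, `alt_reads`, `depth`.
#' @param min_alt_reads Minimum alternate-supporting reads.
#' @param min_alt_frac Optional minimum `alt_reads / depth`; `NULL` (default)
#'   disables the fraction filter.
#' @return The subset of `evidence` rows passing the filter.
#' @export
call_replicate_snps <- function(evidence, min_alt_reads = 10,
                                min_alt_frac = NULL) {
  check_evidence(evidence)
  keep <- evidence$alt_reads >= min_alt_reads
  if (!is.null(min_alt_frac)) {
    keep <- keep & evidence$alt_reads / evidence$depth >= min_alt_frac
  }
  out <- evidence[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_evidence <- function(evidence) {
  need <- c("transcript", "pos", "ref", "alt", "genotype", "tissue",
            "replicate", "alt_reads", "depth")
  if (!is.data.frame(evidence) || !all(need %in% names(evidence))) {
    stop("evidence must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(evidence$alt_reads > evidence$depth)) {
    stop("malformed evidence: alt_reads exceeds depth")
  }
  if (any(evidence$alt_reads < 0) || any(evidence$pos < 0)) {
    stop("malformed evidence: negative alt_reads or position")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(evidence$ref %in% bases) || !all(evidence$alt %in% bases)) {
    stop("malformed evidence: bases must be A/C/G/T")
  }
  if (any(evidence$ref == evidence$alt)) {
    stop("malformed evidence: ref equals alt")
  }
  invisible(evidence)
}

#' Replicate-concordance SNP consolidation
#'
#' A variant passes for a (genotype, tissue) when it is present in the
#' candidate set of all `replicates` biological replicates (the atlas'
#' false-positive guard).
#'
#' @param candidates Filtered evidence from [call_replicate_snps()].
#' @param replicates Uniform replicate count per (genotype, tissue).
#' @return data.frame of passing occurrences: `transcript`, `pos`, `ref`,
#'   `alt`, `genotype`, `tissue`.
#' @export
consolidate_snps <- function(candidates, replicates = 3) {
  key <- paste(candidates$transcript, candidates$pos, candidates$ref,
               candidates$alt, candidates$genotype, candidates$tissue,
               sep = "\r")
  nrep <- vapply(split(candidates$replicate, key), function(r) {
    length(unique(r))
  }, integer(1))
  pass <- names(nrep)[nrep >= replicates]
  if (length(pass) == 0) {
    return(data.frame(transcript = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), tissue = character()))
  }
  parts <- do.call(rbind, strsplit(pass, "\r", fixed = TRUE))
  out <- data.frame(transcript = parts[, 1], pos = as.integer(parts[, 2]),
                    ref = parts[, 3], alt = parts[, 4],
                    genotype = parts[, 5], tissue = parts[, 6])
  out <- out[order(out$transcript, out$pos, out$alt, out$genotype,
                   out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify consolidated SNPs by genotype and tissue occurrence
#'
#' A SNP (a distinct `transcript`/`pos`/`ref`/`alt`) observed only in one
#' genotype is genotype-specific to it; a SNP observed in both genotypes is
#' shared (with the atlas these likely mark allelic variation collapsed into
#' one contig). `tissue_specific` flags SNPs whose occurrences span exactly
#' one tissue. `same_tissue` records whether some tissue passed in both
#' genotypes — the strict reading of a shared (allelic) SNP; with
#' `shared_mode = "same_tissue"` the summary's shared column counts only
#' those, while the record classes always partition the SNP set by genotype
#' overlap.
#'
#' @param passed Passing occurrences from [consolidate_snps()].
#' @param genotypes Genotype labels (defaults to those present, sorted).
#' @param shared_mode `"any_overlap"` (default) or `"same_tissue"`; controls
#'   which shared SNPs the summary counts.
#' @return List with `records` (one row per SNP: `transcript`, `pos`, `ref`,
#'   `alt`, `class` — a genotype label or `"shared"` —, `tissue_specific`,
#'   `same_tissue`, `n_occurrences`) and `summary`, a per-class table of
#'   total SNPs, tissue-specific SNPs and distinct transcripts carrying SNPs.
#' @export
classify_snps <- function(passed, genotypes = NULL,
                          shared_mode = c("any_overlap", "same_tissue")) {
  shared_mode <- match.arg(shared_mode)
  if (is.null(genotypes)) genotypes <- sort(unique(passed$genotype))
  if (length(genotypes) < 2) stop("both genotypes must be analyzed")
  key <- paste(passed$transcript, passed$pos, passed$ref, passed$alt,
               sep = "\r")
  idx <- split(seq_len(nrow(passed)), key)
  rec <- lapply(idx, function(i) {
    g <- unique(passed$genotype[i])
    t <- unique(passed$tissue[i])
    same <- any(vapply(t, function(ti) {
      length(unique(passed$genotype[i][passed$tissue[i] == ti])) > 1
    }, logical(1)))
    data.frame(transcript = passed$transcript[i[1]],
               pos = passed$pos[i[1]], ref = passed$ref[i[1]],
               alt = passed$alt[i[1]],
               class = if (length(g) == 1) g else "shared",
               tissue_specific = length(t) == 1,
               same_tissue = same, n_occurrences = length(i))
  })
  records <- do.call(rbind, rec)
  records <- records[order(records$transcript, records$pos, records$alt), ,
                     drop = FALSE]
  rownames(records) <- NULL

  classes <- c(genotypes, "shared")
  in_class <- function(cl) {
    if (cl != "shared") return(records$class == cl)
    if (shared_mode == "same_tissue") {
      records$class == "shared" & records$same_tissue
    } else {
      records$class == "shared"
    }
  }
  summary <- data.frame(row.names = c("total_snps", "tissue_specific_snps",
                                      "transcripts_with_snps"))
  for (cl in classes) {
    k <- in_class(cl)
    summary[[cl]] <- c(sum(k), sum(k & records$tissue_specific),
                       length(unique(records$transcript[k])))
  }
  list(records = records, summary = summary)
}

#' Table-shaped SNP summary as a plain list
#'
#' @param classified Result of [classify_snps()].
#' @return List mirroring the summary data.frame, convenient for JSON
#'   serialization.
#' @export
snp_summary <- function(classified) {
  s <- classified$summary
  list(classes = colnames(s),
       total_snps = as.integer(s["total_snps", ]),
       tissue_specific_snps = as.integer(s["tissue_specific_snps", ]),
       transcripts_with_snps = as.integer(s["transcripts_with_snps", ]),
       grand_total = sum(as.integer(s["total_snps", ])))
}
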