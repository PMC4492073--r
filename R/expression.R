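#' RPKM normalization
#'
#' Converts raw mapped-read counts to reads per kilobase of transcript per
#' million mapped reads: `RPKM[t, l] = 1e9 * C[t, l] / (N[l] * L[t])`, where
#' `C` is the count, `N[l]` the library's mapped-read total and `L[t]` the
#' transcript length in bp.
#'
#' By default `N[l]` is the column sum of `counts`; when reads were mapped
#' against a larger reference than the matrix covers, the externally known
#' mapped-read totals can be supplied through `lib_sizes`.
#'
#' @param counts Integer matrix, transcripts x libraries, with dimnames.
#' @param lengths Named numeric vector of transcript lengths (bp) covering
#'   every row of `counts`.
#' @param lib_sizes Optional named numeric vector of per-library mapped-read
#'   totals; must be >= the column sums of `counts`.
#' @return Numeric matrix of RPKM values with the axes of `counts`.
#' @examples
#' cnt <- matrix(c(1000L, 0L), 2, 1,
#'               dimnames = list(c("t1", "t2"), "lib1"))
#' rpkm_normalize(cnt, c(t1 = 1000, t2 = 500),
#'                lib_sizes = c(lib1 = 1e6))  # 1000, 0
#' @export
rpkm_normalize <- function(counts, lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have transcript rownames and library colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss) > 0) {
    stop("transcripts missing from the catalog: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  L <- lengths[rownames(counts)]
  if (any(L < 1)) stop("transcript lengths must be >= 1 bp")
  if (is.null(lib_sizes)) {
    N <- colSums(counts)
  } else {
    miss <- setdiff(colnames(counts), names(lib_sizes))
    if (length(miss) > 0) stop("lib_sizes missing libraries")
    N <- lib_sizes[colnames(counts)]
    if (any(N < colSums(counts))) {
      stop("lib_sizes smaller than the column sums of counts")
    }
  }
  if (any(N <= 0)) {
    stop("invalid library: zero mapped-read total in ",
         paste(colnames(counts)[N <= 0], collapse = ", "))
  }
  1e9 * counts / outer(as.numeric(L), as.numeric(N))
}

#' Recover counts from an RPKM matrix
#'
#' Inverts [rpkm_normalize()]: `C = RPKM * N * L / 1e9`. Used for round-trip
#' verification of the normalization.
#'
#' @param rpkm RPKM matrix as returned by [rpkm_normalize()].
#' @param lengths Named transcript lengths (bp).
#' @param lib_sizes Named per-library mapped-read totals used for the
#'   normalization.
#' @return Numeric matrix of counts.
#' @export
counts_from_rpkm <- function(rpkm, lengths, lib_sizes) {
  L <- lengths[rownames(rpkm)]
  N <- lib_sizes[colnames(rpkm)]
  rpkm * outer(as.numeric(L), as.numeric(N)) / 1e9
}

#' Low-expression read-retention filter
#'
#' Retains a transcript when at least one (genotype, tissue) group has
#' `min_reads` or more reads in at least `min_reps` of its replicates; the
#' default (10 reads in 2 of 3 replicates) is the atlas assembly filter that
#' guards against false-positive expression from stray reads.
#'
#' @param counts Count matrix, transcripts x libraries.
#' @param design Library design from [atlas_design()].
#' @param min_reads Minimum reads per replicate.
#' @param min_reps Minimum qualifying replicates within a group.
#' @return Character vector of retained transcript ids (in row order).
#' @export
retention_filter <- function(counts, design, min_reads = 10, min_reps = 2) {
  check_design(design, counts)
  reps <- nrow(design) /
    length(unique(paste(design$genotype, design$tissue)))
  if (min_reps > reps) {
    stop("invalid config: min_reps (", min_reps,
         ") exceeds the replicate count (", reps, ")")
  }
  groups <- split(design$library, paste(design$genotype, design$tissue))
  keep <- rep(FALSE, nrow(counts))
  for (libs in groups) {
    hits <- rowSums(counts[, libs, drop = FALSE] >= min_reads)
    keep <- keep | hits >= min_reps
  }
  rownames(counts)[keep]
}

# Per-genotype tissue means: arithmetic mean of replicate RPKMs.
# Returns a transcripts x tissues matrix.
tissue_means <- function(rpkm, design, genotype) {
  tissues <- unique(design$tissue)
  out <- vapply(tissues, function(ti) {
    rowMeans(rpkm[, libs_for(design, genotype, ti), drop = FALSE])
  }, numeric(nrow(rpkm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(rpkm), tissues)
  out
}

#' Classify transcripts by expression breadth
#'
#' Per genotype, a transcript is *expressed* in a tissue when the arithmetic
#' mean of its replicate RPKMs reaches the `presence` threshold (default
#' RPKM >= 1). A transcript is *tissue-specific* when exactly one tissue
#' reaches `presence` and every other tissue stays below `absence`.
#' A transcript is *genotype-specific* when it is expressed in at least one
#' tissue of exactly one genotype. A tissue-specific call *common* to both
#' genotypes is one with the same tissue label in each.
#'
#' @param rpkm RPKM matrix, transcripts x libraries.
#' @param design Library design.
#' @param presence RPKM threshold at or above which a tissue counts as
#'   expressed.
#' @param absence RPKM threshold below which a tissue counts as silent for
#'   the tissue-specificity call; must be <= `presence`.
#' @return An object of class `expression_classification`: per-genotype
#'   tissue-mean and expressed matrices, per-genotype tissue-specific labels,
#'   a genotype-specific label per transcript, and the common tissue-specific
#'   label, all indexed by transcript.
#' @seealso [expression_summary()] for the per-tissue summary table.
#' @export
classify_expression <- function(rpkm, design, presence = 1, absence = 1) {
  check_design(design, rpkm)
  if (presence < absence) {
    stop("invalid config: presence threshold below absence threshold")
  }
  genotypes <- unique(design$genotype)
  tissues <- unique(design$tissue)
  tx <- rownames(rpkm)

  tm <- lapply(genotypes, function(g) tissue_means(rpkm, design, g))
  names(tm) <- genotypes
  expressed <- lapply(tm, function(m) m >= presence)

  tissue_specific <- lapply(genotypes, function(g) {
    m <- tm[[g]]
    n_pres <- rowSums(m >= presence)
    n_above_abs <- rowSums(m >= absence)
    # exactly one tissue at/above presence, none of the rest at/above absence
    ok <- n_pres == 1L & (n_above_abs - 1L) == 0L
    lab <- rep(NA_character_, nrow(m))
    lab[ok] <- tissues[max.col(m[ok, , drop = FALSE], ties.method = "first")]
    names(lab) <- tx
    lab
  })
  names(tissue_specific) <- genotypes

  n_expr_geno <- vapply(expressed, function(e) rowSums(e) > 0, logical(length(tx)))
  if (is.null(dim(n_expr_geno))) {
    n_expr_geno <- matrix(n_expr_geno, nrow = 1)
  }
  genotype_specific <- rep(NA_character_, length(tx))
  one <- rowSums(n_expr_geno) == 1L
  genotype_specific[one] <-
    genotypes[max.col(n_expr_geno[one, , drop = FALSE], ties.method = "first")]
  names(genotype_specific) <- tx

  common <- rep(NA_character_, length(tx))
  if (length(genotypes) >= 2) {
    a <- tissue_specific[[1L]]
    b <- tissue_specific[[2L]]
    same <- !is.na(a) & !is.na(b) & a == b
    common[same] <- a[same]
  }
  names(common) <- tx

  structure(
    list(genotypes = genotypes, tissues = tissues, transcripts = tx,
         tissue_means = tm, expressed = expressed,
         tissue_specific = tissue_specific,
         genotype_specific = genotype_specific,
         common_tissue_specific = common,
         presence = presence, absence = absence),
    class = "expression_classification")
}

#' @export
print.expression_classification <- function(x, ...) {
  cat("expression_classification:", length(x$transcripts), "transcripts,",
      length(x$genotypes), "genotypes,", length(x$tissues), "tissues\n")
  cat("  presence threshold RPKM >=", x$presence,
      "| absence threshold RPKM <", x$absence, "\n")
  for (g in x$genotypes) {
    cat(sprintf("  %s: expressed %d, tissue-specific %d\n", g,
                sum(rowSums(x$expressed[[g]]) > 0),
                sum(!is.na(x$tissue_specific[[g]]))))
  }
  invisible(x)
}

#' Per-tissue expression summary
#'
#' Tabulates, per tissue and genotype, the number of expressed and
#' tissue-specific transcripts plus the count of tissue-specific calls common
#' to both genotypes, with a totals row (expressed-anywhere and column
#' totals). The bookkeeping identity
#' `|specific(g1)| + |specific(g2)| - |common| = |union of calls|`
#' is returned alongside.
#'
#' @param cls An `expression_classification`.
#' @return A list with `tissues`, per-genotype `expressed` and
#'   `tissue_specific` count vectors, `common`, `totals`, and
#'   `tissue_specific_union` (the size of the union of tissue-specific calls
#'   across genotypes).
#' @export
expression_summary <- function(cls) {
  stopifnot(inherits(cls, "expression_classification"))
  g <- cls$genotypes
  tiss <- cls$tissues
  expressed <- lapply(cls$expressed, function(e) colSums(e))
  ts <- lapply(cls$tissue_specific, function(lab) {
    v <- table(factor(lab, levels = tiss))
    stats::setNames(as.integer(v), tiss)
  })
  common <- stats::setNames(as.integer(table(factor(
    cls$common_tissue_specific, levels = tiss))), tiss)
  union_ts <- sum(vapply(seq_along(cls$transcripts), function(i) {
    any(!is.na(vapply(cls$tissue_specific, `[`, character(1), i)))
  }, logical(1)))
  list(
    tissues = tiss,
    expressed = expressed,
    tissue_specific = ts,
    common = common,
    totals = list(
      expressed = vapply(cls$expressed, function(e) sum(rowSums(e) > 0),
                         integer(1)),
      tissue_specific = vapply(ts, sum, integer(1)),
      common = sum(common)),
    tissue_specific_union = union_ts,
    all_total = length(cls$transcripts))
}

#' Most highly expressed transcripts of a genotype
#'
#' Ranks transcripts by either the maximum tissue-mean RPKM within the
#' genotype (default) or the mean RPKM over the genotype's libraries, in
#' descending order with ties broken lexicographically by id, and returns the
#' top `n`.
#'
#' @param rpkm RPKM matrix.
#' @param design Library design.
#' @param genotype Genotype label.
#' @param n List length (default 500, the atlas' headline list size).
#' @param metric `"max_tissue_mean"` or `"mean"`.
#' @return Character vector of `n` transcript ids, best first.
#' @export
top_expressed <- function(rpkm, design, genotype, n = 500,
                          metric = c("max_tissue_mean", "mean")) {
  metric <- match.arg(metric)
  if (!genotype %in% design$genotype) stop("unknown genotype: ", genotype)
  if (n > nrow(rpkm)) stop("n exceeds the transcript count")
  score <- switch(metric,
    max_tissue_mean = apply(tissue_means(rpkm, design, genotype), 1, max),
    mean = rowMeans(rpkm[, libs_for(design, genotype), drop = FALSE]))
  ids <- rownames(rpkm)
  ids[order(-score, ids)][seq_len(n)]
}

#' Overlap of two ranked transcript lists
#'
#' @param listA,listB Character vectors of transcript ids.
#' @return Sorted character vector of shared ids.
#' @export
top_overlap <- function(listA, listB) {
  sort(intersect(listA, listB))
}

#' Stably expressed (housekeeping-candidate) transcripts
#'
#' Scores transcripts whose RPKM strictly exceeds `min_rpkm` in every
#' in-scope sample by their co-variance COV = sd/mean (sd is the sample
#' standard deviation, n-1 denominator), keeps those with COV below
#' `cov_max`, and returns the `top_n` most stable. This mirrors the atlas'
#' screen for qRT-PCR reference-gene candidates (RPKM > 2 everywhere,
#' COV < 0.13, top 50).
#'
#' @param rpkm RPKM matrix.
#' @param design Library design.
#' @param genotype Optional genotype restricting the sample scope; `NULL`
#'   scores across all libraries.
#' @param min_rpkm Strict lower RPKM bound required in every sample.
#' @param cov_max Keep transcripts with COV strictly below this value.
#' @param top_n Maximum number of records returned.
#' @return data.frame with columns `transcript`, `mean`, `sd`, `cov`,
#'   sorted ascending by `cov` (ties by id).
#' @export
stable_transcripts <- function(rpkm, design, genotype = NULL, min_rpkm = 2,
                               cov_max = 0.13, top_n = 50) {
  check_design(design, rpkm)
  libs <- libs_for(design, genotype)
  if (length(libs) == 0) stop("empty sample scope")
  m <- rpkm[, libs, drop = FALSE]
  keep <- rowSums(m > min_rpkm) == ncol(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(transcript = character(), mean = numeric(),
                      sd = numeric(), cov = numeric()))
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cov <- sdv / mu
  out <- data.frame(transcript = rownames(m), mean = mu, sd = sdv, cov = cov,
                    row.names = NULL)
  out <- out[out$cov < cov_max, , drop = FALSE]
  out <- out[order(out$cov, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
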