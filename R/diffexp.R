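#' Within-condition noise distribution for the M-D test
#'
#' The nonparametric caller contrasts each transcript's between-condition
#' signal `(|M|, D)` against a noise cloud built from biological replicates:
#' for every within-condition replicate pair and every transcript it records
#' `Mn = |log2((x_i + pseudo) / (x_j + pseudo))|` and `Dn = |x_i - x_j|`,
#' pooled across both conditions. With R replicates per condition the cloud
#' holds `2 * choose(R, 2)` points per transcript.
#'
#' @param rpkm RPKM (or other normalized expression) matrix.
#' @param groupA,groupB Character vectors of library ids for the two
#'   conditions; each needs at least two replicates.
#' @param pseudo Pseudo-count added before the log ratio.
#' @return Numeric matrix with columns `Mn`, `Dn`.
#' @export
build_noise <- function(rpkm, groupA, groupB, pseudo = 0.5) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("noise undefined: each condition needs >= 2 replicates")
  }
  one <- function(libs) {
    m <- rpkm[, libs, drop = FALSE]
    pairs <- utils::combn(ncol(m), 2)
    pts <- lapply(seq_len(ncol(pairs)), function(k) {
      x <- m[, pairs[1, k]]
      y <- m[, pairs[2, k]]
      cbind(Mn = abs(log2((x + pseudo) / (y + pseudo))), Dn = abs(x - y))
    })
    do.call(rbind, pts)
  }
  out <- rbind(one(groupA), one(groupB))
  rownames(out) <- NULL
  out
}

# Fraction of noise points dominating each signal point (strict >= in both
# coordinates); q = 1 - fraction.
q_from_noise <- function(absM, D, noise) {
  nM <- noise[, 1]
  nD <- noise[, 2]
  n <- length(nM)
  frac <- vapply(seq_along(absM), function(i) {
    sum(nM >= absM[i] & nD >= D[i])
  }, numeric(1)) / n
  1 - frac
}

#' Nonparametric M-D differential expression call
#'
#' For each transcript, computes the log2 ratio `M` and absolute difference
#' `D` of the two condition means (means of raw values; the log ratio uses a
#' pseudo-count) and an empirical probability of signal
#' `q = 1 - P(noise dominates)`, where a noise point dominates when
#' `Mn >= |M|` and `Dn >= D` over the pooled replicate-pair noise cloud of
#' [build_noise()]. A transcript is called differentially expressed when its
#' pseudo-counted fold change reaches `fc_min` and `q >= q_min`; the default
#' `q_min = 0.95` is the conventional analog of an FDR of 0.05 for this
#' family of tests, and `fc_min = 2` is the atlas' fold-change rule.
#' Transcripts at zero in every library of both groups are reported with
#' `q = 0` and never called.
#'
#' @param rpkm Normalized expression matrix.
#' @param groupA,groupB Disjoint library-id vectors, >= 2 replicates each.
#' @param fc_min Minimum fold change `max(meanA, meanB) / min(meanA, meanB)`
#'   (computed after the pseudo-count).
#' @param q_min Minimum probability of signal.
#' @param pseudo Pseudo-count for ratios.
#' @param noise Optionally a precomputed noise matrix from [build_noise()]
#'   (with the same `pseudo`); built from the two groups when `NULL`.
#' @return data.frame with one row per transcript: `transcript`, `meanA`,
#'   `meanB`, `M`, `D`, `q`, `fold_change`, `called`.
#' @export
call_de <- function(rpkm, groupA, groupB, fc_min = 2, q_min = 0.95,
                    pseudo = 0.5, noise = NULL) {
  if (length(intersect(groupA, groupB)) > 0) {
    stop("condition groups overlap")
  }
  if (is.null(noise)) noise <- build_noise(rpkm, groupA, groupB, pseudo)
  mA <- rowMeans(rpkm[, groupA, drop = FALSE])
  mB <- rowMeans(rpkm[, groupB, drop = FALSE])
  M <- log2((mA + pseudo) / (mB + pseudo))
  D <- abs(mA - mB)
  fc <- pmax(mA + pseudo, mB + pseudo) / pmin(mA + pseudo, mB + pseudo)
  q <- q_from_noise(abs(M), D, noise)
  allzero <- mA == 0 & mB == 0
  q[allzero] <- 0
  called <- !allzero & fc >= fc_min & q >= q_min
  data.frame(transcript = rownames(rpkm), meanA = mA, meanB = mB,
             M = M, D = D, q = q, fold_change = fc, called = called,
             row.names = NULL)
}

#' Summarize a set of differential-expression contrasts
#'
#' @param calls Named list of [call_de()] results; names label the contrasts.
#' @return data.frame with one row per contrast: `contrast`, `n_called`,
#'   `n_up_A` (called with `meanA > meanB`), `n_up_B`.
#' @export
summarize_de <- function(calls) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  out <- lapply(names(calls), function(nm) {
    x <- calls[[nm]]
    data.frame(contrast = nm,
               n_called = sum(x$called),
               n_up_A = sum(x$called & x$M > 0),
               n_up_B = sum(x$called & x$M < 0))
  })
  do.call(rbind, out)
}

#' Between-genotype differential expression per tissue
#'
#' Runs [call_de()] for each tissue, contrasting the replicates of the first
#' genotype against the second, and tabulates the per-tissue call counts
#' (the shape of the atlas' between-subspecies DE table).
#'
#' @param rpkm Normalized expression matrix.
#' @param design Library design.
#' @param genotypes Pair of genotype labels; defaults to the design's first
#'   two.
#' @param ... Passed to [call_de()].
#' @return List with `calls` (per-tissue [call_de()] data.frames),
#'   `per_tissue` (named integer vector of call counts) and `total_union`
#'   (number of distinct transcripts called in at least one tissue).
#' @export
de_between_genotypes <- function(rpkm, design, genotypes = NULL, ...) {
  check_design(design, rpkm)
  if (is.null(genotypes)) genotypes <- unique(design$genotype)[1:2]
  tissues <- unique(design$tissue)
  calls <- lapply(tissues, function(ti) {
    call_de(rpkm, libs_for(design, genotypes[1], ti),
            libs_for(design, genotypes[2], ti), ...)
  })
  names(calls) <- tissues
  per_tissue <- vapply(calls, function(x) sum(x$called), integer(1))
  called_any <- unique(unlist(lapply(calls, function(x) {
    x$transcript[x$called]
  })))
  list(calls = calls, per_tissue = per_tissue,
       total_union = length(called_any))
}

#' Within-genotype tissue-pair differential expression matrix
#'
#' All-pairs tissue contrasts within one genotype, reported as a directional
#' matrix in which cell (row, column) counts the transcripts up-regulated in
#' the column tissue relative to the row tissue (the atlas' within-subspecies
#' DE table shape). The diagonal is `NA`.
#'
#' @param rpkm Normalized expression matrix.
#' @param design Library design.
#' @param genotype Genotype label.
#' @param ... Passed to [call_de()].
#' @return List with `matrix` (tissues x tissues directional counts) and
#'   `total_union` (distinct transcripts called in any pair).
#' @export
de_within_genotype <- function(rpkm, design, genotype, ...) {
  check_design(design, rpkm)
  tissues <- unique(design$tissue)
  k <- length(tissues)
  mat <- matrix(NA_integer_, k, k, dimnames = list(tissues, tissues))
  called_any <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      x <- call_de(rpkm, libs_for(design, genotype, tissues[i]),
                   libs_for(design, genotype, tissues[j]), ...)
      # up in column vs row: cell (row=i, col=j) counts meanB > meanA
      mat[i, j] <- sum(x$called & x$M < 0)
      mat[j, i] <- sum(x$called & x$M > 0)
      called_any <- union(called_any, x$transcript[x$called])
    }
  }
  list(matrix = mat, total_union = length(called_any))
}
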