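#' GO term over-representation by one-sided Fisher's exact test
#'
#' For every term annotated to at least one background transcript, tests
#' whether the term is over-represented in `subset` relative to the
#' background universe using the one-sided hypergeometric tail
#' `P(X >= k)` (Fisher's exact test with alternative "greater"), then
#' applies a Bonferroni correction over the terms tested.
#'
#' @param subset Character vector of transcript ids; must be contained in
#'   the background universe.
#' @param annotations data.frame with columns `transcript`, `term` (one row
#'   per assignment; a transcript may carry many terms).
#' @param universe Background transcript ids; defaults to the distinct
#'   transcripts of `annotations`. Supply the full catalog to include
#'   unannotated transcripts in the background size.
#' @param alpha Significance level on the adjusted p-value.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"less"` (under-representation).
#' @return data.frame sorted ascending by `p_adj`: `term`, `k` (subset
#'   transcripts with the term), `K` (background transcripts with the term),
#'   `n` (subset size), `N` (background size), `p`, `p_adj`, `significant`.
#' @export
fisher_enrichment <- function(subset, annotations, universe = NULL,
                              alpha = 0.05,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(annotations),
            all(c("transcript", "term") %in% names(annotations)))
  if (is.null(universe)) universe <- unique(annotations$transcript)
  if (anyDuplicated(universe)) universe <- unique(universe)
  subset <- unique(subset)
  if (length(setdiff(subset, universe)) > 0) {
    stop("subset contains ids outside the background universe")
  }
  ann <- annotations[annotations$transcript %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("transcript", "term")])
  N <- length(universe)
  n <- length(subset)
  terms <- split(ann$transcript, ann$term)
  K <- vapply(terms, length, integer(1))
  k <- vapply(terms, function(tx) sum(tx %in% subset), integer(1))
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(term = names(terms), k = k, K = K, n = n, N = N,
                    p = p, p_adj = p_adj, significant = p_adj <= alpha,
                    row.names = NULL)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windowed feature-density profile
#'
#' Counts features in half-open genomic windows `[i*w, (i+1)*w)` per
#' chromosome (0-based positions; a position at an exact multiple of the
#' window size falls in the higher window). The default window is 150 kb,
#' the atlas' chromosome-density plotting resolution.
#'
#' @param track data.frame with columns `chrom` and `pos` (bp, >= 0).
#' @param window Window size in bp (> 0).
#' @return data.frame `chrom`, `window` (0-based index), `start` (bp),
#'   `count`, covering every window from 0 to the last occupied window of
#'   each chromosome (zeros included).
#' @export
window_density <- function(track, window = 150000) {
  stopifnot(is.data.frame(track), all(c("chrom", "pos") %in% names(track)))
  if (window <= 0) stop("window must be > 0")
  if (nrow(track) == 0) {
    return(data.frame(chrom = character(), window = integer(),
                      start = numeric(), count = integer()))
  }
  if (any(track$pos < 0)) stop("negative feature position")
  out <- lapply(split(track$pos, track$chrom), function(p) {
    idx <- floor(p / window)
    nb <- max(idx) + 1
    data.frame(window = seq_len(nb) - 1L,
               start = (seq_len(nb) - 1) * window,
               count = tabulate(idx + 1, nbins = nb))
  })
  chroms <- names(out)
  out <- do.call(rbind, Map(function(ch, df) {
    cbind(chrom = ch, df)
  }, chroms, out))
  rownames(out) <- NULL
  out
}
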