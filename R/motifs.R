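#' Six-frame translation of a transcript catalog
#'
#' Translates each DNA sequence in all six reading frames (+1, +2, +3 on the
#' forward strand; -1, -2, -3 on the reverse complement) under the standard
#' genetic code. Trailing partial codons are dropped, stop codons are kept
#' as `*`, and codons containing ambiguous bases become `X`.
#'
#' @param catalog A named character vector of DNA sequences or a
#'   [Biostrings::DNAStringSet].
#' @return data.frame with columns `transcript`, `frame` (integer in
#'   `c(1, 2, 3, -1, -2, -3)`) and `peptide`.
#' @examples
#' six_frame_translate(c(t1 = "ATGTGTTGA"))
#' @export
six_frame_translate <- function(catalog) {
  if (!methods::is(catalog, "DNAStringSet")) {
    catalog <- Biostrings::DNAStringSet(catalog)
  }
  if (is.null(names(catalog))) stop("catalog sequences must be named")
  if (any(Biostrings::width(catalog) == 0)) {
    stop("empty sequence in catalog")
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- lapply(frames, function(f) {
    s <- if (f > 0) catalog else Biostrings::reverseComplement(catalog)
    off <- abs(f) - 1L
    w <- Biostrings::width(s)
    start <- pmin(off + 1L, w + 1L)
    len <- pmax(w - off, 0L)
    len <- len - len %% 3L
    sub <- Biostrings::subseq(s, start = start, width = len)
    pep <- rep("", length(sub))
    nz <- len > 0
    if (any(nz)) {
      pep[nz] <- as.character(Biostrings::translate(
        sub[nz], if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
    data.frame(transcript = names(catalog), frame = f, peptide = pep)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$transcript, names(catalog)),
                   match(out$frame, frames)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a cysteine-spacing motif pattern
#'
#' A pattern of k conserved cysteines separated by bounded runs of arbitrary
#' residues: `C-X(min1..max1)-C-...-C`. The default, four cysteines spaced
#' `C-X(4..20)-C-X(4..30)-C-X(4..20)-C`, is a configurable stand-in for the
#' conserved cysteine cluster of late nodulins and nodule-specific
#' cysteine-rich (NCR) peptides; analyses that need an exact motif should
#' supply their own gap ranges.
#'
#' @param gaps List of `c(min, max)` inter-cysteine gap ranges; the pattern
#'   has `length(gaps) + 1` cysteines.
#' @param name Pattern label.
#' @return An object of class `motif_pattern`.
#' @export
ncr_pattern <- function(gaps = list(c(4, 20), c(4, 30), c(4, 20)),
                        name = "cys4_cluster") {
  if (length(gaps) < 1) stop("pattern needs at least 2 cysteines")
  for (g in gaps) {
    if (length(g) != 2 || g[1] > g[2] || any(g < 0)) {
      stop("each gap range must be c(min, max) with 0 <= min <= max")
    }
  }
  structure(list(gaps = lapply(gaps, as.integer), name = name,
                 k = length(gaps) + 1L),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  spec <- paste(vapply(x$gaps, function(g) {
    sprintf("X(%d..%d)", g[1], g[2])
  }, character(1)), collapse = "-C-")
  cat(sprintf("motif_pattern '%s': C-%s-C (%d cysteines)\n",
              x$name, spec, x$k))
  invisible(x)
}

# Greedy leftmost / shortest-gap (lexicographic backtracking) chain search
# within one stop-free peptide segment. cpos: 1-based cysteine positions.
# Returns the matched cysteine positions or NULL.
chain_from <- function(cpos, start_idx, gaps) {
  path <- integer(length(gaps) + 1L)
  path[1L] <- cpos[start_idx]
  level <- 1L
  # candidate index cursors per level
  cursor <- vector("list", length(gaps))
  while (TRUE) {
    if (level > length(gaps)) return(path)
    prev <- path[level]
    g <- gaps[[level]]
    if (is.null(cursor[[level]])) {
      cand <- cpos[cpos - prev - 1L >= g[1] & cpos - prev - 1L <= g[2]]
      cursor[[level]] <- list(cand = cand, i = 1L)
    }
    st <- cursor[[level]]
    if (st$i <= length(st$cand)) {
      path[level + 1L] <- st$cand[st$i]
      cursor[[level]]$i <- st$i + 1L
      level <- level + 1L
    } else {
      cursor[level] <- list(NULL)
      level <- level - 1L
      if (level < 1L) return(NULL)
    }
  }
}

# Scan one peptide string; returns matrix of matched cysteine positions
# (rows = hits) under greedy non-overlapping (or all leftmost-per-start)
# matching. Matches never span a stop: the peptide is cut at '*'.
scan_peptide <- function(peptide, pattern, all_matches = FALSE) {
  hits <- list()
  if (nchar(peptide) == 0) return(hits)
  segs <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  offset <- 0L
  for (seg in segs) {
    n <- nchar(seg)
    if (n > 0) {
      cpos <- which(strsplit(seg, "", fixed = TRUE)[[1]] == "C")
      i <- 1L
      while (i <= length(cpos)) {
        m <- chain_from(cpos, i, pattern$gaps)
        if (!is.null(m)) {
          hits[[length(hits) + 1L]] <- m + offset
          if (all_matches) {
            i <- i + 1L
          } else {
            # resume after the last matched cysteine
            i <- match(TRUE, cpos > m[length(m)], nomatch = length(cpos) + 1L)
          }
        } else {
          i <- i + 1L
        }
      }
    }
    offset <- offset + n + 1L  # account for the '*' separator
  }
  hits
}

#' Scan translated frames for a cysteine-spacing motif
#'
#' Left-to-right greedy scan of each (transcript, frame) peptide: matches
#' start at the leftmost feasible cysteine, prefer the shortest admissible
#' gaps (with backtracking, so a reported match is the lexicographically
#' first chain), never span a stop codon, and by default do not overlap
#' (the next scan resumes after the last matched cysteine).
#'
#' @param frames Output of [six_frame_translate()].
#' @param pattern A [ncr_pattern()].
#' @param all_matches Report a match from every feasible start cysteine
#'   (overlaps allowed) instead of the non-overlapping greedy set.
#' @return data.frame with columns `transcript`, `frame`, `start`, `end`
#'   (1-based peptide positions of the first and last matched cysteine) and
#'   `cys_positions` (comma-separated matched positions).
#' @export
scan_ncr <- function(frames, pattern, all_matches = FALSE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  rows <- list()
  for (r in seq_len(nrow(frames))) {
    hs <- scan_peptide(frames$peptide[r], pattern, all_matches)
    for (m in hs) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = frames$transcript[r], frame = frames$frame[r],
        start = m[1], end = m[length(m)],
        cys_positions = paste(m, collapse = ","))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript = character(), frame = integer(),
                      start = integer(), end = integer(),
                      cys_positions = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join motif hits with nodule-specific expression calls
#'
#' Intersects motif-bearing transcripts with the transcripts called
#' tissue-specific to the nodule in each genotype, and reports the
#' genotype-unique subsets (motif-bearing nodule-specific transcripts
#' expressed in one genotype but not the other).
#'
#' @param hits Output of [scan_ncr()].
#' @param cls An [classify_expression()] result on the same transcript
#'   universe.
#' @param nodule_tissue Tissue label of the nodule.
#' @return List with per-genotype id vectors `nodule_ncr`, per-genotype
#'   `unique` subsets (additionally genotype-specific), the `common` set
#'   (nodule-specific with the motif in both genotypes) and `counts`.
#' @export
nodule_ncr_join <- function(hits, cls, nodule_tissue = "Nodule") {
  stopifnot(inherits(cls, "expression_classification"))
  if (!nodule_tissue %in% cls$tissues) {
    stop("unknown nodule tissue label: ", nodule_tissue)
  }
  motif_tx <- unique(hits$transcript)
  strange <- setdiff(motif_tx, cls$transcripts)
  if (length(strange) > 0) {
    stop("motif hits reference transcripts outside the classified universe")
  }
  per_g <- lapply(cls$genotypes, function(g) {
    ns <- cls$transcripts[!is.na(cls$tissue_specific[[g]]) &
                            cls$tissue_specific[[g]] == nodule_tissue]
    sort(intersect(ns, motif_tx))
  })
  names(per_g) <- cls$genotypes
  uniq <- lapply(cls$genotypes, function(g) {
    gs <- cls$transcripts[!is.na(cls$genotype_specific) &
                            cls$genotype_specific == g]
    sort(intersect(per_g[[g]], gs))
  })
  names(uniq) <- cls$genotypes
  common <- sort(Reduce(intersect, per_g))
  list(nodule_ncr = per_g, unique = uniq, common = common,
       counts = list(
         per_genotype = vapply(per_g, length, integer(1)),
         unique = vapply(uniq, length, integer(1)),
         common = length(common)))
}
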