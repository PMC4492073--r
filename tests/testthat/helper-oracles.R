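# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: connected components via hand-rolled union-find, the
# hypergeometric tail via explicit combinatorial enumeration, the motif scan
# via lazy regular expressions, binning via a double loop.

oracle_union_find <- function(edges, universe) {
  parent <- stats::setNames(universe, universe)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- find(edges[i, 1])
      b <- find(edges[i, 2])
      if (a != b) parent[[a]] <- b
    }
  }
  roots <- vapply(universe, find, character(1))
  split(universe, roots)
}

# P(X >= k) for X ~ Hypergeom(K carriers, N total, n drawn), by summing
# exact binomial-coefficient counts.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- seq(max(k, 0), min(K, n))
  if (length(j) == 0) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Non-overlapping leftmost lazy-regex motif matches; returns a data.frame of
# (start, end) in full-peptide coordinates. Segments between stops are
# scanned independently so a match can never span '*'.
oracle_regex_scan <- function(peptide, gaps) {
  rx <- paste0("C", paste(vapply(gaps, function(g) {
    sprintf(".{%d,%d}?C", g[1], g[2])
  }, character(1)), collapse = ""))
  segs <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  offset <- 0L
  out <- list()
  for (seg in segs) {
    from <- 1L
    while (from <= nchar(seg)) {
      m <- regexpr(rx, substring(seg, from), perl = TRUE)
      if (m == -1L) break
      st <- from + as.integer(m) - 1L
      en <- st + attr(m, "match.length") - 1L
      out[[length(out) + 1L]] <- c(start = st + offset, end = en + offset)
      from <- en + 1L
    }
    offset <- offset + nchar(seg) + 1L
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

oracle_bin_counts <- function(pos, w, nbins) {
  counts <- integer(nbins)
  for (p in pos) {
    for (b in seq_len(nbins)) {
      if (p >= (b - 1) * w && p < b * w) counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Naive double-loop evaluation of the probability-of-signal definition.
oracle_q <- function(absM, D, noise) {
  vapply(seq_along(absM), function(i) {
    dom <- 0L
    for (j in seq_len(nrow(noise))) {
      if (noise[j, 1] >= absM[i] && noise[j, 2] >= D[i]) dom <- dom + 1L
    }
    1 - dom / nrow(noise)
  }, numeric(1))
}

random_peptide <- function(len, alphabet = c(LETTERS[1:26])) {
  # biased towards C and * so motif chains and stops actually occur
  aa <- c("C", "C", "*", "A", "G", "L", "S", "T", "V", "R", "K", "D", "E")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# small expression fixture: counts with chosen per-(genotype,tissue) means
make_rpkm <- function(tissue_means_by_genotype, design, noise = 0) {
  # tissue_means_by_genotype: list(genotype = matrix transcripts x tissues)
  g1 <- tissue_means_by_genotype[[1]]
  tx <- rownames(g1)
  m <- matrix(0, length(tx), nrow(design),
              dimnames = list(tx, design$library))
  for (g in names(tissue_means_by_genotype)) {
    mg <- tissue_means_by_genotype[[g]]
    for (ti in colnames(mg)) {
      libs <- design$library[design$genotype == g & design$tissue == ti]
      for (l in libs) m[, l] <- mg[, ti]
    }
  }
  if (noise > 0) m <- m + matrix(abs(rnorm(length(m), 0, noise)), nrow(m))
  m
}
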