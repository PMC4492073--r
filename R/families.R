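#' Read a 12-column tabular homology hit file
#'
#' The standard tabular alignment-report dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score.
#'
#' @param path Path to a (possibly headerless) tab-separated hit file.
#' @return data.frame with the standard column names (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) != 12) stop("expected 12 tab-separated columns, got ", ncol(x))
  names(x) <- cols
  x
}

check_hits <- function(hits) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    stop("hits must be a data.frame with at least columns ",
         paste(need, collapse = ", "))
  }
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  invisible(hits)
}

#' Single-linkage gene families from a homology hit table
#'
#' Builds an undirected graph whose vertices are all sequences in the
#' species map and whose edges join query and subject of every hit at or
#' below `family_evalue` (default 0: only hits reported with E = 0 link
#' sequences, mirroring a two-stage search-then-cluster procedure).
#' Gene families are the connected components; sequences without a
#' qualifying edge become singleton families. Output is independent of hit
#' order: families are numbered by their lexicographically smallest member.
#'
#' @param hits Hit table (see [read_blast_tab()]); self-hits are ignored.
#' @param species Named character vector mapping every sequence id to its
#'   species label (the clustering universe).
#' @param family_evalue Maximum E-value for an edge.
#' @return data.frame with one row per sequence: `id`, `species`, `family`
#'   (ids like `fam00001`), sorted by family then id.
#' @export
cluster_families <- function(hits, species, family_evalue = 0) {
  check_hits(hits)
  if (is.null(names(species))) stop("species must be a named vector")
  universe <- sort(names(species))
  unknown <- setdiff(c(hits$qseqid, hits$sseqid), universe)
  if (length(unknown) > 0) {
    stop("hit references ids absent from the species map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  edges <- hits[hits$evalue <= family_evalue & hits$qseqid != hits$sseqid,
                c("qseqid", "sseqid"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = universe)
  comp <- igraph::components(g)$membership
  # renumber components by smallest member id for order-independence
  smallest <- vapply(split(names(comp), comp), min, character(1))
  lev <- names(sort(smallest))
  fam <- sprintf("fam%05d", match(as.character(comp), lev))
  out <- data.frame(id = names(comp), species = unname(species[names(comp)]),
                    family = fam)
  out <- out[order(out$family, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-family member counts for two species
#'
#' @param families Output of [cluster_families()].
#' @param focal,reference Species labels.
#' @return data.frame `family`, `n_focal`, `n_reference`.
#' @export
family_counts <- function(families, focal, reference) {
  fam <- sort(unique(families$family))
  nf <- table(factor(families$family[families$species == focal],
                     levels = fam))
  nr <- table(factor(families$family[families$species == reference],
                     levels = fam))
  data.frame(family = fam, n_focal = as.integer(nf),
             n_reference = as.integer(nr), row.names = NULL)
}

#' Ploidy-aware chi-square test for gene-family expansion
#'
#' For each family with at least `min_total` members across the two species,
#' tests the observed member counts `(n_focal, n_reference)` against the
#' expected proportions `(r/(r+1), 1/(r+1))` with a 1-df chi-square
#' goodness-of-fit statistic. The default `expected_ratio = 2` encodes the
#' focal species' polyploidy (tetraploid vs diploid: a 2:1 transcript
#' expectation); setting it to the genome-wide transcript-count ratio is the
#' main alternative. P-values are Bonferroni-corrected over the families
#' tested.
#'
#' @param families Output of [cluster_families()].
#' @param focal,reference Species labels (focal = the polyploid).
#' @param expected_ratio Expected focal:reference member ratio (> 0).
#' @param alpha Significance level applied to the adjusted p-value.
#' @param min_total Minimum family size (both species) to be tested.
#' @param yates Apply the continuity correction.
#' @return data.frame per tested family: `family`, `n_focal`,
#'   `n_reference`, `chi2`, `p`, `p_adj`, `significant`, `direction`
#'   (`"expanded"` / `"contracted"` / `"as_expected"`), sorted ascending by
#'   `p_adj`.
#' @export
expansion_test <- function(families, focal, reference, expected_ratio = 2,
                           alpha = 0.01, min_total = 5, yates = FALSE) {
  if (expected_ratio <= 0) stop("expected_ratio must be > 0")
  cnt <- family_counts(families, focal, reference)
  cnt <- cnt[cnt$n_focal + cnt$n_reference >= min_total, , drop = FALSE]
  if (nrow(cnt) == 0) {
    return(data.frame(family = character(), n_focal = integer(),
                      n_reference = integer(), chi2 = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), direction = character()))
  }
  total <- cnt$n_focal + cnt$n_reference
  pf <- expected_ratio / (expected_ratio + 1)
  ef <- total * pf
  er <- total * (1 - pf)
  dev_f <- abs(cnt$n_focal - ef)
  dev_r <- abs(cnt$n_reference - er)
  if (yates) {
    dev_f <- pmax(dev_f - 0.5, 0)
    dev_r <- pmax(dev_r - 0.5, 0)
  }
  chi2 <- dev_f^2 / ef + dev_r^2 / er
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  out <- data.frame(family = cnt$family, n_focal = cnt$n_focal,
                    n_reference = cnt$n_reference, chi2 = chi2, p = p,
                    p_adj = p_adj, significant = p_adj <= alpha,
                    direction = ifelse(cnt$n_focal > ef, "expanded",
                                ifelse(cnt$n_focal < ef, "contracted",
                                       "as_expected")))
  out <- out[order(out$p_adj, out$p, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-hit annotation and unique-target counts
#'
#' Keeps hits at or below `evalue_cutoff` and selects one best hit per
#' query: lowest E-value, ties broken by highest bit score, then by
#' lexicographic subject id.
#'
#' @param hits Hit table.
#' @param evalue_cutoff Maximum E-value for a hit to count (default 1e-10,
#'   the atlas' annotation cutoff).
#' @return data.frame of best hits (all input columns, one row per
#'   annotated query).
#' @export
best_hit_annotate <- function(hits, evalue_cutoff = 1e-10) {
  check_hits(hits)
  x <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(x) == 0) {
    return(x)
  }
  x <- x[order(x$qseqid, x$evalue, -x$bitscore, x$sseqid), , drop = FALSE]
  out <- x[!duplicated(x$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname best_hit_annotate
#' @param annotated Output of [best_hit_annotate()].
#' @return `unique_target_count`: named integer vector with `queries`
#'   (queries with at least one qualifying hit) and `subjects` (distinct
#'   subjects hit), the two rows of the atlas' cross-species hit table.
#' @export
unique_target_count <- function(annotated) {
  c(queries = length(unique(annotated$qseqid)),
    subjects = length(unique(annotated$sseqid)))
}
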