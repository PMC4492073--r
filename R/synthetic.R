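#' Configuration for the synthetic atlas generator
#'
#' Bundles every knob of the planted-truth simulator. The default layout
#' emulates the atlas study design — two genotypes (B47, F56) by six tissues
#' by three biological replicates of negative-binomially distributed counts —
#' at desk scale, with planted housekeeping, tissue-specific,
#' genotype-specific and differentially expressed transcripts, planted
#' in-frame cysteine-cluster peptides, planted per-replicate SNP evidence,
#' planted gene families (including 16:2 expansions over a 2:1 background)
#' and one planted enriched GO term.
#'
#' In noiseless mode (the default) cells of absent classes are exactly zero
#' and present cells are floored at `min_present_count`, so classification
#' truth is recoverable without error.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_transcripts Catalog size.
#' @param genotypes,tissues,replicates Study design.
#' @param n_housekeeping Transcripts expressed tightly everywhere.
#' @param n_tissue_specific Per tissue, transcripts expressed in that tissue
#'   only, in both genotypes (common tissue-specific).
#' @param n_genotype_specific Per genotype, transcripts expressed in that
#'   genotype only; a fraction `gs_tissue_frac` of them is additionally
#'   restricted to a single tissue (cycling through the tissue list).
#' @param gs_tissue_frac See above.
#' @param n_de_per_tissue Per tissue, transcripts expressed everywhere with
#'   a planted `de_fold` change between genotypes in that tissue (the
#'   up-regulated genotype alternates).
#' @param de_fold Planted fold change.
#' @param mean_background,mean_housekeeping,mean_specific Negative-binomial
#'   means of present cells by class.
#' @param dispersion,dispersion_housekeeping NB dispersions (variance =
#'   mu + dispersion * mu^2).
#' @param noiseless Absent cells exactly 0 and present cells floored.
#' @param min_present_count Floor for present cells in noiseless mode.
#' @param absent_mean NB mean of absent cells when `noiseless = FALSE`.
#' @param length_range Transcript length range (bp).
#' @param motif_pattern Planted cysteine-spacing pattern; the default is a
#'   strict six-cysteine pattern with exact gaps so that random sequence
#'   essentially never matches.
#' @param n_motif_common_nodule Motif plants among common nodule-specific
#'   transcripts.
#' @param n_motif_gs_nodule Per genotype, motif plants among
#'   genotype-specific nodule-restricted transcripts.
#' @param n_snp_gs Per genotype, planted passing genotype-specific SNPs.
#' @param n_snp_shared Planted passing SNPs in the same tissue of both
#'   genotypes.
#' @param n_snp_fail Planted near-miss SNPs failing in exactly one replicate.
#' @param snp_min_alt Alt-read threshold the plants are built around.
#' @param n_family_background Background families at `family_background_size`
#'   (focal, reference) member counts, matching the 2:1 ploidy expectation.
#' @param family_background_size,family_expanded_size `c(n_focal, n_ref)`.
#' @param n_family_expanded Planted expanded families.
#' @param n_family_singletons Per species, sequences with no homology edge.
#' @param family_species `c(focal = ..., reference = ...)` species labels.
#' @param n_go_terms Number of GO terms; the first is the planted enriched
#'   term.
#' @param go_background_rate,go_enriched_rate Per-transcript annotation
#'   probabilities for the enriched term outside/inside the target subset
#'   (the common nodule-specific transcripts); other terms use the
#'   background rate everywhere.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_transcripts = 2000L,
    genotypes = c("B47", "F56"),
    tissues = msgi_tissues(),
    replicates = 3L,
    n_housekeeping = 50L,
    n_tissue_specific = 30L,
    n_genotype_specific = 60L,
    gs_tissue_frac = 0.4,
    n_de_per_tissue = 20L,
    de_fold = 4,
    mean_background = 100,
    mean_housekeeping = 200,
    mean_specific = 300,
    dispersion = 0.1,
    dispersion_housekeeping = 0.005,
    noiseless = TRUE,
    min_present_count = 20L,
    absent_mean = 0.2,
    length_range = c(300L, 1500L),
    motif_pattern = ncr_pattern(list(c(6, 6), c(9, 9), c(6, 6), c(8, 8),
                                     c(7, 7)),
                                name = "planted_cys6"),
    n_motif_common_nodule = 12L,
    n_motif_gs_nodule = 3L,
    n_snp_gs = 10L,
    n_snp_shared = 10L,
    n_snp_fail = 10L,
    snp_min_alt = 10L,
    n_family_background = 30L,
    family_background_size = c(4L, 2L),
    n_family_expanded = 3L,
    family_expanded_size = c(16L, 2L),
    n_family_singletons = 10L,
    family_species = c(focal = "Msa", reference = "Mtr"),
    n_go_terms = 30L,
    go_background_rate = 0.05,
    go_enriched_rate = 0.5) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  planted <- n_housekeeping + length(tissues) * n_tissue_specific +
    length(genotypes) * n_genotype_specific +
    length(tissues) * n_de_per_tissue
  if (planted > n_transcripts) {
    stop("invalid class sizes: planted classes exceed n_transcripts")
  }
  if (any(c(mean_background, mean_housekeeping, mean_specific) <= 0)) {
    stop("class means must be > 0")
  }
  if (length(genotypes) != 2) stop("the generator assumes two genotypes")
  structure(cfg, class = "simulation_config")
}

# Deterministic class assignment: transcripts are labeled in fixed blocks so
# every simulate_* operation agrees on the planted truth without sharing RNG
# state.
assign_classes <- function(config) {
  n <- config$n_transcripts
  ids <- sprintf("t%05d", seq_len(n))
  cls <- data.frame(transcript = ids, class = "background",
                    tissue = NA_character_, genotype = NA_character_,
                    de_fold = NA_real_)
  i <- 1L
  take <- function(k) {
    idx <- seq.int(i, length.out = k)
    i <<- i + k
    idx
  }
  cls$class[take(config$n_housekeeping)] <- "housekeeping"
  for (ti in config$tissues) {
    idx <- take(config$n_tissue_specific)
    cls$class[idx] <- "tissue_specific"
    cls$tissue[idx] <- ti
  }
  for (g in config$genotypes) {
    k <- config$n_genotype_specific
    idx <- take(k)
    cls$class[idx] <- "genotype_specific"
    cls$genotype[idx] <- g
    k_ts <- ceiling(config$gs_tissue_frac * k)
    if (k_ts > 0) {
      cls$tissue[idx[seq_len(k_ts)]] <-
        rep(config$tissues, length.out = k_ts)
    }
  }
  for (j in seq_along(config$tissues)) {
    idx <- take(config$n_de_per_tissue)
    cls$class[idx] <- "de"
    cls$tissue[idx] <- config$tissues[j]
    # alternate the up-regulated genotype
    cls$genotype[idx] <- config$genotypes[1 + (seq_along(idx) %% 2)]
    cls$de_fold[idx] <- config$de_fold
  }
  cls
}

# Transcript lengths, deterministic for a config (own RNG stream so counts
# and sequences agree).
transcript_lengths <- function(config) {
  set.seed(config$seed + 11L)
  L <- sample(seq(config$length_range[1], config$length_range[2]),
              config$n_transcripts, replace = TRUE)
  names(L) <- sprintf("t%05d", seq_len(config$n_transcripts))
  L
}

#' Simulate the atlas count matrix with planted truth
#'
#' Draws negative-binomial counts per the class layout of the configuration
#' (see [simulation_config()]). Each transcript class defines which
#' (genotype, tissue) cells are "present"; present cells draw
#' `NB(mu, size = 1/dispersion)` (floored in noiseless mode), absent cells
#' are exactly zero in noiseless mode.
#'
#' @param config A [simulation_config()].
#' @return List with `counts` (integer matrix), `design`, `lengths` and
#'   `truth` (per-transcript class table).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  design <- atlas_design(config$genotypes, config$tissues,
                         config$replicates)
  truth <- assign_classes(config)
  L <- transcript_lengths(config)
  set.seed(config$seed + 1L)

  n <- config$n_transcripts
  mu <- matrix(0, n, nrow(design),
               dimnames = list(truth$transcript, design$library))
  size <- rep(1 / config$dispersion, n)
  for (r in seq_len(n)) {
    cl <- truth$class[r]
    if (cl == "housekeeping") {
      mu[r, ] <- config$mean_housekeeping
      size[r] <- 1 / config$dispersion_housekeeping
    } else if (cl == "tissue_specific") {
      mu[r, design$tissue == truth$tissue[r]] <- config$mean_specific
    } else if (cl == "genotype_specific") {
      g <- design$genotype == truth$genotype[r]
      if (is.na(truth$tissue[r])) {
        mu[r, g] <- config$mean_specific
      } else {
        mu[r, g & design$tissue == truth$tissue[r]] <- config$mean_specific
      }
    } else if (cl == "de") {
      mu[r, ] <- config$mean_background
      up <- design$genotype == truth$genotype[r] &
        design$tissue == truth$tissue[r]
      mu[r, up] <- config$mean_background * truth$de_fold[r]
    } else {
      mu[r, ] <- config$mean_background
    }
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(size, ncol(mu))),
                   n, ncol(mu), dimnames = dimnames(mu))
  present <- mu > 0
  if (config$noiseless) {
    counts[present] <- pmax(counts[present], config$min_present_count)
  } else {
    counts[!present] <- stats::rnbinom(sum(!present), mu = config$absent_mean,
                                       size = 1 / config$dispersion)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design, lengths = L, truth = truth)
}

# one arbitrary codon per amino acid (standard code, no ambiguity)
aa_codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Peptide matching `pattern` with non-cysteine gap/flank residues.
motif_peptide <- function(pattern, flank = 5) {
  res <- setdiff(names(aa_codon), "C")
  gap <- function(k) paste(sample(res, k, replace = TRUE), collapse = "")
  gaps <- vapply(pattern$gaps, function(g) {
    g[1] + sample.int(g[2] - g[1] + 1L, 1L) - 1L
  }, numeric(1))
  body <- paste0("C", paste(vapply(seq_along(gaps), function(j) {
    paste0(gap(gaps[j]), "C")
  }, character(1)), collapse = ""))
  paste0(gap(flank), body, gap(flank))
}

reverse_translate <- function(pep) {
  paste(aa_codon[strsplit(pep, "")[[1]]], collapse = "")
}

#' Simulate the transcript catalog with planted motif ORFs
#'
#' Generates random DNA at the configured catalog lengths and embeds, in the
#' designated motif-bearing transcripts (common nodule-specific plus a few
#' genotype-specific nodule-restricted ones), an in-frame peptide matching
#' the configured cysteine pattern. The planted reading frame cycles over
#' all six frames (reverse-strand plants land in the minus frames) and is
#' recorded in the truth table; planted coding regions contain no internal
#' stop within the motif span.
#'
#' @param config A [simulation_config()].
#' @return List with `sequences` (a [Biostrings::DNAStringSet] matching the
#'   catalog lengths) and `truth` (`transcript`, `planted`, `frame`).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cls <- assign_classes(config)
  L <- transcript_lengths(config)
  set.seed(config$seed + 2L)

  plant_ids <- motif_plant_ids(config, cls)
  frames <- rep(c(1L, 2L, 3L, -1L, -2L, -3L), length.out = length(plant_ids))
  names(frames) <- plant_ids

  seqs <- character(config$n_transcripts)
  names(seqs) <- cls$transcript
  for (id in cls$transcript) {
    len <- L[[id]]
    if (!id %in% plant_ids) {
      seqs[[id]] <- random_dna(len)
      next
    }
    f <- frames[[id]]
    pep <- motif_peptide(config$motif_pattern)
    core <- reverse_translate(pep)
    off <- abs(f) - 1L
    pad_total <- len - nchar(core) - off
    if (pad_total < 0) stop("pattern unembeddable in transcript length ", len)
    left_codons <- if (pad_total >= 3) sample(0:(pad_total %/% 3), 1) else 0
    left <- off + 3 * left_codons
    right <- pad_total - 3 * left_codons
    s <- paste0(random_dna(left), core, random_dna(right))
    if (f < 0) {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    seqs[[id]] <- s
  }
  truth <- data.frame(transcript = cls$transcript,
                      planted = cls$transcript %in% plant_ids,
                      frame = ifelse(cls$transcript %in% plant_ids,
                                     frames[cls$transcript], NA_integer_))
  list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
}

# ids designated to carry the planted motif: common nodule-specific first,
# then genotype-specific transcripts restricted to the nodule.
motif_plant_ids <- function(config, cls = assign_classes(config)) {
  nod <- "Nodule"
  if (!nod %in% config$tissues) nod <- config$tissues[length(config$tissues)]
  common <- cls$transcript[cls$class == "tissue_specific" &
                             cls$tissue == nod]
  ids <- utils::head(common, config$n_motif_common_nodule)
  for (g in config$genotypes) {
    gs <- cls$transcript[cls$class == "genotype_specific" &
                           !is.na(cls$tissue) & cls$tissue == nod &
                           cls$genotype == g]
    ids <- c(ids, utils::head(gs, config$n_motif_gs_nodule))
  }
  ids
}

#' Simulate per-replicate SNP evidence with planted pass/fail truth
#'
#' Plants genotype-specific, shared (same tissue, both genotypes) and
#' near-miss SNPs. Passing plants have `alt_reads >= snp_min_alt` in every
#' replicate of their occurrence cells; each near-miss violates exactly one
#' rule (one replicate at `snp_min_alt - 1`). Sub-threshold noise rows are
#' added for realism.
#'
#' @param config A [simulation_config()].
#' @return List with `evidence` (per-replicate rows) and `truth` (one row
#'   per planted SNP: intended pass/fail, class, tissue-specificity).
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cls <- assign_classes(config)
  L <- transcript_lengths(config)
  set.seed(config$seed + 3L)

  hosts <- cls$transcript[cls$class == "background"]
  n_plant <- 2 * config$n_snp_gs + config$n_snp_shared + config$n_snp_fail
  if (length(hosts) < n_plant) stop("not enough background transcripts")
  hosts <- sample(hosts, n_plant)
  bases <- c("A", "C", "G", "T")
  tiss <- config$tissues
  reps <- seq_len(config$replicates)

  truth <- list()
  rows <- list()
  add_rows <- function(tx, pos, ref, alt, g, ti, alt_reads_vec) {
    for (r in reps) {
      ar <- alt_reads_vec[r]
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript = tx, pos = pos, ref = ref, alt = alt, genotype = g,
        tissue = ti, replicate = r, alt_reads = ar,
        depth = ar + 15L + stats::rpois(1, 10))
    }
  }
  pass_reads <- function() config$snp_min_alt + stats::rpois(
    config$replicates, 5)

  h <- 1L
  plant <- function(class_label, g_set, tissues_set, pass) {
    tx <- hosts[h]
    h <<- h + 1L
    pos <- sample.int(L[[tx]], 1) - 1L
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    first_cell <- TRUE
    for (g in g_set) for (ti in tissues_set) {
      ar <- pass_reads()
      if (!pass && first_cell) {
        ar[config$replicates] <- config$snp_min_alt - 1L
      }
      add_rows(tx, pos, ref, alt, g, ti, ar)
      first_cell <- FALSE
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      transcript = tx, pos = pos, ref = ref, alt = alt,
      intended_pass = pass, class = class_label,
      tissue_specific = length(tissues_set) == 1)
  }

  for (g in config$genotypes) {
    k <- config$n_snp_gs
    k_single <- ceiling(k / 2)
    for (j in seq_len(k)) {
      ts <- if (j <= k_single) tiss[1 + (j - 1) %% length(tiss)] else
        tiss[c(1 + (j - 1) %% length(tiss),
               1 + j %% length(tiss))]
      plant(g, g, ts, pass = TRUE)
    }
  }
  for (j in seq_len(config$n_snp_shared)) {
    plant("shared", config$genotypes, tiss[1 + (j - 1) %% length(tiss)],
          pass = TRUE)
  }
  for (j in seq_len(config$n_snp_fail)) {
    plant(config$genotypes[1 + j %% 2],
          config$genotypes[1 + j %% 2],
          tiss[1 + (j - 1) %% length(tiss)], pass = FALSE)
  }
  # sub-threshold noise
  for (j in seq_len(20)) {
    tx <- sample(cls$transcript, 1)
    ref <- sample(bases, 1)
    add_rows(tx, sample.int(L[[tx]], 1) - 1L, ref,
             sample(setdiff(bases, ref), 1),
             sample(config$genotypes, 1), sample(tiss, 1),
             sample(0:(config$snp_min_alt - 1L), config$replicates,
                    replace = TRUE))
  }
  evidence <- do.call(rbind, rows)
  rownames(evidence) <- NULL
  list(evidence = evidence, truth = do.call(rbind, truth))
}

#' Simulate an all-vs-all homology hit table with planted families
#'
#' Emits background families at the 2:1 ploidy-consistent member ratio,
#' planted expanded families, and per-species singletons. Family members
#' form cliques with E-value 0 in the 12-column hit table; weak cross-family
#' hits (E = 1e-25) are added and must be ignored at the E = 0 clustering
#' cutoff.
#'
#' @param config A [simulation_config()].
#' @return List with `hits`, `species` (named vector) and `truth`
#'   (per planted family: smallest member id, member counts, expansion flag).
#' @export
simulate_homology <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 4L)
  sp <- config$family_species
  fams <- list()
  addfam <- function(label, n_focal, n_ref, expanded) {
    members <- c(sprintf("msa_%s_%02d", label, seq_len(n_focal)),
                 if (n_ref > 0) sprintf("mtr_%s_%02d", label, seq_len(n_ref)))
    species <- c(rep(sp[["focal"]], n_focal), rep(sp[["reference"]], n_ref))
    fams[[length(fams) + 1L]] <<- list(label = label, members = members,
                                       species = species,
                                       expanded = expanded)
  }
  for (j in seq_len(config$n_family_expanded)) {
    addfam(sprintf("E%02d", j), config$family_expanded_size[1],
           config$family_expanded_size[2], TRUE)
  }
  for (j in seq_len(config$n_family_background)) {
    addfam(sprintf("B%02d", j), config$family_background_size[1],
           config$family_background_size[2], FALSE)
  }
  species <- unlist(lapply(fams, function(f) {
    stats::setNames(f$species, f$members)
  }))
  singles <- c(stats::setNames(rep(sp[["focal"]], config$n_family_singletons),
                               sprintf("msa_S_%02d",
                                       seq_len(config$n_family_singletons))),
               stats::setNames(rep(sp[["reference"]],
                                   config$n_family_singletons),
                               sprintf("mtr_S_%02d",
                                       seq_len(config$n_family_singletons))))
  species <- c(species, singles)

  hit_row <- function(q, s, evalue) {
    data.frame(qseqid = q, sseqid = s, pident = round(stats::runif(1, 90, 100), 2),
               length = sample(200:1200, 1), mismatch = sample(0:20, 1),
               gapopen = sample(0:3, 1), qstart = 1L, qend = 500L,
               sstart = 1L, send = 500L, evalue = evalue,
               bitscore = round(stats::runif(1, 400, 900), 1))
  }
  rows <- list()
  for (f in fams) {
    pairs <- utils::combn(f$members, 2)
    for (k in seq_len(ncol(pairs))) {
      rows[[length(rows) + 1L]] <- hit_row(pairs[1, k], pairs[2, k], 0)
    }
  }
  # weak cross-family hits, above the family cutoff
  labels <- vapply(fams, function(f) f$members[1], character(1))
  if (length(labels) >= 2) {
    for (k in seq_len(length(labels) - 1)) {
      rows[[length(rows) + 1L]] <- hit_row(labels[k], labels[k + 1], 1e-25)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  truth <- do.call(rbind, lapply(fams, function(f) {
    data.frame(seed_member = min(f$members),
               n_focal = sum(f$species == sp[["focal"]]),
               n_reference = sum(f$species == sp[["reference"]]),
               expanded = f$expanded)
  }))
  list(hits = hits, species = species, truth = truth)
}

#' Simulate GO annotations with one planted enriched term
#'
#' Every term annotates background transcripts at `go_background_rate`; the
#' first term additionally annotates the target subset (the common
#' nodule-specific transcripts) at `go_enriched_rate`, giving a planted
#' over-representation of odds roughly
#' `go_enriched_rate / go_background_rate`.
#'
#' @param config A [simulation_config()].
#' @return List with `annotations` (`transcript`, `term`), `universe`,
#'   and `truth` (`enriched_term`, `subset`).
#' @export
simulate_go <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cls <- assign_classes(config)
  set.seed(config$seed + 5L)
  universe <- cls$transcript
  nod <- "Nodule"
  if (!nod %in% config$tissues) nod <- config$tissues[length(config$tissues)]
  subset <- cls$transcript[cls$class == "tissue_specific" &
                             cls$tissue == nod]
  terms <- sprintf("GO:S%04d", seq_len(config$n_go_terms))
  rows <- list()
  for (j in seq_along(terms)) {
    rate <- rep(config$go_background_rate, length(universe))
    if (j == 1L) rate[universe %in% subset] <- config$go_enriched_rate
    keep <- stats::runif(length(universe)) < rate
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(transcript = universe[keep],
                                              term = terms[j])
    }
  }
  annotations <- do.call(rbind, rows)
  rownames(annotations) <- NULL
  list(annotations = annotations, universe = universe,
       truth = list(enriched_term = terms[1], subset = subset))
}

#' Generate every synthetic input at once
#'
#' Convenience wrapper running [simulate_counts()], [simulate_sequences()],
#' [simulate_variants()], [simulate_homology()] and [simulate_go()] for one
#' configuration. Each generator seeds its own RNG stream from
#' `config$seed`, so components are individually reproducible.
#'
#' @param config A [simulation_config()].
#' @return Named list with components `counts`, `sequences`, `variants`,
#'   `homology`, `go` and the `config`.
#' @export
simulate_atlas <- function(config = simulation_config()) {
  list(counts = simulate_counts(config),
       sequences = simulate_sequences(config),
       variants = simulate_variants(config),
       homology = simulate_homology(config),
       go = simulate_go(config),
       config = config)
}
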