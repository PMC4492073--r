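test_that("six-frame translation follows the standard code and frame math", {
  fr <- six_frame_translate(c(t1 = "ATGTGTTGA"))
  expect_equal(fr$peptide[fr$frame == 1], "MC*")
  # length bookkeeping: floor((L - offset) / 3) residues per frame
  s <- c(t2 = paste(rep("A", 10), collapse = ""))
  fr2 <- six_frame_translate(s)
  expect_equal(nchar(fr2$peptide[fr2$frame == 2]), 3L)   # floor((10-1)/3)
  expect_equal(nchar(fr2$peptide[fr2$frame == 1]), 3L)
  expect_equal(nchar(fr2$peptide[fr2$frame == 3]), 2L)
  # ambiguous codons become X
  fr3 <- six_frame_translate(c(t3 = "ATGNNNTGT"))
  expect_equal(fr3$peptide[fr3$frame == 1], "MXC")
  expect_error(six_frame_translate(c(bad = "")), "empty sequence")
})

test_that("reverse-strand frames equal forward frames of the complement", {
  set.seed(51)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- six_frame_translate(setNames(c(s, rc), c("fwd", "rev")))
    for (f in 1:3) {
      expect_equal(a$peptide[a$transcript == "fwd" & a$frame == -f],
                   a$peptide[a$transcript == "rev" & a$frame == f])
    }
  }
})

test_that("motif scanning finds planted chains and respects stops", {
  pat <- ncr_pattern(list(c(4, 8), c(4, 8), c(4, 8)))
  pep <- paste0("AAAAA", "C", "GGGGGG", "C", "GGGGG", "C", "GGGG", "C", "AAA")
  hits <- scan_ncr(data.frame(transcript = "p1", frame = 1, peptide = pep),
                   pat)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 6L)
  # cysteine-free peptide
  none <- scan_ncr(data.frame(transcript = "p2", frame = 1,
                              peptide = "AGLSTVAGLSTVAGLSTV"), pat)
  expect_equal(nrow(none), 0L)
  # a stop inside the would-be chain kills the match
  pep_stop <- sub("GGGGG", "GG*GG", pep, fixed = TRUE)
  expect_equal(nrow(scan_ncr(
    data.frame(transcript = "p3", frame = 1, peptide = pep_stop), pat)), 0L)
})

test_that("greedy scan equals the lazy-regex oracle on random peptides", {
  set.seed(52)
  pat <- ncr_pattern(list(c(2, 6), c(1, 5), c(2, 4)))
  for (i in 1:200) {
    pep <- random_peptide(sample(30:120, 1))
    got <- scan_ncr(data.frame(transcript = "x", frame = 1, peptide = pep),
                    pat)
    ref <- oracle_regex_scan(pep, pat$gaps)
    expect_equal(nrow(got), nrow(ref), info = pep)
    if (nrow(ref) > 0) {
      expect_equal(got$start, ref$start, info = pep)
      expect_equal(got$end, ref$end, info = pep)
    }
  }
})

test_that("planted frames are recovered with no false frames", {
  cfg <- simulation_config(seed = 53, n_transcripts = 600)
  sq <- simulate_sequences(cfg)
  hits <- scan_ncr(six_frame_translate(sq$sequences), cfg$motif_pattern)
  planted <- sq$truth[sq$truth$planted, ]
  got <- unique(hits[, c("transcript", "frame")])
  expect_setequal(paste(got$transcript, got$frame),
                  paste(planted$transcript, planted$frame))
  # minus-strand plants really are detected in minus frames
  expect_true(any(planted$frame < 0))
})

test_that("the nodule join intersects specificity with motif hits", {
  cfg <- simulation_config(seed = 54, n_transcripts = 600)
  sc <- simulate_counts(cfg)
  cls <- classify_expression(rpkm_normalize(sc$counts, sc$lengths),
                             sc$design)
  sq <- simulate_sequences(cfg)
  hits <- scan_ncr(six_frame_translate(sq$sequences), cfg$motif_pattern)
  jn <- nodule_ncr_join(hits, cls)
  expect_equal(unname(jn$counts$per_genotype),
               rep(cfg$n_motif_common_nodule + cfg$n_motif_gs_nodule, 2))
  expect_equal(unname(jn$counts$unique), rep(cfg$n_motif_gs_nodule, 2))
  expect_equal(jn$counts$common, cfg$n_motif_common_nodule)
  # a flower-specific motif carrier is excluded from the join
  flower <- cls$transcripts[!is.na(cls$common_tissue_specific) &
                              cls$common_tissue_specific == "Flower"][1]
  fake <- rbind(hits, data.frame(transcript = flower, frame = 1, start = 1,
                                 end = 30, cys_positions = "1,30"))
  jn2 <- nodule_ncr_join(fake, cls)
  expect_equal(jn2$counts$per_genotype, jn$counts$per_genotype)
  # universe mismatch errors
  bad <- rbind(hits, data.frame(transcript = "not_in_universe", frame = 1,
                                start = 1, end = 30, cys_positions = "1,30"))
  expect_error(nodule_ncr_join(bad, cls), "universe")
})
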