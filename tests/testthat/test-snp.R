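ev_row <- function(tx = "c1", pos = 5L, ref = "A", alt = "G", g = "B47",
                   ti = "Leaf", rep = 1L, alt_reads = 12L,
                   depth = alt_reads + 20L) {
  data.frame(transcript = tx, pos = pos, ref = ref, alt = alt, genotype = g,
             tissue = ti, replicate = rep, alt_reads = alt_reads,
             depth = depth)
}

test_that("replicate filter keeps alt_reads >= 10 and validates evidence", {
  ev <- rbind(ev_row(alt_reads = 10L), ev_row(rep = 2L, alt_reads = 9L),
              ev_row(rep = 3L, alt_reads = 0L))
  kept <- call_replicate_snps(ev)
  expect_equal(kept$replicate, 1L)
  expect_error(call_replicate_snps(ev_row(alt_reads = 30L, depth = 10L)),
               "malformed evidence")
  expect_error(call_replicate_snps(ev_row(ref = "G", alt = "G")),
               "malformed evidence")
  # brute-force row filter on a mixed table
  set.seed(31)
  ev2 <- do.call(rbind, lapply(1:20, function(i) {
    ev_row(tx = paste0("c", i), alt_reads = sample(0:20, 1))
  }))
  expect_equal(call_replicate_snps(ev2)$transcript,
               ev2$transcript[ev2$alt_reads >= 10])
})

test_that("consolidation requires presence in all replicates", {
  base <- rbind(ev_row(rep = 1L), ev_row(rep = 2L), ev_row(rep = 3L))
  expect_equal(nrow(consolidate_snps(base, 3)), 1L)
  expect_equal(nrow(consolidate_snps(base[1:2, ], 3)), 0L)
  # exhaustive check of all 8 presence patterns over R = 3
  for (mask in 0:7) {
    reps <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0)
    ev <- do.call(rbind, lapply(reps, function(r) ev_row(rep = r)))
    got <- if (is.null(ev)) 0L else nrow(consolidate_snps(ev, 3))
    expect_equal(got, as.integer(length(reps) == 3), info = paste("mask", mask))
  }
})

test_that("raising the read threshold never grows the passed set", {
  set.seed(32)
  ev <- do.call(rbind, lapply(1:120, function(i) {
    ev_row(tx = paste0("c", sample(8, 1)), pos = sample(10L, 1),
           g = sample(c("B47", "F56"), 1), ti = sample(msgi_tissues(), 1),
           rep = sample(3L, 1), alt_reads = sample(0:25, 1))
  }))
  ev <- unique(ev)
  prev <- Inf
  for (thr in c(5, 10, 15, 20)) {
    n <- nrow(consolidate_snps(call_replicate_snps(ev, thr), 3))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("SNP classes partition and occurrence rules match the contract", {
  mk <- function(tx, g, ti) {
    do.call(rbind, lapply(1:3, function(r) {
      ev_row(tx = tx, g = g, ti = ti, rep = r)
    }))
  }
  ev <- rbind(mk("only_b47_leaf", "B47", "Leaf"),
              mk("both_leaf", "B47", "Leaf"), mk("both_leaf", "F56", "Leaf"),
              mk("b47_two_tissues", "B47", "Leaf"),
              mk("b47_two_tissues", "B47", "Root"),
              mk("cross_tissue", "B47", "Leaf"), mk("cross_tissue", "F56", "Root"))
  passed <- consolidate_snps(call_replicate_snps(ev), 3)
  cl <- classify_snps(passed, genotypes = c("B47", "F56"))
  rec <- cl$records
  get <- function(tx) rec[rec$transcript == tx, ]
  expect_equal(get("only_b47_leaf")$class, "B47")
  expect_true(get("only_b47_leaf")$tissue_specific)
  expect_equal(get("both_leaf")$class, "shared")
  expect_true(get("both_leaf")$same_tissue)
  expect_equal(get("b47_two_tissues")$class, "B47")
  expect_false(get("b47_two_tissues")$tissue_specific)
  expect_equal(get("cross_tissue")$class, "shared")
  expect_false(get("cross_tissue")$same_tissue)
  # partition: class counts sum to total retained SNPs
  s <- cl$summary
  expect_equal(sum(unlist(s["total_snps", ])), nrow(rec))
  # same-tissue mode narrows the shared column only
  strict <- classify_snps(passed, genotypes = c("B47", "F56"),
                          shared_mode = "same_tissue")
  expect_equal(strict$summary["total_snps", "shared"], 1)
  expect_equal(s["total_snps", "shared"], 2)
})

test_that("planted pass/fail evidence is recovered exactly", {
  cfg <- simulation_config(seed = 33, n_transcripts = 600)
  sv <- simulate_variants(cfg)
  passed <- consolidate_snps(call_replicate_snps(sv$evidence,
                                                 cfg$snp_min_alt),
                             cfg$replicates)
  cl <- classify_snps(passed, genotypes = cfg$genotypes)
  truth <- sv$truth
  key <- function(d) paste(d$transcript, d$pos, d$ref, d$alt)
  expect_setequal(key(cl$records), key(truth[truth$intended_pass, ]))
  got <- cl$records[match(key(truth[truth$intended_pass, ]),
                          key(cl$records)), ]
  expect_equal(got$class, truth$class[truth$intended_pass])
  expect_equal(got$tissue_specific,
               truth$tissue_specific[truth$intended_pass])
})
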