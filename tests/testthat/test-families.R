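hit <- function(q, s, evalue = 0, bitscore = 500) {
  data.frame(qseqid = q, sseqid = s, pident = 99, length = 500,
             mismatch = 1, gapopen = 0, qstart = 1, qend = 500,
             sstart = 1, send = 500, evalue = evalue, bitscore = bitscore)
}

test_that("single linkage is transitive and singletons survive", {
  sp <- setNames(rep("Msa", 5), c("A", "B", "C", "D", "E"))
  fam <- cluster_families(rbind(hit("A", "B"), hit("B", "C")), sp)
  f <- setNames(fam$family, fam$id)
  expect_equal(length(unique(f[c("A", "B", "C")])), 1L)
  expect_equal(length(unique(f)), 3L)  # {A,B,C}, {D}, {E}
  # empty hit table: all singletons
  fam0 <- cluster_families(hit("A", "B")[0, ], sp)
  expect_equal(length(unique(fam0$family)), 5L)
  # above-cutoff edges are ignored
  fam1 <- cluster_families(rbind(hit("A", "B", evalue = 1e-30)), sp)
  expect_equal(length(unique(fam1$family)), 5L)
  expect_error(cluster_families(rbind(hit("A", "ZZ")), sp), "absent")
})

test_that("components equal a union-find oracle and ignore hit order", {
  set.seed(41)
  for (rep in 1:10) {
    ids <- sprintf("s%02d", 1:20)
    sp <- setNames(rep(c("Msa", "Mtr"), 10), ids)
    e <- data.frame(a = sample(ids, 15, TRUE), b = sample(ids, 15, TRUE))
    e <- e[e$a != e$b, ]
    hits <- do.call(rbind, Map(hit, e$a, e$b))
    fam <- cluster_families(hits, sp)
    oracle <- oracle_union_find(as.matrix(e), ids)
    got <- split(fam$id, fam$family)
    expect_setequal(unname(lapply(got, sort)),
                    unname(lapply(oracle, sort)))
    # permuted rows give identical output
    fam2 <- cluster_families(hits[sample(nrow(hits)), , drop = FALSE], sp)
    expect_identical(fam, fam2)
  }
})

test_that("chi-square expansion statistic matches hand and library oracles", {
  mk_fam <- function(n_focal, n_ref) {
    data.frame(
      id = c(sprintf("a%02d", seq_len(n_focal)),
             sprintf("b%02d", seq_len(n_ref))),
      species = c(rep("Msa", n_focal), rep("Mtr", n_ref)),
      family = "fam00001")
  }
  # exactly the 2:1 expectation: no signal
  r0 <- expansion_test(mk_fam(20, 10), "Msa", "Mtr")
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$direction, "as_expected")
  # the 19:3 mannose-1-phosphate guanylyltransferase family counts
  r1 <- expansion_test(mk_fam(19, 3), "Msa", "Mtr")
  expect_equal(r1$chi2, 3.840909, tolerance = 1e-6)
  expect_false(r1$significant)  # p ~ 0.050 > 0.01
  # strong contraction
  r2 <- expansion_test(mk_fam(0, 30), "Msa", "Mtr")
  expect_equal(r2$direction, "contracted")
  expect_equal(r2$chi2, 60)
  # library oracle on random instances
  set.seed(42)
  for (i in 1:25) {
    nf <- sample(0:40, 1)
    nr <- sample(0:40, 1)
    if (nf + nr < 5) nr <- nr + 5
    ratio <- sample(c(1, 2, 112626 / 50894), 1)
    got <- expansion_test(mk_fam(nf, nr), "Msa", "Mtr",
                          expected_ratio = ratio)
    ref <- suppressWarnings(stats::chisq.test(
      c(nf, nr), p = c(ratio, 1) / (ratio + 1)))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
  }
  expect_error(expansion_test(mk_fam(5, 5), "Msa", "Mtr",
                              expected_ratio = 0), "expected_ratio")
})

test_that("Bonferroni behaves: p_adj >= p and significance shrinks with alpha", {
  cfg <- simulation_config(seed = 43)
  h <- simulate_homology(cfg)
  fam <- cluster_families(h$hits, h$species)
  et <- expansion_test(fam, "Msa", "Mtr", alpha = 0.05)
  expect_true(all(et$p_adj >= et$p))
  expect_true(all(et$p_adj <= 1))
  n_sig <- vapply(c(0.10, 0.05, 0.01),
                  function(a) sum(et$p_adj <= a), integer(1))
  expect_true(all(diff(n_sig) <= 0))
  # chi2 = 0 iff counts match the expected ratio exactly
  expect_true(all((et$chi2 == 0) ==
                    (et$n_focal == 2 * et$n_reference)))
})

test_that("best-hit selection follows evalue, bitscore, then subject id", {
  hits <- rbind(hit("q1", "s2", 1e-30, 100), hit("q1", "s1", 1e-40, 100),
                hit("q2", "s3", 1e-20, 200), hit("q2", "s4", 1e-20, 300),
                hit("q3", "s6", 1e-15, 50), hit("q3", "s5", 1e-15, 50),
                hit("q4", "s9", 1e-9, 500))
  best <- best_hit_annotate(hits)
  expect_equal(best$sseqid[best$qseqid == "q1"], "s1")  # lower evalue
  expect_equal(best$sseqid[best$qseqid == "q2"], "s4")  # higher bitscore
  expect_equal(best$sseqid[best$qseqid == "q3"], "s5")  # lexicographic
  expect_false("q4" %in% best$qseqid)  # 1e-9 misses the 1e-10 cutoff
  expect_equal(unname(unique_target_count(best)), c(3L, 3L))
  # brute-force oracle on random tables
  set.seed(44)
  rnd <- do.call(rbind, lapply(1:80, function(i) {
    hit(paste0("q", sample(6, 1)), paste0("s", sample(8, 1)),
        10^-sample(10:50, 1), sample(100:900, 1))
  }))
  best2 <- best_hit_annotate(rnd)
  for (q in unique(rnd$qseqid)) {
    x <- rnd[rnd$qseqid == q & rnd$evalue <= 1e-10, ]
    x <- x[x$evalue == min(x$evalue), ]
    x <- x[x$bitscore == max(x$bitscore), ]
    expect_equal(best2$sseqid[best2$qseqid == q], min(x$sseqid))
  }
})
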