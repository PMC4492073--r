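test_that("RPKM normalization matches the closed form and handles zeros", {
  cnt <- matrix(c(1000L, 500L,
                  0L,    3L,
                  12L,   205L), nrow = 3, byrow = TRUE,
                dimnames = list(c("t1", "t2", "t3"), c("libA", "libB")))
  lens <- c(t1 = 1000, t2 = 800, t3 = 1352)
  sizes <- c(libA = 1e6, libB = 15250000)
  r <- rpkm_normalize(cnt, lens, lib_sizes = sizes)
  # units cancel exactly: 1 kb transcript, 1000 reads, 1e6 mapped
  expect_equal(r["t1", "libA"], 1000)
  expect_equal(r["t2", "libA"], 0)
  # hand evaluation of 1e9 * 205 / (15.25e6 * 1352)
  expect_equal(r["t3", "libB"], 9.94276845, tolerance = 1e-8)
  expect_true(all((r == 0) == (cnt == 0)))
})

test_that("RPKM errors on missing catalog entries and empty libraries", {
  cnt <- matrix(1L, 1, 1, dimnames = list("t1", "l1"))
  expect_error(rpkm_normalize(cnt, c(zz = 100)), "missing from the catalog")
  cnt0 <- matrix(0L, 1, 1, dimnames = list("t1", "l1"))
  expect_error(rpkm_normalize(cnt0, c(t1 = 100)), "invalid library")
})

test_that("count round-trip through RPKM recovers inputs to 1e-9", {
  set.seed(101)
  for (rep in 1:5) {
    cnt <- matrix(rpois(200, 50), 20, 10,
                  dimnames = list(sprintf("t%02d", 1:20),
                                  sprintf("l%02d", 1:10)))
    lens <- setNames(sample(200:2000, 20), rownames(cnt))
    sizes <- colSums(cnt)
    r <- rpkm_normalize(cnt, lens)
    back <- counts_from_rpkm(r, lens, sizes)
    expect_lt(max(abs(back - cnt) / pmax(cnt, 1)), 1e-9)
  }
})

test_that("retention filter implements >= min_reads in >= min_reps replicates", {
  design <- atlas_design(genotypes = "G1", tissues = c("T1", "T2"),
                         replicates = 3)
  cnt <- matrix(0L, 4, 6, dimnames = list(sprintf("t%d", 1:4),
                                          design$library))
  cnt["t1", design$library[design$tissue == "T1"]] <- c(10L, 10L, 0L)
  cnt["t2", ] <- 9L
  cnt["t3", design$library] <- rep(c(10L, 9L, 9L), 2)
  cnt["t4", design$library[design$tissue == "T2"]] <- c(12L, 47L, 3L)
  kept <- retention_filter(cnt, design)
  expect_setequal(kept, c("t1", "t4"))
  expect_error(retention_filter(cnt, design, min_reps = 4), "invalid config")
})

test_that("retention filter is monotone under added reads", {
  set.seed(7)
  design <- atlas_design()
  for (rep in 1:5) {
    cnt <- matrix(rpois(50 * 36, 6), 50, 36,
                  dimnames = list(sprintf("t%02d", 1:50), design$library))
    before <- retention_filter(cnt, design)
    extra <- cnt + matrix(rpois(length(cnt), 2), nrow(cnt))
    after <- retention_filter(extra, design)
    expect_true(all(before %in% after))
  }
})

test_that("expression classification follows the breadth rules", {
  design <- atlas_design()
  tiss <- msgi_tissues()
  tmg <- function(b47, f56) {
    tx <- c("a", "b", "c")
    dimnames(b47) <- dimnames(f56) <- list(tx, tiss)
    list(B47 = b47, F56 = f56)
  }
  tm <- tmg(rbind(c(1.5, 0, 0, 0, 0, 0),   # a: B47 leaf-specific
                  rep(5, 6),               # b: ubiquitous
                  rep(0.9, 6)),            # c: below presence in B47
            rbind(rep(0, 6),               # a: silent in F56
                  rep(5, 6),               # b
                  c(2, 0, 0, 0, 0, 0)))    # c: F56 leaf-specific
  rpkm <- make_rpkm(tm, design)
  cls <- classify_expression(rpkm, design)
  expect_equal(unname(cls$tissue_specific$B47["a"]), "Leaf")
  expect_equal(unname(cls$genotype_specific["a"]), "B47")
  expect_true(is.na(cls$tissue_specific$B47["b"]))
  expect_true(is.na(cls$genotype_specific["b"]))
  expect_equal(unname(cls$genotype_specific["c"]), "F56")
  expect_equal(unname(cls$tissue_specific$F56["c"]), "Leaf")
  expect_true(is.na(cls$common_tissue_specific["a"]))
  expect_error(classify_expression(rpkm, design, presence = 1, absence = 2),
               "invalid config")
})

test_that("classification partitions and the summary identity hold on random data", {
  set.seed(11)
  design <- atlas_design()
  for (rep in 1:5) {
    rpkm <- matrix(rexp(80 * 36, rate = 1 / 2), 80, 36,
                   dimnames = list(sprintf("t%02d", 1:80), design$library))
    cls <- classify_expression(rpkm, design)
    # at most one tissue-specific label per genotype is structural; check
    # genotype-specific sets are disjoint
    gs <- cls$genotype_specific
    expect_true(all(table(gs[!is.na(gs)]) >= 0))
    s <- expression_summary(cls)
    lhs <- sum(s$totals$tissue_specific) - s$totals$common
    expect_equal(lhs, s$tissue_specific_union)
    # common calls are a subset of each genotype's calls
    expect_true(all(s$common <= s$tissue_specific$B47))
    expect_true(all(s$common <= s$tissue_specific$F56))
  }
})

test_that("top-expressed ranking is deterministic with lexicographic ties", {
  design <- atlas_design(genotypes = "B47", tissues = c("T1", "T2"),
                         replicates = 2)
  rpkm <- matrix(0, 10, 4, dimnames = list(sprintf("t%02d", 10:1),
                                           design$library))
  rpkm[, ] <- seq_len(10)  # distinct per-row scores via recycling
  rpkm <- rpkm[order(rownames(rpkm)), ]
  scores <- rowMeans(rpkm)
  top3 <- top_expressed(rpkm, design, "B47", n = 3)
  expect_equal(top3, names(sort(scores, decreasing = TRUE))[1:3])
  # ties: equal scores resolved by id
  rpkm[] <- 5
  expect_equal(top_expressed(rpkm, design, "B47", n = 3),
               sort(rownames(rpkm))[1:3])
  expect_equal(length(top_overlap(top3, top3)), 3)
  expect_error(top_expressed(rpkm, design, "nope", n = 2), "unknown genotype")
})

test_that("stability screen matches a spreadsheet-style oracle", {
  design <- atlas_design()
  n <- 36
  rpkm <- rbind(
    const = rep(8, n),
    near  = c(rep(8, n - 1), 9),
    low   = c(2, rep(8, n - 1)))  # one sample exactly at the floor
  colnames(rpkm) <- design$library
  out <- stable_transcripts(rpkm, design, min_rpkm = 2, cov_max = 0.13)
  expect_equal(out$transcript[1], "const")
  expect_equal(out$cov[1], 0)
  # independent mean/sd computation
  v <- c(rep(8, n - 1), 9)
  mu <- sum(v) / n
  sdv <- sqrt(sum((v - mu)^2) / (n - 1))
  row <- out[out$transcript == "near", ]
  expect_equal(row$cov, sdv / mu, tolerance = 1e-12)
  # strictly > min_rpkm required in every sample
  expect_false("low" %in% out$transcript)
})
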