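test_that("site classification follows the stated definitions", {
  aln <- alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT",
                     d = "ACGTACGT"))
  st <- align_stats(aln)
  expect_equal(st$conserved_sites, 8L)
  expect_equal(st$parsimony_informative, 0L)
  expect_equal(st$pi_percent, 0)
  expect_equal(st$seq_identity, 1.0)

  # 2x2 state split in both columns: fully informative
  aln2 <- alignment(c(a = "AA", b = "AA", c = "TT", d = "TT"))
  st2 <- align_stats(aln2)
  expect_equal(st2$parsimony_informative, 2L)
  expect_equal(st2$pi_percent, 100)

  # a 2+1+1 column is variable but not informative; gaps are not states
  aln3 <- alignment(c(a = "AT", b = "AC", c = "A-", d = "AG"))
  st3 <- align_stats(aln3)
  expect_equal(st3$conserved_sites, 1L)
  expect_equal(st3$variable_sites, 1L)
  expect_equal(st3$parsimony_informative, 0L)
  expect_true(isTRUE(attr(align_stats(alignment(c(a = "AC", b = "AC"))),
                          "flagged_small")))
})

test_that("the published informative counts give the printed percentages", {
  expect_equal(pi_percent(265, 1575), 16.83)   # matK
  expect_equal(pi_percent(1063, 6327), 16.80)  # ycf1
  t5 <- table5_counts()
  pis <- pi_percent(t5$parsimony_informative, t5$aligned_length)
  expect_equal(pis, c(16.83, 16.80, 16.21, 16.20, 16.14, 15.79, 15.57,
                      14.88, 14.58, 13.56))
})

test_that("Fitch length matches forced cases and the exhaustive oracle", {
  # two taxa: steps equal Hamming distance over non-missing columns
  aln <- alignment(c(t1 = "ACGTN", t2 = "AGGT-"))
  tree <- ape::read.tree(text = "(t1,t2);")
  expect_equal(fitch_length(aln, tree), 1L)
  # quartet column A,A,T,T: 1 step on the matching split, 2 on the other
  alnq <- alignment(c(t1 = "A", t2 = "A", t3 = "T", t4 = "T"))
  expect_equal(fitch_length(alnq, quartet_tree("12|34")), 1L)
  expect_equal(fitch_length(alnq, quartet_tree("13|24")), 2L)
  # invariant columns cost nothing
  alni <- alignment(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA"))
  expect_equal(fitch_length(alni, quartet_tree("12|34")), 0L)
  expect_error(fitch_length(alnq, ape::read.tree(text = "(t1,t2,(t9,t4));")),
               "differ")
  set.seed(14)
  for (rep in 1:8) {
    nt <- sample(4:6, 1)
    aln <- random_alignment(nt, 12, missing_frac = 0.1)
    tree <- ape::rtree(nt, tip.label = paste0("t", 1:nt))
    expect_equal(fitch_length(aln, tree), oracle_fitch(aln, tree))
  }
})

test_that("Fitch length agrees with the phangorn implementation", {
  skip_if_not_installed("phangorn")
  set.seed(3)
  for (rep in 1:5) {
    nt <- sample(4:8, 1)
    aln <- random_alignment(nt, 40)
    tree <- ape::rtree(nt, tip.label = paste0("t", 1:nt))
    pd <- phangorn::phyDat(unclass(aln), type = "DNA")
    expect_equal(fitch_length(aln, tree),
                 as.integer(phangorn::parsimony(tree, pd, method = "fitch")))
  }
})

test_that("consistency and retention indices follow their definitions", {
  # fully tree-compatible data
  aln <- alignment(c(t1 = "AATT", t2 = "AATT", t3 = "TTAA", t4 = "TTAA"))
  ir <- ci_ri(aln, quartet_tree("12|34"))
  expect_equal(ir$ci, 1)
  expect_equal(ir$ri, 1)
  # single incongruent column: m=1, s=2, g=2
  aln1 <- alignment(c(t1 = "A", t2 = "A", t3 = "T", t4 = "T"))
  ir1 <- ci_ri(aln1, quartet_tree("13|24"))
  expect_equal(ir1$ci, 0.5)
  expect_equal(ir1$ri, 0)
  # congruent + incongruent column: CI = 2/3, RI = 1/2
  aln2 <- alignment(c(t1 = "AA", t2 = "AT", t3 = "TA", t4 = "TT"))
  ir2 <- ci_ri(aln2, quartet_tree("12|34"))
  expect_equal(ir2$ci, 2 / 3)
  expect_equal(ir2$ri, 0.5)
  # invariant alignment: both indices flagged 1
  ir3 <- ci_ri(alignment(c(t1 = "AA", t2 = "AA", t3 = "AA", t4 = "AA")),
               quartet_tree("12|34"))
  expect_equal(ir3$ci, 1)
  expect_true(isTRUE(attr(ir3, "no_variable_sites")))
})

test_that("m <= s <= g per column on random alignments and trees", {
  set.seed(99)
  for (rep in 1:10) {
    nt <- sample(4:7, 1)
    aln <- random_alignment(nt, 20, missing_frac = 0.05)
    tree <- ape::rtree(nt, tip.label = paste0("t", 1:nt))
    s <- fitch_length(aln, tree, per_column = TRUE)
    mat <- unclass(aln)
    for (j in seq_len(ncol(mat))) {
      tok <- mat[, j]
      tok <- tok[!tok %in% c("-", "N", "?")]
      if (!length(tok)) next
      tab <- table(tok)
      m <- length(tab) - 1L
      g <- length(tok) - max(tab)
      expect_lte(m, s[j])
      expect_lte(s[j], g)
    }
  }
})

test_that("CI and RI are invariant to taxon order and column permutation", {
  set.seed(7)
  aln <- random_alignment(6, 30)
  tree <- ape::rtree(6, tip.label = paste0("t", 1:6))
  base <- ci_ri(aln, tree)
  mat <- unclass(aln)
  perm_rows <- mat[sample(nrow(mat)), , drop = FALSE]
  perm_cols <- mat[, sample(ncol(mat)), drop = FALSE]
  expect_equal(ci_ri(alignment(perm_rows), tree)[c("ci", "ri")],
               base[c("ci", "ri")])
  expect_equal(ci_ri(alignment(perm_cols), tree)[c("ci", "ri")],
               base[c("ci", "ri")])
})

test_that("gene ranking reproduces the published ordering", {
  t5 <- table5_counts()
  stats <- data.frame(
    gene = t5$gene,
    unaligned_length_ref = t5$unaligned_length_ref,
    aligned_length = t5$aligned_length,
    conserved_sites = t5$conserved_sites,
    parsimony_informative = t5$parsimony_informative,
    pi_percent = pi_percent(t5$parsimony_informative, t5$aligned_length),
    stringsAsFactors = FALSE)
  unfiltered <- rank_genes(stats, min_len = 0)
  expect_equal(unfiltered$gene,
               c("matK", "ycf1", "ccsA", "accD", "rps3", "ndhF", "rps8",
                 "rpl22", "petL", "ndhD"))
  # the default 200 bp filter drops the 96 bp gene
  filtered <- rank_genes(stats)
  expect_false("petL" %in% filtered$gene)
  expect_equal(nrow(filtered), 9L)
  expect_equal(nrow(rank_genes(stats[0, ])), 0L)
  single <- rank_genes(stats[1, , drop = FALSE])
  expect_equal(nrow(single), 1L)
})

test_that("variability_stats assembles the full per-gene row", {
  set.seed(31)
  aln <- random_alignment(6, 60)
  row <- variability_stats(aln, gene = "toy", unaligned_length_ref = 60)
  expect_equal(row$aligned_length, 60L)
  expect_true(row$ci > 0 && row$ci <= 1)
  expect_true(row$ri >= 0 && row$ri <= 1)
  expect_true(row$pi_percent >= 0 && row$pi_percent <= 100)
  expect_true(row$seq_identity > 0 && row$seq_identity < 1)
})
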