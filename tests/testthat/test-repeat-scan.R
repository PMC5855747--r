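test_that("SSR cutoffs, primitivity and maximality behave as specified", {
  pad1 <- "GCTGACGTCGAC"; pad2 <- "CGTCAGCTGGCA"
  # run of 8 A at the mononucleotide cutoff
  h <- find_ssrs(paste0(pad1, "G", strrep("A", 8), "C", pad2))
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "A")
  expect_equal(h$copies, 8L)
  # run of 7 A is below the cutoff
  expect_equal(nrow(find_ssrs(paste0(pad1, "G", strrep("A", 7), "C", pad2))),
               0L)
  # ATATATAT is a dinucleotide hit, never a tetranucleotide
  h2 <- find_ssrs(paste0(pad1, "G", strrep("AT", 4), "G", pad2))
  expect_equal(h2$motif, "AT")
  expect_equal(h2$copies, 4L)
  expect_equal(h2$end - h2$start + 1L, 8L)
  # maximality: a 9th copy extends the same hit, not a new one
  h3 <- find_ssrs(paste0(pad1, "G", strrep("AT", 5), "G", pad2))
  expect_equal(h3$copies, 5L)
  expect_equal(nrow(h3), 1L)
  expect_equal(nrow(find_ssrs("")), 0L)
})

test_that("SSR scanner equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (rep in 1:30) {
    s <- random_seq(400, gc = 0.3)
    # plant a couple of runs to make hits likely
    ins <- paste0(strrep(sample(c("A", "T", "AT", "TA", "AAT", "ATC"), 1),
                         sample(3:9, 1)))
    at <- sample(100:250, 1)
    s <- paste0(substr(s, 1, at), ins, substr(s, at + 1, nchar(s)))
    got <- find_ssrs(s)[c("motif", "copies", "start", "end")]
    want <- oracle_ssrs(s)[c("motif", "copies", "start", "end")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("no reported SSR can be extended by one motif copy", {
  set.seed(55)
  for (rep in 1:10) {
    s <- paste0(random_seq(150), strrep("TA", 6), random_seq(150),
                strrep("C", 9), random_seq(100))
    ch <- oracle_chars(s)
    h <- find_ssrs(s)
    for (i in seq_len(nrow(h))) {
      m <- h$motif_len[i]
      before <- h$start[i] - 1L
      if (before >= 1L)
        expect_false(isTRUE(ch[before] == ch[before + m]))
    }
  }
})

# plant two copies with flanking guard bases chosen so that single-base
# extension of the pairing mismatches immediately in every class
plant_pair <- function(copy1, copy2, class) {
  # A-flanks on copy 1 against C-flanks on copy 2 mismatch under plain
  # equality, reversal, complement and reverse complement alike, so the
  # pairing cannot creep across the planted boundaries cheaply
  paste0(random_seq(120, gc = 0.45), "AAAA", copy1, "AAAA",
         random_seq(70, gc = 0.45), "CCCC", copy2, "CCCC",
         random_seq(120, gc = 0.45))
}

test_that("long repeats of all four classes are detected by construction", {
  set.seed(7)
  seg35 <- random_seq(35, gc = 0.5)
  h <- find_long_repeats(plant_pair(seg35, seg35, "forward"))
  fw <- h[h$type == "forward", ]
  expect_equal(nrow(fw), 1L)
  expect_equal(fw$length, 35L)
  expect_equal(fw$identity, 1.0)

  seg40 <- random_seq(40, gc = 0.5)
  h2 <- find_long_repeats(plant_pair(seg40, revcomp(seg40), "palindromic"))
  expect_true(any(h2$type == "palindromic" & h2$length == 40L &
                    h2$identity == 1.0))

  seg32 <- random_seq(32, gc = 0.5)
  h3 <- find_long_repeats(plant_pair(
    seg32, paste(rev(oracle_chars(seg32)), collapse = ""), "reverse"))
  expect_true(any(h3$type == "reverse" & h3$length == 32L))
  h4 <- find_long_repeats(plant_pair(seg32, chartr("ACGT", "TGCA", seg32),
                                     "complement"))
  expect_true(any(h4$type == "complement" & h4$length == 32L))

  # a 29 bp duplicate is below the length floor
  seg29 <- random_seq(29, gc = 0.5)
  s3 <- plant_pair(seg29, seg29, "forward")
  expect_equal(nrow(find_long_repeats(s3)), 0L)
  expect_error(find_long_repeats(s3, min_len = 7), "seed-length")
})

test_that("the identity threshold separates 3 from 4 substitutions in 35 bp", {
  set.seed(19)
  seg <- oracle_chars(random_seq(35, gc = 0.5))
  mutate_at <- function(x, pos) {
    for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    x
  }
  # mismatches confined to positions 6..30 so that every >= 30 bp window
  # of the pairing carries all of them
  s3 <- plant_pair(paste(seg, collapse = ""),
                   paste(mutate_at(seg, c(8, 17, 26)), collapse = ""),
                   "forward")
  h3 <- find_long_repeats(s3)
  expect_true(any(h3$type == "forward" &
                    abs(h3$identity - 32 / 35) < 1e-9))
  s4 <- plant_pair(paste(seg, collapse = ""),
                   paste(mutate_at(seg, c(8, 14, 20, 26)), collapse = ""),
                   "forward")
  h4 <- find_long_repeats(s4)
  expect_false(any(h4$type == "forward"))
})

test_that("long-repeat scanner equals the brute-force oracle", {
  set.seed(202)
  for (rep in 1:12) {
    s <- random_seq(260, gc = 0.4)
    if (rep %% 2 == 0) {          # plant something half the time
      seg <- random_seq(32, gc = 0.5)
      type <- sample(c("forward", "reverse", "complement", "palindromic"), 1)
      second <- switch(type, forward = seg,
                       reverse = paste(rev(oracle_chars(seg)), collapse = ""),
                       complement = chartr("ACGT", "TGCA", seg),
                       palindromic = revcomp(seg))
      s <- paste0(substr(s, 1, 80), seg, substr(s, 81, 170), second,
                  substr(s, 171, 260))
    }
    got <- find_long_repeats(s)
    want <- oracle_long_repeats(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("facet summaries always sum to the total hit count", {
  # published per-class counts recombine to the printed total
  reps <- data.frame(type = rep(c("palindromic", "forward", "reverse"),
                                c(14, 19, 8)),
                     length = sample(30:95, 41, replace = TRUE))
  sm <- repeat_summary(reps, by = "type")
  expect_equal(sum(sm$count), 41L)
  expect_equal(attr(sm, "total"), 41L)
  sm2 <- repeat_summary(reps, by = "length_bin")
  expect_equal(sum(sm2$count), 41L)
  ssrs <- data.frame(context = rep(c("coding", "intron", "intergenic"),
                                   c(89, 34, 155)))
  sm3 <- repeat_summary(ssrs, by = "context")
  expect_equal(sum(sm3$count), 278L)
  empty <- repeat_summary(data.frame(type = character(0),
                                     length = integer(0)), by = "type")
  expect_equal(sum(empty$count), 0L)
})

test_that("planted features are recovered with full recall and precision", {
  genes <- data.frame(name = "geneA", category = "protein", region = "LSC",
                      duplicated = FALSE, exons = I(list(c(300, 200))),
                      introns = I(list(150)))
  for (seed in c(2, 6)) {
    sp <- plastome_spec(lsc_len = 3000L, ssc_len = 1200L, ir_len = 1000L,
      genes = genes,
      ssrs = data.frame(motif = c("A", "AT", "ACG"), copies = c(9, 5, 4),
                        region = c("LSC", "LSC", "SSC")),
      repeats = data.frame(type = c("forward", "palindromic", "reverse",
                                    "complement"),
                           length = c(35, 40, 32, 36),
                           identity = c(1, 1, 1, 0.917),
                           region = c("LSC", "LSC", "SSC", "LSC")),
      seed = seed)
    g <- generate_plastome(sp)
    expect_null(g$truth$residual_accidental)
    truth <- g$truth$features
    ssr_truth <- truth[truth$kind == "ssr", ]
    got <- find_ssrs(g$record, g$truth$partition)
    expect_equal(nrow(got), nrow(ssr_truth))
    expect_setequal(got$start, ssr_truth$start)
    rep_truth <- truth[truth$kind == "repeat", ]
    reps <- find_long_repeats(g$record, ir = g$truth$ir)
    expect_equal(nrow(reps), nrow(rep_truth))
    for (i in seq_len(nrow(rep_truth))) {
      L <- as.integer(sub(".*len=(\\d+);.*", "\\1", rep_truth$detail[i]))
      expect_true(any(reps$type == rep_truth$name[i] &
                        reps$start1 == rep_truth$start[i] &
                        reps$length == L))
    }
  }
})
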