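test_that("gc_content counts G+C over non-N bases", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  set.seed(11)
  s <- paste(sample(c(rep(c("G", "C"), c(19, 18)), rep(c("A", "T"), c(30, 33)))),
             collapse = "")
  expect_equal(gc_content(s), 0.37)
  expect_equal(gc_content("GCNN"), 1.0)     # N dropped from the denominator
  expect_error(gc_content("NNNN"), "all N")
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ATGX"), "outside")
})

test_that("record validation enforces coordinates and IR copy pairing", {
  ann <- gene_annotation("g1", "protein", "+", 100, 200)
  rec <- plastome_record("x", random_seq(500), ann)
  expect_s3_class(rec, "plastome_record")
  expect_error(plastome_record("x", random_seq(150), ann), "outside")
  bad <- rbind(gene_annotation("d", "tRNA", "+", 10, 40, copy_tag = "IR_A"),
               gene_annotation("d", "tRNA", "+", 60, 90, copy_tag = "IR_A"))
  expect_error(plastome_record("x", random_seq(500), bad), "IR_A and one IR_B")
  expect_error(gene_annotation("g", "protein", "+", c(10, 30), c(35, 60)),
               "overlap")
})

test_that("FASTA+GFF3 and GenBank round-trips preserve sequence and coordinates", {
  g <- generate_plastome(small_spec(seed = 3), screen = FALSE)
  rec <- g$record
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "genome.fasta")
  write_plastome(rec, fa)
  back <- read_plastome(fa, format = "gff3")
  expect_identical(back$sequence, rec$sequence)
  reord <- function(a) {
    a <- a[order(a$gene, a$copy_tag, a$start), ]
    rownames(a) <- NULL
    a[c("gene", "category", "strand", "start", "end", "is_pseudo",
        "copy_tag")]
  }
  expect_identical(reord(back$annotations), reord(rec$annotations))

  gb <- file.path(tmp, "genome.gb")
  write_genbank(rec, gb)
  back2 <- read_plastome(gb, format = "genbank")
  expect_identical(back2$sequence, rec$sequence)
  expect_identical(reord(back2$annotations), reord(rec$annotations))
  expect_true(back2$is_circular)
})

test_that("a minimal GenBank gene feature is captured with its coordinates", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  seqline <- tolower(random_seq(300))
  writeLines(c(
    "LOCUS       mini 300 bp    DNA     linear PLN",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     gene            100..200",
    '                     /gene="tiny"',
    "ORIGIN",
    sprintf("%9d %s", 1, seqline),
    "//"), tmp)
  rec <- read_plastome(tmp, format = "genbank")
  expect_equal(nrow(rec$annotations), 1L)
  expect_equal(rec$annotations$start, 100L)
  expect_equal(rec$annotations$end, 200L)
  expect_equal(rec$annotations$gene, "tiny")
  expect_false(rec$is_circular)
})

test_that("composition reproduces the published region proportions", {
  pr <- region_proportions(c(lsc = 86315, ssc = 18491, ira = 26577,
                             irb = 26577))
  expect_equal(pr$total, 157960)
  expect_equal(unname(pr$percent),
               c(54.6, 11.7, 16.8, 16.8))
  # non-coding arithmetic: intron + intergenic lengths and percentage
  noncoding <- 18474 + 49159
  expect_equal(noncoding, 67633)
  expect_equal(round_half_up(noncoding / 157960 * 100, 1), 42.8)
})

test_that("composition_summary classes tile the genome exactly", {
  g <- generate_plastome(small_spec(seed = 5), screen = FALSE)
  cs <- composition_summary(g$record, g$truth$partition)
  n <- nchar(g$record$sequence)
  expect_equal(sum(cs$regions$length_bp), n)
  expect_equal(sum(cs$classes$length_bp), n)
  expect_true(all(cs$regions$length_percent >= 0 &
                    cs$regions$length_percent <= 100))
  expect_lt(abs(sum(cs$regions$length_percent) - 100), 0.3)
  expect_lt(abs(sum(cs$classes$length_percent) - 100), 0.3)
  # a single gene covering everything leaves no intergenic DNA
  rec1 <- plastome_record("all", random_seq(400),
                          gene_annotation("g", "protein", "+", 1, 400))
  p1 <- partition_from_lengths(200, 50, 100)
  cs1 <- composition_summary(rec1, p1)
  expect_equal(cs1$classes$length_bp[cs1$classes$class == "intergenic"], 0L)
  expect_equal(cs1$classes$length_percent[cs1$classes$class == "protein"],
               100)
  # partition/record length contradiction is an error
  expect_error(composition_summary(rec1, partition_from_lengths(200, 50, 99)),
               "tile")
})

test_that("gene census reproduces the published inventory counts", {
  fx <- inventory_annotations()
  cen <- gene_census(fx$annotations, fx$partition)
  expect_equal(cen$total_copies, 129L)
  expect_equal(cen$distinct_names, 112L)
  expect_equal(cen$duplicated_names, 17L)
  expect_equal(unname(cen$per_category[c("tRNA", "protein", "rRNA")]),
               c(37L, 84L, 8L))
})

test_that("gene census identities hold on random annotation sets", {
  set.seed(91)
  part <- partition_from_lengths(4000, 1000, 1500)
  for (rep in 1:25) {
    n_single <- sample(0:12, 1)
    n_dup <- sample(0:5, 1)
    ann <- plastomekit:::empty_annotations()
    pos <- 1L
    for (i in seq_len(n_single)) {
      len <- sample(30:80, 1)
      ann <- rbind(ann, gene_annotation(
        paste0("s", i), sample(c("protein", "tRNA", "rRNA"), 1), "+",
        pos, pos + len))
      pos <- pos + len + 10L
    }
    for (i in seq_len(n_dup)) {
      len <- sample(30:60, 1)
      a_start <- 4000L + i * 150L
      b_start <- 6500L - i * 150L
      ann <- rbind(ann,
                   gene_annotation(paste0("d", i), "rRNA", "+",
                                   a_start, a_start + len,
                                   copy_tag = "IR_A"),
                   gene_annotation(paste0("d", i), "rRNA", "-",
                                   b_start, b_start + len,
                                   copy_tag = "IR_B"))
    }
    cen <- gene_census(ann, part)
    expect_equal(cen$total_copies, cen$distinct_names + cen$duplicated_names)
    expect_equal(sum(cen$per_category), cen$total_copies)
  }
  # empty input and a single duplicated pair
  cen0 <- gene_census(plastomekit:::empty_annotations(), part)
  expect_equal(cen0$total_copies, 0L)
  ann2 <- rbind(gene_annotation("d", "rRNA", "+", 4100, 4200,
                                copy_tag = "IR_A"),
                gene_annotation("d", "rRNA", "-", 6300, 6400,
                                copy_tag = "IR_B"))
  cen2 <- gene_census(ann2, part)
  expect_equal(cen2$total_copies, 2L)
  expect_equal(cen2$distinct_names, 1L)
  expect_equal(cen2$duplicated_names, 1L)
})
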