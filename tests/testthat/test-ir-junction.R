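test_that("detect_ir recovers planted IRs exactly across seeded genomes", {
  for (seed in 1:12) {
    sp <- plastome_spec(lsc_len = 2500L, ssc_len = 900L, ir_len = 800L,
                        genes = NULL, seed = seed)
    g <- generate_plastome(sp, screen = FALSE)
    ir <- detect_ir(g$record, min_ir_length = 400L)
    expect_equal(ir$ira, g$truth$ir$ira)
    expect_equal(ir$irb, g$truth$ir$irb)
    expect_equal(ir$mismatches, 0L)
  }
})

test_that("detect_ir agrees with the brute-force matcher on small genomes", {
  set.seed(21)
  for (rep in 1:5) {
    core <- random_seq(300)
    s <- paste0(random_seq(500), core, random_seq(250), revcomp(core),
                random_seq(400))
    got <- detect_ir(plastome_record("x", s, is_circular = FALSE),
                     min_ir_length = 100L)
    want <- oracle_ir_exact(s, 100L)
    expect_equal(got$ira, want$ira)
    expect_equal(got$irb, want$irb)
    expect_equal(got$length, want$length)
  }
})

test_that("mismatched IR copies are found within the mismatch budget", {
  set.seed(33)
  core <- oracle_chars(random_seq(1200))
  mut <- core
  pos <- c(200, 400, 600, 800, 1000)
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  s <- paste0(random_seq(800), paste(core, collapse = ""), random_seq(500),
              revcomp(paste(mut, collapse = "")), random_seq(300))
  rec <- plastome_record("m", s, is_circular = FALSE)
  ir <- detect_ir(rec, min_ir_length = 1000L, max_mismatch_frac = 0.01)
  # the planted pair is recovered; the maximal window may absorb a few
  # matching flank bases while staying within the 1% budget
  expect_lte(ir$ira[1], 801L)
  expect_gte(ir$ira[2], 2000L)
  expect_gte(ir$mismatches, 5L)
  expect_lte(ir$mismatches, floor(0.01 * ir$length))
  expect_gte(ir$length, 1200L)
})

test_that("genomes without an IR yield a no-IR result", {
  set.seed(5)
  rec <- plastome_record("plain", random_seq(10000), is_circular = FALSE)
  expect_null(detect_ir(rec, min_ir_length = 1000L))
  expect_error(detect_ir(plastome_record("short", random_seq(1500)),
                         min_ir_length = 1000L), "min_ir_length")
})

test_that("an IR spanning the linearization origin is still detected", {
  sp <- plastome_spec(lsc_len = 2500L, ssc_len = 900L, ir_len = 800L,
                      genes = NULL, seed = 2)
  g <- generate_plastome(sp, screen = FALSE)
  s <- g$record$sequence
  n <- nchar(s)
  # rotate so that IRb straddles the origin
  cut <- g$truth$ir$irb[1L] + 400L
  rot <- paste0(substr(s, cut + 1L, n), substr(s, 1L, cut))
  ir <- detect_ir(plastome_record("rot", rot), min_ir_length = 400L)
  expect_equal(ir$length, 800L)
})

test_that("partition and junctions follow the published arithmetic", {
  part <- partition_from_lengths(86315, 26577, 18491)
  expect_equal(unname(part$junctions),
               c(86315, 112892, 131383, 157960))
  g <- generate_plastome(small_spec(seed = 9), screen = FALSE)
  ir <- detect_ir(g$record, min_ir_length = 500L)
  part2 <- partition_from_ir(g$record, ir)
  expect_equal(part2$junctions, g$truth$partition$junctions)
  expect_equal(part2$lsc, g$truth$partition$lsc)
  expect_equal(part2$ssc, g$truth$partition$ssc)
  # degenerate: equal arcs demand explicit labelling
  s <- random_seq(100)
  rec <- plastome_record("deg", paste0(s, random_seq(40), revcomp(s),
                                       random_seq(40)),
                         is_circular = FALSE)
  ir2 <- structure(list(ira = c(1L, 100L), irb = c(141L, 240L),
                        length = 100L, mismatches = 0L), class = "ir_pair")
  expect_error(partition_from_ir(rec, ir2), "equal length")
})

test_that("junction distances match the published conventions", {
  part <- partition_from_lengths(5000, 2000, 1500)
  n <- 5000 + 2000 + 1500 + 2000
  # rps19 ends 46 bp before J_LA (J_LA = 5000)
  ann <- rbind(
    gene_annotation("rps19", "protein", "+", 4700, 4954),
    # ndhF (SSC side) ends 29 bp after J_SA going right: gene starts at
    # J_SA + 30 leaves a 29 bp downstream gap
    gene_annotation("ndhF", "protein", "-", 7030, 8000),
    # ycf1 spans J_SB (8500): starts in SSC, extends 120 bp into IRb
    gene_annotation("ycf1", "protein", "+", 8200, 8620),
    # trnH spans J_LB-like geometry: gene ending exactly at a junction
    gene_annotation("trnH", "tRNA", "-", 10419, 10500))
  rec <- plastome_record("fix", random_seq(n), ann)
  rep <- junction_report(rec, part)

  rps19 <- rep[rep$junction == "J_LA" & rep$gene == "rps19", ]
  expect_equal(rps19$relation, "upstream_gap")
  expect_equal(rps19$distance, 46L)

  ndhf <- rep[rep$junction == "J_SA" & rep$gene == "ndhF", ]
  expect_equal(ndhf$relation, "downstream_gap")
  expect_equal(ndhf$distance, 29L)

  ycf1 <- rep[rep$junction == "J_SB" & rep$gene == "ycf1", ]
  expect_equal(ycf1$relation, "spans_junction")
  expect_equal(ycf1$distance, 120L)
  expect_equal(ycf1$pseudogene_partner, "psi_ycf1")

  trnh <- rep[rep$junction == "J_LB" & rep$gene == "trnH" &
                rep$relation == "upstream_gap", ]
  expect_equal(trnh$distance, 0L)   # ends exactly at the junction
})

test_that("a trnH-style 8 bp overlap into the IR is reported as spanning", {
  part <- partition_from_lengths(5000, 2000, 1500)
  # gene crossing J_LA with 8 bp inside IRa (mirroring the trnH geometry)
  ann <- gene_annotation("trnH", "tRNA", "-", 4935, 5008)
  rec <- plastome_record("fix", random_seq(10500), ann)
  rep <- junction_report(rec, part)
  sp <- rep[rep$relation == "spans_junction", ]
  expect_equal(sp$junction, "J_LA")
  expect_equal(sp$distance, 8L)
  expect_equal(sp$pseudogene_partner, "psi_trnH")
  expect_false(sp$partner_annotated)
  # annotating the psi copy at the mirrored IRb position is then found:
  # IRa offset of the 8 bp piece is 1..8 -> IRb interval [10493, 10500]
  ann2 <- rbind(ann, gene_annotation("psi_trnH", "tRNA", "+", 10493, 10500,
                                     is_pseudo = TRUE))
  rep2 <- junction_report(plastome_record("fix", random_seq(10500), ann2),
                          part)
  sp2 <- rep2[rep2$relation == "spans_junction" & rep2$gene == "trnH", ]
  expect_true(sp2$partner_annotated)
})

test_that("every published junction distance is reproduced from its layout", {
  part <- partition_from_lengths(5000, 2000, 1500)
  J <- part$junctions[["J_LA"]]
  # genes crossing J_LA into IRa by the published extents
  for (d in c(96L, 186L, 67L, 50L, 30L, 26L, 8L)) {
    ann <- gene_annotation("crosser", "protein", "+", J - 400L, J + d)
    rep <- junction_report(plastome_record("f", random_seq(10500), ann),
                           part)
    row <- rep[rep$relation == "spans_junction", ]
    expect_equal(row$junction, "J_LA")
    expect_equal(row$distance, d)
  }
  # genes ending the published number of bases before a junction
  for (d in c(46L, 12L, 202L, 29L, 27L, 28L, 98L, 19L, 129L, 33L)) {
    ann <- gene_annotation("gapper", "protein", "+", J - 400L, J - d)
    rep <- junction_report(plastome_record("f", random_seq(10500), ann),
                           part)
    row <- rep[rep$junction == "J_LA" & rep$relation == "upstream_gap", ]
    expect_equal(row$distance, d)
  }
})

test_that("mirrored IR positions carry reverse-complement sequence", {
  g <- generate_plastome(small_spec(seed = 4), screen = FALSE)
  s <- g$record$sequence
  part <- g$truth$partition
  ira <- part$ira; irb <- part$irb
  set.seed(77)
  for (d in sample(0:(ira[2] - ira[1]), 20)) {
    p <- ira[1] + d
    q <- irb[2] - d
    expect_identical(substr(s, p, p),
                     revcomp(substr(s, q, q)))
  }
})
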