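# Fixture builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk.

random_seq <- function(n, gc = 0.37) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# small quadripartite spec with a handful of features, used throughout
small_spec <- function(seed = 1L, ...) {
  genes <- data.frame(
    name = "geneA", category = "protein", region = "LSC",
    duplicated = FALSE, exons = I(list(c(300, 200))), introns = I(list(150)))
  plastome_spec(lsc_len = 3000L, ssc_len = 1200L, ir_len = 1000L,
                genes = genes, seed = seed, ...)
}

# annotations laying out the full published gene inventory sequentially,
# with the partition implied by the layout (pure coordinate arithmetic,
# no sequence needed)
inventory_annotations <- function(gap = 10L) {
  inv <- plastid_gene_inventory()
  ann <- plastomekit:::empty_annotations()
  place <- function(region_rows, offset) {
    pos <- offset
    rows <- list()
    for (i in seq_len(nrow(region_rows))) {
      pos <- pos + gap
      ex <- region_rows$exons[[i]]; it <- region_rows$introns[[i]]
      starts <- integer(0); ends <- integer(0); cur <- pos + 1L
      for (e in seq_along(ex)) {
        starts <- c(starts, cur); ends <- c(ends, cur + ex[e] - 1L)
        cur <- cur + ex[e] + if (e < length(ex)) it[e] else 0L
      }
      rows[[i]] <- list(gene = region_rows$name[i],
                        category = region_rows$category[i],
                        duplicated = region_rows$duplicated[i],
                        starts = starts, ends = ends)
      pos <- max(ends)
    }
    list(rows = rows, end = pos + gap)
  }
  lsc <- place(inv[inv$region == "LSC", ], 0L)
  ira <- place(inv[inv$region == "IR", ], lsc$end)
  ssc <- place(inv[inv$region == "SSC", ], ira$end)
  ir_len <- ira$end - lsc$end
  irb_off <- ssc$end
  for (blk in list(lsc, ira, ssc)) {
    for (r in blk$rows) {
      tag <- if (r$duplicated) "IR_A" else "single"
      ann <- rbind(ann, gene_annotation(r$gene, r$category, "+",
                                        r$starts, r$ends, copy_tag = tag))
      if (r$duplicated) {
        # mirror into IRb
        rel_s <- r$starts - lsc$end; rel_e <- r$ends - lsc$end
        mir_s <- sort(irb_off + ir_len - rel_e + 1L)
        mir_e <- sort(irb_off + ir_len - rel_s + 1L)
        ann <- rbind(ann, gene_annotation(r$gene, r$category, "-",
                                          mir_s, mir_e, copy_tag = "IR_B"))
      }
    }
  }
  part <- partition_from_lengths(lsc$end, ir_len, ssc$end - ira$end)
  list(annotations = ann, partition = part)
}

# gene models mirroring the published exon/intron table
table4_models <- function() {
  list(
    gene_model("rpoC1", "LSC", c(1632, 441), 817),
    gene_model("atpF", "LSC", c(396, 159), 699),
    gene_model("petB", "LSC", c(6, 642), 773),
    gene_model("petD", "LSC", c(8, 475), 784),
    gene_model("ndhB", "IR", c(756, 777), 687),
    gene_model("ndhA", "SSC", c(540, 573), 1178),
    gene_model("rpl16", "LSC", c(399, 9), 1119),
    gene_model("rpl2", "IR", c(471, 393), 648),
    gene_model("rps12", "LSC", c(114, 27, 231), c(NA, 546),
               trans_spliced = TRUE),
    gene_model("ycf3", "LSC", c(153, 228, 126), c(727, 731)),
    gene_model("clpP", "LSC", c(231, 291, 69), c(676, 849)),
    gene_model("trnK-UUU", "LSC", c(29, 37), 2495),
    gene_model("trnL-UAA", "LSC", c(37, 50), 540),
    gene_model("trnV-UAC", "LSC", c(37, 39), 663),
    gene_model("trnI-GAU", "IR", c(42, 35), 939),
    gene_model("trnA-UGC", "IR", c(38, 35), 801),
    gene_model("trnG-UCC", "LSC", c(23, 48), 761))
}

# the published per-gene variability counts (gene, reference length,
# aligned length, conserved, informative)
table5_counts <- function() {
  data.frame(
    gene = c("matK", "ycf1", "ccsA", "accD", "rps3", "ndhF", "rps8",
             "rpl22", "petL", "ndhD"),
    unaligned_length_ref = c(1518, 5640, 969, 1509, 648, 2232, 405, 399,
                             96, 1503),
    aligned_length = c(1575, 6327, 987, 1401, 663, 2331, 411, 551, 96,
                       1527),
    conserved_sites = c(1028, 3970, 689, 242, 467, 1606, 294, 345, 70,
                        1116),
    parsimony_informative = c(265, 1063, 160, 227, 107, 368, 64, 82, 14,
                              207),
    stringsAsFactors = FALSE)
}

# published region lengths (LSC, SSC, IR, total) for the eight genomes
table1_lengths <- function() {
  data.frame(
    species = c("C_edulis", "E_japonicus", "H_brasiliensis", "M_esculenta",
                "P_euphratica", "R_communis", "S_purpurea", "V_seoulensis"),
    lsc = c(86315, 85941, 89209, 89295, 84888, 89651, 84452, 85691),
    ssc = c(18491, 18340, 18362, 18250, 16586, 18816, 16220, 18008),
    ir = c(26577, 26678, 26810, 26954, 27646, 27347, 27459, 26404),
    total = c(157960, 157637, 161191, 161453, 156766, 163161, 155590,
              156507),
    stringsAsFactors = FALSE)
}

# 4-taxon quartet tree helpers
quartet_tree <- function(split = c("12|34", "13|24")) {
  split <- match.arg(split)
  txt <- if (split == "12|34") "((t1,t2),(t3,t4));" else "((t1,t3),(t2,t4));"
  ape::read.tree(text = txt)
}

random_alignment <- function(n_taxa, n_col, missing_frac = 0) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_col,
                       replace = TRUE), n_taxa, n_col)
  if (missing_frac > 0) {
    idx <- which(stats::runif(length(mat)) < missing_frac)
    mat[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
  }
  rownames(mat) <- paste0("t", seq_len(n_taxa))
  alignment(mat)
}
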