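# Ground-truth plastome simulation.
#
# The generator assembles a circular quadripartite genome (LSC, IRa, SSC,
# IRb with IRb the exact reverse complement of IRa) from per-region random
# backgrounds hitting region GC targets, plants genes (with introns and IR
# duplication), SSRs, long repeats and primer constructs at recorded
# coordinates, and screens the background so that no accidental SSR or
# long repeat qualifies under the default detection thresholds. Screening
# is local: windows containing accidental features are re-sampled (with IRb
# rebuilt from IRa after every round) up to a retry cap, after which the
# residual accidental features are reported in the truth table.

#' Default gene inventory emulating a Celastraceae plastome
#'
#' 112 distinct genes (37 tRNA copies, 84 protein copies, 8 rRNA copies in
#' total once IR duplication is applied): the canonical angiosperm plastid
#' inventory with 17 IR-duplicated genes, intron-bearing genes carrying
#' their published exon/intron lengths, and nominal lengths elsewhere.
#' rps12 is modelled by its IR-resident 3' portion (trans-spliced; the LSC
#' 5' exon is not placed).
#'
#' @return data frame with columns `name`, `category`, `region`,
#'   `duplicated`, and list columns `exons`, `introns` (lengths in bp).
#' @export
plastid_gene_inventory <- function() {
  g <- function(name, category, region, duplicated, exons,
                introns = integer(0)) {
    data.frame(name = name, category = category, region = region,
               duplicated = duplicated, exons = I(list(exons)),
               introns = I(list(introns)), stringsAsFactors = FALSE)
  }
  simple <- function(names, category, region, len,
                     duplicated = FALSE) {
    do.call(rbind, lapply(names, function(nm)
      g(nm, category, region, duplicated, len)))
  }
  rbind(
    # intron-bearing genes, exon/intron lengths as annotated
    g("rpoC1", "protein", "LSC", FALSE, c(1632, 441), 817),
    g("atpF", "protein", "LSC", FALSE, c(396, 159), 699),
    g("petB", "protein", "LSC", FALSE, c(6, 642), 773),
    g("petD", "protein", "LSC", FALSE, c(8, 475), 784),
    g("ndhB", "protein", "IR", TRUE, c(756, 777), 687),
    g("ndhA", "protein", "SSC", FALSE, c(540, 573), 1178),
    g("rpl16", "protein", "LSC", FALSE, c(399, 9), 1119),
    g("rpl2", "protein", "IR", TRUE, c(471, 393), 648),
    g("rps12", "protein", "IR", TRUE, c(27, 231), 546),
    g("ycf3", "protein", "LSC", FALSE, c(153, 228, 126), c(727, 731)),
    g("clpP", "protein", "LSC", FALSE, c(231, 291, 69), c(676, 849)),
    g("trnK-UUU", "tRNA", "LSC", FALSE, c(29, 37), 2495),
    g("trnL-UAA", "tRNA", "LSC", FALSE, c(37, 50), 540),
    g("trnV-UAC", "tRNA", "LSC", FALSE, c(37, 39), 663),
    g("trnI-GAU", "tRNA", "IR", TRUE, c(42, 35), 939),
    g("trnA-UGC", "tRNA", "IR", TRUE, c(38, 35), 801),
    g("trnG-UCC", "tRNA", "LSC", FALSE, c(23, 48), 761),
    # rps16 carries no intron in this genome (the family-wide intron loss);
    # intron-bearing rps16 models are supplied explicitly when emulating
    # outgroup taxa
    g("rps16", "protein", "LSC", FALSE, 267),
    # rRNA operon, duplicated in the IRs (9050 bp over both copies)
    g("rrn16", "rRNA", "IR", TRUE, 1491),
    g("rrn23", "rRNA", "IR", TRUE, 2810),
    g("rrn4.5", "rRNA", "IR", TRUE, 103),
    g("rrn5", "rRNA", "IR", TRUE, 121),
    # IR-duplicated tRNAs and proteins
    simple(c("trnI-CAU", "trnL-CAA", "trnN-GUU", "trnR-ACG", "trnV-GAC"),
           "tRNA", "IR", 74, duplicated = TRUE),
    simple(c("rps7"), "protein", "IR", 468, duplicated = TRUE),
    simple(c("rpl23"), "protein", "IR", 282, duplicated = TRUE),
    simple(c("ycf2"), "protein", "IR", 6825, duplicated = TRUE),
    # LSC tRNAs (single copy)
    simple(c("trnC-GCA", "trnD-GUC", "trnE-UUC", "trnF-GAA", "trnfM-CAU",
             "trnG-GCC", "trnH-GUG", "trnM-CAU", "trnP-UGG",
             "trnQ-UUG", "trnR-UCU", "trnS-GCU", "trnS-GGA", "trnS-UGA",
             "trnT-GGU", "trnT-UGU", "trnW-CCA", "trnY-GUA"),
           "tRNA", "LSC", 74),
    # SSC tRNA
    simple("trnL-UAG", "tRNA", "SSC", 74),
    # LSC protein genes
    g("matK", "protein", "LSC", FALSE, 1518),
    g("accD", "protein", "LSC", FALSE, 1509),
    g("rbcL", "protein", "LSC", FALSE, 1428),
    g("rpoB", "protein", "LSC", FALSE, 3212),
    g("rpoC2", "protein", "LSC", FALSE, 4100),
    g("rpoA", "protein", "LSC", FALSE, 1014),
    g("psaA", "protein", "LSC", FALSE, 2253),
    g("psaB", "protein", "LSC", FALSE, 2205),
    g("psbA", "protein", "LSC", FALSE, 1062),
    g("psbB", "protein", "LSC", FALSE, 1527),
    g("psbC", "protein", "LSC", FALSE, 1386),
    g("psbD", "protein", "LSC", FALSE, 1062),
    g("atpA", "protein", "LSC", FALSE, 1524),
    g("atpB", "protein", "LSC", FALSE, 1497),
    g("petA", "protein", "LSC", FALSE, 963),
    g("cemA", "protein", "LSC", FALSE, 690),
    g("rps3", "protein", "LSC", FALSE, 648),
    g("rpl22", "protein", "LSC", FALSE, 399),
    g("rps8", "protein", "LSC", FALSE, 405),
    g("petL", "protein", "LSC", FALSE, 96),
    simple(c("rps2", "rps4", "rps11", "rps14", "rps18", "rps19",
             "rpl14", "rpl20", "rpl33", "rpl36",
             "psaI", "psaJ", "psbE", "psbF", "psbH", "psbI", "psbJ",
             "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ",
             "petG", "petN", "atpE", "atpH", "atpI",
             "ndhC", "ndhJ", "ndhK", "ycf4"),
           "protein", "LSC", 500),
    # SSC protein genes
    g("ycf1", "protein", "SSC", FALSE, 5640),
    g("ndhF", "protein", "SSC", FALSE, 2232),
    g("ndhD", "protein", "SSC", FALSE, 1503),
    g("ccsA", "protein", "SSC", FALSE, 969),
    simple(c("ndhE", "ndhG", "ndhH", "ndhI", "psaC", "rps15", "rpl32"),
           "protein", "SSC", 400)
  )
}

#' Specification of a synthetic plastome
#'
#' Defaults mirror the studied Celastraceae-type genome: region lengths
#' 86315 (LSC), 18491 (SSC) and 26577 bp (each IR), per-region GC targets
#' of 35.1, 31.8 and 42.7 percent, and the full gene inventory of
#' [plastid_gene_inventory()].
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp.
#' @param gc named numeric vector of GC targets per region
#'   (`lsc`, `ssc`, `ir`).
#' @param genes gene inventory data frame (see [plastid_gene_inventory()]);
#'   `NULL` for none.
#' @param ssrs data frame `motif`, `copies`, `region` of SSRs to plant, or
#'   `NULL`.
#' @param repeats data frame `type`, `length`, `identity`, `region` of long
#'   repeat pairs to plant, or `NULL`.
#' @param primers data frame `forward`, `reverse`, `product_length`,
#'   `region` of primer constructs to plant, or `NULL`.
#' @param seed integer RNG seed; the genome is fully reproducible from it.
#' @return a `plastome_spec` list.
#' @export
plastome_spec <- function(lsc_len = 86315L, ssc_len = 18491L,
                          ir_len = 26577L,
                          gc = c(lsc = 0.351, ssc = 0.318, ir = 0.427),
                          genes = plastid_gene_inventory(),
                          ssrs = NULL, repeats = NULL, primers = NULL,
                          seed = 1L) {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0, lsc_len != ssc_len,
            all(gc > 0 & gc < 1))
  structure(list(lsc_len = as.integer(lsc_len),
                 ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc = gc, genes = genes,
                 ssrs = ssrs, repeats = repeats, primers = primers,
                 seed = as.integer(seed)),
            class = "plastome_spec")
}

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Generate a synthetic plastome with its truth table
#'
#' @param spec a [plastome_spec()].
#' @param screen screen the background against accidental SSRs and long
#'   repeats (default `TRUE`).
#' @param max_patches retry cap for background re-sampling (default 1000);
#'   features still present afterwards are reported in
#'   `truth$residual_accidental`.
#' @return list with `record` (a `plastome_record`), `truth` (list:
#'   `partition`, `features` data frame of planted feature coordinates,
#'   `residual_accidental`) and `spec`.
#' @export
generate_plastome <- function(spec, screen = TRUE, max_patches = 1000L) {
  stopifnot(inherits(spec, "plastome_spec"))
  set.seed(spec$seed)
  offs <- c(lsc = 0L, ira = spec$lsc_len,
            ssc = spec$lsc_len + spec$ir_len,
            irb = spec$lsc_len + spec$ir_len + spec$ssc_len)
  n <- spec$lsc_len + spec$ssc_len + 2L * spec$ir_len

  items_for <- function(region_key) {
    items <- list()
    region_name <- c(lsc = "LSC", ssc = "SSC", ira = "IR")[[region_key]]
    add <- function(it) items[[length(items) + 1L]] <<- it
    gs <- spec$genes
    for (i in seq_len(NROW(gs))) {
      if (gs$region[i] != region_name) next
      ex <- gs$exons[[i]]; it <- gs$introns[[i]]
      segs <- numeric(0)
      for (e in seq_along(ex)) {
        segs <- c(segs, ex[e])
        if (e < length(ex)) segs <- c(segs, it[e])
      }
      add(list(kind = "gene", name = gs$name[i], category = gs$category[i],
               duplicated = isTRUE(gs$duplicated[i]), segs = segs,
               n_exons = length(ex), len = as.integer(sum(segs))))
    }
    for (i in seq_len(NROW(spec$ssrs))) {
      if (toupper(spec$ssrs$region[i]) != region_name) next
      motif <- toupper(spec$ssrs$motif[i])
      add(list(kind = "ssr", motif = motif,
               copies = as.integer(spec$ssrs$copies[i]),
               len = nchar(motif) * as.integer(spec$ssrs$copies[i])))
    }
    for (i in seq_len(NROW(spec$repeats))) {
      if (toupper(spec$repeats$region[i]) != region_name) next
      add(list(kind = "repeat", type = spec$repeats$type[i],
               rep_len = as.integer(spec$repeats$length[i]),
               identity = spec$repeats$identity[i],
               len = 2L * as.integer(spec$repeats$length[i]) + 50L))
    }
    for (i in seq_len(NROW(spec$primers))) {
      if (toupper(spec$primers$region[i]) != region_name) next
      add(list(kind = "primer", forward = toupper(spec$primers$forward[i]),
               reverse = toupper(spec$primers$reverse[i]),
               len = as.integer(spec$primers$product_length[i])))
    }
    items
  }

  build_region <- function(region_key, region_len, gc) {
    items <- items_for(region_key)
    k <- length(items)
    total <- sum(vapply(items, `[[`, numeric(1), "len"))
    min_gap <- 20L
    if (total + min_gap * (k + 1L) > region_len)
      stop("cannot place features in region ", region_key,
           ": need ", total + min_gap * (k + 1L), " bp, have ", region_len,
           call. = FALSE)
    slack <- region_len - total - min_gap * (k + 1L)
    w <- stats::runif(k + 1L)
    gaps <- min_gap + floor(w / sum(w) * slack)
    gaps[k + 1L] <- region_len - total - sum(gaps[-(k + 1L)])
    pieces <- character(0)
    pos <- 0L
    feats <- list()
    ann <- list()
    for (i in seq_len(k + 1L)) {
      gseq <- paste(random_dna(gaps[i], gc), collapse = "")
      pieces <- c(pieces, gseq); pos <- pos + gaps[i]
      if (i > k) break
      it <- items[[i]]
      rel <- pos + 1L
      if (it$kind == "gene") {
        segs <- it$segs
        sseq <- paste(random_dna(sum(segs), gc), collapse = "")
        cum <- cumsum(c(0L, segs))
        ex_idx <- seq(1L, length(segs), by = 2L)
        ann[[length(ann) + 1L]] <- data.frame(
          gene = it$name, category = it$category,
          rel_start = rel + cum[ex_idx],
          rel_end = rel + cum[ex_idx + 1L] - 1L,
          duplicated = it$duplicated, stringsAsFactors = FALSE)
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "gene", name = it$name, rel_start = rel,
          rel_end = rel + it$len - 1L, detail = it$category,
          stringsAsFactors = FALSE)
        pieces <- c(pieces, sseq); pos <- pos + it$len
      } else if (it$kind == "ssr") {
        sseq <- paste(rep(it$motif, it$copies), collapse = "")
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "ssr", name = it$motif, rel_start = rel,
          rel_end = rel + it$len - 1L,
          detail = as.character(it$copies), stringsAsFactors = FALSE)
        pieces <- c(pieces, sseq); pos <- pos + it$len
      } else if (it$kind == "repeat") {
        L <- it$rep_len
        nmm <- round((1 - it$identity) * L)
        # the construct itself must be clean: no qualifying SSR inside it
        # and exactly the planted pair as its only long repeat, else the
        # planted (protected) span would carry unpatchable accidents
        sseq <- NULL
        for (try in 1:100) {
          x <- random_dna(L, gc)
          y <- x
          if (nmm > 0L) {
            # evenly spaced central mismatches: sub-windows then carry the
            # same error density as the whole, so the full planted span is
            # what the detector reports
            mmpos <- unique(round(seq(0.25 * L, 0.75 * L,
                                      length.out = nmm)))
            for (p in mmpos)
              y[p] <- sample(setdiff(c("A", "C", "G", "T"), y[p]), 1L)
          }
          y <- switch(it$type,
                      forward = y,
                      reverse = rev(y),
                      complement = seq_chars(complement_seq(
                        paste(y, collapse = ""))),
                      palindromic = seq_chars(revcomp(
                        paste(y, collapse = ""))))
          cand <- paste0(paste(x, collapse = ""),
                         paste(random_dna(50L, gc), collapse = ""),
                         paste(y, collapse = ""))
          if (nrow(find_ssrs(cand))) next
          fr <- find_long_repeats(cand)
          if (nrow(fr) == 1L && fr$start1 == 1L && fr$end1 == L &&
              fr$start2 == L + 51L) { sseq <- cand; break }
        }
        if (is.null(sseq))
          stop("could not build a clean ", it$type, " repeat construct",
               call. = FALSE)
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "repeat", name = it$type, rel_start = rel,
          rel_end = rel + it$len - 1L,
          detail = sprintf("len=%d;identity=%.3f;start2=%d", L,
                           1 - nmm / L, rel + L + 50L),
          stringsAsFactors = FALSE)
        pieces <- c(pieces, sseq); pos <- pos + it$len
      } else if (it$kind == "primer") {
        fl <- nchar(it$forward); rl <- nchar(it$reverse)
        ins <- it$len - fl - rl
        if (ins < 0L) stop("primer product shorter than the primers",
                           call. = FALSE)
        sseq <- paste0(it$forward,
                       paste(random_dna(ins, gc), collapse = ""),
                       revcomp(it$reverse))
        for (try in 1:50) {
          if (!nrow(find_ssrs(sseq))) break
          sseq <- paste0(it$forward,
                         paste(random_dna(ins, gc), collapse = ""),
                         revcomp(it$reverse))
        }
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "primer", name = paste0("amplicon_", it$len),
          rel_start = rel, rel_end = rel + it$len - 1L,
          detail = as.character(it$len), stringsAsFactors = FALSE)
        pieces <- c(pieces, sseq); pos <- pos + it$len
      }
    }
    list(seq = paste(pieces, collapse = ""),
         feats = if (length(feats)) do.call(rbind, feats) else NULL,
         ann = if (length(ann)) do.call(rbind, ann) else NULL)
  }

  regions <- list(
    lsc = build_region("lsc", spec$lsc_len, spec$gc[["lsc"]]),
    ira = build_region("ira", spec$ir_len, spec$gc[["ir"]]),
    ssc = build_region("ssc", spec$ssc_len, spec$gc[["ssc"]]))

  # guard SSR flanks so planted runs stay maximal at their planted length
  guard_ssrs <- function(reg) {
    f <- reg$feats
    if (is.null(f)) return(reg)
    ch <- seq_chars(reg$seq)
    for (i in which(f$kind == "ssr")) {
      m <- nchar(f$name[i]); s <- f$rel_start[i]; e <- f$rel_end[i]
      if (s > 1L && ch[s - 1L] == ch[s - 1L + m])
        ch[s - 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                     ch[s - 1L + m]), 1L)
      if (e < length(ch) && ch[e + 1L] == ch[e + 1L - m])
        ch[e + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                     ch[e + 1L - m]), 1L)
    }
    reg$seq <- paste(ch, collapse = "")
    reg
  }
  # guard repeat flanks so the first extension base past a planted copy
  # mismatches its partner and the planted span is reported exactly
  guard_repeats <- function(reg) {
    f <- reg$feats
    if (is.null(f)) return(reg)
    ch <- seq_chars(reg$seq)
    cmp <- c(A = "T", C = "G", G = "C", T = "A")
    force_diff <- function(pos, partner, use_comp) {
      if (pos < 1L || pos > length(ch) ||
          partner < 1L || partner > length(ch)) return()
      tgt <- if (use_comp) cmp[[ch[partner]]] else ch[partner]
      if (ch[pos] == tgt)
        ch[pos] <<- sample(setdiff(c("A", "C", "G", "T"), tgt), 1L)
    }
    for (i in which(f$kind == "repeat")) {
      det <- f$detail[i]
      L <- as.integer(sub(".*len=(\\d+);.*", "\\1", det))
      s2 <- as.integer(sub(".*start2=(\\d+)$", "\\1", det))
      s1 <- f$rel_start[i]; e1 <- s1 + L - 1L; e2 <- s2 + L - 1L
      type <- f$name[i]
      usec <- type %in% c("complement", "palindromic")
      if (type %in% c("forward", "complement")) {
        force_diff(s1 - 1L, s2 - 1L, usec)
        force_diff(e1 + 1L, e2 + 1L, usec)
      } else {
        force_diff(s1 - 1L, e2 + 1L, usec)
        force_diff(e1 + 1L, s2 - 1L, usec)
      }
    }
    reg$seq <- paste(ch, collapse = "")
    reg
  }
  # the planted IR must not extend by chance: the base pair flanking the
  # IRa/SSC and SSC/IRb junctions continues the IR anti-diagonal, so the
  # first and last SSC bases are forced to not be complementary
  guard_ir_boundary <- function(regions) {
    cmp <- c(A = "T", C = "G", G = "C", T = "A")
    for (key in c("ssc", "lsc")) {   # lsc guards the circular LSC arc too
      ch <- seq_chars(regions[[key]]$seq)
      if (ch[1L] == cmp[[ch[length(ch)]]])
        ch[1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                 cmp[[ch[length(ch)]]]), 1L)
      regions[[key]]$seq <- paste(ch, collapse = "")
    }
    regions
  }
  guard_all <- function(regions) {
    regions <- lapply(regions, function(r) guard_repeats(guard_ssrs(r)))
    guard_ir_boundary(regions)
  }
  regions <- guard_all(regions)

  assemble <- function(regions) {
    paste0(regions$lsc$seq, regions$ira$seq, regions$ssc$seq,
           revcomp(regions$ira$seq))
  }

  abs_feats <- function(regions) {
    out <- list()
    for (r in names(regions)) {
      f <- regions[[r]]$feats
      if (is.null(f)) next
      f$start <- f$rel_start + offs[[r]]
      f$end <- f$rel_end + offs[[r]]
      f$region <- toupper(r)
      is_rep <- f$kind == "repeat"
      if (any(is_rep)) { # report the partner-copy start absolutely
        s2 <- as.integer(sub(".*start2=(\\d+)$", "\\1", f$detail[is_rep]))
        f$detail[is_rep] <- sub("start2=\\d+$", "", f$detail[is_rep])
        f$detail[is_rep] <- paste0(f$detail[is_rep], "start2=",
                                   s2 + offs[[r]])
      }
      out[[r]] <- f[, c("kind", "name", "start", "end", "region", "detail")]
    }
    if (!length(out))
      return(data.frame(kind = character(0), name = character(0),
                        start = integer(0), end = integer(0),
                        region = character(0), detail = character(0),
                        stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }

  # planted-feature intervals (absolute, incl. IRb mirrors) for patching
  protected <- function(feats) {
    # gene interiors are random background, hence re-rollable; only planted
    # sequence-level features (SSRs, repeats, primer sites) are protected
    feats <- feats[feats$kind != "gene", , drop = FALSE]
    if (!nrow(feats)) return(cbind(integer(0), integer(0)))
    iv <- cbind(feats$start, feats$end)
    in_ira <- feats$start > offs[["ira"]] &
      feats$end <= offs[["ira"]] + spec$ir_len
    if (any(in_ira)) {
      rel_s <- feats$start[in_ira] - offs[["ira"]]
      rel_e <- feats$end[in_ira] - offs[["ira"]]
      iv <- rbind(iv, cbind(offs[["irb"]] + spec$ir_len - rel_e + 1L,
                            offs[["irb"]] + spec$ir_len - rel_s + 1L))
    }
    iv
  }

  patch_window <- function(regions, a, b) {
    # map absolute window [a, b] to a region-relative window and re-sample
    key <- if (b <= offs[["ira"]]) "lsc"
      else if (b <= offs[["ssc"]]) "ira"
      else if (b <= offs[["irb"]]) "ssc"
      else "irb"
    if (key == "irb") { # patch the IRa mirror instead
      rel_s <- spec$ir_len - (b - offs[["irb"]]) + 1L
      rel_e <- spec$ir_len - (a - offs[["irb"]]) + 1L
      key <- "ira"
    } else {
      rel_s <- a - offs[[key]]; rel_e <- b - offs[[key]]
    }
    if (rel_s < 1L || rel_e > nchar(regions[[key]]$seq)) return(regions)
    gckey <- if (key == "ira") "ir" else key
    fresh <- paste(random_dna(rel_e - rel_s + 1L, spec$gc[[gckey]]),
                   collapse = "")
    s <- regions[[key]]$seq
    regions[[key]]$seq <- paste0(substr(s, 1L, rel_s - 1L), fresh,
                                 substr(s, rel_e + 1L, nchar(s)))
    regions
  }

  feats <- abs_feats(regions)
  prot <- protected(feats)
  overlaps_protected <- function(a, b)
    nrow(prot) > 0L && any(prot[, 1L] <= b & prot[, 2L] >= a)

  truth_ir <- structure(list(ira = c(offs[["ira"]] + 1L,
                                     offs[["ira"]] + spec$ir_len),
                             irb = c(offs[["irb"]] + 1L,
                                     offs[["irb"]] + spec$ir_len),
                             length = spec$ir_len, mismatches = 0L),
                        class = "ir_pair")
  residual <- NULL
  if (screen) {
    patches <- 0L
    repeat {
      genome <- assemble(regions)
      extras <- accidental_features(genome, feats, truth_ir, offs, spec)
      if (!nrow(extras)) { residual <- NULL; break }
      # for a repeat pair either copy may be re-sampled; prefer a fully
      # unprotected interval, else the largest unprotected overhang of
      # either interval (accidents straddling a planted feature's edge)
      unprotected_part <- function(a, b) {
        pos <- a:b
        if (nrow(prot))
          for (x in seq_len(nrow(prot)))
            pos <- pos[pos < prot[x, 1L] | pos > prot[x, 2L]]
        if (!length(pos)) return(NULL)
        runs <- split(pos, cumsum(c(TRUE, diff(pos) != 1L)))
        best <- runs[[which.max(lengths(runs))]]
        c(min(best), max(best))
      }
      win <- lapply(seq_len(nrow(extras)), function(i) {
        if (!overlaps_protected(extras$start[i], extras$end[i]))
          return(c(extras$start[i], extras$end[i]))
        if (!is.na(extras$start_alt[i]) &&
            !overlaps_protected(extras$start_alt[i], extras$end_alt[i]))
          return(c(extras$start_alt[i], extras$end_alt[i]))
        w <- unprotected_part(extras$start[i], extras$end[i])
        if (is.null(w) && !is.na(extras$start_alt[i]))
          w <- unprotected_part(extras$start_alt[i], extras$end_alt[i])
        w
      })
      fixable <- !vapply(win, is.null, logical(1))
      if (!any(fixable) || patches >= max_patches) {
        residual <- extras
        break
      }
      for (i in which(fixable)) {
        if (patches >= max_patches) break
        regions <- patch_window(regions, win[[i]][1L], win[[i]][2L])
        patches <- patches + 1L
      }
      regions <- guard_all(regions)
    }
  }
  genome <- assemble(regions)
  feats <- abs_feats(regions)

  # annotations (absolute); IR genes mirrored into IRb
  ann <- empty_annotations()
  for (r in names(regions)) {
    a <- regions[[r]]$ann
    if (is.null(a)) next
    for (g in unique(a$gene)) {
      rows <- a[a$gene == g, , drop = FALSE]
      dup <- any(rows$duplicated)
      tag <- if (dup && r == "ira") "IR_A" else "single"
      ann <- rbind(ann, gene_annotation(
        gene = g, category = rows$category[1L], strand = "+",
        starts = rows$rel_start + offs[[r]],
        ends = rows$rel_end + offs[[r]], copy_tag = tag))
      if (dup && r == "ira") {
        # mirror of an IRa-relative interval [s, e] is
        # [ir_len - e + 1, ir_len - s + 1] in IRb-relative coordinates
        mir_s <- offs[["irb"]] + spec$ir_len - rows$rel_end + 1L
        mir_e <- offs[["irb"]] + spec$ir_len - rows$rel_start + 1L
        ann <- rbind(ann, gene_annotation(
          gene = g, category = rows$category[1L], strand = "-",
          starts = sort(mir_s), ends = sort(mir_e), copy_tag = "IR_B"))
      }
    }
  }
  rec <- plastome_record(paste0("synthetic_seed", spec$seed), genome, ann,
                         is_circular = TRUE, source = "synthetic")
  partition <- partition_from_lengths(spec$lsc_len, spec$ir_len,
                                      spec$ssc_len)
  list(record = rec,
       truth = list(partition = partition, ir = truth_ir,
                    features = feats, residual_accidental = residual),
       spec = spec)
}

# accidental = detected SSRs / long repeats not matching a planted feature
accidental_features <- function(genome, feats, truth_ir, offs, spec) {
  planted_ssr <- feats[feats$kind == "ssr", , drop = FALSE]
  expect <- cbind(planted_ssr$start, planted_ssr$end)
  if (nrow(planted_ssr)) {
    in_ira <- planted_ssr$start > offs[["ira"]] &
      planted_ssr$end <= offs[["ira"]] + spec$ir_len
    if (any(in_ira)) {
      rel_s <- planted_ssr$start[in_ira] - offs[["ira"]]
      rel_e <- planted_ssr$end[in_ira] - offs[["ira"]]
      expect <- rbind(expect,
                      cbind(offs[["irb"]] + spec$ir_len - rel_e + 1L,
                            offs[["irb"]] + spec$ir_len - rel_s + 1L))
    }
  }
  ssr_hits <- find_ssrs(genome)
  extra_ssr <- ssr_hits[!vapply(seq_len(nrow(ssr_hits)), function(i)
    any(expect[, 1L] == ssr_hits$start[i] & expect[, 2L] == ssr_hits$end[i]),
    logical(1)), , drop = FALSE]
  rep_hits <- find_long_repeats(genome, ir = truth_ir)
  planted_rep <- feats[feats$kind == "repeat", , drop = FALSE]
  extra_rep <- rep_hits[!vapply(seq_len(nrow(rep_hits)), function(i)
    any(planted_rep$start <= rep_hits$start1[i] &
          planted_rep$end >= rep_hits$end2[i]), logical(1)), , drop = FALSE]
  out <- rbind(
    if (nrow(extra_ssr)) data.frame(start = extra_ssr$start,
                                    end = extra_ssr$end,
                                    start_alt = NA_integer_,
                                    end_alt = NA_integer_,
                                    what = "ssr",
                                    stringsAsFactors = FALSE) else NULL,
    if (nrow(extra_rep)) data.frame(start = extra_rep$start1,
                                    end = extra_rep$end1,
                                    start_alt = extra_rep$start2,
                                    end_alt = extra_rep$end2,
                                    what = "repeat",
                                    stringsAsFactors = FALSE) else NULL)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               start_alt = integer(0),
                               end_alt = integer(0), what = character(0),
                               stringsAsFactors = FALSE) else out
}

#' Evolve a set of taxa from an ancestral plastome along a tree
#'
#' Substitutions are placed i.i.d. per site along each branch under an
#' equal-rates (Jukes-Cantor) model: the per-site substitution probability
#' on a branch of length b is 3/4 (1 - exp(-4/3 b r)), so the expected
#' number of substitutions per site is b times r. No indels are introduced;
#' planted loss events are applied on the named tips after evolution.
#' Per-gene alignments come from the known homology (no realignment).
#'
#' @param ancestor an annotated `plastome_record`.
#' @param tree `ape::phylo` with branch lengths; tip labels name the taxa.
#' @param sub_rate substitution rate multiplier (per site per unit branch
#'   length).
#' @param events list of events, each a list with `clade` (character vector
#'   of tip labels), `type` (`"intron_loss"` or `"gene_loss"`) and `gene`.
#' @param seed integer RNG seed.
#' @return list with `records` (named list of `plastome_record`s),
#'   `alignments` (named list of `alignment` objects per gene, built in the
#'   ancestral coordinate frame with lost introns gapped and lost genes'
#'   taxa dropped) and `tree`.
#' @export
evolve_taxa <- function(ancestor, tree, sub_rate = 0.05, events = list(),
                        seed = 1L) {
  stopifnot(inherits(ancestor, "plastome_record"),
            inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  spans <- gene_spans(ancestor$annotations)
  for (ev in events) {
    stopifnot(ev$type %in% c("intron_loss", "gene_loss"))
    if (!ev$gene %in% spans$gene)
      stop("event on unknown gene: ", ev$gene, call. = FALSE)
    if (!all(ev$clade %in% tree$tip.label))
      stop("event clade contains unknown taxa", call. = FALSE)
  }
  nt <- length(tree$tip.label)
  ord <- rev(ape::postorder(tree))      # parent-before-child edge order
  node_seq <- vector("list", nt + tree$Nnode)
  root <- nt + 1L
  node_seq[[root]] <- seq_chars(ancestor$sequence)
  bases <- c("A", "C", "G", "T")
  for (e in ord) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    mu <- tree$edge.length[e] * sub_rate
    p <- 0.75 * (1 - exp(-4 / 3 * mu))
    s <- node_seq[[par]]
    if (p > 0) {
      hit <- which(stats::runif(length(s)) < p)
      if (length(hit))
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1))
    }
    node_seq[[chi]] <- s
  }
  taxa <- tree$tip.label
  seqs <- lapply(seq_len(nt), function(i) node_seq[[i]])
  names(seqs) <- taxa

  # per-gene alignments in the ancestral frame
  ann <- ancestor$annotations
  alignments <- list()
  for (g in unique(spans$gene)) {
    sp <- spans[spans$gene == g, , drop = FALSE][1L, ] # first copy
    rows <- matrix("", 0L, sp$end - sp$start + 1L)
    keep_taxa <- character(0)
    for (tx in taxa) {
      lost_gene <- any(vapply(events, function(ev)
        ev$type == "gene_loss" && ev$gene == g && tx %in% ev$clade,
        logical(1)))
      if (lost_gene) next
      row <- seqs[[tx]][sp$start:sp$end]
      lost_intron <- any(vapply(events, function(ev)
        ev$type == "intron_loss" && ev$gene == g && tx %in% ev$clade,
        logical(1)))
      if (lost_intron) {
        ex <- ann[ann$gene == g & ann$copy_tag == sp$copy_tag, ,
                  drop = FALSE]
        ex <- ex[order(ex$start), , drop = FALSE]
        if (nrow(ex) > 1L)
          for (i in seq_len(nrow(ex) - 1L)) {
            iv <- (ex$end[i] + 1L):(ex$start[i + 1L] - 1L) - sp$start + 1L
            row[iv] <- "-"
          }
      }
      rows <- rbind(rows, row)
      keep_taxa <- c(keep_taxa, tx)
    }
    if (nrow(rows) >= 2L) {
      rownames(rows) <- keep_taxa
      alignments[[g]] <- alignment(rows)
    }
  }

  # final records with loss events applied as physical deletions
  records <- list()
  for (tx in taxa) {
    rec <- plastome_record(tx, paste(seqs[[tx]], collapse = ""),
                           ancestor$annotations, source = "synthetic")
    dels <- list()
    for (ev in events) {
      if (!tx %in% ev$clade) next
      sp <- spans[spans$gene == ev$gene, , drop = FALSE]
      for (ci in seq_len(nrow(sp))) {
        if (ev$type == "gene_loss") {
          dels[[length(dels) + 1L]] <- c(sp$start[ci], sp$end[ci])
        } else {
          ex <- ann[ann$gene == ev$gene & ann$copy_tag == sp$copy_tag[ci], ,
                    drop = FALSE]
          ex <- ex[order(ex$start), , drop = FALSE]
          if (nrow(ex) > 1L)
            for (i in seq_len(nrow(ex) - 1L))
              dels[[length(dels) + 1L]] <- c(ex$end[i] + 1L,
                                             ex$start[i + 1L] - 1L)
        }
      }
    }
    records[[tx]] <- delete_intervals(rec, dels)
  }
  list(records = records, alignments = alignments, tree = tree)
}

# remove intervals from a record's sequence, shifting/pruning annotations
delete_intervals <- function(rec, intervals) {
  if (!length(intervals)) return(rec)
  ivs <- do.call(rbind, intervals)
  ivs <- ivs[order(-ivs[, 1L]), , drop = FALSE]
  s <- rec$sequence
  ann <- rec$annotations
  for (i in seq_len(nrow(ivs))) {
    a <- ivs[i, 1L]; b <- ivs[i, 2L]
    len <- b - a + 1L
    s <- paste0(substr(s, 1L, a - 1L), substr(s, b + 1L, nchar(s)))
    drop <- ann$start <= b & ann$end >= a
    ann <- ann[!drop, , drop = FALSE]
    shift <- ann$start > b
    ann$start[shift] <- ann$start[shift] - len
    ann$end[shift] <- ann$end[shift] - len
  }
  plastome_record(rec$id, s, ann, rec$is_circular, rec$source)
}
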