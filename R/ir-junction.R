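# Inverted-repeat detection, quadripartite partitioning and junction reports.
#
# Detection is k-mer anchoring of the sequence against its reverse
# complement: palindromic k-mer pairs share a base-level anti-diagonal
# (p + q constant for paired bases p, q), so anchors are grouped by
# anti-diagonal and the best diagonal is scanned base-by-base with a
# two-pointer window that enforces the mismatch budget. A quadratic
# brute-force matcher with the same contract lives in the test suite as the
# independent oracle.

#' Detect the inverted-repeat pair of a plastome
#'
#' Finds the longest pair of disjoint intervals whose sequences are reverse
#' complements of one another within a mismatch budget. Ties are broken by
#' the smaller start coordinate of IRa. For circular records the search is
#' repeated on a half-rotated copy so an IR spanning the linearization
#' origin is still found.
#'
#' @param rec a `plastome_record`.
#' @param min_ir_length minimum acceptable IR length in bp (default 1000).
#' @param max_mismatch_frac maximum fraction of mismatched bases allowed
#'   between one IR copy and the reverse complement of the other (default 0;
#'   plastome IRs are typically identical).
#' @param k anchor k-mer size.
#' @return an `ir_pair` list (`ira`, `irb` as `c(start, end)` 1-based
#'   inclusive intervals, `length`, `mismatches`), or `NULL` when no
#'   qualifying pair exists.
#' @export
detect_ir <- function(rec, min_ir_length = 1000L, max_mismatch_frac = 0,
                      k = 21L) {
  s <- rec$sequence
  n <- nchar(s)
  if (n < 2L * min_ir_length)
    stop("genome length ", n, " < 2 x min_ir_length", call. = FALSE)
  best <- detect_ir_linear(s, min_ir_length, max_mismatch_frac, k)
  if (isTRUE(rec$is_circular)) {
    off <- n %/% 2L
    rot <- paste0(substr(s, off + 1L, n), substr(s, 1L, off))
    alt <- detect_ir_linear(rot, min_ir_length, max_mismatch_frac, k)
    if (!is.null(alt) && (is.null(best) || alt$length > best$length)) {
      # map back to the original frame; an interval crossing the origin is
      # reported unwrapped, with end > genome length, meaning modulo n
      map <- function(iv) {
        v <- ((iv - 1L + off) %% n) + 1L
        if (v[2L] < v[1L]) v[2L] <- v[2L] + n
        v
      }
      a <- map(alt$ira); b <- map(alt$irb)
      if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
      best <- list(ira = a, irb = b, length = alt$length,
                   mismatches = alt$mismatches)
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "ir_pair")
}

detect_ir_linear <- function(s, min_ir_length, max_mismatch_frac, k) {
  n <- nchar(s)
  fw <- kmer_vector(s, k)
  rc <- rev(kmer_vector(revcomp(s), k)) # rc[j] = revcomp of s[j..j+k-1]
  uf <- !(duplicated(fw) | duplicated(fw, fromLast = TRUE))
  ur <- !(duplicated(rc) | duplicated(rc, fromLast = TRUE))
  j <- match(fw, rc)
  keep <- !is.na(j) & uf & ur[pmin(j, length(rc))]
  i <- which(keep); j <- j[keep]
  sel <- i < j
  i <- i[sel]; j <- j[sel]
  if (!length(i)) return(NULL)
  # base-level anti-diagonal: paired bases satisfy p + q = i + j + k - 1
  D <- i + j + k - 1L
  cand <- sort(table(D), decreasing = TRUE)
  cand <- as.integer(names(cand))[seq_len(min(20L, length(cand)))]
  ch <- seq_chars(s)
  comp <- chartr("ACGTN", "TGCAN", ch)
  best <- NULL
  for (d in cand) {
    hit <- scan_antidiagonal(ch, comp, d, n, min_ir_length,
                             max_mismatch_frac)
    if (!is.null(hit) &&
        (is.null(best) || hit$length > best$length ||
         (hit$length == best$length && hit$ira[1L] < best$ira[1L])))
      best <- hit
  }
  best
}

# longest window [p1, p2] on anti-diagonal d (base p pairs with base d - p)
# with p2 < d - p2, length >= min_len, mismatches <= floor(frac * length)
scan_antidiagonal <- function(ch, comp, d, n, min_len, frac) {
  lo <- max(1L, d - n)
  hi <- min((d - 1L) %/% 2L, n)
  if (hi - lo + 1L < min_len) return(NULL)
  p <- lo:hi
  mism <- ch[p] != comp[d - p] | ch[p] == "N"
  best_len <- 0L; best <- NULL
  left <- 1L; nm <- 0L
  m <- length(p)
  for (right in seq_len(m)) {
    nm <- nm + mism[right]
    while (nm > floor(frac * (right - left + 1L)) && left <= right) {
      nm <- nm - mism[left]
      left <- left + 1L
    }
    len <- right - left + 1L
    if (len > best_len) {
      best_len <- len
      best <- c(left, right, nm)
    }
  }
  if (is.null(best) || best_len < min_len) return(NULL)
  p1 <- p[best[1L]]; p2 <- p[best[2L]]
  # trim flanking mismatches: a maximal pair should start/end on a match
  while (p1 < p2 && (ch[p1] != comp[d - p1] || ch[p1] == "N")) p1 <- p1 + 1L
  while (p2 > p1 && (ch[p2] != comp[d - p2] || ch[p2] == "N")) p2 <- p2 - 1L
  len <- p2 - p1 + 1L
  if (len < min_len) return(NULL)
  list(ira = c(p1, p2), irb = c(d - p2, d - p1), length = len,
       mismatches = sum(ch[p1:p2] != comp[d - (p1:p2)]))
}

#' Derive the quadripartite partition from an IR pair
#'
#' The two arcs between the IRs are labelled LSC (the longer) and SSC (the
#' shorter); junction coordinates are the circular positions of the last
#' base of each region, in the order J_LA (LSC to IRa), J_SA (IRa to SSC),
#' J_SB (SSC to IRb), J_LB (IRb to LSC).
#'
#' @param rec a `plastome_record`.
#' @param ir an `ir_pair` from [detect_ir()].
#' @return a `region_partition` list with elements `lsc`, `ira`, `ssc`,
#'   `irb` (1-based inclusive intervals; an interval whose end exceeds the
#'   genome length wraps the origin) and `junctions`.
#' @export
partition_from_ir <- function(rec, ir) {
  n <- nchar(rec$sequence)
  a <- ir$ira; b <- ir$irb
  arc1 <- c(a[2L] + 1L, b[1L] - 1L)              # between IRa and IRb
  len1 <- arc1[2L] - arc1[1L] + 1L
  arc2 <- c(b[2L] + 1L, a[1L] - 1L + n)          # wraps the origin
  len2 <- arc2[2L] - arc2[1L] + 1L
  if (len1 < 1L || len2 < 1L)
    stop("IR pair leaves an empty single-copy arc", call. = FALSE)
  if (len1 == len2)
    stop("single-copy arcs are of equal length; explicit LSC/SSC labelling ",
         "required", call. = FALSE)
  # circular order of the four pieces is a, arc1, b, arc2(wrapping);
  # walking the circle from the first LSC base gives LSC, IRa, SSC, IRb
  if (len2 > len1) {
    lsc <- arc2; ira <- a; ssc <- arc1; irb_ <- b
  } else {
    lsc <- arc1; ira <- b; ssc <- arc2; irb_ <- a
  }
  # normalize intervals lying entirely beyond n back onto [1, n]
  norm <- function(iv) if (iv[1L] > n) iv - n else iv
  lsc <- norm(lsc); ira <- norm(ira); ssc <- norm(ssc); irb_ <- norm(irb_)
  wrap1 <- function(x) ((x - 1L) %% n) + 1L
  junctions <- c(J_LA = wrap1(lsc[2L]), J_SA = wrap1(ira[2L]),
                 J_SB = wrap1(ssc[2L]), J_LB = wrap1(irb_[2L]))
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb_,
                 junctions = junctions, genome_length = n),
            class = "region_partition")
}

#' Build a partition directly from known region lengths
#'
#' Convenience constructor for the canonical layout (LSC from base 1,
#' then IRa, SSC, IRb).
#'
#' @param lsc_len,ira_len,ssc_len,irb_len region lengths in bp.
#' @return a `region_partition`.
#' @export
partition_from_lengths <- function(lsc_len, ira_len, ssc_len,
                                   irb_len = ira_len) {
  lsc_len <- as.integer(lsc_len); ira_len <- as.integer(ira_len)
  ssc_len <- as.integer(ssc_len); irb_len <- as.integer(irb_len)
  e1 <- lsc_len; e2 <- e1 + ira_len; e3 <- e2 + ssc_len; e4 <- e3 + irb_len
  structure(list(lsc = c(1L, e1), ira = c(e1 + 1L, e2),
                 ssc = c(e2 + 1L, e3), irb = c(e3 + 1L, e4),
                 junctions = c(J_LA = e1, J_SA = e2, J_SB = e3, J_LB = e4),
                 genome_length = e4),
            class = "region_partition")
}

#' Junction context report
#'
#' For each of the four junctions, reports any gene spanning it (with the
#' extent of the gene beyond the junction into the region holding its
#' minority of bases) and the nearest gene on each side (with the number of
#' bases strictly between the gene end and the junction). For a gene that
#' extends from a single-copy region into an IR, the expected pseudogene
#' partner (`psi_<gene>`) at the mirrored position of the opposite IR is
#' named and its annotation presence checked.
#'
#' @param rec a `plastome_record` with annotations.
#' @param partition a `region_partition`.
#' @return data frame with columns `junction`, `gene`, `relation`
#'   (`spans_junction`, `upstream_gap`, `downstream_gap`), `distance` (bp),
#'   `pseudogene_partner`, `partner_annotated`.
#' @export
junction_report <- function(rec, partition) {
  spans <- gene_spans(rec$annotations)
  out <- data.frame(junction = character(0), gene = character(0),
                    relation = character(0), distance = integer(0),
                    pseudogene_partner = character(0),
                    partner_annotated = logical(0), stringsAsFactors = FALSE)
  if (!nrow(spans)) return(out)
  ira <- partition$ira; irb <- partition$irb
  for (jn in c("J_LA", "J_SA", "J_SB", "J_LB")) {
    J <- partition$junctions[[jn]]
    spanning <- spans[spans$start <= J & spans$end > J, , drop = FALSE]
    for (i in seq_len(nrow(spanning))) {
      g <- spanning[i, ]
      over <- min(g$end - J, J - g$start + 1L)
      partner <- NA_character_; partner_found <- NA
      # gene body crossing from a single-copy region into an IR implies a
      # mirrored (pseudo) fragment in the other IR
      mirror <- NULL
      if (jn == "J_LA" && g$end > J)        # into IRa from LSC
        mirror <- c(irb[2L] - (g$end - J) + 1L, irb[2L])
      if (jn == "J_SB" && g$start <= J)     # ycf1-style: from SSC into IRb
        mirror <- c(ira[1L], ira[1L] + (g$end - J) - 1L)
      if (jn == "J_LB" && g$start <= J)     # trnH-style: from IRb into LSC?
        mirror <- NULL                      # LSC side has no mirror
      if (jn == "J_SA" && g$start <= J)     # from IRa into SSC
        mirror <- c(irb[2L] - (J - g$start + 1L) + 1L, irb[2L])
      if (!is.null(mirror)) {
        partner <- paste0("psi_", g$gene)
        hits <- spans$start <= mirror[2L] & spans$end >= mirror[1L] &
          (spans$gene == partner | (spans$gene == g$gene & spans$is_pseudo))
        partner_found <- any(hits)
      }
      out <- rbind(out, data.frame(
        junction = jn, gene = g$gene, relation = "spans_junction",
        distance = over, pseudogene_partner = partner,
        partner_annotated = partner_found, stringsAsFactors = FALSE))
    }
    up <- spans[spans$end <= J, , drop = FALSE]
    if (nrow(up)) {
      g <- up[which.max(up$end), ]
      out <- rbind(out, data.frame(
        junction = jn, gene = g$gene, relation = "upstream_gap",
        distance = J - g$end, pseudogene_partner = NA_character_,
        partner_annotated = NA, stringsAsFactors = FALSE))
    }
    dn <- spans[spans$start > J, , drop = FALSE]
    if (nrow(dn)) {
      g <- dn[which.min(dn$start), ]
      out <- rbind(out, data.frame(
        junction = jn, gene = g$gene, relation = "downstream_gap",
        distance = g$start - J - 1L, pseudogene_partner = NA_character_,
        partner_annotated = NA, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
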