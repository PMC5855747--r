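# SSR scanning and long-repeat detection (REPuter's four classes).
#
# SSRs are maximal perfect tandem runs of a primitive 1-6 bp motif, kept
# when the copy number reaches the motif-length-specific cutoff. Long
# repeats are gapless locally-maximal pairings of two loci in one of four
# classes (forward, reverse, complement, palindromic) with Hamming identity
# at or above a threshold. Both scanners are seed-and-extend; quadratic
# brute-force oracles with the same contracts live in the test suite.

#' Default SSR copy-number cutoffs
#'
#' Eight copies for mononucleotide motifs, four for dinucleotide, three for
#' tri- through hexanucleotide motifs.
#'
#' @return named integer vector indexed by motif length "1".."6".
#' @export
ssr_thresholds <- function() {
  c(`1` = 8L, `2` = 4L, `3` = 3L, `4` = 3L, `5` = 3L, `6` = 3L)
}

is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (paste(rep(unit, m %/% d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

#' Scan a plastome for simple sequence repeats
#'
#' Reports maximal, non-extendable perfect tandem runs of primitive motifs
#' meeting the copy-number cutoffs. A run reportable at two motif lengths
#' (e.g. a homopolymer inside a longer dinucleotide run) is reported once,
#' preferring the longer total span. Trailing partial motif copies are
#' truncated, so `end - start + 1 == copies * nchar(motif)`.
#'
#' @param rec a `plastome_record` (or plain character sequence).
#' @param partition optional `region_partition` for region assignment.
#' @param thresholds named vector of minimum copies per motif length,
#'   defaults to [ssr_thresholds()].
#' @param collapse_ir when `TRUE` (default) an SSR lying fully inside IRb
#'   whose mirrored locus in IRa is also reported is collapsed to the IRa
#'   representative, so IR loci are counted once.
#' @return data frame with columns `motif`, `motif_len`, `copies`, `start`,
#'   `end`, `region`, `context`.
#' @export
find_ssrs <- function(rec, partition = NULL, thresholds = ssr_thresholds(),
                      collapse_ir = TRUE) {
  s <- if (inherits(rec, "plastome_record")) rec$sequence else toupper(rec)
  n <- nchar(s)
  empty <- data.frame(motif = character(0), motif_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), region = character(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ch <- seq_chars(s)
  hits <- empty
  for (m in as.integer(names(thresholds))) {
    if (n < 2L * m) next
    eq <- ch[seq_len(n - m)] == ch[seq_len(n - m) + m] &
      ch[seq_len(n - m)] != "N"
    r <- rle(eq)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= m * (thresholds[[as.character(m)]] - 1L))) {
      i <- starts_idx[ri]
      total <- r$lengths[ri] + m          # full tandem tract length
      copies <- total %/% m
      if (copies < thresholds[[as.character(m)]]) next
      motif <- substr(s, i, i + m - 1L)
      if (!is_primitive_motif(motif)) next
      hits <- rbind(hits, data.frame(
        motif = motif, motif_len = m, copies = copies,
        start = i, end = i + copies * m - 1L,
        region = NA_character_, context = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (!nrow(hits)) return(empty)
  # containment resolution: keep the longer span when one hit lies inside
  # another (homopolymer inside a dinucleotide tract and the like)
  o <- order(-(hits$end - hits$start), hits$start)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    contained <- keep & seq_len(nrow(hits)) > i &
      hits$start >= hits$start[i] & hits$end <= hits$end[i]
    keep[contained] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  if (!is.null(partition)) {
    hits$region <- vapply(seq_len(nrow(hits)), function(i)
      region_of(hits$start[i], hits$end[i], partition), character(1))
    if (collapse_ir) {
      irb <- partition$irb; ira <- partition$ira
      inside_irb <- hits$start >= irb[1L] & hits$end <= irb[2L]
      mirror_start <- ira[1L] + (irb[2L] - hits$end)
      mirror_end <- ira[1L] + (irb[2L] - hits$start)
      drop <- inside_irb & mapply(function(ms, me) {
        any(hits$start == ms & hits$end == me)
      }, mirror_start, mirror_end)
      hits <- hits[!drop, , drop = FALSE]
    }
  }
  if (inherits(rec, "plastome_record") && nrow(rec$annotations)) {
    masks <- context_masks(rec)
    hits$context <- vapply(seq_len(nrow(hits)), function(i) {
      iv <- hits$start[i]:hits$end[i]
      counts <- c(coding = sum(masks$coding[iv]),
                  intron = sum(masks$intron[iv]),
                  intergenic = sum(masks$intergenic[iv]))
      names(which.max(counts))
    }, character(1))
  }
  rownames(hits) <- NULL
  hits
}

region_of <- function(start, end, partition) {
  ov <- vapply(c(LSC = "lsc", SSC = "ssc", IRa = "ira", IRb = "irb"),
               function(r) {
                 iv <- partition[[r]]
                 max(0L, min(end, iv[2L]) - max(start, iv[1L]) + 1L)
               }, numeric(1))
  c("LSC", "SSC", "IR", "IR")[which.max(ov)]
}

context_masks <- function(rec) {
  n <- nchar(rec$sequence)
  ann <- rec$annotations
  spans <- gene_spans(ann)
  span_mask <- logical(n)
  for (i in seq_len(nrow(spans)))
    span_mask[spans$start[i]:spans$end[i]] <- TRUE
  exon_mask <- logical(n)
  for (i in seq_len(nrow(ann)))
    exon_mask[ann$start[i]:ann$end[i]] <- TRUE
  list(coding = exon_mask, intron = span_mask & !exon_mask,
       intergenic = !span_mask)
}

#' Detect long repeats in the four orientation classes
#'
#' Finds gapless locally-maximal pairs of loci where the second occurrence
#' is, respectively, the identical string (forward), its reversal (reverse),
#' its base complement (complement) or its reverse complement (palindromic),
#' with Hamming identity of at least `min_identity` and length of at least
#' `min_len`. Nested hits (both intervals inside another hit's intervals)
#' and low-complexity hits (an interval with at least 90 percent one
#' nucleotide) are removed. The genome-scale IR pair itself is excluded,
#' and hits lying fully inside both IRs are deduplicated to one
#' representative.
#'
#' @param rec a `plastome_record` (or plain character sequence).
#' @param min_len minimum repeat length (default 30; values below 8 are
#'   rejected, the seed-length bound).
#' @param min_identity minimum per-unit identity (default 0.90).
#' @param ir optional `ir_pair` to exclude; when `NULL` and `rec` is a
#'   plastome record long enough, the IR is detected automatically.
#' @return data frame with columns `type`, `start1`, `end1`, `start2`,
#'   `end2`, `length`, `identity`.
#' @export
find_long_repeats <- function(rec, min_len = 30L, min_identity = 0.90,
                              ir = NULL) {
  if (min_len < 8L) stop("min_len below the seed-length bound of 8",
                         call. = FALSE)
  s <- if (inherits(rec, "plastome_record")) rec$sequence else toupper(rec)
  n <- nchar(s)
  if (n < min_len) stop("sequence shorter than min_len", call. = FALSE)
  if (is.null(ir) && inherits(rec, "plastome_record") && n >= 2000L)
    ir <- tryCatch(suppressWarnings(detect_ir(rec)), error = function(e) NULL)
  k <- 7L
  ch <- seq_chars(s)
  comp <- chartr("ACGTN", "TGCAN", ch)
  fw <- kmer_vector(s, k)
  code <- match(fw, unique(fw))
  hits <- list()
  for (type in c("forward", "reverse", "complement", "palindromic")) {
    tk <- switch(type,
      forward = fw,
      complement = chartr("ACGTN", "TGCAN", fw),
      # reverse of the k-mer at j equals the mirrored k-mer of reverse(s)
      reverse = rev(kmer_vector(reverse_seq(s), k)),
      palindromic = rev(kmer_vector(revcomp(s), k)))
    pairs <- seed_pairs(fw, tk)
    if (!nrow(pairs)) next
    if (!is.null(ir) && type == "palindromic") {
      # drop seeds belonging to the genome-scale IR anti-diagonal
      in_ir <- pairs$i >= ir$ira[1L] & pairs$i <= ir$ira[2L] &
        pairs$j >= ir$irb[1L] & pairs$j <= ir$irb[2L]
      pairs <- pairs[!in_ir, , drop = FALSE]
      if (!nrow(pairs)) next
    }
    antidiag <- type %in% c("reverse", "palindromic")
    line <- if (antidiag) pairs$i + pairs$j + k - 1L else pairs$j - pairs$i
    segs <- seed_clusters(line, pairs$i, min_len)
    if (!nrow(segs)) next
    for (si in seq_len(nrow(segs))) {
      ws <- scan_repeat_line(ch, comp, type, segs$line[si],
                             segs$lo[si], segs$hi[si], n,
                             min_len, min_identity)
      if (length(ws)) hits <- c(hits, ws)
    }
  }
  empty <- data.frame(type = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  out <- unique(do.call(rbind, hits))
  # low-complexity filter: an interval with >= 90% of one nucleotide
  lowc <- function(a, b) {
    tab <- table(ch[a:b])
    max(tab) / (b - a + 1L) >= 0.9
  }
  lc <- vapply(seq_len(nrow(out)), function(i)
    lowc(out$start1[i], out$end1[i]) || lowc(out$start2[i], out$end2[i]),
    logical(1))
  out <- out[!lc, , drop = FALSE]
  # nested-redundancy resolution: when one candidate's intervals lie inside
  # another's, keep the higher-identity representative (ties: the longer)
  if (nrow(out) > 1L) {
    o <- order(-out$identity, -out$length, out$start1)
    out <- out[o, , drop = FALSE]
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      ks <- which(keep)
      nested <- length(ks) && any(
        (out$start1[ks] <= out$start1[i] & out$end1[ks] >= out$end1[i] &
           out$start2[ks] <= out$start2[i] & out$end2[ks] >= out$end2[i]) |
        (out$start1[ks] >= out$start1[i] & out$end1[ks] <= out$end1[i] &
           out$start2[ks] >= out$start2[i] & out$end2[ks] <= out$end2[i]))
      keep[i] <- !nested
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  # IR dedup: a hit fully inside both IRs has a mirrored twin; keep one
  if (!is.null(ir) && nrow(out) > 1L) {
    both_in <- function(a, b) (a >= ir$ira[1L] & b <= ir$ira[2L]) |
      (a >= ir$irb[1L] & b <= ir$irb[2L])
    in_ir <- both_in(out$start1, out$end1) & both_in(out$start2, out$end2)
    mirror <- function(x) ir$irb[2L] - (x - ir$ira[1L])
    key <- vapply(seq_len(nrow(out)), function(i) {
      if (!in_ir[i]) return(paste(out$type[i], out$start1[i], out$start2[i]))
      # canonical key: mirror IRb-resident intervals onto IRa
      iv <- c(out$start1[i], out$end1[i], out$start2[i], out$end2[i])
      canon <- function(a, b) {
        if (a >= ir$irb[1L]) sort(c(mirror(a), mirror(b))) else c(a, b)
      }
      p1 <- canon(iv[1L], iv[2L]); p2 <- canon(iv[3L], iv[4L])
      ps <- if (p1[1L] <= p2[1L]) c(p1, p2) else c(p2, p1)
      paste(out$type[i], paste(ps, collapse = "_"))
    }, character(1))
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

seed_pairs <- function(fw, tk) {
  j <- seq_along(tk)
  byk <- split(j, tk)
  byf <- split(seq_along(fw), fw)
  shared <- intersect(names(byk), names(byf))
  if (!length(shared)) return(data.frame(i = integer(0), j = integer(0)))
  ii <- jj <- vector("list", length(shared))
  for (x in seq_along(shared)) {
    a <- byf[[shared[x]]]; b <- byk[[shared[x]]]
    ii[[x]] <- rep(a, each = length(b))
    jj[[x]] <- rep(b, times = length(a))
  }
  i <- unlist(ii); j <- unlist(jj)
  keep <- i < j
  data.frame(i = i[keep], j = j[keep])
}

# group seed start positions per line; merge within gap, require >= 3 seeds
# (the minimum a qualifying hit can produce), pad by a margin
seed_clusters <- function(line, pos, min_len, gap = 40L, margin = 60L) {
  if (!length(line))
    return(data.frame(line = integer(0), lo = integer(0), hi = integer(0)))
  o <- order(line, pos)
  line <- line[o]; pos <- pos[o]
  brk <- which(c(TRUE, diff(line) != 0L | diff(pos) > gap))
  ends <- c(brk[-1L] - 1L, length(pos))
  cnt <- ends - brk + 1L
  # any qualifying hit yields at least 3 seed positions within the gap
  ok <- cnt >= 3L
  data.frame(line = line[brk[ok]],
             lo = pmax(1L, pos[brk[ok]] - margin),
             hi = pos[ends[ok]] + margin)
}

# Enumerate candidate windows on one line: for every error count e, the
# maximal windows containing exactly e mismatches with match-trimmed ends.
# Any valid pairing is contained in one of these with identity no lower, so
# the identity-dominance containment filter applied afterwards sees every
# potential survivor.
scan_repeat_line <- function(ch, comp, type, line, lo, hi, n,
                             min_len, min_identity) {
  antidiag <- type %in% c("reverse", "palindromic")
  usecomp <- type %in% c("complement", "palindromic")
  if (antidiag) {
    hi <- min(hi, (line - 1L) %/% 2L, n)     # keep intervals disjoint
    lo <- max(lo, line - n)
  } else {
    hi <- min(hi, n - line)                   # partner must fit on sequence
  }
  lo <- max(lo, 1L)
  if (hi - lo + 1L < min_len) return(list())
  if (hi - lo + 1L > 4000L) return(list())    # genome-scale line: that is
                                              # the IR pair, reported apart
  p <- lo:hi
  q <- if (antidiag) line - p else p + line
  other <- if (usecomp) comp[q] else ch[q]
  mv <- ch[p] == other & ch[p] != "N" & other != "N"
  L <- length(p)
  # density prefilter: any valid window contains a min_len sub-window with
  # match density at least 2 * min_identity - 1 (block-averaging argument),
  # which random seed coincidences essentially never reach
  cs <- c(0L, cumsum(mv))
  m_star <- ceiling((2 * min_identity - 1) * min_len)
  if (!any(cs[(min_len + 1L):(L + 1L)] - cs[seq_len(L - min_len + 1L)] >=
           m_star)) return(list())
  match_pos <- which(mv)
  if (!length(match_pos)) return(list())
  bnd <- c(0L, which(!mv), L + 1L)            # sentinel mismatch positions
  K <- length(bnd) - 2L                       # true mismatch count
  e_max <- floor((1 - min_identity) * L)
  res <- list()
  for (e in 0:min(e_max, K)) {
    for (i in seq_len(K - e + 1L) - 1L) {     # window between bnd[i+1] and
      loL <- bnd[i + 1L] + 1L                 # bnd[i+e+2], e mismatches in
      hiR <- bnd[i + e + 2L] - 1L
      if (hiR - loL + 1L < min_len) next
      # trim ends to matches
      l <- match_pos[findInterval(loL - 1L, match_pos) + 1L]
      ridx <- findInterval(hiR, match_pos)
      if (is.na(l) || ridx < 1L) next
      r <- match_pos[ridx]
      if (is.na(r) || r < l) next
      len <- r - l + 1L
      if (len < min_len) next
      em <- sum(!mv[l:r])
      ident <- 1 - em / len
      if (ident < min_identity) next
      s1 <- p[l]; e1 <- p[r]
      iv2 <- if (antidiag) c(line - p[r], line - p[l])
             else c(p[l] + line, p[r] + line)
      res[[length(res) + 1L]] <- data.frame(
        type = type, start1 = s1, end1 = e1,
        start2 = iv2[1L], end2 = iv2[2L], length = len,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  res
}

#' Summarize repeat or SSR hits by a facet
#'
#' @param hits data frame of hits from [find_ssrs()] or
#'   [find_long_repeats()], or any data frame with the requested column.
#' @param by facet: `"type"`, `"length_bin"` (width-10 bins from 30 bp),
#'   `"region"`, `"context"` or `"motif_len"`.
#' @return data frame of `level` and `count` with attribute `total`; counts
#'   always sum to the total number of hits.
#' @export
repeat_summary <- function(hits, by = c("type", "length_bin", "region",
                                        "context", "motif_len")) {
  by <- match.arg(by)
  vals <- if (by == "length_bin") {
    len <- hits$length %||% (hits$end - hits$start + 1L)
    if (nrow(hits)) paste0(30L + 10L * ((len - 30L) %/% 10L), "-",
                           39L + 10L * ((len - 30L) %/% 10L))
    else character(0)
  } else as.character(hits[[by]])
  tab <- table(vals, useNA = "ifany")
  out <- data.frame(level = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(hits)
  out
}
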