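# K-mer dot-plot comparison of two plastomes and rearrangement detection.

#' Shared k-mer anchors between two genomes
#'
#' All exact shared k-mers in both orientations, restricted to k-mers
#' occurring exactly once in each sequence (per orientation) to suppress
#' repeat noise.
#'
#' @param a,b `plastome_record`s or character sequences.
#' @param k k-mer size (default 21; values below 8 are rejected).
#' @return data frame `a_pos`, `b_pos`, `orientation`
#'   (`"forward"`/`"inverted"`); positions are k-mer start coordinates,
#'   1-based, on the respective sequences.
#' @export
dotplot <- function(a, b, k = 21L) {
  if (k < 8L) stop("k below 8 is rejected", call. = FALSE)
  sa <- if (inherits(a, "plastome_record")) a$sequence else toupper(a)
  sb <- if (inherits(b, "plastome_record")) b$sequence else toupper(b)
  if (nchar(sa) < k || nchar(sb) < k)
    stop("both sequences must be at least k long", call. = FALSE)
  ka <- kmer_vector(sa, k)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  anchors <- function(kb, orientation) {
    ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
    idx <- match(ka, kb)
    keep <- !is.na(idx) & ua & ub[pmin(idx, length(kb))]
    if (!any(keep)) return(NULL)
    data.frame(a_pos = which(keep), b_pos = idx[keep],
               orientation = orientation, stringsAsFactors = FALSE)
  }
  fwd <- anchors(kmer_vector(sb, k), "forward")
  # inverted: a k-mer of a equals the reverse complement of b's k-mer at
  # b_pos (start coordinate on b's forward strand)
  inv <- anchors(rev(kmer_vector(revcomp(sb), k)), "inverted")
  out <- rbind(fwd, inv)
  if (is.null(out))
    return(data.frame(a_pos = integer(0), b_pos = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Chain dot-plot anchors into collinear segments and call inversions
#'
#' Anchors are grouped by orientation and diagonal (`b_pos - a_pos` for
#' forward anchors, `a_pos + b_pos` for inverted ones) with single-linkage
#' merging of anchors within a gap tolerance, then nearby chains on
#' neighbouring diagonals are merged. Inverted segments spanning at least
#' `min_block` are reported as inversions.
#'
#' @param anchors data frame from [dotplot()].
#' @param min_block minimum inversion span in bp (default 5000).
#' @param k k-mer size used for the anchors (sets the chain gap tolerance
#'   of `2 * k`).
#' @param min_chain minimum anchors per reported segment (default 5).
#' @param max_gap maximum positional gap between consecutive anchors of one
#'   chain (default 1000 bp; repeat-filtered anchors leave holes where
#'   k-mers are non-unique).
#' @param exclude optional list of two `c(start, end)` interval pairs (e.g.
#'   detected IRs on each genome); inverted segments lying inside both are
#'   not counted as inversions.
#' @return list with `segments` (data frame `a_start`, `a_end`, `b_start`,
#'   `b_end`, `orientation`, `anchors`), `inversions` (the inverted
#'   segments of span at least `min_block`) and `verdict`
#'   (`"collinear"` or `"rearranged"`).
#' @export
detect_rearrangements <- function(anchors, min_block = 5000L, k = 21L,
                                  min_chain = 5L, exclude = NULL,
                                  max_gap = 1000L) {
  gap_tol <- 2L * k
  segs <- list()
  for (ori in c("forward", "inverted")) {
    an <- anchors[anchors$orientation == ori, , drop = FALSE]
    if (!nrow(an)) next
    diag <- if (ori == "forward") an$b_pos - an$a_pos else
      an$a_pos + an$b_pos
    o <- order(diag, an$a_pos)
    ap <- an$a_pos[o]; bp <- an$b_pos[o]; diag <- diag[o]
    brk <- which(c(TRUE, abs(diff(diag)) > gap_tol | diff(ap) > max_gap))
    ends <- c(brk[-1L] - 1L, length(ap))
    cnt <- ends - brk + 1L
    ok <- which(cnt >= min_chain)
    for (ci in ok) {
      idx <- brk[ci]:ends[ci]
      segs[[length(segs) + 1L]] <- data.frame(
        a_start = min(ap[idx]), a_end = max(ap[idx]) + k - 1L,
        b_start = min(bp[idx]), b_end = max(bp[idx]) + k - 1L,
        orientation = ori, anchors = cnt[ci], stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(a_start = integer(0), a_end = integer(0),
               b_start = integer(0), b_end = integer(0),
               orientation = character(0), anchors = integer(0),
               stringsAsFactors = FALSE)
  # merge chains of the same orientation whose ranges are contiguous
  segments <- merge_segments(segments, max_gap)
  inv <- segments[segments$orientation == "inverted" &
                    (segments$a_end - segments$a_start + 1L) >= min_block, ,
                  drop = FALSE]
  if (!is.null(exclude) && nrow(inv)) {
    inside <- function(s, e, iv) s >= iv[1L] && e <= iv[2L]
    drop <- vapply(seq_len(nrow(inv)), function(i)
      (inside(inv$a_start[i], inv$a_end[i], exclude[[1L]]) &&
         inside(inv$b_start[i], inv$b_end[i], exclude[[2L]])) ||
      (inside(inv$a_start[i], inv$a_end[i], exclude[[2L]]) &&
         inside(inv$b_start[i], inv$b_end[i], exclude[[1L]])),
      logical(1))
    inv <- inv[!drop, , drop = FALSE]
  }
  list(segments = segments, inversions = inv,
       verdict = if (nrow(inv)) "rearranged" else "collinear")
}

merge_segments <- function(segments, tol) {
  if (nrow(segments) < 2L) return(segments)
  segments <- segments[order(segments$orientation, segments$a_start), ,
                       drop = FALSE]
  out <- segments[1L, , drop = FALSE]
  for (i in 2L:nrow(segments)) {
    cur <- segments[i, ]
    last <- out[nrow(out), ]
    if (cur$orientation == last$orientation &&
        cur$a_start <= last$a_end + tol &&
        cur$b_start <= last$b_end + tol && cur$b_end + tol >= last$b_start) {
      out[nrow(out), c("a_end", "b_end")] <-
        c(max(last$a_end, cur$a_end), max(last$b_end, cur$b_end))
      out[nrow(out), c("a_start", "b_start")] <-
        c(min(last$a_start, cur$a_start), min(last$b_start, cur$b_start))
      out[nrow(out), "anchors"] <- last$anchors + cur$anchors
    } else {
      out <- rbind(out, cur)
    }
  }
  rownames(out) <- NULL
  out
}
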