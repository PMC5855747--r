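# Brute-force oracles, written directly from the operation definitions and
# independent of the package's seed-and-extend implementations.

oracle_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

oracle_comp <- function(ch) chartr("ACGTN", "TGCAN", ch)

# longest exact palindromic pair (reverse-complement match, disjoint
# intervals) by direct scan over every anti-diagonal
oracle_ir_exact <- function(s, min_len) {
  ch <- oracle_chars(s)
  comp <- oracle_comp(ch)
  n <- length(ch)
  best <- NULL
  for (D in 3L:(2L * n - 1L)) {
    lo <- max(1L, D - n)
    hi <- min(n, (D - 1L) %/% 2L)
    if (hi - lo + 1L < min_len) next
    p <- lo:hi
    ok <- ch[p] == comp[D - p] & ch[p] != "N"
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    for (i in which(r$values & r$lengths >= min_len)) {
      len <- r$lengths[i]
      p2 <- p[ends[i]]; p1 <- p2 - len + 1L
      if (is.null(best) || len > best$length ||
          (len == best$length && p1 < best$ira[1L]))
        best <- list(ira = c(p1, p2), irb = c(D - p2, D - p1),
                     length = len, mismatches = 0L)
    }
  }
  best
}

# SSRs by direct per-position maximal-run testing
oracle_ssrs <- function(s, thresholds = ssr_thresholds()) {
  ch <- oracle_chars(s)
  n <- length(ch)
  hits <- list()
  for (m in as.integer(names(thresholds))) {
    i <- 1L
    while (i + m <= n) {
      if (ch[i] == "N") { i <- i + 1L; next }
      # leftmost phase of a tandem tract: the base-level period must be
      # broken immediately to the left
      if (i > 1L && ch[i - 1L] != "N" && ch[i - 1L] == ch[i - 1L + m]) {
        i <- i + 1L; next
      }
      j <- i
      while (j + m <= n && ch[j + m] == ch[j] && ch[j] != "N") j <- j + 1L
      total <- j - i + m
      copies <- total %/% m
      if (copies >= thresholds[[as.character(m)]]) {
        motif <- paste(ch[i:(i + m - 1L)], collapse = "")
        primitive <- TRUE
        for (d in seq_len(m - 1L))
          if (m %% d == 0L &&
              paste(rep(substr(motif, 1L, d), m %/% d),
                    collapse = "") == motif) primitive <- FALSE
        if (primitive)
          hits[[length(hits) + 1L]] <- data.frame(
            motif = motif, motif_len = m, copies = copies, start = i,
            end = i + copies * m - 1L, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(0), motif_len = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  # containment: keep the longer span
  o <- order(-(out$end - out$start), out$start)
  out <- out[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    inner <- keep & seq_len(nrow(out)) > i &
      out$start >= out$start[i] & out$end <= out$end[i]
    keep[inner] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# long repeats by full enumeration of mismatch-flanked valid windows on
# every line of every class, then the same redundancy rules as contracted
oracle_long_repeats <- function(s, min_len = 30L, min_identity = 0.90) {
  ch <- oracle_chars(s)
  comp <- oracle_comp(ch)
  n <- length(ch)
  res <- list()
  collect <- function(type, p, mv, line, antidiag) {
    L <- length(p)
    for (l in seq_len(L)) {
      if (!mv[l] || (l > 1L && mv[l - 1L])) next
      for (r in l:L) {
        if (!mv[r] || (r < L && mv[r + 1L])) next
        len <- r - l + 1L
        if (len < min_len) next
        mm <- sum(!mv[l:r])
        ident <- 1 - mm / len
        if (ident < min_identity) next
        iv2 <- if (antidiag) c(line - p[r], line - p[l])
               else c(p[l] + line, p[r] + line)
        res[[length(res) + 1L]] <<- data.frame(
          type = type, start1 = p[l], end1 = p[r],
          start2 = iv2[1L], end2 = iv2[2L], length = len,
          identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  for (delta in seq_len(n - 1L)) {
    p <- 1L:(n - delta)
    if (length(p) < min_len) next
    q <- p + delta
    mvf <- ch[p] == ch[q] & ch[p] != "N"
    mvc <- ch[p] == comp[q] & ch[p] != "N"
    collect("forward", p, mvf, delta, FALSE)
    collect("complement", p, mvc, delta, FALSE)
  }
  for (D in 3L:(2L * n - 1L)) {
    lo <- max(1L, D - n); hi <- min(n, (D - 1L) %/% 2L)
    if (hi - lo + 1L < min_len) next
    p <- lo:hi
    q <- D - p
    mvr <- ch[p] == ch[q] & ch[p] != "N"
    mvp <- ch[p] == comp[q] & ch[p] != "N"
    collect("reverse", p, mvr, D, TRUE)
    collect("palindromic", p, mvp, D, TRUE)
  }
  if (!length(res))
    return(data.frame(type = character(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), length = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, res))
  lowc <- function(a, b) {
    tab <- table(ch[a:b]); max(tab) / (b - a + 1L) >= 0.9
  }
  lc <- vapply(seq_len(nrow(out)), function(i)
    lowc(out$start1[i], out$end1[i]) || lowc(out$start2[i], out$end2[i]),
    logical(1))
  out <- out[!lc, , drop = FALSE]
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
  rownames(out) <- NULL
  out
}

# in-silico PCR by direct window comparison
oracle_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                       max_product = 10000L) {
  ch <- oracle_chars(toupper(template))
  n <- length(ch)
  fw <- oracle_chars(toupper(fwd))
  rs <- oracle_chars(revcomp(toupper(rev)))
  site_hits <- function(pat, anchor_left) {
    k <- length(pat)
    out <- list()
    for (i in seq_len(n - k + 1L)) {
      win <- ch[i:(i + k - 1L)]
      d <- sum(win != pat)
      anch <- if (anchor_left) 1:3 else (k - 2L):k
      if (d <= max_mismatch && all(win[anch] == pat[anch]))
        out[[length(out) + 1L]] <- c(i, i + k - 1L, d)
    }
    out
  }
  f <- site_hits(fw, FALSE)
  r <- site_hits(rs, TRUE)
  prods <- list()
  for (a in f) for (b in r) {
    if (b[1L] <= a[2L]) next
    len <- b[2L] - a[1L] + 1L
    if (len > max_product || len < length(fw) + length(rs)) next
    prods[[length(prods) + 1L]] <- data.frame(
      start = a[1L], end = b[2L], length = len,
      fwd_mismatches = a[3L], rev_mismatches = b[3L])
  }
  if (!length(prods))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  out <- do.call(rbind, prods)
  rownames(out) <- NULL
  out
}

# Fitch steps for one column by exhaustive internal labelling (<= 7 taxa)
oracle_fitch_column <- function(tokens, tree) {
  tips <- tree$tip.label
  nt <- length(tips)
  stopifnot(length(tokens) == nt)
  bases <- c("A", "C", "G", "T")
  n_int <- tree$Nnode
  grid <- expand.grid(rep(list(bases), n_int), stringsAsFactors = FALSE)
  best <- Inf
  for (gi in seq_len(nrow(grid))) {
    lab <- unlist(grid[gi, ], use.names = FALSE)
    cost <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
      sa <- lab[a - nt]
      sb <- if (b <= nt) tokens[b] else lab[b - nt]
      if (!sb %in% bases) next          # missing leaf: free
      if (sa != sb) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

oracle_fitch <- function(aln, tree) {
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(mat)), function(j)
    oracle_fitch_column(mat[, j], tree), numeric(1)))
}

# exhaustive global alignment score over all alignments (tiny inputs)
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (substr(a, i, i) == substr(b, j, j)) match
                    else mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}
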