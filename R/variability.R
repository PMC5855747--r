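# Per-gene alignment statistics and parsimony-derived indices.
#
# Gap policy: gaps ("-") and "N" are missing data for site classification
# and for Fitch (they contribute the full state set), and pairs of rows are
# compared only at positions where neither is missing for sequence
# identity.

#' Build an alignment object
#'
#' @param x named character vector of equal-length aligned sequences
#'   (A,C,G,T,N,-), or a character matrix (rows = taxa).
#' @return an `alignment` object (character matrix with taxa as rownames).
#' @export
alignment <- function(x) {
  if (is.matrix(x)) {
    mat <- toupper(x)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must all have the same length", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(mat) <- names(x)
  }
  if (nrow(mat) < 2L) stop("an alignment needs at least 2 rows",
                           call. = FALSE)
  structure(mat, class = c("alignment", class(mat)))
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned (equal-length, gapped) FASTA file.
#' @return an `alignment`.
#' @export
read_alignment <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  x <- as.character(dna)
  names(x) <- sub("\\s.*$", "", names(dna))
  alignment(x)
}

MISSING_TOKENS <- c("-", "N", "?")

#' Site-pattern statistics of an alignment
#'
#' A column is conserved when all non-missing tokens are identical (and at
#' least one is present); variable otherwise; parsimony-informative when at
#' least two states each occur in at least two taxa. Sequence identity is
#' the mean over all row pairs of the fraction of identical positions among
#' positions where neither row is missing.
#'
#' @param aln an `alignment`.
#' @return list with `aligned_length`, `conserved_sites`, `variable_sites`,
#'   `parsimony_informative`, `pi_percent` (rounded half-up, 2 decimals) and
#'   `seq_identity`; attribute `flagged_small` is `TRUE` for alignments of
#'   fewer than 4 rows (which cannot contain informative sites).
#' @export
align_stats <- function(aln) {
  mat <- unclass(aln)
  n <- nrow(mat); L <- ncol(mat)
  miss <- matrix(mat %in% MISSING_TOKENS, n, L)
  conserved <- variable <- informative <- logical(L)
  for (j in seq_len(L)) {
    tok <- mat[!miss[, j], j]
    if (!length(tok)) next
    tab <- table(tok)
    if (length(tab) == 1L) conserved[j] <- TRUE else variable[j] <- TRUE
    informative[j] <- sum(tab >= 2L) >= 2L
  }
  pairs <- utils::combn(n, 2L)
  ident <- apply(pairs, 2L, function(pr) {
    ok <- !miss[pr[1L], ] & !miss[pr[2L], ]
    if (!any(ok)) return(NA_real_)
    mean(mat[pr[1L], ok] == mat[pr[2L], ok])
  })
  out <- list(aligned_length = L,
              conserved_sites = sum(conserved),
              variable_sites = sum(variable),
              parsimony_informative = sum(informative),
              pi_percent = pi_percent(sum(informative), L),
              seq_identity = mean(ident, na.rm = TRUE))
  attr(out, "flagged_small") <- n < 4L
  out
}

#' Parsimony-informative percentage
#'
#' `informative / aligned_length * 100`, rounded half away from zero to two
#' decimals (the precision used in printed variability tables).
#'
#' @param informative number of parsimony-informative sites.
#' @param aligned_length alignment length in columns.
#' @return numeric scalar.
#' @export
pi_percent <- function(informative, aligned_length) {
  round_half_up(informative / aligned_length * 100, 2)
}

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

encode_states <- function(mat) {
  enc <- matrix(15L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (b in names(BASE_BITS)) enc[mat == b] <- BASE_BITS[[b]]
  enc
}

#' Fitch parsimony length of an alignment on a tree
#'
#' Sum over columns of the minimum number of state changes on the given
#' topology (Fitch's downward pass). Tokens outside A,C,G,T are missing and
#' contribute the full state set.
#'
#' @param aln an `alignment`.
#' @param tree an `ape::phylo` whose tip labels equal the alignment's taxa.
#' @param per_column return the per-column step vector instead of the sum.
#' @return integer steps (or integer vector when `per_column`).
#' @export
fitch_length <- function(aln, tree, per_column = FALSE) {
  mat <- unclass(aln)
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree/alignment taxa differ: tree-only {",
         paste(setdiff(tree$tip.label, rownames(mat)), collapse = ","),
         "}, alignment-only {",
         paste(setdiff(rownames(mat), tree$tip.label), collapse = ","),
         "}", call. = FALSE)
  enc <- encode_states(mat)[tree$tip.label, , drop = FALSE]
  L <- ncol(enc)
  tree <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  nnode <- nt + tree$Nnode
  states <- matrix(0L, nnode, L)
  states[seq_len(nt), ] <- enc
  steps <- integer(L)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
    child <- states[chi, ]
    cur <- states[par, ]
    unset <- cur == 0L
    inter <- bitwAnd(cur, child)
    new <- ifelse(unset, child,
                  ifelse(inter > 0L, inter, bitwOr(cur, child)))
    steps <- steps + (!unset & inter == 0L)
    states[par, ] <- new
  }
  if (per_column) steps else sum(steps)
}

#' Consistency and retention indices
#'
#' Per column i with s_i observed Fitch steps, m_i = (number of observed
#' states - 1) the minimum conceivable steps, and g_i = (non-missing tokens
#' minus the largest state frequency) the steps on a star topology:
#' CI = sum(m)/sum(s) and RI = (sum(g) - sum(s)) / (sum(g) - sum(m)),
#' summed over variable columns (invariant columns contribute zero to all
#' three sums). Both indices are 1, with attribute `no_variable_sites`,
#' when the alignment has no variable columns; RI is 1 when sum(g) equals
#' sum(m).
#'
#' @param aln an `alignment`.
#' @param tree an `ape::phylo`; when `NULL` a neighbour-joining topology
#'   from the pairwise p-distance matrix is used.
#' @return list with `ci`, `ri` and the sums `s`, `m`, `g`.
#' @export
ci_ri <- function(aln, tree = NULL) {
  mat <- unclass(aln)
  if (is.null(tree)) tree <- nj_from_alignment(aln)
  s <- fitch_length(aln, tree, per_column = TRUE)
  L <- ncol(mat)
  m <- g <- integer(L)
  for (j in seq_len(L)) {
    tok <- mat[, j]
    tok <- tok[!tok %in% MISSING_TOKENS]
    if (!length(tok)) next
    tab <- table(tok)
    m[j] <- length(tab) - 1L
    g[j] <- length(tok) - max(tab)
  }
  S <- sum(s); M <- sum(m); G <- sum(g)
  if (M == 0L) {
    out <- list(ci = 1, ri = 1, s = S, m = M, g = G)
    attr(out, "no_variable_sites") <- TRUE
    return(out)
  }
  list(ci = M / S, ri = if (G == M) 1 else (G - S) / (G - M),
       s = S, m = M, g = G)
}

#' Neighbour-joining topology from pairwise identity
#'
#' p-distance (1 - pairwise identity under the missing-data policy), no
#' rate correction; used when no tree is supplied for the parsimony
#' indices.
#'
#' @param aln an `alignment`.
#' @return an `ape::phylo`.
#' @export
nj_from_alignment <- function(aln) {
  mat <- unclass(aln)
  n <- nrow(mat)
  if (n <= 3L)
    return(ape::read.tree(
      text = paste0("(", paste(rownames(mat), collapse = ","), ");")))
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  miss <- matrix(mat %in% MISSING_TOKENS, n, ncol(mat))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !miss[i, ] & !miss[j, ]
    p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    d[i, j] <- d[j, i] <- p
  }
  ape::nj(stats::as.dist(d))
}

#' Full variability statistics for one gene alignment
#'
#' @param aln an `alignment`.
#' @param gene gene name.
#' @param unaligned_length_ref unaligned length (bp) of the gene in the
#'   reference taxon.
#' @param tree optional `ape::phylo` for the parsimony indices.
#' @return one-row data frame in the variability-table schema.
#' @export
variability_stats <- function(aln, gene, unaligned_length_ref,
                              tree = NULL) {
  st <- align_stats(aln)
  ir <- if (nrow(unclass(aln)) >= 4L || !is.null(tree))
    ci_ri(aln, tree) else list(ci = NA_real_, ri = NA_real_)
  data.frame(gene = gene,
             unaligned_length_ref = unaligned_length_ref,
             aligned_length = st$aligned_length,
             conserved_sites = st$conserved_sites,
             parsimony_informative = st$parsimony_informative,
             pi_percent = st$pi_percent,
             ci = ir$ci, ri = ir$ri,
             seq_identity = st$seq_identity, stringsAsFactors = FALSE)
}

#' Rank genes by parsimony-informative percentage
#'
#' @param stats data frame of per-gene rows (schema of
#'   [variability_stats()]).
#' @param min_len genes with `unaligned_length_ref` greater than this are
#'   kept (default 200 bp); use `min_len = 0` for the unfiltered variant.
#' @return the filtered rows sorted by `pi_percent` descending, ties broken
#'   by `aligned_length` descending then gene name, with a `rank` column.
#' @export
rank_genes <- function(stats, min_len = 200L) {
  if (!nrow(stats)) return(cbind(stats, rank = integer(0)))
  keep <- stats[stats$unaligned_length_ref > min_len, , drop = FALSE]
  o <- order(-keep$pi_percent, -keep$aligned_length, keep$gene)
  keep <- keep[o, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}
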