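# Exon/intron accounting, cross-taxon intron presence and in-silico PCR.

#' Construct a gene model
#'
#' @param name gene symbol.
#' @param location region label (`"LSC"`, `"SSC"`, `"IR"`).
#' @param exons integer vector of exon lengths (bp, 5' to 3').
#' @param introns integer vector of intron lengths; must have one fewer
#'   element than `exons` for cis-spliced genes. A trans-spliced junction is
#'   encoded as `NA` in `introns` with `trans_spliced = TRUE`.
#' @param trans_spliced logical.
#' @return a `gene_model` list.
#' @export
gene_model <- function(name, location = "LSC", exons, introns = integer(0),
                       trans_spliced = FALSE) {
  stopifnot(length(exons) >= 1L, all(exons > 0),
            all(is.na(introns) | introns > 0))
  if (length(exons) > 1L && length(introns) != length(exons) - 1L)
    stop("gene ", name, ": need one intron slot between consecutive exons",
         call. = FALSE)
  if (any(is.na(introns)) && !trans_spliced)
    stop("gene ", name, ": NA intron length only allowed for trans-spliced ",
         "models", call. = FALSE)
  structure(list(name = name, location = location,
                 exons = as.numeric(exons), introns = as.numeric(introns),
                 trans_spliced = isTRUE(trans_spliced)),
            class = "gene_model")
}

#' Derive gene models from a plastome record
#'
#' One model per gene copy; intron lengths are the genomic gaps between
#' consecutive exons.
#'
#' @param rec a `plastome_record`.
#' @param partition optional partition for the location column.
#' @param trans_spliced character vector of gene names to flag trans-spliced.
#' @return named list of `gene_model` objects (names `gene.copy_tag`).
#' @export
gene_models <- function(rec, partition = NULL, trans_spliced = "rps12") {
  ann <- rec$annotations
  out <- list()
  spans <- gene_spans(ann)
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    ex <- ann[ann$gene == sp$gene & ann$copy_tag == sp$copy_tag, ,
              drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    exon_len <- ex$end - ex$start + 1L
    intr_len <- if (nrow(ex) > 1L)
      ex$start[-1L] - ex$end[-nrow(ex)] - 1L else integer(0)
    # exons left adjacent by a physical intron deletion merge into one
    while (any(intr_len == 0L)) {
      i <- which(intr_len == 0L)[1L]
      exon_len[i] <- exon_len[i] + exon_len[i + 1L]
      exon_len <- exon_len[-(i + 1L)]
      intr_len <- intr_len[-i]
    }
    if (sp$strand == "-") {
      exon_len <- rev(exon_len); intr_len <- rev(intr_len)
    }
    loc <- if (is.null(partition)) NA_character_
           else region_of(sp$start, sp$end, partition)
    ts <- sp$gene %in% trans_spliced
    intr_len[intr_len < 0L] <- NA_real_
    out[[paste(sp$gene, sp$copy_tag, sep = ".")]] <-
      gene_model(sp$gene, loc, exon_len, intr_len, trans_spliced = ts)
  }
  out
}

#' Exon/intron length table
#'
#' One row per gene model with exon and intron lengths, intron count, total
#' and longest intron; the overall longest intron is returned as an
#' attribute. Trans-spliced junctions (NA intron length) are excluded from
#' cis intron counting.
#'
#' @param models list of `gene_model` objects.
#' @return data frame; attributes `longest_intron_bp` and
#'   `longest_intron_gene`.
#' @export
intron_table <- function(models) {
  rows <- lapply(models, function(m) {
    ex <- m$exons; it <- m$introns
    cis <- it[!is.na(it)]
    data.frame(gene = m$name, location = m$location,
               exon1 = ex[1L],
               intron1 = if (length(it) >= 1L) it[1L] else NA_real_,
               exon2 = if (length(ex) >= 2L) ex[2L] else NA_real_,
               intron2 = if (length(it) >= 2L) it[2L] else NA_real_,
               exon3 = if (length(ex) >= 3L) ex[3L] else NA_real_,
               n_introns = length(cis),
               intron_total = if (length(cis)) sum(cis) else 0,
               longest_intron = if (length(cis)) max(cis) else NA_real_,
               trans_spliced = m$trans_spliced, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  li <- out$longest_intron
  if (any(!is.na(li))) {
    attr(out, "longest_intron_bp") <- max(li, na.rm = TRUE)
    attr(out, "longest_intron_gene") <- out$gene[which.max(li)]
  }
  out
}

#' Primer pair
#'
#' @param forward,reverse primer sequences, 5' to 3', length at least 15.
#' @param max_mismatch maximum mismatches tolerated per primer site (the
#'   three 3'-terminal bases must always match exactly).
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nchar(forward) >= 15L, nchar(reverse) >= 15L,
            !grepl("[^ACGT]", forward), !grepl("[^ACGT]", reverse))
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Predict PCR products on a template
#'
#' Locates forward-primer sites on the plus strand and reverse-primer sites
#' as reverse complements downstream, each within the primer pair's
#' mismatch budget (3'-terminal 3 bases exact), and emits every pairing
#' whose outer-coordinate product length is within `max_product`. Circular
#' templates allow origin-spanning products.
#'
#' @param template character scalar DNA.
#' @param primers a [primer_pair()].
#' @param circular logical.
#' @param max_product product length cap in bp (default 10000).
#' @return data frame `start`, `end`, `length`, `fwd_mismatches`,
#'   `rev_mismatches`; `end` may exceed the template length for
#'   origin-spanning products on circular templates.
#' @export
in_silico_pcr <- function(template, primers, circular = FALSE,
                          max_product = 10000L) {
  template <- toupper(template)
  stopifnot(nchar(template) >= 1L, inherits(primers, "primer_pair"))
  n <- nchar(template)
  work <- if (circular) paste0(template,
                               substr(template, 1L,
                                      min(n, max_product))) else template
  fwd <- primers$forward
  rev_site <- revcomp(primers$reverse)
  mm <- primers$max_mismatch
  find_sites <- function(pattern, anchor_3prime_left) {
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(work),
                                  max.mismatch = mm)
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    keep <- rep(TRUE, length(st))
    mmc <- integer(length(st))
    for (i in seq_along(st)) {
      site <- substr(work, st[i], en[i])
      d <- sum(seq_chars(site) != seq_chars(pattern))
      mmc[i] <- d
      # 3' anchor: the template-proximal 3 bases must match exactly; for
      # the forward primer that is the right end of the site, for the
      # reverse-complemented reverse primer the left end
      anch <- if (anchor_3prime_left) 1:3 else
        (nchar(pattern) - 2L):nchar(pattern)
      keep[i] <- d <= mm &&
        all(seq_chars(site)[anch] == seq_chars(pattern)[anch])
    }
    data.frame(start = st[keep], end = en[keep], mism = mmc[keep])
  }
  f <- find_sites(fwd, anchor_3prime_left = FALSE)
  r <- find_sites(rev_site, anchor_3prime_left = TRUE)
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), fwd_mismatches = integer(0),
                    rev_mismatches = integer(0))
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
    if (r$start[j] <= f$end[i]) next
    len <- r$end[j] - f$start[i] + 1L
    if (len > max_product) next
    if (len < nchar(fwd) + nchar(rev_site)) next
    if (circular && f$start[i] > n) next       # canonical copy only
    out <- rbind(out, data.frame(
      start = f$start[i], end = r$end[j], length = len,
      fwd_mismatches = f$mism[i], rev_mismatches = r$mism[j]))
  }
  if (circular && nrow(out)) out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Cross-taxon intron presence/absence for one gene
#'
#' @param models_by_taxon named list: taxon name to list of `gene_model`s.
#' @param gene gene symbol to inspect.
#' @param reference_taxon taxon whose intron count is the reference; the
#'   gene must be present there with at least one intron.
#' @return data frame `taxon`, `intron_count`, `call` where `call` is
#'   `"none"`, `"intron_loss"` or `"gene_loss"`.
#' @export
intron_presence <- function(models_by_taxon, gene, reference_taxon) {
  if (!reference_taxon %in% names(models_by_taxon))
    stop("reference taxon not found: ", reference_taxon, call. = FALSE)
  count_for <- function(models) {
    hit <- Filter(function(m) m$name == gene, models)
    if (!length(hit)) return(NA_integer_)
    max(vapply(hit, function(m) sum(!is.na(m$introns)), integer(1)))
  }
  ref <- count_for(models_by_taxon[[reference_taxon]])
  if (is.na(ref))
    stop("gene ", gene, " absent from reference taxon", call. = FALSE)
  if (ref < 1L)
    stop("gene ", gene, " has no intron in the reference taxon",
         call. = FALSE)
  counts <- vapply(models_by_taxon, count_for, integer(1))
  call <- ifelse(is.na(counts), "gene_loss",
                 ifelse(counts < ref, "intron_loss", "none"))
  data.frame(taxon = names(models_by_taxon),
             intron_count = unname(counts), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Global pairwise alignment with linear gap costs
#'
#' Needleman-Wunsch with deterministic tie-breaking: on equal scores the
#' traceback prefers the diagonal, then the gap in the second sequence,
#' then the gap in the first.
#'
#' @param a,b non-empty strings.
#' @param match,mismatch,gap scoring parameters.
#' @return list with `a_aln`, `b_aln` (gapped strings) and `score`.
#' @export
pairwise_global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) < 1L || nchar(b) < 1L)
    stop("both sequences must be non-empty", call. = FALSE)
  A <- seq_chars(toupper(a)); B <- seq_chars(toupper(b))
  na <- length(A); nb <- length(B)
  S <- matrix(0, na + 1L, nb + 1L)
  S[, 1L] <- gap * (0:na)
  S[1L, ] <- gap * (0:nb)
  for (i in seq_len(na)) {
    sub <- ifelse(A[i] == B, match, mismatch)
    for (j in seq_len(nb))
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
  }
  # traceback with fixed preference order: diagonal, up (gap in b), left
  i <- na; j <- nb
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
        S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1L
    }
  }
  list(a_aln = paste(ra, collapse = ""), b_aln = paste(rb, collapse = ""),
       score = S[na + 1L, nb + 1L])
}
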