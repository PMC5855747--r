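#' Construct a plastome record
#'
#' A `plastome_record` holds a linearized circular plastid genome (by
#' convention starting at LSC base 1) together with its gene annotations.
#' Coordinates are 1-based inclusive on the linearized sequence.
#'
#' @param id character scalar, genome identifier.
#' @param sequence character scalar over A,C,G,T,N.
#' @param annotations data frame of exon-level annotations as produced by
#'   [gene_annotation()] (columns `gene`, `category`, `strand`, `exon`,
#'   `start`, `end`, `is_pseudo`, `copy_tag`), or `NULL` for none.
#' @param is_circular logical, whether the molecule is circular.
#' @param source character scalar, file path or `"synthetic"`.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(id, sequence, annotations = NULL,
                            is_circular = TRUE, source = "synthetic") {
  sequence <- toupper(sequence)
  validate_dna(sequence)
  if (is.null(annotations)) annotations <- empty_annotations()
  rec <- structure(
    list(id = as.character(id), sequence = sequence,
         is_circular = isTRUE(is_circular),
         annotations = as.data.frame(annotations),
         source = as.character(source)),
    class = "plastome_record")
  validate_plastome(rec)
  rec
}

empty_annotations <- function() {
  data.frame(gene = character(0), category = character(0),
              strand = character(0), exon = integer(0),
              start = integer(0), end = integer(0),
              is_pseudo = logical(0), copy_tag = character(0),
              stringsAsFactors = FALSE)
}

#' Build exon-level annotation rows for one gene copy
#'
#' @param gene gene symbol (anticodon suffix allowed, e.g. `"trnK-UUU"`).
#' @param category one of `"protein"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends integer vectors of exon coordinates, 1-based
#'   inclusive, in ascending genomic order.
#' @param is_pseudo logical, pseudogene flag.
#' @param copy_tag one of `"single"`, `"IR_A"`, `"IR_B"`; IR-duplicated
#'   genes carry one copy per IR.
#' @return data frame with one row per exon.
#' @export
gene_annotation <- function(gene, category = "protein", strand = "+",
                            starts, ends, is_pseudo = FALSE,
                            copy_tag = "single") {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L,
            all(starts <= ends),
            category %in% c("protein", "tRNA", "rRNA"),
            strand %in% c("+", "-"),
            copy_tag %in% c("single", "IR_A", "IR_B"))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("exons of ", gene, " overlap", call. = FALSE)
  # exon rank runs along the strand
  rank <- if (strand == "+") seq_along(starts) else rev(seq_along(starts))
  data.frame(gene = gene, category = category, strand = strand,
             exon = rank, start = starts, end = ends,
             is_pseudo = is_pseudo, copy_tag = copy_tag,
             stringsAsFactors = FALSE)
}

#' Validate a plastome record
#'
#' Checks the sequence alphabet, that all annotation coordinates lie on the
#' sequence, that exons of a gene copy do not overlap, and that any
#' IR-duplicated name has exactly one `IR_A` and one `IR_B` copy.
#'
#' @param rec a `plastome_record`.
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_plastome <- function(rec) {
  stopifnot(inherits(rec, "plastome_record"))
  validate_dna(rec$sequence)
  ann <- rec$annotations
  n <- nchar(rec$sequence)
  if (nrow(ann)) {
    if (any(ann$start < 1L) || any(ann$end > n))
      stop("annotation coordinates outside [1, ", n, "]", call. = FALSE)
    if (any(ann$start > ann$end))
      stop("annotation with start > end", call. = FALSE)
    for (key in unique(paste(ann$gene, ann$copy_tag))) {
      rows <- ann[paste(ann$gene, ann$copy_tag) == key, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      if (nrow(rows) > 1L &&
          any(rows$start[-1L] <= rows$end[-nrow(rows)]))
        stop("overlapping exons within gene copy ", key, call. = FALSE)
    }
    tags <- unique(ann[ann$copy_tag != "single", c("gene", "copy_tag")])
    for (g in unique(tags$gene)) {
      tg <- sort(tags$copy_tag[tags$gene == g])
      if (!identical(tg, c("IR_A", "IR_B")))
        stop("duplicated gene ", g,
             " must have exactly one IR_A and one IR_B copy", call. = FALSE)
    }
  }
  invisible(rec)
}

#' Per-copy gene spans
#'
#' Collapses exon-level annotations to one row per gene copy with the span
#' (min start to max end), exon count and total exonic length.
#'
#' @param annotations exon-level annotation data frame.
#' @return data frame with columns `gene`, `copy_tag`, `category`, `strand`,
#'   `start`, `end`, `n_exons`, `exonic_len`, `is_pseudo`.
#' @export
gene_spans <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(gene = character(0), copy_tag = character(0),
                      category = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_exons = integer(0), exonic_len = integer(0),
                      is_pseudo = logical(0), stringsAsFactors = FALSE))
  key <- paste(annotations$gene, annotations$copy_tag, sep = "\r")
  idx <- split(seq_len(nrow(annotations)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    a <- annotations[i, , drop = FALSE]
    data.frame(gene = a$gene[1L], copy_tag = a$copy_tag[1L],
               category = a$category[1L], strand = a$strand[1L],
               start = min(a$start), end = max(a$end),
               n_exons = nrow(a),
               exonic_len = sum(a$end - a$start + 1L),
               is_pseudo = any(a$is_pseudo), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("<plastome_record> ", x$id, "\n",
      "  length: ", nchar(x$sequence), " bp",
      if (x$is_circular) " (circular)" else " (linear)", "\n",
      "  gene copies: ", nrow(gene_spans(x$annotations)),
      "  source: ", x$source, "\n", sep = "")
  invisible(x)
}
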