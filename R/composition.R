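# Region and coding-class composition summaries and the gene census.

#' GC content of a DNA sequence
#'
#' Fraction (G + C) over non-N bases; `N` is excluded from the denominator.
#'
#' @param sequence character scalar over A,C,G,T,N.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  validate_dna(sequence)
  sequence <- toupper(sequence)
  ch <- seq_chars(sequence)
  denom <- sum(ch != "N")
  if (denom == 0L) stop("GC content undefined: sequence is all N",
                        call. = FALSE)
  sum(ch == "G" | ch == "C") / denom
}

#' Region length proportions
#'
#' Percent of the genome occupied by each region, rounded half away from
#' zero to one decimal, as printed in comparative plastome size tables.
#'
#' @param lengths numeric vector of region lengths covering the genome once
#'   (e.g. `c(LSC = 86315, SSC = 18491, IRa = 26577, IRb = 26577)`).
#' @return list with `total` (bp) and `percent` (per input region, summing
#'   to 100 up to rounding).
#' @export
region_proportions <- function(lengths) {
  stopifnot(is.numeric(lengths), all(lengths > 0))
  total <- sum(lengths)
  list(total = total,
       percent = round_half_up(lengths / total * 100, 1))
}

#' Composition summary of a partitioned plastome
#'
#' Per-region rows (length, GC%, length% of genome) and per-class rows
#' (protein / tRNA / rRNA exonic DNA, introns, intergenic DNA) computed by
#' per-base masking so the classes tile the genome exactly: every base is
#' assigned to exactly one class, with exons taking precedence over introns
#' and introns over intergenic. Overlapping gene spans are set-unioned, so
#' nothing is double counted.
#'
#' @param rec a `plastome_record` with annotations.
#' @param partition a `region_partition` for `rec`.
#' @return list of two data frames, `regions` and `classes`; percentages
#'   rounded half away from zero to 1 decimal.
#' @export
composition_summary <- function(rec, partition) {
  n <- nchar(rec$sequence)
  if (partition_total(partition) != n)
    stop("partition does not tile the record's sequence (", n, " bp)",
         call. = FALSE)
  ch <- seq_chars(rec$sequence)
  gc_of <- function(mask) {
    d <- sum(mask & ch != "N")
    if (d == 0L) return(NA_real_)
    sum(mask & (ch == "G" | ch == "C")) / d
  }
  regions <- do.call(rbind, lapply(
    c(LSC = "lsc", IRa = "ira", SSC = "ssc", IRb = "irb"),
    function(r) {
      iv <- partition[[r]]
      # intervals may wrap the origin (end > n means modulo n)
      idx <- ((iv[1L]:iv[2L]) - 1L) %% n + 1L
      mask <- logical(n); mask[idx] <- TRUE
      data.frame(length_bp = iv[2L] - iv[1L] + 1L,
                 gc_percent = round_half_up(100 * gc_of(mask), 1),
                 length_percent = round_half_up(
                   100 * (iv[2L] - iv[1L] + 1L) / n, 1))
    }))
  regions <- cbind(region = rownames(regions), regions)
  rownames(regions) <- NULL

  # per-base class mask: 0 intergenic, 1 intron, 2 protein, 3 tRNA, 4 rRNA
  cls <- integer(n)
  ann <- rec$annotations
  spans <- gene_spans(ann)
  for (i in seq_len(nrow(spans)))
    cls[spans$start[i]:spans$end[i]] <- 1L
  code <- c(protein = 2L, tRNA = 3L, rRNA = 4L)
  for (i in seq_len(nrow(ann)))
    cls[ann$start[i]:ann$end[i]] <- code[[ann$category[i]]]
  class_rows <- do.call(rbind, lapply(
    c(protein = 2L, tRNA = 3L, rRNA = 4L, intron = 1L, intergenic = 0L),
    function(v) {
      mask <- cls == v
      data.frame(length_bp = sum(mask),
                 length_percent = round_half_up(100 * sum(mask) / n, 1),
                 gc_percent = round_half_up(100 * gc_of(mask), 1))
    }))
  class_rows <- cbind(class = rownames(class_rows), class_rows)
  rownames(class_rows) <- NULL
  list(regions = regions, classes = class_rows,
       total_bp = n,
       total_gc_percent = round_half_up(100 * gc_content(rec$sequence), 1))
}

partition_total <- function(partition) {
  sum(vapply(c("lsc", "ira", "ssc", "irb"), function(r) {
    iv <- partition[[r]]
    as.numeric(iv[2L] - iv[1L] + 1L)
  }, numeric(1)))
}

#' Gene census of an annotated plastome
#'
#' Counts gene copies and distinct names, identifies IR-duplicated genes,
#' tallies copies per category, and assigns each gene copy to the region
#' holding the majority of its bases. Genes whose span crosses a region
#' boundary are additionally listed in `boundary_spanning`.
#'
#' @param annotations exon-level annotation data frame.
#' @param partition a `region_partition`.
#' @return list with `total_copies`, `distinct_names`, `duplicated_names`,
#'   `per_category` (copies), `per_region` (distinct gene names, IRs pooled),
#'   and `boundary_spanning` (character vector of gene names). Names seen
#'   more than twice trigger a warning and are counted by actual copies.
#' @export
gene_census <- function(annotations, partition) {
  spans <- gene_spans(annotations)
  if (!nrow(spans))
    return(list(total_copies = 0L, distinct_names = 0L,
                duplicated_names = 0L,
                per_category = c(tRNA = 0L, protein = 0L, rRNA = 0L),
                per_region = c(LSC = 0L, SSC = 0L, IR = 0L),
                boundary_spanning = character(0)))
  copies_per_name <- table(spans$gene)
  if (any(copies_per_name > 2L))
    warning("gene name(s) with more than two copies: ",
            paste(names(copies_per_name)[copies_per_name > 2L],
                  collapse = ", "), call. = FALSE)
  dup <- vapply(unique(spans$gene), function(g) {
    tg <- spans$copy_tag[spans$gene == g]
    all(c("IR_A", "IR_B") %in% tg)
  }, logical(1))
  per_cat <- vapply(c("tRNA", "protein", "rRNA"),
                    function(k) sum(spans$category == k), integer(1))
  # majority-base region per copy; IRs pooled as one region
  reg_of <- function(start, end) {
    ov <- vapply(c(LSC = "lsc", SSC = "ssc", IRa = "ira", IRb = "irb"),
                 function(r) {
                   iv <- partition[[r]]
                   max(0L, min(end, iv[2L]) - max(start, iv[1L]) + 1L)
                 }, numeric(1))
    list(major = c("LSC", "SSC", "IR", "IR")[which.max(ov)],
         n_regions = sum(ov > 0))
  }
  regs <- lapply(seq_len(nrow(spans)),
                 function(i) reg_of(spans$start[i], spans$end[i]))
  major <- vapply(regs, `[[`, character(1), "major")
  spanning <- vapply(regs, function(r) r$n_regions > 1L, logical(1))
  per_region <- vapply(c("LSC", "SSC", "IR"), function(r)
    length(unique(spans$gene[major == r])), integer(1))
  list(total_copies = nrow(spans),
       distinct_names = length(unique(spans$gene)),
       duplicated_names = sum(dup),
       per_category = per_cat,
       per_region = per_region,
       boundary_spanning = sort(unique(spans$gene[spanning])))
}
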