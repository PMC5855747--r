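# Reading and writing annotated plastomes.
#
# Two on-disk forms are supported: GenBank flat files (a minimal feature
# table with gene/tRNA/rRNA features, join()/complement() locations and
# /gene, /pseudo qualifiers) and single-record FASTA paired with GFF3.
# GFF3 is parsed with rtracklayer; FASTA with Biostrings.

#' Read an annotated plastome
#'
#' @param path path to a GenBank flat file, or to the FASTA file when
#'   `format = "gff3"`.
#' @param format `"genbank"` or `"gff3"` (FASTA + GFF3 pair).
#' @param gff path to the GFF3 file; defaults to `path` with its extension
#'   replaced by `.gff3`.
#' @return a [plastome_record()].
#' @export
read_plastome <- function(path, format = c("genbank", "gff3"), gff = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genbank") return(read_genbank_plastome(path))
  gff <- gff %||% sub("\\.[^.]+$", ".gff3", path)
  if (!file.exists(gff)) stop("GFF3 file not found: ", gff, call. = FALSE)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) != 1L)
    stop("expected a single FASTA record in ", path, call. = FALSE)
  id <- sub("\\s.*$", "", names(dna)[1L])
  g <- rtracklayer::readGFF(gff)
  g <- as.data.frame(g)
  ann <- empty_annotations()
  genes <- g[g$type == "gene", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    row <- genes[i, ]
    gid <- as.character(row$ID)
    ex <- exons[as.character(exons$Parent) == gid, , drop = FALSE]
    if (nrow(ex) == 0L) ex <- row
    ann <- rbind(ann, gene_annotation(
      gene = as.character(row$Name %||% row$ID),
      category = gff_category(as.character(row$biotype %||% "protein_coding")),
      strand = as.character(row$strand),
      starts = ex$start, ends = ex$end,
      is_pseudo = identical(as.character(row$pseudo), "true"),
      copy_tag = as.character(row$copy_tag %||% "single")))
  }
  plastome_record(id, as.character(dna[[1L]]), ann, source = path)
}

gff_category <- function(biotype) {
  switch(biotype, tRNA = "tRNA", rRNA = "rRNA", "protein")
}

#' Write an annotated plastome as FASTA + GFF3
#'
#' @param rec a `plastome_record`.
#' @param path output FASTA path; the GFF3 is written next to it.
#' @param gff output GFF3 path (default: `path` with `.gff3` extension).
#' @return invisibly, the two paths written.
#' @export
write_plastome <- function(rec, path, gff = NULL) {
  validate_plastome(rec)
  gff <- gff %||% sub("\\.[^.]+$", ".gff3", path)
  dna <- Biostrings::DNAStringSet(rec$sequence)
  names(dna) <- rec$id
  Biostrings::writeXStringSet(dna, path, width = 70L)
  lines <- "##gff-version 3"
  ann <- rec$annotations
  spans <- gene_spans(ann)
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    gid <- paste0(sp$gene, ".", sp$copy_tag)
    attr_g <- sprintf("ID=%s;Name=%s;biotype=%s;copy_tag=%s%s", gid, sp$gene,
                      c(protein = "protein_coding", tRNA = "tRNA",
                        rRNA = "rRNA")[[sp$category]], sp$copy_tag,
                      if (sp$is_pseudo) ";pseudo=true" else "")
    lines <- c(lines, paste(rec$id, "plastomekit", "gene", sp$start, sp$end,
                            ".", sp$strand, ".", attr_g, sep = "\t"))
    ex <- ann[ann$gene == sp$gene & ann$copy_tag == sp$copy_tag, ,
              drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, paste(
        rec$id, "plastomekit", "exon", ex$start[j], ex$end[j], ".",
        sp$strand, ".", sprintf("ID=%s.exon%d;Parent=%s", gid, j, gid),
        sep = "\t"))
  }
  writeLines(lines, gff)
  invisible(c(fasta = path, gff3 = gff))
}

# ---- GenBank flat file (minimal profile) -----------------------------------

read_genbank_plastome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS): ", path,
                           call. = FALSE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  circular <- grepl("circular", locus[1L])
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record lacks ORIGIN: ", path, call. = FALSE)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)
  ann <- empty_annotations()
  if (length(feat_start)) {
    block <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
    # unfold: a new feature starts at column 6 with a key
    keys <- grepl("^ {5}\\S", block)
    idx <- cumsum(keys)
    for (fi in setdiff(unique(idx), 0L)) {
      fl <- block[idx == fi]
      key <- strsplit(trimws(fl[1L]), "\\s+")[[1L]][1L]
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      body <- paste(trimws(fl), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", body)
      loc <- sub("\\s*/.*$", "", loc)
      quals <- regmatches(body, gregexpr("/[A-Za-z_]+(=\"[^\"]*\"|=\\S+)?",
                                         body))[[1L]]
      qget <- function(name) {
        hit <- grep(paste0("^/", name, "\\b"), quals, value = TRUE)
        if (!length(hit)) return(NULL)
        gsub("^[^=]*=?\"?|\"$", "", hit[1L])
      }
      parsed <- parse_gb_location(loc, line = fl[1L])
      name <- qget("gene") %||% qget("locus_tag") %||% key
      ann <- rbind(ann, gene_annotation(
        gene = name,
        category = switch(key, tRNA = "tRNA", rRNA = "rRNA",
                          qget("category") %||% "protein"),
        strand = parsed$strand,
        starts = parsed$starts, ends = parsed$ends,
        is_pseudo = any(grepl("^/pseudo\\b", quals)),
        copy_tag = qget("copy_tag") %||% "single"))
    }
    # the same gene emitted as both gene and CDS collapses to one copy
    ann <- ann[!duplicated(ann[c("gene", "copy_tag", "start", "end")]), ,
               drop = FALSE]
  }
  if (nchar(sequence) == 0L)
    stop("empty sequence in GenBank record: ", path, call. = FALSE)
  if (nrow(ann) && max(ann$end) > nchar(sequence))
    stop("feature coordinates beyond sequence length in ", path,
         call. = FALSE)
  plastome_record(id, sequence, ann, is_circular = circular, source = path)
}

parse_gb_location <- function(loc, line = loc) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  starts <- ends <- integer(0)
  for (mm in m) {
    if (length(mm) == 0L || mm[1L] == "")
      stop("cannot parse GenBank location near: ", line, call. = FALSE)
    if (mm[4L] != "") { starts <- c(starts, as.integer(mm[4L]))
                        ends <- c(ends, as.integer(mm[4L])) }
    else { starts <- c(starts, as.integer(mm[2L]))
           ends <- c(ends, as.integer(mm[3L])) }
  }
  list(strand = strand, starts = starts, ends = ends)
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits a minimal feature table (one feature per gene copy keyed by
#' category) that [read_plastome()] round-trips exactly.
#'
#' @param rec a `plastome_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  validate_plastome(rec)
  n <- nchar(rec$sequence)
  lines <- sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                   rec$id, n, if (rec$is_circular) "circular" else "linear")
  lines <- c(lines, sprintf("DEFINITION  %s plastome.", rec$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
  ann <- rec$annotations
  spans <- gene_spans(ann)
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    ex <- ann[ann$gene == sp$gene & ann$copy_tag == sp$copy_tag, ,
              drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    ivs <- sprintf("%d..%d", ex$start, ex$end)
    loc <- if (length(ivs) > 1L) sprintf("join(%s)",
                                         paste(ivs, collapse = ",")) else ivs
    if (sp$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- c(protein = "gene", tRNA = "tRNA", rRNA = "rRNA")[[sp$category]]
    lines <- c(lines,
               sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", sp$gene),
               sprintf("                     /category=\"%s\"", sp$category),
               sprintf("                     /copy_tag=\"%s\"", sp$copy_tag))
    if (sp$is_pseudo)
      lines <- c(lines, "                     /pseudo")
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(rec$sequence, p, min(p + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p,
                              tolower(paste(blocks, collapse = " "))))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Write a quadripartite partition as BED
#'
#' BED is 0-based half-open; internal 1-based inclusive intervals are
#' converted at this boundary.
#'
#' @param partition a `region_partition` (see [partition_from_ir()]).
#' @param id sequence name for the first BED column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_bed <- function(partition, id, path) {
  rows <- lapply(c("lsc", "ira", "ssc", "irb"), function(r) {
    iv <- partition[[r]]
    sprintf("%s\t%d\t%d\t%s", id, iv[1L] - 1L, iv[2L], toupper(r))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Canonical machine output for all report tables.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
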