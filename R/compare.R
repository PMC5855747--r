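# Side-by-side comparison of multiple annotated plastomes.

#' Compare plastome records side by side
#'
#' Runs the single-genome analyses (partition and composition, gene census,
#' junction distances, SSR and long-repeat counts) on each record and
#' assembles one column per species plus min/max range rows with species
#' attribution. A record whose IR detection fails is retained with blank
#' partition-dependent cells and a warning.
#'
#' @param records list of at least two `plastome_record`s.
#' @param include character vector of analysis blocks to run, a subset of
#'   `c("composition", "census", "ssr", "repeats")`.
#' @param min_ir_length minimum IR length passed to [detect_ir()].
#' @return list with `table` (data frame, one row per metric, one column
#'   per species) and `ranges` (data frame `metric`, `min`, `min_species`,
#'   `max`, `max_species`).
#' @export
compare_genomes <- function(records,
                            include = c("composition", "census", "ssr",
                                        "repeats"),
                            min_ir_length = 1000L) {
  if (length(records) < 2L)
    stop("compare_genomes needs at least two records", call. = FALSE)
  include <- match.arg(include, several.ok = TRUE)
  cols <- list()
  for (rec in records) {
    part <- tryCatch({
      ir <- detect_ir(rec, min_ir_length = min_ir_length)
      if (is.null(ir)) stop("no IR detected")
      partition_from_ir(rec, ir)
    }, error = function(e) {
      warning("IR detection failed for ", rec$id, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    v <- c(total_length_bp = nchar(rec$sequence),
           gc_percent = round_half_up(100 * gc_content(rec$sequence), 1))
    if (!is.null(part)) {
      v <- c(v,
             lsc_length_bp = unname(part$lsc[2L] - part$lsc[1L] + 1L),
             ssc_length_bp = unname(part$ssc[2L] - part$ssc[1L] + 1L),
             ir_length_bp = unname(part$ira[2L] - part$ira[1L] + 1L))
    } else {
      v <- c(v, lsc_length_bp = NA, ssc_length_bp = NA, ir_length_bp = NA)
    }
    if ("census" %in% include) {
      cen <- if (!is.null(part)) gene_census(rec$annotations, part) else NULL
      v <- c(v, gene_copies = if (is.null(cen)) NA else cen$total_copies,
             distinct_genes = if (is.null(cen)) NA else cen$distinct_names,
             duplicated_genes = if (is.null(cen)) NA else
               cen$duplicated_names)
    }
    if ("ssr" %in% include)
      v <- c(v, ssr_count = nrow(find_ssrs(rec, part)))
    if ("repeats" %in% include)
      v <- c(v, repeat_count = nrow(find_long_repeats(rec)))
    cols[[rec$id]] <- v
  }
  tab <- as.data.frame(cols, check.names = FALSE)
  tab <- cbind(metric = rownames(tab), tab)
  rownames(tab) <- NULL
  sp <- names(cols)
  ranges <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    vals <- suppressWarnings(as.numeric(tab[i, -1L]))
    if (all(is.na(vals))) return(NULL)
    data.frame(metric = tab$metric[i],
               min = min(vals, na.rm = TRUE),
               min_species = sp[which.min(vals)],
               max = max(vals, na.rm = TRUE),
               max_species = sp[which.max(vals)],
               stringsAsFactors = FALSE)
  }))
  list(table = tab, ranges = ranges)
}
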