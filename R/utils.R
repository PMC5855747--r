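# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A,C,G,T,N (case-insensitive).
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement without reversal (for "complement"-class repeats)
complement_seq <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", x)
}

reverse_seq <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in comparative
#' plastome work use conventional half-away-from-zero rounding, so reports
#' in this package go through this helper.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# all k-mers of s as a character vector (positions 1..n-k+1)
kmer_vector <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# 1-based inclusive intervals -> total covered length (set union)
union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce + 1L) {
      ce <- max(ce, ends[i])
    } else {
      tot <- tot + (ce - cs + 1L)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  tot + (ce - cs + 1L)
}

# logical mask of covered positions for a genome of length n
coverage_mask <- function(starts, ends, n) {
  m <- logical(n)
  for (i in seq_along(starts)) m[starts[i]:ends[i]] <- TRUE
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  bad <- gsub("[ACGTN]", "", toupper(sequence))
  if (nchar(bad) > 0L)
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(seq_chars(bad))[1:5], collapse = ","), call. = FALSE)
  invisible(TRUE)
}
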