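#' @useDynLib graftmobile, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain uppercase DNA strings.
#'
#' @param x character vector of DNA sequences over A/C/G/T.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assemble a transcript table
#'
#' The pipeline's in-memory transcriptome: one row per transcript with its
#' species tag, sequence and CDS interval in 0-based half-open coordinates.
#'
#' @param id character transcript identifiers, unique.
#' @param species species tag (e.g. "Csa", "Cmo"), recycled if length 1.
#' @param seq uppercase DNA sequences over A/C/G/T.
#' @param cds_start,cds_end CDS interval, 0-based half-open. Defaults to the
#'   whole transcript.
#' @return a `data.frame` with columns id, species, seq, cds_start, cds_end.
#' @export
transcript_table <- function(id, species, seq,
                             cds_start = 0L, cds_end = nchar(seq)) {
  if (anyDuplicated(id)) {
    stop("duplicate transcript id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(nchar(seq) == 0L)) stop("empty sequence for id(s): ",
                                  paste(id[nchar(seq) == 0L], collapse = ", "))
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) stop("non-ACGT characters in sequence(s): ",
                     paste(id[bad], collapse = ", "))
  df <- data.frame(id = as.character(id), species = as.character(species),
                   seq = as.character(seq),
                   cds_start = as.integer(cds_start),
                   cds_end = as.integer(cds_end),
                   stringsAsFactors = FALSE)
  with(df, stopifnot(cds_start >= 0L, cds_start < cds_end,
                     cds_end <= nchar(seq)))
  df
}

cds_length <- function(transcripts) {
  transcripts$cds_end - transcripts$cds_start
}

`%||%` <- function(a, b) if (is.null(a)) b else a
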