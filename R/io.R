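# Readers and writers for the plain-text formats the pipeline touches.
# File coordinates are 1-based (VCF/GFF convention); everything in memory is
# 0-based half-open.

#' Read a FASTA transcriptome
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. IUPAC ambiguity
#' codes other than A/C/G/T are rejected: the downstream SNP logic requires
#' fully resolved bases.
#'
#' @param path FASTA file.
#' @param species species tag stored on every record (default `NA`).
#' @return a transcript table (see [transcript_table()]); CDS defaults to the
#'   full sequence until annotated via [read_cds_table()].
#' @export
read_fasta <- function(path, species = NA_character_) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  transcript_table(id = ids, species = species, seq = seqs)
}

#' Write a transcript table as FASTA
#'
#' @param transcripts transcript table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(transcripts$seq)
  names(set) <- transcripts$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read FASTQ reads
#'
#' Four-line records; gzip is handled transparently. Qualities are retained
#' but ignored by the aligner (reads are assumed quality-filtered upstream;
#' a minimum-length gate is exposed instead).
#'
#' @param path FASTQ file, optionally gzipped.
#' @param min_len drop reads shorter than this many bases (default 100).
#' @return `data.frame` with columns id, seq, qual.
#' @export
read_fastq <- function(path, min_len = 100L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file ", path, " does not contain complete 4-line records")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  heads <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(heads, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+")) {
    stop("malformed FASTQ record structure in ", path)
  }
  ids <- sub("\\s.*$", "", substring(heads, 2L))
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop("sequence/quality length mismatch for record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  keep <- nchar(seqs) >= min_len
  data.frame(id = ids[keep], seq = toupper(seqs[keep]), qual = quals[keep],
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads `data.frame` with columns id, seq and optionally qual (a
#'   constant placeholder quality is written when absent).
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a variant table (VCF-subset TSV)
#'
#' Columns CHROM, POS (1-based), ID, REF, ALT; `#`-prefixed lines are
#' skipped. Only single-nucleotide variants are supported: the consensus
#' construction and the diagnostic-SNP classifier are substitution-only, so
#' indel lines are rejected outright.
#'
#' @param path variant file.
#' @param reference optional transcript table; when supplied, each REF base
#'   is checked against the reference sequence.
#' @return `data.frame` with columns target_id, pos (0-based), ref, alt,
#'   sorted by (target_id, pos).
#' @export
read_variants <- function(path, reference = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("target_id", "pos", "id", "ref", "alt"),
                          colClasses = c("character", "integer", "character",
                                         "character", "character"))
  if (nrow(df) == 0L) {
    return(data.frame(target_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  indel <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  if (any(indel)) {
    stop("only single-nucleotide variants are supported; indel record(s) at ",
         paste(df$target_id[indel], df$pos[indel], collapse = "; "))
  }
  if (any(df$ref == df$alt)) stop("variant with REF == ALT in ", path)
  out <- data.frame(target_id = df$target_id, pos = df$pos - 1L,
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("target_id", "pos")])) {
    stop("multiple variant records at one (target, pos) in ", path)
  }
  out <- out[order(out$target_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(reference)) check_variants_against(out, reference)
  out
}

check_variants_against <- function(variants, reference) {
  seqs <- stats::setNames(reference$seq, reference$id)
  missing <- setdiff(variants$target_id, names(seqs))
  if (length(missing)) stop("variant target(s) absent from reference: ",
                            paste(unique(missing), collapse = ", "))
  at <- substr(seqs[variants$target_id], variants$pos + 1L, variants$pos + 1L)
  bad <- at != variants$ref
  if (any(bad)) {
    stop("REF base disagrees with reference at ",
         paste(variants$target_id[bad], variants$pos[bad] + 1L,
               collapse = "; "))
  }
  invisible(TRUE)
}

#' Write a variant table (VCF-subset TSV)
#'
#' @param variants `data.frame` as returned by [read_variants()] (0-based
#'   `pos`); written 1-based.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#CHROM\tPOS\tID\tREF\tALT", con)
  if (nrow(variants)) {
    writeLines(paste(variants$target_id, variants$pos + 1L, ".",
                     variants$ref, variants$alt, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a CDS annotation table (GFF-lite)
#'
#' Three tab-separated columns: transcript_id, cds_start, cds_end, 1-based
#' inclusive in the file; converted to 0-based half-open in memory.
#'
#' @param path annotation file.
#' @param transcripts optional transcript table to annotate in place.
#' @return when `transcripts` is supplied, the table with cds_start/cds_end
#'   replaced; otherwise a `data.frame` of the converted intervals.
#' @export
read_cds_table <- function(path, transcripts = NULL) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("id", "cds_start", "cds_end"),
                          colClasses = c("character", "integer", "integer"))
  df$cds_start <- df$cds_start - 1L  # half-open end is the 1-based inclusive end
  if (is.null(transcripts)) return(df)
  i <- match(transcripts$id, df$id)
  if (anyNA(i)) stop("transcripts missing from CDS table: ",
                     paste(transcripts$id[is.na(i)], collapse = ", "))
  transcripts$cds_start <- df$cds_start[i]
  transcripts$cds_end <- df$cds_end[i]
  stopifnot(transcripts$cds_end <= nchar(transcripts$seq))
  transcripts
}

#' Write a CDS annotation table (GFF-lite)
#'
#' @param transcripts transcript table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cds_table <- function(transcripts, path) {
  utils::write.table(
    data.frame(transcripts$id, transcripts$cds_start + 1L, transcripts$cds_end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table
#' @param path file written by [write_tsv()].
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
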