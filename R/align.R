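# Mismatch-bounded read placement on transcript sets.
#
# Reads are seeded with non-overlapping k-mers and verified by ungapped
# Hamming extension. With k = floor(read_len / (max_mismatch + 1)) the
# pigeonhole principle guarantees at least one exact seed for every placement
# within the mismatch bound, so seeding loses no true hit.

#' Build a k-mer index over a transcript set
#'
#' The index stores every forward k-mer; queries probe the read and its
#' reverse complement, so both strands are searchable.
#'
#' @param transcripts transcript table.
#' @param k seed length; default `floor(read_len / (max_mismatch + 1))`,
#'   floored at 11.
#' @param read_len,max_mismatch used only to derive the default `k`.
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(transcripts, k = NULL,
                             read_len = 150L, max_mismatch = 3L) {
  if (is.null(k)) k <- max(11L, read_len %/% (max_mismatch + 1L))
  k <- as.integer(k)
  if (k < 11L) stop("seed length k must be >= 11")
  lens <- nchar(transcripts$seq)
  if (k > min(lens)) stop("k exceeds the shortest transcript")
  tabs <- lapply(seq_len(nrow(transcripts)), function(i) {
    L <- lens[i]
    off <- 0:(L - k)  # 0-based
    data.table::data.table(kmer = substring(transcripts$seq[i], off + 1L, off + k),
                           tidx = i, off = off)
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  structure(list(k = k, ids = transcripts$id, species = transcripts$species,
                 seqs = transcripts$seq, lens = lens, table = dt),
            class = "kmer_index")
}

#' Align reads to an indexed transcript set
#'
#' Returns every co-optimal placement (minimum mismatch count, both strands)
#' within `max_mismatch` for each read. Alignment is ungapped: "edit
#' distance" here is Hamming distance, consistent with the substitution-only
#' SNP data model.
#'
#' @param reads data.frame with columns id, seq (equal-length reads), or a
#'   character vector of sequences.
#' @param index a [build_kmer_index()] result.
#' @param max_mismatch maximum mismatches (default 3).
#' @return data.frame: read_id, target_id, species, offset (0-based), strand,
#'   mismatches — empty when nothing places.
#' @export
align_reads <- function(reads, index, max_mismatch = 3L) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  }
  empty <- data.frame(read_id = character(), target_id = character(),
                      species = character(), offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  rl <- unique(nchar(reads$seq))
  if (length(rl) != 1L) {  # mixed lengths: align per length class
    parts <- split(reads, nchar(reads$seq))
    out <- do.call(rbind, lapply(parts, align_reads, index = index,
                                 max_mismatch = max_mismatch))
    rownames(out) <- NULL
    return(out)
  }
  k <- index$k
  if (rl < k) stop("read length ", rl, " is shorter than seed length ", k)
  n_seeds <- min(max_mismatch + 1L, rl %/% k)
  seed_starts <- (seq_len(n_seeds) - 1L) * k  # 0-based within read

  queries <- c(reads$seq, revcomp(reads$seq))
  strands <- rep(c("+", "-"), each = nrow(reads))
  qread <- rep(seq_len(nrow(reads)), 2L)

  # one row per (query, seed): exact k-mer lookup, then implied offsets
  nq <- length(queries)
  seed_seq <- substring(rep(queries, each = n_seeds),
                        rep(seed_starts, nq) + 1L,
                        rep(seed_starts, nq) + k)
  lut <- data.table::data.table(
    qidx = rep(seq_len(nq), each = n_seeds),
    spos = rep(seed_starts, nq),
    kmer = seed_seq)
  hits <- index$table[lut, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits[, offset := off - spos]
  hits <- hits[offset >= 0L & offset + rl <= index$lens[tidx]]
  if (nrow(hits) == 0L) return(empty)
  cand <- unique(hits[, list(qidx, tidx, offset)])
  cand[, mm := cpp_count_mismatches(queries, cand$qidx, index$seqs,
                                    cand$tidx, cand$offset,
                                    as.integer(max_mismatch))]
  cand <- cand[mm <= max_mismatch]
  if (nrow(cand) == 0L) return(empty)
  cand[, ridx := qread[qidx]]
  cand[, best := min(mm), by = ridx]
  cand <- cand[mm == best]
  out <- data.frame(read_id = reads$id[cand$ridx],
                    target_id = index$ids[cand$tidx],
                    species = index$species[cand$tidx],
                    offset = cand$offset,
                    strand = strands[cand$qidx],
                    mismatches = cand$mm,
                    stringsAsFactors = FALSE)
  out[order(match(out$read_id, reads$id), out$target_id, out$offset), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Best placements of a single read
#'
#' @param read a single read sequence.
#' @param index a [build_kmer_index()] result.
#' @param max_mismatch maximum mismatches.
#' @return data.frame of all co-optimal hits (possibly empty).
#' @export
best_hits <- function(read, index, max_mismatch = 3L) {
  stopifnot(is.character(read), length(read) == 1L)
  align_reads(data.frame(id = "query", seq = read, stringsAsFactors = FALSE),
              index, max_mismatch)
}

#' Summarise best hits per read
#'
#' Collapses an [align_reads()] table to one row per read: the minimum
#' mismatch count, the best target when it is unique at that minimum, and
#' whether the read is gene-ambiguous (co-optimal on several targets).
#'
#' @param hits an [align_reads()] result.
#' @return data.frame: read_id, best_mm, n_targets, target_id (NA when
#'   ambiguous), species.
#' @export
summarize_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(read_id = character(), best_mm = integer(),
                      n_targets = integer(), target_id = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(hits)
  s <- dt[, list(best_mm = mismatches[1L],
                 n_targets = data.table::uniqueN(target_id),
                 target_id = target_id[1L], species = species[1L]),
          by = read_id]
  s[n_targets > 1L, `:=`(target_id = NA_character_, species = NA_character_)]
  as.data.frame(s)
}

#' FPKM quantification from read placements
#'
#' Reads with a unique best gene are counted as fragments; reads co-optimal
#' on several genes are discarded (ambiguity cannot support a count). FPKM
#' uses the CDS length: `count * 1e9 / (cds_len_bp * total_assigned)`.
#'
#' @param hits an [align_reads()] result for one sample.
#' @param transcripts transcript table defining the gene universe and CDS
#'   lengths.
#' @return data.frame: gene_id, count, length_kb, fpkm (one row per gene).
#' @export
quantify_fpkm <- function(hits, transcripts) {
  s <- summarize_hits(hits)
  assigned <- s$target_id[!is.na(s$target_id)]
  counts <- table(factor(assigned, levels = transcripts$id))
  total <- sum(counts)
  len_bp <- cds_length(transcripts)
  if (total == 0L) {
    warning("no assigned fragments; all FPKM set to 0")
    fpkm <- rep(0, nrow(transcripts))
  } else {
    fpkm <- as.numeric(counts) * 1e9 / (len_bp * total)
  }
  data.frame(gene_id = transcripts$id, count = as.integer(counts),
             length_kb = len_bp / 1000, fpkm = fpkm,
             stringsAsFactors = FALSE)
}
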