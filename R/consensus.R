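# Consensus transcriptome construction: place resequencing-style reads,
# tally per-position base counts, call majority variants, and substitute them
# into the reference. The majority rule stands in for a genotype-likelihood
# caller, which is sufficient for homozygous inbred material.

#' Per-position base tallies from placed reads
#'
#' Reads are placed by [align_reads()] within `max_mismatch`; only reads with
#' a unique best placement contribute (an ambiguous placement cannot attest a
#' position). Unplaced reads are ignored.
#'
#' @param reads data.frame with columns id, seq.
#' @param reference transcript table.
#' @param max_mismatch placement bound (default 3).
#' @param index optional prebuilt [build_kmer_index()] over `reference`.
#' @return data.frame: target_id, pos (0-based), A, C, G, T, depth; only
#'   covered positions are listed.
#' @export
pileup <- function(reads, reference, max_mismatch = 3L, index = NULL) {
  empty <- data.frame(target_id = character(), pos = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  if (is.null(index)) {
    index <- build_kmer_index(reference, read_len = min(nchar(reads$seq)),
                              max_mismatch = max_mismatch)
  }
  hits <- align_reads(reads, index, max_mismatch)
  if (nrow(hits) == 0L) return(empty)
  dt <- data.table::as.data.table(hits)
  dt <- dt[, if (.N == 1L) .SD, by = read_id]  # unique best placement only
  if (nrow(dt) == 0L) return(empty)
  seqs <- stats::setNames(reads$seq, reads$id)[dt$read_id]
  seqs[dt$strand == "-"] <- revcomp(seqs[dt$strand == "-"])

  # expand each placed read into (target, pos, base) triples, vectorised
  rlens <- nchar(seqs)
  tvec <- rep(dt$target_id, rlens)
  pvec <- rep(dt$offset, rlens) + (sequence(rlens) - 1L)
  bvec <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  tab <- data.table::data.table(target_id = tvec, pos = pvec, base = bvec)
  agg <- tab[, list(n = .N), by = list(target_id, pos, base)]
  wide <- data.table::dcast(agg, target_id + pos ~ base, value.var = "n",
                            fill = 0L)
  for (b in DNA_BASES) if (is.null(wide[[b]])) wide[, (b) := 0L]
  data.table::setcolorder(wide, c("target_id", "pos", DNA_BASES))
  wide[, depth := A + C + G + T]
  data.table::setorder(wide, target_id, pos)
  as.data.frame(wide)
}

#' Call majority variants from a pileup
#'
#' A variant is emitted where the majority base differs from the reference,
#' total depth is at least `min_depth` and the majority fraction is at least
#' `min_alt_frac`. Ties and sub-threshold alternates retain the reference
#' base: a wrong consensus base would manufacture fake diagnostic SNPs
#' downstream, so the rule is deliberately conservative.
#'
#' @param pile a [pileup()] result.
#' @param reference transcript table.
#' @param min_depth minimum depth (default 5).
#' @param min_alt_frac minimum majority fraction, in (0.5, 1] (default 0.8).
#' @return variant data.frame (target_id, pos, ref, alt), sorted.
#' @export
call_variants <- function(pile, reference, min_depth = 5L,
                          min_alt_frac = 0.8) {
  stopifnot(min_depth >= 1L, min_alt_frac > 0.5, min_alt_frac <= 1)
  empty <- data.frame(target_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pile) == 0L) return(empty)
  counts <- as.matrix(pile[DNA_BASES])
  top <- max.col(counts, ties.method = "first")
  top_n <- counts[cbind(seq_len(nrow(counts)), top)]
  tied <- rowSums(counts == top_n) > 1L
  seqs <- stats::setNames(reference$seq, reference$id)
  refb <- substr(seqs[pile$target_id], pile$pos + 1L, pile$pos + 1L)
  altb <- DNA_BASES[top]
  keep <- !tied & altb != refb & pile$depth >= min_depth &
    top_n / pile$depth >= min_alt_frac
  out <- data.frame(target_id = pile$target_id[keep], pos = pile$pos[keep],
                    ref = refb[keep], alt = altb[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply variants to a reference transcriptome
#'
#' Substitutes each variant's alternate allele into the reference; lengths
#' are unchanged and every REF allele is checked first. Idempotent for a
#' fixed variant set, and variants at distinct positions commute.
#'
#' @param reference transcript table.
#' @param variants variant data.frame (target_id, pos 0-based, ref, alt).
#' @return the modified (consensus) transcript table.
#' @export
apply_variants <- function(reference, variants) {
  if (nrow(variants) == 0L) return(reference)
  check_variants_against(variants, reference)
  out <- reference
  for (i in which(out$id %in% variants$target_id)) {
    v <- variants[variants$target_id == out$id[i], , drop = FALSE]
    s <- strsplit(out$seq[i], "", fixed = TRUE)[[1]]
    s[v$pos + 1L] <- v$alt
    out$seq[i] <- paste(s, collapse = "")
  }
  out
}

#' Build a consensus transcriptome from resequencing-style reads
#'
#' Convenience wrapper: pileup, majority variant calling, application.
#'
#' @inheritParams pileup
#' @inheritParams call_variants
#' @return list(consensus = transcript table, variants = variant table).
#' @export
build_consensus <- function(reads, reference, max_mismatch = 3L,
                            min_depth = 5L, min_alt_frac = 0.8) {
  pile <- pileup(reads, reference, max_mismatch)
  variants <- call_variants(pile, reference, min_depth, min_alt_frac)
  list(consensus = apply_variants(reference, variants), variants = variants)
}
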