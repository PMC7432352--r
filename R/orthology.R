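# Cross-species comparison: reciprocal-best-hit orthology by local protein
# alignment, duplicate collapsing, multi-set overlap counting, and the scalar
# summaries (RT-qPCR concordance, delta-delta-Ct, ordination input table).

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

#' Optimal local protein alignment score
#'
#' Smith-Waterman score under BLOSUM62 with affine gaps (a gap of length k
#' costs `gap_open + k * gap_ext`; defaults 11/1). Deterministic and
#' symmetric; the score floor in [reciprocal_best_hits()] plays the role an
#' E-value cutoff plays at database scale.
#'
#' @param seq_a,seq_b protein sequences over the 20 standard residues.
#' @param gap_open,gap_ext affine gap parameters.
#' @return the optimal local alignment score (>= 0).
#' @export
local_protein_score <- function(seq_a, seq_b, gap_open = 11, gap_ext = 1) {
  sub <- blosum62_matrix()
  enc <- function(s) {
    v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], AA_ALPHABET)
    if (anyNA(v)) stop("invalid amino-acid residue in sequence")
    v
  }
  cpp_sw_affine(enc(seq_a), enc(seq_b), sub, gap_open, gap_ext)
}

#' Translate CDS transcripts to proteins
#'
#' Standard-code translation of each CDS interval; the sequence is truncated
#' at the first stop codon (diverged homologs can acquire premature stops).
#'
#' @param transcripts transcript table.
#' @return named character vector of protein sequences (possibly empty
#'   strings for immediate stops).
#' @export
translate_cds <- function(transcripts) {
  cds <- substr(transcripts$seq, transcripts$cds_start + 1L,
                transcripts$cds_end)
  cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "X"))
  aa <- sub("\\*.*$", "", aa)
  stats::setNames(aa, transcripts$id)
}

#' Reciprocal-best-hit ortholog pairing
#'
#' All-versus-all local protein scores; a pair is reported when each gene is
#' the other's top scorer and both directions clear `min_score`. Top-score
#' ties are broken lexicographically by gene id (and reported via the
#' `ties` attribute) so results are deterministic.
#'
#' @param set_a,set_b named character vectors of protein sequences.
#' @param min_score raw-score floor (default 50).
#' @return data.frame: gene_a, gene_b, score_ab, score_ba,
#'   is_reciprocal_best (all TRUE in the returned rows).
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_score = 50) {
  stopifnot(length(set_a) > 0L, length(set_b) > 0L,
            !is.null(names(set_a)), !is.null(names(set_b)))
  a_ord <- order(names(set_a)); set_a <- set_a[a_ord]
  b_ord <- order(names(set_b)); set_b <- set_b[b_ord]
  scores <- matrix(0, length(set_a), length(set_b),
                   dimnames = list(names(set_a), names(set_b)))
  for (i in seq_along(set_a)) {
    if (nchar(set_a[i]) == 0L) next
    for (j in seq_along(set_b)) {
      if (nchar(set_b[j]) == 0L) next
      scores[i, j] <- local_protein_score(set_a[[i]], set_b[[j]])
    }
  }
  # which.max on a lexicographically ordered dimension breaks ties by id
  best_b <- apply(scores, 1L, which.max)
  best_a <- apply(scores, 2L, which.max)
  tie_rows <- which(apply(scores, 1L, function(x) sum(x == max(x)) > 1L))
  recip <- which(best_a[best_b] == seq_along(set_a))
  keep <- recip[scores[cbind(recip, best_b[recip])] >= min_score]
  out <- data.frame(gene_a = names(set_a)[keep],
                    gene_b = names(set_b)[best_b[keep]],
                    score_ab = scores[cbind(keep, best_b[keep])],
                    score_ba = scores[cbind(keep, best_b[keep])],
                    is_reciprocal_best = TRUE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ties") <- names(set_a)[tie_rows]
  out
}

#' Collapse duplicate partners in an ortholog mapping
#'
#' Several genes may share one best partner; one entry per distinct partner
#' is kept (first by gene id), and the bookkeeping is reported.
#'
#' @param pairs data.frame with columns gene_a, gene_b (gene_b the partner).
#' @return list(partners = character vector, n_input, n_distinct,
#'   n_removed).
#' @export
collapse_duplicates <- function(pairs) {
  ord <- order(pairs$gene_a)
  partners <- unique(pairs$gene_b[ord])
  list(partners = partners, n_input = nrow(pairs),
       n_distinct = length(partners),
       n_removed = nrow(pairs) - length(partners))
}

#' Overlap (Venn) counts over named gene sets
#'
#' Counts every nonempty region of the Venn partition of 2-6 sets; region
#' counts sum to the union size.
#'
#' @param sets named list of 2-6 character vectors.
#' @return data.frame: region (member set names joined by "&"), count.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2L || length(sets) > 6L) {
    stop("overlap_counts supports 2 to 6 sets")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named")
  }
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes))
  region <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  tab <- table(region)
  data.frame(region = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' RT-qPCR / RNA-seq concordance rate
#'
#' @param n_confirmed transcripts whose mobility was confirmed.
#' @param n_tested transcripts tested.
#' @return percentage, to two decimals.
#' @export
concordance_rate <- function(n_confirmed, n_tested) {
  if (n_tested <= 0L) stop("n_tested must be positive")
  stopifnot(n_confirmed >= 0L, n_confirmed <= n_tested)
  round(100 * n_confirmed / n_tested, 2L)
}

#' Relative quantity by the delta-delta-Ct method
#'
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,control -
#' Ct_ref,control))`; invariant to adding a constant to all four Ct values.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample.
#' @param ct_target_control,ct_ref_control the same in the control.
#' @return fold change relative to control.
#' @export
ddct_relative_quantity <- function(ct_target_sample, ct_ref_sample,
                                   ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  2^-((ct_target_sample - ct_ref_sample) -
        (ct_target_control - ct_ref_control))
}

#' Four-parameter ordination summary of a mobile catalog
#'
#' The per-system row used for cross-study ordination: percentage of mobile
#' and non-mobile mRNAs and the mean CDS length of each class.
#'
#' @param mobile_lengths CDS lengths (bp) of the mobile genes.
#' @param nonmobile_lengths CDS lengths of the remaining genes.
#' @param system label for the row.
#' @return one-row data.frame: system, pct_mobile, pct_nonmobile,
#'   mean_cds_len_mobile, mean_cds_len_nonmobile.
#' @export
summary_params <- function(mobile_lengths, nonmobile_lengths,
                           system = NA_character_) {
  n_mob <- length(mobile_lengths); n_non <- length(nonmobile_lengths)
  total <- n_mob + n_non
  if (total == 0L) stop("at least one gene is required")
  data.frame(system = system,
             pct_mobile = 100 * n_mob / total,
             pct_nonmobile = 100 * n_non / total,
             mean_cds_len_mobile = if (n_mob) mean(mobile_lengths) else NA_real_,
             mean_cds_len_nonmobile = if (n_non) mean(nonmobile_lengths)
                                      else NA_real_,
             stringsAsFactors = FALSE)
}
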