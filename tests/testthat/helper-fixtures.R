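# Shared fixtures: everything is generated in code, nothing read from disk.

# small transcript set with known sequences
tiny_transcripts <- function() {
  transcript_table(
    id = c("t1", "t2"),
    species = "Csa",
    seq = c(paste(rep("ACGT", 30), collapse = ""),   # 120 bp
            paste(rep("GATTACA", 20), collapse = "")))  # 140 bp
}

# a deterministic random transcriptome
random_transcripts <- function(n, len = 300L, species = "Csa",
                               prefix = "g", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  transcript_table(sprintf("%s%03d", prefix, seq_len(n)), species, seqs)
}

# random protein sequence over the 20 standard residues
random_protein <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# small, fast experiment configuration for pipeline-level tests
small_config <- function(seed = 11L, ...) {
  sim_config(n_genes = 40L, cds_len_range = c(450L, 900L), depth = 2500L,
             error_rate = 0, seed = seed, ...)
}

# exhaustive mismatch-bounded scan used as the aligner's independent oracle:
# every offset on every target and strand, Hamming distance via Biostrings.
oracle_scan <- function(read, transcripts, max_mismatch) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp(read)
    p <- Biostrings::DNAString(q)
    for (i in seq_len(nrow(transcripts))) {
      subj <- Biostrings::DNAString(transcripts$seq[i])
      n_off <- nchar(transcripts$seq[i]) - nchar(read) + 1L
      if (n_off < 1L) next
      d <- Biostrings::neditStartingAt(p, subj, starting.at = seq_len(n_off),
                                       with.indels = FALSE)
      hit <- which(d <= max_mismatch)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          target_id = transcripts$id[i], offset = hit - 1L, strand = strand,
          mismatches = d[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(target_id = character(), offset = integer(),
                      strand = character(), mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[res$mismatches == min(res$mismatches), , drop = FALSE]
  res[order(res$target_id, res$offset, res$strand), , drop = FALSE]
}

# quadratic-space textbook local aligner with affine gaps, for cross-checking
# the compiled scorer (kept deliberately naive and independent)
naive_sw <- function(a, b, submat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
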