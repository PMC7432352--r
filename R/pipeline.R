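# End-to-end orchestration: simulate -> (optional consensus from
# resequencing-style reads) -> align/quantify -> detect -> directionality,
# plus evaluation of a run against the simulation's truth manifest.

pool_reads <- function(read_sets, ids) {
  do.call(rbind, lapply(read_sets[ids], `[[`, "reads"))
}

sample_ids <- function(scion, rootstock, tissue) {
  sprintf("%s_%s_%s_rep%d", scion, rootstock, tissue, 1:3)
}

#' Run the full mobile-mRNA detection pipeline on a simulated experiment
#'
#' Stages: simulation (or a supplied experiment), optional consensus
#' reconstruction of each transcriptome from simulated resequencing reads,
#' homograft FPKM quantification (three replicates pooled per tissue),
#' per-replicate read-origin detection in the four recipient heterograft
#' tissues, replicate combination, and direction classification for both
#' species. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param classifier a [classifier_config()].
#' @param experiment optional pre-simulated [simulate_graft_experiment()]
#'   result (must match `config`); simulated from `config` when NULL.
#' @param consensus_from_reseq when TRUE the detector runs on consensus
#'   transcriptomes rebuilt from simulated resequencing reads against a
#'   perturbed public reference, exercising the consensus stage end-to-end;
#'   when FALSE (default) the generator's transcriptomes are used directly.
#' @param reseq_ref_divergence,reseq_coverage public-reference divergence and
#'   resequencing coverage used when `consensus_from_reseq` is TRUE.
#' @param reseq_max_mismatch mapping bound for the resequencing pileup; wider
#'   than the RNA classifier's bound because it must absorb the full
#'   line-to-reference divergence along a read (default 8).
#' @return list of class `graft_run`: config echo, classifier echo,
#'   per-species results (calls per side, direction table), fpkm tables,
#'   stage record counts and timings, and the experiment.
#' @export
run_graft_pipeline <- function(config = sim_config(),
                               classifier = classifier_config(),
                               experiment = NULL,
                               consensus_from_reseq = FALSE,
                               reseq_ref_divergence = 0.005,
                               reseq_coverage = 30,
                               reseq_max_mismatch = 8L) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  if (is.null(experiment)) experiment <- simulate_graft_experiment(config)
  sp <- config$species
  tick("simulate")

  truth <- split(experiment$transcripts, experiment$transcripts$species)
  consensus <- truth
  reseq_variants <- NULL
  if (consensus_from_reseq) {
    reseq_variants <- list()
    for (s in sp) {
      tr <- truth[[s]]
      ref <- perturb_reference(tr, reseq_ref_divergence)
      depth <- round(reseq_coverage * sum(nchar(tr$seq)) / config$read_len)
      reseq <- simulate_sample(tr, stats::setNames(rep(1, nrow(tr)), tr$id),
                               NULL, depth = depth,
                               read_len = config$read_len,
                               error_rate = config$error_rate,
                               sample_id = paste0(s, "_reseq"))
      built <- build_consensus(reseq$reads, ref,
                               max_mismatch = reseq_max_mismatch)
      consensus[[s]] <- built$consensus
      reseq_variants[[s]] <- built$variants
    }
    tick("consensus")
  }

  idx <- lapply(consensus, build_kmer_index,
                read_len = config$read_len,
                max_mismatch = classifier$self_discard_max_mm)

  # homograft FPKM per species and tissue (replicates pooled)
  fpkm <- list()
  for (s in sp) {
    for (t in c("leaf", "root")) {
      reads <- pool_reads(experiment$read_sets, sample_ids(s, s, t))
      hits <- align_reads(reads, idx[[s]], classifier$self_discard_max_mm)
      fpkm[[paste(s, t, sep = ".")]] <- quantify_fpkm(hits, consensus[[s]])
    }
  }
  tick("fpkm")

  # detection sides: donor species, the graft carrying it, recipient tissue
  other <- stats::setNames(rev(sp), sp)
  results <- list()
  for (s in sp) {
    sides <- list(
      down = list(scion = s, rootstock = other[[s]], tissue = "root"),
      up = list(scion = other[[s]], rootstock = s, tissue = "leaf"))
    side_calls <- lapply(sides, function(sd) {
      ids <- sample_ids(sd$scion, sd$rootstock, sd$tissue)
      per_rep <- lapply(ids, function(id) {
        detect_mobile_per_replicate(
          experiment$read_sets[[id]]$reads,
          donor_index = idx[[s]], recipient_index = idx[[other[[s]]]],
          donor_homograft_fpkm = fpkm[[paste(s, sd$tissue, sep = ".")]],
          config = classifier)
      })
      combine_replicates(per_rep, classifier)
    })
    dir_tab <- classify_direction(mobile_set(side_calls$down),
                                  mobile_set(side_calls$up), species = s)
    results[[s]] <- list(calls_down = side_calls$down,
                         calls_up = side_calls$up,
                         direction = dir_tab)
  }
  tick("detect")

  n_reads <- sum(vapply(experiment$read_sets,
                        function(x) nrow(x$reads), integer(1)))
  structure(list(config = config, classifier = classifier,
                 consensus_from_reseq = consensus_from_reseq,
                 reseq_variants = reseq_variants,
                 fpkm = fpkm, results = results,
                 counts = list(samples = length(experiment$read_sets),
                               reads = n_reads),
                 timings = timings, experiment = experiment),
            class = "graft_run")
}

# a "public" reference: the true transcriptome with random substitutions
perturb_reference <- function(transcripts, divergence) {
  out <- transcripts
  for (i in seq_len(nrow(out))) {
    b <- strsplit(out$seq[i], "", fixed = TRUE)[[1]]
    n <- round(divergence * length(b))
    if (n > 0L) {
      pos <- sample.int(length(b), n)
      b[pos] <- vapply(b[pos], function(x) sample(setdiff(DNA_BASES, x), 1L),
                       character(1), USE.NAMES = FALSE)
      out$seq[i] <- paste(b, collapse = "")
    }
  }
  out
}

window_snp_counts <- function(starts, read_len, snp_positions) {
  vapply(starts, function(s)
    sum(snp_positions >= s & snp_positions < s + read_len), integer(1))
}

#' Score a pipeline run against the truth manifest
#'
#' A mobile gene is *eligible* when the signal the method requires actually
#' reached the recipient tissue: among its realized foreign reads, those that
#' span at least `min_diagnostic_snps` diagnostic SNPs and are uncorrupted by
#' sequencing error (a read with errors cannot satisfy the perfect-match
#' condition) must reach `min_reads_per_gene` in at least `min_replicates`
#' replicates on some side, and the gene's true donor-homograft abundance
#' must clear the FPKM floor. Sensitivity is recovered/eligible; false
#' positives are passing calls whose manifest label is "none"; direction
#' accuracy compares each recovered gene's class with the class its manifest
#' label implies on the sides where it was detected.
#'
#' @param run a [run_graft_pipeline()] result.
#' @return list: per-species and overall sensitivity, false_positive count,
#'   direction_accuracy, and the underlying gene sets.
#' @export
evaluate_run <- function(run) {
  experiment <- run$experiment
  config <- run$config
  classifier <- run$classifier
  sp <- config$species
  other <- stats::setNames(rev(sp), sp)
  genes <- experiment$manifest$genes
  snp <- experiment$snp

  eligible <- list(); recovered <- list()
  fp <- character(0); dir_ok <- 0L; dir_tot <- 0L
  for (s in sp) {
    res <- run$results[[s]]
    final_down <- mobile_set(res$calls_down)
    final_up <- mobile_set(res$calls_up)
    g <- genes[genes$species == s, ]
    mobile <- g[g$direction != "none", ]
    fp <- c(fp, setdiff(union(final_down, final_up), mobile$gene_id))

    elig_side <- function(side) {
      tissue <- if (side == "down") "root" else "leaf"
      scion <- if (side == "down") s else other[[s]]
      rootstock <- if (side == "down") other[[s]] else s
      ids <- sample_ids(scion, rootstock, tissue)
      want <- mobile$gene_id[mobile$direction %in%
                               c(side, "bidirectional")]
      if (!length(want)) return(character(0))
      truth_tr <- experiment$transcripts
      qualifying <- sapply(ids, function(sid) {
        rs <- experiment$read_sets[[sid]]$reads
        if (nrow(rs) == 0L) return(stats::setNames(integer(length(want)), want))
        org <- parse_read_origin(rs$id)
        fr <- org$gene_id %in% want
        if (!any(fr)) return(stats::setNames(integer(length(want)), want))
        org <- org[fr, ]; seqs <- rs$seq[fr]
        # diagnostic SNPs are recorded against the donor gene id
        key <- org$gene_id
        nsnp_win <- mapply(function(gid, st) {
          length(snp_in_window(snp, gid, s, sp, st, config$read_len))
        }, key, org$start)
        clean <- read_is_clean(seqs, org, truth_tr)
        ok <- nsnp_win >= classifier$min_diagnostic_snps & clean
        tab <- table(factor(org$gene_id[ok], levels = want))
        stats::setNames(as.integer(tab), want)
      })
      qualifying <- matrix(qualifying, nrow = length(want),
                           dimnames = list(want, ids))
      n_support <- rowSums(qualifying >= classifier$min_reads_per_gene)
      names(want)[] <- want
      want[n_support >= classifier$min_replicates]
    }
    e_down <- elig_side("down"); e_up <- elig_side("up")
    elig <- union(e_down, e_up)
    # FPKM floor on true donor-homograft abundance (matched tissue)
    elig <- elig[vapply(elig, function(gid) {
      any(vapply(c("root", "leaf"), function(t) {
        true_fpkm(experiment, s, t, gid) >= classifier$min_fpkm
      }, logical(1)))
    }, logical(1))]
    eligible[[s]] <- elig
    recovered[[s]] <- intersect(union(final_down, final_up), elig)

    # direction agreement on recovered truly-mobile genes
    rec_mobile <- intersect(union(final_down, final_up), mobile$gene_id)
    if (length(rec_mobile)) {
      lab <- stats::setNames(mobile$direction, mobile$gene_id)[rec_mobile]
      in_down <- rec_mobile %in% final_down
      in_up <- rec_mobile %in% final_up
      assigned <- ifelse(in_down & in_up, "bidirectional",
                         ifelse(in_down, "down", "up"))
      expected <- ifelse(lab == "bidirectional", assigned, lab)
      ok <- (lab == "bidirectional") |
        (lab == "down" & assigned == "down") |
        (lab == "up" & assigned == "up")
      dir_ok <- dir_ok + sum(ok & assigned == expected)
      dir_tot <- dir_tot + length(rec_mobile)
    }
  }
  n_elig <- sum(lengths(eligible)); n_rec <- sum(lengths(recovered))
  list(sensitivity = if (n_elig) n_rec / n_elig else NA_real_,
       sensitivity_by_species = stats::setNames(vapply(sp, function(s) {
         if (length(eligible[[s]])) {
           length(recovered[[s]]) / length(eligible[[s]])
         } else NA_real_
       }, numeric(1)), sp),
       n_eligible = n_elig,
       false_positives = length(unique(fp)),
       direction_accuracy = if (dir_tot) dir_ok / dir_tot else NA_real_,
       eligible = eligible, recovered = recovered,
       false_positive_genes = unique(fp))
}

# SNP positions are stored for the first species' gene ids; map through the
# partner for the second species, positions are shared (same pair).
snp_in_window <- function(snp, gid, species, sp, start, read_len) {
  key <- if (species == sp[1]) gid else sub(paste0("^", sp[2]), sp[1], gid)
  pos <- snp[[key]]
  if (is.null(pos)) return(integer(0))
  pos[pos >= start & pos < start + read_len]
}

# TRUE when the read equals its source window exactly (no sequencing error)
read_is_clean <- function(seqs, org, transcripts) {
  src <- transcripts$seq[match(org$gene_id, transcripts$id)]
  win <- substr(src, org$start + 1L, org$start + nchar(seqs))
  win[org$strand == "-"] <- revcomp(win[org$strand == "-"])
  seqs == win
}

# FPKM-equivalent from the manifest's true homograft read counts
true_fpkm <- function(experiment, species, tissue, gene_id) {
  ids <- sample_ids(species, species, tissue)
  cnt <- experiment$manifest$counts
  cnt <- cnt[cnt$sample_id %in% ids, ]
  total <- sum(cnt$count)
  if (total == 0L) return(0)
  n <- sum(cnt$count[cnt$gene_id == gene_id])
  len <- nchar(experiment$transcripts$seq[
    match(gene_id, experiment$transcripts$id)])
  n * 1e9 / (len * total)
}

#' @export
print.graft_run <- function(x, ...) {
  cat("graft mobile-mRNA run:", x$counts$samples, "samples,",
      x$counts$reads, "reads\n")
  for (s in names(x$results)) {
    d <- x$results[[s]]$direction
    cat(sprintf("  %s: %d mobile (%s)\n", s, d$total[1L],
                paste(sprintf("%s %d (%.5g%%)", d$class, d$n, d$pct),
                      collapse = ", ")))
  }
  invisible(x)
}
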