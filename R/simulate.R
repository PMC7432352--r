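# Synthetic reciprocal graft experiment with known ground truth.
#
# Two species' transcriptomes are generated as ortholog pairs with controlled
# SNP divergence; four graft combinations x two tissues x three replicates of
# 150 bp single-end reads are drawn, with designated mobile genes contributing
# a fixed fraction of their source-tissue abundance to the recipient tissue.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Parameterises the in-silico graft experiment. Defaults describe the demo
#' scale used throughout the package: 200 ortholog pairs, 1% homolog
#' divergence, 5% of a mobile gene's source abundance transferred, 10,000
#' reads per sample (50 reads per gene on average).
#'
#' @param n_genes number of ortholog pairs.
#' @param cds_len_range CDS length range in bp (lengths drawn as codon
#'   multiples within it).
#' @param divergence per-base substitution probability between homologs.
#' @param mobile_down_frac,mobile_up_frac,mobile_bidir_frac fractions of each
#'   species' genes designated mobile scion-to-rootstock, rootstock-to-scion,
#'   and bidirectional.
#' @param mobile_transfer_frac fraction of a mobile gene's source-tissue
#'   abundance appearing in the recipient tissue.
#' @param expr_meanlog,expr_sdlog log-normal parameters of per-gene
#'   expression.
#' @param tissue_sdlog sd(log) of the per-tissue expression jitter around the
#'   gene's base expression.
#' @param read_len read length in bp.
#' @param depth reads per sample.
#' @param error_rate per-base substitution sequencing-error probability.
#' @param seed integer seed; all randomness flows from it.
#' @param species the two species tags, scion-first in graft naming.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       cds_len_range = c(600L, 1800L),
                       divergence = 0.01,
                       mobile_down_frac = 0.10,
                       mobile_up_frac = 0.02,
                       mobile_bidir_frac = 0.03,
                       mobile_transfer_frac = 0.05,
                       expr_meanlog = log(10),
                       expr_sdlog = 1,
                       tissue_sdlog = 0.25,
                       read_len = 150L,
                       depth = 10000L,
                       error_rate = 0.001,
                       seed = 1L,
                       species = c("Csa", "Cmo")) {
  fr <- c(mobile_down_frac, mobile_up_frac, mobile_bidir_frac)
  stopifnot(all(fr >= 0), all(fr <= 1), sum(fr) <= 1,
            divergence >= 0, divergence <= 0.2,
            mobile_transfer_frac >= 0, mobile_transfer_frac <= 1,
            read_len <= cds_len_range[1], length(species) == 2L,
            n_genes >= 1L, depth >= 0L, error_rate >= 0, error_rate < 1)
  structure(list(n_genes = as.integer(n_genes),
                 cds_len_range = as.integer(cds_len_range),
                 divergence = divergence,
                 mobile_down_frac = mobile_down_frac,
                 mobile_up_frac = mobile_up_frac,
                 mobile_bidir_frac = mobile_bidir_frac,
                 mobile_transfer_frac = mobile_transfer_frac,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 tissue_sdlog = tissue_sdlog,
                 read_len = as.integer(read_len), depth = as.integer(depth),
                 error_rate = error_rate, seed = as.integer(seed),
                 species = species),
            class = "sim_config")
}

random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_mid <- len %/% 3L - 2L
  codons <- apply(matrix(sample(DNA_BASES, 3L * n_mid, replace = TRUE), nrow = 3L),
                  2L, paste, collapse = "")
  while (any(codons %in% STOP_CODONS)) {
    i <- codons %in% STOP_CODONS
    codons[i] <- apply(matrix(sample(DNA_BASES, 3L * sum(i), replace = TRUE),
                              nrow = 3L), 2L, paste, collapse = "")
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate one diverged ortholog pair
#'
#' The recipient homolog differs from the donor at exactly
#' `round(divergence * length)` positions, chosen uniformly without
#' replacement; substituted bases are drawn uniformly from the three
#' alternatives. Pairs rounding to zero SNPs are emitted with a warning —
#' they are the classifier's structural blind spot.
#'
#' @param length CDS length (codon multiple).
#' @param divergence per-base substitution probability.
#' @return list(donor, recipient, snp_positions) with 0-based sorted
#'   positions.
#' @export
make_ortholog_pair <- function(length, divergence) {
  donor <- random_cds(length)
  n_snp <- round(divergence * length)
  if (n_snp == 0L) {
    if (divergence > 0) {
      warning("divergence x length < 0.5: emitting a zero-SNP ortholog pair")
    }
    return(list(donor = donor, recipient = donor,
                snp_positions = integer(0)))
  }
  pos <- sort(sample.int(length, n_snp))  # 1-based here
  bases <- strsplit(donor, "", fixed = TRUE)[[1]]
  bases[pos] <- vapply(bases[pos],
                       function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1), USE.NAMES = FALSE)
  list(donor = donor, recipient = paste(bases, collapse = ""),
       snp_positions = pos - 1L)
}

mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(b), n_err[i])
    b[pos] <- vapply(b[pos], function(x) sample(setdiff(DNA_BASES, x), 1L),
                     character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

#' Simulate one RNA-seq sample
#'
#' Per-gene read counts are multinomial over expression-times-length weights
#' scaled to `depth`; read starts are uniform over valid offsets; strands are
#' unbiased; each base is substituted independently with probability
#' `error_rate`. Read ids encode the true origin
#' (`sample:species:gene:start0:strand:serial`) for downstream evaluation.
#'
#' @param transcripts transcript table covering every gene in `expression`
#'   and `mobile_contributions`.
#' @param expression named vector of native per-gene expression (≥ 0).
#' @param mobile_contributions named vector of foreign-gene weights on the
#'   expression scale (already scaled by the transfer fraction); may be NULL.
#' @param depth total reads to draw; 0 yields an empty sample.
#' @param read_len read length.
#' @param error_rate per-base substitution probability.
#' @param sample_id sample identifier embedded in read ids.
#' @return list(sample_id, reads = data.frame(id, seq),
#'   true_counts = data.frame(gene_id, origin_species, count)).
#' @export
simulate_sample <- function(transcripts, expression,
                            mobile_contributions = NULL,
                            depth, read_len, error_rate,
                            sample_id = "sample") {
  stopifnot(all(expression >= 0))
  w <- c(expression, mobile_contributions %||% stats::setNames(numeric(0), character(0)))
  idx <- match(names(w), transcripts$id)
  if (anyNA(idx)) stop("genes absent from transcript table: ",
                       paste(names(w)[is.na(idx)], collapse = ", "))
  lens <- nchar(transcripts$seq[idx])
  stopifnot(all(lens >= read_len))
  w <- w * lens
  empty <- data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE)
  if (depth == 0L || sum(w) == 0) {
    return(list(sample_id = sample_id, reads = empty,
                true_counts = data.frame(gene_id = character(),
                                         origin_species = character(),
                                         count = integer())))
  }
  counts <- as.integer(stats::rmultinom(1L, depth, w))
  gi <- rep.int(seq_along(w), counts)          # per-read gene slot
  starts <- floor(stats::runif(depth) * (lens[gi] - read_len + 1L))  # 0-based
  strands <- ifelse(stats::runif(depth) < 0.5, "+", "-")
  seqs <- substr(rep(transcripts$seq[idx], counts), starts + 1L,
                 starts + read_len)
  rc <- strands == "-"
  seqs[rc] <- revcomp(seqs[rc])
  seqs <- mutate_reads(seqs, error_rate)
  ids <- sprintf("%s:%s:%s:%d:%s:%d", sample_id,
                 rep(transcripts$species[idx], counts),
                 rep(names(w), counts), starts, strands, seq_len(depth))
  tc <- data.frame(gene_id = names(w),
                   origin_species = transcripts$species[idx],
                   count = counts, stringsAsFactors = FALSE)
  list(sample_id = sample_id,
       reads = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
       true_counts = tc[tc$count > 0L, , drop = FALSE])
}

#' Parse the origin encoded in simulated read ids
#'
#' @param ids read ids produced by [simulate_sample()].
#' @return data.frame with sample_id, origin_species, gene_id, start (0-based)
#'   and strand.
#' @export
parse_read_origin <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stop("read id(s) without origin encoding: ",
                     paste(utils::head(ids[bad], 3L), collapse = ", "))
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  data.frame(sample_id = m[, 1L], origin_species = m[, 2L], gene_id = m[, 3L],
             start = as.integer(m[, 4L]), strand = m[, 5L],
             stringsAsFactors = FALSE)
}

#' Simulate a complete reciprocal graft experiment
#'
#' Generates the two transcriptomes, per-tissue expression, mobile-gene
#' designations, and the 24 read sets (4 grafts x 2 tissues x 3 replicates),
#' plus a ground-truth manifest. Mobile "down" genes contribute reads to the
#' recipient root of the graft where their species is the scion; "up" genes
#' to the recipient scion of the reverse graft; "bidirectional" genes to
#' both. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements config, transcripts (both species),
#'   snp (per-pair diagnostic positions), expression (long table),
#'   read_sets (named list of 24 samples), manifest (list of `genes` and
#'   `counts` data.frames).
#' @export
simulate_graft_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sp <- config$species
  n <- config$n_genes

  lens <- 3L * sample(seq(config$cds_len_range[1] %/% 3L,
                          config$cds_len_range[2] %/% 3L), n, replace = TRUE)
  pairs <- lapply(lens, make_ortholog_pair, divergence = config$divergence)
  ids1 <- sprintf("%s_g%04d", sp[1], seq_len(n))
  ids2 <- sprintf("%s_g%04d", sp[2], seq_len(n))
  tr1 <- transcript_table(ids1, sp[1], vapply(pairs, `[[`, "", "donor"))
  tr2 <- transcript_table(ids2, sp[2], vapply(pairs, `[[`, "", "recipient"))
  transcripts <- rbind(tr1, tr2)
  snp <- stats::setNames(lapply(pairs, `[[`, "snp_positions"), ids1)

  # Per-species, per-tissue expression: shared gene effect, mild tissue jitter.
  tissues <- c("leaf", "root")
  expr <- list()
  for (s in sp) {
    base <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    for (t in tissues) {
      expr[[paste(s, t, sep = ".")]] <- stats::setNames(
        base * stats::rlnorm(n, 0, config$tissue_sdlog),
        if (s == sp[1]) ids1 else ids2)
    }
  }

  # Mobile designations per species (disjoint down / up / bidirectional).
  n_down <- round(config$mobile_down_frac * n)
  n_up <- round(config$mobile_up_frac * n)
  n_bid <- round(config$mobile_bidir_frac * n)
  direction <- list()
  for (s in sp) {
    ids <- if (s == sp[1]) ids1 else ids2
    lab <- rep("none", n)
    picked <- sample(ids, n_down + n_up + n_bid)
    lab[match(picked, ids)] <- rep(c("down", "up", "bidirectional"),
                                   c(n_down, n_up, n_bid))
    direction[[s]] <- stats::setNames(lab, ids)
  }

  grafts <- list(c(sp[1], sp[1]), c(sp[2], sp[2]),
                 c(sp[1], sp[2]), c(sp[2], sp[1]))
  read_sets <- list()
  counts_acc <- list()
  for (g in grafts) {
    scion <- g[1]; root <- g[2]
    for (t in tissues) {
      native_sp <- if (t == "leaf") scion else root
      foreign_sp <- if (t == "leaf") root else scion
      for (r in 1:3) {
        sid <- sprintf("%s_%s_%s_rep%d", scion, root, t, r)
        native_expr <- expr[[paste(native_sp, t, sep = ".")]]
        mc <- NULL
        if (scion != root) {
          # direction of entry into this tissue from the foreign partner
          want <- if (t == "root") c("down", "bidirectional")
                  else c("up", "bidirectional")
          mob <- names(direction[[foreign_sp]])[direction[[foreign_sp]] %in% want]
          if (length(mob)) {
            src_tissue <- if (t == "root") "leaf" else "root"
            mc <- config$mobile_transfer_frac *
              expr[[paste(foreign_sp, src_tissue, sep = ".")]][mob]
          }
        }
        smp <- simulate_sample(transcripts, native_expr, mc,
                               depth = config$depth,
                               read_len = config$read_len,
                               error_rate = config$error_rate,
                               sample_id = sid)
        smp$scion <- scion; smp$rootstock <- root
        smp$tissue <- t; smp$replicate <- r
        read_sets[[sid]] <- smp
        if (nrow(smp$true_counts)) {
          counts_acc[[sid]] <- cbind(sample_id = sid, smp$true_counts)
        }
      }
    }
  }

  genes <- data.frame(
    gene_id = c(ids1, ids2),
    species = rep(sp, each = n),
    partner_id = c(ids2, ids1),
    n_snps = rep(lengths(snp), 2L),
    snp_positions = rep(vapply(snp, paste, "", collapse = ","), 2L),
    direction = c(direction[[sp[1]]], direction[[sp[2]]]),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  list(config = config, transcripts = transcripts, snp = snp,
       expression = expr, read_sets = read_sets,
       manifest = list(genes = genes,
                       counts = do.call(rbind, c(counts_acc,
                                                 make.row.names = FALSE))))
}

#' Write a simulated experiment to disk
#'
#' Emits one FASTA per species, the CDS table, the expression table, the
#' truth manifest (two TSVs) and 24 gzipped FASTQ files named
#' `{scion}_{rootstock}_{tissue}_rep{n}.fastq.gz`.
#'
#' @param experiment result of [simulate_graft_experiment()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- experiment$config$species
  for (s in sp) {
    write_fasta(experiment$transcripts[experiment$transcripts$species == s, ],
                file.path(dir, paste0(s, ".fa")))
  }
  write_cds_table(experiment$transcripts, file.path(dir, "cds.tsv"))
  expr <- do.call(rbind, lapply(names(experiment$expression), function(k) {
    v <- experiment$expression[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(species = parts[1], tissue = parts[2],
               gene_id = names(v), expression = unname(v))
  }))
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(experiment$manifest$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(experiment$manifest$counts, file.path(dir, "truth_counts.tsv"))
  for (smp in experiment$read_sets) {
    write_fastq(smp$reads,
                file.path(dir, paste0(smp$sample_id, ".fastq.gz")))
  }
  invisible(dir)
}
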