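# Read-origin classification and mobile-gene calling.
#
# A recipient-tissue read is called donor-origin when it places well on the
# donor consensus, its best recipient placement carries at least the minimum
# number of diagnostic SNPs (or is absent), and the donor placement is
# strictly better. Candidate genes are then filtered on donor-homograft
# expression and replicate support, and the surviving sets from the two
# reciprocal grafts are partitioned into direction classes.

#' Classifier configuration
#'
#' @param self_discard_max_mm mismatch bound for the native-read discard
#'   stage (default 3).
#' @param donor_accept_max_mm mismatch bound for the donor placement
#'   (default 1).
#' @param min_diagnostic_snps minimum mismatches an accepted read must show
#'   against its best recipient placement (default 2).
#' @param require_perfect_donor_homograft_match when TRUE (default) an
#'   accepted read must match the donor consensus perfectly, mirroring the
#'   perfect-match retention against donor homograft reads.
#' @param min_fpkm donor-homograft expression floor (default 1).
#' @param min_replicates replicate support required (default 2 of 3; set 3
#'   for the stricter all-replicates rule).
#' @param min_reads_per_gene supporting reads per gene per replicate
#'   (default 2).
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(self_discard_max_mm = 3L,
                              donor_accept_max_mm = 1L,
                              min_diagnostic_snps = 2L,
                              require_perfect_donor_homograft_match = TRUE,
                              min_fpkm = 1.0,
                              min_replicates = 2L,
                              min_reads_per_gene = 2L) {
  stopifnot(min_diagnostic_snps >= 1L, min_replicates >= 1L,
            min_replicates <= 3L, min_fpkm >= 0, min_reads_per_gene >= 1L,
            donor_accept_max_mm >= 0L, self_discard_max_mm >= 0L)
  structure(list(self_discard_max_mm = as.integer(self_discard_max_mm),
                 donor_accept_max_mm = as.integer(donor_accept_max_mm),
                 min_diagnostic_snps = as.integer(min_diagnostic_snps),
                 require_perfect_donor_homograft_match =
                   isTRUE(require_perfect_donor_homograft_match),
                 min_fpkm = min_fpkm,
                 min_replicates = as.integer(min_replicates),
                 min_reads_per_gene = as.integer(min_reads_per_gene)),
            class = "classifier_config")
}

#' Classify reads by species of origin
#'
#' Each read is labelled `donor_origin`, `native`, or `ambiguous`. A read is
#' native when its best recipient placement shows fewer than
#' `min_diagnostic_snps` mismatches. It is donor-origin when its donor
#' placement is within `donor_accept_max_mm` (perfect, under the default
#' perfect-match rule), maps to a unique donor gene, its best recipient
#' placement is absent or carries at least `min_diagnostic_snps` mismatches,
#' and the donor placement is strictly better. Everything else — equal
#' evidence, multi-gene co-optimal placements, no placement — is ambiguous
#' and never counted for either species.
#'
#' @param reads data.frame with columns id, seq.
#' @param donor_index,recipient_index [build_kmer_index()] objects over the
#'   donor and recipient consensus transcriptomes.
#' @param config a [classifier_config()].
#' @return data.frame: read_id, label, donor_gene (NA unless donor_origin),
#'   donor_mm, recipient_mm (NA when unplaced).
#' @export
classify_reads <- function(reads, donor_index, recipient_index, config) {
  stopifnot(inherits(config, "classifier_config"))
  search_mm <- max(config$self_discard_max_mm, config$donor_accept_max_mm)
  don <- summarize_hits(align_reads(reads, donor_index, search_mm))
  rec <- summarize_hits(align_reads(reads, recipient_index,
                                    config$self_discard_max_mm))
  di <- match(reads$id, don$read_id)
  ri <- match(reads$id, rec$read_id)
  donor_mm <- don$best_mm[di]
  donor_gene <- don$target_id[di]
  donor_multi <- !is.na(di) & don$n_targets[di] > 1L
  rec_mm <- rec$best_mm[ri]

  donor_cap <- if (config$require_perfect_donor_homograft_match) 0L else
    config$donor_accept_max_mm
  native <- !is.na(rec_mm) & rec_mm < config$min_diagnostic_snps
  donor_ok <- !is.na(donor_mm) & donor_mm <= donor_cap & !donor_multi &
    (is.na(rec_mm) | (rec_mm >= config$min_diagnostic_snps &
                        donor_mm < rec_mm))
  label <- ifelse(native, "native",
                  ifelse(donor_ok, "donor_origin", "ambiguous"))
  data.frame(read_id = reads$id, label = label,
             donor_gene = ifelse(label == "donor_origin", donor_gene,
                                 NA_character_),
             donor_mm = donor_mm, recipient_mm = rec_mm,
             stringsAsFactors = FALSE)
}

#' Classify a single read
#'
#' @param read one read sequence.
#' @inheritParams classify_reads
#' @return one of "donor_origin", "native", "ambiguous".
#' @export
classify_read <- function(read, donor_index, recipient_index, config) {
  classify_reads(data.frame(id = "query", seq = read,
                            stringsAsFactors = FALSE),
                 donor_index, recipient_index, config)$label
}

#' Detect candidate mobile genes in one replicate
#'
#' Donor-origin reads are assigned to the donor gene of their unique best
#' hit; duplicate gene ids are collapsed to per-gene read counts; genes are
#' annotated with their donor-homograft FPKM and flagged (not silently
#' dropped) when below the expression floor, so replicate combination can
#' report the failure reason.
#'
#' @param reads recipient-tissue reads (data.frame id, seq).
#' @param donor_index,recipient_index consensus indexes as in
#'   [classify_reads()].
#' @param donor_homograft_fpkm [quantify_fpkm()] table from the donor-species
#'   homograft, matched tissue (required).
#' @param config a [classifier_config()].
#' @return data.frame: gene_id, supporting_reads, fpkm, passed_fpkm, sorted
#'   by gene_id.
#' @export
detect_mobile_per_replicate <- function(reads, donor_index, recipient_index,
                                        donor_homograft_fpkm, config) {
  if (missing(donor_homograft_fpkm) || is.null(donor_homograft_fpkm)) {
    stop("donor homograft expression table is required")
  }
  cls <- classify_reads(reads, donor_index, recipient_index, config)
  genes <- cls$donor_gene[cls$label == "donor_origin"]
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(), supporting_reads = integer(),
                      fpkm = numeric(), passed_fpkm = logical(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(genes)
  out <- data.frame(gene_id = names(tab),
                    supporting_reads = as.integer(tab),
                    stringsAsFactors = FALSE)
  fi <- match(out$gene_id, donor_homograft_fpkm$gene_id)
  if (anyNA(fi)) stop("gene(s) missing from homograft expression table: ",
                      paste(out$gene_id[is.na(fi)], collapse = ", "))
  out$fpkm <- donor_homograft_fpkm$fpkm[fi]
  out$passed_fpkm <- out$fpkm >= config$min_fpkm
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine replicate detections into mobility calls
#'
#' A replicate supports a gene when it contributes at least
#' `min_reads_per_gene` donor-origin reads; a gene passes when its
#' donor-homograft FPKM clears the floor and at least `min_replicates`
#' replicates support it. Failure reasons are ordered: `low_fpkm`, then
#' `low_replicates` (seen in too few replicates at all), then `low_reads`
#' (seen widely but with too few reads where it counts).
#'
#' @param replicate_lists list of exactly 3 [detect_mobile_per_replicate()]
#'   results.
#' @param config a [classifier_config()].
#' @return data.frame: gene_id, reads_rep1..3, replicate_support, n_support,
#'   fpkm, passed_filters, fail_reason.
#' @export
combine_replicates <- function(replicate_lists, config) {
  stopifnot(length(replicate_lists) == 3L)
  genes <- sort(unique(unlist(lapply(replicate_lists, `[[`, "gene_id"))))
  if (length(genes) == 0L) {
    return(data.frame(gene_id = character(), reads_rep1 = integer(),
                      reads_rep2 = integer(), reads_rep3 = integer(),
                      replicate_support = character(), n_support = integer(),
                      fpkm = numeric(), passed_filters = logical(),
                      fail_reason = character(), stringsAsFactors = FALSE))
  }
  reads <- sapply(replicate_lists, function(df) {
    v <- df$supporting_reads[match(genes, df$gene_id)]
    ifelse(is.na(v), 0L, v)
  })
  reads <- matrix(reads, nrow = length(genes))
  fpkm_mat <- matrix(sapply(replicate_lists, function(df) {
    df$fpkm[match(genes, df$gene_id)]
  }), nrow = length(genes))
  fpkm <- apply(fpkm_mat, 1L, function(x) x[!is.na(x)][1L])
  support <- reads >= config$min_reads_per_gene
  n_support <- rowSums(support)
  seen <- rowSums(reads > 0L)
  passed_fpkm <- fpkm >= config$min_fpkm
  passed <- passed_fpkm & n_support >= config$min_replicates
  fail <- rep("none", length(genes))
  fail[!passed & !passed_fpkm] <- "low_fpkm"
  fail[!passed & passed_fpkm & seen < config$min_replicates] <- "low_replicates"
  fail[!passed & passed_fpkm & seen >= config$min_replicates] <- "low_reads"
  data.frame(gene_id = genes,
             reads_rep1 = reads[, 1L], reads_rep2 = reads[, 2L],
             reads_rep3 = reads[, 3L],
             replicate_support = apply(support, 1L, function(s)
               paste(which(s), collapse = ",")),
             n_support = n_support, fpkm = fpkm,
             passed_filters = passed, fail_reason = fail,
             stringsAsFactors = FALSE)
}

#' Final mobile gene set from mobility calls
#' @param calls a [combine_replicates()] result.
#' @return character vector of passing gene ids.
#' @export
mobile_set <- function(calls) calls$gene_id[calls$passed_filters]

format_pct <- function(x) {
  # print style of the direction tables: two decimals below 1%, one above
  ifelse(x < 1, round(x, 2L), round(x, 1L))
}

#' Partition one species' mobile genes into direction classes
#'
#' `down` is the final mobile set seen in the recipient rootstock of the
#' graft where the species is scion; `up` the set seen in the recipient
#' scion of the reverse graft. Scion-to-rootstock movers are `down \ up`,
#' rootstock-to-scion movers `up \ down`, bidirectional the intersection;
#' percentages are over the union.
#'
#' @param down_set,up_set character vectors of final (replicate-combined,
#'   filter-passed) gene ids.
#' @param species species tag for labelling.
#' @return data.frame of class `direction_table`: species, class, n, pct
#'   (printed rounding), plus a `genes` attribute with the three sets.
#' @export
classify_direction <- function(down_set, up_set, species = NA_character_) {
  down_set <- unique(down_set); up_set <- unique(up_set)
  s2r <- setdiff(down_set, up_set)
  r2s <- setdiff(up_set, down_set)
  bidir <- intersect(down_set, up_set)
  total <- length(union(down_set, up_set))
  n <- c(length(s2r), length(r2s), length(bidir))
  pct <- if (total > 0L) format_pct(100 * n / total) else rep(NA_real_, 3L)
  out <- data.frame(species = species,
                    class = c("scion_to_rootstock", "rootstock_to_scion",
                              "bidirectional"),
                    n = n, total = total, pct = pct,
                    stringsAsFactors = FALSE)
  attr(out, "genes") <- list(scion_to_rootstock = sort(s2r),
                             rootstock_to_scion = sort(r2s),
                             bidirectional = sort(bidir))
  class(out) <- c("direction_table", class(out))
  out
}
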