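#!/usr/bin/env Rscript
# Stage 6 — orthology and cross-catalog summaries.
#
# Translates the demo ortholog pairs, recovers them by reciprocal best hits
# on local protein alignment, collapses duplicate partners, counts overlaps
# between the detected per-direction gene sets, and emits the four-parameter
# table used for cross-study ordination.

suppressPackageStartupMessages(library(graftmobile))
dir.create("results/orthology", showWarnings = FALSE, recursive = TRUE)

cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "graftmobile"))
run <- run_graft_pipeline(cfg$simulation, cfg$classifier)
exp1 <- run$experiment
sp <- cfg$simulation$species

# RBH on a 60-pair subset keeps the all-vs-all protein comparison quick
tr1 <- exp1$transcripts[exp1$transcripts$species == sp[1], ][1:60, ]
tr2 <- exp1$transcripts[exp1$transcripts$species == sp[2], ][1:60, ]
rbh <- reciprocal_best_hits(translate_cds(tr1), translate_cds(tr2))
truth <- sub(sp[1], sp[2], tr1$id)
correct <- sum(rbh$gene_b[match(tr1$id, rbh$gene_a)] == truth, na.rm = TRUE)
cat(sprintf("RBH: %d pairs reported, %d/%d true pairs recovered\n",
            nrow(rbh), correct, nrow(tr1)))
write_tsv(rbh, "results/orthology/rbh_pairs.tsv")

dedup <- collapse_duplicates(rbh)
cat(sprintf("duplicate filtering: %d pairs -> %d distinct partners (%d removed)\n",
            dedup$n_input, dedup$n_distinct, dedup$n_removed))

# overlap of the final mobile sets across species, mapped through orthology
sets <- lapply(sp, function(s) {
  r <- run$results[[s]]
  union(mobile_set(r$calls_down), mobile_set(r$calls_up))
})
names(sets) <- sp
# compare on pair index so the two species' catalogs share a namespace
strip <- function(x) sub("^[A-Za-z]+_", "", x)
venn <- overlap_counts(lapply(sets, strip))
write_tsv(venn, "results/orthology/mobile_overlap.tsv")
cat("mobile-set overlap across species (by ortholog pair):\n")
print(venn, row.names = FALSE)

# four-parameter ordination input, one row per species
g <- exp1$manifest$genes
pca_rows <- do.call(rbind, lapply(sp, function(s) {
  tr <- exp1$transcripts[exp1$transcripts$species == s, ]
  len <- setNames(nchar(tr$seq), tr$id)
  mob <- sets[[s]]
  summary_params(len[mob], len[setdiff(tr$id, mob)], system = s)
}))
write_tsv(pca_rows, "results/orthology/pca_input.tsv")
print(pca_rows, row.names = FALSE)
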