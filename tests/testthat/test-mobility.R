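# Builds a controlled two-gene scenario: donor and recipient homologs with
# SNPs planted at known positions, so read windows with 0, 1, or >= 2
# diagnostic SNPs can be cut deliberately.
make_homolog_fixture <- function(seed = 90) {
  set.seed(seed)
  don <- random_transcripts(1, len = 600L, species = "Csa", prefix = "don",
                            seed = seed)
  rec <- don
  rec$id <- "rec001"; rec$species <- "Cmo"
  b <- strsplit(don$seq, "")[[1]]
  snp_pos <- c(100L, 140L, 160L, 400L)  # 0-based
  b[snp_pos + 1L] <- vapply(b[snp_pos + 1L], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  rec$seq <- paste(b, collapse = "")
  list(donor = don, recipient = rec, snp_pos = snp_pos,
       don_idx = build_kmer_index(don, k = 25L),
       rec_idx = build_kmer_index(rec, k = 25L))
}

test_that("read-origin classification follows the diagnostic-SNP conditions", {
  fx <- make_homolog_fixture()
  cfg <- classifier_config()
  # window [60, 210) spans 3 SNPs: perfect donor read -> donor origin
  r3 <- substr(fx$donor$seq, 61, 210)
  expect_equal(classify_read(r3, fx$don_idx, fx$rec_idx, cfg), "donor_origin")
  # a recipient read from the same window is native to the recipient index
  expect_equal(classify_read(substr(fx$recipient$seq, 61, 210),
                             fx$rec_idx, fx$don_idx, cfg), "donor_origin")
  expect_equal(classify_read(substr(fx$recipient$seq, 61, 210),
                             fx$don_idx, fx$rec_idx, cfg), "native")
  # window [350, 500) has exactly 1 SNP: ambiguous at the default threshold,
  # donor origin when a single diagnostic SNP is allowed
  r1 <- substr(fx$donor$seq, 351, 500)
  expect_equal(classify_read(r1, fx$don_idx, fx$rec_idx, cfg), "native")
  cfg1 <- classifier_config(min_diagnostic_snps = 1L)
  expect_equal(classify_read(r1, fx$don_idx, fx$rec_idx, cfg1),
               "donor_origin")
  # a window with no SNPs matches both perfectly: native (blind spot)
  r0 <- substr(fx$donor$seq, 421, 570)
  expect_equal(classify_read(r0, fx$don_idx, fx$rec_idx, cfg), "native")
})

test_that("errored donor reads fail the perfect-match rule unless relaxed", {
  fx <- make_homolog_fixture(91)
  cfg <- classifier_config()
  r <- substr(fx$donor$seq, 61, 210)
  substr(r, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                               substr(r, 75, 75))[1]
  expect_equal(classify_read(r, fx$don_idx, fx$rec_idx, cfg), "ambiguous")
  relaxed <- classifier_config(require_perfect_donor_homograft_match = FALSE)
  expect_equal(classify_read(r, fx$don_idx, fx$rec_idx, relaxed),
               "donor_origin")
})

test_that("zero-divergence homolog pairs never yield donor-origin calls", {
  set.seed(92)
  don <- random_transcripts(3, len = 450L, species = "Csa", prefix = "don",
                            seed = 92)
  rec <- don; rec$id <- sub("don", "rec", rec$id); rec$species <- "Cmo"
  di <- build_kmer_index(don, k = 25L); ri <- build_kmer_index(rec, k = 25L)
  smp <- simulate_sample(don, stats::setNames(rep(1, 3), don$id), NULL,
                         depth = 60L, read_len = 150L, error_rate = 0)
  cls <- classify_reads(smp$reads, di, ri, classifier_config())
  expect_true(all(cls$label == "native"))
})

test_that("per-replicate detection applies the expression floor", {
  fx <- make_homolog_fixture(93)
  cfg <- classifier_config()
  reads <- data.frame(id = c("a", "b"),
                      seq = rep(substr(fx$donor$seq, 61, 210), 2),
                      stringsAsFactors = FALSE)
  fpkm_hi <- data.frame(gene_id = "don001", fpkm = 12, stringsAsFactors = FALSE)
  det <- detect_mobile_per_replicate(reads, fx$don_idx, fx$rec_idx,
                                     fpkm_hi, cfg)
  expect_equal(det$gene_id, "don001")
  expect_equal(det$supporting_reads, 2L)
  expect_true(det$passed_fpkm)

  fpkm_lo <- data.frame(gene_id = "don001", fpkm = 0.5,
                        stringsAsFactors = FALSE)
  det_lo <- detect_mobile_per_replicate(reads, fx$don_idx, fx$rec_idx,
                                        fpkm_lo, cfg)
  expect_false(det_lo$passed_fpkm)
  calls <- combine_replicates(list(det_lo, det_lo, det_lo), cfg)
  expect_false(calls$passed_filters)
  expect_equal(calls$fail_reason, "low_fpkm")

  expect_error(detect_mobile_per_replicate(reads, fx$don_idx, fx$rec_idx,
                                           NULL, cfg), "required")
})

test_that("replicate combination implements both published support rules", {
  cfg <- classifier_config()  # 2 of 3
  det <- function(n) data.frame(gene_id = "g", supporting_reads = n,
                                fpkm = 10, passed_fpkm = TRUE,
                                stringsAsFactors = FALSE)
  none <- det(0)[0, ]
  # seen in replicates 1 and 2 -> passes the 2-of-3 rule
  calls <- combine_replicates(list(det(3), det(2), none), cfg)
  expect_true(calls$passed_filters)
  expect_equal(calls$replicate_support, "1,2")
  # replicate 3 only -> fails with low_replicates
  calls <- combine_replicates(list(none, none, det(5)), cfg)
  expect_false(calls$passed_filters)
  expect_equal(calls$fail_reason, "low_replicates")
  # the stricter all-three rule rejects a 2-of-3 gene
  cfg3 <- classifier_config(min_replicates = 3L)
  calls <- combine_replicates(list(det(3), det(2), none), cfg3)
  expect_false(calls$passed_filters)
  # seen everywhere but with single reads -> low_reads
  calls <- combine_replicates(list(det(1), det(1), det(1)), cfg)
  expect_false(calls$passed_filters)
  expect_equal(calls$fail_reason, "low_reads")
})

test_that("direction classes partition the union with printed rounding", {
  d <- classify_direction(c("g1", "g2", "g3"), "g3")
  expect_equal(d$n, c(2L, 0L, 1L))
  expect_equal(d$pct, c(66.7, 0.0, 33.3))
  g <- attr(d, "genes")
  expect_equal(g$scion_to_rootstock, c("g1", "g2"))
  expect_equal(g$bidirectional, "g3")
  expect_equal(sum(d$n), d$total[1])
})

test_that("published class counts reproduce the printed percentages", {
  # first species: 3585 down-only, 39 up-only, 299 bidirectional
  down <- sprintf("d%04d", 1:(3585 + 299))
  up <- c(sprintf("u%04d", 1:39), down[1:299])
  d <- classify_direction(down, up, species = "Csa")
  expect_equal(d$total[1], 3923L)
  expect_equal(d$pct, c(91.4, 0.99, 7.6))
  # second species: 1064 down-only, 192 up-only out of 1788
  down2 <- sprintf("d%04d", 1:(1064 + 532))
  up2 <- c(sprintf("u%04d", 1:192), down2[1:532])
  d2 <- classify_direction(down2, up2, species = "Cmo")
  expect_equal(d2$total[1], 1788L)
  expect_equal(d2$pct[1:2], c(59.5, 10.7))
})

test_that("tightening any threshold never enlarges the final mobile set", {
  run <- run_graft_pipeline(small_config(seed = 94), classifier_config())
  base_sets <- lapply(run$results, function(r)
    union(mobile_set(r$calls_down), mobile_set(r$calls_up)))
  tighter <- list(classifier_config(min_diagnostic_snps = 3L),
                  classifier_config(min_fpkm = 50),
                  classifier_config(min_replicates = 3L),
                  classifier_config(min_reads_per_gene = 3L))
  for (cfg in tighter) {
    run2 <- run_graft_pipeline(small_config(seed = 94), cfg,
                               experiment = run$experiment)
    for (s in names(base_sets)) {
      s2 <- union(mobile_set(run2$results[[s]]$calls_down),
                  mobile_set(run2$results[[s]]$calls_up))
      expect_true(all(s2 %in% base_sets[[s]]))
    }
  }
})
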