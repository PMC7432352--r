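test_that("local alignment score matches self-alignment and non-negativity", {
  set.seed(100)
  b62 <- blosum62()
  s <- random_protein(40)
  diag_sum <- sum(b62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(local_protein_score(s, s), diag_sum)
  # disjoint residue alphabets still score >= 0 by the local definition
  expect_gte(local_protein_score(strrep("A", 15), strrep("W", 15)), 0)
  expect_error(local_protein_score("ACGT*", "ACGT"), "invalid")
})

test_that("compiled scorer equals a textbook quadratic implementation", {
  set.seed(101)
  b62 <- blosum62()
  for (i in 1:10) {
    a <- random_protein(60)
    b <- random_protein(60)
    expect_equal(local_protein_score(a, b), naive_sw(a, b, b62))
    expect_equal(local_protein_score(a, b), local_protein_score(b, a))
  }
  # and on related sequences, where gaps actually enter the optimum
  for (i in 1:5) {
    a <- random_protein(50)
    b <- paste0(substr(a, 1, 20), random_protein(4), substr(a, 26, 50))
    expect_equal(local_protein_score(a, b), naive_sw(a, b, b62))
  }
})

test_that("compiled scorer agrees with an independent aligner", {
  set.seed(102)
  b62 <- blosum62()
  for (i in 1:10) {
    a <- random_protein(60)
    b <- paste0(substr(a, 1, 30), random_protein(25))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(local_protein_score(a, b), ref)
  }
})

test_that("reciprocal best hits pair identical sets and reject asymmetry", {
  set.seed(103)
  prots <- stats::setNames(vapply(1:5, function(i) random_protein(50),
                                  character(1)), sprintf("p%d", 1:5))
  rbh <- reciprocal_best_hits(prots, stats::setNames(prots, paste0("q", 1:5)))
  expect_equal(nrow(rbh), 5L)
  expect_equal(sub("q", "p", rbh$gene_b), rbh$gene_a)

  # a1's best is b1, but b1's best is a2: (a1, b1) must not be reported
  a2 <- random_protein(60)
  a1 <- paste0(substr(a2, 1, 40), random_protein(20))
  b1 <- a2
  rbh2 <- reciprocal_best_hits(c(a1 = a1, a2 = a2), c(b1 = b1),
                               min_score = 10)
  expect_equal(rbh2$gene_a, "a2")
})

test_that("RBH recovers translated synthetic ortholog pairs", {
  set.seed(104)
  cfg <- sim_config(n_genes = 30L, cds_len_range = c(300L, 600L),
                    divergence = 0.02, depth = 0L, error_rate = 0,
                    seed = 104L)
  ex <- simulate_graft_experiment(cfg)
  sp1 <- ex$transcripts[ex$transcripts$species == "Csa", ]
  sp2 <- ex$transcripts[ex$transcripts$species == "Cmo", ]
  rbh <- reciprocal_best_hits(translate_cds(sp1), translate_cds(sp2))
  truth <- sub("Csa", "Cmo", sp1$id)
  hit <- rbh$gene_b[match(sp1$id, rbh$gene_a)]
  expect_gte(mean(hit == truth, na.rm = TRUE) *
               mean(!is.na(hit)), 0.99)
})

test_that("duplicate collapsing keeps one entry per partner", {
  pairs <- data.frame(gene_a = c("m1", "m2", "m3"),
                      gene_b = c("h1", "h1", "h2"), stringsAsFactors = FALSE)
  out <- collapse_duplicates(pairs)
  expect_equal(sort(out$partners), c("h1", "h2"))
  expect_equal(out$n_removed, 1L)
  inj <- data.frame(gene_a = c("m1", "m2"), gene_b = c("h1", "h2"),
                    stringsAsFactors = FALSE)
  expect_equal(collapse_duplicates(inj)$n_removed, 0L)
  set.seed(105)
  for (i in 1:20) {
    p <- data.frame(gene_a = sample(letters, 15, TRUE),
                    gene_b = sample(LETTERS[1:8], 15, TRUE))
    expect_lte(collapse_duplicates(p)$n_distinct, nrow(p))
  }
})

test_that("overlap counts cover the Venn partition and sum to the union", {
  v <- overlap_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(v$count[v$region == "A&B"], 2L)
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)

  disj <- overlap_counts(list(A = c("a"), B = c("b")))
  expect_false("A&B" %in% disj$region)

  set.seed(106)
  for (i in 1:20) {
    sets <- lapply(1:sample(2:6, 1), function(j)
      sample(letters, sample(3:15, 1)))
    names(sets) <- paste0("S", seq_along(sets))
    v <- overlap_counts(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
  }
  expect_error(overlap_counts(rep(list(letters), 7)), "2 to 6")
})

test_that("concordance rate reproduces its closed form", {
  expect_equal(concordance_rate(63, 80), 78.75)
  expect_equal(concordance_rate(0, 80), 0)
  expect_equal(concordance_rate(80, 80), 100)
  expect_error(concordance_rate(1, 0), "positive")
})

test_that("delta-delta-Ct relative quantities follow the definition", {
  expect_equal(ddct_relative_quantity(20, 15, 22, 15), 4)
  expect_equal(ddct_relative_quantity(20, 15, 20, 15), 1)
  # one-cycle decrease in target Ct doubles the quantity
  expect_equal(ddct_relative_quantity(19, 15, 22, 15),
               2 * ddct_relative_quantity(20, 15, 22, 15))
  # invariant to a constant shift of all four Ct values
  expect_equal(ddct_relative_quantity(21.5, 16.5, 23.5, 16.5),
               ddct_relative_quantity(20, 15, 22, 15))
})

test_that("ordination summary percentages always sum to 100", {
  s <- summary_params(rep(1000, 10), rep(1500, 90))
  expect_equal(s$pct_mobile, 10)
  expect_equal(s$pct_nonmobile, 90)
  expect_equal(summary_params(c(900, 1100), 1:5)$mean_cds_len_mobile, 1000)
  set.seed(107)
  for (i in 1:20) {
    s <- summary_params(runif(sample(1:50, 1), 500, 2000),
                        runif(sample(1:50, 1), 500, 2000))
    expect_equal(s$pct_mobile + s$pct_nonmobile, 100)
  }
  expect_error(summary_params(numeric(0), numeric(0)), "at least one")
})
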