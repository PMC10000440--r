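# Smith-Waterman aligner, homology screen and the positive-vs-random
# evaluation.

test_that("alignment handles self, near-identity and no-hit cases", {
  self <- local_align("KTDAQAISL", "KTDAQAISL")
  expect_equal(self$percent_identity, 100)
  expect_equal(self$n_identical, 9L)
  near <- local_align("AAAAAAAAA", "AAAAAAAAT")
  expect_equal(near$n_identical, 8L)
  expect_equal(near$alignment_length, 9L)
  expect_equal(round(near$percent_identity, 1), 88.9)
  none <- local_align("AAAA", "WWWW")
  expect_equal(none$score, 0)
  expect_equal(none$percent_identity, 0)
  expect_error(local_align("AB*C", "AAAA"), "alphabet")
})

test_that("aligner agrees with the reference DP on random peptide pairs", {
  set.seed(41)
  for (i in 1:60) {
    q <- random_peptide(sample(3:11, 1L))
    t <- random_peptide(sample(3:11, 1L))
    got <- local_align(q, t)
    ref <- sw_ref(q, t)
    expect_equal(got$score, ref$score)
    expect_equal(got$n_identical, ref$n_identical)
    # score symmetry under argument swap
    expect_equal(local_align(t, q)$score, got$score)
  }
})

test_that("aligner score matches Biostrings pairwiseAlignment", {
  B <- noncneo:::.blosum62()
  set.seed(43)
  for (i in 1:40) {
    q <- random_peptide(sample(4:11, 1L))
    t <- random_peptide(sample(4:11, 1L))
    ours <- local_align(q, t)$score
    theirs <- Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = B,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, max(0, theirs))
  }
})

test_that("non-aligning flanks do not change the reported identity", {
  q <- "KTDAQHISL"          # no W anywhere
  t0 <- "KTDAQAISL"
  a0 <- local_align(q, t0)
  a1 <- local_align(q, paste0("WW", t0, "WW"))
  expect_equal(a1$percent_identity, a0$percent_identity)
  expect_equal(a1$score, a0$score)
})

cand_df <- function(kmers) {
  data.frame(kmer = kmers, allele = "HLA-A*02:01",
             percentile_rank = seq(0.1, by = 0.1, length.out = length(kmers)),
             sample_id = "S1", stringsAsFactors = FALSE)
}

test_that("high confidence requires strictly more than 60% identity", {
  refset <- c("KTDAQAISL")
  # interspersed mismatches: the optimal local alignment is full-length
  # with 5/9 = 55.6% identity
  hits5 <- screen_candidates(cand_df("KWDWQWIWL"), refset)
  expect_equal(round(hits5$percent_identity, 1), 55.6)
  expect_false(hits5$high_confidence)
  hits7 <- screen_candidates(cand_df("KTDAQAHHH"), refset)   # 6/9 = 66.7%
  expect_true(hits7$high_confidence)
  exact <- screen_candidates(cand_df("KTDAQAISL"), refset)
  expect_true(exact$high_confidence)
  expect_equal(exact$percent_identity, 100)
  expect_error(screen_candidates(cand_df("KTDAQAISL"), character(0)),
               "reference")
})

test_that("screening is monotone in the identity threshold", {
  set.seed(44)
  refset <- vapply(1:5, function(i) random_peptide(9L), character(1))
  cands <- cand_df(vapply(1:8, function(i) random_peptide(9L), character(1)))
  s0 <- screen_candidates(cands, refset, identity_threshold = 0)
  s60 <- screen_candidates(cands, refset, identity_threshold = 60)
  s100 <- screen_candidates(cands, refset, identity_threshold = 100)
  expect_true(all(s100$kmer[s100$high_confidence] %in%
                    s60$kmer[s60$high_confidence]))
  expect_true(all(s60$kmer[s60$high_confidence] %in%
                    s0$kmer[s0$high_confidence]))
  # thresholds act strictly on the best-hit identity
  expect_equal(s0$high_confidence, s0$percent_identity > 0)
  expect_equal(s100$high_confidence, s100$percent_identity > 100)
})

test_that("BLAST tabular hits drive the screen with the E-value rule", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("PEPA\tref1\t77.8\t9\t2\t0\t1\t9\t1\t9\t0.01\t25.1",
               "PEPB\tref2\t77.8\t9\t2\t0\t1\t9\t1\t9\t0.9\t12.0",
               "PEPC\tref3\t55.6\t9\t4\t0\t1\t9\t1\t9\t0.01\t15.0"), f)
  hits <- parse_blast_outfmt6(f)
  expect_equal(names(hits)[c(1, 3, 11)], c("qseqid", "pident", "evalue"))
  cands <- cand_df(c("PEPA", "PEPB", "PEPC"))
  got <- screen_candidates(cands, "KTDAQAISL", blast_hits = hits)
  hc <- got$high_confidence[match(c("PEPA", "PEPB", "PEPC"), got$kmer)]
  expect_equal(hc, c(TRUE, FALSE, FALSE))   # identity and E-value both needed
})

test_that("the rank-sum test is exact for small tie-free groups", {
  expect_equal(similarity_wilcoxon(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(similarity_wilcoxon(c(1, 2, 3), c(1, 2, 3))$p.value, 1.0)
  # complete separation at n = 4 gives the minimal attainable exact p
  expect_equal(similarity_wilcoxon(1:4, 5:8)$p.value, 2 / choose(8, 4))
  expect_error(similarity_wilcoxon(numeric(0), 1), "at least one")
})

test_that("positive-vs-random evaluation summarizes per-sample proportions", {
  refpos <- "KTDAQAISL"
  refrnd <- "WWWWWWWWW"
  cands <- data.frame(
    kmer = c("KTDAQAISL", "KTDAQAHHH", "HHHHHHHHH",
             "KTDAQAISL", "HHHHHHHHH"),
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    stringsAsFactors = FALSE)
  ev <- evaluate_positive_vs_random(cands, refpos, refrnd)
  expect_equal(sort(ev$proportions$sample_id), c("s1", "s2"))
  expect_equal(ev$proportions$prop_positive[ev$proportions$sample_id == "s1"],
               2 / 3)
  expect_equal(ev$proportions$prop_random, c(0, 0))
  expect_true(ev$p.value > 0 && ev$p.value <= 1)
})
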