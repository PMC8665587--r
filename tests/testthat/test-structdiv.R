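test_that("local alignment finds exact substrings and matches the DP oracle", {
  set.seed(5)
  g <- random_dna(500)
  ex <- substr(g, 101, 180)
  al <- align_exon_to_gene(ex, g)
  expect_equal(al$start, 101)
  expect_equal(al$end, 180)
  expect_equal(al$identity, 1)
  expect_error(align_exon_to_gene("ACQT", g), "non-ACGTN")

  for (i in 1:12) {
    a <- random_dna(sample(40:100, 1))
    b <- paste0(random_dna(40), mutate_dna(a, 0.1), random_dna(40))
    al <- align_exon_to_gene(a, b)
    expect_equal(al$score, oracle_sw_score(a, b))
  }
})

test_that("identical genes give the identity exon correspondence", {
  pr <- sim_paralog_pair("NONE", mutation_rate = 0, seed = 11)
  corr <- build_correspondence(pr$A, pr$B)
  expect_equal(corr$AtoB$hit_exons, as.character(seq_len(nrow(corr$AtoB))))
  expect_true(all(corr$AtoB$assignment == "exon"))
  dv <- classify_pair(corr, pr$A, pr$B)
  expect_equal(dv$primary, "NONE")
  expect_equal(nrow(dv$events), 0L)
})

test_that("each planted mechanism is recovered as the primary call", {
  mechs <- c("EXON_INTRON_GAIN_LOSS", "INTRON_ELONGATION", "EXONIZATION",
             "BOUNDARY_SHIFT", "EXON_SPLIT")
  for (m in mechs) {
    ok <- 0
    for (r in 1:5) {
      pr <- sim_paralog_pair(m, seed = 9000 + 10 * match(m, mechs) + r)
      dv <- classify_pair(build_correspondence(pr$A, pr$B), pr$A, pr$B)
      ok <- ok + (dv$primary == classifier_label(m))
    }
    expect_gte(ok, 4)
  }
})

test_that("an intron elongated 64 -> ~900 bp is called with its ratio", {
  pr <- sim_paralog_pair("INTRON_ELONGATION", intron_len = c(64, 64),
                         elongation_factor = 14, seed = 64)
  dv <- classify_pair(build_correspondence(pr$A, pr$B), pr$A, pr$B)
  expect_equal(dv$primary, "INTRON_ELONGATION")
  ev <- dv$events[dv$events$mechanism == "INTRON_ELONGATION", ]
  expect_gte(nrow(ev), 1)
  # the report carries both homologous intron lengths
  rep_ <- pair_report(dv, pr$A, pr$B)
  ia <- rep_$lengths_A$intron[pr$truth$intron_A]
  ib <- rep_$lengths_B$intron[pr$truth$intron_A]
  expect_equal(ia, 64L)
  expect_gt(ib / ia, 2)
  expect_true(grepl(sprintf("%d vs %d", min(ia, ib), max(ia, ib)),
                    ev$detail[1]) ||
              grepl(sprintf("%d vs %d", max(ia, ib), min(ia, ib)),
                    ev$detail[1]))
})

test_that("classification is symmetric in the pair", {
  for (m in c("EXON_INTRON_GAIN_LOSS", "INTRON_ELONGATION", "EXON_SPLIT")) {
    pr <- sim_paralog_pair(m, seed = 300 + nchar(m))
    d1 <- classify_pair(build_correspondence(pr$A, pr$B), pr$A, pr$B)
    d2 <- classify_pair(build_correspondence(pr$B, pr$A), pr$B, pr$A)
    expect_equal(sort(d1$events$mechanism), sort(d2$events$mechanism))
    expect_equal(d1$primary, d2$primary)
  }
})

test_that("pair reports tally every emitted event", {
  pr <- sim_paralog_pair("EXON_SPLIT", seed = 41)
  dv <- classify_pair(build_correspondence(pr$A, pr$B), pr$A, pr$B)
  rp <- pair_report(dv, pr$A, pr$B)
  expect_equal(sum(rp$mechanism_tally), nrow(dv$events))
  pr0 <- sim_paralog_pair("NONE", seed = 42)
  dv0 <- classify_pair(build_correspondence(pr0$A, pr0$B), pr0$A, pr0$B)
  rp0 <- pair_report(dv0, pr0$A, pr0$B)
  expect_true(all(rp0$mechanism_tally == 0))
})
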