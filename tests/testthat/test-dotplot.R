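test_that("a duplicated block produces an off-diagonal run at its offset", {
  set.seed(8)
  x <- random_dna(100)
  seq <- paste0(x, x)
  dm <- self_dot_matrix(seq)
  m <- dm$matches
  expect_true(all(m$j - m$i == 100))
  expect_equal(min(m$i), 1)
  expect_equal(max(m$j) + dm$window - 1, 200)
  expect_error(self_dot_matrix("ACGT", window = 30), "shorter")
})

test_that("match sets equal the naive double-loop oracle", {
  set.seed(9)
  rp <- sim_repeat_sequence(40, 4, 80, 0.05, seed = 21)
  for (seq in list(rp$seq, random_dna(300))) {
    dm <- self_dot_matrix(seq)
    o <- oracle_dot_matches(seq)
    expect_equal(nrow(dm$matches), nrow(o))
    if (nrow(o)) {
      expect_equal(dm$matches$i[order(dm$matches$i, dm$matches$j)],
                   o[order(o[, "i"], o[, "j"]), "i"])
      expect_equal(dm$matches$j[order(dm$matches$i, dm$matches$j)],
                   o[order(o[, "i"], o[, "j"]), "j"])
    }
  }
})

test_that("planted tandem repeats are called with the right unit and span", {
  rp <- sim_repeat_sequence(50, 6, 500, 0.02, seed = 5)
  cr <- call_repeats(self_dot_matrix(rp$seq))
  expect_equal(nrow(cr), 1L)
  expect_lte(abs(cr$unit_length - 50), 2)
  ov <- min(cr$end, rp$truth$end) - max(cr$start, rp$truth$start) + 1
  expect_gte(ov / (rp$truth$end - rp$truth$start + 1), 0.9)

  empty <- call_repeats(self_dot_matrix(random_dna(200)))
  expect_equal(nrow(empty), 0L)
})

test_that("two separated repeat regions yield two ordered calls", {
  r1 <- sim_repeat_sequence(40, 5, 300, 0.02, seed = 61)
  r2 <- sim_repeat_sequence(60, 5, 300, 0.02, seed = 62)
  seq <- paste0(r1$seq, r2$seq)
  cr <- call_repeats(self_dot_matrix(seq))
  expect_equal(nrow(cr), 2L)
  expect_true(cr$start[1] < cr$start[2])
  expect_lte(abs(cr$unit_length[1] - 40), 2)
  expect_lte(abs(cr$unit_length[2] - 60), 2)
})

test_that("intron annotation localizes the repeat to the elongated intron", {
  pr <- sim_paralog_pair("INTRON_ELONGATION", seed = 77)
  gm <- pr$B
  # the B-side intron index equals the A-side one (structure is preserved)
  tgt <- pr$truth$intron_A
  dm <- self_dot_matrix(gm$genomic_seq)
  cr <- call_repeats(dm)
  ann <- annotate_introns(gm, cr)
  expect_true(all(ann$repeat_bp <= ann$length))
  expect_gte(ann$repeat_fraction[tgt], 0.5)
  expect_true(all(ann$repeat_fraction[-tgt] < 0.5))

  none <- annotate_introns(pr$A, call_repeats(self_dot_matrix(pr$A$genomic_seq)))
  expect_true(all(none$repeat_bp == 0))
})
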