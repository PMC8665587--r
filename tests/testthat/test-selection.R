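test_that("codon site counts match enumeration of single-base mutants", {
  expect_equal(unname(codon_sites("CCC")), c(1, 2))
  expect_equal(unname(codon_sites("ATG")), c(0, 3))
  expect_equal(unname(codon_sites("TTT")), c(1 / 3, 8 / 3), tolerance = 1e-12)
  # every sense codon contributes exactly 3 sites, and agrees with the oracle
  sense <- names(CODE)[CODE != "*"]
  for (cd in sense) {
    got <- codon_sites(cd)
    expect_equal(sum(got), 3)
    expect_equal(unname(got), oracle_codon_sites(cd), tolerance = 1e-12)
  }
  expect_error(codon_sites("TAA"), "stop")
  expect_error(codon_sites("AXG"))
})

test_that("codon differences average over mutational pathways", {
  expect_equal(unname(codon_differences("AAA", "AAA")[1:2]), c(0, 0))
  expect_equal(unname(codon_differences("GTT", "GTA")[1:2]), c(1, 0))
  # two differences: path via GTT (nonsyn+syn) and via TTA (nonsyn+nonsyn)
  expect_equal(unname(codon_differences("TTT", "GTA")[1:2]), c(0.5, 1.5))
  # random codon pairs vs oracle
  set.seed(42)
  sense <- names(CODE)[CODE != "*"]
  for (i in 1:50) {
    ab <- sample(sense, 2)
    expect_equal(unname(codon_differences(ab[1], ab[2])[1:2]),
                 oracle_codon_diffs(ab[1], ab[2]), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction matches the closed form and its domain", {
  expect_identical(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.5), 0.8239592, tolerance = 1e-6)
  expect_true(jukes_cantor(0.1) >= 0.1)  # d >= p
  expect_error(jukes_cantor(0.75), "saturation")
  expect_error(jukes_cantor(-0.1))
})

test_that("pairwise dN/dS reproduces the hand-checked single-difference case", {
  a <- strrep("TTT", 9)
  b <- paste0("TTC", strrep("TTT", 8))
  r <- pairwise_dnds(a, b)
  expect_equal(r$S, 3)
  expect_equal(r$N, 24)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 1 / 3, tolerance = 1e-12)
  expect_equal(r$dS, 0.4408, tolerance = 1e-4)
  expect_equal(r$dN, 0)
  expect_true(is.na(pairwise_dnds(a, a)$omega))
  expect_error(pairwise_dnds("TTTA", "TTTA"), "multiple of 3")
})

test_that("full-sequence dN/dS equals the brute-force oracle on random pairs", {
  set.seed(7)
  for (i in 1:25) {
    cp <- sim_codon_pair(sample(15:40, 1), stats::runif(1, 0, 2),
                         sample(10:40, 1))
    r <- pairwise_dnds(cp$cdsA, cp$cdsB)
    o <- oracle_ng86(cp$cdsA, cp$cdsB)
    for (f in c("S", "N", "Sd", "Nd", "dS", "dN")) {
      expect_equal(r[[f]], o[[f]], tolerance = 1e-9)
    }
  }
})

test_that("gapped and ambiguous codons are dropped pairwise", {
  a <- paste0("TT-", strrep("TTT", 8))
  b <- paste0("TTC", "TTN", strrep("TTT", 7))
  r <- pairwise_dnds(a, b)
  expect_equal(r$n_codons, 7)
  expect_equal(r$Sd + r$Nd, 0)
})

test_that("sliding windows tile the alignment as specified", {
  cp <- sim_codon_pair(90, 0.5, 30, seed = 3)
  tr <- sliding_window(cp$cdsA, cp$cdsB, window = 45, step = 9)
  expect_equal(tr$start_codon, c(1, 10, 19, 28, 37, 46))
  expect_equal(tr$end_codon, tr$start_codon + 44)

  same <- sliding_window(cp$cdsA, cp$cdsA)
  expect_true(all(same$selection_class == "UNDEFINED"))

  short <- sim_codon_pair(20, 0.5, 10, seed = 4)
  expect_warning(tr2 <- sliding_window(short$cdsA, short$cdsB), "shorter")
  expect_equal(nrow(tr2), 1L)
})

test_that("selection classes follow the 1.5 / 0.67 thresholds", {
  expect_identical(classify_selection(1.6), "POSITIVE")
  expect_identical(classify_selection(0.5), "PURIFYING")
  expect_identical(classify_selection(1.0), "INTERMEDIATE")
  expect_identical(classify_selection(1.5), "INTERMEDIATE")
  expect_identical(classify_selection(0.67), "INTERMEDIATE")
  expect_identical(classify_selection(NA_real_), "UNDEFINED")
  expect_error(classify_selection(-0.2), "negative")
})

test_that("dS/dN are monotone in the underlying p-distances", {
  p <- seq(0, 0.74, by = 0.02)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
})

test_that("a single whole-sequence window is both N- and C-terminal", {
  cp <- sim_codon_pair(45, 0.5, 30, seed = 9)
  tr <- sliding_window(cp$cdsA, cp$cdsB, window = 45, step = 9)
  s <- nterm_cterm_summary(tr)
  expect_equal(s$nterm_max_omega, s$cterm_max_omega)
})
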