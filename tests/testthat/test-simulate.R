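test_that("every generator is a pure function of its seed", {
  pc <- data.frame(chrom = 1, start_rank = 10, size = 3, max_internal_gap = 2)
  c1 <- sim_catalog_with_family(family_size = 4, planted_clusters = pc, seed = 5)
  c2 <- sim_catalog_with_family(family_size = 4, planted_clusters = pc, seed = 5)
  expect_identical(c1$catalog$genes, c2$catalog$genes)
  expect_identical(c1$truth, c2$truth)

  p1 <- sim_paralog_pair("EXON_SPLIT", seed = 6)
  p2 <- sim_paralog_pair("EXON_SPLIT", seed = 6)
  expect_identical(p1$B$genomic_seq, p2$B$genomic_seq)
  expect_identical(p1$truth, p2$truth)

  k1 <- sim_codon_pair(30, 0.5, 20, seed = 7)
  k2 <- sim_codon_pair(30, 0.5, 20, seed = 7)
  expect_identical(k1, k2)

  f1 <- sim_gene_trees_dl("((A,B),C);", 0.5, 0.2, 10, seed = 8)
  f2 <- sim_gene_trees_dl("((A,B),C);", 0.5, 0.2, 10, seed = 8)
  expect_identical(lapply(f1$gene_trees, function(x) ape::write.tree(x$tree)),
                   lapply(f2$gene_trees, function(x) ape::write.tree(x$tree)))
  expect_identical(f1$truth, f2$truth)

  e1 <- sim_expression(c("EE", "L2"), 20, 2, 0.3, seed = 9)
  e2 <- sim_expression(c("EE", "L2"), 20, 2, 0.3, seed = 9)
  expect_identical(e1$matrix, e2$matrix)

  r1 <- sim_repeat_sequence(seed = 10)
  r2 <- sim_repeat_sequence(seed = 10)
  expect_identical(r1, r2)
})

test_that("catalog simulation plants clusters and separated singletons", {
  pc <- data.frame(chrom = 1, start_rank = 10, size = 3, max_internal_gap = 3)
  sim <- sim_catalog_with_family(n_chroms = 1, genes_per_chrom = 100,
                                 family_size = 4, planted_clusters = pc,
                                 seed = 2)
  expect_equal(sum(!is.na(sim$truth$cluster)), 3)
  expect_equal(sum(is.na(sim$truth$cluster)), 1)
  # singleton is >= 21 genes from every cluster member
  sr <- sim$truth$rank[is.na(sim$truth$cluster)]
  cr <- sim$truth$rank[!is.na(sim$truth$cluster)]
  expect_true(all(abs(sr - cr) > 21))

  empty <- sim_catalog_with_family(family_size = 0,
                                   planted_clusters = NULL, seed = 3)
  expect_length(empty$family, 0)

  # infeasible: too many singletons for the required separation
  expect_error(sim_catalog_with_family(
    n_chroms = 1, genes_per_chrom = 50, family_size = 5,
    planted_clusters = NULL, seed = 4), "singleton")
})

test_that("paralog pairs respect their planted geometry", {
  pr <- sim_paralog_pair("NONE", seed = 15)
  expect_equal(feature_lengths(pr$A), feature_lengths(pr$B))

  sp <- sim_paralog_pair("EXON_SPLIT", seed = 16)
  flA <- feature_lengths(sp$A); flB <- feature_lengths(sp$B)
  expect_equal(length(flB$exon), length(flA$exon) + 1L)
  k <- sp$truth$exon_A
  expect_equal(flB$exon[k] + flB$exon[k + 1], flA$exon[k])
  expect_equal(flB$exon[k], sp$truth$split_offset)

  el <- sim_paralog_pair("INTRON_ELONGATION", seed = 17)
  expect_gt(el$truth$ratio, 2)

  bs <- sim_paralog_pair("BOUNDARY_SHIFT", seed = 18)
  kb <- bs$truth$exon_A
  expect_equal(abs(feature_lengths(bs$B)$exon[kb] -
                   feature_lengths(bs$A)$exon[kb]), 9L)

  expect_error(sim_paralog_pair("EXON_SPLIT", exon_len = c(40L, 60L),
                                seed = 19), "long enough")
  expect_error(sim_paralog_pair("nope"))
})

test_that("codon-pair evolution obeys the acceptance rule", {
  cp0 <- sim_codon_pair(50, 0, 60, seed = 20)
  expect_equal(cp0$n_nonsyn, 0)
  # no stops anywhere
  cods <- substring(cp0$cdsB, seq(1, nchar(cp0$cdsB), 3),
                    seq(3, nchar(cp0$cdsB), 3))
  expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  expect_error(sim_codon_pair(10, 1, 5), "at least 15")

  # neutral evolution: realized Nd/Sd approaches the N/S site ratio
  tot_n <- 0; tot_s <- 0; exp_ratio <- c()
  for (s in 1:30) {
    cp <- sim_codon_pair(300, 1, 60, seed = 400 + s)
    tot_n <- tot_n + cp$n_nonsyn; tot_s <- tot_s + cp$n_syn
    st <- vapply(substring(cp$cdsA, seq(1, 900, 3), seq(3, 900, 3)),
                 function(cd) codon_sites(cd)[["s_sites"]], numeric(1))
    exp_ratio <- c(exp_ratio, (900 - sum(st)) / sum(st))
  }
  expect_equal(tot_n / tot_s, mean(exp_ratio), tolerance = 0.15)
})

relabel <- function(gt) {
  phy <- gt$tree
  phy$tip.label <- unname(gt$species_of[phy$tip.label])
  phy
}

test_that("birth-death forests degenerate correctly at zero rates", {
  sp <- "((A,B),C);"
  f <- sim_gene_trees_dl(sp, 0, 0, 5, seed = 21)
  expect_equal(nrow(f$truth), 0)
  for (gt in f$gene_trees) {
    expect_equal(ape::Ntip(gt$tree), 3)
    expect_setequal(unname(gt$species_of), c("A", "B", "C"))
    rf <- ape::dist.topo(ape::unroot(relabel(gt)), ape::unroot(ape::read.tree(text = sp)))
    expect_equal(as.numeric(rf), 0)
  }
  expect_error(sim_gene_trees_dl(sp, 0, 50, 5, seed = 22), "extinct")
})

test_that("expression simulation plants archetypes and divergent pairs", {
  st <- c("EE", "L2", "L4", "YA")
  ex <- sim_expression(st, 40, 4, 0, pair_plan = c(concordant = 3, divergent = 3),
                       seed = 23)
  m <- log2(ex$matrix + 1)
  onehot <- ex$truth$archetype <= length(st)
  am <- colnames(m)[max.col(m[ex$truth$gene[onehot], ])]
  expect_true(all(am == ex$truth$peak_stage[onehot]))
  expect_equal(sum(ex$pairs$divergent), 3)
  # divergent pairs have different planted peaks
  tr <- ex$truth
  for (i in which(ex$pairs$divergent)) {
    pa <- tr$peak_stage[tr$gene == ex$pairs$geneA[i]]
    pb <- tr$peak_stage[tr$gene == ex$pairs$geneB[i]]
    expect_false(pa == pb)
  }
  expect_error(sim_expression(st, 10, 9, 0.1, seed = 1), "archetypes")
  expect_error(sim_expression(st, 10, 3, -1, seed = 1), "noise_sd")
})

test_that("repeat sequences honour their guards and truth coordinates", {
  rp <- sim_repeat_sequence(50, 6, 500, 0, seed = 24)
  expect_equal(nchar(rp$seq), 500 + 300 + 500)
  unit <- substr(rp$seq, 501, 550)
  expect_identical(substr(rp$seq, 551, 600), unit)
  expect_error(sim_repeat_sequence(5, 6, 100, 0.01), "unit_len")
  expect_error(sim_repeat_sequence(50, 1, 100, 0.01), "n_copies")
  expect_error(sim_repeat_sequence(50, 6, 100, 1), "maximum")
})
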