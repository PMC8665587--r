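# catalog of n genes on given chromosomes, 100 bp apart
toy_catalog <- function(n = 60, chrom = "c1") {
  df <- data.frame(gene_id = sprintf("%s_g%02d", chrom, 0:(n - 1)),
                   chrom = chrom, start = (0:(n - 1)) * 100 + 1,
                   end = (0:(n - 1)) * 100 + 50, strand = "+")
  gene_catalog(df)
}

test_that("gap rule links pairs and chains transitively", {
  cat1 <- toy_catalog()
  # gaps of 3 and 24 intervening genes: ranks 1,5 link; 30 stays single
  t1 <- cluster_tandem(cat1, c("c1_g01", "c1_g05", "c1_g30"))
  expect_equal(sort(t1$clusters$gene_id), c("c1_g01", "c1_g05"))
  expect_equal(t1$singletons, "c1_g30")
  s1 <- summarize_tandem(t1, 3)
  expect_equal(s1$n_tandem, 2)
  expect_equal(s1$n_single, 1)

  # gaps 13 and 13: ends are 27 apart yet chaining makes one cluster of 3
  t2 <- cluster_tandem(cat1, c("c1_g01", "c1_g15", "c1_g29"), max_gap = 13)
  expect_equal(nrow(t2$clusters), 3L)
  expect_equal(length(unique(t2$clusters$cluster_id)), 1L)

  # diameter-bound mode splits that chain
  t3 <- cluster_tandem(cat1, c("c1_g01", "c1_g15", "c1_g29"), max_gap = 13,
                       chain = FALSE)
  expect_lt(nrow(t3$clusters), 3L)

  expect_error(cluster_tandem(cat1, "missing_gene"), "missing_gene")
})

test_that("family members on different chromosomes are all singletons", {
  cats <- rbind(toy_catalog(20, "c1")$genes, toy_catalog(20, "c2")$genes,
                toy_catalog(20, "c3")$genes)
  cat3 <- gene_catalog(cats)
  t <- cluster_tandem(cat3, c("c1_g05", "c2_g05", "c3_g05"))
  expect_equal(nrow(t$clusters), 0L)
  expect_length(t$singletons, 3)
  expect_equal(summarize_tandem(t)$percent_tandem, 0)
})

test_that("summary percentages and consistency checks behave", {
  cat1 <- toy_catalog()
  fam <- c("c1_g01", "c1_g02", "c1_g03", "c1_g30", "c1_g55")
  t <- cluster_tandem(cat1, fam, max_gap = 2)
  s <- summarize_tandem(t, length(fam))
  expect_equal(s$n_tandem + s$n_single, length(fam))
  expect_error(summarize_tandem(t, 99), "family_size")
})

test_that("big_clusters filters by size with stable ordering", {
  sim <- sim_catalog_with_family(
    n_chroms = 2, genes_per_chrom = 200, family_size = 15,
    planted_clusters = data.frame(chrom = c(1, 1, 2), start_rank = c(5, 100, 20),
                                  size = c(6, 5, 4), max_internal_gap = 2),
    seed = 31)
  t <- cluster_tandem(sim$catalog, sim$family)
  bc <- big_clusters(t, min_size = 5)
  expect_equal(bc$n_members, c(6L, 5L))
  expect_true(all(diff(bc$span_start[bc$chrom == bc$chrom[1]]) > 0))
  empty <- cluster_tandem(sim$catalog, character(0))
  expect_equal(nrow(big_clusters(empty)), 0L)
})

test_that("density track counts every family gene exactly once", {
  df <- data.frame(gene_id = c("a", "b", "c"), chrom = "c1",
                   start = c(1e5, 2e5, 1.5e6), end = c(1e5, 2e5, 1.5e6) + 100,
                   strand = "+")
  cat1 <- gene_catalog(df, chrom_lengths = c(c1 = 2e6))
  d <- density_track(cat1, c("a", "b", "c"))
  expect_equal(d$count, c(2, 1))
  expect_equal(sum(d$count), 3)
  d0 <- density_track(cat1, character(0))
  expect_true(all(d0$count == 0))
})

test_that("clustering equals the O(n^2) union-find oracle on random catalogs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(50:300, 1)
    cat1 <- toy_catalog(n)
    fam <- sample(cat1$genes$gene_id, sample(3:min(25, n), 1))
    mg <- sample(c(2, 5, 20), 1)
    t <- cluster_tandem(cat1, fam, max_gap = mg)
    ranks <- catalog_rank(cat1, fam)
    o <- oracle_tandem(split(ranks$rank, ranks$chrom), mg)[["c1"]]
    got_sizes <- sort(c(table(t$clusters$cluster_id),
                        rep(1L, length(t$singletons))))
    exp_sizes <- sort(lengths(o))
    expect_equal(unname(as.integer(got_sizes)), unname(as.integer(exp_sizes)))
    # identical partitions, not just sizes
    got_parts <- c(split(catalog_rank(cat1, t$clusters$gene_id)$rank,
                         t$clusters$cluster_id),
                   as.list(catalog_rank(cat1, t$singletons)$rank))
    norm <- function(p) sort(unname(vapply(p, function(x)
      paste(sort(x), collapse = ","), "")))
    expect_equal(norm(got_parts), norm(o))
  }
})

test_that("tandem count is monotone in max_gap", {
  set.seed(77)
  cat1 <- toy_catalog(200)
  fam <- sample(cat1$genes$gene_id, 30)
  counts <- vapply(c(0, 1, 2, 5, 10, 20, 50), function(mg)
    summarize_tandem(cluster_tandem(cat1, fam, max_gap = mg))$n_tandem,
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("fragmenting chromosomes into contigs never inflates tandem counts", {
  set.seed(55)
  for (rep in 1:10) {
    cat1 <- toy_catalog(150)
    fam <- sample(cat1$genes$gene_id, 25)
    full <- summarize_tandem(cluster_tandem(cat1, fam))$n_tandem
    # split into contigs at random breakpoints
    brk <- sort(sample(10:140, 4))
    g <- cat1$genes
    g$chrom <- paste0("ctg", findInterval(g$rank, brk))
    frag <- gene_catalog(g[, c("gene_id", "chrom", "start", "end", "strand")])
    split_n <- summarize_tandem(cluster_tandem(frag, fam))$n_tandem
    expect_lte(split_n, full)
  }
})
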