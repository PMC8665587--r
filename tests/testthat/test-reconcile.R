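sp_ab <- read_newick("(A,B);", text = TRUE)
sp_abc <- read_newick("((A,B),C);", text = TRUE)

test_that("a duplicated two-species family maps one duplication to the root", {
  gt <- read_newick("((A|g1,B|g2),(A|g3,B|g4));", text = TRUE)
  r <- lca_reconcile(gt, sp_ab)
  expect_equal(r$n_dup, 1)
  expect_equal(r$n_loss, 0)
  expect_equal(r$cost, 1)
  expect_equal(r$dup_at, "A+B")
})

test_that("a missing species implies one loss on its branch", {
  gt <- read_newick("(A|g1,C|g2);", text = TRUE)
  r <- lca_reconcile(gt, sp_abc)
  expect_equal(r$n_dup, 0)
  expect_equal(r$losses, data.frame(branch = "B", count = 1L))
  expect_equal(r$root_species, "A+B+C")
})

test_that("a gene tree congruent with the species tree is all speciations", {
  gt <- read_newick("((A|g1,B|g2),C|g3);", text = TRUE)
  r <- lca_reconcile(gt, sp_abc)
  expect_equal(r$cost, 0)
  expect_true(all(r$event_labels == "SPECIATION"))
  expect_error(lca_reconcile(read_newick("(A|g1,Z|g2);", text = TRUE), sp_abc),
               "Z")
})

test_that("aggregation sums events per branch and keeps the count identity", {
  g1 <- read_newick("((A|g1,B|g2),(A|g3,B|g4));", text = TRUE)
  g2 <- read_newick("(A|g5,C|g6);", text = TRUE)
  h <- aggregate_histories(list(lca_reconcile(g1, sp_abc),
                                lca_reconcile(g2, sp_abc)), sp_abc)
  hd <- as.data.frame(h)
  expect_equal(hd$gains[hd$node == "A+B"], 1L)
  expect_equal(hd$losses[hd$node == "B"], 1L)
  # branch bookkeeping: count(child) = count(parent) + gains - losses
  for (i in seq_len(nrow(hd))) {
    if (is.na(hd$parent[i])) next
    pc <- hd$count[hd$node == hd$parent[i]]
    expect_equal(hd$count[i],
                 pc + hd$gains[i] + hd$origin_gains[i] - hd$losses[i])
  }
  expect_equal(hd$count[hd$node == "A"], 3L)  # g1, g3, g5
  expect_equal(hd$count[hd$node == "B"], 2L)
})

test_that("an empty forest aggregates to an all-zero history", {
  h <- as.data.frame(aggregate_histories(list(), sp_abc))
  expect_true(all(h$gains == 0) && all(h$losses == 0) && all(h$count == 0))
})

test_that("LCA cost equals the exhaustive-mapping oracle on random trees", {
  set.seed(202)
  for (rep in 1:25) {
    sim <- tryCatch(
      sim_gene_trees_dl(sp_abc, dup_rate = 0.6, loss_rate = 0.3,
                        n_families = 1, seed = 500 + rep),
      error = function(e) NULL)  # family went extinct at this seed
    if (is.null(sim)) next
    gt <- sim$gene_trees[[1]]
    if (ape::Ntip(gt$tree) > 6) next
    r <- lca_reconcile(gt, sp_abc)
    expect_equal(r$cost, oracle_dl_cost(gt$tree, sp_abc$tree, gt$species_of))
  }
})

test_that("observed-count validation rejects inconsistent totals", {
  g1 <- read_newick("((A|g1,B|g2),(A|g3,B|g4));", text = TRUE)
  rc <- lca_reconcile(g1, sp_ab)
  expect_silent(aggregate_histories(list(rc), sp_ab,
                                    observed_counts = c(A = 2, B = 2)))
  expect_error(aggregate_histories(list(rc), sp_ab,
                                   observed_counts = c(A = 5, B = 2)),
               "inconsistent")
})
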