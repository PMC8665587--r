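toy_matrix <- function() {
  m <- rbind(g1 = c(0, 0, 0, 8),
             g2 = c(5, 5, 5, 5),
             g3 = c(100, 2, 2, 2))
  colnames(m) <- c("EE", "L2", "L4", "YA")
  m
}

test_that("z-profiles are standardized, with flat genes flagged", {
  prof <- zscore_profiles(toy_matrix())
  expect_equal(unname(prof$peak_stage["g1"]), "YA")
  expect_true(prof$constant[["g2"]])
  expect_true(all(prof$z["g2", ] == 0))
  for (g in rownames(prof$z)) {
    expect_equal(mean(prof$z[g, ]), 0, tolerance = 1e-12)
    expect_true(abs(stats::sd(prof$z[g, ]) - 1) < 1e-12 ||
                all(prof$z[g, ] == 0))
  }
  expect_error(zscore_profiles(toy_matrix()[, 1, drop = FALSE]), "2 stages")
  expect_error(zscore_profiles(-toy_matrix()), "non-negative")
})

test_that("low-signal genes get a flat profile rather than amplified noise", {
  m <- rbind(weak = 2^c(2.1, 2.0, 1.9, 2.05) - 1,
             strong = 2^c(8, 2, 2, 2) - 1)
  colnames(m) <- c("EE", "L2", "L4", "YA")
  prof <- zscore_profiles(m)
  expect_true(prof$low_signal[["weak"]])
  expect_true(all(prof$z["weak", ] == 0))
  expect_false(prof$flat[["strong"]])
})

test_that("stage specificity requires exactly one high stage", {
  prof <- zscore_profiles(toy_matrix())
  sp <- stage_specificity(prof)
  expect_true(sp$is_stage_specific[sp$gene == "g1"])
  expect_identical(sp$peak_stage[sp$gene == "g1"], "YA")
  expect_false(sp$is_stage_specific[sp$gene == "g2"])
})

test_that("pair divergence combines correlation and peak criteria", {
  m <- rbind(a1 = c(64, 1, 1, 1), a2 = c(60, 2, 1, 1),
             b1 = c(64, 1, 1, 1), b2 = c(1, 1, 64, 1),
             flat = c(5, 5, 5, 5))
  colnames(m) <- c("EE", "L2", "L4", "YA")
  prof <- zscore_profiles(m)
  same <- pair_expression_divergence(prof, "a1", "a2")
  expect_false(same$divergent)
  expect_gt(same$r, 0.9)
  diff_ <- pair_expression_divergence(prof, "b1", "b2")
  expect_true(diff_$divergent)
  expect_true(diff_$peak_mismatch)
  # symmetric
  expect_equal(pair_expression_divergence(prof, "b2", "b1")$divergent,
               diff_$divergent)
  # flat vs peaked: correlation undefined, decided on peaks, flagged
  fl <- pair_expression_divergence(prof, "flat", "b1")
  expect_false(fl$r_defined)
  expect_error(pair_expression_divergence(prof, "a1", "zz"), "missing")
})

test_that("clustering is deterministic given a seed and validates k", {
  ex <- sim_expression(c("EE", "L2", "L4", "YA"), 60, 5, 0.2, seed = 14)
  prof <- zscore_profiles(ex$matrix)
  c1 <- cluster_stage_patterns(prof, k = 5, seed = 3)
  c2 <- cluster_stage_patterns(prof, k = 5, seed = 3)
  expect_identical(c1, c2)
  expect_error(cluster_stage_patterns(prof, k = 61, seed = 3), "exceeds")
})

test_that("noise-free archetypes cluster and peak perfectly", {
  st <- c("EE", "LE", "L1", "L2", "L3", "L4", "YA")
  ex <- sim_expression(st, 140, 7, 0, seed = 8)
  prof <- zscore_profiles(ex$matrix)
  peaks <- prof$peak_stage[ex$truth$gene]
  expect_true(all(unname(peaks) == ex$truth$peak_stage))
  cl <- cluster_stage_patterns(prof, k = 7, seed = 4)
  tab <- table(cl[ex$truth$gene], ex$truth$archetype)
  # one-to-one mapping between clusters and archetypes
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("paragroup dispersion counts occupied clusters", {
  asg <- c(a = 1, b = 1, c = 2, d = 3)
  pd <- paragroup_dispersion(asg, list(p1 = c("a", "b"), p2 = c("b", "c", "d")))
  expect_true(pd$all_same_cluster[pd$paragroup == "p1"])
  expect_equal(pd$n_clusters_occupied[pd$paragroup == "p2"], 3L)
  expect_error(paragroup_dispersion(asg, list(p = c("a", "zz"))), "zz")
})
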