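test_that("pairwise_r2 matches hand-derived values and flags degeneracy", {
  expect_equal(pairwise_r2(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pairwise_r2(c(1, 2, 3), c(3, 2, 1)), 1)  # negative slope, R2 = 1
  # hand-derived: cov = 1.5, var_x = 1, var_y = 3 -> r2 = 2.25/3 = 0.75
  expect_equal(pairwise_r2(c(0, 1, 2), c(1, 1, 4)), 0.75)
  expect_true(is.na(pairwise_r2(c(5, 5, 5), c(1, 2, 3))))  # zero variance
})

test_that("pairwise_r2 is symmetric and affine-invariant", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(3, 0, 100); b <- runif(3, 0, 100)
    r2 <- pairwise_r2(a, b)
    expect_equal(pairwise_r2(b, a), r2)
    s <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    expect_equal(pairwise_r2(s * a + runif(1, -10, 10), b), r2,
                 tolerance = 1e-12)
  }
})

test_that("r2_matrix agrees with elementwise pairwise_r2", {
  m <- random_triples(6, seed = 3)
  r2 <- r2_matrix(m)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(r2[i, j], pairwise_r2(m[i, ], m[j, ]))
  expect_equal(r2, t(r2))
})

test_that("clustering separates proportional families and honours r2_min", {
  # two exact proportional pairs with low cross-family correlation
  p1 <- proportional_profiles(c(10, 20, 30), c(1, 2), prefix = 1L)
  p2 <- proportional_profiles(c(30, 20, 25), c(1, 3), prefix = 2L)
  prof <- normalize_dsc(rbind(p1, p2))
  class(prof) <- c("expression_profiles", "data.frame")
  mat <- profile_matrix(prof)
  sgs <- cluster_subgroups(prof$gene_id, mat, r2_min = 0.90,
                           parent_group = "G1")
  expect_length(sgs, 2)
  expect_equal(lengths(lapply(sgs, `[[`, "members")), c(2L, 2L))
  expect_true(all(vapply(sgs, `[[`, numeric(1), "min_pairwise_r2") >= 0.90))
  expect_equal(sgs[[1]]$subgroup_id, "G1A")

  # identical profiles collapse to one subgroup
  same <- normalize_dsc(proportional_profiles(c(5, 9, 2), rep(1, 4)))
  one <- cluster_subgroups(same$gene_id, profile_matrix(same), 0.90)
  expect_length(one, 1)
  expect_length(one[[1]]$members, 4)

  # r2_min = 1 with generic noisy profiles -> all singletons
  m <- random_triples(6, seed = 5)
  alone <- cluster_subgroups(rownames(m), m, r2_min = 1)
  expect_length(alone, 6)

  expect_error(cluster_subgroups(rownames(m), m, r2_min = 1.2), "r2_min")
})

test_that("greedy clustering matches the exhaustive oracle on small instances", {
  for (seed in 1:25) {
    n <- 4 + (seed %% 5)
    m <- random_triples(n, seed = 100 + seed)
    for (r2_min in c(0.5, 0.8, 0.9, 0.99)) {
      sgs <- cluster_subgroups(rownames(m), m, r2_min = r2_min)
      r2 <- r2_matrix(m)
      expect_true(check_partition_oracle(sgs, rownames(m), r2, r2_min),
                  info = sprintf("seed %d r2_min %.2f", seed, r2_min))
      # emitted min_pairwise_r2 verified exhaustively
      for (s in sgs) {
        if (length(s$members) > 1) {
          pairs <- utils::combn(s$members, 2)
          mins <- min(apply(pairs, 2, function(p)
            pairwise_r2(m[p[1], ], m[p[2], ])))
          expect_equal(s$min_pairwise_r2, mins)
          expect_gte(s$min_pairwise_r2, r2_min)
        }
      }
    }
  }
})

test_that("clustering is invariant to input order and excludes degenerates", {
  m <- random_triples(8, seed = 9)
  sgs1 <- cluster_subgroups(rownames(m), m, 0.8)
  sgs2 <- cluster_subgroups(rev(rownames(m)), m, 0.8)
  expect_equal(lapply(sgs1, `[[`, "members"), lapply(sgs2, `[[`, "members"))

  m2 <- rbind(m, At8g00099 = c(4, 4, 4))  # zero-variance profile
  sgs3 <- cluster_subgroups(rownames(m2), m2, 0.8)
  expect_equal(attr(sgs3, "degenerate"), "At8g00099")
  expect_false("At8g00099" %in% unlist(lapply(sgs3, `[[`, "members")))
})

test_that("leave-one-out group sums behave as the linearity oracle predicts", {
  # proportional members: sums stay proportional, R2 = 1 for any exclusion
  prof <- normalize_dsc(proportional_profiles(c(10, 25, 2), c(1, 1.5, 0.7)))
  mat <- profile_matrix(prof)
  for (g in prof$gene_id)
    expect_equal(loo_group_sum_r2(prof$gene_id, mat, g), 1)

  # two members: reduces to the plain pairwise value
  m <- random_triples(2, seed = 21)
  expect_equal(loo_group_sum_r2(rownames(m), m, rownames(m)[1]),
               pairwise_r2(m[1, ], m[2, ]))

  expect_error(loo_group_sum_r2(rownames(m), m, "At8g09999"), "not a")
  expect_error(loo_group_sum_r2(rownames(m)[1], m, rownames(m)[1]),
               "singleton")
})

test_that("planted subgroups pass leave-one-out validation at 5% noise", {
  # Monte-Carlo bound pinned from an oracle run: 0.985 of 1,000 seeded
  # replicates reach R2 >= 0.90; assert the >= 0.95 bound on a 200-replicate
  # subsample to stay within the test-time budget.
  ok <- vapply(1:200, function(i) {
    cfg <- simulation_config(n_subgroups = 1, genes_per_subgroup = 7,
                             noise_cv = 0.05, background_genes = 0,
                             seed = 20000 + i)
    sim <- simulate_dataset(cfg)
    m <- profile_matrix(normalize_dsc(sim$profiles))
    loo_group_sum_r2(rownames(m), m, rownames(m)[1]) >= 0.90
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("between-subgroup R2 follows the construction", {
  base <- c(10, 20, 15)
  a <- normalize_dsc(proportional_profiles(base, c(1, 2), prefix = 3L))
  b <- normalize_dsc(proportional_profiles(base, c(3, 0.5), prefix = 4L))
  prof <- rbind(a, b)
  class(prof) <- c("expression_profiles", "data.frame")
  mat <- profile_matrix(prof)
  # same base profile -> sum profiles proportional -> R2 = 1
  expect_equal(between_subgroup_r2(a$gene_id, b$gene_id, mat,
                                   a$gene_id[1], b$gene_id[1]), 1)
  # leave-one-out sums reduce to single profiles, picked to have zero
  # sample covariance: (1,2,3) vs (5,0,5) -> R2 = 0
  m0 <- rbind(At8g00001 = c(1, 2, 3), At8g00002 = c(9, 9, 9.5),
              At8g00003 = c(5, 0, 5), At8g00004 = c(7, 1, 2))
  expect_equal(stats::cov(c(1, 2, 3), c(5, 0, 5)), 0)  # by construction
  expect_equal(between_subgroup_r2(c("At8g00001", "At8g00002"),
                                   c("At8g00003", "At8g00004"), m0,
                                   "At8g00002", "At8g00004"),
               0, tolerance = 1e-9)
  # and to the plain pairwise value in the two-member case
  expect_equal(between_subgroup_r2(c("At8g00001", "At8g00002"),
                                   c("At8g00003", "At8g00004"), m0,
                                   "At8g00001", "At8g00003"),
               pairwise_r2(c(9, 9, 9.5), c(7, 1, 2)))
})
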