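test_that("noise-free subgroups are exactly proportional; cross R2 bounded", {
  cfg <- simulation_config(n_subgroups = 2, genes_per_subgroup = 3,
                           noise_cv = 0, background_genes = 0,
                           frac_auxin_up = 0, frac_auxin_down = 1,
                           gradient_pattern = c("up", "up"),
                           base_r2_max = 0.5, seed = 5)
  sim <- simulate_dataset(cfg)
  mat <- profile_matrix(normalize_dsc(sim$profiles))
  for (s in unique(sim$truth$subgroup)) {
    mem <- sim$truth$gene_id[sim$truth$subgroup == s]
    r2 <- r2_matrix(mat[mem, , drop = FALSE])
    expect_equal(r2[upper.tri(r2)], rep(1, 3), tolerance = 1e-12)
  }
  cross <- pairwise_r2(mat[sim$truth$gene_id[1], ],
                       mat[sim$truth$gene_id[4], ])
  expect_lte(cross, 0.5 + 1e-9)  # equals the base-profile R2 bound
})

test_that("simulation respects seed determinism and filter planting", {
  cfg <- simulation_config(n_subgroups = 3, genes_per_subgroup = 4,
                           background_genes = 50, low_signal_frac = 1,
                           seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  for (f in c("expression.tsv", "auxin_up.txt", "auxin_down.txt", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # emitted files pass expression_io validation with zero warnings
  expect_no_warning(prof <- load_expression_table(file.path(d1,
                                                            "expression.tsv")))
  # low_signal_frac = 1: every background gene sits below the filter
  flt <- filter_low_signal(normalize_dsc(prof), normalization_config())
  truth <- read.delim(file.path(d1, "truth.tsv"))
  bg <- truth$gene_id[truth$subgroup == "background"]
  expect_setequal(flt$dropped$gene_id, bg)
})

test_that("end-to-end recovery: planted groups and subgroups at low noise", {
  cfg <- simulation_config(n_subgroups = 5, genes_per_subgroup = 6,
                           noise_cv = 0.01, background_genes = 30,
                           low_signal_frac = 0.2, seed = 123)
  sim <- simulate_dataset(cfg)
  prof <- normalize_dsc(sim$profiles)
  flt <- filter_low_signal(prof, normalization_config())
  grouping <- assign_groups(flt$kept, sim$auxin_up, sim$auxin_down)

  # every planted auxin-labelled gene lands in the gradient group its
  # planted (auxin, gradient) pair dictates
  gmap <- default_group_map()
  truth <- sim$truth[sim$truth$auxin != "none", ]
  for (i in seq_len(nrow(gmap))) {
    want <- truth$gene_id[truth$auxin == gmap$auxin_response[i] &
                            truth$gradient == gmap$gradient[i]]
    expect_setequal(grouping$groups[[gmap$group_id[i]]]$genes, want)
  }

  # subgroup recovery: adjusted Rand index 1 within each gradient group
  mat <- profile_matrix(flt$kept)
  for (g in grouping$groups) {
    if (length(g$genes) < 2) next
    sgs <- cluster_subgroups(g$genes, mat, r2_min = 0.90,
                             parent_group = g$group_id)
    found <- subgroup_table(sgs)
    planted <- sim$truth$subgroup[match(found$gene_id, sim$truth$gene_id)]
    expect_equal(adjusted_rand_index(found$subgroup_id, planted), 1)
  }
})

test_that("recovery degrades monotonically with noise", {
  grid <- c(0, 0.05, 0.2, 0.5)
  mean_ari <- vapply(grid, function(cv) {
    aris <- vapply(1:20, function(rep) {
      cfg <- simulation_config(n_subgroups = 4, genes_per_subgroup = 5,
                               noise_cv = cv, background_genes = 0,
                               frac_auxin_up = 0, frac_auxin_down = 1,
                               seed = 3000 + rep)
      sim <- simulate_dataset(cfg)
      mat <- profile_matrix(normalize_dsc(sim$profiles))
      # cluster within each planted gradient group, as the pipeline does
      found <- do.call(rbind, lapply(unique(sim$truth$gradient), function(g) {
        genes <- sim$truth$gene_id[sim$truth$gradient == g]
        subgroup_table(cluster_subgroups(genes, mat, r2_min = 0.90,
                                         parent_group = paste0("grad-", g)))
      }))
      planted <- sim$truth$subgroup[match(found$gene_id,
                                          sim$truth$gene_id)]
      adjusted_rand_index(found$subgroup_id, planted)
    }, numeric(1))
    mean(aris)
  }, numeric(1))
  expect_equal(mean_ari[1], 1)
  expect_true(all(diff(mean_ari) <= 1e-9))
})

test_that("adjusted Rand index matches the independent oracle values", {
  # frozen from scikit-learn adjusted_rand_score
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2, 2, 2),
                                   c(1, 1, 2, 2, 3, 3)), 8 / 33)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(letters[1:4], c(2, 3, 4, 1)), 1)
  expect_equal(adjusted_rand_index(c("x", "x", "y"), c("u", "u", "v")), 1)
})

test_that("simulated germination assays stay in range and obey the seed", {
  a1 <- simulate_germination(n_pairs = 8, wt_mean = 0.5, effect = 0,
                             total_per_dish = 100, seed = 4)
  a2 <- simulate_germination(n_pairs = 8, wt_mean = 0.5, effect = 0,
                             total_per_dish = 100, seed = 4)
  expect_identical(a1, a2)
  expect_true(all(a1$germinated >= 0 & a1$germinated <= 100))
  expect_error(simulate_germination(wt_mean = 0.9, effect = 0.2), "\\[0, 1\\]")
  # global RNG stream is not disturbed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_germination(seed = 9)); after <- runif(1)
  expect_identical(before, after)
})
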