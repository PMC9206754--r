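test_that("simulated trees have the right shape and are reproducible", {
  tr <- simulate_tree(5, seed = 4)
  expect_equal(length(tr$tip.label), 5)
  expect_equal(nrow(tr$edge), 8)            # 2n - 2 for a rooted bifurcating tree
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(simulate_tree(5, seed = 4)), ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(5, seed = 5)), ape::write.tree(tr)))
  expect_error(simulate_tree(1), "at least 2")
  # mean branch length ~ 0.1 (exponential, scaled)
  lens <- unlist(lapply(1:300, function(s) simulate_tree(8, seed = s)$edge.length))
  expect_lt(abs(mean(lens) - 0.1), 3 * 0.1 / sqrt(length(lens)))  # 3 MC sd
})

test_that("cohort design: counts, age support, seasons, spacing", {
  p <- sim_params()
  meta <- simulate_cohort(p, seed = 1)
  expect_equal(nrow(meta), 51 * 3 * 4)
  expect_true(all(meta$age >= 6 & meta$age <= 26))
  tab <- table(meta$individual_id, meta$season)
  expect_true(all(tab == 4))                # every host in every season
  # within-host within-season dates at least 2 days apart
  sp <- tapply(seq_len(nrow(meta)), paste(meta$individual_id, meta$season),
               function(ix) min(diff(sort(meta$collection_date[ix]))))
  expect_true(all(sp >= 2))
})

test_that("count simulation is deterministic and carries coherent ground truth", {
  p <- small_params()
  meta <- simulate_cohort(p, seed = 2)
  a <- simulate_counts(p, meta, seed = 3)
  b <- simulate_counts(p, meta, seed = 3)
  expect_identical(a$table, b$table)
  expect_false(identical(a$table, simulate_counts(p, meta, seed = 4)$table))
  expect_equal(dim(a$table), c(p$n_taxa, nrow(meta)))
  expect_equal(colnames(a$table), meta$sample_id)
  expect_equal(dim(a$ground_truth$compositions), dim(a$table))
  expect_equal(colSums(a$ground_truth$compositions), rep(1, nrow(meta)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("core taxa reach high prevalence at simulated depths", {
  d <- simulate_dataset(sim_params(n_individuals = 10, n_taxa = 100,
                                   samples_per_season = 2), seed = 6)
  core <- d$ground_truth$core_taxa
  prev <- rowMeans(d$table > 0)
  expect_gte(mean(prev[core] >= 0.9), 0.9)
  expect_gte(mean(prev[core]), 0.95)
})

test_that("no signature means no identity effect; stronger personalization widens the age gap", {
  p0 <- sim_params(n_individuals = 10, n_taxa = 40, samples_per_season = 2,
                   sigma_ind = 0, beta_pers = 0, lambda_social = 0,
                   sigma_drift = 0, beta_fast = 0, sigma_eps = 0,
                   sigma_group = 0)   # cross-group shifts would masquerade as identity
  d0 <- simulate_dataset(p0, seed = 11)
  dm0 <- bray_curtis(d0$table)
  s0 <- intra_inter_summary(dm0, d0$metadata)
  expect_lt(abs(s0$percent_difference), 3)    # centred on zero
  # monotonicity of the closest-neighbour age gap in beta_pers
  gap <- function(bp, seed) {
    d <- simulate_dataset(sim_params(n_individuals = 14, n_taxa = 40,
                                     samples_per_season = 2, beta_pers = bp),
                          seed = seed)
    dm <- bray_curtis(d$table)
    recs <- min_inter_dissimilarity(dm, d$metadata)
    ok <- !recs$flagged
    mean(recs$min_dissimilarity[ok & recs$age > 19]) -
      mean(recs$min_dissimilarity[ok & recs$age < 13])
  }
  gaps <- vapply(1:6, function(s) c(gap(0.05, s * 11), gap(0.45, s * 11)), numeric(2))
  expect_gt(mean(gaps[2, ] - gaps[1, ]), 0)
})

test_that("Dirichlet-multinomial counts converge to the latent composition", {
  p <- sim_params(n_individuals = 2, n_taxa = 5, samples_per_season = 1,
                  theta = 0, depth_meanlog = log(1e6), depth_sdlog = 0)
  meta <- simulate_cohort(p, seed = 8)
  out <- simulate_counts(p, meta, seed = 9)
  prop <- sweep(out$table, 2, colSums(out$table), "/")
  expect_equal(unclass(prop), unclass(out$ground_truth$compositions),
               tolerance = 0.01)
})

test_that("grooming dyads stay within groups and scale with observation time", {
  p <- small_params()
  meta <- simulate_cohort(p, seed = 10)
  g <- simulate_grooming(p, meta, seed = 11)
  grp <- meta$group[match(g$id_a, meta$individual_id)]
  grp_b <- meta$group[match(g$id_b, meta$individual_id)]
  expect_true(all(grp == grp_b))
  expect_true(all(g$id_a != g$id_b))
  # Poisson scaling: doubling observation hours ~doubles expected events
  p2 <- sim_params(n_individuals = 24, n_groups = 1, beta_groom = 0, groom_sd = 0,
                   obs_hours_range = c(30, 30))
  meta2 <- simulate_cohort(p2, seed = 1)
  e1 <- mean(simulate_grooming(p2, meta2, seed = 3)$events)
  p3 <- p2; p3$obs_hours_range <- c(60, 60)
  e2 <- mean(simulate_grooming(p3, meta2, seed = 3)$events)
  expect_equal(e2 / e1, 2, tolerance = 0.1)
})

test_that("full datasets are byte-identical under a shared master seed", {
  a <- simulate_dataset(small_params(), seed = 123)
  b <- simulate_dataset(small_params(), seed = 123)
  expect_identical(a$table, b$table)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$grooming, b$grooming)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})
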