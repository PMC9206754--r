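test_that("PERMANOVA partitions variance exactly as the projection oracle", {
  for (seed in 1:5) {
    n <- 10
    meta <- withr::with_seed(seed, data.frame(
      sample_id = paste0("s", 1:n),
      individual_id = paste0("I", rep(1:5, 2)),
      g1 = factor(sample(c("a", "b"), n, TRUE)),
      g2 = factor(sample(c("u", "v", "w"), n, TRUE)),
      x = rnorm(n)))
    if (nlevels(droplevels(meta$g1)) < 2 || nlevels(droplevels(meta$g2)) < 2) next
    d <- withr::with_seed(seed + 99, as.matrix(dist(matrix(rnorm(n * 3), n))))
    dimnames(d) <- list(meta$sample_id, meta$sample_id)
    got <- permanova(d, meta, terms = c("g1", "g2", "x"), n_perm = 999, seed = 1)
    want <- brute_permanova_ss(d, meta, c("g1", "g2", "x"))
    expect_equal(got$table$SS[1:3], unname(want$ss), tolerance = 1e-10)
    expect_equal(got$table$SS[got$table$term == "Total"], want$total,
                 tolerance = 1e-10)
    expect_equal(sum(got$table$R2[got$table$term != "Total"]), 100,
                 tolerance = 1e-9)
    # SS_total = (1/n) * sum of squared distances over pairs
    expect_equal(want$total, sum(d[upper.tri(d)]^2) / n, tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on R2 and F", {
  n <- 12
  meta <- withr::with_seed(5, data.frame(
    sample_id = paste0("s", 1:n),
    f = factor(rep(c("a", "b", "c"), 4)),
    x = rnorm(n)))
  d <- withr::with_seed(6, as.matrix(dist(matrix(rnorm(n * 4), n))))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  got <- permanova(d, meta, terms = c("f", "x"), n_perm = 999, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ f + x, data = meta, permutations = 99, by = "terms")
  expect_equal(got$table$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(got$table$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
})

test_that("perfectly separated groups take all the variance", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     f = factor(rep(c("a", "b"), each = 3)))
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  got <- permanova(d, meta, terms = "f", n_perm = 999, seed = 1)
  expect_equal(got$table$R2[1], 100, tolerance = 1e-9)
})

test_that("strata-invariant terms are reported NA with a warning", {
  meta <- toy_metadata(k = 4, m = 3)
  meta$grp <- factor(rep(c("a", "b"), each = 6))     # constant within host
  meta$noise <- withr::with_seed(1, factor(sample(c("u", "v"), 12, TRUE)))
  d <- withr::with_seed(2, as.matrix(dist(matrix(rnorm(36), 12))))
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  expect_warning(
    out <- permanova(d, meta, terms = c("grp", "noise"),
                     strata = "individual_id", n_perm = 999, seed = 1),
    "permutation-invariant")
  expect_true(is.na(out$table$p[1]))
  expect_false(is.na(out$table$p[2]))
  # all-singleton strata are rejected
  meta$single <- as.character(seq_len(nrow(meta)))
  expect_error(permanova(d, meta, terms = "noise", strata = "single",
                         n_perm = 999, seed = 1), "singleton")
})

test_that("Smithson-Verkuilen transform maps the boundary as printed", {
  expect_equal(smithson_transform(0.5, 999), 0.5)
  expect_lt(abs(smithson_transform(0, 543) - 0.000921), 1e-6)
  expect_lt(abs(smithson_transform(1, 543) - 0.999079), 1e-6)
  x <- seq(0, 1, by = 0.1)
  y <- smithson_transform(x, 100)
  expect_true(all(diff(y) > 0))                 # strictly monotone
  expect_true(all(y > 0 & y < 1))
  expect_equal(range(y), c(0.5 / 100, 1 - 0.5 / 100))
  expect_error(smithson_transform(1.2, 10), "0, 1")
})

test_that("taxonomic aggregation sums counts by lineage", {
  m <- tiny_counts()
  tax <- data.frame(taxon_id = c("A", "B", "C"),
                    genus = c("g1", "g1", "g2"),
                    phylum = c("p1", "p1", "p1"))
  agg <- aggregate_taxa(m, tax, "genus")
  expect_equal(agg["g1", ], m["A", ] + m["B", ])
  expect_equal(agg["g2", ], m["C", ])
  expect_equal(unname(colSums(agg)), unname(colSums(m)))
  expect_error(aggregate_taxa(m, tax, "family"), "unknown taxonomy level")
})

test_that("taxon-group log-ratio is depth-invariant and finite at zeros", {
  m <- tiny_counts()
  lr <- taxon_log_ratio(m, c("A", "B"), "C")
  expect_equal(taxon_log_ratio(3L * m, c("A", "B"), "C"),
               log((3 * colSums(m[c("A", "B"), ]) + 0.5) / (3 * m["C", ] + 0.5)))
  expect_true(all(is.finite(taxon_log_ratio(m, "A", "B"))))  # B has a zero cell
  expect_error(taxon_log_ratio(m, "A", "Z"), "not in table")
})

test_that("taxon trend models recover a simulated logit-scale age slope", {
  ests <- disps <- numeric(25)
  for (r in seq_len(25)) {
    set.seed(r * 13)
    n <- 200
    meta <- data.frame(sample_id = paste0("s", 1:n),
                       individual_id = paste0("I", rep(1:40, 5)),
                       age = rep(runif(40, 6, 26), 5),
                       group = factor(rep(c("a", "b"), length.out = n)),
                       season = factor(rep(c("x", "y"), each = n / 2)),
                       gestation = 0)
    z <- (meta$age - mean(meta$age)) / sd(meta$age)
    mu <- plogis(qlogis(0.2) + 0.5 * z)
    phi <- exp(4 + 0.4 * z)
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    depth <- 5000L
    counts <- rbind(tx = as.integer(round(y * depth)),
                    other = as.integer(depth - round(y * depth)))
    colnames(counts) <- meta$sample_id
    tr <- fit_taxon_trend(counts, meta, "tx")
    ests[r] <- tr$estimate; disps[r] <- tr$disp_estimate
  }
  expect_equal(mean(ests), 0.5, tolerance = 0.1)
  expect_gte(mean(disps > 0), 0.95)   # dispersion-age sign recovered
})

test_that("trend classification applies BH within level and direction rules", {
  tr <- data.frame(taxon = paste0("t", 1:4), level = "genus",
                   estimate = c(1, -1, 2, -2), disp_estimate = 0,
                   lrt_stat = 1, df = 2,
                   p_raw = c(0.01, 0.02, 0.03, 0.04), p_fdr = NA_real_,
                   direction = NA_character_, prevalence = c(95, 95, 50, 50),
                   core = c(TRUE, TRUE, FALSE, FALSE), converged = TRUE)
  out <- classify_trends(tr)
  expect_equal(out$p_fdr, rep(0.04, 4))          # hand BH computation
  expect_equal(out$direction, c("increase", "decrease", "increase", "decrease"))
  tr$p_raw <- rep(1, 4)
  expect_true(all(classify_trends(tr)$direction == "none"))
  # FDR p never below raw p, monotone in raw p
  tr$p_raw <- c(0.001, 0.01, 0.04, 0.8)
  out <- classify_trends(tr)
  expect_true(all(out$p_fdr >= tr$p_raw))
  expect_true(all(diff(out$p_fdr[order(tr$p_raw)]) >= -1e-12))
})

test_that("core repartition reproduces a hand-enumerated table with 90% inclusive", {
  dirs <- rep(c("increase", "decrease", "none"), c(6, 6, 8))
  prev <- c(rep(c(95, 50), 3), rep(c(90, 85), 3), rep(c(99, 40), 4))
  tr <- data.frame(taxon = paste0("t", 1:20), level = "genus",
                   estimate = ifelse(dirs == "decrease", -1, 1),
                   disp_estimate = 0, lrt_stat = 1, df = 2,
                   p_raw = ifelse(dirs == "none", 0.9, 0.01), p_fdr = 0.5,
                   direction = dirs, prevalence = prev,
                   core = prev >= 90, converged = TRUE)
  out <- core_repartition(tr)
  want <- matrix(c(3, 3, 3, 3, 4, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(direction = c("increase", "decrease", "none"),
                                 core = c("core", "noncore")))
  expect_equal(out$counts, want, ignore_attr = TRUE)
  expect_true(all(tr$core[tr$prevalence == 90]))  # boundary inclusive
})
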