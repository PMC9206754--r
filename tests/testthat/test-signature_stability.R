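test_that("identity Mantel detects a perfect identity structure", {
  meta <- toy_metadata(k = 3, m = c(2, 3, 4)[1])  # equal blocks
  meta <- toy_metadata(k = 3, m = 3)
  ind <- outer(meta$individual_id, meta$individual_id, "!=") * 1
  d <- labeled_dist(ind, meta$sample_id); diag(d) <- 0
  res <- identity_mantel(d, meta, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 0.05)
  expect_error(identity_mantel(d, meta, n_perm = 50), "at least 99")
  one <- meta; one$individual_id <- "only"
  expect_error(identity_mantel(d, one, n_perm = 999), "two individuals")
})

test_that("identity Mantel sign convention: intra below inter gives r > 0", {
  meta <- toy_metadata(k = 4, m = 3)
  same <- outer(meta$individual_id, meta$individual_id, "==")
  d <- matrix(0.7, nrow(meta), nrow(meta))
  d[same] <- 0.4
  diag(d) <- 0
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  expect_gt(identity_mantel(d, meta, n_perm = 199, seed = 1)$r, 0)
})

test_that("intra/inter summary arithmetic is exact on a constructed matrix", {
  meta <- toy_metadata(k = 2, m = 2)
  same <- outer(meta$individual_id, meta$individual_id, "==")
  d <- matrix(0.69, 4, 4); d[same] <- 0.60; diag(d) <- 0
  dimnames(d) <- list(meta$sample_id, meta$sample_id)
  s <- intra_inter_summary(d, meta)
  expect_equal(s$intra_mean, 0.60)
  expect_equal(s$inter_mean, 0.69)
  expect_equal(s$percent_difference, 100 * (0.69 - 0.60) / 0.69, tolerance = 1e-12)
  # all distances equal: zero percent difference
  d2 <- matrix(0.5, 4, 4); diag(d2) <- 0
  dimnames(d2) <- dimnames(d)
  expect_equal(intra_inter_summary(d2, meta)$percent_difference, 0)
})

test_that("time-gap Mantel: monotone dissimilarity gives r > 0; exclusion bookkeeping", {
  meta <- toy_metadata(k = 3, m = 4, gap = 40)
  n <- nrow(meta)
  gapm <- abs(outer(as.numeric(meta$collection_date), as.numeric(meta$collection_date), "-"))
  d <- labeled_dist(gapm / max(gapm), meta$sample_id)
  res <- timegap_mantel(d, meta, n_perm = 199, seed = 1)
  expect_gt(res$r, 0.99)
  expect_lt(res$p, 0.05)
  # host with all samples within 10 days is dropped by the plateau rule
  meta2 <- meta
  meta2$collection_date[meta2$individual_id == "I1"] <-
    as.Date("2020-01-01") + c(0, 2, 4, 6)
  res2 <- timegap_mantel(d, meta2, exclude_within_days = 10, n_perm = 199, seed = 1)
  expect_equal(res2$n_individuals_dropped, 1)
  expect_equal(res2$n_individuals_retained, 2)
})

test_that("stability coefficients flag degenerate hosts and rank clean ones", {
  meta <- toy_metadata(k = 3, m = 4, gap = 25)
  gapm <- abs(outer(as.numeric(meta$collection_date), as.numeric(meta$collection_date), "-"))
  d <- labeled_dist(gapm / max(gapm), meta$sample_id)
  # host I2: constant dissimilarity
  i2 <- meta$sample_id[meta$individual_id == "I2"]
  d[i2, i2] <- 0.5; d[cbind(i2, i2)] <- 0
  recs <- stability_coefficients(d, meta)
  expect_equal(recs$coefficient[recs$individual_id == "I1"], 1)
  expect_true(recs$flagged[recs$individual_id == "I2"])
  expect_equal(recs$reason[recs$individual_id == "I2"], "zero variance")
  # too few pairs gets flagged, not computed
  meta3 <- toy_metadata(k = 2, m = 2)
  d3 <- labeled_dist(matrix(c(0, .1, .2, .3, .1, 0, .4, .5, .2, .4, 0, .6,
                              .3, .5, .6, 0), 4), meta3$sample_id)
  r3 <- stability_coefficients(d3, meta3)
  expect_true(all(r3$flagged))
  expect_true(all(r3$reason == "too few pairs"))
})

test_that("Kruskal-Wallis on the classic three-group ladder gives H = 7.2", {
  recs <- data.frame(individual_id = paste0("I", 1:9),
                     coefficient = 1:9 / 10,
                     n_pairs = 10,
                     age = rep(c(7, 14, 20), each = 3),
                     age_category = factor(rep(c("young", "mid", "old"), each = 3),
                                           levels = c("young", "mid", "old")),
                     flagged = FALSE, reason = "")
  out <- stability_by_age(recs)
  expect_equal(out$statistic, 7.2, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # identical values across groups: H = 0
  recs$coefficient <- 0.5
  expect_equal(stability_by_age(recs)$statistic, 0)
})

test_that("restricted permutations are calibrated under an exchangeable null", {
  # iid distances: both Mantel tests should reject at ~nominal rate
  rej_id <- rej_tg <- logical(60)
  for (r in seq_len(60)) {
    meta <- toy_metadata(k = 5, m = 4, gap = 21)
    n <- nrow(meta)
    d <- withr::with_seed(r, {
      v <- matrix(runif(n * n), n)
      m <- (v + t(v)) / 2; diag(m) <- 0; m
    })
    dimnames(d) <- list(meta$sample_id, meta$sample_id)
    rej_id[r] <- identity_mantel(d, meta, n_perm = 199, seed = r)$p < 0.05
    rej_tg[r] <- timegap_mantel(d, meta, n_perm = 199, seed = r)$p < 0.05
  }
  expect_lte(mean(rej_id), 0.15)
  expect_lte(mean(rej_tg), 0.15)
})
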