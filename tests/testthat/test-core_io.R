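test_that("count tables round-trip through TSV in both orientations", {
  m <- tiny_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, f)
  expect_identical(load_count_table(f), m)
  # transposed file with samples as rows loads to the same table
  ft <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(load_count_table(ft, orientation = "samples_rows"), m)
})

test_that("invalid count tables are rejected", {
  m <- tiny_counts()
  bad <- m; rownames(bad) <- c("A", "A", "C")
  expect_error(validate_count_table(bad), "duplicate taxon")
  bad <- m; bad[1, 1] <- -1L
  expect_error(validate_count_table(bad), "negative")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts1", "A\t1\t2", "B\t3\t4"), f)
  expect_error(load_count_table(f), "duplicate sample")
})

test_that("age categories follow the printed adult boundaries", {
  expect_equal(as.character(derive_age_category(c(6, 10, 10.1, 17.9, 18, 26))),
               c("young", "young", "mid", "mid", "old", "old"))
  expect_error(derive_age_category(5.5), "non-adult")
})

test_that("metadata loader parses, validates and derives age categories", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(sample_id = paste0("s", 1:6),
                   individual_id = rep(c("A", "B"), each = 3),
                   age = c(7, 7, 7, 18, 18, 18),
                   group = "G1", season = "wet", gestation = 0,
                   collection_date = as.character(as.Date("2020-01-01") + 0:5),
                   rainfall_30d = 10)
  utils::write.csv(df, f, row.names = FALSE)
  meta <- load_metadata(f)
  expect_equal(nrow(meta), 6)
  expect_s3_class(meta$collection_date, "Date")
  expect_equal(as.character(meta$age_category), rep(c("young", "old"), each = 3))

  df2 <- df; df2$collection_date[3] <- "not-a-date"
  utils::write.csv(df2, f, row.names = FALSE)
  expect_error(load_metadata(f), "row")
  df3 <- df[, setdiff(colnames(df), "season")]
  utils::write.csv(df3, f, row.names = FALSE)
  expect_error(load_metadata(f), "season")
})

test_that("spurious-signal filter drops singletons and zeroes sub-threshold cells", {
  # 4 taxa x 3 samples; t4 occurs once; t3 has one cell at 0.1% of its sample
  m <- matrix(c(500L, 500L, 500L,
                498L, 499L, 499L,
                1L,   500L, 500L,
                0L,   0L,   300L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  out <- filter_spurious(m, min_relab = 0.0025)
  rep_ <- attr(out, "removal_report")
  expect_false("t4" %in% rownames(out))          # single-sample taxon dropped
  expect_equal(out["t3", "s1"], 0L)              # 1/999 = 0.1% zeroed
  expect_equal(out["t3", c("s2", "s3")], c(s2 = 500L, s3 = 500L))
  expect_equal(out["t1", ], m["t1", ])           # untouched cells unchanged
  expect_true(rep_$cells_zeroed >= 1)

  # taxon at 0.30% everywhere is retained everywhere
  m2 <- rbind(t1 = rep(9970L, 4), t2 = rep(30L, 4))
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(filter_spurious(m2)["t2", ], m2["t2", ], ignore_attr = TRUE)
})

test_that("spurious-signal filter is idempotent", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed,
      matrix(rnbinom(30 * 8, mu = 30, size = 0.3), 30, 8,
             dimnames = list(paste0("t", 1:30), paste0("s", 1:8))))
    m <- m[, colSums(m) > 0, drop = FALSE]
    f1 <- filter_spurious(m)
    f2 <- filter_spurious(f1)
    expect_equal(unclass(f2), unclass(f1), ignore_attr = TRUE)
  }
})

test_that("rarefaction hits the target depth exactly and never inflates cells", {
  m <- withr::with_seed(1,
    matrix(rpois(20 * 5, 40), 20, 5,
           dimnames = list(paste0("t", 1:20), paste0("s", 1:5))))
  r <- rarefy(m, depth = 300, seed = 7)
  expect_true(all(colSums(r) == 300))
  expect_true(all(r <= m))
  expect_identical(rarefy(m, depth = 300, seed = 7), r)   # deterministic
  # a sample whose total equals the depth is returned unchanged
  expect_identical(rarefy(m, depth = min(colSums(m)), seed = 1)[, which.min(colSums(m))],
                   m[, which.min(colSums(m))])
  expect_error(rarefy(m, depth = 10000, seed = 1), "exceeds total reads")
  expect_error(rarefy(m, depth = 0, seed = 1), "at least 1")
})

test_that("rarefaction draws are hypergeometric in expectation", {
  m <- matrix(c(60L, 40L), 2, 1, dimnames = list(c("a", "b"), "s"))
  draws <- vapply(1:3000, function(s) rarefy(m, depth = 10, seed = s)["a", 1],
                  numeric(1))
  # multivariate hypergeometric mean 10 * 60/100 = 6, sd of the mean ~ 0.022
  expect_equal(mean(draws), 6, tolerance = 0.02)
})

test_that("distance matrices round-trip exactly and reorder consistently", {
  set.seed(3)
  x <- matrix(runif(12), 4, 3)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, f)
  expect_equal(load_distance_matrix(f), d, tolerance = 0)
  perm <- c("s3", "s1", "s4", "s2")
  expect_equal(load_distance_matrix(f, labels = perm), d[perm, perm], tolerance = 0)
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(write_distance_matrix(bad, f), "asymmetric")
  bad <- d; diag(bad) <- 0.5
  expect_error(write_distance_matrix(bad, f), "diagonal")
})
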