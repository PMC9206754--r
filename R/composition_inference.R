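# Gower double-centered inner-product matrix from a distance matrix
gower_matrix <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' PERMANOVA with sequential sums of squares and restricted permutations
#'
#' Partitions the Gower-centered variance of a dissimilarity matrix
#' among predictors in the given order (Type I), with pseudo-F tests
#' whose permutation null can be restricted to shuffle samples only
#' within `strata` blocks (repeated sampling of the same host). A
#' predictor that is constant within every stratum has a
#' permutation-invariant statistic under the restricted scheme; its p is
#' reported as `NA` with a warning rather than fabricated.
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata holding the predictors.
#' @param terms character vector of predictor column names, in the
#'   sequential order wanted.
#' @param strata optional metadata column name defining permutation
#'   blocks (e.g. `"individual_id"`).
#' @param n_perm number of permutations (>= 999).
#' @param seed integer seed.
#' @return object of class `permanova`: data.frame `term, df, SS, R2,
#'   pseudo_F, p` including `Residual` and `Total` rows; `R2` in percent.
#' @export
permanova <- function(d, metadata, terms, strata = NULL, n_perm = 999, seed = 1L) {
  if (n_perm < 999) stop("n_perm must be at least 999")
  meta <- align_metadata(metadata, rownames(d))
  n <- nrow(d)
  G <- gower_matrix(d)
  ss_total <- sum(diag(G))

  blocks <- NULL
  if (!is.null(strata)) {
    blk <- factor(meta[[strata]])
    blocks <- split(seq_len(n), blk)
    if (all(lengths(blocks) < 2))
      stop("all strata are singletons: no permutable structure")
  }

  Q <- matrix(1 / sqrt(n), n, 1)
  term_cols <- list()
  invariant <- logical(length(terms))
  names(invariant) <- terms
  for (t_ in terms) {
    v <- meta[[t_]]
    if (is.null(v)) stop("unknown term: ", t_)
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v) && nlevels(droplevels(v)) < 2)
      stop("term with a single level: ", t_)
    X <- stats::model.matrix(~v)[, -1, drop = FALSE]
    if (!is.null(blocks))
      invariant[t_] <- all(vapply(blocks, function(pos)
        all(apply(X[pos, , drop = FALSE], 2, function(col) length(unique(col)) == 1)),
        logical(1)))
    R <- X - Q %*% crossprod(Q, X)
    qr_ <- qr(R)
    rank <- qr_$rank
    if (rank == 0) stop("term adds no information after earlier terms: ", t_)
    U <- qr.Q(qr_)[, seq_len(rank), drop = FALSE]
    term_cols[[t_]] <- ncol(Q) - 1 + seq_len(rank)
    Q <- cbind(Q, U)
  }
  U_all <- Q[, -1, drop = FALSE]
  k <- ncol(U_all)
  df_terms <- lengths(term_cols)
  df_res <- n - 1 - k
  if (df_res <= 0) stop("model saturates the samples")

  ss_cols <- colSums(U_all * (G %*% U_all))
  ss_terms <- vapply(term_cols, function(ix) sum(ss_cols[ix]), numeric(1))
  ss_res <- ss_total - sum(ss_terms)
  F_obs <- (ss_terms / df_terms) / (ss_res / df_res)

  exceed <- withr::with_seed(seed, {
    P <- if (is.null(blocks)) {
      vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
    } else {
      block_perm_matrix(blocks, n, n_perm)
    }
    # batched quadratic forms: for each orthonormal model column u,
    # SS under every permutation at once via one matrix product
    sc <- matrix(0, k, n_perm)
    for (j in seq_len(k)) {
      Uj <- matrix(U_all[P, j], n, n_perm)
      sc[j, ] <- colSums(Uj * (G %*% Uj))
    }
    st <- do.call(rbind, lapply(term_cols, function(ix)
      colSums(sc[ix, , drop = FALSE])))
    sr <- ss_total - colSums(st)
    Fp <- (st / df_terms) / rep(sr / df_res, each = length(terms))
    rowSums(Fp >= F_obs)
  })
  pvals <- (exceed + 1) / (n_perm + 1)
  if (any(invariant)) {
    warning("term(s) constant within every stratum have permutation-invariant F: ",
            paste(terms[invariant], collapse = ", "))
    pvals[invariant] <- NA_real_
  }
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    R2 = 100 * c(ss_terms, ss_res, ss_total) / ss_total,
    pseudo_F = c(F_obs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out, n_perm = n_perm, strata = strata), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "permutations",
      if (!is.null(x$strata)) paste0(", strata = ", x$strata), ")\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Host-identity effect size from an identity-only PERMANOVA
#'
#' The share of dissimilarity variance explained by host identity is
#' computed from a model with identity as the only predictor (identity
#' cannot be tested under within-host strata, so its own model uses free
#' permutations).
#'
#' @inheritParams permanova
#' @param id_col metadata column naming the host.
#' @return the `permanova` object for the identity-only model.
#' @export
permanova_identity <- function(d, metadata, id_col = "individual_id",
                               n_perm = 999, seed = 1L) {
  permanova(d, metadata, terms = id_col, strata = NULL, n_perm = n_perm, seed = seed)
}

#' Smithson-Verkuilen boundary shrinkage for proportions
#'
#' `f(x) = (x * (n - 1) + 0.5) / n`, mapping \[0, 1\] strictly inside
#' (0, 1) without pseudo-counts; order preserving.
#'
#' @param x proportions in \[0, 1\].
#' @param n number of data points in the modeled sample.
#' @return transformed proportions in (0, 1).
#' @export
smithson_transform <- function(x, n) {
  if (any(x < 0 | x > 1)) stop("proportions must lie in [0, 1]")
  if (n < 1) stop("n must be at least 1")
  (x * (n - 1) + 0.5) / n
}

#' Sum counts to a higher taxonomic level
#'
#' @param counts taxa x samples matrix (rows are base taxa).
#' @param taxonomy data.frame with `taxon_id` and one column per level.
#' @param level taxonomy column to aggregate to.
#' @return aggregated counts, rows named by the level's labels.
#' @export
aggregate_taxa <- function(counts, taxonomy, level) {
  if (!level %in% colnames(taxonomy)) stop("unknown taxonomy level: ", level)
  lab <- taxonomy[[level]][match(rownames(counts), taxonomy$taxon_id)]
  if (any(is.na(lab))) stop("taxa missing from taxonomy: ",
                            paste(rownames(counts)[is.na(lab)][1:5], collapse = ", "))
  out <- rowsum(counts, lab)
  storage.mode(out) <- "integer"
  out
}

#' Log-ratio of two taxon groups' summed abundances
#'
#' Per-sample `log(sum(numerator) / sum(denominator))` (e.g. the
#' Firmicutes/Bacteroidota balance), invariant to sequencing depth; a
#' half-count offset keeps it finite when one side is absent.
#'
#' @param counts taxa x samples matrix.
#' @param numerator,denominator row names of the two groups.
#' @return numeric vector, one log-ratio per sample.
#' @export
taxon_log_ratio <- function(counts, numerator, denominator) {
  miss <- setdiff(c(numerator, denominator), rownames(counts))
  if (length(miss)) stop("taxa not in table: ", paste(miss, collapse = ", "))
  num <- colSums(counts[numerator, , drop = FALSE])
  den <- colSums(counts[denominator, , drop = FALSE])
  log((num + 0.5) / (den + 0.5))
}

#' Age-trend model for one taxon's relative abundance
#'
#' Variable-dispersion beta regression of the Smithson-transformed
#' within-sample relative abundance: `logit(mean) ~ z(age) + season +
#' gestation + group`, `log(precision) ~ z(age)`, observations weighted
#' by read count (normalized to mean 1), host-clustered robust errors.
#' Significance of age is a likelihood-ratio test against the reference
#' without age (dropped jointly from mean and precision, 2 df, or from
#' the mean only with `drop_scope = "mean_only"`), with the statistic
#' divided by the full model's Pearson dispersion ratio when that ratio
#' exceeds 1. Non-converged fits are returned flagged, mirroring the
#' practice of excluding them from downstream classification.
#'
#' @param counts taxa x samples matrix at the level of analysis (use
#'   [aggregate_taxa()] first for phylum/family/genus analyses).
#' @param metadata per-sample metadata.
#' @param taxon row name of the taxon to model.
#' @param level label stored in the output (e.g. `"genus"`).
#' @param drop_scope scope of the age drop in the reference model.
#' @param core_prevalence core threshold in percent (inclusive).
#' @return one-row data.frame (a taxon-trend record): `taxon, level,
#'   estimate, disp_estimate, lrt_stat, df, p_raw, p_fdr, direction,
#'   prevalence, core, converged`.
#' @export
fit_taxon_trend <- function(counts, metadata, taxon, level = "taxon",
                            drop_scope = c("joint", "mean_only"),
                            core_prevalence = 90) {
  drop_scope <- match.arg(drop_scope)
  if (!taxon %in% rownames(counts)) stop("taxon not in table: ", taxon)
  meta <- align_metadata(metadata, colnames(counts))
  tot <- colSums(counts)
  x <- counts[taxon, ] / tot
  prevalence <- 100 * mean(counts[taxon, ] > 0)
  if (prevalence < 1)
    stop("insufficient prevalence for ", taxon, " (", round(prevalence, 2), "%)")
  rec <- data.frame(taxon = taxon, level = level, estimate = NA_real_,
                    disp_estimate = NA_real_, lrt_stat = NA_real_, df = NA_integer_,
                    p_raw = NA_real_, p_fdr = NA_real_, direction = NA_character_,
                    prevalence = prevalence, core = prevalence >= core_prevalence,
                    converged = FALSE, stringsAsFactors = FALSE)
  y <- smithson_transform(x, length(x))
  meta$age_z <- z_score(meta$age)
  meta$gestation <- as.numeric(meta$gestation)
  Xf <- stats::model.matrix(~ age_z + season + gestation + group, meta)
  Xr <- stats::model.matrix(~ season + gestation + group, meta)
  Zf <- stats::model.matrix(~ age_z, meta)
  Zr <- matrix(1, nrow(meta), 1, dimnames = list(NULL, "(Intercept)"))
  w <- tot
  cl <- factor(meta$individual_id)
  full <- tryCatch(beta_ml(y, Xf, Zf, weights = w, cluster = cl),
                   error = function(e) NULL)
  if (is.null(full) || !full$converged) return(rec)
  ref <- tryCatch(
    if (drop_scope == "joint") beta_ml(y, Xr, Zr, weights = w, cluster = cl)
    else beta_ml(y, Xr, Zf, weights = w, cluster = cl),
    error = function(e) NULL)
  if (is.null(ref) || !ref$converged) return(rec)
  lrt <- lrt_beta_ml(full, ref)
  rec$estimate <- full$coefficients$mean[["age_z"]]
  rec$disp_estimate <- full$coefficients$precision[["age_z"]]
  rec$lrt_stat <- lrt$statistic
  rec$df <- lrt$df
  rec$p_raw <- lrt$p
  rec$converged <- TRUE
  rec
}

#' Fit age-trend models for every taxon at a level
#'
#' @inheritParams fit_taxon_trend
#' @param min_prevalence skip taxa present in fewer than this percent of
#'   samples.
#' @return data.frame of taxon-trend records (see [fit_taxon_trend()]).
#' @export
fit_all_taxon_trends <- function(counts, metadata, level = "taxon",
                                 drop_scope = "joint", min_prevalence = 1) {
  prev <- 100 * rowMeans(counts > 0)
  keep <- rownames(counts)[prev >= min_prevalence]
  out <- lapply(keep, function(tx)
    fit_taxon_trend(counts, metadata, tx, level = level, drop_scope = drop_scope))
  do.call(rbind, out)
}

#' Classify taxon trends with FDR control
#'
#' Benjamini-Hochberg adjustment across converged taxa within each
#' taxonomic level; `direction` is the sign of the age estimate when the
#' raw p is below `alpha` (`none` otherwise); `fdr_significant` flags
#' the stricter FDR-level call.
#'
#' @param trends data.frame of taxon-trend records.
#' @param alpha direction threshold on the raw p.
#' @return the input with `p_fdr`, `direction`, `fdr_significant` filled.
#' @export
classify_trends <- function(trends, alpha = 0.05) {
  trends$fdr_significant <- FALSE
  for (lv in unique(trends$level)) {
    sel <- trends$level == lv & trends$converged
    trends$p_fdr[sel] <- stats::p.adjust(trends$p_raw[sel], method = "fdr")
  }
  ok <- trends$converged
  trends$direction[ok] <- ifelse(trends$p_raw[ok] < alpha,
                                 ifelse(trends$estimate[ok] > 0, "increase", "decrease"),
                                 "none")
  trends$fdr_significant <- !is.na(trends$p_fdr) & trends$p_fdr < alpha
  trends
}

#' Core/noncore repartition of age trends
#'
#' 3 x 2 contingency of trend direction (increase / decrease / none)
#' against core membership (prevalence at least 90% of samples,
#' inclusive), with proportions.
#'
#' @param trends classified taxon-trend records.
#' @param counts optional count table to recompute prevalence from
#'   presence; otherwise the `prevalence` column is used.
#' @param core_prevalence core threshold in percent.
#' @return list `counts` (3 x 2 matrix), `proportions` (column-wise).
#' @export
core_repartition <- function(trends, counts = NULL, core_prevalence = 90) {
  tr <- trends[trends$converged & !is.na(trends$direction), , drop = FALSE]
  prev <- tr$prevalence
  if (!is.null(counts)) {
    prev <- 100 * rowMeans(counts[tr$taxon, , drop = FALSE] > 0)
  }
  core <- factor(ifelse(prev >= core_prevalence, "core", "noncore"),
                 levels = c("core", "noncore"))
  dir <- factor(tr$direction, levels = c("increase", "decrease", "none"))
  tab <- table(direction = dir, core = core)
  list(counts = unclass(tab),
       proportions = sweep(unclass(tab), 2, pmax(colSums(tab), 1), "/"))
}
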