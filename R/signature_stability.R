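# ranks of the upper-triangle entries of d, returned as a full symmetric
# matrix so permuted lookups stay O(1)
.rank_matrix <- function(d) {
  n <- nrow(d)
  ix <- upper_pairs(n)
  r <- rank(d[ix])
  R <- matrix(0, n, n)
  R[ix] <- r
  R[ix[, c(2, 1)]] <- r
  R
}

#' Mantel test of a personal gut-community signature
#'
#' Spearman correlation between pairwise dissimilarity and a
#' same/different-host indicator (same = 0, different = 1, so r > 0
#' means intra-host pairs are less dissimilar than inter-host pairs).
#' The permutation null reassigns samples to hosts (free permutation of
#' the sample-to-host labels, preserving the per-host sample counts).
#' Permuting sample positions *within* hosts would leave the indicator
#' matrix — and hence r — exactly invariant, so the within-block scheme
#' is reserved for the time-gap test where it is well defined.
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata with `individual_id`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param alternative `"greater"` (one-sided concordance, default) or
#'   `"two.sided"`.
#' @return list `r, p, n_perm`.
#' @export
identity_mantel <- function(d, metadata, n_perm = 999, seed = 1L,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("n_perm must be at least 99")
  meta <- align_metadata(metadata, rownames(d))
  ind <- factor(meta$individual_id)
  if (nlevels(ind) < 2) stop("need at least two individuals")
  if (sum(table(ind) >= 2) < 2) stop("need >= 2 individuals with >= 2 samples")
  n <- nrow(d)
  ix <- upper_pairs(n)
  same <- as.integer(ind)[ix[, 1]] == as.integer(ind)[ix[, 2]]
  dv <- d[ix]
  r_obs <- stats::cor(dv, as.numeric(!same), method = "spearman")
  # r is affine-decreasing in the intra-pair rank sum at fixed class sizes
  R <- .rank_matrix(d)
  pos_by_host <- split(seq_len(n), ind)
  ipairs <- do.call(rbind, lapply(pos_by_host, function(pos) {
    if (length(pos) < 2) return(NULL)
    pr <- upper_pairs(length(pos))
    cbind(pos[pr[, 1]], pos[pr[, 2]])
  }))
  S_obs <- sum(R[ipairs])
  S_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      map <- sample.int(n)
      sum(R[cbind(map[ipairs[, 1]], map[ipairs[, 2]])])
    }, numeric(1))
  })
  p_low <- (sum(S_perm <= S_obs) + 1) / (n_perm + 1)   # small S  <=>  large r
  p_high <- (sum(S_perm >= S_obs) + 1) / (n_perm + 1)
  p <- if (alternative == "greater") p_low else min(1, 2 * min(p_low, p_high))
  list(r = r_obs, p = p, n_perm = n_perm)
}

#' Intra- vs inter-individual dissimilarity summary
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata with `individual_id`.
#' @return list with `intra_mean, intra_sd, inter_mean, inter_sd,
#'   percent_difference` (100 * (inter - intra) / inter).
#' @export
intra_inter_summary <- function(d, metadata) {
  meta <- align_metadata(metadata, rownames(d))
  ind <- meta$individual_id
  ix <- upper_pairs(nrow(d))
  same <- ind[ix[, 1]] == ind[ix[, 2]]
  if (!any(same)) stop("no intra-individual pairs")
  if (all(same)) stop("no inter-individual pairs")
  dv <- d[ix]
  inter <- mean(dv[!same])
  intra <- mean(dv[same])
  list(intra_mean = intra, intra_sd = stats::sd(dv[same]),
       inter_mean = inter, inter_sd = stats::sd(dv[!same]),
       percent_difference = 100 * (inter - intra) / inter)
}

# intra-individual pair bookkeeping shared by the time-gap analyses:
# one row per within-host sample pair with dissimilarity and day gap
.intra_pairs <- function(d, metadata) {
  meta <- align_metadata(metadata, rownames(d))
  out <- list()
  for (id in unique(meta$individual_id)) {
    pos <- which(meta$individual_id == id)
    if (length(pos) < 2) next
    pr <- upper_pairs(length(pos))
    a <- pos[pr[, 1]]; b <- pos[pr[, 2]]
    out[[id]] <- data.frame(
      individual_id = id, i = a, j = b, dissimilarity = d[cbind(a, b)],
      gap_days = abs(as.numeric(meta$collection_date[a] - meta$collection_date[b])),
      stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, out), meta = meta)
}

#' Mantel test of intra-individual dissimilarity versus time gap
#'
#' Spearman correlation between within-host pairwise dissimilarity and
#' the day gap between collections, with a restricted permutation null:
#' sample positions are permuted only within each host's own block (the
#' dissimilarity matrix is permuted, the gap structure stays fixed).
#' With `exclude_within_days` set, pairs at most that many days apart are
#' removed first (the plateau rule) and hosts left without pairs are
#' dropped and counted.
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata with `individual_id` and
#'   `collection_date`.
#' @param exclude_within_days drop pairs with gap <= this value
#'   (`NULL` keeps all pairs; the analysis uses 10 for the plateau test).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return list `r, p, n_individuals_retained, n_individuals_dropped,
#'   n_pairs, n_perm`.
#' @export
timegap_mantel <- function(d, metadata, exclude_within_days = NULL,
                           n_perm = 999, seed = 1L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("n_perm must be at least 99")
  ip <- .intra_pairs(d, metadata)
  pairs <- ip$pairs
  if (is.null(pairs) || nrow(pairs) == 0) stop("no intra-individual pairs")
  before <- unique(pairs$individual_id)
  if (!is.null(exclude_within_days))
    pairs <- pairs[pairs$gap_days > exclude_within_days, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no pairs remain after the exclusion window")
  retained <- unique(pairs$individual_id)
  r_obs <- stats::cor(pairs$dissimilarity, pairs$gap_days, method = "spearman")
  # the permutation p uses one identical rank procedure (first-occurrence
  # ties) for observed and permuted data, so the comparison is exchangeable
  gr <- rank(pairs$gap_days)
  grc <- gr - mean(gr)
  gss <- sqrt(sum(grc^2))
  spearman_first <- function(DV) {
    RD <- col_ranks_first(DV)
    RD <- RD - rep(colMeans(RD), each = nrow(RD))
    drop(crossprod(RD, grc)) / (sqrt(colSums(RD^2)) * gss)
  }
  s_obs <- spearman_first(cbind(pairs$dissimilarity))
  m <- nrow(pairs)
  blocks <- split(seq_len(nrow(ip$meta)), ip$meta$individual_id)
  r_perm <- withr::with_seed(seed, {
    P <- block_perm_matrix(blocks, nrow(ip$meta), n_perm)
    DV <- matrix(d[cbind(as.vector(P[pairs$i, ]), as.vector(P[pairs$j, ]))],
                 m, n_perm)
    spearman_first(DV)
  })
  r_perm <- r_perm[is.finite(r_perm)]
  p_high <- (sum(r_perm >= s_obs) + 1) / (length(r_perm) + 1)
  p_low <- (sum(r_perm <= s_obs) + 1) / (length(r_perm) + 1)
  p <- if (alternative == "greater") p_high else min(1, 2 * min(p_low, p_high))
  list(r = r_obs, p = p,
       n_individuals_retained = length(retained),
       n_individuals_dropped = length(setdiff(before, retained)),
       n_pairs = nrow(pairs), n_perm = n_perm)
}

#' Per-individual composition-stability coefficients
#'
#' For every host with enough within-host sample pairs, the correlation
#' between intra-individual dissimilarity and the day gap between
#' collections; more positive values indicate lower stability. Hosts
#' with too few pairs or zero-variance inputs are flagged, never
#' silently dropped.
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata.
#' @param method correlation flavor, `"spearman"` (default) or
#'   `"pearson"`.
#' @param min_pairs minimum pairs for a defined coefficient.
#' @return data.frame `individual_id, coefficient, n_pairs, age,
#'   age_category, flagged, reason`.
#' @export
stability_coefficients <- function(d, metadata, method = c("spearman", "pearson"),
                                   min_pairs = 3) {
  method <- match.arg(method)
  ip <- .intra_pairs(d, metadata)
  meta <- ip$meta
  ids <- unique(meta$individual_id)
  out <- lapply(ids, function(id) {
    sub <- ip$pairs[ip$pairs$individual_id == id, , drop = FALSE]
    age <- mean(meta$age[meta$individual_id == id])
    rec <- data.frame(individual_id = id, coefficient = NA_real_,
                      n_pairs = nrow(sub), age = age,
                      age_category = derive_age_category(age),
                      flagged = TRUE, reason = "", stringsAsFactors = FALSE)
    if (nrow(sub) < min_pairs) {
      rec$reason <- "too few pairs"
    } else if (stats::sd(sub$dissimilarity) == 0 || stats::sd(sub$gap_days) == 0) {
      rec$reason <- "zero variance"
    } else {
      rec$coefficient <- stats::cor(sub$dissimilarity, sub$gap_days, method = method)
      rec$flagged <- FALSE
    }
    rec
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis comparison of stability across age categories
#'
#' Tie-corrected Kruskal-Wallis H across `young`/`mid`/`old` with a
#' chi-square p on k - 1 df; flagged records are excluded; empty
#' categories reduce the df with a warning.
#'
#' @param records output of [stability_coefficients()].
#' @return list `statistic, df, p, n`.
#' @export
stability_by_age <- function(records) {
  ok <- records[!records$flagged & is.finite(records$coefficient), , drop = FALSE]
  grp <- droplevels(factor(ok$age_category, levels = c("young", "mid", "old")))
  if (nlevels(grp) < 2) stop("need at least two non-empty age categories")
  if (nlevels(grp) < 3) warning("an age category is empty; df reduced")
  if (stats::sd(ok$coefficient) == 0) {
    return(list(statistic = 0, df = nlevels(grp) - 1L, p = 1, n = nrow(ok)))
  }
  kw <- stats::kruskal.test(ok$coefficient, grp)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, n = nrow(ok))
}
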