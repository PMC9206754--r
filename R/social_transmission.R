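#' Grooming rates corrected for dyadic observation time
#'
#' @param grooming data.frame `id_a, id_b, events, duration_s, obs_hours`
#'   (unordered dyads unique, `id_a != id_b`).
#' @return the table with `frequency` (events/h) and `duration_rate`
#'   (s/h) added.
#' @export
dyadic_rates <- function(grooming) {
  req <- c("id_a", "id_b", "events", "duration_s", "obs_hours")
  miss <- setdiff(req, colnames(grooming))
  if (length(miss)) stop("missing grooming column(s): ", paste(miss, collapse = ", "))
  if (any(grooming$id_a == grooming$id_b)) stop("self-dyads are not allowed")
  key <- paste(pmin(grooming$id_a, grooming$id_b), pmax(grooming$id_a, grooming$id_b))
  if (anyDuplicated(key)) stop("duplicated unordered dyads")
  if (any(grooming$obs_hours <= 0)) stop("zero or negative dyadic observation time")
  grooming$frequency <- grooming$events / grooming$obs_hours
  grooming$duration_rate <- grooming$duration_s / grooming$obs_hours
  grooming
}

#' Mean between-host dissimilarity per grooming dyad
#'
#' For each dyad, the mean dissimilarity over all cross pairs of the two
#' members' samples (never within-host pairs). Dyads with a member
#' lacking samples are flagged missing. The returned table carries the
#' host-by-host mean-dissimilarity matrix as attribute `pair_means`
#' (used by the node-permutation null of [dyadic_model()]).
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata.
#' @param grooming output of [dyadic_rates()].
#' @return the dyad table with `mean_dissimilarity`, `n_sample_pairs`,
#'   `shared_group` and `flagged` added.
#' @export
dyadic_dissimilarity <- function(d, metadata, grooming) {
  meta <- align_metadata(metadata, rownames(d))
  ids <- unique(meta$individual_id)
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  npair <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  pos <- split(seq_len(nrow(meta)), meta$individual_id)
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    pa <- pos[[ids[a]]]; pb <- pos[[ids[b]]]
    if (length(pa) && length(pb)) {
      M[a, b] <- M[b, a] <- mean(d[pa, pb])
      npair[a, b] <- npair[b, a] <- length(pa) * length(pb)
    }
  }
  grp <- meta$group[match(ids, meta$individual_id)]
  names(grp) <- ids
  known <- grooming$id_a %in% ids & grooming$id_b %in% ids
  grooming$mean_dissimilarity <- NA_real_
  grooming$n_sample_pairs <- 0L
  grooming$mean_dissimilarity[known] <- M[cbind(grooming$id_a[known], grooming$id_b[known])]
  grooming$n_sample_pairs[known] <- npair[cbind(grooming$id_a[known], grooming$id_b[known])]
  grooming$shared_group <- as.character(grp[grooming$id_a])
  grooming$flagged <- !is.finite(grooming$mean_dissimilarity)
  attr(grooming, "pair_means") <- M
  attr(grooming, "host_group") <- grp
  grooming
}

#' Per-host top-partner and average grooming summaries
#'
#' @param grooming output of [dyadic_rates()].
#' @return data.frame `individual_id, top_frequency, avg_frequency,
#'   top_duration, avg_duration`.
#' @export
grooming_summaries <- function(grooming) {
  grooming <- if ("frequency" %in% colnames(grooming)) grooming else dyadic_rates(grooming)
  ids <- sort(unique(c(grooming$id_a, grooming$id_b)))
  out <- lapply(ids, function(id) {
    sub <- grooming[grooming$id_a == id | grooming$id_b == id, , drop = FALSE]
    data.frame(individual_id = id,
               top_frequency = max(sub$frequency),
               avg_frequency = mean(sub$frequency),
               top_duration = max(sub$duration_rate),
               avg_duration = mean(sub$duration_rate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Dyadic grooming-dissimilarity model with a node-permutation null
#'
#' Point estimate from ML beta regression of dyad mean dissimilarity on
#' the z-scored grooming predictor plus group. The non-independence of
#' dyads sharing a member is handled by a node-label permutation null:
#' host identities are permuted within groups, the dyadic mean
#' dissimilarities recomputed from the host-pair mean matrix, and a
#' group-partialled correlation between the predictor and
#' `logit(mean dissimilarity)` re-evaluated each time. `p_neg` is the
#' permutation probability of an effect at least as negative as
#' observed (values near 1 support social transmission), mirroring a
#' posterior probability of a negative effect.
#'
#' @param records output of [dyadic_dissimilarity()] (must carry the
#'   `pair_means` attribute).
#' @param predictor `"frequency"` or `"duration"`.
#' @param n_perm number of node permutations.
#' @param seed integer seed.
#' @return list `estimate, se, ci, p_neg, p_two, statistic, n_dyads,
#'   n_perm, fit`.
#' @export
dyadic_model <- function(records, predictor = c("frequency", "duration"),
                         n_perm = 999, seed = 1L) {
  predictor <- match.arg(predictor)
  M <- attr(records, "pair_means")
  grp <- attr(records, "host_group")
  if (is.null(M) || is.null(grp))
    stop("records must come from dyadic_dissimilarity()")
  col <- if (predictor == "frequency") "frequency" else "duration_rate"
  rec <- records[!records$flagged, , drop = FALSE]
  if (nrow(rec) < 30) stop("need at least 30 dyads")
  if (stats::sd(rec[[col]]) == 0) stop("degenerate (constant) predictor")
  x <- z_score(rec[[col]])
  y <- rec$mean_dissimilarity
  if (any(y <= 0 | y >= 1)) y <- smithson_transform(y, length(y))
  gfac <- factor(rec$shared_group)
  X <- if (nlevels(gfac) > 1) stats::model.matrix(~ x + gfac) else cbind(`(Intercept)` = 1, x = x)
  fit <- beta_ml(y, X)
  est <- fit$coefficients$mean[["x"]]
  se <- sqrt(diag(fit$vcov))[["x"]]
  ci <- est + c(-1, 1) * stats::qnorm(0.975) * se

  # permutation statistic: correlation between the predictor and
  # logit(dyadic dissimilarity) after partialling out group and additive
  # host effects (host indicator columns play the multimembership role:
  # host-level personalization differences cancel, leaving the
  # dyad-specific signal)
  hostmm <- matrix(0, nrow(rec), length(rownames(M)),
                   dimnames = list(NULL, rownames(M)))
  hostmm[cbind(seq_len(nrow(rec)), match(rec$id_a, colnames(hostmm)))] <- 1
  hostmm[cbind(seq_len(nrow(rec)), match(rec$id_b, colnames(hostmm)))] <- 1
  Xg <- cbind(if (nlevels(gfac) > 1) stats::model.matrix(~gfac)
              else matrix(1, nrow(rec), 1),
              hostmm[, colSums(hostmm) > 0, drop = FALSE])
  qrX <- qr(Xg)
  rx <- qr.resid(qrX, x)
  stat_obs <- function(yv) {
    ry <- qr.resid(qrX, stats::qlogis(pmin(pmax(yv, 1e-10), 1 - 1e-10)))
    sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  }
  s_obs <- stat_obs(y)
  hosts <- rownames(M)
  hgrp <- as.character(grp[hosts])
  s_perm <- withr::with_seed(seed, {
    P <- block_perm_matrix(split(seq_along(hosts), hgrp), length(hosts), n_perm)
    ia <- match(rec$id_a, hosts); ib <- match(rec$id_b, hosts)
    Y <- matrix(M[cbind(as.vector(P[ia, ]), as.vector(P[ib, ]))],
                nrow(rec), n_perm)
    keep <- colSums(!is.finite(Y)) == 0
    Y <- stats::qlogis(pmin(pmax(Y[, keep, drop = FALSE], 1e-10), 1 - 1e-10))
    RY <- qr.resid(qrX, Y)
    colSums(rx * RY) / sqrt(sum(rx^2) * colSums(RY^2))
  })
  s_perm <- s_perm[is.finite(s_perm)]
  np <- length(s_perm)
  p_neg <- (sum(s_perm >= s_obs) + 1) / (np + 1)
  p_two <- min(1, 2 * min(p_neg, (sum(s_perm <= s_obs) + 1) / (np + 1)))
  list(estimate = est, se = se, ci = ci, p_neg = p_neg, p_two = p_two,
       statistic = s_obs, n_dyads = nrow(rec), n_perm = np, fit = fit,
       method = "node-permutation")
}

#' Age regression of per-host grooming summaries
#'
#' Ordinary least squares of a z-scored grooming summary (top partner or
#' group average, frequency or duration) on host age, correcting for
#' social group; one row per host. Influence diagnostics (max |DFBETA|
#' of the age term) are reported.
#'
#' @param metadata per-sample metadata (host age and group are taken per
#'   host).
#' @param grooming_summary output of [grooming_summaries()].
#' @param summary `"top"` or `"average"` partner summary.
#' @param measure `"frequency"` or `"duration"`.
#' @return list of class `grooming_age_fit`: `coefficients` table,
#'   `age_slope`, `ci`, `overall_F`, `max_dfbeta_age`, `n`, `fit`.
#' @export
grooming_age_regression <- function(metadata, grooming_summary,
                                    summary = c("top", "average"),
                                    measure = c("frequency", "duration")) {
  summary <- match.arg(summary)
  measure <- match.arg(measure)
  ids <- unique(metadata$individual_id)
  if (length(ids) < 10) stop("need at least 10 hosts")
  col <- paste0(if (summary == "top") "top_" else "avg_", measure)
  idx <- match(ids, grooming_summary$individual_id)
  df <- data.frame(
    individual_id = ids,
    age = vapply(ids, function(i) mean(metadata$age[metadata$individual_id == i]),
                 numeric(1)),
    group = factor(vapply(ids, function(i)
      as.character(metadata$group[metadata$individual_id == i][1]), character(1))),
    y = grooming_summary[[col]][idx], stringsAsFactors = FALSE)
  if (any(is.na(df$y))) stop("hosts missing from grooming summary")
  df$y_z <- z_score(df$y)
  df$age_z <- z_score(df$age)
  fit <- stats::lm(y_z ~ age_z + group, data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit)["age_z", ]
  dfb <- stats::dfbeta(fit)[, "age_z"]
  tab <- data.frame(term = rownames(sm$coefficients), sm$coefficients,
                    check.names = FALSE, row.names = NULL)
  structure(list(coefficients = tab,
                 age_slope = unname(stats::coef(fit)["age_z"]),
                 ci = unname(ci),
                 p_age = sm$coefficients["age_z", "Pr(>|t|)"],
                 overall_F = unname(sm$fstatistic["value"]),
                 max_dfbeta_age = max(abs(dfb)), n = nrow(df), fit = fit),
            class = "grooming_age_fit")
}

#' @export
print.grooming_age_fit <- function(x, ...) {
  cat("Grooming-age regression (n =", x$n, "hosts)\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("age slope %.3f [%.3f, %.3f], p = %.4g\n",
              x$age_slope, x$ci[1], x$ci[2], x$p_age))
  invisible(x)
}
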