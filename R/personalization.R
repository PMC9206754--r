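#' Closest-neighbour minimum dissimilarity per sample
#'
#' For each sample, the smallest dissimilarity to any sample from a
#' *different* host in the *same* group collected in the *same* season.
#' Samples with no eligible comparator are flagged missing, never
#' silently dropped; ties are broken by the lexicographically smallest
#' comparator id so the comparator column is reproducible.
#'
#' @param d labeled dissimilarity matrix.
#' @param metadata per-sample metadata with `individual_id`, `group`,
#'   `season` (and covariates carried through: `age`, `gestation`).
#' @return data.frame `sample_id, min_dissimilarity, comparator,
#'   individual_id, age, season, group, gestation, flagged`.
#' @export
min_inter_dissimilarity <- function(d, metadata) {
  meta <- align_metadata(metadata, rownames(d))
  n <- nrow(d)
  recs <- lapply(seq_len(n), function(i) {
    elig <- which(meta$individual_id != meta$individual_id[i] &
                    meta$group == meta$group[i] &
                    meta$season == meta$season[i])
    rec <- data.frame(sample_id = meta$sample_id[i],
                      min_dissimilarity = NA_real_, comparator = NA_character_,
                      individual_id = meta$individual_id[i], age = meta$age[i],
                      season = meta$season[i], group = meta$group[i],
                      gestation = meta$gestation[i], flagged = TRUE,
                      stringsAsFactors = FALSE)
    if (length(elig)) {
      v <- d[i, elig]
      best <- elig[v == min(v)]
      best <- best[order(meta$sample_id[best])][1]
      rec$min_dissimilarity <- d[i, best]
      rec$comparator <- meta$sample_id[best]
      rec$flagged <- FALSE
    }
    rec
  })
  out <- do.call(rbind, recs)
  if (all(out$flagged)) stop("no sample has an eligible comparator")
  out
}

#' Age model of closest-neighbour personalization
#'
#' Variable-dispersion beta regression of minimum dissimilarity:
#' `logit(mean) ~ z(age) * season + group + gestation`,
#' `log(precision) ~ z(age)`; full-versus-reference likelihood-ratio
#' test where the reference lacks age, season and their interaction;
#' host-clustered robust standard errors; optional percentile CIs by
#' seeded parametric bootstrap. A positive precision-age slope means the
#' spread of minimum dissimilarity shrinks with age (beta variance is
#' `mu (1 - mu) / (1 + phi)`).
#'
#' @param records output of [min_inter_dissimilarity()] (flagged rows are
#'   excluded).
#' @param n_boot parametric-bootstrap draws for percentile CIs (0 skips).
#' @param seed bootstrap seed.
#' @return list of class `personalization_fit`: `fit` (the [beta_ml()]
#'   object), coefficient table, `lrt`, `ci`, `deviation` note.
#' @export
fit_personalization_model <- function(records, n_boot = 1000, seed = 1L) {
  rec <- records[!records$flagged, , drop = FALSE]
  if (nrow(rec) < 20) stop("too few records with eligible comparators")
  y <- rec$min_dissimilarity
  if (any(y <= 0 | y >= 1)) y <- smithson_transform(y, length(y))
  rec$age_z <- z_score(rec$age)
  rec$gestation <- as.numeric(rec$gestation)
  rec$season <- droplevels(factor(rec$season))
  rec$group <- droplevels(factor(rec$group))
  Xf <- stats::model.matrix(~ age_z * season + group + gestation, rec)
  Xr <- stats::model.matrix(~ group + gestation, rec)
  Z <- stats::model.matrix(~ age_z, rec)
  cl <- factor(rec$individual_id)
  full <- beta_ml(y, Xf, Z, cluster = cl)
  if (!full$converged)
    stop("personalization model did not converge (gradient norm ",
         format(full$gradient_norm), ")")
  ref <- beta_ml(y, Xr, Z, cluster = cl)
  lrt <- lrt_beta_ml(full, ref, overdispersion_correct = FALSE)
  vc <- full$vcov_cluster
  se <- sqrt(pmax(diag(vc), 0))
  tab <- data.frame(term = names(full$par), estimate = unname(full$par),
                    se_cluster = unname(se),
                    p = unname(2 * stats::pnorm(-abs(full$par / se))),
                    stringsAsFactors = FALSE)
  ci <- beta_ml_boot_ci(full, n_boot = n_boot, seed = seed)
  structure(list(fit = full, reference = ref, coefficients = tab, lrt = lrt,
                 ci = ci, n = nrow(rec),
                 age_estimate = full$coefficients$mean[["age_z"]],
                 dispersion_age_estimate = full$coefficients$precision[["age_z"]],
                 deviation = "fixed-effects ML with host-clustered robust SE (random-slope GLMM approximated)"),
            class = "personalization_fit")
}

#' @export
print.personalization_fit <- function(x, ...) {
  cat("Closest-neighbour personalization model (beta ML, n =", x$n, ")\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("Full vs reference LRT: chi2 = %.3f, df = %d, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p))
  cat("Note:", x$deviation, "\n")
  invisible(x)
}

#' Personalization model with grooming covariates
#'
#' Adds each host's z-scored top-partner and average grooming frequency
#' to the personalization mean model and reports how the age coefficient
#' moves.
#'
#' @param records output of [min_inter_dissimilarity()].
#' @param grooming_summary output of [grooming_summaries()].
#' @param measure grooming measure to use.
#' @param n_boot,seed bootstrap controls, as in
#'   [fit_personalization_model()].
#' @return list `fit`, coefficient table, `age_estimate`,
#'   `age_estimate_without_grooming`, grooming coefficient rows.
#' @export
personalization_with_grooming <- function(records, grooming_summary,
                                          measure = c("frequency", "duration"),
                                          n_boot = 0, seed = 1L) {
  measure <- match.arg(measure)
  base <- fit_personalization_model(records, n_boot = 0, seed = seed)
  rec <- records[!records$flagged, , drop = FALSE]
  topcol <- paste0("top_", measure)
  avgcol <- paste0("avg_", measure)
  idx <- match(rec$individual_id, grooming_summary$individual_id)
  if (any(is.na(idx))) stop("hosts missing from grooming summary")
  rec$top_groom <- z_score(grooming_summary[[topcol]][idx])
  rec$avg_groom <- z_score(grooming_summary[[avgcol]][idx])
  y <- rec$min_dissimilarity
  if (any(y <= 0 | y >= 1)) y <- smithson_transform(y, length(y))
  rec$age_z <- z_score(rec$age)
  rec$gestation <- as.numeric(rec$gestation)
  rec$season <- droplevels(factor(rec$season))
  rec$group <- droplevels(factor(rec$group))
  Xf <- stats::model.matrix(~ age_z * season + group + gestation +
                              top_groom + avg_groom, rec)
  Z <- stats::model.matrix(~ age_z, rec)
  cl <- factor(rec$individual_id)
  full <- beta_ml(y, Xf, Z, cluster = cl)
  vc <- full$vcov_cluster
  se <- sqrt(pmax(diag(vc), 0))
  tab <- data.frame(term = names(full$par), estimate = unname(full$par),
                    se_cluster = unname(se),
                    p = unname(2 * stats::pnorm(-abs(full$par / se))),
                    stringsAsFactors = FALSE)
  ci <- beta_ml_boot_ci(full, n_boot = n_boot, seed = seed)
  list(fit = full, coefficients = tab, ci = ci,
       age_estimate = full$coefficients$mean[["age_z"]],
       age_estimate_without_grooming = base$age_estimate,
       grooming_terms = tab[tab$term %in% c("top_groom", "avg_groom"), ])
}
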