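#' Run the full trajectory analysis end to end
#'
#' Sequences preparation (spurious-signal filter, rarefaction at the
#' minimum depth), alpha diversity and its age models, the dissimilarity
#' matrices, identity and time-gap Mantel tests, stability coefficients
#' and their age comparison, PERMANOVA, per-taxon trends with the
#' core/noncore repartition, closest-neighbour personalization, and the
#' dyadic grooming analyses. Every stage writes a TSV/JSON file into
#' `out_dir` and the run closes with a manifest recording seeds, package
#' version, row counts and the modeling deviation notes. All randomness
#' flows from `config$seed` through fixed per-stage offsets so stage
#' reruns reproduce full-run values.
#'
#' @param config list (or YAML path) with entries: either `counts`,
#'   `metadata`, `tree` (newick), `grooming` file paths, or
#'   `simulate = TRUE` plus optional `sim` parameter overrides; `seed`
#'   (default 1); `out_dir`; `n_perm` (default 999); `exclude_days`
#'   (default 10); `fdr_alpha` (default 0.05); `trend_level` (default
#'   `"genus"`); `n_boot` (default 0).
#' @return invisibly, a list of all stage results (also serialized).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_perm <- config$n_perm %||% 999
  exclude_days <- config$exclude_days %||% 10
  results <- list()
  stage_log <- list()
  log_stage <- function(name, ...) {
    stage_log[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)), unlist(list(...)),
                                   sep = "=", collapse = " "))
  }

  if (isTRUE(config$simulate)) {
    params <- do.call(sim_params, config$sim %||% list())
    data <- simulate_dataset(params, seed = seed)
  } else {
    data <- list(
      table = load_count_table(config$counts),
      metadata = load_metadata(config$metadata),
      tree = if (!is.null(config$tree) && file.exists(config$tree))
        ape::read.tree(config$tree) else NULL,
      grooming = if (!is.null(config$grooming)) utils::read.csv(config$grooming)
        else NULL,
      taxonomy = if (!is.null(config$taxonomy)) utils::read.table(
        config$taxonomy, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
        else NULL)
  }
  meta <- data$metadata
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  prepared <- filter_spurious(data$table)
  rep_ <- attr(prepared, "removal_report")
  log_stage("prep", taxa = nrow(prepared), samples = ncol(prepared),
            taxa_dropped = length(rep_$taxa_dropped), cells_zeroed = rep_$cells_zeroed)
  rarefied <- rarefy(prepared, seed = seed + 5L)
  write_count_table(rarefied, file.path(out_dir, "rarefied_counts.tsv"))

  alpha <- alpha_diversity(prepared, tree = data$tree)
  utils::write.table(alpha, file.path(out_dir, "alpha.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  alpha_fits <- lapply(intersect(c("richness", "evenness",
                                   if (!is.null(data$tree)) "faith_pd"),
                                 colnames(alpha)),
                       function(r) fit_alpha_age_model(alpha, meta, r))
  names(alpha_fits) <- vapply(alpha_fits, `[[`, "", "response")
  results$alpha <- list(table = alpha, fits = alpha_fits)
  log_stage("alpha", responses = length(alpha_fits))

  mats <- if (!is.null(data$tree)) all_metrics(rarefied, data$tree) else {
    message("[beta] no tree supplied: UniFrac stages skipped, Bray-Curtis only")
    list(BC = bray_curtis(rarefied))
  }
  for (m in names(mats))
    write_distance_matrix(mats[[m]], file.path(out_dir, paste0("dist_", m, ".tsv")))
  log_stage("beta", metrics = paste(names(mats), collapse = ","))

  results$signature <- lapply(mats, function(dm) {
    list(identity = identity_mantel(dm, meta, n_perm = n_perm, seed = seed + 6L),
         intra_inter = intra_inter_summary(dm, meta),
         timegap_all = timegap_mantel(dm, meta, n_perm = n_perm, seed = seed + 6L),
         timegap_excl = timegap_mantel(dm, meta, exclude_within_days = exclude_days,
                                       n_perm = n_perm, seed = seed + 6L))
  })
  stab <- stability_coefficients(mats$BC, meta)
  utils::write.table(stab, file.path(out_dir, "stability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$stability <- list(records = stab, by_age = stability_by_age(stab))
  log_stage("stability", n = nrow(stab),
            kw = results$stability$by_age$statistic)

  results$permanova <- lapply(mats, function(dm) {
    list(identity = permanova_identity(dm, meta, n_perm = max(n_perm, 999),
                                       seed = seed + 7L),
         terms = permanova(dm, meta,
                           terms = c("season", "group", "age", "gestation"),
                           strata = "individual_id", n_perm = max(n_perm, 999),
                           seed = seed + 7L))
  })
  log_stage("permanova", metrics = length(results$permanova))

  if (!is.null(data$taxonomy)) {
    lvl <- config$trend_level %||% "genus"
    agg <- aggregate_taxa(prepared, data$taxonomy, lvl)
    trends <- classify_trends(fit_all_taxon_trends(agg, meta, level = lvl),
                              alpha = config$fdr_alpha %||% 0.05)
    utils::write.table(trends, file.path(out_dir, "trends.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$trends <- list(table = trends, repartition = core_repartition(trends, agg))
    log_stage("trends", fitted = sum(trends$converged), level = lvl)
  }

  results$personalization <- lapply(mats, function(dm) {
    recs <- min_inter_dissimilarity(dm, meta)
    list(records = recs,
         fit = fit_personalization_model(recs, n_boot = config$n_boot %||% 0,
                                         seed = seed + 9L))
  })
  log_stage("personalization", metrics = length(results$personalization))

  if (!is.null(data$grooming)) {
    rates <- dyadic_rates(data$grooming)
    dyads <- dyadic_dissimilarity(mats$BC, meta, rates)
    gs <- grooming_summaries(rates)
    results$social <- list(
      dyadic = tryCatch(dyadic_model(dyads, "frequency", n_perm = n_perm,
                                     seed = seed + 8L), error = function(e) e$message),
      top_age = grooming_age_regression(meta, gs, "top", "frequency"),
      avg_age = grooming_age_regression(meta, gs, "average", "frequency"),
      with_grooming = personalization_with_grooming(
        results$personalization$BC$records, gs, seed = seed + 9L))
    utils::write.table(dyads[, setdiff(colnames(dyads), "flagged")],
                       file.path(out_dir, "dyads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("social", dyads = sum(!dyads$flagged))
  }

  manifest <- list(
    package = "microtraj",
    version = as.character(utils::packageVersion("microtraj")),
    seed = seed,
    seed_rule = "stage seeds are seed + fixed offsets (rarefy +5, mantel +6, permanova +7, social +8, personalization +9)",
    n_perm = n_perm,
    deviations = list(
      alpha = "fixed-effects ML + host-clustered robust SE in place of random-slope GLMMs",
      dyadic = "node-permutation inference in place of Bayesian multimembership fit"),
    stages = stage_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Calibration / power grid over generator effect sizes
#'
#' For each `(beta_stab, beta_pers, lambda_social)` cell, simulates
#' `n_replicates` cohorts and records the rejection rate of the
#' stability age comparison, the sign-recovery rate of the
#' personalization age and dispersion-age slopes, and the rate of
#' strong dyadic support (`p_neg >= 0.9`).
#'
#' @param grid data.frame with columns `beta_stab, beta_pers,
#'   lambda_social`.
#' @param n_replicates cohorts per cell.
#' @param seed master seed.
#' @param params_base baseline [sim_params()] overrides (list), e.g.
#'   reduced cohort size for desk-scale runs.
#' @param n_perm permutations for the dyadic null.
#' @param alpha rejection level.
#' @return `grid` with rate columns appended.
#' @export
recovery_suite <- function(grid, n_replicates = 20, seed = 1L,
                           params_base = list(n_individuals = 20, n_taxa = 60,
                                              samples_per_season = 2),
                           n_perm = 199, alpha = 0.05) {
  out <- grid
  out$stability_reject <- out$pers_age_sign <- out$pers_disp_sign <-
    out$dyadic_support <- NA_real_
  for (g in seq_len(nrow(grid))) {
    hits <- matrix(NA, n_replicates, 4)
    for (r in seq_len(n_replicates)) {
      pars <- do.call(sim_params, c(params_base,
                                    list(beta_stab = grid$beta_stab[g],
                                         beta_pers = grid$beta_pers[g],
                                         lambda_social = grid$lambda_social[g])))
      dat <- simulate_dataset(pars, seed = seed + g * 10000L + r * 10L)
      dm <- bray_curtis(rarefy(dat$table, seed = seed + r))
      kw <- stability_by_age(stability_coefficients(dm, dat$metadata))
      fit <- tryCatch(fit_personalization_model(
        min_inter_dissimilarity(dm, dat$metadata), n_boot = 0),
        error = function(e) NULL)
      dy <- tryCatch(dyadic_model(
        dyadic_dissimilarity(dm, dat$metadata, dyadic_rates(dat$grooming)),
        "frequency", n_perm = n_perm, seed = seed + r),
        error = function(e) NULL)
      hits[r, ] <- c(kw$p < alpha,
                     if (is.null(fit)) NA else fit$age_estimate > 0,
                     if (is.null(fit)) NA else fit$dispersion_age_estimate > 0,
                     if (is.null(dy)) NA else dy$p_neg >= 0.9)
    }
    rates <- colMeans(hits, na.rm = TRUE)
    out$stability_reject[g] <- rates[1]
    out$pers_age_sign[g] <- rates[2]
    out$pers_disp_sign[g] <- rates[3]
    out$dyadic_support[g] <- rates[4]
  }
  out
}
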