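#' Simulation parameters for a longitudinal gut-microbiome cohort
#'
#' Defaults emulate the study design the package targets: 51 adult
#' females aged 6--26, three social groups, three seasonal sampling
#' windows over roughly 540 days with four samples per female per season,
#' 300 taxa of which about 55% form a high-prevalence core, individual
#' compositional signatures whose magnitude can scale with age
#' (`beta_pers`), continuous-time AR(1) temporal turnover whose
#' innovation scale can grow with age (`beta_stab`), season and group
#' shifts, Dirichlet-multinomial read noise, lognormal sequencing depth,
#' within-group grooming dyads whose rate declines with dyad age
#' (`beta_groom`), and optional signature homogenization between top
#' grooming partners (`lambda_social`).
#'
#' @param n_individuals number of hosts.
#' @param age_range uniform support of host ages (years).
#' @param n_groups number of social groups (balanced assignment).
#' @param season_labels season names, chronological.
#' @param samples_per_season samples per host per seasonal window.
#' @param season_starts day offsets of the season windows.
#' @param season_length window length in days.
#' @param study_start calendar date of day 0.
#' @param gestation_prob per-sample Bernoulli gestation probability
#'   (pure noise: gestation has no effect in the generator).
#' @param rainfall_means,rainfall_sd mm of 30-day cumulative rainfall per
#'   season (collinear with season by construction) and its noise sd.
#' @param n_taxa,core_fraction taxa count and fraction forming the core.
#' @param base_core_mean,base_rare_mean,sigma_base log-abundance baseline
#'   means of core/rare taxa and their spread.
#' @param sigma_ind permanent individual-signature scale.
#' @param beta_pers age coefficient of the signature scale
#'   (`exp(beta_pers * z(age))` multiplier; > 0 means older hosts are
#'   more personalized).
#' @param sigma_pers_het between-host spread of the personalization
#'   level at the young end of the age range, decaying linearly to zero
#'   at the old end (aging drives hosts toward a uniformly high
#'   personalization ceiling); inactive when `beta_pers = 0` so null
#'   cohorts have age-invariant spread.
#' @param rho per-30-day AR(1) autocorrelation of the fast temporal
#'   component (low values reproduce the sharp few-day rise of
#'   within-host dissimilarity followed by a plateau).
#' @param sigma_eps stationary scale of the fast temporal component at
#'   mean age.
#' @param beta_fast age coefficient of the fast-component scale
#'   (negative by default: young hosts fluctuate more from day to day,
#'   the mirror image of the progressive drift that grows with age).
#' @param sigma_drift full-study scale of the slow directed drift along a
#'   host-specific community axis (per-taxon sd accumulated over the
#'   whole study for a host at mean age).
#' @param beta_stab age coefficient of the drift scale
#'   (`sigma_drift * exp(beta_stab * z(age))`; > 0 means older hosts
#'   keep diverging from themselves, i.e. are less stable).
#' @param sigma_season,sigma_group scales of season and group shifts.
#' @param sigma_sample scale of transient per-sample latent noise (the
#'   day-to-day floor of compositional dissimilarity that no covariate
#'   explains).
#' @param theta Dirichlet-multinomial overdispersion (0 = multinomial);
#'   kept small by default so core taxa are not zero-inflated away.
#' @param depth_meanlog,depth_sdlog lognormal sequencing-depth parameters.
#' @param groom_mean_rate,groom_sd mean grooming rate (events/h) and
#'   lognormal spread.
#' @param beta_groom slope of log grooming rate on z(mean dyad age),
#'   negative for social disengagement with age.
#' @param obs_hours_range dyadic observation time range (hours).
#' @param bout_seconds mean grooming bout duration (s).
#' @param lambda_social homogenization weight between top grooming
#'   partners' signatures, in \[0, 1).
#' @param turnover_rank dimension of each host's temporal-drift subspace:
#'   the AR(1) process lives on this many host-specific community axes
#'   (low rank mimics real gut series, where a few taxon trade-offs carry
#'   most of the short-term turnover), with per-taxon marginal sd equal
#'   to the innovation scale.
#' @param taxon_age_slopes optional per-taxon slope of latent log
#'   abundance on z(age), recycled to `n_taxa` (used to seed known
#'   age trends for recovery tests).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 51, age_range = c(6, 26), n_groups = 3,
                       season_labels = c("rich", "lean", "intermediate"),
                       samples_per_season = 4,
                       season_starts = c(0, 240, 480), season_length = 60,
                       study_start = as.Date("2018-06-01"),
                       gestation_prob = 0.2,
                       rainfall_means = c(rich = 260, lean = 30, intermediate = 120),
                       rainfall_sd = 25,
                       n_taxa = 300, core_fraction = 0.55,
                       base_core_mean = 0, base_rare_mean = -3.5, sigma_base = 1,
                       sigma_ind = 1.1, beta_pers = 0.3, sigma_pers_het = 2,
                       rho = 0.1, sigma_eps = 0.15, beta_fast = -0.6,
                       sigma_drift = 0.8, beta_stab = 0.4,
                       sigma_season = 0.15, sigma_group = 0.3,
                       sigma_sample = 0.3, theta = 5e-4,
                       depth_meanlog = log(9000), depth_sdlog = 0.3,
                       groom_mean_rate = 0.5, groom_sd = 0.3, beta_groom = -0.3,
                       obs_hours_range = c(20, 60), bout_seconds = 60,
                       lambda_social = 0.5,
                       turnover_rank = 1,
                       taxon_age_slopes = NULL) {
  p <- as.list(environment())
  if (p$rho < 0 || p$rho >= 1) stop("rho must lie in [0, 1)")
  scales <- c(p$sigma_base, p$sigma_ind, p$sigma_eps, p$sigma_season,
              p$sigma_group, p$theta, p$groom_sd)
  if (any(scales < 0)) stop("scale parameters must be non-negative")
  if (p$lambda_social < 0 || p$lambda_social >= 1)
    stop("lambda_social must lie in [0, 1)")
  if (p$n_taxa < 2) stop("need at least 2 taxa")
  class(p) <- "sim_params"
  p
}

#' Simulate a rooted taxon tree
#'
#' Random bifurcating topology with branch lengths drawn Exponential with
#' mean 0.1; leaves labeled like taxa (`t001`, ...).
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] rooted tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("need at least 2 taxa for a tree")
  tr <- withr::with_seed(seed,
    ape::rtree(n_taxa, rooted = TRUE, br = function(k) stats::rexp(k) * 0.1))
  tr$tip.label <- taxon_ids(n_taxa)
  tr
}

taxon_ids <- function(n) sprintf("t%03d", seq_len(n))

#' Simulate the longitudinal sampling design
#'
#' Each host gets a fixed age (uniform on `age_range`) and a balanced
#' group assignment; within every seasonal window, `samples_per_season`
#' collection dates at least two days apart; gestation is Bernoulli
#' noise; rainfall follows the season with noise.
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed.
#' @return metadata data.frame (one row per sample).
#' @export
simulate_cohort <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(seed, {
    n <- params$n_individuals
    ids <- sprintf("F%02d", seq_len(n))
    # stratified uniform ages: every cohort spans the whole adult range
    # (field studies select focal females across the age distribution)
    q <- (seq_len(n) - stats::runif(n)) / n
    ages <- params$age_range[1] + diff(params$age_range) * sample(q)
    groups <- paste0("G", rep_len(seq_len(params$n_groups), n))
    rows <- list()
    for (i in seq_len(n)) {
      for (s in seq_along(params$season_labels)) {
        grid <- seq(0, params$season_length - 1, by = 2)
        days <- sort(sample(grid, params$samples_per_season))
        date <- params$study_start + params$season_starts[s] + days
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = ids[i], age = ages[i], group = groups[i],
          season = params$season_labels[s], collection_date = date,
          stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, rows)
    meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
    meta$gestation <- stats::rbinom(nrow(meta), 1, params$gestation_prob)
    meta$rainfall_30d <- pmax(0, params$rainfall_means[meta$season] +
                                   stats::rnorm(nrow(meta), 0, params$rainfall_sd))
    meta$age_category <- derive_age_category(meta$age)
    meta$group <- factor(meta$group)
    meta$season <- factor(meta$season, levels = params$season_labels)
    rownames(meta) <- NULL
    meta[, c("sample_id", "individual_id", "age", "age_category", "group",
             "season", "gestation", "collection_date", "rainfall_30d")]
  })
}

# nested dummy taxonomy: phyla > families > genera
simulate_taxonomy <- function(n_taxa, seed = 1L, n_phyla = 4, fam_per_phylum = 3,
                              gen_per_family = 4) {
  withr::with_seed(seed, {
    phy <- sample(sprintf("P%02d", seq_len(n_phyla)), n_taxa, replace = TRUE)
    fam <- paste0(phy, sprintf(".f%d", sample.int(fam_per_phylum, n_taxa, replace = TRUE)))
    gen <- paste0(fam, sprintf(".g%d", sample.int(gen_per_family, n_taxa, replace = TRUE)))
    data.frame(taxon_id = taxon_ids(n_taxa), phylum = phy, family = fam,
               genus = gen, stringsAsFactors = FALSE)
  })
}

#' Simulate read counts for a cohort
#'
#' Latent log abundance for taxon t of host i at time tau is
#' `base_t + group_g(i),t + season_s(tau),t + u_it * exp(beta_pers * z(age_i))
#' + eps_it(tau)`, with `u_it ~ N(0, sigma_ind^2)` the permanent personal
#' signature and `eps` a per-host continuous-time AR(1) with correlation
#' `rho^(gap_days/30)` and stationary sd
#' `sigma_eps * exp(beta_stab * z(age_i))`. Optional per-taxon age slopes
#' add `taxon_age_slopes[t] * z(age_i)`. When `lambda_social > 0` and a
#' grooming table is supplied, each host's signature is blended with its
#' top partner's mean signature with weight
#' `lambda_social * rate/max(rate)`. Compositions are the softmax over
#' taxa; counts are Dirichlet-multinomial with parameter
#' `composition / theta` at a lognormal depth.
#'
#' @param params a [sim_params()] list.
#' @param metadata output of [simulate_cohort()].
#' @param grooming optional [simulate_grooming()] table (needed for
#'   `lambda_social > 0`).
#' @param seed integer seed.
#' @return list with `table` (taxa x samples integer matrix),
#'   `taxonomy`, and `ground_truth` (parameters, per-host signatures,
#'   latent compositions).
#' @export
simulate_counts <- function(params, metadata, grooming = NULL, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  T_ <- params$n_taxa
  ids <- unique(metadata$individual_id)
  n_ind <- length(ids)
  ages <- metadata$age[match(ids, metadata$individual_id)]
  z_age <- (ages - mean(ages)) / stats::sd(ages)
  taxonomy <- simulate_taxonomy(T_, seed = seed + 7L)
  out <- withr::with_seed(seed, {
    n_core <- round(params$core_fraction * T_)
    # core baselines get half the spread so every core taxon stays well
    # above the detection floor at the simulated depths
    base <- c(stats::rnorm(n_core, params$base_core_mean, 0.35 * params$sigma_base),
              stats::rnorm(T_ - n_core, params$base_rare_mean, params$sigma_base))
    core_flag <- rep(c(TRUE, FALSE), c(n_core, T_ - n_core))
    groups <- levels(metadata$group)
    seasons <- levels(metadata$season)
    g_eff <- matrix(stats::rnorm(length(groups) * T_, 0, params$sigma_group),
                    length(groups), T_, dimnames = list(groups, NULL))
    s_eff <- matrix(stats::rnorm(length(seasons) * T_, 0, params$sigma_season),
                    length(seasons), T_, dimnames = list(seasons, NULL))
    slopes <- if (is.null(params$taxon_age_slopes)) rep(0, T_) else
      rep_len(params$taxon_age_slopes, T_)
    # random signature direction; magnitude grows with age (beta_pers)
    # while its between-host spread shrinks with age: young hosts differ
    # in how personalized they already are, old hosts converge to a
    # uniformly high personalization level. The heterogeneity term is
    # tied to beta_pers so a beta_pers = 0 null has age-invariant spread.
    # random sign pattern with fixed per-taxon magnitude: every host's
    # signature perturbs the community by the same amount, in its own
    # direction, so the effective personalization level is controlled by
    # pers_scale alone rather than by direction luck
    u <- matrix(sign(stats::rnorm(n_ind * T_)) * params$sigma_ind,
                n_ind, T_, dimnames = list(ids, NULL))
    if (params$lambda_social > 0 && !is.null(grooming) && nrow(grooming) > 0) {
      rate <- grooming$events / grooming$obs_hours
      ref <- stats::quantile(rate[rate > 0], 0.9, names = FALSE)
      w <- params$lambda_social * pmin(1, rate / max(ref, 1e-12))
      top <- vapply(ids, function(id) {
        hit <- which(grooming$id_a == id | grooming$id_b == id)
        if (!length(hit)) return(NA_integer_)
        hit[which.max(rate[hit])]
      }, integer(1))
      u0 <- u
      for (k in seq_along(ids)) {
        h <- top[k]
        if (is.na(h)) next
        partner <- setdiff(c(grooming$id_a[h], grooming$id_b[h]), ids[k])
        ubar <- (u0[ids[k], ] + u0[partner, ]) / 2
        u[ids[k], ] <- (1 - w[h]) * u0[ids[k], ] + w[h] * ubar
      }
    }
    # quantile-balanced heterogeneity assigned within consecutive age
    # blocks: every age class realizes the nominal between-host spread of
    # personalization levels in every cohort (with ~6 hosts per class,
    # i.i.d. draws often collapse by chance)
    pers_het <- numeric(n_ind)
    ord <- order(z_age)
    bsize <- 4L
    for (s0 in seq(1, n_ind, by = bsize)) {
      blk <- ord[s0:min(s0 + bsize - 1, n_ind)]
      qs <- stats::qnorm((seq_along(blk) - 0.5) / length(blk))
      pers_het[blk] <- sample(qs) * params$sigma_pers_het
    }
    het_ramp <- pmin(1, pmax(0, (max(z_age) - z_age) / max(diff(range(z_age)), 1e-9)))
    pers_scale <- exp(params$beta_pers * z_age +
                        pers_het * het_ramp * (params$beta_pers > 0))
    # cap the per-taxon latent shift so no host wipes out core taxa
    pers_scale <- pmin(pers_scale, 2.2 / max(params$sigma_ind, 1e-9))
    drift_scale <- params$sigma_drift * exp(params$beta_stab * z_age)
    fast_scale <- params$sigma_eps * exp((params$beta_fast %||% 0) * z_age)
    study_days <- max(1, as.numeric(diff(range(metadata$collection_date))))
    comp <- matrix(NA_real_, T_, nrow(metadata),
                   dimnames = list(taxon_ids(T_), metadata$sample_id))
    rk <- max(1L, as.integer(params$turnover_rank %||% 1L))
    # shared compositional aging axis; hosts travel along it at an
    # age-dependent speed, so within-host turnover grows with age while
    # between-host geometry is barely disturbed
    wd <- stats::rnorm(T_)
    t0 <- min(metadata$collection_date)
    for (k in seq_len(n_ind)) {
      rows <- which(metadata$individual_id == ids[k])
      rows <- rows[order(metadata$collection_date[rows])]
      m <- length(rows)
      # fast component: stationary AR(1) on host-specific axes, common scale;
      # per-taxon marginal sd = sigma_eps
      W <- matrix(stats::rnorm(T_ * rk, 0, 1 / sqrt(rk)), T_, rk)
      ar <- matrix(0, m, rk)
      ar[1, ] <- stats::rnorm(rk, 0, fast_scale[k])
      if (m > 1) for (j in 2:m) {
        gap <- as.numeric(metadata$collection_date[rows[j]] -
                          metadata$collection_date[rows[j - 1]])
        phi <- params$rho^(gap / 30)
        ar[j, ] <- phi * ar[j - 1, ] +
          stats::rnorm(rk, 0, fast_scale[k] * sqrt(1 - phi^2))
      }
      eps <- ar %*% t(W)
      # slow component: Brownian drift along one host-specific axis whose
      # accumulated scale over the study grows with age (beta_stab > 0:
      # older hosts keep diverging from their own past composition)
      if (params$sigma_drift > 0) {
        tt <- as.numeric(metadata$collection_date[rows] - t0)
        b <- (tt / study_days) * drift_scale[k]
        eps <- eps + b %o% wd
      }
      eta <- (base + g_eff[as.character(metadata$group[rows[1]]), ] +
                u[k, ] * pers_scale[k] + slopes * z_age[k]) +
        t(s_eff[as.character(metadata$season[rows]), , drop = FALSE]) +
        t(eps) +
        matrix(stats::rnorm(T_ * m, 0, params$sigma_sample), T_, m)
      if (any(!is.finite(eta))) stop("non-finite latent abundance")
      e <- exp(sweep(eta, 2, apply(eta, 2, max)))
      comp[, rows] <- sweep(e, 2, colSums(e), "/")
    }
    depth <- pmax(500L, as.integer(round(stats::rlnorm(nrow(metadata),
                                                       params$depth_meanlog,
                                                       params$depth_sdlog))))
    counts <- matrix(0L, T_, nrow(metadata), dimnames = dimnames(comp))
    for (r in seq_len(nrow(metadata))) {
      pr <- comp[, r]
      if (params$theta > 0) {
        g <- stats::rgamma(T_, shape = pr / params$theta)
        pr <- if (sum(g) > 0) g / sum(g) else pr
      }
      counts[, r] <- stats::rmultinom(1, depth[r], pr)
    }
    list(counts = counts, comp = comp, u = u, core = core_flag, depth = depth)
  })
  list(table = out$counts, taxonomy = taxonomy,
       ground_truth = list(params = params, signatures = out$u,
                           compositions = out$comp, core_taxa = out$core,
                           ages = stats::setNames(ages, ids), depth = out$depth))
}

#' Simulate within-group grooming dyads
#'
#' All within-group pairs of hosts; log rate is
#' `log(groom_mean_rate) + beta_groom * z(mean dyad age) + noise`; events
#' are Poisson at `rate * obs_hours`; duration is proportional to events
#' with lognormal noise.
#'
#' @param params a [sim_params()] list.
#' @param metadata output of [simulate_cohort()].
#' @param seed integer seed.
#' @return data.frame `id_a, id_b, events, duration_s, obs_hours`.
#' @export
simulate_grooming <- function(params, metadata, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  ids <- unique(metadata$individual_id)
  age <- metadata$age[match(ids, metadata$individual_id)]
  grp <- as.character(metadata$group[match(ids, metadata$individual_id)])
  withr::with_seed(seed, {
    rows <- list()
    for (g in unique(grp)) {
      member <- which(grp == g)
      if (length(member) < 2) next
      pr <- utils::combn(member, 2)
      for (c_ in seq_len(ncol(pr))) {
        a <- pr[1, c_]; b <- pr[2, c_]
        rows[[length(rows) + 1]] <- data.frame(
          id_a = ids[a], id_b = ids[b],
          mean_age = (age[a] + age[b]) / 2, stringsAsFactors = FALSE)
      }
    }
    dy <- do.call(rbind, rows)
    z <- (dy$mean_age - mean(dy$mean_age)) / stats::sd(dy$mean_age)
    rate <- exp(log(params$groom_mean_rate) + params$beta_groom * z +
                stats::rnorm(nrow(dy), 0, params$groom_sd))
    dy$obs_hours <- stats::runif(nrow(dy), params$obs_hours_range[1],
                                 params$obs_hours_range[2])
    dy$events <- stats::rpois(nrow(dy), rate * dy$obs_hours)
    dy$duration_s <- round(dy$events * params$bout_seconds *
                             exp(stats::rnorm(nrow(dy), 0, 0.2)))
    dy$mean_age <- NULL
    dy
  })
}

#' Simulate a complete dataset (tree, cohort, grooming, counts)
#'
#' Convenience wrapper deriving per-stage seeds from one master seed
#' (tree: seed+1, cohort: seed+2, grooming: seed+3, counts: seed+4).
#'
#' @param params a [sim_params()] list.
#' @param seed master integer seed.
#' @return list `tree, metadata, grooming, table, taxonomy, ground_truth`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L) {
  tree <- simulate_tree(params$n_taxa, seed = seed + 1L)
  metadata <- simulate_cohort(params, seed = seed + 2L)
  grooming <- simulate_grooming(params, metadata, seed = seed + 3L)
  cnt <- simulate_counts(params, metadata, grooming = grooming, seed = seed + 4L)
  metadata$read_count <- colSums(cnt$table)[metadata$sample_id]
  list(tree = tree, metadata = metadata, grooming = grooming,
       table = cnt$table, taxonomy = cnt$taxonomy,
       ground_truth = cnt$ground_truth)
}
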