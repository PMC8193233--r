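# Synthetic study generator: seasonal metadata with the field campaign's
# covariate profiles, OTU tables with planted correlation modules and planted
# indicator OTUs, random phylogenies, and EcoPlate colour kinetics.

#' Default per-group environmental profiles
#'
#' Means and standard deviations of the seven pore-water covariates for the
#' three seasonal groups (May, August, November), as measured in the field
#' campaign the generator emulates.
#'
#' @return tibble `group`, `variable`, `mean`, `sd`.
#' @export
default_env_profiles <- function() {
  vars <- c("DOC", "DO", "ORP", "EC", "pH", "PWT", "WT")
  means <- rbind(
    May      = c(15.23, 0.34,  84.77, 16.67, 4.53, 22.78,  1),
    August   = c(14.24, 1.34, 147.63, 18.14, 5.18, 23.55, -2),
    November = c(10.14, 2.75, 224.45, 18.34, 5.35,  7.98, -7)
  )
  sds <- rbind(
    May      = c(4.28, 0.14, 24.46, 5.36, 0.41, 3.49, 5),
    August   = c(1.85, 0.38, 20.26, 5.19, 0.24, 1.78, 4),
    November = c(3.58, 0.89, 41.19, 3.80, 0.24, 0.36, 5)
  )
  colnames(means) <- colnames(sds) <- vars
  tidyr::pivot_longer(as_tibble(means, rownames = "group"),
                      -"group", names_to = "variable",
                      values_to = "mean") |>
    left_join(
      tidyr::pivot_longer(as_tibble(sds, rownames = "group"),
                          -"group", names_to = "variable",
                          values_to = "sd"),
      by = c("group", "variable")
    )
}

#' Default EcoPlate kinetic parameters
#'
#' Logistic colour development with a ~24-h lag, a rapid 24-72-h rise and a
#' plateau beyond ~168 h. `cmax` per guild encodes the observed substrate
#' preference order (esters, amino acids and amines utilised most, alcohols
#' least). The logistic midpoint is placed a quarter of the way from the lag
#' to the plateau. The per-sample rate is scaled by
#' `exp(rate_temp_coef * (PWT - 15))`, an increasing function of pore-water
#' temperature.
#'
#' @return named list of kinetic parameters.
#' @export
default_plate_params <- function() {
  list(
    lag_h = 24, plateau_h = 168,
    rate = 0.09,               # logistic steepness per hour at 15 degC
    rate_temp_coef = 0.04,     # per degC scaling of the rate
    cmax = c(carbohydrate = 1.2, amino_acid = 1.6, amine = 1.5,
             ester = 1.8, carboxylic_acid = 1.0, alcohol = 0.6),
    cmax_sd = 0.2,             # lognormal spread of Cmax per substrate/sample
    noise_sd = 0.01,           # additive Gaussian read noise (OD units)
    base590 = 0.08, base750 = 0.05,
    control_drift = 0.005,     # slow colour drift of the water control
    read_every_h = 12, total_h = 240
  )
}

#' Synthetic scenario configuration
#'
#' The default scenario mirrors the study conditions the analysis assumes:
#' 3 seasonal groups x 12 samples, 600 OTUs, sequencing depth around 40,205
#' reads, 4 planted correlation modules of 8 OTUs at latent correlation 0.9,
#' and 5 planted indicator OTUs per group with an 8-fold enrichment in their
#' own group (and the same factor of suppression elsewhere).
#'
#' @param n_groups number of sample groups (the default profiles define 3).
#' @param samples_per_group samples per group.
#' @param n_otus total number of OTUs.
#' @param depth_mean mean sequencing depth per sample.
#' @param n_modules,module_size planted correlation modules.
#' @param module_correlation pairwise latent correlation within a module,
#'   in (0, 1).
#' @param n_indicators_per_group,indicator_fold planted indicator OTUs;
#'   `indicator_fold = Inf` makes indicators present only in their own group.
#' @param env_profiles per-group covariate means/SDs
#'   (see [default_env_profiles()]).
#' @param plate EcoPlate kinetic parameters (see [default_plate_params()]).
#' @param base_log_mean_sd SD of the baseline log-abundance across OTUs.
#' @param sample_log_sd per-sample log-abundance dispersion.
#' @param module_log_mean,indicator_log_mean baseline log-abundance offsets
#'   for planted module/indicator OTUs (keeps them comfortably above the
#'   abundance filter).
#' @param env_link optional named list mapping module index to a covariate
#'   name, coupling that module's latent factor to the covariate.
#' @param env_link_weight coupling weight in (0, 1) when `env_link` is set.
#' @param count_model `"multinomial"` (compositional, default) or
#'   `"negbin"`.
#' @param nb_size negative-binomial size parameter for `count_model =
#'   "negbin"`.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_groups = 3, samples_per_group = 12,
                            n_otus = 600, depth_mean = 40205,
                            n_modules = 4, module_size = 8,
                            module_correlation = 0.9,
                            n_indicators_per_group = 5, indicator_fold = 8,
                            env_profiles = default_env_profiles(),
                            plate = default_plate_params(),
                            base_log_mean_sd = 1.5, sample_log_sd = 0.8,
                            module_log_mean = 1.5, indicator_log_mean = 1.0,
                            env_link = NULL, env_link_weight = 0.3,
                            count_model = c("multinomial", "negbin"),
                            nb_size = 10,
                            seed = 1) {
  count_model <- match.arg(count_model)
  cfg <- list(
    n_groups = as.integer(n_groups),
    samples_per_group = as.integer(samples_per_group),
    n_otus = as.integer(n_otus), depth_mean = as.integer(depth_mean),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_correlation = module_correlation,
    n_indicators_per_group = as.integer(n_indicators_per_group),
    indicator_fold = indicator_fold,
    env_profiles = env_profiles, plate = plate,
    base_log_mean_sd = base_log_mean_sd, sample_log_sd = sample_log_sd,
    module_log_mean = module_log_mean,
    indicator_log_mean = indicator_log_mean,
    env_link = env_link, env_link_weight = env_link_weight,
    count_model = count_model, nb_size = nb_size,
    seed = check_seed(seed)
  )
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (cfg$n_groups < 1 || cfg$samples_per_group < 1 || cfg$n_otus < 1) {
    abort("Counts in the scenario config must be >= 1.")
  }
  if (cfg$module_correlation < 0 || cfg$module_correlation >= 1) {
    abort("`module_correlation` must lie in [0, 1).")
  }
  if (cfg$n_modules * cfg$module_size +
      cfg$n_groups * cfg$n_indicators_per_group > cfg$n_otus) {
    abort("Planted modules and indicators exceed `n_otus`.")
  }
  if (!is.infinite(cfg$indicator_fold) && cfg$indicator_fold <= 1) {
    abort("`indicator_fold` must be > 1 (or Inf).")
  }
  if (any(cfg$env_profiles$sd < 0)) abort("Covariate SDs must be >= 0.")
  if (length(unique(cfg$env_profiles$group)) < cfg$n_groups) {
    abort("`env_profiles` must define at least `n_groups` groups.")
  }
  if (cfg$plate$plateau_h <= cfg$plate$lag_h) {
    abort("Plate `plateau_h` must exceed `lag_h`.")
  }
  structure(cfg, class = c("scenario_config", "list"))
}

scenario_groups <- function(cfg) {
  unique(cfg$env_profiles$group)[seq_len(cfg$n_groups)]
}

#' Generate sample metadata
#'
#' One row per sample with its group label and Gaussian draws of the seven
#' environmental covariates from the per-group profiles.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return tibble `sample_id`, `group`, plus one column per covariate.
#' @export
gen_metadata <- function(cfg, seed = cfg$seed) {
  seed <- check_seed(seed)
  groups <- scenario_groups(cfg)
  prof <- filter(cfg$env_profiles, .data$group %in% groups)
  vars <- unique(prof$variable)
  withr::with_seed(seed, {
    purrr::map(groups, function(g) {
      pg <- filter(prof, .data$group == g)
      draws <- vapply(vars, function(v) {
        row <- pg[pg$variable == v, ]
        rnorm(cfg$samples_per_group, row$mean, row$sd)
      }, numeric(cfg$samples_per_group))
      draws <- matrix(draws, nrow = cfg$samples_per_group,
                      dimnames = list(NULL, vars))
      bind_cols(
        tibble(sample_id = sprintf("%s_%02d", g,
                                   seq_len(cfg$samples_per_group)),
               group = g),
        as_tibble(draws)
      )
    }) |>
      bind_rows()
  })
}

#' Generate an OTU table with planted structure
#'
#' Latent log-normal abundances; OTUs of a planted module share a latent
#' Gaussian factor so that every within-module pair has latent correlation
#' `module_correlation` (optionally tied to one environmental covariate via
#' `env_link`). Planted indicator OTUs are multiplied by `indicator_fold`
#' in their own group and divided by it elsewhere (`Inf` means present only
#' in the own group). Counts are drawn multinomially per sample at a
#' Poisson(depth_mean) depth (or per-OTU negative-binomially with
#' `count_model = "negbin"`).
#'
#' @param cfg a [scenario_config()].
#' @param meta metadata tibble from [gen_metadata()].
#' @param seed integer seed (defaults to the config seed).
#' @return list with `table` (OTU tibble) and `truth` (a `ground_truth`
#'   list: `module_of_otu`, `indicator_otus`, `env_link`, `otu_ids`).
#' @export
gen_otu_table <- function(cfg, meta, seed = cfg$seed) {
  seed <- check_seed(seed)
  n <- nrow(meta)
  p <- cfg$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(p))
  groups <- meta$group

  n_mod_otus <- cfg$n_modules * cfg$module_size
  n_ind <- cfg$n_groups * cfg$n_indicators_per_group
  module_of <- setNames(rep(NA_integer_, p), otu_ids)
  indicator_group <- setNames(rep(NA_character_, p), otu_ids)

  withr::with_seed(seed, {
    planted <- sample.int(p, n_mod_otus + n_ind)
    mod_idx <- planted[seq_len(n_mod_otus)]
    ind_idx <- planted[n_mod_otus + seq_len(n_ind)]
    module_of[mod_idx] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
    glabels <- scenario_groups(cfg)
    indicator_group[ind_idx] <- rep(glabels, each = cfg$n_indicators_per_group)

    mu <- rnorm(p, 0, cfg$base_log_mean_sd)
    mu[mod_idx] <- cfg$module_log_mean + rnorm(n_mod_otus, 0, 0.3)
    mu[ind_idx] <- cfg$indicator_log_mean + rnorm(n_ind, 0, 0.3)

    # latent per-sample deviations
    z <- matrix(rnorm(n * p), n, p)
    rho <- cfg$module_correlation
    for (mod in seq_len(cfg$n_modules)) {
      f <- rnorm(n)
      if (!is.null(cfg$env_link) && !is.null(cfg$env_link[[as.character(mod)]])) {
        v <- cfg$env_link[[as.character(mod)]]
        w <- cfg$env_link_weight
        f <- sqrt(1 - w^2) * f + w * as.vector(scale(meta[[v]]))
      }
      cols <- which(module_of == mod)
      z[, cols] <- sqrt(rho) * f + sqrt(1 - rho) * z[, cols]
    }

    lambda <- sweep(cfg$sample_log_sd * z, 2, mu, "+")
    lf <- if (is.infinite(cfg$indicator_fold)) 0 else log(cfg$indicator_fold)
    for (i in ind_idx) {
      own <- groups == indicator_group[i]
      if (is.infinite(cfg$indicator_fold)) {
        lambda[!own, i] <- -Inf
      } else {
        lambda[own, i] <- lambda[own, i] + lf
        lambda[!own, i] <- lambda[!own, i] - lf
      }
    }
    wgt <- exp(lambda)

    counts <- matrix(0L, n, p, dimnames = list(meta$sample_id, otu_ids))
    if (cfg$count_model == "multinomial") {
      depths <- pmax(rpois(n, cfg$depth_mean), 1L)
      for (s in seq_len(n)) {
        counts[s, ] <- as.integer(rmultinom(1, depths[s], wgt[s, ]))
      }
    } else {
      rel <- wgt / rowSums(wgt)
      for (s in seq_len(n)) {
        counts[s, ] <- as.integer(stats::rnbinom(
          p, mu = cfg$depth_mean * rel[s, ], size = cfg$nb_size))
      }
    }

    truth <- structure(
      list(module_of_otu = module_of,
           indicator_otus = split(otu_ids[ind_idx],
                                  indicator_group[ind_idx]),
           env_link = cfg$env_link,
           otu_ids = otu_ids, seed = seed),
      class = c("ground_truth", "list")
    )
    list(table = otu_tibble(counts), truth = truth)
  })
}

#' Generate a random phylogeny over the OTUs
#'
#' Random coalescent-style rooted bifurcating tree with the OTU ids as tips.
#'
#' @param otu_ids character vector of >= 2 unique OTU ids.
#' @param seed integer seed.
#' @return an `ape::phylo` tree.
#' @export
gen_tree <- function(otu_ids, seed = 1) {
  seed <- check_seed(seed)
  if (length(otu_ids) < 2) abort("Need >= 2 OTUs for a tree.")
  if (anyDuplicated(otu_ids)) abort("Duplicate OTU ids.")
  withr::with_seed(seed, ape::rcoal(length(otu_ids), tip.label = otu_ids))
}

#' Generate EcoPlate absorbance series
#'
#' Per-substrate logistic colour development
#' `C(t) = Cmax / (1 + exp(-r (t - t_mid)))` with guild-specific `Cmax`,
#' per-sample rate scaled by an increasing function of the sample's
#' pore-water temperature (PWT), additive Gaussian read noise, and near-flat
#' water-control wells. Readings are emitted at both wavelengths (590 and
#' 750 nm) every 12 h up to 240 h by default.
#'
#' @param cfg a [scenario_config()].
#' @param meta metadata tibble with a `PWT` column.
#' @param seed integer seed (defaults to the config seed).
#' @param layout plate layout (default [eco_layout()]).
#' @return a `plate_series` tibble covering every sample of `meta`.
#' @export
gen_plate_series <- function(cfg, meta, seed = cfg$seed,
                             layout = eco_layout()) {
  seed <- check_seed(seed)
  pp <- cfg$plate
  if (pp$plateau_h <= pp$lag_h) abort("Plate `plateau_h` must exceed `lag_h`.")
  t_mid <- pp$lag_h + (pp$plateau_h - pp$lag_h) / 4
  times <- seq(0, pp$total_h, by = pp$read_every_h)
  well_map <- tibble(
    substrate_id = rep(layout$substrate_id, lengths(layout$wells)),
    guild = rep(layout$guild, lengths(layout$wells)),
    is_control = rep(layout$is_control, lengths(layout$wells)),
    well = unlist(layout$wells)
  )
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(nrow(meta)), function(s) {
      rate <- pp$rate * exp(pp$rate_temp_coef * (meta$PWT[s] - 15))
      cmax <- ifelse(
        well_map$is_control, 0,
        pp$cmax[well_map$guild] * exp(rnorm(nrow(well_map), 0, pp$cmax_sd)))
      grid <- tidyr::expand_grid(well_map, time_h = times)
      # control wells develop a faint colour with the same kinetics, so the
      # blank-corrected response is (Cmax - drift) * logistic(t): monotone
      cmax_g <- rep(ifelse(well_map$is_control, pp$control_drift, cmax),
                    each = length(times))
      signal <- cmax_g / (1 + exp(-rate * (grid$time_h - t_mid)))
      a590 <- pp$base590 + signal + rnorm(nrow(grid), 0, pp$noise_sd)
      a750 <- pp$base750 + rnorm(nrow(grid), 0, pp$noise_sd)
      tibble(
        sample_id = meta$sample_id[s],
        time_h = rep(grid$time_h, 2),
        wavelength = rep(c(590L, 750L), each = nrow(grid)),
        well = rep(grid$well, 2),
        od = pmax(c(a590, a750), 0)
      )
    }) |>
      bind_rows()
    plate_series(out, layout = layout)
  })
}

#' Score module recovery against the planted truth
#'
#' Adjusted Rand index between the planted module membership and a network
#' partition, computed over the planted-module OTUs present in the
#' partition.
#'
#' @param truth a `ground_truth` object from [gen_otu_table()].
#' @param module_of named vector mapping node ids to module ids (e.g.
#'   `graph_topology(g)$module_of`).
#' @return tibble with `ari`, `n_scored`, `n_planted`.
#' @export
score_module_recovery <- function(truth, module_of) {
  planted <- names(truth$module_of_otu)[!is.na(truth$module_of_otu)]
  scored <- intersect(planted, names(module_of))
  ari <- if (length(scored) >= 2) {
    mclust::adjustedRandIndex(truth$module_of_otu[scored],
                              module_of[scored])
  } else NA_real_
  tibble(ari = ari, n_scored = length(scored), n_planted = length(planted))
}

#' Score indicator recovery against the planted truth
#'
#' Sensitivity (fraction of planted indicator OTUs selected) and the
#' fraction of selections that are not planted indicators.
#'
#' @param truth a `ground_truth` object from [gen_otu_table()].
#' @param result an `indval_result` from [indval_test()].
#' @return tibble with `sensitivity`, `false_selection_rate`, `n_selected`,
#'   `n_planted`.
#' @export
score_indicator_recovery <- function(truth, result) {
  planted <- unlist(truth$indicator_otus, use.names = FALSE)
  sel <- result$otu_id[result$selected]
  tibble(
    sensitivity = if (length(planted)) mean(planted %in% sel) else NA_real_,
    false_selection_rate = if (length(sel)) mean(!sel %in% planted)
      else 0,
    n_selected = length(sel),
    n_planted = length(planted)
  )
}

#' Write a synthetic scenario to disk
#'
#' Generates metadata, the OTU table, a phylogeny and plate series, and
#' writes `otu_table.tsv`, `metadata.tsv`, `tree.nwk`, `plates/<sample>.csv`,
#' `truth.json` and `scenario.cfg` (plain key=value) under `outdir`.
#'
#' @param cfg a [scenario_config()].
#' @param outdir output directory (created if missing).
#' @param seed integer seed (defaults to the config seed).
#' @return invisible list with the generated objects and file paths.
#' @export
generate_scenario <- function(cfg, outdir, seed = cfg$seed) {
  seed <- check_seed(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "plates"), showWarnings = FALSE)
  meta <- gen_metadata(cfg, seed = seed)
  gen <- gen_otu_table(cfg, meta, seed = seed + 1L)
  tree <- gen_tree(gen$truth$otu_ids, seed = seed + 2L)
  plates <- gen_plate_series(cfg, meta, seed = seed + 3L)

  readr::write_tsv(meta, file.path(outdir, "metadata.tsv"))
  readr::write_tsv(gen$table, file.path(outdir, "otu_table.tsv"))
  ape::write.tree(tree, file.path(outdir, "tree.nwk"))
  plate_paths <- vapply(unique(plates$sample_id), function(s) {
    path <- file.path(outdir, "plates", paste0(s, ".csv"))
    readr::write_csv(as_tibble(plates)[plates$sample_id == s, ], path)
    path
  }, character(1))
  jsonlite::write_json(
    list(module_of_otu = as.list(
           truth_modules <- gen$truth$module_of_otu[
             !is.na(gen$truth$module_of_otu)]),
         indicator_otus = gen$truth$indicator_otus,
         seed = seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE)
  cfg_lines <- c(
    paste0("n_groups=", cfg$n_groups),
    paste0("samples_per_group=", cfg$samples_per_group),
    paste0("n_otus=", cfg$n_otus),
    paste0("depth_mean=", cfg$depth_mean),
    paste0("n_modules=", cfg$n_modules),
    paste0("module_size=", cfg$module_size),
    paste0("module_correlation=", cfg$module_correlation),
    paste0("n_indicators_per_group=", cfg$n_indicators_per_group),
    paste0("indicator_fold=", cfg$indicator_fold),
    paste0("count_model=", cfg$count_model),
    paste0("seed=", seed)
  )
  writeLines(cfg_lines, file.path(outdir, "scenario.cfg"))

  invisible(list(
    meta = meta, table = gen$table, truth = gen$truth, tree = tree,
    plates = plates,
    paths = list(
      metadata = file.path(outdir, "metadata.tsv"),
      otu_table = file.path(outdir, "otu_table.tsv"),
      tree = file.path(outdir, "tree.nwk"),
      plates = unname(plate_paths),
      truth = file.path(outdir, "truth.json"),
      config = file.path(outdir, "scenario.cfg")
    )
  ))
}
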