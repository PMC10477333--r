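# End-to-end orchestration: generate -> calibrate -> impute -> simulate ->
# counterfactual -> estimate -> map, from one nested configuration, with
# per-stage substream seeds, cached intermediates and tabular outputs.

#' Default pipeline configuration
#'
#' A nested list covering every stage. All randomness flows from
#' `master_seed` through named substreams; `output_dir = NULL` keeps all
#' results in memory.
#'
#' @param overrides named list merged over the defaults (top-level and
#'   second-level keys)
#' @return a validated configuration list
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    master_seed = 1,
    n_locations = 500,
    years = c(1979, 2015),
    assessment_years = c(1995, 2015),
    total_area_ha = 125.4e6,
    n_replicates = 30,
    n_regions = 4,
    domain_km = c(800, 500),
    imputation = list(M = 6, termination = "herbicide", n_donors = 400),
    calibration = list(n_sites = 50, n_treatments = 4,
                       bias = list(intercept = 5, slope = 0.9),
                       re_sd = 5, resid_sd = 5,
                       run_screening = FALSE, sobol_n_base = 256,
                       sir_n_prior = 2000, sir_n_resample = 500),
    monte_carlo = list(n_iter = 1000, use_replicates = TRUE,
                       include_prediction_error = TRUE),
    mapping = list(cell_size_km = 5, radius_km = 20, min_points = 5, power = 2),
    model_params = list(),
    output_dir = NULL
  )
  if (!is.null(overrides)) {
    for (k in names(overrides)) {
      if (is.list(overrides[[k]]) && is.list(cfg[[k]]))
        cfg[[k]][names(overrides[[k]])] <- overrides[[k]]
      else cfg[[k]] <- overrides[[k]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg configuration list
#' @return `cfg` invisibly; stops with the missing key's name otherwise
#' @export
validate_config <- function(cfg) {
  required <- c("master_seed", "n_locations", "years", "assessment_years",
                "total_area_ha", "n_replicates", "imputation", "calibration",
                "monte_carlo", "mapping")
  for (k in required)
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k, call. = FALSE)
  for (k in c("M", "termination")) if (is.null(cfg$imputation[[k]]))
    stop("config is missing required key: imputation$", k, call. = FALSE)
  if (is.null(cfg$monte_carlo$n_iter))
    stop("config is missing required key: monte_carlo$n_iter", call. = FALSE)
  check_that(cfg$n_locations >= 1, "n_locations must be >= 1")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path
#' @param cfg configuration list (for writing)
#' @return the configuration list (reading); `path` invisibly (writing)
#' @export
read_config <- function(path) default_config(yaml::read_yaml(path))

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# small deterministic hash of the configuration for output provenance
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
  sprintf("%08x", h)
}

#' Derive imputation trend inputs from adoption curves
#'
#' Converts the national adoption trend table into the tabular trend inputs
#' the imputation stage consumes: per-block tillage marginals (NT/RT/FT) and
#' per-block cover-crop census targets.
#'
#' @param adoption trend table as from [default_adoption_trends()]
#' @return list `(tillage_marginals, cc_targets, n_trend = NULL)`
#' @export
trends_from_adoption <- function(adoption) {
  blocks <- BLOCK_STARTS
  agg <- function(col, b) mean(adoption[[col]][adoption$year >= b &
                                                 adoption$year <= b + 4])
  tm <- data.frame(block_start = blocks)
  ct <- vapply(blocks, agg, numeric(1), col = "cons_till")
  nts <- vapply(blocks, agg, numeric(1), col = "nt_share")
  tm$NT <- ct * nts
  tm$RT <- ct * (1 - nts)
  tm$FT <- 1 - ct
  cc <- data.frame(block_start = blocks[blocks > ANCHOR_BLOCK])
  cc$fraction <- vapply(cc$block_start, agg, numeric(1), col = "cover_crop")
  list(tillage_marginals = tm, cc_targets = cc, n_trend = NULL)
}

#' Run the full counterfactual pipeline
#'
#' Executes the stages in order — synthetic world generation, calibration
#' (bias model, optionally Sobol screening + SIR), imputation, paired
#' baseline/counterfactual simulation per imputation set, national
#' estimation with Monte Carlo uncertainty, and effect mapping — and returns
#' every intermediate. When `cfg$output_dir` is set, tabular results are
#' written there with the config hash in a provenance sidecar.
#'
#' @param cfg configuration from [default_config()] or [read_config()]
#' @param stages character vector of stages to run (`"all"` or a subset of
#'   generate/calibrate/impute/counterfactual/estimate/map); later stages
#'   require earlier ones, supplied via `state`
#' @param state optional partial result list from a previous call (cached
#'   upstream intermediates)
#' @param verbose print per-stage progress?
#' @return list with `frame`, `weather`, `truth`, `donors`, `sites`,
#'   `bias_model`, `screening`, `imputations`, `runs`, `summary`, `maps`,
#'   `config`
#' @export
run_pipeline <- function(cfg = default_config(), stages = "all", state = NULL,
                         verbose = interactive()) {
  validate_config(cfg)
  all_stages <- c("generate", "calibrate", "impute", "counterfactual",
                  "estimate", "map")
  if (identical(stages, "all")) stages <- all_stages
  check_that(all(stages %in% all_stages), "unknown stage name")
  seed <- cfg$master_seed
  out <- state %||% list()
  out$config <- cfg
  years <- seq(cfg$years[1], cfg$years[2])
  ay <- seq(cfg$assessment_years[1], cfg$assessment_years[2])
  params <- default_params(cfg$model_params)
  say <- function(...) if (verbose) message("[soccf] ", ...)

  if ("generate" %in% stages) {
    say("generating synthetic survey world")
    out$frame <- generate_frame(cfg$n_locations, cfg$domain_km,
                                cfg$total_area_ha, cfg$n_replicates,
                                cfg$n_regions, seed = seed)
    out$adoption <- default_adoption_trends(years)
    out$truth <- generate_truth_histories(out$frame, out$adoption,
                                          years = years, seed = seed)
    out$weather <- generate_weather(out$frame, years, seed = seed)
    out$donors <- generate_donors(out$frame, out$truth,
                                  n_donors = cfg$imputation$n_donors %||% 400,
                                  seed = seed)
    cal <- cfg$calibration
    out$sites <- generate_calibration_sites(
      n_sites = cal$n_sites, bias = cal$bias, re_sd = cal$re_sd,
      resid_sd = cal$resid_sd, n_treatments = cal$n_treatments, seed = seed)
  }

  if ("calibrate" %in% stages) {
    say("fitting bias model")
    out$bias_model <- fit_bias_model(out$sites)
    if (isTRUE(cfg$calibration$run_screening)) {
      say("running sensitivity screening and SIR calibration")
      out$screening <- calibrate_surrogate(out$sites, params,
                                           n_base = cfg$calibration$sobol_n_base,
                                           n_prior = cfg$calibration$sir_n_prior,
                                           n_resample = cfg$calibration$sir_n_resample,
                                           seed = seed)
      params <- out$screening$params
    }
  }

  if ("impute" %in% stages) {
    say("building ", cfg$imputation$M, " imputation sets")
    out$trends <- trends_from_adoption(out$adoption %||%
                                         default_adoption_trends(years))
    out$imputations <- build_imputations(
      out$frame, out$truth, out$donors, out$trends,
      M = cfg$imputation$M, termination = cfg$imputation$termination,
      seed = seed)
  }

  if ("counterfactual" %in% stages) {
    out$runs <- lapply(out$imputations, function(im) {
      say("simulating imputation set ", im$imputation_id)
      run_all_scenarios(out$frame, im$histories, params, out$weather,
                        seed = substream_seed(seed, paste0("cf:", im$imputation_id)))
    })
  }

  if ("estimate" %in% stages) {
    say("national estimation and Monte Carlo uncertainty")
    out$summary <- summarize_national(
      out$runs, out$frame, out$bias_model,
      n_iter = cfg$monte_carlo$n_iter, years = ay, seed = seed,
      use_replicates = isTRUE(cfg$monte_carlo$use_replicates),
      include_prediction_error = isTRUE(cfg$monte_carlo$include_prediction_error))
  }

  if ("map" %in% stages) {
    say("interpolating effect maps")
    mp <- cfg$mapping
    grid <- default_grid(out$frame, mp$cell_size_km)
    eff1 <- effect_matrices(out$runs[[1]], years = ay)
    out$maps <- lapply(setdiff(names(eff1), "total"), function(s) {
      e <- eff1[[s]]
      pts <- average_effect_map(
        data.frame(location_id = rep(out$frame$locations$location_id, each = nrow(e)),
                   year = rep(ay, ncol(e)), effect = as.vector(e)),
        out$frame, years = ay)
      idw_interpolate(pts, grid, radius_km = mp$radius_km,
                      min_points = mp$min_points, power = mp$power,
                      scenario = s)
    })
    names(out$maps) <- setdiff(names(eff1), "total")
  }

  if (!is.null(cfg$output_dir)) write_outputs(out, cfg)
  out
}

# surrogate calibration chain: Sobol screening of the equilibrium response,
# then SIR against the calibration-site measurements; returns selected
# parameters, the posterior sample and params updated to the MAP
calibrate_surrogate <- function(sites, params, n_base = 256, n_prior = 2000,
                                n_resample = 500, seed = 1) {
  ranges <- list(k_active = c(3, 12), k_slow = c(0.1, 0.4),
                 k_passive = c(0.002, 0.008), q10 = c(1.5, 3),
                 till_ft = c(1.1, 1.6), w_half = c(0.1, 0.6),
                 cover_crop_c = c(0.4, 1.2), native_input = c(2, 4))
  site_mean <- list(clay = mean(sites$clay_frac), tmean = mean(sites$tmean_c))
  eq_total <- function(x) {
    p <- params
    p$k <- c(active = x[["k_active"]], slow = x[["k_slow"]],
             passive = x[["k_passive"]])
    p$q10 <- x[["q10"]]
    p$till_mult["FT"] <- x[["till_ft"]]
    p$w_half <- x[["w_half"]]
    mT <- min(p$q10^((site_mean$tmean - p$t_ref) / 10), p$m_t_cap)
    solve_equilibrium(p, list(m_T = mT, m_W = 0.5 / (0.5 + p$w_half),
                              m_till = p$till_mult[["NT"]]),
                      x[["native_input"]], site_mean$clay)$total
  }
  screening <- sobol_total_indices(function(m) apply(m, 1, eq_total),
                                   ranges, n_base = n_base, seed = seed)
  sel <- screening$param_name[screening$selected]

  obs <- tapply(sites$measured_soc, sites$site_id, mean)
  sd_obs <- max(stats::sd(obs), 1e-6)
  prior_sampler <- function(n) {
    m <- sapply(names(ranges), function(k)
      stats::runif(n, ranges[[k]][1], ranges[[k]][2]))
    colnames(m) <- names(ranges)
    m
  }
  loglik <- function(m) {
    apply(m, 1, function(x) {
      pred <- eq_total(x)
      sum(stats::dnorm(obs, pred, sd_obs, log = TRUE))
    })
  }
  post <- sir_calibrate(prior_sampler, loglik, n_prior = n_prior,
                        n_resample = n_resample, seed = seed)
  map <- post$map_estimate
  p2 <- params
  p2$k <- c(active = map[["k_active"]], slow = map[["k_slow"]],
            passive = map[["k_passive"]])
  p2$q10 <- map[["q10"]]
  p2$till_mult["FT"] <- max(map[["till_ft"]], p2$till_mult[["RT"]])
  p2$w_half <- map[["w_half"]]
  list(screening = screening, posterior = post, selected = sel, params = p2)
}

# write tabular pipeline outputs with a provenance sidecar
write_outputs <- function(out, cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(cfg)
  wr <- function(d, name)
    utils::write.csv(d, file.path(cfg$output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  if (!is.null(out$frame)) wr(out$frame$locations, "survey_frame")
  if (!is.null(out$truth)) wr(out$truth, "truth_histories")
  if (!is.null(out$donors)) wr(out$donors, "donor_survey")
  if (!is.null(out$summary)) {
    wr(out$summary$national, "national_series")
    wr(out$summary$mc, "mc_estimates")
  }
  if (!is.null(out$maps))
    for (s in names(out$maps))
      write_effect_grid(out$maps[[s]],
                        file.path(cfg$output_dir, paste0("effect_map_", s, ".asc")))
  writeLines(c(paste("config_hash:", h),
               paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(cfg$output_dir, "PROVENANCE.txt"))
  write_config(cfg, file.path(cfg$output_dir, "config.yaml"))
  invisible(out)
}
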