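# Shared small synthetic world, built once per test run and cached.
.world_cache <- new.env(parent = emptyenv())

small_world <- function() {
  if (!is.null(.world_cache$world)) return(.world_cache$world)
  frame <- generate_frame(120, seed = 42)
  truth <- generate_truth_histories(frame, seed = 42)
  weather <- generate_weather(frame, 1979:2015, seed = 42)
  donors <- generate_donors(frame, truth, n_donors = 200, seed = 42)
  trends <- trends_from_adoption(default_adoption_trends())
  imputations <- suppressWarnings(
    build_imputations(frame, truth, donors, trends, M = 2, seed = 42))
  runs <- lapply(imputations, function(im)
    run_all_scenarios(frame, im$histories, default_params(), weather,
                      seed = 42 + im$imputation_id))
  sites <- generate_calibration_sites(n_sites = 40, seed = 42)
  bias <- suppressWarnings(fit_bias_model(sites))
  .world_cache$world <- list(frame = frame, truth = truth, weather = weather,
                             donors = donors, trends = trends,
                             imputations = imputations, runs = runs,
                             sites = sites, bias = bias)
  .world_cache$world
}

# constant-forcing weather for a single synthetic location
constant_weather <- function(years, tmean = 12, precip = 2.5) {
  nd <- 365 * length(years)
  list(tmean = rep(tmean, nd), precip = rep(precip, nd),
       year = rep(years, each = 365), doy = rep(1:365, length(years)))
}

# a bare single-location description
one_location <- function(clay = 0.2) {
  list(location_id = 1L, clay_frac = clay, sand_frac = 0.3, weight = 1000)
}

# a simple constant management history
flat_history <- function(years = 1979:2015, crop = "grass", tillage = "NT",
                         fert = 0, manure = 0, cc = FALSE,
                         termination = "none", set_aside = FALSE) {
  data.frame(location_id = 1L, year = years, crop = crop, tillage = tillage,
             fert_n = fert, manure_n = manure, cover_crop = cc,
             termination = ifelse(cc, termination, "none"),
             irrigated = FALSE, set_aside = set_aside)
}

random_marginal <- function() {
  p <- stats::rexp(3)
  p / sum(p)
}
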