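# Per-location SOC trajectory simulation: equilibrium initialisation, staged
# base history, and the survey-era management-driven run with daily forcing.

#' Extract one location's weather from a `weather_series`
#'
#' @param weather a `weather_series`
#' @param location_id a single location id
#' @return list with `tmean`, `precip`, `year`, `doy`
#' @export
weather_for <- function(weather, location_id) {
  j <- match(location_id, weather$location_id)
  check_that(!is.na(j), "location not present in weather series")
  list(tmean = weather$tmean[, j], precip = weather$precip[, j],
       year = weather$year, doy = weather$doy)
}

# Daily decomposition forcing for one location: temperature and moisture
# modifiers for each weather day, plus their long-run means used for the
# constant-forcing base-history phases. Relative water is an exponentially
# smoothed precipitation index w = s/(s + mean(p)), a scalar bucket proxy.
prepare_forcing <- function(weather_loc, params) {
  m_T <- pmin(params$q10^((weather_loc$tmean - params$t_ref) / 10), params$m_t_cap)
  p <- weather_loc$precip
  lambda <- 0.9
  s <- stats::filter((1 - lambda) * p, lambda, method = "recursive",
                     init = mean(p))
  rel_water <- as.numeric(s / (s + mean(p)))
  rel_water <- pmin(pmax(rel_water, 0), 1)
  m_W <- rel_water / (rel_water + params$w_half)
  list(m_T = m_T, m_W = m_W,
       mbar_T = mean(m_T), mbar_W = mean(m_W),
       year = weather_loc$year, doy = weather_loc$doy)
}

# Annual carbon input (t C/ha) for each history year, split into the crop
# component (scaled by productivity/vegetation index), cover-crop winter
# input, and manure-derived carbon.
annual_inputs <- function(history, params, evi_scale = NULL) {
  crop_in <- unname(params$crop_c_input[history$crop])
  check_that(!any(is.na(crop_in)), "history contains a crop without an input parameter")
  if (!is.null(evi_scale)) crop_in <- crop_in * evi_scale
  cover_in <- ifelse(history$cover_crop, params$cover_crop_c, 0)
  manure_in <- history$manure_n * params$manure_cn / 1000
  list(crop = crop_in, cover = cover_in, manure = manure_in)
}

# Growing-season day windows (day-of-year) used to spread annual inputs.
GS_ANNUAL <- 121:273    # annual crops
GS_PERENNIAL <- 91:304  # hay, pasture, grass cover
CC_WINDOW <- 60:89      # winter cover-crop input, early spring
MANURE_WINDOW <- 110:119
PULSE_START_DOY <- 90   # tillage-termination decomposition pulse start

#' Simulate the SOC trajectory of one survey location
#'
#' Runs the full staged simulation: analytic equilibrium under native
#' vegetation and mean forcing; a low-input base history from
#' `params$base_start` to 1949; a linear productivity ramp 1950-1978; then
#' the management-driven era with daily weather forcing over the history
#' years. Cover crops add a winter carbon input; tillage termination of a
#' cover crop applies an extra full-till decomposition window in the
#' termination year (herbicide termination does not); manure adds carbon via
#' its C:N ratio; set-aside years are simulated as continuous grass cover
#' under no-till.
#'
#' @param location one row of `frame$locations` (list or data.frame row)
#' @param weather_loc one location's weather, as from [weather_for()]
#' @param history this location's `management_history` rows (complete,
#'   contiguous years, each inside the weather span)
#' @param params `soc_params`
#' @param evi optional daily vegetation-index series (length = weather days,
#'   `NA` where unobserved); when supplied, annual-crop inputs for years from
#'   2000 on are scaled by the growing-season mean of the gap-filled index
#'   relative to `params$evi_ref`
#' @param forcing optional precomputed [prepare_forcing()] result (reused
#'   across counterfactual runs of the same location)
#' @return data.frame of class `soc_trajectory`: `location_id`, `year`,
#'   `soc` (Dec 31 stock, t C/ha), `delta_soc` (t C/ha/yr); attributes
#'   `annual_input` and `annual_respired` carry the per-year carbon budget
#' @export
simulate_location <- function(location, weather_loc, history,
                              params = default_params(), evi = NULL,
                              forcing = NULL) {
  years <- sort(history$year)
  check_that(length(years) > 0, "empty history")
  check_that(all(diff(years) == 1), "missing history year")
  check_that(all(years %in% weather_loc$year), "weather must cover all history years")
  history <- history[order(history$year), ]
  ny <- length(years)
  dpy <- params$days_per_year
  clay <- location$clay_frac
  if (is.null(forcing)) forcing <- prepare_forcing(weather_loc, params)
  tf <- transfer_fracs(params, clay)
  kv <- unname(params$k); rv <- unname(params$resp_frac)
  dt <- 1 / dpy

  # --- equilibrium under native vegetation ---
  eq <- solve_equilibrium(
    params,
    mean_forcing = list(m_T = forcing$mbar_T, m_W = forcing$mbar_W,
                        m_till = params$till_mult[["NT"]]),
    mean_input = params$native_c_input, clay_frac = clay)
  pools <- c(eq$active, eq$slow, eq$passive)

  # --- base history: low-input agriculture to 1949, constant mean forcing ---
  ft <- params$till_mult[["FT"]]
  n_low <- max(0L, 1950L - params$base_start)
  if (n_low > 0) {
    sp <- cpp_spinup(pools, kv, rv, tf$f_ap, tf$f_sp,
                     forcing$mbar_T, forcing$mbar_W, ft,
                     params$base_crop_input * params$low_input_scale / dpy,
                     n_low * dpy, dt)
    pools <- sp$final
  }

  # --- productivity ramp 1950 to the year before the history starts ---
  ramp <- params$ramp_years[params$ramp_years < years[1]]
  if (length(ramp) > 0) {
    scales <- seq(params$low_input_scale, 1, length.out = length(ramp) + 1)[-1]
    nr <- length(ramp)
    m_in <- rep(params$base_crop_input * scales / dpy, each = dpy)
    run <- cpp_run_days(pools, kv, rv, tf$f_ap, tf$f_sp,
                        rep(forcing$mbar_T, nr * dpy), rep(forcing$mbar_W, nr * dpy),
                        rep(ft, nr * dpy), m_in, dt,
                        as.integer(nr * dpy))
    pools <- run$final
  }

  # --- survey era: daily weather forcing, management-driven inputs ---
  sel <- forcing$year %in% years
  m_T <- forcing$m_T[sel]; m_W <- forcing$m_W[sel]
  check_that(length(m_T) == ny * dpy, "weather days do not align with 365-day years")

  evi_scale <- NULL
  if (!is.null(evi)) {
    filled <- sg_gapfill(evi)
    idx <- sel & (weather_loc$doy %in% GS_ANNUAL)
    gmean <- tapply(filled[idx], forcing$year[idx], mean)
    sc <- rep(1, ny)
    hit <- years >= 2000 & as.character(years) %in% names(gmean)
    sc[hit] <- gmean[as.character(years[hit])] / params$evi_ref
    evi_scale <- sc
  }

  # set-aside years override management: grass cover, no-till, no amendments
  eff_crop <- ifelse(history$set_aside, SET_ASIDE_CROP, history$crop)
  eff_till <- ifelse(history$set_aside, "NT", history$tillage)
  eff_hist <- history
  eff_hist$crop <- eff_crop
  ai <- annual_inputs(eff_hist, params, evi_scale)
  perennial <- eff_crop %in% c(HAY_PASTURE_CROPS, SET_ASIDE_CROP)

  inp <- matrix(0, dpy, ny)
  ann <- which(!perennial); per <- which(perennial)
  if (length(ann)) inp[GS_ANNUAL, ann] <- rep(ai$crop[ann] / length(GS_ANNUAL),
                                              each = length(GS_ANNUAL))
  if (length(per)) inp[GS_PERENNIAL, per] <- rep(ai$crop[per] / length(GS_PERENNIAL),
                                                 each = length(GS_PERENNIAL))
  has_cc <- which(ai$cover > 0)
  if (length(has_cc)) inp[CC_WINDOW, has_cc] <-
    inp[CC_WINDOW, has_cc] + rep(ai$cover[has_cc] / length(CC_WINDOW),
                                 each = length(CC_WINDOW))
  has_man <- which(ai$manure > 0)
  if (length(has_man)) inp[MANURE_WINDOW, has_man] <-
    inp[MANURE_WINDOW, has_man] + rep(ai$manure[has_man] / length(MANURE_WINDOW),
                                      each = length(MANURE_WINDOW))

  till <- matrix(rep(unname(params$till_mult[eff_till]), each = dpy), dpy, ny)
  pulse <- which(history$cover_crop & history$termination == "tillage" &
                   !history$set_aside)
  if (length(pulse)) {
    win <- PULSE_START_DOY:(PULSE_START_DOY + params$till_pulse_days - 1)
    till[win, pulse] <- pmax(till[win, pulse], ft)
  }

  run <- cpp_run_days(pools, kv, rv, tf$f_ap, tf$f_sp,
                      m_T, m_W, as.vector(till), as.vector(inp), dt,
                      as.integer(seq_len(ny) * dpy))
  soc <- run$soc
  prev <- c(sum(pools), soc[-ny])
  out <- data.frame(location_id = location$location_id, year = years,
                    soc = soc, delta_soc = soc - prev)
  attr(out, "annual_input") <- diff(c(0, run$cum_input))
  attr(out, "annual_respired") <- diff(c(0, run$cum_respired))
  attr(out, "initial_soc") <- sum(pools)
  class(out) <- c("soc_trajectory", "data.frame")
  out
}
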