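# Synthetic survey world: frame, weather, true management histories, donor
# surveys and calibration sites. Generates every input the counterfactual
# pipeline consumes, with the statistical structure the analysis assumes,
# so the full analysis runs without confidential survey microdata.

#' Default national adoption trends for climate-smart practices
#'
#' Annual national area fractions, 1979-2015, for each practice the pipeline
#' tracks. The shapes emulate the historical record for US cropland: cover
#' crops absent before 1990 and ramping linearly to modest levels (about 2 Mha
#' by 2015 on a 125.4 Mha land base); conservation tillage rising steeply
#' after 2000 to roughly a quarter of cropland; hay/pasture in rotation
#' declining (4.7 to 2.3 Mha over 1995-2015); manure amendments flat at about
#' 4.5 Mha; and set-aside (reserve) area building through the late 1980s and
#' declining thereafter.
#'
#' @param years integer years covered (default 1979:2015)
#' @return data.frame with columns `year`, `cover_crop`, `cons_till`,
#'   `nt_share` (NT share within conservation tillage), `hay_pasture`,
#'   `manure`, `set_aside`; all fractions in `[0, 1]`
#' @export
default_adoption_trends <- function(years = 1979:2015) {
  ramp <- function(y, y0, v0, y1, v1) {
    v <- v0 + (v1 - v0) * (y - y0) / (y1 - y0)
    pmin(pmax(v, pmin(v0, v1)), max(v0, v1))
  }
  cc <- ifelse(years < 1990, 0,
               ifelse(years <= 2000, ramp(years, 1990, 0, 2000, 0.012),
                      ramp(years, 2000, 0.012, 2015, 0.016)))
  ct <- ifelse(years <= 2000, ramp(years, 1979, 0.05, 2000, 0.15),
               ramp(years, 2000, 0.15, 2013, 0.24))
  hp <- ifelse(years <= 1995, ramp(years, 1979, 0.045, 1995, 0.0375),
               ramp(years, 1995, 0.0375, 2015, 0.018))
  sa <- ifelse(years < 1986, 0,
               ifelse(years <= 1993, ramp(years, 1986, 0, 1993, 0.10),
                      ramp(years, 1995, 0.10, 2015, 0.05)))
  data.frame(
    year = years,
    cover_crop = cc,
    cons_till = ct,
    nt_share = ramp(years, 1979, 0.3, 2015, 0.6),
    hay_pasture = hp,
    manure = 0.036,
    set_aside = sa
  )
}

#' Generate a synthetic cropland survey frame
#'
#' Emulates a two-stage national area survey: locations scattered in a planar
#' rectangular domain (km) with clustered regional strata, positive expansion
#' weights (ha) rescaled to a configured national cropland area, and
#' delete-a-group jackknife replicate weights for design-based variance
#' estimation.
#'
#' @param n number of survey locations (>= 1)
#' @param domain_km numeric length-2 extent (x, y) of the study domain in km
#' @param total_area_ha national cropland area the weights must sum to
#' @param n_replicates number of jackknife replicate weight vectors G (>= 2)
#' @param n_regions number of regional strata
#' @param seed integer seed
#' @return object of class `survey_frame`: a list with `locations` (data.frame
#'   `location_id`, `x_km`, `y_km`, `weight`, `clay_frac`, `sand_frac`,
#'   `region_id`, `irrigated`, `jk_group`), `replicate_weights` (n x G
#'   matrix), `domain_km`, `total_area_ha`
#' @export
generate_frame <- function(n, domain_km = c(800, 500), total_area_ha = 125.4e6,
                           n_replicates = 30, n_regions = 4, seed = 1) {
  check_that(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1")
  check_that(total_area_ha > 0, "total_area_ha must be positive")
  check_that(n_replicates >= 2, "n_replicates must be >= 2")
  n <- as.integer(n)
  set.seed(substream_seed(seed, "frame"))

  # clustered strata: region centres on a jittered grid, locations scattered
  # around their region centre and clipped to the domain
  gx <- ceiling(sqrt(n_regions))
  gy <- ceiling(n_regions / gx)
  centres <- expand.grid(
    cx = (seq_len(gx) - 0.5) / gx * domain_km[1],
    cy = (seq_len(gy) - 0.5) / gy * domain_km[2]
  )[seq_len(n_regions), ]
  region <- sample.int(n_regions, n, replace = TRUE)
  x <- pmin(pmax(centres$cx[region] + stats::rnorm(n, 0, domain_km[1] / (6 * gx)), 0),
            domain_km[1])
  y <- pmin(pmax(centres$cy[region] + stats::rnorm(n, 0, domain_km[2] / (6 * gy)), 0),
            domain_km[2])

  w_raw <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
  weight <- w_raw / sum(w_raw) * total_area_ha

  clay <- stats::rbeta(n, 2.2, 5.5)                  # mean ~0.29
  sand <- (1 - clay) * stats::rbeta(n, 2, 3)         # clay + sand <= 1

  G <- as.integer(n_replicates)
  jk_group <- sample(rep_len(seq_len(G), n))         # balanced random groups
  # replicate g drops group g and scales the rest up by G/(G-1)
  rep_w <- matrix(weight, n, G) * G / (G - 1)
  for (g in seq_len(G)) rep_w[jk_group == g, g] <- 0
  colnames(rep_w) <- paste0("rep", seq_len(G))

  locations <- data.frame(
    location_id = seq_len(n),
    x_km = x, y_km = y,
    weight = weight,
    clay_frac = clay, sand_frac = sand,
    region_id = paste0("R", region),
    irrigated = stats::runif(n) < 0.08,
    jk_group = jk_group
  )
  structure(
    list(locations = locations, replicate_weights = rep_w,
         domain_km = domain_km, total_area_ha = total_area_ha),
    class = "survey_frame"
  )
}

#' @export
print.survey_frame <- function(x, ...) {
  cat("survey_frame:", nrow(x$locations), "locations,",
      ncol(x$replicate_weights), "replicate weight vectors\n")
  cat("  total area:", format(sum(x$locations$weight), big.mark = ","), "ha;",
      "regions:", paste(sort(unique(x$locations$region_id)), collapse = ", "), "\n")
  invisible(x)
}

#' Default regional climate normals for the weather generator
#'
#' @param region_ids character vector of region labels
#' @return data.frame of per-region normals: annual mean temperature (degC),
#'   seasonal amplitude (degC), mean annual precipitation (mm), AR(1)
#'   autocorrelation of daily temperature anomalies, anomaly s.d., and the
#'   two-state precipitation occurrence chain probabilities
#' @export
default_climate <- function(region_ids) {
  k <- length(region_ids)
  data.frame(
    region_id = region_ids,
    tmean_mean = seq(8, 16, length.out = max(k, 2))[seq_len(k)],
    tmean_amp = seq(13, 9, length.out = max(k, 2))[seq_len(k)],
    map_mm = seq(450, 1100, length.out = max(k, 2))[seq_len(k)],
    rho = 0.7,
    temp_sd = 3,
    p_wet_given_dry = 0.25,
    p_wet_given_wet = 0.55
  )
}

#' Generate daily weather series for every survey location
#'
#' Daily mean temperature is a regional seasonal sinusoid plus AR(1) noise;
#' daily precipitation follows a two-state occurrence chain with exponential
#' wet-day intensities calibrated so long-run means match the regional
#' normals. Years are 365 days (no leap days).
#'
#' @param frame a `survey_frame`
#' @param years integer vector of calendar years to generate (contiguous)
#' @param climate per-region normals as from [default_climate()]
#' @param seed integer seed
#' @return object of class `weather_series`: list with `tmean` and `precip`
#'   (day x location matrices), `year` and `doy` day index vectors, and
#'   `location_id`
#' @export
generate_weather <- function(frame, years, climate = NULL, seed = 1) {
  check_that(length(years) >= 1, "empty year span")
  years <- sort(unique(as.integer(years)))
  check_that(all(diff(years) == 1), "years must be contiguous")
  loc <- frame$locations
  if (is.null(climate)) climate <- default_climate(sort(unique(loc$region_id)))
  check_that(all(loc$region_id %in% climate$region_id),
             "climate must cover every region in the frame")
  set.seed(substream_seed(seed, "weather"))

  nd_year <- 365L
  nd <- nd_year * length(years)
  n <- nrow(loc)
  ci <- match(loc$region_id, climate$region_id)
  doy <- rep(seq_len(nd_year), length(years))
  yr <- rep(years, each = nd_year)

  seas <- outer(cos(2 * pi * (doy - 196) / nd_year), climate$tmean_amp[ci]) # peak mid-July
  mu <- matrix(climate$tmean_mean[ci], nd, n, byrow = TRUE)
  rho <- climate$rho[ci]
  innov_sd <- climate$temp_sd[ci] * sqrt(1 - rho^2)
  eps <- matrix(stats::rnorm(nd * n), nd, n) * matrix(innov_sd, nd, n, byrow = TRUE)
  ar <- matrix(0, nd, n)
  for (j in seq_len(n)) {
    ar[, j] <- stats::filter(eps[, j], rho[j], method = "recursive")
  }
  tmean <- mu + seas + ar

  # precipitation: stationary wet-day probability pi = p01 / (1 + p01 - p11)
  p01 <- climate$p_wet_given_dry[ci]
  p11 <- climate$p_wet_given_wet[ci]
  pi_wet <- p01 / (1 + p01 - p11)
  mean_int <- climate$map_mm[ci] / (nd_year * pi_wet)  # mm per wet day
  wet <- matrix(FALSE, nd, n)
  wet[1, ] <- stats::runif(n) < pi_wet
  u <- matrix(stats::runif(nd * n), nd, n)
  for (d in 2:nd) {
    p <- ifelse(wet[d - 1, ], p11, p01)
    wet[d, ] <- u[d, ] < p
  }
  intensity <- matrix(stats::rexp(nd * n), nd, n) *
    matrix(mean_int, nd, n, byrow = TRUE)
  precip <- ifelse(wet, intensity, 0)

  colnames(tmean) <- colnames(precip) <- loc$location_id
  structure(
    list(tmean = tmean, precip = precip, year = yr, doy = doy,
         location_id = loc$location_id),
    class = "weather_series"
  )
}

#' @export
print.weather_series <- function(x, ...) {
  cat("weather_series:", length(x$location_id), "locations,",
      length(unique(x$year)), "years (", min(x$year), "-", max(x$year), ")\n")
  invisible(x)
}

#' Generate true per-location management histories
#'
#' Builds annual management records 1979-2015 whose weighted national adoption
#' matches the configured trend curves in expectation. Persistence is induced
#' by per-location latent uniforms: a location adopts a practice in year `y`
#' iff its uniform is below the national fraction for `y`, so monotone trends
#' produce realistic persistent adoption/abandonment spells rather than
#' year-to-year churn. Cover crops are impossible before 1990. Set-aside years
#' carry grass cover, no-till and no amendments; practice thresholds are
#' rescaled by the eligible area so national fractions are honoured despite
#' precedence (set-aside > hay/pasture > annual crops).
#'
#' @param frame a `survey_frame`
#' @param adoption trend data.frame as from [default_adoption_trends()]
#' @param years integer years (default 1979:2015)
#' @param termination default cover-crop termination practice assigned to
#'   cover-cropped years (`"herbicide"` or `"tillage"`)
#' @param seed integer seed
#' @return data.frame of class `management_history` with one row per
#'   location-year: `location_id`, `year`, `crop`, `tillage`, `fert_n`,
#'   `manure_n`, `cover_crop`, `termination`, `irrigated`, `set_aside`
#' @export
generate_truth_histories <- function(frame, adoption = default_adoption_trends(),
                                     years = 1979:2015,
                                     termination = "herbicide", seed = 1) {
  trend_cols <- c("cover_crop", "cons_till", "nt_share", "hay_pasture",
                  "manure", "set_aside")
  check_that(all(trend_cols %in% names(adoption)), "adoption is missing trend columns")
  check_that(all(years %in% adoption$year), "adoption must cover all years")
  vals <- as.matrix(adoption[match(years, adoption$year), trend_cols])
  check_that(all(vals >= 0 & vals <= 1), "adoption fractions must lie in [0, 1]")
  check_that(all(vals[years < 1990, "cover_crop"] == 0),
             "cover-crop adoption must be zero before 1990")
  check_that(termination %in% c("herbicide", "tillage"), "unknown termination")

  loc <- frame$locations
  n <- nrow(loc)
  ny <- length(years)
  set.seed(substream_seed(seed, "truth"))

  u_sa <- stats::runif(n); u_hay <- stats::runif(n); u_cc <- stats::runif(n)
  u_ct <- stats::runif(n); u_nt <- stats::runif(n); u_man <- stats::runif(n)

  f <- function(name) vals[, name]
  f_sa <- f("set_aside")
  elig <- pmax(1 - f_sa, 1e-12)          # non-set-aside area fraction

  # n x ny logical matrices; thresholds rescaled by eligible area
  below <- function(u, fr) outer(u, fr, `<`)
  sa <- below(u_sa, f_sa)
  # hay/pasture is a rotation system: while a location is in the system it
  # grows hay/pasture one year in `hay_cycle`, so the fraction of locations
  # in the system is hay_cycle times the national hay-area fraction
  hay_cycle <- 3L
  hay_sys <- below(u_hay, pmin(hay_cycle * f("hay_pasture") / elig, 1))
  hay_phase <- sample.int(hay_cycle, n, replace = TRUE)
  in_hay_year <- outer(hay_phase, years, function(ph, y) (y + ph) %% hay_cycle == 0)
  hay <- hay_sys & in_hay_year & !sa
  cc <- below(u_cc, pmin(f("cover_crop") / elig, 1)) & !sa & !hay
  ct <- below(u_ct, pmin(f("cons_till") / elig, 1)) & !sa
  nt <- ct & below(u_nt, f("nt_share"))
  man <- below(u_man, pmin(f("manure") / elig, 1)) & !sa

  # crop pools: 2-3 annual crops per location, rotated cyclically
  crop_pool_all <- c("corn", "soybean", "wheat", "cotton", "barley", "sorghum")
  pools <- lapply(seq_len(n), function(i) {
    k <- sample(2:3, 1)
    sample(crop_pool_all, k)
  })
  crop <- matrix("", n, ny)
  for (i in seq_len(n)) {
    p <- pools[[i]]
    crop[i, ] <- p[(seq_len(ny) - 1L) %% length(p) + 1L]
  }
  hay_type <- ifelse(stats::runif(n) < 0.5, "hay", "pasture")
  for (i in seq_len(n)) crop[i, hay[i, ]] <- hay_type[i]
  crop[sa] <- SET_ASIDE_CROP

  # the tillage class labels the location's management system and persists
  # through hay years; set-aside years are untilled grass
  tillage <- matrix("FT", n, ny)
  tillage[ct] <- "RT"
  tillage[nt] <- "NT"
  tillage[sa] <- "NT"

  fert_base <- c(corn = 150, soybean = 15, wheat = 90, cotton = 110,
                 barley = 70, sorghum = 90, hay = 30, pasture = 20, grass = 0)
  fert_trend <- pmin(0.7 + 0.3 * (years - 1979) / (2000 - 1979), 1)
  loc_mult <- exp(stats::rnorm(n, 0, 0.2))
  fert <- matrix(fert_base[crop], n, ny) *
    outer(loc_mult, fert_trend)
  fert[sa] <- 0

  manure_rate <- 120 * exp(stats::rnorm(n, 0, 0.3))
  manure <- matrix(0, n, ny)
  manure[man] <- rep(manure_rate, ny)[which(man)]

  out <- data.frame(
    location_id = rep(loc$location_id, ny),
    year = rep(years, each = n),
    crop = as.vector(crop),
    tillage = as.vector(tillage),
    fert_n = as.vector(fert),
    manure_n = as.vector(manure),
    cover_crop = as.vector(cc),
    termination = ifelse(as.vector(cc), termination, "none"),
    irrigated = rep(loc$irrigated, ny),
    set_aside = as.vector(sa)
  )
  out <- out[order(out$location_id, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("management_history", "data.frame")
  out
}

#' Generate a donor survey from true histories
#'
#' Samples donor records (stand-ins for field-level management survey
#' responses) from the truth histories over the anchor years, with
#' multiplicative observation noise on N rates, stratified by region, crop
#' group and soil texture class so every stratum used downstream has at least
#' one donor.
#'
#' @param frame a `survey_frame`
#' @param truth a `management_history` from [generate_truth_histories()]
#' @param n_donors target number of donors (>= number of strata)
#' @param anchor_years years donors are drawn from (default 2001:2005)
#' @param noise_sd s.d. of multiplicative log-normal observation noise on N
#' @param seed integer seed
#' @return data.frame `donor_survey`: `donor_id`, `region_id`, `crop_group`,
#'   `texture_class`, `year`, `fert_n`, `manure_n`, `tillage`, `cover_crop`
#' @export
generate_donors <- function(frame, truth, n_donors = 400,
                            anchor_years = 2001:2005, noise_sd = 0.1, seed = 1) {
  loc <- frame$locations
  cand <- truth[truth$year %in% anchor_years & !truth$set_aside, ]
  check_that(nrow(cand) > 0, "no donor candidates in anchor years")
  li <- match(cand$location_id, loc$location_id)
  cand$region_id <- loc$region_id[li]
  cand$texture_class <- texture_class(loc$clay_frac[li], loc$sand_frac[li])
  cand$crop_group <- ifelse(cand$crop %in% HAY_PASTURE_CROPS, "hay_pasture", "annual")
  strata <- unique(cand[, c("region_id", "crop_group", "texture_class")])
  check_that(n_donors >= nrow(strata), "n_donors must be >= number of strata")
  set.seed(substream_seed(seed, "donors"))

  idx <- sample.int(nrow(cand), n_donors, replace = n_donors > nrow(cand))
  picked <- cand[idx, ]
  # guarantee stratum coverage: add one donor from each uncovered stratum
  key <- function(d) paste(d$region_id, d$crop_group, d$texture_class)
  missing <- setdiff(key(strata), unique(key(picked)))
  for (k in missing) {
    rows <- which(key(cand) == k)
    if (length(rows) == 0) stop("empty donor stratum: ", k, call. = FALSE)
    picked <- rbind(picked, cand[rows[sample.int(length(rows), 1)], ])
  }
  m <- nrow(picked)
  pi2 <- match(picked$location_id, loc$location_id)
  out <- data.frame(
    donor_id = seq_len(m),
    region_id = picked$region_id,
    crop_group = picked$crop_group,
    texture_class = picked$texture_class,
    clay_frac = loc$clay_frac[pi2],
    year = picked$year,
    fert_n = picked$fert_n * exp(stats::rnorm(m, 0, noise_sd)),
    manure_n = picked$manure_n * exp(stats::rnorm(m, 0, noise_sd)),
    tillage = picked$tillage,
    cover_crop = picked$cover_crop
  )
  rownames(out) <- NULL
  class(out) <- c("donor_survey", "data.frame")
  out
}

#' Generate calibration sites with known model bias
#'
#' Emulates long-term experiment data used to quantify structural model
#' uncertainty: each site has several treatments; "measured" SOC is a linear
#' transformation of the model-simulated SOC plus a site-level random effect
#' and residual noise, so the configured bias is recoverable by
#' [fit_bias_model()].
#'
#' @param n_sites number of experimental sites (>= 3)
#' @param bias list with `intercept` (t C/ha) and `slope` applied to the
#'   simulated stock
#' @param re_sd s.d. of the site-level random effect (t C/ha)
#' @param resid_sd residual s.d. (t C/ha)
#' @param region_re_sd s.d. of a region-level random effect (default 0)
#' @param n_treatments treatments per site (>= 2)
#' @param n_regions regions the sites are grouped into
#' @param soc_model function `(clay_frac, tmean_c, tillage, input_mult)` ->
#'   simulated SOC (t C/ha); defaults to the analytic equilibrium of the
#'   surrogate pool model
#' @param seed integer seed
#' @return data.frame `calibration_sites`: `site_id`, `region_id`,
#'   `treatment_id`, `simulated_soc`, `measured_soc`, `clay_frac`, `tmean_c`
#' @export
generate_calibration_sites <- function(n_sites = 50,
                                       bias = list(intercept = 5, slope = 0.9),
                                       re_sd = 5, resid_sd = 5,
                                       region_re_sd = 0, n_treatments = 4,
                                       n_regions = 4, soc_model = NULL, seed = 1) {
  check_that(n_sites >= 3, "n_sites must be >= 3")
  check_that(n_treatments >= 2, "need >= 2 treatments per site")
  set.seed(substream_seed(seed, "calibration_sites"))
  if (is.null(soc_model)) {
    soc_model <- function(clay_frac, tmean_c, tillage, input_mult) {
      params <- default_params()
      eq <- solve_equilibrium(
        params,
        mean_forcing = list(
          m_T = decomp_modifiers(tmean_c, 0.5, tillage, params)$m_T,
          m_W = 0.5, m_till = params$till_mult[[tillage]]),
        mean_input = params$native_c_input * input_mult,
        clay_frac = clay_frac)
      eq$total
    }
  }
  clay <- stats::rbeta(n_sites, 2.2, 5.5)
  tmean <- stats::runif(n_sites, 6, 18)
  region <- paste0("R", sample.int(n_regions, n_sites, replace = TRUE))
  tills <- rep_len(TILLAGE_LEVELS, n_treatments)
  input_mult <- rep_len(c(1, 0.8, 1.2, 0.9), n_treatments)
  site_eff <- stats::rnorm(n_sites, 0, re_sd)
  region_eff <- stats::rnorm(n_regions, 0, region_re_sd)
  names(region_eff) <- paste0("R", seq_len(n_regions))

  rows <- expand.grid(site = seq_len(n_sites), trt = seq_len(n_treatments))
  sim <- mapply(function(s, t) soc_model(clay[s], tmean[s], tills[t], input_mult[t]),
                rows$site, rows$trt)
  measured <- bias$intercept + bias$slope * sim +
    site_eff[rows$site] + region_eff[region[rows$site]] +
    stats::rnorm(nrow(rows), 0, resid_sd)
  out <- data.frame(
    site_id = paste0("S", rows$site),
    region_id = region[rows$site],
    treatment_id = paste0("T", rows$trt),
    simulated_soc = sim,
    measured_soc = measured,
    clay_frac = clay[rows$site],
    tmean_c = tmean[rows$site]
  )
  rownames(out) <- NULL
  class(out) <- c("calibration_sites", "data.frame")
  out
}
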