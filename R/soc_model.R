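# Surrogate multi-pool soil organic carbon model. A transparent, documented
# stand-in for a full daily-step biogeochemistry model: three SOC pools
# (active, slow, passive) with first-order decay, climate and tillage
# modifiers on decomposition, clay-dependent transfers, crop-driven carbon
# inputs and exact mass balance. Defaults follow classic multi-pool soil
# organic matter models. The simulator sits behind a small interface so a
# process-model binding could replace it without touching the pipeline.

#' Default surrogate model parameters
#'
#' Base decay rates (yr^-1) and respiration fractions follow classic
#' multi-pool soil organic matter models; transfer fractions to the passive
#' pool increase with clay content. Tillage multiplies decomposition of the
#' active and slow pools (FT >= RT >= NT). Crop carbon inputs are annual
#' totals (t C/ha/yr) allocated over the growing season.
#'
#' @param overrides named list of parameter overrides
#' @return a list of class `soc_params`
#' @export
default_params <- function(overrides = NULL) {
  p <- list(
    k = c(active = 7.3, slow = 0.2, passive = 0.0045),  # yr^-1
    resp_frac = c(active = 0.55, slow = 0.55, passive = 0.55),
    f_ap_base = 0.004, f_ap_clay = 0.03,    # active -> passive, clay-dependent
    f_sp_base = 0.003, f_sp_clay = 0.009,   # slow -> passive, clay-dependent
    q10 = 2, t_ref = 25, m_t_cap = 2,
    w_half = 0.3,
    till_mult = c(NT = 1.00, RT = 1.15, FT = 1.30),
    crop_c_input = c(corn = 2.8, soybean = 2.0, wheat = 2.2, cotton = 1.8,
                     barley = 2.0, sorghum = 2.4, hay = 3.0, pasture = 3.2,
                     grass = 3.0),
    cover_crop_c = 0.8,        # t C/ha winter cover input
    manure_cn = 15,            # manure C:N ratio (kg C per kg N)
    native_c_input = 3.0,      # t C/ha/yr under native vegetation
    base_crop_input = 2.2,     # mean annual-crop input before modern varieties
    low_input_scale = 0.5,     # productivity scale of pre-1950 agriculture
    base_start = 1910,         # first year of the base-history simulation
    ramp_years = 1950:1978,    # productivity ramp to modern levels
    till_pulse_days = 30,      # extra full-till window for tillage termination
    evi_ref = 0.5,             # reference growing-season vegetation index
    days_per_year = 365L
  )
  if (!is.null(overrides)) p[names(overrides)] <- overrides
  validate_params(p)
  structure(p, class = "soc_params")
}

validate_params <- function(p) {
  check_that(all(p$k > 0), "decay rates must be positive")
  check_that(p$k[["active"]] > p$k[["slow"]] && p$k[["slow"]] > p$k[["passive"]],
             "decay rates must satisfy k_active > k_slow > k_passive")
  check_that(all(p$resp_frac >= 0 & p$resp_frac <= 1), "resp_frac outside [0,1]")
  tm <- p$till_mult
  check_that(tm[["FT"]] >= tm[["RT"]] && tm[["RT"]] >= tm[["NT"]],
             "till_mult must satisfy FT >= RT >= NT")
  invisible(p)
}

transfer_fracs <- function(params, clay_frac) {
  list(f_ap = params$f_ap_base + params$f_ap_clay * clay_frac,
       f_sp = params$f_sp_base + params$f_sp_clay * clay_frac)
}

#' Decomposition rate modifiers
#'
#' Temperature modifier `m_T = q10^((T - t_ref)/10)` capped at
#' `params$m_t_cap`; moisture modifier `m_W = w / (w + w_half)` on relative
#' water `w` in `[0, 1]`; tillage modifier from the class multiplier map.
#'
#' @param tmean_c mean temperature (degC), vectorised
#' @param rel_water relative soil water in `[0, 1]`, vectorised
#' @param tillage tillage class (`"NT"`, `"RT"`, `"FT"`), vectorised
#' @param params `soc_params`
#' @return list with components `m_T`, `m_W`, `m_till`
#' @export
decomp_modifiers <- function(tmean_c, rel_water, tillage, params = default_params()) {
  check_that(all(rel_water >= 0 & rel_water <= 1), "rel_water outside [0, 1]")
  check_that(all(tillage %in% TILLAGE_LEVELS), "unknown tillage class")
  list(
    m_T = pmin(params$q10^((tmean_c - params$t_ref) / 10), params$m_t_cap),
    m_W = rel_water / (rel_water + params$w_half),
    m_till = unname(params$till_mult[tillage])
  )
}

#' Advance the pool state by one time step
#'
#' Each pool decays by `k * m_T * m_W * m_till * dt` (the tillage modifier
#' applies to the active and slow pools only); the decayed flux splits into
#' respiration and transfers; inputs enter the active pool. Mass balance is
#' exact: `delta(total) = input - respired`.
#'
#' @param state named numeric `c(active=, slow=, passive=)` in t C/ha
#' @param c_input_day carbon input this step (t C/ha)
#' @param modifiers list `(m_T, m_W, m_till)` as from [decomp_modifiers()]
#' @param params `soc_params`
#' @param dt_days step length in days
#' @param clay_frac clay fraction for transfer coefficients
#' @return list with `state` (named numeric) and `respired` (t C/ha)
#' @export
step_pools <- function(state, c_input_day, modifiers, params = default_params(),
                       dt_days = 1, clay_frac = 0.2) {
  check_that(dt_days > 0, "dt_days must be positive")
  check_that(c_input_day >= 0, "c_input_day must be non-negative")
  dt <- dt_days / params$days_per_year
  tf <- transfer_fracs(params, clay_frac)
  base <- modifiers$m_T * modifiers$m_W * dt
  d <- state * params$k * base * c(modifiers$m_till, modifiers$m_till, 1)
  if (any(d > state))
    stop("pool driven negative: time step too large for decay rates", call. = FALSE)
  resp <- params$resp_frac
  respired <- sum(resp * d)
  new <- state
  new[1] <- state[1] + c_input_day - d[1] +
    (1 - resp[2] - tf$f_sp) * d[2] + (1 - resp[3]) * d[3]
  new[2] <- state[2] + (1 - resp[1] - tf$f_ap) * d[1] - d[2]
  new[3] <- state[3] + tf$f_ap * d[1] + tf$f_sp * d[2] - d[3]
  list(state = new, respired = unname(respired))
}

#' Analytic steady state of the pool system
#'
#' Under constant modifiers and input the pool system is linear; the steady
#' state solves the flux-balance system exactly and agrees with a long
#' brute-force spin-up (the production pipeline initialises from this solve;
#' the equivalence is verified against multi-millennial spin-up runs in the
#' test suite).
#'
#' @param params `soc_params`
#' @param mean_forcing list `(m_T, m_W, m_till)` of mean modifiers
#' @param mean_input mean carbon input (t C/ha/yr)
#' @param clay_frac clay fraction
#' @return list of class `pool_state`: `active`, `slow`, `passive`, `total`
#' @export
solve_equilibrium <- function(params, mean_forcing, mean_input, clay_frac = 0.2) {
  tf <- transfer_fracs(params, clay_frac)
  m <- mean_forcing$m_T * mean_forcing$m_W
  k_eff <- params$k * m * c(mean_forcing$m_till, mean_forcing$m_till, 1)
  resp <- params$resp_frac
  # transfer matrix T[i, j]: fraction of pool j's decayed flux entering pool i
  Tm <- matrix(0, 3, 3)
  Tm[2, 1] <- 1 - resp[1] - tf$f_ap   # active -> slow
  Tm[3, 1] <- tf$f_ap                 # active -> passive
  Tm[1, 2] <- 1 - resp[2] - tf$f_sp   # slow -> active
  Tm[3, 2] <- tf$f_sp                 # slow -> passive
  Tm[1, 3] <- 1 - resp[3]             # passive -> active
  u <- c(mean_input, 0, 0)
  d <- tryCatch(solve(diag(3) - Tm, u),
                error = function(e) stop("no equilibrium: singular transfer structure",
                                         call. = FALSE))
  if (any(!is.finite(d)) || any(k_eff <= 0))
    stop("no equilibrium: degenerate rates", call. = FALSE)
  pools <- d / k_eff
  structure(list(active = pools[[1]], slow = pools[[2]], passive = pools[[3]],
                 total = sum(pools)), class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("pool_state: active %.2f, slow %.2f, passive %.2f, total %.2f t C/ha\n",
              x$active, x$slow, x$passive, x$total))
  invisible(x)
}

#' Savitzky-Golay gap filling of a regularly sampled index series
#'
#' Fills missing entries (e.g. a vegetation index observed at roughly 8-day
#' intervals) by Savitzky-Golay-style local polynomial smoothing generalised
#' to irregular support: each output value is the least-squares polynomial of
#' order `poly_order` fitted to the `window` nearest observed samples,
#' evaluated at that position. Polynomial signals up to `poly_order` are
#' reconstructed exactly (including at gaps and edges); observed entries are
#' preserved to within the smoothing tolerance.
#'
#' @param series numeric vector with `NA` at missing entries
#' @param window odd number of observed samples in each local fit,
#'   `> poly_order` and `< length(series)`
#' @param poly_order polynomial order of the local fit
#' @return filled numeric series of the same length
#' @export
sg_gapfill <- function(series, window = 15, poly_order = 3) {
  check_that(window %% 2 == 1, "window must be odd")
  check_that(window > poly_order, "window must exceed poly_order")
  check_that(window < length(series), "window must be shorter than the series")
  obs <- which(!is.na(series))
  check_that(length(obs) >= window, "too few observed samples for the window")
  n <- length(series)
  out <- numeric(n)
  yobs <- series[obs]
  for (i in seq_len(n)) {
    nb <- obs[order(abs(obs - i))[seq_len(window)]]
    xs <- (nb - i)
    X <- outer(xs, 0:poly_order, `^`)
    beta <- qr.coef(qr(X), series[nb])
    out[i] <- beta[1]                      # polynomial evaluated at offset 0
  }
  out
}

#' Convert a carbon mass to CO2 equivalents
#'
#' Multiplies by the molar mass ratio 44/12 (CO2 to C).
#'
#' @param mt_c carbon mass (Mt C), vectorised
#' @return Mt CO2 equivalents
#' @export
c_to_co2e <- function(mt_c) mt_c * 44 / 12
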