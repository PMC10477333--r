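test_that("decomposition modifiers follow their defining forms", {
  p <- default_params()
  m <- decomp_modifiers(p$t_ref, 0.5, "NT", p)
  expect_equal(m$m_T, 1)
  m2 <- decomp_modifiers(p$t_ref + 10, 0.5, "FT", p)   # one q10 doubling
  expect_equal(m2$m_T, 2)
  expect_equal(m2$m_till, p$till_mult[["FT"]])
  # strictly increasing below the cap
  ts <- seq(0, 35, by = 1)
  mT <- decomp_modifiers(ts, 0.5, "NT", p)$m_T
  below_cap <- mT < p$m_t_cap
  expect_true(all(diff(mT[below_cap]) > 0))
  expect_error(decomp_modifiers(10, 1.2, "NT", p), "rel_water")
  expect_error(decomp_modifiers(10, 0.5, "XX", p), "tillage")
})

test_that("a pool step conserves carbon exactly and is inert without decay", {
  p <- default_params()
  s0 <- c(active = 2, slow = 30, passive = 40)
  # zero effective decay: state unchanged, nothing respired
  r0 <- step_pools(s0, 0, list(m_T = 0, m_W = 0, m_till = 1), p)
  expect_equal(r0$state, s0)
  expect_equal(r0$respired, 0)
  # conservation: delta(total) = input - respired, over random steps
  set.seed(5)
  for (i in 1:50) {
    s <- c(active = runif(1, 0, 5), slow = runif(1, 5, 60), passive = runif(1, 10, 80))
    inp <- runif(1, 0, 0.05)
    m <- list(m_T = runif(1, 0.1, 2), m_W = runif(1, 0.1, 1),
              m_till = sample(unname(p$till_mult), 1))
    r <- step_pools(s, inp, m, p, clay_frac = runif(1, 0, 0.6))
    expect_lt(abs((sum(r$state) - sum(s)) - (inp - r$respired)),
              1e-9 * max(sum(s), 1))
  }
})

test_that("an isolated pool decays exponentially over a year of daily steps", {
  # oracle: closed-form exp(-k t); k_eff = 0.1 / yr via the modifiers
  p <- default_params()
  s <- c(active = 10, slow = 0, passive = 0)
  m <- list(m_T = 0.1 / p$k[["active"]], m_W = 1, m_till = 1)
  for (d in 1:365) s <- step_pools(s, 0, m, p)$state
  expect_lt(abs(s[["active"]] / (10 * exp(-0.1)) - 1), 1e-3)
})

test_that("analytic equilibrium matches its defining limits", {
  # no transfers: every pool is input / k_eff for its own balance
  p <- default_params(list(resp_frac = c(active = 1, slow = 1, passive = 1),
                           f_ap_base = 0, f_ap_clay = 0,
                           f_sp_base = 0, f_sp_clay = 0))
  fo <- list(m_T = 0.5, m_W = 0.5, m_till = 1)
  eq <- solve_equilibrium(p, fo, mean_input = 2, clay_frac = 0.2)
  expect_equal(eq$active, 2 / (p$k[["active"]] * 0.25), tolerance = 1e-12)
  expect_equal(eq$slow, 0)
  expect_equal(eq$passive, 0)
  # linearity: doubling input doubles every pool
  p2 <- default_params()
  a <- solve_equilibrium(p2, fo, 2, 0.3)
  b <- solve_equilibrium(p2, fo, 4, 0.3)
  expect_equal(b$total, 2 * a$total, tolerance = 1e-12)
  expect_equal(b$active, 2 * a$active, tolerance = 1e-12)
})

test_that("equilibrium solve agrees with a brute-force multi-millennial spin-up", {
  set.seed(17)
  p0 <- default_params()
  for (i in 1:10) {
    p <- default_params(list(
      k = c(active = runif(1, 4, 10), slow = runif(1, 0.12, 0.35),
            passive = runif(1, 0.0035, 0.007)),
      resp_frac = c(active = runif(1, 0.4, 0.7), slow = runif(1, 0.4, 0.7),
                    passive = runif(1, 0.4, 0.7))))
    clay <- runif(1, 0.05, 0.5)
    # mean forcing kept in the regime where the passive pool's effective
    # turnover is well inside the spin-up horizon (as a 6000-yr "approximate
    # steady state" presumes)
    fo <- list(m_T = runif(1, 0.6, 1.5), m_W = runif(1, 0.5, 0.9),
               m_till = sample(unname(p$till_mult), 1))
    inp <- runif(1, 1, 4)
    eq <- solve_equilibrium(p, fo, inp, clay)
    tf <- soccf:::transfer_fracs(p, clay)
    sp <- soccf:::cpp_spinup(c(0, 0, 0), unname(p$k), unname(p$resp_frac),
                             tf$f_ap, tf$f_sp, fo$m_T, fo$m_W, fo$m_till,
                             inp / 365, 6000L * 365L, 1 / 365)
    expect_lt(abs(sum(sp$final) / eq$total - 1), 0.005)
  }
})

test_that("raising any decomposition multiplier never raises equilibrium SOC", {
  p <- default_params()
  fo <- list(m_T = 0.5, m_W = 0.5, m_till = 1)
  base <- solve_equilibrium(p, fo, 3, 0.2)$total
  expect_lt(solve_equilibrium(p, list(m_T = 0.7, m_W = 0.5, m_till = 1), 3, 0.2)$total, base)
  expect_lt(solve_equilibrium(p, list(m_T = 0.5, m_W = 0.7, m_till = 1), 3, 0.2)$total, base)
  expect_lt(solve_equilibrium(p, list(m_T = 0.5, m_W = 0.5, m_till = 1.3), 3, 0.2)$total, base)
})

test_that("a location at equilibrium conditions holds a steady state", {
  wl <- constant_weather(1979:2015)
  h <- flat_history(crop = "grass", tillage = "NT")
  # no agricultural base history: the run starts at the native equilibrium
  # and the history continues the same conditions
  p <- default_params(list(native_c_input = 3.0,
                           crop_c_input = c(grass = 3.0),
                           base_start = 1979, ramp_years = integer(0)))
  tr <- simulate_location(one_location(), wl, h, p)
  # input seasonality vs the year-round equilibrium assumption leaves only a
  # small transient; annual stock changes stay near zero throughout
  expect_lt(max(abs(tr$delta_soc)), 0.15)
  expect_lt(abs(mean(tr$delta_soc)), 0.02)
})

test_that("trajectories respect mass balance and tillage monotonicity", {
  w <- small_world()
  loc <- w$frame$locations[3, ]
  wl <- weather_for(w$weather, loc$location_id)
  h_nt <- flat_history(crop = "corn", tillage = "NT", fert = 120)
  h_ft <- flat_history(crop = "corn", tillage = "FT", fert = 120)
  t_nt <- simulate_location(loc, wl, h_nt)
  t_ft <- simulate_location(loc, wl, h_ft)
  expect_true(all(t_nt$soc >= t_ft$soc))
  # annual carbon budget closes: delta = input - respired
  bal <- (t_nt$soc - c(attr(t_nt, "initial_soc"), head(t_nt$soc, -1))) -
    (attr(t_nt, "annual_input") - attr(t_nt, "annual_respired"))
  expect_lt(max(abs(bal)), 1e-9 * max(t_nt$soc))
  # delta_soc is consistent with successive stocks
  expect_equal(t_nt$delta_soc[-1], diff(t_nt$soc), tolerance = 1e-12)
  expect_error(simulate_location(loc, wl, h_nt[-5, ]), "missing history year")
})

test_that("practice contrasts fall in the plausible 0-1 t C/ha/yr band", {
  w <- small_world()
  loc <- w$frame$locations[5, ]
  wl <- weather_for(w$weather, loc$location_id)
  t_nt <- simulate_location(loc, wl, flat_history(crop = "corn", tillage = "NT"))
  t_ft <- simulate_location(loc, wl, flat_history(crop = "corn", tillage = "FT"))
  d <- mean(t_nt$delta_soc[t_nt$year %in% 1995:2015] -
              t_ft$delta_soc[t_ft$year %in% 1995:2015])
  expect_gt(d, 0)
  expect_lt(d, 1)
})

test_that("cover-crop termination method orders carbon gains as expected", {
  w <- small_world()
  loc <- w$frame$locations[7, ]
  wl <- weather_for(w$weather, loc$location_id)
  h_herb <- flat_history(crop = "corn", tillage = "NT", cc = TRUE,
                         termination = "herbicide")
  h_till <- flat_history(crop = "corn", tillage = "NT", cc = TRUE,
                         termination = "tillage")
  h_none <- flat_history(crop = "corn", tillage = "NT")
  s_herb <- simulate_location(loc, wl, h_herb)
  s_till <- simulate_location(loc, wl, h_till)
  s_none <- simulate_location(loc, wl, h_none)
  gain_herb <- mean(s_herb$delta_soc - s_none$delta_soc)
  gain_till <- mean(s_till$delta_soc - s_none$delta_soc)
  expect_gt(gain_herb, gain_till)   # tillage termination sequesters less
  expect_gt(gain_herb, 0)
})

test_that("Savitzky-Golay gap filling reconstructs smooth series", {
  x <- seq_len(120)
  quad <- 2 + 0.3 * x - 0.002 * x^2
  holey <- quad
  holey[seq(3, 118, by = 8)] <- NA          # ~8-day gaps
  filled <- sg_gapfill(holey, window = 11, poly_order = 2)
  expect_equal(filled, quad, tolerance = 1e-8)
  expect_equal(sg_gapfill(rep(4, 60), window = 9, poly_order = 2), rep(4, 60),
               tolerance = 1e-10)
  # noisy sinusoid: smoothing beats the raw noise level
  set.seed(8)
  truth <- sin(2 * pi * x / 60)
  noisy <- truth + rnorm(120, 0, 0.2)
  noisy[seq(5, 115, by = 8)] <- NA
  sm <- sg_gapfill(noisy, window = 15, poly_order = 3)
  expect_lt(sqrt(mean((sm - truth)^2)), 0.2)
  expect_error(sg_gapfill(quad, window = 10, poly_order = 2), "odd")
  expect_error(sg_gapfill(quad[1:5], window = 7, poly_order = 2), "shorter")
})

test_that("carbon to CO2-equivalent conversion uses the molar ratio", {
  expect_equal(c_to_co2e(12), 44)
  expect_equal(c_to_co2e(0), 0)
  expect_equal(c_to_co2e(16.6), 16.6 * 44 / 12)
})

test_that("a vegetation index series rescales annual crop inputs", {
  wl <- constant_weather(1998:2005)
  h <- flat_history(years = 1998:2005, crop = "corn", tillage = "NT")
  loc <- one_location()
  evi_hi <- rep(NA_real_, length(wl$tmean))
  evi_hi[seq(1, length(evi_hi), by = 8)] <- 0.75   # 1.5x the reference index
  t_base <- simulate_location(loc, wl, h)
  t_evi <- simulate_location(loc, wl, h, evi = evi_hi)
  # pre-2000 years are untouched; later years get more input, hence more SOC
  expect_equal(t_evi$soc[t_evi$year < 2000], t_base$soc[t_base$year < 2000],
               tolerance = 1e-9)
  expect_true(all(t_evi$soc[t_evi$year >= 2001] > t_base$soc[t_base$year >= 2001]))
})
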