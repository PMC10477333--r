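test_that("survey frame honours weight, soil and replicate-weight invariants", {
  fr <- generate_frame(500, total_area_ha = 1e6, seed = 7)
  loc <- fr$locations
  expect_equal(sum(loc$weight), 1e6, tolerance = 1e-3)
  expect_true(all(loc$weight > 0))
  expect_true(all(loc$clay_frac + loc$sand_frac <= 1))
  expect_true(all(loc$clay_frac >= 0 & loc$clay_frac <= 1))
  # each replicate-weight vector sums to within 5% of the full-sample total
  expect_true(all(abs(colSums(fr$replicate_weights) / sum(loc$weight) - 1) < 0.05))
  # weighted sum of a per-location constant equals constant x total area
  expect_equal(sum(3.7 * loc$weight), 3.7 * 1e6, tolerance = 1e-9)
})

test_that("frame generation is deterministic in the seed and errors on bad input", {
  a <- generate_frame(50, seed = 3)
  b <- generate_frame(50, seed = 3)
  expect_identical(a, b)
  c <- generate_frame(50, seed = 4)
  expect_false(identical(a$locations$weight, c$locations$weight))
  expect_error(generate_frame(0), "n must be")
  expect_error(generate_frame(10, total_area_ha = -1), "positive")
  expect_error(generate_frame(10, n_replicates = 1), "n_replicates")
})

test_that("jackknife variance of a weighted iid total tracks the analytic variance", {
  # oracle: Var(sum w_i x_i) = sigma^2 * sum(w_i^2) for iid x_i; the
  # delete-a-group jackknife estimate is compared on average over repeats
  fr <- generate_frame(1000, total_area_ha = 1e6, n_replicates = 30, seed = 11)
  w <- fr$locations$weight
  sigma <- 0.4
  analytic <- sigma^2 * sum(w^2) / 1e12      # Mt C scale
  set.seed(99)
  vjk <- replicate(30, {
    x <- rnorm(1000, 0.2, sigma)
    replicate_interval(function(wt) weighted_total(x, wt), fr)$sd^2
  })
  expect_lt(abs(mean(vjk) / analytic - 1), 0.2)
})

test_that("weather generator matches configured normals and basic physics", {
  fr <- generate_frame(12, n_regions = 2, seed = 5)
  cl <- default_climate(sort(unique(fr$locations$region_id)))
  w <- generate_weather(fr, 1986:2015, climate = cl, seed = 5)
  expect_true(all(w$precip >= 0))
  expect_equal(length(w$year), 30 * 365)
  ci <- match(fr$locations$region_id, cl$region_id)
  # 30-year temperature means within 0.3 degC of the regional normal
  expect_true(all(abs(colMeans(w$tmean) - cl$tmean_mean[ci]) < 0.3))
  # long-run precipitation close to the configured normal (10% tolerance)
  ann_precip <- colSums(w$precip) / 30
  expect_true(all(abs(ann_precip / cl$map_mm[ci] - 1) < 0.1))
  expect_error(generate_weather(fr, integer(0)), "empty")
})

test_that("zero-amplitude, noise-free climate yields a constant temperature series", {
  fr <- generate_frame(4, n_regions = 1, seed = 2)
  cl <- default_climate("R1")
  cl$tmean_amp <- 0
  cl$temp_sd <- 0
  w <- generate_weather(fr, 2000:2002, climate = cl, seed = 2)
  expect_equal(max(w$tmean) - min(w$tmean), 0, tolerance = 1e-12)
  expect_equal(mean(w$tmean), cl$tmean_mean, tolerance = 1e-9)
})

test_that("truth histories track the adoption curves and forbid pre-1990 cover crops", {
  fr <- generate_frame(2000, seed = 13)
  ad <- default_adoption_trends()
  tr <- generate_truth_histories(fr, ad, seed = 13)
  expect_false(any(tr$cover_crop[tr$year < 1990]))
  w <- fr$locations$weight
  wtot <- sum(w)
  wfrac <- function(flag, yr) {
    r <- tr$year == yr
    sum(w[match(tr$location_id[r][flag[r]], fr$locations$location_id)]) / wtot
  }
  # realized weighted cover-crop adoption within 3 binomial s.e. of target
  target <- ad$cover_crop[ad$year == 2015]
  se <- sqrt(target * (1 - target) / 2000)
  expect_lt(abs(wfrac(tr$cover_crop, 2015) - target), 3 * se)
  # set-aside area non-increasing in expectation over the declining phase
  sa_series <- vapply(1995:2015, function(y) wfrac(tr$set_aside, y), numeric(1))
  expect_lt(unname(coef(lm(sa_series ~ seq_along(sa_series)))[2]), 0)
  # termination is none iff no cover crop
  expect_identical(tr$termination == "none", !tr$cover_crop)
  # set-aside years carry grass cover
  expect_true(all(tr$crop[tr$set_aside] == "grass"))
})

test_that("all-zero adoption yields full tillage with no amendments anywhere", {
  fr <- generate_frame(60, seed = 21)
  ad <- default_adoption_trends()
  ad[, c("cover_crop", "cons_till", "hay_pasture", "manure", "set_aside")] <- 0
  tr <- generate_truth_histories(fr, ad, seed = 21)
  expect_true(all(tr$tillage == "FT"))
  expect_false(any(tr$cover_crop))
  expect_true(all(tr$manure_n == 0))
  expect_false(any(tr$set_aside))
  bad <- ad
  bad$cover_crop[bad$year == 2000] <- 1.2
  expect_error(generate_truth_histories(fr, bad, seed = 1), "\\[0, 1\\]")
})

test_that("donor survey covers every stratum with sane, near-truth N rates", {
  w <- small_world()
  dn <- w$donors
  expect_true(all(dn$fert_n >= 0 & dn$manure_n >= 0))
  cand <- w$truth[w$truth$year %in% 2001:2005 & !w$truth$set_aside, ]
  li <- match(cand$location_id, w$frame$locations$location_id)
  cand$stratum <- paste(
    w$frame$locations$region_id[li],
    ifelse(cand$crop %in% c("hay", "pasture"), "hay_pasture", "annual"),
    texture_class(w$frame$locations$clay_frac[li],
                  w$frame$locations$sand_frac[li]))
  expect_true(all(unique(cand$stratum) %in%
                    paste(dn$region_id, dn$crop_group, dn$texture_class)))
  # donor fert mean within 2 s.e. of the truth mean in the largest stratum
  big <- names(which.max(table(cand$stratum)))
  truth_vals <- cand$fert_n[cand$stratum == big]
  don_vals <- dn$fert_n[paste(dn$region_id, dn$crop_group, dn$texture_class) == big]
  se <- sqrt(var(don_vals) / length(don_vals) + var(truth_vals) / length(truth_vals))
  expect_lt(abs(mean(don_vals) - mean(truth_vals)), 2 * se + 0.15 * mean(truth_vals))
})

test_that("calibration sites encode the configured bias exactly when noise-free", {
  cs <- generate_calibration_sites(n_sites = 10, bias = list(intercept = 0, slope = 1),
                                   re_sd = 0, resid_sd = 0, seed = 9)
  expect_equal(cs$measured_soc, cs$simulated_soc, tolerance = 1e-9)
  cs2 <- generate_calibration_sites(n_sites = 10, bias = list(intercept = 3, slope = 0.8),
                                    re_sd = 0, resid_sd = 0, seed = 9)
  expect_equal(cs2$measured_soc, 3 + 0.8 * cs2$simulated_soc, tolerance = 1e-9)
  expect_error(generate_calibration_sites(n_sites = 2), ">= 3")
})

test_that("site-level intraclass correlation matches the variance ratio at large n", {
  re_sd <- 6; resid_sd <- 3
  cs <- generate_calibration_sites(n_sites = 400, bias = list(intercept = 0, slope = 1),
                                   re_sd = re_sd, resid_sd = resid_sd,
                                   n_treatments = 4, seed = 31)
  # remove the structural signal, then estimate ICC from a one-way layout
  resid <- cs$measured_soc - cs$simulated_soc
  m <- tapply(resid, cs$site_id, mean)
  v_between <- var(m) - resid_sd^2 / 4    # correct for within-site averaging
  icc_hat <- v_between / (v_between + resid_sd^2)
  icc_true <- re_sd^2 / (re_sd^2 + resid_sd^2)
  expect_lt(abs(icc_hat - icc_true), 0.08)
})
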