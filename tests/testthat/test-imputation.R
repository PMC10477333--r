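mk_series <- function(blocks, props) {
  d <- data.frame(block_start = blocks)
  d$NT <- props[, 1]; d$RT <- props[, 2]; d$FT <- props[, 3]
  d
}

test_that("tillage series harmonization maps, renormalizes and gap-fills", {
  blocks <- c(1981, 1986, 1991, 1996, 2001, 2006, 2011)
  # identical overlap: pre-overlap values pass through unchanged
  ctic <- mk_series(blocks[1:5], cbind(c(.1, .12, .15, .2, .25),
                                       c(.1, .1, .12, .15, .15),
                                       c(.8, .78, .73, .65, .6)))
  ceap <- mk_series(blocks[4:7], cbind(c(.2, .25, NA, .3), c(.15, .15, NA, .2),
                                       c(.65, .6, NA, .5)))
  out <- harmonize_tillage_series(ctic, ceap)
  expect_equal(unlist(out[out$block_start == 1981, c("NT", "RT", "FT")]),
               c(NT = .1, RT = .1, FT = .8), tolerance = 1e-9)
  # 2006-2010 gap filled by linear interpolation between neighbours
  expect_equal(out$NT[out$block_start == 2006], (.25 + .3) / 2, tolerance = 1e-9)
  expect_equal(rowSums(out[c("NT", "RT", "FT")]), rep(1, nrow(out)),
               tolerance = 1e-9)

  # constant offset: pre-overlap values shifted then renormalized
  ctic2 <- mk_series(c(1991, 1996, 2001), cbind(c(.2, .3, .4), c(.3, .3, .3),
                                                c(.5, .4, .3)))
  ceap2 <- mk_series(c(1996, 2001), cbind(c(.4, .5), c(.4, .4), c(.5, .4)))
  out2 <- harmonize_tillage_series(ctic2, ceap2)
  shifted <- c(.2 + .1, .3 + .1, .5 + .1)
  expect_equal(unlist(out2[out2$block_start == 1991, c("NT", "RT", "FT")]),
               setNames(shifted / sum(shifted), c("NT", "RT", "FT")),
               tolerance = 1e-9)
  expect_error(harmonize_tillage_series(ctic2[1, ], ceap2), ">= 2 overlap")
})

test_that("maximal-stay coupling attains the LP optimum with exact marginals", {
  # identity when marginals match
  p <- c(0.2, 0.3, 0.5)
  expect_equal(max_stay_transition(p, p), diag(3), ignore_attr = TRUE)
  # worked example: stay mass 0.8, all residual moves FT -> NT
  Tm <- max_stay_transition(c(0.3, 0.3, 0.4), c(0.5, 0.3, 0.2))
  J <- Tm * c(0.3, 0.3, 0.4)
  expect_equal(sum(diag(J)), 0.8, tolerance = 1e-12)
  expect_equal(J["FT", "NT"], 0.2, tolerance = 1e-12)
  # forced transport
  T2 <- max_stay_transition(c(1, 0, 0), c(0, 1, 0))
  expect_equal(T2["NT", "RT"], 1)
  # 200 random pairs: diagonal mass equals sum(min(p, q)) exactly; p T = q
  set.seed(9)
  for (i in 1:200) {
    p <- random_marginal(); q <- random_marginal()
    Tm <- max_stay_transition(p, q)
    expect_equal(sum(diag(Tm) * p), sum(pmin(p, q)), tolerance = 1e-14)
    expect_equal(as.numeric(p %*% Tm), q, tolerance = 1e-12)
    expect_true(all(Tm >= 0))
    expect_equal(unname(rowSums(Tm)), rep(1, 3), tolerance = 1e-12)
  }
  expect_error(max_stay_transition(c(.5, .5, .1), c(1, 0, 0)), "sum to 1")
})

test_that("imputed tillage reproduces the block marginal targets at scale", {
  n <- 10000
  fr <- generate_frame(n, seed = 31)
  marg <- mk_series(soccf:::BLOCK_STARTS,
                    cbind(seq(0.05, 0.35, length.out = 7),
                          seq(0.10, 0.25, length.out = 7),
                          1 - seq(0.05, 0.35, length.out = 7) -
                            seq(0.10, 0.25, length.out = 7)))
  # donors drawn to match the anchor-block target
  anchor <- unlist(marg[marg$block_start == 2001, c("NT", "RT", "FT")])
  set.seed(77)
  donors <- expand.grid(region_id = paste0("R", 1:4),
                        crop_group = "annual",
                        texture_class = c("coarse", "medium", "fine"),
                        rep = 1:60, stringsAsFactors = FALSE)
  donors$donor_id <- seq_len(nrow(donors))
  donors$tillage <- sample(c("NT", "RT", "FT"), nrow(donors), TRUE, prob = anchor)
  donors$cover_crop <- FALSE
  donors$fert_n <- 100; donors$manure_n <- 0
  till <- impute_tillage(fr, donors, marg, seed = 55)
  for (b in soccf:::BLOCK_STARTS) {
    target <- unlist(marg[marg$block_start == b, c("NT", "RT", "FT")])
    got <- table(factor(till$tillage[till$block_start == b],
                        levels = c("NT", "RT", "FT"))) / n
    se <- sqrt(target * (1 - target) / n)
    # 3 binomial s.e. plus the donor-sampling error carried down the chain
    don_se <- sqrt(target * (1 - target) / nrow(donors))
    expect_true(all(abs(as.numeric(got) - target) < 3 * (se + don_se)),
                info = paste("block", b))
  }
})

test_that("constant marginals yield zero tillage switching; full shifts force transport", {
  fr <- generate_frame(400, seed = 8)
  const <- mk_series(soccf:::BLOCK_STARTS,
                     matrix(rep(c(0.3, 0.3, 0.4), each = 7), 7))
  donors <- data.frame(donor_id = 1:90, region_id = rep(paste0("R", 1:4), le = 90),
                       crop_group = "annual",
                       texture_class = rep(c("coarse", "medium", "fine"), le = 90),
                       tillage = rep(c("NT", "RT", "FT"), 30),
                       cover_crop = FALSE, fert_n = 100, manure_n = 0)
  till <- impute_tillage(fr, donors, const, seed = 4)
  switches <- tapply(till$tillage, till$location_id,
                     function(x) sum(head(x, -1) != tail(x, -1)))
  expect_equal(sum(switches), 0)    # identity transitions: no churn at all
  # wholesale FT -> NT shift: every FT location transitions, none reverse
  shift <- mk_series(soccf:::BLOCK_STARTS,
                     rbind(matrix(rep(c(0, 0, 1), each = 5), 5),
                           c(0.5, 0, 0.5), c(1, 0, 0)))
  donors_ft <- transform(donors, tillage = "FT")
  till2 <- impute_tillage(fr, donors_ft, shift, seed = 4)
  last <- till2$tillage[till2$block_start == 2011]
  expect_true(all(last == "NT"))
})

test_that("predictive mean matching assigns nearest-prediction donors with stated ties", {
  fr <- generate_frame(1, seed = 1)
  donors <- data.frame(donor_id = 1:3, region_id = "R1", crop_group = "annual",
                       texture_class = "medium",
                       fert_n = c(500, 800, 1100), manure_n = c(0, 40, 0),
                       tillage = "FT", cover_crop = FALSE)
  pred <- function(d, newdata) {
    if (".response" %in% names(newdata)) c(50, 80, 110) else 78
  }
  out <- impute_n_inputs(fr, donors, predictor_fn = pred, years = 2000)
  expect_equal(out$fert_n, 800)     # donor 2 is nearest (|78-80| = 2)
  expect_equal(out$manure_n, 40)    # the matched donor supplies both N fields
  # equidistant predictions: lowest donor_id wins
  pred_tie <- function(d, newdata) {
    if (".response" %in% names(newdata)) c(70, 86, 110) else 78
  }
  out2 <- impute_n_inputs(fr, donors, predictor_fn = pred_tie, years = 2000)
  expect_equal(out2$fert_n, 500)
  expect_error(impute_n_inputs(fr, donors[0, ], years = 2000), "no donors")
})

test_that("imputed N values never leave the donor support and follow trends", {
  w <- small_world()
  out <- impute_n_inputs(w$frame, w$donors, years = 2000:2001, seed = 3)
  expect_true(all(out$fert_n %in% w$donors$fert_n))
  expect_true(all(out$manure_n %in% w$donors$manure_n))
  trend <- data.frame(region_id = rep(sort(unique(w$frame$locations$region_id)), 2),
                      year = rep(2000:2001, each = 4),
                      mult = rep(c(1, 1.5), each = 4))
  out2 <- impute_n_inputs(w$frame, w$donors, trend_by_region = trend,
                          years = 2000:2001, seed = 3)
  y0 <- out2$fert_n[out2$year == 2000]
  y1 <- out2$fert_n[out2$year == 2001]
  expect_equal(y1, 1.5 * y0, tolerance = 1e-12)
})

test_that("cover-crop imputation ramps linearly from zero in 1990", {
  fr <- generate_frame(4000, seed = 19)
  donors <- data.frame(donor_id = 1:200, region_id = rep(paste0("R", 1:4), 50),
                       crop_group = "annual",
                       texture_class = rep(c("coarse", "medium", "fine"), le = 200),
                       tillage = "FT", fert_n = 100, manure_n = 0,
                       cover_crop = rep(c(TRUE, FALSE), c(80, 120)))  # 40% anchor
  cc <- impute_cover_crops(fr, donors, seed = 23)
  frac <- function(y) mean(cc$cover_crop[cc$year == y])
  expect_equal(frac(1990), 0)       # exactly zero adoption in 1990
  expect_equal(frac(1985), 0)
  anchor_level <- frac(2003)
  se <- sqrt(anchor_level * (1 - anchor_level) / 4000)
  # 1995 adoption is half the 2000 level (the anchor level), within 3 s.e.
  expect_lt(abs(frac(1995) - anchor_level / 2), 3 * se)
  expect_lt(abs(frac(2000) - anchor_level), 3 * se)
  # termination set exactly on cover-cropped years
  expect_identical(cc$termination == "none", !cc$cover_crop)
  cc_t <- impute_cover_crops(fr, donors, termination = "tillage", seed = 23)
  expect_true(all(cc_t$termination[cc_t$cover_crop] == "tillage"))
})

test_that("post-anchor census targets steer cover-crop adoption", {
  fr <- generate_frame(3000, seed = 29)
  donors <- data.frame(donor_id = 1:100, region_id = rep(paste0("R", 1:4), 25),
                       crop_group = "annual",
                       texture_class = rep(c("coarse", "medium", "fine"), le = 100),
                       tillage = "FT", fert_n = 100, manure_n = 0,
                       cover_crop = rep(c(TRUE, FALSE), c(30, 70)))
  w <- fr$locations$weight
  targets <- data.frame(block_start = c(2006, 2011), fraction = c(0.5, 0.1))
  cc <- impute_cover_crops(fr, donors, census_targets = targets, seed = 2)
  lv <- function(y) {
    r <- cc$year == y
    sum(w[cc$cover_crop[r]]) / sum(w)
  }
  expect_lt(abs(lv(2008) - 0.5), 0.05)
  expect_lt(abs(lv(2013) - 0.1), 0.05)
  # target equal to the realized anchor level leaves adoption unchanged
  anchor_lv <- lv(2003)
  cc2 <- impute_cover_crops(fr, donors,
                            census_targets = data.frame(block_start = 2006,
                                                        fraction = anchor_lv),
                            seed = 2)
  expect_identical(cc2$cover_crop[cc2$year == 2008], cc2$cover_crop[cc2$year == 2003])
  expect_error(impute_cover_crops(fr, donors,
                                  census_targets = data.frame(block_start = 2006,
                                                              fraction = 1.4)),
               "\\[0, 1\\]")
})

test_that("imputation sets are complete, distinct and statistically consistent", {
  w <- small_world()
  imps <- w$imputations
  expect_length(imps, 2)
  h1 <- imps[[1]]$histories; h2 <- imps[[2]]$histories
  expect_false(anyNA(h1$tillage))
  expect_false(anyNA(h1$fert_n))
  expect_false(anyNA(h1$cover_crop))
  expect_identical(nrow(h1), nrow(w$truth))
  # independently seeded sets differ in at least one cell
  expect_true(any(h1$tillage != h2$tillage) || any(h1$cover_crop != h2$cover_crop))
  # irrigation is copied through from the survey, not imputed
  expect_identical(h1$irrigated, w$truth$irrigated)
  # weighted adoption statistics agree across sets within sampling error
  wgt <- w$frame$locations$weight
  consfrac <- function(h) {
    r <- h$year == 2010
    idx <- match(h$location_id[r], w$frame$locations$location_id)
    sum(wgt[idx] * (h$tillage[r] %in% c("NT", "RT"))) / sum(wgt)
  }
  p <- mean(c(consfrac(h1), consfrac(h2)))
  expect_lt(abs(consfrac(h1) - consfrac(h2)),
            6 * sqrt(p * (1 - p) / nrow(w$frame$locations)))
  # a failing sub-imputation names its stage
  bad_trends <- w$trends
  bad_trends$tillage_marginals <- bad_trends$tillage_marginals[1:2, ]
  expect_error(
    suppressWarnings(build_imputations(w$frame, w$truth, w$donors, bad_trends,
                                       M = 1, seed = 1)),
    "stage 'tillage'")
})
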