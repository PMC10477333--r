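# Management-history imputation: harmonized tillage trend series, maximal-stay
# Markov-chain tillage sequences constrained to 5-year block marginals,
# predict-then-match (predictive mean matching) nitrogen inputs, and hot-deck
# cover crops with a linear adoption ramp back to zero in 1990. Six
# independently seeded imputation sets represent management-input uncertainty.

# 5-year blocks follow the survey convention: 2001-2005 is the hot-deck anchor
# block, so block starts are 1981, 1986, ..., 2011 and the years 1979-1980 are
# folded into the first block.
BLOCK_STARTS <- seq(1981L, 2011L, by = 5L)
ANCHOR_BLOCK <- 2001L

#' Map calendar years to 5-year imputation blocks
#' @param year integer years
#' @return the block start year for each input year
#' @export
block_start <- function(year) {
  BLOCK_STARTS[pmax(findInterval(year, BLOCK_STARTS), 1L)]
}

#' Harmonize two tillage trend series and gap-fill missing blocks
#'
#' Fits, per tillage class, an ordinary least squares regression of the
#' reference survey series on the longer historical series over their overlap
#' blocks; maps pre-overlap historical values through the fit (clamped to
#' `[0, 1]` and renormalized across classes); and fills any remaining missing
#' blocks by linear interpolation between neighbours.
#'
#' @param ctic_series,ceap_series data.frames `(block_start, NT, RT, FT)`;
#'   `NA` rows mark missing blocks. `ceap_series` is the reference whose
#'   scale the output adopts.
#' @param overlap_blocks block starts present in both series used to fit the
#'   regression (default: all blocks with data in both)
#' @return data.frame `(block_start, NT, RT, FT)` of class `marginal_series`
#'   covering the union of blocks, rows summing to 1
#' @export
harmonize_tillage_series <- function(ctic_series, ceap_series,
                                     overlap_blocks = NULL) {
  cls <- TILLAGE_LEVELS
  has <- function(d) d$block_start[stats::complete.cases(d[cls])]
  if (is.null(overlap_blocks))
    overlap_blocks <- intersect(has(ctic_series), has(ceap_series))
  check_that(length(overlap_blocks) >= 2,
             "need >= 2 overlap blocks to fit the harmonization regression")
  blocks <- sort(union(ctic_series$block_start, ceap_series$block_start))
  out <- data.frame(block_start = blocks)
  for (k in cls) out[[k]] <- NA_real_

  io_ct <- match(overlap_blocks, ctic_series$block_start)
  io_ce <- match(overlap_blocks, ceap_series$block_start)
  fits <- lapply(cls, function(k) {
    x <- ctic_series[[k]][io_ct]; y <- ceap_series[[k]][io_ce]
    if (stats::sd(x) < 1e-12) c(intercept = mean(y - x), slope = 1)
    else {
      co <- stats::coef(stats::lm(y ~ x))
      c(intercept = co[[1]], slope = co[[2]])
    }
  })
  names(fits) <- cls

  for (b in blocks) {
    i <- match(b, blocks)
    ice <- match(b, ceap_series$block_start)
    ict <- match(b, ctic_series$block_start)
    if (!is.na(ice) && !anyNA(unlist(ceap_series[ice, cls]))) {
      out[i, cls] <- ceap_series[ice, cls]
    } else if (b < min(overlap_blocks) && !is.na(ict) &&
               !anyNA(unlist(ctic_series[ict, cls]))) {
      v <- vapply(cls, function(k)
        fits[[k]]["intercept"] + fits[[k]]["slope"] * ctic_series[[k]][ict],
        numeric(1))
      v <- pmin(pmax(v, 0), 1)
      out[i, cls] <- v / sum(v)
    }
  }
  # linear interpolation for remaining gaps, then renormalize
  for (k in cls) {
    v <- out[[k]]
    if (anyNA(v)) {
      ok <- !is.na(v)
      check_that(sum(ok) >= 2, "too few known blocks to interpolate")
      out[[k]] <- stats::approx(blocks[ok], v[ok], xout = blocks, rule = 2)$y
    }
  }
  s <- rowSums(out[cls])
  out[cls] <- out[cls] / s
  class(out) <- c("marginal_series", "data.frame")
  out
}

#' Maximal-stay transition matrix between two marginal distributions
#'
#' Builds the transition matrix of an inhomogeneous Markov chain over tillage
#' classes that changes state as little as possible: the joint mass places
#' `min(p_i, q_i)` on each diagonal cell (the maximum achievable stay mass),
#' and distributes the residual supply/demand by the northwest-corner rule
#' over the fixed class order NT < RT < FT, making the off-diagonal pattern
#' deterministic. Rows with `p_i = 0` are set to `q`. The result satisfies
#' `p %*% T = q` exactly.
#'
#' @param p,q numeric length-3 start/end marginals over `(NT, RT, FT)`, each
#'   summing to 1 (tolerance 1e-6)
#' @return 3x3 transition matrix with `dimnames` `(NT, RT, FT)`
#' @export
max_stay_transition <- function(p, q) {
  check_that(length(p) == 3 && length(q) == 3, "p and q must have length 3")
  check_that(abs(sum(p) - 1) <= 1e-6 && abs(sum(q) - 1) <= 1e-6,
             "marginals must sum to 1 (tolerance 1e-6)")
  check_that(all(p >= 0) && all(q >= 0), "marginals must be non-negative")
  p <- p / sum(p); q <- q / sum(q)
  J <- diag(pmin(p, q))
  supply <- p - diag(J)
  demand <- q - diag(J)
  # northwest-corner rule on the residual mass, fixed order NT < RT < FT
  i <- 1L; j <- 1L
  while (i <= 3L && j <= 3L) {
    if (supply[i] <= 1e-15) { i <- i + 1L; next }
    if (demand[j] <= 1e-15) { j <- j + 1L; next }
    m <- min(supply[i], demand[j])
    J[i, j] <- J[i, j] + m
    supply[i] <- supply[i] - m
    demand[j] <- demand[j] - m
  }
  Tm <- J / ifelse(p > 0, p, 1)
  for (i in which(p == 0)) Tm[i, ] <- q
  dimnames(Tm) <- list(TILLAGE_LEVELS, TILLAGE_LEVELS)
  Tm
}

# hot-deck donor pool lookup with stratum fallback: exact stratum, then
# region, then all donors
hotdeck_pool <- function(donors, region, crop_group, texture) {
  pool <- which(donors$region_id == region & donors$crop_group == crop_group &
                  donors$texture_class == texture)
  if (!length(pool)) pool <- which(donors$region_id == region)
  if (!length(pool)) pool <- seq_len(nrow(donors))
  pool
}

#' Impute per-block tillage sequences for the survey frame
#'
#' The anchor block (2001-2005) is hot-decked within region x crop-group x
#' soil-texture strata from the donor survey (falling back to region-level
#' donors for empty strata, with a warning); earlier and later blocks are
#' sampled location-wise through chained [max_stay_transition()] matrices so
#' that block marginals track the target series while tillage changes as
#' rarely as possible at each location.
#'
#' @param frame a `survey_frame`
#' @param donors a `donor_survey`
#' @param marginal_series data.frame `(block_start, NT, RT, FT)` covering all
#'   blocks 1981-2011
#' @param crop_group per-location crop group used for stratification
#'   (default `"annual"`)
#' @param seed integer seed
#' @return data.frame `location_id`, `block_start`, `tillage`
#' @export
impute_tillage <- function(frame, donors, marginal_series,
                           crop_group = NULL, seed = 1) {
  loc <- frame$locations
  n <- nrow(loc)
  if (is.null(crop_group)) crop_group <- rep("annual", n)
  check_that(all(BLOCK_STARTS %in% marginal_series$block_start),
             "marginal series must cover all blocks")
  marg <- as.matrix(marginal_series[match(BLOCK_STARTS, marginal_series$block_start),
                                    TILLAGE_LEVELS])
  set.seed(substream_seed(seed, "impute_tillage"))

  tex <- texture_class(loc$clay_frac, loc$sand_frac)
  fellback <- FALSE
  anchor <- character(n)
  for (i in seq_len(n)) {
    exact <- which(donors$region_id == loc$region_id[i] &
                     donors$crop_group == crop_group[i] &
                     donors$texture_class == tex[i])
    if (!length(exact)) fellback <- TRUE
    pool <- if (length(exact)) exact else
      hotdeck_pool(donors, loc$region_id[i], crop_group[i], tex[i])
    anchor[i] <- donors$tillage[pool[sample.int(length(pool), 1)]]
  }
  if (fellback)
    warning("empty anchor stratum for some locations; fell back to region-level donors")

  a <- match(ANCHOR_BLOCK, BLOCK_STARTS)
  nb <- length(BLOCK_STARTS)
  till <- matrix("", n, nb)
  till[, a] <- anchor
  chain <- function(from_idx, to_idx) {
    Tm <- max_stay_transition(marg[from_idx, ], marg[to_idx, ])
    cur <- till[, from_idx]
    nxt <- character(n)
    for (s in TILLAGE_LEVELS) {
      rows <- which(cur == s)
      if (length(rows))
        nxt[rows] <- sample(TILLAGE_LEVELS, length(rows), replace = TRUE,
                            prob = Tm[s, ])
    }
    nxt
  }
  for (b in seq(a - 1, 1)) till[, b] <- chain(b + 1, b)   # backward in time
  if (a < nb) for (b in seq(a + 1, nb)) till[, b] <- chain(b - 1, b)

  data.frame(location_id = rep(loc$location_id, nb),
             block_start = rep(BLOCK_STARTS, each = n),
             tillage = as.vector(till))
}

#' Impute nitrogen inputs by predict-then-match
#'
#' Fits a predictor of N rates on the donor survey (default: linear
#' regression on stratum covariates), predicts a value for every donor and
#' recipient, and assigns each recipient the observed value of the donor
#' whose own prediction is nearest (predictive mean matching; ties break to
#' the lowest `donor_id`). Synthetic fertilizer and manure N are matched
#' separately, then regional year multipliers are applied.
#'
#' @param frame a `survey_frame`
#' @param donors a `donor_survey`
#' @param trend_by_region optional data.frame `(region_id, year, mult)` of
#'   regional trend multipliers (default: 1 everywhere)
#' @param predictor_fn optional function `(donors, newdata) -> predictions`
#'   replacing the default linear-regression predictor; it receives the donor
#'   table (with the response in column `.response`) and the frame to score
#' @param crop_group per-location crop group (default `"annual"`)
#' @param years years to expand to (default 1979:2015)
#' @param seed integer seed
#' @return data.frame `location_id`, `year`, `fert_n`, `manure_n`
#' @export
impute_n_inputs <- function(frame, donors, trend_by_region = NULL,
                            predictor_fn = NULL, crop_group = NULL,
                            years = 1979:2015, seed = 1) {
  check_that(nrow(donors) > 0, "no donors in scope")
  loc <- frame$locations
  n <- nrow(loc)
  if (is.null(crop_group)) crop_group <- rep("annual", n)
  set.seed(substream_seed(seed, "impute_n"))
  recip <- data.frame(region_id = loc$region_id, crop_group = crop_group,
                      texture_class = texture_class(loc$clay_frac, loc$sand_frac),
                      clay_frac = loc$clay_frac)
  donors <- donors[order(donors$donor_id), ]  # tie-break: lowest donor_id wins

  d <- donors
  d$.response <- donors$fert_n
  if (is.null(predictor_fn)) {
    # drop predictors that are constant in the donor pool
    terms <- c("region_id", "crop_group", "texture_class", "clay_frac")
    terms <- terms[vapply(terms, function(k)
      !is.null(d[[k]]) && length(unique(d[[k]])) > 1, logical(1))]
    f <- stats::as.formula(paste(".response ~",
                                 if (length(terms)) paste(terms, collapse = " + ")
                                 else "1"))
    fit <- stats::lm(f, data = d)
    pd <- unname(stats::predict(fit, newdata = d))
    pr <- unname(stats::predict(fit, newdata = recip))
  } else {
    pd <- predictor_fn(d, d)
    pr <- predictor_fn(d, recip)
  }
  # predictive mean matching: nearest donor prediction wins; the matched
  # donor record supplies both N inputs so their joint structure is preserved
  idx <- vapply(pr, function(x) which.min(abs(pd - x)), integer(1))
  fert_base <- donors$fert_n[idx]
  manure_base <- donors$manure_n[idx]

  out <- data.frame(location_id = rep(loc$location_id, length(years)),
                    year = rep(years, each = n),
                    fert_n = rep(fert_base, length(years)),
                    manure_n = rep(manure_base, length(years)))
  if (!is.null(trend_by_region)) {
    key <- paste(rep(loc$region_id, length(years)), out$year)
    mult <- trend_by_region$mult[match(key, paste(trend_by_region$region_id,
                                                  trend_by_region$year))]
    mult[is.na(mult)] <- 1
    out$fert_n <- out$fert_n * mult
    out$manure_n <- out$manure_n * mult
  }
  out
}

#' Impute cover crops with a hot-deck anchor and linear adoption ramp
#'
#' The anchor block 2001-2005 is hot-decked from donor cover-crop responses
#' within strata. Backwards in time, adoption declines linearly to zero in
#' 1990: a location cover-cropped at the anchor is cover-cropped in year
#' `y` of 1991-2000 with probability `(y - 1990) / 10` (one persistent
#' adoption year per location), and never before 1991. Blocks after 2005
#' randomly add or remove cover crops to match the census target fractions.
#'
#' @param frame a `survey_frame`
#' @param donors a `donor_survey`
#' @param census_targets data.frame `(block_start, fraction)` of national
#'   adoption targets for post-2005 blocks (fractions in `[0, 1]`)
#' @param crop_group per-location crop group (default `"annual"`)
#' @param termination termination practice for cover-cropped years
#'   (`"herbicide"` or `"tillage"`)
#' @param years years to expand to (default 1979:2015)
#' @param seed integer seed
#' @return data.frame `location_id`, `year`, `cover_crop`, `termination`
#' @export
impute_cover_crops <- function(frame, donors, census_targets = NULL,
                               crop_group = NULL, termination = "herbicide",
                               years = 1979:2015, seed = 1) {
  check_that(termination %in% c("herbicide", "tillage"), "unknown termination")
  if (!is.null(census_targets))
    check_that(all(census_targets$fraction >= 0 & census_targets$fraction <= 1),
               "census target fractions must lie in [0, 1]")
  loc <- frame$locations
  n <- nrow(loc)
  if (is.null(crop_group)) crop_group <- rep("annual", n)
  set.seed(substream_seed(seed, "impute_cc"))

  tex <- texture_class(loc$clay_frac, loc$sand_frac)
  anchor <- logical(n)
  for (i in seq_len(n)) {
    pool <- hotdeck_pool(donors, loc$region_id[i], crop_group[i], tex[i])
    anchor[i] <- donors$cover_crop[pool[sample.int(length(pool), 1)]]
  }
  u_ramp <- stats::runif(n)   # persistent adoption-year uniform per location

  w <- loc$weight
  state <- matrix(FALSE, n, length(years))
  colnames(state) <- years
  for (k in seq_along(years)) {
    y <- years[k]
    if (y <= 1990) next
    if (y <= 2000) state[, k] <- anchor & (u_ramp < (y - 1990) / 10)
    else if (y <= 2005) state[, k] <- anchor
  }
  # post-2005 blocks: persistently add/remove to match census targets
  post <- BLOCK_STARTS[BLOCK_STARTS > ANCHOR_BLOCK]
  cur <- anchor
  for (b in post) {
    target <- if (!is.null(census_targets) && b %in% census_targets$block_start)
      census_targets$fraction[match(b, census_targets$block_start)] else NA
    if (!is.na(target)) {
      level <- sum(w[cur]) / sum(w)
      if (target > level) {
        flip <- !cur & (stats::runif(n) < (target - level) / max(1 - level, 1e-12))
        cur <- cur | flip
      } else if (target < level) {
        drop_p <- (level - target) / max(level, 1e-12)
        cur <- cur & !(stats::runif(n) < drop_p)
      }
    }
    yrs <- years >= b & years <= b + 4
    state[, yrs] <- matrix(cur, n, sum(yrs))
  }
  cc <- as.vector(state)
  data.frame(location_id = rep(loc$location_id, length(years)),
             year = rep(years, each = n),
             cover_crop = cc,
             termination = ifelse(cc, termination, "none"))
}

#' Build M complete management imputation sets
#'
#' Combines the observed survey components (crop sequence, set-aside and
#' irrigation, taken as known from the survey) with independently seeded
#' imputations of tillage, N inputs and cover crops. The default of six sets
#' carries management-input uncertainty into the Monte Carlo analysis.
#'
#' @param frame a `survey_frame`
#' @param truth a `management_history` providing the observed components
#' @param donors a `donor_survey`
#' @param trends list with `tillage_marginals` (block marginal series),
#'   optional `n_trend` (regional year multipliers) and optional `cc_targets`
#'   (census block targets)
#' @param M number of imputation sets (default 6)
#' @param termination cover-crop termination variant applied to every set
#' @param seed integer master seed
#' @return list of `M` imputation sets, each a list
#'   `(imputation_id, histories)` with `histories` a `management_history`
#' @export
build_imputations <- function(frame, truth, donors, trends, M = 6,
                              termination = "herbicide", seed = 1) {
  check_that(M >= 1, "M must be >= 1")
  loc <- frame$locations
  years <- sort(unique(truth$year))
  n <- nrow(loc)

  # per-location crop group over the anchor block, from the observed sequence
  anchor_rows <- truth$year %in% ANCHOR_BLOCK:(ANCHOR_BLOCK + 4)
  hp <- tapply(truth$crop[anchor_rows] %in% HAY_PASTURE_CROPS,
               truth$location_id[anchor_rows], mean)
  crop_group <- ifelse(hp[match(loc$location_id, as.integer(names(hp)))] > 0.5,
                       "hay_pasture", "annual")
  crop_group[is.na(crop_group)] <- "annual"

  obs <- truth[order(truth$location_id, truth$year),
               c("location_id", "year", "crop", "irrigated", "set_aside")]

  lapply(seq_len(M), function(m) {
    sub <- substream_seed(seed, paste0("imputation:", m))
    run <- function(stage, expr) {
      tryCatch(expr, error = function(e)
        stop("imputation ", m, " failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE))
    }
    tl <- run("tillage", impute_tillage(frame, donors, trends$tillage_marginals,
                                        crop_group = crop_group, seed = sub))
    nn <- run("n_inputs", impute_n_inputs(frame, donors, trends$n_trend,
                                          crop_group = crop_group,
                                          years = years, seed = sub))
    cc <- run("cover_crops", impute_cover_crops(frame, donors, trends$cc_targets,
                                                crop_group = crop_group,
                                                termination = termination,
                                                years = years, seed = sub))
    h <- obs
    tb <- block_start(h$year)
    h$tillage <- tl$tillage[match(paste(h$location_id, tb),
                                  paste(tl$location_id, tl$block_start))]
    nk <- match(paste(h$location_id, h$year), paste(nn$location_id, nn$year))
    h$fert_n <- nn$fert_n[nk]
    h$manure_n <- nn$manure_n[nk]
    ck <- match(paste(h$location_id, h$year), paste(cc$location_id, cc$year))
    h$cover_crop <- cc$cover_crop[ck]
    h$termination <- cc$termination[ck]
    # observed set-aside years override imputed practices
    h$fert_n[h$set_aside] <- 0
    h$manure_n[h$set_aside] <- 0
    h$cover_crop[h$set_aside] <- FALSE
    h$termination[h$set_aside] <- "none"
    h <- h[, c("location_id", "year", "crop", "tillage", "fert_n", "manure_n",
               "cover_crop", "termination", "irrigated", "set_aside")]
    class(h) <- c("management_history", "data.frame")
    list(imputation_id = m, histories = h)
  })
}
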