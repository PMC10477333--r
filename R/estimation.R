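# National estimation: survey-weighted totals, delete-a-group jackknife
# variance, practice areas and per-area rates, and the three-source Monte
# Carlo uncertainty propagation (imputation x bias-model parameters x
# replicate weights).

#' Survey-weighted national total of per-area effects
#'
#' @param effects per-location effects (t C/ha/yr)
#' @param weights expansion weights (ha), aligned with `effects`
#' @return national total in Mt C/yr
#' @export
weighted_total <- function(effects, weights) {
  check_that(length(effects) == length(weights), "effects and weights must align")
  check_that(all(weights >= 0), "negative weight")
  sum(effects * weights) / 1e6
}

#' Jackknife estimate, standard deviation and confidence interval
#'
#' Evaluates an estimator under the full-sample weights and under each
#' delete-a-group jackknife replicate-weight vector; the variance is
#' `(G-1)/G * sum((theta_g - theta)^2)` and the interval is the normal
#' approximation. Replicates on which the estimator fails are dropped (with a
#' warning) and G adjusted.
#'
#' @param estimator_fn function `weights -> scalar`
#' @param frame a `survey_frame` carrying the replicate weights
#' @param level confidence level (default 0.95)
#' @return list `(estimate, sd, ci)` with `ci` a length-2 vector
#' @export
replicate_interval <- function(estimator_fn, frame, level = 0.95) {
  rw <- frame$replicate_weights
  check_that(ncol(rw) >= 2, "need >= 2 replicate-weight vectors")
  est <- estimator_fn(frame$locations$weight)
  reps <- numeric(0)
  failed <- 0
  for (g in seq_len(ncol(rw))) {
    v <- tryCatch(estimator_fn(rw[, g]), error = function(e) NA_real_)
    if (is.na(v)) failed <- failed + 1 else reps <- c(reps, v)
  }
  if (failed > 0)
    warning(failed, " replicate(s) dropped after estimator failure; G adjusted")
  G <- length(reps)
  v <- (G - 1) / G * sum((reps - est)^2)
  s <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, sd = s, ci = c(est - z * s, est + z * s))
}

#' Practice area and per-area sequestration rate
#'
#' The practice area in a year is the summed weight of locations exposed to
#' the practice that year; the rate is the national effect divided by that
#' area. A zero area leaves the rate undefined (flagged, not zero).
#'
#' @param runs a `scenario_runs` (carries exposure masks and effects)
#' @param frame a `survey_frame`
#' @param scenario an effect label (e.g. `"conservation_tillage"`,
#'   `"manure"`, `"set_aside"`, `"cover_crop_herbicide"`)
#' @param year assessment year
#' @return list `(area_mha, rate_t_c_ha, total_mt_c, undefined)`
#' @export
practice_area_and_rate <- function(runs, frame, scenario, year) {
  check_that(scenario %in% names(runs$exposure), paste("unknown scenario:", scenario))
  yi <- match(year, runs$years)
  check_that(!is.na(yi), "year not simulated")
  eff <- effect_matrices(runs, years = year)[[scenario]][1, ]
  w <- frame$locations$weight
  w[is.na(eff)] <- 0
  eff[is.na(eff)] <- 0
  exposed <- runs$exposure[[scenario]][, yi]
  area <- sum(w[exposed]) / 1e6                 # Mha
  total <- weighted_total(eff, w)               # Mt C
  if (area <= 0)
    return(list(area_mha = 0, rate_t_c_ha = NA_real_, total_mt_c = total,
                undefined = TRUE))
  list(area_mha = area, rate_t_c_ha = total / area, total_mt_c = total,
       undefined = FALSE)
}

#' Monte Carlo propagation of the three uncertainty sources
#'
#' Each iteration draws (i) one of the M cached imputation runs, (ii) a
#' bias-model fixed-effect vector from `Normal(beta, beta_cov)` plus a
#' residual prediction-error surface added to the annual stocks (shared
#' across the runs of a location, so it cancels in practice effects but
#' propagates into the total stock-change series), and (iii) one jackknife
#' replicate-weight vector, then recomputes all national series. Simulations
#' are never re-run inside the loop; cached stocks are resampled.
#'
#' @param runs_by_imputation list of `scenario_runs`, one per imputation set
#' @param bias_model a `bias_model`
#' @param frame a `survey_frame`
#' @param n_iter number of iterations (>= 2; default 1000)
#' @param years assessment years
#' @param use_replicates draw replicate-weight vectors? (`FALSE` uses the
#'   full-sample weights in every iteration)
#' @param include_prediction_error add the residual prediction-error draw?
#' @param seed integer seed
#' @return data.frame of class `mc_estimate`: `scenario`, `year`, `mean`,
#'   `sd`, `ci_low`, `ci_high` (2.5/97.5 percentiles), `n_iter`
#' @export
run_monte_carlo <- function(runs_by_imputation, bias_model, frame,
                            n_iter = 1000, years = 1995:2015,
                            use_replicates = TRUE,
                            include_prediction_error = TRUE, seed = 1) {
  check_that(n_iter >= 2, "n_iter must be >= 2")
  M <- length(runs_by_imputation)
  check_that(M >= 1, "need at least one imputation run set")
  set.seed(substream_seed(seed, "monte_carlo"))

  eff_by_m <- lapply(runs_by_imputation, effect_matrices, years = years)
  sa_mask_by_m <- lapply(runs_by_imputation, function(r) {
    yi <- match(years, r$years)
    t(r$exposure$set_aside[, yi, drop = FALSE])
  })
  scen <- names(eff_by_m[[1]])
  ny <- length(years)
  n <- nrow(frame$locations)
  w_full <- frame$locations$weight
  rw <- frame$replicate_weights
  slope_idx <- match("simulated_soc", names(bias_model$beta))
  sd_resid <- if (include_prediction_error) bias_model$sigma_resid else 0
  no_beta_var <- all(bias_model$beta_cov == 0)

  draws <- array(NA_real_, c(n_iter, length(scen), ny),
                 dimnames = list(NULL, scen, years))
  for (it in seq_len(n_iter)) {
    m <- if (M == 1) 1L else sample.int(M, 1)
    beta <- if (no_beta_var) bias_model$beta else
      drop(draw_bias_params(bias_model, 1))
    b1 <- beta[slope_idx]
    w <- if (use_replicates) rw[, sample.int(ncol(rw), 1)] else w_full
    eff <- eff_by_m[[m]]
    bad <- is.na(eff$total[1, ])
    if (any(bad)) w[bad] <- 0
    # residual prediction error is drawn independently per model run
    # (management-variant-specific model error), at the stock level, then
    # differenced into stock changes
    dE <- NULL
    if (sd_resid > 0) {
      dE <- lapply(RUN_NAMES, function(r)
        apply(matrix(stats::rnorm((ny + 1) * n, 0, sd_resid), ny + 1, n), 2, diff))
      names(dE) <- RUN_NAMES
    }
    for (s in scen) {
      e <- b1 * eff[[s]]
      if (!is.null(dE)) {
        if (s == "total") e <- e + dE$baseline_herbicide
        else if (s == "set_aside")
          e <- e + dE$baseline_herbicide * sa_mask_by_m[[m]]
        else {
          pair <- EFFECT_RUNS[[s]]
          e <- e + dE[[pair[1]]] - dE[[pair[2]]]
        }
      }
      e[is.na(e)] <- 0
      draws[it, s, ] <- as.numeric(e %*% w) / 1e6
    }
  }
  out <- expand.grid(year = years, scenario = scen, stringsAsFactors = FALSE)
  out <- out[, c("scenario", "year")]
  stat <- function(f) mapply(function(s, y) f(draws[, s, as.character(y)]),
                             out$scenario, out$year)
  out$mean <- stat(mean)
  out$sd <- stat(stats::sd)
  out$ci_low <- stat(function(x) stats::quantile(x, 0.025, names = FALSE))
  out$ci_high <- stat(function(x) stats::quantile(x, 0.975, names = FALSE))
  out$n_iter <- n_iter
  rownames(out) <- NULL
  class(out) <- c("mc_estimate", "data.frame")
  out
}

#' Assemble the national series with areas, rates and uncertainty
#'
#' Builds the deterministic national stock-change series per scenario
#' (imputation-averaged, point bias adjustment, full-sample weights) with
#' practice areas (Mha), per-area rates (t C/ha/yr) and CO2-equivalents, an
#' explicit `other_management` residual series (total minus the sum of
#' attributed practice effects, herbicide cover-crop variant; practice
#' effects are not forced to add up to the total because practices
#' interact), and the Monte Carlo uncertainty table.
#'
#' @param runs_by_imputation list of `scenario_runs`, one per imputation
#' @param frame a `survey_frame`
#' @param bias_model a `bias_model`
#' @param n_iter Monte Carlo iterations
#' @param years assessment years (default 1995:2015)
#' @param seed integer seed
#' @param ... further arguments passed to [run_monte_carlo()]
#' @return list of class `national_summary`: `national` (data.frame
#'   `scenario`, `year`, `total_mt_c`, `area_mha`, `rate_t_c_ha_yr`,
#'   `co2e_mt`) and `mc` (the `mc_estimate` table)
#' @export
summarize_national <- function(runs_by_imputation, frame, bias_model,
                               n_iter = 1000, years = 1995:2015, seed = 1, ...) {
  M <- length(runs_by_imputation)
  b1 <- bias_model$beta[[match("simulated_soc", names(bias_model$beta))]]
  w0 <- frame$locations$weight
  eff_by_m <- lapply(runs_by_imputation, effect_matrices, years = years)
  scen <- names(eff_by_m[[1]])

  totals <- sapply(scen, function(s) {
    rowMeans(sapply(eff_by_m, function(e) {
      x <- e[[s]]
      w <- w0; w[is.na(x[1, ])] <- 0; x[is.na(x)] <- 0
      as.numeric(x %*% w) / 1e6 * b1
    }))
  })                                       # ny x nscen
  areas <- sapply(scen, function(s) {
    if (s == "total") return(rep(sum(w0) / 1e6, length(years)))
    rowMeans(sapply(runs_by_imputation, function(r) {
      yi <- match(years, r$years)
      as.numeric(t(r$exposure[[s]][, yi, drop = FALSE]) %*% w0) / 1e6
    }))
  })

  practice <- setdiff(scen, c("total", "cover_crop_tillage"))
  other <- totals[, "total"] - rowSums(totals[, practice, drop = FALSE])

  nat <- do.call(rbind, lapply(c(scen, "other_management"), function(s) {
    tot <- if (s == "other_management") other else totals[, s]
    ar <- if (s == "other_management") rep(NA_real_, length(years)) else areas[, s]
    data.frame(scenario = s, year = years, total_mt_c = tot,
               area_mha = ar,
               rate_t_c_ha_yr = ifelse(!is.na(ar) & ar > 0, tot / ar, NA_real_),
               co2e_mt = c_to_co2e(tot))
  }))
  rownames(nat) <- NULL
  mc <- run_monte_carlo(runs_by_imputation, bias_model, frame,
                        n_iter = n_iter, years = years, seed = seed, ...)
  structure(list(national = nat, mc = mc), class = "national_summary")
}

#' @export
print.national_summary <- function(x, ...) {
  tot <- x$national[x$national$scenario == "total", ]
  cat("national_summary:", min(tot$year), "-", max(tot$year), "\n")
  cat(sprintf("  total stock change: %.1f Mt C/yr (%d) to %.1f Mt C/yr (%d)\n",
              tot$total_mt_c[1], tot$year[1],
              tot$total_mt_c[nrow(tot)], tot$year[nrow(tot)]))
  invisible(x)
}
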