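# Calibration chain: Sobol sensitivity screening to select influential
# parameters, sampling importance resampling (SIR) to approximate their
# posterior, and the linear mixed-effect bias model that maps simulated SOC
# onto measured stocks for structural-uncertainty propagation.

#' Sobol total-order sensitivity indices (Saltelli sampling, Jansen estimator)
#'
#' Screens model parameters by their total-order contribution to output
#' variance under independent uniform priors on the given ranges. Parameters
#' with a total index above the threshold are flagged for calibration
#' (default threshold 0.025, i.e. total sensitivity > 2.5%).
#'
#' @param model_fn function taking a named numeric parameter vector (or a
#'   matrix with named columns, one row per evaluation) and returning a
#'   scalar (or vector) output
#' @param param_ranges named list of `c(min, max)` ranges
#' @param n_base base sample size N (>= 64); the scheme evaluates the model
#'   `N * (k + 2)` times for k parameters
#' @param threshold selection threshold on the total index
#' @param seed integer seed
#' @return data.frame of class `sensitivity_result`: `param_name`,
#'   `total_index`, `selected`
#' @export
sobol_total_indices <- function(model_fn, param_ranges, n_base = 1024,
                                threshold = 0.025, seed = 1) {
  check_that(n_base >= 64, "n_base must be >= 64")
  rng <- do.call(rbind, param_ranges)
  check_that(all(is.finite(rng)), "parameter ranges must be finite")
  k <- length(param_ranges)
  nm <- names(param_ranges)
  set.seed(substream_seed(seed, "sobol"))

  scale_mat <- function(u) {
    m <- sweep(u, 2, rng[, 2] - rng[, 1], `*`)
    m <- sweep(m, 2, rng[, 1], `+`)
    colnames(m) <- nm
    m
  }
  A <- scale_mat(matrix(stats::runif(n_base * k), n_base, k))
  B <- scale_mat(matrix(stats::runif(n_base * k), n_base, k))

  evaluate <- function(m) {
    y <- tryCatch(model_fn(m), error = function(e) NULL)
    if (is.null(y) || length(y) != nrow(m)) y <- apply(m, 1, model_fn)
    if (any(!is.finite(y)))
      stop("non-finite model output at parameter set: ",
           paste(round(m[which(!is.finite(y))[1], ], 4), collapse = ", "),
           call. = FALSE)
    as.numeric(y)
  }
  fA <- evaluate(A)
  fB <- evaluate(B)
  V <- stats::var(c(fA, fB))
  total <- numeric(k)
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- evaluate(ABi)
    total[i] <- mean((fA - fABi)^2) / (2 * V)   # Jansen total-order estimator
  }
  structure(
    data.frame(param_name = nm, total_index = total,
               selected = total > threshold),
    class = c("sensitivity_result", "data.frame"))
}

#' Sampling importance resampling (SIR) calibration
#'
#' Draws particles from the prior, weights them by the normalised likelihood
#' (model output closer to the measurements receives higher weight) and
#' resamples with replacement. Log-weights are normalised by log-sum-exp to
#' avoid underflow. The maximum a posteriori (MAP) estimate is operationalised
#' as the highest-weight particle among those resampled.
#'
#' @param prior_sampler function `n -> matrix` (n draws x k parameters; a
#'   vector return is treated as a single-parameter matrix)
#' @param loglik_fn function returning log-likelihood for each row of a
#'   parameter matrix (vectorised, or applied row-wise as a fallback)
#' @param n_prior number of prior particles
#' @param n_resample resample size (<= n_prior)
#' @param seed integer seed
#' @return list of class `posterior_sample`: `draws` (resampled particle
#'   matrix), `weights` (normalised prior-particle weights), `map_estimate`,
#'   `effective_sample_size`
#' @export
sir_calibrate <- function(prior_sampler, loglik_fn, n_prior = 1e5,
                          n_resample = 1e4, seed = 1) {
  check_that(n_resample <= n_prior, "n_resample must be <= n_prior")
  set.seed(substream_seed(seed, "sir"))
  draws <- prior_sampler(n_prior)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  ll <- tryCatch(loglik_fn(draws), error = function(e) NULL)
  if (is.null(ll) || length(ll) != nrow(draws)) {
    ll <- apply(draws, 1, loglik_fn)
  }
  lse <- log_sum_exp(ll)
  if (!is.finite(lse))
    stop("degenerate likelihood: all weights underflow to zero", call. = FALSE)
  w <- exp(ll - lse)
  idx <- sample.int(n_prior, n_resample, replace = TRUE, prob = w)
  map <- draws[idx[which.max(w[idx])], , drop = TRUE]
  structure(
    list(draws = draws[idx, , drop = FALSE], weights = w, map_estimate = map,
         effective_sample_size = 1 / sum(w^2)),
    class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample:", nrow(x$draws), "resampled particles; ESS",
      round(x$effective_sample_size, 1), "\n")
  cat("  MAP:", paste(signif(x$map_estimate, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the linear mixed-effect bias model
#'
#' REML fit of measured SOC on simulated SOC (plus optional covariates) with
#' site and region random intercepts, capturing the dependence of
#' observations from the same experimental site and region. If the
#' region-level variance component is not identifiable the fit falls back to
#' a site-only random effect (with a warning); if no mixed model can be fit
#' (e.g. noise-free data) a fixed-effects fit with zero variance components
#' is returned.
#'
#' @param calibration_sites data.frame with `measured_soc`, `simulated_soc`,
#'   `site_id`, `region_id` and any covariate columns
#' @param covariates character vector of additional covariate column names
#' @return list of class `bias_model`: `beta` (named fixed effects),
#'   `beta_cov` (their sampling covariance), `sigma_site`, `sigma_region`,
#'   `sigma_resid`, `covariates`
#' @export
fit_bias_model <- function(calibration_sites, covariates = character(0)) {
  d <- calibration_sites
  check_that(length(unique(d$site_id)) >= 3, "need >= 3 sites")
  rhs <- paste(c("simulated_soc", covariates), collapse = " + ")
  f_full <- stats::as.formula(paste("measured_soc ~", rhs,
                                    "+ (1 | site_id) + (1 | region_id)"))
  f_site <- stats::as.formula(paste("measured_soc ~", rhs, "+ (1 | site_id)"))

  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(f_full, data = d, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-6)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    reg_var <- vc$vcov[vc$grp == "region_id"]
    if (length(reg_var) && reg_var < 1e-8) {
      warning("region variance component not identifiable; using site-only random effect")
      fit <- tryCatch(
        suppressWarnings(suppressMessages(lme4::lmer(f_site, data = d, REML = TRUE))),
        error = function(e) NULL)
    }
  }
  if (is.null(fit)) {
    warning("region variance component not identifiable; using site-only random effect")
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(f_site, data = d, REML = TRUE))),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sd_of <- function(grp) {
      v <- vc$sdcor[vc$grp == grp]
      if (length(v)) v[1] else 0
    }
    out <- list(beta = lme4::fixef(fit),
                beta_cov = as.matrix(stats::vcov(fit)),
                sigma_site = sd_of("site_id"),
                sigma_region = sd_of("region_id"),
                sigma_resid = sd_of("Residual"),
                covariates = covariates)
  } else {
    warning("mixed model could not be fit; falling back to fixed-effects regression")
    lmfit <- stats::lm(stats::as.formula(paste("measured_soc ~", rhs)), data = d)
    s <- summary(lmfit)$sigma
    if (!is.finite(s)) s <- 0
    out <- list(beta = stats::coef(lmfit),
                beta_cov = as.matrix(stats::vcov(lmfit)),
                sigma_site = 0, sigma_region = 0, sigma_resid = s,
                covariates = covariates)
  }
  names(out$beta)[1] <- "(Intercept)"
  class(out) <- "bias_model"
  out
}

#' @export
print.bias_model <- function(x, ...) {
  cat("bias_model: measured ~", paste(names(x$beta)[-1], collapse = " + "), "\n")
  cat("  beta:", paste(sprintf("%s=%.4g", names(x$beta), x$beta), collapse = ", "), "\n")
  cat(sprintf("  sigma: site %.3g, region %.3g, residual %.3g\n",
              x$sigma_site, x$sigma_region, x$sigma_resid))
  invisible(x)
}

#' An identity bias model (no adjustment, no uncertainty)
#'
#' Convenience constructor used for degenerate uncertainty configurations.
#'
#' @return a `bias_model` with slope 1, intercept 0 and all variances 0
#' @export
identity_bias_model <- function() {
  structure(
    list(beta = c("(Intercept)" = 0, simulated_soc = 1),
         beta_cov = matrix(0, 2, 2), sigma_site = 0, sigma_region = 0,
         sigma_resid = 0, covariates = character(0)),
    class = "bias_model")
}

#' Bias-adjust simulated SOC stocks
#'
#' Applies the bias model's linear predictor to simulated stocks, optionally
#' with a sampled fixed-effect vector (for Monte Carlo propagation), and
#' reports the prediction standard deviation
#' `sqrt(sigma_site^2 + sigma_region^2 + sigma_resid^2)`.
#'
#' @param simulated_soc numeric vector of simulated stocks (t C/ha)
#' @param covariates data.frame of covariate columns (or `NULL` when the
#'   model has none)
#' @param bias_model a `bias_model`
#' @param param_draw optional fixed-effect vector, e.g. one draw from
#'   `Normal(beta, beta_cov)`
#' @return list with `adjusted_soc` and `prediction_sd`
#' @export
adjust_prediction <- function(simulated_soc, covariates = NULL, bias_model,
                              param_draw = NULL) {
  beta <- param_draw %||% bias_model$beta
  X <- cbind(1, simulated_soc)
  if (length(bias_model$covariates)) {
    check_that(!is.null(covariates) &&
                 all(bias_model$covariates %in% names(covariates)),
               "covariate mismatch: bias model requires covariates not supplied")
    X <- cbind(X, as.matrix(covariates[bias_model$covariates]))
  }
  check_that(ncol(X) == length(beta), "covariate mismatch: wrong predictor count")
  list(adjusted_soc = as.numeric(X %*% beta),
       prediction_sd = sqrt(bias_model$sigma_site^2 + bias_model$sigma_region^2 +
                              bias_model$sigma_resid^2))
}

#' Draw fixed-effect vectors from the bias model's sampling distribution
#'
#' @param bias_model a `bias_model`
#' @param n number of draws
#' @return n x p matrix of fixed-effect vectors
#' @export
draw_bias_params <- function(bias_model, n = 1) {
  p <- length(bias_model$beta)
  S <- bias_model$beta_cov
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% t(L), 2, bias_model$beta, `+`)
}
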