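# Counterfactual scenario construction and paired-simulation attribution:
# one practice is removed at a time, the location is re-simulated, and the
# practice effect is the difference in annual SOC stock changes
# (baseline minus counterfactual). Set-aside is attributed directly from the
# baseline simulation.

SCENARIOS <- c("NO_COVER_CROP", "FULL_TILLAGE", "NO_HAY_PASTURE",
               "MANURE_TO_SYNTHETIC")

#' Build a counterfactual management history by eliminating one practice
#'
#' Edits span the full history (1979-2015) so the assessment years carry no
#' artificial transient from an abrupt management shift:
#' * `NO_COVER_CROP` - cover crops removed everywhere (termination `none`);
#' * `FULL_TILLAGE` - every NT/RT year becomes FT;
#' * `NO_HAY_PASTURE` - each hay/pasture year is replaced by an annual crop
#'   sampled uniformly from the other annual crops grown at that location
#'   (locations growing only hay/pasture fall back to `fallback_crop`, with a
#'   warning);
#' * `MANURE_TO_SYNTHETIC` - manure N is moved to synthetic fertilizer
#'   (`fert_n + manure_n` is conserved exactly), removing the manure carbon
#'   input but not the N available to crops.
#'
#' Each scenario edits only its own practice fields and is idempotent.
#'
#' @param history a `management_history`
#' @param scenario one of `r paste(SCENARIOS, collapse=", ")`
#' @param seed integer seed (used by `NO_HAY_PASTURE` crop sampling)
#' @param fallback_crop annual crop used when a location grows only
#'   hay/pasture (default the regional staple `"corn"`; pass a named vector
#'   keyed by location id for per-location fallbacks)
#' @return the edited `management_history`
#' @export
apply_scenario <- function(history, scenario, seed = 1, fallback_crop = "corn") {
  check_that(scenario %in% SCENARIOS, paste("unknown scenario:", scenario))
  h <- history
  if (scenario == "NO_COVER_CROP") {
    h$cover_crop <- FALSE
    h$termination <- "none"
  } else if (scenario == "FULL_TILLAGE") {
    h$tillage[h$tillage %in% c("NT", "RT")] <- "FT"
  } else if (scenario == "MANURE_TO_SYNTHETIC") {
    h$fert_n <- h$fert_n + h$manure_n
    h$manure_n <- 0
  } else if (scenario == "NO_HAY_PASTURE") {
    set.seed(substream_seed(seed, "no_hay_pasture"))
    is_hp <- h$crop %in% HAY_PASTURE_CROPS
    warned <- FALSE
    for (id in unique(h$location_id[is_hp])) {
      rows <- which(h$location_id == id & is_hp)
      pool <- setdiff(unique(h$crop[h$location_id == id]),
                      c(HAY_PASTURE_CROPS, SET_ASIDE_CROP))
      if (!length(pool)) {
        pool <- if (!is.null(names(fallback_crop)))
          fallback_crop[[as.character(id)]] else fallback_crop
        warned <- TRUE
      }
      h$crop[rows] <- if (length(pool) == 1) pool else
        sample(pool, length(rows), replace = TRUE)
    }
    if (warned)
      warning("some locations grow only hay/pasture; substituted the fallback annual crop")
  }
  h
}

#' Attribute a practice effect from paired trajectories
#'
#' The per-location, per-year practice effect is the difference in annual
#' stock changes, `delta_soc(baseline) - delta_soc(counterfactual)`, reported
#' over the assessment years.
#'
#' @param baseline_traj,counterfactual_traj `soc_trajectory` tables sharing
#'   locations and years
#' @param years assessment years (default 1995:2015)
#' @return data.frame `location_id`, `year`, `effect` (t C/ha/yr)
#' @export
attribute_effect <- function(baseline_traj, counterfactual_traj,
                             years = 1995:2015) {
  b <- baseline_traj[baseline_traj$year %in% years, ]
  k <- match(paste(b$location_id, b$year),
             paste(counterfactual_traj$location_id, counterfactual_traj$year))
  check_that(!anyNA(k), "trajectories do not share locations and years")
  data.frame(location_id = b$location_id, year = b$year,
             effect = b$delta_soc - counterfactual_traj$delta_soc[k])
}

#' Direct attribution of the set-aside effect
#'
#' Set-aside (reserve) land is the only practice at its location-years, so
#' its effect is read directly from the baseline simulation: the baseline
#' stock change in enrolled years, zero elsewhere.
#'
#' @param baseline_traj a `soc_trajectory` table
#' @param history the matching `management_history` marking set-aside years
#' @param years assessment years (default 1995:2015)
#' @return data.frame `location_id`, `year`, `effect`
#' @export
setaside_effect <- function(baseline_traj, history, years = 1995:2015) {
  b <- baseline_traj[baseline_traj$year %in% years, ]
  k <- match(paste(b$location_id, b$year),
             paste(history$location_id, history$year))
  check_that(!anyNA(k), "history does not cover the trajectory years")
  data.frame(location_id = b$location_id, year = b$year,
             effect = ifelse(history$set_aside[k], b$delta_soc, 0))
}

RUN_NAMES <- c("baseline_herbicide", "baseline_tillage", "no_cover_crop",
               "full_tillage", "no_hay_pasture", "manure_synthetic")

# scenario label -> (baseline run, counterfactual run) used for attribution
EFFECT_RUNS <- list(
  cover_crop_herbicide = c("baseline_herbicide", "no_cover_crop"),
  cover_crop_tillage = c("baseline_tillage", "no_cover_crop"),
  conservation_tillage = c("baseline_herbicide", "full_tillage"),
  hay_pasture = c("baseline_herbicide", "no_hay_pasture"),
  manure = c("baseline_herbicide", "manure_synthetic")
)

#' Run the baseline and all elimination scenarios for one imputation set
#'
#' Simulates each location under the baseline history (under both cover-crop
#' termination variants) and under each one-practice-removed counterfactual,
#' reusing the baseline trajectory wherever a scenario leaves a location's
#' history untouched (which also guarantees exactly zero attributed effect
#' for locations never exposed to a practice). Returns cached annual stock
#' matrices for Monte Carlo reuse plus per-practice exposure masks.
#'
#' @param frame a `survey_frame`
#' @param histories one imputation's `management_history`
#' @param params `soc_params`
#' @param weather a `weather_series` covering the history years
#' @param seed integer seed (crop resampling in `NO_HAY_PASTURE`)
#' @return object of class `scenario_runs`: list with `stocks` (named list of
#'   (1 + n_years) x n_locations matrices; first row is the pre-history
#'   stock), `exposure` (named list of n_locations x n_years masks), `years`,
#'   `frame`, `histories` (baseline, herbicide variant), `failed` (excluded
#'   locations and their weights)
#' @export
run_all_scenarios <- function(frame, histories, params = default_params(),
                              weather, seed = 1) {
  loc <- frame$locations
  n <- nrow(loc)
  years <- sort(unique(histories$year))
  ny <- length(years)

  set_term <- function(h, term) {
    h$termination <- ifelse(h$cover_crop, term, "none")
    h
  }
  base_h <- set_term(histories, "herbicide")
  variants <- list(
    baseline_herbicide = base_h,
    baseline_tillage = set_term(histories, "tillage"),
    no_cover_crop = apply_scenario(base_h, "NO_COVER_CROP"),
    full_tillage = apply_scenario(base_h, "FULL_TILLAGE"),
    no_hay_pasture = suppressWarnings(
      apply_scenario(base_h, "NO_HAY_PASTURE", seed = seed)),
    manure_synthetic = apply_scenario(base_h, "MANURE_TO_SYNTHETIC")
  )

  sim_cols <- c("crop", "tillage", "fert_n", "manure_n", "cover_crop",
                "termination", "set_aside")
  stocks <- lapply(variants, function(v) matrix(NA_real_, ny + 1, n))
  failed <- data.frame(location_id = integer(0), weight = numeric(0),
                       message = character(0))

  split_rows <- split(seq_len(nrow(base_h)), base_h$location_id)
  for (i in seq_len(n)) {
    id <- loc$location_id[i]
    rows <- split_rows[[as.character(id)]]
    wl <- weather_for(weather, id)
    forcing <- prepare_forcing(wl, params)
    loc_i <- loc[i, ]
    base_hist <- variants$baseline_herbicide[rows, ]
    traj <- list()
    ok <- TRUE
    for (v in names(variants)) {
      hv <- variants[[v]][rows, ]
      same <- v != "baseline_herbicide" &&
        identical(unname(as.list(hv[sim_cols])),
                  unname(as.list(base_hist[sim_cols])))
      if (same) {
        stocks[[v]][, i] <- stocks$baseline_herbicide[, i]
        next
      }
      res <- tryCatch(
        simulate_location(loc_i, wl, hv, params, forcing = forcing),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed <- rbind(failed, data.frame(location_id = id,
                                           weight = loc$weight[i],
                                           message = conditionMessage(res)))
        ok <- FALSE
        break
      }
      stocks[[v]][, i] <- c(attr(res, "initial_soc"), res$soc)
    }
    if (!ok) for (v in names(variants)) stocks[[v]][, i] <- NA_real_
  }
  if (nrow(failed))
    warning(sprintf("%d location(s) excluded after simulation failure (total weight %.0f ha)",
                    nrow(failed), sum(failed$weight)))

  ord <- order(base_h$location_id, base_h$year)
  bh <- base_h[ord, ]
  exposure <- list(
    cover_crop_herbicide = t(matrix(bh$cover_crop, ny, n)),
    cover_crop_tillage = t(matrix(bh$cover_crop, ny, n)),
    conservation_tillage = t(matrix(bh$tillage %in% c("NT", "RT") & !bh$set_aside,
                                    ny, n)),
    hay_pasture = t(matrix(bh$crop %in% HAY_PASTURE_CROPS, ny, n)),
    manure = t(matrix(bh$manure_n > 0, ny, n)),
    set_aside = t(matrix(bh$set_aside, ny, n))
  )
  structure(
    list(stocks = stocks, exposure = exposure, years = years, frame = frame,
         histories = base_h, failed = failed),
    class = "scenario_runs")
}

#' @export
print.scenario_runs <- function(x, ...) {
  cat("scenario_runs:", length(x$stocks), "runs x", ncol(x$stocks[[1]]),
      "locations,", length(x$years), "years\n")
  invisible(x)
}

#' Raw (unadjusted) practice-effect matrices from cached scenario runs
#'
#' @param runs a `scenario_runs`
#' @param years assessment years
#' @return named list of year x location effect matrices (t C/ha/yr), one per
#'   scenario, plus `total` (the baseline stock-change series) and
#'   `set_aside`
#' @export
effect_matrices <- function(runs, years = 1995:2015) {
  yi <- match(years, runs$years)
  check_that(!anyNA(yi), "assessment years missing from runs")
  d <- lapply(runs$stocks, function(S) apply(S, 2, diff)[yi, , drop = FALSE])
  out <- lapply(EFFECT_RUNS, function(pair) d[[pair[1]]] - d[[pair[2]]])
  out$set_aside <- d$baseline_herbicide *
    t(runs$exposure$set_aside[, yi, drop = FALSE])
  out$total <- d$baseline_herbicide
  out
}
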