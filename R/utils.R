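# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a stage name
#'
#' All randomness in the package flows from one master seed through named
#' substreams, one per pipeline stage, so any stage can be re-run in isolation
#' and reproduce its output exactly. The mapping is a small polynomial hash of
#' the stage name folded into the master seed, kept inside the 32-bit integer
#' range `set.seed()` accepts.
#'
#' @param seed master integer seed
#' @param name character stage name (e.g. `"frame"`, `"weather"`,
#'   `"imputation:3"`)
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  s <- (abs(seed) %% m) + 1
  as.integer((s * 48271 + h) %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Classify soil texture from clay and sand fractions
#'
#' A coarse three-class scheme (coarse / medium / fine) used to stratify
#' donor surveys and imputation, standing in for the soil texture classes
#' assigned from soil survey data.
#'
#' @param clay_frac clay fraction in `[0, 1]`
#' @param sand_frac sand fraction in `[0, 1]`
#' @return character vector of `"coarse"`, `"medium"`, `"fine"`
#' @export
texture_class <- function(clay_frac, sand_frac) {
  out <- rep("medium", length(clay_frac))
  out[sand_frac >= 0.5] <- "coarse"
  out[clay_frac >= 0.35] <- "fine"
  out
}

# stop() wrapper producing consistent invalid-argument messages
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# tillage state order is fixed throughout the package
TILLAGE_LEVELS <- c("NT", "RT", "FT")

# crops treated as perennial forage (the hay/pasture rotation practice)
HAY_PASTURE_CROPS <- c("hay", "pasture")

# grass cover used for land set aside from production
SET_ASIDE_CROP <- "grass"
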