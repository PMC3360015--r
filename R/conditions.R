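# Movement-condition variants: how bimanual movement distorts the
# population's tuning relative to unimanual movement. The central variant
# is the quenched Gaussian rotation of the encoding PDs; the others
# (annealed rotation, depth-only change, joint encoding+decoding
# rotation) isolate which feature of the distortion drives
# reorganization.

CONDITION_REGIMES <- c(
  "unimanual", "bimanual_quenched", "bimanual_annealed",
  "bimanual_depth_only", "bimanual_enc_dec"
)

#' Construct a movement condition
#'
#' @param regime One of `"unimanual"`, `"bimanual_quenched"`,
#'   `"bimanual_annealed"`, `"bimanual_depth_only"`, `"bimanual_enc_dec"`.
#' @param sigma Standard deviation, in degrees, of the zero-mean Gaussian
#'   PD rotations (ignored by the unimanual and depth-only regimes).
#' @param depth_sigma Spread of the quenched multiplicative depth change,
#'   on the log scale (depth-only regime).
#' @param seed Seed for the quenched draws (rotations or depth factors).
#' @return An object of class `"condition"`.
#' @export
condition <- function(regime = "unimanual", sigma = 0, depth_sigma = 0,
                      seed = 1L) {
  regime <- match.arg(regime, CONDITION_REGIMES)
  if (!is.numeric(sigma) || sigma < 0) {
    stop("rotation spread `sigma` must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(depth_sigma) || depth_sigma < 0) {
    stop("`depth_sigma` must be nonnegative", call. = FALSE)
  }
  if (regime == "unimanual" && sigma != 0) {
    stop("the unimanual regime has no PD rotation; set sigma = 0", call. = FALSE)
  }
  structure(
    list(
      regime = regime, sigma = sigma, depth_sigma = depth_sigma,
      seed = as.integer(seed)
    ),
    class = "condition"
  )
}

condition_regime <- function(condition) {
  if (!inherits(condition, "condition")) {
    stop("expected a `condition` object", call. = FALSE)
  }
  condition$regime
}

condition_depth_factors <- function(condition, n) {
  make_depth_change(n, condition$depth_sigma, condition$seed)
}

#' @export
print.condition <- function(x, ...) {
  cat(sprintf(
    "<condition> %s (sigma = %g deg, depth_sigma = %g, seed = %d)\n",
    x$regime, x$sigma, x$depth_sigma, x$seed
  ))
  invisible(x)
}

#' Quenched PD rotation offsets
#'
#' Draws one zero-mean Gaussian rotation per neuron, fixed for the life of
#' the condition ("quenched": invariant across trials). The draw is a pure
#' function of `(n, sigma, seed)`.
#'
#' @param n Number of neurons.
#' @param sigma Standard deviation in degrees; `sigma = 0` gives exact
#'   zeros.
#' @param seed Integer seed.
#' @return Numeric vector of `n` rotation offsets in degrees.
#' @export
make_quenched_rotations <- function(n, sigma, seed = 1L) {
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) {
    return(numeric(n))
  }
  local_rng(seed, stats::rnorm(n, 0, sigma))
}

#' Annealed PD rotation offsets
#'
#' The trial-by-trial variant of [make_quenched_rotations()]: offsets are
#' redrawn every trial from the caller's current RNG stream.
#'
#' @inheritParams make_quenched_rotations
#' @return Numeric vector of `n` fresh rotation offsets in degrees.
#' @export
resample_annealed_rotations <- function(n, sigma) {
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) {
    return(numeric(n))
  }
  stats::rnorm(n, 0, sigma)
}

#' Quenched multiplicative depth factors
#'
#' The depth-only bimanual variant changes modulation depths but leaves
#' PDs untouched. Factors are `exp(N(0, depth_sigma^2))`, so they are
#' strictly positive, center on 1, and are pure in `(n, depth_sigma,
#' seed)`.
#'
#' @param n Number of neurons.
#' @param depth_sigma Log-scale spread; 0 gives factors identically 1.
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive factors.
#' @export
make_depth_change <- function(n, depth_sigma, seed = 1L) {
  if (depth_sigma < 0) stop("`depth_sigma` must be nonnegative", call. = FALSE)
  if (depth_sigma == 0) {
    return(rep(1, n))
  }
  local_rng(seed + 1L, exp(stats::rnorm(n, 0, depth_sigma)))
}

#' Install a condition's quenched state on a population
#'
#' Writes the condition's quenched rotation offsets into
#' `pop$rotation_offset` (regimes with PD rotation) or zeros them
#' (unimanual / depth-only). Annealed offsets are installed per trial by
#' [run_rehabilitation()].
#'
#' @param pop A [population()].
#' @param condition A [condition()].
#' @return The population with offsets installed.
#' @export
realize_condition <- function(pop, condition) {
  stopifnot(inherits(pop, "population"))
  regime <- condition_regime(condition)
  pop$rotation_offset <- switch(regime,
    unimanual = ,
    bimanual_depth_only = numeric(pop$n),
    bimanual_quenched = ,
    bimanual_enc_dec = make_quenched_rotations(pop$n, condition$sigma, condition$seed),
    bimanual_annealed = numeric(pop$n) # drawn per trial
  )
  pop
}
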