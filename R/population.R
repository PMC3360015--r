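# Population container and the forward pass: cosine tuning with a
# rectified nonlinearity, signal-dependent noise, population-vector
# decoding.

#' Construct a neural population
#'
#' A population is the basic state object of the model: one cosine-tuned
#' neuron per entry, described by its unimanual (base) encoding preferred
#' direction, a quenched rotation offset applied during bimanual movement,
#' a nonnegative modulation depth, and an alive flag. Lesions flip `alive`
#' to `FALSE`; learning moves `base_pd` of alive neurons only.
#'
#' @param n Number of neurons (ignored when `base_pd` is supplied).
#' @param base_pd Optional numeric vector of base encoding PDs in degrees;
#'   wrapped to \[0, 360). Default: `n` PDs laid out per `layout`.
#' @param layout `"spaced"` for equally spaced PDs (deterministic, the
#'   default) or `"uniform"` for i.i.d. uniform draws.
#' @param depth Modulation depth per neuron, recycled; must be >= 0.
#' @param rotation_offset Quenched per-neuron rotation in degrees,
#'   recycled; 0 corresponds to unimanual tuning.
#' @param alive Logical vector, recycled.
#' @param seed Seed for the `"uniform"` layout draw.
#' @return An object of class `"population"`: a list with fields
#'   `base_pd`, `rotation_offset`, `depth`, `alive`, `n`.
#' @examples
#' pop <- population(8)
#' pop$base_pd # 0, 45, ..., 315
#' @export
population <- function(n = NULL, base_pd = NULL, layout = c("spaced", "uniform"),
                       depth = 1, rotation_offset = 0, alive = TRUE,
                       seed = NULL) {
  layout <- match.arg(layout)
  if (is.null(base_pd)) {
    if (is.null(n) || n < 1) {
      stop("supply `n` >= 1 or an explicit `base_pd` vector", call. = FALSE)
    }
    base_pd <- switch(layout,
      spaced = (seq_len(n) - 1) * 360 / n,
      uniform = {
        if (!is.null(seed)) {
          base_pd <- local_rng(seed, stats::runif(n, 0, 360))
        } else {
          stats::runif(n, 0, 360)
        }
      }
    )
  }
  n <- length(base_pd)
  depth <- rep_len(as.numeric(depth), n)
  rotation_offset <- rep_len(as.numeric(rotation_offset), n)
  alive <- rep_len(as.logical(alive), n)
  if (any(depth < 0)) stop("modulation depths must be nonnegative", call. = FALSE)
  if (anyNA(base_pd) || anyNA(depth) || anyNA(alive)) {
    stop("population fields must not contain NA", call. = FALSE)
  }
  structure(
    list(
      base_pd = wrap_angle(as.numeric(base_pd)),
      rotation_offset = rotation_offset,
      depth = depth,
      alive = alive,
      n = n
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "<population> %d neurons (%d alive), depth range [%.3g, %.3g]\n",
    x$n, sum(x$alive), min(x$depth), max(x$depth)
  ))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps quenched draws pure in (args, seed).
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Signal-dependent noise model
#'
#' Activity noise is zero-mean Gaussian with variance proportional to the
#' mean activity (`variance = k * mean`), so silent neurons are exactly
#' noise-free. Sampled activities are re-rectified at zero.
#'
#' @param k Nonnegative noise strength; `k = 0` makes the forward pass
#'   deterministic.
#' @param form Variance law tag; only `"proportional"` is defined.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(k = 0.1, form = "proportional") {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0) {
    stop("noise strength `k` must be a single nonnegative number", call. = FALSE)
  }
  form <- match.arg(form, "proportional")
  structure(list(k = k, form = form), class = "noise_model")
}

#' Encoding preferred directions under a movement condition
#'
#' Unimanual movement leaves the base PDs untouched; bimanual variants
#' with PD rotation add the quenched (or currently installed annealed)
#' per-neuron offsets. The depth-only variant does not rotate PDs.
#'
#' @param pop A [population()].
#' @param condition A [condition()].
#' @return Numeric vector of encoding PDs in degrees, wrapped to \[0, 360).
#' @export
encoding_pd <- function(pop, condition) {
  stopifnot(inherits(pop, "population"))
  regime <- condition_regime(condition)
  switch(regime,
    unimanual = ,
    bimanual_depth_only = pop$base_pd,
    bimanual_quenched = ,
    bimanual_annealed = ,
    bimanual_enc_dec = wrap_angle(pop$base_pd + pop$rotation_offset),
    stop(sprintf("unknown condition regime '%s'", regime), call. = FALSE)
  )
}

# Effective modulation depth this condition presents to the tuning curve.
effective_depth <- function(pop, condition) {
  if (condition_regime(condition) == "bimanual_depth_only") {
    pop$depth * condition_depth_factors(condition, pop$n)
  } else {
    pop$depth
  }
}

#' Mean (noiseless) tuning-curve activity
#'
#' Each alive neuron responds with a rectified cosine of the angle between
#' the target and its encoding PD, scaled by its modulation depth:
#' `rectify(depth * cos(target - encoding_pd))`. Dead neurons contribute
#' exactly zero.
#'
#' @param pop A [population()].
#' @param condition A [condition()] selecting the movement regime.
#' @param target Target direction in degrees.
#' @return Nonnegative numeric vector of mean activities, length `pop$n`.
#' @export
mean_activity <- function(pop, condition, target) {
  enc <- encoding_pd(pop, condition)
  dep <- effective_depth(pop, condition)
  a <- pmax(dep * cos(deg2rad(target - enc)), 0)
  a[!pop$alive] <- 0
  a
}

#' Sample noisy activities
#'
#' Adds zero-mean Gaussian noise with variance `k * mean` to each mean
#' activity and re-rectifies at zero. A zero mean therefore always samples
#' to exactly zero (the signal-dependence contract).
#'
#' @param mean_act Nonnegative vector of mean activities.
#' @param noise A [noise_model()].
#' @return Vector of sampled activities, same length, all >= 0. Draws come
#'   from the current RNG stream; seed it with `set.seed()` for
#'   reproducibility.
#' @export
sample_activity <- function(mean_act, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(mean_act < 0)) stop("mean activities must be nonnegative", call. = FALSE)
  if (noise$k == 0) {
    return(mean_act)
  }
  sd <- sqrt(noise$k * mean_act)
  pmax(mean_act + stats::rnorm(length(mean_act), 0, sd), 0)
}

#' Decoding preferred directions under a movement condition
#'
#' Decoding PDs model the cortical-spinal-muscle readout. They equal the
#' base PDs in every regime except the joint encoding-and-decoding
#' rotation variant, where the quenched offsets are applied to decoding
#' as well.
#'
#' @inheritParams encoding_pd
#' @return Numeric vector of decoding PDs in degrees.
#' @export
decoding_pd <- function(pop, condition) {
  stopifnot(inherits(pop, "population"))
  regime <- condition_regime(condition)
  if (regime == "bimanual_enc_dec") {
    wrap_angle(pop$base_pd + pop$rotation_offset)
  } else {
    pop$base_pd
  }
}

#' Population vector
#'
#' The activity-weighted average of decoding-PD unit vectors,
#' `PV = (1/N) * sum_i a_i * (cos psi_i, sin psi_i)`, summed over alive
#' neurons but normalized by the population's original neuron count `N`.
#' Keeping `N` fixed across a lesion is what lets the lesion slow the
#' modeled reach: surviving activity is spread over the same denominator.
#' The PV angle models reach direction, its norm reach speed.
#'
#' @param pop A [population()].
#' @param activities Activity vector aligned with `pop` (dead entries are
#'   ignored).
#' @param condition A [condition()]; selects the decoding PDs.
#' @return An object of class `"pv"`: list with `x`, `y`, `angle`
#'   (degrees in \[0, 360), `NA` when the norm is zero), `norm`, and
#'   `defined` (FALSE when all activity vanished).
#' @export
population_vector <- function(pop, activities, condition) {
  stopifnot(inherits(pop, "population"), length(activities) == pop$n)
  psi <- deg2rad(decoding_pd(pop, condition))
  a <- ifelse(pop$alive, activities, 0)
  x <- sum(a * cos(psi)) / pop$n
  y <- sum(a * sin(psi)) / pop$n
  nrm <- sqrt(x^2 + y^2)
  defined <- nrm > 0
  structure(
    list(
      x = x, y = y,
      angle = if (defined) wrap_angle(rad2deg(atan2(y, x))) else NA_real_,
      norm = nrm,
      defined = defined
    ),
    class = "pv"
  )
}

#' @export
print.pv <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<pv> angle %.3f deg, norm %.5g\n", x$angle, x$norm))
  } else {
    cat("<pv> undefined (zero norm)\n")
  }
  invisible(x)
}

#' Write / read a population as CSV
#'
#' Flat serialization with columns `index`, `base_pd_deg`,
#' `rotation_offset_deg`, `depth`, `alive`.
#'
#' @param pop A [population()].
#' @param path File path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a [population()].
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  df <- data.frame(
    index = seq_len(pop$n),
    base_pd_deg = pop$base_pd,
    rotation_offset_deg = pop$rotation_offset,
    depth = pop$depth,
    alive = pop$alive
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("base_pd_deg", "rotation_offset_deg", "depth", "alive")
  if (!all(needed %in% names(df))) {
    stop("population CSV must have columns ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  population(
    base_pd = df$base_pd_deg,
    rotation_offset = df$rotation_offset_deg,
    depth = df$depth,
    alive = as.logical(df$alive)
  )
}
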