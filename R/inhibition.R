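# Analytic account of WHY bimanual movement rotates encoding PDs:
# right-hemisphere neurons, active during bimanual movement, drive
# inhibitory interneurons that subtract cosine-tuned input from each
# left-hemisphere neuron. A sum of cosines of the same angular frequency
# is again a cosine, so the effective tuning keeps its shape but shifts
# its peak -- the effective PD rotation.

#' Resultant of a sum of equal-frequency cosines
#'
#' Computes `(A, P)` such that `sum_j a_j * cos(theta - p_j)` equals
#' `A * cos(theta - P)` for all `theta`, by summing the terms as planar
#' vectors `(a_j cos p_j, a_j sin p_j)`.
#'
#' @param amplitude Numeric vector of term amplitudes (may be negative:
#'   a negative amplitude is an inhibitory term).
#' @param phase Numeric vector of term phases in degrees.
#' @return List with `amplitude` (>= 0), `phase` (degrees in \[0, 360),
#'   `NA` when the resultant vanishes), and `defined`.
#' @examples
#' cosine_sum(c(1, 1), c(0, 90)) # amplitude sqrt(2), phase 45
#' @export
cosine_sum <- function(amplitude, phase) {
  if (length(amplitude) < 1 || length(amplitude) != length(phase)) {
    stop("`amplitude` and `phase` must be nonempty and equal length",
      call. = FALSE
    )
  }
  p <- deg2rad(phase)
  x <- sum(amplitude * cos(p))
  y <- sum(amplitude * sin(p))
  a <- sqrt(x^2 + y^2)
  # exact cancellations leave roundoff-sized resultants; treat them as zero
  defined <- a > 1e-12 * max(sum(abs(amplitude)), .Machine$double.xmin)
  list(
    amplitude = if (defined) a else 0,
    phase = if (defined) wrap_angle(rad2deg(atan2(y, x))) else NA_real_,
    defined = defined
  )
}

#' Inter-hemispheric inhibition parameters
#'
#' @param c_inh Inhibition strength per projecting neuron (>= 0),
#'   determined by the corpus-callosum and interneuron connection
#'   strengths.
#' @param right_pds PDs (degrees) of the right-hemisphere neurons
#'   projecting to this neuron's inhibitory interneuron; its length is the
#'   connectivity `K`.
#' @return An object of class `"inhibition_params"` with fields `c`, `K`,
#'   `right_pds`.
#' @export
inhibition_params <- function(c_inh, right_pds) {
  if (!is.numeric(c_inh) || length(c_inh) != 1 || c_inh < 0) {
    stop("inhibition strength must be a single nonnegative number",
      call. = FALSE
    )
  }
  structure(
    list(c = c_inh, K = length(right_pds), right_pds = wrap_angle(right_pds)),
    class = "inhibition_params"
  )
}

#' Effective tuning under inter-hemispheric inhibition
#'
#' The neuron's direct drive `depth * cos(theta - base_pd)` is summed with
#' `K` inhibitory terms `-c * cos(theta - rho_k)`, one per projecting
#' right-hemisphere neuron. The resultant is again a cosine; its phase
#' shift relative to `base_pd` is the effective encoding-PD rotation that
#' bimanual movement induces. With `c = 0` the rotation is exactly zero.
#' When inhibition overwhelms the direct drive the resultant amplitude is
#' reported as degenerate rather than clipped.
#'
#' @param base_pd Unimanual encoding PD, degrees.
#' @param depth Modulation depth of the direct drive.
#' @param params An [inhibition_params()].
#' @return List with `effective_depth`, `effective_pd` (degrees),
#'   `rotation` (signed degrees, `NA` when degenerate), and `degenerate`.
#' @export
inhibition_rotation <- function(base_pd, depth, params) {
  stopifnot(inherits(params, "inhibition_params"))
  if (params$K == 0 || params$c == 0) {
    return(list(
      effective_depth = depth, effective_pd = wrap_angle(base_pd),
      rotation = 0, degenerate = FALSE
    ))
  }
  res <- cosine_sum(
    c(depth, rep(-params$c, params$K)),
    c(base_pd, params$right_pds)
  )
  # Degenerate when the resultant vanishes or points away from the direct
  # drive (inhibition exceeded excitation): no meaningful rotation.
  if (!res$defined || abs(wrap_diff(res$phase - base_pd)) >= 90) {
    return(list(
      effective_depth = res$amplitude, effective_pd = res$phase,
      rotation = NA_real_, degenerate = TRUE
    ))
  }
  list(
    effective_depth = res$amplitude,
    effective_pd = res$phase,
    rotation = wrap_diff(res$phase - base_pd),
    degenerate = FALSE
  )
}

#' Rotation profile of a population under inter-hemispheric inhibition
#'
#' Samples, for each of `n` neurons with uniformly spaced base PDs, `K`
#' right-hemisphere PDs i.i.d. uniform on the circle and computes the
#' effective-tuning rotation. Sparse connectivity (small `K`) with
#' per-projection strength `c_inh` produces random per-neuron rotations;
#' in the dense regime (`K` large) the inhibitory terms average out
#' (`scale_dense = TRUE` divides `c_inh` by `K`) and rotations vanish by
#' the law of large numbers.
#'
#' @param n Number of left-hemisphere neurons.
#' @param c_inh Total inhibition strength.
#' @param K Connectivity: projecting right-hemisphere neurons per
#'   interneuron.
#' @param depth Direct-drive modulation depth.
#' @param scale_dense If `TRUE`, each projection has strength `c_inh / K`.
#' @param seed Seed for the connectivity draw.
#' @return Data frame with columns `neuron`, `base_pd`, `rotation`,
#'   `effective_depth`, `degenerate`.
#' @export
inhibition_profile <- function(n, c_inh, K = 3, depth = 1,
                               scale_dense = FALSE, seed = 1L) {
  base <- (seq_len(n) - 1) * 360 / n
  per <- if (scale_dense) c_inh / K else c_inh
  rp <- local_rng(seed, matrix(stats::runif(n * K, 0, 360), nrow = n))
  out <- lapply(seq_len(n), function(i) {
    r <- inhibition_rotation(base[i], depth, inhibition_params(per, rp[i, ]))
    data.frame(
      neuron = i, base_pd = base[i], rotation = r$rotation,
      effective_depth = r$effective_depth, degenerate = r$degenerate
    )
  })
  do.call(rbind, out)
}
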