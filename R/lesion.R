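# Stroke implementation: deplete a contiguous wedge of preferred
# directions, modeling the directional reaching deficit of stroke
# patients.

#' Lesion specification
#'
#' The lesion kills exactly the neurons whose base encoding PD lies
#' within `fraction * 180` degrees of `center`, i.e. a wedge covering a
#' `fraction` of the circle.
#'
#' @param center Wedge center, degrees (default 90: straight ahead /
#'   far-from-body, the direction stroke patients typically struggle
#'   with).
#' @param fraction Fraction of the circle depleted, in \[0, 1).
#' @return An object of class `"lesion_spec"`.
#' @export
lesion_spec <- function(center = 90, fraction = 0.25) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("lesion `fraction` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(center = wrap_angle(center), fraction = fraction),
    class = "lesion_spec"
  )
}

#' Apply a lesion to a population
#'
#' Sets `alive = FALSE` on every neuron inside the wedge
#' `|wrap(base_pd - center)| <= fraction * 180`; all other fields are
#' untouched. Returns a new population (the input is not modified).
#'
#' @param pop A [population()].
#' @param spec A [lesion_spec()].
#' @return The lesioned population.
#' @export
apply_lesion <- function(pop, spec) {
  stopifnot(inherits(pop, "population"), inherits(spec, "lesion_spec"))
  if (spec$fraction == 0) {
    return(pop)
  }
  killed <- abs(wrap_diff(pop$base_pd - spec$center)) <= spec$fraction * 180
  pop$alive <- pop$alive & !killed
  pop
}
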