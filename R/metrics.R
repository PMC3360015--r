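# Quantifying reorganization (where did the surviving PDs end up?) and
# movement quality (how accurate and fast are unimanual reaches?).

#' Circular histogram and uniformity of the alive preferred directions
#'
#' Bins the base PDs of alive neurons into `n_bins` equal circular bins
#' and summarizes the distribution with a normalized circular Shannon
#' entropy (`1` when all bins hold equal counts, lower as mass
#' concentrates) and, when a lesion is supplied, the fraction of alive
#' neurons whose base PD lies inside the original lesion wedge
#' (`wedge_fill`; 0 immediately post-lesion, rising as reorganization
#' refills the depleted region).
#'
#' @param pop A [population()].
#' @param n_bins Number of equal circular bins (>= 2; default 36).
#' @param lesion Optional [lesion_spec()] against which to compute
#'   `wedge_fill`.
#' @return An object of class `"reorg_summary"`: list with `counts`
#'   (length `n_bins`), `breaks` (bin lower edges, degrees), `uniformity`
#'   in \[0, 1\], `wedge_fill` (`NA` without a lesion), `n_alive`, and
#'   `empty` (TRUE when no neuron is alive).
#' @export
pd_histogram <- function(pop, n_bins = 36, lesion = NULL) {
  stopifnot(inherits(pop, "population"))
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  pds <- pop$base_pd[pop$alive]
  breaks <- (seq_len(n_bins) - 1) * 360 / n_bins
  if (length(pds) == 0) {
    return(structure(
      list(
        counts = integer(n_bins), breaks = breaks, uniformity = NA_real_,
        wedge_fill = NA_real_, n_alive = 0L, empty = TRUE
      ),
      class = "reorg_summary"
    ))
  }
  idx <- floor(wrap_angle(pds) / (360 / n_bins)) + 1
  idx[idx > n_bins] <- n_bins # guard against 360-epsilon rounding
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / sum(counts)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  wedge_fill <- NA_real_
  if (!is.null(lesion)) {
    stopifnot(inherits(lesion, "lesion_spec"))
    inside <- abs(wrap_diff(pds - lesion$center)) <= lesion$fraction * 180
    wedge_fill <- mean(inside)
  }
  structure(
    list(
      counts = counts, breaks = breaks, uniformity = h / log(n_bins),
      wedge_fill = wedge_fill, n_alive = length(pds), empty = FALSE
    ),
    class = "reorg_summary"
  )
}

#' @export
print.reorg_summary <- function(x, ...) {
  if (x$empty) {
    cat("<reorg_summary> no alive neurons\n")
  } else {
    cat(sprintf(
      "<reorg_summary> %d alive neurons in %d bins; uniformity %.3f%s\n",
      x$n_alive, length(x$counts), x$uniformity,
      if (is.na(x$wedge_fill)) "" else sprintf(", wedge fill %.3f", x$wedge_fill)
    ))
  }
  invisible(x)
}

#' Evaluate unimanual reaching performance
#'
#' Runs `n_reps` noisy unimanual forward passes per target (no learning)
#' and reports the mean absolute angular error and mean PV norm with
#' Monte-Carlo standard errors. This is the behavioral readout used to
#' compare rehabilitation regimes: rehabilitation happens under a
#' movement condition, but patients are assessed reaching unimanually.
#'
#' @param pop A [population()].
#' @param targets Target angles, degrees (default the 8 standard targets).
#' @param n_reps Repetitions per target (>= 1).
#' @param noise A [noise_model()].
#' @param seed Seed for the evaluation draws.
#' @return A data frame of class `"direction_profile"` with columns
#'   `target`, `mean_abs_err`, `se_abs_err`, `mean_norm`, `se_norm`,
#'   `n_reps`.
#' @export
evaluate_unimanual <- function(pop, targets = STANDARD_TARGETS, n_reps = 200,
                               noise = noise_model(), seed = 1L) {
  stopifnot(inherits(pop, "population"), n_reps >= 1)
  uni <- condition("unimanual")
  pop <- realize_condition(pop, uni)
  rows <- local_rng(seed, {
    lapply(targets, function(tg) {
      errs <- numeric(n_reps)
      norms <- numeric(n_reps)
      m <- mean_activity(pop, uni, tg)
      for (r in seq_len(n_reps)) {
        a <- sample_activity(m, noise)
        pv <- population_vector(pop, a, uni)
        errs[r] <- abs(angular_error(pv$angle, tg))
        norms[r] <- pv$norm
      }
      data.frame(
        target = tg,
        mean_abs_err = mean(errs),
        se_abs_err = stats::sd(errs) / sqrt(n_reps),
        mean_norm = mean(norms),
        se_norm = stats::sd(norms) / sqrt(n_reps),
        n_reps = n_reps
      )
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("direction_profile", class(out))
  out
}
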