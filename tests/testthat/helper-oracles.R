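# Independent brute-force oracles, deliberately written without reusing
# the package's internals: plain loops and textbook formulas.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population vector by explicit per-neuron summation.
oracle_pv <- function(pds_deg, activities, alive, n_total) {
  x <- 0
  y <- 0
  for (i in seq_along(pds_deg)) {
    if (alive[i]) {
      x <- x + activities[i] * cos(pds_deg[i] * pi / 180)
      y <- y + activities[i] * sin(pds_deg[i] * pi / 180)
    }
  }
  x <- x / n_total
  y <- y / n_total
  list(
    x = x, y = y, norm = sqrt(x^2 + y^2),
    angle = (atan2(y, x) * 180 / pi) %% 360
  )
}

# Wedge membership by scanning every neuron with the raw rule.
oracle_wedge <- function(pds_deg, center, fraction) {
  out <- logical(length(pds_deg))
  for (i in seq_along(pds_deg)) {
    d <- (pds_deg[i] - center) %% 360
    if (d > 180) d <- d - 360
    out[i] <- abs(d) <= fraction * 180
  }
  out
}

# Circular binning by scanning bin edges.
oracle_bin_counts <- function(pds_deg, n_bins) {
  counts <- integer(n_bins)
  w <- 360 / n_bins
  for (pd in pds_deg %% 360) {
    for (b in seq_len(n_bins)) {
      if (pd >= (b - 1) * w && pd < b * w) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# Evaluate a sum of cosines directly on a grid of angles.
oracle_cosine_sum_curve <- function(amps, phases_deg, thetas_deg) {
  sapply(thetas_deg, function(th) {
    sum(amps * cos((th - phases_deg) * pi / 180))
  })
}

# A small config for fast simulation tests: fewer neurons and trials,
# coarse evaluation. Study-condition parameters (lesion, sigma, rates,
# noise) stay at package defaults.
small_config <- function(seed = 1L, n = 120L, n_trials = 400L) {
  cfg <- base_config()
  cfg$population$n <- n
  cfg$protocol$n_trials <- n_trials
  cfg$protocol$snapshots <- n_trials
  cfg$metrics$n_reps <- 5L
  cfg$seeds$population <- 100L + seed
  cfg$seeds$rotation <- 1000L + seed
  cfg$seeds$trials <- 2000L + seed
  cfg$seeds$evaluation <- 3000L + seed
  cfg
}

# Full-size config at the package's study conditions, with evaluation
# repetitions trimmed where standard errors are not under test.
paired_config <- function(seed, n_reps = 5L) {
  cfg <- base_config()
  cfg$metrics$n_reps <- n_reps
  cfg$seeds$population <- 100L + seed
  cfg$seeds$rotation <- 1000L + seed
  cfg$seeds$trials <- 2000L + seed
  cfg$seeds$evaluation <- 3000L + seed
  cfg
}

final_fill <- function(res) res$summaries$wedge_fill[res$summaries$state == "final"]
final_unif <- function(res) res$summaries$uniformity[res$summaries$state == "final"]
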