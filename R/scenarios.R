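# Scripted experiment scenarios: each one is the base rehabilitation
# protocol with one factor manipulated, so paired-seed comparisons
# isolate that factor.

SCENARIO_NAMES <- c(
  "unimanual", "bimanual_quenched", "depth_only", "enc_dec_rotation",
  "nonuniform_targets", "supervised_only", "unsupervised_only",
  "annealed_drift"
)

#' Default run configuration
#'
#' The nested configuration all experiments start from: a 500-neuron
#' equally spaced population, a wedge lesion centered at 90 degrees
#' depleting a quarter of the circle, proportional signal-dependent noise
#' `k = 0.1`, quenched rotation spread `sigma = 60` degrees for bimanual
#' regimes, and 3000 rehabilitation trials with snapshots at 1000, 2000,
#' 3000. See the package vignette for how each default was chosen.
#'
#' @return A nested list of class `"run_config"`.
#' @export
base_config <- function() {
  structure(
    list(
      population = list(n = 500L, layout = "spaced", depth = 1),
      lesion = list(center = 90, fraction = 0.25),
      condition = list(regime = "unimanual", sigma = 60, depth_sigma = 0.5),
      learning = list(
        eta_sup = 0.05, eta_unsup = 0.05, lam = 0.01, drift_sigma = 0,
        gradient_mode = "analytic", update_targets = "encoding_and_decoding"
      ),
      protocol = list(
        targets = STANDARD_TARGETS, target_probs = NULL,
        n_trials = 3000L, snapshots = c(1000L, 2000L, 3000L)
      ),
      noise = list(k = 0.1),
      metrics = list(n_bins = 36L, n_reps = 200L),
      seeds = list(
        population = 101L, rotation = 211L, trials = 307L, evaluation = 401L
      ),
      drift = list(sigma = 1)
    ),
    class = "run_config"
  )
}

# The three standard targets nearest the lesion center, for the
# nonuniform (restricted) target schedule.
restricted_targets <- function(center, targets = STANDARD_TARGETS, k = 3) {
  d <- abs(wrap_diff(targets - center))
  sort(targets[order(d)][seq_len(k)])
}

# Translate a scenario name into the (condition, learning, protocol)
# deltas it applies on top of the base configuration.
scenario_deltas <- function(name, config) {
  sig <- config$condition$sigma
  switch(name,
    unimanual = list(condition = condition("unimanual", seed = config$seeds$rotation)),
    bimanual_quenched = list(
      condition = condition("bimanual_quenched", sigma = sig, seed = config$seeds$rotation)
    ),
    depth_only = list(
      condition = condition("bimanual_depth_only",
        depth_sigma = config$condition$depth_sigma, seed = config$seeds$rotation
      )
    ),
    enc_dec_rotation = list(
      condition = condition("bimanual_enc_dec", sigma = sig, seed = config$seeds$rotation)
    ),
    nonuniform_targets = list(
      condition = condition("bimanual_quenched", sigma = sig, seed = config$seeds$rotation),
      targets = restricted_targets(config$lesion$center, config$protocol$targets)
    ),
    supervised_only = list(
      condition = condition("bimanual_quenched", sigma = sig, seed = config$seeds$rotation),
      learning = list(eta_unsup = 0)
    ),
    unsupervised_only = list(
      condition = condition("bimanual_quenched", sigma = sig, seed = config$seeds$rotation),
      learning = list(eta_sup = 0)
    ),
    annealed_drift = list(
      condition = condition("unimanual", seed = config$seeds$rotation),
      learning = list(drift_sigma = config$drift$sigma)
    ),
    stop(sprintf(
      "unknown scenario '%s'; expected one of: %s",
      name, paste(SCENARIO_NAMES, collapse = ", ")
    ), call. = FALSE)
  )
}

#' Run a named experiment scenario
#'
#' Builds the scenario's condition / learning / target-schedule deltas on
#' top of `config`, constructs and lesions the population, runs the full
#' rehabilitation course, and summarizes reorganization (circular
#' histogram, uniformity, lesion-wedge fill) and unimanual reaching
#' performance at each snapshot and at the end.
#'
#' Scenarios: `unimanual` (no PD rotation), `bimanual_quenched` (the
#' central manipulation: quenched encoding-PD rotations),
#' `depth_only` (modulation-depth change, no rotation),
#' `enc_dec_rotation` (encoding and decoding PDs rotated together),
#' `nonuniform_targets` (quenched rotations, schedule restricted to the
#' three targets nearest the lesion), `supervised_only` /
#' `unsupervised_only` (learning-rule ablations under quenched
#' rotations), `annealed_drift` (unimanual movement with Gaussian
#' synaptic drift in every update).
#'
#' @param name Scenario name; see above.
#' @param config A configuration from [base_config()], possibly modified.
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   snapshot population CSVs, `summary.json`, and the resolved
#'   configuration.
#' @return List with `trajectory`, `summaries` (data frame: one row per
#'   snapshot plus post-lesion baseline and final state, with
#'   `uniformity` and `wedge_fill`), `profiles` (named list of
#'   [evaluate_unimanual()] data frames, including `post_lesion`), the
#'   realized `condition`, `lesion`, and `scenario` name.
#' @export
run_scenario <- function(name, config = base_config(), out_dir = NULL) {
  name <- as.character(name)
  deltas <- scenario_deltas(name, config)

  pop <- population(
    n = config$population$n, layout = config$population$layout,
    depth = config$population$depth, seed = config$seeds$population
  )
  lesion <- lesion_spec(config$lesion$center, config$lesion$fraction)
  lesioned <- apply_lesion(pop, lesion)

  lc <- config$learning
  for (nm in names(deltas$learning)) lc[[nm]] <- deltas$learning[[nm]]
  cfg <- learning_config(
    eta_sup = lc$eta_sup, eta_unsup = lc$eta_unsup, lam = lc$lam,
    drift_sigma = lc$drift_sigma, gradient_mode = lc$gradient_mode,
    update_targets = lc$update_targets
  )
  targets <- if (!is.null(deltas$targets)) deltas$targets else config$protocol$targets
  proto <- protocol(
    targets = targets, target_probs = config$protocol$target_probs,
    n_trials = config$protocol$n_trials,
    snapshot_trials = config$protocol$snapshots,
    seed = config$seeds$trials
  )
  noise <- noise_model(config$noise$k)

  traj <- run_rehabilitation(lesioned, deltas$condition, proto, cfg, noise)

  states <- c(
    list(post_lesion = traj$initial),
    traj$snapshots,
    list(final = traj$final)
  )
  nb <- config$metrics$n_bins
  summaries <- do.call(rbind, lapply(names(states), function(nm) {
    h <- pd_histogram(states[[nm]], n_bins = nb, lesion = lesion)
    data.frame(
      state = nm, n_alive = h$n_alive,
      uniformity = h$uniformity, wedge_fill = h$wedge_fill
    )
  }))
  profiles <- lapply(states, function(st) {
    evaluate_unimanual(st,
      targets = STANDARD_TARGETS, n_reps = config$metrics$n_reps,
      noise = noise, seed = config$seeds$evaluation
    )
  })

  result <- list(
    scenario = name, trajectory = traj, summaries = summaries,
    profiles = profiles, condition = deltas$condition, lesion = lesion,
    config = config
  )
  if (!is.null(out_dir)) write_scenario(result, out_dir)
  result
}

#' Run a simulation directly from a configuration
#'
#' Unlike [run_scenario()], which applies a named manipulation on top of
#' the base configuration, this builds the condition, lesion, learning
#' rule, and protocol exactly as the configuration states them — any
#' regime, including `bimanual_annealed`.
#'
#' @param config A `"run_config"`, e.g. from [load_config()].
#' @param out_dir Optional output directory (same files as
#'   [run_scenario()]).
#' @return The same structure as [run_scenario()], with `scenario` set to
#'   the condition regime.
#' @export
run_simulation <- function(config = base_config(), out_dir = NULL) {
  pop <- population(
    n = config$population$n, layout = config$population$layout,
    depth = config$population$depth, seed = config$seeds$population
  )
  lesion <- lesion_spec(config$lesion$center, config$lesion$fraction)
  lesioned <- apply_lesion(pop, lesion)
  cond <- condition(
    regime = config$condition$regime,
    sigma = if (config$condition$regime == "unimanual") 0 else config$condition$sigma,
    depth_sigma = config$condition$depth_sigma,
    seed = config$seeds$rotation
  )
  cfg <- do.call(learning_config, config$learning)
  proto <- protocol(
    targets = config$protocol$targets, target_probs = config$protocol$target_probs,
    n_trials = config$protocol$n_trials,
    snapshot_trials = config$protocol$snapshots, seed = config$seeds$trials
  )
  traj <- run_rehabilitation(lesioned, cond, proto, cfg, noise_model(config$noise$k))
  states <- c(list(post_lesion = traj$initial), traj$snapshots, list(final = traj$final))
  summaries <- do.call(rbind, lapply(names(states), function(nm) {
    h <- pd_histogram(states[[nm]], n_bins = config$metrics$n_bins, lesion = lesion)
    data.frame(
      state = nm, n_alive = h$n_alive,
      uniformity = h$uniformity, wedge_fill = h$wedge_fill
    )
  }))
  result <- list(
    scenario = config$condition$regime, trajectory = traj,
    summaries = summaries, profiles = list(), condition = cond,
    lesion = lesion, config = config
  )
  if (!is.null(out_dir)) write_scenario(result, out_dir)
  result
}

# Persist a scenario result: trajectory files plus summary.json and the
# fully resolved configuration.
write_scenario <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory(result$trajectory, out_dir)
  summary <- list(
    scenario = result$scenario,
    summaries = result$summaries,
    profiles = lapply(result$profiles, function(p) as.data.frame(p))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows"
  )
  cfg <- result$config
  cfg$scenario <- result$scenario
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(out_dir)
}
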