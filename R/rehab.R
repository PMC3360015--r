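# The rehabilitation trial loop: draw a target, run the forward pass
# under the movement condition, score the reach, take one learning step.

STANDARD_TARGETS <- seq(0, 315, by = 45)

#' Rehabilitation protocol
#'
#' @param targets Target angles in degrees (default: the 8 standard
#'   radially distributed center-out targets, 0, 45, ..., 315).
#' @param target_probs Selection probabilities, aligned with `targets`
#'   (default uniform).
#' @param n_trials Number of rehabilitation trials.
#' @param snapshot_trials Trial indices at which to record a copy of the
#'   population (default 1000, 2000, 3000, clipped to `n_trials`).
#' @param seed Seed for the trial stream (target draws, activity noise,
#'   drift, annealed rotations).
#' @return An object of class `"protocol"`.
#' @export
protocol <- function(targets = STANDARD_TARGETS, target_probs = NULL,
                     n_trials = 3000, snapshot_trials = c(1000, 2000, 3000),
                     seed = 1L) {
  if (is.null(target_probs)) target_probs <- rep(1 / length(targets), length(targets))
  if (length(target_probs) != length(targets)) {
    stop("`target_probs` must align with `targets`", call. = FALSE)
  }
  if (any(target_probs < 0) || abs(sum(target_probs) - 1) > 1e-8) {
    stop("`target_probs` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(
    list(
      targets = wrap_angle(targets), target_probs = target_probs,
      n_trials = as.integer(n_trials),
      snapshot_trials = sort(unique(snapshot_trials[snapshot_trials <= n_trials])),
      seed = as.integer(seed)
    ),
    class = "protocol"
  )
}

#' Run a rehabilitation course
#'
#' Executes `protocol$n_trials` trials. Each trial draws a target from the
#' protocol distribution, computes the condition's encoding PDs (annealed
#' rotations are redrawn here every trial), samples noisy activities,
#' decodes the population vector with the condition's decoding PDs,
#' records the angular error and trial cost, and applies one
#' [learning_step()]. The whole course is a deterministic function of the
#' population, condition, configuration, and the protocol seed.
#'
#' @param pop A [population()] (typically already lesioned). The
#'   condition's quenched offsets are installed with
#'   [realize_condition()] before the first trial.
#' @param condition A [condition()].
#' @param proto A [protocol()].
#' @param cfg A [learning_config()].
#' @param noise A [noise_model()].
#' @return An object of class `"trajectory"`: list with `trials` (data
#'   frame: trial, target_deg, pv_angle_deg, pv_norm, err_deg, cost,
#'   rejected), `snapshots` (named list of populations at the requested
#'   trials), `initial`, `final`, and the run configuration.
#' @export
run_rehabilitation <- function(pop, condition, proto, cfg,
                               noise = noise_model()) {
  stopifnot(
    inherits(pop, "population"), inherits(condition, "condition"),
    inherits(proto, "protocol"), inherits(cfg, "learning_config")
  )
  pop <- realize_condition(pop, condition)
  initial <- pop
  n <- proto$n_trials
  rec <- list(
    trial = integer(n), target_deg = numeric(n), pv_angle_deg = numeric(n),
    pv_norm = numeric(n), err_deg = numeric(n), cost = numeric(n),
    rejected = logical(n)
  )
  snapshots <- list()
  annealed <- condition_regime(condition) == "bimanual_annealed"

  set.seed(proto$seed)
  for (t in seq_len(n)) {
    target <- proto$targets[
      sample.int(length(proto$targets), 1L, prob = proto$target_probs)
    ]
    if (annealed) {
      pop$rotation_offset <- resample_annealed_rotations(pop$n, condition$sigma)
    }
    m <- mean_activity(pop, condition, target)
    a <- sample_activity(m, noise)
    pv <- population_vector(pop, a, condition)
    err <- angular_error(pv$angle, target)
    cost <- trial_cost(pv$angle, target, ifelse(pop$alive, a, 0), cfg$lam)
    pop <- learning_step(pop, condition, target, a, cfg)

    rec$trial[t] <- t
    rec$target_deg[t] <- target
    rec$pv_angle_deg[t] <- if (pv$defined) pv$angle else NA_real_
    rec$pv_norm[t] <- pv$norm
    rec$err_deg[t] <- err
    rec$cost[t] <- cost
    rec$rejected[t] <- isTRUE(attr(pop, "rejected"))
    attr(pop, "rejected") <- NULL

    if (t %in% proto$snapshot_trials) {
      snapshots[[paste0("trial_", t)]] <- pop
    }
  }
  structure(
    list(
      trials = as.data.frame(rec),
      snapshots = snapshots,
      initial = initial,
      final = pop,
      condition = condition,
      protocol = proto,
      learning = cfg,
      noise = noise
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$trials)
  if (n > 0) {
    head_err <- mean(abs(x$trials$err_deg[seq_len(min(200, n))]))
    tail_err <- mean(abs(x$trials$err_deg[seq.int(max(1, n - 199), n)]))
    cat(sprintf(
      "<trajectory> %d trials (%s); mean |err| first 200: %.2f deg, last 200: %.2f deg\n",
      n, x$condition$regime, head_err, tail_err
    ))
  } else {
    cat("<trajectory> 0 trials\n")
  }
  invisible(x)
}

#' Write a trajectory to a directory
#'
#' Emits `trials.csv`, one `snapshot_trial_<t>.csv` population file per
#' snapshot, and `run.json` with the full configuration and package
#' version.
#'
#' @param traj A trajectory from [run_rehabilitation()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(traj$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  for (nm in names(traj$snapshots)) {
    write_population(
      traj$snapshots[[nm]],
      file.path(dir, paste0("snapshot_", nm, ".csv"))
    )
  }
  meta <- list(
    package = "bimanrehab",
    version = as.character(utils::packageVersion("bimanrehab")),
    condition = unclass(traj$condition),
    protocol = unclass(traj$protocol),
    learning = unclass(traj$learning),
    noise = unclass(traj$noise),
    n_neurons = traj$initial$n
  )
  jsonlite::write_json(meta, file.path(dir, "run.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
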