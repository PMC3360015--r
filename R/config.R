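# Configuration files and fixture generation. A run configuration is a
# nested list mirroring base_config(); it can be loaded from YAML,
# patched with dotted-path overrides, and is validated before any
# simulation starts.

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected, known keys override [base_config()]
#' defaults, and the merged configuration is validated.
#'
#' @param path Path to a YAML file whose top-level blocks are a subset of
#'   the blocks in [base_config()].
#' @param overrides Character vector of dotted-path overrides such as
#'   `"condition.sigma=30"`; applied after the file.
#' @return A validated `"run_config"` list.
#' @export
load_config <- function(path = NULL, overrides = character()) {
  config <- base_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    # keep short keys like `n` as strings (YAML 1.1 would read them as
    # booleans)
    user <- yaml::read_yaml(path, handlers = list(
      "bool#yes" = function(x) x, "bool#no" = function(x) x
    ))
    config <- merge_config(config, user, path = character())
  }
  for (ov in overrides) config <- apply_override(config, ov)
  validate_config(config)
}

merge_config <- function(base, user, path) {
  if (is.null(user)) {
    return(base)
  }
  if (!is.list(user)) {
    stop(sprintf(
      "config field '%s' must be a block, got a scalar",
      paste(path, collapse = ".")
    ), call. = FALSE)
  }
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(base)) {
      stop(sprintf("unknown config key '%s'", paste(here, collapse = ".")),
        call. = FALSE
      )
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

apply_override <- function(config, spec) {
  parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop(sprintf("override '%s' is not of the form path.key=value", spec),
      call. = FALSE
    )
  }
  keys <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
  value <- utils::type.convert(parts[2], as.is = TRUE)
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node)) {
      stop(sprintf("unknown config key '%s' in override '%s'", parts[1], spec),
        call. = FALSE
      )
    }
    node <- node[[k]]
  }
  config[[keys]] <- value
  config
}

# Range checks happen here once, before any simulation; the constructors
# re-check their own arguments.
validate_config <- function(config) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  check(config$population$n >= 1, "population.n must be >= 1")
  check(config$population$layout %in% c("spaced", "uniform"), "population.layout")
  check(all(config$population$depth >= 0), "population.depth must be >= 0")
  check(
    config$lesion$fraction >= 0 && config$lesion$fraction < 1,
    "lesion.fraction must lie in [0, 1)"
  )
  check(config$condition$regime %in% CONDITION_REGIMES, "condition.regime")
  check(config$condition$sigma >= 0, "condition.sigma must be >= 0")
  check(config$condition$depth_sigma >= 0, "condition.depth_sigma must be >= 0")
  with(config$learning, {
    check(eta_sup >= 0 && eta_unsup >= 0, "learning rates must be >= 0")
    check(lam >= 0, "learning.lam must be >= 0")
    check(drift_sigma >= 0, "learning.drift_sigma must be >= 0")
    check(
      gradient_mode %in% c("analytic", "finite_difference"),
      "learning.gradient_mode"
    )
    check(
      update_targets %in% c("encoding_only", "encoding_and_decoding"),
      "learning.update_targets"
    )
  })
  check(config$protocol$n_trials >= 0, "protocol.n_trials must be >= 0")
  if (!is.null(config$protocol$target_probs)) {
    check(
      length(config$protocol$target_probs) == length(config$protocol$targets),
      "protocol.target_probs must align with protocol.targets"
    )
    check(all(config$protocol$target_probs >= 0) &&
      abs(sum(config$protocol$target_probs) - 1) < 1e-8,
    "protocol.target_probs must be nonnegative and sum to 1"
    )
  }
  check(config$noise$k >= 0, "noise.k must be >= 0")
  check(config$metrics$n_bins >= 2, "metrics.n_bins must be >= 2")
  check(config$metrics$n_reps >= 1, "metrics.n_reps must be >= 1")
  check(config$drift$sigma >= 0, "drift.sigma must be >= 0")
  structure(config, class = "run_config")
}

#' Generate population fixtures
#'
#' Writes the small population CSVs used in tests and examples:
#' `two_neuron_worked_example` (encoding PDs 30 and 60 degrees, equal
#' depth — the population whose noiseless PV points at 45 degrees),
#' `uniform_intact` (equally spaced PDs), and `post_lesion`
#' (`uniform_intact` after the default wedge lesion).
#'
#' @param kind One of `"two_neuron_worked_example"`, `"uniform_intact"`,
#'   `"post_lesion"`.
#' @param out_path Output CSV path.
#' @param n Population size for the uniform kinds.
#' @return The written path, invisibly.
#' @export
make_fixture <- function(kind = c(
                           "two_neuron_worked_example", "uniform_intact",
                           "post_lesion"
                         ),
                         out_path, n = 8) {
  kind <- match.arg(kind)
  pop <- switch(kind,
    two_neuron_worked_example = population(base_pd = c(30, 60)),
    uniform_intact = population(n),
    post_lesion = apply_lesion(population(n), lesion_spec())
  )
  write_population(pop, out_path)
  invisible(out_path)
}
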