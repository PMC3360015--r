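# The cost function and the learning rule. Rehabilitation is modeled as
# stochastic gradient descent of
#
#   cost = err^2 + lambda * sum_i a_i^2
#
# over the base encoding PDs phi_i of the surviving neurons, where `err`
# is the wrapped angular error (degrees) between the population vector
# and the target and the second term is the metabolic (unsupervised)
# cost of the trial's activities. The supervised and unsupervised terms
# carry separate learning rates so either can be ablated exactly.

#' Learning configuration
#'
#' @param eta_sup Supervised learning rate (on the squared angular error,
#'   degree-scaled).
#' @param eta_unsup Unsupervised learning rate (on the metabolic term).
#' @param lam Regularization weight of the metabolic term in the cost.
#' @param drift_sigma Standard deviation, in degrees, of zero-mean
#'   Gaussian synaptic drift added to every update (0 disables it).
#' @param gradient_mode `"analytic"` (closed form, default) or
#'   `"finite_difference"` (central differences on the trial cost; slow,
#'   for verification).
#' @param update_targets `"encoding_and_decoding"` (default): the full
#'   gradient of the trial cost with respect to the base PDs. Because the
#'   decoding PDs are yoked to the base PDs, moving a PD changes both the
#'   neuron's tuning and its readout direction, and both paths belong to
#'   the gradient; only the full path is a descent direction for the
#'   cost. `"encoding_only"` drops the decoding-path term (the decoding
#'   unit vectors are held fixed within a step), for sensitivity
#'   analysis.
#' @return An object of class `"learning_config"`.
#' @export
learning_config <- function(eta_sup = 0.05, eta_unsup = 0.05, lam = 0.01,
                            drift_sigma = 0,
                            gradient_mode = c("analytic", "finite_difference"),
                            update_targets = c("encoding_and_decoding", "encoding_only")) {
  if (eta_sup < 0 || eta_unsup < 0) stop("learning rates must be >= 0", call. = FALSE)
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (drift_sigma < 0) stop("`drift_sigma` must be >= 0", call. = FALSE)
  structure(
    list(
      eta_sup = eta_sup, eta_unsup = eta_unsup, lam = lam,
      drift_sigma = drift_sigma,
      gradient_mode = match.arg(gradient_mode),
      update_targets = match.arg(update_targets)
    ),
    class = "learning_config"
  )
}

#' Signed angular error
#'
#' Wrapped difference `pv_angle - target` in (-180, 180]. An undefined PV
#' angle (zero norm) is treated as the maximal error of 180 degrees.
#'
#' @param pv_angle PV angle in degrees (`NA` when the PV norm is zero).
#' @param target Target angle in degrees.
#' @return Signed error in degrees.
#' @export
angular_error <- function(pv_angle, target) {
  ifelse(is.na(pv_angle), 180, wrap_diff(pv_angle - target))
}

#' Trial cost
#'
#' `angular_error^2 + lam * sum(activities^2)`: the supervised
#' (angular-error) term plus the unsupervised (metabolic) term.
#'
#' @param pv_angle PV angle in degrees (`NA` allowed, treated as maximal
#'   error).
#' @param target Target angle in degrees.
#' @param activities This trial's activities.
#' @param lam Regularization weight, >= 0.
#' @return Scalar cost (degrees squared for the first term).
#' @export
trial_cost <- function(pv_angle, target, activities, lam) {
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  angular_error(pv_angle, target)^2 + lam * sum(activities^2)
}

# Shared pieces of the analytic gradient. Returns, per neuron, the
# derivative of this trial's activity w.r.t. its own base PD (degrees),
# using subgradient 0 at both rectifier kinks, plus the PV partials.
trial_gradients <- function(pop, condition, target, activities) {
  enc <- encoding_pd(pop, condition)
  dep <- effective_depth(pop, condition)
  diff_rad <- deg2rad(target - enc)
  u <- dep * cos(diff_rad) # pre-rectification drive
  active <- pop$alive & u > 0 & activities > 0
  # a_i = rect(rect(u_i) + eps_i); d a_i / d phi_i in per-degree units
  da_dphi <- ifelse(active, dep * sin(diff_rad) * pi / 180, 0)

  psi <- deg2rad(decoding_pd(pop, condition))
  a <- ifelse(pop$alive, activities, 0)
  x <- sum(a * cos(psi)) / pop$n
  y <- sum(a * sin(psi)) / pop$n
  r2 <- x^2 + y^2
  # d pv_angle(deg) / d a_i
  dang_da <- if (r2 > 0) {
    rad2deg((x * sin(psi) - y * cos(psi)) / (pop$n * r2))
  } else {
    numeric(pop$n)
  }
  # d pv_angle(deg) / d psi_i(deg), for the decoding-path variant
  dang_dpsi <- if (r2 > 0) {
    a * (x * cos(psi) + y * sin(psi)) / (pop$n * r2)
  } else {
    numeric(pop$n)
  }
  list(
    da_dphi = da_dphi, dang_da = dang_da, dang_dpsi = dang_dpsi,
    x = x, y = y, r2 = r2
  )
}

# Analytic gradient of the trial cost w.r.t. each base PD (degrees),
# returned as its supervised and unsupervised components.
cost_gradient_analytic <- function(pop, condition, target, activities, cfg) {
  g <- trial_gradients(pop, condition, target, activities)
  pv_angle <- if (g$r2 > 0) wrap_angle(rad2deg(atan2(g$y, g$x))) else NA_real_
  err <- angular_error(pv_angle, target)
  derr_dphi <- g$dang_da * g$da_dphi
  if (cfg$update_targets == "encoding_and_decoding") {
    derr_dphi <- derr_dphi + ifelse(pop$alive, g$dang_dpsi, 0)
  }
  sup <- 2 * err * derr_dphi
  unsup <- cfg$lam * 2 * ifelse(pop$alive, activities, 0) * g$da_dphi
  list(supervised = sup, unsupervised = unsup)
}

# Finite-difference gradient of the full trial cost, holding the noise
# realization fixed: the additive noise on each rectified mean is
# recovered from (activity - mean) and re-applied after the PD
# perturbation. Respects `cfg$update_targets`: under `encoding_only` the
# decoding PDs stay at their pre-perturbation values, matching the
# analytic path. Used as the `finite_difference` gradient mode.
cost_gradient_fd <- function(pop, condition, target, activities, cfg,
                             h = 1e-5) {
  mean0 <- mean_activity(pop, condition, target)
  eps <- activities - mean0
  psi0 <- deg2rad(decoding_pd(pop, condition))
  cost_at <- function(phi) {
    p2 <- pop
    p2$base_pd <- wrap_angle(phi)
    m <- mean_activity(p2, condition, target)
    a <- pmax(m + eps, 0)
    a[!p2$alive] <- 0
    if (cfg$update_targets == "encoding_only") {
      x <- sum(a * cos(psi0)) / p2$n
      y <- sum(a * sin(psi0)) / p2$n
      ang <- if (x^2 + y^2 > 0) wrap_angle(rad2deg(atan2(y, x))) else NA_real_
    } else {
      pv <- population_vector(p2, a, condition)
      ang <- pv$angle
    }
    trial_cost(ang, target, a, cfg$lam)
  }
  grad <- numeric(pop$n)
  for (i in which(pop$alive)) {
    up <- pop$base_pd
    dn <- pop$base_pd
    up[i] <- up[i] + h
    dn[i] <- dn[i] - h
    grad[i] <- (cost_at(up) - cost_at(dn)) / (2 * h)
  }
  grad
}

#' One learning update
#'
#' Updates the base PDs of alive neurons by gradient descent on the trial
#' cost, evaluated at this trial's sampled activities (the same noise
#' realization that produced the movement), then adds Gaussian synaptic
#' drift if configured:
#' `phi_i <- phi_i - eta_sup * d(err^2)/d(phi_i)
#'                - eta_unsup * d(lam * sum a^2)/d(phi_i) + drift_i`.
#' Dead neurons, depths, and quenched offsets are never touched. A
#' nonfinite gradient rejects the step (the population is returned
#' unchanged with attribute `rejected = TRUE`).
#'
#' @param pop A [population()].
#' @param condition A [condition()].
#' @param target This trial's target, degrees.
#' @param activities This trial's sampled activities.
#' @param cfg A [learning_config()].
#' @return The updated population. Drift draws (if any) come from the
#'   current RNG stream.
#' @export
learning_step <- function(pop, condition, target, activities, cfg) {
  stopifnot(inherits(pop, "population"), inherits(cfg, "learning_config"))
  if (cfg$gradient_mode == "analytic") {
    g <- cost_gradient_analytic(pop, condition, target, activities, cfg)
    step <- cfg$eta_sup * g$supervised + cfg$eta_unsup * g$unsupervised
  } else {
    # Finite differences see the combined cost; the two rates must agree
    # for the split to be meaningful.
    full <- cost_gradient_fd(pop, condition, target, activities, cfg)
    step <- cfg$eta_sup * full
  }
  if (any(!is.finite(step))) {
    attr(pop, "rejected") <- TRUE
    return(pop)
  }
  delta <- -step
  if (cfg$drift_sigma > 0) {
    delta <- delta + stats::rnorm(pop$n, 0, cfg$drift_sigma)
  }
  pop$base_pd <- wrap_angle(pop$base_pd + ifelse(pop$alive, delta, 0))
  pop
}
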