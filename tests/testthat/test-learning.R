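test_that("zero learning rates and zero drift leave the population unchanged", {
  pop <- population(20)
  uni <- condition("unimanual")
  a <- mean_activity(pop, uni, 45)
  cfg <- learning_config(eta_sup = 0, eta_unsup = 0, drift_sigma = 0)
  out <- learning_step(pop, uni, 45, a, cfg)
  expect_identical(out$base_pd, pop$base_pd)
})

test_that("analytic gradient matches central finite differences on smooth configurations", {
  set.seed(42)
  for (mode in c("encoding_and_decoding", "encoding_only")) {
    worst <- 0
    for (rep in 1:20) {
      n <- sample(5:12, 1)
      pop <- population(base_pd = runif(n, 0, 360), depth = runif(n, 0.5, 2))
      cond <- condition("bimanual_quenched", sigma = 30, seed = rep)
      pop <- realize_condition(pop, cond)
      target <- runif(1, 0, 360)
      m <- mean_activity(pop, cond, target)
      a <- m + runif(n, 0.05, 0.2) # all sampled activities strictly positive
      cfg <- learning_config(
        eta_sup = 1, eta_unsup = 1, lam = 0.01,
        update_targets = mode
      )
      g <- bimanrehab:::cost_gradient_analytic(pop, cond, target, a, cfg)
      ana <- g$supervised + g$unsupervised
      # step 1e-4 keeps the difference quotient above roundoff on costs
      # of order err^2 ~ 1e4
      fd <- bimanrehab:::cost_gradient_fd(pop, cond, target, a, cfg, h = 1e-4)
      # relative to the gradient's largest component: near-zero entries
      # have no meaningful relative error of their own
      scale <- max(abs(fd), 1e-8)
      worst <- max(worst, abs(ana - fd) / scale)
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("a single neuron descends onto the target", {
  pop <- population(base_pd = 80)
  uni <- condition("unimanual")
  cfg <- learning_config(eta_sup = 0.05, eta_unsup = 0.05, lam = 0, drift_sigma = 0)
  pds <- numeric(40)
  costs <- numeric(40)
  for (i in 1:40) {
    a <- mean_activity(pop, uni, 90)
    pv <- population_vector(pop, a, uni)
    costs[i] <- trial_cost(pv$angle, 90, a, cfg$lam)
    pop <- learning_step(pop, uni, 90, a, cfg)
    pds[i] <- pop$base_pd
  }
  expect_true(all(diff(costs) <= 1e-12))
  expect_true(all(diff(abs(pds - 90)) <= 1e-12)) # monotone approach
  expect_lt(abs(pds[40] - 90), abs(80 - 90))
})

test_that("learning never resurrects dead neurons or touches depths and offsets", {
  cfg <- base_config()
  cfg$population$n <- 80L
  cfg$protocol$n_trials <- 150L
  cfg$metrics$n_reps <- 2L
  res <- run_scenario("bimanual_quenched", cfg)
  ini <- res$trajectory$initial
  fin <- res$trajectory$final
  expect_identical(fin$alive, ini$alive)
  expect_identical(fin$depth, ini$depth)
  expect_identical(fin$rotation_offset, ini$rotation_offset)
  expect_identical(fin$base_pd[!fin$alive], ini$base_pd[!ini$alive])
  expect_false(all(fin$base_pd[fin$alive] == ini$base_pd[ini$alive]))
})

test_that("each learning term can be ablated exactly", {
  set.seed(7)
  pop <- population(base_pd = runif(15, 0, 360))
  cond <- condition("bimanual_quenched", sigma = 40, seed = 2)
  pop <- realize_condition(pop, cond)
  a <- mean_activity(pop, cond, 90)
  g <- bimanrehab:::cost_gradient_analytic(
    pop, cond, 90, a, learning_config(lam = 0.01)
  )

  sup_only <- learning_step(pop, cond, 90, a,
    learning_config(eta_sup = 0.2, eta_unsup = 0, drift_sigma = 0)
  )
  expect_equal(sup_only$base_pd, wrap_angle(pop$base_pd - 0.2 * g$supervised))

  unsup_only <- learning_step(pop, cond, 90, a,
    learning_config(eta_sup = 0, eta_unsup = 0.2, drift_sigma = 0)
  )
  expect_equal(unsup_only$base_pd, wrap_angle(pop$base_pd - 0.2 * g$unsupervised))
})

test_that("finite-difference gradient mode takes the same step as the analytic mode", {
  pop <- population(12)
  cond <- condition("bimanual_quenched", sigma = 20, seed = 5)
  pop <- realize_condition(pop, cond)
  a <- mean_activity(pop, cond, 30)
  ana <- learning_step(pop, cond, 30, a,
    learning_config(eta_sup = 0.1, eta_unsup = 0.1, drift_sigma = 0)
  )
  fd <- learning_step(pop, cond, 30, a,
    learning_config(
      eta_sup = 0.1, eta_unsup = 0.1, drift_sigma = 0,
      gradient_mode = "finite_difference"
    )
  )
  expect_equal(fd$base_pd, ana$base_pd, tolerance = 1e-6)
})
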