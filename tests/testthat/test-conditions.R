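test_that("quenched rotations are pure in (n, sigma, seed) and match the stated law", {
  expect_identical(make_quenched_rotations(5, 0), rep(0, 5))
  a <- make_quenched_rotations(100, 30, seed = 3)
  b <- make_quenched_rotations(100, 30, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, make_quenched_rotations(100, 30, seed = 4)))

  big <- make_quenched_rotations(1e5, 30, seed = 1)
  expect_lt(abs(mean(big)), 0.5)
  expect_lt(abs(sd(big) - 30), 0.5)
})

test_that("annealed rotations are redrawn from the live stream", {
  expect_identical(resample_annealed_rotations(4, 0), rep(0, 4))
  set.seed(9)
  r1 <- resample_annealed_rotations(50, 30)
  r2 <- resample_annealed_rotations(50, 30)
  expect_false(any(r1 == r2))
  set.seed(10)
  longrun <- rowMeans(replicate(400, resample_annealed_rotations(20, 30)))
  expect_lt(max(abs(longrun)), 3 * 30 / sqrt(400) * 3)
})

test_that("depth factors are quenched, positive, and centered on 1", {
  expect_identical(make_depth_change(6, 0), rep(1, 6))
  f <- make_depth_change(200, 0.5, seed = 2)
  expect_identical(f, make_depth_change(200, 0.5, seed = 2))
  expect_true(all(f > 0))
  expect_false(any(f == 1))
  # depth-only condition perturbs depths but not PDs
  pop <- population(20)
  cond <- condition("bimanual_depth_only", depth_sigma = 0.5, seed = 2)
  pop <- realize_condition(pop, cond)
  expect_equal(encoding_pd(pop, cond), pop$base_pd)
  expect_false(all(mean_activity(pop, cond, 0) ==
    mean_activity(pop, condition("unimanual"), 0)))
})

test_that("condition constructor validates its arguments", {
  expect_error(condition("unimanual", sigma = 30), "sigma = 0")
  expect_error(condition("bimanual_quenched", sigma = -1), "nonnegative")
  expect_error(condition("not_a_regime"), "arg")
})

test_that("cosine_sum matches the analytic identity and a brute-force curve", {
  r <- cosine_sum(c(1, 1), c(0, 90))
  expect_equal(r$amplitude, sqrt(2))
  expect_equal(r$phase, 45)

  single <- cosine_sum(2.5, 123)
  expect_equal(single$amplitude, 2.5)
  expect_equal(single$phase, 123)

  expect_false(cosine_sum(c(1, 1), c(0, 180))$defined)

  set.seed(21)
  thetas <- 0:359
  for (rep in 1:20) {
    amps <- runif(5, -2, 2)
    phases <- runif(5, 0, 360)
    res <- cosine_sum(amps, phases)
    direct <- oracle_cosine_sum_curve(amps, phases, thetas)
    closed <- res$amplitude * cos((thetas - res$phase) * pi / 180)
    expect_lt(max(abs(direct - closed)), 1e-9)
  }
})

test_that("cosine_sum is associative up to numerical tolerance", {
  set.seed(22)
  amps <- runif(6, 0.2, 2)
  phases <- runif(6, 0, 360)
  whole <- cosine_sum(amps, phases)
  left <- cosine_sum(amps[1:3], phases[1:3])
  right <- cosine_sum(amps[4:6], phases[4:6])
  merged <- cosine_sum(c(left$amplitude, right$amplitude), c(left$phase, right$phase))
  expect_equal(merged$amplitude, whole$amplitude, tolerance = 1e-12)
  expect_lt(abs(wrap_diff(merged$phase - whole$phase)), 1e-9)
})
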