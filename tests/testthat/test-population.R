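test_that("population construction wraps, recycles, and validates", {
  pop <- population(8)
  expect_equal(pop$base_pd, seq(0, 315, by = 45))
  expect_true(all(pop$alive))
  expect_equal(pop$depth, rep(1, 8))

  pop2 <- population(base_pd = c(-10, 370, 720))
  expect_equal(pop2$base_pd, c(350, 10, 0))

  expect_error(population(base_pd = c(0, 90), depth = -1), "nonnegative")
  expect_error(population(), "supply")

  # uniform layout is reproducible in the seed
  u1 <- population(50, layout = "uniform", seed = 7)
  u2 <- population(50, layout = "uniform", seed = 7)
  expect_identical(u1$base_pd, u2$base_pd)
  expect_true(all(u1$base_pd >= 0 & u1$base_pd < 360))
})

test_that("encoding PDs follow the movement regime", {
  pop <- population(base_pd = c(10, 350), rotation_offset = c(30, 20))
  expect_equal(encoding_pd(pop, condition("unimanual")), c(10, 350))
  bi <- condition("bimanual_quenched", sigma = 30)
  expect_equal(encoding_pd(pop, bi), c(40, 10)) # additivity and wrap
  expect_equal(decoding_pd(pop, bi), c(10, 350)) # decoding not rotated
  ed <- condition("bimanual_enc_dec", sigma = 30)
  expect_equal(decoding_pd(pop, ed), c(40, 10))
  expect_error(encoding_pd(pop, "unimanual"), "condition")
})

test_that("mean activity is a rectified cosine scaled by depth", {
  pop <- population(base_pd = 0)
  uni <- condition("unimanual")
  expect_equal(mean_activity(pop, uni, 0), 1) # peak at PD
  expect_equal(mean_activity(pop, uni, 180), 0) # rectified
  expect_equal(mean_activity(pop, uni, 60), 0.5) # cos 60
  pop2 <- population(base_pd = c(0, 0), depth = c(2, 1), alive = c(TRUE, FALSE))
  expect_equal(mean_activity(pop2, uni, 0), c(2, 0)) # depth scales, dead silent
})

test_that("signal-dependent noise: zero-noise identity, silent stays silent, variance law", {
  m <- c(0, 0.5, 1)
  expect_identical(sample_activity(m, noise_model(k = 0)), m)
  set.seed(1)
  s <- sample_activity(c(0, 4), noise_model(k = 0.1))
  expect_identical(s[1], 0) # variance 0 at mean 0
  expect_error(noise_model(k = -1), "nonnegative")

  # Monte-Carlo check of variance = k * mean, on a mean large enough
  # that re-rectification is negligible
  k <- 0.1
  mu <- 4
  nrep <- 1e5
  set.seed(42)
  draws <- sample_activity(rep(mu, nrep), noise_model(k))
  v <- var(draws)
  se_v <- sqrt(2 / (nrep - 1)) * k * mu # SE of a normal-sample variance
  expect_lt(abs(v - k * mu), 3 * se_v)
  expect_true(all(draws >= 0))
})

test_that("population vector matches brute force and handles degeneracy", {
  uni <- condition("unimanual")
  # single alive neuron points along its decoding PD
  p1 <- population(base_pd = 90)
  pv1 <- population_vector(p1, 0.7, uni)
  expect_equal(pv1$angle, 90)

  # uniform 360-neuron population: PV angle hits all 8 standard targets,
  # norm identical across targets
  p360 <- population(360)
  norms <- sapply(seq(0, 315, by = 45), function(tg) {
    pv <- population_vector(p360, mean_activity(p360, uni, tg), uni)
    expect_lt(abs(wrap_diff(pv$angle - tg)), 1e-6)
    pv$norm
  })
  expect_lt(max(norms) - min(norms), 1e-6)

  # zero activity flags an undefined angle
  pv0 <- population_vector(p1, 0, uni)
  expect_false(pv0$defined)
  expect_true(is.na(pv0$angle))
  expect_equal(pv0$norm, 0)

  # brute-force agreement on random instances
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    pop <- population(
      base_pd = runif(n, 0, 360), depth = runif(n, 0, 2),
      alive = runif(n) > 0.2
    )
    a <- runif(n, 0, 2)
    pv <- population_vector(pop, a, uni)
    o <- oracle_pv(pop$base_pd, a, pop$alive, n)
    expect_equal(pv$x, o$x, tolerance = 1e-12)
    expect_equal(pv$y, o$y, tolerance = 1e-12)
    if (pv$defined) expect_equal(pv$angle, o$angle, tolerance = 1e-9)
  }
})

test_that("noiseless PV is rotationally equivariant", {
  uni <- condition("unimanual")
  set.seed(3)
  pop <- population(base_pd = runif(20, 0, 360), depth = runif(20, 0.5, 2))
  for (shift in c(13.7, 90, 201.3)) {
    tg <- 77
    pv0 <- population_vector(pop, mean_activity(pop, uni, tg), uni)
    pop2 <- pop
    pop2$base_pd <- wrap_angle(pop$base_pd + shift)
    pv1 <- population_vector(pop2, mean_activity(pop2, uni, tg + shift), uni)
    expect_lt(abs(wrap_diff(pv1$angle - (pv0$angle + shift))), 1e-9)
    expect_lt(abs(pv1$norm - pv0$norm), 1e-9)
  }
})

test_that("noisy PV of a uniform intact population is unbiased", {
  uni <- condition("unimanual")
  pop <- population(360)
  m <- mean_activity(pop, uni, 45)
  set.seed(5)
  angs <- replicate(1e4, {
    population_vector(pop, sample_activity(m, noise_model(0.1)), uni)$angle
  })
  deg <- angs * pi / 180
  circ_mean <- atan2(mean(sin(deg)), mean(cos(deg))) * 180 / pi
  expect_lt(abs(wrap_diff(circ_mean - 45)), 1)
})

test_that("fixed-N normalization: depth doubling doubles norm, half-kill halves it", {
  uni <- condition("unimanual")
  pop <- population(100)
  pv <- population_vector(pop, mean_activity(pop, uni, 30), uni)

  dbl <- population(100, depth = 2)
  pv2 <- population_vector(dbl, mean_activity(dbl, uni, 30), uni)
  expect_equal(pv2$norm, 2 * pv$norm, tolerance = 1e-12)

  half <- population(100, alive = rep(c(TRUE, FALSE), 50))
  pvh <- population_vector(half, mean_activity(half, uni, 30), uni)
  expect_equal(pvh$norm, pv$norm / 2, tolerance = 1e-3)
})

test_that("population CSV round-trips", {
  pop <- population(base_pd = c(30, 60, 200), depth = c(1, 2, 0.5),
                    rotation_offset = c(0, -10, 25), alive = c(TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(back$base_pd, pop$base_pd)
  expect_equal(back$rotation_offset, pop$rotation_offset)
  expect_equal(back$depth, pop$depth)
  expect_equal(back$alive, pop$alive)
})
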