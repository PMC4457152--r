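test_that("stationarity detection accepts constant and rejects drifting series", {
  mcs <- seq(0, 400, by = 4)
  const <- cbind(C = rep(0.4, length(mcs)), L = rep(0.6, length(mcs)))
  st <- is_stationary(fake_timeseries(mcs, const), window = 100, tol = 0.01)
  expect_true(st$stationary)
  expect_equal(st$onset_mcs, 200)        # earliest testable time
  expect_equal(st$stationary_since, 0)

  # linear drift of 0.1 per 100-MCS window exceeds tol = 0.01
  drift <- cbind(C = 0.1 + 0.001 * mcs, L = 0.9 - 0.001 * mcs)
  st <- is_stationary(fake_timeseries(mcs, drift), window = 100, tol = 0.01)
  expect_false(st$stationary)
  expect_true(is.na(st$onset_mcs))

  # too-short series is inconclusive, not FALSE
  short <- fake_timeseries(seq(0, 80, 4),
                           cbind(C = rep(0.5, 21), L = rep(0.5, 21)))
  expect_true(is.na(is_stationary(short, window = 100)$stationary))

  # drift that stops: onset after the bend, certified stretch begins there
  bent <- cbind(C = pmin(0.05 + 0.002 * mcs, 0.45))
  bent <- cbind(bent, L = 1 - bent)
  st <- is_stationary(fake_timeseries(mcs, bent), window = 100, tol = 0.01)
  expect_true(st$stationary)
  expect_gt(st$onset_mcs, 200)
  expect_equal(st$stationary_since, st$onset_mcs - 200)
})

test_that("a homogeneous start classifies trivially to that strategy", {
  cfg <- simulation_config("minimal_CLM", beta = 0.9, gamma = 1.5, L = 20,
                           max_mcs = 250, sample_every = 1,
                           relaxation_mcs = 150, seed = 5,
                           init = list(mode = "weighted_random",
                                       weights = c(C = 1)))
  pt <- classify_point(cfg, replicates = 2)
  expect_equal(pt$surviving, "C")
  expect_false(pt$unresolved)
  expect_equal(unname(pt$fractions[["C"]]), 1)
})

test_that("sweep over a single phase yields zero transitions", {
  base <- simulation_config("minimal_CLM", beta = 0.5, gamma = 1.5, L = 20,
                            max_mcs = 250, sample_every = 1,
                            relaxation_mcs = 150, seed = 5,
                            init = list(mode = "weighted_random",
                                        weights = c(C = 1)))
  pd <- sweep_phase("beta", c(0.4, 0.5, 0.6), base, replicates = 1)
  expect_equal(nrow(pd$transitions), 0)
  expect_equal(phase_sequence(pd), "C")
})

test_that("a sweep across the L/M crossover finds one midpoint transition", {
  base <- simulation_config("minimal_CLM", beta = 0.5, gamma = 1.5, L = 50,
                            max_mcs = 600, sample_every = 2,
                            relaxation_mcs = 400, seed = 8)
  pd <- sweep_phase("beta", c(0.5, 0.9), base, replicates = 3)
  expect_equal(phase_sequence(pd), c("C+L", "C+M"))
  expect_equal(nrow(pd$transitions), 1)
  expect_equal(pd$transitions$location, 0.7)
  expect_equal(pd$transitions$from, "C+L")
  expect_equal(pd$transitions$to, "C+M")
})

test_that("stationary_fraction returns zero dispersion for extinct strategies", {
  cfg <- simulation_config("minimal_CLM", beta = 0.5, gamma = 1.5, L = 20,
                           max_mcs = 200, sample_every = 1,
                           relaxation_mcs = 100, seed = 5,
                           init = list(mode = "weighted_random",
                                       weights = c(C = 1)))
  sf <- stationary_fraction(cfg, "M", replicates = 3)
  expect_equal(sf$mean, 0)
  expect_equal(sf$se, 0)
  expect_error(stationary_fraction(cfg, "O"), "strategy")
})

test_that("surviving set is independent of the initial arrangement", {
  # uniform random start and prepared stripes settle on the same phase
  for (beta in c(0.5, 0.9)) {
    uni <- simulation_config("minimal_CLM", beta = beta, gamma = 1.5, L = 60,
                             max_mcs = 800, sample_every = 2,
                             relaxation_mcs = 600, seed = 31)
    blk <- uni
    blk$init <- list(mode = "blocks")
    p_uni <- classify_point(uni, replicates = 3)
    p_blk <- classify_point(blk, replicates = 3)
    expect_setequal(p_uni$surviving, p_blk$surviving)
  }
})

test_that("pairwise invasion restricts dynamics to the two contestants", {
  cfg <- simulation_config("minimal_CLM", beta = 0.7, gamma = 1.5, L = 30,
                           max_mcs = 400, sample_every = 2,
                           relaxation_mcs = 300, seed = 17)
  res <- pairwise_invasion("L", "M", cfg, replicates = 3)
  expect_equal(res$outcome, "a_wins")
  expect_equal(res$point$surviving, "L")
  # C never appears: the dynamics only ever copies existing strategies
  expect_equal(unname(res$point$fractions[["C"]]), 0)
})
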