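base_cfg <- fast_config(duration = 96)
base_traj <- run_dfba(toy_net, config = base_cfg)

test_that("rss is zero on the truth and additive over observations", {
  obs <- generate_synthetic_observations(toy_net, config = base_cfg,
                                         noise_sd = 0, seed = 1)
  expect_equal(rss(base_traj, obs), 0, tolerance = 1e-12)
  i48 <- which.min(abs(base_traj$time_h - 48))
  one <- data.frame(time_h = base_traj$time_h[i48], variable = "biomass",
                    value_gL = base_traj$biomass[i48] + 1)
  expect_equal(rss(base_traj, one, weights = c(biomass = 1)), 1)
  two <- rbind(one, one)
  expect_equal(rss(base_traj, two, weights = c(biomass = 1)), 2)
  expect_error(rss(base_traj, transform(one, variable = "ethanol")),
               "unknown variable")
  expect_error(rss(base_traj, transform(one, time_h = 1e6)),
               "outside the trajectory")
})

test_that("aic matches the closed form and the inert-parameter penalty", {
  expect_equal(aic(2, 10, 10), 4)
  expect_equal(aic(8, 84, 84 * exp((300 - 16) / 84)), 300)
  set.seed(3)
  for (i in 1:200) {
    k <- sample(0:10, 1); n <- sample(1:500, 1); r <- runif(1, 1e-6, 1e3)
    expect_identical(aic(k, n, r), 2 * k + n * log(r / n))
  }
  # one extra parameter at unchanged RSS costs exactly 2
  expect_equal(aic(6, 84, 5) - aic(5, 84, 5), 2)
  expect_error(aic(1, 0, 1), "n must be")
  expect_error(aic(1, 10, 0), "rss must be")
})

test_that("synthetic observations are deterministic and well shaped", {
  obs <- generate_synthetic_observations(toy_net, config = base_cfg,
                                         variables = c("biomass",
                                                       "glucose",
                                                       "phosphate"),
                                         noise_sd = 0.02, seed = 42)
  # samples every 24 h on the inoculation clock, 3 variables
  expect_equal(nrow(obs), 3 * length(seq(24, 96 + 18, by = 24)))
  expect_true(all(obs$value_gL >= 0))
  obs2 <- generate_synthetic_observations(toy_net, config = base_cfg,
                                          variables = c("biomass",
                                                        "glucose",
                                                        "phosphate"),
                                          noise_sd = 0.02, seed = 42)
  expect_identical(obs, obs2)
  obs3 <- generate_synthetic_observations(toy_net, config = base_cfg,
                                          variables = "biomass",
                                          noise_sd = 0, seed = 1)
  sim <- approx(base_traj$time_h, base_traj$biomass, obs3$time_h)$y
  expect_equal(obs3$value_gL, sim, tolerance = 1e-12)
})

test_that("an empty free set echoes the base parameters with k = 0", {
  obs <- generate_synthetic_observations(toy_net, config = base_cfg,
                                         noise_sd = 0.01, seed = 1)
  fr <- fit_parameters(toy_net, kinetic_parameters(), free = list(),
                       obs = obs, config = base_cfg)
  expect_equal(fr$k, 0L)
  expect_equal(fr$n, nrow(obs))
  expect_equal(fr$aic, aic(0, nrow(obs), fr$rss))
})

test_that("fit is invariant to observation ordering", {
  obs <- generate_synthetic_observations(toy_net, config = base_cfg,
                                         noise_sd = 0.02, seed = 9)
  cfg_fit <- fast_config(duration = 96, dt = 0.2)
  f1 <- fit_parameters(toy_net, kinetic_parameters(),
                       free = list(v_Pe_max = c(0.02, 0.3)), obs = obs,
                       config = cfg_fit, seed = 4, n_starts = 1,
                       maxit = 40)
  f2 <- fit_parameters(toy_net, kinetic_parameters(),
                       free = list(v_Pe_max = c(0.02, 0.3)),
                       obs = obs[sample(nrow(obs)), ],
                       config = cfg_fit, seed = 4, n_starts = 1,
                       maxit = 40)
  expect_equal(f1$par$v_Pe_max, f2$par$v_Pe_max, tolerance = 1e-6)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-6)
})

test_that("a singly freed parameter is recovered from clean data", {
  cfg <- fast_config(duration = 96, dt = 0.25)
  truth <- kinetic_parameters(v_CIT = 0.09)
  obs <- generate_synthetic_observations(toy_net, truth, cfg,
                                         variables = c("biomass",
                                                       "phosphate",
                                                       "citrate"),
                                         noise_sd = 0, seed = 2)
  fr <- fit_parameters(toy_net, kinetic_parameters(),
                       free = list(v_CIT = c(0.03, 0.3)), obs = obs,
                       config = cfg, seed = 1, n_starts = 1)
  expect_equal(fr$par$v_CIT, 0.09, tolerance = 0.01)
  expect_equal(fr$k, 1L)
})
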