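test_that("a single step is exact Euler arithmetic on the pools", {
  cfg <- simulation_config(dt = 0.1, duration = 0.1, phosphate = 0.17,
                           glucose = 100)
  st <- acidflux:::initial_state(cfg)
  st2 <- dfba_step(st, toy_net, kinetic_parameters(), cfg)
  d <- attr(st2, "diag")
  B <- st$biomass; dt <- cfg$dt
  expect_equal(st$glucose - st2$glucose,
               dt * B * (d[["glc_flux"]] + d[["gox_flux"]]))
  expect_equal(st$phosphate - st2$phosphate, dt * B * d[["pie_flux"]])
  expect_equal(st2$stored_phosphate - st$stored_phosphate,
               dt * B * (d[["pstore_flux"]] - d[["pi_flux"]]))
  expect_equal(st2$biomass, B * (1 + d[["growth_rate"]] * dt))
  expect_equal(st2$t, st$t + dt)
})

test_that("a state without carbon or phosphate only advances the clock", {
  cfg <- simulation_config(dt = 0.1, duration = 0.1, glucose = 0,
                           phosphate = 0)
  st <- acidflux:::initial_state(cfg)
  st2 <- dfba_step(st, toy_net, kinetic_parameters(), cfg)
  expect_equal(st2$t, st$t + 0.1)
  expect_equal(st2$biomass, st$biomass)
  expect_equal(st2$glucose, st$glucose)
  expect_equal(unname(st2$acids), unname(st$acids))
})

test_that("zero duration returns only the initial state", {
  traj <- run_dfba(toy_net, config = simulation_config(duration = 0))
  expect_equal(nrow(traj), 1)
  expect_equal(traj$time_h, 18)
})

test_that("trajectories have the right shape and monotone pools", {
  traj <- run_dfba(toy_net, config = fast_config(duration = 96))
  expect_equal(nrow(traj), 96 / 0.1 + 1)
  expect_equal(diff(traj$t_sim), rep(0.1, nrow(traj) - 1),
               tolerance = 1e-9)
  expect_true(all(diff(traj$biomass) >= -1e-12))
  expect_true(all(diff(traj$glucose) <= 1e-12))
  expect_true(all(diff(traj$phosphate) <= 1e-12))
  for (a in acid_table()$name)
    expect_true(all(diff(traj[[a]]) >= -1e-12))
  # pH never rises: protons are only ever added
  expect_true(all(diff(traj$pH) <= 1e-12))
})

test_that("phosphate is stored during growth then released after", {
  traj <- run_dfba(toy_net, config = fast_config(duration = 96))
  pre <- traj$objective %in% "PHOSPHATE_STORAGE"
  expect_gt(sum(pre), 10)
  # during the storage phase P_e falls and the store fills
  i <- which(pre)[2:sum(pre)]
  expect_true(all(diff(traj$phosphate[i]) < 0))
  expect_true(all(diff(traj$stored_phosphate[i]) > 0))
})

test_that("citrate appears exactly at the diauxic switch", {
  traj <- run_dfba(toy_net, config = fast_config(duration = 96))
  sw <- diauxic_switch_time(traj)
  expect_false(is.na(sw))
  expect_true(all(traj$citric[traj$time_h < sw] == 0))
  expect_gt(max(traj$citric[traj$time_h > sw + 5]), 0)
  # more initial phosphate cannot switch earlier
  traj2 <- run_dfba(toy_net, config = fast_config(duration = 96,
                                                  phosphate = 0.34))
  expect_gte(diauxic_switch_time(traj2), sw)
})

test_that("a never-switching run reports no switch time", {
  traj <- run_dfba(toy_net, config = fast_config(duration = 5))
  expect_true(is.na(diauxic_switch_time(traj)))
  expect_error(diauxic_switch_time(traj[0, ]), "empty")
})

test_that("knockouts zero their acid trajectories", {
  cfg <- fast_config(duration = 96, initial_pH = 7,
                     knockouts = c("oah", "gox"))
  traj <- run_dfba(toy_net, config = cfg)
  expect_true(all(traj$oxalic == 0))
  expect_true(all(traj$gluconic == 0))
  # control at pH 7 does secrete gluconate early
  ctrl <- run_dfba(toy_net, config = fast_config(duration = 96,
                                                 initial_pH = 7))
  expect_gt(max(ctrl$gluconic), 0)
})

test_that("secretion caps are respected at every step", {
  traj <- run_dfba(toy_net, config = fast_config(duration = 96))
  ok <- is.finite(traj$citric_flux)
  expect_true(all(traj$citric_flux[ok] <= traj$cit_cap[ok] + 1e-9))
  expect_true(all(traj$oxalic_flux[ok] <= traj$oxa_cap[ok] + 1e-9))
  # oxalate shuts off strictly below pH 2 (fluxes in row k+1 are computed
  # at the step-start pH of row k)
  start_pH <- c(NA, traj$pH[-nrow(traj)])
  low <- ok & !is.na(start_pH) & start_pH < 2
  expect_true(all(traj$oxalic_flux[low] == 0))
})

test_that("per-step carbon and phosphorus balances close", {
  traj <- as.data.frame(run_dfba(toy_net,
                                 config = fast_config(duration = 48)))
  d <- traj[-1, ]
  bio <- acidflux:::biomass_demands(toy_net$biomass_composition)
  acid_c <- setNames(acid_table()$carbons, acid_table()$name)
  carbon_in <- 6 * d$glc_flux + 5 * d$xyl_flux
  carbon_out <- d$growth_rate * bio[["carbon"]] * toy_net$carbon_overhead
  for (a in names(acid_c))
    carbon_out <- carbon_out + acid_c[[a]] * d[[paste0(a, "_flux")]] -
      ifelse(a == "gluconic", acid_c[[a]] * d$gox_flux, 0)
  expect_lt(max(abs(carbon_in - carbon_out) /
                  pmax(1e-6, abs(carbon_in))), 1e-6)
  p_in <- d$pie_flux + d$pi_flux
  p_out <- d$growth_rate * bio[["phosphorus"]] + d$pstore_flux
  expect_lt(max(abs(p_in - p_out)), 1e-7)
})

test_that("halving dt converges at first order", {
  # assessed on the smooth early window: once threshold events (the
  # 150 g/L low-affinity switch, the diauxic switch) enter, their grid
  # quantisation adds an O(dt) sawtooth that makes single-endpoint
  # Richardson ratios oscillate even though the error still shrinks
  run_at <- function(dt) run_dfba(toy_net,
                                  config = simulation_config(
                                    dt = dt, duration = 16))
  t1 <- run_at(0.2); t2 <- run_at(0.1); t3 <- run_at(0.05)
  at <- function(traj, var) traj[[var]][nrow(traj)]
  orders <- vapply(c("biomass", "phosphate", "stored_phosphate"),
                   function(v) {
    e12 <- abs(at(t1, v) - at(t2, v))
    e23 <- abs(at(t2, v) - at(t3, v))
    if (e23 < 1e-12) return(1)
    log2(e12 / e23)
  }, numeric(1))
  expect_true(all(orders >= 0.8))
})

test_that("a dead culture terminates early with a reason", {
  cfg <- simulation_config(dt = 0.5, duration = 100, glucose = 0,
                           phosphate = 0)
  traj <- run_dfba(toy_net, config = cfg)
  expect_lt(nrow(traj), 100 / 0.5 + 1)
  expect_match(attr(traj, "stop_reason"), "24 h")
})
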