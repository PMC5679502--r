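# The dFBA engine: explicit-Euler time stepping of the external pools with
# a double-optimisation FBA solve at every step.
#
# Pools are tracked per litre of culture (mM; protons in mol/L; biomass in
# gDW/L), so the Euler update C <- C + dt * f * B holds with fluxes in
# mmol gDW^-1 h^-1.  Pool depletion is prevented *before* the LP: every
# uptake bound is additionally capped by pool/(B*dt), so the optimiser can
# never overdraw a pool within one step and the per-step mass balances
# close exactly.

#' Environment state of the culture
#'
#' @param t hours since the simulation (dFBA) start
#' @param biomass gDW/L (> 0)
#' @param glucose,xylose,phosphate,stored_phosphate mM
#' @param acids named numeric (mM) over the seven acids of [acid_table()]
#' @param H_e external proton concentration (mol/L)
#' @return object of class `environment_state`
#' @export
environment_state <- function(t = 0, biomass, glucose = 0, xylose = 0,
                              phosphate = 0, stored_phosphate = 0,
                              acids = NULL, H_e = 1e-2) {
  nm <- acid_table()$name
  if (is.null(acids)) acids <- setNames(numeric(7), nm)
  if (!setequal(names(acids), nm)) stop("acids must be named over: ",
                                        paste(nm, collapse = ", "))
  acids <- acids[nm]
  vals <- c(biomass, glucose, xylose, phosphate, stored_phosphate, acids)
  if (any(vals < 0)) stop("concentrations must be >= 0")
  if (biomass <= 0) stop("biomass must be > 0")
  if (H_e <= 0) stop("proton concentration must be > 0")
  structure(list(t = t, biomass = biomass, glucose = glucose,
                 xylose = xylose, phosphate = phosphate,
                 stored_phosphate = stored_phosphate, acids = acids,
                 H_e = H_e, pH = -log10(H_e)),
            class = "environment_state")
}

#' Simulation configuration
#'
#' Defaults reproduce the reference batch setup: time-step 1/60 h, the
#' simulation clock starting at spore germination (18 h after inoculation),
#' initial biomass 0.3125 g/L, and a glucose/phosphate medium at initial
#' pH 2.  Initial concentrations are given in g/L (phosphate as PO4) and
#' converted to mM internally.
#'
#' @param dt Euler time-step (h)
#' @param duration simulated hours (must be a multiple of `dt`)
#' @param start_offset hours between inoculation and the simulation start
#' @param initial_biomass gDW/L
#' @param initial_pH starting pH
#' @param glucose,xylose,phosphate,citrate initial concentrations (g/L)
#' @param knockouts character subset of `c("oah", "gox")`
#' @param delta relative growth-fixing slack of the second optimisation
#' @param seed integer seed (used by the fitting harness only)
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(dt = 1 / 60, duration = 192,
                              start_offset = 18, initial_biomass = 0.3125,
                              initial_pH = 2, glucose = 160, xylose = 0,
                              phosphate = 0.17, citrate = 0,
                              knockouts = character(), delta = 1e-6,
                              seed = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (duration < 0) stop("duration must be >= 0")
  n <- duration / dt
  if (abs(n - round(n)) > 1e-9) stop("duration must be a multiple of dt")
  if (initial_biomass <= 0) stop("initial biomass must be > 0")
  if (initial_pH <= 0 || initial_pH >= 14) stop("initial pH out of range")
  if (any(c(glucose, xylose, phosphate, citrate) < 0))
    stop("initial concentrations must be >= 0")
  bad <- setdiff(knockouts, c("oah", "gox"))
  if (length(bad)) stop("unknown knockout(s): ", paste(bad, collapse = ", "))
  structure(list(dt = dt, duration = duration, start_offset = start_offset,
                 initial_biomass = initial_biomass, initial_pH = initial_pH,
                 glucose = glucose, xylose = xylose, phosphate = phosphate,
                 citrate = citrate, knockouts = knockouts, delta = delta,
                 seed = seed),
            class = "simulation_config")
}

initial_state <- function(config) {
  acids <- setNames(numeric(7), acid_table()$name)
  acids[["citric"]] <- gl_to_mM(config$citrate, "citric")
  environment_state(
    t = 0, biomass = config$initial_biomass,
    glucose = gl_to_mM(config$glucose, "glucose"),
    xylose = gl_to_mM(config$xylose, "xylose"),
    phosphate = gl_to_mM(config$phosphate, "phosphate"),
    stored_phosphate = 0, acids = acids, H_e = 10^(-config$initial_pH))
}

# vectorised proton release over the seven acids
protons_released_all <- function(K, H_e) {
  t1 <- K[, 1] / H_e
  t2 <- K[, 1] * K[, 2] / H_e^2
  t3 <- K[, 1] * K[, 2] * K[, 3] / H_e^3
  (t1 + 2 * t2 + 3 * t3) / (1 + t1 + t2 + t3)
}

# everything the per-step solve needs, computed once per run
engine_context <- function(net, params, config) {
  net <- apply_knockout(net, config$knockouts)
  prob <- fba_problem(net)
  need <- c("biomass", "hpe", "pie", "pi", "pstore", "glc")
  miss <- need[vapply(prob$idx[need], is.na, TRUE)]
  if (length(miss))
    stop("network lacks tagged reaction(s) required by the engine: ",
         paste(miss, collapse = ", "))
  tab <- acid_table()
  K <- cbind(ifelse(is.na(tab$pKa1), 0, 10^-tab$pKa1),
             ifelse(is.na(tab$pKa2), 0, 10^-tab$pKa2),
             ifelse(is.na(tab$pKa3), 0, 10^-tab$pKa3))
  rownames(K) <- tab$name
  dis <- prob$dis[tab$name]
  if (anyNA(dis)) stop("network lacks dissociation reactions for all acids")
  gox_ko <- "gox" %in% config$knockouts ||
    (!is.na(prob$idx$gox) && prob$idx$gox > 0 &&
       prob$upper[prob$idx$gox] <= 0)
  list(prob = prob, K = K, dis = dis, gox_ko = gox_ko,
       base_upper = prob$upper, params = params, config = config)
}

# advance one Euler step; returns list(state, diag)
step_core <- function(ctx, state) {
  prob <- ctx$prob; params <- ctx$params; config <- ctx$config
  dt <- config$dt
  B <- state$biomass
  pH <- state$pH
  avail <- function(pool) pool / (B * dt)

  # proton coefficients of the dissociation reactions at step-start pH
  H <- protons_released_all(ctx$K, state$H_e)
  prob$S[prob$hp_row, ctx$dis] <- H

  # kinetic + availability-capped bounds
  ix <- prob$idx
  pie_cap <- min(phosphate_uptake(state$phosphate, params, t = state$t,
                                  initial_pH = config$initial_pH),
                 avail(state$phosphate), ctx$base_upper[ix$pie])
  prob$upper[ix$pie] <- pie_cap
  prob$upper[ix$pi] <- min(stored_phosphate_release(state$stored_phosphate,
                                                    params),
                           avail(state$stored_phosphate),
                           ctx$base_upper[ix$pi])
  glc_avail <- avail(state$glucose)
  v_gox <- 0
  if (!is.na(ix$gox)) {
    v_gox <- min(gox_rate(state$glucose, pH, params, ctx$gox_ko),
                 glc_avail, ctx$base_upper[ix$gox])
    prob$lower[ix$gox] <- v_gox
    prob$upper[ix$gox] <- v_gox
  }
  prob$upper[ix$glc] <- max(min(glucose_uptake(state$glucose,
                                               state$acids[["citric"]],
                                               params),
                                glc_avail - v_gox,
                                ctx$base_upper[ix$glc]), 0)
  if (!is.na(ix$xyl))
    prob$upper[ix$xyl] <- min(xylose_uptake(state$xylose, params),
                              avail(state$xylose), ctx$base_upper[ix$xyl])
  caps <- secretion_caps(config$initial_pH, pH, params)
  isec_cit <- prob$sec[["citric"]]; isec_oxa <- prob$sec[["oxalic"]]
  prob$upper[isec_cit] <- min(caps[["v_CIT_cap"]], ctx$base_upper[isec_cit])
  prob$upper[isec_oxa] <- min(caps[["v_OXAL_cap"]], ctx$base_upper[isec_oxa])

  sol <- double_optimize_prob(prob, pie_constraint = pie_cap,
                              delta = config$delta)
  v <- sol$fluxes
  v[abs(v) < 1e-11] <- 0           # simplex dust must not seed the pools
  mu <- v[[ix$biomass]]
  v_dis <- v[ctx$dis]

  clamp0 <- function(x) if (x < 0) { if (x < -1e-9) stop(
    "pool went negative despite availability caps") else 0 } else x
  acids <- state$acids + dt * B * unname(v_dis)
  state2 <- environment_state(
    t = state$t + dt,
    biomass = B * (1 + mu * dt),
    glucose = clamp0(state$glucose - dt * B * (v[[ix$glc]] + v_gox)),
    xylose = if (is.na(ix$xyl)) state$xylose else
      clamp0(state$xylose - dt * B * v[[ix$xyl]]),
    phosphate = clamp0(state$phosphate - dt * B * v[[ix$pie]]),
    stored_phosphate = clamp0(state$stored_phosphate +
                                dt * B * (v[[ix$pstore]] - v[[ix$pi]])),
    acids = acids,
    H_e = max(state$H_e + dt * B * sum(v_dis * H) / 1000, 1e-14))

  diag <- c(growth_rate = mu, secondary_value = sol$objective_value,
            pie_flux = v[[ix$pie]], pie_cap = pie_cap,
            pi_flux = v[[ix$pi]], pstore_flux = v[[ix$pstore]],
            glc_flux = v[[ix$glc]], gox_flux = v_gox,
            xyl_flux = if (is.na(ix$xyl)) 0 else v[[ix$xyl]],
            hpe_flux = v[[ix$hpe]],
            cit_cap = caps[["v_CIT_cap"]], oxa_cap = caps[["v_OXAL_cap"]],
            setNames(unname(v_dis), paste0(names(ctx$dis), "_flux")))
  list(state = state2, diag = diag,
       objective = attr(sol, "secondary"))
}

#' Advance the environment by one dFBA step
#'
#' Computes all kinetic constraints from the current state, rewrites the
#' proton coefficients of the acid-dissociation reactions at the current
#' pH, forces the glucose oxidase flux, runs the double optimisation, and
#' Euler-updates every tracked pool.
#'
#' @param state `environment_state`
#' @param net metabolic_network
#' @param params `kinetic_parameters`
#' @param config `simulation_config`
#' @return updated `environment_state` with attributes `diag` (named flux
#'   diagnostics) and `objective` (secondary objective used)
#' @export
dfba_step <- function(state, net, params = kinetic_parameters(),
                      config = simulation_config()) {
  ctx <- engine_context(net, params, config)
  res <- step_core(ctx, state)
  out <- res$state
  attr(out, "diag") <- res$diag
  attr(out, "objective") <- res$objective
  out
}

#' Run a batch fermentation simulation
#'
#' Runs `duration/dt` Euler steps from the configured initial state and
#' returns the trajectory, one row per step plus the initial state.  The
#' run terminates early (with a logged reason) if growth and the secondary
#' objective both stay at zero for 24 consecutive simulated hours.
#'
#' @param net metabolic_network (defaults to the bundled toy network)
#' @param params `kinetic_parameters`
#' @param config `simulation_config`
#' @return object of class `dfba_trajectory`: a data.frame with one row
#'   per time-point (`time_h` on the inoculation clock, `t_sim` on the
#'   simulation clock), pools, pH, growth rate, the objective in force and
#'   per-step flux diagnostics
#' @export
run_dfba <- function(net = make_toy_network(),
                     params = kinetic_parameters(),
                     config = simulation_config()) {
  ctx <- engine_context(net, params, config)
  state <- initial_state(config)
  n_steps <- round(config$duration / config$dt)
  acid_names <- acid_table()$name

  diag_names <- c("growth_rate", "secondary_value", "pie_flux", "pie_cap",
                  "pi_flux", "pstore_flux", "glc_flux", "gox_flux",
                  "xyl_flux", "hpe_flux", "cit_cap", "oxa_cap",
                  paste0(acid_names, "_flux"))
  pool_names <- c("t_sim", "biomass", "glucose", "xylose", "phosphate",
                  "stored_phosphate", acid_names, "H_e", "pH")
  M <- matrix(NA_real_, n_steps + 1,
              length(pool_names) + length(diag_names),
              dimnames = list(NULL, c(pool_names, diag_names)))
  objective <- rep(NA_character_, n_steps + 1)
  as_row <- function(s) c(s$t, s$biomass, s$glucose, s$xylose, s$phosphate,
                          s$stored_phosphate, unname(s$acids), s$H_e, s$pH)
  M[1, seq_along(pool_names)] <- as_row(state)

  zero_hours <- 0
  stop_reason <- NULL
  last <- n_steps + 1
  for (k in seq_len(n_steps)) {
    res <- step_core(ctx, state)
    state <- res$state
    M[k + 1, seq_along(pool_names)] <- as_row(state)
    M[k + 1, length(pool_names) + seq_along(diag_names)] <-
      res$diag[diag_names]
    objective[k + 1] <- res$objective
    if (res$diag[["growth_rate"]] < 1e-9 &&
        abs(res$diag[["secondary_value"]]) < 1e-9) {
      zero_hours <- zero_hours + config$dt
      if (zero_hours >= 24) {
        stop_reason <- sprintf(
          "terminated at t = %.2f h: growth and secondary objective zero for 24 h",
          state$t)
        last <- k + 1
        break
      }
    } else zero_hours <- 0
  }

  df <- as.data.frame(M[seq_len(last), , drop = FALSE])
  df$objective <- objective[seq_len(last)]
  df$time_h <- df$t_sim + config$start_offset
  df <- df[, c("time_h", setdiff(names(df), "time_h"))]
  structure(df, class = c("dfba_trajectory", "data.frame"),
            config = config, knockouts = config$knockouts,
            stop_reason = stop_reason)
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("dfba_trajectory:", nrow(x), "time-points, dt =",
      format(cfg$dt, digits = 4), "h\n")
  fin <- x[nrow(x), ]
  cat(sprintf("  final (t = %.1f h): biomass %.3f g/L, citrate %.2f g/L, pH %.2f\n",
              fin$time_h, fin$biomass, mM_to_gl(fin$citric, "citric"),
              fin$pH))
  sw <- diauxic_switch_time(x)
  cat("  diauxic switch:",
      if (is.na(sw)) "none" else sprintf("%.2f h (inoculation clock)", sw),
      "\n")
  if (!is.null(attr(x, "stop_reason")))
    cat(" ", attr(x, "stop_reason"), "\n")
  invisible(x)
}

#' Time of the diauxic switch
#'
#' First time-point at which the secondary objective is proton production,
#' reported on the inoculation clock.  `NA` if the trajectory never
#' switches.
#'
#' @param traj `dfba_trajectory`
#' @return hours (inoculation clock) or `NA`
#' @export
diauxic_switch_time <- function(traj) {
  if (nrow(traj) == 0) stop("empty trajectory")
  i <- which(traj$objective == "PROTON_PRODUCTION")[1]
  if (is.na(i)) return(NA_real_)
  traj$time_h[i]
}
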