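# Least-squares fitting of kinetic / biomass-composition parameters to
# observed fermentation time-series, and AIC-based model selection.

OBS_VARIABLES <- c(biomass = NA, glucose = "glucose", xylose = "xylose",
                   phosphate = "phosphate", citrate = "citric",
                   oxalate = "oxalic", gluconate = "gluconic")

# trajectory columns (g/L) for each observable variable
trajectory_observable <- function(traj, variable) {
  switch(variable,
         biomass = traj$biomass,
         glucose = mM_to_gl(traj$glucose, "glucose"),
         xylose = mM_to_gl(traj$xylose, "xylose"),
         phosphate = mM_to_gl(traj$phosphate, "phosphate"),
         citrate = mM_to_gl(traj$citric, "citric"),
         oxalate = mM_to_gl(traj$oxalic, "oxalic"),
         gluconate = mM_to_gl(traj$gluconic, "gluconic"),
         stop("unknown observable variable: ", variable))
}

#' Residual sum of squares of a trajectory against observations
#'
#' Simulated values are linearly interpolated at the observation times
#' (inoculation clock).  Because the variables mix units and scales, each
#' variable is weighted; the default weight is the inverse squared range of
#' its observed values (so every variable contributes on a comparable
#' scale), overridable per variable.
#'
#' @param traj `dfba_trajectory`
#' @param obs data.frame with columns `time_h`, `variable`, `value_gL`
#' @param weights optional named per-variable weights
#' @return weighted residual sum of squares
#' @export
rss <- function(traj, obs, weights = NULL) {
  unknown <- setdiff(unique(obs$variable), names(OBS_VARIABLES))
  if (length(unknown))
    stop("unknown variable(s) in observations: ",
         paste(unknown, collapse = ", "))
  if (any(obs$time_h < min(traj$time_h) - 1e-9 |
          obs$time_h > max(traj$time_h) + 1e-9))
    stop("observation times outside the trajectory range")
  total <- 0
  for (v in unique(obs$variable)) {
    o <- obs[obs$variable == v, ]
    sim <- approx(traj$time_h, trajectory_observable(traj, v),
                  xout = o$time_h, rule = 2)$y
    w <- if (!is.null(weights) && v %in% names(weights)) weights[[v]]
    else {
      r <- diff(range(o$value_gL))
      if (r > 0) 1 / r^2 else 1
    }
    total <- total + w * sum((sim - o$value_gL)^2)
  }
  total
}

#' Akaike information criterion
#'
#' `AIC = 2k + n * ln(RSS / n)`; no small-sample correction.
#'
#' @param k number of fitted parameters
#' @param n number of data-points
#' @param rss residual sum of squares (> 0)
#' @return AIC score
#' @export
aic <- function(k, n, rss) {
  if (n <= 0) stop("n must be > 0")
  if (rss <= 0) stop("rss must be > 0")
  2 * k + n * log(rss / n)
}

# apply named free-parameter values: kinetic parameters by name, biomass
# adjustment via the reserved names nucleic_acid_scale / phospholipid_scale
apply_free_params <- function(net, base_params, values) {
  adj <- intersect(names(values), c("nucleic_acid_scale",
                                    "phospholipid_scale"))
  kin <- setdiff(names(values), adj)
  params <- base_params
  for (nm in kin) {
    if (!nm %in% names(params)) stop("unknown free parameter: ", nm)
    params[[nm]] <- values[[nm]]
  }
  if (length(adj)) {
    s <- c(nucleic_acid_scale = 1, phospholipid_scale = 1)
    s[adj] <- unlist(values[adj])
    net <- apply_biomass_adjustment(net, s[["nucleic_acid_scale"]],
                                    s[["phospholipid_scale"]])
  }
  list(net = net, params = params)
}

#' Fit free parameters to observations
#'
#' Derivative-free bounded minimisation of [rss()] by multi-start
#' Nelder-Mead: parameters are mapped to the real line through a logistic
#' transform of their bounds, and `n_starts` seeded starting points (the
#' base value plus random draws) are polished independently.
#' Deterministic given `seed`.
#'
#' @param net metabolic_network
#' @param base_params `kinetic_parameters` baseline
#' @param free named list of `c(lower, upper)` bounds; names may be kinetic
#'   parameters or `nucleic_acid_scale` / `phospholipid_scale`
#' @param obs observations data.frame (`time_h`, `variable`, `value_gL`,
#'   and `scenario` when fitting several runs jointly)
#' @param config `simulation_config`, or a named list of them for a joint
#'   fit over several experimental scenarios (e.g. phosphate levels)
#' @param seed integer seed
#' @param n_starts number of Nelder-Mead starts
#' @param maxit iteration cap per start (exceeding it returns the best
#'   point so far with `budget_exceeded = TRUE`, never silently)
#' @param weights forwarded to [rss()]
#' @return object of class `fit_result`: fitted values, `k`, `n`, `rss`,
#'   `aic`, `budget_exceeded`
#' @export
fit_parameters <- function(net, base_params = kinetic_parameters(), free,
                           obs, config, seed = 1, n_starts = 2,
                           maxit = 200, weights = NULL) {
  k <- length(free)
  # `config` may be a named list of configurations (e.g. several initial
  # phosphate levels fitted jointly, as in a multi-level batch design);
  # observations then carry a `scenario` column naming their run
  configs <- if (inherits(config, "simulation_config")) list(config)
  else config
  if (length(configs) > 1) {
    if (is.null(obs$scenario))
      stop("multi-scenario fits need a `scenario` column in obs")
    if (!all(obs$scenario %in% names(configs)))
      stop("observation scenarios missing from the config list")
  }
  eval_values <- function(values) {
    mod <- apply_free_params(net, base_params, values)
    total <- 0
    for (i in seq_along(configs)) {
      o <- if (length(configs) > 1)
        obs[obs$scenario == names(configs)[i], ] else obs
      traj <- run_dfba(mod$net, mod$params, configs[[i]])
      total <- total + rss(traj, o, weights)
    }
    total
  }
  n <- nrow(obs)
  # a perfect (zero-RSS) fit has no finite AIC; report -Inf
  safe_aic <- function(k, n, r) if (r <= 0) -Inf else aic(k, n, r)
  if (k == 0) {
    r <- eval_values(list())
    return(structure(list(par = numeric(), k = 0L, n = n, rss = r,
                          aic = safe_aic(0, n, r),
                          budget_exceeded = FALSE),
                     class = "fit_result"))
  }
  lo <- vapply(free, `[`, numeric(1), 1)
  hi <- vapply(free, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("free parameter bounds must satisfy lower < upper")
  to_par <- function(theta) lo + (hi - lo) / (1 + exp(-theta))
  to_theta <- function(p) {
    f <- pmin(pmax((p - lo) / (hi - lo), 1e-6), 1 - 1e-6)
    log(f / (1 - f))
  }
  objective <- function(theta) {
    p <- as.list(to_par(theta))
    names(p) <- names(free)
    eval_values(p)
  }
  base_vals <- vapply(names(free), function(nm) {
    if (nm %in% c("nucleic_acid_scale", "phospholipid_scale")) 1
    else base_params[[nm]]
  }, numeric(1))
  base_vals <- pmin(pmax(base_vals, lo), hi)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  starts <- list(to_theta(base_vals))
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- to_theta(lo + (hi - lo) * runif(k, 0.1, 0.9))
  best <- NULL
  exceeded <- FALSE
  if (k == 1) {
    # 1-D objectives here are often flat once a cap stops binding, which
    # defeats plain golden-section search; scan a deterministic coarse
    # grid first, then refine inside the bracketing interval
    fgrid <- seq(0.02, 0.98, length.out = 12)
    tgrid <- log(fgrid / (1 - fgrid))
    vgrid <- vapply(tgrid, objective, numeric(1))
    ib <- which.min(vgrid)
    lo_t <- tgrid[max(ib - 1, 1)]
    hi_t <- tgrid[min(ib + 1, length(tgrid))]
    opt <- optim(tgrid[ib], objective, method = "Brent",
                 lower = lo_t, upper = hi_t,
                 control = list(maxit = maxit))
    if (opt$value > vgrid[ib]) opt <- list(par = tgrid[ib],
                                           value = vgrid[ib],
                                           convergence = 0)
    best <- opt
  } else {
    for (th0 in starts) {
      opt <- optim(th0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit))
      if (opt$convergence == 1) exceeded <- TRUE
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (exceeded)
    warning("optimizer budget exceeded; returning best point found")
  par <- setNames(as.list(to_par(best$par)), names(free))
  structure(list(par = par, k = as.integer(k), n = n, rss = best$value,
                 aic = safe_aic(k, n, best$value),
                 budget_exceeded = exceeded),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: k = %d, n = %d, RSS = %.6g, AIC = %.2f\n",
              x$k, x$n, x$rss, x$aic))
  if (x$k > 0)
    cat("  ", paste(names(x$par), format(unlist(x$par), digits = 5),
                    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Fit a set of model variants and rank them by AIC
#'
#' @param candidates named list; each element is a list with `free` (as in
#'   [fit_parameters()]) and optionally `net`, `params`, `config` overrides
#' @param obs observations
#' @param config default `simulation_config`
#' @param net default network
#' @param base_params default kinetic parameters
#' @param ... forwarded to [fit_parameters()]
#' @return data.frame ranked by ascending AIC (stable on ties) with the
#'   fit results in the `fit` list-column
#' @export
select_model <- function(candidates, obs, config, net = make_toy_network(),
                         base_params = kinetic_parameters(), ...) {
  if (length(candidates) < 2) stop("need at least two candidate variants")
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("variant", seq_along(candidates))
  fits <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    fit_parameters(net = if (!is.null(cand$net)) cand$net else net,
                   base_params = if (!is.null(cand$params)) cand$params
                   else base_params,
                   free = cand$free, obs = obs,
                   config = if (!is.null(cand$config)) cand$config
                   else config, ...)
  })
  out <- data.frame(variant = nm,
                    k = vapply(fits, `[[`, integer(1), "k"),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    stringsAsFactors = FALSE)
  ord <- order(out$aic)          # order() is stable: ties keep input order
  out <- out[ord, ]
  out$fit <- fits[ord]
  rownames(out) <- NULL
  out
}

#' Generate synthetic observations from a simulation
#'
#' Runs the engine, samples the requested variables every `interval` hours
#' on the inoculation clock (as in daily shake-flask sampling), adds seeded
#' Gaussian noise and floors at zero.
#'
#' @param net metabolic_network
#' @param params `kinetic_parameters`
#' @param config `simulation_config`
#' @param variables observable names (see [rss()])
#' @param noise_sd single fraction of each variable's trajectory maximum,
#'   or a named numeric of absolute standard deviations (g/L)
#' @param seed integer seed
#' @param interval sampling interval (h)
#' @param scenario optional scenario label attached to every row
#' @return observations data.frame (`time_h`, `variable`, `value_gL`, `sd`)
#' @export
generate_synthetic_observations <- function(net = make_toy_network(),
                                            params = kinetic_parameters(),
                                            config = simulation_config(),
                                            variables = c("biomass",
                                                          "glucose",
                                                          "phosphate",
                                                          "citrate"),
                                            noise_sd = 0.02, seed = 1,
                                            interval = 24,
                                            scenario = NULL) {
  if (any(unlist(noise_sd) < 0)) stop("noise_sd must be >= 0")
  traj <- run_dfba(net, params, config)
  tmax <- max(traj$time_h)
  times <- seq(interval * ceiling(min(traj$time_h) / interval), tmax,
               by = interval)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  out <- list()
  for (v in variables) {
    y <- approx(traj$time_h, trajectory_observable(traj, v),
                xout = times)$y
    sd_v <- if (length(noise_sd) == 1 && is.null(names(noise_sd)))
      noise_sd * max(trajectory_observable(traj, v))
    else if (v %in% names(noise_sd)) noise_sd[[v]]
    else stop("no noise_sd given for variable ", v)
    obs <- pmax(y + rnorm(length(y), 0, sd_v), 0)
    out[[v]] <- data.frame(time_h = times, variable = v, value_gL = obs,
                           sd = sd_v, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(scenario)) out$scenario <- scenario
  out
}
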