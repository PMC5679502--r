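# Flux balance analysis on a metabolic_network, and the double
# optimisation: maximise growth, then - at (almost) fixed growth - maximise
# either phosphate storage or proton production depending on whether the
# external phosphate influx saturated its kinetic constraint.

# precompute the LP skeleton once; the engine mutates bounds and the
# proton coefficients of the dissociation columns in place each step
fba_problem <- function(net) {
  S <- stoichiometric_matrix(net)
  rxn <- net$reactions
  idx <- list(
    biomass = reaction_by_tag(net, "BIOMASS"),
    hpe = reaction_by_tag(net, "PROTON_OUT"),
    pie = reaction_by_tag(net, "EXTERNAL_P_IN"),
    pi = reaction_by_tag(net, "STORED_P_IN"),
    pstore = reaction_by_tag(net, "STORAGE"),
    glc = reaction_by_tag(net, "GLUCOSE_EX"),
    xyl = reaction_by_tag(net, "XYLOSE_EX"),
    gox = reaction_by_tag(net, "GOX"),
    oah = reaction_by_tag(net, "OAH"))
  dis <- which(rxn$tag == "ACID_DISSOCIATION")
  sec <- which(rxn$tag == "ACID_SECRETION")
  list(S = S, lower = rxn$lower, upper = rxn$upper, ids = rxn$id,
       tags = setNames(rxn$tag, rxn$id), idx = idx,
       dis = setNames(dis, rxn$acid[dis]),
       sec = setNames(sec, rxn$acid[sec]),
       hp_row = match("hp", rownames(S)))
}

#' Flux bounds override
#'
#' Named lower/upper overrides of the network defaults for one solve.
#'
#' @param lower,upper named numeric vectors (names = reaction ids)
#' @return object of class `flux_bounds`
#' @export
flux_bounds <- function(lower = numeric(), upper = numeric()) {
  structure(list(lower = lower, upper = upper), class = "flux_bounds")
}

apply_bounds <- function(prob, bounds) {
  if (is.null(bounds)) return(prob)
  for (nm in names(bounds$lower)) {
    i <- match(nm, prob$ids)
    if (is.na(i)) stop("unknown reaction in bounds: ", nm)
    prob$lower[i] <- bounds$lower[[nm]]
  }
  for (nm in names(bounds$upper)) {
    i <- match(nm, prob$ids)
    if (is.na(i)) stop("unknown reaction in bounds: ", nm)
    prob$upper[i] <- bounds$upper[[nm]]
  }
  if (any(prob$lower > prob$upper + 1e-12))
    stop("flux bounds violate lower <= upper")
  prob
}

solve_problem <- function(prob, objective, maximize = TRUE) {
  n <- length(prob$ids)
  if (is.character(objective)) {
    c_vec <- numeric(n)
    i <- match(objective, prob$ids)
    if (is.na(i)) stop("objective reaction not in network: ", objective)
    c_vec[i] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    c_vec <- numeric(n)
    i <- match(names(objective), prob$ids)
    if (anyNA(i)) stop("objective names not in network")
    c_vec[i] <- objective
  } else stop("objective must be a reaction id or a named coefficient vector")
  res <- solve_lp(prob$S, numeric(nrow(prob$S)), c_vec,
                  prob$lower, prob$upper, maximize)
  structure(list(objective_value = res$objective,
                 fluxes = setNames(res$fluxes, prob$ids),
                 status = res$status),
            class = "flux_solution", tags = prob$tags)
}

#' Solve the flux balance LP
#'
#' Steady-state optimisation `max/min c'v` subject to `S v = 0` on the
#' balanced metabolites and the (possibly overridden) reaction bounds.
#' Infeasibility is reported in `status`, never silently zeroed.
#'
#' @param net metabolic_network
#' @param bounds optional [flux_bounds()] overrides
#' @param objective reaction id, or a named numeric vector of objective
#'   coefficients over reaction ids
#' @param sense `"maximize"` or `"minimize"`
#' @return `flux_solution` with `objective_value`, `fluxes`, `status`
#' @export
solve_fba <- function(net, bounds = NULL, objective,
                      sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  prob <- apply_bounds(fba_problem(net), bounds)
  solve_problem(prob, objective, maximize = sense == "maximize")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, "objective =",
      format(x$objective_value, digits = 8), "\n")
  invisible(x)
}

#' Secondary-objective decision rule
#'
#' If the external phosphate influx of the growth-maximising solution lies
#' strictly below its kinetic constraint (with relative tolerance `tol`),
#' there is spare uptake capacity and the second optimisation stores the
#' surplus (`PHOSPHATE_STORAGE`); otherwise growth is phosphate-limited and
#' the second optimisation maximises proton production
#' (`PROTON_PRODUCTION`).
#'
#' @param sol `flux_solution` from the growth optimisation
#' @param pie_constraint external phosphate uptake bound used in that solve
#' @param tol relative tolerance on the comparison
#' @param atol absolute tolerance guard: once the uptake capacity itself is
#'   at numerical zero (an exponentially depleted pool), the relative test
#'   is meaningless and the state counts as phosphate-limited
#' @return `"PHOSPHATE_STORAGE"` or `"PROTON_PRODUCTION"`
#' @export
choose_secondary_objective <- function(sol, pie_constraint, tol = 1e-6,
                                       atol = 1e-9) {
  if (pie_constraint < 0) stop("pie_constraint must be >= 0")
  tags <- attr(sol, "tags")
  pie_id <- names(tags)[tags == "EXTERNAL_P_IN"]
  if (length(pie_id) != 1 || !pie_id %in% names(sol$fluxes))
    stop("solution carries no external phosphate input flux")
  v <- sol$fluxes[[pie_id]]
  if (v < pie_constraint * (1 - tol) - atol) "PHOSPHATE_STORAGE"
  else "PROTON_PRODUCTION"
}

#' Double optimisation: growth first, then the phosphate/proton objective
#'
#' Step 1 maximises the biomass reaction with the storage reaction closed
#' (so that surplus phosphate uptake cannot mask the growth demand).
#' Step 2 fixes growth at `mu_max * (1 - delta)` as a lower bound and
#' maximises the secondary objective chosen by
#' [choose_secondary_objective()]: net phosphate storage (storage flux
#' minus stored-phosphate release) or proton output.  If step 2 is
#' infeasible at the tight slack it is retried once with `delta_retry`,
#' then errors.
#'
#' @param net metabolic_network
#' @param bounds optional [flux_bounds()] including all kinetic constraints
#' @param pie_constraint external phosphate uptake bound in force
#' @param delta relative growth-fixing slack
#' @param delta_retry relaxed slack used on one retry
#' @param tol tolerance of the decision boolean
#' @return `flux_solution` of step 2 with attributes `secondary`
#'   (objective used) and `mu_max` (step-1 growth)
#' @export
double_optimize <- function(net, bounds = NULL, pie_constraint,
                            delta = 1e-6, delta_retry = 1e-3, tol = 1e-6) {
  prob <- apply_bounds(fba_problem(net), bounds)
  double_optimize_prob(prob, pie_constraint, delta, delta_retry, tol)
}

# internal fast path used by the engine (problem already built)
double_optimize_prob <- function(prob, pie_constraint, delta = 1e-6,
                                 delta_retry = 1e-3, tol = 1e-6) {
  ib <- prob$idx$biomass; ip <- prob$idx$pstore
  if (is.na(ib)) stop("network has no BIOMASS-tagged reaction")
  p1 <- prob
  if (!is.na(ip)) { p1$lower[ip] <- 0; p1$upper[ip] <- 0 }
  sol1 <- solve_problem(p1, prob$ids[ib])
  if (sol1$status != "optimal")
    stop("growth optimisation not optimal: ", sol1$status)
  mu_max <- sol1$objective_value
  secondary <- choose_secondary_objective(sol1, pie_constraint, tol)

  p2 <- prob
  if (secondary == "PHOSPHATE_STORAGE") {
    obj <- setNames(c(1, -1), prob$ids[c(ip, prob$idx$pi)])
    if (is.na(ip)) stop("network has no STORAGE-tagged reaction")
  } else {
    ih <- prob$idx$hpe
    if (is.na(ih)) stop("network has no PROTON_OUT-tagged reaction")
    obj <- setNames(1, prob$ids[ih])
    if (!is.na(ip)) { p2$lower[ip] <- 0; p2$upper[ip] <- 0 }
  }
  for (d in c(delta, delta_retry)) {
    p2$lower[ib] <- max(mu_max * (1 - d), 0)
    sol2 <- solve_problem(p2, obj)
    if (sol2$status == "optimal") {
      attr(sol2, "secondary") <- secondary
      attr(sol2, "mu_max") <- mu_max
      return(sol2)
    }
  }
  stop("secondary optimisation infeasible even at relaxed growth slack")
}
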