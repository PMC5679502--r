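# Time-dependent flux constraints: Michaelis-Menten uptake kinetics for
# phosphate, glucose (with non-competitive citrate inhibition and a
# low-affinity system active only at very high glucose), xylose, the forced
# extracellular glucose oxidase flux, and the conditional secretion caps.

# molar masses (g/mol) used for every g/L <-> mM conversion
MOLAR_MASS <- c(glucose = 180.16, xylose = 150.13, citric = 192.12,
                oxalic = 90.03, gluconic = 196.16, acetic = 60.05,
                malic = 134.09, succinic = 118.09, lactic = 90.08,
                phosphate = 94.97)

gl_to_mM <- function(gl, species) gl / MOLAR_MASS[[species]] * 1000
mM_to_gl <- function(mM, species) mM * MOLAR_MASS[[species]] / 1000

# the low-affinity sugar transport systems switch on at 150 g/L
GLUCOSE_LOWAFF_mM <- 150 / MOLAR_MASS[["glucose"]] * 1000   # 832.6 mM
XYLOSE_LOWAFF_mM  <- 150 / MOLAR_MASS[["xylose"]]  * 1000   # 999.1 mM

#' Kinetic parameter set
#'
#' All rates in mmol gDW^-1 h^-1, Michaelis and inhibition constants in mM.
#' The defaults are the calibrated batch-fermentation values: transport
#' kinetics for the high/low-affinity glucose systems and glucose oxidase
#' come from the enzymological literature; phosphate uptake/release, passive
#' diffusion coefficients, xylose transport, the GOX enzyme loading and the
#' citrate/oxalate secretion caps are fitted values.  Conditional variants:
#' the external phosphate uptake capacity drops 8 h after the simulation
#' start (to `pie_after_8h_pH2` when the culture starts at pH <= 2, else
#' `pie_after_8h_pH7`), and the citrate secretion cap is `v_CIT_high_pH`
#' instead of `v_CIT` when the initial pH is above 2.
#'
#' @param ... overrides of individual parameters by name
#' @return object of class `kinetic_parameters`
#' @export
kinetic_parameters <- function(...) {
  p <- list(
    # phosphate (fitted)
    v_Pe_max = 0.08, K_Pe = 0.0333,
    v_P_max = 0.0008, K_P = 0.0833,
    # glucose: passive (fitted) + facilitated (literature)
    v_G1 = 0.00031419,
    v_G2_max = 0.186, K_G2 = 0.26, K_i2 = 933,
    v_G3_max = 2.706, K_G3 = 3.67, K_i3 = 233.21,
    # xylose (fitted)
    v_X1 = 0.00033,
    v_X2_max = 0.2, K_X2 = 3.33,
    v_X3_max = 2.5, K_X3 = 3.33,
    # glucose oxidase: v_GOX_max = v_GOX_coef * GOX_conc (literature rate
    # per mg of enzyme, fitted enzyme loading in mg gDW^-1)
    v_GOX_coef = 27.48, K_GOX = 33, GOX_conc = 0.1,
    # secretion caps (fitted)
    v_CIT = 0.12, v_OXAL = 0.01,
    # conditional variants
    pie_after_8h_pH2 = 0.015, pie_after_8h_pH7 = 0.004,
    v_CIT_high_pH = 0.016,
    pie_switch_time = 8)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  vals <- unlist(p)
  if (any(vals < 0)) stop("kinetic parameters must be >= 0")
  km <- c("K_Pe", "K_P", "K_G2", "K_G3", "K_X2", "K_X3", "K_GOX",
          "K_i2", "K_i3")
  if (any(unlist(p[km]) <= 0)) stop("Michaelis constants must be > 0")
  structure(p, class = "kinetic_parameters")
}

#' External phosphate uptake rate constraint
#'
#' Michaelis-Menten in the external phosphate concentration.  From 8 h
#' after the simulation start the maximum rate is replaced by the
#' conditional value keyed to the initial pH.
#'
#' @param P_e external phosphate (mM)
#' @param params `kinetic_parameters`
#' @param t hours since the simulation (dFBA) start
#' @param initial_pH culture starting pH (selects the post-8 h rate)
#' @return uptake bound (mmol gDW^-1 h^-1)
#' @export
phosphate_uptake <- function(P_e, params = kinetic_parameters(), t = 0,
                             initial_pH = 2) {
  if (any(P_e < 0)) stop("phosphate concentration must be >= 0")
  vmax <- if (t >= params$pie_switch_time) {
    if (initial_pH > 2) params$pie_after_8h_pH7 else params$pie_after_8h_pH2
  } else params$v_Pe_max
  vmax * P_e / (params$K_Pe + P_e)
}

#' Stored (polyphosphate) phosphate release rate constraint
#'
#' @param P stored phosphate (mM, per litre of culture)
#' @param params `kinetic_parameters`
#' @return release bound (mmol gDW^-1 h^-1)
#' @export
stored_phosphate_release <- function(P, params = kinetic_parameters()) {
  if (any(P < 0)) stop("stored phosphate must be >= 0")
  params$v_P_max * P / (params$K_P + P)
}

#' Glucose uptake rate constraint
#'
#' Passive diffusion plus citrate-inhibited facilitated transport.  The
#' low-affinity system contributes only while external glucose is at or
#' above 150 g/L (re-evaluated every call).  The inhibition factor
#' multiplies both the Michaelis and the substrate term of the denominator,
#' as the transport model is stated.
#'
#' @param G external glucose (mM)
#' @param C external citrate (mM)
#' @param params `kinetic_parameters`
#' @return uptake bound (mmol gDW^-1 h^-1)
#' @export
glucose_uptake <- function(G, C = 0, params = kinetic_parameters()) {
  if (any(G < 0) || any(C < 0)) stop("concentrations must be >= 0")
  i2 <- 1 + C / params$K_i2
  v <- params$v_G1 * G +
    params$v_G2_max * G / (params$K_G2 * i2 + G * i2)
  hi <- G >= GLUCOSE_LOWAFF_mM
  if (any(hi)) {
    i3 <- 1 + C / params$K_i3
    v[hi] <- v[hi] +
      (params$v_G3_max * G / (params$K_G3 * i3 + G * i3))[hi]
  }
  v
}

#' Xylose uptake rate constraint
#'
#' @param X external xylose (mM)
#' @param params `kinetic_parameters`
#' @return uptake bound (mmol gDW^-1 h^-1)
#' @export
xylose_uptake <- function(X, params = kinetic_parameters()) {
  if (any(X < 0)) stop("concentrations must be >= 0")
  v <- params$v_X1 * X + params$v_X2_max * X / (params$K_X2 + X)
  hi <- X >= XYLOSE_LOWAFF_mM
  if (any(hi))
    v[hi] <- v[hi] + (params$v_X3_max * X / (params$K_X3 + X))[hi]
  v
}

#' Proportion of active glucose oxidase as a function of pH
#'
#' Quadratic activity profile clamped to `[0, 1]`; the raw polynomial is
#' negative below pH ~2.2 and must never yield a negative rate.
#'
#' @param pH ambient pH
#' @return active fraction in `[0, 1]`
#' @export
p_gox <- function(pH) {
  pmin(pmax(-0.102 * pH^2 + 1.082 * pH - 1.95, 0), 1)
}

#' Forced extracellular glucose oxidase flux
#'
#' @param G external glucose (mM)
#' @param pH ambient pH
#' @param params `kinetic_parameters`
#' @param gox_knocked_out if `TRUE` the rate is identically zero
#' @return forced flux (mmol gDW^-1 h^-1)
#' @export
gox_rate <- function(G, pH, params = kinetic_parameters(),
                     gox_knocked_out = FALSE) {
  if (any(G < 0)) stop("glucose concentration must be >= 0")
  if (gox_knocked_out) return(0 * G)
  vmax <- params$v_GOX_coef * params$GOX_conc
  p_gox(pH) * vmax * G / (params$K_GOX + G)
}

#' Conditional secretion caps for citrate and oxalate
#'
#' The citrate output cap depends on the *initial* culture pH (0.12 at or
#' below pH 2, 0.016 above); the oxalate cap is 0.01 but forced to zero
#' whenever the *current* pH is strictly below 2 (oxalate production is
#' absent under strongly acidic conditions).
#'
#' @param initial_pH culture starting pH
#' @param current_pH ambient pH at this time-step
#' @param params `kinetic_parameters`
#' @return named numeric `c(v_CIT_cap =, v_OXAL_cap =)`
#' @export
secretion_caps <- function(initial_pH, current_pH,
                           params = kinetic_parameters()) {
  if (initial_pH <= 0 || initial_pH >= 14 ||
      current_pH <= 0 || current_pH >= 14)
    stop("pH values must lie in (0, 14)")
  cit <- if (initial_pH > 2) params$v_CIT_high_pH else params$v_CIT
  oxa <- if (current_pH < 2) 0 else params$v_OXAL
  c(v_CIT_cap = cit, v_OXAL_cap = oxa)
}
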