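# Polyprotic acid dissociation chemistry and the dynamic proton pool.
#
# The number of protons released per mole of secreted acid at ambient
# proton concentration H_e follows from the equilibrium speciation of a
# (up to tri-) protic acid with stepwise dissociation constants K1 >= K2
# >= K3:
#
#   H = (K1/H + 2 K1K2/H^2 + 3 K1K2K3/H^3) /
#       (1 + K1/H  +  K1K2/H^2  +  K1K2K3/H^3)
#
# Absent sites are encoded as K = 0 and contribute nothing.

#' Acid species
#'
#' @param name acid name
#' @param pKa1,pKa2,pKa3 stepwise pKa values; `NA` for absent sites
#' @param carbon_count carbons per molecule
#' @return object of class `acid_species` with fields `K1`, `K2`, `K3`
#' @export
acid_species <- function(name, pKa1, pKa2 = NA, pKa3 = NA, carbon_count) {
  K <- vapply(c(pKa1, pKa2, pKa3),
              function(p) if (is.na(p)) 0 else 10^(-p), numeric(1))
  if (K[2] > 0 && K[1] < K[2]) stop("successive pKa values must increase")
  if (K[3] > 0 && K[2] < K[3]) stop("successive pKa values must increase")
  structure(list(name = name, K1 = K[1], K2 = K[2], K3 = K[3],
                 carbon_count = as.integer(carbon_count)),
            class = "acid_species")
}

acid_species_row <- function(tab, i) {
  acid_species(tab$name[i], tab$pKa1[i], tab$pKa2[i], tab$pKa3[i],
               tab$carbons[i])
}

#' Dissociation constants of the seven secreted acids
#'
#' @return data.frame with columns `name`, `pKa1`, `pKa2`, `pKa3`, `carbons`
#' @export
acid_table <- function() {
  data.frame(
    name    = c("citric", "oxalic", "gluconic", "acetic", "malic",
                "succinic", "lactic"),
    pKa1    = c(3.128, 1.252, 3.7, 4.757, 3.459, 4.207, 3.86),
    pKa2    = c(4.761, 4.266, NA, NA, 5.097, 5.636, NA),
    pKa3    = c(6.396, NA, NA, NA, NA, NA, NA),
    carbons = c(6L, 2L, 6L, 2L, 4L, 4L, 3L),
    stringsAsFactors = FALSE)
}

#' Protons released per mole of secreted acid
#'
#' @param acid `acid_species`
#' @param H_e external proton concentration (molar); vectorised
#' @return moles of protons released per mole of acid, in `[0, 3]`
#' @export
protons_released <- function(acid, H_e) {
  if (any(H_e <= 0)) stop("proton concentration must be > 0")
  k1 <- acid$K1; k2 <- acid$K2; k3 <- acid$K3
  t1 <- k1 / H_e
  t2 <- k1 * k2 / H_e^2
  t3 <- k1 * k2 * k3 / H_e^3
  (t1 + 2 * t2 + 3 * t3) / (1 + t1 + t2 + t3)
}

#' Protons released per carbon secreted
#'
#' Diagnostic for the acidification-efficiency hierarchy: which acid buys
#' the most medium acidification per unit of carbon diverted from growth.
#'
#' @param acid `acid_species`
#' @param pH ambient pH in (0, 14)
#' @return protons per carbon (dimensionless)
#' @export
acidification_efficiency <- function(acid, pH) {
  if (any(pH <= 0 | pH >= 14)) stop("pH must lie in (0, 14)")
  protons_released(acid, 10^(-pH)) / acid$carbon_count
}

#' External proton pool
#'
#' @param pH initial pH, or give `H_e` directly (molar)
#' @param H_e molar proton concentration
#' @return object of class `proton_pool`
#' @export
proton_pool <- function(pH = NULL, H_e = NULL) {
  if (is.null(H_e)) {
    if (is.null(pH)) stop("give either pH or H_e")
    H_e <- 10^(-pH)
  }
  if (H_e <= 0) stop("proton concentration must be > 0")
  structure(list(H_e = H_e, pH = -log10(H_e)), class = "proton_pool")
}

#' Advance the proton pool by one Euler step
#'
#' Adds `dt * biomass * sum(flux_a * H_a(pH)) / 1000` mol/L of protons,
#' where `H_a` is evaluated at the step-start pH (explicit Euler).  Acid
#' fluxes are in mmol per gDW per hour, hence the factor 1000.
#'
#' @param pool `proton_pool`
#' @param fluxes named non-negative acid-dissociation fluxes
#'   (mmol gDW^-1 h^-1); names must match [acid_table()] acids
#' @param biomass gDW per litre
#' @param dt time-step (h)
#' @return updated `proton_pool`
#' @export
update_proton_pool <- function(pool, fluxes, biomass, dt) {
  if (any(fluxes < 0)) stop("dissociation fluxes must be >= 0")
  tab <- acid_table()
  unknown <- setdiff(names(fluxes), tab$name)
  if (length(unknown))
    stop("unknown acid(s): ", paste(unknown, collapse = ", "))
  rate <- 0
  for (a in names(fluxes)) {
    i <- match(a, tab$name)
    rate <- rate + fluxes[[a]] * protons_released(acid_species_row(tab, i),
                                                  pool$H_e)
  }
  proton_pool(H_e = pool$H_e + dt * biomass * rate / 1000)
}
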