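#' @useDynLib acidflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx optim rnorm runif setNames
#' @importFrom utils modifyList read.delim write.table read.csv write.csv
NULL

# recognised reaction role tags; STORAGE marks the explicit polyphosphate
# storage reaction (the paired counterpart of STORED_P_IN)
REACTION_TAGS <- c("BIOMASS", "PROTON_OUT", "STORED_P_IN", "EXTERNAL_P_IN",
                   "GLUCOSE_EX", "XYLOSE_EX", "ACID_SECRETION",
                   "ACID_DISSOCIATION", "GOX", "OAH", "STORAGE", "OTHER")

ACID_NAMES <- c("citric", "oxalic", "gluconic", "acetic", "malic",
                "succinic", "lactic")

# mass fraction of carbon / phosphorus per gram of each biomass class
BIOMASS_CLASSES <- c("protein", "carbohydrate", "lipid", "nucleic_acid",
                     "glycerol", "other")
CLASS_CARBON_FRAC <- c(protein = 0.530, carbohydrate = 0.444, lipid = 0.650,
                       nucleic_acid = 0.340, glycerol = 0.391, other = 0)
CLASS_PHOSPHORUS_FRAC <- c(protein = 0, carbohydrate = 0, lipid = 0.040,
                           nucleic_acid = 0.095, glycerol = 0, other = 0)
MW_CARBON <- 12.011
MW_PHOSPHORUS <- 30.974

#' Construct a stoichiometric metabolic network
#'
#' A `metabolic_network` bundles a metabolite table, a reaction table, the
#' full stoichiometric matrix and (optionally) a biomass composition in mass
#' fractions (g per gDW).  Metabolites in the `"external"` compartment are
#' boundary species: they are tracked as dynamic pools by the dFBA engine
#' and excluded from the steady-state mass-balance rows of the FBA problem.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of `"external"`, `"cytosol"`, `"mitochondrion"`), `carbon_count`.
#' @param reactions data.frame with columns `id`, `lower`, `upper`,
#'   `reversible`, `tag`, `acid` (acid name for `ACID_*` tags, else `NA`).
#' @param S stoichiometric matrix, metabolites x reactions (signed;
#'   consumed negative, produced positive).
#' @param biomass_composition named numeric of mass fractions over
#'   `r paste(BIOMASS_CLASSES, collapse = ", ")`; must sum to 1.
#' @param carbon_overhead total carbon consumed by the biomass reaction per
#'   carbon incorporated into biomass (>= 1); the excess is respired to CO2.
#' @return object of class `metabolic_network`
#' @export
metabolic_network <- function(metabolites, reactions, S,
                              biomass_composition = NULL,
                              carbon_overhead = 1) {
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        S = S, biomass_composition = biomass_composition,
                        carbon_overhead = carbon_overhead),
                   class = "metabolic_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  met <- net$metabolites; rxn <- net$reactions; S <- net$S
  if (anyDuplicated(met$id)) stop("metabolite ids must be unique")
  if (anyDuplicated(rxn$id)) stop("reaction ids must be unique")
  if (!all(met$carbon_count >= 0)) stop("carbon counts must be non-negative")
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    stop("stoichiometric matrix dimensions inconsistent with tables")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    stop("stoichiometric matrix dimnames must match metabolite/reaction ids")
  bad <- rxn$lower > rxn$upper + 1e-12
  if (any(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rxn$id[bad], collapse = ", "))
  bad <- !rxn$reversible & rxn$lower < -1e-12
  if (any(bad))
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(rxn$id[bad], collapse = ", "))
  if (!all(rxn$tag %in% REACTION_TAGS))
    stop("unknown reaction tag(s): ",
         paste(setdiff(rxn$tag, REACTION_TAGS), collapse = ", "))
  solo <- setdiff(REACTION_TAGS, c("OTHER", "ACID_SECRETION",
                                   "ACID_DISSOCIATION"))
  for (tg in solo)
    if (sum(rxn$tag == tg) > 1) stop("tag ", tg, " appears more than once")
  for (tg in c("ACID_SECRETION", "ACID_DISSOCIATION")) {
    a <- rxn$acid[rxn$tag == tg]
    if (anyDuplicated(a))
      stop("duplicate ", tg, " for acid(s): ",
           paste(unique(a[duplicated(a)]), collapse = ", "))
  }
  if (!is.null(net$biomass_composition)) {
    bc <- net$biomass_composition
    if (!setequal(names(bc), BIOMASS_CLASSES))
      stop("biomass composition must cover classes: ",
           paste(BIOMASS_CLASSES, collapse = ", "))
    if (abs(sum(bc) - 1) > 1e-9)
      stop("biomass composition mass fractions must sum to 1")
    if (any(bc < 0)) stop("biomass composition fractions must be >= 0")
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  tg <- table(x$reactions$tag)
  cat("  tags:", paste(names(tg), tg, sep = "=", collapse = " "), "\n")
  if (!is.null(x$biomass_composition))
    cat("  biomass composition:",
        paste(names(x$biomass_composition),
              sprintf("%.3f", x$biomass_composition), collapse = " "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of the balanced (non-external) metabolites
#'
#' @param net metabolic_network
#' @param balanced_only drop rows for boundary (external) species
#' @return numeric matrix, metabolites x reactions
#' @export
stoichiometric_matrix <- function(net, balanced_only = TRUE) {
  if (!balanced_only) return(net$S)
  net$S[net$metabolites$compartment != "external", , drop = FALSE]
}

reaction_by_tag <- function(net, tag, acid = NULL) {
  sel <- net$reactions$tag == tag
  if (!is.null(acid)) sel <- sel & !is.na(net$reactions$acid) &
      net$reactions$acid == acid
  idx <- which(sel)
  if (length(idx) == 0) return(NA_integer_)
  idx[1]
}

# mmol of carbon / phosphorus per gDW implied by a biomass composition
biomass_demands <- function(composition) {
  carbon <- sum(composition * CLASS_CARBON_FRAC[names(composition)]) /
    MW_CARBON * 1000
  phosphorus <- sum(composition * CLASS_PHOSPHORUS_FRAC[names(composition)]) /
    MW_PHOSPHORUS * 1000
  c(carbon = carbon, phosphorus = phosphorus)
}

# rewrite the BIOMASS column from the composition metadata
rebuild_biomass_reaction <- function(net) {
  ib <- reaction_by_tag(net, "BIOMASS")
  if (is.na(ib)) stop("network has no BIOMASS-tagged reaction")
  dem <- biomass_demands(net$biomass_composition)
  cons <- dem[["carbon"]] * net$carbon_overhead
  col <- numeric(nrow(net$metabolites))
  names(col) <- net$metabolites$id
  col["c1"] <- -cons
  col["p"] <- -dem[["phosphorus"]]
  col["co2_e"] <- cons - dem[["carbon"]]
  net$S[, ib] <- col
  net
}

#' Bundled toy stoichiometric network
#'
#' A deterministic, hand-checkable stand-in for a genome-scale fungal
#' network.  Carbon flows through a single internal carbon-unit currency
#' (`c1`, one carbon per unit): glucose contributes 6 units per mmol,
#' xylose 5.  Phosphate enters from the external pool (`PIE`) or from the
#' stored polyphosphate pool (`PI`), and can be banked into storage
#' (`PSTORE`).  Biomass consumes carbon units (with a fixed respiratory
#' overhead released as CO2) plus phosphate according to the biomass
#' composition.  Each of the seven organic acids has a secretion reaction
#' (carbon units to the undissociated acid) paired with a dissociation
#' reaction that releases the acid to the medium together with a
#' pH-dependent number of protons; the proton-output reaction `HPE`
#' exports those protons and is the objective when maximising proton
#' production.  Oxalate is produced via the OAH-tagged oxaloacetate
#' hydrolase reaction; gluconate is produced extracellularly by the
#' GOX-tagged glucose oxidase reaction whose flux the engine forces.
#'
#' The wild-type fixture only opens secretion of the three acids this
#' organism secretes in batch fermentation (citric, oxalic, gluconic); the
#' four minor acids (acetic, malic, succinic, lactic) carry complete
#' secretion/dissociation machinery but default secretion bounds of zero.
#'
#' @param dissociation_pH reference pH used for the baseline proton
#'   coefficients of the dissociation reactions (the engine rewrites them
#'   every time-step from the dynamic pH).
#' @return metabolic_network
#' @export
make_toy_network <- function(dissociation_pH = 7) {
  acid_carbons <- c(citric = 6, oxalic = 2, gluconic = 6, acetic = 2,
                    malic = 4, succinic = 4, lactic = 3)
  met <- data.frame(
    id = c("glc_e", "xyl_e", "pi_e", "pstor", "h_e", "co2_e",
           paste0(c("cit", "oxa", "glcn", "ace", "mal", "suc", "lac"), "_e"),
           "c1", "p", "hp", "oxa_c",
           paste0(c("cit", "oxa", "glcn", "ace", "mal", "suc", "lac"), "_u")),
    name = c("glucose (external)", "xylose (external)",
             "phosphate (external)", "stored phosphate (polyphosphate pool)",
             "protons (external)", "carbon dioxide (external)",
             paste(ACID_NAMES, "acid (external, dissociated)"),
             "carbon unit", "phosphate (internal)",
             "protons from acid dissociation", "oxalate (cytosolic)",
             paste(ACID_NAMES, "acid (undissociated)")),
    compartment = c(rep("external", 13), rep("cytosol", 11)),
    carbon_count = c(6, 5, 0, 0, 0, 1, unname(acid_carbons),
                     1, 0, 0, 2, unname(acid_carbons)),
    stringsAsFactors = FALSE)

  composition <- c(protein = 0.42, carbohydrate = 0.40, lipid = 0.03,
                   nucleic_acid = 0.02, glycerol = 0.05, other = 0.08)
  overhead <- 5  # 4 carbons respired per carbon fixed into biomass

  ac <- acid_table()
  hdefault <- vapply(seq_len(nrow(ac)), function(i)
    protons_released(acid_species_row(ac, i), 10^(-dissociation_pH)),
    numeric(1))
  names(hdefault) <- ac$name

  rx <- list()
  add <- function(id, stoich, lower = 0, upper = 1000, reversible = FALSE,
                  tag = "OTHER", acid = NA_character_) {
    rx[[length(rx) + 1]] <<- list(id = id, stoich = stoich, lower = lower,
                                  upper = upper, reversible = reversible,
                                  tag = tag, acid = acid)
  }
  add("EX_GLC", c(glc_e = -1, c1 = 6), tag = "GLUCOSE_EX")
  add("EX_XYL", c(xyl_e = -1, c1 = 5), tag = "XYLOSE_EX")
  add("PIE", c(pi_e = -1, p = 1), tag = "EXTERNAL_P_IN")
  add("PI", c(pstor = -1, p = 1), tag = "STORED_P_IN")
  add("PSTORE", c(p = -1, pstor = 1), tag = "STORAGE")
  add("BIOMASS", c(c1 = -1, p = -1, co2_e = 1), tag = "BIOMASS")  # rebuilt
  add("OAH", c(c1 = -2, oxa_c = 1), tag = "OAH")
  add("GOX", c(glc_e = -1, glcn_u = 1), tag = "GOX")
  stub <- c(cit = "citric", oxa = "oxalic", glcn = "gluconic",
            ace = "acetic", mal = "malic", suc = "succinic", lac = "lactic")
  for (s in names(stub)) {
    an <- stub[[s]]
    nc <- acid_carbons[[an]]
    sec_ub <- if (an %in% c("citric", "oxalic")) 1000 else 0
    src <- if (an == "oxalic") c(oxa_c = -1) else
      setNames(-nc, "c1")
    sec_st <- c(src, setNames(1, paste0(s, "_u")))
    add(paste0("SEC_", toupper(s)), sec_st, upper = sec_ub,
        tag = "ACID_SECRETION", acid = an)
    dis_st <- setNames(c(-1, 1, hdefault[[an]]),
                       c(paste0(s, "_u"), paste0(s, "_e"), "hp"))
    add(paste0("DIS_", toupper(s)), dis_st,
        tag = "ACID_DISSOCIATION", acid = an)
  }
  add("HPE", c(hp = -1, h_e = 1), tag = "PROTON_OUT")

  rxn <- data.frame(
    id = vapply(rx, `[[`, "", "id"),
    lower = vapply(rx, `[[`, 0, "lower"),
    upper = vapply(rx, `[[`, 0, "upper"),
    reversible = vapply(rx, `[[`, FALSE, "reversible"),
    tag = vapply(rx, `[[`, "", "tag"),
    acid = vapply(rx, `[[`, "", "acid"),
    stringsAsFactors = FALSE)
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  for (i in seq_along(rx)) S[names(rx[[i]]$stoich), i] <- rx[[i]]$stoich

  net <- metabolic_network(met, rxn, S, biomass_composition = composition,
                           carbon_overhead = overhead)
  net <- rebuild_biomass_reaction(net)
  validate_network(net)
  net
}

#' Biomass-equation adjustment
#'
#' Scales the nucleic-acid and phospholipid mass fractions of the biomass
#' composition; the glycerol fraction absorbs the mass difference so the
#' total biomass mass per gDW is unchanged.  The BIOMASS reaction
#' coefficients (carbon and phosphate demand, CO2 release) are then rebuilt
#' from the adjusted composition.
#'
#' @param net metabolic_network carrying a biomass composition
#' @param nucleic_acid_scale,phospholipid_scale positive multipliers
#' @return adjusted metabolic_network
#' @export
apply_biomass_adjustment <- function(net, nucleic_acid_scale = 1,
                                     phospholipid_scale = 1) {
  if (is.null(net$biomass_composition))
    stop("network carries no biomass composition to adjust")
  if (nucleic_acid_scale <= 0 || phospholipid_scale <= 0)
    stop("biomass adjustment scales must be > 0")
  bc <- net$biomass_composition
  delta <- bc[["nucleic_acid"]] * (nucleic_acid_scale - 1) +
    bc[["lipid"]] * (phospholipid_scale - 1)
  glyc <- bc[["glycerol"]] - delta
  if (glyc < -1e-12)
    stop("biomass adjustment would drive the glycerol fraction negative ",
         sprintf("(%.4f)", glyc))
  bc[["nucleic_acid"]] <- bc[["nucleic_acid"]] * nucleic_acid_scale
  bc[["lipid"]] <- bc[["lipid"]] * phospholipid_scale
  bc[["glycerol"]] <- max(glyc, 0)
  net$biomass_composition <- bc
  net <- rebuild_biomass_reaction(net)
  validate_network(net)
  net
}

#' Simulate gene knockouts
#'
#' `oah` closes the oxaloacetate hydrolase reaction (no oxalate production);
#' `gox` closes the extracellular glucose oxidase reaction and disables its
#' flux forcing in the engine (no gluconate production).  Idempotent and
#' commutative.
#'
#' @param net metabolic_network
#' @param genes character subset of `c("oah", "gox")`
#' @return metabolic_network with knockout bounds applied
#' @export
apply_knockout <- function(net, genes = character()) {
  genes <- unique(genes)
  bad <- setdiff(genes, c("oah", "gox"))
  if (length(bad))
    stop("unknown knockout gene(s): ", paste(bad, collapse = ", "),
         "; supported knockouts are: oah, gox")
  for (g in genes) {
    idx <- reaction_by_tag(net, toupper(g))
    if (is.na(idx)) stop("network has no ", toupper(g), "-tagged reaction")
    net$reactions$lower[idx] <- 0
    net$reactions$upper[idx] <- 0
  }
  net$knockouts <- sort(unique(c(net$knockouts, genes)))
  net
}

#' Internal-reaction carbon balance
#'
#' Checks that every purely internal reaction (no boundary species in its
#' stoichiometry) conserves carbon.
#'
#' @param net metabolic_network
#' @return named numeric of carbon imbalances per internal reaction
#' @export
carbon_balance <- function(net) {
  ext <- net$metabolites$compartment == "external"
  internal <- colSums(abs(net$S[ext, , drop = FALSE])) == 0
  bal <- drop(crossprod(net$S[, internal, drop = FALSE],
                        net$metabolites$carbon_count))
  setNames(as.numeric(bal), net$reactions$id[internal])
}

#' Network summary
#'
#' @param net metabolic_network
#' @param path optional file path; if given the summary is written as JSON
#' @return list of counts, tags and composition (invisibly when written)
#' @export
network_summary <- function(net, path = NULL) {
  acid_dis <- net$reactions$acid[net$reactions$tag == "ACID_DISSOCIATION"]
  out <- list(
    n_metabolites = nrow(net$metabolites),
    n_reactions = nrow(net$reactions),
    n_external = sum(net$metabolites$compartment == "external"),
    tags = as.list(table(net$reactions$tag)),
    acids_with_dissociation = sort(acid_dis),
    biomass_composition = as.list(net$biomass_composition),
    knockouts = if (is.null(net$knockouts)) character() else net$knockouts)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}
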