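# SBML import/export (Level 3 + fbc version 2 written; Level 2 tolerated on
# read).  Role tags, carbon counts and the biomass composition ride along
# in notes elements so that a round-trip through SBML preserves the network
# exactly; foreign SBML files are tagged by configurable id patterns.

SBML_NS_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# id-pattern defaults cover the bundled toy ids and common fungal
# genome-scale naming (DGLCe/XYLe/PIe/PI/Hpe)
default_tag_patterns <- function() {
  list(BIOMASS = "^(BIOMASS|biomass|bof)", PROTON_OUT = "^(HPE|Hpe)$",
       STORED_P_IN = "^PI$", EXTERNAL_P_IN = "^(PIE|PIe)$",
       GLUCOSE_EX = "^(EX_GLC|DGLCe)", XYLOSE_EX = "^(EX_XYL|XYLe)",
       GOX = "^GOX", OAH = "^OAH", STORAGE = "^PSTORE")
}

notes_node <- function(lines) {
  paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
         paste0("<p>", lines, "</p>", collapse = ""), "</body></notes>")
}

num <- function(x) sprintf("%.17g", x)
xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a network as SBML (Level 3, fbc v2)
#'
#' @param net metabolic_network
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sbml <- function(net, path) {
  met <- net$metabolites; rxn <- net$reactions
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"),
            SBML_NS_CORE, SBML_NS_FBC),
    "<model id=\"acidflux_network\" fbc:strict=\"false\">")
  mnotes <- character()
  if (!is.null(net$biomass_composition))
    mnotes <- c(mnotes, paste0("biomass_composition: ",
                               jsonlite::toJSON(as.list(net$biomass_composition),
                                                auto_unbox = TRUE,
                                                digits = NA)),
                paste0("carbon_overhead: ", num(net$carbon_overhead)))
  if (length(mnotes)) lines <- c(lines, notes_node(xesc(mnotes)))
  lines <- c(lines, "<listOfCompartments>",
             sprintf("<compartment id=\"%s\" constant=\"true\"/>",
                     unique(met$compartment)),
             "</listOfCompartments>", "<listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    ext <- met$compartment[i] == "external"
    lines <- c(lines, sprintf(
      paste0("<species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "boundaryCondition=\"%s\" hasOnlySubstanceUnits=\"false\" ",
             "constant=\"false\">"),
      met$id[i], xesc(met$name[i]), met$compartment[i],
      tolower(ext)),
      notes_node(paste0("carbon_count: ", met$carbon_count[i])),
      "</species>")
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (i in seq_len(nrow(rxn)))
    lines <- c(lines, sprintf(
      "<parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
      rxn$id[i], num(rxn$lower[i])), sprintf(
      "<parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
      rxn$id[i], num(rxn$upper[i])))
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    st <- net$S[, i]
    nz <- which(abs(st) > 0)
    notes <- paste0("tag: ", rxn$tag[i])
    if (!is.na(rxn$acid[i]) && nzchar(rxn$acid[i]))
      notes <- c(notes, paste0("acid: ", rxn$acid[i]))
    lines <- c(lines, sprintf(
      paste0("<reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"lb_%s\" fbc:upperFluxBound=\"ub_%s\">"),
      rxn$id[i], tolower(rxn$reversible[i]), rxn$id[i], rxn$id[i]),
      notes_node(notes))
    sref <- function(j) sprintf(
      "<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
      net$metabolites$id[j], num(abs(st[j])))
    cons <- nz[st[nz] < 0]; prod <- nz[st[nz] > 0]
    if (length(cons)) lines <- c(lines, "<listOfReactants>",
                                 vapply(cons, sref, ""),
                                 "</listOfReactants>")
    if (length(prod)) lines <- c(lines, "<listOfProducts>",
                                 vapply(prod, sref, ""),
                                 "</listOfProducts>")
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

xml_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

notes_fields <- function(node) {
  ps <- xml2::xml_find_all(node,
                           "./*[local-name()='notes']//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  kv <- regmatches(txt, regexec("^([A-Za-z_]+):\\s*(.*)$", txt))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Load a metabolic network from SBML
#'
#' Reads Level 3 (+fbc) or Level 2 SBML.  Flux bounds are taken from fbc
#' attributes (via the parameter list), from `lower_bound`/`upper_bound`
#' notes, or default to (-1000, 1000) for reversible and (0, 1000) for
#' irreversible reactions.  Role tags come from notes when present (as
#' written by [write_sbml()]); otherwise they are assigned from the
#' configurable id patterns, with `tag_overrides` taking final precedence.
#'
#' @param path SBML file
#' @param tag_patterns named list of regular expressions, tag -> pattern
#' @param tag_overrides named character, reaction id -> tag (or
#'   `"TAG:acid"` for acid reactions)
#' @return metabolic_network
#' @export
load_sbml <- function(path, tag_patterns = default_tag_patterns(),
                      tag_overrides = character()) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML in '", path, "': ", conditionMessage(e)))
  model <- xml_local(doc, "model")
  if (length(model) == 0) stop("malformed SBML: no <model> element")
  model <- model[[1]]

  pars <- xml_local(model, "parameter")
  parmap <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  sp <- xml2::xml_find_all(model, paste0(
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']"))
  if (length(sp) == 0) stop("malformed SBML: no <species> elements")
  comp <- xml2::xml_attr(sp, "compartment")
  bc <- tolower(xml2::xml_attr(sp, "boundaryCondition")) %in% "true"
  compartment <- ifelse(comp %in% c("external", "cytosol", "mitochondrion"),
                        comp, ifelse(bc, "external", "cytosol"))
  carbon <- vapply(seq_along(sp), function(i) {
    nf <- notes_fields(sp[[i]])
    if (!is.null(nf$carbon_count)) as.numeric(nf$carbon_count) else 0
  }, numeric(1))
  met <- data.frame(id = xml2::xml_attr(sp, "id"),
                    name = ifelse(is.na(xml2::xml_attr(sp, "name")), "",
                                  xml2::xml_attr(sp, "name")),
                    compartment = compartment, carbon_count = carbon,
                    stringsAsFactors = FALSE)

  rnodes <- xml2::xml_find_all(model, paste0(
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']"))
  if (length(rnodes) == 0) stop("malformed SBML: no <reaction> elements")
  nr <- length(rnodes)
  id <- xml2::xml_attr(rnodes, "id")
  rev <- tolower(xml2::xml_attr(rnodes, "reversible")) %in% "true"
  S <- matrix(0, nrow(met), nr, dimnames = list(met$id, id))
  lower <- numeric(nr); upper <- numeric(nr)
  tag <- rep("OTHER", nr); acid <- rep(NA_character_, nr)
  for (i in seq_len(nr)) {
    rn <- rnodes[[i]]
    for (side in c(-1, 1)) {
      lst <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", lst))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        if (!sid %in% met$id)
          stop("SBML reaction '", id[i], "' references unknown species '",
               sid, "'")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        S[sid, i] <- S[sid, i] + side * coef
      }
    }
    nf <- notes_fields(rn)
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    lower[i] <- if (!is.na(lbref) && lbref %in% names(parmap))
      parmap[[lbref]]
    else if (!is.null(nf$lower_bound)) as.numeric(nf$lower_bound)
    else if (rev[i]) -1000 else 0
    upper[i] <- if (!is.na(ubref) && ubref %in% names(parmap))
      parmap[[ubref]]
    else if (!is.null(nf$upper_bound)) as.numeric(nf$upper_bound)
    else 1000
    if (!is.null(nf$tag)) {
      tag[i] <- nf$tag
      if (!is.null(nf$acid)) acid[i] <- nf$acid
    } else {
      for (tg in names(tag_patterns))
        if (grepl(tag_patterns[[tg]], id[i])) { tag[i] <- tg; break }
    }
    if (id[i] %in% names(tag_overrides)) {
      ov <- strsplit(tag_overrides[[id[i]]], ":", fixed = TRUE)[[1]]
      tag[i] <- ov[1]
      if (length(ov) > 1) acid[i] <- ov[2]
    }
  }
  rxn <- data.frame(id = id, lower = lower, upper = upper,
                    reversible = rev, tag = tag, acid = acid,
                    stringsAsFactors = FALSE)
  if (!any(tag == "BIOMASS"))
    stop("SBML model has no biomass reaction (no BIOMASS tag matched)")

  composition <- NULL; overhead <- 1
  nf <- notes_fields(model)
  if (!is.null(nf$biomass_composition))
    composition <- unlist(jsonlite::fromJSON(nf$biomass_composition))
  if (!is.null(nf$carbon_overhead))
    overhead <- as.numeric(nf$carbon_overhead)
  metabolic_network(met, rxn, S, biomass_composition = composition,
                    carbon_overhead = overhead)
}
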