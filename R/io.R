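# Configuration loading, tabular trajectory/observation writers, the run
# manifest and the command-line entry point.

#' Load a simulation configuration file
#'
#' YAML or JSON with up to three top-level sections: `simulation`
#' (arguments of [simulation_config()]), `parameters` (overrides of
#' [kinetic_parameters()]) and `network` (`"toy"` or an SBML path).
#' Omitted fields take the documented defaults; unknown keys are rejected
#' with their path.
#'
#' @param path config file (`.yml`/`.yaml`/`.json`)
#' @return list with `config`, `params`, `network`
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("simulation", "parameters", "network"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  sim <- raw$simulation
  if (is.null(sim)) sim <- list()
  allowed <- names(formals(simulation_config))
  bad <- setdiff(names(sim), allowed)
  if (length(bad))
    stop("unknown key(s) under simulation: ",
         paste0("simulation.", bad, collapse = ", "))
  if (!is.null(sim$knockouts)) sim$knockouts <- as.character(sim$knockouts)
  config <- do.call(simulation_config, sim)
  pars <- raw$parameters
  if (is.null(pars)) pars <- list()
  params <- do.call(kinetic_parameters, pars)
  network <- if (is.null(raw$network)) "toy" else raw$network
  list(config = config, params = params, network = network)
}

resolve_network <- function(network) {
  if (identical(network, "toy")) make_toy_network() else load_sbml(network)
}

TRAJECTORY_COLUMNS <- c("time_h", "biomass_gL", "glucose_gL", "xylose_gL",
                        "phosphate_gL", "stored_P_mM", "citrate_gL",
                        "oxalate_gL", "gluconate_gL", "acetate_gL",
                        "malate_gL", "succinate_gL", "lactate_gL", "pH",
                        "objective", "growth_rate")

#' Write a trajectory as CSV
#'
#' Fixed column order; concentrations reported in g/L (converted from the
#' internal mM pools with the documented molar masses), stored phosphate
#' in mM, plus pH, the secondary objective in force and the growth rate.
#'
#' @param traj `dfba_trajectory`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(
    time_h = traj$time_h,
    biomass_gL = traj$biomass,
    glucose_gL = mM_to_gl(traj$glucose, "glucose"),
    xylose_gL = mM_to_gl(traj$xylose, "xylose"),
    phosphate_gL = mM_to_gl(traj$phosphate, "phosphate"),
    stored_P_mM = traj$stored_phosphate,
    citrate_gL = mM_to_gl(traj$citric, "citric"),
    oxalate_gL = mM_to_gl(traj$oxalic, "oxalic"),
    gluconate_gL = mM_to_gl(traj$gluconic, "gluconic"),
    acetate_gL = mM_to_gl(traj$acetic, "acetic"),
    malate_gL = mM_to_gl(traj$malic, "malic"),
    succinate_gL = mM_to_gl(traj$succinic, "succinic"),
    lactate_gL = mM_to_gl(traj$lactic, "lactic"),
    pH = traj$pH,
    objective = ifelse(is.na(traj$objective), "none", traj$objective),
    growth_rate = ifelse(is.na(traj$growth_rate), 0, traj$growth_rate))
  stopifnot(identical(names(df), TRAJECTORY_COLUMNS))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# stable 32-bit FNV-1a hash of a deparsed R object (manifest identity)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run summary / manifest
#'
#' @param traj `dfba_trajectory`
#' @param path optional JSON output path
#' @return list (invisibly when written)
#' @export
run_summary <- function(traj, path = NULL) {
  fin <- traj[nrow(traj), ]
  cfg <- attr(traj, "config")
  out <- list(
    software = paste0("acidflux ",
                      as.character(utils::packageVersion("acidflux"))),
    solver = "bounded-variable simplex (Bland's rule)",
    config_hash = config_hash(unclass(cfg)),
    config = unclass(cfg),
    n_timepoints = nrow(traj),
    diauxic_switch_h = diauxic_switch_time(traj),
    final = list(time_h = fin$time_h, biomass_gL = fin$biomass,
                 glucose_gL = mM_to_gl(fin$glucose, "glucose"),
                 citrate_gL = mM_to_gl(fin$citric, "citric"),
                 oxalate_gL = mM_to_gl(fin$oxalic, "oxalic"),
                 gluconate_gL = mM_to_gl(fin$gluconic, "gluconic"),
                 pH = fin$pH),
    caps_hit = list(
      citrate_steps = sum(traj$citric_flux >= traj$cit_cap * (1 - 1e-6),
                          na.rm = TRUE),
      oxalate_steps = sum(traj$oxalic_flux >= traj$oxa_cap * (1 - 1e-6) &
                            traj$oxa_cap > 0, na.rm = TRUE)),
    events = list(
      phosphate_rate_switch_h = cfg$start_offset +
        kinetic_parameters()$pie_switch_time,
      low_affinity_glucose_steps = sum(traj$glucose >=
                                         GLUCOSE_LOWAFF_mM),
      oxalate_shutoff_steps = sum(!is.na(traj$oxa_cap) &
                                    traj$oxa_cap == 0)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stop_reason = attr(traj, "stop_reason"))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    return(invisible(out))
  }
  out
}

#' Read / write observation tables
#'
#' CSV with columns `time_h`, `variable`, `value_gL` and optional `sd`.
#'
#' @param path CSV path
#' @return observations data.frame
#' @export
read_observations <- function(path) {
  obs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "variable", "value_gL")
  if (!all(need %in% names(obs)))
    stop("observations file must have columns: ",
         paste(need, collapse = ", "))
  obs
}

#' @rdname read_observations
#' @param obs observations data.frame
#' @export
write_observations <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the bundled toy network fixture as TSV
#'
#' Two plain-text tables: the reaction table (id, equation string, bounds,
#' tag, acid) and the metabolite table (id, name, compartment, carbons).
#'
#' @param net metabolic_network
#' @param rxn_path,met_path output TSV paths
#' @return invisibly, the two paths
#' @export
write_reaction_table <- function(net, rxn_path, met_path) {
  eqs <- vapply(seq_len(nrow(net$reactions)), function(i) {
    st <- net$S[, i]
    term <- function(j) paste0(sprintf("%.17g", abs(st[j])), " ",
                               net$metabolites$id[j])
    lhs <- paste(vapply(which(st < 0), term, ""), collapse = " + ")
    rhs <- paste(vapply(which(st > 0), term, ""), collapse = " + ")
    paste(lhs, "->", rhs)
  }, "")
  rxn <- cbind(net$reactions[, c("id", "lower", "upper", "reversible",
                                 "tag", "acid")],
               equation = eqs)[, c("id", "equation", "lower", "upper",
                                   "reversible", "tag", "acid")]
  write.table(rxn, rxn_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(net$metabolites, met_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(rxn_path, met_path))
}

#' @rdname write_reaction_table
#' @param biomass_composition,carbon_overhead metadata not expressible in
#'   the tables (defaults match the bundled fixture)
#' @export
read_reaction_table <- function(rxn_path, met_path,
                                biomass_composition = NULL,
                                carbon_overhead = 1) {
  rxn <- read.delim(rxn_path, stringsAsFactors = FALSE)
  met <- read.delim(met_path, stringsAsFactors = FALSE)
  S <- matrix(0, nrow(met), nrow(rxn), dimnames = list(met$id, rxn$id))
  for (i in seq_len(nrow(rxn))) {
    sides <- strsplit(rxn$equation[i], " -> ", fixed = TRUE)[[1]]
    parse_side <- function(s, sign) {
      if (is.na(s) || !nzchar(trimws(s))) return()
      for (term in strsplit(s, " + ", fixed = TRUE)[[1]]) {
        kv <- strsplit(trimws(term), " ", fixed = TRUE)[[1]]
        S[kv[2], i] <<- S[kv[2], i] + sign * as.numeric(kv[1])
      }
    }
    parse_side(sides[1], -1)
    parse_side(sides[2], +1)
  }
  rxn$acid[rxn$acid == "" | is.na(rxn$acid)] <- NA_character_
  metabolic_network(met, rxn[, c("id", "lower", "upper", "reversible",
                                 "tag", "acid")], S,
                    biomass_composition = biomass_composition,
                    carbon_overhead = carbon_overhead)
}

cli_opts <- function(args) {
  opts <- list()
  pos <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1])) {
        opts[[key]] <- TRUE
        i <- i + 1
      } else {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  list(opts = opts, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit`, `select`, `make-toy`, `synth-obs`.
#' See the README for usage; an executable wrapper ships in
#' `inst/exec/acidflux`.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
acidflux_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("--help", "-h")) {
    cat("usage: acidflux <simulate|fit|select|make-toy|synth-obs> [options]\n")
    return(invisible(0))
  }
  if (args[1] == "--version") {
    cat("acidflux", as.character(utils::packageVersion("acidflux")), "\n")
    return(invisible(0))
  }
  cmd <- args[1]
  pa <- cli_opts(args[-1])
  o <- pa$opts
  get_cfg <- function() {
    if (!is.null(o$config)) load_config(o$config)
    else list(config = simulation_config(), params = kinetic_parameters(),
              network = "toy")
  }
  switch(cmd,
    "make-toy" = {
      out <- if (is.null(o$out)) "." else o$out
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      net <- make_toy_network()
      write_reaction_table(net, file.path(out, "toy_network.tsv"),
                           file.path(out, "toy_metabolites.tsv"))
      write_sbml(net, file.path(out, "toy_network.xml"))
      network_summary(net, file.path(out, "toy_summary.json"))
      message("toy network written to ", out)
    },
    "simulate" = {
      cfg <- get_cfg()
      if (!is.null(o$network)) cfg$network <- o$network
      net <- resolve_network(cfg$network)
      traj <- run_dfba(net, cfg$params, cfg$config)
      out <- if (is.null(o$out)) "." else o$out
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_trajectory(traj, file.path(out, "trajectory.csv"))
      run_summary(traj, file.path(out, "summary.json"))
      message("trajectory written to ", file.path(out, "trajectory.csv"))
    },
    "synth-obs" = {
      cfg <- get_cfg()
      net <- resolve_network(cfg$network)
      noise <- if (is.null(o$noise)) 0.02 else as.numeric(o$noise)
      seed <- if (is.null(o$seed)) 1 else as.integer(o$seed)
      obs <- generate_synthetic_observations(net, cfg$params, cfg$config,
                                             noise_sd = noise, seed = seed)
      path <- if (is.null(o$out)) "observations.csv" else o$out
      write_observations(obs, path)
      message("observations written to ", path)
    },
    "fit" = {
      cfg <- get_cfg()
      net <- resolve_network(cfg$network)
      if (is.null(o$obs)) stop("fit requires --obs <csv>")
      obs <- read_observations(o$obs)
      if (is.null(o$free)) stop("fit requires --free <name,name,...>")
      nm <- strsplit(o$free, ",", fixed = TRUE)[[1]]
      free <- lapply(nm, function(p) {
        base <- if (p %in% c("nucleic_acid_scale", "phospholipid_scale")) 1
        else cfg$params[[p]]
        c(base * 0.2, base * 5)
      })
      names(free) <- nm
      seed <- if (is.null(o$seed)) 1 else as.integer(o$seed)
      fr <- fit_parameters(net, cfg$params, free, obs, cfg$config,
                           seed = seed)
      print(fr)
      if (!is.null(o$out))
        jsonlite::write_json(unclass(fr), o$out, auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
    },
    "select" = {
      cfg <- get_cfg()
      net <- resolve_network(cfg$network)
      if (is.null(o$obs) || is.null(o$variants))
        stop("select requires --obs <csv> and --variants <yaml>")
      obs <- read_observations(o$obs)
      vr <- yaml::read_yaml(o$variants)
      candidates <- lapply(vr, function(v)
        list(free = lapply(v$free, function(b) as.numeric(b))))
      seed <- if (is.null(o$seed)) 1 else as.integer(o$seed)
      res <- select_model(candidates, obs, cfg$config, net = net,
                          base_params = cfg$params, seed = seed)
      print(res[, c("variant", "k", "rss", "aic")])
      if (!is.null(o$out))
        jsonlite::write_json(res[, c("variant", "k", "rss", "aic")],
                             o$out, pretty = TRUE, digits = NA)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0)
}
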