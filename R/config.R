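#' Define a bacterial genus
#'
#' A genus is characterized by the metabolites it can consume, the metabolites
#' it produces per unit consumed, its doubling time, and its share of the
#' initial seeded population.
#'
#' @param name Genus identifier, e.g. `"Bifidobacterium"`.
#' @param consumes Character vector of metabolite names the genus can eat.
#'   Must be non-empty.
#' @param produces Named list/vector: units of each metabolite deposited on the
#'   colony's element per unit consumed (stoichiometric yield).
#' @param doubling_time Reproduction period in timesteps (>= 1).
#' @param initial_percent Share of the seeded population, in percent.
#' @return A list of class `genus_spec`.
#' @export
genus_spec <- function(name, consumes, produces = list(),
                       doubling_time = 480L, initial_percent = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(consumes), length(consumes) >= 1L)
  structure(list(name = name,
                 consumes = consumes,
                 produces = as.list(produces),
                 doubling_time = as.integer(doubling_time),
                 initial_percent = as.numeric(initial_percent)),
            class = "genus_spec")
}

#' Define a metabolite
#'
#' @param name Metabolite identifier.
#' @param inflow_per_step Units added to the entrance element each timestep.
#' @return A list of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, inflow_per_step = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, inflow_per_step = as.numeric(inflow_per_step)),
            class = "metabolite_spec")
}

#' Reference physiology behind the default flow parameters
#'
#' Constants used to scale the simulation: mean lateral (luminal) flow through
#' the gut, bacterial self-propulsion speed, and the real-time duration of one
#' timestep. Self-propulsion is about 5% of the lateral flow, which is why
#' colony motility is neglected and only advection moves free colonies.
#'
#' @return Named list: `lateral_flow_cm_per_min`, `self_motility_cm_per_min`,
#'   `timestep_seconds`, `steps_per_day`.
#' @export
ileum_physiology <- function() {
  list(lateral_flow_cm_per_min = 2.22,
       self_motility_cm_per_min = 0.12,
       timestep_seconds = 26.3,
       steps_per_day = 86400 / 26.3)
}

#' Default simulation configuration
#'
#' The reference configuration for the four-genus ileum model: a 1x100 lattice,
#' displacement 0.278 elements/step (26.3 s each), glucose inflow 30 units/step,
#' starvation horizon 1440 steps, hungry threshold 80/100 energy, reproduction
#' above 50 energy on a 480-step doubling time, mucus escape probability 0.10
#' and permanent embedding probability 0.05. The population is seeded as
#' 78.43% Bifidobacterium, 18.27% Bacteroides, 3.06% Clostridium and 0.23%
#' Desulfovibrio. Bifidobacterium consumes glucose, lactose,
#' fructooligosaccharide and inulin and produces lactate; Desulfovibrio
#' consumes only lactate; Clostridium and Bacteroides both consume glucose.
#'
#' Parameters with no established reference value (secondary carbohydrate
#' inflows, lactate yield, adhesion ceiling `gamma_max`, crowding midpoint
#' `n_mid`, energy gain per unit) are calibration knobs, chosen so the seeded
#' community holds a stable baseline; see the methods vignette.
#'
#' @return A list of class `gut_config`.
#' @export
default_config <- function() {
  cfg <- list(
    n_elements = 100L,
    genera = list(
      genus_spec("Bifidobacterium",
                 consumes = c("glucose", "lactose", "fructooligosaccharide",
                              "inulin"),
                 produces = list(lactate = 0.01),
                 doubling_time = 480L, initial_percent = 78.43),
      genus_spec("Bacteroides", consumes = "glucose",
                 doubling_time = 480L, initial_percent = 18.27),
      genus_spec("Clostridium", consumes = "glucose",
                 doubling_time = 480L, initial_percent = 3.06),
      genus_spec("Desulfovibrio", consumes = "lactate",
                 doubling_time = 480L, initial_percent = 0.23)
    ),
    metabolites = list(
      metabolite_spec("glucose", 30),
      metabolite_spec("lactose", 4),
      metabolite_spec("fructooligosaccharide", 4),
      metabolite_spec("inulin", 4),
      metabolite_spec("lactate", 0),
      metabolite_spec("unassigned", 0)   # spare slot: no inflow, no consumers
    ),
    adhesion = list(gamma_max = 0.01, n_mid = 30, p_unstick = 0.10,
                    p_embed = 0.05),
    energy = list(energy_max = 100, hungry_threshold = 80,
                  starvation_steps = 1440L, gain_per_unit = 20,
                  reproduce_min_energy = 50),
    flow = list(displacement_per_step = 0.278, timestep_seconds = 26.3,
                advect_metabolites = TRUE),
    initial_total = 10000L,
    max_per_element = 200L,
    bacteria_inflow_per_step = c(Bifidobacterium = 0.7843,
                                 Bacteroides = 0.1827,
                                 Clostridium = 0.0306,
                                 Desulfovibrio = 0),
    seed_adhesion = "mucus",
    probiotic_dose_mode = "replace",
    consumption_priority = c("glucose", "lactose", "fructooligosaccharide",
                             "inulin", "lactate"),
    rng_seed = 42L
  )
  structure(cfg, class = "gut_config")
}

#' @export
print.gut_config <- function(x, ...) {
  cat("<gut_config>", x$n_elements, "elements,",
      length(x$genera), "genera,", length(x$metabolites), "metabolites\n")
  for (g in x$genera)
    cat(sprintf("  %-16s %5.2f%%  eats: %s\n", g$name, g$initial_percent,
                paste(g$consumes, collapse = ", ")))
  cat(sprintf("  displacement %.3f el/step, timestep %.1f s, glucose inflow %g/step\n",
              x$flow$displacement_per_step, x$flow$timestep_seconds,
              metabolite_inflows(x)[["glucose"]]))
  invisible(x)
}

genus_names <- function(config) {
  vapply(config$genera, `[[`, character(1), "name")
}

metabolite_names <- function(config) {
  vapply(config$metabolites, `[[`, character(1), "name")
}

metabolite_inflows <- function(config) {
  stats::setNames(vapply(config$metabolites, `[[`, numeric(1),
                         "inflow_per_step"),
                  metabolite_names(config))
}

#' Per-step energy decay implied by the starvation horizon
#'
#' Energy is lost at `energy_max / starvation_steps` per step so that a colony
#' at full energy survives exactly `starvation_steps` timesteps without eating.
#'
#' @param config A `gut_config`.
#' @return Energy units lost per timestep.
#' @export
energy_decay <- function(config) {
  config$energy$energy_max / config$energy$starvation_steps
}

#' Validate a configuration
#'
#' Checks every structural invariant of a configuration and reports all
#' violations at once, each prefixed with the path of the offending field
#' (e.g. `flow.displacement_per_step`).
#'
#' @param config A `gut_config`.
#' @return The config, invisibly, if valid; otherwise an error listing every
#'   violated field.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  chk <- function(ok, path, msg) {
    if (!isTRUE(ok)) bad <<- c(bad, paste0(path, ": ", msg))
  }
  chk(is.numeric(config$n_elements) && config$n_elements >= 1,
      "n_elements", "must be a positive integer")
  chk(length(config$genera) >= 1, "genera", "at least one genus required")
  mn <- metabolite_names(config)
  chk(!anyDuplicated(mn), "metabolites", "duplicate metabolite names")
  for (i in seq_along(config$genera)) {
    g <- config$genera[[i]]
    path <- paste0("genera.", g$name)
    chk(length(g$consumes) >= 1, paste0(path, ".consumes"), "must be non-empty")
    chk(all(g$consumes %in% mn), paste0(path, ".consumes"),
        "names an unknown metabolite")
    chk(all(names(g$produces) %in% mn), paste0(path, ".produces"),
        "names an unknown metabolite")
    chk(g$doubling_time >= 1, paste0(path, ".doubling_time"), "must be >= 1")
    chk(g$initial_percent >= 0, paste0(path, ".initial_percent"),
        "must be >= 0")
  }
  pct <- sum(vapply(config$genera, `[[`, numeric(1), "initial_percent"))
  chk(abs(pct - 100) <= 0.05, "genera.initial_percent",
      sprintf("must sum to ~100 (got %.4f)", pct))
  for (m in config$metabolites)
    chk(m$inflow_per_step >= 0,
        paste0("metabolites.", m$name, ".inflow_per_step"), "must be >= 0")
  a <- config$adhesion
  for (f in c("gamma_max", "p_unstick", "p_embed"))
    chk(a[[f]] >= 0 && a[[f]] <= 1, paste0("adhesion.", f),
        "must be a probability in [0, 1]")
  chk(a$n_mid > 0, "adhesion.n_mid", "must be > 0")
  en <- config$energy
  chk(en$energy_max > 0, "energy.energy_max", "must be > 0")
  chk(en$hungry_threshold > 0 && en$hungry_threshold <= en$energy_max,
      "energy.hungry_threshold", "must be in (0, energy_max]")
  chk(en$reproduce_min_energy > 0 && en$reproduce_min_energy < en$energy_max,
      "energy.reproduce_min_energy", "must be in (0, energy_max)")
  chk(en$starvation_steps >= 1, "energy.starvation_steps", "must be >= 1")
  chk(en$gain_per_unit > 0, "energy.gain_per_unit", "must be > 0")
  chk(config$flow$displacement_per_step >= 0, "flow.displacement_per_step",
      "must be >= 0")
  chk(config$flow$timestep_seconds > 0, "flow.timestep_seconds", "must be > 0")
  chk(config$initial_total >= 0, "initial_total", "must be >= 0")
  chk(config$max_per_element >= 1, "max_per_element", "must be >= 1")
  chk(all(config$bacteria_inflow_per_step >= 0), "bacteria_inflow_per_step",
      "must be >= 0")
  chk(all(names(config$bacteria_inflow_per_step) %in% genus_names(config)),
      "bacteria_inflow_per_step", "names an unknown genus")
  chk(config$seed_adhesion %in% c("mucus", "free"), "seed_adhesion",
      "must be 'mucus' or 'free'")
  chk(config$probiotic_dose_mode %in% c("replace", "add"),
      "probiotic_dose_mode", "must be 'replace' or 'add'")
  chk(all(config$consumption_priority %in% mn), "consumption_priority",
      "names an unknown metabolite")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(config)
}

# Flat parameter list handed to the C++ engine.
engine_params <- function(config) {
  gn <- genus_names(config)
  mn <- metabolite_names(config)
  nG <- length(gn)
  nM <- length(mn)
  consumes <- matrix(0L, nG, nM, dimnames = list(gn, mn))
  produces <- matrix(0, nG, nM, dimnames = list(gn, mn))
  for (i in seq_len(nG)) {
    g <- config$genera[[i]]
    consumes[i, match(g$consumes, mn)] <- 1L
    if (length(g$produces))
      produces[i, match(names(g$produces), mn)] <- unlist(g$produces)
  }
  inflow <- stats::setNames(rep(0, nG), gn)
  given <- config$bacteria_inflow_per_step
  inflow[names(given)] <- as.numeric(given)
  pr <- match(config$consumption_priority, mn)
  pr <- c(pr, setdiff(seq_len(nM), pr)) - 1L
  list(
    n_elements = as.integer(config$n_elements),
    n_genera = nG,
    n_mets = nM,
    displacement = config$flow$displacement_per_step,
    advect_mets = isTRUE(config$flow$advect_metabolites),
    met_inflow = unname(metabolite_inflows(config)),
    bact_inflow = unname(inflow),
    gamma_max = config$adhesion$gamma_max,
    n_mid = config$adhesion$n_mid,
    p_unstick = config$adhesion$p_unstick,
    p_embed = config$adhesion$p_embed,
    energy_max = config$energy$energy_max,
    hungry = config$energy$hungry_threshold,
    decay = energy_decay(config),
    gain = config$energy$gain_per_unit,
    repro_min = config$energy$reproduce_min_energy,
    doubling = vapply(config$genera, function(g) as.integer(g$doubling_time),
                      integer(1)),
    max_per_element = as.integer(config$max_per_element),
    priority = as.integer(pr),
    consumes = consumes,
    produces = produces,
    dose_replace = identical(config$probiotic_dose_mode, "replace")
  )
}
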