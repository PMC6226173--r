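# Configuration files mirror the gut_config structure field-for-field; YAML is
# the native dialect and JSON parses through the same reader.

config_to_plain <- function(config) {
  list(
    n_elements = config$n_elements,
    genera = lapply(config$genera, function(g)
      list(name = g$name, consumes = as.list(g$consumes),
           produces = g$produces, doubling_time = g$doubling_time,
           initial_percent = g$initial_percent)),
    metabolites = lapply(config$metabolites, function(m)
      list(name = m$name, inflow_per_step = m$inflow_per_step)),
    adhesion = config$adhesion,
    energy = config$energy,
    flow = config$flow,
    initial_total = config$initial_total,
    max_per_element = config$max_per_element,
    bacteria_inflow_per_step = as.list(config$bacteria_inflow_per_step),
    seed_adhesion = config$seed_adhesion,
    probiotic_dose_mode = config$probiotic_dose_mode,
    consumption_priority = as.list(config$consumption_priority),
    rng_seed = config$rng_seed
  )
}

#' Write a configuration to a YAML file
#'
#' @param config A `gut_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config_to_plain(config), path, precision = 15L)
  invisible(path)
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) document mirroring the configuration structure,
#' fills every omitted field from [default_config()] (genera and metabolites
#' merge by name), and validates the result. An empty file yields the default
#' configuration unchanged.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `gut_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e2)
               stop("cannot parse config file ", path, ": ",
                    conditionMessage(e), call. = FALSE)))
  config <- default_config()
  if (is.null(doc)) return(validate_config(config))
  if (!is.list(doc)) stop("config file must be a mapping/object")

  for (key in c("n_elements", "initial_total", "max_per_element", "rng_seed"))
    if (!is.null(doc[[key]])) config[[key]] <- as.integer(doc[[key]])
  for (key in c("seed_adhesion", "probiotic_dose_mode"))
    if (!is.null(doc[[key]])) config[[key]] <- as.character(doc[[key]])
  if (!is.null(doc$consumption_priority))
    config$consumption_priority <- as.character(unlist(doc$consumption_priority))
  for (grp in c("adhesion", "energy", "flow"))
    if (!is.null(doc[[grp]]))
      config[[grp]] <- utils::modifyList(config[[grp]], doc[[grp]])
  if (!is.null(doc$bacteria_inflow_per_step)) {
    v <- unlist(doc$bacteria_inflow_per_step)
    config$bacteria_inflow_per_step <- stats::setNames(as.numeric(v), names(v))
  }
  if (!is.null(doc$metabolites)) {
    have <- metabolite_names(config)
    for (m in doc$metabolites) {
      i <- match(m$name, have)
      spec <- metabolite_spec(m$name,
                              if (is.null(m$inflow_per_step)) 0
                              else m$inflow_per_step)
      if (is.na(i)) config$metabolites[[length(config$metabolites) + 1L]] <- spec
      else {
        if (is.null(m$inflow_per_step))
          spec$inflow_per_step <- config$metabolites[[i]]$inflow_per_step
        config$metabolites[[i]] <- spec
      }
      have <- metabolite_names(config)
    }
  }
  if (!is.null(doc$genera)) {
    have <- genus_names(config)
    for (g in doc$genera) {
      i <- match(g$name, have)
      base <- if (is.na(i)) list(name = g$name, consumes = character(0),
                                 produces = list(), doubling_time = 480L,
                                 initial_percent = 0)
              else unclass(config$genera[[i]])
      merged <- utils::modifyList(base, g)
      spec <- genus_spec(merged$name, as.character(unlist(merged$consumes)),
                         merged$produces, merged$doubling_time,
                         merged$initial_percent)
      if (is.na(i)) config$genera[[length(config$genera) + 1L]] <- spec
      else config$genera[[i]] <- spec
      have <- genus_names(config)
    }
  }
  validate_config(config)
  config
}

#' Deterministic miniature worlds for testing and exploration
#'
#' \describe{
#'   \item{tiny-world}{5 elements, 10 colonies, reduced inflows, seed 0: small
#'     enough that full bookkeeping can be audited over thousands of steps.}
#'   \item{starvation-single}{one colony at full energy, zero metabolites and
#'     inflows everywhere, reproduction effectively disabled: isolates the
#'     energy-decay clock.}
#'   \item{stuck-lattice}{`n` colonies of one genus on element 0 with no flow
#'     and no nutrients: isolates the adhesion transition probabilities
#'     (`adhesion = "mucus"` or `"free"`).}
#'   \item{dosing-minimal}{an empty world with zero inflows; the attached
#'     `dosing` attribute holds the low-dose probiotic rule.}
#' }
#'
#' @param name Fixture name.
#' @param n Colony count for `stuck-lattice`.
#' @param adhesion Initial adhesion state for `stuck-lattice`.
#' @return A `gut_world` (for `dosing-minimal`, with a `dosing` attribute).
#' @export
make_fixture <- function(name, n = 1000L, adhesion = c("mucus", "free")) {
  adhesion <- match.arg(adhesion)
  config <- default_config()
  config$rng_seed <- 0L
  switch(name,
    "tiny-world" = {
      config$n_elements <- 5L
      config$initial_total <- 10L
      config$max_per_element <- 50L
      for (i in seq_along(config$metabolites))
        config$metabolites[[i]]$inflow_per_step <- 0
      config$metabolites[[match("glucose", metabolite_names(config))]]$inflow_per_step <- 3
      config$bacteria_inflow_per_step <- c(Bifidobacterium = 1)
      # 10 colonies cannot represent the sub-1% genera; that is intentional
      suppressWarnings(seed_world(config))
    },
    "starvation-single" = {
      config$initial_total <- 1L
      config$flow$displacement_per_step <- 0
      config$genera <- list(genus_spec("Bifidobacterium", "glucose",
                                       doubling_time = 10^9,
                                       initial_percent = 100))
      for (i in seq_along(config$metabolites))
        config$metabolites[[i]]$inflow_per_step <- 0
      config$bacteria_inflow_per_step <- c(Bifidobacterium = 0)
      seed_world(config)
    },
    "stuck-lattice" = {
      config$initial_total <- 0L
      config$flow$displacement_per_step <- 0
      for (i in seq_along(config$metabolites))
        config$metabolites[[i]]$inflow_per_step <- 0
      config$bacteria_inflow_per_step <- c(Bifidobacterium = 0)
      config$max_per_element <- max(config$max_per_element, as.integer(n))
      state <- seed_world(config)
      state$genus <- rep(1L, n)
      state$energy <- rep(config$energy$energy_max, n)
      state$x <- stats::runif(n)   # all on element 0
      state$adhesion <- rep(if (adhesion == "mucus") 1L else 0L, n)
      state
    },
    "dosing-minimal" = {
      config$initial_total <- 0L
      for (i in seq_along(config$metabolites))
        config$metabolites[[i]]$inflow_per_step <- 0
      config$bacteria_inflow_per_step <- c(Bifidobacterium = 0)
      state <- seed_world(config)
      attr(state, "dosing") <- list(genus = "Bifidobacterium",
                                    amount = 5000L, period = 480L)
      state
    },
    stop("unknown fixture: ", name)
  )
}

#' Write ensemble outputs as tidy CSVs plus a run manifest
#'
#' Writes `series.csv` (`scenario, replicate, timestep, genus, count`),
#' `spatial.csv` (`scenario, replicate, timestep, element, count`),
#' `summary.csv` (`scenario, timestep, genus, mean, lo, hi`), `heatmap.csv`
#' (ensemble-mean totals; rows = elements, columns = recorded timesteps),
#' `config.yaml`, and `manifest.json` recording the seeds, replicate count,
#' file list and config checksum needed for an exact rerun.
#'
#' @param results A `gut_ensemble`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  stopifnot(inherits(results, "gut_ensemble"), length(results$runs) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- results$scenario
  runs <- results$runs

  series <- do.call(rbind, lapply(runs, function(r)
    cbind(scenario = scen, replicate = r$seed, r$series)))
  utils::write.csv(series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)

  spatial <- do.call(rbind, lapply(runs, function(r) {
    m <- r$spatial
    data.frame(scenario = scen, replicate = r$seed,
               timestep = rep(as.integer(rownames(m)), times = ncol(m)),
               element = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               count = as.vector(m))
  }))
  utils::write.csv(spatial, file.path(out_dir, "spatial.csv"),
                   row.names = FALSE)

  smry <- summarize_ensemble(results)
  utils::write.csv(cbind(scenario = scen, smry$series),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)

  heat <- Reduce(`+`, lapply(runs, `[[`, "spatial")) / length(runs)
  hm <- as.data.frame(t(heat))
  names(hm) <- paste0("t", rownames(runs[[1]]$spatial))
  hm <- cbind(element = seq_len(nrow(hm)) - 1L, hm)
  utils::write.csv(hm, file.path(out_dir, "heatmap.csv"), row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(runs[[1]]$state$config, cfg_path)

  manifest <- list(
    package = "gutsim",
    version = as.character(utils::packageVersion("gutsim")),
    scenario = scen,
    base_seed = results$base_seed,
    seeds = vapply(runs, `[[`, integer(1), "seed"),
    n_replicates = length(runs),
    total_steps = max(runs[[1]]$series$timestep),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = c("series.csv", "spatial.csv", "summary.csv", "heatmap.csv",
              "config.yaml"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
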