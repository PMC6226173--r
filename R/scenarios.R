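#' Scenario names understood by [build_scenario()]
#' @export
scenario_names <- function() {
  c("control", "probiotic-low", "probiotic-high", "glucose-high",
    "glucose-low", "constipation", "diarrhea")
}

#' Build the three-phase perturbation protocol for a named scenario
#'
#' Every scenario is a baseline / perturbation / recovery schedule of three
#' equal phases (10000 steps each by default, about three simulated days per
#' phase at 26.3 s/step). Only the middle phase carries overrides:
#' \describe{
#'   \item{probiotic-low / probiotic-high}{5000 / 10000 Bifidobacterium
#'     colonies dosed at the inlet every 480 steps (~3.5 h).}
#'   \item{glucose-high / glucose-low}{glucose inflow 60 / 15 units per step
#'     (baseline 30).}
#'   \item{constipation / diarrhea}{displacement divided / multiplied by 3
#'     (baseline 0.278).}
#'   \item{control}{no overrides, no dosing.}
#' }
#'
#' @param name One of [scenario_names()].
#' @param base Base configuration.
#' @param phase_steps Length of each phase in timesteps.
#' @return List of three phases; each phase has `name`, `start`, `end`
#'   (half-open `[start, end)`), `overrides` (named list) and `dosing`
#'   (`NULL` or a rule with `genus`, `amount`, `period`).
#' @export
build_scenario <- function(name, base = default_config(),
                           phase_steps = 10000L) {
  name <- match.arg(name, scenario_names())
  phase_steps <- as.integer(phase_steps)
  stopifnot(phase_steps >= 1)
  d0 <- base$flow$displacement_per_step
  overrides <- switch(name,
    "control" = list(),
    "probiotic-low" = list(),
    "probiotic-high" = list(),
    "glucose-high" = list(glucose_inflow = 60),
    "glucose-low" = list(glucose_inflow = 15),
    "constipation" = list(displacement = d0 / 3),
    "diarrhea" = list(displacement = d0 * 3))
  dosing <- switch(name,
    "probiotic-low" = list(genus = "Bifidobacterium", amount = 5000L,
                           period = 480L),
    "probiotic-high" = list(genus = "Bifidobacterium", amount = 10000L,
                            period = 480L),
    NULL)
  mk <- function(nm, k, ov, dose) {
    list(name = nm, start = (k - 1L) * phase_steps, end = k * phase_steps,
         overrides = ov, dosing = dose)
  }
  list(mk("baseline", 1L, list(), NULL),
       mk("perturbation", 2L, overrides, dosing),
       mk("recovery", 3L, list(), NULL))
}

#' Dosing timesteps within a phase
#'
#' Doses land at `phase$start + k * period` for `k = 0, 1, ...` while inside
#' `[start, end)`; the first dose coincides with the phase's first timestep.
#'
#' @param rule Dosing rule (`genus`, `amount`, `period`).
#' @param phase A phase from [build_scenario()].
#' @return Integer vector of absolute timesteps, ascending (empty for an
#'   empty phase).
#' @export
dosing_times <- function(rule, phase) {
  stopifnot(rule$amount > 0, rule$period >= 1)
  if (phase$end <= phase$start) return(integer(0))
  seq.int(phase$start, phase$end - 1L, by = as.integer(rule$period))
}

# Apply a phase's partial overrides to a configuration.
apply_overrides <- function(config, overrides) {
  for (key in names(overrides)) {
    val <- overrides[[key]]
    switch(key,
      glucose_inflow = {
        i <- match("glucose", metabolite_names(config))
        config$metabolites[[i]]$inflow_per_step <- val
      },
      displacement = {
        config$flow$displacement_per_step <- val
      },
      stop("unknown override: ", key))
  }
  config
}

#' Run one scenario replicate
#'
#' Seeds a world from `base` (with `rng_seed = seed`), then iterates the
#' engine through the scenario's three phases, applying the perturbation
#' phase's overrides and dosing events and reverting them for recovery.
#' Genus counts and per-element totals are recorded every `record_interval`
#' steps (including `t = 0`); full spatial profiles are kept at four key
#' timesteps straddling the perturbation boundaries
#' (`phase_steps -/+ snapshot_offset` and `2*phase_steps -/+ snapshot_offset`).
#'
#' @param name One of [scenario_names()].
#' @param base Base configuration.
#' @param total_steps Total run length; must be divisible by 3 (three equal
#'   phases) and by `record_interval`.
#' @param seed Replicate seed (drives every stochastic draw).
#' @param record_interval Recording period, timesteps.
#' @param snapshot_offset Offset of the key spatial snapshots from the phase
#'   boundaries; must be a multiple of `record_interval`.
#' @return A `gut_run`: `scenario`, `seed`, `series` (data frame `timestep`,
#'   `genus`, `count`), `spatial` (matrix, recorded timesteps x elements),
#'   `snapshots` (4 x elements matrix), `step_log` (data frame, one row per
#'   step), `phases`, and the final `state`.
#' @export
run_scenario <- function(name, base = default_config(), total_steps = 30000L,
                         seed = 1L, record_interval = 100L,
                         snapshot_offset = 100L) {
  total_steps <- as.integer(total_steps)
  record_interval <- as.integer(record_interval)
  if (total_steps %% 3L != 0L)
    stop("total_steps must be divisible by 3")
  if (record_interval >= 1 && total_steps %% record_interval != 0L)
    stop("total_steps must be a multiple of record_interval")
  phase_steps <- total_steps %/% 3L
  phases <- build_scenario(name, base, phase_steps)
  config <- base
  config$rng_seed <- as.integer(seed)
  state <- seed_world(config)
  gn <- genus_names(config)

  series <- list(data.frame(timestep = 0L, genus = gn,
                            count = tabulate(state$genus, length(gn)),
                            stringsAsFactors = FALSE))
  sp0 <- tabulate(floor(state$x) + 1L, config$n_elements)
  spatial <- list(matrix(sp0, 1, config$n_elements, dimnames = list("0", NULL)))
  logs <- list()

  for (ph in phases) {
    eff <- apply_overrides(config, ph$overrides)
    state$config <- eff
    dt <- if (!is.null(ph$dosing)) dosing_times(ph$dosing, ph) else integer(0)
    out <- run_world(state, n_steps = ph$end - ph$start,
                     record_interval = record_interval,
                     dose_times = dt,
                     dose_genus = if (is.null(ph$dosing)) NA_character_
                                  else ph$dosing$genus,
                     dose_amount = if (is.null(ph$dosing)) 0L
                                   else ph$dosing$amount)
    state <- out$state
    series[[length(series) + 1L]] <- out$series
    spatial[[length(spatial) + 1L]] <- out$spatial
    logs[[length(logs) + 1L]] <- out$reports
  }
  state$config <- config   # recovery == baseline config, restored

  series <- do.call(rbind, series)
  series <- series[order(series$timestep, match(series$genus, gn)), ]
  rownames(series) <- NULL
  spatial <- do.call(rbind, spatial)
  snap_t <- c(phase_steps - snapshot_offset, phase_steps + snapshot_offset,
              2L * phase_steps - snapshot_offset,
              2L * phase_steps + snapshot_offset)
  snap_t <- snap_t[snap_t >= 0 & snap_t <= total_steps]
  snapshots <- spatial[as.character(snap_t), , drop = FALSE]
  structure(list(scenario = name, seed = as.integer(seed),
                 series = series, spatial = spatial, snapshots = snapshots,
                 step_log = do.call(rbind, logs), phases = phases,
                 state = state),
            class = "gut_run")
}

#' @export
print.gut_run <- function(x, ...) {
  last <- x$series[x$series$timestep == max(x$series$timestep), ]
  cat("<gut_run>", x$scenario, "| seed", x$seed, "|",
      max(x$series$timestep), "steps\n final counts:",
      paste(sprintf("%s=%d", last$genus, last$count), collapse = ", "), "\n")
  invisible(x)
}
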