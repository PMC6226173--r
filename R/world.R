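#' Seed a world from a configuration
#'
#' Creates `round(initial_total * initial_percent / 100)` colonies per genus,
#' placed uniformly along the lattice at full energy. Seeded colonies start in
#' the mucus layer by default (`config$seed_adhesion = "mucus"`) so the
#' resident community is not washed out before dynamics equilibrate; set
#' `seed_adhesion = "free"` to start them in the lumen instead. The metabolite
#' field starts empty, `t = 0`, and the R RNG is seeded from `config$rng_seed`.
#'
#' @param config A `gut_config` (validated on entry).
#' @return A `gut_world` state: colony vectors (`genus`, `energy`, `x`,
#'   `adhesion`), metabolite matrix `met` (element x metabolite), timestep `t`
#'   and the originating `config`.
#' @export
seed_world <- function(config = default_config()) {
  validate_config(config)
  set.seed(as.integer(config$rng_seed))
  gn <- genus_names(config)
  mn <- metabolite_names(config)
  pct <- vapply(config$genera, `[[`, numeric(1), "initial_percent")
  counts <- round(config$initial_total * pct / 100)
  lost <- pct > 0 & counts == 0 & config$initial_total > 0
  if (any(lost))
    warning("initial_total too small to represent: ",
            paste(gn[lost], collapse = ", "))
  n <- sum(counts)
  genus <- rep(seq_along(gn), counts)
  adh <- if (identical(config$seed_adhesion, "mucus")) 1L else 0L
  state <- list(
    config = config,
    genus = as.integer(genus),
    energy = rep(config$energy$energy_max, n),
    x = stats::runif(n, 0, config$n_elements),
    adhesion = rep(adh, n),
    met = matrix(0, config$n_elements, length(mn),
                 dimnames = list(NULL, mn)),
    binflow_acc = stats::setNames(rep(0, length(gn)), gn),
    t = 0L
  )
  structure(state, class = "gut_world")
}

#' @export
print.gut_world <- function(x, ...) {
  gn <- genus_names(x$config)
  counts <- tabulate(x$genus, length(gn))
  cat("<gut_world> t =", x$t, "|", length(x$genus), "colonies |",
      sprintf("%.1f metabolite units\n", sum(x$met)))
  cat(paste(sprintf("  %s: %d", gn, counts), collapse = "\n"), "\n")
  invisible(x)
}

#' Colony table of a world state
#'
#' @param x A `gut_world`.
#' @param ... Unused.
#' @return A data frame with one row per colony: `genus`, `x`, `element`
#'   (0-based, `floor(x)`), `energy`, `adhesion` (`FREE`/`MUCUS`/`SEED`).
#' @export
as.data.frame.gut_world <- function(x, ...) {
  data.frame(genus = genus_names(x$config)[x$genus],
             x = x$x,
             element = floor(x$x),
             energy = x$energy,
             adhesion = c("FREE", "MUCUS", "SEED")[x$adhesion + 1L],
             stringsAsFactors = FALSE)
}

# Internal: the fields the C++ engine consumes / returns.
.engine_state <- function(state) {
  acc <- state$binflow_acc
  if (is.null(acc)) acc <- rep(0, length(state$config$genera))
  list(genus = state$genus, energy = state$energy, x = state$x,
       adhesion = state$adhesion, met = state$met,
       binflow_acc = as.numeric(acc), t = as.numeric(state$t))
}

.merge_state <- function(state, engine_world) {
  state$genus <- engine_world$genus
  state$energy <- engine_world$energy
  state$x <- engine_world$x
  state$adhesion <- engine_world$adhesion
  met <- engine_world$met
  dimnames(met) <- list(NULL, metabolite_names(state$config))
  state$met <- met
  state$binflow_acc <- stats::setNames(engine_world$binflow_acc,
                                       genus_names(state$config))
  state$t <- as.integer(engine_world$t)
  state
}

.extra_vector <- function(state, extra) {
  gn <- genus_names(state$config)
  out <- stats::setNames(rep(-1L, length(gn)), gn)
  if (length(extra)) {
    stopifnot(!is.null(names(extra)), all(names(extra) %in% gn),
              all(extra >= 0))
    out[names(extra)] <- as.integer(extra)
  }
  out
}

#' Apply the fixed-flux boundary condition
#'
#' Adds each metabolite's `inflow_per_step` units to the entrance element and
#' introduces the configured per-genus colony inflow at the entrance (positions
#' uniform in element 0, full energy, FREE). `extra` colonies, e.g. a probiotic
#' dose, are added on top of (`replace = FALSE`) or instead of
#' (`replace = TRUE`) the configured inflow for the named genera.
#'
#' @param state A `gut_world`.
#' @param extra Named integer vector, genus -> colony count; may be empty.
#' @param replace Whether `extra` replaces the configured inflow for that
#'   genus this step (probiotic dosing semantics) or adds to it.
#' @return List with the updated `state` and a named `report` vector.
#' @export
inject_boundary <- function(state, extra = integer(), replace = FALSE) {
  out <- cpp_inject(.engine_state(state), engine_params(state$config),
                    .extra_vector(state, extra), replace)
  list(state = .merge_state(state, out$world), report = out$report)
}

#' Census of one lattice element
#'
#' @param state A `gut_world`.
#' @param element 0-based element index (`floor(x)` convention).
#' @return List: `genus` (named counts), `total`, and `hungry` (named by
#'   metabolite: colonies with energy below the hungry threshold that can
#'   consume that metabolite).
#' @export
local_census <- function(state, element) {
  config <- state$config
  if (element < 0 || element >= config$n_elements)
    stop("element must be in [0, ", config$n_elements, ")")
  gn <- genus_names(config)
  mn <- metabolite_names(config)
  here <- floor(state$x) == element
  counts <- tabulate(state$genus[here], length(gn))
  hungry <- state$energy < config$energy$hungry_threshold & here
  eats <- vapply(mn, function(m) {
    ok <- vapply(config$genera, function(g) m %in% g$consumes, logical(1))
    sum(hungry & ok[state$genus])
  }, numeric(1))
  list(genus = stats::setNames(counts, gn),
       total = sum(counts),
       hungry = eats)
}
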