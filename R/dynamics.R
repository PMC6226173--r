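#' Probability that a free colony sticks to the mucus layer
#'
#' The per-step adhesion probability decreases with local crowding:
#' \deqn{\gamma = \gamma_{max}\left[1 - \frac{N}{N_{mid} + N}\right]
#'             = \gamma_{max}\frac{N_{mid}}{N_{mid} + N}}
#' where `N` is the number of colonies on the element and `N_mid` the crowding
#' midpoint (the local count at which the probability halves). At `N = 0` the
#' probability equals `gamma_max`; it is strictly decreasing in `N`.
#'
#' @param N Local colony count(s), >= 0. Vectorized.
#' @param params Adhesion parameter list with `gamma_max` and `n_mid`
#'   (e.g. `default_config()$adhesion`).
#' @return Stick probability in `[0, gamma_max]`.
#' @export
stuck_probability <- function(N, params) {
  stopifnot(all(N >= 0), params$n_mid > 0)
  params$gamma_max * params$n_mid / (params$n_mid + N)
}

.op_wrap <- function(state, fun) {
  out <- fun(.engine_state(state), engine_params(state$config))
  list(state = .merge_state(state, out$world), report = out$report)
}

#' Adhesion transitions for every colony
#'
#' FREE colonies stick with probability [stuck_probability()] evaluated at the
#' local count of their element; MUCUS colonies become permanently embedded
#' (SEED) with probability `p_embed`, otherwise escape back to FREE with
#' probability `p_unstick`. SEED colonies never change state.
#'
#' @param state A `gut_world`.
#' @return List with the updated `state` and a `report` containing
#'   `stuck_events`, `unstuck_events`, `embed_events`.
#' @export
update_adhesion <- function(state) .op_wrap(state, cpp_update_adhesion)

#' Advect free colonies and metabolites downstream
#'
#' Every FREE colony moves by `displacement_per_step` element units; MUCUS and
#' SEED colonies hold their position. Colonies carried past the last element
#' are removed (washout). Unless `flow$advect_metabolites` is `FALSE`, a
#' fraction `min(1, displacement)` of each element's metabolite units moves one
#' element downstream, and units leaving the last element are lost.
#'
#' @param state A `gut_world`.
#' @return List with the updated `state` and a `report` containing `washouts`
#'   and `met_washed`.
#' @export
advect <- function(state) .op_wrap(state, cpp_advect)

#' Consumption, energy bookkeeping and starvation deaths
#'
#' Allocates metabolite units to hungry colonies on every element (see
#' [allocate_consumption()] for the rule), then applies the energetic
#' consequences: each consumer gains `gain_per_unit` energy (capped at
#' `energy_max`) and deposits its production yields on its element; every
#' colony then loses `energy_max / starvation_steps` energy, and colonies
#' whose energy reaches zero are removed as starvation deaths.
#'
#' @param state A `gut_world`.
#' @return List with the updated `state` and a `report` containing
#'   `consumed`, `produced`, `deaths_starvation`.
#' @export
metabolize <- function(state) .op_wrap(state, cpp_metabolize)

#' Scheduled reproduction
#'
#' At timesteps that are multiples of a genus' doubling time, each of its
#' colonies with strictly more than `reproduce_min_energy` energy, on an
#' element below `max_per_element` occupancy, spawns a daughter at the same
#' position. Parent and daughter each keep half the parent's energy; the
#' daughter is released from the mucosal layer (FREE) while the parent retains
#' its adhesion state.
#'
#' @param state A `gut_world`.
#' @return List with the updated `state` and a `report` containing `births`.
#' @export
reproduce <- function(state) .op_wrap(state, cpp_reproduce)

#' Dry-run consumption allocation on one element
#'
#' For each metabolite in the configured priority order with `U` whole units
#' on the element and `H` hungry eligible colonies: if `H <= U` every hungry
#' colony consumes one unit; otherwise exactly `U` colonies drawn uniformly at
#' random (without replacement) consume one unit each. A colony consumes at
#' most one unit of at most one metabolite per step. This helper reports the
#' assignment without modifying the state.
#'
#' @param state A `gut_world`.
#' @param element 0-based element index.
#' @return Data frame with one row per meal: `colony` (index into the state's
#'   colony vectors) and `metabolite` (name).
#' @export
allocate_consumption <- function(state, element) {
  config <- state$config
  if (element < 0 || element >= config$n_elements)
    stop("element must be in [0, ", config$n_elements, ")")
  out <- cpp_allocate_element(.engine_state(state), engine_params(config),
                              as.integer(element))
  data.frame(colony = out$colony,
             metabolite = metabolite_names(config)[out$metabolite],
             stringsAsFactors = FALSE)
}

#' Advance the world by one timestep
#'
#' Applies, in order: boundary inflow ([inject_boundary()]), adhesion
#' transitions ([update_adhesion()]), advection and washout ([advect()]),
#' consumption and energy bookkeeping ([metabolize()]), reproduction
#' ([reproduce()]); then increments `t`. The ordering is a fixed model
#' constant: newly dosed colonies advect and may feed within their arrival
#' step.
#'
#' @param state A `gut_world`.
#' @param extra Named integer vector of extra boundary colonies (see
#'   [inject_boundary()]); dosing semantics follow
#'   `config$probiotic_dose_mode`.
#' @return List with the updated `state` and a `report` vector covering every
#'   rule firing this step (births, deaths, washouts, adhesion events,
#'   consumption and production totals, population and field totals).
#' @export
step_world <- function(state, extra = integer()) {
  out <- cpp_step(.engine_state(state), engine_params(state$config),
                  .extra_vector(state, extra))
  list(state = .merge_state(state, out$world), report = out$report)
}

#' Advance the world many timesteps, recording trajectories
#'
#' Runs the full per-step update in compiled code, recording genus counts and
#' per-element totals whenever `t` is a multiple of `record_interval`, and a
#' per-step report row for every step.
#'
#' @param state A `gut_world`.
#' @param n_steps Number of timesteps to advance.
#' @param record_interval Recording period in timesteps (0 = no recording).
#' @param dose_times Absolute timesteps at which a dose arrives (pre-step
#'   clock values).
#' @param dose_genus Genus name receiving the dose, or `NA`.
#' @param dose_amount Colonies per dose.
#' @return List: updated `state`, `reports` (data frame, one row per step),
#'   `series` (data frame `timestep`, `genus`, `count`), `spatial` (matrix,
#'   recorded timesteps x elements).
#' @export
run_world <- function(state, n_steps, record_interval = 100L,
                      dose_times = integer(), dose_genus = NA_character_,
                      dose_amount = 0L) {
  gn <- genus_names(state$config)
  gi <- if (is.na(dose_genus)) 0L else match(dose_genus, gn)
  if (is.na(gi)) stop("unknown genus: ", dose_genus)
  out <- cpp_run(.engine_state(state), engine_params(state$config),
                 as.integer(n_steps), as.integer(record_interval),
                 as.integer(dose_times), gi, as.integer(dose_amount))
  series <- data.frame(
    timestep = rep(as.integer(out$rec_t), times = length(gn)),
    genus = rep(gn, each = length(out$rec_t)),
    count = as.integer(out$series),
    stringsAsFactors = FALSE)
  spatial <- out$spatial
  rownames(spatial) <- as.integer(out$rec_t)
  list(state = .merge_state(state, out$world),
       reports = as.data.frame(out$reports),
       series = series,
       spatial = spatial)
}
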