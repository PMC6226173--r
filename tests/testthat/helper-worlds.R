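# Small deterministic worlds used across test files.

# A quiet config: no inflows, no initial colonies; single genus eating glucose.
quiet_config <- function(n_elements = 100L) {
  cfg <- default_config()
  cfg$n_elements <- as.integer(n_elements)
  cfg$rng_seed <- 1L
  cfg$initial_total <- 0L
  cfg$genera <- list(genus_spec("Bifidobacterium", "glucose",
                                produces = list(lactate = 0.01),
                                doubling_time = 480L,
                                initial_percent = 100))
  cfg$bacteria_inflow_per_step <- c(Bifidobacterium = 0L)
  for (i in seq_along(cfg$metabolites))
    cfg$metabolites[[i]]$inflow_per_step <- 0
  cfg
}

# Hand-placed colonies on a quiet world.
place_colonies <- function(config, x, energy, adhesion = 0L, genus = 1L) {
  w <- seed_world(config)
  n <- max(length(x), length(energy))
  w$genus <- rep_len(as.integer(genus), n)
  w$energy <- rep_len(as.numeric(energy), n)
  w$x <- rep_len(as.numeric(x), n)
  w$adhesion <- rep_len(as.integer(adhesion), n)
  w
}

genus_counts <- function(state) {
  tabulate(state$genus, length(state$config$genera))
}
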