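test_that("stick probability follows the crowding-saturated form", {
  p <- list(gamma_max = 0.6, n_mid = 30)
  expect_equal(stuck_probability(0, p), 0.6)          # empty element: maximum
  expect_equal(stuck_probability(30, p), 0.3)         # N = N_mid: half
  expect_equal(stuck_probability(90, p), 0.15)        # 0.6 * 30 / 120

  # oracle equivalence over randomized parameter triples
  set.seed(42)
  gmax <- runif(1e4)
  nmid <- runif(1e4, 0.1, 500)
  N <- sample.int(1000, 1e4, replace = TRUE) - 1L
  direct <- gmax * (1 - N / (nmid + N))
  got <- mapply(function(g, m, n)
    stuck_probability(n, list(gamma_max = g, n_mid = m)), gmax, nmid, N)
  expect_lt(max(abs(got - direct)), 1e-12)

  # strictly decreasing in local count
  expect_true(all(diff(stuck_probability(0:100, p)) < 0))
})

test_that("adhesion transitions fire at their configured frequencies", {
  # degenerate probabilities: no transitions ever
  w <- make_fixture("stuck-lattice", n = 1000, adhesion = "mucus")
  w$config$adhesion <- list(gamma_max = 0, n_mid = 30, p_unstick = 0,
                            p_embed = 0)
  set.seed(1)
  out <- update_adhesion(w)
  expect_identical(out$state$adhesion, w$adhesion)

  # certain sticking: gamma_max = 1 with overwhelming n_mid
  wf <- make_fixture("stuck-lattice", n = 1000, adhesion = "free")
  wf$config$adhesion <- list(gamma_max = 1, n_mid = 1e12, p_unstick = 0,
                             p_embed = 0)
  set.seed(1)
  expect_true(all(update_adhesion(wf)$state$adhesion == 1L))

  # Monte Carlo at n = 1e5: escape frequency ~ p_unstick within 3 sigma
  w <- make_fixture("stuck-lattice", n = 100000, adhesion = "mucus")
  w$config$adhesion$p_embed <- 0
  set.seed(101)
  fr <- update_adhesion(w)$report[["unstuck_events"]] / 1e5
  expect_lt(abs(fr - 0.10), 3 * sqrt(0.1 * 0.9 / 1e5))

  # and embedding frequency ~ p_embed with escape disabled
  w$config$adhesion$p_embed <- 0.05
  w$config$adhesion$p_unstick <- 0
  set.seed(102)
  fr <- update_adhesion(w)$report[["embed_events"]] / 1e5
  expect_lt(abs(fr - 0.05), 3 * sqrt(0.05 * 0.95 / 1e5))

  # free colonies at N = n_mid stick at gamma_max / 2
  set.seed(103)
  stuck <- 0L
  wf <- make_fixture("stuck-lattice", n = 30, adhesion = "free")
  wf$config$adhesion <- list(gamma_max = 0.6, n_mid = 30, p_unstick = 0,
                             p_embed = 0)
  for (i in 1:3400)
    stuck <- stuck + update_adhesion(wf)$report[["stuck_events"]]
  fr <- stuck / (30 * 3400)
  expect_lt(abs(fr - 0.3), 3 * sqrt(0.3 * 0.7 / (30 * 3400)))
})

test_that("advection moves only free colonies and washes out past the end", {
  cfg <- quiet_config()
  w <- place_colonies(cfg, x = c(10.0, 99.9, 50.0), energy = 100,
                      adhesion = c(0L, 0L, 1L))
  out <- advect(w)
  expect_equal(out$state$x, c(10.278, 50.0))   # second colony washed out
  expect_equal(out$report[["washouts"]], 1)
  expect_equal(out$state$adhesion, c(0L, 1L))
})

test_that("metabolites advect by fractional transfer and wash out distally", {
  cfg <- quiet_config(5)
  w <- seed_world(cfg)
  w$met[1, "glucose"] <- 100
  w$met[5, "glucose"] <- 10
  out <- advect(w)
  f <- cfg$flow$displacement_per_step
  expect_equal(unname(out$state$met[1, "glucose"]), 100 * (1 - f))
  expect_equal(unname(out$state$met[2, "glucose"]), 100 * f)
  expect_equal(unname(out$state$met[5, "glucose"]), 10 * (1 - f))
  expect_equal(out$report[["met_washed"]], 10 * f)

  cfg$flow$advect_metabolites <- FALSE
  w <- seed_world(cfg)
  w$met[1, "glucose"] <- 100
  expect_equal(unname(advect(w)$state$met[1, "glucose"]), 100)
})

test_that("consumption allocates min(units, hungry) meals, one per colony", {
  cfg <- quiet_config(5)
  # 5 hungry colonies, 3 units: exactly 3 distinct eaters
  w <- place_colonies(cfg, x = seq(2.1, 2.9, length.out = 5), energy = 60)
  w$met[3, "glucose"] <- 3
  a <- allocate_consumption(w, 2)
  expect_equal(nrow(a), 3)
  expect_false(anyDuplicated(a$colony) > 0)
  expect_true(all(a$metabolite == "glucose"))

  # 4 hungry, 10 units: everyone eats, 6 remain after metabolize
  w <- place_colonies(cfg, x = seq(2.1, 2.9, length.out = 4), energy = 60)
  w$met[3, "glucose"] <- 10
  expect_equal(nrow(allocate_consumption(w, 2)), 4)
  out <- metabolize(w)
  expect_equal(unname(out$state$met[3, "glucose"]), 6)
  expect_equal(out$report[["consumed"]], 4)

  # no units: no consumption
  w$met[3, "glucose"] <- 0
  expect_equal(nrow(allocate_consumption(w, 2)), 0)
})

test_that("metabolism pays energy gains, yields, decay and starvation", {
  cfg <- quiet_config(5)
  cfg$genera[[1]]$produces <- list(lactate = 0.5)
  # hungry colony eats one glucose: +gain then -decay, lactate deposited
  w <- place_colonies(cfg, x = 2.5, energy = 60)
  w$met[3, "glucose"] <- 5
  out <- metabolize(w)
  expect_equal(out$state$energy,
               60 + cfg$energy$gain_per_unit - energy_decay(cfg))
  expect_equal(unname(out$state$met[3, "lactate"]), 0.5)
  expect_equal(unname(out$state$met[3, "glucose"]), 4)

  # sated colony does not eat, only decays
  w <- place_colonies(cfg, x = 2.5, energy = 90)
  w$met[3, "glucose"] <- 5
  out <- metabolize(w)
  expect_equal(out$state$energy, 90 - energy_decay(cfg))
  expect_equal(unname(out$state$met[3, "glucose"]), 5)

  # gain is capped at energy_max (raise the threshold so a near-full colony
  # still eats)
  cfg2 <- cfg
  cfg2$energy$hungry_threshold <- 100
  w <- place_colonies(cfg2, x = 2.5, energy = 95)
  w$met[3, "glucose"] <- 1
  expect_equal(metabolize(w)$state$energy, 100 - energy_decay(cfg2))
})

test_that("a non-eating colony dies exactly at the starvation horizon", {
  w <- make_fixture("starvation-single")
  out <- run_world(w, 1441, record_interval = 0)
  death_t <- out$reports$t[out$reports$deaths_starvation > 0]
  expect_equal(death_t, 1440)
  expect_length(out$state$genus, 0)

  # general clock: death step = ceil(E / decay), reproduction disabled
  cfg <- quiet_config()
  cfg$flow$displacement_per_step <- 0
  cfg$genera[[1]]$doubling_time <- 10^9
  for (E in c(10, 33.4, 100)) {
    w <- place_colonies(cfg, x = 50.5, energy = E, adhesion = 2L)
    out <- run_world(w, 1441, record_interval = 0)
    expect_equal(out$reports$t[out$reports$deaths_starvation > 0],
                 ceiling(E / energy_decay(cfg)))
  }
})

test_that("reproduction halves energy, frees the daughter, gates on time,
           energy and space", {
  cfg <- quiet_config(5)
  w <- place_colonies(cfg, x = 2.5, energy = 80, adhesion = 1L)
  w$t <- 479L   # completing step 480 = doubling time

  out <- reproduce(w)
  expect_equal(out$report[["births"]], 1)
  expect_equal(sort(out$state$energy), c(40, 40))
  expect_setequal(out$state$adhesion, c(0L, 1L))   # daughter FREE, parent kept
  expect_equal(out$state$x[1], out$state$x[2])

  # strict threshold: exactly 50 energy does not reproduce
  w50 <- place_colonies(cfg, x = 2.5, energy = 50, adhesion = 1L)
  w50$t <- 479L
  expect_equal(reproduce(w50)$report[["births"]], 0)

  # off-schedule timestep: no births
  w$t <- 480L
  expect_equal(reproduce(w)$report[["births"]], 0)

  # space constraint: full element blocks reproduction
  cfg2 <- quiet_config(5)
  cfg2$max_per_element <- 3L
  wf <- place_colonies(cfg2, x = c(2.2, 2.5, 2.8), energy = 90, adhesion = 1L)
  wf$t <- 479L
  expect_equal(reproduce(wf)$report[["births"]], 0)
})

test_that("the step loop conserves colonies and metabolite books", {
  w <- make_fixture("tiny-world")
  out <- run_world(w, 2000, record_interval = 0)
  rp <- out$reports
  dpop <- diff(c(length(w$genus), rp$population))
  expect_true(all(dpop ==
    rp$births + rp$inflow - rp$deaths_starvation - rp$washouts))
  dmet <- diff(c(sum(w$met), rp$met_total))
  expect_lt(max(abs(dmet -
    (rp$met_in - rp$consumed - rp$met_washed + rp$produced))), 1e-9)
})

test_that("an empty world with no inflow stays empty", {
  w <- make_fixture("dosing-minimal")
  out <- run_world(w, 100, record_interval = 0)
  expect_length(out$state$genus, 0)
  expect_true(all(out$reports[, c("births", "deaths_starvation", "washouts",
                                  "inflow", "consumed")] == 0))
})

test_that("with adhesion and reproduction disabled, washout empties the world
           within one transit time", {
  cfg <- quiet_config()
  cfg$initial_total <- 500L
  cfg$genera[[1]]$doubling_time <- 10^9
  cfg$seed_adhesion <- "free"
  cfg$adhesion$gamma_max <- 0
  w <- seed_world(cfg)
  horizon <- ceiling(cfg$n_elements / cfg$flow$displacement_per_step) + 1
  out <- run_world(w, horizon, record_interval = 0)
  expect_length(out$state$genus, 0)
  expect_true(all(diff(out$reports$population) <= 0))
})

test_that("composed single steps reproduce the compiled run loop exactly", {
  w <- make_fixture("tiny-world")
  set.seed(9)
  a <- run_world(w, 150, record_interval = 0)
  set.seed(9)
  s <- w
  for (k in 1:150) s <- step_world(s)$state
  expect_identical(a$state$genus, s$genus)
  expect_identical(a$state$energy, s$energy)
  expect_identical(a$state$x, s$x)
  expect_identical(a$state$adhesion, s$adhesion)
  expect_identical(a$state$met, s$met)
})

test_that("identical seeds give identical trajectories", {
  w <- make_fixture("tiny-world")
  set.seed(5); a <- run_world(w, 300, record_interval = 50)
  set.seed(5); b <- run_world(w, 300, record_interval = 50)
  expect_identical(a$reports, b$reports)
  expect_identical(a$series, b$series)
  expect_identical(a$state$x, b$state$x)
})
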