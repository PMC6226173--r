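test_that("ci95 matches the closed-form t interval", {
  expect_equal(ci95(c(7, 7, 7)), c(mean = 7, lo = 7, hi = 7))
  expect_equal(ci95(5), c(mean = 5, lo = 5, hi = 5))   # degenerate n = 1
  got <- ci95(c(8, 10, 12))
  expect_equal(unname(got["mean"]), 10)
  # s = 2, t_{0.975,2} = 4.302653: half-width 4.9685
  expect_equal(unname(got["hi"] - got["mean"]), 4.9685, tolerance = 1e-3)
  expect_true(got["lo"] <= got["mean"] && got["mean"] <= got["hi"])
})

test_that("ci width shrinks with replicate count on iid samples", {
  set.seed(31)
  width <- vapply(c(10, 100, 1000), function(n) {
    ci <- ci95(runif(n))
    unname(ci["hi"] - ci["lo"])
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

make_series <- function(counts, genus = "Bifidobacterium") {
  data.frame(timestep = seq(0, by = 100, length.out = length(counts)),
             genus = genus, count = counts, stringsAsFactors = FALSE)
}

test_that("ensembles assign distinct consecutive seeds and aggregate", {
  cfg <- quiet_config()
  cfg$metabolites[[1]]$inflow_per_step <- 3
  cfg$bacteria_inflow_per_step <- c(Bifidobacterium = 1L)
  ens <- run_ensemble("control", cfg, n_replicates = 3, base_seed = 40L,
                      total_steps = 600L)
  expect_equal(vapply(ens$runs, `[[`, integer(1), "seed"), c(41L, 42L, 43L))

  smry <- summarize_ensemble(ens)
  expect_true(all(smry$series$lo <= smry$series$mean + 1e-12))
  expect_true(all(smry$series$mean <= smry$series$hi + 1e-12))

  # cross-table consistency: spatial means sum to the series total mean
  tot <- tapply(smry$series$mean, smry$series$timestep, sum)
  sp <- tapply(smry$spatial$mean, smry$spatial$timestep, sum)
  expect_equal(unname(sp[names(tot)]), unname(tot))

  # single-replicate ensemble mean is the run itself
  e1 <- run_ensemble("control", cfg, n_replicates = 1, base_seed = 40L,
                     total_steps = 600L)
  s1 <- summarize_ensemble(e1)
  expect_equal(s1$series$mean, as.numeric(e1$runs[[1]]$series$count))

  # rerun with the same base seed: identical ensemble
  ens2 <- run_ensemble("control", cfg, n_replicates = 3, base_seed = 40L,
                       total_steps = 600L)
  expect_identical(lapply(ens$runs, `[[`, "series"),
                   lapply(ens2$runs, `[[`, "series"))
})

test_that("percent difference transforms against the control mean", {
  cfg <- quiet_config()
  cfg$metabolites[[1]]$inflow_per_step <- 3
  cfg$bacteria_inflow_per_step <- c(Bifidobacterium = 1L)
  ens <- run_ensemble("control", cfg, n_replicates = 2, base_seed = 40L,
                      total_steps = 600L)
  # a treated arm identical to control differs by exactly zero
  pd <- percent_difference(ens, ens)
  expect_true(all(pd$pct_diff[!pd$undefined] == 0))

  # hand-built arithmetic: treated 340 vs control 200 is +70%
  mk_ens <- function(counts) {
    runs <- lapply(seq_along(counts), function(i)
      structure(list(seed = i, series = make_series(rep(counts[i], 4)),
                     spatial = matrix(0, 4, 1,
                                      dimnames = list(seq(0, 300, 100), NULL))),
                class = "gut_run"))
    structure(list(scenario = "x", base_seed = 0L, runs = runs),
              class = "gut_ensemble")
  }
  pd <- percent_difference(mk_ens(c(340, 340)), mk_ens(c(200, 200)))
  expect_true(all(pd$pct_diff == 70))

  # zero control mean is flagged, never infinite
  pd0 <- percent_difference(mk_ens(c(5, 5)), mk_ens(c(0, 0)))
  expect_true(all(pd0$undefined))
  expect_true(all(is.na(pd0$pct_diff)))
})

test_that("steady-state detection finds the changepoint and rejects trends", {
  # constant series: steady at the first testable point
  s <- make_series(rep(500, 40))
  expect_equal(detect_steady_state(s, window = 500, tol = 0.05), 900)

  # flat after a changepoint at t = 2000: the comparison needs two clean
  # windows, so detection lands within two windows of the changepoint
  set.seed(8)
  counts <- c(seq(2000, 600, length.out = 20) + rnorm(20, 0, 30),
              rep(600, 20))
  st <- detect_steady_state(make_series(counts), window = 500, tol = 0.05)
  expect_true(st >= 2000 && st <= 3000)

  # strictly growing series with tol below the slope: never steady
  expect_true(is.na(detect_steady_state(make_series(seq(100, 4000, 100)),
                                        window = 500, tol = 0.01)))

  expect_error(detect_steady_state(make_series(rep(1, 3)), window = 500),
               "2 windows")
})

test_that("extinction requires hitting zero and staying there", {
  s <- rbind(make_series(c(rep(5, 10), rep(0, 10)), "Desulfovibrio"),
             make_series(c(rep(5, 10), 0, rep(3, 9)), "Clostridium"),
             make_series(rep(2, 20), "Bacteroides"))
  et <- extinction_times(s)
  expect_equal(unname(et["Desulfovibrio"]), 1000)   # 11th point, t = 1000
  expect_true(is.na(et["Clostridium"]))             # dip then recovery
  expect_true(is.na(et["Bacteroides"]))             # never zero
})
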