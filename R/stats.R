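#' Run a replicate ensemble of one scenario
#'
#' Replicate `i` runs with seed `base_seed + i` (`i = 1..n_replicates`), so an
#' ensemble is fully reproducible from its base seed and replicate count.
#'
#' @param name One of [scenario_names()].
#' @param config Base configuration.
#' @param n_replicates Number of independent replicates (the reference
#'   experiments used 100; 10 gives useful intervals in minutes).
#' @param base_seed Integer; replicate seeds are `base_seed + 1 ... + n`.
#' @param ... Passed to [run_scenario()] (`total_steps`, `record_interval`...).
#' @return A `gut_ensemble`: list with `scenario`, `base_seed` and `runs`
#'   (list of `gut_run`).
#' @export
run_ensemble <- function(name, config = default_config(), n_replicates = 10L,
                         base_seed = 1L, ...) {
  stopifnot(n_replicates >= 1)
  runs <- lapply(seq_len(n_replicates), function(i) {
    run_scenario(name, base = config, seed = base_seed + i, ...)
  })
  structure(list(scenario = name, base_seed = as.integer(base_seed),
                 runs = runs),
            class = "gut_ensemble")
}

#' @export
print.gut_ensemble <- function(x, ...) {
  cat("<gut_ensemble>", x$scenario, "|", length(x$runs),
      "replicates | base seed", x$base_seed, "\n")
  invisible(x)
}

#' Mean and 95% confidence interval of replicate samples
#'
#' Student-t interval: mean +/- `qt(0.975, n-1) * s / sqrt(n)`. A single
#' sample yields the degenerate interval `(mean, mean, mean)`.
#'
#' @param values Numeric vector of per-replicate samples (length >= 1).
#' @return Named vector `mean`, `lo`, `hi`.
#' @export
ci95 <- function(values) {
  n <- length(values)
  stopifnot(n >= 1)
  m <- mean(values)
  if (n == 1L) return(c(mean = m, lo = m, hi = m))
  h <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lo = m - h, hi = m + h)
}

# Stack an ensemble's genus series into an array [timestep, genus, replicate].
series_array <- function(ensemble) {
  s1 <- ensemble$runs[[1]]$series
  ts <- sort(unique(s1$timestep))
  gn <- unique(s1$genus)
  arr <- vapply(ensemble$runs, function(r) {
    s <- r$series
    matrix(s$count[order(s$timestep, match(s$genus, gn))],
           nrow = length(ts), ncol = length(gn), byrow = TRUE)
  }, matrix(0, length(ts), length(gn)))
  dimnames(arr) <- list(ts, gn, NULL)
  arr
}

spatial_array <- function(ensemble) {
  mats <- lapply(ensemble$runs, `[[`, "spatial")
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  dimnames(arr) <- list(rownames(mats[[1]]), NULL, NULL)
  arr
}

.apply_ci <- function(arr) {
  m <- apply(arr, c(1, 2), mean)
  n <- dim(arr)[3]
  if (n == 1L) {
    lo <- hi <- m
  } else {
    s <- apply(arr, c(1, 2), stats::sd)
    h <- stats::qt(0.975, n - 1) * s / sqrt(n)
    lo <- m - h
    hi <- m + h
  }
  list(mean = m, lo = lo, hi = hi)
}

#' Cross-replicate summary of an ensemble
#'
#' @param ensemble A `gut_ensemble`.
#' @return A `gut_summary`: `series` (data frame `timestep`, `genus`, `mean`,
#'   `lo`, `hi`) and `spatial` (data frame `timestep`, `element`, `mean`,
#'   `lo`, `hi`; elements 0-based), both with t-based 95% intervals.
#' @export
summarize_ensemble <- function(ensemble) {
  arr <- series_array(ensemble)
  ci <- .apply_ci(arr)
  ts <- as.integer(dimnames(arr)[[1]])
  gn <- dimnames(arr)[[2]]
  series <- data.frame(
    timestep = rep(ts, times = length(gn)),
    genus = rep(gn, each = length(ts)),
    mean = as.vector(ci$mean), lo = as.vector(ci$lo), hi = as.vector(ci$hi),
    stringsAsFactors = FALSE)
  sp <- spatial_array(ensemble)
  sci <- .apply_ci(sp)
  st <- as.integer(dimnames(sp)[[1]])
  nE <- dim(sp)[2]
  spatial <- data.frame(
    timestep = rep(st, times = nE),
    element = rep(seq_len(nE) - 1L, each = length(st)),
    mean = as.vector(sci$mean), lo = as.vector(sci$lo),
    hi = as.vector(sci$hi),
    stringsAsFactors = FALSE)
  structure(list(scenario = ensemble$scenario, n = length(ensemble$runs),
                 series = series, spatial = spatial),
            class = "gut_summary")
}

#' Percent difference from control, per genus and timestep
#'
#' For each (timestep, genus), every treated replicate's count is transformed
#' to `100 * (count - control_mean) / control_mean`, where `control_mean` is
#' the control ensemble mean; the reported value and interval are the mean and
#' t-based 95% CI of those transformed replicates. Timesteps where the control
#' mean is zero are flagged `undefined` (`NA` values, never +/-Inf).
#'
#' @param treated A `gut_ensemble`.
#' @param control A `gut_ensemble` recorded on the same timesteps.
#' @return Data frame: `timestep`, `genus`, `pct_diff`, `lo`, `hi`,
#'   `undefined`.
#' @export
percent_difference <- function(treated, control) {
  ta <- series_array(treated)
  ca <- series_array(control)
  if (!identical(dimnames(ta)[[1]], dimnames(ca)[[1]]))
    stop("control series does not cover the treated timesteps")
  cm <- apply(ca, c(1, 2), mean)
  nrep <- dim(ta)[3]
  pct <- ta
  for (k in seq_len(nrep)) pct[, , k] <- 100 * (ta[, , k] - cm) / cm
  ok <- cm != 0
  ci <- .apply_ci(pct)
  for (f in c("mean", "lo", "hi")) ci[[f]][!ok] <- NA_real_
  ts <- as.integer(dimnames(ta)[[1]])
  gn <- dimnames(ta)[[2]]
  data.frame(
    timestep = rep(ts, times = length(gn)),
    genus = rep(gn, each = length(ts)),
    pct_diff = as.vector(ci$mean), lo = as.vector(ci$lo),
    hi = as.vector(ci$hi),
    undefined = rep(!as.vector(ok)),
    stringsAsFactors = FALSE)
}

#' Detect an approximate steady state in a recorded series
#'
#' Compares consecutive non-overlapping windows of the recorded counts: the
#' first timestep `t` at which, for every genus, the relative change between
#' the window ending at `t` and the previous window satisfies
#' `|m1 - m0| / max(1, m0) < tol` is reported as the steady-state onset.
#'
#' @param series Data frame `timestep`, `genus`, `count` (one trajectory or an
#'   ensemble mean with `mean` renamed to `count`).
#' @param window Window length in timesteps (>= 2 recording intervals).
#' @param tol Relative tolerance between window means.
#' @return The earliest steady timestep, or `NA` if never reached.
#' @export
detect_steady_state <- function(series, window = 1000L, tol = 0.05) {
  ts <- sort(unique(series$timestep))
  if (length(ts) < 2L) stop("series shorter than 2 windows")
  interval <- min(diff(ts))
  k <- max(2L, as.integer(round(window / interval)))
  if (length(ts) < 2L * k) stop("series shorter than 2 windows")
  gn <- unique(series$genus)
  counts <- vapply(gn, function(g) {
    s <- series[series$genus == g, ]
    s$count[order(s$timestep)]
  }, numeric(length(ts)))
  for (j in seq(2L * k, length(ts))) {
    m1 <- colMeans(counts[(j - k + 1L):j, , drop = FALSE])
    m0 <- colMeans(counts[(j - 2L * k + 1L):(j - k), , drop = FALSE])
    if (all(abs(m1 - m0) / pmax(1, m0) < tol)) return(ts[j])
  }
  NA_integer_
}

#' First timestep at which each genus is extinct
#'
#' A genus is extinct at the first recorded timestep where its count is zero
#' and remains zero through the end of the series; a transient dip to zero
#' followed by recovery (e.g. via boundary inflow) does not count.
#'
#' @param series Data frame `timestep`, `genus`, `count`.
#' @return Named integer vector (timestep per genus, `NA` if never extinct).
#' @export
extinction_times <- function(series) {
  gn <- unique(series$genus)
  out <- stats::setNames(rep(NA_integer_, length(gn)), gn)
  for (g in gn) {
    s <- series[series$genus == g, ]
    s <- s[order(s$timestep), ]
    nz <- which(s$count > 0)
    first0 <- if (length(nz) == 0) 1L
              else if (max(nz) == nrow(s)) NA_integer_
              else max(nz) + 1L
    if (!is.na(first0)) out[g] <- s$timestep[first0]
  }
  out
}
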