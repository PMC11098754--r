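#' One binomial tau-leap step of a set of lineages
#'
#' Advances lineage states by `dt` days. Event counts are drawn from
#' binomial distributions evaluated at the step-start state: per lineage,
#' `d_s ~ Binom(s, r_s*dt)` symmetric divisions, `d_a ~ Binom(s, r_a*dt)`
#' transitions and `d_n ~ Binom(a, r_n*dt)` asymmetric divisions (each with
#' mean rate x cell count x dt). The updated state is
#' `s' = s + d_s - d_a`, `a' = a + d_a`, `n' = n + k*d_n`. In the
#' `direct_neurogenesis` variant an additional draw
#' `d_dn ~ Binom(s, r_dn*dt)` consumes one S cell and adds two N cells.
#'
#' Because the S-removing draws are independent of the division draw, their
#' sum can in principle exceed the available `s + d_s`; removal draws are
#' then capped (transition first, then direct neurogenesis) so that counts
#' stay non-negative. Under the automatic step rule the probability of the
#' cap triggering is below 1e-4.
#'
#' @param state Either a named vector `c(s=, a=, n=)` for one lineage or a
#'   list of integer vectors `s`, `a`, `n` of equal length for many.
#' @param params A [model_params()] object.
#' @param dt Step length in days; `dt * max(rates)` must be <= 1.
#' @return An object of the same shape as `state`.
#' @export
step_lineage <- function(state, params, dt) {
  single <- !is.list(state)
  st <- if (single) list(s = state[["s"]], a = state[["a"]], n = state[["n"]])
        else state
  out <- step_lineages_(st, params, dt)
  if (single) c(s = out$s, a = out$a, n = out$n) else out
}

# Vectorized stepping core; `st` is list(s, a, n) of equal-length vectors.
step_lineages_ <- function(st, params, dt) {
  if (dt * max_rate(params) > 1)
    stop_user("dt * max(rates) exceeds 1: binomial event probability invalid")
  L <- length(st$s)
  d_s <- rbinom(L, st$s, params$r_s * dt)
  d_a <- rbinom(L, st$s, params$r_a * dt)
  d_n <- rbinom(L, st$a, params$r_n * dt)
  avail <- st$s + d_s
  d_a <- pmin(d_a, avail)
  if (params$variant == "direct_neurogenesis") {
    d_dn <- pmin(rbinom(L, st$s, params$r_dn * dt), avail - d_a)
  } else {
    d_dn <- 0L
  }
  list(s = st$s + d_s - d_a - d_dn,
       a = st$a + d_a,
       n = st$n + params$k * d_n + 2L * d_dn)
}

# Advance all lineages from t0 to t1 in steps of at most dt.
advance_ <- function(st, params, t0, t1, dt) {
  remaining <- t1 - t0
  n_full <- floor(remaining / dt + 1e-9)
  for (i in seq_len(n_full)) st <- step_lineages_(st, params, dt)
  rest <- remaining - n_full * dt
  if (rest > 1e-9) st <- step_lineages_(st, params, rest)
  st
}

#' Simulate an organoid as independent barcoded lineages
#'
#' Each lineage starts as a single S cell and is advanced with the binomial
#' tau-leap scheme at the automatic time step ([choose_time_step()]); all
#' lineages are statistically independent and there are no death events, so
#' lineage size is non-decreasing. The default organoid comprises 10,000
#' lineages. When all rates are zero the (constant) trajectories are still
#' returned.
#'
#' @param params A [model_params()] object.
#' @param init Optional list of vectors `s`, `a`, `n` giving the starting
#'   state of every lineage (defaults to one S cell each).
#' @param t_start Day at which `init` applies (default 0). Only record
#'   times at or after `t_start` are recorded.
#' @return An object of class `organoid_sim`: a list with `states` (a long
#'   data frame `lineage`, `time`, `s`, `a`, `n`) and `params`.
#' @examples
#' p <- model_params(r_s = 1, variant = "symmetric_only", t_end = 1,
#'                   n_lineages = 50, seed = 1)
#' sim <- simulate_organoid(p)
#' mean(lineage_sizes(sim, 1))  # close to exp(1)
#' @export
simulate_organoid <- function(params, init = NULL, t_start = 0) {
  stopifnot(inherits(params, "clone_model_params"))
  L <- params$n_lineages
  if (is.null(init)) {
    st <- list(s = rep(1L, L), a = rep(0L, L), n = rep(0L, L))
  } else {
    stopifnot(length(init$s) == L, length(init$a) == L, length(init$n) == L)
    st <- lapply(init[c("s", "a", "n")], as.integer)
  }
  rec <- params$record_times[params$record_times >= t_start - 1e-9]
  if (!length(rec)) rec <- params$t_end
  no_events <- max_rate(params) <= 0
  dt <- if (no_events) Inf else choose_time_step(params)

  snap <- vector("list", length(rec))
  run <- function() {
    t_cur <- t_start
    for (i in seq_along(rec)) {
      if (!no_events && rec[i] > t_cur + 1e-9)
        st <<- advance_(st, params, t_cur, rec[i], dt)
      t_cur <- rec[i]
      snap[[i]] <<- st
    }
  }
  with_seed(params$seed, run())

  states <- do.call(rbind, lapply(seq_along(rec), function(i) {
    data.frame(lineage = seq_len(L), time = rec[i],
               s = snap[[i]]$s, a = snap[[i]]$a, n = snap[[i]]$n)
  }))
  structure(list(states = states, params = params), class = "organoid_sim")
}

#' @export
print.organoid_sim <- function(x, ...) {
  cat(sprintf("Organoid simulation: %d lineages, %d record times (%s)\n",
              x$params$n_lineages, length(unique(x$states$time)),
              x$params$variant))
  invisible(x)
}

#' Simulate a single lineage trajectory
#'
#' Convenience wrapper around [simulate_organoid()] for one lineage.
#'
#' @inheritParams simulate_organoid
#' @return A data frame with columns `time`, `s`, `a`, `n`.
#' @export
simulate_lineage <- function(params) {
  p1 <- params
  p1$n_lineages <- 1L
  sim <- simulate_organoid(p1)
  sim$states[c("time", "s", "a", "n")]
}

#' Exact stochastic simulation (Gillespie) reference
#'
#' Event-by-event simulation of the continuous-time Markov model that the
#' binomial stepper approximates: exponential waiting times with
#' propensities `r_s*s` (symmetric division), `r_a*s` (transition),
#' `r_n*a` (asymmetric division) and, in the `direct_neurogenesis`
#' variant, `r_dn*s`. Used as the oracle against which the tau-leaping
#' scheme is validated; exact but much slower for large lineages.
#'
#' @inheritParams simulate_organoid
#' @return A data frame with columns `time`, `s`, `a`, `n`, one row per
#'   record time.
#' @export
exact_ssa_reference <- function(params) {
  stopifnot(inherits(params, "clone_model_params"))
  rec <- params$record_times
  s <- 1L; a <- 0L; n <- 0L
  t_cur <- 0
  out <- matrix(NA_integer_, length(rec), 3L)
  i_rec <- 1L
  dn <- params$variant == "direct_neurogenesis"
  repeat {
    prop <- c(params$r_s * s, params$r_a * s, params$r_n * a,
              if (dn) params$r_dn * s else 0)
    total <- sum(prop)
    t_next <- if (total > 0) t_cur + rexp(1L, total) else Inf
    while (i_rec <= length(rec) && rec[i_rec] <= t_next + 1e-12) {
      out[i_rec, ] <- c(s, a, n)
      i_rec <- i_rec + 1L
    }
    if (i_rec > length(rec)) break
    t_cur <- t_next
    ev <- sample.int(4L, 1L, prob = prop)
    if (ev == 1L) s <- s + 1L
    else if (ev == 2L) { s <- s - 1L; a <- a + 1L }
    else if (ev == 3L) n <- n + params$k
    else { s <- s - 1L; n <- n + 2L }
  }
  data.frame(time = rec, s = out[, 1], a = out[, 2], n = out[, 3])
}

#' Lineage sizes at a recorded time
#'
#' @param sim An `organoid_sim` object.
#' @param time A day contained in the simulation's record times.
#' @return Integer vector of lineage sizes (`s + a + n`), in lineage order.
#' @export
lineage_sizes <- function(sim, time = max(sim$states$time)) {
  st <- sim_states_at(sim, time)
  st$s + st$a + st$n
}

sim_states_at <- function(sim, time) {
  sel <- abs(sim$states$time - time) < 1e-9
  if (!any(sel))
    stop_user("time ", time, " is not among the recorded times")
  sim$states[sel, , drop = FALSE]
}

#' Per-lineage cell-type composition
#'
#' Splits every lineage at a recorded time into progenitors (`s + a`) and
#' postmitotic cells (`n`), and flags whether the lineage still contains
#' symmetrically dividing S cells. In the combined model the largest
#' lineages are enriched for S-containing lineages, while lineages that
#' have lost their S cells stop expanding their progenitor pool.
#'
#' @inheritParams lineage_sizes
#' @return Data frame with columns `lineage`, `progenitors`,
#'   `postmitotic`, `size`, `contains_s`.
#' @export
cell_type_composition <- function(sim, time = max(sim$states$time)) {
  st <- sim_states_at(sim, time)
  data.frame(lineage = st$lineage,
             progenitors = st$s + st$a,
             postmitotic = st$n,
             size = st$s + st$a + st$n,
             contains_s = st$s > 0L)
}

# Two-sample Kolmogorov-Smirnov statistic (no p-value, tie-safe).
ks_stat <- function(x, y) {
  x <- sort(x); y <- sort(y)
  grid <- sort(unique(c(x, y)))
  Fx <- findInterval(grid, x) / length(x)
  Fy <- findInterval(grid, y) / length(y)
  max(abs(Fx - Fy))
}

#' Fit event rates to an observed lineage-size distribution on a grid
#'
#' For every candidate rate combination an organoid is simulated from the
#' template parameters and scored against the observed distribution. The
#' score is the two-sample Kolmogorov-Smirnov statistic between the
#' log-transformed, depth-normalized size distributions plus the relative
#' error between simulated and observed surviving-lineage counts; the grid
#' point with the smallest score wins, ties broken by the lexicographically
#' smallest `(r_s, r_a, r_n)`.
#'
#' @param observed Numeric vector of observed lineage sizes (e.g. RPM).
#' @param grid Data frame of candidate rates; any of the columns `r_s`,
#'   `r_a`, `r_n`, `r_dn`, `k` may be given, missing ones come from
#'   `template`.
#' @param template A [model_params()] object supplying every non-grid
#'   parameter (horizon, lineage number, seed, variant).
#' @return A list with `best` (the winning [model_params()]), `score`,
#'   and `scores` (the grid with a `score` column).
#' @export
fit_rates_grid <- function(observed, grid, template) {
  if (!length(observed)) stop_user("observed distribution is empty")
  if (!NROW(grid)) stop_user("empty candidate grid")
  stopifnot(inherits(template, "clone_model_params"))
  obs_log <- log(observed / sum(observed))
  n_obs <- length(observed)
  scores <- numeric(nrow(grid))
  fitted <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- template
    for (f in intersect(names(grid), c("r_s", "r_a", "r_n", "r_dn", "k")))
      p[[f]] <- grid[[f]][i]
    p <- do.call(model_params, p[c("r_s", "r_a", "r_n", "k", "variant",
                                   "r_dn", "t_end", "n_lineages",
                                   "record_times", "seed")])
    sim <- simulate_organoid(p)
    sz <- lineage_sizes(sim, p$t_end)
    sim_log <- log(sz / sum(sz))
    scores[i] <- ks_stat(obs_log, sim_log) +
      abs(length(sz) - n_obs) / n_obs
    fitted[[i]] <- p
  }
  key <- cbind(scores,
               if ("r_s" %in% names(grid)) grid$r_s else 0,
               if ("r_a" %in% names(grid)) grid$r_a else 0,
               if ("r_n" %in% names(grid)) grid$r_n else 0)
  best <- do.call(order, as.data.frame(key))[1L]
  list(best = fitted[[best]], score = scores[best],
       scores = cbind(as.data.frame(grid), score = scores))
}
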