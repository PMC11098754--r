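#' Parameters of the stochastic clonal growth model
#'
#' A lineage is described by its counts of S cells (symmetrically dividing
#' progenitors), A cells (asymmetrically dividing, self-renewing progenitors)
#' and N cells (postmitotic progeny). Three events modify the counts:
#'
#' * symmetric division, rate `r_s` per S cell per day: `+1 S`;
#' * S-to-A transition, rate `r_a` per S cell per day: `-1 S, +1 A`;
#' * asymmetric division, rate `r_n` per A cell per day: `+k N`, where `k`
#'   abstracts amplification through intermediate progenitors.
#'
#' The `direct_neurogenesis` variant adds a fourth event, direct consumption
#' of an S cell into two postmitotic cells (`-1 S, +2 N`) at rate `r_dn`.
#' The `symmetric_only` variant forces `r_a = r_n = r_dn = 0`.
#'
#' @param r_s Symmetric-division rate (events per S cell per day).
#' @param r_a Transition rate S -> A (events per S cell per day).
#' @param r_n Asymmetric-division rate (events per A cell per day).
#' @param k Number of N cells produced per asymmetric division (integer >= 1).
#' @param variant One of `"combined"`, `"symmetric_only"`,
#'   `"direct_neurogenesis"`.
#' @param r_dn Direct-neurogenesis rate (events per S cell per day); only
#'   used by the `direct_neurogenesis` variant.
#' @param t_end Simulation horizon in days.
#' @param n_lineages Number of independent lineages per simulated organoid.
#' @param record_times Days at which lineage states are recorded; defaults
#'   to `t_end`.
#' @param seed Optional RNG seed making the simulation reproducible.
#' @return An object of class `clone_model_params` (a validated list).
#' @seealso [simulate_organoid()], [choose_time_step()]
#' @examples
#' model_params(r_s = 0.5, r_a = 0.5, r_n = 0.5, k = 2, t_end = 10,
#'              n_lineages = 100, seed = 1)
#' @export
model_params <- function(r_s, r_a = 0, r_n = 0, k = 1,
                         variant = c("combined", "symmetric_only",
                                     "direct_neurogenesis"),
                         r_dn = 0, t_end = 40, n_lineages = 10000,
                         record_times = NULL, seed = NULL) {
  variant <- match.arg(variant)
  if (variant == "symmetric_only") {
    r_a <- 0; r_n <- 0; r_dn <- 0
  }
  if (variant != "direct_neurogenesis") r_dn <- 0
  rates <- c(r_s = r_s, r_a = r_a, r_n = r_n, r_dn = r_dn)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_user("all rates must be finite and >= 0")
  if (k < 1 || k != round(k)) stop_user("k must be an integer >= 1")
  if (t_end < 0) stop_user("t_end must be >= 0")
  if (n_lineages < 1 || n_lineages != round(n_lineages))
    stop_user("n_lineages must be a positive integer")
  if (is.null(record_times)) record_times <- t_end
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < 0) || any(record_times > t_end))
    stop_user("record_times must lie within [0, t_end]")
  structure(
    list(r_s = r_s, r_a = r_a, r_n = r_n, r_dn = r_dn, k = as.integer(k),
         variant = variant, t_end = t_end,
         n_lineages = as.integer(n_lineages),
         record_times = record_times, seed = seed),
    class = "clone_model_params")
}

#' @export
print.clone_model_params <- function(x, ...) {
  cat("Clonal growth model (", x$variant, ")\n", sep = "")
  cat(sprintf("  rates/day: r_s=%g r_a=%g r_n=%g", x$r_s, x$r_a, x$r_n))
  if (x$variant == "direct_neurogenesis") cat(sprintf(" r_dn=%g", x$r_dn))
  cat(sprintf("\n  k=%d, t_end=%g d, n_lineages=%d\n",
              x$k, x$t_end, x$n_lineages))
  invisible(x)
}

max_rate <- function(params) {
  max(params$r_s, params$r_a, params$r_n,
      if (params$variant == "direct_neurogenesis") params$r_dn else 0)
}

#' Automatic tau-leap time step
#'
#' The simulation advances in fixed steps of `0.01 / max(rates)` days, so
#' that the per-cell probability of one event per channel per step is at
#' most 0.01 and the probability that the same cell undergoes two or more
#' events within one step (which the binomial event counts cannot
#' represent) stays well below 1%.
#'
#' @param params A [model_params()] object.
#' @return The time step in days.
#' @examples
#' choose_time_step(model_params(r_s = 1, r_a = 1, r_n = 1, t_end = 1))  # 0.01
#' @export
choose_time_step <- function(params) {
  r <- max_rate(params)
  if (r <= 0)
    stop_user("degenerate model: all event rates are zero, no time step defined")
  0.01 / r
}

#' Analytic per-step double-event probability
#'
#' For a cell firing events as a Poisson process at the maximal model rate
#' `r`, the probability of two or more events within the automatically
#' chosen step `dt` is `1 - exp(-r*dt) - r*dt*exp(-r*dt)`. With
#' `dt = 0.01 / r` this is about 4.97e-5, i.e. about 0.005% -- the
#' approximation error bound of the binomial stepping scheme.
#'
#' @inheritParams choose_time_step
#' @param percent Return the probability in percent (default) or as a
#'   plain probability.
#' @return A single number.
#' @export
step_double_event_prob <- function(params, percent = TRUE) {
  r <- max_rate(params)
  dt <- choose_time_step(params)
  mu <- r * dt
  p <- 1 - exp(-mu) - mu * exp(-mu)
  if (percent) 100 * p else p
}
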