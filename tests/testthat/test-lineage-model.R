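test_that("automatic time step follows the 0.01/max(rates) rule", {
  expect_equal(choose_time_step(model_params(r_s = 1, r_a = 1, r_n = 1,
                                             t_end = 1)), 0.01)
  expect_equal(choose_time_step(model_params(r_s = 2, r_a = 0.5, r_n = 0,
                                             t_end = 1)), 0.005)
  # the direct-neurogenesis rate participates in the maximum
  expect_equal(choose_time_step(model_params(r_s = 0.1, r_a = 0.1,
                                             r_n = 0.1, r_dn = 4,
                                             variant = "direct_neurogenesis",
                                             t_end = 1)), 0.0025)
  expect_error(choose_time_step(model_params(r_s = 0, t_end = 1)),
               "degenerate")
})

test_that("per-cell double-event probability is far below the 1% bound", {
  p <- model_params(r_s = 0.1, r_a = 0.1, r_n = 0.1, t_end = 1)
  expect_equal(choose_time_step(p), 0.1)
  # closed-form Poisson tail at mu = 0.01
  expect_equal(step_double_event_prob(p, percent = FALSE),
               1 - exp(-0.01) - 0.01 * exp(-0.01), tolerance = 1e-12)
  expect_lt(step_double_event_prob(p, percent = FALSE), 0.01)
})

test_that("binomial step obeys the event definitions", {
  p0 <- model_params(r_s = 0, t_end = 1)
  expect_equal(step_lineage(c(s = 1, a = 0, n = 0), p0, 0.01),
               c(s = 1, a = 0, n = 0))
  # conditioned on one asymmetric event from (0,1,0): +k N cells
  pk <- model_params(r_s = 0, r_a = 0, r_n = 1, k = 3, t_end = 1)
  set.seed(1)
  repeat {
    st <- step_lineage(c(s = 0, a = 1, n = 0), pk, 0.01)
    if (st[["n"]] > 0) break
  }
  expect_equal(st, c(s = 0, a = 1, n = 3))
  expect_error(step_lineage(c(s = 1, a = 0, n = 0),
                            model_params(r_s = 2, t_end = 1), 0.6),
               "probability")
})

test_that("binomial event counts have mean rate * cells * dt", {
  p <- model_params(r_s = 1, t_end = 1)
  set.seed(2)
  reps <- 1e5
  st <- list(s = rep(100L, reps), a = rep(0L, reps), n = rep(0L, reps))
  out <- step_lineage(st, p, 0.01)
  d_s <- out$s - 100L
  se <- sqrt(100 * 0.01 * 0.99 / reps)
  expect_lt(abs(mean(d_s) - 1.0), 3 * se)
})

test_that("pure-symmetric simulation matches the Yule closed form", {
  p <- model_params(r_s = 1, variant = "symmetric_only", t_end = 1,
                    n_lineages = 10000, seed = 11)
  sz <- lineage_sizes(simulate_organoid(p), 1)
  se <- sqrt((exp(2) - exp(1)) / length(sz))
  expect_lt(abs(mean(sz) - exp(1)), 3 * se)
})

test_that("single-cell transition count matches the exponential law", {
  p <- model_params(r_s = 0, r_a = 1, r_n = 0, t_end = 2,
                    n_lineages = 10000, seed = 12)
  sim <- simulate_organoid(p)
  st <- sim$states[sim$states$time == 2, ]
  pr <- 1 - exp(-2)
  se <- sqrt(pr * (1 - pr) / nrow(st))
  expect_lt(abs(mean(st$s == 0) - pr), 3 * se)
  # transitioned lineages hold exactly one A cell and nothing else
  expect_true(all(st$a %in% c(0, 1)))
  expect_true(all(st$s + st$a == 1))
})

test_that("zero-duration and zero-rate simulations are constant", {
  p <- model_params(r_s = 1, t_end = 0, n_lineages = 5, seed = 1)
  tr <- simulate_lineage(p)
  expect_equal(tr, data.frame(time = 0, s = 1L, a = 0L, n = 0L))
  p0 <- model_params(r_s = 0, t_end = 3, n_lineages = 200,
                     record_times = c(0, 1.5, 3), seed = 2)
  sim <- simulate_organoid(p0)
  expect_true(all(lineage_sizes(sim, 1.5) == 1))
  expect_true(all(lineage_sizes(sim, 3) == 1))
})

test_that("trajectories conserve invariants and replay under a seed", {
  p <- model_params(r_s = 0.8, r_a = 0.8, r_n = 0.6, k = 2, t_end = 10,
                    n_lineages = 300, record_times = c(2, 5, 8, 10),
                    seed = 33)
  sim1 <- simulate_organoid(p)
  sim2 <- simulate_organoid(p)
  expect_identical(sim1$states, sim2$states)
  st <- sim1$states
  expect_true(all(st$s >= 0 & st$a >= 0 & st$n >= 0))
  expect_true(all(st$s + st$a + st$n >= 1))
  by_lineage <- split(st[order(st$time), ], st$lineage[order(st$time)])
  expect_true(all(vapply(by_lineage,
                         function(d) all(diff(d$n) >= 0), logical(1))))
  expect_true(all(vapply(by_lineage,
                         function(d) all(diff(d$s + d$a + d$n) >= 0),
                         logical(1))))
})

test_that("exact SSA reproduces the geometric Yule size law", {
  p <- model_params(r_s = 1, variant = "symmetric_only", t_end = 1,
                    record_times = 1)
  set.seed(21)
  sz <- replicate(3000, exact_ssa_reference(p)[1, "s"])
  pg <- exp(-1)
  D <- ks1_oracle(sz, function(m) 1 - (1 - pg)^floor(m))
  expect_lt(D, 1.628 / sqrt(length(sz)))
})

test_that("tau-leap and exact SSA sizes agree in distribution", {
  p <- model_params(r_s = 0.5, r_a = 0.5, r_n = 1, k = 2, t_end = 5,
                    n_lineages = 3000, seed = 10)
  tl <- lineage_sizes(simulate_organoid(p), 5)
  p1 <- model_params(r_s = 0.5, r_a = 0.5, r_n = 1, k = 2, t_end = 5,
                     record_times = 5)
  set.seed(22)
  ssa <- replicate(3000, sum(exact_ssa_reference(p1)[1, c("s", "a", "n")]))
  expect_lt(ks2_oracle(tl, ssa), ks2_crit(length(tl), length(ssa)))
})

test_that("cell-type composition conserves cells and tracks S retention", {
  p0 <- model_params(r_s = 0, t_end = 2, n_lineages = 50, seed = 3)
  comp0 <- cell_type_composition(simulate_organoid(p0), 2)
  expect_true(all(comp0$progenitors == 1 & comp0$postmitotic == 0))
  expect_true(all(comp0$contains_s))

  ps <- model_params(r_s = 0.5, variant = "symmetric_only", t_end = 8,
                     n_lineages = 200, record_times = c(4, 8), seed = 4)
  sims <- simulate_organoid(ps)
  expect_true(all(cell_type_composition(sims, 8)$contains_s))

  pc <- model_params(r_s = 1, r_a = 1, r_n = 0.5, k = 3, t_end = 20,
                     n_lineages = 1500, record_times = c(8, 20), seed = 5)
  simc <- simulate_organoid(pc)
  comp <- cell_type_composition(simc, 20)
  expect_equal(sum(comp$progenitors + comp$postmitotic),
               sum(lineage_sizes(simc, 20)))
  # S-retaining fraction decreases in time under equal rates
  expect_lt(mean(comp$contains_s),
            mean(cell_type_composition(simc, 8)$contains_s))
  # the largest lineages are enriched for lineages retaining S cells
  expect_gt(cor(comp$size, as.numeric(comp$contains_s),
                method = "spearman"), 0)
  expect_error(cell_type_composition(simc, 13), "not among")
})

test_that("rate-grid fitting recovers the generating rates", {
  tmpl <- model_params(r_s = 0.45, r_a = 0.45, r_n = 0.5, k = 3, t_end = 8,
                       n_lineages = 400, seed = 42)
  truth <- model_params(r_s = 0.7, r_a = 0.2, r_n = 0.5, k = 3, t_end = 8,
                        n_lineages = 400, seed = 99)
  obs <- lineage_sizes(simulate_organoid(truth), 8)
  grid <- expand.grid(r_s = c(0.2, 0.45, 0.7), r_a = c(0.2, 0.45, 0.7))
  fit <- fit_rates_grid(obs, grid, tmpl)
  expect_equal(c(fit$best$r_s, fit$best$r_a), c(0.7, 0.2))

  one <- fit_rates_grid(obs, data.frame(r_s = 0.3, r_a = 0.3), tmpl)
  expect_equal(one$best$r_s, 0.3)
  expect_equal(one$score, one$scores$score[1])

  # a pure-symmetric observation prefers r_a = 0 over r_a = r_s
  sym <- model_params(r_s = 0.5, variant = "symmetric_only", t_end = 8,
                      n_lineages = 400, seed = 7)
  obs2 <- lineage_sizes(simulate_organoid(sym), 8)
  fit2 <- fit_rates_grid(obs2, data.frame(r_s = 0.5, r_a = c(0, 0.5)), tmpl)
  expect_equal(fit2$best$r_a, 0)
  expect_error(fit_rates_grid(obs, grid[0, , drop = FALSE], tmpl), "empty")
})

test_that("S-domination and S-depletion regimes order as expected", {
  mk <- function(rs, ra, seed)
    model_params(r_s = rs, r_a = ra, r_n = 0.5, k = 3, t_end = 20,
                 n_lineages = 800, record_times = 20, seed = seed)
  fS <- function(p) mean(cell_type_composition(simulate_organoid(p),
                                               20)$contains_s)
  f_hi <- fS(mk(0.7, 0.3, 61))
  f_eq <- fS(mk(0.5, 0.5, 62))
  f_lo <- fS(mk(0.3, 0.7, 63))
  expect_gt(f_hi, f_eq)
  expect_gt(f_eq, f_lo)
})
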