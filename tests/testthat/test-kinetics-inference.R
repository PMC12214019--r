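# Decay fits, bimolecular fits, censoring-aware estimation, event
# detection, dwell times, synchronization, hetero-exchange analysis.

test_that("single-exponential fits recover self-generated curves", {
  t <- seq(0, 600, by = 20)
  f <- fit_exponential_decay(t, exp(-0.01 * t))
  expect_lt(abs(f$k_obs - 0.01), 1e-6)
  expect_false(f$degenerate)
  # with plateau
  f2 <- fit_exponential_decay(t, 0.4 + 0.6 * exp(-0.05 * t),
                              with_plateau = TRUE)
  expect_equal(c(f2$A, f2$k_obs, f2$plateau), c(0.6, 0.05, 0.4),
               tolerance = 1e-5)
  # constant input: degenerate amplitude is flagged
  f3 <- fit_exponential_decay(t, rep(1, length(t)), with_plateau = TRUE)
  expect_true(f3$degenerate)
  expect_error(fit_exponential_decay(t, exp(-0.01 * t) + 2,
                                     fraction_input = TRUE), "fraction")
  expect_error(fit_exponential_decay(1:3, exp(-(1:3))), ">= 5")
})

test_that("decay fit on analytic occupancy recovers the decay rate to 4 figures", {
  # pure single exponential: 2-state scheme, occupancy of A is e^{-kt}
  sc2 <- two_state_scheme(k = 0.01)
  t <- seq(0, 400, by = 8)
  f2 <- fit_exponential_decay(t, analytic_occupancy(sc2, t)[, "A"])
  expect_lt(abs(f2$k_obs - 0.01) / 0.01, 1e-4)
  # ternary scheme: the exact slow relaxation rate is the small
  # eigenvalue of the generator, slightly below the quasi-steady-state
  # reduction k_on * conc * p
  sc <- build_transfer_scheme(example_transfer_rates(), 0.8, 0.2)
  ev <- eigen(t(sc$Q))$values
  k_exact <- -max(Re(ev[Re(ev) < -1e-12]))
  bf <- analytic_bound_fraction(sc, t, states = c("Bound", "Ternary"))
  f <- fit_exponential_decay(t, bf)
  expect_lt(abs(f$k_obs - k_exact) / k_exact, 1e-3)
  expect_lt(abs(f$k_obs - 0.01) / 0.01, 0.02)
})

test_that("bimolecular fits: slope, intercept, degenerate cases", {
  # exact noiseless points: lm warns about the perfect fit, expectedly
  conc <- c(1, 2.5, 5, 7.5, 10) * 1e-8
  fit <- suppressWarnings(fit_bimolecular(conc, 6.1e4 * conc))
  expect_equal(fit$k_bi, 6.1e4, tolerance = 1e-9)
  expect_lt(abs(fit$intercept), 1e-12)
  # constant rates: zero slope
  expect_lt(abs(suppressWarnings(
    fit_bimolecular(conc, rep(2e-3, 5)))$k_bi), 1e-9)
  # a known additive intercept is recovered, not forced away
  fit3 <- suppressWarnings(fit_bimolecular(conc, 1e-3 + 6.1e4 * conc))
  expect_equal(fit3$intercept, 1e-3, tolerance = 1e-9)
  expect_equal(fit3$k_bi, 6.1e4, tolerance = 1e-6)
  expect_error(fit_bimolecular(c(1e-8, 1e-8, 2e-8), c(1, 1, 2) * 1e-3),
               "3 distinct")
})

test_that("censoring-aware rate estimation beats the naive fit", {
  k <- 0.02
  horizon <- 1 / k
  set.seed(10)
  t_true <- stats::rexp(5000, k)
  cens <- t_true > horizon
  obs <- pmin(t_true, horizon)
  est <- fit_exponential_mle(obs, cens)
  expect_lt(abs(est$k - k) / k, 0.10)
  # naive estimator (mean of uncensored events only) errs badly
  expect_gt(abs(est$k_naive - k) / k, 0.25)
})

test_that("detect_events localizes a planted transfer to sub-frame accuracy", {
  pr <- preset("ssb_dwell")
  sc <- preset_transfer_scheme(pr, pr$conc, competitor_labeled = TRUE)
  op <- optics_noise_free(leakage = 0, flow_background_step = 0)
  pat <- excitation_pattern("continuous_green")
  # one failed attempt (5.0-5.2 s), final binding 8.02 s, transfer 8.33 s
  states <- c("Bound", "Ternary1", "Bound", "Ternary1", "FreeDNA")
  # walk the ternary sub-ladder instantly: use sub-state 1 only; the
  # optics only see donor_count/FRET so this is equivalent
  path <- manual_path(c(0, 5.0, 5.2, 8.02, 8.33), states, 20)
  tr <- synthesize_trace(path, sc, op, pat, duration = 15, molecule_id = 7)
  s <- compute_fret(tr, l = 0)
  ev <- detect_events(tr, s, free_e = pr$fret_free, flow_start = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$molecule_id, 7)
  expect_equal(ev$n_failed_attempts, 1L)
  expect_lt(abs(ev$t_bind - 8.02), 0.013)
  expect_lt(abs(ev$t_transfer - 8.33), 0.013)
  expect_equal(ev$t_transfer - ev$t_bind, 0.31, tolerance = 0.05)
  # quiet trace: no events
  quiet <- synthesize_trace(manual_path(0, "Bound", 20), sc, op, pat,
                            duration = 15, molecule_id = 8)
  ev0 <- detect_events(quiet, compute_fret(quiet, l = 0),
                       free_e = pr$fret_free, flow_start = 0)
  expect_equal(nrow(ev0), 0L)
})

test_that("failed-attempt counts match the generator", {
  pr <- preset("ssb_dwell")
  sc <- preset_transfer_scheme(pr, pr$conc, competitor_labeled = TRUE)
  op <- optics_model(flow_background_step = 120, e_sd_molecule = 0)
  pat <- excitation_pattern("continuous_green")
  det <- c(); tru <- c()
  for (i in 1:60) {
    set.seed(derive_seed(99, i))
    path <- gillespie_simulate(sc, pr$horizon)
    if (!any(path$state == "FreeDNA")) next
    tr <- synthesize_trace(path, sc, op, pat, flow_start = pr$flow_start,
                           molecule_id = i)
    ev <- detect_events(tr, compute_fret(tr, l = op$leakage),
                        free_e = pr$fret_free)
    if (nrow(ev) == 0L) next
    det <- c(det, ev$n_failed_attempts)
    tru <- c(tru, sum(path$state == "Ternary1") - 1L)
  }
  expect_gt(length(det), 40L)
  expect_lt(abs(mean(det) - mean(tru)) / max(mean(tru), 1), 0.10)
})

test_that("dwell-time summaries behave at the edges", {
  # too few events: raw deltas, no fit
  ev <- data.frame(molecule_id = 1:5, t_bind = 0,
                   t_transfer = c(0.3, 0.31, 0.29, 0.30, 0.32),
                   n_failed_attempts = 0L)
  dw <- measure_dwell_times(ev)
  expect_false(dw$fit_available)
  expect_equal(dw$n, 5L)
  expect_equal(dw$sample_mean, mean(ev$t_transfer))
  # identical dwells: sd collapses to the binning-limited minimum
  ev2 <- data.frame(molecule_id = 1:30, t_bind = 0, t_transfer = 0.3,
                    n_failed_attempts = 0L)
  dw2 <- measure_dwell_times(ev2)
  expect_true(dw2$fit_available)
  expect_lt(abs(dw2$gaussian_mean - 0.3), 0.05)
  expect_lte(dw2$gaussian_sd, 0.05)
  expect_error(measure_dwell_times(
    data.frame(molecule_id = 1, t_bind = 1, t_transfer = 0.5,
               n_failed_attempts = 0L)), "negative")
})

test_that("synchronized averaging aligns at binding and shows the boost", {
  pr <- preset("ssb_dwell")
  sc <- preset_transfer_scheme(pr, pr$conc, competitor_labeled = TRUE)
  op <- optics_model(flow_background_step = 120, e_sd_molecule = 0)
  pat <- excitation_pattern("continuous_green")
  traces <- list(); events <- list()
  for (i in 1:40) {
    set.seed(derive_seed(55, i))
    path <- gillespie_simulate(sc, pr$horizon)
    tr <- synthesize_trace(path, sc, op, pat, flow_start = pr$flow_start,
                           molecule_id = i)
    ev <- detect_events(tr, compute_fret(tr, l = op$leakage),
                        free_e = pr$fret_free)
    traces[[length(traces) + 1L]] <- tr
    if (nrow(ev)) events[[length(events) + 1L]] <- ev
  }
  ev <- do.call(rbind, events)
  expect_gt(nrow(ev), 20L)
  avg <- synchronize_traces(traces, ev, window = c(-2, 3))
  # acceptor boost right after binding, gone well after the mean dwell
  post <- mean(avg$I_A[avg$offset >= 0.05 & avg$offset <= 0.25])
  pre  <- mean(avg$I_A[avg$offset >= -1 & avg$offset <= -0.3])
  late <- mean(avg$I_A[avg$offset >= 1.5 & avg$offset <= 3])
  expect_gt(post, pre + 300)
  expect_lt(late, pre)        # transferred: DNA-only acceptor level
  # identical traces average to the single trace
  one <- traces[[ev$molecule_id[1L]]]
  avg1 <- synchronize_traces(list(one, one),
                             rbind(ev[1L, ], ev[1L, ]),
                             window = c(-1, 1))
  g <- one[one$excitation == "G", ]
  i0 <- which.min(abs(g$time - ev$t_bind[1L]))
  expect_equal(avg1$I_D[which.min(abs(avg1$offset))], g$I_D[i0],
               tolerance = 1e-9)
  expect_error(synchronize_traces(traces, ev[0, ]), "no events")
})

test_that("spot-count decay yields rate and exchange fraction", {
  t <- seq(0, 900, by = 60)
  # noiseless plateaus
  f <- fit_spot_decay(time = t, count = 30 + 270 * exp(-0.01 * t))
  expect_equal(f$exchange_fraction, 0.9, tolerance = 1e-4)
  f2 <- fit_spot_decay(time = t, count = 120 + 180 * exp(-0.01 * t))
  expect_equal(f2$exchange_fraction, 0.6, tolerance = 1e-4)
  # no exchange: degenerate flag
  f3 <- fit_spot_decay(time = t, count = rep(300, length(t)))
  expect_true(f3$fit$degenerate)
  expect_lt(f3$exchange_fraction, 0.05)
})

test_that("hetero-exchange analysis times and classifies exchanges", {
  op <- optics_model(e_sd_molecule = 0)
  pat <- excitation_pattern("continuous_green")
  run <- function(n_steps, rates, ladder, n = 150, seed = 1,
                  horizon = 300) {
    sc <- build_hetero_scheme(n_steps, rates, ladder)
    traces <- lapply(seq_len(n), function(i) {
      set.seed(derive_seed(seed, i))
      synthesize_trace(gillespie_simulate(sc, horizon), sc, op, pat,
                       flow_start = 10, molecule_id = i)
    })
    hetero_exchange_analysis(traces, flow_start = 10,
                             final_e = ladder[n_steps + 1L],
                             intermediate_e = if (n_steps == 2L)
                               ladder[2L] else 0.45,
                             l = op$leakage)
  }
  # one-step ladder: exponential completion at the step rate
  a1 <- run(1, 0.05, c(0.8, 0.1), seed = 2)
  expect_lt(abs(a1$rate$k - 0.05) / 0.05, 0.15)
  expect_lt(a1$frac_two_step, 0.1)
  # two-step ladder: Erlang completion, classified two-step
  a2 <- run(2, c(0.1, 0.1), c(0.8, 0.45, 0.1), seed = 3)
  done <- a2$completion[!a2$completion$censored, ]
  expect_lt(abs(mean(done$time) - 20) / 20, 0.15)
  expect_gte(a2$frac_two_step, 0.9)
  # flow starting after the recording: everything censored
  sc <- build_hetero_scheme(1, 0.05, c(0.8, 0.1))
  late <- lapply(1:5, function(i) {
    set.seed(i)
    synthesize_trace(gillespie_simulate(sc, 10), sc, op, pat,
                     flow_start = 0, duration = 10, molecule_id = i)
  })
  # ask for completion relative to a flow that never happened in-window
  a3 <- hetero_exchange_analysis(late, flow_start = 9.5, final_e = 0.1,
                                 l = op$leakage)
  expect_true(all(a3$completion$censored) || nrow(a3$completion) == 5L)
})
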