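# Efficiency computation, leakage estimation, donor-only exclusion,
# histograms, Gaussian decomposition and bound fractions.

test_that("compute_fret applies the leakage correction arithmetic", {
  pat <- excitation_pattern("alex")
  mk <- function(e, op) {
    synthesize_trace(manual_path(0, "S", 20), static_scheme(e), op, pat,
                     duration = 5)
  }
  s <- compute_fret(mk(0.8, optics_noise_free(leakage = 0)), l = 0)
  expect_true(all(abs(s$E - 0.8) < 1e-12))
  s <- compute_fret(mk(0.5, optics_noise_free(leakage = 0)), l = 0)
  expect_true(all(abs(s$E - 0.5) < 1e-12))
  # I_D = 400, I_A = 140, l = 0.1 -> E = (140 - 40) / (400 + 100) = 0.2
  tr <- mk(0.2, optics_noise_free(leakage = 0.1, total_intensity = 500))
  s <- compute_fret(tr, l = 0.1, total_intensity = 500)
  expect_true(all(abs(s$E - 0.2) < 1e-12))
  expect_error(compute_fret(tr, l = 0.5), "leakage")
})

test_that("frames below the intensity floor are flagged invalid", {
  pat <- excitation_pattern("alex")
  op <- optics_model(bleach_rate_donor = 0.5, shot_noise = FALSE,
                     read_noise_sd = 0, background_green = 10,
                     background_red = 10, e_sd_molecule = 0)
  set.seed(7)
  tr <- synthesize_trace(manual_path(0, "S", 100), static_scheme(0.8), op,
                         pat, duration = 60)
  s <- compute_fret(tr, l = 0)
  expect_true(any(!s$valid))           # bleached tail
  expect_true(any(s$valid))            # live head
  expect_true(all(abs(s$E[s$valid] - 0.8) < 0.05))
})

test_that("estimate_leakage round-trips the generator value", {
  op <- optics_model(leakage = 0.08)
  donor_only <- static_ensemble(25, 0, op, acceptor = FALSE)
  expect_lt(abs(estimate_leakage(donor_only) - 0.08), 0.005)
  # zero leakage, noise-free: exactly zero
  tr0 <- static_ensemble(3, 0, optics_noise_free(leakage = 0),
                         acceptor = FALSE)
  expect_equal(estimate_leakage(tr0), 0)
  # mixed input rejected: the contract requires verified donor-only
  mixed <- c(donor_only[1:3], static_ensemble(3, 0.8, op, seed_base = 500))
  expect_error(estimate_leakage(mixed), "FRET-active")
})

test_that("donor-only exclusion recovers a planted fraction", {
  op <- optics_model()
  active <- static_ensemble(40, 0.8, op, seed_base = 0)
  donly <- static_ensemble(10, 0, op, seed_base = 200, acceptor = FALSE)
  part <- exclude_donor_only(c(active, donly))
  expect_length(part$donor_only, 10L)
  expect_length(part$fret_active, 40L)
  # continuous-mode traces cannot be screened
  trc <- synthesize_trace(manual_path(0, "S", 10), static_scheme(0.8), op,
                          excitation_pattern("continuous_green"),
                          duration = 5, seed = 1)
  expect_error(exclude_donor_only(list(trc)), "ALEX")
})

test_that("histograms are unit-area and pool 21 frames per molecule", {
  op <- optics_model()
  traces <- static_ensemble(30, 0.8, op)
  series <- lapply(traces, compute_fret, l = op$leakage)
  h <- build_histogram(series)
  expect_lt(abs(sum(h$density) * 0.025 - 1), 1e-9)
  expect_lte(attr(h, "n_frames"), 30L * 21L)
  # single molecule at constant E: all mass in one bin
  tr1 <- synthesize_trace(manual_path(0, "S", 20), static_scheme(0.8),
                          optics_noise_free(leakage = 0),
                          excitation_pattern("alex"), duration = 5)
  h1 <- build_histogram(compute_fret(tr1, l = 0))
  expect_equal(sum(h1$density > 0), 1L)
  # E = 0.8 sits on a bin edge; right-closed binning puts it in (0.775, 0.8]
  expect_equal(h1$bin_center[h1$density > 0], 0.7875, tolerance = 1e-9)
  # 50/50 noise-free mixture: two equal spikes
  mix <- c(
    lapply(1:5, function(i) synthesize_trace(
      manual_path(0, "S", 20), static_scheme(0.2),
      optics_noise_free(leakage = 0), excitation_pattern("alex"),
      duration = 5, molecule_id = i)),
    lapply(6:10, function(i) synthesize_trace(
      manual_path(0, "S", 20), static_scheme(0.8),
      optics_noise_free(leakage = 0), excitation_pattern("alex"),
      duration = 5, molecule_id = i)))
  hm <- build_histogram(lapply(mix, compute_fret, l = 0))
  spikes <- hm[hm$density > 0, ]
  expect_equal(nrow(spikes), 2L)
  expect_equal(spikes$density[1L], spikes$density[2L])
})

test_that("gaussian mixture decomposition recovers planted components", {
  # single component
  set.seed(3)
  e <- pmin(pmax(stats::rnorm(20000, 0.8, 0.05), 0), 1)
  s <- structure(data.frame(time = seq_along(e) * 0.05, E = e,
                            valid = TRUE),
                 class = c("fret_series", "data.frame"))
  h <- build_histogram(list(s), frames_per_molecule = length(e))
  fit <- fit_gaussian_mixture(h, 1, init_means = 0.75)
  expect_lt(abs(fit$components$mean - 0.8), 0.005)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-6)

  # balanced two-component mixture
  set.seed(4)
  e2 <- c(stats::rnorm(10000, 0.2, 0.05), stats::rnorm(10000, 0.8, 0.05))
  s2 <- structure(data.frame(time = seq_along(e2) * 0.05,
                             E = pmin(pmax(e2, 0), 1), valid = TRUE),
                  class = c("fret_series", "data.frame"))
  h2 <- build_histogram(list(s2), frames_per_molecule = length(e2))
  fit2 <- fit_gaussian_mixture(h2, 2, init_means = c(0.25, 0.75))
  expect_equal(fit2$components$mean, c(0.2, 0.8), tolerance = 0.02)
  expect_equal(fit2$components$weight, c(0.5, 0.5), tolerance = 0.02)
  # components come back sorted by mean regardless of init order
  fit2b <- fit_gaussian_mixture(h2, 2, init_means = c(0.75, 0.25))
  expect_true(!is.unsorted(fit2b$components$mean))
  # over-parameterized fit is refused
  expect_error(fit_gaussian_mixture(h1 <- build_histogram(list(
    structure(data.frame(time = 1:50 * 0.05, E = rep(0.5, 50),
                         valid = TRUE),
              class = c("fret_series", "data.frame")))), 3,
    init_means = c(0.2, 0.5, 0.8)), "non-empty bins")
})

test_that("bound_fraction assigns components by proximity, not high E", {
  fit <- structure(list(components = data.frame(
    mean = c(0.1, 0.3), sd = c(0.05, 0.05), weight = c(0.3, 0.7)),
    residual_sse = 0, K = 2L, converged = TRUE),
    class = "gaussian_mixture_fit")
  # RPA-like: bound level below the free level
  expect_equal(bound_fraction(fit, bound_e = 0.1), 0.3)
  expect_equal(bound_fraction(fit, bound_e = 0.3), 0.7)
  expect_equal(bound_fraction(fit, bound_components = c(1L, 2L)), 1)
  expect_error(bound_fraction(fit, bound_components = integer(0)),
               "empty")
  # nothing near the requested level: the bound population is gone
  expect_equal(bound_fraction(fit, bound_e = 0.8), 0)
})

test_that("noise-free end-to-end bound fraction equals the latent state fraction", {
  pr_free <- 0.2; pr_bound <- 0.8
  sc <- build_transfer_scheme(transfer_rates(1e6, 5e-8, 9, 1),
                              pr_bound, pr_free,
                              competitor_labeled = FALSE)
  cond <- experiment_condition("transfer", competitor_conc = 5e-8,
                               n_molecules = 60, seed = 21)
  op <- optics_noise_free(leakage = 0)
  snap_t <- c(50, 150)
  snaps <- synthesize_snapshots(cond, sc, op, excitation_pattern("alex"),
                                times = snap_t)
  bfs <- bound_fraction_series(snaps, snap_t, l = 0, K = 2,
                               init_means = c(pr_free, pr_bound),
                               bound_e = pr_bound, method = "threshold",
                               free_e = pr_free)
  # latent truth: fraction of molecules not yet absorbed at each snapshot
  for (j in seq_along(snap_t)) {
    truth <- mean(vapply(snaps[[j]], function(tr) {
      path <- attr(tr, "truth")
      st <- path$state[findInterval(snap_t[j] + 0.5, path$time)]
      st != "FreeDNA"
    }, logical(1L)))
    expect_lt(abs(bfs$fraction[j] - truth), 0.05)
  }
  # and the ensemble matches the master equation within binomial error
  an <- analytic_bound_fraction(sc, snap_t)
  expect_true(all(abs(bfs$fraction - an) <
                  3 * sqrt(an * (1 - an) / 60) + 0.05))
})
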