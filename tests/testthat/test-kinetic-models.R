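# Kinetic scheme construction, validation, and the effective-rate
# reduction of the ternary-intermediate mechanism.

test_that("kinetic_scheme enforces generator-matrix invariants", {
  sc <- two_state_scheme(k = 2)
  expect_equal(unname(diag(sc$Q)), c(-2, 0))
  expect_equal(unname(rowSums(sc$Q)), c(0, 0))
  expect_equal(sc$absorbing, "B")
  expect_equal(sc$initial_state, "A")

  Q <- matrix(c(0, -1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(kinetic_scheme(Q, c(A = 0.5, B = 0.5)), ">= 0")
  expect_error(two_state_scheme(e_a = 1.2), "fret_level")
  expect_error(transfer_rates(-1, 1e-8, 9, 1), "non-negative")
})

test_that("transfer scheme: structure, donor bookkeeping and limits", {
  sc <- build_transfer_scheme(example_transfer_rates(), 0.8, 0.2)
  expect_setequal(sc$states, c("Bound", "Ternary", "FreeDNA"))
  expect_equal(sc$absorbing, "FreeDNA")
  # labeled competitor doubles the ternary donor count
  expect_equal(sc$donor_count[match("Ternary", sc$states)], 2L)
  expect_equal(unname(sc$Q["Bound", "Ternary"]), 0.1)
  expect_equal(unname(sc$Q["Ternary", "Bound"]), 9)
  expect_equal(unname(sc$Q["Ternary", "FreeDNA"]), 1)

  # no failure channel: every ternary visit absorbs (mean attempts = 1)
  r0 <- transfer_rates(1e6, 1e-7, k_fail = 0, k_succ = 1)
  ens <- gillespie_ensemble(build_transfer_scheme(r0, 0.8, 0.2), 500,
                            horizon = 1e4, seed = 1,
                            count_visits = "Ternary")
  expect_true(all(ens$visits[!ens$censored] == 1L))

  # no association: the molecule never leaves Bound
  rz <- transfer_rates(1e6, 0, k_fail = 9, k_succ = 1)
  path <- gillespie_simulate(build_transfer_scheme(rz, 0.8, 0.2),
                             horizon = 1e5, seed = 2)
  expect_equal(nrow(path), 1L)
  expect_equal(path$state, "Bound")
})

test_that("effective_kobs matches the steady-state reduction", {
  out <- effective_kobs(example_transfer_rates())
  expect_equal(out$k_obs, 0.01)
  expect_true(out$valid)
  # trivial limits
  expect_equal(effective_kobs(transfer_rates(1e6, 1e-7, 0, 5))$k_obs,
               1e6 * 1e-7)
  expect_equal(effective_kobs(transfer_rates(1e6, 0, 9, 1))$k_obs, 0)
  # unresolvable ternary
  expect_error(transfer_rates(1e6, 1e-7, 0, 0), "k_fail")
  # reduction cross-checked against simulated mean first passage
  ens <- gillespie_ensemble(build_transfer_scheme(example_transfer_rates(),
                                                  0.8, 0.2),
                            1e4, horizon = 5e3, seed = 3)
  k_sim <- fit_exponential_mle(ifelse(ens$censored, 5e3,
                                      ens$first_passage),
                               ens$censored)$k
  expect_lt(abs(k_sim - 0.01) / 0.01, 0.05)
})

test_that("exchange scheme limits and donor bookkeeping", {
  # absorbing state drops the donor: the spot disappears on exchange
  sc <- build_exchange_scheme(4.8e5, 1e-8, k_fail = 9, k_succ = 1)
  expect_equal(sc$donor_count[match("UnlabeledBound", sc$states)], 0L)
  # conc = 0: no exchange ever
  sc0 <- build_exchange_scheme(4.8e5, 0, 9, 1)
  p <- gillespie_simulate(sc0, 1e4, seed = 1)
  expect_equal(nrow(p), 1L)
  # k_fail = 0: single-step limit, waiting time Exponential(k_on * conc)
  sc1 <- build_exchange_scheme(4.8e5, 1e-8, k_fail = 0, k_succ = 1e6)
  ens <- gillespie_ensemble(sc1, 5e3, horizon = 1e5, seed = 4)
  expect_lt(abs(mean(ens$first_passage) - 1 / 4.8e-3) / (1 / 4.8e-3), 0.05)
})

test_that("hetero ladder construction and completion means", {
  expect_error(build_hetero_scheme(3, c(1, 1, 1), c(0.8, 0.5, 0.3, 0.1)),
               "n_steps")
  expect_error(build_hetero_scheme(2, c(1), c(0.8, 0.5, 0.1)),
               "step_rates")
  expect_error(build_hetero_scheme(1, 1, c(0.8)), "fret_ladder")
  # mean completion 1/0.1 + 1/0.02 = 60 s
  sc <- build_hetero_scheme(2, c(0.1, 0.02), c(0.8, 0.45, 0.1))
  ens <- gillespie_ensemble(sc, 5e3, horizon = 1e4, seed = 5)
  expect_lt(abs(mean(ens$first_passage) - 60) / 60, 0.05)
  # exponential single step
  sc1 <- build_hetero_scheme(1, 0.05, c(0.8, 0.1))
  e1 <- gillespie_ensemble(sc1, 5e3, horizon = 1e4, seed = 6)
  expect_lt(abs(mean(e1$first_passage) - 20) / 20, 0.05)
})

test_that("competition scheme encodes substrate preference", {
  # DNA substrate, RNA competitor: displacement rate 0, bound forever
  # (with zero association Bound itself has no outflow, so name the
  # bound states explicitly rather than relying on the non-absorbing
  # default)
  dna <- build_competition_scheme("DNA", k_displace_by_RNA = 0,
                                  k_displace_by_DNA = 0, conc_RNA = 1e-5)
  expect_equal(unname(analytic_bound_fraction(dna, c(0, 600, 3600),
                                              states = c("Bound",
                                                         "Ternary"))),
               c(1, 1, 1))
  # RNA substrate, RNA competitor: decays at the effective constant
  rna <- build_competition_scheme("RNA", k_displace_by_RNA = 2.1e5,
                                  k_displace_by_DNA = 0, conc_RNA = 1e-7)
  # the effective decay matches the pseudo-first-order reduction up to
  # O(k_assoc / k_resolution) quasi-steady-state corrections (a few
  # percent at this concentration)
  k <- 2.1e5 * 1e-7
  bf <- analytic_bound_fraction(rna, c(10, 50))
  expect_equal(unname(bf), exp(-k * c(10, 50)), tolerance = 0.05)
  # DNA competitor on DNA substrate reduces to the transfer scheme
  both <- build_competition_scheme("DNA", k_displace_by_RNA = 0,
                                   k_displace_by_DNA = 6.1e4,
                                   conc_DNA = 1e-7)
  expect_equal(unname(analytic_bound_fraction(both, 100)),
               exp(-6.1e4 * 1e-7 * 100), tolerance = 0.02)
})

test_that("experiment_condition validates inputs", {
  expect_error(experiment_condition("transfer", n_molecules = 0),
               "n_molecules")
  expect_error(experiment_condition("transfer", competitor_conc = -1),
               "competitor_conc")
  cond <- experiment_condition("homo_exchange", protein_conc = 1e-8,
                               n_molecules = 10, seed = 7)
  expect_s3_class(cond, "experiment_condition")
  expect_identical(cond$n_molecules, 10L)
})
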