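# Closed-loop recovery harnesses: simulate a preset with its published
# constant as ground truth, run the full analysis pipeline, and compare
# recovered to truth. These back both the acceptance tests and the
# `recover` CLI subcommand.

#' Recover a bimolecular transfer constant through the histogram pipeline
#'
#' For each competitor concentration: simulate an ensemble of tethered
#' molecules under the ternary-intermediate transfer scheme, record
#' short-movie snapshots along the decay, run the population pipeline
#' (FRET series -> histogram -> two-Gaussian decomposition -> bound
#' fraction), fit the bound-fraction decay with a single exponential,
#' then fit the observed rates linearly against concentration. The slope
#' is the recovered bimolecular constant.
#'
#' @param preset_name a transfer-type preset name.
#' @param seed master seed.
#' @param n_molecules molecules per concentration.
#' @param concs concentrations (M); default the preset grid.
#' @param n_snapshots snapshot movies per decay curve.
#' @param horizon_cap maximum wall-clock observation, s.
#' @param optics an [optics_model()].
#' @return list with `k_bi_true`, `k_bi_recovered`, `rel_error`,
#'   `bimolecular` (the fit), `per_conc` (data.frame), `seed`, `n`.
#' @export
recover_transfer_kbi <- function(preset_name, seed = 1L, n_molecules = 300L,
                                 concs = NULL, n_snapshots = 12L,
                                 horizon_cap = 3600,
                                 optics = optics_model()) {
  pr <- preset(preset_name)
  stopifnot(pr$type == "transfer")
  concs <- concs %||% pr$conc_grid
  pattern <- excitation_pattern("alex")
  rows <- lapply(seq_along(concs), function(ci) {
    conc <- concs[ci]
    scheme <- preset_transfer_scheme(pr, conc)
    # observation schedule: image long enough to see most of the decay
    # (the experimenter chooses this from the observed time scale)
    k_exp <- effective_kobs(transfer_rates(pr$k_bi / pr$p_success, conc,
                                           pr$k_resolution * 0.9,
                                           pr$k_resolution * 0.1))$k_obs
    t_max <- min(2.5 / max(k_exp, 1e-6), horizon_cap)
    times <- seq(0, t_max, length.out = n_snapshots)
    cond <- experiment_condition("transfer", competitor_conc = conc,
                                 n_molecules = n_molecules,
                                 seed = derive_seed(seed, ci))
    snaps <- synthesize_snapshots(cond, scheme, optics, pattern, times)
    # strongly overlapping levels (separation within the peak width)
    # need the constrained decomposition
    overlap <- abs(pr$fret_bound - pr$fret_free) <= 0.15
    bfs <- bound_fraction_series(snaps, times, l = optics$leakage,
                                 K = pr$K, init_means = pr$init_means,
                                 bound_e = pr$fret_bound,
                                 free_e = pr$fret_free,
                                 shared_sd = overlap)
    fit <- fit_exponential_decay(bfs$time, bfs$fraction,
                                 with_plateau = FALSE,
                                 fraction_input = TRUE)
    data.frame(conc = conc, k_obs = fit$k_obs, sd = fit$se[["k"]])
  })
  per_conc <- do.call(rbind, rows)
  bi <- fit_bimolecular(per_conc$conc, per_conc$k_obs, per_conc$sd)
  list(preset = preset_name, k_bi_true = pr$k_bi,
       k_bi_recovered = bi$k_bi,
       rel_error = abs(bi$k_bi - pr$k_bi) / pr$k_bi,
       bimolecular = bi, per_conc = per_conc,
       seed = seed, n = n_molecules)
}

#' Recover an exchange rate and exchange fraction from spot-count decays
#'
#' Per protein concentration: sample per-spot departure times from the
#' homotypic exchange scheme (first passage to the unlabeled-bound state;
#' a preset fraction of complexes never exchanges), render field-of-view
#' image series, count spots per image, fit the plateaued exponential
#' decay, then fit the rates against concentration.
#'
#' @param preset_name an exchange-type preset name.
#' @param seed master seed.
#' @param n_spots initial labeled spots per field of view.
#' @param concs protein concentrations (M); default the preset grid.
#' @param n_times images per decay.
#' @param image_shape field-of-view size, pixels.
#' @return list with `k_bi_true`, `k_bi_recovered`, `rel_error`,
#'   `exchange_fraction_true`, `exchange_fraction_recovered` (at the
#'   highest concentration's plateau fit), `bimolecular`, `per_conc`.
#' @export
recover_exchange <- function(preset_name, seed = 1L, n_spots = 300L,
                             concs = NULL, n_times = 14L,
                             image_shape = c(256L, 256L)) {
  pr <- preset(preset_name)
  stopifnot(pr$type == "exchange")
  concs <- concs %||% pr$conc_grid
  rows <- list(); fracs <- numeric(length(concs))
  for (ci in seq_along(concs)) {
    conc <- concs[ci]
    scheme <- build_exchange_scheme(k_on_protein = pr$k_bi / pr$p_success,
                                    conc = conc,
                                    k_fail = pr$k_resolution *
                                      (1 - pr$p_success),
                                    k_succ = pr$k_resolution * pr$p_success)
    k_exp <- pr$k_bi * conc
    horizon <- min(4.5 / max(k_exp, 1e-6), 3600)
    # departure times from the mechanism; residual complexes never exchange
    ens <- gillespie_ensemble(scheme, n_spots, horizon = horizon * 2,
                              seed = derive_seed(seed, ci, 1L))
    set.seed(derive_seed(seed, ci, 2L))
    never <- stats::runif(n_spots) >= pr$exchange_fraction
    dep <- ifelse(never, Inf,
                  ifelse(ens$censored, Inf, ens$first_passage))
    fov <- synthesize_fov_series(n_spots, k = k_exp, residual = 0,
                                 times = seq(0, horizon,
                                             length.out = n_times),
                                 image_shape = image_shape,
                                 seed = derive_seed(seed, ci, 3L),
                                 departure_times = dep)
    sc <- count_series(fov)
    sf <- fit_spot_decay(sc)
    rows[[ci]] <- data.frame(conc = conc, k_obs = sf$fit$k_obs,
                             sd = sf$fit$se[["k"]])
    fracs[ci] <- sf$exchange_fraction
  }
  per_conc <- do.call(rbind, rows)
  bi <- fit_bimolecular(per_conc$conc, per_conc$k_obs, per_conc$sd)
  list(preset = preset_name, k_bi_true = pr$k_bi,
       k_bi_recovered = bi$k_bi,
       rel_error = abs(bi$k_bi - pr$k_bi) / pr$k_bi,
       exchange_fraction_true = pr$exchange_fraction,
       exchange_fraction_recovered = fracs[length(fracs)],
       exchange_fractions = fracs,
       bimolecular = bi, per_conc = per_conc, seed = seed, n = n_spots)
}

#' Recover the binding-to-transfer dwell time from real-time traces
#'
#' Simulates labeled-competitor real-time transfer traces (continuous
#' green excitation, flow background step, 50 ms frames), detects
#' attempts, binding and completed transfers per trace, and fits the
#' dwell-time histogram with a Gaussian.
#'
#' @param preset_name a dwell-type preset name.
#' @param seed master seed.
#' @param n_traces number of molecules simulated.
#' @param optics optics model; the default adds the competitor-flow
#'   background step.
#' @return list with `dwell_true`, `dwell_recovered` (Gaussian mean),
#'   `rel_error`, `dwells` (the `dwell_time_set`), `n_events`,
#'   `mean_failed_attempts`.
#' @export
recover_dwell <- function(preset_name, seed = 1L, n_traces = 220L,
                          optics = NULL) {
  pr <- preset(preset_name)
  stopifnot(pr$type == "dwell")
  optics <- optics %||% optics_model(flow_background_step = 120,
                                     e_sd_molecule = 0)
  pattern <- excitation_pattern("continuous_green")
  scheme <- preset_transfer_scheme(pr, pr$conc, competitor_labeled = TRUE)
  horizon <- pr$horizon
  events <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    set.seed(derive_seed(seed, i))
    path <- gillespie_simulate(scheme, horizon)
    tr <- synthesize_trace(path, scheme, optics, pattern,
                           flow_start = pr$flow_start, molecule_id = i)
    s <- compute_fret(tr, l = optics$leakage)
    events[[i]] <- detect_events(tr, s, free_e = pr$fret_free)
  }
  ev <- do.call(rbind, events)
  dw <- measure_dwell_times(ev)
  list(preset = preset_name, dwell_true = pr$dwell_mean,
       dwell_recovered = dw$gaussian_mean,
       rel_error = abs(dw$gaussian_mean - pr$dwell_mean) / pr$dwell_mean,
       dwells = dw, n_events = nrow(ev),
       mean_failed_attempts = mean(ev$n_failed_attempts),
       seed = seed, n = n_traces)
}

#' DNA/RNA competition check
#'
#' Runs the competition preset on both co-immobilized substrates: the
#' RNA-substrate bound fraction must collapse while the DNA-substrate
#' bound fraction is untouched by the RNA competitor.
#'
#' @param seed master seed.
#' @param n_molecules molecules per substrate.
#' @param preset_name competition preset.
#' @return list with `rna_bound_final`, `dna_bound_final`, the
#'   bound-fraction series of both substrates, and `times`.
#' @export
recover_competition <- function(seed = 1L, n_molecules = 200L,
                                preset_name = "ssb_competition") {
  pr <- preset(preset_name)
  stopifnot(pr$type == "competition")
  optics <- optics_model()
  pattern <- excitation_pattern("alex")
  times <- seq(0, pr$horizon, length.out = 5L)
  run_substrate <- function(substrate, key) {
    if (substrate == "RNA") {
      scheme <- build_competition_scheme(
        "RNA", k_displace_by_RNA = pr$k_displace_by_RNA_on_RNA,
        k_displace_by_DNA = 0, conc_RNA = pr$conc_RNA,
        fret_bound = pr$fret_bound_RNA, fret_free = pr$fret_free_RNA)
      bound_e <- pr$fret_bound_RNA
      init <- sort(c(pr$fret_free_RNA, pr$fret_bound_RNA))
    } else {
      scheme <- build_competition_scheme(
        "DNA", k_displace_by_RNA = pr$k_displace_by_RNA_on_DNA,
        k_displace_by_DNA = 0, conc_RNA = pr$conc_RNA,
        fret_bound = pr$fret_bound_DNA, fret_free = pr$fret_free_DNA)
      bound_e <- pr$fret_bound_DNA
      init <- sort(c(pr$fret_free_DNA, pr$fret_bound_DNA))
    }
    cond <- experiment_condition("competition", competitor_conc = pr$conc_RNA,
                                 n_molecules = n_molecules,
                                 seed = derive_seed(seed, key))
    snaps <- synthesize_snapshots(cond, scheme, optics, pattern, times)
    bound_fraction_series(snaps, times, l = optics$leakage, K = 2L,
                          init_means = init, bound_e = bound_e,
                          free_e = setdiff(init, bound_e))
  }
  rna <- run_substrate("RNA", 1L)
  dna <- run_substrate("DNA", 2L)
  list(times = times, rna = rna, dna = dna,
       rna_bound_final = rna$fraction[nrow(rna)],
       dna_bound_final = dna$fraction[nrow(dna)])
}

#' Hetero-exchange recovery: completion rate and step classification
#'
#' @param preset_name a hetero-type preset name.
#' @param seed master seed.
#' @param n_traces number of molecules.
#' @return list with `analysis` (from [hetero_exchange_analysis()]),
#'   `k_recovered`, `mean_completion`, `frac_two_step`, and the preset's
#'   ground truth.
#' @export
recover_hetero <- function(preset_name, seed = 1L, n_traces = 150L) {
  pr <- preset(preset_name)
  stopifnot(pr$type == "hetero")
  scheme <- build_hetero_scheme(pr$n_steps, pr$step_rates, pr$fret_ladder)
  optics <- optics_model(e_sd_molecule = 0)
  pattern <- excitation_pattern("continuous_green")
  traces <- lapply(seq_len(n_traces), function(i) {
    set.seed(derive_seed(seed, i))
    path <- gillespie_simulate(scheme, pr$horizon)
    synthesize_trace(path, scheme, optics, pattern,
                     flow_start = pr$flow_start, molecule_id = i)
  })
  mid_e <- if (pr$n_steps == 2L) pr$fret_ladder[2L] else 0.45
  an <- hetero_exchange_analysis(traces, flow_start = pr$flow_start,
                                 final_e = pr$fret_ladder[pr$n_steps + 1L],
                                 intermediate_e = mid_e,
                                 l = optics$leakage)
  done <- an$completion[!an$completion$censored, , drop = FALSE]
  list(preset = preset_name,
       analysis = an,
       k_recovered = if (!is.null(an$rate)) an$rate$k else NA_real_,
       mean_completion = mean(done$time),
       frac_two_step = an$frac_two_step,
       truth = list(n_steps = pr$n_steps, step_rates = pr$step_rates,
                    mean_completion = sum(1 / pr$step_rates)),
       seed = seed, n = n_traces)
}
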