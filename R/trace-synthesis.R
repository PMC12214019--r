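# Rendering latent state paths into camera-frame two-channel intensity
# traces, with the optical artifacts the analysis layer must handle:
# donor leakage into the acceptor channel, shot and read noise, per-dye
# photobleaching, a background step when labeled competitor is flowed in,
# and alternating-laser excitation (ALEX) frame blocks.

#' Optics and noise model of the synthetic microscope
#'
#' Camera counts are generated per frame as Poisson shot noise on the
#' expected photon count plus additive Gaussian read noise, clipped at 0.
#' The acquisition described by the experiments gives no count levels or
#' leakage magnitude; the defaults (1000 counts/frame per dye pair, read
#' noise sd 15, leakage 0.08) are documented assumptions that make
#' histogram peak widths comparable to typical published smFRET
#' histograms, and everything is configurable.
#'
#' @param total_intensity expected counts/frame emitted by one
#'   donor-acceptor pair under green excitation.
#' @param leakage fraction of donor signal detected in the acceptor
#'   channel (`0 <= l < 0.5`).
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param shot_noise logical, Poisson noise on expected counts.
#' @param bleach_rate_donor,bleach_rate_acceptor photobleaching rates,
#'   s^-1 (0 disables; short-movie protocols are modeled with 0).
#' @param background_green,background_red background counts/frame in the
#'   donor and acceptor channels.
#' @param flow_background_step extra donor-channel counts/frame after
#'   `flow_start` (diffusing labeled competitor in the evanescent field).
#' @param e_sd_molecule sd of a per-molecule static offset applied to
#'   every state FRET level (molecule-to-molecule heterogeneity that
#'   broadens population histograms); 0 disables.
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(total_intensity = 1000, leakage = 0.08,
                         read_noise_sd = 15, shot_noise = TRUE,
                         bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                         background_green = 50, background_red = 50,
                         flow_background_step = 0, e_sd_molecule = 0.04) {
  if (leakage < 0 || leakage >= 0.5) {
    stop("leakage must satisfy 0 <= l < 0.5", call. = FALSE)
  }
  for (nm in c("total_intensity", "read_noise_sd", "bleach_rate_donor",
               "bleach_rate_acceptor", "background_green", "background_red",
               "flow_background_step")) {
    stop_if_not_scalar_nonneg(get(nm), nm)
  }
  structure(list(total_intensity = total_intensity, leakage = leakage,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 bleach_rate_donor = bleach_rate_donor,
                 bleach_rate_acceptor = bleach_rate_acceptor,
                 background_green = background_green,
                 background_red = background_red,
                 flow_background_step = flow_background_step,
                 e_sd_molecule = e_sd_molecule),
            class = "optics_model")
}

#' Noise-free optics (for exact round-trip checks)
#' @param ... overrides passed to [optics_model()].
#' @export
optics_noise_free <- function(...) {
  args <- utils::modifyList(
    list(read_noise_sd = 0, shot_noise = FALSE, background_green = 0,
         background_red = 0, e_sd_molecule = 0),
    list(...))
  do.call(optics_model, args)
}

#' Excitation pattern
#'
#' Either continuous green excitation or ALEX blocks of 10 green frames,
#' 1 dark frame and 10 red frames (a 21-frame cycle), at 50 ms frame
#' integration by default.
#'
#' @param mode `"continuous_green"` or `"alex"`.
#' @param frame_time frame integration time, s.
#' @return an object of class `excitation_pattern`.
#' @export
excitation_pattern <- function(mode = c("continuous_green", "alex"),
                               frame_time = 0.050) {
  mode <- match.arg(mode)
  if (frame_time <= 0) stop("frame_time must be > 0", call. = FALSE)
  structure(list(mode = mode, frame_time = frame_time,
                 alex_block = c(green = 10L, dark = 1L, red = 10L)),
            class = "excitation_pattern")
}

# excitation label per frame index (1-based)
excitation_of_frames <- function(pattern, frame_idx) {
  if (pattern$mode == "continuous_green") {
    return(rep("G", length(frame_idx)))
  }
  pos <- (frame_idx - 1L) %% 21L
  out <- rep("R", length(frame_idx))
  out[pos < 10L] <- "G"
  out[pos == 10L] <- "dark"
  out
}

#' Render a state path into a camera-frame intensity trace
#'
#' Per green-excited frame the expected donor-channel signal is
#' `n_donors * total * (1 - E) * donor_survival + background_green`
#' (plus the flow background step after `flow_start`), and the expected
#' acceptor-channel signal is
#' `n_donors * total * E * acceptor_alive + leakage * donor_signal +
#' background_red`. Two donors feeding one acceptor during ternary
#' occupancy double both channels (the acceptor "boost" that marks
#' competitor binding). Red frames report direct acceptor excitation
#' (`total` when the acceptor is alive) for donor-only exclusion; dark
#' frames report background only. State changes mid-frame are
#' time-weighted within the frame (camera integration), as are
#' photobleaching cut-offs.
#'
#' @param path a `state_path` from [gillespie_simulate()]; its times are
#'   interpreted as relative to `flow_start`.
#' @param scheme the [kinetic_scheme()] that produced the path.
#' @param optics an [optics_model()].
#' @param pattern an [excitation_pattern()].
#' @param duration trace duration, s; defaults to the path horizon plus
#'   `flow_start`.
#' @param t_start start time of the first rendered frame (s), e.g. the
#'   wall-clock time of a short snapshot movie.
#' @param flow_start time (s) at which the competitor flow starts; before
#'   it the molecule sits in the scheme's initial state.
#' @param seed optional integer seed for noise and bleaching.
#' @param molecule_id identifier stored with the trace.
#' @return an object of class `molecule_trace`: a data.frame with columns
#'   `frame`, `time` (frame start, s), `excitation` ("G"/"R"/"dark"),
#'   `I_D`, `I_A`, and attributes `frame_time`, `optics`, `truth` (the
#'   path), `molecule_id`, `flow_start`.
#' @export
synthesize_trace <- function(path, scheme, optics, pattern,
                             duration = NULL, t_start = 0, flow_start = 0,
                             seed = NULL, molecule_id = 1L) {
  stopifnot(inherits(path, "state_path"), inherits(scheme, "kinetic_scheme"),
            inherits(optics, "optics_model"),
            inherits(pattern, "excitation_pattern"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  dt <- pattern$frame_time
  duration <- duration %||% (attr(path, "horizon") + flow_start - t_start)
  n_frames <- ceiling(duration / dt - 1e-9)
  if (n_frames < 1L) stop("duration shorter than one frame", call. = FALSE)
  f0 <- floor(t_start / dt + 1e-9)          # global index of first frame
  frame_idx <- f0 + seq_len(n_frames)
  fstart <- (frame_idx - 1L) * dt
  exc <- excitation_of_frames(pattern, frame_idx)

  # piecewise-constant state segments on the absolute time axis
  seg_t0 <- c(if (flow_start > 0) 0, flow_start + path$time)
  seg_state <- c(if (flow_start > 0) scheme$initial_state, path$state)
  seg_t1 <- c(seg_t0[-1L], Inf)

  # per-molecule static FRET offset (population heterogeneity)
  e_off <- if (optics$e_sd_molecule > 0) {
    stats::rnorm(1L, 0, optics$e_sd_molecule)
  } else 0
  e_of_state <- clamp(scheme$fret_level + e_off, 0, 1)
  names(e_of_state) <- scheme$states
  nd_of_state <- stats::setNames(scheme$donor_count, scheme$states)
  acc_of_state <- stats::setNames(as.numeric(scheme$acceptor_present),
                                  scheme$states)

  # frame-integrated (time-weighted) emission factors
  don_emit <- numeric(n_frames)   # sum over segments: n_d * (1 - E) * w
  acc_emit <- numeric(n_frames)   # n_d * E * acceptor_present * w
  acc_alive_w <- numeric(n_frames) # acceptor-present fraction of frame
  tr_end <- fstart[n_frames] + dt
  for (s in seq_along(seg_t0)) {
    a <- seg_t0[s]; b <- seg_t1[s]
    if (b <= fstart[1L] || a >= tr_end) next
    i0 <- max(1L, floor((a - fstart[1L]) / dt) + 1L)
    i1 <- min(n_frames, ceiling((b - fstart[1L]) / dt + 1e-12))
    ii <- i0:i1
    w <- (pmin(b, fstart[ii] + dt) - pmax(a, fstart[ii])) / dt
    w[w < 0] <- 0
    st <- seg_state[s]
    don_emit[ii] <- don_emit[ii] + nd_of_state[st] * (1 - e_of_state[st]) * w
    acc_emit[ii] <- acc_emit[ii] +
      nd_of_state[st] * e_of_state[st] * acc_of_state[st] * w
    acc_alive_w[ii] <- acc_alive_w[ii] + acc_of_state[st] * w
  }

  # photobleaching: single cut-off time per dye, frame-weighted
  surv_weight <- function(rate) {
    if (rate <= 0) return(rep(1, n_frames))
    tb <- stats::rexp(1L, rate)
    clamp((tb - fstart) / dt, 0, 1)
  }
  don_surv <- surv_weight(optics$bleach_rate_donor)
  acc_surv <- surv_weight(optics$bleach_rate_acceptor)

  tot <- optics$total_intensity
  flow_bg <- optics$flow_background_step *
    clamp((fstart + dt - flow_start) / dt, 0, 1)  # ramps in within 1 frame

  is_g <- exc == "G"; is_r <- exc == "R"
  exp_D <- rep(optics$background_green, n_frames)
  exp_A <- rep(optics$background_red, n_frames)
  exp_D[is_g] <- exp_D[is_g] + flow_bg[is_g] +
    tot * don_emit[is_g] * don_surv[is_g]
  # FRET transfer needs a live acceptor; lost transfer returns to donor
  fretA <- tot * acc_emit * acc_surv
  lostA <- tot * acc_emit * (1 - acc_surv)   # re-emitted by the donor
  exp_D[is_g] <- exp_D[is_g] + lostA[is_g] * don_surv[is_g]
  exp_A[is_g] <- exp_A[is_g] + fretA[is_g] * don_surv[is_g] +
    optics$leakage * (exp_D[is_g] - optics$background_green)
  exp_A[is_r] <- exp_A[is_r] + tot * acc_alive_w[is_r] * acc_surv[is_r]

  I_D <- exp_D; I_A <- exp_A
  if (optics$shot_noise) {
    I_D <- stats::rpois(n_frames, exp_D)
    I_A <- stats::rpois(n_frames, exp_A)
  }
  if (optics$read_noise_sd > 0) {
    I_D <- I_D + stats::rnorm(n_frames, 0, optics$read_noise_sd)
    I_A <- I_A + stats::rnorm(n_frames, 0, optics$read_noise_sd)
  }
  I_D <- pmax(I_D, 0); I_A <- pmax(I_A, 0)

  tr <- data.frame(frame = frame_idx, time = fstart, excitation = exc,
                   I_D = I_D, I_A = I_A, stringsAsFactors = FALSE)
  attr(tr, "frame_time") <- dt
  attr(tr, "optics") <- optics
  attr(tr, "truth") <- path
  attr(tr, "molecule_id") <- molecule_id
  attr(tr, "flow_start") <- flow_start
  class(tr) <- c("molecule_trace", "data.frame")
  tr
}

#' Simulate an independent ensemble of molecule traces
#'
#' Each molecule gets its own seed stream derived from the condition seed
#' and its index, so ensembles are reproducible and order-independent.
#'
#' @param condition an [experiment_condition()].
#' @param scheme a [kinetic_scheme()].
#' @param optics an [optics_model()].
#' @param pattern an [excitation_pattern()].
#' @param horizon per-molecule kinetic horizon, s (time after
#'   `flow_start`).
#' @param duration rendered trace duration, s; defaults to
#'   `horizon + flow_start`.
#' @return list of `molecule_trace`.
#' @export
synthesize_ensemble <- function(condition, scheme, optics, pattern,
                                horizon = 3600, duration = NULL) {
  stopifnot(inherits(condition, "experiment_condition"))
  lapply(seq_len(condition$n_molecules), function(i) {
    set.seed(derive_seed(condition$seed, i))
    path <- gillespie_simulate(scheme, horizon)
    synthesize_trace(path, scheme, optics, pattern, duration = duration,
                     flow_start = condition$flow_start, molecule_id = i)
  })
}

#' Short-movie snapshot ensemble
#'
#' Emulates the histogram workflow in which short (~2 s) movies are
#' recorded at a series of wall-clock times after competitor addition.
#' Every molecule's latent path spans the whole experiment; only the
#' frames inside each snapshot window are rendered.
#'
#' @inheritParams synthesize_ensemble
#' @param times wall-clock snapshot start times, s (from flow start).
#' @param movie_s snapshot movie length, s (default 2).
#' @return a list (one element per snapshot time) of lists of
#'   `molecule_trace`.
#' @export
synthesize_snapshots <- function(condition, scheme, optics, pattern,
                                 times, movie_s = 2) {
  stopifnot(inherits(condition, "experiment_condition"))
  horizon <- max(times) + movie_s + 1
  per_mol <- lapply(seq_len(condition$n_molecules), function(i) {
    set.seed(derive_seed(condition$seed, i))
    path <- gillespie_simulate(scheme, horizon)
    lapply(seq_along(times), function(j) {
      set.seed(derive_seed(condition$seed, i, j))
      synthesize_trace(path, scheme, optics, pattern,
                       duration = movie_s, t_start = times[j],
                       flow_start = 0, molecule_id = i)
    })
  })
  lapply(seq_along(times), function(j) lapply(per_mol, `[[`, j))
}
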