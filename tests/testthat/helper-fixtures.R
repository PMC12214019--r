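# Shared fixture builders. Everything is generated in code; no data files.

# canonical 2-state A -> B scheme (rate k), absorbing B
two_state_scheme <- function(k = 1, e_a = 0.8, e_b = 0.2) {
  Q <- matrix(c(0, k, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  kinetic_scheme(Q, c(A = e_a, B = e_b))
}

# the worked ternary transfer example: k_on 1e6, conc 1e-7, k_fail 9,
# k_succ 1 -> k_obs 0.01 s^-1, mean attempts 10
example_transfer_rates <- function() {
  transfer_rates(k_on_compete = 1e6, conc_compete = 1e-7,
                 k_fail = 9, k_succ = 1)
}

# static single-state scheme at a fixed FRET level (optionally without
# acceptor, for donor-only molecules)
static_scheme <- function(e, acceptor = TRUE, donors = 1L) {
  Q <- matrix(0, 1, 1, dimnames = list("S", "S"))
  kinetic_scheme(Q, c(S = e), donor_count = c(S = donors),
                 acceptor_present = c(S = acceptor))
}

# hand-built state path (class only; for synthesizing known traces)
manual_path <- function(times, states, horizon) {
  p <- data.frame(time = times, state = states, stringsAsFactors = FALSE)
  attr(p, "horizon") <- horizon
  class(p) <- c("state_path", "data.frame")
  p
}

# a small ALEX ensemble of static molecules at FRET level e
static_ensemble <- function(n, e, optics, duration = 20,
                            seed_base = 100, acceptor = TRUE) {
  sc <- static_scheme(e, acceptor = acceptor)
  pat <- excitation_pattern("alex")
  lapply(seq_len(n), function(i) {
    set.seed(seed_base + i)
    synthesize_trace(gillespie_simulate(sc, duration + 1), sc, optics, pat,
                     duration = duration, molecule_id = seed_base + i)
  })
}
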