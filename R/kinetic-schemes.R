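# Kinetic mechanisms as labelled continuous-time Markov chains (CTMCs).
#
# A scheme couples the generator matrix of the CTMC with the optical
# bookkeeping the trace synthesizer needs: the FRET efficiency of each
# state, how many donor (Cy3-type) dyes are present, and whether the
# acceptor dye is present. Transfer and exchange mechanisms end in an
# absorbing state (the departed protein/competitor complex never rebinds
# under pseudo-first-order conditions).

#' Construct a labelled kinetic scheme
#'
#' @param rate_matrix square matrix of transition rates (s^-1) with
#'   dimnames naming the states. Off-diagonal entries are rates i -> j;
#'   the diagonal is ignored and recomputed as minus the row sum.
#' @param fret_level named numeric vector, FRET efficiency of each state
#'   in `[0, 1]`.
#' @param donor_count named integer vector, number of donor dyes
#'   contributing in each state (drives the two-donor acceptor boost seen
#'   during ternary-intermediate occupancy). Defaults to 1 for all states.
#' @param acceptor_present named logical vector. Defaults to TRUE.
#' @param initial_state state label occupied at t = 0. Defaults to the
#'   first state.
#'
#' @return an object of class `kinetic_scheme` with elements `states`,
#'   `Q` (generator matrix), `fret_level`, `donor_count`,
#'   `acceptor_present`, `absorbing` (labels with zero outflow) and
#'   `initial_state`.
#' @export
kinetic_scheme <- function(rate_matrix, fret_level, donor_count = NULL,
                           acceptor_present = NULL, initial_state = NULL) {
  if (!is.matrix(rate_matrix) || nrow(rate_matrix) != ncol(rate_matrix)) {
    stop("rate_matrix must be a square matrix", call. = FALSE)
  }
  states <- rownames(rate_matrix)
  if (is.null(states) || is.null(colnames(rate_matrix)) ||
      !identical(states, colnames(rate_matrix))) {
    stop("rate_matrix needs identical row/column state names", call. = FALSE)
  }
  Q <- rate_matrix
  diag(Q) <- 0
  if (any(Q < 0) || any(!is.finite(Q))) {
    stop("off-diagonal rates must be finite and >= 0", call. = FALSE)
  }
  diag(Q) <- -rowSums(Q)

  fret_level <- fret_level[states]
  if (anyNA(fret_level) || any(fret_level < 0 | fret_level > 1)) {
    stop("fret_level must cover all states with values in [0, 1]",
         call. = FALSE)
  }
  if (is.null(donor_count)) {
    donor_count <- stats::setNames(rep(1L, length(states)), states)
  }
  donor_count <- donor_count[states]
  if (anyNA(donor_count) || any(donor_count < 0)) {
    stop("donor_count must cover all states with values >= 0", call. = FALSE)
  }
  if (is.null(acceptor_present)) {
    acceptor_present <- stats::setNames(rep(TRUE, length(states)), states)
  }
  acceptor_present <- acceptor_present[states]
  initial_state <- initial_state %||% states[1L]
  if (!initial_state %in% states) stop("unknown initial_state", call. = FALSE)

  structure(
    list(states = states, Q = Q,
         fret_level = fret_level,
         donor_count = as.integer(donor_count),
         acceptor_present = as.logical(acceptor_present),
         absorbing = states[rowSums(Q > 0) == 0L],
         initial_state = initial_state),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  initial:", x$initial_state,
      " absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  cat("  FRET levels:",
      paste(sprintf("%s=%.2f", x$states, x$fret_level), collapse = " "), "\n")
  invisible(x)
}

#' Rate parameters of the ternary-intermediate transfer mechanism
#'
#' Pseudo-first-order strand transfer: a solution competitor strand at
#' fixed concentration associates with the bound protein-DNA complex
#' (bimolecular constant `k_on_compete`), forming a transient ternary
#' intermediate in which the protein contacts both strands. The
#' intermediate resolves either back to the incumbent-bound state
#' (`k_fail`, a failed attempt) or by departure of the protein with the
#' competitor (`k_succ`, successful transfer).
#'
#' @param k_on_compete bimolecular association constant, M^-1 s^-1.
#' @param conc_compete competitor concentration, M.
#' @param k_fail ternary resolution back to the bound state, s^-1.
#' @param k_succ ternary resolution by successful transfer, s^-1.
#' @param k_off_intrinsic spontaneous dissociation of the bound complex,
#'   s^-1. Defaults to 0: bound complexes are stable for hours in the
#'   absence of competitor.
#' @return an object of class `transfer_rates`.
#' @export
transfer_rates <- function(k_on_compete, conc_compete, k_fail, k_succ,
                           k_off_intrinsic = 0) {
  for (nm in c("k_on_compete", "conc_compete", "k_fail", "k_succ",
               "k_off_intrinsic")) {
    stop_if_not_scalar_nonneg(get(nm), nm)
  }
  if (k_on_compete * conc_compete > 0 && k_fail + k_succ <= 0) {
    stop("k_fail + k_succ must be > 0 when association is possible",
         call. = FALSE)
  }
  structure(list(k_on_compete = k_on_compete, conc_compete = conc_compete,
                 k_fail = k_fail, k_succ = k_succ,
                 k_off_intrinsic = k_off_intrinsic),
            class = "transfer_rates")
}

#' Build the ternary-intermediate strand-transfer scheme
#'
#' Three macroscopic states: `Bound` (protein on the tethered strand),
#' `Ternary` (protein bridging tethered and competitor strands) and
#' `FreeDNA` (absorbing; the protein departed with the competitor and the
#' tethered strand is regenerated).
#'
#' The lifetime of a ternary visit is `1/(k_fail + k_succ)` and each
#' visit resolves successfully with probability
#' `k_succ / (k_fail + k_succ)`, giving a geometric number of attempts.
#' With `n_sub > 1` the ternary lifetime is subdivided into `n_sub`
#' sequential sub-states of equal rate (an Erlang lifetime with the same
#' mean and success probability). Measured dwell-time histograms of the
#' binding-to-transfer interval are bell-shaped rather than exponential,
#' which is what a multi-microstep resolution produces; `n_sub = 1`
#' retains the memoryless limit.
#'
#' @param rates a [transfer_rates()] object.
#' @param fret_bound,fret_free FRET efficiencies of the protein-bound and
#'   regenerated (protein-free) tethered strand.
#' @param competitor_labeled logical; when TRUE (labeled competitor, as in
#'   real-time transfer imaging) ternary states carry two donors.
#' @param n_sub number of sequential ternary sub-states (>= 1).
#' @return a [kinetic_scheme()].
#' @export
build_transfer_scheme <- function(rates, fret_bound, fret_free,
                                  competitor_labeled = TRUE, n_sub = 1L) {
  stopifnot(inherits(rates, "transfer_rates"))
  if (fret_bound < 0 || fret_bound > 1 || fret_free < 0 || fret_free > 1) {
    stop("FRET levels must lie in [0, 1]", call. = FALSE)
  }
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) stop("n_sub must be >= 1", call. = FALSE)

  k_assoc <- rates$k_on_compete * rates$conc_compete
  k_res <- rates$k_fail + rates$k_succ
  p_succ <- if (k_res > 0) rates$k_succ / k_res else 0
  tern <- if (n_sub == 1L) "Ternary" else paste0("Ternary", seq_len(n_sub))
  states <- c("Bound", tern, "FreeDNA")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  Q["Bound", tern[1L]] <- k_assoc
  Q["Bound", "FreeDNA"] <- rates$k_off_intrinsic
  r_sub <- n_sub * k_res          # Erlang(n_sub, r_sub) lifetime, mean 1/k_res
  if (n_sub > 1L) {
    for (i in seq_len(n_sub - 1L)) Q[tern[i], tern[i + 1L]] <- r_sub
  }
  Q[tern[n_sub], "FreeDNA"] <- r_sub * p_succ
  Q[tern[n_sub], "Bound"]  <- r_sub * (1 - p_succ)

  fret <- stats::setNames(
    c(fret_bound, rep(fret_bound, n_sub), fret_free), states)
  donors <- stats::setNames(
    c(1L, rep(if (competitor_labeled) 2L else 1L, n_sub), 1L), states)
  kinetic_scheme(Q, fret, donors, initial_state = "Bound")
}

#' Build the homotypic protein-exchange scheme
#'
#' A labeled protein bound to tethered DNA is replaced by an unlabeled
#' solution protein via a transient ternary (two-protein) intermediate.
#' The absorbing `UnlabeledBound` state has zero donors: the fluorescent
#' spot disappears when the labeled protein departs.
#'
#' @param k_on_protein bimolecular association constant of the incoming
#'   protein, M^-1 s^-1.
#' @param conc protein concentration, M.
#' @param k_fail,k_succ ternary resolution rates, s^-1.
#' @param labeled_initial logical; if FALSE the donor bookkeeping is
#'   inverted (spot appears on exchange).
#' @param fret_bound FRET level of the bound states (the tethered DNA's
#'   own dye pair, if any); exchange assays track donor spots, so this
#'   defaults to 0.5 and is mostly cosmetic.
#' @return a [kinetic_scheme()].
#' @export
build_exchange_scheme <- function(k_on_protein, conc, k_fail, k_succ,
                                  labeled_initial = TRUE, fret_bound = 0.5) {
  stop_if_not_scalar_nonneg(k_on_protein, "k_on_protein")
  stop_if_not_scalar_nonneg(conc, "conc")
  stop_if_not_scalar_nonneg(k_fail, "k_fail")
  stop_if_not_scalar_nonneg(k_succ, "k_succ")
  k_assoc <- k_on_protein * conc
  if (k_assoc > 0 && k_fail + k_succ <= 0) {
    stop("k_fail + k_succ must be > 0 when association is possible",
         call. = FALSE)
  }
  states <- c("LabeledBound", "Ternary", "UnlabeledBound")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  Q["LabeledBound", "Ternary"] <- k_assoc
  Q["Ternary", "LabeledBound"] <- k_fail
  Q["Ternary", "UnlabeledBound"] <- k_succ
  fret <- stats::setNames(rep(fret_bound, 3), states)
  donors <- if (labeled_initial) c(1L, 1L, 0L) else c(0L, 0L, 1L)
  kinetic_scheme(Q, fret, stats::setNames(donors, states),
                 initial_state = "LabeledBound")
}

#' Build a stepwise hetero-exchange ladder
#'
#' Hetero-protein exchange (e.g. SSB replaced by RPA) proceeds through a
#' linear ladder of one or two irreversible steps, each with its own rate
#' and FRET level; completion is entry into the last state.
#'
#' @param n_steps 1 or 2.
#' @param step_rates numeric vector of per-step rates (s^-1), length
#'   `n_steps`.
#' @param fret_ladder FRET levels of the `n_steps + 1` ladder states,
#'   starting at the incumbent-bound level and ending at the fully
#'   exchanged level.
#' @return a [kinetic_scheme()].
#' @export
build_hetero_scheme <- function(n_steps, step_rates, fret_ladder) {
  n_steps <- as.integer(n_steps)
  if (!n_steps %in% c(1L, 2L)) stop("n_steps must be 1 or 2", call. = FALSE)
  if (length(step_rates) != n_steps) {
    stop("length(step_rates) must equal n_steps", call. = FALSE)
  }
  if (length(fret_ladder) != n_steps + 1L) {
    stop("length(fret_ladder) must equal n_steps + 1", call. = FALSE)
  }
  if (any(step_rates < 0)) stop("step rates must be >= 0", call. = FALSE)
  states <- paste0("S", 0:n_steps)
  Q <- matrix(0, n_steps + 1L, n_steps + 1L,
              dimnames = list(states, states))
  for (i in seq_len(n_steps)) Q[states[i], states[i + 1L]] <- step_rates[i]
  kinetic_scheme(Q, stats::setNames(fret_ladder, states),
                 initial_state = "S0")
}

#' Build a DNA/RNA competition scheme
#'
#' Encodes the substrate preference observed in competition assays: an
#' RNA competitor displaces protein from RNA-bound complexes but not from
#' DNA-bound complexes (`k_displace_by_RNA = 0` on the DNA substrate even
#' at micromolar RNA), whereas a DNA competitor displaces protein from
#' both.
#'
#' @param substrate `"DNA"` or `"RNA"`: the tethered substrate the
#'   protein starts on.
#' @param k_displace_by_RNA,k_displace_by_DNA bimolecular displacement
#'   constants (M^-1 s^-1) of the RNA and DNA competitors acting on this
#'   substrate's bound complex.
#' @param conc_RNA,conc_DNA competitor concentrations, M.
#' @param k_fail,k_succ ternary resolution rates shared by both
#'   displacement routes, s^-1.
#' @param fret_bound,fret_free substrate-specific FRET levels.
#' @return a [kinetic_scheme()]; reduces to [build_transfer_scheme()]
#'   with the summed effective association rate.
#' @export
build_competition_scheme <- function(substrate = c("DNA", "RNA"),
                                     k_displace_by_RNA, k_displace_by_DNA,
                                     conc_RNA = 0, conc_DNA = 0,
                                     k_fail = 9, k_succ = 1,
                                     fret_bound = 0.8, fret_free = 0.2) {
  substrate <- match.arg(substrate)
  stop_if_not_scalar_nonneg(k_displace_by_RNA, "k_displace_by_RNA")
  stop_if_not_scalar_nonneg(k_displace_by_DNA, "k_displace_by_DNA")
  k_eff <- k_displace_by_RNA * conc_RNA + k_displace_by_DNA * conc_DNA
  # fold both routes into one effective pseudo-first-order association;
  # the displacement constants are effective (per-success) bimolecular
  # constants, so the attempt rate is inflated by 1/p_success
  p_succ <- if (k_fail + k_succ > 0) k_succ / (k_fail + k_succ) else 1
  rates <- transfer_rates(k_on_compete = 1 / p_succ, conc_compete = k_eff,
                          k_fail = k_fail, k_succ = k_succ)
  sc <- build_transfer_scheme(rates, fret_bound, fret_free,
                              competitor_labeled = FALSE)
  attr(sc, "substrate") <- substrate
  sc
}

#' Effective pseudo-first-order transfer rate
#'
#' Steady-state reduction of the ternary-intermediate scheme: attempts
#' arrive at `k_on * conc` and each succeeds with probability
#' `k_succ / (k_succ + k_fail)`, so
#' `k_obs = k_on * conc * k_succ / (k_succ + k_fail)`
#' (plus any intrinsic dissociation). The reduction is a good description
#' of the first-passage time when ternary resolution is fast compared to
#' attempt arrival; `valid` flags that regime.
#'
#' @param rates a [transfer_rates()] object.
#' @return list with `k_obs` (s^-1) and logical `valid`.
#' @export
effective_kobs <- function(rates) {
  stopifnot(inherits(rates, "transfer_rates"))
  k_assoc <- rates$k_on_compete * rates$conc_compete
  k_res <- rates$k_fail + rates$k_succ
  if (k_res == 0) {
    if (k_assoc > 0) stop("k_fail = k_succ = 0: ternary never resolves",
                          call. = FALSE)
    return(list(k_obs = rates$k_off_intrinsic, valid = TRUE))
  }
  k_obs <- k_assoc * rates$k_succ / k_res + rates$k_off_intrinsic
  list(k_obs = k_obs, valid = (k_res >= 10 * k_assoc))
}

#' Experimental condition metadata
#'
#' @param mechanism one of `"transfer"`, `"homo_exchange"`,
#'   `"hetero_exchange"`, `"competition"`.
#' @param competitor_conc,protein_conc molar concentrations.
#' @param flow_start time (s) at which the competitor enters the chamber.
#' @param n_molecules ensemble size.
#' @param seed master seed for the condition.
#' @param salt_label free-text buffer note (metadata only).
#' @export
experiment_condition <- function(mechanism = c("transfer", "homo_exchange",
                                               "hetero_exchange",
                                               "competition"),
                                 competitor_conc = 0, protein_conc = 0,
                                 flow_start = 0, n_molecules = 1L,
                                 seed = 1L, salt_label = "") {
  mechanism <- match.arg(mechanism)
  stop_if_not_scalar_nonneg(competitor_conc, "competitor_conc")
  stop_if_not_scalar_nonneg(protein_conc, "protein_conc")
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1", call. = FALSE)
  structure(list(mechanism = mechanism, competitor_conc = competitor_conc,
                 protein_conc = protein_conc, flow_start = flow_start,
                 n_molecules = n_molecules, seed = as.integer(seed),
                 salt_label = salt_label),
            class = "experiment_condition")
}
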