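# Exact stochastic simulation of kinetic schemes and their analytic
# (master-equation) oracle.

#' Simulate one exact state path of a kinetic scheme
#'
#' Gillespie's direct method: the waiting time in state i is exponential
#' with rate `-Q[i, i]` and the next state is drawn proportionally to the
#' off-diagonal rates. The path ends at the first entry into an absorbing
#' (zero-outflow) state or at the horizon, whichever comes first.
#'
#' @param scheme a [kinetic_scheme()].
#' @param horizon simulation horizon, s (> 0).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return an object of class `state_path`: a data.frame with columns
#'   `time` (entry time, s; first row at t = 0) and `state`, plus a
#'   `horizon` attribute.
#' @export
gillespie_simulate <- function(scheme, horizon, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  Q <- scheme$Q
  states <- scheme$states
  cur <- match(scheme$initial_state, states)
  t <- 0
  cap <- 64L
  ev_t <- numeric(cap); ev_s <- integer(cap)
  n <- 1L; ev_t[1L] <- 0; ev_s[1L] <- cur
  repeat {
    out <- -Q[cur, cur]
    if (out <= 0) break                       # absorbing (or trapped) state
    t <- t + stats::rexp(1L, rate = out)
    if (t >= horizon) break
    p <- Q[cur, ]; p[cur] <- 0
    cur <- sample.int(length(states), 1L, prob = p)
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_s) <- cap
    }
    ev_t[n] <- t; ev_s[n] <- cur
  }
  path <- data.frame(time = ev_t[seq_len(n)],
                     state = states[ev_s[seq_len(n)]],
                     stringsAsFactors = FALSE)
  attr(path, "horizon") <- horizon
  class(path) <- c("state_path", "data.frame")
  path
}

#' Vectorized ensemble Gillespie simulation
#'
#' Simulates many independent realizations of a scheme simultaneously
#' (one synchronized jump layer per loop iteration, vectorized across
#' paths). Returns summary quantities rather than full paths; use
#' [gillespie_simulate()] when the path itself is needed.
#'
#' @param scheme a [kinetic_scheme()].
#' @param n number of paths.
#' @param horizon horizon, s.
#' @param seed optional integer seed.
#' @param occupancy_times optional numeric vector of times at which the
#'   occupied state of every path is recorded.
#' @param count_visits optional state label; visits to it are counted
#'   per path.
#' @return list with
#'   `first_passage` (time of first entry into any absorbing state, NA if
#'   censored at the horizon), `censored` (logical), `final_state`,
#'   `visits` (if requested) and `occupancy` (matrix paths x times of
#'   state labels, if requested).
#' @export
gillespie_ensemble <- function(scheme, n, horizon, seed = NULL,
                               occupancy_times = NULL, count_visits = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  states <- scheme$states
  ns <- length(states)
  Q <- scheme$Q
  out_rate <- -diag(Q)
  # per-state cumulative jump distributions
  jump_prob <- Q
  diag(jump_prob) <- 0
  for (i in seq_len(ns)) {
    if (out_rate[i] > 0) jump_prob[i, ] <- jump_prob[i, ] / out_rate[i]
  }
  cum_jump <- t(apply(jump_prob, 1L, cumsum))

  cur <- rep(match(scheme$initial_state, states), n)
  t_now <- numeric(n)
  fp <- rep(NA_real_, n)
  absorbing_idx <- match(scheme$absorbing, states)
  visits <- integer(n)
  visit_idx <- if (!is.null(count_visits)) match(count_visits, states) else NA
  rec <- NULL
  if (!is.null(occupancy_times)) {
    rec <- matrix(NA_integer_, n, length(occupancy_times))
  }
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    r <- out_rate[cur[idx]]
    trapped <- r <= 0
    if (any(trapped)) {
      tr <- idx[trapped]
      done_absorbed <- cur[tr] %in% absorbing_idx
      fp[tr[done_absorbed]] <- t_now[tr[done_absorbed]]
      if (!is.null(rec)) {
        for (j in seq_along(occupancy_times)) {
          late <- occupancy_times[j] >= t_now[tr]
          rec[tr[late], j] <- cur[tr[late]]
        }
      }
      active[tr] <- FALSE
      idx <- idx[!trapped]
      if (!length(idx)) next
      r <- out_rate[cur[idx]]
    }
    t_new <- t_now[idx] + stats::rexp(length(idx), rate = r)
    # record occupancy for sampling times passed during this sojourn
    if (!is.null(rec)) {
      for (j in seq_along(occupancy_times)) {
        hit <- occupancy_times[j] >= t_now[idx] &
          occupancy_times[j] < pmin(t_new, horizon)
        rec[idx[hit], j] <- cur[idx[hit]]
      }
    }
    over <- t_new >= horizon
    if (any(over)) active[idx[over]] <- FALSE
    idx <- idx[!over]; t_new <- t_new[!over]
    if (!length(idx)) next
    u <- stats::runif(length(idx))
    nxt <- integer(length(idx))
    for (s in unique(cur[idx])) {
      sel <- cur[idx] == s
      nxt[sel] <- findInterval(u[sel], cum_jump[s, ]) + 1L
    }
    t_now[idx] <- t_new
    cur[idx] <- nxt
    if (!is.na(visit_idx)) visits[idx] <- visits[idx] + (nxt == visit_idx)
    absorbed <- nxt %in% absorbing_idx
    if (any(absorbed)) {
      ai <- idx[absorbed]
      fp[ai] <- t_new[absorbed]
      if (!is.null(rec)) {
        for (j in seq_along(occupancy_times)) {
          late <- occupancy_times[j] >= t_new[absorbed]
          rec[ai[late], j] <- nxt[absorbed][late]
        }
      }
      active[ai] <- FALSE
    }
  }
  occ <- NULL
  if (!is.null(rec)) {
    occ <- matrix(states[rec], n, length(occupancy_times))
    colnames(occ) <- as.character(occupancy_times)
  }
  list(first_passage = fp,
       censored = is.na(fp),
       final_state = states[cur],
       visits = if (!is.null(count_visits)) visits else NULL,
       occupancy = occ)
}

#' Exact state occupancy from the master equation
#'
#' Solves `p(t) = p(0) exp(Q t)` with the matrix exponential.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t time, s (>= 0). May be a vector.
#' @return if `t` is scalar, a named probability vector; otherwise a
#'   matrix with one row per time.
#' @export
analytic_occupancy <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p0 <- as.numeric(scheme$states == scheme$initial_state)
  res <- vapply(t, function(tt) {
    if (tt == 0) return(p0)
    P <- as.matrix(Matrix::expm(Matrix::Matrix(scheme$Q * tt,
                                               sparse = FALSE)))
    as.numeric(p0 %*% P)
  }, numeric(length(scheme$states)))
  res <- t(res)
  colnames(res) <- scheme$states
  if (length(t) == 1L) res[1L, ] else res
}

#' Probability that the scheme is still in a non-absorbed "bound" set
#'
#' Convenience oracle: sums analytic occupancy over the given states.
#' @param scheme a [kinetic_scheme()].
#' @param t numeric vector of times.
#' @param states character vector of state labels counted as bound;
#'   defaults to all non-absorbing states.
#' @export
analytic_bound_fraction <- function(scheme, t, states = NULL) {
  states <- states %||% setdiff(scheme$states, scheme$absorbing)
  occ <- analytic_occupancy(scheme, t)
  if (is.null(dim(occ))) occ <- matrix(occ, 1L,
                                       dimnames = list(NULL, scheme$states))
  rowSums(occ[, states, drop = FALSE])
}

#' Export a state path as a two-column CSV
#' @param path a `state_path`.
#' @param file destination path.
#' @export
write_state_path_csv <- function(path, file) {
  stopifnot(inherits(path, "state_path"))
  utils::write.csv(data.frame(time_s = path$time, state = path$state),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
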