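# Per-molecule and population FRET computations: efficiency with donor
# leakage correction, donor-only exclusion via the red-excitation frames,
# normalized population histograms, multi-Gaussian decomposition and
# bound-fraction extraction.

#' FRET efficiency series of a trace
#'
#' Per green-excited frame: the acceptor channel is corrected for donor
#' leakage, `I_A' = I_A - l * I_D` (floored at 0), and
#' `E = I_A' / (I_D + I_A')`, clamped to `[0, 1]`. Frames with total
#' corrected intensity below `floor_frac * total_intensity` (bleached or
#' dark frames) are flagged invalid.
#'
#' @param trace a `molecule_trace`.
#' @param l donor leakage fraction (`0 <= l < 0.5`).
#' @param floor_frac intensity floor as a fraction of the optics model's
#'   total intensity; frames below it are invalid.
#' @param total_intensity reference intensity for the floor; defaults to
#'   the trace's optics model.
#' @return an object of class `fret_series`: data.frame with columns
#'   `time`, `E`, `valid`, plus `molecule_id` attribute.
#' @export
compute_fret <- function(trace, l = 0, floor_frac = 0.2,
                         total_intensity = NULL) {
  stopifnot(inherits(trace, "molecule_trace"))
  if (l < 0 || l >= 0.5) stop("leakage must satisfy 0 <= l < 0.5",
                              call. = FALSE)
  g <- trace[trace$excitation == "G", , drop = FALSE]
  if (nrow(g) == 0L) stop("trace has no green-excited frames", call. = FALSE)
  total_intensity <- total_intensity %||%
    attr(trace, "optics")$total_intensity %||% 0
  IAc <- pmax(g$I_A - l * g$I_D, 0)
  tot <- g$I_D + IAc
  E <- ifelse(tot > 0, IAc / tot, 0)
  out <- data.frame(time = g$time, E = clamp(E, 0, 1),
                    valid = tot >= floor_frac * total_intensity)
  attr(out, "molecule_id") <- attr(trace, "molecule_id")
  class(out) <- c("fret_series", "data.frame")
  out
}

#' Estimate the donor leakage fraction from donor-only traces
#'
#' On a donor-only molecule the background-corrected acceptor channel
#' carries only leaked donor signal, so the per-frame ratio
#' `(I_A - bg_A) / (I_D - bg_D)` estimates `l` directly (equivalently,
#' `l` is the raw donor-only efficiency mapped through the inverse of the
#' leakage correction). Channel backgrounds are estimated from the ALEX
#' dark frames of the traces themselves when present, else taken from
#' the attached optics model. Inputs are pre-checked to be truly
#' donor-only (no acceptor signal under red excitation).
#'
#' @param traces list of `molecule_trace` verified donor-only.
#' @param check logical, verify the donor-only contract via
#'   [exclude_donor_only()] and error on FRET-active molecules.
#' @return leakage fraction estimate (median over all valid frames).
#' @export
estimate_leakage <- function(traces, check = TRUE) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  if (check) {
    part <- exclude_donor_only(traces)
    if (length(part$fret_active) > 0L) {
      stop("input contains FRET-active molecules (acceptor alive under ",
           "red excitation); estimate_leakage needs donor-only traces",
           call. = FALSE)
    }
  }
  raw <- unlist(lapply(traces, function(tr) {
    g <- tr[tr$excitation == "G", , drop = FALSE]
    dk <- tr[tr$excitation == "dark", , drop = FALSE]
    op <- attr(tr, "optics")
    bg_D <- if (nrow(dk) > 0L) stats::median(dk$I_D) else
      op$background_green %||% 0
    bg_A <- if (nrow(dk) > 0L) stats::median(dk$I_A) else
      op$background_red %||% 0
    d <- g$I_D - bg_D
    keep <- d > 0.2 * (op$total_intensity %||% 1)
    ((g$I_A - bg_A) / d)[keep]
  }))
  if (length(raw) == 0L) stop("no usable green frames", call. = FALSE)
  max(stats::median(raw), 0)
}

#' Partition traces into FRET-active and donor-only molecules
#'
#' Uses the alternating-excitation red frames: a molecule is donor-only
#' iff its mean red-frame acceptor signal does not exceed the red-channel
#' background by more than 3 read-noise sd.
#'
#' @param traces list of `molecule_trace` recorded with ALEX.
#' @return list with elements `fret_active` and `donor_only`, each a list
#'   of traces.
#' @export
exclude_donor_only <- function(traces) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  is_donor_only <- vapply(traces, function(tr) {
    r <- tr[tr$excitation == "R", , drop = FALSE]
    if (nrow(r) == 0L) {
      stop("trace has no red-excitation frames; donor-only exclusion ",
           "requires an ALEX excitation pattern (mode = \"alex\")",
           call. = FALSE)
    }
    op <- attr(tr, "optics")
    thr <- (op$background_red %||% 0) + 3 * (op$read_noise_sd %||% 0) +
      3 * sqrt(max(op$background_red %||% 0, 1))   # shot noise on background
    mean(r$I_A) <= thr
  }, logical(1L))
  list(fret_active = traces[!is_donor_only],
       donor_only = traces[is_donor_only])
}

#' Build a normalized population FRET histogram
#'
#' Pools the first `frames_per_molecule` valid efficiency values of each
#' molecule and normalizes the histogram to unit area. Bin width 0.025
#' over `[-0.05, 1.05]` (values are already clamped to `[0, 1]` upstream).
#'
#' @param series list of `fret_series` (or a single one).
#' @param frames_per_molecule frames pooled per molecule.
#' @param bin_width histogram bin width in E units.
#' @return object of class `fret_histogram`: data.frame with `bin_center`
#'   and `density`, plus attributes `bin_edges`, `n_molecules`,
#'   `frames_per_molecule`, `n_frames`.
#' @export
build_histogram <- function(series, frames_per_molecule = 21L,
                            bin_width = 0.025) {
  if (inherits(series, "fret_series")) series <- list(series)
  if (length(series) == 0L) stop("no FRET series supplied", call. = FALSE)
  pooled <- unlist(lapply(series, function(s) {
    e <- s$E[s$valid]
    utils::head(e, frames_per_molecule)
  }))
  if (length(pooled) == 0L) stop("all frames invalid", call. = FALSE)
  edges <- seq(-0.05, 1.05, by = bin_width)
  h <- graphics::hist(clamp(pooled, -0.049, 1.049), breaks = edges,
                      plot = FALSE)
  out <- data.frame(bin_center = h$mids, density = h$density)
  attr(out, "bin_edges") <- edges
  attr(out, "n_molecules") <- length(series)
  attr(out, "frames_per_molecule") <- frames_per_molecule
  attr(out, "n_frames") <- length(pooled)
  class(out) <- c("fret_histogram", "data.frame")
  out
}

# density of a K-component Gaussian mixture with free areas
mixture_density <- function(x, a, mu, sd) {
  y <- 0
  for (k in seq_along(a)) y <- y + a[k] * stats::dnorm(x, mu[k], sd[k])
  y
}

#' Fit a multi-peak Gaussian decomposition to a FRET histogram
#'
#' Nonlinear least squares on the binned density (the histogram-fit
#' workflow, not per-frame maximum likelihood). The number of components
#' K and initial means come from the experiment preset, so the fit is
#' deterministic given the initialization. Optimization is bounded
#' L-BFGS-B on (area, mean, sd) per component; weights are the component
#' areas renormalized to sum to 1, and components are reported sorted by
#' mean so downstream bound-state assignment is stable.
#'
#' @param hist a `fret_histogram`.
#' @param K number of Gaussian components (>= 1).
#' @param init_means numeric vector of length K, initial component means.
#' @param init_sd initial component sd (recycled).
#' @param mean_window box constraint half-width on each component mean
#'   around its initial value (the peak positions are known from
#'   calibration histograms; the fit refines, it does not roam).
#' @param shared_sd constrain all components to one common width.
#'   Recommended when peaks overlap strongly (level separation
#'   comparable to the peak width), where per-component widths let the
#'   components trade population freely.
#' @return object of class `gaussian_mixture_fit`: list with `components`
#'   (data.frame mean, sd, weight, sorted by mean), `residual_sse`, `K`,
#'   `converged`.
#' @export
fit_gaussian_mixture <- function(hist, K, init_means, init_sd = 0.05,
                                 mean_window = 0.08, shared_sd = FALSE) {
  stopifnot(inherits(hist, "fret_histogram"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (length(init_means) != K) {
    stop("init_means must have length K", call. = FALSE)
  }
  x <- hist$bin_center; y <- hist$density
  if (3L * K >= sum(y > 0)) {
    stop("too few non-empty bins for ", K, " components", call. = FALSE)
  }
  init_sd <- rep_len(init_sd, K)
  # start areas: local mass near each init mean
  a0 <- vapply(init_means, function(m) {
    max(sum(y[abs(x - m) <= 0.1]) * (x[2] - x[1]), 0.05)
  }, numeric(1L))
  n_sd <- if (shared_sd) 1L else K
  par0 <- c(a0, init_means, init_sd[seq_len(n_sd)])
  lower <- c(rep(0, K), pmax(init_means - mean_window, -0.05),
             rep(0.008, n_sd))
  upper <- c(rep(5, K), pmin(init_means + mean_window, 1.05),
             rep(0.35, n_sd))
  obj <- function(p) {
    sds <- rep_len(p[2 * K + seq_len(n_sd)], K)
    sum((y - mixture_density(x, p[1:K], p[K + 1:K], sds))^2)
  }
  fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500L, factr = 1e7))
  a <- fit$par[1:K]; mu <- fit$par[K + 1:K]
  sd <- rep_len(fit$par[2 * K + seq_len(n_sd)], K)
  w <- if (sum(a) > 0) a / sum(a) else rep(1 / K, K)
  ord <- order(mu)
  comps <- data.frame(mean = clamp(mu[ord], 0, 1), sd = sd[ord],
                      weight = w[ord])
  structure(list(components = comps, residual_sse = fit$value, K = K,
                 converged = fit$convergence == 0L),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("<gaussian_mixture_fit> K =", x$K,
      if (!x$converged) "(NOT converged)", "\n")
  print(round(x$components, 4))
  cat("residual SSE:", signif(x$residual_sse, 4), "\n")
  invisible(x)
}

#' Bound-protein fraction from a mixture fit
#'
#' The bound fraction is the summed weight of the components assigned to
#' the bound state. Assignment is by proximity of the component mean to
#' the configured bound-state FRET level, never by "high FRET":
#' RPA-bound DNA sits *below* the free-DNA level. When the free-substrate
#' level is supplied, each component is assigned to whichever configured
#' level is nearer (required when bound and free levels are closer than
#' the assignment window, e.g. RPA on dT70: bound ~0.1 vs free ~0.2);
#' otherwise components within `tol` of `bound_e` count as bound.
#'
#' @param fit a `gaussian_mixture_fit`.
#' @param bound_e configured FRET level(s) of the bound state(s); or pass
#'   `bound_components` directly.
#' @param tol assignment window around `bound_e` (ignored when `free_e`
#'   is given).
#' @param free_e optional configured free-substrate FRET level(s) for
#'   nearest-level assignment.
#' @param bound_components optional integer indices (in mean-sorted
#'   order) of the components counted as bound, overriding proximity
#'   assignment.
#' @return fraction in `[0, 1]`.
#' @export
bound_fraction <- function(fit, bound_e = NULL, tol = 0.15,
                           free_e = NULL, bound_components = NULL) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (is.null(bound_components)) {
    if (is.null(bound_e)) stop("give bound_e or bound_components",
                               call. = FALSE)
    bound_components <- which(vapply(fit$components$mean, function(m) {
      d_bound <- min(abs(m - bound_e))
      if (!is.null(free_e)) d_bound < min(abs(m - free_e))
      else d_bound <= tol
    }, logical(1L)))
    # no component near the bound level: the bound population is gone
    if (length(bound_components) == 0L) return(0)
  }
  if (length(bound_components) == 0L) {
    stop("empty bound-component selection", call. = FALSE)
  }
  if (any(bound_components < 1L | bound_components > fit$K)) {
    stop("bound_components out of range", call. = FALSE)
  }
  clamp(sum(fit$components$weight[bound_components]), 0, 1)
}

#' Bound-fraction time series from snapshot ensembles
#'
#' Full population pipeline for one experimental condition: for every
#' snapshot, compute per-molecule FRET series, exclude donor-only
#' molecules (ALEX data), build the normalized histogram, decompose into
#' K Gaussians and extract the bound-component weight.
#'
#' @param snapshots list (per time point) of lists of `molecule_trace`,
#'   e.g. from [synthesize_snapshots()].
#' @param times snapshot times, s.
#' @param l leakage fraction used in [compute_fret()].
#' @param K,init_means mixture preset passed to [fit_gaussian_mixture()].
#' @param bound_e bound-state FRET level(s) for component assignment.
#' @param alex_exclude apply ALEX donor-only exclusion first.
#' @param shared_sd passed to [fit_gaussian_mixture()].
#' @param method `"gaussian"` (component weights; primary) or
#'   `"threshold"` (fraction of frames nearer to bound than free level;
#'   sensitivity alternative).
#' @param free_e free-substrate FRET level (needed for the threshold
#'   method).
#' @return object of class `bound_fraction_series`: data.frame `time`,
#'   `fraction`, `n_molecules`.
#' @export
bound_fraction_series <- function(snapshots, times, l, K, init_means,
                                  bound_e, alex_exclude = FALSE,
                                  method = c("gaussian", "threshold"),
                                  free_e = NULL, shared_sd = FALSE) {
  method <- match.arg(method)
  stopifnot(length(snapshots) == length(times))
  rows <- lapply(seq_along(times), function(j) {
    traces <- snapshots[[j]]
    if (alex_exclude) {
      traces <- exclude_donor_only(traces)$fret_active
    }
    series <- lapply(traces, compute_fret, l = l)
    frac <- if (method == "gaussian") {
      h <- build_histogram(series)
      fit <- fit_gaussian_mixture(h, K, init_means, shared_sd = shared_sd)
      bound_fraction(fit, bound_e = bound_e, free_e = free_e)
    } else {
      if (is.null(free_e)) stop("threshold method needs free_e",
                                call. = FALSE)
      e <- unlist(lapply(series, function(s) {
        utils::head(s$E[s$valid], 21L)
      }))
      mean(abs(e - bound_e[1L]) < abs(e - free_e))
    }
    data.frame(time = times[j], fraction = frac,
               n_molecules = length(traces))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bound_fraction_series", "data.frame")
  out
}
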