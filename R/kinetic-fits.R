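# Kinetic fitting layer: single-exponential decays, bimolecular (linear)
# fits of k_obs vs concentration, censoring-aware first-passage rate
# estimation and spot-count decays with exchange fractions.

#' Fit a single-exponential decay
#'
#' Model `f(t) = A * exp(-k t) + c`, with `c` fixed at 0 unless
#' `with_plateau` (incomplete exchange leaves a residual plateau).
#' Weighted nonlinear least squares via `nls` (port algorithm) with
#' log-linear initialization; parameter standard errors come from the fit
#' covariance.
#'
#' @param times,values decay curve samples.
#' @param with_plateau include the plateau term `c`.
#' @param weights optional fit weights (e.g. `1/sd^2`).
#' @param fraction_input logical; when TRUE values are validated to lie
#'   in `[0, 1.05]` (bound-fraction inputs).
#' @return object of class `decay_fit`: list with `k_obs`, `A`,
#'   `plateau`, `se` (named), `fitted`, `degenerate` (flag for amplitude
#'   indistinguishable from zero), `fit_window`.
#' @export
fit_exponential_decay <- function(times, values, with_plateau = FALSE,
                                  weights = NULL, fraction_input = FALSE) {
  if (length(times) < 5L) stop("need >= 5 points", call. = FALSE)
  if (length(times) != length(values)) stop("length mismatch", call. = FALSE)
  if (fraction_input && any(values < -1e-9 | values > 1.05)) {
    stop("fraction values outside [0, 1.05]", call. = FALSE)
  }
  weights <- weights %||% rep(1, length(times))
  c0 <- if (with_plateau) min(values) * 0.9 else 0
  A0 <- max(values) - c0
  pos <- values - c0 > max(A0 * 0.05, 1e-12) & times > min(times)
  k0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(values[pos] - c0) ~ times[pos]))[2L]
    max(-sl, 1e-6)
  } else 1 / max(diff(range(times)), 1e-9)
  df <- data.frame(t = times, y = values, w = weights)
  fit <- NULL
  if (with_plateau) {
    fit <- tryCatch(
      stats::nls(y ~ A * exp(-k * t) + c, data = df, weights = w,
                 start = list(A = A0, k = k0, c = max(c0, 0)),
                 lower = c(A = 0, k = 0, c = 0),
                 upper = c(A = Inf, k = Inf, c = Inf),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200L,
                                              warnOnly = TRUE)),
      error = function(e) NULL)
  } else {
    fit <- tryCatch(
      stats::nls(y ~ A * exp(-k * t), data = df, weights = w,
                 start = list(A = A0, k = k0),
                 lower = c(A = 0, k = 0), upper = c(A = Inf, k = Inf),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200L,
                                              warnOnly = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    # essentially constant input: no decay to fit; flag instead of error
    if (stats::sd(values) <= 0.02 * max(abs(mean(values)), 1e-12) ||
        diff(range(values)) < 1e-12) {
      return(structure(list(k_obs = 0, A = 0, plateau = mean(values),
                            se = c(A = NA_real_, k = NA_real_,
                                   c = NA_real_),
                            fitted = rep(mean(values), length(values)),
                            degenerate = TRUE,
                            fit_window = range(times)),
                       class = "decay_fit"))
    }
    stop("exponential fit failed to converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  A <- unname(cf["A"]); k <- unname(cf["k"])
  cc <- if (with_plateau) unname(cf["c"]) else 0
  degenerate <- is.na(se["A"]) || A < 2 * se["A"] || A < 1e-3 * max(values, 1e-12)
  structure(list(k_obs = k, A = A, plateau = cc,
                 se = c(A = unname(se["A"]), k = unname(se["k"]),
                        c = if (with_plateau) unname(se["c"]) else 0),
                 fitted = stats::fitted(fit),
                 degenerate = degenerate,
                 fit_window = range(times)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g s^-1 (se %.2g), A = %.3g, plateau = %.3g%s\n",
              x$k_obs, x$se["k"], x$A, x$plateau,
              if (x$degenerate) " [degenerate amplitude]" else ""))
  invisible(x)
}

#' Bimolecular rate constant from k_obs vs concentration
#'
#' Weighted linear regression of observed pseudo-first-order rates on
#' competitor (or protein) concentration. The slope is the bimolecular
#' constant; the intercept is left free (and a through-origin fit is also
#' reported for comparison).
#'
#' @param conc concentrations, M (>= 3 distinct values).
#' @param k_obs observed rates, s^-1.
#' @param sd optional per-point standard errors of `k_obs`.
#' @return object of class `bimolecular_fit`: list with `k_bi` (M^-1
#'   s^-1), `intercept`, `se` (slope, intercept), `r_squared`,
#'   `k_bi_origin` (through-origin slope), `points`.
#' @export
fit_bimolecular <- function(conc, k_obs, sd = NULL) {
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct concentrations", call. = FALSE)
  }
  if (length(conc) != length(k_obs)) stop("length mismatch", call. = FALSE)
  w <- if (!is.null(sd) && all(is.finite(sd)) && all(sd > 0)) 1 / sd^2
       else rep(1, length(conc))
  fit <- stats::lm(k_obs ~ conc, weights = w)
  cf <- summary(fit)$coefficients
  fit0 <- stats::lm(k_obs ~ conc + 0, weights = w)
  structure(list(k_bi = unname(stats::coef(fit)["conc"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 se = c(slope = cf["conc", "Std. Error"],
                        intercept = cf["(Intercept)", "Std. Error"]),
                 r_squared = summary(fit)$r.squared,
                 k_bi_origin = unname(stats::coef(fit0)["conc"]),
                 points = data.frame(conc = conc, k_obs = k_obs,
                                     sd = if (is.null(sd)) NA_real_ else sd)),
            class = "bimolecular_fit")
}

#' @export
print.bimolecular_fit <- function(x, ...) {
  cat(sprintf("<bimolecular_fit> k_bi = %.4g M^-1 s^-1 (se %.2g), intercept = %.3g s^-1, R^2 = %.4f\n",
              x$k_bi, x$se["slope"], x$intercept, x$r_squared))
  invisible(x)
}

#' Censoring-aware exponential rate from first-passage times
#'
#' Maximum-likelihood rate for exponentially distributed first-passage
#' times under right censoring at the observation horizon:
#' `k = n_events / sum(observation times)`, where censored molecules
#' contribute their full (censored) observation time. A naive fit that
#' averages only the observed events is biased high when the horizon is
#' comparable to `1/k`; this estimator is not.
#'
#' @param times observed times: event time if `censored` is FALSE,
#'   horizon otherwise.
#' @param censored logical vector.
#' @return list with `k` (s^-1), `se`, `n_events`, `n_censored`,
#'   `k_naive` (uncensored-mean estimator, for comparison).
#' @export
fit_exponential_mle <- function(times, censored = NULL) {
  censored <- censored %||% rep(FALSE, length(times))
  if (length(times) != length(censored)) stop("length mismatch",
                                              call. = FALSE)
  d <- sum(!censored)
  if (d == 0L) stop("no uncensored events", call. = FALSE)
  k <- d / sum(times)
  list(k = k, se = k / sqrt(d), n_events = d, n_censored = sum(censored),
       k_naive = 1 / mean(times[!censored]))
}

#' Fit a spot-count decay and extract the exchange fraction
#'
#' Model `N(t) = N_res + (N0 - N_res) exp(-k t)` with Poisson weighting
#' (`sd = sqrt(N)`). The exchange fraction is `(N0 - N_res) / N0`.
#'
#' @param series a `spot_count_series` (data.frame with `time`, `count`)
#'   or two vectors via `time =`/`count =`.
#' @param time,count alternative vector interface.
#' @return list with `fit` (a `decay_fit`), `exchange_fraction`, `N0`,
#'   `N_res`, and `increasing_flag` (counts rising beyond noise).
#' @export
fit_spot_decay <- function(series = NULL, time = NULL, count = NULL) {
  if (!is.null(series)) {
    time <- series$time; count <- series$count
  }
  if (length(time) < 5L) stop("need >= 5 time points", call. = FALSE)
  w <- 1 / pmax(count, 1)
  fit <- fit_exponential_decay(time, count, with_plateau = TRUE, weights = w)
  N0 <- fit$A + fit$plateau
  frac <- if (N0 > 0) fit$A / N0 else 0
  # flag a rising series: late mean above early mean by > 3 Poisson sd
  n <- length(count)
  early <- count[seq_len(ceiling(n / 3))]
  late <- count[seq.int(n - ceiling(n / 3) + 1L, n)]
  rising <- mean(late) - mean(early) >
    3 * sqrt(mean(late) / length(late) + mean(early) / length(early))
  list(fit = fit, exchange_fraction = frac, N0 = N0, N_res = fit$plateau,
       increasing_flag = rising)
}
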