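# Synthetic field-of-view image series for the spot-count exchange assay,
# and detection/counting of fluorescent spots.

#' Synthesize a field-of-view image series with exponentially vanishing spots
#'
#' Each initially labeled spot survives to time t with probability
#' `residual + (1 - residual) * exp(-k t)`: a `residual` fraction of
#' complexes never exchanges, the rest exchange at rate `k` (the labeled
#' protein departs and the spot disappears). Surviving spots are rendered
#' as 2-D Gaussian PSFs on a constant background with Poisson shot noise
#' and Gaussian read noise. Positions are uniform with a minimum
#' separation and a border margin.
#'
#' @param n_initial_spots spots at t = 0.
#' @param k exchange rate, s^-1.
#' @param residual fraction of spots that never exchange.
#' @param times image acquisition times, s.
#' @param image_shape c(rows, cols) in pixels.
#' @param psf_sigma PSF sd, pixels.
#' @param amplitude peak expected counts of one spot above background.
#' @param background expected background counts/pixel.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param min_separation minimum pairwise spot distance, pixels.
#' @param margin border margin, pixels.
#' @param seed integer seed.
#' @param departure_times optional vector of per-spot departure times
#'   (s; `Inf` for spots that never exchange), e.g. first-passage times
#'   sampled from an exchange scheme; overrides the internal
#'   exponential-survival sampling from `k` and `residual`.
#' @return object of class `fov_series`: list with `times`, `images`
#'   (list of matrices), `truth_positions` (list of data.frames x, y),
#'   `psf_sigma`, `params`.
#' @export
synthesize_fov_series <- function(n_initial_spots, k, residual = 0,
                                  times, image_shape = c(256L, 256L),
                                  psf_sigma = 1.3, amplitude = 800,
                                  background = 100, read_noise_sd = 5,
                                  min_separation = 6, margin = 8,
                                  seed = 1L, departure_times = NULL) {
  if (n_initial_spots < 0) stop("n_initial_spots must be >= 0",
                                call. = FALSE)
  set.seed(as.integer(seed))
  H <- image_shape[1L]; W <- image_shape[2L]
  # capacity check for rejection sampling at the minimum separation
  if (n_initial_spots * (min_separation^2) > 0.5 * (H - 2 * margin) *
      (W - 2 * margin)) {
    stop("image too small for requested spot count at min separation",
         call. = FALSE)
  }
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n_initial_spots) {
    x <- stats::runif(1L, margin, W - margin)
    y <- stats::runif(1L, margin, H - margin)
    if (length(xs) == 0L ||
        min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  # survival bookkeeping: residual spots never exchange
  if (!is.null(departure_times)) {
    if (length(departure_times) != n_initial_spots) {
      stop("departure_times must have one entry per spot", call. = FALSE)
    }
    t_exchange <- departure_times
  } else {
    is_residual <- stats::runif(n_initial_spots) < residual
    t_exchange <- ifelse(is_residual, Inf,
                         if (k > 0) stats::rexp(n_initial_spots, k) else Inf)
  }

  render <- function(alive_idx) {
    img <- matrix(background, H, W)
    win <- ceiling(4 * psf_sigma)
    for (i in alive_idx) {
      cx <- xs[i]; cy <- ys[i]
      c0 <- max(1L, floor(cx) - win); c1 <- min(W, ceiling(cx) + win)
      r0 <- max(1L, floor(cy) - win); r1 <- min(H, ceiling(cy) + win)
      cc <- c0:c1; rr <- r0:r1
      gx <- exp(-(cc - cx)^2 / (2 * psf_sigma^2))
      gy <- exp(-(rr - cy)^2 / (2 * psf_sigma^2))
      img[rr, cc] <- img[rr, cc] + amplitude * outer(gy, gx)
    }
    noisy <- matrix(stats::rpois(H * W, img), H, W)
    if (read_noise_sd > 0) {
      noisy <- noisy + matrix(stats::rnorm(H * W, 0, read_noise_sd), H, W)
    }
    pmax(noisy, 0)
  }
  images <- vector("list", length(times))
  truth <- vector("list", length(times))
  for (j in seq_along(times)) {
    alive <- which(t_exchange > times[j])
    images[[j]] <- render(alive)
    truth[[j]] <- data.frame(x = xs[alive], y = ys[alive])
  }
  structure(list(times = times, images = images, truth_positions = truth,
                 psf_sigma = psf_sigma,
                 params = list(n_initial_spots = n_initial_spots, k = k,
                               residual = residual, amplitude = amplitude,
                               background = background,
                               read_noise_sd = read_noise_sd)),
            class = "fov_series")
}

#' Spot-detection parameters
#'
#' @param background_radius radius (pixels) of the local-mean background
#'   estimate subtracted before detection (rolling-ball style); default
#'   5x the expected PSF sigma.
#' @param detection_threshold threshold in multiples of the robust sd of
#'   the background-subtracted image.
#' @param min_separation maxima closer than this (pixels) are merged to
#'   the brighter peak.
#' @param psf_sigma_expected expected PSF sd, pixels (sets the smoothing
#'   kernel).
#' @export
spot_detection_params <- function(background_radius = NULL,
                                  detection_threshold = 5,
                                  min_separation = 3,
                                  psf_sigma_expected = 1.3) {
  background_radius <- background_radius %||%
    ceiling(5 * psf_sigma_expected)
  for (nm in c("background_radius", "detection_threshold", "min_separation",
               "psf_sigma_expected")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  structure(list(background_radius = background_radius,
                 detection_threshold = detection_threshold,
                 min_separation = min_separation,
                 psf_sigma_expected = psf_sigma_expected),
            class = "spot_detection_params")
}

# separable box mean filter with replicated edges (fast via cumsum)
box_mean <- function(img, r) {
  smooth1 <- function(m, r) {
    n <- nrow(m)
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(n, r), , drop = FALSE])
    cs <- apply(padded, 2L, cumsum)
    (cs[(2L * r + 1L):(n + 2L * r), , drop = FALSE] -
       rbind(0, cs[seq_len(n - 1L) + 0L, , drop = FALSE])) / (2L * r + 1L)
  }
  t(smooth1(t(smooth1(img, r)), r))
}

#' Detect fluorescent spots in a single image
#'
#' Local-mean background subtraction, light smoothing at the expected PSF
#' scale, then 8-neighborhood local maxima above
#' `detection_threshold * robust sd`. Maxima closer than `min_separation`
#' are merged, keeping the brighter peak.
#'
#' @param image 2-D numeric matrix.
#' @param params a [spot_detection_params()].
#' @return data.frame with `x` (column), `y` (row), `intensity`
#'   (background-subtracted peak height) and attribute `saturated`
#'   (TRUE when >= 1% of pixels sit at the image maximum).
#' @export
detect_spots <- function(image, params = spot_detection_params()) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  saturated <- mean(image >= max(image)) > 0.01
  bg <- box_mean(image, as.integer(params$background_radius))
  corr <- image - bg
  sm <- box_mean(corr, max(1L, round(params$psf_sigma_expected)))
  thr <- params$detection_threshold * max(robust_sd(as.numeric(sm)), 1e-9)

  inner_r <- 2:(H - 1L); inner_c <- 2:(W - 1L)
  ctr <- sm[inner_r, inner_c]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (ctr >= sm[inner_r + dr, inner_c + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
    attr(out, "saturated") <- saturated
    return(out)
  }
  ys <- idx[, 1L] + 1L; xs <- idx[, 2L] + 1L
  ints <- corr[cbind(ys, xs)]
  # merge near-coincident maxima, brighter peak wins
  ord <- order(ints, decreasing = TRUE)
  keep <- logical(length(ord))
  kx <- numeric(0); ky <- numeric(0)
  for (i in ord) {
    if (length(kx) == 0L ||
        min((kx - xs[i])^2 + (ky - ys[i])^2) >= params$min_separation^2) {
      keep[i] <- TRUE
      kx <- c(kx, xs[i]); ky <- c(ky, ys[i])
    }
  }
  out <- data.frame(x = xs[keep], y = ys[keep], intensity = ints[keep])
  attr(out, "saturated") <- saturated
  out
}

#' Count spots across a field-of-view series
#'
#' @param fov a `fov_series`.
#' @param params a [spot_detection_params()].
#' @param bleach_control optional second `fov_series` recorded without
#'   exchange; when given, counts are ratio-corrected by the control's
#'   relative count decay (photobleaching correction; off by default).
#' @return object of class `spot_count_series`: data.frame `time`,
#'   `count` (plus `count_raw` when corrected).
#' @export
count_series <- function(fov, params = spot_detection_params(),
                         bleach_control = NULL) {
  stopifnot(inherits(fov, "fov_series"))
  counts <- vapply(fov$images, function(img) nrow(detect_spots(img, params)),
                   numeric(1L))
  out <- data.frame(time = fov$times, count = counts)
  if (!is.null(bleach_control)) {
    cc <- vapply(bleach_control$images,
                 function(img) nrow(detect_spots(img, params)), numeric(1L))
    ratio <- cc / max(cc[1L], 1)
    out$count_raw <- out$count
    out$count <- out$count / pmax(ratio, 1e-9)
  }
  class(out) <- c("spot_count_series", "data.frame")
  out
}
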