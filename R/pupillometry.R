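# Pupillometry: geometric circle fit to confident pupil-edge landmarks,
# linear interpolation across blinks, pupil-size (area) and ocular-movement
# (center-displacement) traces.

#' Fit a circle to confident pupil landmarks
#'
#' Minimizes sum_i (||p_i - c|| - r)^2 with a Nelder-Mead simplex search
#' initialized at the landmark centroid and the mean centroid distance. Only
#' landmarks with confidence above `conf_min` enter the fit; a frame needs
#' at least three such points to be valid (blinks fail this).
#'
#' @param points n x 2 matrix of (x, y) landmark coordinates
#' @param confidences per-landmark confidences in [0, 1]
#' @param conf_min inclusion threshold (default 0.8)
#' @return list with `center` (x, y), `radius`, `n_used`, `valid`,
#'   `objective` (residual sum of squares at the solution)
#' @export
fit_circle <- function(points, confidences, conf_min = 0.8) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) == length(confidences))
  use <- confidences > conf_min
  n_used <- sum(use)
  if (n_used < 3L) {
    return(list(center = c(NA_real_, NA_real_), radius = NA_real_,
                n_used = n_used, valid = FALSE, objective = NA_real_))
  }
  pt <- points[use, , drop = FALSE]
  ctr0 <- colMeans(pt)
  r0 <- mean(sqrt(rowSums(sweep(pt, 2, ctr0)^2)))
  obj <- function(par) {
    d <- sqrt((pt[, 1] - par[1])^2 + (pt[, 2] - par[2])^2)
    sum((d - par[3])^2)
  }
  fit <- stats::optim(c(ctr0, r0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  # simplex must not end worse than its initialization
  if (fit$value > obj(c(ctr0, r0))) {
    fit$par <- c(ctr0, r0)
    fit$value <- obj(c(ctr0, r0))
  }
  list(center = fit$par[1:2], radius = abs(fit$par[3]), n_used = n_used,
       valid = TRUE, objective = fit$value)
}

#' Fit circles to every frame of a pupil landmark set
#'
#' @param pupil list with n x k matrices `x`, `y`, `conf` (as produced by
#'   [generate_pupil_points()] or read from a pose-estimation table)
#' @param conf_min confidence threshold (default 0.8)
#' @return data.frame with `cx`, `cy`, `radius`, `n_used`, `valid`
#' @export
fit_pupil_frames <- function(pupil, conf_min = 0.8) {
  n <- nrow(pupil$x)
  out <- lapply(seq_len(n), function(i) {
    f <- fit_circle(cbind(pupil$x[i, ], pupil$y[i, ]), pupil$conf[i, ],
                    conf_min)
    data.frame(cx = f$center[1], cy = f$center[2], radius = f$radius,
               n_used = f$n_used, valid = f$valid)
  })
  do.call(rbind, out)
}

#' Pupil-size and ocular-movement traces from per-frame circle fits
#'
#' Invalid (blink) frames are linearly interpolated in radius/center space,
#' then pupil size is the fitted circle's area (pi r^2) and ocular movement
#' the per-step displacement of its center; both are z-scored to the whole
#' trace.
#'
#' @param fits data.frame from [fit_pupil_frames()]
#' @param fs sampling rate
#' @param interp_space `"radius"` (default; geometrically consistent) or
#'   `"area"` (interpolate the area directly)
#' @return object of class `pupil_traces`: list with `size` (z-scored
#'   area), `ocular` (z-scored displacement, first sample 0),
#'   `interpolated_mask`, `area`, `radius`, `fs`; z-score degeneracy is
#'   flagged via attributes on the respective vectors
#' @export
pupil_traces <- function(fits, fs, interp_space = c("radius", "area")) {
  interp_space <- match.arg(interp_space)
  n <- nrow(fits)
  ok <- fits$valid & is.finite(fits$radius)
  if (sum(ok) < 2L) stop("need at least 2 valid pupil frames")
  idx <- seq_len(n)
  interp <- function(v) stats::approx(idx[ok], v[ok], xout = idx, rule = 2)$y
  cx <- interp(fits$cx)
  cy <- interp(fits$cy)
  if (interp_space == "radius") {
    r <- interp(fits$radius)
    area <- pi * r^2
  } else {
    area <- interp(pi * fits$radius^2)
    r <- sqrt(area / pi)
  }
  ocular <- c(0, sqrt(diff(cx)^2 + diff(cy)^2))
  out <- list(size = zscore(area), ocular = zscore(ocular),
              interpolated_mask = !ok, area = area, radius = r,
              center = cbind(cx, cy), fs = fs)
  class(out) <- "pupil_traces"
  out
}
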