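#' Beam-spot shape model
#'
#' Second-degree polynomial model for the lateral Gaussian spreads
#' \eqn{\sigma_x(z)}, \eqn{\sigma_y(z)} (mm) of the beam spot as a function of
#' the distance z (cm) from the exit window.
#'
#' @param coeffs_x,coeffs_y numeric length-3 vectors `c(a0, a1, a2)` such
#'   that \eqn{\sigma(z) = a0 + a1 z + a2 z^2}.  Shorter vectors are padded
#'   with zeros.
#' @param z_domain numeric length-2 declared validity domain in cm.
#' @return An object of class `spot_shape`.
#' @export
spot_shape_model <- function(coeffs_x, coeffs_y, z_domain = c(0, 10)) {
  pad <- function(v) { v <- as.numeric(v); c(v, numeric(3L - length(v))) }
  if (length(coeffs_x) > 3L || length(coeffs_y) > 3L)
    stop("coefficients must have length <= 3 (second-degree polynomial)")
  structure(list(coeffs_x = pad(coeffs_x), coeffs_y = pad(coeffs_y),
                 z_domain = sort(as.numeric(z_domain))),
            class = "spot_shape")
}

#' @export
print.spot_shape <- function(x, ...) {
  cat("<spot_shape> sigma(z) = a0 + a1*z + a2*z^2  [mm; z in cm]\n")
  cat(sprintf("  x: (%.4g, %.4g, %.4g)   y: (%.4g, %.4g, %.4g)   z in [%g, %g]\n",
              x$coeffs_x[1], x$coeffs_x[2], x$coeffs_x[3],
              x$coeffs_y[1], x$coeffs_y[2], x$coeffs_y[3],
              x$z_domain[1], x$z_domain[2]))
  invisible(x)
}

#' Evaluate the spot spreads at a distance
#'
#' @param model a [spot_shape_model()].
#' @param z distance from the exit window in cm; must lie in the declared
#'   domain.
#' @return Named numeric `c(sigma_x =, sigma_y =)` in mm; an error is raised
#'   if either evaluated spread is non-positive.
#' @export
sigma_at <- function(model, z) {
  stopifnot(inherits(model, "spot_shape"), length(z) == 1L)
  if (z < model$z_domain[1] || z > model$z_domain[2])
    stop(sprintf("z = %g cm outside declared domain [%g, %g]",
                 z, model$z_domain[1], model$z_domain[2]))
  ev <- function(cf) cf[1] + cf[2] * z + cf[3] * z^2
  sx <- ev(model$coeffs_x); sy <- ev(model$coeffs_y)
  if (sx <= 0 || sy <= 0)
    stop(sprintf("non-positive spot spread at z = %g cm (sigma_x = %.3g, sigma_y = %.3g)",
                 z, sx, sy))
  c(sigma_x = sx, sigma_y = sy)
}

#' Fit the spot-spread polynomial from spread measurements
#'
#' Least-squares degree-2 polynomial fit of measured Gaussian spreads versus
#' distance, per axis.
#'
#' @param z distances from the exit window, cm (>= 3 distinct values).
#' @param sigma_x,sigma_y measured spreads in mm at each `z`.  `sigma_y` may
#'   be omitted to fit a single axis (then reused for both).
#' @param z_domain declared validity domain for the fitted model; defaults to
#'   the range of `z`.
#' @return A `spot_shape` with extra fields `fit_x`, `fit_y` (each a list
#'   with `residuals` and `se` of the coefficients).
#' @export
fit_sigma_polynomial <- function(z, sigma_x, sigma_y = sigma_x,
                                 z_domain = range(z)) {
  z <- as.numeric(z)
  if (length(unique(z)) < 3L)
    stop("need >= 3 distinct z values to fit a second-degree polynomial")
  fit1 <- function(s) {
    d <- data.frame(z = z, s = as.numeric(s))
    f <- lm(s ~ z + I(z^2), data = d)
    if (any(!is.finite(coef(f))))
      stop("degenerate design: polynomial coefficients not identifiable")
    # vcov emits a spurious warning on exact-interpolation data
    se <- suppressWarnings(unname(sqrt(diag(vcov(f)))))
    list(coef = unname(coef(f)), residuals = unname(residuals(f)), se = se)
  }
  fx <- fit1(sigma_x); fy <- fit1(sigma_y)
  m <- spot_shape_model(fx$coef, fy$coef, z_domain)
  m$fit_x <- fx[c("residuals", "se")]
  m$fit_y <- fy[c("residuals", "se")]
  m
}

#' Fit a single 2-D Gaussian to a beam-spot image
#'
#' Fits the model
#' \eqn{I(x,y) = A \exp(-(x-x_0)^2/2\sigma_x^2 - (y-y_0)^2/2\sigma_y^2) + b}
#' to a film-like intensity grid.  `method = "ls"` (default) is a
#' Levenberg-Marquardt least-squares fit initialised from image moments;
#' `method = "moments"` returns the background-subtracted moment estimates
#' directly.
#'
#' @param image numeric matrix of non-negative intensities with a single
#'   dominant peak; rows index x, columns index y.
#' @param pitch pixel pitch in mm.
#' @param method `"ls"` or `"moments"`.
#' @return An object of class `spot_fit`: list with `sigma_x`, `sigma_y`
#'   (mm), `centre` (mm, relative to the image origin at the first pixel
#'   centre), `amplitude`, `offset`, `method`.
#' @export
fit_gaussian_spot <- function(image, pitch, method = c("ls", "moments")) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) stop("'image' must be a numeric matrix")
  if (any(image < 0)) stop("'image' must be non-negative")
  if (max(image) <= min(image)) stop("flat or all-zero image: no peak to fit")
  nx <- nrow(image); ny <- ncol(image)
  x <- (seq_len(nx) - 1) * pitch
  y <- (seq_len(ny) - 1) * pitch
  # moment estimates on the background-subtracted image (background = border median)
  border <- c(image[1, ], image[nx, ], image[, 1], image[, ny])
  b0 <- median(border)
  w <- pmax(image - b0, 0)
  tot <- sum(w)
  if (tot <= 0) stop("image has no signal above the border background")
  mx <- sum(outer(x, rep(1, ny)) * w) / tot
  my <- sum(outer(rep(1, nx), y) * w) / tot
  vx <- sum(outer(x - mx, rep(1, ny))^2 * w) / tot
  vy <- sum(outer(rep(1, nx), y - my)^2 * w) / tot
  mom <- list(sigma_x = sqrt(vx), sigma_y = sqrt(vy),
              centre = c(x = mx, y = my),
              amplitude = max(w), offset = b0)
  if (method == "moments")
    return(structure(c(mom, list(method = "moments")), class = "spot_fit"))
  dat <- data.frame(gx = rep(x, times = ny), gy = rep(y, each = nx),
                    I = as.vector(image))
  start <- list(A = mom$amplitude, x0 = mx, y0 = my,
                sx = max(mom$sigma_x, pitch / 2),
                sy = max(mom$sigma_y, pitch / 2), b = b0)
  fit <- minpack.lm::nlsLM(
    I ~ A * exp(-(gx - x0)^2 / (2 * sx^2) - (gy - y0)^2 / (2 * sy^2)) + b,
    data = dat, start = start,
    lower = c(A = 0, x0 = min(x), y0 = min(y), sx = pitch / 10,
              sy = pitch / 10, b = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(sigma_x = unname(abs(cf["sx"])),
                 sigma_y = unname(abs(cf["sy"])),
                 centre = c(x = unname(cf["x0"]), y = unname(cf["y0"])),
                 amplitude = unname(cf["A"]), offset = unname(cf["b"]),
                 method = "ls", fit = fit),
            class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf("<spot_fit> sigma_x = %.4g mm, sigma_y = %.4g mm (method: %s)\n",
              x$sigma_x, x$sigma_y, x$method))
  cat(sprintf("  centre (%.4g, %.4g) mm, amplitude %.4g, offset %.4g\n",
              x$centre[1], x$centre[2], x$amplitude, x$offset))
  invisible(x)
}

#' @export
coef.spot_fit <- function(object, ...) {
  c(sigma_x = object$sigma_x, sigma_y = object$sigma_y,
    x0 = unname(object$centre[1]), y0 = unname(object$centre[2]),
    amplitude = object$amplitude, offset = object$offset)
}
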