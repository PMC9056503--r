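#' Constrained triple-exponential decay decomposition
#'
#' Decomposes a background-corrected 511-keV count time series into the
#' contributions of \eqn{^{18}}F, \eqn{^{11}}C and \eqn{^{13}}N,
#' \deqn{A_{meas}(t) = A_{18F} e^{-\lambda_{18F} t} + A_{11C} e^{-\lambda_{11C} t}
#'       + A_{13N} e^{-\lambda_{13N} t},}
#' with the decay constants fixed at their physical values, by weighted least
#' squares on the bin-integrated model (expected counts per bin rather than
#' the midpoint rate).  Because the decay constants are fixed the problem is
#' linear in the amplitudes; the exact non-negativity-constrained weighted
#' least-squares minimiser is found by active-set enumeration, and amplitudes
#' pinned at the zero bound are flagged.  Weights are the reciprocal stored
#' per-bin variances (`max(raw, 1) + background variance`, Neyman weighting).
#'
#' Under the ratio constraint the \eqn{^{13}}N amplitude is tied to
#' \eqn{A_{13N} = A_{11C}\,(1-f_{18O})\cdot 0.394} (see
#' [expected_ratio_13N_11C()]) and only two amplitudes are free.
#'
#' @param series a [count_series()] (times in s since end of irradiation).
#' @param isotopes isotope table from [isotopes()].
#' @param constraint `"none"` or `"ratio"`.
#' @param f18O the enrichment fraction used by the ratio constraint.
#' @param ratio_constant calibrated constant of the ratio constraint.
#' @return An object of class `decay_fit` with amplitudes (counts/s at the
#'   end of irradiation), covariance, chi-square and dof.
#' @export
fit_decay_triple <- function(series, isotopes = petrv::isotopes(),
                             constraint = c("none", "ratio"), f18O = NULL,
                             ratio_constant = 0.394) {
  constraint <- match.arg(constraint)
  stopifnot(inherits(series, "count_series"))
  ok <- !series$masked
  if (sum(ok) < 3L) stop("need at least 3 unmasked bins")
  if (all(series$raw[ok] == 0)) stop("all-zero series: nothing to fit")
  t1 <- series$t_start_s[ok]; t2 <- series$t_end_s[ok]
  span_min <- (max(t2) - min(t1)) / 60
  if (span_min <= isotopes["N13", "half_life_min"])
    warning(sprintf("series spans only %.1f min (< one 13N half-life); amplitudes may be poorly separated",
                    span_min))
  lam_s <- setNames(isotopes$lambda_per_min / 60, isotopes$name)
  gcol <- function(iso) (exp(-lam_s[iso] * t1) - exp(-lam_s[iso] * t2)) / lam_s[iso]
  G <- cbind(F18 = gcol("F18"), C11 = gcol("C11"), N13 = gcol("N13"))
  if (constraint == "ratio") {
    if (is.null(f18O)) stop("the ratio constraint requires 'f18O'")
    r <- expected_ratio_13N_11C(f18O, "mc_constant", constant = ratio_constant)
    X <- cbind(F18 = G[, "F18"], C11 = G[, "C11"] + r * G[, "N13"])
  } else {
    X <- G
  }
  y <- series$net[ok]
  w <- 1 / series$var[ok]
  sol <- .wnnls(X, y, w)
  beta <- sol$beta
  fitted_free <- as.vector(X %*% beta)
  chi2 <- sum(w * (y - fitted_free)^2)
  dof <- length(y) - sum(!sol$at_bound)
  # expand to the three isotopes
  if (constraint == "ratio") {
    J <- rbind(F18 = c(1, 0), C11 = c(0, 1), N13 = c(0, r))
    A <- as.vector(J %*% beta)
    V <- J %*% sol$cov %*% t(J)
    at_bound <- c(sol$at_bound[1], sol$at_bound[2], sol$at_bound[2])
  } else {
    A <- beta
    V <- sol$cov
    at_bound <- sol$at_bound
  }
  names(A) <- c("F18", "C11", "N13")
  dimnames(V) <- list(names(A), names(A))
  names(at_bound) <- names(A)
  structure(list(amplitudes = A, vcov = V, at_bound = at_bound,
                 chisq = chi2, dof = dof,
                 constraint = constraint, f18O = f18O,
                 ratio_constant = if (constraint == "ratio") ratio_constant else NA_real_,
                 isotopes = isotopes, reference_time_min = 0,
                 series = series),
            class = "decay_fit")
}

# exact non-negative weighted least squares by active-set enumeration
# (p <= 3 free parameters). Covariance of the free (non-bound) parameters is
# (X'WX)^-1 with the known weights; bound parameters get zero rows/cols.
.wnnls <- function(X, y, w) {
  p <- ncol(X)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    free <- bitwAnd(mask, 2^(seq_len(p) - 1)) == 0
    if (!any(free)) {
      rss <- sum(w * y^2)
      cand <- list(beta = numeric(p), rss = rss, free = free)
    } else {
      Xf <- X[, free, drop = FALSE]
      XtW <- t(Xf * w)
      M <- XtW %*% Xf
      bf <- tryCatch(solve(M, XtW %*% y), error = function(e) NULL)
      if (is.null(bf) || any(bf < 0)) next
      beta <- numeric(p); beta[free] <- bf
      rss <- sum(w * (y - as.vector(Xf %*% bf))^2)
      cand <- list(beta = beta, rss = rss, free = free, M = M)
    }
    # KKT: gradient wrt bound-at-zero parameters must be non-positive
    resid <- y - as.vector(X %*% cand$beta)
    grad <- as.vector(t(X * w) %*% resid)  # dRSS/dbeta = -2*grad
    if (any(!cand$free & grad > 1e-8 * max(1, sum(w * y^2)))) next
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best)) stop("non-negative least squares failed: singular design")
  V <- matrix(0, p, p)
  if (any(best$free)) {
    Xf <- X[, best$free, drop = FALSE]
    V[best$free, best$free] <- solve(t(Xf * w) %*% Xf)
  }
  list(beta = best$beta, cov = V, at_bound = !best$free, rss = best$rss)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> amplitudes at end of irradiation [counts/s]:\n")
  se <- sqrt(diag(x$vcov))
  for (nm in names(x$amplitudes))
    cat(sprintf("  %s: %9.3f +- %.3f%s\n", nm, x$amplitudes[nm], se[nm],
                if (x$at_bound[nm]) "  (at zero bound)" else ""))
  cat(sprintf("  constraint: %s%s;  chi-square %.1f on %d dof\n",
              x$constraint,
              if (x$constraint == "ratio")
                sprintf(" (f18O = %.4g, constant %.3g)", x$f18O, x$ratio_constant)
              else "",
              x$chisq, x$dof))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$amplitudes

#' @export
vcov.decay_fit <- function(object, ...) object$vcov

#' @export
summary.decay_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- list(table = data.frame(amplitude = object$amplitudes, se = se,
                                 at_bound = object$at_bound,
                                 row.names = names(object$amplitudes)),
              chisq = object$chisq, dof = object$dof,
              p_value = pchisq(object$chisq, object$dof, lower.tail = FALSE),
              constraint = object$constraint, f18O = object$f18O)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("Triple-exponential decay fit (amplitudes at end of irradiation, counts/s)\n")
  print(x$table)
  cat(sprintf("chi-square %.1f on %d dof (p = %.3g); constraint: %s\n",
              x$chisq, x$dof, x$p_value, x$constraint))
  invisible(x)
}

#' Model predictions from a decay fit
#'
#' @param object a `decay_fit`.
#' @param t_s times (s since end of irradiation) at which to evaluate the
#'   total count rate; defaults to the fitted bin midpoints.
#' @param by_isotope return per-isotope rates instead of the total.
#' @param ... unused.
#' @return Count rate(s) in counts/s.
#' @export
predict.decay_fit <- function(object, t_s = NULL,
                              by_isotope = FALSE, ...) {
  if (is.null(t_s))
    t_s <- (object$series$t_start_s + object$series$t_end_s) / 2
  lam_s <- setNames(object$isotopes$lambda_per_min / 60, object$isotopes$name)
  comp <- sapply(names(object$amplitudes), function(nm)
    object$amplitudes[nm] * exp(-lam_s[nm] * t_s))
  comp <- matrix(comp, nrow = length(t_s),
                 dimnames = list(NULL, names(object$amplitudes)))
  if (by_isotope) comp else rowSums(comp)
}

#' @export
residuals.decay_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  s <- object$series
  ok <- !s$masked
  lam_s <- setNames(object$isotopes$lambda_per_min / 60, object$isotopes$name)
  mu <- numeric(sum(ok))
  for (nm in names(object$amplitudes))
    mu <- mu + object$amplitudes[nm] / lam_s[nm] *
      (exp(-lam_s[nm] * s$t_start_s[ok]) - exp(-lam_s[nm] * s$t_end_s[ok]))
  r <- s$net[ok] - mu
  if (type == "pearson") r / sqrt(s$var[ok]) else r
}

#' @export
plot.decay_fit <- function(x, ...) {
  s <- x$series
  ok <- !s$masked
  tm <- (s$t_start_s + s$t_end_s) / 2 / 60
  width <- s$t_end_s - s$t_start_s
  rate <- s$net / width
  plot(tm[ok], rate[ok], pch = 16, cex = 0.5,
       xlab = "time since end of irradiation [min]",
       ylab = "net count rate [counts/s]", ...)
  tt <- seq(min(s$t_start_s), max(s$t_end_s), length.out = 200)
  comp <- predict(x, tt, by_isotope = TRUE)
  matlines(tt / 60, comp, lty = 2, col = c("blue", "red", "darkgreen"))
  lines(tt / 60, rowSums(comp), col = "purple")
  legend("topright", bty = "n", lty = c(2, 2, 2, 1),
         col = c("blue", "red", "darkgreen", "purple"),
         legend = c("18F", "11C", "13N", "total"))
  invisible(x)
}
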