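#' Decay-correct an activity to a reference time
#'
#' Rescales an activity measured at `t_meas` to the reference time `t_ref`
#' using the isotope's physical decay constant:
#' \eqn{A(t_{ref}) = A(t_{meas}) e^{\lambda (t_{meas} - t_{ref})}}.  The
#' correction is an exact group action: correcting
#' \eqn{t_1 \to t_2 \to t_3} equals \eqn{t_1 \to t_3}.
#'
#' @param A measured activity (any unit, vectorised).
#' @param t_meas,t_ref measurement and reference times, minutes (any common
#'   origin).
#' @param isotope isotope name (`"F18"`, `"C11"`, `"N13"`).
#' @return Activity referred to `t_ref`, same units as `A`.
#' @export
decay_correct <- function(A, t_meas, t_ref = 0, isotope = "F18") {
  A * exp(decay_constant(isotope) * (t_meas - t_ref))
}

#' Retention fractions from pre- and post-wash decay fits
#'
#' Ratio of decay-corrected amplitudes after versus before washing, per
#' isotope.  Both [fit_decay_triple()] results carry amplitudes at the end of
#' irradiation, so the ratio is formed directly at that common reference
#' time (a different `t_ref` leaves the ratio unchanged because the physical
#' decay factor cancels).  \eqn{^{11}}C and \eqn{^{13}}N are additionally
#' pooled under the assumption that their activity ratio is maintained
#' through washing (their amplitudes are summed before forming the ratio,
#' with covariance-propagated uncertainty).
#'
#' @param pre,post `decay_fit` objects for the pre- and post-wash
#'   measurements.
#' @param t_ref reference time in minutes after end of irradiation (kept for
#'   the report; the ratio itself is time-invariant).
#' @return An object of class `retention_result`: data.frame with rows
#'   `F18`, `C11`, `N13`, `C11_N13_pooled` and columns `retention`, `se`,
#'   `defined`.
#' @export
retention_fractions <- function(pre, post, t_ref = 0) {
  stopifnot(inherits(pre, "decay_fit"), inherits(post, "decay_fit"))
  ratio1 <- function(a_pre, a_post, v_pre, v_post) {
    if (a_pre <= 0) return(c(NA_real_, NA_real_, FALSE))
    r <- a_post / a_pre
    se <- r * sqrt(v_post / max(a_post, .Machine$double.eps)^2 +
                     v_pre / a_pre^2)
    c(r, se, TRUE)
  }
  rows <- lapply(c("F18", "C11", "N13"), function(nm)
    ratio1(pre$amplitudes[nm], post$amplitudes[nm],
           pre$vcov[nm, nm], post$vcov[nm, nm]))
  # pooled 11C + 13N (sum amplitudes, full covariance)
  gsum <- function(fit) {
    J <- c(0, 1, 1)
    list(a = sum(fit$amplitudes[c("C11", "N13")]),
         v = as.numeric(t(J) %*% fit$vcov %*% J))
  }
  sp <- gsum(pre); so <- gsum(post)
  rows <- c(rows, list(ratio1(sp$a, so$a, sp$v, so$v)))
  m <- do.call(rbind, rows)
  out <- data.frame(retention = m[, 1], se = m[, 2],
                    defined = as.logical(m[, 3]),
                    row.names = c("F18", "C11", "N13", "C11_N13_pooled"))
  structure(out, t_ref_min = t_ref,
            class = c("retention_result", "data.frame"))
}

#' @export
print.retention_result <- function(x, ...) {
  cat("Retention fractions (post-wash / pre-wash, decay-corrected):\n")
  for (nm in rownames(x)) {
    if (!x[nm, "defined"])
      cat(sprintf("  %-15s undefined (pre-wash amplitude at zero)\n", nm))
    else
      cat(sprintf("  %-15s %5.1f%% +- %.1f%%\n", nm,
                  100 * x[nm, "retention"], 100 * x[nm, "se"]))
  }
  invisible(x)
}

#' Combined and biological washout half-lives
#'
#' For an activity decaying as the product of physical decay and a
#' biological washout exponential, the reciprocal half-lives add:
#' \eqn{1/T_{comb} = 1/T_{phys} + 1/T_{bio}}.  The two functions are mutual
#' inverses on their domain.
#'
#' @param T_phys physical half-life, minutes (default \eqn{^{18}}F).
#' @param T_bio biological washout half-life, minutes (`Inf` for no
#'   washout).
#' @return Half-life in minutes.
#' @export
combined_half_life <- function(T_phys = 109.77, T_bio = Inf) {
  stopifnot(T_phys > 0, T_bio > 0)
  1 / (1 / T_phys + 1 / T_bio)
}

#' @rdname combined_half_life
#' @param T_comb combined (observed) half-life, minutes; must be smaller
#'   than `T_phys`.
#' @export
washout_half_life <- function(T_comb, T_phys = 109.77) {
  stopifnot(T_comb > 0, T_phys > 0)
  if (T_comb >= T_phys)
    stop("no positive washout: combined half-life is not below the physical half-life")
  1 / (1 / T_comb - 1 / T_phys)
}

#' Biological retention factor at a time after irradiation
#'
#' Fraction of the initial activity still present once physical decay is
#' divided out: \eqn{2^{-t/T_{bio}}}.
#'
#' @param t_h time after irradiation, hours.
#' @param T_bio_h biological washout half-life, hours (> 0).
#' @return Retention fraction in `(0, 1]`.
#' @export
biological_retention <- function(t_h, T_bio_h) {
  stopifnot(T_bio_h > 0)
  2^(-t_h / T_bio_h)
}
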