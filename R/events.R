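#' List-mode gamma event record
#'
#' Event-by-event detector record: time since acquisition start (s) and
#' energy (keV), plus the acquisition start time relative to the end of
#' irradiation and any live-time gaps.
#'
#' @param t_s event timestamps in s since acquisition start, non-decreasing.
#' @param E_keV event energies in keV, > 0.
#' @param start_min acquisition start, minutes after the end of irradiation.
#' @param gaps list of `c(start, end)` pairs in s (acquisition clock) during
#'   which the detector was not live; must be non-overlapping and within the
#'   acquisition.
#' @param duration_s total acquisition duration in s; defaults to the last
#'   event time (or 0 for an empty list).
#' @return An object of class `gamma_events`.
#' @export
gamma_events <- function(t_s, E_keV, start_min = 0, gaps = list(),
                         duration_s = NULL) {
  t_s <- as.numeric(t_s); E_keV <- as.numeric(E_keV)
  if (length(t_s) != length(E_keV)) stop("t_s and E_keV must have equal length")
  if (length(t_s) && any(diff(t_s) < 0)) stop("timestamps must be non-decreasing")
  if (any(E_keV <= 0)) stop("energies must be > 0")
  if (is.null(duration_s)) duration_s <- if (length(t_s)) max(t_s) else 0
  if (length(gaps)) {
    g <- do.call(rbind, lapply(gaps, as.numeric))
    if (any(g[, 2] <= g[, 1])) stop("gaps must have end > start")
    g <- g[order(g[, 1]), , drop = FALSE]
    if (nrow(g) > 1 && any(g[-1, 1] < g[-nrow(g), 2]))
      stop("gaps must be non-overlapping")
    if (any(g[, 1] < 0) || any(g[, 2] > duration_s))
      stop("gaps must lie within the acquisition")
    gaps <- lapply(seq_len(nrow(g)), function(i) g[i, ])
  }
  structure(list(t_s = t_s, E_keV = E_keV, start_min = start_min,
                 gaps = gaps, duration_s = duration_s),
            class = "gamma_events")
}

#' @export
print.gamma_events <- function(x, ...) {
  cat(sprintf("<gamma_events> %d events over %.4g s, start %.4g min post-irradiation, %d gap(s)\n",
              length(x$t_s), x$duration_s, x$start_min, length(x$gaps)))
  invisible(x)
}

#' 511-keV energy window
#'
#' Acceptance window around the annihilation photopeak.  The default is a
#' fractional half-width of 10% of 511 keV, i.e. `[459.9, 562.1]` keV.  The
#' alternative reading (total width 10%) is selected with
#' `convention = "total_width"`.
#'
#' @param centre_keV window centre in keV.
#' @param half_width fractional half-width in `(0, 1)`.
#' @param convention `"half_width"` (default) or `"total_width"`.
#' @return An object of class `energy_window` with `lo` and `hi` in keV.
#' @export
energy_window <- function(centre_keV = 511, half_width = 0.10,
                          convention = c("half_width", "total_width")) {
  convention <- match.arg(convention)
  if (half_width <= 0 || half_width >= 1)
    stop("half_width must lie in (0, 1)")
  hw <- if (convention == "half_width") half_width else half_width / 2
  structure(list(centre = centre_keV, half_width = hw,
                 lo = centre_keV * (1 - hw), hi = centre_keV * (1 + hw),
                 convention = convention),
            class = "energy_window")
}

#' Filter events to an energy window
#'
#' Keeps events with energy in `[lo, hi]`; order-preserving and idempotent.
#'
#' @param events a [gamma_events()].
#' @param window an [energy_window()].
#' @return A `gamma_events` containing only the in-window events.
#' @export
window_counts <- function(events, window = energy_window()) {
  stopifnot(inherits(events, "gamma_events"), inherits(window, "energy_window"))
  keep <- events$E_keV >= window$lo & events$E_keV <= window$hi
  gamma_events(events$t_s[keep], events$E_keV[keep],
               start_min = events$start_min, gaps = events$gaps,
               duration_s = events$duration_s)
}

#' Background-corrected count time series
#'
#' Low-level constructor; most users build one with [bin_and_subtract()].
#' Bin edges are stored in seconds since the end of irradiation (the
#' package-wide time origin), so fitted amplitudes refer to the end of
#' irradiation.
#'
#' @param t_start_s,t_end_s bin edges, s since end of irradiation, strictly
#'   increasing.
#' @param raw raw integer counts per bin (>= 0).
#' @param background_rate,background_unc in-window background in counts/s
#'   and its 1-sigma uncertainty.
#' @param masked logical mask of bins excluded from fits (live-time gaps).
#' @param check_integer enforce integer raw counts (the invariant for real
#'   data); generators of exact expected-value series disable this.
#' @return An object of class `count_series`: data.frame with columns
#'   `t_start_s`, `t_end_s`, `raw`, `net`, `var`, `masked`.
#' @export
count_series <- function(t_start_s, t_end_s, raw, background_rate = 0,
                         background_unc = 0, masked = FALSE,
                         check_integer = TRUE) {
  if (any(t_end_s <= t_start_s)) stop("bin edges must be strictly increasing")
  if (any(raw < 0) || (check_integer && any(raw != round(raw))))
    stop("raw counts must be non-negative integers")
  width <- t_end_s - t_start_s
  d <- data.frame(t_start_s = t_start_s, t_end_s = t_end_s, raw = raw,
                  net = raw - background_rate * width,
                  var = pmax(raw, 1) + (background_unc * width)^2,
                  masked = rep_len(masked, length(raw)))
  structure(d, background_rate = background_rate,
            background_unc = background_unc,
            class = c("count_series", "data.frame"))
}

#' Bin events and subtract a background rate
#'
#' Histograms the (already energy-windowed) events into fixed-width bins on
#' the package time origin (seconds since end of irradiation), subtracts
#' `background_rate * bin_width` per bin and masks any bin overlapping a
#' live-time gap.  Per-bin variance is stored as
#' `max(raw, 1) + (background_unc * bin_width)^2` (Neyman weights for the
#' later fit).
#'
#' @param events a [gamma_events()].
#' @param bin_width_s bin width in s, > 0.
#' @param background_rate in-window background rate, counts/s (>= 0).
#' @param background_unc 1-sigma uncertainty of the background rate,
#'   counts/s.
#' @return A [count_series()].
#' @export
bin_and_subtract <- function(events, bin_width_s = 10, background_rate = 0,
                             background_unc = 0) {
  stopifnot(inherits(events, "gamma_events"))
  if (bin_width_s <= 0) stop("bin width must be > 0")
  if (background_rate < 0) stop("background rate must be >= 0")
  n_bins <- max(1L, ceiling(events$duration_s / bin_width_s))
  edges <- seq(0, n_bins * bin_width_s, by = bin_width_s)
  raw <- if (length(events$t_s))
    tabulate(pmin(floor(events$t_s / bin_width_s) + 1L, n_bins), nbins = n_bins)
  else integer(n_bins)
  masked <- rep(FALSE, n_bins)
  for (g in events$gaps) {
    masked <- masked | (edges[-length(edges)] < g[2] & edges[-1] > g[1])
  }
  off <- events$start_min * 60
  count_series(off + edges[-length(edges)], off + edges[-1], raw,
               background_rate = background_rate,
               background_unc = background_unc, masked = masked)
}

#' Read / write the event CSV dialect
#'
#' Columns `t_s,E_keV`; `#`-prefixed header lines carry `start_min:` (the
#' acquisition start relative to the end of irradiation), optional
#' `duration_s:` and `gap:` lines (`gap: start,end` in s).
#'
#' @param path file path.
#' @return [read_events()] returns a `gamma_events`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get1 <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_real_)
    as.numeric(trimws(sub(paste0("^#\\s*", key, ":"), "", m[1L])))
  }
  gaps <- lapply(grep("^#\\s*gap:", hdr, value = TRUE), function(m)
    as.numeric(strsplit(trimws(sub("^#\\s*gap:", "", m)), ",")[[1]]))
  dat <- read.csv(text = lines[!grepl("^#", lines)])
  sm <- get1("start_min"); du <- get1("duration_s")
  gamma_events(dat$t_s, dat$E_keV,
               start_min = if (is.na(sm)) 0 else sm,
               gaps = gaps,
               duration_s = if (is.na(du)) NULL else du)
}

#' @rdname read_events
#' @param events a `gamma_events` to write.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# start_min: %.10g", events$start_min),
               sprintf("# duration_s: %.10g", events$duration_s),
               vapply(events$gaps, function(g)
                 sprintf("# gap: %.10g,%.10g", g[1], g[2]), character(1))),
             con)
  write.csv(data.frame(t_s = events$t_s, E_keV = events$E_keV), con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the binned-counts CSV dialect
#'
#' Columns `t_start_s,t_end_s,counts,masked`; `#` header lines carry
#' `background_rate:` and `background_unc:` (counts/s).
#'
#' @param path file path.
#' @return [read_count_series()] returns a [count_series()].
#' @export
read_count_series <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get1 <- function(key, default = 0) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(trimws(sub(paste0("^#\\s*", key, ":"), "", m[1L])))
  }
  dat <- read.csv(text = lines[!grepl("^#", lines)])
  count_series(dat$t_start_s, dat$t_end_s, dat$counts,
               background_rate = get1("background_rate"),
               background_unc = get1("background_unc"),
               masked = as.logical(dat$masked))
}

#' @rdname read_count_series
#' @param series a `count_series` to write.
#' @export
write_count_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# background_rate: %.10g", attr(series, "background_rate")),
               sprintf("# background_unc: %.10g", attr(series, "background_unc"))),
             con)
  write.csv(data.frame(t_start_s = series$t_start_s, t_end_s = series$t_end_s,
                       counts = series$raw, masked = series$masked),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
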