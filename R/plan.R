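#' Irradiation spot plan
#'
#' A list of pencil-beam spots in beam's-eye-view coordinates.  The number of
#' protons per spot is derived from the beam current and dwell time as
#' \eqn{N = I t / e} with \eqn{e = 1.602176634\times 10^{-19}} C.
#'
#' @param x,y spot positions in mm.
#' @param dwell_time_s dwell time per spot in s (> 0), recycled.
#' @param current_nA beam current per spot in nA (> 0), recycled.
#' @param entry_energy proton energy at the target surface, MeV.
#' @return An object of class `spot_plan` (data.frame of spots with a
#'   `protons` column, plus attributes).
#' @export
spot_plan <- function(x, y, dwell_time_s, current_nA, entry_energy = 7.5) {
  n <- max(length(x), length(y))
  d <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  dwell_time_s = rep_len(as.numeric(dwell_time_s), n),
                  current_nA = rep_len(as.numeric(current_nA), n))
  if (any(d$dwell_time_s <= 0)) stop("dwell times must be > 0")
  if (any(d$current_nA <= 0)) stop("beam currents must be > 0")
  d$protons <- d$current_nA * 1e-9 * d$dwell_time_s / .const$e_charge
  structure(d, entry_energy = entry_energy, class = c("spot_plan", "data.frame"))
}

#' The nine-spot grid plan used throughout the package examples
#'
#' 3 x 3 grid with 1.2-mm spot separation, 10-s dwell time per spot and
#' 6.0 nA beam current, 7.5 MeV at the target surface (the delivery
#' conditions of the irradiations the analysis chain models).
#'
#' @param pitch_mm grid pitch in mm.
#' @param dwell_time_s,current_nA,entry_energy see [spot_plan()].
#' @return A `spot_plan` centred on the origin.
#' @export
grid_plan_3x3 <- function(pitch_mm = 1.2, dwell_time_s = 10,
                          current_nA = 6.0, entry_energy = 7.5) {
  g <- expand.grid(x = pitch_mm * (-1:1), y = pitch_mm * (-1:1))
  spot_plan(g$x, g$y, dwell_time_s, current_nA, entry_energy)
}

#' Point evaluation of the planned fluence
#'
#' Sum over spots of the normalised 2-D Gaussian
#' \eqn{N/(2\pi\sigma_x\sigma_y)\exp(-\Delta x^2/2\sigma_x^2 -
#' \Delta y^2/2\sigma_y^2)}, converted to protons/cm^2.
#'
#' @param plan a [spot_plan()].
#' @param x,y evaluation points in mm (vectorised, recycled).
#' @param sigma_x,sigma_y Gaussian spot spreads in mm.
#' @return Fluence in protons/cm^2.
#' @export
fluence_at <- function(plan, x, y, sigma_x, sigma_y) {
  stopifnot(inherits(plan, "spot_plan"), sigma_x > 0, sigma_y > 0)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  out <- numeric(n)
  norm <- 1 / (2 * pi * sigma_x * sigma_y)  # per mm^2
  for (i in seq_len(nrow(plan))) {
    out <- out + plan$protons[i] * norm *
      exp(-(x - plan$x[i])^2 / (2 * sigma_x^2) -
           (y - plan$y[i])^2 / (2 * sigma_y^2))
  }
  out * 100  # 1/mm^2 -> 1/cm^2
}

#' Planned fluence map on a regular grid
#'
#' Evaluates [fluence_at()] on a regular grid of cell centres.  The grid must
#' cover at least 4 sigma beyond the outermost spot; maps whose edge fluence
#' exceeds `1e-3` of the maximum raise a warning (or an error with
#' `edge_action = "error"`).
#'
#' @inheritParams fluence_at
#' @param pitch grid pitch in mm (cell size).
#' @param extent half-extent of the grid in mm (grid spans `[-extent, extent]`
#'   in x and y around the plan centroid).
#' @param edge_action `"warn"` or `"error"` for poor grid coverage.
#' @return An object of class `fluence_map`: list with `x`, `y` (cell-centre
#'   coordinates, mm), `values` (matrix, protons/cm^2), `pitch`, `origin`,
#'   `total_protons`, `units`.
#' @export
fluence_map <- function(plan, sigma_x, sigma_y, pitch = 0.05, extent = 5,
                        edge_action = c("warn", "error")) {
  edge_action <- match.arg(edge_action)
  stopifnot(inherits(plan, "spot_plan"))
  cx <- mean(range(plan$x)); cy <- mean(range(plan$y))
  need <- max(abs(c(plan$x - cx, plan$y - cy))) + 4 * max(sigma_x, sigma_y)
  if (extent < need)
    stop(sprintf("grid extent %.3g mm < required %.3g mm (outermost spot + 4 sigma)",
                 extent, need))
  x <- seq(cx - extent, cx + extent, by = pitch)
  y <- seq(cy - extent, cy + extent, by = pitch)
  g <- expand.grid(x = x, y = y)
  v <- matrix(fluence_at(plan, g$x, g$y, sigma_x, sigma_y),
              nrow = length(x), ncol = length(y))
  edge <- max(v[1, ], v[length(x), ], v[, 1], v[, length(y)])
  if (edge > 1e-3 * max(v)) {
    msg <- sprintf("grid too small: edge fluence is %.2g of the maximum",
                   edge / max(v))
    if (edge_action == "error") stop(msg) else warning(msg)
  }
  structure(list(x = x, y = y, values = v, pitch = pitch,
                 origin = c(x = cx, y = cy),
                 total_protons = sum(plan$protons),
                 sigma = c(sigma_x = sigma_x, sigma_y = sigma_y),
                 entry_energy = attr(plan, "entry_energy"),
                 units = "protons/cm^2"),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d cells, pitch %g mm, max %.4g %s\n",
              length(x$x), length(x$y), x$pitch, max(x$values), x$units))
  ii <- map_integral(x)
  cat(sprintf("  grid integral %.4g protons (delivered %.4g)\n",
              ii, x$total_protons))
  invisible(x)
}

#' Grid integral of a map
#'
#' Sum of cell values times cell area.  For a [fluence_map()] this is the
#' total number of protons represented by the grid and should match the
#' delivered protons to within the grid tolerance (0.1% at default settings).
#'
#' @param map a `fluence_map` or `dose_map`.
#' @return The integral (protons for a fluence map; Gy mm^2 for a dose map).
#' @export
map_integral <- function(map) {
  cell_cm2 <- (map$pitch / 10)^2
  if (identical(map$units, "protons/cm^2")) sum(map$values) * cell_cm2
  else sum(map$values) * map$pitch^2
}

#' Surface dose from a fluence
#'
#' Dose averaged over a thin surface slab:
#' \eqn{D = \Phi\, \bar S\, 1.602\times10^{-10}} Gy, with \eqn{\bar S} the
#' mean mass stopping power over the slab obtained by slowing the proton
#' across it (200 RK4 steps).  The slab must be much thinner than the
#' residual range.
#'
#' @param fluence proton fluence in protons/cm^2 (vectorised).
#' @param E proton energy entering the slab, MeV.
#' @param slab_um slab (averaging) thickness in micrometres.
#' @param table stopping-power table of the slab material (default bundled
#'   water).
#' @return Dose in Gy.
#' @export
surface_dose <- function(fluence, E, slab_um = 100, table = sp_material("water")) {
  stopifnot(inherits(table, "sp_table"), slab_um > 0)
  t_cm <- slab_um * 1e-4
  if (csda_range(table, E) <= t_cm)
    stop("slab thickness exceeds the residual proton range")
  n <- 200L
  h <- t_cm / n
  Ecur <- E
  dEdx <- function(e) -table$density * interpolate_sp(table, e)
  for (i in seq_len(n)) {
    k1 <- dEdx(Ecur); k2 <- dEdx(Ecur + h / 2 * k1)
    k3 <- dEdx(Ecur + h / 2 * k2); k4 <- dEdx(Ecur + h * k3)
    Ecur <- Ecur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  mean_sp <- (E - Ecur) / (table$density * t_cm)  # MeV cm^2/g
  fluence * mean_sp * .const$mev_to_gy
}

#' Planned surface-dose map
#'
#' Composition of [fluence_map()] and [surface_dose()]: because every cell
#' sees the same proton energy, the dose map is the fluence map scaled by the
#' dose per unit fluence.
#'
#' @inheritParams fluence_map
#' @inheritParams surface_dose
#' @param E proton energy at the surface; defaults to the plan's entry energy.
#' @return An object of class `dose_map` (same geometry as the fluence map,
#'   values in Gy, with `averaging_depth_um`).
#' @export
dose_map <- function(plan, sigma_x, sigma_y, table = sp_material("water"),
                     slab_um = 100, E = attr(plan, "entry_energy"),
                     pitch = 0.05, extent = 5) {
  fm <- fluence_map(plan, sigma_x, sigma_y, pitch = pitch, extent = extent)
  d_per_phi <- surface_dose(1, E, slab_um, table)
  dm <- fm
  dm$values <- fm$values * d_per_phi
  dm$units <- "Gy"
  dm$averaging_depth_um <- slab_um
  dm$fluence <- fm
  class(dm) <- "dose_map"
  dm
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d cells, pitch %g mm, max %.4g Gy (averaged over %g um)\n",
              length(x$x), length(x$y), x$pitch, max(x$values),
              x$averaging_depth_um))
  invisible(x)
}

#' Dose homogeneity within a radius
#'
#' Summarises the dose variation over all cells within `radius_mm` of the
#' plan centre.  There is no single standard homogeneity index for this kind
#' of spot grid, so the metric is a parameter: `"max_dev"` is the largest
#' absolute relative deviation from the central dose, `"range_ratio"` is
#' \eqn{(D_{max}-D_{min})/D_{max}}, and `"cv"` is the coefficient of
#' variation of the in-radius dose.
#'
#' @param map a `dose_map` (or `fluence_map`).
#' @param radius_mm radius around the map origin, mm.
#' @param metric one of `"max_dev"`, `"range_ratio"`, `"cv"`.
#' @return The homogeneity figure (dimensionless; 0 is perfectly flat).
#' @export
dose_homogeneity <- function(map, radius_mm = 2,
                             metric = c("max_dev", "range_ratio", "cv")) {
  metric <- match.arg(metric)
  dx <- map$x - map$origin["x"]; dy <- map$y - map$origin["y"]
  inside <- outer(dx^2, dy^2, "+") <= radius_mm^2
  v <- map$values[inside]
  if (!length(v)) stop("no grid cells within the requested radius")
  centre <- map$values[which.min(abs(dx)), which.min(abs(dy))]
  switch(metric,
         max_dev = max(abs(v - centre)) / centre,
         range_ratio = (max(v) - min(v)) / max(v),
         cv = sd(v) / mean(v))
}

#' Isodose / isofluence contour polygons
#'
#' @param map a `fluence_map` or `dose_map`.
#' @param levels contour levels in the map's units; default quartiles of the
#'   maximum.
#' @return A list of polygons as returned by [grDevices::contourLines()].
#' @export
map_contours <- function(map, levels = max(map$values) * c(0.25, 0.5, 0.75, 0.95)) {
  contourLines(map$x, map$y, map$values, levels = levels)
}

#' Export a map as delimited text plus a JSON sidecar
#'
#' Writes `values` as a tab-separated grid and a `<file>.json` sidecar with
#' origin, pitch and units.
#'
#' @param map a `fluence_map` or `dose_map`.
#' @param file output path for the grid.
#' @return Invisibly, the sidecar path.
#' @export
write_map <- function(map, file) {
  write.table(map$values, file, sep = "\t", row.names = FALSE, col.names = FALSE)
  sidecar <- paste0(file, ".json")
  meta <- list(origin = as.list(map$origin), pitch_mm = map$pitch,
               units = map$units, nx = length(map$x), ny = length(map$y),
               total_protons = map$total_protons)
  if (!is.null(map$averaging_depth_um))
    meta$averaging_depth_um <- map$averaging_depth_um
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a map written by [write_map()]
#'
#' @param file path to the grid file (expects `<file>.json` alongside).
#' @return A list with `values`, `x`, `y`, `pitch`, `origin`, `units`.
#' @export
read_map <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  v <- as.matrix(read.csv(file, sep = "\t", header = FALSE))
  dimnames(v) <- NULL
  x <- meta$origin$x + (seq_len(meta$nx) - (meta$nx + 1) / 2) * meta$pitch_mm
  y <- meta$origin$y + (seq_len(meta$ny) - (meta$ny + 1) / 2) * meta$pitch_mm
  list(values = v, x = x, y = y, pitch = meta$pitch_mm,
       origin = unlist(meta$origin), units = meta$units,
       total_protons = meta$total_protons)
}
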