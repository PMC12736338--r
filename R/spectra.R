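# Stick spectra -> broadened, ensemble-averaged absorption profiles, band
# maxima and solvatochromic shifts.

default_grid <- c(1.5, 8.0, 0.01)

spectrum_grid <- function(grid) {
  if (length(grid) != 3 || grid[2] <= grid[1] || grid[3] <= 0) {
    fq_abort("`grid` must be c(min, max, step) with min < max and step > 0.",
             "fqembed_bad_value")
  }
  seq(grid[1], grid[2], by = grid[3])
}

new_spectrum_curve <- function(energy, intensity, fwhm, n_snapshots) {
  structure(
    tibble::tibble(energy_ev = energy, intensity = intensity),
    class = c("spectrum_curve", class(tibble::tibble())),
    fwhm = fwhm, n_snapshots = n_snapshots
  )
}

#' Gaussian broadening of a stick spectrum
#'
#' Convolves the transitions of one snapshot with a normalized-height Gaussian
#' of the given full width at half maximum:
#' `I(E) = sum_k f_k exp(-(E - E_k)^2 / (2 sigma^2))` with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, so the integrated area is
#' `sum_k f_k * sigma * sqrt(2 pi)`. If the grid clips more than 0.1% of that
#' area a truncation warning reports the clipped mass.
#'
#' @param sticks tibble with columns `energy_ev` and `strength` (one
#'   snapshot's transitions; may be empty).
#' @param fwhm full width at half maximum, eV.
#' @param grid `c(min, max, step)` in eV.
#' @return a `spectrum_curve` tibble (`energy_ev`, `intensity`).
#' @export
convolve_gaussian <- function(sticks, fwhm = 0.3, grid = default_grid) {
  if (fwhm <= 0) fq_abort("`fwhm` must be positive.", "fqembed_bad_value")
  e_grid <- spectrum_grid(grid)
  if (nrow(sticks) == 0) {
    return(new_spectrum_curve(e_grid, rep(0, length(e_grid)), fwhm, 0L))
  }
  if (any(sticks$energy_ev <= 0) || any(sticks$strength < 0)) {
    fq_abort("sticks must have positive energies and nonnegative strengths.",
             "fqembed_bad_value")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  ker <- exp(-outer(e_grid, sticks$energy_ev, "-")^2 / (2 * sigma^2))
  intensity <- as.numeric(ker %*% sticks$strength)
  area_exact <- sum(sticks$strength) * sigma * sqrt(2 * pi)
  area_grid <- trapz(e_grid, intensity)
  if (area_exact > 0 && abs(area_grid - area_exact) / area_exact > 1e-3) {
    rlang::warn(sprintf(
      "grid clips %.2f%% of the broadened area; widen c(min, max).",
      100 * abs(area_grid - area_exact) / area_exact),
      class = "fqembed_truncation")
  }
  new_spectrum_curve(e_grid, intensity, fwhm,
                     length(unique(sticks$snapshot_id %||% 1L)))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Pointwise ensemble average of spectra
#'
#' @param curves a list of `spectrum_curve`s on identical energy grids.
#' @return the mean `spectrum_curve`, with `n_snapshots` set to the count.
#' @export
ensemble_average <- function(curves) {
  if (length(curves) == 0) fq_abort("no curves to average.",
                                    "fqembed_bad_value")
  g0 <- curves[[1]]$energy_ev
  for (cv in curves) {
    if (length(cv$energy_ev) != length(g0) ||
        max(abs(cv$energy_ev - g0)) > 1e-9) {
      fq_abort("curves are on mismatched energy grids.",
               "fqembed_grid_mismatch")
    }
  }
  m <- rowMeans(vapply(curves, function(cv) cv$intensity,
                       numeric(length(g0))))
  new_spectrum_curve(g0, m, attr(curves[[1]], "fwhm"), length(curves))
}

#' Broadened ensemble spectrum of a stick table
#'
#' Broadens each snapshot's sticks and averages the per-snapshot curves —
#' equivalently (by linearity of the convolution) the broadened sum of all
#' sticks divided by the number of snapshots.
#'
#' @param sticks a stick tibble covering one or more `snapshot_id`s.
#' @inheritParams convolve_gaussian
#' @return the averaged `spectrum_curve`.
#' @export
ensemble_spectrum <- function(sticks, fwhm = 0.3, grid = default_grid) {
  curves <- lapply(split(sticks, sticks$snapshot_id),
                   convolve_gaussian, fwhm = fwhm, grid = grid)
  ensemble_average(curves)
}

#' Band maximum of a spectrum inside a window
#'
#' Finds the grid point of maximum intensity inside `window` and refines it by
#' three-point parabolic interpolation. A flat (or empty) curve in the window
#' raises a no-band error.
#'
#' @param curve a `spectrum_curve`.
#' @param window `c(lo, hi)` in eV; defaults to the whole grid.
#' @return band maximum position, eV.
#' @export
band_maximum <- function(curve, window = NULL) {
  e <- curve$energy_ev
  if (is.null(window)) window <- range(e)
  sel <- which(e >= window[1] & e <= window[2])
  if (length(sel) < 3) fq_abort("window too narrow for the grid.",
                                "fqembed_bad_value")
  y <- curve$intensity[sel]
  if (max(y) - min(y) < .Machine$double.eps * max(1, max(abs(y)))) {
    fq_abort("curve is flat in the window: no band to locate.",
             "fqembed_no_band")
  }
  i <- which.max(y)
  if (i == 1 || i == length(y)) return(e[sel[i]])
  # parabola through the three points around the discrete maximum
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  shift <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y1 - y3) / denom
  e[sel[i]] + shift * (e[2] - e[1])
}

#' Solvatochromic shift between gas phase and solution
#'
#' `delta_e = e_vac - e_solv`: positive when solvation moves the band to lower
#' energy (a red shift).
#'
#' @param e_vac gas-phase absorption energy of the first bright transition, eV.
#' @param e_solv solution-phase band energy, eV.
#' @return a one-row `shift_result` tibble (`e_vac`, `e_solv`, `delta_e`).
#' @export
solvatochromic_shift <- function(e_vac, e_solv) {
  if (e_vac <= 0 || e_solv <= 0) {
    fq_abort("absorption energies must be positive.", "fqembed_bad_value")
  }
  structure(
    tibble::tibble(e_vac = e_vac, e_solv = e_solv,
                   delta_e = e_vac - e_solv),
    class = c("shift_result", class(tibble::tibble()))
  )
}

#' Measured full width at half maximum of a single-band curve
#'
#' Reads the width directly off the curve by linear interpolation of the two
#' half-maximum crossings. Intended for lineshape checks on isolated bands.
#'
#' @param curve a `spectrum_curve` with a single dominant band.
#' @return width in eV.
#' @export
measure_fwhm <- function(curve) {
  y <- curve$intensity
  e <- curve$energy_ev
  i <- which.max(y)
  half <- y[i] / 2
  lo <- which(y[1:i] <= half)
  hi <- which(y[i:length(y)] <= half) + i - 1
  if (length(lo) == 0 || length(hi) == 0) {
    fq_abort("band not fully contained in the grid.", "fqembed_no_band")
  }
  l <- max(lo)
  r <- min(hi)
  el <- e[l] + (half - y[l]) / (y[l + 1] - y[l]) * (e[l + 1] - e[l])
  er <- e[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) * (e[r] - e[r - 1])
  er - el
}
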