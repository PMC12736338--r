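# Structural post-processing of snapshot ensembles: spherical cutting,
# site-site radial distribution functions and running coordination numbers.

#' Cut snapshots to a spherical droplet
#'
#' Retains every water molecule whose oxygen lies within `radius` of `center`
#' (whole-molecule rule keyed on the oxygen, so no water is ever broken across
#' the boundary) and always retains the solute. Any periodic-cell attribute is
#' dropped.
#'
#' @param snapshots ensemble (or single-snapshot) tibble.
#' @param center 3-vector, Angstrom.
#' @param radius cut radius, Angstrom (> 0).
#' @return the cut ensemble tibble.
#' @export
spherical_cut <- function(snapshots, center = c(0, 0, 0), radius) {
  if (radius <= 0) fq_abort("`radius` must be positive.", "fqembed_bad_value")
  center <- as.numeric(center)
  ox <- dplyr::filter(snapshots, .data$role == "water", .data$element == "O")
  d <- sqrt((ox$x - center[1])^2 + (ox$y - center[2])^2 + (ox$z - center[3])^2)
  keep <- ox[d <= radius, c("snapshot_id", "molecule_id")]
  out <- dplyr::filter(
    snapshots,
    .data$role == "solute" |
      paste(.data$snapshot_id, .data$molecule_id) %in%
        paste(keep$snapshot_id, keep$molecule_id)
  )
  if (!any(out$role == "water")) {
    rlang::warn("spherical cut removed every solvent molecule.",
                class = "fqembed_empty_cut")
  }
  attr(out, "config") <- attr(snapshots, "config")
  attr(out, "box") <- NULL
  out
}

select_sites <- function(snapshots, quo) {
  sel <- dplyr::filter(snapshots, !!quo)
  if (nrow(sel) == 0) {
    fq_abort("site selector matched no atoms.", "fqembed_empty_selection")
  }
  sel
}

#' Site-site radial distribution function of an ensemble
#'
#' Histograms all A-B distances per snapshot and normalizes by the ideal-gas
#' expectation `N_A * 4 pi r^2 dr * rho_B`, with the B-site density measured
#' inside the analysis sphere of radius `r_max` around the A sites (the
#' appropriate reference for finite droplets). The curve is averaged over
#' snapshots.
#'
#' @param snapshots ensemble tibble.
#' @param site_a,site_b unquoted logical expressions selecting the two site
#'   sets from the ensemble columns, e.g. `element == "H" & role == "water"`.
#' @param r_max histogram range, Angstrom.
#' @param bin_width histogram bin, Angstrom.
#' @return an `rdf_curve` tibble with columns `r`, `g`; bulk density, pair
#'   label and snapshot count in attributes.
#' @export
radial_distribution <- function(snapshots, site_a, site_b,
                                r_max = 8, bin_width = 0.05) {
  if (bin_width <= 0) fq_abort("`bin_width` must be positive.",
                               "fqembed_bad_value")
  qa <- rlang::enquo(site_a)
  qb <- rlang::enquo(site_b)
  a_all <- select_sites(snapshots, qa)
  b_all <- select_sites(snapshots, qb)

  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-9) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  n_a_total <- 0
  in_range_total <- 0
  ids <- unique(snapshots$snapshot_id)
  for (id in ids) {
    A <- as.matrix(a_all[a_all$snapshot_id == id, c("x", "y", "z")])
    B <- as.matrix(b_all[b_all$snapshot_id == id, c("x", "y", "z")])
    if (nrow(A) == 0 || nrow(B) == 0) next
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    d[d < 1e-9] <- Inf                 # drop self pairs (overlapping selectors)
    d <- d[d <= r_max]
    counts <- counts + hist_counts(d, edges)
    n_a_total <- n_a_total + nrow(A)
    in_range_total <- in_range_total + length(d)
  }
  if (n_a_total == 0) {
    fq_abort("no A sites found in any snapshot.", "fqembed_empty_selection")
  }
  vol <- 4 / 3 * pi * r_max^3
  rho_b <- in_range_total / n_a_total / vol
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  shell <- 4 * pi * centers^2 * widths
  g <- counts / (n_a_total * shell * rho_b)
  g[counts == 0] <- 0
  structure(
    tibble::tibble(r = centers, g = g),
    class = c("rdf_curve", class(tibble::tibble())),
    bulk_density = rho_b,
    pair_label = c(rlang::as_label(qa), rlang::as_label(qb)),
    n_snapshots = length(ids)
  )
}

hist_counts <- function(x, edges) {
  if (length(x) == 0) return(numeric(length(edges) - 1))
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
  idx[x == 0] <- 1L
  tabulate(idx, nbins = length(edges) - 1)
}

#' Running coordination number from a radial distribution function
#'
#' Integrates the RDF as `n(r) = 4 pi rho_B integral_0^r g(s) s^2 ds` by
#' trapezoidal accumulation on the stored grid, with the bulk density the RDF
#' was normalized with. `n(r)` equals the average number of B sites within
#' distance `r` of an A site.
#'
#' @param rdf an `rdf_curve` from [radial_distribution()].
#' @return an `rcn_curve` tibble with columns `r`, `n` (monotone, `n(0) = 0`).
#' @export
running_coordination_number <- function(rdf) {
  rho <- attr(rdf, "bulk_density")
  if (is.null(rho)) {
    fq_abort("`rdf` lacks its bulk density; use radial_distribution().",
             "fqembed_bad_value")
  }
  r <- c(0, rdf$r)
  f <- c(0, 4 * pi * rho * rdf$g * rdf$r^2)
  n <- cumsum(c(0, diff(r) * (head(f, -1) + tail(f, -1)) / 2))
  structure(
    tibble::tibble(r = r[-1], n = n[-1]),
    class = c("rcn_curve", class(tibble::tibble())),
    bulk_density = rho
  )
}

#' Locate the maximum of a radial distribution function
#'
#' Reads the position of the RDF peak inside a window: the curve is smoothed
#' with a 5-point running mean to suppress single-bin counting noise, the
#' discrete maximum is found, and the position is refined by three-point
#' parabolic interpolation.
#'
#' @param rdf an `rdf_curve`.
#' @param window `c(lo, hi)` in Angstrom; defaults to the full range.
#' @return peak position in Angstrom.
#' @export
rdf_peak <- function(rdf, window = range(rdf$r)) {
  k <- stats::filter(rdf$g, rep(1 / 5, 5), sides = 2)
  k[is.na(k)] <- rdf$g[is.na(k)]
  k <- as.numeric(k)
  sel <- which(rdf$r >= window[1] & rdf$r <= window[2])
  if (length(sel) < 3 || max(k[sel]) <= 0) {
    fq_abort("no RDF peak found in the window.", "fqembed_no_band")
  }
  i <- sel[which.max(k[sel])]
  if (i == 1 || i == length(k)) return(rdf$r[i])
  y1 <- k[i - 1]; y2 <- k[i]; y3 <- k[i + 1]
  denom <- y1 - 2 * y2 + y3
  shift <- if (abs(denom) < .Machine$double.eps) 0 else
    0.5 * (y1 - y3) / denom
  rdf$r[i] + shift * (rdf$r[2] - rdf$r[1])
}

#' Read a running coordination number at a radius
#'
#' Linear interpolation of the `rcn_curve` at `r` — typically the first-shell
#' boundary from [first_shell_minimum()], where the value counts the
#' hydrogen-bond partners.
#'
#' @param rcn an `rcn_curve`.
#' @param r radius, Angstrom.
#' @return interpolated coordination number.
#' @export
coordination_at <- function(rcn, r) {
  stats::approx(rcn$r, rcn$n, xout = r)$y
}

#' First-shell boundary of a radial distribution function
#'
#' Locates the first local minimum of the 5-point-smoothed RDF after its first
#' maximum — the conventional radius at which the running coordination number
#' is read to count hydrogen-bond partners.
#'
#' @param rdf an `rdf_curve`.
#' @return radius in Angstrom.
#' @export
first_shell_minimum <- function(rdf) {
  g <- rdf$g
  k <- stats::filter(g, rep(1 / 5, 5), sides = 2)
  k[is.na(k)] <- g[is.na(k)]
  k <- as.numeric(k)
  n <- length(k)
  imax <- NA_integer_
  for (i in 2:(n - 1)) {
    if (k[i] > k[i - 1] && k[i] >= k[i + 1] && k[i] > 0.5) { imax <- i; break }
  }
  if (is.na(imax)) {
    fq_abort("no RDF maximum found; cannot locate the first shell.",
             "fqembed_no_band")
  }
  for (i in (imax + 1):(n - 1)) {
    if (k[i] < k[i - 1] && k[i] <= k[i + 1]) return(rdf$r[i])
  }
  rdf$r[n]
}
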