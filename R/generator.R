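# Synthetic solvation-droplet generator. Emulates the two engines a real
# spectroscopy workflow would call out to: a classical MD sampler (droplet
# snapshots with a hydrogen-bonded shell around a carbonyl acceptor) and an
# excited-state engine (per-snapshot stick spectra responding to the local
# electrostatic environment; see mock_excitations()).

# rigid three-site water geometry (TIP3P-style)
WATER_OH <- 0.9572       # Angstrom
WATER_HOH <- 104.52      # degrees

#' Default point-charge solute: a carbonyl probe
#'
#' A minimal rigid solute carrying a polar C=O group (the hydrogen-bond
#' acceptor, labelled `O2`) and two neutral-ish ring carbons for excluded
#' volume. Charges sum to zero.
#'
#' @return tibble with columns `x`, `y`, `z` (Angstrom), `charge` (a.u.),
#'   `element`, `name`.
#' @export
carbonyl_solute <- function() {
  tibble::tibble(
    x = c(0, 1.23, -1.45, -1.45),
    y = c(0, 0, 0.70, -0.70),
    z = 0,
    charge = c(0.45, -0.57, 0.06, 0.06),
    element = c("C", "O", "C", "C"),
    name = c("C1", "O2", "C3", "C4")
  )
}

#' Configuration of the droplet generator
#'
#' The defaults emulate the study conditions of an aqueous-dye spectroscopy
#' workflow: 100 snapshots, a 17 Angstrom spherical droplet at liquid-water
#' number density, and a carbonyl acceptor whose hydrogen-bond shell holds on
#' average two donor waters at an acceptor-hydrogen distance of 1.8 Angstrom.
#'
#' @param n_snapshots number of snapshots to generate.
#' @param droplet_radius droplet radius, Angstrom (> 5).
#' @param water_density water number density, molecules per cubic Angstrom.
#' @param solute point-charge solute table (see [carbonyl_solute()]).
#' @param hb_acceptor_index row of `solute` acting as the hydrogen-bond
#'   acceptor (the carbonyl oxygen).
#' @param hb_count_mean expected number of hydrogen-bonded waters (Poisson).
#' @param hb_distance_mean,hb_distance_sd normal law of the acceptor to donor
#'   hydrogen distance, Angstrom.
#' @param contact_dist minimum heavy-atom contact distance for bulk water
#'   insertion, Angstrom.
#' @param shell_exclusion bulk waters are kept at least this far (oxygen to
#'   acceptor) so the acceptor's first shell is populated only by the
#'   explicitly placed hydrogen-bond waters.
#' @param seed integer seed; every stochastic draw derives from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_snapshots = 100,
                             droplet_radius = 17,
                             water_density = 0.0334,
                             solute = carbonyl_solute(),
                             hb_acceptor_index = 2,
                             hb_count_mean = 2,
                             hb_distance_mean = 1.8,
                             hb_distance_sd = 0.1,
                             contact_dist = 2.4,
                             shell_exclusion = 3.4,
                             seed = 1L) {
  if (droplet_radius <= 5) {
    fq_abort("`droplet_radius` must exceed 5 Angstrom.", "fqembed_bad_config")
  }
  if (water_density <= 0) {
    fq_abort("`water_density` must be positive.", "fqembed_bad_config")
  }
  if (hb_distance_mean <= 1.2) {
    fq_abort("`hb_distance_mean` must exceed 1.2 Angstrom.",
             "fqembed_bad_config")
  }
  structure(list(
    n_snapshots = as.integer(n_snapshots),
    droplet_radius = droplet_radius,
    water_density = water_density,
    solute = tibble::as_tibble(solute),
    hb_acceptor_index = as.integer(hb_acceptor_index),
    hb_count_mean = hb_count_mean,
    hb_distance_mean = hb_distance_mean,
    hb_distance_sd = hb_distance_sd,
    contact_dist = contact_dist,
    shell_exclusion = shell_exclusion,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# --- small geometry helpers --------------------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

random_unit_vector <- function() unit3(rnorm(3))

# uniform random rotation via normalized quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# any unit vector orthogonal to u
orthonormal_to <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(a - sum(a * u) * u)
}

# rigid water site matrix (rows O, H1, H2) centred on the oxygen, with the
# O->H1 bond along `h1_dir` and the second hydrogen at the water angle,
# azimuth `phi` about the O->H1 axis.
water_from_donor <- function(o_pos, h1_dir, phi) {
  u <- unit3(h1_dir)
  e1 <- orthonormal_to(u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- WATER_HOH * pi / 180
  w <- cos(ang) * u + sin(ang) * (cos(phi) * e1 + sin(phi) * e2)
  rbind(o_pos,
        o_pos + WATER_OH * u,
        o_pos + WATER_OH * w)
}

# direction uniform in a cone of half-angle `half_angle` about `axis`
random_cone_direction <- function(axis, half_angle) {
  axis <- unit3(axis)
  cosmax <- cos(half_angle)
  c_theta <- runif(1, cosmax, 1)
  s_theta <- sqrt(1 - c_theta^2)
  phi <- runif(1, 0, 2 * pi)
  e1 <- orthonormal_to(axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  c_theta * axis + s_theta * (cos(phi) * e1 + sin(phi) * e2)
}

# --- snapshot generation -----------------------------------------------------

#' Generate an ensemble of solvation-droplet snapshots
#'
#' Each snapshot holds the rigid solute at its reference pose at the droplet
#' centre, a Poisson-distributed number of hydrogen-bonded waters whose donor
#' hydrogen points at the acceptor at a normally distributed distance, and
#' bulk waters placed uniformly in the droplet with random orientations,
#' rejected below the heavy-atom contact distance. The generation is fully
#' reproducible: the configuration seed spawns one independent substream per
#' snapshot.
#'
#' @param config a [generator_config()].
#' @return a tibble with one row per atom and columns `snapshot_id`, `atom`,
#'   `role` (`"solute"`/`"water"`), `molecule_id` (0 for the solute), `element`,
#'   `name`, `x`, `y`, `z` (Angstrom). The configuration and per-snapshot
#'   seeds are stored in attributes `config` and `snapshot_seeds`.
#' @export
generate_snapshots <- function(config = generator_config()) {
  set.seed(config$seed)
  snap_seeds <- sample.int(.Machine$integer.max - 1L, config$n_snapshots)
  frames <- lapply(seq_len(config$n_snapshots), function(i) {
    set.seed(snap_seeds[i])
    frame <- generate_one_snapshot(config)
    frame$snapshot_id <- i
    frame
  })
  out <- dplyr::bind_rows(frames)
  out <- out[, c("snapshot_id", "atom", "role", "molecule_id",
                 "element", "name", "x", "y", "z")]
  attr(out, "config") <- config
  attr(out, "snapshot_seeds") <- snap_seeds
  out
}

generate_one_snapshot <- function(config) {
  sol <- config$solute
  acc <- as.numeric(sol[config$hb_acceptor_index, c("x", "y", "z")])
  centroid <- colMeans(as.matrix(sol[, c("x", "y", "z")]))
  hb_axis <- acc - centroid
  if (sum(hb_axis^2) < 1e-12) hb_axis <- c(1, 0, 0)

  R <- config$droplet_radius
  n_target <- round(4 / 3 * pi * R^3 * config$water_density)

  waters <- list()
  # hydrogen-bond shell: donor hydrogen toward the acceptor, oxygen behind it.
  # The draw is capped at 5 donors (a carbonyl cannot sterically accept more);
  # at the default mean of 2 the cap changes the expected count by < 0.03.
  n_hb <- min(rpois(1, config$hb_count_mean), 5L, n_target)
  tries <- 0
  while (length(waters) < n_hb) {
    tries <- tries + 1
    if (tries > 500 * max(1, n_hb)) {
      fq_abort("could not place the hydrogen-bond shell (crowded acceptor).",
               "fqembed_generation_error")
    }
    u <- random_cone_direction(hb_axis, 85 * pi / 180)
    d <- rnorm(1, config$hb_distance_mean, config$hb_distance_sd)
    if (d < 1.2) next
    o_pos <- acc + (d + WATER_OH) * u
    if (sqrt(sum(o_pos^2)) > R) next
    ok <- all(vapply(waters, function(w) {
      sqrt(sum((w[1, ] - o_pos)^2)) >= config$contact_dist
    }, logical(1)))
    if (!ok) next
    # donor hydrogen points back at the acceptor (linear hydrogen bond)
    waters[[length(waters) + 1]] <- water_from_donor(o_pos, -u, runif(1, 0, 2 * pi))
  }

  # bulk waters: uniform positions, uniform orientations, hard contacts
  heavy <- as.matrix(sol[sol$element != "H", c("x", "y", "z")])
  o_existing <- if (length(waters) > 0) {
    do.call(rbind, lapply(waters, function(w) w[1, , drop = FALSE]))
  } else matrix(numeric(0), 0, 3)
  n_bulk <- n_target - length(waters)
  attempts <- 0
  max_attempts <- 2000 + 400 * max(1, n_bulk)
  placed <- 0
  while (placed < n_bulk) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      fq_abort(sprintf(
        "unsatisfiable packing: placed %d of %d bulk waters (density too high?).",
        placed, n_bulk), "fqembed_generation_error")
    }
    o_pos <- R * runif(1)^(1 / 3) * random_unit_vector()
    if (min(sqrt(rowSums(sweep(heavy, 2, o_pos)^2))) < config$contact_dist) next
    if (sqrt(sum((o_pos - acc)^2)) < config$shell_exclusion) next
    if (nrow(o_existing) > 0 &&
        min(sqrt(rowSums(sweep(o_existing, 2, o_pos)^2))) < config$contact_dist) next
    rot <- random_rotation()
    h1 <- as.numeric(rot %*% c(1, 0, 0))
    waters[[length(waters) + 1]] <- water_from_donor(o_pos, h1, runif(1, 0, 2 * pi))
    o_existing <- rbind(o_existing, o_pos)
    placed <- placed + 1
  }

  solute_tbl <- tibble::tibble(
    role = "solute", molecule_id = 0L,
    element = sol$element, name = sol$name,
    x = sol$x, y = sol$y, z = sol$z
  )
  if (length(waters) > 0) {
    wmat <- do.call(rbind, waters)
    dimnames(wmat) <- NULL
    water_tbl <- tibble::tibble(
      role = "water",
      molecule_id = rep(seq_along(waters), each = 3),
      element = rep(c("O", "H", "H"), length(waters)),
      name = rep(c("OW", "HW1", "HW2"), length(waters)),
      x = wmat[, 1], y = wmat[, 2], z = wmat[, 3]
    )
    out <- dplyr::bind_rows(solute_tbl, water_tbl)
  } else {
    out <- solute_tbl
  }
  out$atom <- seq_len(nrow(out))
  out
}

#' Split an ensemble tibble into per-snapshot tibbles
#'
#' @param snapshots an ensemble tibble from [generate_snapshots()].
#' @return a named list of single-snapshot tibbles.
#' @export
split_snapshots <- function(snapshots) {
  split(snapshots, snapshots$snapshot_id)
}
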