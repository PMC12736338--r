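# Shared fixtures: small water clusters and toy topologies, built in code.

toy_params <- fq_parameters("toy")

# a single rigid water as a site tibble (Angstrom)
water_sites_tbl <- function(o = c(0, 0, 0), rot = diag(3), molecule_id = 1L) {
  local <- rbind(c(0, 0, 0),
                 c(0.9572, 0, 0),
                 c(0.9572 * cos(104.52 * pi / 180),
                   0.9572 * sin(104.52 * pi / 180), 0))
  xyz <- t(rot %*% t(local)) + matrix(o, 3, 3, byrow = TRUE)
  tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 element = c("O", "H", "H"),
                 molecule_id = as.integer(molecule_id))
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

# random cluster of n_mol rigid waters, oxygens >= 2.6 Angstrom apart
random_water_cluster <- function(n_mol, variant = "FQ", spread = 4.5) {
  os <- matrix(numeric(0), 0, 3)
  while (nrow(os) < n_mol) {
    cand <- runif(3, -spread, spread)
    if (nrow(os) == 0 || min(sqrt(rowSums(sweep(os, 2, cand)^2))) >= 2.6) {
      os <- rbind(os, cand)
    }
  }
  tbl <- purrr::map(seq_len(n_mol), function(m) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rot <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      3, 3, byrow = TRUE)
    water_sites_tbl(os[m, ], rot, m)
  }) |> purrr::list_rbind()
  tbl <- dplyr::left_join(tbl, toy_params[, c("element", "chi", "eta", "alpha")],
                          by = "element")
  if (variant == "FQ") tbl$alpha <- NA_real_
  mm_topology(tbl)
}

# random external source with both potential and field
random_source <- function(topology, scale = 0.05) {
  external_source(rnorm(nrow(topology), 0, scale),
                  matrix(rnorm(3 * nrow(topology), 0, scale),
                         nrow(topology), 3),
                  topology)
}

# tiny snapshot tibble wrapper around a water cluster, for excitation tests
cluster_snapshot <- function(topology, snapshot_id = 1L) {
  tibble::tibble(
    snapshot_id = as.integer(snapshot_id),
    atom = seq_len(nrow(topology)),
    role = "water",
    molecule_id = topology$molecule_id,
    element = topology$element,
    name = ifelse(topology$element == "O", "OW", "HW"),
    x = topology$x, y = topology$y, z = topology$z
  )
}

# hand-constructed rdf_curve (for closed-form integration checks)
make_rdf <- function(r, g, rho) {
  structure(tibble::tibble(r = r, g = g),
            class = c("rdf_curve", class(tibble::tibble())),
            bulk_density = rho, pair_label = c("A", "B"), n_snapshots = 1L)
}
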