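# a compact hand-built ensemble: solute point at the origin plus waters at
# prescribed oxygen positions
frame_with_waters <- function(o_list, snapshot_id = 1L) {
  solute <- tibble::tibble(role = "solute", molecule_id = 0L, element = "C",
                           name = "C1", x = 0, y = 0, z = 0)
  wat <- purrr::imap(o_list, function(o, m) {
    w <- water_sites_tbl(o, molecule_id = as.integer(m))
    tibble::tibble(role = "water", molecule_id = as.integer(m),
                   element = w$element,
                   name = c("OW", "HW1", "HW2"),
                   x = w$x, y = w$y, z = w$z)
  }) |> purrr::list_rbind()
  out <- dplyr::bind_rows(solute, wat)
  out$atom <- seq_len(nrow(out))
  out$snapshot_id <- as.integer(snapshot_id)
  out
}

test_that("spherical cut keeps whole molecules keyed on the oxygen", {
  fr <- frame_with_waters(list(c(5, 0, 0), c(16.9, 0, 0), c(19, 0, 0)))
  all_kept <- spherical_cut(fr, c(0, 0, 0), 100)
  expect_identical(nrow(all_kept), nrow(fr))

  cut <- spherical_cut(fr, c(0, 0, 0), 17)
  kept_mols <- unique(cut$molecule_id[cut$role == "water"])
  expect_setequal(kept_mols, c(1L, 2L))
  # molecule 2's oxygen is inside at 16.9 even though a hydrogen pokes out
  w2 <- cut[cut$molecule_id == 2L & cut$role == "water", ]
  expect_identical(nrow(w2), 3L)
  expect_warning(spherical_cut(fr, c(0, 0, 0), 2),
                 class = "fqembed_empty_cut")
})

test_that("spherical cut agrees with a brute-force per-molecule check", {
  cfg <- generator_config(n_snapshots = 2, droplet_radius = 12, seed = 29)
  snaps <- generate_snapshots(cfg)
  radius <- 9
  cut <- spherical_cut(snaps, c(0, 0, 0), radius)
  for (fr in split_snapshots(snaps)) {
    ox <- dplyr::filter(fr, .data$role == "water", .data$element == "O")
    expected <- ox$molecule_id[sqrt(ox$x^2 + ox$y^2 + ox$z^2) <= radius]
    got <- unique(cut$molecule_id[cut$snapshot_id == fr$snapshot_id[1] &
                                    cut$role == "water"])
    expect_setequal(got, expected)
  }
})

test_that("ideal-gas points give a flat RDF near one", {
  set.seed(37)
  n_snap <- 50
  n_pts <- 500
  frames <- purrr::map(seq_len(n_snap), function(i) {
    u <- matrix(rnorm(3 * n_pts), n_pts, 3)
    u <- u / sqrt(rowSums(u^2)) * 12 * runif(n_pts)^(1 / 3)
    tibble::tibble(snapshot_id = i, atom = seq_len(n_pts), role = "water",
                   molecule_id = seq_len(n_pts), element = "X", name = "X",
                   x = u[, 1], y = u[, 2], z = u[, 3],
                   central = sqrt(rowSums(u^2)) < 4)
  }) |> purrr::list_rbind()
  rdf <- radial_distribution(frames, central, element == "X",
                             r_max = 8, bin_width = 0.1)
  sel <- rdf$r > 2 & rdf$r < 4
  expect_true(all(abs(rdf$g[sel] - 1) < 0.1))
})

test_that("a single fixed-distance pair lands in the bin containing it", {
  d <- 2.63
  fr <- tibble::tibble(snapshot_id = 1L, atom = 1:2, role = "water",
                       molecule_id = 1:2, element = c("A", "B"),
                       name = c("A", "B"),
                       x = c(0, d), y = 0, z = 0)
  rdf <- radial_distribution(fr, element == "A", element == "B",
                             r_max = 4, bin_width = 0.05)
  hit <- which(rdf$g > 0)
  expect_length(hit, 1)
  expect_lt(abs(rdf$r[hit] - d), 0.05 / 2 + 1e-12)
})

test_that("running coordination number reproduces closed forms", {
  rho <- 0.02
  r <- seq(0.02, 8, by = 0.02)
  rcn <- running_coordination_number(make_rdf(r, rep(1, length(r)), rho))
  expect_equal(rcn$n[length(r)], 4 / 3 * pi * 8^3 * rho, tolerance = 0.005)
  at4 <- coordination_at(rcn, 4)
  expect_equal(at4, 4 / 3 * pi * 4^3 * rho, tolerance = 0.005)

  rcn0 <- running_coordination_number(make_rdf(r, rep(0, length(r)), rho))
  expect_true(all(rcn0$n == 0))
  expect_true(all(diff(rcn$n) >= 0))
})

test_that("RCN at r equals the direct average neighbour count", {
  cfg <- generator_config(n_snapshots = 20, droplet_radius = 9, seed = 41)
  snaps <- generate_snapshots(cfg)
  rdf <- radial_distribution(snaps, role == "solute" & name == "O2",
                             role == "water" & element == "H",
                             r_max = 6, bin_width = 0.05)
  rcn <- running_coordination_number(rdf)
  acc <- dplyr::filter(snaps, .data$role == "solute", .data$name == "O2")
  hw <- dplyr::filter(snaps, .data$role == "water", .data$element == "H")
  for (r_at in c(2.5, 4.0, 5.5)) {
    direct <- mean(vapply(split(hw, hw$snapshot_id), function(h) {
      a <- acc[acc$snapshot_id == h$snapshot_id[1], ]
      sum(sqrt((h$x - a$x)^2 + (h$y - a$y)^2 + (h$z - a$z)^2) <= r_at)
    }, numeric(1)))
    bin_content <- max(diff(c(0, rcn$n))[abs(rcn$r - r_at) < 0.2])
    expect_lt(abs(coordination_at(rcn, r_at) - direct),
              bin_content + 0.05)
  }
})

test_that("the RDF is invariant under rigid motions of every snapshot", {
  cfg <- generator_config(n_snapshots = 5, droplet_radius = 8, seed = 43)
  snaps <- generate_snapshots(cfg)
  rdf0 <- radial_distribution(snaps, role == "solute" & name == "O2",
                              role == "water" & element == "H",
                              r_max = 5, bin_width = 0.05)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  xyz <- as.matrix(snaps[, c("x", "y", "z")]) %*% t(rot)
  moved <- snaps
  moved$x <- xyz[, 1] + 3.2
  moved$y <- xyz[, 2] - 1.1
  moved$z <- xyz[, 3] + 0.4
  rdf1 <- radial_distribution(moved, role == "solute" & name == "O2",
                              role == "water" & element == "H",
                              r_max = 5, bin_width = 0.05)
  expect_equal(rdf1$g, rdf0$g, tolerance = 1e-12)
})

test_that("coarser bins preserve the density-weighted RDF integral", {
  cfg <- generator_config(n_snapshots = 30, droplet_radius = 9, seed = 47)
  snaps <- generate_snapshots(cfg)
  integral <- function(bw) {
    rdf <- radial_distribution(snaps, role == "solute" & name == "O2",
                               role == "water" & element == "H",
                               r_max = 6, bin_width = bw)
    rho <- attr(rdf, "bulk_density")
    sel <- rdf$r >= 1 & rdf$r <= 5
    sum(4 * pi * rho * rdf$g[sel] * rdf$r[sel]^2 * bw)
  }
  i1 <- integral(0.05)
  i2 <- integral(0.10)
  expect_lt(abs(i2 - i1) / i1, 0.01)
})

test_that("empty selections are reported", {
  fr <- frame_with_waters(list(c(4, 0, 0)))
  expect_error(radial_distribution(fr, element == "ZZ", element == "H",
                                   r_max = 5, bin_width = 0.1),
               class = "fqembed_empty_selection")
})
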