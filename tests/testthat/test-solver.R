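test_that("uniform electronegativity and zero source give a dead-neutral molecule", {
  w <- water_sites_tbl()
  w$chi <- 0.2
  w$eta <- c(0.6, 0.7, 0.7)
  w$alpha <- c(6, 1, 1)
  top <- mm_topology(w)
  for (v in c("FQFMU", "FQFMU_CT")) {
    sol <- solve_embedding(top, v)
    expect_equal(sol$sites$q, rep(0, 3), tolerance = 1e-12)
    expect_equal(unlist(sol$sites[, c("mux", "muy", "muz")]),
                 rep(0, 9), tolerance = 1e-12, ignore_attr = TRUE)
  }
  top_fq <- mm_topology(dplyr::mutate(w, alpha = NA_real_))
  expect_equal(solve_embedding(top_fq, "FQ")$sites$q, rep(0, 3),
               tolerance = 1e-12)
})

test_that("solver matches the brute-force constrained minimizer on toy water", {
  set.seed(11)
  top <- random_water_cluster(1, variant = "FQ")
  sol <- solve_embedding(top, "FQ")
  orc <- oracle_solve(top, "FQ")
  expect_equal(sol$sites$q, orc$q, tolerance = 1e-8)
})

test_that("solver matches the oracle across variants, kernels and sources", {
  set.seed(23)
  for (variant in c("FQ", "FQFMU", "FQFMU_CT")) {
    for (form in c("ohno", "coulomb")) {
      n_mol <- sample(1:4, 1)
      top <- random_water_cluster(n_mol, variant = variant)
      src <- random_source(top)
      sol <- solve_embedding(top, variant, src, form)
      orc <- oracle_solve(top, variant, src, form)
      expect_equal(sol$sites$q, orc$q, tolerance = 1e-8)
      if (!is.null(orc$mu)) {
        expect_equal(as.matrix(sol$sites[, c("mux", "muy", "muz")]),
                     orc$mu, tolerance = 1e-8, ignore_attr = TRUE)
      }
    }
  }
})

test_that("charge constraints hold to 1e-10 and CT moves charge between molecules", {
  set.seed(31)
  top <- random_water_cluster(2, variant = "FQFMU")
  # strong asymmetric source: a point charge close to molecule 1
  o1 <- as.numeric(top[1, c("x", "y", "z")])
  src <- solute_point_source(
    tibble::tibble(x = o1[1] + 1.6, y = o1[2], z = o1[3], charge = 1.5), top)
  sol_fm <- solve_embedding(top, "FQFMU", src)
  per_mol <- tapply(sol_fm$sites$q, sol_fm$sites$molecule_id, sum)
  expect_lt(max(abs(per_mol - 0)), 1e-10)

  sol_ct <- solve_embedding(top, "FQFMU_CT", src)
  per_mol_ct <- tapply(sol_ct$sites$q, sol_ct$sites$molecule_id, sum)
  expect_lt(abs(sum(sol_ct$sites$q)), 1e-10)
  expect_gt(abs(per_mol_ct[1]), 1e-4)                 # genuine charge transfer
  expect_equal(unname(per_mol_ct[1]), -unname(per_mol_ct[2]),
               tolerance = 1e-10)
})

test_that("the induced response is linear in the source and superposes", {
  set.seed(43)
  top <- random_water_cluster(2, variant = "FQFMU")
  base <- solve_embedding(top, "FQFMU")
  s1 <- random_source(top)
  s2 <- random_source(top)
  sol1 <- solve_embedding(top, "FQFMU", s1)
  sol2 <- solve_embedding(top, "FQFMU", s2)
  alpha <- 2.5
  s_scaled <- external_source(alpha * s1$potential,
                              alpha * cbind(s1$ex, s1$ey, s1$ez), top)
  sol_scaled <- solve_embedding(top, "FQFMU", s_scaled)
  expect_equal(sol_scaled$sites$q - base$sites$q,
               alpha * (sol1$sites$q - base$sites$q), tolerance = 1e-10)
  s_sum <- external_source(s1$potential + s2$potential,
                           cbind(s1$ex + s2$ex, s1$ey + s2$ey,
                                 s1$ez + s2$ez), top)
  sol_sum <- solve_embedding(top, "FQFMU", s_sum)
  expect_equal(sol_sum$sites$q - base$sites$q,
               (sol1$sites$q - base$sites$q) +
                 (sol2$sites$q - base$sites$q), tolerance = 1e-10)
})

test_that("mirror-symmetric topology and source give mirror-symmetric response", {
  # two waters mirror-imaged through the yz plane, mirror-symmetric source
  w1 <- water_sites_tbl(o = c(2, 0, 0), molecule_id = 1L)
  w2 <- w1
  w2$x <- -w2$x
  w2$molecule_id <- 2L
  tbl <- dplyr::bind_rows(w1, w2)
  tbl <- dplyr::left_join(tbl, toy_params[, c("element", "chi", "eta", "alpha")],
                          by = "element")
  top <- mm_topology(tbl)
  src <- solute_point_source(tibble::tibble(x = 0, y = 0.8, z = 0,
                                            charge = -0.8), top)
  sol <- solve_embedding(top, "FQFMU", src)
  q <- sol$sites$q
  expect_equal(q[1:3], q[4:6], tolerance = 1e-10)
  expect_equal(sol$sites$mux[1:3], -sol$sites$mux[4:6], tolerance = 1e-10)
  expect_equal(sol$sites$muy[1:3], sol$sites$muy[4:6], tolerance = 1e-10)
  expect_equal(sol$sites$muz[1:3], sol$sites$muz[4:6], tolerance = 1e-10)
})

test_that("an isolated polarizable site with frozen charge obeys mu = alpha E", {
  top <- mm_topology(tibble::tibble(x = 0, y = 0, z = 0, element = "O",
                                    chi = 0.15, eta = 0.6, alpha = 6,
                                    molecule_id = 1L))
  E <- c(0.013, -0.007, 0.002)
  src <- external_source(0, matrix(E, 1, 3), top)
  sol <- solve_embedding(top, "FQFMU", src)
  expect_equal(sol$sites$q, 0, tolerance = 1e-14)
  expect_equal(as.numeric(sol$sites[, c("mux", "muy", "muz")]), 6 * E,
               tolerance = 1e-14)
})

test_that("the solution is a constrained minimum of the energy functional", {
  set.seed(57)
  top <- random_water_cluster(2, variant = "FQFMU")
  src <- random_source(top)
  sol <- solve_embedding(top, "FQFMU", src)
  q <- sol$sites$q
  mu <- as.matrix(sol$sites[, c("mux", "muy", "muz")])
  e0 <- oracle_energy(top, "FQFMU", src, "ohno", q, mu)
  for (rep in 1:20) {
    dq <- rnorm(nrow(top), 0, 1e-4)
    # project onto the constraint manifold (zero net change per molecule)
    for (m in unique(top$molecule_id)) {
      idx <- top$molecule_id == m
      dq[idx] <- dq[idx] - mean(dq[idx])
    }
    dmu <- matrix(rnorm(3 * nrow(top), 0, 1e-4), nrow(top), 3)
    e1 <- oracle_energy(top, "FQFMU", src, "ohno", q + dq, mu + dmu)
    expect_gte(e1, e0 - 1e-12)
  }
})

test_that("interaction energies follow the charge-minus-dipole convention", {
  top2 <- mm_topology(tibble::tibble(
    x = c(0, 3), y = 0, z = 0, element = "O", chi = 0.1, eta = 0.6,
    molecule_id = 1:2))
  sol <- solve_embedding(top2, "FQ")
  sol$sites$q <- c(0.1, -0.1)
  src <- external_source(c(1, 2), topology = top2)
  expect_equal(interaction_energy(sol, src), -0.1)

  sol$sites$q <- c(0, 0)
  expect_equal(interaction_energy(sol, src), 0)

  set.seed(71)
  top <- random_water_cluster(2, variant = "FQFMU")
  src <- random_source(top)
  sol <- solve_embedding(top, "FQFMU", src)
  naive <- 0
  for (i in seq_len(nrow(top))) {
    naive <- naive + sol$sites$q[i] * src$potential[i]
    naive <- naive - sol$sites$mux[i] * src$ex[i] -
      sol$sites$muy[i] * src$ey[i] - sol$sites$muz[i] * src$ez[i]
  }
  expect_equal(interaction_energy(sol, src), naive, tolerance = 1e-12)
  expect_error(interaction_energy(sol, src, variant = "FQ"),
               class = "fqembed_variant_mismatch")
})

test_that("point-charge sources reproduce Coulomb's law and the naive loop", {
  top <- mm_topology(tibble::tibble(
    x = 2 * fq_constants$angstrom_per_bohr, y = 0, z = 0, element = "O",
    chi = 0.1, eta = 0.6, molecule_id = 1L))
  src <- solute_point_source(tibble::tibble(x = 0, y = 0, z = 0, charge = 1),
                             top)
  expect_equal(src$potential, 0.5, tolerance = 1e-12)
  expect_equal(sqrt(src$ex^2 + src$ey^2 + src$ez^2), 0.25, tolerance = 1e-12)

  # midpoint between opposite charges: zero potential, field along the axis
  top_mid <- mm_topology(tibble::tibble(x = 0, y = 0, z = 0, element = "O",
                                        chi = 0.1, eta = 0.6,
                                        molecule_id = 1L))
  src_mid <- solute_point_source(
    tibble::tibble(x = c(-2, 2), y = 0, z = 0, charge = c(1, -1)), top_mid)
  expect_equal(src_mid$potential, 0, tolerance = 1e-14)
  expect_equal(src_mid$ey, 0, tolerance = 1e-14)
  expect_equal(src_mid$ez, 0, tolerance = 1e-14)
  expect_gt(src_mid$ex, 0)   # field points from the + charge toward the - one

  set.seed(83)
  top9 <- random_water_cluster(3, variant = "FQ")
  solute <- tibble::tibble(x = runif(4, 8, 12), y = runif(4, -2, 2),
                           z = runif(4, -2, 2), charge = rnorm(4))
  src9 <- solute_point_source(solute, top9)
  b <- fq_constants$bohr_per_angstrom
  for (i in seq_len(nrow(top9))) {
    v <- 0; e <- c(0, 0, 0)
    for (k in 1:4) {
      d <- c(top9$x[i] - solute$x[k], top9$y[i] - solute$y[k],
             top9$z[i] - solute$z[k]) * b
      r <- sqrt(sum(d^2))
      v <- v + solute$charge[k] / r
      e <- e + solute$charge[k] * d / r^3
    }
    expect_equal(src9$potential[i], v, tolerance = 1e-12)
    expect_equal(c(src9$ex[i], src9$ey[i], src9$ez[i]), e, tolerance = 1e-12)
  }

  expect_error(
    solute_point_source(tibble::tibble(x = top9$x[1], y = top9$y[1],
                                       z = top9$z[1] + 0.2, charge = 1),
                        top9),
    class = "fqembed_site_collision")
})
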