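# Constrained solve of the fluctuating-charge(-and-dipole) stationarity
# conditions, external-source construction, and interaction energies.

#' External electrostatic source at the MM sites
#'
#' Bundles the scalar potential and the electric-field vector felt by each MM
#' site (both in atomic units). These play the role of the imprint of the
#' quantum-mechanical solute density on the solvent in a full embedding
#' calculation; here they are typically produced by [solute_point_source()].
#'
#' @param potential numeric vector, potential at each site (a.u.).
#' @param field matrix with one row per site and columns `ex`, `ey`, `ez`
#'   (a.u.), or `NULL` for a potential-only source.
#' @param topology optional [mm_topology()] used to validate lengths.
#' @return an `external_source` tibble with columns `site`, `potential`,
#'   `ex`, `ey`, `ez`.
#' @export
external_source <- function(potential, field = NULL, topology = NULL) {
  n <- length(potential)
  if (is.null(field)) field <- matrix(0, n, 3)
  field <- as.matrix(field)
  if (nrow(field) != n || ncol(field) != 3) {
    fq_abort("`field` must be an n x 3 matrix matching `potential`.",
             "fqembed_dimension_mismatch")
  }
  if (!is.null(topology) && n != nrow(topology)) {
    fq_abort("source length does not match the topology's site count.",
             "fqembed_dimension_mismatch")
  }
  tibble::tibble(site = seq_len(n),
                 potential = unname(as.numeric(potential)),
                 ex = unname(field[, 1]), ey = unname(field[, 2]),
                 ez = unname(field[, 3])) |>
    structure(class = c("external_source", class(tibble::tibble())))
}

zero_source <- function(topology) {
  external_source(rep(0, nrow(topology)), topology = topology)
}

source_field_matrix <- function(source) {
  as.matrix(source[, c("ex", "ey", "ez")])
}

#' Potential and field of a point-charge solute at the MM sites
#'
#' Evaluates the bare Coulomb potential V_i = sum_k c_k / |r_i - r_k| and field
#' E_i = sum_k c_k (r_i - r_k) / |r_i - r_k|^3 (atomic units) generated by a
#' set of solute point charges at every site of the MM topology.
#'
#' @param solute_charges data frame with columns `x`, `y`, `z` (Angstrom) and
#'   `charge` (a.u.).
#' @param topology an [mm_topology()].
#' @return an [external_source()].
#' @export
solute_point_source <- function(solute_charges, topology) {
  solute_charges <- tibble::as_tibble(solute_charges)
  rs <- angstrom_to_bohr(as.matrix(solute_charges[, c("x", "y", "z")]))
  q <- solute_charges$charge
  rm <- topology_positions_bohr(topology)
  n <- nrow(rm)
  V <- numeric(n)
  E <- matrix(0, n, 3)
  min_sep <- 0.5 * fq_constants$bohr_per_angstrom
  for (k in seq_along(q)) {
    d <- sweep(rm, 2, rs[k, ])        # r_i - r_k
    r <- sqrt(rowSums(d^2))
    if (any(r < min_sep)) {
      fq_abort("solute charge closer than 0.5 Angstrom to an MM site.",
               "fqembed_site_collision")
    }
    V <- V + q[k] / r
    E <- E + q[k] * d / r^3
  }
  external_source(V, E, topology)
}

#' Assemble the constrained saddle-point linear system
#'
#' Builds the symmetric block matrix and right-hand side whose solution gives
#' the fluctuating charges, Lagrange multipliers and (for dipole-carrying
#' variants) induced dipoles. Unknown ordering is charges, then multipliers,
#' then dipoles (site-major x,y,z). Sign conventions: the charge-row RHS is
#' -(chi + V), the constraint rows carry the target molecular (or total)
#' charges, and the dipole rows carry +E.
#'
#' @param kernels a [build_kernels()] result.
#' @param topology the matching [mm_topology()].
#' @param variant force-field variant.
#' @param source an [external_source()]; `NULL` means zero potential/field.
#' @return a list with `A` (matrix), `b` (RHS), and an `index` list mapping
#'   the unknown blocks.
#' @export
assemble_system <- function(kernels, topology, variant = "FQ", source = NULL) {
  variant <- ff_variant(variant)
  if (!identical(attr(kernels, "variant"), variant)) {
    fq_abort("kernels were built for a different variant.",
             "fqembed_variant_mismatch")
  }
  n <- nrow(topology)
  if (attr(kernels, "n_sites") != n) {
    fq_abort("kernels and topology disagree on the site count.",
             "fqembed_dimension_mismatch")
  }
  if (is.null(source)) source <- zero_source(topology)
  if (nrow(source) != n) {
    fq_abort("source length does not match the topology.",
             "fqembed_dimension_mismatch")
  }
  C <- kernels$constraint
  nc <- ncol(C)
  q_rhs <- -(topology$chi + source$potential)
  c_rhs <- if (variant == "FQFMU_CT") system_charge(topology) else
    as.numeric(molecule_charges(topology))

  if (variant_uses_dipoles(variant)) {
    E <- source_field_matrix(source)
    nd <- 3 * n
    A <- rbind(
      cbind(kernels$Tqq, C, kernels$Tqmu),
      cbind(t(C), matrix(0, nc, nc), matrix(0, nc, nd)),
      cbind(t(kernels$Tqmu), matrix(0, nd, nc), kernels$Tmumu)
    )
    b <- c(q_rhs, c_rhs, as.numeric(t(E)))
    index <- list(q = 1:n, lambda = n + 1:nc, mu = n + nc + 1:nd)
  } else {
    A <- rbind(cbind(kernels$Tqq, C),
               cbind(t(C), matrix(0, nc, nc)))
    b <- c(q_rhs, c_rhs)
    index <- list(q = 1:n, lambda = n + 1:nc, mu = integer(0))
  }
  list(A = A, b = b, index = index, variant = variant)
}

#' Solve the polarizable-embedding linear system
#'
#' Assembles and solves the constrained stationarity conditions of the
#' quadratic charge(-and-dipole) energy functional: charges equilibrate
#' electronegativity under the molecular (or total) charge constraints, and
#' dipoles respond to the total field. A direct factorization of the
#' saddle-point matrix is used; a singular system (e.g. from coincident sites)
#' raises a numerical-degeneracy error.
#'
#' @inheritParams assemble_system
#' @param kernel_form kernel family passed to [build_kernels()].
#' @param tol residual tolerance for the solved system (a.u.).
#' @return an `embedding_solution` object; see [tidy.embedding_solution()].
#' @export
solve_embedding <- function(topology, variant = "FQ", source = NULL,
                            kernel_form = "ohno", tol = 1e-8) {
  variant <- ff_variant(variant)
  kern <- build_kernels(topology, variant, kernel_form)
  sys <- assemble_system(kern, topology, variant, source)
  x <- tryCatch(solve(sys$A, sys$b),
                error = function(e) {
                  fq_abort(paste0("saddle-point system is numerically singular: ",
                                  conditionMessage(e)),
                           "fqembed_singular_system")
                })
  x <- unname(as.numeric(x))
  resid <- max(abs(sys$A %*% x - sys$b))
  scale <- max(1, max(abs(sys$b)))
  if (!is.finite(resid) || resid > tol * scale) {
    fq_abort(sprintf("solver residual %.3e exceeds tolerance %.3e.",
                     resid, tol * scale), "fqembed_singular_system")
  }
  q <- x[sys$index$q]
  lambda <- x[sys$index$lambda]
  mu <- if (length(sys$index$mu) > 0) {
    matrix(x[sys$index$mu], ncol = 3, byrow = TRUE)
  } else NULL
  sites <- tibble::tibble(
    site = topology$site, element = topology$element,
    x = topology$x, y = topology$y, z = topology$z,
    molecule_id = topology$molecule_id, q = q,
    mux = if (is.null(mu)) NA_real_ else mu[, 1],
    muy = if (is.null(mu)) NA_real_ else mu[, 2],
    muz = if (is.null(mu)) NA_real_ else mu[, 3]
  )
  structure(
    list(sites = sites, multipliers = lambda, variant = variant,
         kernel_form = kernel_form, residual = resid,
         molecule_charges = molecule_charges(topology),
         system_charge = system_charge(topology)),
    class = "embedding_solution"
  )
}

#' @export
print.embedding_solution <- function(x, ...) {
  cat(sprintf("<embedding_solution> %s (%s kernel): %d sites, %d constraint(s), residual %.2e\n",
              x$variant, x$kernel_form, nrow(x$sites),
              length(x$multipliers), x$residual))
  print(x$sites, n = 6)
  invisible(x)
}

solution_dipoles <- function(solution) {
  if (!variant_uses_dipoles(solution$variant)) return(NULL)
  as.matrix(solution$sites[, c("mux", "muy", "muz")])
}

#' Embedding interaction energy with an external source
#'
#' Computes the electrostatic interaction energy between the solved MM charges
#' (and dipoles) and the external potential/field: `sum(q * V)` for the
#' charge-only force field, and `sum(q * V) - sum(mu . E)` when induced dipoles
#' are present (the dipole term enters with a minus sign).
#'
#' @param solution an `embedding_solution`.
#' @param source the [external_source()] the solution was obtained with.
#' @param variant force-field variant; defaults to the solution's own.
#' @return interaction energy in Hartree.
#' @export
interaction_energy <- function(solution, source,
                               variant = solution$variant) {
  variant <- ff_variant(variant)
  if (variant == "FQ" && !all(is.na(solution$sites$mux))) {
    fq_abort("solution carries dipoles but variant FQ was requested.",
             "fqembed_variant_mismatch")
  }
  if (nrow(source) != nrow(solution$sites)) {
    fq_abort("source and solution are dimensionally inconsistent.",
             "fqembed_dimension_mismatch")
  }
  e <- sum(solution$sites$q * source$potential)
  if (variant_uses_dipoles(variant)) {
    mu <- solution_dipoles(solution)
    e <- e - sum(mu * source_field_matrix(source))
  }
  e
}

#' Electric field of the solved solvent at a point
#'
#' Sums the Coulomb field of every solved charge and (when present) point
#' dipole at an arbitrary probe point. Used by the mock excitation model to
#' couple the local electrostatic environment to the transition energy.
#'
#' @param solution an `embedding_solution`.
#' @param point 3-vector in Angstrom.
#' @return field 3-vector in atomic units.
#' @export
solvent_field <- function(solution, point) {
  p <- angstrom_to_bohr(as.numeric(point))
  pos <- angstrom_to_bohr(as.matrix(solution$sites[, c("x", "y", "z")]))
  d <- sweep(-pos, 2, p, "+")         # p - r_site
  r <- sqrt(rowSums(d^2))
  if (any(r < 0.5 * fq_constants$bohr_per_angstrom)) {
    fq_abort("probe point within 0.5 Angstrom of an MM site.",
             "fqembed_site_collision")
  }
  Efield <- colSums(solution$sites$q * d / r^3)
  mu <- solution_dipoles(solution)
  if (!is.null(mu)) {
    rhat <- d / r
    mr <- rowSums(mu * rhat)
    Efield <- Efield + colSums((3 * mr * rhat - mu) / r^3)
  }
  Efield
}
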