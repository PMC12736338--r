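# Interaction kernels of the fluctuating-charge(-and-dipole) energy
# functional. All kernel algebra is in atomic units; site coordinates are
# converted from Angstrom on entry.
#
# The damped ("ohno") family uses the pairwise screened Coulomb form
#   s(r) = 1 / sqrt(r^2 + d_ij^2),   d_ij = 1 / eta_ij,  eta_ij = (eta_i+eta_j)/2
# so that s(0) = eta_ij joins smoothly onto the diagonal hardness self-term and
# s(r) -> 1/r at large separation. Charge-dipole and dipole-dipole blocks are
# the first and second derivatives of the same screened potential, which keeps
# the quadratic energy functional consistent across blocks. The "coulomb" form
# sets d_ij = 0 off the diagonal (bare multipole interactions).

#' Assemble interaction-kernel matrices for a topology
#'
#' Builds the charge-charge block `Tqq` (with per-site hardness on the
#' diagonal), and for dipole-carrying variants the charge-dipole block `Tqmu`
#' and dipole-dipole block `Tmumu` (with inverse polarizability on its diagonal
#' 3x3 blocks), plus the molecule-indicator constraint block.
#'
#' @param topology an [mm_topology()].
#' @param variant force-field variant, see [ff_variant()].
#' @param kernel_form `"ohno"` (hardness-damped, default) or `"coulomb"`.
#' @return a `kernel_matrices` list with elements `Tqq`, `Tqmu`, `Tmumu`
#'   (the latter two `NULL` for `"FQ"`), and `constraint`.
#' @export
build_kernels <- function(topology, variant = "FQ",
                          kernel_form = c("ohno", "coulomb")) {
  variant <- check_variant_topology(topology, variant)
  kernel_form <- match.arg(kernel_form)
  pos <- topology_positions_bohr(topology)
  n <- nrow(pos)
  eta <- topology$eta

  r2 <- as.matrix(dist(pos))^2
  if (n > 1 && min(r2[upper.tri(r2)]) <= (0.1 * fq_constants$bohr_per_angstrom)^2) {
    fq_abort("degenerate geometry: overlapping sites.",
             "fqembed_degenerate_geometry")
  }
  if (kernel_form == "ohno") {
    eta_pair <- outer(eta, eta, "+") / 2
    d2 <- 1 / eta_pair^2
  } else {
    d2 <- matrix(0, n, n)
  }
  s2 <- r2 + d2
  Tqq <- 1 / sqrt(s2)
  diag(Tqq) <- eta

  kern <- list(Tqq = Tqq, Tqmu = NULL, Tmumu = NULL,
               constraint = constraint_block(topology, variant))

  if (variant_uses_dipoles(variant)) {
    alpha <- topology$alpha
    s3 <- s2^(-1.5)
    s5 <- s2^(-2.5)
    diag(s3) <- 0
    diag(s5) <- 0
    # Intramolecular polarization exclusion (Thole/AMOEBA convention): the
    # induced dipoles do not couple to charges or dipoles of their own
    # molecule — those interactions are considered folded into the
    # parameterization. Charge-charge coupling keeps its intramolecular terms
    # (electronegativity equalization within the molecule requires them).
    same_mol <- outer(topology$molecule_id, topology$molecule_id, "==")
    s3[same_mol] <- 0
    s5[same_mol] <- 0
    D <- lapply(1:3, function(k) outer(pos[, k], pos[, k], "-"))
    Tqmu <- matrix(0, n, 3 * n)
    Tmumu <- matrix(0, 3 * n, 3 * n)
    for (k in 1:3) {
      cols_k <- seq(k, 3 * n, by = 3)
      Tqmu[, cols_k] <- D[[k]] * s3
      for (m in 1:3) {
        cols_m <- seq(m, 3 * n, by = 3)
        blk <- -3 * D[[k]] * D[[m]] * s5
        if (k == m) blk <- blk + s3
        Tmumu[cols_k, cols_m] <- blk
      }
    }
    for (i in seq_len(n)) {
      idx <- 3 * (i - 1) + 1:3
      Tmumu[idx, idx] <- diag(3) / alpha[i]
    }
    kern$Tqmu <- Tqmu
    kern$Tmumu <- Tmumu
  }

  structure(kern, class = "kernel_matrices",
            variant = variant, kernel_form = kernel_form,
            n_sites = n)
}

# molecule-indicator columns (the Lagrange "1" blocks); a single all-ones
# column when the charge-transfer variant constrains only the total charge.
constraint_block <- function(topology, variant) {
  n <- nrow(topology)
  if (variant == "FQFMU_CT") {
    matrix(1, n, 1)
  } else {
    mols <- sort(unique(topology$molecule_id))
    C <- vapply(mols, function(m) as.numeric(topology$molecule_id == m),
                numeric(n))
    matrix(C, nrow = n)
  }
}
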