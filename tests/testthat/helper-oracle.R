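# Independent oracles for the embedding solver: the quadratic energy
# functional and its gradient are built with explicit scalar loops (no shared
# code with the package's vectorized kernel assembly), and the constrained
# minimum is found by conjugate-gradient minimization in
# constraint-eliminated coordinates. Everything here is deliberately slow and
# simple.

.bohr <- 1 / 0.529177210903

oracle_s <- function(r2, eta_i, eta_j, form) {
  if (form == "ohno") {
    d <- 2 / (eta_i + eta_j)
    1 / sqrt(r2 + d^2)
  } else {
    1 / sqrt(r2)
  }
}

# full gradient of the energy functional at (q, mu); loops over every pair.
# mu is an n x 3 matrix (zero and unused for variant FQ).
oracle_gradient <- function(top, variant, source, form, q, mu) {
  n <- nrow(top)
  pos <- as.matrix(top[, c("x", "y", "z")]) * .bohr
  eta <- top$eta
  mol <- top$molecule_id
  V <- source$potential
  E <- cbind(source$ex, source$ey, source$ez)
  gq <- top$chi + V + eta * q
  gmu <- matrix(0, n, 3)
  if (variant %in% c("FQFMU", "FQFMU_CT")) {
    gmu <- mu / top$alpha - E
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rij <- pos[i, ] - pos[j, ]
      r2 <- sum(rij^2)
      gq[i] <- gq[i] + oracle_s(r2, eta[i], eta[j], form) * q[j]
      if (variant %in% c("FQFMU", "FQFMU_CT") && mol[i] != mol[j]) {
        s3 <- (r2 + if (form == "ohno") (2 / (eta[i] + eta[j]))^2 else 0)^(-1.5)
        s5 <- (r2 + if (form == "ohno") (2 / (eta[i] + eta[j]))^2 else 0)^(-2.5)
        # charge i with dipole j: q_i mu_j . (r_i - r_j) s3
        gq[i] <- gq[i] + sum(mu[j, ] * rij) * s3
        gmu[j, ] <- gmu[j, ] + q[i] * rij * s3
        # dipole-dipole, accumulated once per ordered pair onto gmu[i, ]
        Tij <- s3 * diag(3) - 3 * s5 * (rij %o% rij)
        gmu[i, ] <- gmu[i, ] + as.numeric(Tij %*% mu[j, ])
      }
    }
  }
  list(gq = gq, gmu = gmu)
}

# energy functional value (for stationarity checks)
oracle_energy <- function(top, variant, source, form, q, mu) {
  n <- nrow(top)
  pos <- as.matrix(top[, c("x", "y", "z")]) * .bohr
  eta <- top$eta
  mol <- top$molecule_id
  E <- cbind(source$ex, source$ey, source$ez)
  en <- sum((top$chi + source$potential) * q) + 0.5 * sum(eta * q^2)
  if (variant %in% c("FQFMU", "FQFMU_CT")) {
    en <- en + 0.5 * sum(rowSums(mu^2) / top$alpha) - sum(mu * E)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      rij <- pos[i, ] - pos[j, ]
      r2 <- sum(rij^2)
      en <- en + oracle_s(r2, eta[i], eta[j], form) * q[i] * q[j]
      if (variant %in% c("FQFMU", "FQFMU_CT") && mol[i] != mol[j]) {
        d2 <- if (form == "ohno") (2 / (eta[i] + eta[j]))^2 else 0
        s3 <- (r2 + d2)^(-1.5)
        s5 <- (r2 + d2)^(-2.5)
        en <- en + q[i] * sum(mu[j, ] * rij) * s3
        en <- en + q[j] * sum(mu[i, ] * -rij) * s3
        Tij <- s3 * diag(3) - 3 * s5 * (rij %o% rij)
        en <- en + as.numeric(mu[i, ] %*% Tij %*% mu[j, ])
      }
    }
  }
  en
}

# orthonormal basis of the null space of t(rep(1, n))
null_ones <- function(n) {
  if (n == 1) return(matrix(numeric(0), 1, 0))
  qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# constrained minimizer by conjugate gradients on the reduced coordinates
oracle_solve <- function(top, variant, source = NULL, form = "ohno") {
  n <- nrow(top)
  if (is.null(source)) {
    source <- external_source(rep(0, n), topology = top)
  }
  mol <- top$molecule_id
  mols <- sort(unique(mol))
  qmol <- molecule_charges(top)
  dip <- variant %in% c("FQFMU", "FQFMU_CT")

  if (variant == "FQFMU_CT") {
    q0 <- rep(system_charge(top) / n, n)
    Z <- list(list(idx = seq_len(n), Z = null_ones(n)))
  } else {
    q0 <- numeric(n)
    Z <- lapply(mols, function(m) {
      idx <- which(mol == m)
      q0[idx] <<- qmol[[as.character(m)]] / length(idx)
      list(idx = idx, Z = null_ones(length(idx)))
    })
  }
  ny <- sum(vapply(Z, function(z) ncol(z$Z), integer(1)))
  ntot <- ny + if (dip) 3 * n else 0

  expand <- function(x) {
    q <- q0
    off <- 0
    for (z in Z) {
      k <- ncol(z$Z)
      if (k > 0) q[z$idx] <- q[z$idx] + as.numeric(z$Z %*% x[off + seq_len(k)])
      off <- off + k
    }
    mu <- if (dip) matrix(x[ny + seq_len(3 * n)], n, 3, byrow = TRUE) else
      matrix(0, n, 3)
    list(q = q, mu = mu)
  }
  gfun <- function(x) {
    st <- expand(x)
    g <- oracle_gradient(top, variant, source, form, st$q, st$mu)
    gy <- numeric(ny)
    off <- 0
    for (z in Z) {
      k <- ncol(z$Z)
      if (k > 0) gy[off + seq_len(k)] <- as.numeric(t(z$Z) %*% g$gq[z$idx])
      off <- off + k
    }
    if (dip) c(gy, as.numeric(t(g$gmu))) else gy
  }

  if (ntot == 0) {
    st <- expand(numeric(0))
    return(list(q = st$q, mu = if (dip) st$mu else NULL))
  }
  g0 <- gfun(numeric(ntot))
  Hv <- function(v) gfun(v) - g0      # gradient is affine in x
  x <- numeric(ntot)
  r <- -g0
  p <- r
  rs <- sum(r * r)
  for (it in seq_len(3 * ntot + 20)) {
    if (sqrt(rs) < 1e-13) break
    Ap <- Hv(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  st <- expand(x)
  list(q = st$q, mu = if (dip) st$mu else NULL)
}
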