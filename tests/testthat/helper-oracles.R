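# Independent oracles. Each reimplements the quantity under test by a
# different route than the package and must stay free of package internals.

# Optimal-superposition rmsd via the quaternion characteristic-polynomial
# route: the largest eigenvalue of the 4x4 key matrix built from the
# correlation matrix of the centred point sets gives
# rmsd = sqrt((GA + GB - 2*lmax)/n).
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  GA <- sum(Pc^2); GB <- sum(Qc^2)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (GA + GB - 2 * lmax)) / n)
}

# Brute-force equilibrium heats for the 1:1 model: the bound concentration
# after each injection is found by bisection on the mass-action equation
# Ka*(n*Mt - B)*(Lt - B) - B = 0 rather than by the closed-form root, with
# its own dilution bookkeeping.
bisection_heats <- function(protocol, params) {
  V0 <- protocol$cell_volume
  dv <- protocol$injection_volumes
  k <- length(dv)
  Mt <- protocol$cell_conc
  Lt <- 0
  Qprev <- 0
  out <- numeric(k)
  for (i in seq_len(k)) {
    f <- 1 - dv[i] / V0
    Mt <- Mt * f
    Lt <- Lt * f + protocol$syringe_conc * dv[i] / V0
    g <- function(B) params$Ka * (params$n * Mt - B) * (Lt - B) - B
    upper <- min(params$n * Mt, Lt)
    B <- if (upper <= 0) 0 else
      uniroot(g, c(0, upper), tol = 1e-18 * max(upper, 1e-30))$root
    Q <- B * params$dH * V0 * 1e9
    out[i] <- Q - Qprev + (dv[i] / V0) * (Q + Qprev) / 2 + params$q_offset
    Qprev <- Q
  }
  out
}

# torsion angle (degrees) from four points, by the atan2 formula
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# phi/psi of an atom tibble chain, computed only from raw coordinates
backbone_dihedrals <- function(st, chain) {
  st <- st[st$chain == chain & st$type == "ATOM", ]
  res <- sort(unique(st$resno))
  at <- function(rn, nm) {
    r <- st[st$resno == rn & st$elety == nm, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  out <- NULL
  for (i in seq_along(res)) {
    rn <- res[i]
    phi <- if (i > 1 && res[i - 1] == rn - 1) {
      torsion_angle(at(rn - 1, "C"), at(rn, "N"), at(rn, "CA"), at(rn, "C"))
    } else NA_real_
    psi <- if (i < length(res) && res[i + 1] == rn + 1) {
      torsion_angle(at(rn, "N"), at(rn, "CA"), at(rn, "C"), at(rn + 1, "N"))
    } else NA_real_
    out <- rbind(out, data.frame(resno = rn, phi = phi, psi = psi))
  }
  out
}
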