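# Fixture builders shared across the test files.

# minimal hand-written PDB text (two atoms, one residue)
write_two_atom_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# PDB with alternate locations: altloc A occupancy 0.4, B occupancy 0.6,
# plus a tied pair (C/D at 0.5) to pin down deterministic resolution
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  OG ASER A   1       2.000   1.000   0.000  0.40  0.00           O",
    "ATOM      4  OG BSER A   1       2.000  -1.000   0.000  0.60  0.00           O",
    "ATOM      5  C  CSER A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      6  C  DSER A   1       3.000   0.500   0.000  0.50  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# ten-residue poly-ALA helix written to disk for selection tests
write_ten_residue_pdb <- function(path) {
  st <- build_peptide(strrep("A", 10), phi = -57, psi = -47, chain = "A")
  write_structure(st, path)
  path
}

# structure containing only waters and a calcium ion (no polymer)
write_hetero_only_pdb <- function(path) {
  lines <- c(
    "HETATM    1 CA    CA A 201       0.000   0.000   0.000  1.00  0.00          CA",
    "HETATM    2  O   HOH A 301       2.400   0.000   0.000  1.00  0.00           O",
    "END"
  )
  writeLines(lines, path)
  path
}

# Flat idealized antiparallel beta ladder. Strands are built on an exact
# template in which paired N-H...O=C bonds are collinear with N...O = 2.9 A
# (Kabsch-Sander energy about -2.9 kcal/mol), so the hydrogen-bond pattern
# is planted by construction. Strand s sits at y = s*4.13 A; odd strands
# run +x, even strands -x, with the antiparallel register j + i = len + 13
# between neighbours. Residue numbering leaves a gap of 4 between strands.
make_beta_ladder <- function(n_strands = 2, len = 8, chain = "A") {
  d <- 4.13
  rows <- NULL
  for (s in seq_len(n_strands)) {
    base <- (s - 1) * (len + 4)
    up <- s %% 2 == 1   # odd strands run +x
    for (m in seq_len(len)) {
      resno <- base + m
      if (up) {
        xn <- 3.4 * m - 1.2; xc <- 3.4 * m + 1.2; xca <- 3.4 * m
        sgn <- ifelse(m %% 2 == 0, 1, -1)   # even residues face +y
      } else {
        i_eq <- len + 1 - m                  # register partner index
        xn <- 3.4 * i_eq + 1.2; xc <- 3.4 * i_eq - 1.2; xca <- 3.4 * i_eq
        sgn <- ifelse(m %% 2 == 0, 1, -1)   # odd residues face -y
      }
      y <- (s - 1) * d
      z <- 0.6 * (-1)^m
      rows <- rbind(rows, data.frame(
        elety = c("N", "CA", "C", "O"),
        x = c(xn, xca, xc, xc),
        y = c(y, y, y, y + sgn * 1.23),
        z = c(0, z, 0, 0),
        resno = resno
      ))
    }
  }
  tibble::tibble(
    type = "ATOM", eleno = seq_len(nrow(rows)), elety = rows$elety,
    alt = "", resid = "GLY", chain = chain, resno = rows$resno,
    insert = "", x = rows$x, y = rows$y, z = rows$z, o = 1, b = 0,
    elesy = substr(rows$elety, 1, 1)
  )
}

# two-residue inter-chain fixture with a planted Ser OG ... His ND1 bond:
# OG at origin-side 2.9 A from ND1, antecedents placed so the angle
# criterion is met on both sides
make_ser_his_fixture <- function(distance = 2.9) {
  tibble::tibble(
    type = "ATOM",
    eleno = 1:10,
    elety = c("N", "CA", "CB", "OG", "N", "CA", "CB", "CG", "ND1", "CE1"),
    alt = "",
    resid = c(rep("SER", 4), rep("HIS", 6)),
    chain = c(rep("A", 4), rep("B", 6)),
    resno = c(rep(1, 4), rep(1, 6)),
    insert = "",
    x = c(-3.0, -2.0, -1.4, 0.0,
          distance + 3.2, distance + 2.4, distance + 1.9,
          distance + 1.4, distance, distance + 0.7),
    y = c(0.5, 0.8, 0, 0, 0.6, 1.2, 1.0, 0, 0, 1.2),
    z = 0,
    o = 1, b = 0,
    elesy = c("N", "C", "C", "O", "N", "C", "C", "C", "N", "C")
  )
}

# Leu/Ile side-chain pair with terminal carbons at a chosen distance
make_leu_ile_fixture <- function(distance = 4.0) {
  tibble::tibble(
    type = "ATOM",
    eleno = 1:12,
    elety = c("N", "CA", "CB", "CG", "CD1",
              "N", "CA", "CB", "CG1", "CG2", "CD1", "C"),
    alt = "",
    resid = c(rep("LEU", 5), rep("ILE", 7)),
    chain = c(rep("A", 5), rep("B", 7)),
    resno = 1,
    insert = "",
    x = c(-4.5, -3.5, -2.5, -1.3, 0,
          distance + 4.5, distance + 3.6, distance + 2.6,
          distance + 1.4, distance + 2.9, distance, distance + 4.3),
    y = c(0.2, 0.9, 0.1, 0.6, 0, 0.3, 1.0, 0.2, 0.7, 1.6, 0, 1.8),
    z = 0,
    o = 1, b = 0,
    elesy = c("N", "C", "C", "C", "C", "N", "C", "C", "C", "C", "C", "C")
  )
}

# Lys NZ / Glu OE1 pair for salt-bridge tagging
make_salt_bridge_fixture <- function(distance = 3.8) {
  tibble::tibble(
    type = "ATOM",
    eleno = 1:10,
    elety = c("N", "CA", "CD", "CE", "NZ", "N", "CA", "CD", "OE1", "OE2"),
    alt = "",
    resid = c(rep("LYS", 5), rep("GLU", 5)),
    chain = c(rep("A", 5), rep("B", 5)),
    resno = 1,
    insert = "",
    x = c(-4.0, -3.2, -2.4, -1.3, 0,
          distance + 4.0, distance + 3.2, distance + 2.4,
          distance, distance + 1.9),
    y = c(0.4, 1.0, 0.2, 0.5, 0, 0.4, 1.0, 0.6, 0, -1.1),
    z = 0,
    o = 1, b = 0,
    elesy = c("N", "C", "C", "C", "N", "N", "C", "C", "O", "O")
  )
}

# planted octahedral calcium site: ion + 5 Asp OD1 ligands from distinct
# residues + one water
make_octahedral_site <- function(chain = "A") {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1))
  rows <- NULL
  for (k in 1:5) {
    p <- 2.4 * dirs[k, ]
    rows <- rbind(rows, data.frame(
      type = "ATOM", elety = c("CA", "CB", "OD1"),
      resid = "ASP", resno = c(10, 10, 10) + (k - 1) * 2,
      x = c(6 * dirs[k, 1], 4 * dirs[k, 1], p[1]),
      y = c(6 * dirs[k, 2], 4 * dirs[k, 2], p[2]),
      z = c(6 * dirs[k, 3], 4 * dirs[k, 3], p[3])
    ))
  }
  rows <- rbind(rows,
                data.frame(type = "HETATM", elety = "CA", resid = "CA",
                           resno = 201, x = 0, y = 0, z = 0),
                data.frame(type = "HETATM", elety = "O", resid = "HOH",
                           resno = 301, x = 0, y = 0, z = -2.4))
  tibble::tibble(
    type = rows$type, eleno = seq_len(nrow(rows)), elety = rows$elety,
    alt = "", resid = rows$resid, chain = chain, resno = rows$resno,
    insert = "", x = rows$x, y = rows$y, z = rows$z, o = 1, b = 0,
    elesy = ifelse(rows$resid == "CA", "CA", substr(rows$elety, 1, 1))
  )
}

random_rigid_motion <- function() {
  # uniform-ish random rotation from QR of a Gaussian matrix, forced proper
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, motion) {
  sweep(as.matrix(xyz) %*% t(motion$rotation), 2, -motion$translation)
}
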