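# Synthetic structure fixtures: idealized dockerins with tunable internal
# two-fold symmetry, a cohesin-like contact plateau, and ITC datasets.
# Geometry is internal-coordinate (NeRF) with standard bond lengths and
# angles; fixtures are geometric objects for exercising the pipeline, not
# energy-minimized models.

BOND <- list(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
             CA_CB = 1.53, SC = 1.52)
ANGLE <- list(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7,
              CA_C_O = 120.5)

unit <- function(v) v / sqrt(sum(v^2))

# place atom d given positions a, b, c with bond |c-d|, angle b-c-d and
# torsion a-b-c-d (degrees) -- the standard NeRF construction
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# CB from the backbone frame (tetrahedral, fixed handedness)
place_cb <- function(n, ca, c) {
  u1 <- unit(n - ca); u2 <- unit(c - ca)
  e1 <- unit(u1 + u2); e2 <- unit(pracma_cross(u1, u2))
  ca + BOND$CA_CB * (-0.604 * e1 + 0.797 * e2)
}

# idealized side chain grown outward from CB along the CA->CB direction
# with small alternating deflections; geometry is schematic beyond CB
grow_sidechain <- function(resid, pos) {
  topo <- SIDECHAIN_TOPOLOGY[[resid]]
  if (is.null(topo)) abort(paste0("unknown residue code '", resid, "'"))
  if (length(topo) == 0) return(pos)
  pos$CB <- place_cb(pos$N, pos$CA, pos$C)
  if (length(topo) == 1) return(pos)
  axis1 <- unit(pracma_cross(pos$CB - pos$CA, pos$C - pos$CA))
  axis2 <- unit(pracma_cross(axis1, pos$CB - pos$CA))
  kids_seen <- list()
  for (name in names(topo)[-1]) {
    parent <- topo[[name]]
    pp <- pos[[parent]]
    if (is.null(pp)) next
    gp_name <- if (parent == "CB") "CA" else SIDECHAIN_TOPOLOGY[[resid]][[parent]]
    gp <- pos[[gp_name]]
    d <- unit(pp - gp)
    k <- length(kids_seen[[parent]] %||% character(0))
    defl <- switch(as.character(k),
                   "0" = 0.45 * axis1, "1" = -0.55 * axis1 - 0.3 * axis2,
                   0.5 * axis2)
    pos[[name]] <- pp + BOND$SC * unit(d + defl)
    kids_seen[[parent]] <- c(kids_seen[[parent]] %||% character(0), name)
  }
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an idealized peptide from a sequence and backbone dihedrals
#'
#' Constructs main-chain N, CA, C, O atoms from standard bond geometry and
#' the supplied phi/psi angles, plus schematic idealized side chains. An
#' all-helix peptide uses phi = -57, psi = -47; extended strand geometry is
#' approximately phi = -120, psi = 120.
#'
#' @param sequence one-letter string or character vector.
#' @param phi,psi backbone dihedrals in degrees, recycled to the sequence
#'   length.
#' @param chain chain identifier.
#' @param start_resno auth number of the first residue.
#' @return atom tibble (see [read_structure()] for columns).
#' @export
#' @examples
#' hx <- build_peptide(strrep("A", 15), phi = -57, psi = -47)
build_peptide <- function(sequence, phi = -57, psi = -47, chain = "A",
                          start_resno = 1) {
  if (length(sequence) == 1) sequence <- strsplit(sequence, "")[[1]]
  nres <- length(sequence)
  resids <- unname(AA_ONE_TO_THREE[sequence])
  if (anyNA(resids)) abort("sequence contains unknown residue codes")
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  N <- CA <- C <- O <- matrix(NA_real_, nres, 3)
  # seed the first residue
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND$N_CA, 0, 0)
  ang <- ANGLE$N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND$CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(nres)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND$C_N, ANGLE$CA_C_N, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND$N_CA, ANGLE$C_N_CA, 180)  # omega
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           BOND$CA_C, ANGLE$N_CA_C, phi[i])
    }
  }
  for (i in seq_len(nres)) {
    ref_psi <- if (i < nres) psi[i] else psi[i]
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         BOND$C_O, ANGLE$CA_C_O, ref_psi + 180)
  }
  rows <- NULL
  for (i in seq_len(nres)) {
    pos <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    pos <- grow_sidechain(resids[i], pos)
    for (nm in names(pos)) {
      p <- pos[[nm]]
      rows <- bind_rows(rows, tibble(
        type = "ATOM", elety = nm, resid = resids[i],
        chain = chain, resno = start_resno + i - 1,
        x = p[1], y = p[2], z = p[3],
        elesy = substr(nm, 1, 1)
      ))
    }
  }
  finalize_structure(rows)
}

finalize_structure <- function(rows) {
  rows |>
    mutate(eleno = row_number(), alt = "", insert = "", o = 1, b = 0) |>
    select("type", "eleno", "elety", "alt", "resid", "chain", "resno",
           "insert", "x", "y", "z", "o", "b", "elesy")
}

#' Specification of a synthetic dockerin fixture
#'
#' The defaults emulate a group-1-like dockerin: a 28-residue repeat
#' (11-residue calcium loop + 17-residue helix, matching the auth 28-55
#' frame of the reference dockerin), perfect duplication of the repeat
#' across an exact two-fold, a 9-residue inter-repeat linker gap, and
#' calcium sites with the canonical \{0, 2, 4, 11\} coordination offsets
#' plus one water each.
#'
#' @param repeat_length residues per repeat (>= helix_length + 4).
#' @param helix_length residues in the repeat's helix.
#' @param sequence_repeat1 one-letter sequence of repeat 1
#'   (length `repeat_length`).
#' @param substitutions list of `list(position, residue)` pairs: `position`
#'   is a repeat-1 auth number whose symmetry mate in repeat 2 is replaced
#'   by one-letter code `residue`.
#' @param rotation_axis_jitter degrees of random extra rotation applied to
#'   repeat 2 (0 = exact two-fold).
#' @param coordinate_jitter Gaussian sd (Å) of coordinate noise added to
#'   the protein atoms.
#' @param seed integer seed for the jitters.
#' @param start_resno auth number of repeat 1's first residue.
#' @param linker_length residues between the repeats (left as a chain gap:
#'   fixtures carry no physical linker).
#' @param chain chain identifier of the dockerin.
#' @return list of class `dockerin_spec`.
#' @export
dockerin_spec <- function(repeat_length = 28, helix_length = 17,
                          sequence_repeat1 = NULL,
                          substitutions = list(),
                          rotation_axis_jitter = 0,
                          coordinate_jitter = 0,
                          seed = NULL, start_resno = 28,
                          linker_length = 9, chain = "D") {
  if (repeat_length < helix_length + 4) {
    abort("repeat_length must be at least helix_length + 4")
  }
  if (is.null(sequence_repeat1)) {
    loop_len <- repeat_length - helix_length
    loop <- rep("G", loop_len)
    loop[c(2, 4, 6)[c(2, 4, 6) <= loop_len]] <- "D"   # offsets 0, 2, 4
    helix <- rep("A", helix_length)
    fixed <- c(1, 2, 4, 5, 6, 8, 9, 13, 16, 17)
    codes <- c("I", "S", "S", "V", "L", "M", "Q", "K", "K", "Y")
    keep <- fixed <= helix_length
    helix[fixed[keep]] <- codes[keep]
    sequence_repeat1 <- paste(c(loop, helix), collapse = "")
  }
  if (nchar(sequence_repeat1) != repeat_length) {
    abort("sequence_repeat1 must have repeat_length residues")
  }
  for (s in substitutions) {
    p <- as.numeric(s[[1]])
    if (p < start_resno || p >= start_resno + repeat_length) {
      abort(paste0("substitution position ", p, " outside repeat 1"))
    }
    if (!toupper(s[[2]]) %in% names(AA_ONE_TO_THREE)) {
      abort(paste0("unknown residue code '", s[[2]], "'"))
    }
  }
  structure(
    list(repeat_length = repeat_length, helix_length = helix_length,
         sequence_repeat1 = sequence_repeat1, substitutions = substitutions,
         rotation_axis_jitter = rotation_axis_jitter,
         coordinate_jitter = coordinate_jitter, seed = seed,
         start_resno = start_resno, linker_length = linker_length,
         chain = chain),
    class = "dockerin_spec"
  )
}

# coordinating-residue offsets of the fixture's calcium loop
FIXTURE_CA_OFFSETS <- c(0, 2, 4, 11)

#' Generate an idealized dockerin with exact internal two-fold symmetry
#'
#' Repeat 1 is built as an extended calcium loop followed by an ideal
#' alpha-helix (phi = -57, psi = -47); repeat 2 is an exact copy rotated
#' 180 degrees about a two-fold axis perpendicular to the helix. Each
#' repeat carries a placed Ca2+ ion coordinated by side-chain oxygens of
#' the residues at offsets \{0, 2, 4, 11\} from the loop anchor plus one
#' water. Self-clashing geometry (non-bonded atoms closer than 1.5 Å)
#' raises an error.
#'
#' @param spec a [dockerin_spec()] without substitutions.
#' @return atom tibble of the dockerin chain with its ions and waters.
#' @export
make_symmetric_dockerin <- function(spec = dockerin_spec()) {
  if (length(spec$substitutions) > 0) {
    abort("symmetric fixture takes no substitutions; use make_asymmetric_dockerin()")
  }
  build_dockerin_fixture(spec)
}

#' Generate a dockerin whose second repeat breaks the two-fold symmetry
#'
#' As [make_symmetric_dockerin()], then replaces the symmetry mates of the
#' stated repeat-1 positions in repeat 2 with other residues (idealized
#' side-chain geometry), emulating a single-binding-mode dockerin whose
#' rotated face carries incompatible residues.
#'
#' @param spec a [dockerin_spec()] with at least one substitution.
#' @return atom tibble.
#' @export
make_asymmetric_dockerin <- function(spec) {
  if (length(spec$substitutions) == 0) {
    abort("asymmetric fixture requires at least one substitution")
  }
  build_dockerin_fixture(spec)
}

build_dockerin_fixture <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  loop_len <- spec$repeat_length - spec$helix_length
  phi <- c(rep(-120, loop_len), rep(-57, spec$helix_length))
  psi <- c(rep(120, loop_len), rep(-47, spec$helix_length))
  rep1 <- build_peptide(spec$sequence_repeat1, phi = phi, psi = psi,
                        chain = spec$chain, start_resno = spec$start_resno)

  anchor <- spec$start_resno + 1
  coord_res <- anchor + FIXTURE_CA_OFFSETS
  site1 <- place_calcium_site(rep1, coord_res, ion_resno = 201,
                              wat_resno = 301, chain = spec$chain)
  rep1 <- site1$structure

  # two-fold axis perpendicular to the helix, offset so the repeats sit
  # side by side without clashing
  hx_first <- spec$start_resno + loop_len
  hx_last <- spec$start_resno + spec$repeat_length - 1
  ca_of <- function(st, rn) {
    r <- st[st$resno == rn & st$elety == "CA" & st$type == "ATOM", ]
    c(r$x[1], r$y[1], r$z[1])
  }
  w <- unit(ca_of(rep1, hx_last) - ca_of(rep1, hx_first))
  h <- (ca_of(rep1, hx_last) + ca_of(rep1, hx_first)) / 2
  e <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- unit(pracma_cross(w, e))
  u <- unit(pracma_cross(a, w))
  # keep repeat 2 on the side opposite the first calcium ion so the two
  # sites stay cleanly separated
  ion1 <- rep1[rep1$type == "HETATM" & rep1$resid == "CA", ]
  if (nrow(ion1) && sum(u * (c(ion1$x[1], ion1$y[1], ion1$z[1]) - h)) > 0) {
    u <- -u
  }
  centre <- h + 8.0 * u
  R <- rotation_about_axis(a, 180)
  if (spec$rotation_axis_jitter > 0) {
    jit_axis <- unit(rnorm(3))
    R <- rotation_about_axis(jit_axis,
                             rnorm(1, 0, spec$rotation_axis_jitter)) %*% R
  }
  offset <- spec$repeat_length + spec$linker_length
  rep2 <- rep1
  xyz <- as.matrix(rep2[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, centre) %*% t(R), 2, -centre)
  rep2$x <- xyz[, 1]; rep2$y <- xyz[, 2]; rep2$z <- xyz[, 3]
  rep2$resno <- rep2$resno + ifelse(rep2$type == "ATOM", offset,
                                    ifelse(rep2$resid == "CA", 1, 1))

  # apply substitutions to repeat-2 side chains
  for (s in spec$substitutions) {
    pos2 <- as.numeric(s[[1]]) + offset
    new3 <- AA_ONE_TO_THREE[[toupper(s[[2]])]]
    res <- rep2[rep2$resno == pos2 & rep2$type == "ATOM", ]
    bb <- res[res$elety %in% c("N", "CA", "C", "O"), ]
    pos <- list(N = c(bb$x[bb$elety == "N"], bb$y[bb$elety == "N"],
                      bb$z[bb$elety == "N"]),
                CA = c(bb$x[bb$elety == "CA"], bb$y[bb$elety == "CA"],
                       bb$z[bb$elety == "CA"]),
                C = c(bb$x[bb$elety == "C"], bb$y[bb$elety == "C"],
                      bb$z[bb$elety == "C"]),
                O = c(bb$x[bb$elety == "O"], bb$y[bb$elety == "O"],
                      bb$z[bb$elety == "O"]))
    pos <- grow_sidechain(new3, pos)
    newrows <- NULL
    for (nm in names(pos)) {
      p <- pos[[nm]]
      newrows <- bind_rows(newrows, tibble(
        type = "ATOM", elety = nm, resid = new3, chain = spec$chain,
        resno = pos2, x = p[1], y = p[2], z = p[3],
        elesy = substr(nm, 1, 1)
      ))
    }
    rep2 <- bind_rows(rep2[!(rep2$resno == pos2 & rep2$type == "ATOM"), ],
                      finalize_structure(newrows))
  }

  out <- bind_rows(rep1, rep2)
  # clash validation runs on the ideal geometry; coordinate jitter is a
  # deliberate perturbation applied afterwards
  check_clashes(out)
  if (spec$coordinate_jitter > 0) {
    prot <- out$type == "ATOM"
    out$x[prot] <- out$x[prot] + rnorm(sum(prot), 0, spec$coordinate_jitter)
    out$y[prot] <- out$y[prot] + rnorm(sum(prot), 0, spec$coordinate_jitter)
    out$z[prot] <- out$z[prot] + rnorm(sum(prot), 0, spec$coordinate_jitter)
  }
  out <- out |>
    arrange(.data$type != "ATOM", .data$resno) |>
    mutate(eleno = row_number())
  out
}

# place a calcium ion near the designated residues' CB centroid, pushed
# outward until no unintended protein O/N lies inside the cutoff, then pin
# each coordinating residue's terminal oxygen (and one water) at 2.4 A
place_calcium_site <- function(st, coord_res, ion_resno, wat_resno, chain) {
  terminal_o <- c(ASP = "OD1", SER = "OG", THR = "OG1", ASN = "OD1",
                  GLU = "OE1", GLN = "OE1", TYR = "OH")
  prot <- st[st$type == "ATOM", ]
  cb <- prot[prot$resno %in% coord_res & prot$elety == "CB", ]
  if (nrow(cb) < length(coord_res)) {
    abort("coordinating residues must have side chains (no Gly)")
  }
  cb_cen <- c(mean(cb$x), mean(cb$y), mean(cb$z))
  ca_all <- prot[prot$elety == "CA", ]
  mol_cen <- c(mean(ca_all$x), mean(ca_all$y), mean(ca_all$z))
  outward <- unit(cb_cen - mol_cen)
  lig_names <- terminal_o[prot$resid[match(coord_res, prot$resno)]]
  # search directions near `outward` (then further afield) for a position
  # with no unintended protein O/N inside the coordination cutoff
  o2 <- unit(pracma_cross(outward,
                          if (abs(outward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  o3 <- pracma_cross(outward, o2)
  cand_dirs <- rbind(outward,
                     t(vapply(seq(0, 315, by = 45), function(th) {
                       unit(outward + cos(th * pi / 180) * o2 +
                              sin(th * pi / 180) * o3)
                     }, numeric(3))),
                     o2, -o2, o3, -o3)
  other <- prot[!(prot$resno %in% coord_res &
                    prot$elety %in% unname(lig_names)), ]
  on <- other[substr(other$elesy, 1, 1) %in% c("O", "N"), ]
  ion <- NULL
  for (push in seq(2.5, 9, by = 0.25)) {
    for (di in seq_len(nrow(cand_dirs))) {
      cand <- cb_cen + push * cand_dirs[di, ]
      d <- sqrt((on$x - cand[1])^2 + (on$y - cand[2])^2 +
                  (on$z - cand[3])^2)
      if (all(d > 3.1)) { ion <- cand; break }
    }
    if (!is.null(ion)) break
  }
  if (is.null(ion)) abort("could not place a clean calcium site")
  # ligand oxygens sit on distinct octahedral/cube vertices around the ion
  # so they never collide with each other or the chain
  e1 <- outward
  e2 <- unit(pracma_cross(e1, if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e3 <- pracma_cross(e1, e2)
  frame <- rbind(e1, e2, e3)
  verts <- rbind(
    c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)) / sqrt(3)
  )
  verts <- as.matrix(verts) %*% frame   # rows are unit directions
  taken <- rep(FALSE, nrow(verts))
  all_xyz <- as.matrix(st[, c("x", "y", "z")])
  for (k in seq_along(coord_res)) {
    rn <- coord_res[k]
    resid <- prot$resid[match(rn, prot$resno)]
    oat <- terminal_o[[resid]]
    if (is.null(oat) || is.na(oat)) {
      abort(paste0("residue ", resid, " has no coordinating oxygen"))
    }
    sel <- st$resno == rn & st$elety == oat & st$type == "ATOM"
    if (!any(sel)) abort(paste0("atom ", oat, " missing in residue ", rn))
    cbp <- cb[cb$resno == rn, ]
    toward <- unit(c(cbp$x, cbp$y, cbp$z) - ion)
    score <- as.vector(verts %*% toward)
    placed <- FALSE
    for (vi in order(-score)) {
      if (taken[vi]) next
      tgt <- ion + 2.4 * verts[vi, ]
      dmin <- min(sqrt(rowSums(sweep(all_xyz[!sel, , drop = FALSE],
                                     2, tgt)^2)))
      if (dmin < 1.8) next
      st$x[sel] <- tgt[1]; st$y[sel] <- tgt[2]; st$z[sel] <- tgt[3]
      all_xyz[sel, ] <- matrix(tgt, sum(sel), 3, byrow = TRUE)
      taken[vi] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) abort("could not place a clean calcium ligand")
  }
  wat <- ion + 2.4 * e1
  extra <- tibble(
    type = "HETATM", eleno = 0L, elety = c("CA", "O"), alt = "",
    resid = c("CA", "HOH"), chain = chain,
    resno = c(ion_resno, wat_resno), insert = "",
    x = c(ion[1], wat[1]), y = c(ion[2], wat[2]), z = c(ion[3], wat[3]),
    o = 1, b = 0, elesy = c("CA", "O")
  )
  list(structure = bind_rows(st, extra), ion = ion)
}

check_clashes <- function(st, tol = 1.5) {
  xyz <- as.matrix(st[, c("x", "y", "z")])
  d2 <- pair_distances(st, st)
  near <- which(d2 < tol^2, arr.ind = TRUE)
  near <- near[near[, 1] < near[, 2], , drop = FALSE]
  if (nrow(near) == 0) return(invisible(TRUE))
  same_or_adjacent <- abs(st$resno[near[, 1]] - st$resno[near[, 2]]) <= 1
  if (any(!same_or_adjacent)) {
    abort("fixture geometry self-clash beyond tolerance")
  }
  invisible(TRUE)
}

#' Add a cohesin-like hydrophobic plateau facing the dockerin's helix-1
#'
#' Places a two-strand beta-ribbon slab parallel to helix-1 on the face
#' opposite repeat 2, with leucine side chains pinned within hydrophobic
#' contact range (4.0 Å) of the designated helix-1 positions, and
#' optionally a histidine whose ND1 is planted 2.9 Å beyond the hydroxyl
#' of a designated (non-calcium-coordinating) helix serine to give exactly
#' one polar contact.
#'
#' @param doc dockerin atom tibble from the fixture generators.
#' @param contact_positions repeat-1 auth numbers to pin hydrophobic
#'   contacts at (default 39 and 43 with the default spec frame).
#' @param polar_position auth number of the serine to pair with the planted
#'   histidine, or `NULL` for no polar plant.
#' @param spec the [dockerin_spec()] used to build `doc`.
#' @param chain chain identifier of the plateau.
#' @return combined atom tibble with the dockerin chain and the plateau
#'   chain.
#' @export
make_cohesin_plateau <- function(doc, contact_positions = c(39, 43),
                                 polar_position = 42,
                                 spec = dockerin_spec(), chain = "C") {
  loop_len <- spec$repeat_length - spec$helix_length
  hx_first <- spec$start_resno + loop_len
  hx_last <- spec$start_resno + spec$repeat_length - 1
  prot <- doc[doc$type == "ATOM", ]
  ca_of <- function(rn) {
    r <- prot[prot$resno == rn & prot$elety == "CA", ]
    c(r$x[1], r$y[1], r$z[1])
  }
  w <- unit(ca_of(hx_last) - ca_of(hx_first))
  h <- (ca_of(hx_last) + ca_of(hx_first)) / 2
  rep2_ca <- prot[prot$elety == "CA" &
                    prot$resno > spec$start_resno + spec$repeat_length, ]
  r2cen <- c(mean(rep2_ca$x), mean(rep2_ca$y), mean(rep2_ca$z))
  v <- unit(r2cen - h)

  # two extended leucine strands along the helix axis, 10 A out on the
  # face opposite repeat 2
  n_strand <- 8
  perp <- unit(pracma_cross(v, w))
  strand <- function(start_resno, lateral) {
    s <- build_peptide(strrep("L", n_strand), phi = -120, psi = 120,
                       chain = chain, start_resno = start_resno)
    cas <- s[s$elety == "CA", ]
    ax <- unit(c(cas$x[n_strand] - cas$x[1], cas$y[n_strand] - cas$y[1],
                 cas$z[n_strand] - cas$z[1]))
    b2 <- unit(pracma_cross(ax, c(cas$x[2] - cas$x[1], cas$y[2] - cas$y[1],
                                  cas$z[2] - cas$z[1]) + c(0.1, 0.2, 0.3)))
    S <- cbind(ax, b2, pracma_cross(ax, b2))
    Tm <- cbind(w, perp, pracma_cross(w, perp))
    R <- Tm %*% t(S)
    cen <- c(mean(cas$x), mean(cas$y), mean(cas$z))
    tgt <- h - 10 * v + lateral
    transform_coords(s, list(rotation = R,
                             translation = tgt - as.vector(R %*% cen)))
  }
  slab <- bind_rows(strand(1, -2.4 * perp), strand(101, 2.4 * perp))

  # pin leucine side chains at 4.0 A from the designated apolar tips;
  # each planted feature claims its own slab residue
  used_rn <- integer(0)
  for (p in contact_positions) {
    resid_p <- prot$resid[match(p, prot$resno)]
    tips <- APOLAR_CARBONS[[resid_p]]
    tip_at <- prot[prot$resno == p & prot$elety == tail(tips, 1), ]
    if (nrow(tip_at) == 0) {
      abort(paste0("contact position ", p, " has no apolar tip atom"))
    }
    tip <- c(tip_at$x[1], tip_at$y[1], tip_at$z[1])
    cas <- slab[slab$elety == "CA" & !slab$resno %in% used_rn, ]
    d <- sqrt((cas$x - tip[1])^2 + (cas$y - tip[2])^2 + (cas$z - tip[3])^2)
    near_rn <- cas$resno[which.min(d)]
    used_rn <- c(used_rn, near_rn)
    cap <- c(cas$x[which.min(d)], cas$y[which.min(d)], cas$z[which.min(d)])
    dirn <- unit(cap - tip)
    anchor <- tip + 4.0 * dirn
    for (nm in c("CB", "CG", "CD1", "CD2")) {
      sel <- slab$resno == near_rn & slab$elety == nm
      tgt <- switch(nm,
        CB = cap - 1.52 * dirn,
        CG = anchor + 1.52 * dirn,
        CD1 = anchor,
        CD2 = anchor + 1.5 * unit(pracma_cross(dirn, w))
      )
      slab$x[sel] <- tgt[1]; slab$y[sel] <- tgt[2]; slab$z[sel] <- tgt[3]
    }
  }

  # plant the Ser-OG / His-ND1 polar pair
  if (!is.null(polar_position)) {
    og <- prot[prot$resno == polar_position & prot$elety == "OG", ]
    if (nrow(og) == 0) {
      abort(paste0("polar_position ", polar_position, " has no OG atom"))
    }
    ogp <- c(og$x[1], og$y[1], og$z[1])
    cbs <- prot[prot$resno == polar_position & prot$elety == "CB", ]
    cas <- slab[slab$elety == "CA" & !slab$resno %in% used_rn, ]
    d <- sqrt((cas$x - ogp[1])^2 + (cas$y - ogp[2])^2 + (cas$z - ogp[3])^2)
    his_rn <- cas$resno[which.min(d)]
    cap <- c(cas$x[which.min(d)], cas$y[which.min(d)], cas$z[which.min(d)])
    # extend straight out along the serine's CB->OG bond so the histidine
    # side chain stays clear of the dockerin surface
    dirn <- unit(ogp - c(cbs$x[1], cbs$y[1], cbs$z[1]))
    nd1 <- ogp + 2.9 * dirn
    his <- tibble(
      type = "ATOM", elety = c("N", "CA", "C", "O", "CB", "CG", "ND1",
                               "CD2", "CE1", "NE2"),
      resid = "HIS", chain = chain, resno = his_rn,
      x = NA_real_, y = NA_real_, z = NA_real_, elesy = NA_character_
    )
    bb <- slab[slab$resno == his_rn & slab$elety %in% c("N", "CA", "C", "O"), ]
    coords <- list(
      N = c(bb$x[bb$elety == "N"], bb$y[bb$elety == "N"], bb$z[bb$elety == "N"]),
      CA = cap,
      C = c(bb$x[bb$elety == "C"], bb$y[bb$elety == "C"], bb$z[bb$elety == "C"]),
      O = c(bb$x[bb$elety == "O"], bb$y[bb$elety == "O"], bb$z[bb$elety == "O"]),
      CB = cap - 1.52 * dirn * 0.5 + 1.3 * unit(pracma_cross(dirn, w)),
      ND1 = nd1,
      CG = nd1 + 1.37 * dirn,
      CE1 = nd1 + 1.32 * unit(pracma_cross(dirn, w)),
      CD2 = nd1 + 2.2 * dirn + 1.1 * unit(pracma_cross(dirn, w)),
      NE2 = nd1 + 2.1 * dirn + 1.3 * unit(pracma_cross(dirn, w))
    )
    for (k in seq_len(nrow(his))) {
      p <- coords[[his$elety[k]]]
      his$x[k] <- p[1]; his$y[k] <- p[2]; his$z[k] <- p[3]
      his$elesy[k] <- substr(his$elety[k], 1, 1)
    }
    slab <- bind_rows(slab[slab$resno != his_rn, ], finalize_structure(his))
  }

  out <- bind_rows(doc, slab) |>
    mutate(eleno = row_number())
  out
}

#' Write a simulated ITC dataset file
#'
#' Simulates a titration (default protocol: 28 x 10 µL injections) and
#' writes it in the delimited ITC text format; byte-identical under a fixed
#' seed.
#'
#' @param params a [thermo_params()].
#' @param protocol an [itc_protocol()]; defaults to the standard schedule
#'   with the cell concentration chosen from `params$Ka` (c ~ 100).
#' @param noise_sd Gaussian heat noise, µcal.
#' @param seed integer seed.
#' @param path output path.
#' @return the dataset tibble, invisibly; the file is written to `path`.
#' @export
make_itc_dataset <- function(params, protocol = NULL, noise_sd = 0,
                             seed = NULL, path) {
  if (is.null(protocol)) protocol <- itc_protocol(Ka = params$Ka)
  ds <- simulate_titration(protocol, params, noise_sd = noise_sd,
                           seed = seed)
  write_itc(ds, path)
  invisible(ds)
}
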