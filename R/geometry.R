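#' Optimal rigid-body superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation between `R %*% p + t` and the target points
#' `Q`. Reflections are excluded: the returned rotation always has
#' determinant +1, so mirror images are never superposed onto each other.
#'
#' @param P n x 3 matrix of mobile coordinates (Å).
#' @param Q n x 3 matrix of target coordinates, row-paired with `P`.
#' @return An object of class `superposition`: a list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Å), `n_atoms` and `pairing`
#'   (`NULL` here; filled by [superpose_chains()]).
#' @seealso [superpose_chains()], [transform_coords()], [rotation_angle()]
#' @export
#' @examples
#' P <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(P, P)$rmsd
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3) {
    abort("P and Q must be n x 3 matrices of equal size")
  }
  n <- nrow(P)
  if (n < 3) abort("at least 3 paired points are required")
  if (!all(is.finite(P)) || !all(is.finite(Q))) {
    abort("coordinates must be finite")
  }
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  # degenerate (collinear) point sets have rank < 2 and no unique rotation
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2) {
    abort("degenerate point set: points are collinear or coincident")
  }
  C <- crossprod(Pc, Qc)              # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - as.vector(R %*% pc)
  diffs <- Qc - Pc %*% t(R)
  rmsd <- sqrt(sum(diffs^2) / n)
  structure(
    list(rotation = R, translation = t, rmsd = rmsd,
         n_atoms = n, pairing = NULL),
    class = "superposition"
  )
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix, or an atom tibble with `x`,`y`,`z`.
#' @param transform a `superposition` object or a list with `rotation` and
#'   `translation`.
#' @return Same shape as the input, transformed.
#' @export
transform_coords <- function(xyz, transform) {
  R <- transform$rotation; t <- transform$translation
  if (is.data.frame(xyz)) {
    m <- as.matrix(xyz[, c("x", "y", "z")]) %*% t(R)
    xyz$x <- m[, 1] + t[1]; xyz$y <- m[, 2] + t[2]; xyz$z <- m[, 3] + t[3]
    return(xyz)
  }
  sweep(as.matrix(xyz) %*% t(R), 2, -t)
}

#' Rotation angle of a transform, in degrees
#'
#' Computed from the trace of the rotation matrix; lies in \[0, 180\].
#'
#' @param transform a `superposition` object or 3 x 3 rotation matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(transform) {
  R <- if (is.matrix(transform)) transform else transform$rotation
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid-body superposition\n")
  cat(sprintf("  paired atoms: %d\n", x$n_atoms))
  cat(sprintf("  rmsd: %.3f Angstrom\n", x$rmsd))
  cat(sprintf("  rotation angle: %.1f degrees\n", rotation_angle(x)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.superposition <- function(x, ...) {
  if (is.null(x$pairing)) return(tibble())
  x$pairing
}

#' @exportS3Method generics::glance
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         rotation_angle = rotation_angle(x))
}

# global pairwise alignment with identity scoring and affine gaps;
# returns an integer map: for each residue index of a, the paired index of b
align_sequences <- function(seq_a, seq_b, gap_opening = 10,
                            gap_extension = 0.5) {
  alpha <- c(unname(AA_THREE_TO_ONE), "X")
  m <- matrix(-1, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- 1
  m["X", "X"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seq_a, collapse = "")),
    Biostrings::AAString(paste(seq_b, collapse = "")),
    substitutionMatrix = m, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global"
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- ib <- 0L
  map <- integer(0)
  pos_a <- integer(0)
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      pos_a <- c(pos_a, ia)
      map <- c(map, ib)
    }
  }
  tibble(idx_a = pos_a, idx_b = map)
}

#' Superpose one chain onto another
#'
#' Residue correspondence is built by global sequence alignment of the two
#' chains (identity scoring, affine gap penalties); only aligned residues
#' whose selected atoms are present in both chains contribute paired atoms,
#' which are then fitted with [kabsch_superpose()]. The mobile chain is
#' `chain_a` of `structure_a`; the transform maps it onto `chain_b` of
#' `structure_b`.
#'
#' @param structure_a,structure_b atom tibbles.
#' @param chain_a,chain_b chain identifiers (mobile, target).
#' @param atoms `"CA"` (alpha-carbons, default) or `"mainchain"`
#'   (N, CA, C, O).
#' @return A `superposition` object whose `pairing` tibble lists the paired
#'   residues and atoms.
#' @export
superpose_chains <- function(structure_a, chain_a, structure_b, chain_b,
                             atoms = c("CA", "mainchain")) {
  atoms <- match.arg(atoms)
  atom_set <- if (atoms == "CA") "CA" else c("N", "CA", "C", "O")
  keys_a <- polymer_residues(structure_a, chain_a)
  keys_b <- polymer_residues(structure_b, chain_b)
  seq_a <- aa_three_to_one(keys_a$resid)
  seq_b <- aa_three_to_one(keys_b$resid)
  map <- align_sequences(seq_a, seq_b)
  pairing <- NULL
  P <- Q <- NULL
  for (k in seq_len(nrow(map))) {
    ra <- keys_a[map$idx_a[k], ]; rb <- keys_b[map$idx_b[k], ]
    at_a <- filter(structure_a, .data$chain == chain_a,
                   .data$resno == ra$resno, .data$insert == ra$insert,
                   .data$elety %in% atom_set)
    at_b <- filter(structure_b, .data$chain == chain_b,
                   .data$resno == rb$resno, .data$insert == rb$insert,
                   .data$elety %in% atom_set)
    shared <- intersect(at_a$elety, at_b$elety)
    if (length(shared) == 0) next
    at_a <- at_a[match(shared, at_a$elety), ]
    at_b <- at_b[match(shared, at_b$elety), ]
    P <- rbind(P, as.matrix(at_a[, c("x", "y", "z")]))
    Q <- rbind(Q, as.matrix(at_b[, c("x", "y", "z")]))
    pairing <- bind_rows(pairing, tibble(
      resno_a = ra$resno, resid_a = ra$resid,
      resno_b = rb$resno, resid_b = rb$resid, elety = shared
    ))
  }
  if (is.null(P) || nrow(P) < 3) {
    abort("alignment yields fewer than 3 paired atoms")
  }
  sup <- kabsch_superpose(P, Q)
  sup$pairing <- pairing
  sup$atoms <- atoms
  sup
}
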