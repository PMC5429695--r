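#' Default geometric criteria for the interface and calcium detectors
#'
#' @param hbond_cutoff donor-acceptor heavy-atom distance, Å.
#' @param hbond_angle_min minimum antecedent-donor-acceptor angle, degrees.
#' @param salt_bridge_cutoff distance for charged-pair tagging, Å.
#' @param hydrophobic_cutoff carbon-carbon distance, Å.
#' @param ca_ligand_cutoff calcium-ligand distance, Å.
#' @param temperature temperature for thermodynamic identities, K.
#' @param classes residue class table, see [residue_classes()].
#' @return named list of criteria.
#' @export
analysis_config <- function(hbond_cutoff = 3.5, hbond_angle_min = 90,
                            salt_bridge_cutoff = 4.0,
                            hydrophobic_cutoff = 4.5,
                            ca_ligand_cutoff = 3.0,
                            temperature = 308,
                            classes = residue_classes()) {
  cfg <- list(hbond_cutoff = hbond_cutoff, hbond_angle_min = hbond_angle_min,
              salt_bridge_cutoff = salt_bridge_cutoff,
              hydrophobic_cutoff = hydrophobic_cutoff,
              ca_ligand_cutoff = ca_ligand_cutoff,
              temperature = temperature, classes = classes)
  num <- unlist(cfg[1:6])
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all cutoffs and the temperature must be positive")
  }
  cfg
}

# donor atoms of one chain's protein residues: donor atom row plus the
# coordinates of its antecedent(s)
donor_table <- function(structure, chain) {
  st <- filter(structure, .data$chain == !!chain,
               .data$resid %in% names(AA_THREE_TO_ONE))
  out <- NULL
  for (i in seq_len(nrow(st))) {
    a <- st[i, ]
    ante <- NULL
    if (a$elety == "N" && a$resid != "PRO") {
      ante <- "CA"
    } else {
      d <- SIDECHAIN_DONORS[[a$resid]]
      if (!is.null(d) && a$elety %in% names(d)) ante <- d[[a$elety]]
    }
    if (is.null(ante)) next
    ant <- st[st$resno == a$resno & st$insert == a$insert &
                st$elety %in% ante, c("x", "y", "z")]
    out <- bind_rows(out, mutate(a, antecedents = list(as.matrix(ant))))
  }
  out
}

acceptor_table <- function(structure, chain) {
  st <- filter(structure, .data$chain == !!chain,
               .data$resid %in% names(AA_THREE_TO_ONE))
  keep <- st$elety %in% c("O", "OXT")
  for (res in names(SIDECHAIN_ACCEPTORS)) {
    keep <- keep | (st$resid == res & st$elety %in% SIDECHAIN_ACCEPTORS[[res]])
  }
  st[keep, ]
}

charged_atoms <- function(structure, chain, sign) {
  tab <- if (sign > 0) CHARGED_POSITIVE else CHARGED_NEGATIVE
  st <- filter(structure, .data$chain == !!chain)
  keep <- rep(FALSE, nrow(st))
  for (res in names(tab)) {
    keep <- keep | (st$resid == res & st$elety %in% tab[[res]])
  }
  st[keep, ]
}

vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cs))) * 180 / pi
}

pair_distances <- function(A, B) {
  ax <- structure_xyz(A); bx <- structure_xyz(B)
  outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
}

contact_row <- function(a, b, distance, kind) {
  tibble(
    kind = kind,
    chain_a = a$chain, resno_a = a$resno, resid_a = a$resid,
    elety_a = a$elety,
    chain_b = b$chain, resno_b = b$resno, resid_b = b$resid,
    elety_b = b$elety,
    distance = distance
  )
}

# directional donor->acceptor search between two atom tables
polar_pairs_one_way <- function(don, acc, cutoff, angle_min) {
  out <- NULL
  if (is.null(don) || nrow(don) == 0 || nrow(acc) == 0) return(out)
  d2 <- pair_distances(don, acc)
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, 1]; j <- hits[r, 2]
    dp <- c(don$x[i], don$y[i], don$z[i])
    ap <- c(acc$x[j], acc$y[j], acc$z[j])
    ant <- don$antecedents[[i]]
    ok <- TRUE
    if (!is.null(ant) && nrow(ant) > 0) {
      angs <- apply(ant, 1, function(p) vec_angle(p, dp, ap))
      ok <- any(angs >= angle_min)
    }
    if (!ok) next
    out <- bind_rows(out, contact_row(don[i, ], acc[j, ],
                                      sqrt(max(d2[i, j], 0)), "hbond"))
  }
  out
}

#' Detect polar contacts (hydrogen bonds and salt bridges) between chains
#'
#' Heavy-atom criterion: a donor and an acceptor on different chains within
#' `hbond_cutoff` (default 3.5 Å) with an antecedent-donor-acceptor angle of
#' at least `hbond_angle_min` (default 90 degrees) for at least one covalent
#' antecedent. Donor/acceptor capacity comes from a fixed per-residue table
#' (His ND1/NE2 and the Ser/Thr/Tyr hydroxyls act as both). Pairs where both
#' atoms carry formal charge (Lys/Arg N+ vs Asp/Glu O-) within
#' `salt_bridge_cutoff` (default 4.0 Å) are tagged `salt_bridge`; a salt
#' bridge is a sub-classification, not an extra contact.
#'
#' @param structure atom tibble.
#' @param chain_a,chain_b the two chains.
#' @param config criteria from [analysis_config()].
#' @return tibble of contacts: `kind`, atom identity on both sides
#'   (`chain_*`, `resno_*`, `resid_*`, `elety_*`) and `distance` (Å).
#'   `_a` columns always refer to `chain_a`.
#' @export
detect_polar_contacts <- function(structure, chain_a, chain_b,
                                  config = analysis_config()) {
  for (ch in c(chain_a, chain_b)) {
    if (!any(structure$chain == ch)) abort(paste0("unknown chain '", ch, "'"))
  }
  don_a <- donor_table(structure, chain_a)
  don_b <- donor_table(structure, chain_b)
  acc_a <- acceptor_table(structure, chain_a)
  acc_b <- acceptor_table(structure, chain_b)
  ab <- polar_pairs_one_way(don_a, acc_b, config$hbond_cutoff,
                            config$hbond_angle_min)
  ba <- polar_pairs_one_way(don_b, acc_a, config$hbond_cutoff,
                            config$hbond_angle_min)
  if (!is.null(ba) && nrow(ba) > 0) {
    ba <- tibble(
      kind = ba$kind,
      chain_a = ba$chain_b, resno_a = ba$resno_b, resid_a = ba$resid_b,
      elety_a = ba$elety_b,
      chain_b = ba$chain_a, resno_b = ba$resno_a, resid_b = ba$resid_a,
      elety_b = ba$elety_a, distance = ba$distance
    )
  }
  contacts <- bind_rows(ab, ba)
  # charged pairs up to the (larger) salt-bridge cutoff
  sb <- NULL
  for (sgn in c(1, -1)) {
    pos <- charged_atoms(structure, chain_a, sgn)
    neg <- charged_atoms(structure, chain_b, -sgn)
    if (nrow(pos) == 0 || nrow(neg) == 0) next
    d2 <- pair_distances(pos, neg)
    hits <- which(d2 <= config$salt_bridge_cutoff^2, arr.ind = TRUE)
    for (r in seq_len(nrow(hits))) {
      sb <- bind_rows(sb, contact_row(pos[hits[r, 1], ], neg[hits[r, 2], ],
                                      sqrt(max(d2[hits[r, 1], hits[r, 2]], 0)),
                                      "salt_bridge"))
    }
  }
  contacts <- bind_rows(contacts, sb)
  if (is.null(contacts) || nrow(contacts) == 0) {
    return(tibble(kind = character(0), chain_a = character(0),
                  resno_a = integer(0), resid_a = character(0),
                  elety_a = character(0), chain_b = character(0),
                  resno_b = integer(0), resid_b = character(0),
                  elety_b = character(0), distance = numeric(0)))
  }
  # unique atom pairs; salt_bridge wins over hbond for the same pair
  contacts |>
    mutate(kind = factor(.data$kind, levels = c("salt_bridge", "hbond"))) |>
    arrange(.data$kind) |>
    distinct(.data$chain_a, .data$resno_a, .data$elety_a,
             .data$chain_b, .data$resno_b, .data$elety_b,
             .keep_all = TRUE) |>
    mutate(kind = as.character(.data$kind)) |>
    arrange(.data$resno_a, .data$elety_a, .data$resno_b)
}

#' Detect hydrophobic contacts between chains
#'
#' Carbon-carbon pairs within `hydrophobic_cutoff` (default 4.5 Å) where both
#' carbons are apolar (aliphatic or aromatic carbons not bonded to N/O, from
#' a fixed per-residue table). Reported at residue-pair granularity with the
#' minimum atomic distance; the atom-level pairs are kept in the
#' `atom_pairs` attribute.
#'
#' @inheritParams detect_polar_contacts
#' @return tibble with one row per residue pair: `chain_a`, `resno_a`,
#'   `resid_a`, `chain_b`, `resno_b`, `resid_b`, `min_distance`,
#'   `n_atom_pairs`.
#' @export
detect_hydrophobic_contacts <- function(structure, chain_a, chain_b,
                                        config = analysis_config()) {
  for (ch in c(chain_a, chain_b)) {
    if (!any(structure$chain == ch)) abort(paste0("unknown chain '", ch, "'"))
  }
  apolar <- function(chain) {
    st <- filter(structure, .data$chain == !!chain)
    keep <- rep(FALSE, nrow(st))
    for (res in names(APOLAR_CARBONS)) {
      keep <- keep | (st$resid == res & st$elety %in% APOLAR_CARBONS[[res]])
    }
    st[keep, ]
  }
  A <- apolar(chain_a); B <- apolar(chain_b)
  empty <- tibble(chain_a = character(0), resno_a = integer(0),
                  resid_a = character(0), chain_b = character(0),
                  resno_b = integer(0), resid_b = character(0),
                  min_distance = numeric(0), n_atom_pairs = integer(0))
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  d2 <- pair_distances(A, B)
  hits <- which(d2 <= config$hydrophobic_cutoff^2, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  atom_pairs <- tibble(
    chain_a = A$chain[hits[, 1]], resno_a = A$resno[hits[, 1]],
    resid_a = A$resid[hits[, 1]], elety_a = A$elety[hits[, 1]],
    chain_b = B$chain[hits[, 2]], resno_b = B$resno[hits[, 2]],
    resid_b = B$resid[hits[, 2]], elety_b = B$elety[hits[, 2]],
    distance = sqrt(pmax(d2[hits], 0))
  )
  out <- atom_pairs |>
    group_by(.data$chain_a, .data$resno_a, .data$resid_a,
             .data$chain_b, .data$resno_b, .data$resid_b) |>
    summarise(min_distance = min(.data$distance),
              n_atom_pairs = n(), .groups = "drop") |>
    arrange(.data$resno_a, .data$resno_b)
  attr(out, "atom_pairs") <- atom_pairs
  out
}

#' Combined interface report grouped by dockerin helix
#'
#' Runs the polar and hydrophobic detectors between a dockerin chain and a
#' cohesin chain and tags every contact `H1`, `H3` or `other` by the
#' dockerin residue's helix membership.
#'
#' @param structure atom tibble.
#' @param doc_chain,coh_chain dockerin and cohesin chain identifiers.
#' @param helix_ranges list with numeric `helix1 = c(start, end)` and
#'   `helix3 = c(start, end)` in dockerin auth numbering (e.g. from
#'   [segment_repeats()]).
#' @param config criteria from [analysis_config()].
#' @return An object of class `interface_report`: list with `polar` and
#'   `hydrophobic` contact tibbles (each with a `helix` column), `counts`
#'   (tibble of contact counts per kind) and `helix_counts` (per tag).
#' @export
interface_report <- function(structure, doc_chain, coh_chain, helix_ranges,
                             config = analysis_config()) {
  tag <- function(resno) {
    h1 <- helix_ranges$helix1; h3 <- helix_ranges$helix3
    dplyr::case_when(
      !is.null(h1) & resno >= h1[1] & resno <= h1[2] ~ "H1",
      !is.null(h3) & resno >= h3[1] & resno <= h3[2] ~ "H3",
      TRUE ~ "other"
    )
  }
  polar <- detect_polar_contacts(structure, doc_chain, coh_chain, config)
  hydro <- detect_hydrophobic_contacts(structure, doc_chain, coh_chain, config)
  polar$helix <- if (nrow(polar)) tag(polar$resno_a) else character(0)
  hydro$helix <- if (nrow(hydro)) tag(hydro$resno_a) else character(0)
  kinds <- c(table(factor(polar$kind, levels = c("hbond", "salt_bridge"))))
  counts <- tibble(
    kind = c("hbond", "salt_bridge", "hydrophobic"),
    n = c(unname(kinds), nrow(hydro))
  )
  tags <- factor(c(polar$helix, hydro$helix), levels = c("H1", "H3", "other"))
  helix_counts <- tibble(helix = levels(tags), n = c(unname(table(tags))))
  structure(
    list(polar = polar, hydrophobic = hydro, counts = counts,
         helix_counts = helix_counts, doc_chain = doc_chain,
         coh_chain = coh_chain, config = config),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface %s (dockerin) vs %s (cohesin)\n",
              x$doc_chain, x$coh_chain))
  cat("  contacts:", paste(x$counts$kind, x$counts$n, sep = "=",
                           collapse = " "), "\n")
  cat("  by helix:", paste(x$helix_counts$helix, x$helix_counts$n,
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write an interface report's polar contacts as a TSV table
#'
#' Column layout mirrors the conventional published polar-contact tables:
#' dockerin atom/residue/number, a separator, cohesin atom/residue/number
#' and the helix tag.
#'
#' @param report an `interface_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(report, path) {
  p <- report$polar
  out <- tibble(
    helix = p$helix, atom_doc = p$elety_a, residue_doc = p$resid_a,
    resno_doc = p$resno_a, sep = "<>", atom_coh = p$elety_b,
    residue_coh = p$resid_b, resno_coh = p$resno_b,
    kind = p$kind, distance = round(p$distance, 2)
  )
  readr::write_tsv(out, path)
  invisible(path)
}
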