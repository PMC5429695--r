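# Main-chain hydrogen-bond secondary-structure assignment in the
# Kabsch-Sander style: the amide hydrogen is reconstructed from the
# preceding carbonyl, bond energies follow the electrostatic model
# E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol,
# and a bond is called below -0.5 kcal/mol.

HB_ENERGY_CUTOFF <- -0.5

# backbone geometry of one chain: one row per residue with N/CA/C/O and the
# reconstructed amide H; residues missing main-chain atoms are dropped
backbone_frame <- function(structure, chain) {
  st <- filter(structure, .data$chain == !!chain, .data$type == "ATOM",
               .data$elety %in% c("N", "CA", "C", "O"))
  keys <- polymer_residues(structure, chain)
  get <- function(resno, insert, name) {
    r <- st[st$resno == resno & st$insert == insert & st$elety == name, ]
    if (nrow(r) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(r$x[1], r$y[1], r$z[1])
  }
  n <- nrow(keys)
  arr <- array(NA_real_, dim = c(n, 4, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  for (i in seq_len(n)) {
    for (a in c("N", "CA", "C", "O")) {
      arr[i, a, ] <- get(keys$resno[i], keys$insert[i], a)
    }
  }
  complete <- apply(arr, 1, function(m) all(is.finite(m)))
  H <- matrix(NA_real_, n, 3)
  for (i in 2:max(n, 2)) {
    if (i > n) break
    consecutive <- keys$resno[i] == keys$resno[i - 1] + 1 &&
      keys$insert[i] == "" && keys$insert[i - 1] == ""
    if (!consecutive || !complete[i] || !complete[i - 1]) next
    if (keys$resid[i] == "PRO") next
    co <- arr[i - 1, "C", ] - arr[i - 1, "O", ]
    H[i, ] <- arr[i, "N", ] + co / sqrt(sum(co^2))
  }
  list(keys = keys, xyz = arr, H = H, complete = complete)
}

# hb[i, j]: C=O of residue i accepts a hydrogen bond from N-H of residue j
hbond_matrix <- function(bf) {
  n <- nrow(bf$keys)
  hb <- matrix(FALSE, n, n)
  donors <- which(apply(bf$H, 1, function(h) all(is.finite(h))))
  acceptors <- which(bf$complete)
  for (j in donors) {
    Nj <- bf$xyz[j, "N", ]; Hj <- bf$H[j, ]
    for (i in acceptors) {
      if (abs(i - j) < 2) next
      Oi <- bf$xyz[i, "O", ]; Ci <- bf$xyz[i, "C", ]
      rON <- sqrt(sum((Oi - Nj)^2))
      if (rON > 5.2) next
      rCH <- sqrt(sum((Ci - Hj)^2))
      rOH <- sqrt(sum((Oi - Hj)^2))
      rCN <- sqrt(sum((Ci - Nj)^2))
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (E < HB_ENERGY_CUTOFF) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign secondary structure from main-chain hydrogen bonds
#'
#' Labels each residue `H` (alpha-helix), `E` (beta-strand) or `C` (coil)
#' from the pattern of main-chain hydrogen bonds: helices from runs of
#' i -> i+4 turns, strands from parallel/antiparallel bridge ladders.
#' Strand segments of length >= 2 are numbered in sequence order and
#' grouped into sheets by transitive bridge pairing. Residues with missing
#' main-chain atoms are labelled `C` with a warning.
#'
#' @param structure atom tibble.
#' @param chain chain identifier.
#' @return An object of class `secondary_structure`: list with `residues`
#'   (tibble: `resno`, `resid`, `ss`), `strands` (tibble: `strand`,
#'   `start`, `end`), `sheets` (list of integer vectors of strand indices
#'   in spatial order) and `helices` (tibble: `start`, `end`).
#' @export
assign_secondary_structure <- function(structure, chain) {
  bf <- backbone_frame(structure, chain)
  n <- nrow(bf$keys)
  if (sum(bf$complete) < 5) {
    abort("chain needs main-chain N, CA, C, O for at least 5 residues")
  }
  if (any(!bf$complete)) {
    warn(sprintf("%d residue(s) missing main-chain atoms; labelled C",
                 sum(!bf$complete)))
  }
  hb <- hbond_matrix(bf)
  ss <- rep("C", n)

  # helices: two consecutive i -> i+4 turns make residues i..i+3 helical
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n - 4)) turn4[i] <- hb[i, i + 4]
  for (i in 2:max(n - 4, 2)) {
    if (i > n - 4) break
    if (turn4[i - 1] && turn4[i]) ss[i:(i + 3)] <- "H"
  }

  # bridges
  bridge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 3) next
      anti <- (hb[i, j] && hb[j, i]) ||
        (i > 1 && j < n && i + 1 <= n && j - 1 >= 1 &&
           hb[i - 1, j + 1] && hb[j - 1, i + 1])
      par <- (i > 1 && i + 1 <= n && hb[i - 1, j] && hb[j, i + 1]) ||
        (j > 1 && j + 1 <= n && hb[j - 1, i] && hb[i, j + 1])
      if (anti || par) bridge[i, j] <- bridge[j, i] <- TRUE
    }
  }
  is_bridge <- apply(bridge, 1, any)
  ss[is_bridge & ss != "H"] <- "E"
  ss[!bf$complete] <- "C"   # incomplete backbone cannot carry a label

  # strand segments: maximal E runs of length >= 2 (singletons demoted)
  runs <- rle(ss == "E")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- NULL
  for (k in seq_along(runs$values)) {
    if (runs$values[k] && runs$lengths[k] >= 2) {
      seg <- bind_rows(seg, tibble(start_idx = starts[k], end_idx = ends[k]))
    } else if (runs$values[k]) {
      ss[starts[k]:ends[k]] <- "C"
    }
  }
  strands <- tibble(strand = integer(0), start = integer(0), end = integer(0))
  strand_of <- rep(NA_integer_, n)
  if (!is.null(seg)) {
    strands <- tibble(
      strand = seq_len(nrow(seg)),
      start = bf$keys$resno[seg$start_idx],
      end = bf$keys$resno[seg$end_idx]
    )
    for (k in seq_len(nrow(seg))) {
      strand_of[seg$start_idx[k]:seg$end_idx[k]] <- k
    }
  }

  # strand pairing graph from bridges
  ns <- nrow(strands)
  adj <- matrix(FALSE, ns, ns)
  if (ns > 1) {
    idx <- which(bridge, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      si <- strand_of[idx[r, 1]]; sj <- strand_of[idx[r, 2]]
      if (!is.na(si) && !is.na(sj) && si != sj) adj[si, sj] <- adj[sj, si] <- TRUE
    }
  }
  sheets <- sheet_components(adj)

  hel <- NULL
  runs <- rle(ss == "H")
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) {
      hel <- bind_rows(hel, tibble(start = bf$keys$resno[starts[k]],
                                   end = bf$keys$resno[ends[k]]))
    }
  }
  structure(
    list(
      residues = tibble(resno = bf$keys$resno, resid = bf$keys$resid, ss = ss),
      strands = strands,
      sheets = sheets,
      helices = if (is.null(hel)) tibble(start = integer(0), end = integer(0)) else hel,
      adjacency = adj
    ),
    class = "secondary_structure"
  )
}

# connected components of the strand pairing graph, each ordered by walking
# the adjacency path from a terminal strand
sheet_components <- function(adj) {
  ns <- nrow(adj)
  if (ns == 0) return(list())
  seen <- rep(FALSE, ns)
  sheets <- list()
  for (s in seq_len(ns)) {
    if (seen[s] || !any(adj[s, ])) next
    comp <- s
    frontier <- s
    while (length(frontier)) {
      nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2, any)), comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    seen[comp] <- TRUE
    deg <- rowSums(adj[comp, comp, drop = FALSE])
    start <- comp[which.min(ifelse(deg == 1, 0, deg))]
    ordered <- start
    repeat {
      nbrs <- setdiff(which(adj[tail(ordered, 1), ]), ordered)
      nbrs <- intersect(nbrs, comp)
      if (length(nbrs) == 0) break
      ordered <- c(ordered, nbrs[1])
    }
    # append any strands not reached by the simple walk (branched sheets)
    ordered <- c(ordered, setdiff(comp, ordered))
    sheets[[length(sheets) + 1]] <- ordered
  }
  sheets
}

#' Ordered strand composition of each sheet
#'
#' Strands are indexed 1..n in sequence order; each sheet is reported as the
#' ordered list of strand indices along the sheet's spatial adjacency.
#'
#' @param ss a `secondary_structure` object.
#' @return list of integer vectors (empty when no strands pair).
#' @export
sheet_topology <- function(ss) {
  ss$sheets
}

#' @export
print.secondary_structure <- function(x, ...) {
  tab <- table(factor(x$residues$ss, levels = c("H", "E", "C")))
  cat("Secondary structure: ", paste(names(tab), tab, sep = "=",
                                     collapse = " "), "\n")
  cat(sprintf("  %d strand(s), %d helix(ces), %d sheet(s)\n",
              nrow(x$strands), nrow(x$helices), length(x$sheets)))
  invisible(x)
}
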