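# Per-residue chemistry tables used by the contact detectors and the
# symmetry compatibility calls. Heavy atoms only: the crystal structures
# carry no hydrogens, so donor capacity is judged from the donor heavy atom
# and its covalent antecedent(s).

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Residue chemical classes used for symmetry-mate compatibility
#'
#' One-letter residue codes grouped into nonpolar, polar, positively and
#' negatively charged classes. Two symmetry-related residues are called
#' `conserved` when identical, `compatible` when they share a class and
#' `incompatible` otherwise. Glycine is grouped with the polar (small,
#' flexible) residues. The table is an argument to the symmetry functions
#' and can be replaced wholesale.
#'
#' @return Named list of character vectors with elements `nonpolar`,
#'   `polar`, `positive`, `negative`.
#' @export
#' @examples
#' residue_classes()$nonpolar
residue_classes <- function() {
  list(
    nonpolar = c("A", "V", "L", "I", "M", "F", "W", "C", "P"),
    polar    = c("S", "T", "N", "Q", "Y", "H", "G"),
    positive = c("K", "R"),
    negative = c("D", "E")
  )
}

# Side-chain hydrogen-bond donors: donor atom -> covalent antecedent(s).
# Main-chain N (antecedent CA) is added for every residue except proline.
SIDECHAIN_DONORS <- list(
  SER = list(OG  = "CB"),
  THR = list(OG1 = "CB"),
  TYR = list(OH  = "CZ"),
  ASN = list(ND2 = "CG"),
  GLN = list(NE2 = "CD"),
  LYS = list(NZ  = "CE"),
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = list(ND1 = c("CG", "CE1"), NE2 = c("CD2", "CE1")),
  TRP = list(NE1 = c("CD1", "CE2")),
  CYS = list(SG  = "CB")
)

# Side-chain hydrogen-bond acceptors.
SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = "OD1",
  GLN = "OE1",
  SER = "OG",
  THR = "OG1",
  TYR = "OH",
  HIS = c("ND1", "NE2")
)

# Formally charged atoms (physiological pH) for salt-bridge tagging.
CHARGED_POSITIVE <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
CHARGED_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Apolar carbons: aliphatic/aromatic carbons not covalently bonded to N or O.
APOLAR_CARBONS <- list(
  ALA = "CB",
  ARG = c("CB", "CG"),
  ASN = "CB",
  ASP = "CB",
  CYS = "CB",
  GLN = c("CB", "CG"),
  GLU = c("CB", "CG"),
  HIS = "CB",
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"),
  THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2")
)

# Side-chain heavy atoms per residue in build order, with the atom each is
# bonded to. Used by the fixture generator.
SIDECHAIN_TOPOLOGY <- list(
  GLY = list(),
  ALA = list(CB = "CA"),
  SER = list(CB = "CA", OG = "CB"),
  CYS = list(CB = "CA", SG = "CB"),
  THR = list(CB = "CA", OG1 = "CB", CG2 = "CB"),
  VAL = list(CB = "CA", CG1 = "CB", CG2 = "CB"),
  LEU = list(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG"),
  ILE = list(CB = "CA", CG1 = "CB", CG2 = "CB", CD1 = "CG1"),
  MET = list(CB = "CA", CG = "CB", SD = "CG", CE = "SD"),
  PRO = list(CB = "CA", CG = "CB", CD = "CG"),
  PHE = list(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
             CE2 = "CD2", CZ = "CE1"),
  TYR = list(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
             CE2 = "CD2", CZ = "CE1", OH = "CZ"),
  TRP = list(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", NE1 = "CD1",
             CE2 = "CD2", CE3 = "CD2", CZ2 = "CE2", CZ3 = "CE3", CH2 = "CZ2"),
  ASP = list(CB = "CA", CG = "CB", OD1 = "CG", OD2 = "CG"),
  GLU = list(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", OE2 = "CD"),
  ASN = list(CB = "CA", CG = "CB", OD1 = "CG", ND2 = "CG"),
  GLN = list(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", NE2 = "CD"),
  HIS = list(CB = "CA", CG = "CB", ND1 = "CG", CD2 = "CG", CE1 = "ND1",
             NE2 = "CD2"),
  LYS = list(CB = "CA", CG = "CB", CD = "CG", CE = "CD", NZ = "CE"),
  ARG = list(CB = "CA", CG = "CB", CD = "CG", NE = "CD", CZ = "NE",
             NH1 = "CZ", NH2 = "CZ")
)

aa_three_to_one <- function(resid) {
  out <- unname(AA_THREE_TO_ONE[resid])
  out[is.na(out)] <- "X"
  out
}

residue_class_of <- function(one_letter, classes = residue_classes()) {
  cls <- rep(NA_character_, length(one_letter))
  for (nm in names(classes)) {
    cls[one_letter %in% classes[[nm]]] <- nm
  }
  cls
}

#' Classify a pair of residues as conserved, compatible or incompatible
#'
#' @param a,b one-letter residue codes (vectorised).
#' @param classes class table as returned by [residue_classes()].
#' @return character vector in `c("conserved", "compatible", "incompatible")`.
#' @export
residue_compatibility <- function(a, b, classes = residue_classes()) {
  ca <- residue_class_of(a, classes)
  cb <- residue_class_of(b, classes)
  out <- ifelse(a == b, "conserved",
                ifelse(!is.na(ca) & !is.na(cb) & ca == cb,
                       "compatible", "incompatible"))
  out[is.na(a) | is.na(b)] <- "incompatible"
  out
}
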