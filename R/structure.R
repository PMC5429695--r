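#' Read a macromolecular structure into a tidy atom table
#'
#' Parses a PDB or mmCIF file and returns one row per atom. Waters and metal
#' ions are retained as hetero atoms, only the first model of multi-model
#' files is kept, and where alternate locations are present only the
#' highest-occupancy altloc of each atom survives (ties broken by altloc
#' character order, so the result is deterministic).
#'
#' Residue numbers are the author (auth) numbers of the deposited file, so
#' they match the residue labels used in the structural literature.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (default, by file extension), `"pdb"` or `"mmcif"`.
#' @return A tibble with columns `type` (`ATOM`/`HETATM`), `eleno`, `elety`
#'   (atom name), `alt`, `resid` (3-letter residue code), `chain`, `resno`
#'   (auth residue number), `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`
#'   (element symbol). Attributes `id` and `source_format` record provenance.
#' @export
#' @examples
#' pdb <- make_symmetric_dockerin()
#' tmp <- tempfile(fileext = ".pdb")
#' write_structure(pdb, tmp)
#' str2 <- read_structure(tmp)
#' nrow(str2) == nrow(pdb)
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      abort(paste0("cannot infer structure format from extension '.", ext,
                   "'; pass format = \"pdb\" or \"mmcif\""))
    )
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  atoms <- as_tibble(parsed$atom)
  atoms$alt <- ifelse(is.na(atoms$alt), "", atoms$alt)
  atoms$insert <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms$chain <- ifelse(is.na(atoms$chain), "", atoms$chain)
  atoms$o <- ifelse(is.na(atoms$o), 1, atoms$o)
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy))) {
    atoms$elesy <- guess_element(atoms$elety)
  } else {
    miss <- is.na(atoms$elesy) | atoms$elesy == ""
    atoms$elesy[miss] <- guess_element(atoms$elety[miss])
  }
  atoms <- atoms |>
    group_by(.data$chain, .data$resno, .data$insert, .data$resid,
             .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$chain, .data$resno, .data$insert, .data$eleno) |>
    select(dplyr::any_of(c("type", "eleno", "elety", "alt", "resid",
                           "chain", "resno", "insert", "x", "y", "z",
                           "o", "b", "elesy")))
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    abort(paste0("non-finite coordinates at atom record(s) ",
                 paste(atoms$eleno[bad][1:min(3, sum(bad))], collapse = ", ")))
  }
  attr(atoms, "id") <- tools::file_path_sans_ext(basename(path))
  attr(atoms, "source_format") <- format
  atoms
}

# crude element guess from the atom name when the element column is absent
guess_element <- function(elety) {
  two <- c("CA2" = "CA", "MG" = "MG", "ZN" = "ZN", "NA" = "NA", "CL" = "CL",
           "MN" = "MN", "FE" = "FE", "K" = "K")
  nm <- toupper(trimws(elety))
  out <- substr(gsub("[0-9']", "", nm), 1, 1)
  ifelse(nm %in% names(two), unname(two[nm]), out)
}

#' Write an atom table to a PDB file
#'
#' @param structure atom tibble as returned by [read_structure()] or the
#'   fixture generators.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  st <- structure
  xyz <- as.vector(t(as.matrix(st[, c("x", "y", "z")])))
  chain <- ifelse(st$chain == "", " ", st$chain)
  insert <- ifelse(is.na(st$insert) | st$insert == "", "", st$insert)
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz, type = st$type,
    resno = st$resno, resid = st$resid, eleno = st$eleno,
    elety = st$elety, chain = chain, insert = insert,
    o = st$o, b = if (is.null(st$b)) 0 else st$b,
    elesy = st$elesy
  )
  invisible(path)
}

#' Download a deposited structure from the PDB
#'
#' Convenience helper: fetches an entry from RCSB (`files.rcsb.org`) into a
#' local directory and returns the file path. Requires network access; none
#' of the package's core functionality depends on it.
#'
#' @param id 4-character PDB accession, e.g. `"5M2O"`.
#' @param dir directory to download into (created if needed).
#' @param format `"pdb"` or `"mmcif"`.
#' @param timeout download timeout, seconds.
#' @return path to the downloaded file.
#' @export
fetch_structure <- function(id, dir = tempdir(), format = c("pdb", "mmcif"),
                            timeout = 30) {
  format <- match.arg(format)
  id <- toupper(id)
  ext <- if (format == "pdb") ".pdb" else ".cif"
  dest <- file.path(dir, paste0(id, ext))
  if (file.exists(dest)) return(dest)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  url <- paste0("https://files.rcsb.org/download/", id, ext)
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) {
      if (file.exists(dest)) unlink(dest)
      abort(paste0("failed to fetch ", id, " from RCSB: ",
                   conditionMessage(e)))
    }
  )
  if (!identical(status, 0L)) abort(paste0("failed to fetch ", id))
  dest
}

# polymer residues: anything with a CA (alpha-carbon) atom; skips waters/ions
polymer_residues <- function(structure, chain) {
  st <- filter(structure, .data$chain == !!chain)
  if (nrow(st) == 0) abort(paste0("unknown chain '", chain, "'"))
  keys <- st |>
    filter(.data$elety == "CA" & .data$elesy == "C") |>
    distinct(.data$resno, .data$insert, .data$resid) |>
    arrange(.data$resno, .data$insert)
  keys
}

#' One-letter amino-acid sequence of a chain
#'
#' Standard residues map to their one-letter codes, non-standard polymer
#' residues to `"X"`; waters and ions are skipped.
#'
#' @param structure atom tibble.
#' @param chain chain identifier.
#' @return named character vector of one-letter codes, names are auth
#'   residue numbers (with insertion code appended when present).
#' @export
chain_sequence <- function(structure, chain) {
  keys <- polymer_residues(structure, chain)
  if (nrow(keys) == 0) {
    abort(paste0("chain '", chain, "' has no polymer residues"))
  }
  setNames(aa_three_to_one(keys$resid),
           paste0(keys$resno, ifelse(keys$insert == "", "", keys$insert)))
}

#' Select atoms by chain, residue range and atom name
#'
#' @param structure atom tibble.
#' @param chain chain identifier.
#' @param residue_range `NULL` (all residues) or a length-2 numeric
#'   `c(first, last)` of auth residue numbers, inclusive.
#' @param atom_names character vector of atom names to keep (`NULL` = all).
#' @return atom tibble in residue order; attribute `n_missing` counts
#'   requested atom names absent from residues inside the range.
#' @export
select_atoms <- function(structure, chain, residue_range = NULL,
                         atom_names = NULL) {
  st <- filter(structure, .data$chain == !!chain)
  if (nrow(st) == 0) abort(paste0("unknown chain '", chain, "'"))
  if (!is.null(residue_range)) {
    st <- filter(st, .data$resno >= residue_range[1],
                 .data$resno <= residue_range[2])
  }
  n_missing <- 0L
  if (!is.null(atom_names)) {
    per_res <- st |>
      group_by(.data$resno, .data$insert) |>
      summarise(n_found = sum(unique(atom_names) %in% .data$elety),
                .groups = "drop")
    n_missing <- sum(length(unique(atom_names)) - per_res$n_found)
    st <- filter(st, .data$elety %in% atom_names)
  }
  st <- arrange(st, .data$resno, .data$insert,
                match(.data$elety, unique(.data$elety)))
  attr(st, "n_missing") <- as.integer(n_missing)
  st
}

structure_xyz <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}
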