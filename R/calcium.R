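#' Detect calcium sites and their coordinating atoms
#'
#' For every Ca2+ ion assigned to `chain`, collects the protein O/N atoms of
#' that chain and water oxygens (any chain) within `ca_ligand_cutoff`
#' (default 3.0 Å, generous around the typical 2.2-2.6 Å Ca-O distance).
#' Residues contributing only main-chain oxygens still count as
#' coordinating residues.
#'
#' @param structure atom tibble with hetero atoms retained.
#' @param chain chain the ions belong to.
#' @param config criteria from [analysis_config()].
#' @return An object of class `calcium_sites`: a tibble with one row per
#'   coordinating atom (`site`, `ion_eleno`, `chain`, `resno`, `resid`,
#'   `elety`, `distance`, `is_water`) ordered by ion appearance. The
#'   `summary` attribute (also via [summary()]) gives per-site offsets,
#'   water counts and pattern classification.
#' @export
detect_calcium_sites <- function(structure, chain,
                                 config = analysis_config()) {
  ions <- filter(structure, .data$chain == !!chain,
                 .data$resid %in% c("CA", "CA2"),
                 toupper(.data$elesy) == "CA")
  ligands_protein <- filter(structure, .data$chain == !!chain,
                            .data$resid %in% names(AA_THREE_TO_ONE),
                            substr(.data$elesy, 1, 1) %in% c("O", "N"))
  waters <- filter(structure, .data$resid %in% c("HOH", "WAT", "DOD"),
                   substr(.data$elesy, 1, 1) == "O")
  rows <- NULL
  for (k in seq_len(nrow(ions))) {
    ion <- ions[k, ]
    p <- c(ion$x, ion$y, ion$z)
    near <- function(tb) {
      if (nrow(tb) == 0) return(tb[0, ])
      d <- sqrt((tb$x - p[1])^2 + (tb$y - p[2])^2 + (tb$z - p[3])^2)
      tb <- tb[d <= config$ca_ligand_cutoff, ]
      tb$distance <- d[d <= config$ca_ligand_cutoff]
      tb
    }
    pr <- near(ligands_protein)
    wa <- near(waters)
    site_rows <- bind_rows(
      if (nrow(pr)) mutate(pr, is_water = FALSE),
      if (nrow(wa)) mutate(wa, is_water = TRUE)
    )
    if (is.null(site_rows) || nrow(site_rows) == 0) {
      site_rows <- tibble(chain = character(0), resno = integer(0),
                          resid = character(0), elety = character(0),
                          distance = numeric(0), is_water = logical(0))
    }
    rows <- bind_rows(rows, tibble(
      site = k, ion_eleno = ion$eleno,
      chain = site_rows$chain, resno = site_rows$resno,
      resid = site_rows$resid, elety = site_rows$elety,
      distance = site_rows$distance, is_water = site_rows$is_water
    ))
  }
  if (is.null(rows)) {
    rows <- tibble(site = integer(0), ion_eleno = integer(0),
                   chain = character(0), resno = integer(0),
                   resid = character(0), elety = character(0),
                   distance = numeric(0), is_water = logical(0))
  }
  class(rows) <- c("calcium_sites", class(rows))
  rows
}

#' Per-site summary of detected calcium sites
#'
#' @param object a `calcium_sites` tibble from [detect_calcium_sites()].
#' @param ... unused.
#' @return tibble with one row per site: `site`, `first_resno` (anchor of
#'   the coordination pattern), `n_residues`, `water_count`, `offsets`
#'   (list-column of sorted auth-number offsets from the anchor) and
#'   `pattern` from [classify_coordination_pattern()].
#' @export
summary.calcium_sites <- function(object, ...) {
  if (nrow(object) == 0) {
    return(tibble(site = integer(0), first_resno = integer(0),
                  n_residues = integer(0), water_count = integer(0),
                  offsets = list(), pattern = character(0),
                  low_confidence = logical(0)))
  }
  object |>
    as_tibble() |>
    group_by(.data$site) |>
    summarise(
      first_resno = if (any(!.data$is_water))
        min(.data$resno[!.data$is_water]) else NA_integer_,
      n_residues = length(unique(.data$resno[!.data$is_water])),
      water_count = sum(.data$is_water),
      offsets = list(sort(unique(.data$resno[!.data$is_water])) -
                       .data$first_resno),
      .groups = "drop"
    ) |>
    mutate(
      pattern = purrr::map2_chr(.data$offsets, .data$water_count,
                                classify_coordination_pattern),
      low_confidence = .data$n_residues < 3
    ) |>
    arrange(.data$first_resno)
}

#' Classify a calcium coordination-offset pattern
#'
#' Offsets are auth-number differences of the coordinating residues from
#' the first (anchor) coordinating residue. The canonical EF-hand-like
#' dockerin arrangement is offsets \{0, 2, 4, 11\} plus at least one water;
#' the atypical arrangement of the second repeat is \{0, 6, 12\} plus a
#' water. Matching is exact-set: extra coordinating residues beyond the
#' pattern demote the site to `"other"` (waters do not).
#'
#' @param offsets integer vector of offsets (must start at 0).
#' @param water_count number of coordinating waters.
#' @return `"canonical"`, `"atypical"` or `"other"`.
#' @export
#' @examples
#' classify_coordination_pattern(c(0, 2, 4, 11), 1)
#' classify_coordination_pattern(c(0, 6, 12), 1)
classify_coordination_pattern <- function(offsets, water_count) {
  offsets <- sort(unique(offsets))
  if (length(offsets) > 0 && offsets[1] != 0) {
    abort("offsets must be relative to the first coordinating residue (start at 0)")
  }
  if (setequal(offsets, c(0, 2, 4, 11)) && water_count >= 1) return("canonical")
  if (setequal(offsets, c(0, 6, 12)) && water_count >= 1) return("atypical")
  "other"
}
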