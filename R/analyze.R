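#' Full analysis of a cohesin-dockerin complex
#'
#' Runs the pipeline end to end on one complex: secondary structure of the
#' dockerin, calcium-site detection and classification, repeat
#' segmentation, interface contact mapping grouped by helix, the internal
#' two-fold superposition, symmetry-mate mapping and the single- versus
#' dual-binding-mode verdict.
#'
#' @param x path to a structure file, or an atom tibble.
#' @param doc_chain,coh_chain dockerin and cohesin chain identifiers. Set
#'   `doc_chain = "auto"` to infer the dockerin as the chain carrying two
#'   calcium sites (emits a warning naming the choice).
#' @param config criteria from [analysis_config()].
#' @return An object of class `complex_report`: list with elements
#'   `secondary_structure`, `calcium` (site summary tibble), `segmentation`,
#'   `interface`, `superposition`, `symmetry` (the `symmetry_report`),
#'   `verdict` and the `config` snapshot.
#' @export
analyze_complex <- function(x, doc_chain, coh_chain,
                            config = analysis_config()) {
  st <- if (is.character(x)) read_structure(x) else x
  chains <- unique(st$chain)
  if (identical(doc_chain, "auto")) {
    counts <- vapply(chains, function(ch) {
      s <- detect_calcium_sites(st, ch, config)
      nrow(summary(s))
    }, numeric(1))
    hit <- chains[counts == 2]
    if (length(hit) == 0) abort("no chain with two calcium sites found")
    doc_chain <- hit[1]
    warn(paste0("inferred dockerin chain '", doc_chain, "'"))
  }
  for (ch in c(doc_chain, coh_chain)) {
    if (!ch %in% chains) abort(paste0("unknown chain '", ch, "'"))
  }
  ss <- assign_secondary_structure(st, doc_chain)
  sites <- detect_calcium_sites(st, doc_chain, config)
  seg <- segment_repeats(st, doc_chain, sites, ss)
  report <- interface_report(st, doc_chain, coh_chain,
                             helix_ranges = seg, config = config)
  sup <- internal_symmetry_superpose(st, doc_chain, seg)
  mates <- map_symmetry_mates(seg, sup, classes = config$classes)
  sym <- assess_dual_binding(report, mates, seg, superposition = sup)
  structure(
    list(
      secondary_structure = ss,
      calcium = summary(sites),
      segmentation = seg,
      interface = report,
      superposition = sup,
      symmetry = sym,
      verdict = sym$verdict,
      doc_chain = doc_chain, coh_chain = coh_chain,
      config = config
    ),
    class = "complex_report"
  )
}

#' @export
print.complex_report <- function(x, ...) {
  cat("Cohesin-dockerin complex analysis\n")
  cat(sprintf("  dockerin chain %s, cohesin chain %s\n",
              x$doc_chain, x$coh_chain))
  cat(sprintf("  calcium sites: %d (%s)\n", nrow(x$calcium),
              paste(x$calcium$pattern, collapse = ", ")))
  cat("  contacts:", paste(x$interface$counts$kind, x$interface$counts$n,
                           sep = "=", collapse = " "), "\n")
  cat("  binding-mode verdict:", x$verdict, "\n")
  invisible(x)
}

#' Serialize a complex report (or symmetry/interface report) to JSON
#'
#' @param report a `complex_report`, `symmetry_report` or
#'   `interface_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "secondary_structure")) {
      return(list(residues = x$residues, strands = x$strands,
                  sheets = x$sheets, helices = x$helices))
    }
    if (inherits(x, "superposition")) {
      return(list(rmsd = x$rmsd, n_atoms = x$n_atoms,
                  rotation_angle = rotation_angle(x),
                  rotation = x$rotation, translation = x$translation))
    }
    if (inherits(x, "repeat_segmentation") || inherits(x, "symmetry_report") ||
        inherits(x, "interface_report") || inherits(x, "complex_report")) {
      return(lapply(unclass(x), to_plain))
    }
    x
  }
  jsonlite::write_json(to_plain(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
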