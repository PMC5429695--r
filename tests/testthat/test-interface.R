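test_that("chains far apart produce no contacts", {
  a <- build_peptide("LIV", chain = "A")
  b <- transform_coords(build_peptide("LIV", chain = "B"),
                        list(rotation = diag(3), translation = c(50, 0, 0)))
  st <- dplyr::bind_rows(a, b)
  expect_equal(nrow(detect_polar_contacts(st, "A", "B")), 0)
  expect_equal(nrow(detect_hydrophobic_contacts(st, "A", "B")), 0)
})

test_that("a planted Ser OG / His ND1 pair gives exactly one hydrogen bond", {
  st <- make_ser_his_fixture(distance = 2.9)
  out <- detect_polar_contacts(st, "A", "B")
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "hbond")
  expect_equal(out$elety_a, "OG")
  expect_equal(out$elety_b, "ND1")
  expect_equal(out$distance, 2.9, tolerance = 1e-9)
  # beyond the cutoff the pair disappears
  expect_equal(nrow(detect_polar_contacts(make_ser_his_fixture(3.7),
                                          "A", "B")), 0)
})

test_that("charged pairs within 4 A are tagged salt bridges", {
  out <- detect_polar_contacts(make_salt_bridge_fixture(3.8), "A", "B")
  expect_equal(nrow(out), 1)
  expect_equal(out$kind, "salt_bridge")
  # a close charged pair is still a single salt-bridge contact, not an
  # extra hbond row
  close <- detect_polar_contacts(make_salt_bridge_fixture(3.0), "A", "B")
  nz <- close[close$elety_a == "NZ" & close$elety_b == "OE1", ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$kind, "salt_bridge")
  expect_equal(nrow(detect_polar_contacts(make_salt_bridge_fixture(4.3),
                                          "A", "B")), 0)
})

test_that("a planted Leu/Ile pair registers one hydrophobic residue pair", {
  st <- make_leu_ile_fixture(distance = 4.0)
  out <- detect_hydrophobic_contacts(st, "A", "B")
  expect_equal(nrow(out), 1)
  expect_equal(out$min_distance, 4.0, tolerance = 1e-9)
  expect_equal(out$resid_a, "LEU")
  expect_equal(out$resid_b, "ILE")
  expect_equal(nrow(detect_hydrophobic_contacts(make_leu_ile_fixture(4.8),
                                                "A", "B")), 0)
  # glycines carry no apolar carbons
  g <- dplyr::bind_rows(
    build_peptide("GGG", chain = "A"),
    transform_coords(build_peptide("GGG", chain = "B"),
                     list(rotation = diag(3), translation = c(10, 0, 0))))
  expect_equal(nrow(detect_hydrophobic_contacts(g, "A", "B")), 0)
})

test_that("contact detection is symmetric in the chain arguments", {
  doc <- make_symmetric_dockerin()
  st <- make_cohesin_plateau(doc)
  ab <- detect_polar_contacts(st, "D", "C")
  ba <- detect_polar_contacts(st, "C", "D")
  key <- function(d, swap = FALSE) {
    if (swap) {
      sort(paste(d$resno_b, d$elety_b, d$resno_a, d$elety_a))
    } else {
      sort(paste(d$resno_a, d$elety_a, d$resno_b, d$elety_b))
    }
  }
  expect_equal(key(ab), key(ba, swap = TRUE))
  hab <- detect_hydrophobic_contacts(st, "D", "C")
  hba <- detect_hydrophobic_contacts(st, "C", "D")
  expect_equal(sort(paste(hab$resno_a, hab$resno_b)),
               sort(paste(hba$resno_b, hba$resno_a)))
})

test_that("relaxing the distance cutoffs never removes a contact", {
  doc <- make_symmetric_dockerin()
  st <- make_cohesin_plateau(doc)
  key_p <- function(d) paste(d$resno_a, d$elety_a, d$resno_b, d$elety_b)
  key_h <- function(d) paste(d$resno_a, d$resno_b)
  prev_p <- character(0); prev_h <- character(0)
  for (grow in c(0, 0.25, 0.5, 1.0)) {
    cfg <- analysis_config(hbond_cutoff = 3.5 + grow,
                           salt_bridge_cutoff = 4.0 + grow,
                           hydrophobic_cutoff = 4.5 + grow)
    p <- key_p(detect_polar_contacts(st, "D", "C", cfg))
    h <- key_h(detect_hydrophobic_contacts(st, "D", "C", cfg))
    expect_true(all(prev_p %in% p))
    expect_true(all(prev_h %in% h))
    prev_p <- p; prev_h <- h
  }
})

test_that("interface_report tags contacts by dockerin helix membership", {
  doc <- make_symmetric_dockerin()
  st <- make_cohesin_plateau(doc)
  rep <- interface_report(st, "D", "C",
                          helix_ranges = list(helix1 = c(39, 55),
                                              helix3 = c(76, 92)))
  expect_s3_class(rep, "interface_report")
  expect_true(all(rep$polar$helix == "H1"))
  h1 <- rep$helix_counts$n[rep$helix_counts$helix == "H1"]
  expect_equal(h1, nrow(rep$polar) + sum(rep$hydrophobic$helix == "H1"))
  expect_equal(sum(rep$counts$n),
               nrow(rep$polar) + nrow(rep$hydrophobic))
  # planted helix-1 contacts are recovered at the designated positions
  expect_true(all(c(39, 43) %in% rep$hydrophobic$resno_a))
  # an empty interface is a zero-count report, not an error
  far <- st
  far$x[far$chain == "C"] <- far$x[far$chain == "C"] + 100
  rep0 <- interface_report(far, "D", "C",
                           helix_ranges = list(helix1 = c(39, 55),
                                               helix3 = c(76, 92)))
  expect_equal(sum(rep0$counts$n), 0)
  expect_error(interface_report(st, "D", "Z", list(helix1 = c(39, 55),
                                                   helix3 = c(76, 92))),
               "unknown chain")
})

test_that("the TSV contact table mirrors the report", {
  doc <- make_symmetric_dockerin()
  st <- make_cohesin_plateau(doc)
  rep <- interface_report(st, "D", "C",
                          helix_ranges = list(helix1 = c(39, 55),
                                              helix3 = c(76, 92)))
  path <- tempfile(fileext = ".tsv")
  write_contacts_tsv(rep, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(rep$polar))
  expect_true(all(c("atom_doc", "resno_doc", "atom_coh", "resno_coh",
                    "helix") %in% names(tab)))
})
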