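doc_pipeline <- function(doc) {
  st <- make_cohesin_plateau(doc)
  sites <- detect_calcium_sites(st, "D")
  ss <- assign_secondary_structure(st, "D")
  seg <- segment_repeats(st, "D", sites, ss)
  sup <- internal_symmetry_superpose(st, "D", seg)
  rep <- interface_report(st, "D", "C", helix_ranges = seg)
  mates <- map_symmetry_mates(seg, sup)
  list(st = st, seg = seg, sup = sup, rep = rep, mates = mates,
       sym = assess_dual_binding(rep, mates, seg, superposition = sup))
}

test_that("a perfectly duplicated dockerin segments into equal repeats", {
  doc <- make_symmetric_dockerin()
  sites <- detect_calcium_sites(doc, "D")
  ss <- assign_secondary_structure(doc, "D")
  seg <- segment_repeats(doc, "D", sites, ss)
  len1 <- diff(seg$repeat1); len2 <- diff(seg$repeat2)
  expect_equal(len1, len2)
  expect_false(seg$low_confidence)
  # helix-1 inside repeat 1, helix-3 inside repeat 2, separated by a linker
  expect_true(seg$helix1[1] >= seg$repeat1[1] &&
                seg$helix1[2] <= seg$repeat1[2])
  expect_true(seg$helix3[1] >= seg$repeat2[1] &&
                seg$helix3[2] <= seg$repeat2[2])
  expect_true(seg$linker[1] > seg$repeat1[2] &&
                seg$linker[2] < seg$repeat2[1])
})

test_that("segmentation falls back to a midpoint split without 2 Ca sites", {
  doc <- make_symmetric_dockerin()
  noca <- doc[doc$resid != "CA", ]
  ss <- assign_secondary_structure(noca, "D")
  sites <- detect_calcium_sites(noca, "D")
  expect_warning(seg <- segment_repeats(noca, "D", sites, ss),
                 "midpoint")
  expect_true(seg$low_confidence)
  expect_equal(seg$repeat1[2] + 1, seg$repeat2[1])
})

test_that("the internal superposition of exact duplicates is a 180-degree rotation", {
  doc <- make_symmetric_dockerin()
  out <- doc_pipeline(doc)
  expect_lt(out$sup$rmsd, 0.1)
  expect_equal(rotation_angle(out$sup), 180, tolerance = 0.5)
  # pairing spans both helices
  h1 <- seq(out$seg$helix1[1], out$seg$helix1[2])
  h3 <- seq(out$seg$helix3[1], out$seg$helix3[2])
  expect_true(all(h1 %in% out$sup$pairing$resno_b))
  expect_true(all(h3 %in% out$sup$pairing$resno_a))
})

test_that("structurally unrelated repeats superpose poorly", {
  helix <- build_peptide(strrep("ALKAMAQS", 2), phi = -57, psi = -47,
                         chain = "D", start_resno = 1)
  ext <- build_peptide(strrep("ALKAMAQS", 2), phi = -120, psi = 120,
                       chain = "D", start_resno = 30)
  st <- dplyr::bind_rows(helix, ext)
  st$eleno <- seq_len(nrow(st))
  seg <- list(repeat1 = c(1, 16), repeat2 = c(30, 45))
  sup <- internal_symmetry_superpose(st, "D", seg)
  expect_gt(sup$rmsd, 2)
})

test_that("the two-fold transform composed with itself is the identity", {
  doc <- make_symmetric_dockerin()
  out <- doc_pipeline(doc)
  once <- build_rotated_model(doc, "D", out$sup)
  twice <- build_rotated_model(once, "D", out$sup)
  dev <- sqrt(mean((twice$x - doc$x)^2 + (twice$y - doc$y)^2 +
                     (twice$z - doc$z)^2))
  expect_lt(dev, 0.2)
  # the rotated model is a faithful copy
  expect_equal(nrow(once), nrow(doc))
  expect_equal(once$resid, doc$resid)
  expect_equal(chain_sequence(once, "D"), chain_sequence(doc, "D"))
  # and the transform maps repeat 2 onto repeat 1
  r2 <- dplyr::filter(once, .data$resno >= out$seg$repeat2[1],
                      .data$resno <= out$seg$repeat2[2], .data$elety == "CA")
  r1 <- dplyr::filter(doc, .data$resno >= out$seg$repeat1[1],
                      .data$resno <= out$seg$repeat1[2], .data$elety == "CA")
  expect_equal(nrow(r2), nrow(r1))
  expect_lt(max(abs(r2$x - r1$x)), 0.1)
})

test_that("symmetry mates of exact duplicates are all conserved", {
  out <- doc_pipeline(make_symmetric_dockerin())
  expect_true(all(out$mates$compatibility == "conserved"))
  m39 <- out$mates[out$mates$position == 39, ]
  expect_equal(m39$mate, 76)
  expect_equal(m39$resid_mate, "ILE")
})

test_that("substituted mates classify by residue class", {
  # nonpolar -> polar across the class boundary: incompatible
  vq <- doc_pipeline(make_asymmetric_dockerin(
    dockerin_spec(substitutions = list(list(43, "Q")))))
  m43 <- vq$mates[vq$mates$position == 43, ]
  expect_equal(m43$resid_mate, "GLN")
  expect_equal(m43$compatibility, "incompatible")
  expect_equal(vq$sym$verdict, "single")
  expect_lt(vq$sym$contact_conservation, 1)
  # nonpolar -> nonpolar within the class: compatible, verdict unchanged
  iv <- doc_pipeline(make_asymmetric_dockerin(
    dockerin_spec(substitutions = list(list(39, "V")))))
  m39 <- iv$mates[iv$mates$position == 39, ]
  expect_equal(m39$compatibility, "compatible")
  expect_equal(iv$sym$verdict, "dual")
  expect_equal(iv$sym$contact_conservation, 1)
})

test_that("the symmetric fixture against the plateau is called dual", {
  out <- doc_pipeline(make_symmetric_dockerin())
  expect_equal(out$sym$verdict, "dual")
  expect_equal(out$sym$contact_conservation, 1)
  expect_true(length(out$sym$key_positions) >= 2)
})

test_that("repairing an incompatible mate never flips dual to single", {
  vq <- doc_pipeline(make_asymmetric_dockerin(
    dockerin_spec(substitutions = list(list(43, "Q")))))
  fixed <- vq$mates
  bad <- fixed$compatibility == "incompatible"
  fixed$compatibility[bad] <- "conserved"
  fixed$resid_mate[bad] <- fixed$resid_position[bad]
  sym <- assess_dual_binding(vq$rep, fixed, vq$seg, superposition = vq$sup)
  expect_equal(sym$verdict, "dual")
})

test_that("an empty interface is indeterminate with a warning", {
  doc <- make_symmetric_dockerin()
  st <- make_cohesin_plateau(doc)
  st$x[st$chain == "C"] <- st$x[st$chain == "C"] + 100
  sites <- detect_calcium_sites(st, "D")
  ss <- assign_secondary_structure(st, "D")
  seg <- segment_repeats(st, "D", sites, ss)
  sup <- internal_symmetry_superpose(st, "D", seg)
  rep <- interface_report(st, "D", "C", helix_ranges = seg)
  mates <- map_symmetry_mates(seg, sup)
  expect_warning(sym <- assess_dual_binding(rep, mates, seg, sup),
                 "empty interface")
  expect_equal(sym$verdict, "indeterminate")
})

test_that("verdicts are 100% correct over the generator grid", {
  across_class <- c("Q", "D", "K")      # V (nonpolar) -> other classes
  within_class <- c("I", "L", "A")      # stays nonpolar
  for (s in 1:6) {
    sym <- doc_pipeline(make_symmetric_dockerin(
      dockerin_spec(coordinate_jitter = 0.3, seed = s)))$sym
    expect_equal(sym$verdict, "dual")
  }
  for (k in seq_along(across_class)) {
    sym <- doc_pipeline(make_asymmetric_dockerin(
      dockerin_spec(substitutions = list(list(43, across_class[k])),
                    coordinate_jitter = 0.2, seed = k)))$sym
    expect_equal(sym$verdict, "single")
  }
  for (k in seq_along(within_class)) {
    sym <- doc_pipeline(make_asymmetric_dockerin(
      dockerin_spec(substitutions = list(list(43, within_class[k])),
                    coordinate_jitter = 0.2, seed = 10 + k)))$sym
    expect_equal(sym$verdict, "dual")
  }
})

test_that("sequence fingerprints read the diagnostic frame positions", {
  # synthetic group-1-like frame: position 1 = auth 29
  seq64 <- rep("A", 64)
  seq64[c(11, 15, 19, 55, 59)] <- c("I", "V", "Q", "Q", "L")
  fp <- sequence_fingerprint(paste(seq64, collapse = ""))
  expect_true(fp$nonpolar_pass)
  expect_equal(fp$positions$residue[fp$positions$frame_pos == 11], "I")
  expect_equal(fp$positions$residue[fp$positions$frame_pos == 15], "V")
  # polar residue at #15 fails the nonpolar test
  qv <- seq64; qv[15] <- "Q"
  expect_false(sequence_fingerprint(paste(qv, collapse = ""))$nonpolar_pass)
  # nonpolar substitution at #11 still passes
  mv <- seq64; mv[11] <- "M"
  expect_true(sequence_fingerprint(paste(mv, collapse = ""))$nonpolar_pass)
})

test_that("fingerprints map through an alignment to a reference frame", {
  ref <- rep("A", 64)
  ref[c(11, 15, 19, 55, 59)] <- c("I", "V", "Q", "Q", "L")
  ref <- paste(ref, collapse = "")
  # query with a 3-residue N-terminal truncation: direct indexing would
  # misread the positions, the alignment must recover them
  query <- substr(ref, 4, 64)
  fp <- sequence_fingerprint(query, reference = ref)
  expect_equal(fp$positions$residue[fp$positions$frame_pos == 11], "I")
  expect_equal(fp$positions$residue[fp$positions$frame_pos == 15], "V")
  expect_true(fp$nonpolar_pass)
  # named chain_sequence input uses auth numbers directly
  doc <- make_symmetric_dockerin()
  fp2 <- sequence_fingerprint(chain_sequence(doc, "D"))
  expect_equal(fp2$positions$residue[fp2$positions$frame_pos == 11], "I")
  expect_equal(fp2$positions$residue[fp2$positions$frame_pos == 15], "V")
  expect_error(sequence_fingerprint("AAAAA", reference = ref),
               "50%")
})
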