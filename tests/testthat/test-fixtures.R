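test_that("generated fixtures are valid reader input", {
  doc <- make_symmetric_dockerin()
  path <- tempfile(fileext = ".pdb")
  write_structure(doc, path)
  st <- read_structure(path)
  expect_equal(nrow(st), nrow(doc))
  expect_equal(sum(st$resid == "CA"), 2)
  expect_equal(sum(st$resid == "HOH"), 2)
  cplx <- make_cohesin_plateau(doc)
  write_structure(cplx, path)
  st2 <- read_structure(path)
  expect_setequal(unique(st2$chain), c("D", "C"))
})

test_that("the generator enforces its specification invariants", {
  expect_error(dockerin_spec(repeat_length = 18, helix_length = 17),
               "helix_length")
  expect_error(dockerin_spec(substitutions = list(list(999, "Q"))),
               "outside repeat 1")
  expect_error(dockerin_spec(substitutions = list(list(43, "Z"))),
               "unknown residue")
  expect_error(make_asymmetric_dockerin(dockerin_spec()),
               "at least one substitution")
  expect_error(make_symmetric_dockerin(
    dockerin_spec(substitutions = list(list(43, "Q")))),
    "no substitutions")
})

test_that("substitutions rewrite only the targeted repeat-2 residue", {
  doc <- make_asymmetric_dockerin(
    dockerin_spec(substitutions = list(list(43, "Q"))))
  sq <- chain_sequence(doc, "D")
  expect_equal(unname(sq["43"]), "V")   # repeat 1 untouched
  expect_equal(unname(sq["80"]), "Q")   # its mate rewritten
  ref <- chain_sequence(make_symmetric_dockerin(), "D")
  expect_equal(sq[names(sq) != "80"], ref[names(ref) != "80"])
})

test_that("plateau contacts are planted at the designated positions", {
  doc <- make_symmetric_dockerin()
  cplx <- make_cohesin_plateau(doc)
  hyd <- detect_hydrophobic_contacts(cplx, "D", "C")
  expect_true(all(c(39, 43) %in% hyd$resno_a))
  pol <- detect_polar_contacts(cplx, "D", "C")
  expect_equal(nrow(pol), 1)
  expect_equal(pol$elety_a, "OG")
  expect_equal(pol$elety_b, "ND1")
  # moving the slab away removes every contact
  far <- cplx
  far$x[far$chain == "C"] <- far$x[far$chain == "C"] + 20
  far$y[far$chain == "C"] <- far$y[far$chain == "C"] + 20
  expect_equal(nrow(detect_hydrophobic_contacts(far, "D", "C")), 0)
  expect_equal(nrow(detect_polar_contacts(far, "D", "C")), 0)
})

test_that("ITC fixture files have the stated schedule and are reproducible", {
  pars <- thermo_params(n = 1, Ka = 1.18e8, dH = -50.68)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  make_itc_dataset(pars, noise_sd = 0.5, seed = 42, path = p1)
  make_itc_dataset(pars, noise_sd = 0.5, seed = 42, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  d <- read_itc(p1)
  expect_equal(nrow(d), 28)
  expect_equal(d$volume_uL, rep(10, 28))
  make_itc_dataset(pars, noise_sd = 0, seed = 1, path = p1)
  expect_equal(read_itc(p1)$heat_ucal,
               model_heats(itc_protocol(Ka = pars$Ka), pars),
               tolerance = 1e-9)
})

test_that("jittered fixtures keep their designed classification", {
  for (s in c(3, 8, 17)) {
    sym <- make_symmetric_dockerin(
      dockerin_spec(coordinate_jitter = 0.3, seed = s))
    expect_equal(analyze_complex(make_cohesin_plateau(sym), "D", "C")$verdict,
                 "dual")
    asym <- make_asymmetric_dockerin(
      dockerin_spec(substitutions = list(list(43, "Q")),
                    coordinate_jitter = 0.3, seed = s))
    expect_equal(analyze_complex(make_cohesin_plateau(asym), "D", "C")$verdict,
                 "single")
  }
})
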