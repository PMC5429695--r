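wt_params <- function() thermo_params(n = 1, Ka = 1.18e8, dH = -50.68)
wt_protocol <- function() itc_protocol(Ka = 1.18e8)

test_that("protocol defaults give the standard well-conditioned design", {
  p <- wt_protocol()
  expect_equal(length(p$injection_volumes), 28)
  expect_equal(p$injection_volumes[1], 10e-6)
  expect_equal(p$temperature, 308)
  expect_equal(1 * 1.18e8 * p$cell_conc, 100)       # Wiseman c
  expect_equal(p$syringe_conc / p$cell_conc, 15)
  expect_error(itc_protocol(cell_conc = 1e-5, n_injections = 200,
                            injection_volume = 10e-6),
               "smaller than the cell volume")
  expect_error(thermo_params(n = 1, Ka = -5, dH = -10), "positive")
})

test_that("zero enthalpy leaves only the per-injection offset", {
  q <- model_heats(wt_protocol(), thermo_params(1, 1e7, 0, q_offset = 2.5))
  expect_equal(q, rep(2.5, 28))
})

test_that("at very large Ka early injections bind stoichiometrically", {
  p <- itc_protocol(cell_conc = 1e-5)
  pars <- thermo_params(n = 1, Ka = 1e15, dH = -10)
  q <- model_heats(p, pars)
  # closed-form stoichiometric oracle: before the equivalence point every
  # titrant molecule in the cell is bound, B_i = Lt_i, so the heats follow
  # from the dilution series and the displaced-volume convention alone
  V0 <- p$cell_volume
  Lt <- 0; Qprev <- 0
  for (i in 1:5) {
    dv <- p$injection_volumes[i]
    Lt <- Lt * (1 - dv / V0) + p$syringe_conc * dv / V0
    Q <- Lt * pars$dH * V0 * 1e9
    q_exp <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2
    expect_equal(q[i] / q_exp, 1, tolerance = 1e-3)
    Qprev <- Q
  }
})

test_that("model heats match the bisection equilibrium oracle", {
  set.seed(71)
  for (k in 1:40) {
    Ka <- 10^runif(1, 4, 9)
    pars <- thermo_params(n = runif(1, 0.8, 1.2), Ka = Ka,
                          dH = runif(1, -80, -5),
                          q_offset = runif(1, -1, 1))
    p <- itc_protocol(Ka = Ka, c_value = 10^runif(1, 0.8, 2.8),
                      n_injections = sample(15:28, 1))
    q <- model_heats(p, pars)
    qb <- bisection_heats(p, pars)
    expect_lt(max(abs(q - qb)) / max(abs(q)), 1e-6)
  }
})

test_that("simulation is seed-deterministic with unbiased noise", {
  p <- wt_protocol(); pars <- wt_params()
  expect_equal(simulate_titration(p, pars, 0)$heat_ucal,
               model_heats(p, pars))
  a <- simulate_titration(p, pars, 1, seed = 7)
  b <- simulate_titration(p, pars, 1, seed = 7)
  expect_identical(a$heat_ucal, b$heat_ucal)
  c <- simulate_titration(p, pars, 1, seed = 8)
  expect_false(identical(a$heat_ucal, c$heat_ucal))
  # law of large numbers on the noise: mean of (simulated - model) ~ 0
  # with standard error noise_sd/sqrt(N)
  set.seed(72)
  devs <- replicate(200, {
    mean(simulate_titration(p, pars, 2)$heat_ucal - model_heats(p, pars))
  })
  expect_lt(abs(mean(devs)), 4 * 2 / sqrt(28 * 200))
  expect_equal(sd(devs), 2 / sqrt(28), tolerance = 0.15)
})

test_that("noiseless fits recover the generating parameters exactly", {
  for (Ka in c(1.18e8, 1.91e6)) {
    for (n_true in c(0.9, 1)) {
      pars <- thermo_params(n = n_true, Ka = Ka, dH = -50.68,
                            q_offset = 0.4)
      p <- itc_protocol(Ka = Ka)
      fit <- fit_single_site(simulate_titration(p, pars, 0))
      expect_true(fit$converged)
      expect_equal(fit$Ka / Ka, 1, tolerance = 1e-4)
      expect_equal(fit$n, n_true, tolerance = 1e-4)
      expect_equal(fit$dH / pars$dH, 1, tolerance = 1e-4)
      expect_equal(fit$q_offset, 0.4, tolerance = 1e-3)
    }
  }
})

test_that("refitting from the fitted optimum is idempotent", {
  p <- wt_protocol()
  d <- simulate_titration(p, wt_params(), 0.3, seed = 9)
  f1 <- fit_single_site(d)
  f2 <- fit_single_site(d, init = thermo_params(n = f1$n, Ka = f1$Ka,
                                                dH = f1$dH,
                                                q_offset = f1$q_offset))
  expect_equal(f2$Ka, f1$Ka, tolerance = 1e-6)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
  expect_equal(f2$residual_rms, f1$residual_rms, tolerance = 1e-8)
})

test_that("the thermodynamic identities hold exactly for every fit", {
  p <- wt_protocol()
  d <- simulate_titration(p, wt_params(), 0.3, seed = 10)
  fit <- fit_single_site(d)
  expect_equal(fit$dG, -R_KCAL * 308 * log(fit$Ka), tolerance = 1e-12)
  expect_equal(fit$dG, fit$dH - fit$TdS, tolerance = 1e-12)
  th <- derive_thermodynamics(1, 5)
  expect_equal(th$dG, 0)
  expect_equal(th$TdS, 5)
  expect_equal(R_KCAL * 308, 0.6121, tolerance = 1e-4)
  expect_error(derive_thermodynamics(-1, 5), "positive")
})

test_that("heat sums converge to the saturation total", {
  # with the ligand in large excess by the end, the summed heats approach
  # n * Mt_end * dH * V0 (small injections keep the displaced-volume
  # correction negligible)
  pars <- thermo_params(n = 1, Ka = 1e9, dH = -40)
  p <- itc_protocol(cell_conc = 1e-5, syringe_conc = 5e-3,
                    n_injections = 10, injection_volume = 2e-6)
  q <- model_heats(p, pars)
  expected <- pars$n * 1e-5 * prod(1 - p$injection_volumes / p$cell_volume) *
    pars$dH * p$cell_volume * 1e9
  expect_equal(sum(q) / expected, 1, tolerance = 0.03)
})

test_that("ITC files round-trip through the delimited format", {
  d <- simulate_titration(wt_protocol(), wt_params(), 0.05, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_itc(d, path)
  back <- read_itc(path)
  expect_equal(back$heat_ucal, d$heat_ucal)
  expect_equal(back$injection, d$injection)
  fit <- itc_fit_file(path, cell_conc = wt_protocol()$cell_conc,
                      syringe_conc = wt_protocol()$syringe_conc)
  expect_true(fit$converged)
  expect_equal(fit$Ka / 1.18e8, 1, tolerance = 0.25)
  # malformed input is rejected with the offending row
  bad <- readLines(path)
  bad[5] <- "3\tten\tNA"
  writeLines(bad, path)
  expect_error(suppressWarnings(read_itc(path)), "row")
})

test_that("fits require at least six injections", {
  p <- itc_protocol(Ka = 1e7, n_injections = 3)
  d <- simulate_titration(p, thermo_params(1, 1e7, -40), 0)
  expect_error(fit_single_site(d), "at least 6")
})

test_that("tidy, glance and autoplot expose the fit", {
  d <- simulate_titration(wt_protocol(), wt_params(), 0.3, seed = 12)
  fit <- fit_single_site(d)
  td <- tidy(fit)
  expect_equal(td$term,
               c("n", "Ka", "dH", "q_offset", "dG", "TdS"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_injections, 28)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("parameter recovery is essentially unbiased across c values", {
  set.seed(73)
  rel_ka <- rel_dh <- rel_n <- c()
  for (cv in c(10, 100, 500)) {
    p <- itc_protocol(Ka = 1e7, c_value = cv)
    pars <- thermo_params(n = 1, Ka = 1e7, dH = -50)
    noise <- 0.01 * max(abs(model_heats(p, pars)))
    for (k in 1:12) {
      f <- fit_single_site(simulate_titration(p, pars, noise))
      rel_ka <- c(rel_ka, f$Ka / 1e7 - 1)
      rel_dh <- c(rel_dh, f$dH / -50 - 1)
      rel_n <- c(rel_n, f$n - 1)
    }
  }
  expect_lt(abs(mean(rel_ka)), 0.02)
  expect_lt(abs(mean(rel_dh)), 0.02)
  expect_lt(abs(mean(rel_n)), 0.02)
})
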