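# Single-site (1:1) isothermal titration calorimetry: Wiseman isotherm
# simulation, nonlinear fitting and the standard thermodynamic identities.

#' Gas constant in kcal mol-1 K-1
#' @export
R_KCAL <- 1.9872e-3

#' Define an ITC titration protocol
#'
#' Defaults follow the standard cell experiment: 28 successive 10 µL
#' injections at 220 s intervals into a 1.4 mL cell at 308 K. Cell and
#' syringe concentrations default to a well-conditioned design: the cell
#' (macromolecule) concentration is chosen so that the Wiseman c-value
#' `n * Ka * Mt0` is about 100 when `Ka` is supplied, and the syringe
#' (titrant) concentration is 15 times the cell concentration.
#'
#' @param cell_conc macromolecule concentration in the cell, M. If `NULL`,
#'   derived from `Ka` and `c_value`.
#' @param syringe_conc titrant concentration in the syringe, M. If `NULL`,
#'   `15 * cell_conc`.
#' @param Ka association constant used to choose `cell_conc`, M^-1.
#' @param c_value target Wiseman c-value (default 100).
#' @param n_injections number of injections (default 28).
#' @param injection_volume per-injection volume, L (default 10 µL).
#' @param cell_volume working cell volume, L (default 1.4 mL).
#' @param temperature K (default 308).
#' @param injection_spacing s between injections (metadata; default 220).
#' @return list of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_conc = NULL, syringe_conc = NULL, Ka = NULL,
                         c_value = 100, n_injections = 28,
                         injection_volume = 10e-6, cell_volume = 1.4e-3,
                         temperature = 308, injection_spacing = 220) {
  if (is.null(cell_conc)) {
    if (is.null(Ka)) abort("supply cell_conc or Ka (to choose c ~ c_value)")
    cell_conc <- c_value / Ka
  }
  if (is.null(syringe_conc)) syringe_conc <- 15 * cell_conc
  injection_volumes <- rep(injection_volume, n_injections)
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0) {
    abort("concentrations and volumes must be positive")
  }
  if (sum(injection_volumes) >= cell_volume) {
    abort("total injected volume must be smaller than the cell volume")
  }
  structure(
    list(cell_conc = cell_conc, syringe_conc = syringe_conc,
         injection_volumes = injection_volumes, cell_volume = cell_volume,
         temperature = temperature, injection_spacing = injection_spacing),
    class = "itc_protocol"
  )
}

#' Define single-site binding parameters
#'
#' @param n stoichiometry (sites per macromolecule), > 0.
#' @param Ka association constant, M^-1, > 0.
#' @param dH binding enthalpy, kcal mol^-1.
#' @param q_offset constant per-injection dilution heat, µcal.
#' @return list of class `thermo_params`.
#' @export
thermo_params <- function(n = 1, Ka, dH, q_offset = 0) {
  if (Ka <= 0 || n <= 0) abort("Ka and n must be positive")
  structure(list(n = n, Ka = Ka, dH = dH, q_offset = q_offset),
            class = "thermo_params")
}

# diluted total concentrations after each injection (perfusion convention:
# each injection of volume dv multiplies existing cell contents by
# (1 - dv/V0) and adds titrant at dv/V0 of syringe concentration)
dilution_series <- function(protocol) {
  V0 <- protocol$cell_volume
  dv <- protocol$injection_volumes
  k <- length(dv)
  Mt <- Lt <- numeric(k)
  m <- protocol$cell_conc
  l <- 0
  for (i in seq_len(k)) {
    f <- 1 - dv[i] / V0
    m <- m * f
    l <- l * f + protocol$syringe_conc * dv[i] / V0
    Mt[i] <- m; Lt[i] <- l
  }
  list(Mt = Mt, Lt = Lt)
}

#' Per-injection heats of the single-site binding model
#'
#' After injection i the bound concentration `B_i` solves the mass-action
#' equation `Ka (n Mt_i - B)(Lt_i - B) = B` (the physical, smaller root of
#' the quadratic); the cumulative heat is `Q_i = B_i dH V0` and the
#' reported per-injection heat applies the usual displaced-volume
#' correction `q_i = Q_i - Q_(i-1) + (dv_i/V0) (Q_i + Q_(i-1))/2 +
#' q_offset`.
#'
#' @param protocol an [itc_protocol()].
#' @param params a [thermo_params()].
#' @return numeric vector of per-injection heats, µcal.
#' @export
model_heats <- function(protocol, params) {
  V0 <- protocol$cell_volume
  dv <- protocol$injection_volumes
  dil <- dilution_series(protocol)
  nMt <- params$n * dil$Mt
  Lt <- dil$Lt
  s <- nMt + Lt + 1 / params$Ka
  disc <- s^2 - 4 * nMt * Lt
  if (any(disc < -1e-12)) abort("non-physical root in the binding quadratic")
  B <- (s - sqrt(pmax(disc, 0))) / 2
  if (any(B < -1e-12) || any(B > pmin(nMt, Lt) * (1 + 1e-9) + 1e-15)) {
    abort("non-physical bound concentration")
  }
  Q <- B * params$dH * V0 * 1e9   # kcal -> µcal
  Qprev <- c(0, head(Q, -1))
  Q - Qprev + (dv / V0) * (Q + Qprev) / 2 + params$q_offset
}

#' Simulate a titration with Gaussian heat noise
#'
#' @param protocol an [itc_protocol()].
#' @param params a [thermo_params()].
#' @param noise_sd standard deviation of i.i.d. Gaussian noise added to
#'   each heat, µcal (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return tibble of class `itc_dataset` with columns `injection`,
#'   `volume_uL`, `heat_ucal`; the protocol, parameters and seed are kept
#'   as attributes.
#' @export
simulate_titration <- function(protocol, params, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  q <- model_heats(protocol, params)
  if (noise_sd > 0) q <- q + rnorm(length(q), 0, noise_sd)
  out <- tibble(
    injection = seq_along(q),
    volume_uL = protocol$injection_volumes * 1e6,
    heat_ucal = q
  )
  attr(out, "protocol") <- protocol
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("itc_dataset", class(out))
  out
}

#' Read / write the delimited ITC dataset format
#'
#' Tab-delimited text with a required header line naming the columns
#' `injection_index`, `volume_uL`, `heat_ucal`.
#'
#' @param path file path.
#' @return `read_itc()`: tibble with columns `injection`, `volume_uL`,
#'   `heat_ucal`.
#' @export
read_itc <- function(path) {
  if (!file.exists(path)) abort(paste0("ITC file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(need %in% names(raw))) {
    abort(paste0("ITC file must have header columns ",
                 paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(raw$volume_uL) | !is.finite(raw$heat_ucal))
  if (length(bad)) {
    abort(paste0("malformed ITC data at row ", bad[1] + 1))
  }
  tibble(injection = as.integer(raw$injection_index),
         volume_uL = raw$volume_uL, heat_ucal = raw$heat_ucal)
}

#' @param data tibble with columns `injection`, `volume_uL`, `heat_ucal`.
#' @rdname read_itc
#' @export
write_itc <- function(data, path) {
  out <- tibble(injection_index = data$injection,
                volume_uL = data$volume_uL, heat_ucal = data$heat_ucal)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Derive free energy and entropy term from Ka and dH
#'
#' `dG = -R T ln(Ka)` and `TdS = dH - dG`, with
#' R = 1.9872e-3 kcal mol-1 K-1.
#'
#' @param Ka association constant, M^-1 (> 0).
#' @param dH binding enthalpy, kcal mol^-1.
#' @param temperature K (> 0).
#' @return tibble with columns `dG`, `TdS` (kcal mol^-1).
#' @export
#' @examples
#' derive_thermodynamics(1, 5)       # dG = 0, TdS = dH
derive_thermodynamics <- function(Ka, dH, temperature = 308) {
  if (any(Ka <= 0) || any(temperature <= 0)) {
    abort("Ka and temperature must be positive")
  }
  dG <- -R_KCAL * temperature * log(Ka)
  tibble(dG = dG, TdS = dH - dG)
}

# data-driven starting values: n = 1; dH from the largest-magnitude heat
# scaled by the moles injected per injection; Ka from the width of the
# transition around the steepest part of the isotherm
itc_init <- function(heats, protocol) {
  dv <- protocol$injection_volumes
  mol_inj <- protocol$syringe_conc * dv          # mol per injection
  q0 <- mean(tail(heats, 3))
  qc <- heats - q0
  i_big <- which.max(abs(qc))
  dH0 <- qc[i_big] / (mol_inj[i_big] * 1e9)
  dil <- dilution_series(protocol)
  r <- dil$Lt / dil$Mt                            # molar ratio
  # transition width in molar-ratio units from the normalized steepest step
  dq <- abs(diff(qc))
  rng <- max(abs(qc))
  step <- if (rng > 0) max(dq) / rng else 0
  dr <- mean(diff(r))
  width <- if (step > 0) dr / step else diff(range(r))
  c0 <- min(max(20 / max(width, 1e-3), 1), 1e6)
  Ka0 <- c0 / protocol$cell_conc
  list(n = 1, Ka = Ka0, dH = dH0, q_offset = q0)
}

#' Fit the single-site binding model to a titration
#'
#' Least-squares fit of (n, log Ka, dH, q_offset) to the per-injection
#' heats with the Levenberg-Marquardt algorithm; Ka is fitted on the log
#' scale to enforce positivity. Standard errors come from the residual
#' covariance; dG and TdS are derived through the thermodynamic identities
#' so that `dG = dH - TdS` holds exactly.
#'
#' @param data an `itc_dataset` (from [simulate_titration()] or
#'   [read_itc()]); at least 6 injections.
#' @param protocol an [itc_protocol()]; defaults to the one attached to
#'   `data`. Cell/syringe concentrations must be supplied here when the
#'   data came from a file.
#' @param init optional [thermo_params()] starting values.
#' @param exclude_first drop the first injection before fitting (off by
#'   default).
#' @return An object of class `itc_fit`: list with `n`, `Ka`, `dH`,
#'   `q_offset` and their standard errors, `dG`, `TdS`, `residual_rms`,
#'   `converged`, `wiseman_c`, the data and fitted heats. A Wiseman
#'   c-value above 1e4 sets the `ill_conditioned` flag.
#' @export
fit_single_site <- function(data, protocol = attr(data, "protocol"),
                            init = NULL, exclude_first = FALSE) {
  if (is.null(protocol)) abort("a protocol with concentrations is required")
  heats <- data$heat_ucal
  if (length(heats) < 6) abort("at least 6 injections are required")
  keep <- seq_along(heats)
  if (exclude_first) keep <- keep[-1]
  if (is.null(init)) {
    ini <- itc_init(heats, protocol)
  } else {
    ini <- unclass(init)
  }
  par0 <- c(n = ini$n, lKa = log(ini$Ka), dH = ini$dH,
            q0 = ini$q_offset)
  resid_fn <- function(par) {
    pr <- thermo_params(n = max(par[["n"]], 1e-6),
                        Ka = exp(min(par[["lKa"]], 60)),
                        dH = par[["dH"]], q_offset = par[["q0"]])
    model_heats(protocol, pr)[keep] - heats[keep]
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  converged <- fit$info %in% 1:4
  par <- fit$par
  covm <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, 4) else sqrt(pmax(diag(covm), 0))
  names(se) <- names(par0)
  Ka <- exp(par[["lKa"]])
  th <- derive_thermodynamics(Ka, par[["dH"]], protocol$temperature)
  res <- resid_fn(par)
  c_val <- par[["n"]] * Ka * protocol$cell_conc
  structure(
    list(
      n = par[["n"]], Ka = Ka, dH = par[["dH"]], q_offset = par[["q0"]],
      se = list(n = se[["n"]], Ka = Ka * se[["lKa"]], dH = se[["dH"]],
                q_offset = se[["q0"]]),
      dG = th$dG, TdS = th$TdS,
      temperature = protocol$temperature,
      residual_rms = sqrt(mean(res^2)),
      converged = converged,
      ill_conditioned = c_val > 1e4,
      wiseman_c = c_val,
      data = data, protocol = protocol,
      fitted = heats[keep] - res,
      used = keep,
      message = fit$message
    ),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit", if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  N    : %.3f +/- %.3f sites\n", x$n, x$se$n))
  cat(sprintf("  Ka   : %.3e +/- %.2e M-1\n", x$Ka, x$se$Ka))
  cat(sprintf("  dG   : %.2f kcal/mol\n", x$dG))
  cat(sprintf("  dH   : %.2f +/- %.2f kcal/mol\n", x$dH, x$se$dH))
  cat(sprintf("  TdS  : %.2f kcal/mol  (T = %.0f K)\n", x$TdS,
              x$temperature))
  cat(sprintf("  rms residual: %.3f ucal over %d injections\n",
              x$residual_rms, length(x$used)))
  if (x$ill_conditioned) {
    cat(sprintf("  warning: Wiseman c = %.2e > 1e4 (ill-conditioned)\n",
                x$wiseman_c))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("n", "Ka", "dH", "q_offset", "dG", "TdS"),
    estimate = c(x$n, x$Ka, x$dH, x$q_offset, x$dG, x$TdS),
    std.error = c(x$se$n, x$se$Ka, x$se$dH, x$se$q_offset, NA, NA),
    unit = c("sites", "M-1", "kcal/mol", "ucal", "kcal/mol", "kcal/mol")
  )
}

#' @exportS3Method generics::glance
glance.itc_fit <- function(x, ...) {
  tibble(
    n = x$n, Ka = x$Ka, dG = x$dG, dH = x$dH, TdS = x$TdS,
    residual_rms = x$residual_rms, wiseman_c = x$wiseman_c,
    converged = x$converged, n_injections = length(x$used)
  )
}

#' Plot an ITC fit as a binding isotherm
#'
#' Normalized heat per mole of injectant against molar ratio, with the
#' fitted model curve.
#'
#' @param object an `itc_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.itc_fit <- function(object, ...) {
  pr <- object$protocol
  dil <- dilution_series(pr)
  ratio <- (dil$Lt / dil$Mt)[object$used]
  mol_inj <- (pr$syringe_conc * pr$injection_volumes)[object$used]
  ykcal <- function(q) (q - object$q_offset) * 1e-9 / mol_inj
  df <- tibble(ratio = ratio,
               observed = ykcal(object$data$heat_ucal[object$used]),
               fitted = ykcal(object$fitted))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "molar ratio (titrant/macromolecule)",
                  y = "kcal per mol of injectant",
                  title = sprintf("1:1 fit: N = %.2f, Ka = %.2e M-1",
                                  object$n, object$Ka)) +
    ggplot2::theme_minimal()
}

#' Fit an ITC file with a stated experimental design
#'
#' Reads the delimited ITC format and fits the single-site model; the
#' concentrations and cell volume are not part of the file format and must
#' be given here.
#'
#' @param path ITC dataset file.
#' @param cell_conc,syringe_conc concentrations, M.
#' @param cell_volume L.
#' @param temperature K.
#' @param ... passed on to [fit_single_site()].
#' @return an `itc_fit`.
#' @export
itc_fit_file <- function(path, cell_conc, syringe_conc,
                         cell_volume = 1.4e-3, temperature = 308, ...) {
  data <- read_itc(path)
  protocol <- itc_protocol(
    cell_conc = cell_conc, syringe_conc = syringe_conc,
    n_injections = nrow(data),
    injection_volume = mean(data$volume_uL) * 1e-6,
    cell_volume = cell_volume, temperature = temperature
  )
  protocol$injection_volumes <- data$volume_uL * 1e-6
  fit_single_site(data, protocol, ...)
}
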