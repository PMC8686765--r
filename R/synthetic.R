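#' Strain profiles calibrated to the measured rate table
#'
#' Per-strain "true" parameter sets (growth rate and specific exchange
#' rates) for the synthetic-culture generator, taken from the measured
#' anaerobic rate tables (see [atpase_exchange_rates()]); they are inputs to
#' forward simulation, not invented values. Growth-arrest profiles have
#' mu = 0 and a higher initial biomass, mirroring the experimental setup.
#'
#' @param condition `"growth"` or `"arrest"`.
#' @return Data frame of profiles: `strain`, `mode`, `mu_true`, `r_<analyte>`
#'   (signed: glucose negative = consumed, products positive), `x0`
#'   (initial biomass gDW/l), `glc0` (initial glucose mmol/l).
#' @export
strain_profiles <- function(condition = c("growth", "arrest")) {
  condition <- match.arg(condition)
  tab <- atpase_exchange_rates(condition)
  data.frame(
    strain = tab$strain,
    mode = if (condition == "growth") "growth" else "arrest",
    mu_true = tab$mu,
    r_glc = -tab$glc,
    r_eth = tab$eth, r_ace = tab$ace, r_for = tab[["for"]],
    r_lac = tab$lac, r_suc = tab$suc,
    x0 = if (condition == "growth") 0.02 else 0.44,
    glc0 = 22.2,
    stringsAsFactors = FALSE
  )
}

#' Simulate a fermentation time course
#'
#' Forward mass balances dX/dt = mu X and dc_M/dt = r_M X with constant
#' specific rates. In growth mode the closed forms are
#' X(t) = X0 e^{mu t} and c_M(t) = c_M0 + (r_M/mu)(X(t) - X0); under growth
#' arrest X stays at X0 and c_M(t) = c_M0 + r_M X0 t. Glucose is clamped at
#' zero after exhaustion, with all rates ceasing from that point on.
#' Measurement noise is multiplicative lognormal on biomass (OD-like) and
#' additive Gaussian truncated at zero on concentrations (HPLC-like).
#'
#' @param profile One row of [strain_profiles()] (or a list with the same
#'   fields).
#' @param sample_times Increasing sampling times (h).
#' @param noise List with `sigma_biomass_rel` (relative, lognormal) and
#'   `sigma_conc_abs` (mmol/l); both zero for a noiseless culture.
#' @param seed RNG seed.
#' @return Time-course data frame with columns `time_h`, `biomass_gDW_l`,
#'   `glc`, `eth`, `ace`, `for`, `lac`, `suc`.
#' @export
simulate_culture <- function(profile, sample_times = seq(0, 6, by = 0.75),
                             noise = list(sigma_biomass_rel = 0,
                                          sigma_conc_abs = 0),
                             seed = 1) {
  if (is.unsorted(sample_times, strictly = TRUE)) {
    stop("sample_times must be strictly increasing")
  }
  stopifnot(noise$sigma_biomass_rel >= 0, noise$sigma_conc_abs >= 0)
  p <- as.list(profile)
  analytes <- c("glc", "eth", "ace", "for", "lac", "suc")
  r <- unlist(p[paste0("r_", analytes)])
  names(r) <- analytes

  mu <- p$mu_true
  x0 <- p$x0
  ## time at which glucose runs out (rates cease afterwards)
  cum_biomass <- function(t) {
    if (mu > 0) (x0 * (exp(mu * t) - 1)) / mu else x0 * t
  }
  t_exhaust <- Inf
  if (r[["glc"]] < 0) {
    target <- p$glc0 / abs(r[["glc"]])  # integral of X dt at exhaustion
    t_exhaust <- if (mu > 0) {
      log(1 + mu * target / x0) / mu
    } else {
      target / x0
    }
    if (t_exhaust < sample_times[min(2, length(sample_times))]) {
      warning("glucose exhausted before the second sample")
    }
  }

  tt <- pmin(sample_times, t_exhaust)
  X <- if (mu > 0) x0 * exp(mu * pmin(sample_times, t_exhaust)) else
    rep(x0, length(sample_times))
  conc <- sapply(analytes, function(a) {
    c0 <- if (a == "glc") p$glc0 else 0
    pmax(c0 + r[[a]] * cum_biomass(tt), 0)
  })

  set.seed(seed)
  if (noise$sigma_biomass_rel > 0) {
    X <- X * exp(stats::rnorm(length(X), 0, noise$sigma_biomass_rel))
  }
  if (noise$sigma_conc_abs > 0) {
    conc <- pmax(conc + matrix(stats::rnorm(length(conc), 0,
                                            noise$sigma_conc_abs),
                               nrow(conc)), 0)
  }

  out <- data.frame(time_h = sample_times, biomass_gDW_l = X, conc,
                    check.names = FALSE)
  names(out) <- c("time_h", "biomass_gDW_l", analytes)
  out
}

#' Synthetic replicate rate table
#'
#' Simulates `n_replicates` noisy cultures per profile, recomputes the rates
#' with the estimators of the rates module ([summarize_rates()]), and
#' returns a per-strain table of means and SDs, i.e. a synthetic counterpart
#' of the measured exchange-rate table.
#'
#' @param profiles Data frame of profiles ([strain_profiles()]).
#' @param noise Noise list as in [simulate_culture()].
#' @param n_replicates Number of replicate cultures per strain.
#' @param seed RNG seed (replicates get distinct derived seeds).
#' @param sample_times Sampling grid (h).
#' @return Data frame: `strain`, `mu`, and signed `r_<analyte>` columns with
#'   `sd_` companions.
#' @export
make_rate_table <- function(profiles, noise = list(sigma_biomass_rel = 0.02,
                                                   sigma_conc_abs = 0.1),
                            n_replicates = 3, seed = 1,
                            sample_times = seq(0, 6, by = 0.75)) {
  stopifnot(n_replicates >= 1)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    p <- profiles[i, ]
    tcs <- lapply(seq_len(n_replicates), function(k) {
      simulate_culture(p, sample_times, noise,
                       seed = seed + 1000L * i + k)
    })
    s <- summarize_rates(tcs, mode = p$mode)
    means <- stats::setNames(s$mean, s$quantity)
    sds <- stats::setNames(s$sd, s$quantity)
    cbind(data.frame(strain = p$strain),
          as.data.frame(as.list(means), check.names = FALSE),
          stats::setNames(as.data.frame(as.list(sds), check.names = FALSE),
                          paste0("sd_", names(sds))))
  })
  do.call(rbind, rows)
}

#' Log-uniform perturbation of the saturation parameters
#'
#' Applies independent multiplicative factors 10^U(-decades/2, +decades/2)
#' to every Michaelis constant of the model (the fixture-level counterpart
#' of the steady-state-preserving resampling in the control-analysis
#' module; no vmax rescaling here).
#'
#' @param model A [kinetic_model].
#' @param decades Total range in orders of magnitude; 0 returns the model
#'   unchanged.
#' @param seed RNG seed.
#' @return The perturbed model.
#' @export
perturb_parameters <- function(model, decades, seed = 1) {
  stopifnot(decades >= 0)
  if (decades == 0) return(model)
  set.seed(seed)
  half <- decades / 2
  for (id in names(model$reactions)) {
    r <- model$reactions[[id]]
    for (fld in c("km_f", "km_r")) {
      if (!is.null(r[[fld]])) {
        r[[fld]] <- r[[fld]] * 10^stats::runif(length(r[[fld]]),
                                               -half, half)
      }
    }
    model$reactions[[id]] <- r
  }
  model$fast <- compile_rates(model)
  model
}

#' Read or write a time course as TSV
#'
#' @param path File path.
#' @param tc Time-course data frame.
#' @return `read_timecourse()` returns the data frame; an `od420` column is
#'   converted to `biomass_gDW_l` with the standard conversion factor of
#'   0.22 gDW/l per OD420 unit.
#' @export
read_timecourse <- function(path) {
  tc <- utils::read.delim(path, check.names = FALSE)
  if (!("biomass_gDW_l" %in% names(tc)) && "od420" %in% names(tc)) {
    tc$biomass_gDW_l <- tc$od420 * 0.22
  }
  tc
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  utils::write.table(tc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
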