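test_that("noiseless cultures follow the closed-form mass balances", {
  pr <- strain_profiles("growth")
  wt <- pr[pr$strain == "WT", ]
  t <- seq(0, 3, by = 0.5)
  tc <- simulate_culture(wt, t)
  expect_equal(tc$biomass_gDW_l, wt$x0 * exp(0.476 * t), tolerance = 1e-12)
  expect_equal(tc$glc,
               wt$glc0 - 13.48 / 0.476 * (tc$biomass_gDW_l - wt$x0),
               tolerance = 1e-9)
  # zero-rate, zero-noise profile gives flat concentrations
  flat <- wt
  flat[paste0("r_", c("glc", "eth", "ace", "for", "lac", "suc"))] <- 0
  tf <- simulate_culture(flat, t)
  expect_true(all(apply(tf[, c("eth", "lac")], 2, function(x) all(x == 0))))
  expect_equal(tf$glc, rep(wt$glc0, length(t)))
})

test_that("growth-arrest cultures accumulate products linearly", {
  pa <- strain_profiles("arrest")
  hc <- pa[pa$strain == "HC_ATPase", ]
  t <- seq(0, 2, by = 0.25)
  tc <- simulate_culture(hc, t)
  expect_equal(tc$biomass_gDW_l, rep(hc$x0, length(t)))
  slope <- diff(tc$lac) / diff(tc$time_h)
  expect_equal(slope, rep(13.78 * hc$x0, length(slope)), tolerance = 1e-9)
})

test_that("glucose exhaustion clamps concentrations and warns", {
  pr <- strain_profiles("growth")
  fast <- pr[pr$strain == "WT", ]
  fast$glc0 <- 0.2                      # runs out almost immediately
  expect_warning(tc <- simulate_culture(fast, seq(0, 4, by = 1)),
                 "exhausted")
  expect_true(all(tc$glc >= 0))
  expect_equal(tc$glc[4], 0)
})

test_that("rates recovered from noiseless synthetic cultures are exact", {
  pr <- strain_profiles("growth")
  for (st in c("WT", "MC_ATPase")) {
    p <- pr[pr$strain == st, ]
    tc <- simulate_culture(p, seq(0, 3, by = 0.5))
    mu <- fit_growth_rate(tc)$mu
    expect_equal(mu, p$mu_true, tolerance = 1e-9)
    n <- nrow(tc)
    r_glc <- specific_rate_growth(mu, tc$glc[1], tc$glc[n],
                                  tc$biomass_gDW_l[1], tc$biomass_gDW_l[n])
    expect_equal(r_glc, p$r_glc, tolerance = 1e-9)
  }
  # arrest variant
  pa <- strain_profiles("arrest")
  p <- pa[pa$strain == "HC_ATPase", ]
  tc <- simulate_culture(p, seq(0, 2, by = 0.25))
  n <- nrow(tc)
  r_lac <- specific_rate_arrest(tc$lac[1], tc$lac[n],
                                mean(tc$biomass_gDW_l),
                                tc$time_h[n] - tc$time_h[1])
  expect_equal(r_lac, 13.78, tolerance = 1e-9)
})

test_that("a noiseless single-replicate table equals the true profiles", {
  pr <- strain_profiles("growth")
  pr <- pr[pr$strain %in% c("WT", "LC_ATPase"), ]
  tab <- make_rate_table(pr, noise = list(sigma_biomass_rel = 0,
                                          sigma_conc_abs = 0),
                         n_replicates = 1, seed = 4)
  expect_equal(tab$mu, pr$mu_true, tolerance = 1e-9)
  expect_equal(tab$r_glc, pr$r_glc, tolerance = 1e-9)
  expect_equal(tab$r_lac, pr$r_lac, tolerance = 1e-9)
})

test_that("noisy replicate rates stay within the propagated estimator error", {
  pr <- strain_profiles("growth")
  p <- pr[pr$strain == "MC_control", ]
  noise <- list(sigma_biomass_rel = 0.02, sigma_conc_abs = 0.1)
  t <- seq(0, 3, by = 0.375)
  tab <- make_rate_table(p, noise, n_replicates = 3, seed = 8,
                         sample_times = t)
  # analytic error of the endpoint rate estimator r = mu (dc)/(dX):
  # concentration noise on the two endpoints plus relative biomass noise
  # on mu and dX, divided by sqrt(replicates)
  dX <- p$x0 * (exp(p$mu_true * max(t)) - 1)
  for (a in c("glc", "lac")) {
    r_true <- p[[paste0("r_", a)]]
    sig <- sqrt((p$mu_true * sqrt(2) * noise$sigma_conc_abs / dX)^2 +
                  (r_true * 2 * noise$sigma_biomass_rel)^2) / sqrt(3)
    expect_lt(abs(tab[[paste0("r_", a)]] - r_true), 3 * sig + 1e-9)
  }
})

test_that("carbon-overflowing profiles are physically impossible fixtures", {
  # products carrying more carbon than the consumed glucose: the rate table
  # cannot be reconciled without large adjustments
  sm <- default_stoich_model()
  bad <- c(mu = 0, glc = 1, eth = 3, ace = 3, "for" = 3, lac = 3, suc = 3)
  rec <- reconcile_rates(sm, bad)
  expect_gt(max(abs(rec$adjustments)), 0.5)
})

test_that("parameter perturbation is deterministic and range-bounded", {
  m <- fk_model("v1")
  expect_identical(perturb_parameters(m, 0, seed = 1), m)
  a <- perturb_parameters(m, 2, seed = 9)
  b <- perturb_parameters(m, 2, seed = 9)
  expect_equal(vapply(a$reactions, function(r) r$km_f[[1]], 0),
               vapply(b$reactions, function(r) r$km_f[[1]], 0))
  ratios <- unlist(lapply(names(m$reactions), function(id) {
    a$reactions[[id]]$km_f / m$reactions[[id]]$km_f
  }))
  expect_true(all(ratios >= 10^-1 - 1e-12 & ratios <= 10 + 1e-12))
  # over many draws the factors fill the two-decade range
  big <- unlist(lapply(1:200, function(k) {
    mk <- perturb_parameters(m, 2, seed = k)
    unlist(lapply(names(m$reactions), function(id) {
      mk$reactions[[id]]$km_f / m$reactions[[id]]$km_f
    }))
  }))
  expect_lt(min(big), 10^-0.95)
  expect_gt(max(big), 10^0.95)
})

test_that("synthetic rate tables feed the flux-analysis pipeline end to end", {
  pr <- strain_profiles("growth")
  pr <- pr[pr$strain %in% c("MC_control", "MC_ATPase"), ]
  tab <- make_rate_table(pr, noise = list(sigma_biomass_rel = 0.03,
                                          sigma_conc_abs = 0.1),
                         n_replicates = 3, seed = 21)
  as_meas <- function(row) {
    c(mu = row$mu, glc = abs(row$r_glc), eth = row$r_eth, ace = row$r_ace,
      "for" = row$r_for, lac = row$r_lac, suc = row$r_suc)
  }
  sm <- default_stoich_model()
  est <- estimate_atpase_flux(sm,
                              as_meas(tab[tab$strain == "MC_ATPase", ]),
                              as_meas(tab[tab$strain == "MC_control", ]))
  # the generating profiles are the measured table rows, for which the
  # model-based ATPM gap is ~30; noisy recovery must stay within 15%
  ref <- estimate_atpase_flux(sm,
                              as_meas(data.frame(mu = 0.197, r_glc = -17.70,
                                                 r_eth = 15.63, r_ace = 14.90,
                                                 r_for = 30.24, r_lac = 0.84,
                                                 r_suc = 1.66)),
                              as_meas(data.frame(mu = 0.461, r_glc = -15.02,
                                                 r_eth = 10.51, r_ace = 10.93,
                                                 r_for = 21.21, r_lac = 0.98,
                                                 r_suc = 1.85)))
  expect_lt(abs(est$atpase - ref$atpase) / ref$atpase, 0.15)
})

test_that("time courses round-trip through TSV with OD conversion support", {
  pr <- strain_profiles("growth")
  tc <- simulate_culture(pr[pr$strain == "WT", ], seq(0, 2, by = 0.5))
  path <- tempfile(fileext = ".tsv")
  write_timecourse(tc, path)
  tc2 <- read_timecourse(path)
  expect_equal(tc2$biomass_gDW_l, tc$biomass_gDW_l, tolerance = 1e-9)
  # OD420 column converts with the 0.22 gDW/l factor
  od <- data.frame(time_h = 0:2, od420 = c(1, 2, 3))
  write_timecourse(od, path)
  expect_equal(read_timecourse(path)$biomass_gDW_l, c(0.22, 0.44, 0.66))
})
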