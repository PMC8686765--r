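test_that("a fully saturated upstream step carries all flux control", {
  # step 1 saturated (S >> Km), step 2 and 3 responsive: classic result
  # C^J_1 ~ 1, downstream control ~ 0
  cfg <- toy_chain_config(vmax = c(2, 10, 10), km = c(1e-6, 1, 1))
  m <- build_model(cfg)
  s <- steady_state(m, c(A = 0.5, B = 0.5))
  expect_true(s$converged)
  f <- compute_fccs(m, s)
  expect_equal(unname(f$scaled["R3", "R1"]), 1, tolerance = 1e-3)
  expect_equal(unname(f$scaled["R3", "R2"]), 0, tolerance = 1e-3)
  expect_equal(unname(f$scaled["R3", "R3"]), 0, tolerance = 1e-3)
})

test_that("matrix-method FCCs match the finite-difference oracle", {
  fd_fcc <- function(m, s, flux, enzyme, h = 1e-4) {
    v0 <- m$reactions[[enzyme]]$vmax
    solve_at <- function(v) {
      args <- list(m); args[[enzyme]] <- v
      steady_state(do.call(set_vmax, args), s$conc[m$dynamic_ids])
    }
    jp <- solve_at(v0 * (1 + h))$flux[[flux]]
    jm <- solve_at(v0 * (1 - h))$flux[[flux]]
    (jp - jm) / (2 * h * s$flux[[flux]])
  }

  # random 3-step chain
  set.seed(3)
  cfg <- toy_chain_config(vmax = c(3, 7, 5), km = c(0.2, 1.5, 0.8))
  m <- build_model(cfg)
  s <- steady_state(m, c(A = 1, B = 1))
  f <- compute_fccs(m, s)
  for (e in c("R1", "R2", "R3")) {
    expect_equal(unname(f$scaled["R3", e]), fd_fcc(m, s, "R3", e),
                 tolerance = 1e-3)
  }

  # full model at the wild-type reference
  m1 <- fk_model("v1")
  wt <- fk_wt_state("v1")
  f1 <- compute_fccs(m1, wt)
  for (e in c("PFK", "NGAM", "PTS")) {
    expect_equal(unname(f1$scaled["PTS", e]), fd_fcc(m1, wt, "PTS", e),
                 tolerance = 1e-3)
  }
})

test_that("the summation theorem holds for every flux", {
  f <- compute_fccs(fk_model("v1"), fk_wt_state("v1"))
  ok <- !is.na(f$scaled[, 1])
  expect_true(any(ok))
  expect_lt(max(abs(rowSums(f$scaled[ok, , drop = FALSE]) - 1)), 1e-3)
})

test_that("NGAM exerts positive control on glucose uptake at the wild type", {
  f <- compute_fccs(fk_model("v1"), fk_wt_state("v1"))
  expect_gt(f$scaled["PTS", "NGAM"], 0)
})

test_that("steady-state-preserving sampling reproduces the reference fluxes", {
  m <- fk_model("v1")
  wt <- fk_wt_state("v1")
  set.seed(11)
  for (i in 1:20) {
    mi <- fermkin:::resample_saturation(m, wt, 2)
    v <- model_rates(mi, wt$conc)
    expect_equal(unname(v), unname(wt$flux[names(v)]), tolerance = 1e-9)
  }
})

test_that("a degenerate sampling range returns the unperturbed coefficients", {
  m <- fk_model("v1")
  wt <- fk_wt_state("v1")
  ss <- sample_preserving_steady_state(m, wt, n = 1, seed = 5, decades = 0)
  expect_equal(ss$samples[[1]]$scaled, compute_fccs(m, wt)$scaled)
})

test_that("sampling is reproducible under a fixed seed", {
  m <- fk_model("v1")
  wt <- fk_wt_state("v1")
  a <- sample_preserving_steady_state(m, wt, n = 10, seed = 7)
  b <- sample_preserving_steady_state(m, wt, n = 10, seed = 7)
  expect_equal(a$sign_fractions, b$sign_fractions)
  expect_equal(a$samples[[10]]$scaled, b$samples[[10]]$scaled)
  expect_equal(a$n_rejected, b$n_rejected)
})

test_that("sign dominance summarizes sampled coefficient signs", {
  m <- fk_model("v1")
  wt <- fk_wt_state("v1")
  ss <- sample_preserving_steady_state(m, wt, n = 10, seed = 3)
  sd1 <- sign_dominance(ss, "PTS", "NGAM")
  expect_true(sd1[["positive"]] + sd1[["negative"]] <= 1)
  expect_equal(unname(sd1[["positive"]]),
               mean(vapply(ss$samples,
                           function(f) f$scaled["PTS", "NGAM"] > 0, TRUE)))
})

test_that("doubling every vmax doubles all fluxes and keeps concentrations", {
  m <- fk_model("v1")
  wt <- fk_wt_state("v1")
  m2 <- m
  for (id in names(m2$reactions)) {
    args <- list(m2); args[[id]] <- 2 * m2$reactions[[id]]$vmax
    m2 <- do.call(set_vmax, args)
  }
  s2 <- steady_state(m2, wt$conc[m$dynamic_ids])
  expect_true(s2$converged)
  expect_equal(s2$flux, 2 * wt$flux, tolerance = 1e-6)
  expect_equal(s2$conc, wt$conc, tolerance = 1e-6)
})

test_that("scan-matched reference states land on the right branch", {
  m <- fk_model("v2")
  sc <- fk_scan("v2", by = 1)
  peak <- which.max(sc$summary$glc_uptake)
  lc <- reference_state(m, "LC", scan = sc)
  hc <- reference_state(m, "HC", scan = sc)
  expect_lte(attr(lc, "vmax_atpase"), sc$summary$vmax_atpase[peak])
  expect_gte(attr(hc, "vmax_atpase"), sc$summary$vmax_atpase[peak])
  expect_lt(abs(hc$flux[["PTS"]] - 5.13), 1.5)
  expect_lt(hc$energy_charge, fk_wt_state("v2")$energy_charge)
})
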