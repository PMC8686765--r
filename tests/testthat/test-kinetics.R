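test_that("irreversible convenience kinetics has the Michaelis-Menten limits", {
  p <- list(vmax = 10, km_f = c(S = 2))
  expect_equal(convenience_rate(p, c(S = 0)), 0)
  expect_equal(convenience_rate(p, c(S = 2)), 5)              # half-saturation
  expect_gt(convenience_rate(p, c(S = 2000)), 10 * 0.99)      # saturation
  # two substrates multiply; missing concentration errors
  p2 <- list(vmax = 4, km_f = c(A = 1, B = 1))
  expect_equal(convenience_rate(p2, c(A = 1, B = 1)), 1)
  expect_error(convenience_rate(p2, c(A = 1)), "missing concentration")
})

test_that("modifier terms act multiplicatively with the expected half-points", {
  base <- list(vmax = 10, km_f = c(S = 1))
  act <- c(base, list(modifiers = list(
    list(species = "X", role = "activator", k = 2, hill = 1))))
  inh <- c(base, list(modifiers = list(
    list(species = "X", role = "inhibitor", k = 2, hill = 1))))
  conc <- c(S = 1e6, X = 2)
  expect_equal(convenience_rate(act, conc), 5, tolerance = 1e-4)
  expect_equal(convenience_rate(inh, conc), 5, tolerance = 1e-4)
})

test_that("every rate law is homogeneous of degree one in vmax", {
  m <- fk_model("v2")
  conc <- m$reference$conc
  v1 <- model_rates(m, conc)
  m2 <- m
  for (id in names(m2$reactions)) {
    args <- list(m2)
    args[[id]] <- 2 * m2$reactions[[id]]$vmax
    m2 <- do.call(set_vmax, args)
  }
  expect_equal(model_rates(m2, conc), 2 * v1, tolerance = 1e-12)
})

test_that("fast indexed evaluator agrees with the reference evaluator", {
  for (version in c("v1", "v2")) {
    m <- fk_model(version)
    set.seed(42)
    for (i in 1:5) {
      conc <- m$reference$conc * exp(rnorm(length(m$reference$conc), 0, 0.5))
      expect_equal(model_rates(m, conc),
                   fermkin:::model_rates_reference(m, conc),
                   tolerance = 1e-13)
      expect_equal(model_rates(m, conc, clamp_adp_activation = 0.3),
                   fermkin:::model_rates_reference(m, conc, 0.3),
                   tolerance = 1e-13)
    }
  }
})

test_that("isolated PFK flux is biphasic in the ADP fraction at the measured working point", {
  m <- fk_model("v1")
  pfk <- m$reactions$PFK
  # fixed working point: PEP 0.27, F6P 0.91, FBP 9.74, ATP+ADP 2.67 umol/gDW
  total <- 2.67
  f <- seq(0.01, 0.99, by = 0.01)
  flux <- vapply(f, function(fr) {
    pfk_rate(pfk, c(F6P = 0.91, PEP = 0.27, FBP = 9.74,
                    ATP = total * (1 - fr), ADP = total * fr))
  }, 0)
  i <- which.max(flux)
  expect_gt(i, 1)
  expect_lt(i, length(f))
  expect_gt(flux[i], flux[which.min(abs(f - 0.05))])
  expect_gt(flux[i], flux[which.min(abs(f - 0.95))])
  # strictly increasing then strictly decreasing around the unique maximum
  expect_true(all(diff(flux[1:i]) > 0))
  expect_true(all(diff(flux[i:length(f)]) < 0))
  # ATP exhausted (f -> 1) kills the flux
  expect_equal(pfk_rate(pfk, c(F6P = 0.91, PEP = 0.27, FBP = 9.74,
                               ATP = 0, ADP = total)), 0)
  expect_error(pfk_rate(pfk, c(F6P = 1, PEP = 0.1, FBP = 1, ATP = 0,
                               ADP = 0)), "adenylate")
})

test_that("clamping the ADP activation term makes the PFK sweep monotone non-increasing", {
  m <- fk_model("v1")
  pfk <- m$reactions$PFK
  total <- 2.67
  f <- seq(0.01, 0.99, by = 0.01)
  flux <- vapply(f, function(fr) {
    pfk_rate(pfk, c(F6P = 0.91, PEP = 0.27, FBP = 9.74,
                    ATP = total * (1 - fr), ADP = total * fr),
             clamp_adp_activation = 0.2)
  }, 0)
  expect_true(all(diff(flux) <= 1e-12))
})

test_that("PFL vmax modulation saturates, floors and is monotone", {
  m <- fk_model("v2")
  pfl <- m$reactions$PFL
  vmax <- pfl$vmax
  gmin <- pfl$vmax_modulation$gmin
  kg <- pfl$vmax_modulation$kg
  expect_equal(pfl_vmax_modulation(pfl, 0), gmin * vmax)
  expect_equal(pfl_vmax_modulation(pfl, 100 * kg), vmax, tolerance = 0.01)
  set.seed(1)
  a <- sort(runif(200, 0, 10))
  g <- vapply(a, function(x) pfl_vmax_modulation(pfl, x), 0)
  expect_true(all(diff(g) >= 0))
  # not defined on version-1 models
  expect_error(pfl_vmax_modulation(fk_model("v1")$reactions$PFL, 1),
               "version-2")
})

test_that("pyruvate inhibition of PYK is 1 at zero and strictly decreasing", {
  m <- fk_model("v2")
  pyk <- m$reactions$PYK
  ki <- Filter(function(x) x$species == "PYR", pyk$modifiers)[[1]]$k
  expect_equal(pyk_pyruvate_inhibition(pyk, 0), 1)
  grid <- seq(0, 10 * ki, length.out = 101)
  fac <- vapply(grid, function(p) pyk_pyruvate_inhibition(pyk, p), 0)
  expect_true(all(diff(fac) < 0))
  expect_true(all(fac > 0 & fac <= 1))
  # half-inhibition at Ki for a first-order term
  p1 <- pyk
  p1$modifiers <- list(list(species = "PYR", role = "inhibitor",
                            k = 2, hill = 1))
  expect_equal(pyk_pyruvate_inhibition(p1, 2), 0.5)
  expect_error(pyk_pyruvate_inhibition(fk_model("v1")$reactions$PYK, 1),
               "version-2")
})

test_that("energy charge follows the adenylate formula", {
  expect_equal(energy_charge(c(ATP = 1, ADP = 0, AMP = 0)), 1)
  expect_equal(energy_charge(c(ATP = 1, ADP = 1, AMP = 1)), 0.5)
  expect_equal(energy_charge(c(ATP = 1, ADP = 2, AMP = 1)), 0.5)
  expect_error(energy_charge(c(ATP = 0, ADP = 0, AMP = 0)), "zero")
})
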