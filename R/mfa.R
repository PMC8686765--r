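#' Construct a stoichiometric model for flux analysis
#'
#' Builds the linear-programming representation used by [reconcile_rates()]
#' and [maximize_atpm()]: a stoichiometric matrix over internal (balanced)
#' metabolites, irreversible fluxes (reversible steps are split into
#' forward/backward pairs by the caller), a mapping from measured quantities
#' to flux ids, and the id of the ATP-maintenance pseudo-reaction.
#'
#' @param reactions Named list; each element is a named numeric vector of
#'   stoichiometric coefficients over internal metabolites (negative =
#'   consumed).
#' @param measured Named character vector mapping measured quantities (e.g.
#'   `glc`, `mu`) to flux ids, all in positive-magnitude convention.
#' @param atpm Id of the ATP-maintenance reaction.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(reactions, measured, atpm = "ATPM") {
  species <- sort(unique(unlist(lapply(reactions, names))))
  S <- matrix(0, length(species), length(reactions),
              dimnames = list(species, names(reactions)))
  for (id in names(reactions)) S[names(reactions[[id]]), id] <- reactions[[id]]
  if (!(atpm %in% names(reactions))) stop("no ATPM reaction named ", atpm)
  if (!all(measured %in% names(reactions))) {
    stop("measured map refers to unknown flux ids")
  }
  ## an independent row basis (cofactor pairs make rows like ATP/ADP
  ## linearly dependent, which equality-constrained solvers reject)
  qrS <- qr(t(S))
  keep <- sort(qrS$pivot[seq_len(qrS$rank)])
  structure(list(S = S, S_indep = S[keep, , drop = FALSE],
                 reactions = names(reactions), measured = measured,
                 atpm = atpm),
            class = "stoich_model")
}

#' Default stoichiometric model of anaerobic central metabolism
#'
#' A reconstruction of the anaerobic central carbon metabolism of
#' *E. coli* for flux analysis: PTS glycolysis, the fermentative branches
#' (pyruvate formate-lyase, lactate dehydrogenase, phosphotransacetylase /
#' acetate kinase, alcohol dehydrogenase), anaplerosis with both PEP
#' carboxylase and the reversible PEP carboxykinase, the reductive branch to
#' succinate, the oxidative stub to alpha-ketoglutarate, transhydrogenase, a
#' biomass reaction draining precursors with growth-associated ATP, and the
#' ATPM pseudo-reaction hydrolyzing ATP. Every ATP and NADH coefficient is
#' visible in the returned stoichiometry. The published 83-reaction model
#' this stands in for is not printed anywhere, so absolute ATPM values from
#' this reconstruction are comparable in magnitude, not identical.
#'
#' @param gam Growth-associated ATP demand (mmol ATP per gDW biomass).
#' @return A [stoich_model].
#' @export
default_stoich_model <- function(gam = 75) {
  bm <- c(G6P = 0.205, F6P = 0.071, PG3 = 1.496, PEP = 0.519, PYR = 2.833,
          ACCOA = 3.747, OAA = 1.787, AKG = 1.079)
  biomass <- c(-bm, NADPH = -12, NADP = 12, ATP = -gam, ADP = gam,
               COA = unname(bm["ACCOA"]))
  names(biomass)[seq_along(bm)] <- names(bm)

  rx <- list(
    PTS = c(GLC = -1, PEP = -1, G6P = 1, PYR = 1),
    PGI = c(G6P = -1, F6P = 1),
    PFK = c(F6P = -1, ATP = -1, FBP = 1, ADP = 1),
    FBA = c(FBP = -1, DHAP = 1, GAP = 1),
    TPI = c(DHAP = -1, GAP = 1),
    GAPDH_PGK = c(GAP = -1, NAD = -1, ADP = -1, PG3 = 1, NADH = 1, ATP = 1),
    PGM_ENO = c(PG3 = -1, PEP = 1),
    PYK = c(PEP = -1, ADP = -1, PYR = 1, ATP = 1),
    PFL = c(PYR = -1, COA = -1, ACCOA = 1, FOR = 1),
    LDH = c(PYR = -1, NADH = -1, LAC = 1, NAD = 1),
    PTA_ACK = c(ACCOA = -1, ADP = -1, ACE = 1, ATP = 1, COA = 1),
    ACDH_ADH = c(ACCOA = -1, NADH = -2, ETH = 1, NAD = 2, COA = 1),
    PPC = c(PEP = -1, CO2 = -1, OAA = 1),
    PCK_F = c(OAA = -1, ATP = -1, PEP = 1, ADP = 1, CO2 = 1),
    PCK_R = c(PEP = -1, ADP = -1, CO2 = -1, OAA = 1, ATP = 1),
    CS_ICDH = c(ACCOA = -1, OAA = -1, NADP = -1,
                AKG = 1, NADPH = 1, COA = 1, CO2 = 1),
    MDH_FRD = c(OAA = -1, NADH = -2, SUC = 1, NAD = 2, CO2 = 0.0),
    THD_F = c(NADH = -1, NADP = -1, NAD = 1, NADPH = 1),
    THD_R = c(NADPH = -1, NAD = -1, NADP = 1, NADH = 1),
    BIOMASS = biomass,
    ATPM = c(ATP = -1, ADP = 1),
    EX_GLC = c(GLC = 1),
    EX_ETH = c(ETH = -1),
    EX_ACE = c(ACE = -1),
    EX_FOR = c(FOR = -1),
    EX_LAC = c(LAC = -1),
    EX_SUC = c(SUC = -1),
    EX_CO2_OUT = c(CO2 = -1),
    EX_CO2_IN = c(CO2 = 1)
  )
  rx$MDH_FRD <- rx$MDH_FRD[names(rx$MDH_FRD) != "CO2"]
  stoich_model(rx, measured = c(mu = "BIOMASS", glc = "EX_GLC",
                                eth = "EX_ETH", ace = "EX_ACE",
                                "for" = "EX_FOR", lac = "EX_LAC",
                                suc = "EX_SUC"))
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("Stoichiometric model: ", nrow(x$S), " internal metabolites, ",
      ncol(x$S), " fluxes (ATPM = ", x$atpm, ")\n", sep = "")
  invisible(x)
}

#' Reconcile measured exchange rates with the stoichiometric model
#'
#' Finds the SD-weighted least-squares minimal adjustment of the measured
#' rates such that a non-negative flux vector exists with S v = 0 and the
#' adjusted rates imposed; solved as a quadratic program over the flux
#' space. Rates that are already consistent come back unchanged.
#'
#' @param model A [stoich_model].
#' @param measured Named numeric vector of measured quantities matching
#'   `model$measured` (positive-magnitude convention: uptake, secretion and
#'   growth all positive).
#' @param sd Named numeric vector of the measurement SDs (same names);
#'   zero/missing SDs are replaced by a small floor so the weights stay
#'   finite.
#' @return List with `reconciled` (adjusted rates), `adjustments`,
#'   `v` (a feasible flux vector attaining them) and `sum_sq` (the weighted
#'   objective).
#' @export
reconcile_rates <- function(model, measured, sd = NULL) {
  meas_ids <- names(model$measured)
  missing <- setdiff(meas_ids, names(measured))
  if (length(missing) > 0) {
    stop("missing measured rate(s): ", paste(missing, collapse = ", "))
  }
  m <- unlist(measured[meas_ids])
  if (is.null(sd)) sd <- rep(1, length(m))
  else {
    if (any(unlist(sd) < 0, na.rm = TRUE)) stop("negative SD in input")
    sd <- unlist(sd)[meas_ids]
    sd[is.na(sd)] <- 1
  }
  sd <- pmax(sd, 1e-3)
  w <- 1 / sd^2

  n <- ncol(model$S)
  E <- matrix(0, length(meas_ids), n,
              dimnames = list(meas_ids, colnames(model$S)))
  for (q in meas_ids) E[q, model$measured[[q]]] <- 1

  ## min (Ev - m)' W (Ev - m) + ridge ||v||^2  s.t. S v = 0, v >= 0
  ridge <- 1e-8
  C <- 2 * (t(E) %*% diag(w, length(w)) %*% E + ridge * diag(n))
  d <- as.vector(-2 * t(E) %*% (w * m))
  sol <- pracma::quadprog(C = C, d = d, Aeq = model$S_indep,
                          beq = rep(0, nrow(model$S_indep)),
                          lb = rep(0, n), ub = rep(1e4, n))
  v <- sol$xmin
  names(v) <- colnames(model$S)
  rec <- as.vector(E %*% v)
  names(rec) <- meas_ids
  list(reconciled = rec, adjustments = rec - m, v = v,
       sum_sq = sum(w * (rec - m)^2))
}

#' Maximize the ATP-maintenance flux given fixed exchange rates
#'
#' Linear program: maximize the ATPM flux subject to steady state
#' (S v = 0), non-negative fluxes, and the supplied (reconciled) exchange
#' and growth rates imposed as equalities. The optimum absorbs all ATP
#' turnover that the measured physiology cannot attribute to growth.
#'
#' @param model A [stoich_model].
#' @param rates Named numeric vector of the fixed quantities (as from
#'   [reconcile_rates()]).
#' @return List with `atpm` (mmol/gDW/h), `v` (optimal flux vector) and
#'   `status` (solver message).
#' @export
maximize_atpm <- function(model, rates) {
  meas_ids <- names(model$measured)
  m <- unlist(rates[meas_ids])
  if (any(is.na(m))) stop("missing fixed rate(s)")
  n <- ncol(model$S)
  E <- matrix(0, length(meas_ids), n)
  for (i in seq_along(meas_ids)) E[i, match(model$measured[[meas_ids[i]]],
                                            colnames(model$S))] <- 1
  Aeq <- rbind(model$S_indep, E)
  beq <- c(rep(0, nrow(model$S_indep)), m)
  ## drop linearly dependent equality rows (fixed exchanges can overlap the
  ## span of the balance rows); consistency is checked on the solution
  qrA <- qr(t(Aeq))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  Aeq_r <- Aeq[keep, , drop = FALSE]
  beq_r <- beq[keep]

  cc <- as.numeric(colnames(model$S) == model$atpm)
  cap <- 1e4
  sol <- tryCatch(
    pracma::linprog(cc = cc, A = matrix(cc, 1), b = cap, Aeq = Aeq_r,
                    beq = beq_r, maxiter = 500, maximize = TRUE),
    error = function(e) NULL)
  v <- if (!is.null(sol) && !is.null(sol$x) && sol$errno == 1) sol$x else NULL
  status <- if (!is.null(sol)) sol$message else "linprog failed"
  if (is.null(v)) {
    ## dual active-set fallback: the LP with a vanishing quadratic term
    qp <- pracma::quadprog(C = diag(2e-9, n), d = -cc, Aeq = Aeq_r,
                           beq = beq_r, lb = rep(0, n), ub = rep(cap, n))
    v <- qp$xmin
    status <- "regularized QP fallback"
  }
  names(v) <- colnames(model$S)
  if (max(abs(Aeq %*% v - beq)) > 1e-5 || any(v < -1e-6)) {
    stop("ATPM maximization failed: fixed rates are infeasible ",
         "(reconcile first)")
  }
  if (v[model$atpm] >= cap - 1e-6) {
    stop("unbounded ATPM: the model admits an energy-generating cycle")
  }
  list(atpm = unname(v[model$atpm]), v = v, status = status)
}

#' ATPase flux as the ATPM difference between strain and control
#'
#' The ATPM flux of an ATPase-overexpressing strain contains both the
#' non-growth-associated maintenance and the enforced hydrolysis; the
#' ATPase flux is therefore the difference between its ATPM and that of the
#' corresponding control strain.
#'
#' @param atpm_strain,atpm_control ATPM fluxes (mmol/gDW/h), non-negative.
#' @return Difference in mmol/gDW/h (sign preserved; a negative estimate
#'   triggers a warning).
#' @examples
#' atpase_flux(29.06, 3.61) # 25.45
#' @export
atpase_flux <- function(atpm_strain, atpm_control) {
  stopifnot(atpm_strain >= 0, atpm_control >= 0)
  d <- atpm_strain - atpm_control
  if (d < 0) warning("ATPase strain has lower ATPM than its control")
  d
}

#' End-to-end ATPase flux estimation from measured rates
#'
#' Reconciles the measured rates of an ATPase strain and its control,
#' maximizes ATPM for both, and reports the ATPase flux as the difference.
#'
#' @param model A [stoich_model].
#' @param strain,control Named numeric vectors of measured rates
#'   (mu, glc, eth, ace, for, lac, suc).
#' @param sd_strain,sd_control Optional SD vectors for the reconciliation
#'   weights.
#' @return List with per-strain reconciliation and ATPM results plus
#'   `atpase` (mmol/gDW/h).
#' @export
estimate_atpase_flux <- function(model, strain, control,
                                 sd_strain = NULL, sd_control = NULL) {
  rs <- reconcile_rates(model, strain, sd_strain)
  rc <- reconcile_rates(model, control, sd_control)
  ms <- maximize_atpm(model, rs$reconciled)
  mc <- maximize_atpm(model, rc$reconciled)
  list(strain = list(reconciliation = rs, atpm = ms$atpm),
       control = list(reconciliation = rc, atpm = mc$atpm),
       atpase = atpase_flux(ms$atpm, mc$atpm))
}

#' Carbon balance of a reconciled scenario
#'
#' Product carbon plus biomass carbon plus net CO2 out, relative to glucose
#' carbon (6 C per glucose); at most 1 up to solver tolerance for any
#' mass-balanced scenario.
#'
#' @param model A [stoich_model] (the default reconstruction).
#' @param v Flux vector from [maximize_atpm()] or [reconcile_rates()].
#' @return Fraction of glucose carbon recovered.
#' @export
carbon_recovery <- function(model, v) {
  bm_c <- sum(c(G6P = 6, F6P = 6, PG3 = 3, PEP = 3, PYR = 3, ACCOA = 2,
                OAA = 4, AKG = 5) *
                c(0.205, 0.071, 1.496, 0.519, 2.833, 3.747, 1.787, 1.079))
  prod_c <- 2 * v[["EX_ETH"]] + 2 * v[["EX_ACE"]] + 1 * v[["EX_FOR"]] +
    3 * v[["EX_LAC"]] + 4 * v[["EX_SUC"]]
  co2 <- v[["EX_CO2_OUT"]] - v[["EX_CO2_IN"]]
  glc_c <- 6 * v[["EX_GLC"]]
  if (glc_c == 0) return(NA_real_)
  (prod_c + bm_c * v[["BIOMASS"]] + co2) / glc_c
}
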