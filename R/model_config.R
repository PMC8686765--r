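#' Default kinetic model configuration
#'
#' Builds the configuration for the shipped kinetic model of anaerobic central
#' fermentative metabolism of *E. coli*: glycolysis via the phosphotransferase
#' uptake system (PTS), the fermentative branches to ethanol, acetate, formate,
#' lactate and succinate, anaplerosis (PPC/PCK), the reductive and oxidative
#' stubs of the TCA cycle, adenylate kinase, a biomass (growth) reaction, and
#' the ATP-consuming maintenance (NGAM) and ATPase reactions. The network
#' comprises 33 metabolites (27 dynamic, 6 clamped boundary species) and 28
#' reactions.
#'
#' The more than one hundred rate-law parameters of the published model are not
#' printed anywhere; the defaults shipped here are a synthetic, plausible set
#' constructed as follows. A reference wild-type steady state is fixed
#' (concentrations at measured magnitudes, including the phosphofructokinase
#' working point PEP 0.27, F6P 0.91, FBP 9.74 and ATP+ADP 2.67 umol/gDW; fluxes
#' balanced around the measured wild-type exchange rates), Michaelis and
#' allosteric constants are set relative to those reference concentrations, and
#' every vmax is then calibrated so that the reference state is an *exact*
#' steady state of the ODE system. See the package vignette for the full
#' rationale.
#'
#' Model version 2 differs from version 1 only by (i) an ATP-dependent
#' modulation of the PFL vmax (lower effective PFL abundance at low ATP) and
#' (ii) an allosteric inhibition of pyruvate kinase by pyruvate.
#'
#' @param version Model version, `"v1"` or `"v2"`.
#' @return A list with elements `species`, `reactions`, `parameters`,
#'   `reference` (the calibration steady state) and `version`, suitable for
#'   [build_model()].
#' @seealso [build_model()], [read_model_config()]
#' @export
default_model_config <- function(version = c("v1", "v2")) {
  version <- match.arg(version)

  ## ---- species ------------------------------------------------------------
  ## Concentrations in umol/gDW for intracellular species; external glucose is
  ## clamped and carried in mM (its units only enter through the PTS Km).
  conc <- c(
    G6P = 1.5, F6P = 0.91, FBP = 9.74, DHAP = 2.0, GAP = 0.4, BPG = 0.1,
    "3PG" = 1.5, "2PG" = 0.4, PEP = 0.27, PYR = 0.8,
    ACCOA = 0.4, COA = 0.6, ACP = 0.15, ACALD = 0.05,
    OAA = 0.1, MAL = 1.0, FUM = 0.3, AKG = 0.5,
    ATP = 2.25, ADP = 0.42, AMP = 0.078,
    NAD = 1.80, NADH = 0.45, NADP = 0.08, NADPH = 0.12,
    MQ = 0.5, MQH2 = 0.5
  )
  boundary <- c(GLC_EX = 20, ETH = 0, ACE = 0, FOR = 0, LAC = 0, SUC = 0)

  species <- data.frame(
    id = c(names(conc), names(boundary)),
    boundary = c(rep(FALSE, length(conc)), rep(TRUE, length(boundary))),
    conc = unname(c(conc, boundary)),
    stringsAsFactors = FALSE
  )

  ## ---- biomass composition ------------------------------------------------
  ## Precursor drains in mmol per gDW of biomass formed; ATP includes the
  ## growth-associated maintenance.
  bm <- c(
    G6P = 0.205, F6P = 0.071, "3PG" = 1.496, PEP = 0.519, PYR = 2.833,
    ACCOA = 3.747, OAA = 1.787, AKG = 1.079, NADPH = 12.0, ATP = 40.0
  )
  growth_stoich <- c(
    -bm,
    ADP = unname(bm["ATP"]), NADP = unname(bm["NADPH"]),
    COA = unname(bm["ACCOA"])
  )
  names(growth_stoich)[seq_along(bm)] <- names(bm)

  ## ---- reactions ----------------------------------------------------------
  rxn <- function(stoich, law = "convenience", reversible = FALSE,
                  km_f = NULL, km_r = NULL, hill_s = NULL, drive = NA_real_,
                  vmax = NA_real_, modifiers = list()) {
    list(stoich = stoich, law = law, reversible = reversible,
         km_f = km_f, km_r = km_r, hill_s = hill_s, drive = drive,
         vmax = vmax, modifiers = modifiers)
  }
  act <- function(species, ka, hill = 2) {
    list(species = species, role = "activator", k = ka, hill = hill)
  }
  inh <- function(species, ki, hill = 2) {
    list(species = species, role = "inhibitor", k = ki, hill = hill)
  }

  reactions <- list(
    PTS = rxn(c(GLC_EX = -1, PEP = -1, G6P = 1, PYR = 1),
              km_f = c(GLC_EX = 0.02, PEP = 0.1),
              modifiers = list(inh("G6P", 4.0, hill = 1))),
    PGI = rxn(c(G6P = -1, F6P = 1), reversible = TRUE,
              km_f = c(G6P = 1.5), km_r = c(F6P = 0.91), drive = 0.2),
    PFK = rxn(c(F6P = -1, ATP = -1, FBP = 1, ADP = 1), law = "pfk",
              km_f = c(F6P = 0.30, ATP = 0.50),
              modifiers = list(act("ADP", 0.8), inh("PEP", 1.5))),
    FBA = rxn(c(FBP = -1, DHAP = 1, GAP = 1), reversible = TRUE,
              km_f = c(FBP = 5.0), km_r = c(DHAP = 2.0, GAP = 0.4),
              drive = 0.5, modifiers = list(inh("PEP", 1.0))),
    TPI = rxn(c(DHAP = -1, GAP = 1), reversible = TRUE,
              km_f = c(DHAP = 2.0), km_r = c(GAP = 0.4), drive = 0.2),
    GHD = rxn(c(GAP = -1, NAD = -1, BPG = 1, NADH = 1), reversible = TRUE,
              km_f = c(GAP = 0.4, NAD = 1.8),
              km_r = c(BPG = 0.1, NADH = 0.45), drive = 0.4),
    PGK = rxn(c(BPG = -1, ADP = -1, "3PG" = 1, ATP = 1), reversible = TRUE,
              km_f = c(BPG = 0.1, ADP = 0.42),
              km_r = c("3PG" = 1.5, ATP = 2.25), drive = 0.05),
    PGM = rxn(c("3PG" = -1, "2PG" = 1), reversible = TRUE,
              km_f = c("3PG" = 1.5), km_r = c("2PG" = 0.4), drive = 0.2),
    ENO = rxn(c("2PG" = -1, PEP = 1), reversible = TRUE,
              km_f = c("2PG" = 0.4), km_r = c(PEP = 0.27), drive = 0.3),
    PYK = rxn(c(PEP = -1, ADP = -1, PYR = 1, ATP = 1),
              km_f = c(PEP = 0.3, ADP = 0.5),
              modifiers = list(act("FBP", 8.0))),
    PFL = rxn(c(PYR = -1, COA = -1, ACCOA = 1, FOR = 1),
              km_f = c(PYR = 1.0, COA = 0.3)),
    LDH = rxn(c(PYR = -1, NADH = -1, LAC = 1, NAD = 1),
              km_f = c(PYR = 2.5, NADH = 0.3)),
    PTA = rxn(c(ACCOA = -1, ACP = 1, COA = 1), reversible = TRUE,
              km_f = c(ACCOA = 0.4), km_r = c(ACP = 0.15, COA = 0.6),
              drive = 0.5),
    ACK = rxn(c(ACP = -1, ADP = -1, ACE = 1, ATP = 1),
              km_f = c(ACP = 0.15, ADP = 0.4)),
    ACDH = rxn(c(ACCOA = -1, NADH = -1, ACALD = 1, NAD = 1, COA = 1),
               km_f = c(ACCOA = 0.4, NADH = 0.45)),
    ADH = rxn(c(ACALD = -1, NADH = -1, ETH = 1, NAD = 1),
              km_f = c(ACALD = 0.05, NADH = 0.45)),
    PPC = rxn(c(PEP = -1, OAA = 1), km_f = c(PEP = 0.3),
              modifiers = list(inh("MAL", 1.5, hill = 1))),
    PCK = rxn(c(OAA = -1, ATP = -1, PEP = 1, ADP = 1), reversible = TRUE,
              km_f = c(OAA = 0.1, ATP = 2.25),
              km_r = c(PEP = 0.27, ADP = 0.42),
              drive = 0, vmax = 10.0),
    CSICDH = rxn(c(ACCOA = -1, OAA = -1, NADP = -1,
                   AKG = 1, NADPH = 1, COA = 1),
                 km_f = c(ACCOA = 0.4, OAA = 0.1, NADP = 0.08),
                 modifiers = list(inh("AKG", 1.0, hill = 1))),
    MDH = rxn(c(OAA = -1, NADH = -1, MAL = 1, NAD = 1), reversible = TRUE,
              km_f = c(OAA = 0.1, NADH = 0.45),
              km_r = c(MAL = 1.0, NAD = 1.8), drive = 0.4),
    FHD = rxn(c(MAL = -1, FUM = 1), reversible = TRUE,
              km_f = c(MAL = 1.0), km_r = c(FUM = 0.3), drive = 0.3),
    FRD = rxn(c(FUM = -1, MQH2 = -1, SUC = 1, MQ = 1),
              km_f = c(FUM = 0.3, MQH2 = 0.5)),
    NDH = rxn(c(NADH = -1, MQ = -1, NAD = 1, MQH2 = 1), reversible = TRUE,
              km_f = c(NADH = 0.45, MQ = 0.5),
              km_r = c(NAD = 1.8, MQH2 = 0.5), drive = 0.5),
    THD = rxn(c(NADH = -1, NADP = -1, NAD = 1, NADPH = 1), reversible = TRUE,
              km_f = c(NADH = 0.45, NADP = 0.08),
              km_r = c(NAD = 1.8, NADPH = 0.12), drive = 0.5),
    ADK = rxn(c(ATP = -1, AMP = -1, ADP = 2), reversible = TRUE,
              km_f = c(ATP = 2.25, AMP = 0.078), km_r = c(ADP = 0.42),
              drive = 0, vmax = 20.0),
    GROWTH = rxn(growth_stoich,
                 km_f = c(G6P = 0.375, F6P = 0.2275, "3PG" = 0.375,
                          PEP = 0.0675, PYR = 0.2, ACCOA = 0.1, OAA = 0.025,
                          AKG = 0.125, NADPH = 0.03, ATP = 1.2),
                 hill_s = c(ATP = 2)),
    NGAM = rxn(c(ATP = -1, ADP = 1), km_f = c(ATP = 0.5),
               hill_s = c(ATP = 2)),
    ATPASE = rxn(c(ATP = -1, ADP = 1), km_f = c(ATP = 0.4),
                 hill_s = c(ATP = 3), vmax = 0)
  )

  ## adenylate kinase carries the squared ADP term of its mass-action ratio
  reactions$ADK$stoich_exp <- c(ADP = 2)

  ## version 2 additions: PFL enzyme-level downregulation at low ATP and
  ## pyruvate inhibition of PYK
  if (version == "v2") {
    reactions$PFL$vmax_modulation <- list(species = "ATP", gmin = 0.05,
                                          kg = 1.0)
    reactions$PYK$modifiers <- c(reactions$PYK$modifiers,
                                 list(inh("PYR", 2.0)))
  }

  ## ---- reference wild-type fluxes (exactly balanced) ----------------------
  ref_flux <- wt_reference_fluxes(bm)

  list(species = species, reactions = reactions,
       biomass = bm, reference = list(conc = c(conc, boundary),
                                      flux = ref_flux),
       version = version)
}

#' Exactly balanced wild-type reference fluxes
#'
#' Derives a self-consistent steady-state flux distribution for the default
#' network from the measured wild-type growth rate, glucose uptake, lactate and
#' succinate secretion, propagating mass balances through the network. Ethanol
#' and acetate fluxes follow from the NADH and acetyl-CoA balances rather than
#' being imposed, so that the resulting vector satisfies N v = 0 exactly.
#'
#' @param bm Named biomass precursor coefficients (mmol/gDW).
#' @param mu Growth rate (1/h).
#' @param r_glc,r_lac,r_suc Specific exchange rates (mmol/gDW/h).
#' @return Named flux vector over the 28 reactions (mmol/gDW/h).
#' @keywords internal
wt_reference_fluxes <- function(bm, mu = 0.476, r_glc = 13.48,
                                r_lac = 0.83, r_suc = 1.77) {
  drain <- bm * mu
  f <- c()
  f["PTS"] <- r_glc
  f["PGI"] <- f["PTS"] - drain["G6P"]
  f["PFK"] <- f["PGI"] - drain["F6P"]
  f["FBA"] <- f["PFK"]
  f["TPI"] <- f["FBA"]
  f["GHD"] <- f["FBA"] + f["TPI"]
  f["PGK"] <- f["GHD"]
  f["PGM"] <- f["PGK"] - drain["3PG"]
  f["ENO"] <- f["PGM"]
  f["CSICDH"] <- drain["AKG"]
  f["MDH"] <- r_suc
  f["FHD"] <- r_suc
  f["FRD"] <- r_suc
  f["NDH"] <- r_suc
  f["PPC"] <- drain["OAA"] + f["CSICDH"] + f["MDH"]
  f["PCK"] <- 0
  f["PYK"] <- f["ENO"] - f["PTS"] - drain["PEP"] - f["PPC"]
  f["LDH"] <- r_lac
  f["PFL"] <- f["PTS"] + f["PYK"] - drain["PYR"] - f["LDH"]
  f["THD"] <- drain["NADPH"] - f["CSICDH"]
  nadh_other <- f["LDH"] + f["MDH"] + f["NDH"] + f["THD"]
  f["ADH"] <- (f["GHD"] - nadh_other) / 2
  f["ACDH"] <- f["ADH"]
  f["PTA"] <- f["PFL"] - drain["ACCOA"] - f["CSICDH"] - f["ACDH"]
  f["ACK"] <- f["PTA"]
  f["ADK"] <- 0
  f["GROWTH"] <- mu
  f["NGAM"] <- f["PGK"] + f["PYK"] + f["ACK"] - f["PFK"] - drain["ATP"]
  f["ATPASE"] <- 0
  names(f) <- sub("\\..*$", "", names(f))
  f
}

#' Read or write a model configuration as YAML
#'
#' The configuration round-trips losslessly: `read_model_config()` applied to
#' the output of `write_model_config()` reproduces the configuration.
#'
#' @param path File path.
#' @param config A configuration list as returned by [default_model_config()].
#' @return `read_model_config()` returns a configuration list.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$species <- as.data.frame(cfg$species, stringsAsFactors = FALSE)
  for (i in seq_along(cfg$reactions)) {
    r <- cfg$reactions[[i]]
    for (fld in c("stoich", "km_f", "km_r", "hill_s", "stoich_exp")) {
      if (!is.null(r[[fld]])) r[[fld]] <- unlist(r[[fld]])
    }
    cfg$reactions[[i]] <- r
  }
  cfg$biomass <- unlist(cfg$biomass)
  cfg$reference$conc <- unlist(cfg$reference$conc)
  cfg$reference$flux <- unlist(cfg$reference$flux)
  cfg
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  ## named numeric vectors must become maps, not sequences, to keep names
  as_map <- function(x) if (is.null(x)) NULL else as.list(x)
  cfg <- config
  for (i in seq_along(cfg$reactions)) {
    for (fld in c("stoich", "km_f", "km_r", "hill_s", "stoich_exp")) {
      cfg$reactions[[i]][[fld]] <- as_map(cfg$reactions[[i]][[fld]])
    }
  }
  cfg$biomass <- as_map(cfg$biomass)
  cfg$reference$conc <- as_map(cfg$reference$conc)
  cfg$reference$flux <- as_map(cfg$reference$flux)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
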