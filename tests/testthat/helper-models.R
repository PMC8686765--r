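# cached builds shared across test files (building is cheap, scanning is not)
.fk_cache <- new.env(parent = emptyenv())

fk_model <- function(version = "v1") {
  key <- paste0("model_", version)
  if (is.null(.fk_cache[[key]])) .fk_cache[[key]] <- build_model(version = version)
  .fk_cache[[key]]
}

fk_wt_state <- function(version = "v1") {
  key <- paste0("wt_", version)
  if (is.null(.fk_cache[[key]])) {
    .fk_cache[[key]] <- steady_state(fk_model(version))
  }
  .fk_cache[[key]]
}

fk_scan <- function(version = "v1", by = 1) {
  key <- paste0("scan_", version, "_", by)
  if (is.null(.fk_cache[[key]])) {
    .fk_cache[[key]] <- scan_atpase(fk_model(version), seq(0, 85, by = by))
  }
  .fk_cache[[key]]
}

# minimal irreversible Michaelis-Menten chain as a kinetic_model:
# S_EX -> A -> B -> P_EX, used as an independently solvable MCA toy
toy_chain_config <- function(vmax = c(10, 8, 6), km = c(0.5, 1, 1)) {
  species <- data.frame(
    id = c("A", "B", "S_EX", "P_EX"),
    boundary = c(FALSE, FALSE, TRUE, TRUE),
    conc = c(1, 1, 10, 0),
    stringsAsFactors = FALSE
  )
  rxn <- function(st, v, k) {
    list(stoich = st, law = "convenience", reversible = FALSE,
         km_f = k, km_r = NULL, hill_s = NULL, drive = NA_real_,
         vmax = v, modifiers = list())
  }
  list(
    species = species,
    reactions = list(
      R1 = rxn(c(S_EX = -1, A = 1), vmax[1], c(S_EX = km[1])),
      R2 = rxn(c(A = -1, B = 1), vmax[2], c(A = km[2])),
      R3 = rxn(c(B = -1, P_EX = 1), vmax[3], c(B = km[3]))
    ),
    biomass = NULL,
    reference = list(conc = c(A = 1, B = 1, S_EX = 10, P_EX = 0),
                     flux = c(R1 = NA, R2 = NA, R3 = NA)),
    version = "v1"
  )
}

# toy fermentation network for the flux-analysis oracle
toy_ferm_model <- function(acetate_branch = FALSE) {
  rx <- list(
    GLYC = c(GLC = -1, PYR = 2, ATP = 2, ADP = -2),
    LDH = c(PYR = -1, LAC = 1),
    ATPM = c(ATP = -1, ADP = 1),
    EX_GLC = c(GLC = 1),
    EX_LAC = c(LAC = -1)
  )
  measured <- c(glc = "EX_GLC", lac = "EX_LAC")
  if (acetate_branch) {
    rx$PTAACK <- c(PYR = -1, ADP = -1, ATP = 1, ACE = 1)
    rx$ETH <- c(PYR = -1, ETH = 1)
    rx$EX_ACE <- c(ACE = -1)
    rx$EX_ETH <- c(ETH = -1)
    measured <- c(measured, ace = "EX_ACE", eth = "EX_ETH")
  }
  stoich_model(rx, measured = measured)
}

# measured rates of one strain as the named vector the mfa module expects
strain_rates <- function(condition, strain) {
  tab <- atpase_exchange_rates(condition)
  row <- tab[tab$strain == strain, ]
  c(mu = row$mu, glc = row$glc, eth = row$eth, ace = row$ace,
    "for" = row[["for"]], lac = row$lac, suc = row$suc)
}

strain_sds <- function(condition, strain) {
  tab <- atpase_exchange_rates(condition)
  row <- tab[tab$strain == strain, ]
  c(mu = row$sd_mu, glc = row$sd_glc, eth = row$sd_eth, ace = row$sd_ace,
    "for" = row$sd_for, lac = row$sd_lac, suc = row$sd_suc)
}
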