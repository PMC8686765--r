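#' Build a kinetic model from a configuration
#'
#' Validates the network structure (every species referenced by a reaction or
#' modifier must be declared, stoichiometric coefficients must be nonzero,
#' rate-law constants must be positive), assembles the stoichiometric matrix,
#' verifies the conserved moieties (adenylate ATP+ADP+AMP, NAD+NADH,
#' NADP+NADPH, CoA+acetyl-CoA, menaquinone MQ+MQH2), and calibrates every
#' unset vmax so that the configuration's reference state is an exact steady
#' state of the ODE system dx/dt = N v(x).
#'
#' @param config A model configuration, see [default_model_config()];
#'   defaults to the shipped network.
#' @param version Model version `"v1"` or `"v2"`; only used when `config` is
#'   not supplied (a supplied configuration carries its own version).
#' @return An object of class `kinetic_model`.
#' @examples
#' m <- build_model()
#' m$n_metabolites # 33
#' m$n_reactions   # 28
#' @export
build_model <- function(config = NULL, version = c("v1", "v2")) {
  if (is.null(config)) config <- default_model_config(match.arg(version))

  sp <- config$species
  if (anyDuplicated(sp$id)) stop("duplicate species ids in configuration")
  if (any(sp$conc < 0)) stop("negative species concentration in configuration")

  rxns <- config$reactions
  if (length(rxns) == 0) stop("configuration declares no reactions")

  ## structural validation
  for (id in names(rxns)) {
    r <- rxns[[id]]
    unknown <- setdiff(names(r$stoich), sp$id)
    if (length(unknown) > 0) {
      stop("reaction ", id, " references undeclared species: ",
           paste(unknown, collapse = ", "))
    }
    if (any(r$stoich == 0)) {
      stop("reaction ", id, " has a zero stoichiometric coefficient")
    }
    for (m in r$modifiers) {
      if (!(m$species %in% sp$id)) {
        stop("reaction ", id, " declares modifier on undeclared species ",
             m$species)
      }
      if (m$k <= 0) stop("non-positive modifier constant in reaction ", id)
      if (m$hill < 1) stop("Hill exponent < 1 in reaction ", id)
    }
    for (fld in c("km_f", "km_r")) {
      if (!is.null(r[[fld]]) && any(r[[fld]] <= 0)) {
        stop("non-positive Michaelis constant in reaction ", id)
      }
    }
    if (!is.na(r$vmax) && r$vmax < 0) {
      stop("negative vmax in reaction ", id)
    }
  }

  ## stoichiometric matrix (all species x reactions)
  N <- matrix(0, nrow(sp), length(rxns),
              dimnames = list(sp$id, names(rxns)))
  for (id in names(rxns)) {
    st <- rxns[[id]]$stoich
    N[names(st), id] <- st
  }
  dyn <- sp$id[!sp$boundary]
  N_dyn <- N[dyn, , drop = FALSE]

  ## every dynamic species must take part in at least one reaction
  orphan <- dyn[rowSums(N_dyn != 0) == 0]
  if (length(orphan) > 0) {
    stop("dynamic species in no reaction: ", paste(orphan, collapse = ", "))
  }

  ref_conc <- config$reference$conc
  ref_flux <- config$reference$flux

  ## reversible reactions: fix keq from the reference state and the
  ## configured net-drive fraction (drive = net flux / forward term;
  ## drive 0 marks reactions poised at equilibrium at the reference)
  for (id in names(rxns)) {
    r <- rxns[[id]]
    if (!isTRUE(r$reversible) || !is.null(r$keq)) next
    Fh <- prod((ref_conc[names(r$km_f)] / r$km_f)^kin_exp(r, names(r$km_f)))
    Rh <- prod((ref_conc[names(r$km_r)] / r$km_r)^kin_exp(r, names(r$km_r)))
    drv <- r$drive
    if (is.na(drv)) stop("reversible reaction ", id, " without drive or keq")
    rxns[[id]]$keq <- if (drv <= 0) Rh / Fh else Rh / (Fh * (1 - drv))
  }

  ## vmax calibration against the reference steady state
  for (id in names(rxns)) {
    r <- rxns[[id]]
    if (!is.na(r$vmax)) next
    r1 <- r; r1$vmax <- 1
    if (!is.null(r$vmax_modulation)) {
      r1$vmax <- pfl_vmax_modulation(list(vmax = 1,
                                          vmax_modulation = r$vmax_modulation),
                                     ref_conc[[r$vmax_modulation$species]])
    }
    unit_rate <- convenience_rate(r1, ref_conc)
    if (unit_rate <= 0) {
      stop("cannot calibrate vmax of reaction ", id,
           ": zero unit rate at the reference state")
    }
    rxns[[id]]$vmax <- unname(ref_flux[[id]] / unit_rate)
  }

  model <- structure(list(
    species = sp,
    reactions = rxns,
    N = N,
    N_dyn = N_dyn,
    dynamic_ids = dyn,
    boundary_ids = sp$id[sp$boundary],
    version = config$version,
    reference = list(conc = ref_conc, flux = ref_flux),
    n_metabolites = nrow(sp),
    n_reactions = length(rxns),
    n_dynamic = length(dyn)
  ), class = "kinetic_model")

  model$moieties <- detect_moieties(model)
  model$fast <- compile_rates(model)
  model
}

## kinetic exponents (default 1; explicit stoich_exp overrides, e.g. the
## squared ADP term of adenylate kinase)
kin_exp <- function(r, ids) {
  e <- rep(1, length(ids)); names(e) <- ids
  if (!is.null(r$stoich_exp)) {
    hit <- intersect(ids, names(r$stoich_exp))
    e[hit] <- r$stoich_exp[hit]
  }
  e
}

## conserved-moiety candidates checked against the left null space of N_dyn
detect_moieties <- function(model) {
  cand <- list(
    adenylate = c(ATP = 1, ADP = 1, AMP = 1),
    nicotinamide = c(NAD = 1, NADH = 1),
    nicotinamide_p = c(NADP = 1, NADPH = 1),
    coenzyme_a = c(COA = 1, ACCOA = 1),
    menaquinone = c(MQ = 1, MQH2 = 1)
  )
  out <- list()
  for (nm in names(cand)) {
    v <- cand[[nm]]
    if (!all(names(v) %in% model$dynamic_ids)) next
    y <- numeric(length(model$dynamic_ids))
    names(y) <- model$dynamic_ids
    y[names(v)] <- v
    if (max(abs(crossprod(y, model$N_dyn))) < 1e-9) {
      total <- sum(model$reference$conc[names(v)] * v)
      out[[nm]] <- list(species = names(v), weights = v, total = total)
    }
  }
  out
}

#' Stoichiometric matrix of a kinetic model
#'
#' @param model A [kinetic_model] object.
#' @param dynamic_only If `TRUE` (default) return only the rows of the
#'   dynamic (non-boundary) species, i.e. the matrix N of the ODE system
#'   dx/dt = N v(x).
#' @return A numeric matrix, species by reactions.
#' @export
stoichiometric_matrix <- function(model, dynamic_only = TRUE) {
  if (dynamic_only) model$N_dyn else model$N
}

#' Replace the maximal rate of one or more reactions
#'
#' @param model A [kinetic_model].
#' @param ... Named vmax values, e.g. `ATPASE = 40` (mmol/gDW/h).
#' @return The modified model.
#' @export
set_vmax <- function(model, ...) {
  vals <- list(...)
  for (id in names(vals)) {
    if (!(id %in% names(model$reactions))) stop("unknown reaction: ", id)
    if (vals[[id]] < 0) stop("negative vmax for reaction ", id)
    model$reactions[[id]]$vmax <- vals[[id]]
    if (!is.null(model$fast)) model$fast[[id]]$vmax <- vals[[id]]
  }
  model
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model of anaerobic central fermentative metabolism (",
      x$version, ")\n", sep = "")
  cat("  ", x$n_metabolites, " metabolites (", x$n_dynamic, " dynamic, ",
      length(x$boundary_ids), " boundary), ", x$n_reactions,
      " reactions\n", sep = "")
  cat("  conserved moieties:", paste(names(x$moieties), collapse = ", "), "\n")
  cat("  vmax(ATPASE) =", x$reactions$ATPASE$vmax, "mmol/gDW/h\n")
  invisible(x)
}

#' @export
summary.kinetic_model <- function(object, ...) {
  print(object)
  n_mod <- sum(vapply(object$reactions,
                      function(r) length(r$modifiers), integer(1)))
  cat("  allosteric modifier terms:", n_mod, "\n")
  rev <- names(Filter(function(r) isTRUE(r$reversible), object$reactions))
  cat("  reversible reactions:", paste(rev, collapse = ", "), "\n")
  invisible(object)
}
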