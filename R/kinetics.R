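#' Convenience-kinetics rate law
#'
#' Evaluates the generalized Michaelis-Menten (convenience kinetics) rate law
#' with multiplicative allosteric modifier terms. For irreversible reactions
#'
#' \deqn{v = v_{max} \prod_s \frac{(c_s/K_s)^{h_s}}{1+(c_s/K_s)^{h_s}}
#'       \prod_a \frac{c_a^h}{K_a^h + c_a^h}
#'       \prod_i \frac{K_i^h}{K_i^h + c_i^h}}
#'
#' and for reversible reactions the reversible convenience form
#' \eqn{v = v_{max}(F - R/k_{eq}) / (P_F + P_R - 1)} with
#' \eqn{F = \prod_s (c_s/K_s)^{|n_s|}}, \eqn{R = \prod_p (c_p/K_p)^{|n_p|}}
#' and \eqn{P_F, P_R} the corresponding products of \eqn{(1 + c/K)} terms,
#' multiplied by the same modifier terms.
#'
#' @param params A rate-law parameter list with elements `vmax`, `km_f`
#'   (named Michaelis constants of the forward reactants), and optionally
#'   `km_r`, `keq`, `hill_s` (per-substrate Hill exponents), `stoich_exp`
#'   (named kinetic exponents, defaulting to 1) and `modifiers` (a list of
#'   `list(species, role, k, hill)` entries with role `"activator"` or
#'   `"inhibitor"`).
#' @param conc Named concentration vector; must contain every species named in
#'   `km_f`, `km_r` and the modifiers.
#' @return Flux in mmol/gDW/h.
#' @examples
#' p <- list(vmax = 10, km_f = c(S = 2))
#' convenience_rate(p, c(S = 2)) # half-saturation: 5
#' @export
convenience_rate <- function(params, conc) {
  need <- c(names(params$km_f), names(params$km_r),
            vapply(params$modifiers, function(m) m$species, ""))
  missing <- setdiff(need, names(conc))
  if (length(missing) > 0) {
    stop("missing concentration(s) for declared reactant(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(all(conc[need] >= 0))

  sat_terms <- function(km, hill, expo) {
    c_over_k <- (conc[names(km)] / km)
    if (!is.null(hill)) {
      h <- rep(1, length(km)); names(h) <- names(km)
      h[names(hill)] <- hill
      c_over_k <- c_over_k^h
    }
    if (!is.null(expo)) {
      e <- rep(1, length(km)); names(e) <- names(km)
      hit <- intersect(names(km), names(expo))
      e[hit] <- expo[hit]
      c_over_k <- c_over_k^e
    }
    list(num = prod(c_over_k), den = prod(1 + c_over_k))
  }

  fwd <- sat_terms(params$km_f, params$hill_s, params$stoich_exp)
  if (isTRUE(params$reversible)) {
    rev <- sat_terms(params$km_r, NULL, params$stoich_exp)
    core <- (fwd$num - rev$num / params$keq) / (fwd$den + rev$den - 1)
  } else {
    core <- fwd$num / fwd$den
  }

  mods <- modifier_factor(params$modifiers, conc)
  unname(params$vmax * core * mods)
}

## product of multiplicative activation/inhibition terms
modifier_factor <- function(modifiers, conc) {
  out <- 1
  for (m in modifiers) {
    ch <- conc[[m$species]]^m$hill
    kh <- m$k^m$hill
    out <- out * if (m$role == "activator") ch / (kh + ch) else kh / (kh + ch)
  }
  out
}

#' Phosphofructokinase rate with dual ADP/ATP dependency
#'
#' The PFK rate law: convenience kinetics in the substrates F6P and ATP,
#' multiplied by an allosteric ADP activation term and a PEP inhibition term.
#' ATP is a substrate while ADP activates, so sweeping the ADP fraction
#' f = ADP/(ATP+ADP) at fixed total adenylate produces a biphasic flux curve
#' with a unique interior maximum: at low f the activator ADP is limiting, at
#' high f the co-substrate ATP is exhausted.
#'
#' @param params PFK parameter list (see [convenience_rate()]); the modifier
#'   list must contain the ADP activator and PEP inhibitor entries.
#' @param conc Named concentrations including F6P, ATP, ADP, PEP (and FBP,
#'   which is part of the PFK working point but does not enter this law).
#' @param clamp_adp_activation Optional numeric: if supplied, the ADP
#'   activation term is frozen at this value instead of being evaluated (used
#'   for the counterfactual scans without ADP activation).
#' @return Flux in mmol/gDW/h.
#' @export
pfk_rate <- function(params, conc, clamp_adp_activation = NULL) {
  if ((conc[["ATP"]] + conc[["ADP"]]) <= 0) {
    stop("total adenylate ATP+ADP must be positive")
  }
  if (is.null(clamp_adp_activation)) {
    return(convenience_rate(params, conc))
  }
  keep <- vapply(params$modifiers,
                 function(m) !(m$species == "ADP" && m$role == "activator"),
                 logical(1))
  p2 <- params
  p2$modifiers <- params$modifiers[keep]
  clamp_adp_activation * convenience_rate(p2, conc)
}

#' ATP-dependent modulation of the PFL maximal rate
#'
#' In model version 2 the effective vmax of pyruvate formate-lyase is scaled by
#' a hyperbolic factor \eqn{g(ATP) = g_{min} + (1-g_{min})\,ATP/(K_g + ATP)},
#' representing the lower PFL abundance observed at low ATP. g is monotone
#' non-decreasing, tends to 1 at high ATP and to `gmin` as ATP approaches 0.
#'
#' @param params Reaction parameter list carrying a `vmax_modulation` element
#'   with fields `gmin` and `kg` (set only in version-2 models).
#' @param atp ATP concentration (umol/gDW), non-negative.
#' @return Effective vmax (mmol/gDW/h).
#' @export
pfl_vmax_modulation <- function(params, atp) {
  mod <- params$vmax_modulation
  if (is.null(mod)) {
    stop("PFL vmax modulation is only defined for version-2 models")
  }
  stopifnot(atp >= 0)
  g <- mod$gmin + (1 - mod$gmin) * atp / (mod$kg + atp)
  params$vmax * g
}

#' Pyruvate inhibition factor of pyruvate kinase
#'
#' Model version 2 inhibits the PYK flux under high pyruvate:
#' \eqn{K_i^h / (K_i^h + PYR^h)}, a factor in (0, 1] that equals 1 at
#' PYR = 0 and decreases monotonically with pyruvate.
#'
#' @param params PYK parameter list of a version-2 model (its modifier list
#'   must contain the pyruvate inhibitor entry).
#' @param pyr Pyruvate concentration (umol/gDW).
#' @return Inhibition factor in (0, 1].
#' @export
pyk_pyruvate_inhibition <- function(params, pyr) {
  hit <- Filter(function(m) m$species == "PYR" && m$role == "inhibitor",
                params$modifiers)
  if (length(hit) == 0) {
    stop("pyruvate inhibition of PYK is only defined for version-2 models")
  }
  m <- hit[[1]]
  stopifnot(pyr >= 0)
  unname(m$k^m$hill / (m$k^m$hill + pyr^m$hill))
}

#' Evaluate all reaction rates of a model
#'
#' @param model A [kinetic_model] object.
#' @param conc Named concentration vector over all species (dynamic and
#'   boundary).
#' @param clamp_adp_activation Optional numeric; if supplied the ADP activation
#'   term of PFK is frozen at this value (see [scan_atpase()]).
#' @return Named flux vector (mmol/gDW/h) over the model's reactions.
#' @export
model_rates <- function(model, conc, clamp_adp_activation = NULL) {
  if (!is.null(model$fast)) {
    conc <- conc[model$species$id]
    return(eval_rates_fast(model$fast, conc, clamp_adp_activation))
  }
  model_rates_reference(model, conc, clamp_adp_activation)
}

## reference (name-based) evaluator; the fast indexed evaluator must agree
## with this one to machine precision
model_rates_reference <- function(model, conc, clamp_adp_activation = NULL) {
  v <- vapply(names(model$reactions), function(id) {
    r <- model$reactions[[id]]
    p <- r
    if (!is.null(r$vmax_modulation)) {
      p$vmax <- pfl_vmax_modulation(r, conc[[r$vmax_modulation$species]])
    }
    if (id == "PFK" && !is.null(clamp_adp_activation)) {
      pfk_rate(p, conc, clamp_adp_activation)
    } else {
      convenience_rate(p, conc)
    }
  }, numeric(1))
  names(v) <- names(model$reactions)
  v
}

## compile reactions to integer-indexed parameter tables for fast evaluation
compile_rates <- function(model) {
  sp <- model$species$id
  idx <- function(ids) match(ids, sp)
  lapply(model$reactions, function(r) {
    ef <- kin_exp(r, names(r$km_f))
    hf <- rep(1, length(r$km_f)); names(hf) <- names(r$km_f)
    if (!is.null(r$hill_s)) {
      hit <- intersect(names(hf), names(r$hill_s))
      hf[hit] <- r$hill_s[hit]
    }
    mods <- lapply(r$modifiers, function(m) {
      list(i = idx(m$species), kh = m$k^m$hill, h = m$hill,
           act = m$role == "activator",
           is_adp_act = m$species == "ADP" && m$role == "activator")
    })
    list(
      vmax = r$vmax,
      i_f = idx(names(r$km_f)), km_f = unname(r$km_f),
      e_f = unname(ef * hf),
      rev = isTRUE(r$reversible),
      i_r = if (!is.null(r$km_r)) idx(names(r$km_r)),
      km_r = unname(r$km_r),
      e_r = if (!is.null(r$km_r)) unname(kin_exp(r, names(r$km_r))),
      keq = r$keq,
      mods = mods,
      vmod = if (!is.null(r$vmax_modulation)) {
        list(i = idx(r$vmax_modulation$species),
             gmin = r$vmax_modulation$gmin, kg = r$vmax_modulation$kg)
      }
    )
  })
}

eval_rates_fast <- function(fast, conc, clamp = NULL) {
  n <- length(fast)
  v <- numeric(n)
  names(v) <- names(fast)
  for (k in seq_len(n)) {
    r <- fast[[k]]
    cf <- (conc[r$i_f] / r$km_f)^r$e_f
    if (r$rev) {
      cr <- (conc[r$i_r] / r$km_r)^r$e_r
      core <- (prod(cf) - prod(cr) / r$keq) /
        (prod(1 + cf) + prod(1 + cr) - 1)
    } else {
      core <- prod(cf) / prod(1 + cf)
    }
    vm <- r$vmax
    if (!is.null(r$vmod)) {
      a <- conc[r$vmod$i]
      vm <- vm * (r$vmod$gmin + (1 - r$vmod$gmin) * a / (r$vmod$kg + a))
    }
    m <- 1
    for (mo in r$mods) {
      if (!is.null(clamp) && names(fast)[k] == "PFK" && mo$is_adp_act) {
        m <- m * clamp
      } else {
        ch <- conc[mo$i]^mo$h
        m <- m * if (mo$act) ch / (mo$kh + ch) else mo$kh / (mo$kh + ch)
      }
    }
    v[k] <- vm * core * m
  }
  v
}

#' Adenylate energy charge
#'
#' \eqn{EC = ([ATP] + 0.5 [ADP]) / ([ATP] + [ADP] + [AMP])}, a number in
#' \[0, 1\] that is high in energetically healthy cells.
#'
#' @param conc Named concentrations containing ATP, ADP and AMP.
#' @return Energy charge.
#' @examples
#' energy_charge(c(ATP = 1, ADP = 2, AMP = 1)) # 0.5
#' @export
energy_charge <- function(conc) {
  a <- conc[["ATP"]]; d <- conc[["ADP"]]; m <- conc[["AMP"]]
  stopifnot(a >= 0, d >= 0, m >= 0)
  tot <- a + d + m
  if (tot == 0) stop("all adenylates are zero; energy charge undefined")
  (a + 0.5 * d) / tot
}
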