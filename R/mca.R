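#' Flux control coefficients at a steady state
#'
#' Computes the matrix of scaled flux control coefficients
#' \eqn{C^{J_i}_{e_k} = (v_k / J_i) \, \partial J_i / \partial v_{max,k}}
#' from the elasticity matrix via the control-analysis matrix relations on the
#' moiety-reduced system: with reduced stoichiometry \eqn{N_R}, link matrix
#' \eqn{L} and elasticities \eqn{\epsilon = \partial v / \partial x},
#' the unscaled flux control matrix is
#' \eqn{C = I - \epsilon L (N_R \epsilon L)^{-1} N_R}, which is then scaled by
#' the steady-state fluxes. Because every rate law is homogeneous of degree
#' one in its vmax, the scaled coefficients of each flux sum to one
#' (summation theorem).
#'
#' @param model A [kinetic_model].
#' @param state A converged [steady_state] of `model`.
#' @return An object of class `fcc_matrix`: list with `scaled` (fluxes x
#'   enzymes; rows of near-zero fluxes are `NA`), `unscaled`, `state`.
#' @export
compute_fccs <- function(model, state) {
  if (!isTRUE(state$converged)) stop("state is not a converged steady state")
  model <- sync_atpase(model, state)
  conc <- state$conc
  v <- state$flux
  dyn <- model$dynamic_ids

  E <- elasticity_matrix(model, conc, state$clamp_adp_activation)
  fcc_from_elasticities(model, state, E)
}

## align the model's ATPase expression with the one that produced a state
sync_atpase <- function(model, state) {
  va <- state$vmax_atpase
  if (!is.null(va) && "ATPASE" %in% names(model$reactions) &&
      !identical(va, model$reactions$ATPASE$vmax)) {
    model <- set_vmax(model, ATPASE = va)
  }
  model
}

## control matrix algebra given a precomputed elasticity matrix
fcc_from_elasticities <- function(model, state, E) {
  v <- state$flux
  red <- reduction_matrices(model)
  M <- red$N_R %*% E %*% red$L
  Minv <- tryCatch(solve(M), error = function(e) {
    stop("singular Jacobian at the steady state; ",
         "consider finite-difference control coefficients")
  })
  n_r <- model$n_reactions
  C_unscaled <- diag(n_r) - E %*% red$L %*% Minv %*% red$N_R
  dimnames(C_unscaled) <- list(names(model$reactions),
                               names(model$reactions))

  scaled <- C_unscaled * outer(1 / v, v)
  scaled[abs(v) < 1e-6, ] <- NA_real_
  structure(list(scaled = scaled, unscaled = C_unscaled,
                 flux = v, state = state),
            class = "fcc_matrix")
}

## numeric elasticities dv/dx over dynamic species (central differences)
elasticity_matrix <- function(model, conc, clamp = NULL) {
  dyn <- model$dynamic_ids
  E <- matrix(0, model$n_reactions, length(dyn),
              dimnames = list(names(model$reactions), dyn))
  for (s in dyn) {
    h <- max(1e-6 * conc[[s]], 1e-9)
    cp <- conc; cp[[s]] <- conc[[s]] + h
    cm <- conc; cm[[s]] <- max(conc[[s]] - h, 0)
    vp <- model_rates(model, cp, clamp)
    vm <- model_rates(model, cm, clamp)
    E[, s] <- (vp - vm) / (cp[[s]] - cm[[s]])
  }
  E
}

## reduced stoichiometry and link matrix from the conserved moieties
reduction_matrices <- function(model) {
  dyn <- model$dynamic_ids
  dep <- vapply(model$moieties, function(m) m$species[length(m$species)], "")
  indep <- setdiff(dyn, dep)
  L <- matrix(0, length(dyn), length(indep), dimnames = list(dyn, indep))
  L[indep, indep] <- diag(length(indep))
  for (nm in names(model$moieties)) {
    mo <- model$moieties[[nm]]
    d <- dep[[nm]]
    others <- setdiff(mo$species, d)
    L[d, others] <- -mo$weights[others] / mo$weights[d]
  }
  list(N_R = model$N_dyn[indep, , drop = FALSE], L = L, indep = indep)
}

#' @export
print.fcc_matrix <- function(x, ...) {
  cat("Flux control coefficients (", nrow(x$scaled), " fluxes x ",
      ncol(x$scaled), " enzymes)\n", sep = "")
  ok <- !is.na(x$scaled[, 1])
  dev <- max(abs(rowSums(x$scaled[ok, , drop = FALSE]) - 1))
  cat("  max |row sum - 1| over defined fluxes:", format(dev, digits = 3),
      "\n")
  if ("PTS" %in% rownames(x$scaled)) {
    top <- sort(abs(x$scaled["PTS", ]), decreasing = TRUE)[1:5]
    cat("  largest controls on PTS:",
        paste(names(top), round(x$scaled["PTS", names(top)], 3),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Monte Carlo resampling of saturation parameters preserving the steady state
#'
#' Draws `n` random variants of the model's Michaelis constants: every Km
#' (forward and reverse) is multiplied by an independent log-uniform factor
#' spanning `decades` orders of magnitude (10^U(-decades/2, +decades/2));
#' allosteric constants are left at their fitted values, so that the
#' regulatory structure itself is not redrawn. For each variant, the vmax of every
#' reaction is rescaled so that the reaction rate at the reference state's
#' concentrations reproduces the reference flux exactly (for reversible
#' reactions poised at equilibrium the scaled equilibrium constant is
#' re-derived instead); the supplied steady state is therefore a steady state
#' of every sampled model, by construction. Parameter draws under which that
#' steady state loses dynamic stability (the Jacobian of the moiety-reduced
#' system acquires an eigenvalue with positive real part) do not represent a
#' consistent alternative parameterization of the observed state and are
#' rejected and redrawn; the number of rejections is reported. Flux control
#' coefficients are recomputed for every accepted sample.
#'
#' @param model A [kinetic_model].
#' @param state A converged [steady_state] used as the preserved reference.
#' @param n Number of samples.
#' @param seed RNG seed (integer).
#' @param decades Total sampling range in orders of magnitude (default 2).
#' @return An object of class `fcc_samples`: list with `samples` (list of
#'   `fcc_matrix`), `n`, `seed`, `decades` and `sign_fractions` (matrix of
#'   the fraction of samples with positive FCC per flux/enzyme pair).
#' @export
sample_preserving_steady_state <- function(model, state, n = 200, seed = 1,
                                           decades = 2) {
  if (!isTRUE(state$converged)) stop("state is not a converged steady state")
  model <- sync_atpase(model, state)
  stopifnot(n >= 1, decades >= 0)
  set.seed(seed)
  red <- reduction_matrices(model)
  samples <- vector("list", n)
  n_rejected <- 0L
  i <- 1L
  attempts <- 0L
  while (i <= n) {
    attempts <- attempts + 1L
    if (attempts > 100 * n) {
      stop("too many unstable parameter draws; reference state appears ",
           "marginally stable")
    }
    mi <- resample_saturation(model, state, decades)
    E <- elasticity_matrix(mi, state$conc, state$clamp_adp_activation)
    J <- red$N_R %*% E %*% red$L
    if (decades > 0 &&
        max(Re(eigen(J, only.values = TRUE)$values)) >= 0) {
      n_rejected <- n_rejected + 1L
      next
    }
    samples[[i]] <- fcc_from_elasticities(mi, state, E)
    i <- i + 1L
  }
  pos <- Reduce(`+`, lapply(samples, function(f) {
    (f$scaled > 0) * 1
  }))
  structure(list(samples = samples, n = n, seed = seed, decades = decades,
                 n_rejected = n_rejected,
                 sign_fractions = pos / n, reference = state),
            class = "fcc_samples")
}

## one resampled model: redraw all saturation constants, restore the
## reference fluxes at the reference concentrations by vmax rescaling
resample_saturation <- function(model, state, decades) {
  conc <- state$conc
  v_ref <- state$flux
  half <- decades / 2
  draw <- function(k) k * 10^stats::runif(length(k), -half, half)

  for (id in names(model$reactions)) {
    r <- model$reactions[[id]]
    if (decades > 0) {
      if (!is.null(r$km_f)) r$km_f <- draw(r$km_f)
      if (!is.null(r$km_r)) r$km_r <- draw(r$km_r)
    }
    if (isTRUE(r$reversible)) {
      ## preserve the disequilibrium ratio rho = (R/keq)/F at the reference,
      ## so the reaction keeps its direction and relative reverse pressure
      Fo <- prod((conc[names(model$reactions[[id]]$km_f)] /
                    model$reactions[[id]]$km_f)^
                   kin_exp(r, names(r$km_f)))
      Ro <- prod((conc[names(model$reactions[[id]]$km_r)] /
                    model$reactions[[id]]$km_r)^
                   kin_exp(r, names(r$km_r)))
      rho <- (Ro / model$reactions[[id]]$keq) / Fo
      Fn <- prod((conc[names(r$km_f)] / r$km_f)^kin_exp(r, names(r$km_f)))
      Rn <- prod((conc[names(r$km_r)] / r$km_r)^kin_exp(r, names(r$km_r)))
      r$keq <- Rn / (Fn * rho)
    }
    r1 <- r; r1$vmax <- 1
    if (!is.null(r$vmax_modulation)) {
      r1$vmax <- pfl_vmax_modulation(list(vmax = 1,
                                          vmax_modulation = r$vmax_modulation),
                                     conc[[r$vmax_modulation$species]])
    }
    unit <- convenience_rate(r1, conc)
    if (abs(v_ref[[id]]) > 1e-12) {
      if (unit == 0 || sign(unit) != sign(v_ref[[id]])) {
        stop("resampling produced an inconsistent rate for ", id)
      }
      r$vmax <- unname(v_ref[[id]] / unit)
      if (r$vmax <= 0) stop("non-positive rescaled vmax for ", id)
    }
    model$reactions[[id]] <- r
  }
  model$fast <- compile_rates(model)
  model
}

#' Sign dominance of sampled flux control coefficients
#'
#' @param samples An `fcc_samples` object.
#' @param flux Flux (reaction) id whose control is examined.
#' @param enzyme Enzyme (reaction) id exerting the control.
#' @return Named vector with the fraction of samples in which the FCC is
#'   positive and negative.
#' @export
sign_dominance <- function(samples, flux, enzyme) {
  vals <- vapply(samples$samples, function(f) f$scaled[flux, enzyme], 0)
  c(positive = mean(vals > 0), negative = mean(vals < 0))
}

#' Steady-state effect of doubling enzyme levels
#'
#' For each listed reaction the vmax is doubled (corresponding to a doubling
#' of the enzyme level), the steady state is re-solved starting from the
#' reference state, and the resulting glucose uptake (PTS flux) is reported.
#'
#' @param model A [kinetic_model].
#' @param state Reference [steady_state].
#' @param reaction_ids Character vector of reaction ids to double.
#' @return Data frame with reaction, new PTS flux, relative change and
#'   convergence flag.
#' @export
predict_enzyme_doubling <- function(model, state, reaction_ids) {
  if (!isTRUE(state$converged)) stop("state is not a converged steady state")
  model <- sync_atpase(model, state)
  ref_pts <- state$flux[["PTS"]]
  x0 <- state$conc[model$dynamic_ids]
  rows <- lapply(reaction_ids, function(id) {
    if (!(id %in% names(model$reactions))) stop("unknown reaction: ", id)
    args <- list(model)
    args[[id]] <- 2 * model$reactions[[id]]$vmax
    m2 <- do.call(set_vmax, args)
    s <- steady_state(m2, x0, clamp_adp_activation =
                        state$clamp_adp_activation)
    data.frame(reaction = id, pts_flux = s$flux[["PTS"]],
               rel_change = s$flux[["PTS"]] / ref_pts - 1,
               converged = s$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference steady states matching measured strain phenotypes
#'
#' The wild type is the vmax(ATPase) = 0 steady state. For the low-, medium-
#' and high-copy ATPase strains the ATPase vmax is chosen as the scan grid
#' point whose steady-state glucose uptake is closest to the strain's
#' measured uptake rate, with the low/medium-copy strains matched on the
#' ascending branch of the response curve and the high-copy strain on the
#' descending branch beyond the peak.
#'
#' @param model A [kinetic_model].
#' @param label One of `"WT"`, `"LC"`, `"MC"`, `"HC"`.
#' @param scan Optional precomputed [scan_atpase()] result to avoid
#'   re-scanning.
#' @param targets Measured uptake rates (mmol/gDW/h) used for matching.
#' @return A [steady_state] with attribute `"vmax_atpase"`.
#' @export
reference_state <- function(model, label = c("WT", "LC", "MC", "HC"),
                            scan = NULL,
                            targets = c(LC = 16.38, MC = 17.70, HC = 5.13)) {
  label <- match.arg(label)
  if (label == "WT") {
    s <- steady_state(set_vmax(model, ATPASE = 0))
    attr(s, "vmax_atpase") <- 0
    return(s)
  }
  if (is.null(scan)) scan <- scan_atpase(model)
  su <- scan$summary
  peak <- which.max(su$glc_uptake)
  idx <- if (label == "HC") {
    cand <- seq(peak, nrow(su))
    cand[which.min(abs(su$glc_uptake[cand] - targets[["HC"]]))]
  } else {
    cand <- seq_len(peak)
    cand[which.min(abs(su$glc_uptake[cand] - targets[[label]]))]
  }
  s <- scan$states[[idx]]
  attr(s, "vmax_atpase") <- su$vmax_atpase[idx]
  s
}
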