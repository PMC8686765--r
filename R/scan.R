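#' Steady-state response scan over ATPase expression
#'
#' Recomputes the steady state of the model along a grid of ATPase vmax
#' values (the expression knob of the ATP-hydrolyzing F1-ATPase), solving
#' each grid point by continuation from the previous steady state. Optionally
#' the ADP activation term of phosphofructokinase is frozen (clamped) at its
#' wild-type value, the counterfactual that removes the biphasic response of
#' glucose uptake.
#'
#' @param model A [kinetic_model].
#' @param grid Increasing vector of ATPase vmax values (mmol/gDW/h),
#'   default 0 to 85 in steps of 1.
#' @param clamp_adp_activation If `TRUE`, evaluate the PFK ADP activation
#'   term once at the vmax = 0 steady state and keep it fixed along the scan.
#' @param tol_ss,t_max Passed to [steady_state()].
#' @return An object of class `atpase_scan`: a list with `grid`, `states`
#'   (list of [steady_state] objects), `summary` (data frame with one row per
#'   grid point: vmax_atpase, glucose uptake, ATPase flux, energy charge,
#'   growth rate, convergence flag) and `clamped_adp_activation`.
#' @export
scan_atpase <- function(model, grid = seq(0, 85, by = 1),
                        clamp_adp_activation = FALSE,
                        tol_ss = 1e-8, t_max = 1) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing")
  }
  if (any(grid < 0)) stop("negative ATPase vmax in grid")

  clamp_val <- NULL
  if (clamp_adp_activation) {
    wt <- steady_state(set_vmax(model, ATPASE = 0), tol_ss = tol_ss)
    clamp_val <- pfk_adp_activation_term(model, wt$conc)
  }

  states <- vector("list", length(grid))
  x <- model$reference$conc[model$dynamic_ids]
  for (i in seq_along(grid)) {
    s <- steady_state(set_vmax(model, ATPASE = grid[i]), x,
                      tol_ss = tol_ss, t_max = t_max,
                      clamp_adp_activation = clamp_val)
    states[[i]] <- s
    if (s$converged) x <- s$conc[model$dynamic_ids]
  }

  summ <- data.frame(
    vmax_atpase = grid,
    glc_uptake = vapply(states, function(s) s$flux[["PTS"]], 0),
    atpase_flux = vapply(states, function(s) s$flux[["ATPASE"]], 0),
    energy_charge = vapply(states, function(s) s$energy_charge, 0),
    growth_rate = vapply(states, function(s) s$flux[["GROWTH"]], 0),
    converged = vapply(states, function(s) s$converged, TRUE)
  )
  if (any(!summ$converged)) {
    warning(sum(!summ$converged), " grid point(s) did not converge; ",
            "the scan has gaps")
  }
  structure(list(grid = grid, states = states, summary = summ,
                 clamped_adp_activation = clamp_adp_activation,
                 clamp_value = clamp_val),
            class = "atpase_scan")
}

## the PFK ADP activation factor evaluated at a given state
pfk_adp_activation_term <- function(model, conc) {
  mods <- model$reactions$PFK$modifiers
  hit <- Filter(function(m) m$species == "ADP" && m$role == "activator", mods)
  if (length(hit) == 0) stop("PFK has no ADP activation term")
  m <- hit[[1]]
  unname(conc[["ADP"]]^m$hill / (m$k^m$hill + conc[["ADP"]]^m$hill))
}

#' Detect a biphasic response in a scanned quantity
#'
#' A discrete scan curve is called biphasic when its maximum lies strictly in
#' the interior of the grid and the terminal value lies at least `drop` below
#' the maximum (relative), which distinguishes a genuine rise-then-fall from
#' a plateau.
#'
#' @param x Numeric vector of responses along an increasing grid.
#' @param drop Required relative drop from peak to terminal value.
#' @return `TRUE` or `FALSE`.
#' @export
is_biphasic <- function(x, drop = 0.05) {
  i <- which.max(x)
  i > 1 && i < length(x) && x[length(x)] < x[i] * (1 - drop)
}

#' @export
print.atpase_scan <- function(x, ...) {
  s <- x$summary
  cat("ATPase expression scan, ", nrow(s), " points on [",
      min(s$vmax_atpase), ", ", max(s$vmax_atpase), "] mmol/gDW/h",
      if (x$clamped_adp_activation) " (PFK ADP activation clamped)",
      "\n", sep = "")
  i <- which.max(s$glc_uptake)
  cat("  glucose uptake: ", round(s$glc_uptake[1], 2), " at vmax 0, peak ",
      round(s$glc_uptake[i], 2), " at vmax ", s$vmax_atpase[i],
      ", terminal ", round(s$glc_uptake[nrow(s)], 2), "\n", sep = "")
  j <- which.max(s$atpase_flux)
  cat("  ATPase flux peak ", round(s$atpase_flux[j], 2), " at vmax ",
      s$vmax_atpase[j], "\n", sep = "")
  cat("  energy charge: ", round(s$energy_charge[1], 3), " -> ",
      round(s$energy_charge[nrow(s)], 3), "\n", sep = "")
  if (any(!s$converged)) {
    cat("  WARNING:", sum(!s$converged), "non-converged grid points\n")
  }
  invisible(x)
}

#' @export
plot.atpase_scan <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$vmax_atpase, s$glc_uptake, type = "l",
                 xlab = "", ylab = "glucose uptake [mmol/gDW/h]", ...)
  graphics::plot(s$vmax_atpase, s$energy_charge, type = "l",
                 xlab = "", ylab = "energy charge", ylim = c(0, 1))
  graphics::plot(s$vmax_atpase, s$atpase_flux, type = "l",
                 xlab = "vmax ATPase [mmol/gDW/h]",
                 ylab = "ATPase flux [mmol/gDW/h]")
  invisible(x)
}

#' Write a scan to a TSV file
#'
#' One row per grid point with vmax, all fluxes, all concentrations and the
#' energy charge.
#'
#' @param scan An `atpase_scan`.
#' @param path Output file.
#' @export
write_scan_tsv <- function(scan, path) {
  rows <- lapply(scan$states, function(s) {
    c(flux = as.list(s$flux), conc = as.list(s$conc),
      energy_charge = s$energy_charge, converged = s$converged)
  })
  df <- cbind(vmax_atpase = scan$grid,
              as.data.frame(do.call(rbind, lapply(rows, unlist))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
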