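#' Growth rate from a biomass time course
#'
#' The specific growth rate is the slope of the linear regression of
#' ln(biomass) against time within the exponential window.
#'
#' @param tc A time-course data frame with columns `time_h` and
#'   `biomass_gDW_l` (see [simulate_culture()] / [read_timecourse()]).
#' @param window Optional numeric length-2 vector (start, end time in h)
#'   restricting the fit; defaults to the whole series.
#' @return List with `mu` (1/h) and `r_squared`.
#' @examples
#' tc <- data.frame(time_h = 0:5, biomass_gDW_l = 0.1 * exp(0.3 * (0:5)))
#' fit_growth_rate(tc)$mu # 0.3
#' @export
fit_growth_rate <- function(tc, window = NULL) {
  if (!is.null(window)) {
    tc <- tc[tc$time_h >= window[1] & tc$time_h <= window[2], ]
  }
  if (nrow(tc) < 3) stop("need at least 3 time points in the window")
  if (any(tc$biomass_gDW_l <= 0)) stop("biomass must be positive")
  fit <- stats::lm(log(biomass_gDW_l) ~ time_h, data = tc)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(mu = unname(stats::coef(fit)[["time_h"]]), r_squared = r2)
}

#' Specific exchange rate during exponential growth
#'
#' \deqn{r_M = \mu \, (c_{M,e} - c_{M,s}) / (c_{X,e} - c_{X,s})}
#'
#' Positive values indicate net production, negative net consumption; tables
#' conventionally report uptake rates as positive magnitudes, which is a
#' presentation choice left to the caller.
#'
#' @param mu Growth rate (1/h).
#' @param c_m_start,c_m_end Metabolite concentrations (mmol/l) at the start
#'   and end of the window.
#' @param c_x_start,c_x_end Biomass concentrations (gDW/l) at the start and
#'   end of the window.
#' @return Specific rate (mmol/gDW/h).
#' @export
specific_rate_growth <- function(mu, c_m_start, c_m_end,
                                 c_x_start, c_x_end) {
  if (c_x_end == c_x_start) {
    stop("no biomass change; use specific_rate_arrest() for ",
         "growth-arrested cultures")
  }
  mu * (c_m_end - c_m_start) / (c_x_end - c_x_start)
}

#' Specific exchange rate under growth arrest
#'
#' \deqn{r_M = (c_{M,e} - c_{M,s}) / X_{Av} / \Delta t}
#'
#' @param c_m_start,c_m_end Metabolite concentrations (mmol/l).
#' @param x_avg Average biomass concentration (gDW/l), positive.
#' @param dt Length of the time period (h), positive.
#' @return Specific rate (mmol/gDW/h).
#' @export
specific_rate_arrest <- function(c_m_start, c_m_end, x_avg, dt) {
  if (dt <= 0) stop("time period must be positive")
  if (x_avg <= 0) stop("average biomass must be positive")
  (c_m_end - c_m_start) / x_avg / dt
}

#' Product yield by regression
#'
#' The yield of a metabolite is the slope of the regression of its
#' concentration change against the glucose concentration change over the
#' sampled time points; the biomass yield uses gDW/l against g/l glucose.
#'
#' @param tc Time-course data frame; analyte columns in mmol/l, `glc`
#'   for glucose.
#' @param analyte Column name of the product (e.g. `"lac"`), or
#'   `"biomass_gDW_l"` for the biomass yield.
#' @param glucose_molar_mass Used only for the biomass yield (g/mol).
#' @return Yield (mol/mol, or gDW/g for biomass).
#' @export
yield_regression <- function(tc, analyte, glucose_molar_mass = 180.16) {
  if (nrow(tc) < 3) stop("need at least 3 time points")
  d_glc <- tc$glc - tc$glc[1]
  if (all(d_glc == 0)) stop("no glucose consumed")
  d_m <- tc[[analyte]] - tc[[analyte]][1]
  if (analyte == "biomass_gDW_l") {
    d_glc <- d_glc * glucose_molar_mass / 1000  # mmol/l -> g/l
  }
  fit <- stats::lm(d_m ~ d_glc)
  abs(unname(stats::coef(fit)[["d_glc"]]))
}

#' Percent change relative to a reference
#'
#' 100 (value - reference) / reference. Rounding to one decimal is applied at
#' reporting time by the caller, not here.
#'
#' @param value,reference Numeric; `reference` must be nonzero.
#' @return Percent change.
#' @examples
#' percent_change(16.38, 14.05) # +16.6 (one decimal)
#' @export
percent_change <- function(value, reference) {
  if (reference == 0) stop("reference must be nonzero")
  100 * (value - reference) / reference
}

#' Cumulated carbon yield of the fermentation products
#'
#' Sum of the product yields weighted by their carbon numbers (ethanol and
#' acetate 2, formate 1, lactate 3, succinate 4), relative to the six carbon
#' atoms of glucose:
#' \deqn{Y_C = \sum_i Y_i \, C_i / 6 \quad
#'   [mol_{product\,C} / mol_{Glc\,C}]}
#'
#' @param yields Named numeric vector or list with entries `eth`, `ace`,
#'   `for`, `lac`, `suc` (mol/mol glucose).
#' @return Carbon yield (mol product C per mol glucose C).
#' @examples
#' carbon_yield(c(eth = 0, ace = 0, `for` = 0, lac = 2, suc = 0)) # 1.0
#' @export
carbon_yield <- function(yields) {
  carbons <- c(eth = 2, ace = 2, "for" = 1, lac = 3, suc = 4)
  yields <- unlist(yields)
  missing <- setdiff(names(carbons), names(yields))
  if (length(missing) > 0) {
    stop("missing yield(s) for: ", paste(missing, collapse = ", "))
  }
  sum(yields[names(carbons)] * carbons) / 6
}

#' Per-replicate rate summary of a set of time courses
#'
#' Computes the growth rate, specific exchange rates and yields for each
#' replicate time course, then the means and standard deviations across
#' replicates (each replicate is processed individually, as in the
#' experimental protocol).
#'
#' @param tcs List of time-course data frames (replicates).
#' @param mode `"growth"` (exponential) or `"arrest"` (constant biomass).
#' @param analytes Analyte column names to summarize.
#' @return A data frame with one row per quantity (`mu` and one `r_<analyte>`
#'   per analyte) and columns `mean` and `sd`.
#' @export
summarize_rates <- function(tcs, mode = c("growth", "arrest"),
                            analytes = c("glc", "eth", "ace", "for",
                                         "lac", "suc")) {
  mode <- match.arg(mode)
  per_rep <- lapply(tcs, function(tc) {
    n <- nrow(tc)
    if (mode == "growth") {
      mu <- fit_growth_rate(tc)$mu
      r <- vapply(analytes, function(a) {
        specific_rate_growth(mu, tc[[a]][1], tc[[a]][n],
                             tc$biomass_gDW_l[1], tc$biomass_gDW_l[n])
      }, 0)
    } else {
      mu <- 0
      dt <- tc$time_h[n] - tc$time_h[1]
      x_avg <- mean(tc$biomass_gDW_l)
      r <- vapply(analytes, function(a) {
        specific_rate_arrest(tc[[a]][1], tc[[a]][n], x_avg, dt)
      }, 0)
    }
    c(mu = mu, r)
  })
  mat <- do.call(rbind, per_rep)
  data.frame(quantity = c("mu", paste0("r_", analytes)),
             mean = colMeans(mat),
             sd = apply(mat, 2, stats::sd),
             row.names = NULL)
}
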