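#' Default adult exposure factors for dust contact
#'
#' The standard adult exposure-factor set used throughout the package: dust
#' ingestion rate, inhalation rate, body weight, exposure frequency and
#' duration, averaging time, exposed skin surface, skin adherence, dermal
#' absorption fraction and the particle emission factor. Averaging time
#' defaults to `365 * ED` days (non-carcinogenic convention), so `EF * ED / AT`
#' is 1 for the default profile; it stays an explicit field so alternative
#' averaging scenarios remain expressible.
#'
#' @param R_ing dust ingestion rate, mg/day
#' @param R_inh inhalation rate, m^3/day
#' @param BW body weight, kg
#' @param EF exposure frequency, day/year
#' @param ED exposure duration, year
#' @param AT averaging time, day; defaults to `365 * ED`
#' @param SA exposed skin surface, cm^2
#' @param SL skin adherence factor, mg/cm^2
#' @param ABS dermal absorption factor, dimensionless (at most 1)
#' @param PEF particle emission factor, m^3/kg
#' @return An object of class `exposure_factors` (a named list).
#' @examples
#' f <- exposure_factors()
#' f$EF * f$ED / f$AT  # 1 under the default averaging time
#' @export
exposure_factors <- function(R_ing = 100, R_inh = 20, BW = 70, EF = 365,
                             ED = 24, AT = 365 * ED, SA = 5700, SL = 0.07,
                             ABS = 0.001, PEF = 1.36e9) {
  f <- list(R_ing = R_ing, R_inh = R_inh, BW = BW, EF = EF, ED = ED,
            AT = AT, SA = SA, SL = SL, ABS = ABS, PEF = PEF)
  vals <- unlist(f)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_dustrisk("all exposure factors must be finite and strictly positive")
  if (ABS > 1) stop_dustrisk("ABS is a fraction and cannot exceed 1")
  structure(f, class = "exposure_factors")
}

#' @export
print.exposure_factors <- function(x, ...) {
  cat("Adult exposure factors:\n")
  for (nm in names(x)) cat(sprintf("  %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Reference doses (RfD) for the ten urban-dust metals
#'
#' Path-specific reference doses, in mg/kg/day, for Ba, Cd, Co, Cr, Cu, Fe,
#' Mn, Ni, Pb and Zn — the compilation most used in the urban-dust risk
#' literature. A reference dose is the daily intake of a metal judged
#' acceptable over a lifetime for the given exposure path.
#'
#' @return A data.frame with columns `metal`, `ing`, `derm`, `inh`.
#' @examples
#' rfd_table()[rfd_table()$metal == "Fe", ]
#' @export
rfd_table <- function() {
  data.frame(
    metal = c("Ba", "Cd", "Co", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn"),
    ing  = c(7e-2, 5e-4, 3e-2, 3e-3, 4e-2, 0.7, 2e-2, 2e-2, 14e-4, 0.300),
    derm = c(14e-3, 5e-6, 5e-6, 15e-6, 12e-3, 2.2e-4, 8e-4, 54e-4, 42e-5, 0.0600),
    inh  = c(5e-4, 2e-5, 6e-6, 1.4e-4, 1e-4, 7e-3, 5e-5, 2e-5, 1e-4, 0.300),
    stringsAsFactors = FALSE
  )
}

#' Worked Fe concentrations bracketing the reported ingestion hazard range
#'
#' The iron concentrations (mg/kg) that reproduce the published minimum and
#' maximum ingestion hazard quotients for Fe (6.10e-5 and 2.57e-4) under the
#' default adult exposure factors and the Fe ingestion reference dose. They
#' are obtained by inverting the ingestion dose chain
#' (`c = HQ * RfD_ing * BW / (R_ing * 1e-6)` when `EF * ED = AT`) and serve as
#' worked-example inputs for the hazard calculators.
#'
#' @return Named numeric vector with elements `min` and `max`.
#' @export
fe_reference_concentrations <- function() c(min = 29.89, max = 125.93)

#' Published three-factor reference solution for urban-dust metals
#'
#' A published oblique three-factor pattern for the ten metals (factors
#' labelled in extraction order F1-F3) together with its factor correlation
#' matrix. Shipped as a small reference fixture: it lets the factor-analysis
#' diagnostics (communalities under correlated factors, Hoffman complexity)
#' be exercised and cross-checked against published per-metal values without
#' access to the underlying concentration matrix.
#'
#' @return List with `loadings` (10 x 3 matrix, rows named by metal) and
#'   `factor_corr` (3 x 3 correlation matrix).
#' @export
fa_reference_solution <- function() {
  metals <- c("Cd", "Cr", "Cu", "Ni", "Pb", "Co", "Ba", "Fe", "Mn", "Zn")
  L <- matrix(c(
    -0.45, 0.03, 0.64,
    -0.15, 0.83, -0.15,
     0.53, 0.04, -0.08,
    -0.11, -0.08, 0.37,
     0.47, 0.23, 0.31,
     0.09, -0.03, 0.99,
     0.43, 0.41, -0.21,
     0.86, 0.11, 0.07,
     0.26, 0.77, 0.18,
     0.97, -0.03, -0.02
  ), nrow = 10, byrow = TRUE,
  dimnames = list(metals, c("F1", "F2", "F3")))
  Phi <- matrix(c(1, 0.54, 0.03,
                  0.54, 1, -0.02,
                  0.03, -0.02, 1), 3, 3,
                dimnames = list(c("F1", "F2", "F3"), c("F1", "F2", "F3")))
  list(loadings = L, factor_corr = Phi)
}
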