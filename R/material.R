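# Material parameters and the small calibration utilities linking osmotic
# compression measurements to elastic moduli.

#' Create a compressible Neo-Hookean material
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio in [0, 0.5).
#' @return a [Material].
#' @examples
#' m <- material(1800, 0.443)
#' bulkModulus(m)     # E / (3 (1 - 2 nu))
#' @export
material <- function(E, nu) new("Material", E = as.numeric(E),
                                nu = as.numeric(nu))

#' Fit the bulk modulus from an osmotic compression series
#'
#' Least-squares slope through the origin of applied osmotic pressure
#' versus volumetric strain \eqn{-\Delta V/V}, restricted to strains at or
#' below `strainCutoff` (the small-strain elastic regime). The intercept is
#' fixed at zero: zero pressure produces zero strain.
#'
#' @param pressure applied osmotic pressures, Pa (>= 0).
#' @param strain volumetric strains \eqn{-\Delta V/V}, dimensionless.
#' @param strainCutoff largest strain included in the fit.
#' @return named numeric vector with `kappa` (Pa) and `se` (standard error
#'   of the slope, Pa; 0 for an exact line).
#' @examples
#' s <- seq(0, 0.1, by = 0.02)
#' fitBulkModulus(6200 * s, s)     # kappa = 6200, se = 0
#' @export
fitBulkModulus <- function(pressure, strain, strainCutoff = 0.15) {
  stopifnot(length(pressure) == length(strain))
  if (any(!is.finite(pressure)) || any(!is.finite(strain)))
    stop("pressure and strain must be finite")
  if (any(pressure < 0)) stop("pressures must be non-negative")
  if (any(abs(strain) >= 1)) stop("strains must lie in (-1, 1)")
  keep <- strain <= strainCutoff
  if (sum(keep) < 2)
    stop("need at least 2 points with strain <= strainCutoff")
  fit <- lm(pressure[keep] ~ 0 + strain[keep])
  # summary.lm warns on an exact fit; se is simply 0 there
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  if (!is.finite(se)) se <- 0
  c(kappa = unname(coef(fit)[1]), se = se)
}

#' Young's modulus from the bulk modulus
#'
#' \eqn{E = 3\kappa(1 - 2\nu)}.
#'
#' @param kappa bulk modulus, Pa (> 0).
#' @param nu Poisson ratio in [0, 0.5).
#' @return Young's modulus, Pa.
#' @examples
#' youngFromBulk(6200, 0.443)    # about 2120 Pa
#' @export
youngFromBulk <- function(kappa, nu) {
  stopifnot(kappa > 0)
  if (any(nu >= 0.5) || any(nu < 0))
    stop("nu must lie in [0, 0.5): the incompressible limit has no finite E")
  3 * kappa * (1 - 2 * nu)
}

#' Bulk modulus from Young's modulus
#'
#' Inverse of [youngFromBulk()]: \eqn{\kappa = E/(3(1 - 2\nu))}.
#'
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson ratio in [0, 0.5).
#' @return bulk modulus, Pa.
#' @export
bulkFromYoung <- function(E, nu) {
  stopifnot(E > 0)
  if (any(nu >= 0.5) || any(nu < 0))
    stop("nu must lie in [0, 0.5)")
  E / (3 * (1 - 2 * nu))
}

#' Read an osmotic compression series from CSV
#'
#' Expects columns `pressure_Pa` and `volumetric_strain`.
#'
#' @param path CSV file path.
#' @return data.frame with `pressure_Pa` and `volumetric_strain`.
#' @export
readCompressionSeries <- function(path) {
  df <- read.csv(path)
  need <- c("pressure_Pa", "volumetric_strain")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  df[need]
}
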