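#' Rheology parameters
#'
#' Parameters of the empirical in-vitro blood rheology closure: the plasma
#' viscosity used in the Poiseuille resistance, and the flag controlling a
#' warning for sub-2.5 um diameters where the empirical laws are an
#' extrapolation.
#'
#' @param mu_plasma plasma dynamic viscosity in Pa s (default 1.2e-3).
#' @param warn_small_d warn when a diameter below `warn_below_um` is queried.
#' @param warn_below_um diameter threshold for the extrapolation warning (um).
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(mu_plasma = 1.2e-3, warn_small_d = TRUE,
                            warn_below_um = 2.5) {
  stopifnot(is.numeric(mu_plasma), length(mu_plasma) == 1L, mu_plasma > 0)
  structure(list(mu_plasma = mu_plasma, warn_small_d = warn_small_d,
                 warn_below_um = warn_below_um),
            class = "rheology_params")
}

# Fahraeus bracket: ht/hd = hd + (1 - hd) * B(d)
.fahraeus_bracket <- function(d) {
  1 + 1.7 * exp(-0.415 * d) - 0.6 * exp(-0.011 * d)
}

#' Discharge hematocrit from tube hematocrit
#'
#' Inverts the empirical Fahraeus relation
#' `ht/hd = hd + (1 - hd) (1 + 1.7 exp(-0.415 d) - 0.6 exp(-0.011 d))`
#' for the discharge hematocrit `hd`. The relation is quadratic in `hd`, so
#' the closed-form positive root is used. By the Fahraeus effect `hd >= ht`.
#'
#' @param ht tube hematocrit, in `[0, 1)`. Vectorized.
#' @param d vessel diameter in um. Vectorized (recycled against `ht`).
#' @param params a [rheology_params()] object.
#' @return discharge hematocrit `hd`, same length as the recycled inputs.
#' @export
discharge_hematocrit <- function(ht, d, params = rheology_params()) {
  n <- max(length(ht), length(d))
  ht <- rep_len(ht, n)
  d <- rep_len(d, n)
  if (any(ht < 0 | ht >= 1)) stop("tube hematocrit must lie in [0, 1)")
  if (any(d <= 0)) stop("diameter must be positive")
  if (isTRUE(params$warn_small_d) && any(d < params$warn_below_um)) {
    warning("diameter below ", params$warn_below_um,
            " um: hematocrit law evaluated outside its calibrated range")
  }
  B <- .fahraeus_bracket(d)
  # (1 - B) hd^2 + B hd - ht = 0
  a <- 1 - B
  hd <- ifelse(abs(a) < 1e-12,
               ht / B,
               (-B + sqrt(B^2 + 4 * a * ht)) / (2 * a))
  hd <- pmax(hd, ht) # guard rounding at ht ~ 0
  bad <- !is.finite(hd) | hd < 0 | hd >= 1
  if (any(bad & ht > 0)) {
    stop("no admissible discharge hematocrit in [0, 1) for ht = ",
         ht[which(bad)[1]], ", d = ", d[which(bad)[1]])
  }
  hd[ht == 0] <- 0
  hd
}

# apparent relative viscosity at hd = 0.45 (diameter in um)
.mu_045 <- function(d) {
  220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
}

# shape exponent of the hematocrit dependence (diameter in um)
.visc_shape_C <- function(d) {
  f <- 1 / (1 + 1e-11 * d^12)
  (0.8 + exp(-0.075 * d)) * (-1 + f) + f
}

#' Relative apparent viscosity of blood in a narrow tube
#'
#' Empirical in-vitro viscosity law. The tube hematocrit is first converted
#' to discharge hematocrit via [discharge_hematocrit()], then
#' `mu_vitro = 1 + (mu_0.45 - 1) * ((1 - hd)^C - 1) / ((1 - 0.45)^C - 1)`
#' with the diameter-dependent `mu_0.45(d)` and shape exponent `C(d)`.
#'
#' @inheritParams discharge_hematocrit
#' @return dimensionless relative apparent viscosity (1 for pure plasma).
#' @export
relative_viscosity <- function(ht, d, params = rheology_params()) {
  n <- max(length(ht), length(d))
  ht <- rep_len(ht, n)
  d <- rep_len(d, n)
  hd <- discharge_hematocrit(ht, d, params)
  m45 <- .mu_045(d)
  C <- .visc_shape_C(d)
  1 + (m45 - 1) * ((1 - hd)^C - 1) / ((1 - 0.45)^C - 1)
}

#' Effective hydrodynamic resistance of a vessel
#'
#' Poiseuille resistance of a circular tube multiplied by the relative
#' apparent viscosity accounting for the RBCs present:
#' `R_e = mu_vitro(ht, d) * 128 mu_plasma L / (pi d^4)` in SI units.
#'
#' @param d vessel diameter in um.
#' @param L vessel length in um.
#' @param ht tube hematocrit in `[0, 1)`.
#' @param params a [rheology_params()] object.
#' @return effective resistance in Pa s m^-3.
#' @export
effective_resistance <- function(d, L, ht = 0, params = rheology_params()) {
  if (any(d <= 0) || any(L <= 0)) stop("diameter and length must be positive")
  mu <- relative_viscosity(ht, d, params)
  mu * 128 * params$mu_plasma * (L * UM_TO_M) / (pi * (d * UM_TO_M)^4)
}

#' Tabulate the relative apparent viscosity over a (d, ht) grid
#'
#' @param d diameters in um.
#' @param ht tube hematocrits in `[0, 1)`.
#' @param params a [rheology_params()] object.
#' @return a data.frame with columns `d`, `ht`, `hd`, `mu_vitro`.
#' @export
rheology_table <- function(d = seq(3, 40, by = 1),
                           ht = seq(0.05, 0.45, by = 0.05),
                           params = rheology_params()) {
  g <- expand.grid(d = d, ht = ht, KEEP.OUT.ATTRS = FALSE)
  g$hd <- discharge_hematocrit(g$ht, g$d, params)
  g$mu_vitro <- relative_viscosity(g$ht, g$d, params)
  g
}
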