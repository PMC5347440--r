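#' Unit conversion constants
#'
#' Geometry is carried in micrometres, pressures at the user interface in
#' mmHg, and all hydrodynamic quantities internally in SI units.
#'
#' @format `MMHG_TO_PA` is the number of pascal per mmHg (133.322).
#' @name units
NULL

#' @rdname units
#' @export
MMHG_TO_PA <- 133.322

#' @rdname units
#' @export
UM_TO_M <- 1e-6

# cross-sectional lumen area of a vessel, m^2, from diameter in um
.lumen_area <- function(d_um) pi * (d_um * UM_TO_M)^2 / 4

# cylinder volume in m^3 from diameter and length in um
.vessel_volume <- function(d_um, L_um) .lumen_area(d_um) * (L_um * UM_TO_M)
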