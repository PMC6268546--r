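#' Convert an HPLC peak area to a concentration
#'
#' Single-point calibration against the time-zero reference injection: the
#' analyte concentration is `C_D0_nominal * area / area_t0`, i.e. the nominal
#' donor concentration scaled by the ratio of the observed peak area to the
#' peak area of the starting solution. Donor and acceptor wells share one
#' response factor per compound (same analyte, same chromatographic method),
#' so the ratio is all that is needed; no calibration curve is fitted.
#'
#' @param area observed peak area (detector response units, >= 0). Vectorised.
#' @param area_t0 reference peak area of the time-zero donor solution (> 0).
#'   Recycled against `area`.
#' @param C_D0_nominal nominal donor concentration (mol cm^-3).
#' @return Concentration(s) in mol cm^-3, linear in `area`.
#' @examples
#' peak_area_to_concentration(1250, 2500, 1e-7)  # half the t0 area -> 5e-8
#' @export
peak_area_to_concentration <- function(area, area_t0, C_D0_nominal) {
  if (any(!is.finite(area_t0)) || any(area_t0 <= 0))
    stop("area_t0 must be > 0 (no time-zero reference peak)", call. = FALSE)
  if (any(!is.finite(area)) || any(area < 0))
    stop("peak areas must be finite and >= 0", call. = FALSE)
  if (!is.numeric(C_D0_nominal) || any(C_D0_nominal <= 0))
    stop("C_D0_nominal must be > 0", call. = FALSE)
  C_D0_nominal * area / area_t0
}
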