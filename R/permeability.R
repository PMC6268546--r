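#' Regression linking membrane permeability to human skin permeability
#'
#' Coefficients of the published linear relationship between the effective
#' permeability coefficient measured through a 70% silicone oil / 30%
#' isopropyl myristate membrane and the human skin permeability coefficient,
#'
#'   log Kp = slope * log Pe + intercept,
#'
#' fitted on 31 reference compounds (r^2 = 0.81). The defaults are that fit:
#' slope 1.34 (se 0.12), intercept 0.28 (se 0.56), both on the log10(cm/s)
#' scale. The regression is never refitted here; its training data belong to
#' the reference study.
#'
#' @param slope,intercept regression coefficients.
#' @param slope_se,intercept_se their standard errors (carried for reporting,
#'   not used in point prediction).
#' @return An object of class `"kp_regression"`.
#' @export
kp_regression <- function(slope = 1.34, intercept = 0.28,
                          slope_se = 0.12, intercept_se = 0.56) {
  if (!is.finite(slope) || slope == 0)
    stop("regression slope must be finite and non-zero", call. = FALSE)
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 slope_se = slope_se, intercept_se = intercept_se),
            class = "kp_regression")
}

#' @export
print.kp_regression <- function(x, ...) {
  cat(sprintf("log Kp = (%g +/- %g) log Pe + (%g +/- %g)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Predict human skin log Kp from a membrane log Pe
#'
#' Applies the [kp_regression()] line. Reported values in the literature are
#' printed to two decimals with half-up rounding; set `rounded = TRUE` to get
#' that reporting convention (the raw value can differ in the third decimal).
#'
#' @param log_pe log10 effective permeability (cm/s). Vectorised; `NA` in,
#'   `NA` out.
#' @param regression a [kp_regression()] object.
#' @param rounded round half-up to 2 decimals for reporting?
#' @return Predicted log10 skin permeability coefficient(s).
#' @examples
#' log_kp_from_log_pe(-4.10)               # -5.2140
#' log_kp_from_log_pe(-4.10, rounded = TRUE)  # -5.21
#' @export
log_kp_from_log_pe <- function(log_pe, regression = kp_regression(),
                               rounded = FALSE) {
  stopifnot(inherits(regression, "kp_regression"))
  if (any(is.infinite(log_pe)))
    stop("log_pe must be finite (or NA)", call. = FALSE)
  out <- regression$slope * log_pe + regression$intercept
  if (rounded) round_half_up(out, 2L) else out
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals, as used
#' when printing log Kp values: ties go away from zero rather than to the
#' even digit as in [round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Membrane retention factor from a well's mass balance
#'
#' The retention factor R is the mole fraction of the dosed compound that is
#' neither in the donor nor the acceptor well at the end of incubation, i.e.
#' lost to the membrane, the filter and the plate materials:
#'
#'   R = 1 - C_D(t)/C_D(0) - (V_A/V_D) * C_A(t)/C_D(0)       ("actual")
#'   R = 1 - C_D(t)/C_D(0) - C_A(t)/C_D(0)                   ("equal")
#'
#' The `"equal"` form drops the volume ratio and is exact only for
#' V_A = V_D; it is provided because the literature often quotes it even for
#' unequal wells. Measurement noise can push the raw balance slightly outside
#' \[0, 1\]; raw values within `tol` of the interval are clamped to it and
#' flagged, values further out are an error (the triplet of concentrations is
#' then internally inconsistent).
#'
#' @param wells data frame with columns `C_D0`, `C_Dt`, `C_At` (mol cm^-3),
#'   one row per replicate well, as produced by [read_plate_table()].
#' @param geometry a [pampa_geometry()].
#' @param volume_mode `"actual"` (default) or `"equal"`.
#' @param tol clamp tolerance outside \[0, 1\] (absolute, default 0.05).
#' @return Numeric vector of retention fractions in \[0, 1\], with a logical
#'   attribute `"clamped"` marking wells whose raw balance was clamped.
#' @examples
#' w <- data.frame(C_D0 = 1e-7, C_Dt = 5e-8, C_At = 2.1e-8)
#' retention_factor(w, pampa_geometry())          # 1 - 0.5 - (4/3)*0.21 = 0.22
#' @export
retention_factor <- function(wells, geometry = pampa_geometry(),
                             volume_mode = c("actual", "equal"), tol = 0.05) {
  volume_mode <- match.arg(volume_mode)
  stopifnot(inherits(geometry, "pampa_geometry"))
  check_well_columns(wells)
  if (any(wells$C_D0 <= 0))
    stop("C_D0 must be > 0 to form concentration ratios", call. = FALSE)
  vr <- if (volume_mode == "actual") geometry$V_A / geometry$V_D else 1
  raw <- 1 - wells$C_Dt / wells$C_D0 - vr * wells$C_At / wells$C_D0
  bad <- raw < -tol | raw > 1 + tol
  if (any(bad))
    stop("inconsistent mass balance: raw retention ",
         paste(signif(raw[bad], 4), collapse = ", "),
         " outside [-", tol, ", 1+", tol, "] (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  # flag only genuine excursions; sub-epsilon overshoot is FP roundoff
  clamped <- raw < -1e-12 | raw > 1 + 1e-12
  structure(pmin(pmax(raw, 0), 1), clamped = clamped)
}

#' Permeation parameter C_A(t)/C_D(0)
#'
#' The fraction of the initial donor concentration found in the acceptor
#' compartment at the end of incubation — the assay's direct measure of how
#' much compound crossed the membrane.
#'
#' @inheritParams retention_factor
#' @return Numeric vector of acceptor/donor concentration ratios.
#' @export
permeation_parameter <- function(wells) {
  check_well_columns(wells)
  if (any(wells$C_D0 <= 0))
    stop("C_D0 must be > 0 to form concentration ratios", call. = FALSE)
  wells$C_At / wells$C_D0
}

check_well_columns <- function(wells) {
  need <- c("C_D0", "C_Dt", "C_At")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("well data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in need)
    if (any(!is.finite(wells[[nm]])) || any(wells[[nm]] < 0))
      stop("column ", nm, " must be finite and >= 0", call. = FALSE)
  invisible(wells)
}

#' Effective permeability coefficient from retention and permeation
#'
#' Inverts the two-compartment first-order transport model for the
#' permeability coefficient Pe (cm/s), with the effective diffusion area
#' `A_eff = A_filter * porosity` and the post-lag transport time
#' `t' = t_incubation - tau_lag`:
#'
#' * `"actual"` (default, exact for unequal well volumes):
#'   `Pe = -(V_A*V_D) / ((V_A+V_D) * A_eff * t') *
#'         ln(1 - (V_A+V_D) / ((1-R)*V_D) * p)`
#' * `"equal"` (the commonly quoted equal-volume form, with `V = V_D`):
#'   `Pe = -V / (2 * A_eff * t') * ln(1 - 2*p / (1-R))`
#'
#' where `p` is the permeation parameter C_A(t)/C_D(0) and `R` the retention
#' factor; `1 - R` rescales the equilibrium for the material trapped in the
#' membrane. When the acceptor is at or beyond its equilibrium concentration
#' the log argument is <= 0 and Pe is unidentifiable at this incubation time:
#' by default such wells yield a flagged `NA` (with a warning) so that plate
#' processing continues; set `undefined = "error"` to make them fatal.
#'
#' @param perm_param permeation parameter(s) C_A(t)/C_D(0), >= 0. Vectorised.
#' @param R retention fraction(s) in \[0, 1); recycled against `perm_param`.
#' @param geometry a [pampa_geometry()].
#' @param volume_mode `"actual"` or `"equal"`.
#' @param undefined what to do when the acceptor is at/over equilibrium.
#' @return Pe in cm/s (`NA` where undefined); 0 when `perm_param` is 0.
#' @examples
#' g <- pampa_geometry(V_A = 0.3)           # equal volumes, t' = 24000 s
#' effective_permeability(0.25, 0, g, "equal")  # 0.3/(2*0.196*24000)*ln 2
#' @export
effective_permeability <- function(perm_param, R, geometry = pampa_geometry(),
                                   volume_mode = c("actual", "equal"),
                                   undefined = c("na", "error")) {
  volume_mode <- match.arg(volume_mode)
  undefined <- match.arg(undefined)
  stopifnot(inherits(geometry, "pampa_geometry"))
  if (any(!is.finite(perm_param)) || any(perm_param < 0))
    stop("perm_param must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(R)) || any(R < 0))
    stop("R must be finite and >= 0", call. = FALSE)
  if (any(R >= 1))
    stop("R >= 1: the whole dose is retained; Pe is undefined", call. = FALSE)
  tp <- geometry$t_incubation - geometry$tau_lag
  if (tp <= 0) stop("post-lag time t_incubation - tau_lag must be > 0",
                    call. = FALSE)
  A_eff <- geometry$A_eff
  V_A <- geometry$V_A; V_D <- geometry$V_D
  if (volume_mode == "equal") V_A <- V_D  # V/(2 A t') form, V = V_D
  pref <- V_A * V_D / ((V_A + V_D) * A_eff * tp)
  arg <- 1 - (V_A + V_D) / ((1 - R) * V_D) * perm_param
  pe <- rep(NA_real_, length(arg))
  ok <- arg > 0
  pe[ok] <- -pref * log(arg[ok])
  if (any(!ok)) {
    msg <- paste0(sum(!ok), " well(s) at or over acceptor equilibrium; ",
                  "Pe undefined at this incubation time")
    if (undefined == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                    call. = FALSE)
  }
  pe
}

#' Aggregate replicate permeability results per compound
#'
#' Collapses per-well results to one row per compound: mean and sample
#' standard deviation (n-1 denominator) of the retention factor, the
#' permeation parameter and log10 Pe. log Pe is averaged in the log domain
#' (permeabilities are reported and compared as log Pe +/- sd). Wells with an
#' undefined Pe are excluded from the log Pe statistics but still counted and
#' contribute to the R/permeation means. log Kp is predicted from the mean
#' log Pe. SD columns are `NA` for compounds with a single usable replicate.
#'
#' @param results per-well results with columns `compound`, `R`, `perm`,
#'   `log_Pe` (as built by [pampa()]; `log_Pe` may contain `NA` for
#'   undefined wells).
#' @param regression a [kp_regression()] used for log Kp.
#' @param rule a [permeate_rule()] used for the group label.
#' @return Data frame, one row per compound in order of first appearance:
#'   `compound`, `n`, `n_pe_defined`, `R_mean`, `R_sd`, `perm_mean`,
#'   `perm_sd`, `logPe_mean`, `logPe_sd`, `logKp`, `logKp_2dp`, `group`,
#'   `below_detection_R` (TRUE when the mean retention is under 1%, the
#'   "<1" reporting convention).
#' @export
aggregate_replicates <- function(results, regression = kp_regression(),
                                 rule = permeate_rule()) {
  need <- c("compound", "R", "perm", "log_Pe")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(results$compound)
  rows <- lapply(ids, function(id) {
    r <- results[results$compound == id, , drop = FALSE]
    lp <- r$log_Pe[!is.na(r$log_Pe)]
    n_def <- length(lp)
    if (n_def == 0L)
      warning("compound ", id, ": no well with a defined Pe; ",
              "log Pe/log Kp unreported", call. = FALSE)
    sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
    logpe_mean <- if (n_def) mean(lp) else NA_real_
    data.frame(
      compound = id, n = nrow(r), n_pe_defined = n_def,
      R_mean = mean(r$R), R_sd = sd_or_na(r$R),
      perm_mean = mean(r$perm), perm_sd = sd_or_na(r$perm),
      logPe_mean = logpe_mean, logPe_sd = sd_or_na(lp),
      logKp = if (n_def) log_kp_from_log_pe(logpe_mean, regression)
              else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$logKp_2dp <- round_half_up(out$logKp, 2L)
  out$group <- classify_permeate(out$R_mean, out$perm_mean, rule)
  out$below_detection_R <- out$R_mean < 0.01
  rownames(out) <- NULL
  out
}
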