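#' Fit permeability parameters to a PAMPA plate
#'
#' The package's central reduction: takes per-well donor/acceptor
#' concentrations, computes for each replicate the membrane retention
#' factor, the permeation parameter C_A(t)/C_D(0), the effective
#' permeability coefficient Pe (and log10 Pe), and the predicted human skin
#' log Kp; then aggregates replicates per compound (mean, sample SD, log Pe
#' averaged in the log domain) and classifies each compound into permeate
#' group I, II or III.
#'
#' Robustness conventions, chosen so one bad well never aborts a plate:
#' retention factors within `clamp_tol` outside \[0, 1\] are clamped and
#' flagged (further out is an error); wells at or beyond acceptor
#' equilibrium — where Pe is unidentifiable at this incubation time — get a
#' flagged `NA` Pe, are excluded from the log Pe statistics, but still
#' count towards retention/permeation means.
#'
#' @param data wells as a data frame with columns `compound`, `replicate`,
#'   `C_D0`, `C_Dt`, `C_At` (see [read_plate_table()]), or a path to a
#'   plate CSV in `"concentrations"` layout.
#' @param geometry a [pampa_geometry()].
#' @param volume_mode `"actual"` (exact unequal-volume inversion, the
#'   default) or `"equal"` (the commonly quoted equal-volume form); the two
#'   coincide when `V_A == V_D`.
#' @param regression a [kp_regression()] for log Kp prediction.
#' @param rule a [permeate_rule()] for group assignment.
#' @param clamp_tol clamp tolerance for slightly out-of-range retention.
#' @return An object of class `"pampa"` with components `wells` (per
#'   replicate results), `compounds` (per-compound summaries, see
#'   [aggregate_replicates()]), and the `geometry`, `volume_mode`,
#'   `regression`, `rule` and `call` used.
#' @seealso [summary.pampa()], [coef.pampa()], [predict.pampa()],
#'   [simulate.pampa()], [plot.pampa()]
#' @examples
#' plate <- simulate_plate(c("fast", "slow"), Pe = c(2e-5, 5e-7),
#'                         R = c(0.4, 0.05), noise_cv = 0, seed = 1)
#' csv <- tempfile(fileext = ".csv")
#' utils::write.csv(plate, csv, row.names = FALSE)
#' fit <- pampa(read_plate_table(csv, mode = "areas"))
#' coef(fit)
#' @export
pampa <- function(data, geometry = pampa_geometry(),
                  volume_mode = c("actual", "equal"),
                  regression = kp_regression(), rule = permeate_rule(),
                  clamp_tol = 0.05) {
  volume_mode <- match.arg(volume_mode)
  stopifnot(inherits(geometry, "pampa_geometry"),
            inherits(regression, "kp_regression"),
            inherits(rule, "permeate_rule"))
  if (is.character(data) && length(data) == 1L)
    data <- read_plate_table(data, geometry, mode = "concentrations")
  need <- c("compound", "replicate", "C_D0", "C_Dt", "C_At")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("plate data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("empty plate data", call. = FALSE)

  wells <- data[, need]
  R <- retention_factor(wells, geometry, volume_mode, tol = clamp_tol)
  wells$R <- as.numeric(R)
  wells$R_clamped <- attr(R, "clamped")
  if (any(wells$R_clamped))
    warning(sum(wells$R_clamped),
            " well(s) with retention clamped into [0, 1]", call. = FALSE)
  wells$perm <- permeation_parameter(wells)

  wells$Pe <- NA_real_
  sat <- wells$R >= 1           # fully retained: nothing left to permeate
  if (any(sat))
    warning(sum(sat), " well(s) with R = 1; Pe undefined", call. = FALSE)
  if (any(!sat))
    wells$Pe[!sat] <- effective_permeability(
      wells$perm[!sat], wells$R[!sat], geometry, volume_mode,
      undefined = "na")
  zero <- !is.na(wells$Pe) & wells$Pe == 0
  wells$log_Pe <- ifelse(is.na(wells$Pe) | zero, NA_real_,
                         log10(wells$Pe))
  if (any(zero))
    warning(sum(zero), " well(s) with no measurable transfer; ",
            "log Pe unreported", call. = FALSE)
  wells$log_Kp <- ifelse(is.na(wells$log_Pe), NA_real_,
                         log_kp_from_log_pe(wells$log_Pe, regression))

  compounds <- aggregate_replicates(wells, regression, rule)
  structure(list(wells = wells, compounds = compounds, geometry = geometry,
                 volume_mode = volume_mode, regression = regression,
                 rule = rule, call = match.call()),
            class = "pampa")
}

#' @export
print.pampa <- function(x, ...) {
  cat("PAMPA permeability fit (volume mode: ", x$volume_mode, ")\n", sep = "")
  cat(sprintf("  %d compound(s), %d well(s)\n",
              nrow(x$compounds), nrow(x$wells)))
  tab <- x$compounds
  show <- data.frame(compound = tab$compound, n = tab$n,
                     `R%` = signif(100 * tab$R_mean, 3),
                     `perm%` = signif(100 * tab$perm_mean, 3),
                     logPe = round(tab$logPe_mean, 2),
                     logKp = tab$logKp_2dp, group = tab$group,
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Summarise a PAMPA fit
#'
#' Per-compound triplicate statistics plus a per-group census
#' ([summarize_groups()]) and counts of flagged wells.
#'
#' @param object a [pampa()] fit.
#' @param ... unused.
#' @return An object of class `"summary.pampa"`.
#' @export
summary.pampa <- function(object, ...) {
  structure(list(compounds = object$compounds,
                 groups = summarize_groups(object$compounds),
                 n_wells = nrow(object$wells),
                 n_clamped = sum(object$wells$R_clamped),
                 n_undefined_pe = sum(is.na(object$wells$log_Pe)),
                 volume_mode = object$volume_mode),
            class = "summary.pampa")
}

#' @export
print.summary.pampa <- function(x, ...) {
  cat("PAMPA fit summary (volume mode: ", x$volume_mode, ")\n", sep = "")
  cat(sprintf("  wells: %d (%d clamped R, %d undefined Pe)\n",
              x$n_wells, x$n_clamped, x$n_undefined_pe))
  tab <- x$compounds
  show <- data.frame(
    compound = tab$compound, n = tab$n,
    `R% (mean+/-sd)` = paste0(ifelse(tab$below_detection_R, "<1",
                                     signif(100 * tab$R_mean, 3)),
                              ifelse(is.na(tab$R_sd), "",
                                     paste0(" +/- ",
                                            signif(100 * tab$R_sd, 2)))),
    `perm%` = signif(100 * tab$perm_mean, 3),
    logPe = round(tab$logPe_mean, 2), logKp = tab$logKp_2dp,
    group = tab$group, check.names = FALSE)
  print(show, row.names = FALSE)
  cat("\nGroup census:\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Extract per-compound coefficients of a PAMPA fit
#'
#' @param object a [pampa()] fit.
#' @param ... unused.
#' @return Numeric matrix with one row per compound and columns `R`,
#'   `perm`, `Pe`, `logPe`, `logKp` (linear Pe back-transformed from the
#'   log-domain mean).
#' @export
coef.pampa <- function(object, ...) {
  tab <- object$compounds
  m <- cbind(R = tab$R_mean, perm = tab$perm_mean,
             Pe = 10^tab$logPe_mean, logPe = tab$logPe_mean,
             logKp = tab$logKp)
  rownames(m) <- tab$compound
  m
}

#' Predict human skin log Kp from a PAMPA fit
#'
#' With no `newdata`, returns the predicted log Kp of the fitted compounds.
#' `newdata` may be a numeric vector of log Pe values or a data frame with
#' a `logPe_mean` (or `log_Pe`) column, and is pushed through the fit's
#' regression.
#'
#' @param object a [pampa()] fit.
#' @param newdata optional new log Pe values.
#' @param rounded round half-up to 2 decimals (reporting convention)?
#' @param ... unused.
#' @return Named numeric vector of predicted log Kp values.
#' @export
predict.pampa <- function(object, newdata = NULL, rounded = FALSE, ...) {
  if (is.null(newdata)) {
    out <- log_kp_from_log_pe(object$compounds$logPe_mean,
                              object$regression, rounded)
    names(out) <- object$compounds$compound
    return(out)
  }
  lp <- if (is.data.frame(newdata)) {
    col <- intersect(c("logPe_mean", "log_Pe", "logPe"), names(newdata))[1]
    if (is.na(col))
      stop("newdata needs a logPe_mean (or log_Pe) column", call. = FALSE)
    newdata[[col]]
  } else as.numeric(newdata)
  log_kp_from_log_pe(lp, object$regression, rounded)
}

#' Replicate residuals of a PAMPA fit
#'
#' Deviations of each well's log Pe from its compound's log-domain mean —
#' the replicate scatter behind the reported "+/- sd". `NA` for wells with
#' an undefined Pe.
#'
#' @param object a [pampa()] fit.
#' @param ... unused.
#' @return Numeric vector, one element per well.
#' @export
residuals.pampa <- function(object, ...) {
  mu <- object$compounds$logPe_mean[
    match(object$wells$compound, object$compounds$compound)]
  object$wells$log_Pe - mu
}

#' Simulate new plates from a PAMPA fit
#'
#' Parametric simulation: the fitted per-compound (Pe, R) become the ground
#' truth of [simulate_plate()], giving new synthetic plates with the same
#' geometry. Compounds whose Pe is undefined are dropped with a warning.
#'
#' @param object a [pampa()] fit.
#' @param nsim number of plates.
#' @param seed optional seed (plate i uses `seed + i - 1`).
#' @param noise_cv,n_replicates passed to [simulate_plate()].
#' @param ... unused.
#' @return A list of `nsim` plate data frames (peak-area layout).
#' @export
simulate.pampa <- function(object, nsim = 1, seed = NULL, noise_cv = 0.02,
                           n_replicates = 3L, ...) {
  tab <- object$compounds
  usable <- !is.na(tab$logPe_mean)
  if (!all(usable))
    warning("dropping ", sum(!usable),
            " compound(s) with undefined Pe from simulation", call. = FALSE)
  tab <- tab[usable, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no compound with a defined Pe", call. = FALSE)
  lapply(seq_len(nsim), function(i)
    simulate_plate(tab$compound, Pe = 10^tab$logPe_mean, R = tab$R_mean,
                   geometry = object$geometry, noise_cv = noise_cv,
                   n_replicates = n_replicates,
                   seed = if (is.null(seed)) NULL else seed + i - 1L))
}

#' Retention/permeation map of a PAMPA fit
#'
#' Base-graphics scatter of the per-compound permeation parameter against
#' the retention factor (both as %), with the classification thresholds as
#' dashed lines — the plane on which groups I (lower left), II (upper
#' left) and III (lower right) live.
#'
#' @param x a [pampa()] fit.
#' @param labels draw compound ids next to the points?
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.pampa <- function(x, labels = TRUE, ...) {
  tab <- x$compounds
  Rp <- 100 * tab$R_mean; Pp <- 100 * tab$perm_mean
  graphics::plot(Rp, Pp, pch = 21, bg = c("grey30", "white", "grey70",
                                          "red")[as.integer(tab$group)],
                 xlab = "membrane retention R (%)",
                 ylab = "permeation C_A(t)/C_D(0) (%)",
                 xlim = c(0, max(100, Rp)), ylim = c(0, max(100, Pp)), ...)
  graphics::abline(v = 100 * x$rule$retention_threshold, lty = 2)
  graphics::abline(h = 100 * x$rule$permeation_threshold, lty = 2)
  if (labels)
    graphics::text(Rp, Pp, tab$compound, pos = 3, cex = 0.6)
  invisible(x)
}
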