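#' Noise-free two-compartment well timecourse
#'
#' Forward model of one PAMPA well: a donor and an acceptor compartment
#' separated by the membrane, with first-order passive transport and two
#' idealisations matching how the assay is reduced to numbers. Membrane
#' retention is an instantaneous mole-fraction sink — a fraction `R` of the
#' dose is removed at the lag boundary and never returns — and acceptor
#' accumulation starts only after the lag time `tau_lag`, when the
#' transmembrane gradient has stabilised. After the lag,
#'
#'   C_A(t) = C_eq * (1 - exp(-k * (t - tau_lag)))
#'
#' with equilibrium concentration `C_eq = (1-R) * C_D0 * V_D / (V_A + V_D)`
#' and rate constant `k = Pe * A_eff * (1/V_A + 1/V_D)`; the donor follows
#' from exact mass balance, `C_D(t) = (1-R) * C_D0 - (V_A/V_D) * C_A(t)`.
#' Before and at the lag boundary `C_A = 0` and `C_D = (1-R) * C_D0`.
#'
#' This forward model is the exact inverse of [effective_permeability()]'s
#' `"actual"` mode, which is what makes noise-free round-trip recovery of
#' (Pe, R) a machine-precision identity.
#'
#' @param t time(s) since the start of incubation (s, >= 0). Vectorised.
#' @param Pe true effective permeability (cm/s, >= 0).
#' @param R true retention fraction in \[0, 1).
#' @param geometry a [pampa_geometry()]; supplies volumes, `A_eff`,
#'   `tau_lag` and the initial donor concentration `C_D0_nominal`.
#' @return Data frame with columns `t`, `C_D`, `C_A` (mol cm^-3).
#' @examples
#' tc <- simulate_well_timecourse(c(0, 3600, 25200), Pe = 2e-5, R = 0.4)
#' @export
simulate_well_timecourse <- function(t, Pe, R, geometry = pampa_geometry()) {
  stopifnot(inherits(geometry, "pampa_geometry"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (!is.finite(Pe) || Pe < 0) stop("Pe must be >= 0", call. = FALSE)
  if (!is.finite(R) || R < 0 || R >= 1)
    stop("R must be in [0, 1)", call. = FALSE)
  C0 <- geometry$C_D0_nominal
  V_A <- geometry$V_A; V_D <- geometry$V_D
  C_eq <- (1 - R) * C0 * V_D / (V_A + V_D)
  k <- Pe * geometry$A_eff * (1 / V_A + 1 / V_D)
  dt <- pmax(t - geometry$tau_lag, 0)
  C_A <- C_eq * (1 - exp(-k * dt))
  C_D <- (1 - R) * C0 - (V_A / V_D) * C_A
  data.frame(t = t, C_D = C_D, C_A = C_A)
}

#' Simulate a PAMPA plate table with HPLC peak-area noise
#'
#' Generates the raw table a plate run would produce: for each compound,
#' `n_replicates` wells evaluated with [simulate_well_timecourse()] at the
#' incubation endpoint, then converted to detector peak areas with
#' multiplicative Gaussian noise,
#'
#'   area = response_factor * C * (1 + eps),  eps ~ N(0, noise_cv),
#'
#' truncated at zero (a detector never reports a negative area). One noise
#' draw is made per measurement — time-zero donor, endpoint donor, endpoint
#' acceptor — in row-major order over (compound, replicate), so a given seed
#' reproduces the table byte for byte. The default 2% CV is a synthetic
#' assumption representative of HPLC peak-area repeatability; no
#' experimentally derived value exists for this assay.
#'
#' @param compounds character vector of unique compound ids.
#' @param Pe true permeabilities (cm/s), recycled over `compounds`.
#' @param R true retention fractions in \[0, 1), recycled likewise.
#' @param geometry a [pampa_geometry()].
#' @param noise_cv coefficient of variation of the peak-area measurement
#'   (fraction; 0 gives a noise-free plate).
#' @param n_replicates wells per compound (default 3, the triplicate design).
#' @param seed optional integer seed for the plate's pseudo-random stream.
#' @param response_factor detector response per unit concentration
#'   (arbitrary units; cancels in the time-zero ratio quantitation).
#' @param output `"areas"` (default; columns `area_t0`, `area_donor_t`,
#'   `area_acceptor_t`) or `"concentrations"` (noisy `C_D0`, `C_Dt`, `C_At`).
#'   Both layouts are readable by [read_plate_table()] in the matching mode.
#' @return Data frame with `n_replicates` rows per compound: `compound`,
#'   `replicate`, and the three measurement columns.
#' @examples
#' plate <- simulate_plate(c("A", "B"), Pe = c(2e-5, 1e-6), R = c(0.4, 0.1),
#'                         seed = 1)
#' @export
simulate_plate <- function(compounds, Pe, R, geometry = pampa_geometry(),
                           noise_cv = 0.02, n_replicates = 3L, seed = NULL,
                           response_factor = 1,
                           output = c("areas", "concentrations")) {
  output <- match.arg(output)
  stopifnot(inherits(geometry, "pampa_geometry"))
  if (anyDuplicated(compounds))
    stop("duplicate compound ids in a simulated plate", call. = FALSE)
  if (!is.finite(noise_cv) || noise_cv < 0)
    stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (response_factor <= 0)
    stop("response_factor must be > 0", call. = FALSE)
  nC <- length(compounds)
  Pe <- rep_len(Pe, nC); R <- rep_len(R, nC)
  if (!is.null(seed)) set.seed(as.integer(seed))

  end <- vapply(seq_len(nC), function(i) {
    tc <- simulate_well_timecourse(geometry$t_incubation, Pe[i], R[i],
                                   geometry)
    c(tc$C_D, tc$C_A)
  }, numeric(2))
  idx <- rep(seq_len(nC), each = n_replicates)
  out <- data.frame(compound = compounds[idx],
                    replicate = rep(seq_len(n_replicates), times = nC),
                    stringsAsFactors = FALSE)
  true_conc <- cbind(C_D0 = geometry$C_D0_nominal,
                     C_Dt = end[1, idx], C_At = end[2, idx])
  n_meas <- nrow(out) * 3L
  eps <- if (noise_cv > 0) stats::rnorm(n_meas, 0, noise_cv) else
    numeric(n_meas)
  # row-major: the three measurements of well 1, then well 2, ...
  eps <- matrix(eps, ncol = 3L, byrow = TRUE)
  noisy <- pmax(true_conc * (1 + eps), 0)
  if (output == "areas") {
    out$area_t0 <- response_factor * noisy[, 1]
    out$area_donor_t <- response_factor * noisy[, 2]
    out$area_acceptor_t <- response_factor * noisy[, 3]
  } else {
    out$C_D0 <- noisy[, 1]
    out$C_Dt <- noisy[, 2]
    out$C_At <- noisy[, 3]
  }
  out
}
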