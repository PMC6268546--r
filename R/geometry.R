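#' Assay geometry of a PAMPA sandwich
#'
#' Physical constants of the donor/acceptor plate assembly. All quantities are
#' in coherent cgs-like units: volumes in cm^3, areas in cm^2, times in
#' seconds, concentrations in mol cm^-3. Percentages never enter here; they
#' exist only at the reporting boundary.
#'
#' The defaults are the geometry of a standard unstirred skin-PAMPA run:
#' 300 uL donor and 400 uL acceptor wells, a 0.28 cm^2 PVDF filter at 70%
#' nominal porosity, 7 h incubation with an approximate 20 min steady-state
#' lag, and a 100 uM (1e-7 mol cm^-3) nominal donor solution.
#'
#' @param V_D donor well volume (cm^3).
#' @param V_A acceptor well volume (cm^3).
#' @param A_filter filter area (cm^2).
#' @param porosity nominal filter porosity, a fraction in (0, 1]. The
#'   effective diffusion area is `A_filter * porosity`.
#' @param t_incubation incubation time (s).
#' @param tau_lag steady-state lag time (s): the time for the transmembrane
#'   gradient to stabilise; acceptor accumulation is modelled as starting
#'   after it. Must be smaller than `t_incubation`.
#' @param C_D0_nominal nominal donor concentration at time zero (mol cm^-3).
#'
#' @return An object of class `"pampa_geometry"`: a named list of the seven
#'   constants plus the derived effective area `A_eff`.
#' @seealso [read_geometry_config()] to load a geometry from a YAML file.
#' @examples
#' g <- pampa_geometry()
#' g$A_eff                     # 0.28 * 0.7 = 0.196 cm^2
#' pampa_geometry(V_A = 0.3)   # equal-volume sandwich
#' @export
pampa_geometry <- function(V_D = 0.3, V_A = 0.4, A_filter = 0.28,
                           porosity = 0.7, t_incubation = 25200,
                           tau_lag = 1200, C_D0_nominal = 1e-7) {
  g <- list(V_D = as.numeric(V_D), V_A = as.numeric(V_A),
            A_filter = as.numeric(A_filter), porosity = as.numeric(porosity),
            t_incubation = as.numeric(t_incubation),
            tau_lag = as.numeric(tau_lag),
            C_D0_nominal = as.numeric(C_D0_nominal))
  for (nm in names(g)) {
    v <- g[[nm]]
    if (length(v) != 1L || !is.finite(v))
      stop("geometry field '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (g$V_D <= 0 || g$V_A <= 0) stop("well volumes must be > 0", call. = FALSE)
  if (g$A_filter <= 0) stop("A_filter must be > 0", call. = FALSE)
  if (g$porosity <= 0 || g$porosity > 1)
    stop("porosity must be in (0, 1]", call. = FALSE)
  if (g$t_incubation <= 0 || g$tau_lag < 0)
    stop("times must be positive (tau_lag >= 0)", call. = FALSE)
  if (g$tau_lag >= g$t_incubation)
    stop("tau_lag must be smaller than t_incubation", call. = FALSE)
  if (g$C_D0_nominal <= 0) stop("C_D0_nominal must be > 0", call. = FALSE)
  g$A_eff <- g$A_filter * g$porosity
  class(g) <- "pampa_geometry"
  g
}

#' @export
print.pampa_geometry <- function(x, ...) {
  cat("PAMPA assay geometry\n")
  cat(sprintf("  donor volume   V_D = %g cm^3\n", x$V_D))
  cat(sprintf("  acceptor vol.  V_A = %g cm^3\n", x$V_A))
  cat(sprintf("  filter area      A = %g cm^2 x porosity %g -> A_eff = %g cm^2\n",
              x$A_filter, x$porosity, x$A_eff))
  cat(sprintf("  incubation       t = %g s, lag tau = %g s\n",
              x$t_incubation, x$tau_lag))
  cat(sprintf("  nominal C_D(0)     = %g mol cm^-3\n", x$C_D0_nominal))
  invisible(x)
}

geometry_fields <- c("V_D", "V_A", "A_filter", "porosity",
                     "t_incubation", "tau_lag", "C_D0_nominal")

#' Read or write an assay-geometry configuration file
#'
#' The configuration is a flat YAML mapping of the seven
#' [pampa_geometry()] fields; any field missing from the file keeps its
#' default, so a file may override only what differs from the standard
#' sandwich. Unknown keys are an error (they are almost always typos that
#' would otherwise silently fall back to a default).
#'
#' @param path path to a YAML file.
#' @return `read_geometry_config()` returns a `"pampa_geometry"` object;
#'   `write_geometry_config()` returns `path` invisibly.
#' @examples
#' cfg <- system.file("extdata", "geometry_default.yaml", package = "skinpampa")
#' read_geometry_config(cfg)
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path))
    stop("geometry config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("malformed geometry config: ", path, call. = FALSE)
  extra <- setdiff(names(vals), geometry_fields)
  if (length(extra))
    stop("unknown geometry field(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(pampa_geometry, vals)
}

#' @param geometry a `"pampa_geometry"` object to serialise.
#' @rdname read_geometry_config
#' @export
write_geometry_config <- function(geometry, path) {
  stopifnot(inherits(geometry, "pampa_geometry"))
  yaml::write_yaml(unclass(geometry)[geometry_fields], path)
  invisible(path)
}
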