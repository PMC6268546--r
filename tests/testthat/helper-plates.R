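# Shared fixtures, built in code at test time.

# equal-volume sandwich used by the closed-form examples:
# V = 0.3 cm^3, A_eff = 0.196 cm^2, post-lag time 24000 s
geom_equal <- function() pampa_geometry(V_A = 0.3)

# write a wells data frame to a temp CSV and return the path
plate_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# analytic wells for given ground truth under the standard geometry
true_wells <- function(Pe, R, geometry = pampa_geometry()) {
  tc <- simulate_well_timecourse(geometry$t_incubation, Pe, R, geometry)
  data.frame(compound = "x", replicate = 1L,
             C_D0 = geometry$C_D0_nominal, C_Dt = tc$C_D, C_At = tc$C_A)
}

# independent ODE oracle for the two-compartment model: integrates the
# donor->acceptor flux numerically (no use of the closed form)
ode_acceptor <- function(Pe, R, geometry, t_end) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  C0 <- geometry$C_D0_nominal
  rhs <- function(t, y, parms) {
    C_D <- ((1 - R) * C0 * geometry$V_D - geometry$V_A * y[1]) / geometry$V_D
    list(Pe * geometry$A_eff / geometry$V_A * (C_D - y[1]))
  }
  t_prime <- t_end - geometry$tau_lag
  out <- deSolve::lsoda(c(C_A = 0), times = c(0, t_prime), func = rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-18)
  unname(out[nrow(out), "C_A"])
}
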