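fit_grid <- function(noise_cv = 0, seed = 1) {
  truth <- expand.grid(Pe = c(5e-7, 5e-6, 5e-5), R = c(0.05, 0.45, 0.8))
  truth$compound <- sprintf("g%02d", seq_len(nrow(truth)))
  plate <- simulate_plate(truth$compound, truth$Pe, truth$R,
                          noise_cv = noise_cv, seed = seed)
  wells <- read_plate_table(plate_csv(plate), mode = "areas")
  list(truth = truth, fit = pampa(wells))
}

test_that("the fit recovers simulated ground truth exactly without noise", {
  fg <- fit_grid(noise_cv = 0)
  co <- coef(fg$fit)[fg$truth$compound, ]
  expect_equal(unname(co[, "R"]), fg$truth$R, tolerance = 1e-10)
  expect_equal(unname(co[, "Pe"]), fg$truth$Pe, tolerance = 1e-9)
  # noise-free triplicates: zero spread
  expect_equal(fg$fit$compounds$logPe_sd, rep(0, 9), tolerance = 1e-12)
  # groups match truth-derived labels end to end
  expect_identical(fg$fit$compounds$group,
                   classify_permeate(fg$truth$R, coef(fg$fit)[, "perm"]))
})

test_that("methods give coherent views of one fit", {
  fg <- fit_grid(noise_cv = 0.02, seed = 4)
  fit <- fg$fit

  s <- summary(fit)
  expect_s3_class(s, "summary.pampa")
  expect_equal(sum(s$groups$n), nrow(fit$compounds))
  expect_output(print(fit), "PAMPA permeability fit")
  expect_output(print(s), "Group census")

  expect_equal(predict(fit),
               setNames(1.34 * fit$compounds$logPe_mean + 0.28,
                        fit$compounds$compound))
  expect_equal(unname(predict(fit, newdata = -4.10, rounded = TRUE)), -5.21)

  r <- residuals(fit)
  expect_equal(length(r), nrow(fit$wells))
  expect_equal(as.numeric(tapply(r, fit$wells$compound, mean)),
               rep(0, 9), tolerance = 1e-12)

  sims <- simulate(fit, nsim = 2, seed = 10)
  expect_length(sims, 2L)
  expect_identical(sims[[1]],
                   simulate_plate(fit$compounds$compound,
                                  10^fit$compounds$logPe_mean,
                                  fit$compounds$R_mean,
                                  geometry = fit$geometry, seed = 10))

  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("degenerate wells are flagged, warned about, and never abort", {
  g <- pampa_geometry()
  wells <- data.frame(
    compound = c("ok", "ok", "eq", "neg"), replicate = c(1, 2, 1, 1),
    C_D0 = 1e-7,
    C_Dt = c(5e-8, 5.1e-8, 0, 1.02e-7),
    C_At = c(1e-8, 0.9e-8, 6e-8, 0))   # "eq" is over equilibrium
  w <- capture_warnings(fit <- pampa(wells, g))
  expect_match(w, "clamped", all = FALSE)
  expect_match(w, "equilibrium", all = FALSE)
  expect_equal(nrow(fit$compounds), 3L)
  eq <- fit$compounds[fit$compounds$compound == "eq", ]
  expect_true(is.na(eq$logPe_mean) && is.na(eq$logKp))
  expect_equal(eq$n_pe_defined, 0L)
  expect_equal(fit$wells$R[fit$wells$compound == "neg"], 0)
  expect_true(fit$wells$R_clamped[fit$wells$compound == "neg"])
})

test_that("the end-to-end analyze command writes results plus a manifest", {
  plate <- simulate_plate(c("fast", "trap"), Pe = c(8e-5, 5e-6),
                          R = c(0.05, 0.7), noise_cv = 0, seed = 2)
  csv <- plate_csv(plate)
  out <- file.path(tempdir(), "run1")
  res <- pampa_analyze(csv, out, mode = "areas")
  expect_true(all(file.exists(res$paths)))

  man <- jsonlite::read_json(res$paths[["manifest"]])
  # every geometry value used is echoed
  expect_equal(man$geometry$V_A, 0.4)
  expect_equal(man$geometry$tau_lag, 1200)
  expect_equal(man$inputs[[1]]$md5, unname(tools::md5sum(csv)))

  back <- read_results_table(res$paths[["results"]])
  expect_identical(as.character(back$group), c("II", "III"))

  # reanalysis of the same inputs is byte-identical (manifest aside)
  out2 <- file.path(tempdir(), "run2")
  res2 <- pampa_analyze(csv, out2, mode = "areas")
  expect_identical(readLines(res$paths[["results"]]),
                   readLines(res2$paths[["results"]]))

  expect_error(pampa_analyze(tempfile(), out, mode = "areas"), "not found")
})

test_that("reporting summarises classified tables and rejects unclassified", {
  tab <- table1_fixture()
  rep_out <- capture.output(r <- pampa_report(tab))
  expect_equal(r$groups$n[r$groups$group == "III"], 13L)
  expect_true(any(grepl("standard panel", rep_out)))
  # standards section: exactly one group III member
  std <- summarize_groups(tab, tab$compound[tab$role == "standard"])
  expect_equal(std$n[std$group == "III"], 1L)
  # the whole fluocinolone acetonide ester series is group III
  fa_esters <- sprintf("FA-21-%s", c("MP", "EP", "PhP", "MB", "EB"))
  expect_true(all(tab$group[tab$compound %in% fa_esters] == "III"))

  tab$group <- NULL
  expect_error(pampa_report(tab), "not classified")
  expect_error(pampa_report(tab[0, ]), "empty")
})
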