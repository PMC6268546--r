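#' Analyse a plate table end to end
#'
#' Batch orchestration around [pampa()]: read a plate CSV (optionally with
#' a YAML geometry override), fit, and write three artefacts into
#' `out_dir` — `wells.csv` (per-replicate results), `results.csv`
#' (per-compound summaries with group labels, via
#' [write_results_table()]) and `manifest.json`, a run manifest recording
#' the package version, input paths with md5 hashes, every geometry value
#' used, the classification thresholds, the volume mode, the seed (if the
#' plate was simulated in the same run) and a timestamp. No geometry value
#' is ever applied silently: whatever was used is echoed in the manifest.
#'
#' @param plate_csv path to the input plate table.
#' @param out_dir output directory (created if needed).
#' @param geometry_config optional YAML geometry file
#'   ([read_geometry_config()]); defaults to the standard sandwich.
#' @param mode plate layout, `"concentrations"` or `"areas"`.
#' @param volume_mode,regression,rule,clamp_tol passed to [pampa()].
#' @param seed recorded in the manifest (e.g. the simulation seed that
#'   produced `plate_csv`); not used for computation here.
#' @return Invisibly, a list with the `fit` and the three output `paths`.
#' @export
pampa_analyze <- function(plate_csv, out_dir,
                          geometry_config = NULL,
                          mode = c("concentrations", "areas"),
                          volume_mode = c("actual", "equal"),
                          regression = kp_regression(),
                          rule = permeate_rule(), clamp_tol = 0.05,
                          seed = NULL) {
  mode <- match.arg(mode)
  volume_mode <- match.arg(volume_mode)
  geometry <- if (is.null(geometry_config)) pampa_geometry()
              else read_geometry_config(geometry_config)
  wells <- read_plate_table(plate_csv, geometry, mode)
  fit <- pampa(wells, geometry, volume_mode, regression, rule, clamp_tol)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wells_path <- file.path(out_dir, "wells.csv")
  results_path <- file.path(out_dir, "results.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  utils::write.csv(fit$wells, wells_path, row.names = FALSE)
  write_results_table(fit$compounds, results_path)
  inputs <- c(plate_csv, geometry_config)
  manifest <- list(
    tool = "skinpampa",
    version = as.character(utils::packageVersion("skinpampa")),
    inputs = data.frame(path = inputs,
                        md5 = unname(tools::md5sum(inputs)),
                        stringsAsFactors = FALSE),
    geometry = unclass(fit$geometry)[geometry_fields],
    volume_mode = volume_mode,
    regression = unclass(regression),
    rule = unclass(fit$rule),
    clamp_tol = clamp_tol,
    seed = seed,
    n_wells = nrow(fit$wells),
    n_clamped_R = sum(fit$wells$R_clamped),
    n_undefined_Pe = sum(is.na(fit$wells$log_Pe)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fit = fit,
                 paths = c(wells = wells_path, results = results_path,
                           manifest = manifest_path)))
}

#' Report group membership of classified results
#'
#' Text-and-table report over a classified results table: per-group counts
#' and retention/permeation ranges ([summarize_groups()]), split by an
#' optional `role` column (e.g. ester vs standard panels), plus the
#' two-column (R%, perm%) table that underlies a retention-permeation
#' scatter. Output ordering is deterministic.
#'
#' @param results a classified compound table: a data frame with `group`,
#'   or a path to a results CSV written by [write_results_table()].
#' @param out_csv optional path for the group-summary CSV.
#' @return Invisibly, a list with `groups` (the census data frame) and
#'   `points` (compound, R_pct, perm_pct, group).
#' @export
pampa_report <- function(results, out_csv = NULL) {
  if (is.character(results) && length(results) == 1L)
    results <- read_results_table(results)
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  if (!"group" %in% names(results) || anyNA(results$group))
    stop("results are not classified; run the classification first",
         call. = FALSE)
  census <- summarize_groups(results)
  cat("Permeate group census (", nrow(results), " compounds)\n", sep = "")
  print(census, row.names = FALSE)
  if ("role" %in% names(results)) {
    for (r in unique(results$role)) {
      cat("\n", r, " panel:\n", sep = "")
      print(summarize_groups(results, results$compound[results$role == r]),
            row.names = FALSE)
    }
  }
  points <- data.frame(compound = results$compound,
                       R_pct = 100 * results$R_mean,
                       perm_pct = 100 * results$perm_mean,
                       group = as.character(results$group),
                       stringsAsFactors = FALSE)
  points <- points[order(points$group, points$compound), ]
  rownames(points) <- NULL
  if (!is.null(out_csv))
    utils::write.csv(census, out_csv, row.names = FALSE)
  invisible(list(groups = census, points = points))
}
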