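#' Read a plate measurement table
#'
#' Reads one CSV row per replicate well into the canonical well layout
#' (`compound`, `replicate`, `C_D0`, `C_Dt`, `C_At`, concentrations in
#' mol cm^-3). Two input layouts are supported:
#'
#' * `mode = "concentrations"` — columns `C_D0`, `C_Dt`, `C_At` are taken
#'   verbatim;
#' * `mode = "areas"` — columns `area_t0`, `area_donor_t`,
#'   `area_acceptor_t` hold raw HPLC peak areas; each well's concentrations
#'   are derived by [peak_area_to_concentration()] against its own
#'   time-zero reference area and the geometry's nominal donor
#'   concentration. A time-zero reference measured once per compound is
#'   simply repeated across that compound's rows.
#'
#' Reading is total and order-preserving: n input rows yield n wells or an
#' error (named missing column, or a validation error carrying the
#' offending row number); rows are never silently dropped.
#'
#' @param path CSV file (comma-separated, `.` decimal, header required).
#' @param geometry a [pampa_geometry()]; supplies `C_D0_nominal` in areas
#'   mode.
#' @param mode input layout, `"concentrations"` or `"areas"`.
#' @return Data frame of wells: `compound`, `replicate`, `C_D0`, `C_Dt`,
#'   `C_At`.
#' @export
read_plate_table <- function(path, geometry = pampa_geometry(),
                             mode = c("concentrations", "areas")) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "pampa_geometry"))
  if (!file.exists(path)) stop("plate table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty plate table: ", path, call. = FALSE)
  value_cols <- if (mode == "areas")
    c("area_t0", "area_donor_t", "area_acceptor_t")
  else c("C_D0", "C_Dt", "C_At")
  need <- c("compound", "replicate", value_cols)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("plate table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in value_cols) {
    v <- tab[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column ", nm, " must be numeric and complete (row ",
           paste(which(!is.finite(suppressWarnings(as.numeric(v)))),
                 collapse = ", "), ")", call. = FALSE)
    if (any(v < 0))
      stop("negative value in column ", nm, " (row ",
           paste(which(v < 0), collapse = ", "), ")", call. = FALSE)
  }
  if (mode == "areas") {
    if (any(tab$area_t0 <= 0))
      stop("area_t0 must be > 0 (row ",
           paste(which(tab$area_t0 <= 0), collapse = ", "), ")",
           call. = FALSE)
    C0 <- geometry$C_D0_nominal
    wells <- data.frame(
      compound = tab$compound, replicate = tab$replicate,
      C_D0 = peak_area_to_concentration(tab$area_t0, tab$area_t0, C0),
      C_Dt = peak_area_to_concentration(tab$area_donor_t, tab$area_t0, C0),
      C_At = peak_area_to_concentration(tab$area_acceptor_t, tab$area_t0, C0),
      stringsAsFactors = FALSE)
  } else {
    if (any(tab$C_D0 <= 0))
      stop("C_D0 must be > 0 (row ",
           paste(which(tab$C_D0 <= 0), collapse = ", "), ")", call. = FALSE)
    wells <- tab[, need]
  }
  wells
}

#' Write (and re-read) a compound results table
#'
#' Serialises compound summaries to CSV in the reporting layout: one row
#' per compound with columns `compound`, `n`, `R_pct_mean`, `R_pct_sd`,
#' `perm_pct_mean`, `perm_pct_sd`, `logPe_mean`, `logPe_sd`, `logKp`,
#' `group`, plus the display column `R_pct_display` in which a mean
#' retention under 1% is rendered `"<1"` (the below-detection reporting
#' convention) while the numeric column keeps the value. Retention and
#' permeation appear as percentages here — the only place the package uses
#' them. Numbers are written with enough digits that a write/read round
#' trip is lossless well past 12 significant digits.
#'
#' @param summaries compound summary data frame from [pampa()] /
#'   [aggregate_replicates()] (or [table1_fixture()]).
#' @param path output (input) CSV path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the summaries with fractional
#'   `R_mean`/`perm_mean` columns reconstructed.
#' @export
write_results_table <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    stop("no compound summaries to write", call. = FALSE)
  need <- c("compound", "n", "R_mean", "R_sd", "perm_mean", "perm_sd",
            "logPe_mean", "logPe_sd", "logKp", "group")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    compound = summaries$compound,
    n = summaries$n,
    R_pct_mean = 100 * summaries$R_mean,
    R_pct_sd = 100 * summaries$R_sd,
    R_pct_display = ifelse(summaries$R_mean < 0.01, "<1",
                           num_chr(100 * summaries$R_mean)),
    perm_pct_mean = 100 * summaries$perm_mean,
    perm_pct_sd = 100 * summaries$perm_sd,
    logPe_mean = summaries$logPe_mean,
    logPe_sd = summaries$logPe_sd,
    logKp = summaries$logKp,
    group = as.character(summaries$group),
    stringsAsFactors = FALSE)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
  out[num] <- lapply(out[num], num_chr)
  ok <- tryCatch(utils::write.csv(out, path, row.names = FALSE,
                                  quote = FALSE, na = "NA"),
                 error = function(e)
                   stop("failed writing results table ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  invisible(path)
}

# full-precision decimal rendering for lossless CSV round trips
num_chr <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g"),
    character(1))
  out
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path))
    stop("results table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "n", "R_pct_mean", "perm_pct_mean", "logPe_mean",
            "logKp", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("results table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab$R_mean <- tab$R_pct_mean / 100
  tab$R_sd <- if ("R_pct_sd" %in% names(tab)) tab$R_pct_sd / 100 else NA_real_
  tab$perm_mean <- tab$perm_pct_mean / 100
  tab$perm_sd <- if ("perm_pct_sd" %in% names(tab)) tab$perm_pct_sd / 100
                 else NA_real_
  tab$group <- factor(tab$group, levels = group_levels)
  tab
}
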