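#' Reference corticosteroid PAMPA panel (26 compounds)
#'
#' The packaged reference table of a published skin-PAMPA screen of twenty
#' newly synthesised corticosteroid C-21 esters plus six corticosteroid
#' standards (fluocinolone acetonide, dexamethasone, triamcinolone
#' acetonide, hydrocortisone, hydrocortisone acetate and mometasone
#' furoate): triplicate-mean retention factor, permeation parameter and
#' log Pe with their reported spreads. These are wet-lab measurements and
#' ship as fixture inputs for the downstream computations (log Kp
#' prediction, group classification); they are not re-derivable from each
#' other.
#'
#' Five compounds have a below-detection retention printed as "<1%"; they
#' carry `below_detection_R = TRUE` and, for any computation needing a
#' number, `R_mean = 0.005` — the midpoint of the censoring interval
#' \[0, 1)% — while `R_pct`/`R_pct_sd` stay `NA` as printed.
#'
#' @param rule a [permeate_rule()] used to attach group labels.
#' @param regression a [kp_regression()] used to attach predicted log Kp.
#' @return Data frame of 26 rows: `compound`, `role` (`"ester"` or
#'   `"standard"`), printed columns `R_pct`, `R_pct_sd`, `perm_pct`,
#'   `perm_pct_sd`, `logPe`, `logPe_sd`, flag `below_detection_R`, and the
#'   derived columns `R_mean`, `perm_mean`, `logPe_mean` (fractions /
#'   log10), `logKp`, `logKp_2dp`, `group`.
#' @examples
#' tab <- table1_fixture()
#' subset(tab, compound == "MF", c(R_pct, perm_pct, logKp_2dp, group))
#' @export
table1_fixture <- function(rule = permeate_rule(),
                           regression = kp_regression()) {
  path <- system.file("extdata", "table1_pampa.csv", package = "skinpampa",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$below_detection_R <- as.logical(tab$below_detection_R)
  tab$R_mean <- ifelse(tab$below_detection_R, 0.005, tab$R_pct / 100)
  tab$perm_mean <- tab$perm_pct / 100
  tab$logPe_mean <- tab$logPe
  tab$logKp <- log_kp_from_log_pe(tab$logPe_mean, regression)
  tab$logKp_2dp <- round_half_up(tab$logKp, 2L)
  tab$group <- classify_permeate(tab$R_mean, tab$perm_mean, rule)
  tab
}
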