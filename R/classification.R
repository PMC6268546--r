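#' Permeate classification rule
#'
#' Thresholds for the group I/II/III taxonomy of permeates measured through
#' a silicone oil / isopropyl myristate membrane:
#'
#' * group I  — retention and permeation both low (below the thresholds);
#' * group II — low retention, high permeation;
#' * group III — high retention, low permeation (the membrane acts as a
#'   trap, the profile sought for topically acting prodrugs).
#'
#' The high-retention/high-permeation cell does not occur in the reference
#' taxonomy and is labelled `UNDEFINED` rather than silently forced into a
#' group. `logkp_cutoff` (-6 by default) is carried for annotation — the
#' literature discusses log Kp >= -6 alongside the groups — but plays no
#' part in the assignment, which uses the retention/permeation relationship
#' only.
#'
#' @param retention_threshold retention fraction separating "low" from
#'   "high" retention (default 0.30, i.e. 30%).
#' @param permeation_threshold permeation fraction separating "low" from
#'   "high" permeation (default 0.30).
#' @param logkp_cutoff annotation cutoff on predicted log Kp (default -6).
#' @return An object of class `"permeate_rule"`.
#' @export
permeate_rule <- function(retention_threshold = 0.30,
                          permeation_threshold = 0.30,
                          logkp_cutoff = -6) {
  if (!is.finite(retention_threshold) || retention_threshold <= 0 ||
      retention_threshold >= 1)
    stop("retention_threshold must be in (0, 1)", call. = FALSE)
  if (!is.finite(permeation_threshold) || permeation_threshold <= 0 ||
      permeation_threshold >= 1)
    stop("permeation_threshold must be in (0, 1)", call. = FALSE)
  structure(list(retention_threshold = retention_threshold,
                 permeation_threshold = permeation_threshold,
                 logkp_cutoff = logkp_cutoff),
            class = "permeate_rule")
}

#' @export
print.permeate_rule <- function(x, ...) {
  cat(sprintf(paste0("permeate rule: R < %g & perm < %g -> I; ",
                     "R < %g & perm >= %g -> II; R >= %g & perm < %g -> III; ",
                     "else UNDEFINED (log Kp cutoff %g, annotation only)\n"),
              x$retention_threshold, x$permeation_threshold,
              x$retention_threshold, x$permeation_threshold,
              x$retention_threshold, x$permeation_threshold, x$logkp_cutoff))
  invisible(x)
}

group_levels <- c("I", "II", "III", "UNDEFINED")

#' Classify compounds into permeate groups I, II, III
#'
#' Assigns each compound a group from its mean retention factor and mean
#' permeation parameter (classification operates on triplicate means, one
#' point per compound). Values exactly at a threshold count as "high".
#'
#' @param R retention fraction(s) in \[0, 1\].
#' @param perm permeation fraction(s) in \[0, 1\]; recycled with `R`.
#' @param rule a [permeate_rule()].
#' @return Factor with levels `I`, `II`, `III`, `UNDEFINED`.
#' @examples
#' classify_permeate(0.81, 0.077)   # III: high retention, low permeation
#' classify_permeate(0.015, 0.008)  # I
#' @export
classify_permeate <- function(R, perm, rule = permeate_rule()) {
  stopifnot(inherits(rule, "permeate_rule"))
  if (any(!is.finite(R)) || any(R < 0 | R > 1))
    stop("R must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(perm)) || any(perm < 0 | perm > 1))
    stop("perm must be in [0, 1]", call. = FALSE)
  k <- max(length(R), length(perm))
  R <- rep_len(R, k); perm <- rep_len(perm, k)
  hiR <- R >= rule$retention_threshold
  hiP <- perm >= rule$permeation_threshold
  lab <- ifelse(!hiR & !hiP, "I",
         ifelse(!hiR &  hiP, "II",
         ifelse( hiR & !hiP, "III", "UNDEFINED")))
  factor(lab, levels = group_levels)
}

#' Summarise group membership
#'
#' Per-group counts and ranges of the mean retention factor and permeation
#' parameter, in the fixed order I, II, III, UNDEFINED.
#'
#' @param summaries compound summary data frame with columns `compound`,
#'   `R_mean`, `perm_mean`, `group` (from [aggregate_replicates()],
#'   [pampa()] or [table1_fixture()]).
#' @param subset optional character vector of compound ids to restrict to.
#' @return Data frame with columns `group`, `n`, `R_min`, `R_max`,
#'   `perm_min`, `perm_max` (ranges `NA` for empty groups).
#' @export
summarize_groups <- function(summaries, subset = NULL) {
  need <- c("compound", "R_mean", "perm_mean", "group")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(subset))
    summaries <- summaries[summaries$compound %in% subset, , drop = FALSE]
  rows <- lapply(group_levels, function(gl) {
    s <- summaries[summaries$group == gl, , drop = FALSE]
    rng <- function(x) if (nrow(s)) range(x) else c(NA_real_, NA_real_)
    rR <- rng(s$R_mean); rP <- rng(s$perm_mean)
    data.frame(group = gl, n = nrow(s), R_min = rR[1], R_max = rR[2],
               perm_min = rP[1], perm_max = rP[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
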