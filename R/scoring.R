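#' ASTM E679 extreme-value finalisation of a session threshold
#'
#' Sessions with extreme response patterns carry no usable gradient
#' information, so — following the standard ASTM E679 decision rule — their
#' thresholds are imputed one log unit beyond the tested range:
#' \itemize{
#'   \item YES to every odorant label received AND NO to every blank
#'     received: threshold = lowest rung - 1.0 (floor; -4.5 on the default
#'     card). These are highly sensitive observers.
#'   \item NO on every trial: threshold = highest rung + 1.0 (ceiling; 1.0
#'     on the default card). NO on blanks is correct behaviour, so blanks do
#'     not exempt a session from the ceiling rule.
#' }
#' Any other pattern keeps the posterior point estimate.
#'
#' The imputed values are derived from the card's ladder, not hard-coded.
#'
#' @param session an \code{aromat_session} with a complete trial record.
#' @param card the \code{aromat_card} used.
#' @return Final reported threshold (log10 units).
#' @export
finalize_threshold <- function(session, card) {
  trials <- session$trials
  if (is.null(trials) || nrow(trials) == 0L)
    stop("incomplete session: no trials recorded")
  odorant <- !is.na(trials$stimulus)
  all_no <- all(trials$response == "N")
  all_yes_odor <- all(trials$response[odorant] == "Y") &&
    all(trials$response[!odorant] == "N")
  if (all_yes_odor && any(odorant)) {
    min(card$ladder) - 1.0
  } else if (all_no) {
    max(card$ladder) + 1.0
  } else {
    session$point
  }
}

#' False-alarm flags for a session
#'
#' \code{fa_first_blank}: the first blank presented was answered YES — the
#' single-blank false-alarm statistic. \code{fa_both_blanks}: the session
#' contained at least two blanks and all of them were answered YES.
#'
#' @param session an \code{aromat_session}.
#' @param card the \code{aromat_card} used (unused beyond the interface; the
#'   trial record already carries blank identity).
#' @return Named logical vector \code{c(fa_first_blank, fa_both_blanks)}.
#' @export
false_alarm_flags <- function(session, card) {
  blanks <- which(is.na(session$trials$stimulus))
  if (length(blanks) == 0L)
    return(c(fa_first_blank = FALSE, fa_both_blanks = FALSE))
  r <- session$trials$response[blanks]
  c(fa_first_blank = r[1] == "Y",
    fa_both_blanks = length(blanks) >= 2L && all(r == "Y"))
}

#' Quality-control classification of a finalised session
#'
#' FLOOR_IMPUTED / CEILING_IMPUTED when the extreme-value rule fired;
#' otherwise INDETERMINATE when the posterior SD exceeds \code{se_cutoff}
#' (an inconsistent response pattern leaves the threshold poorly
#' constrained), else DETERMINATE.
#'
#' @param session an \code{aromat_session}.
#' @param card the \code{aromat_card} used.
#' @param se_cutoff posterior-SD cutoff in log10 units (default 1.0).
#' @return One of "FLOOR_IMPUTED", "CEILING_IMPUTED", "INDETERMINATE",
#'   "DETERMINATE".
#' @export
qc_classify <- function(session, card, se_cutoff = 1.0) {
  trials <- session$trials
  odorant <- !is.na(trials$stimulus)
  if (all(trials$response[odorant] == "Y") &&
      all(trials$response[!odorant] == "N") && any(odorant))
    return("FLOOR_IMPUTED")
  if (all(trials$response == "N")) return("CEILING_IMPUTED")
  if (session$se > se_cutoff) return("INDETERMINATE")
  "DETERMINATE"
}

#' Score a session: finalise threshold, flags and QC in one step
#'
#' @inheritParams qc_classify
#' @return The session with \code{final_threshold}, \code{qc},
#'   \code{fa_first_blank} and \code{fa_both_blanks} filled in.
#' @export
score_session <- function(session, card, se_cutoff = 1.0) {
  session$final_threshold <- finalize_threshold(session, card)
  session$qc <- qc_classify(session, card, se_cutoff)
  flags <- false_alarm_flags(session, card)
  session$fa_first_blank <- unname(flags["fa_first_blank"])
  session$fa_both_blanks <- unname(flags["fa_both_blanks"])
  session$se_cutoff <- se_cutoff
  session
}
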