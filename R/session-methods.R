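#' @export
print.aromat_session <- function(x, ...) {
  cat("Adaptive odor threshold session (", nrow(x$trials), " trials)\n",
      sep = "")
  cat("  path: ", paste(x$trials$label_id, collapse = " -> "),
      "  responses: ", paste(x$trials$response, collapse = ""), "\n",
      sep = "")
  cat(sprintf("  threshold: %.3f log10 (se %.3f)", x$point, x$se))
  if (!is.na(x$qc) && x$qc %in% c("FLOOR_IMPUTED", "CEILING_IMPUTED"))
    cat(sprintf("  -> reported %.1f [%s]", x$final_threshold, x$qc))
  else if (!is.na(x$qc))
    cat(sprintf("  [%s]", x$qc))
  cat("\n")
  invisible(x)
}

#' @export
summary.aromat_session <- function(object, ...) {
  out <- list(
    n_trials = nrow(object$trials),
    labels = object$trials$label_id,
    responses = object$trials$response,
    point = object$point, se = object$se,
    lambda_point = object$lambda_point,
    false_alarm_rate = object$curve_min,
    final_threshold = object$final_threshold,
    qc = object$qc,
    fa_first_blank = object$fa_first_blank,
    fa_both_blanks = object$fa_both_blanks
  )
  class(out) <- "summary.aromat_session"
  out
}

#' @export
print.summary.aromat_session <- function(x, ...) {
  cat("Adaptive odor threshold session\n")
  cat("  trials:", x$n_trials, "\n")
  cat("  label sequence: ", paste(x$labels, collapse = " "), "\n")
  cat("  responses:      ", paste(x$responses, collapse = " "), "\n")
  cat(sprintf("  log10 threshold (posterior mean): %.3f\n", x$point))
  cat(sprintf("  standard error  (posterior SD):   %.3f\n", x$se))
  if (!is.na(x$lambda_point))
    cat(sprintf("  criterion: %.3f (false-alarm prob %.3f)\n",
                x$lambda_point, x$false_alarm_rate))
  cat(sprintf("  reported threshold: %.3f   QC: %s\n",
              x$final_threshold, x$qc))
  cat("  false alarms: first blank =", x$fa_first_blank,
      "; all blanks =", x$fa_both_blanks, "\n")
  invisible(x)
}

#' @export
coef.aromat_session <- function(object, ...) {
  c(log_tau = object$point, lambda = object$lambda_point)
}

#' Predicted YES probabilities from a fitted session
#'
#' @param object an \code{aromat_session} fitted with the posterior grid
#'   retained (i.e. via \code{\link{fit_session}} or
#'   \code{\link{run_session}}).
#' @param newdata numeric vector of nominal log10 concentrations (\code{NA}
#'   for blank); defaults to the session's own stimuli.
#' @param type \code{"point"} evaluates the psychometric curve at the
#'   posterior-mean parameters; \code{"predictive"} averages the curve over
#'   the joint posterior.
#' @param ... unused.
#' @return Numeric vector of YES probabilities.
#' @export
predict.aromat_session <- function(object, newdata = NULL,
                                   type = c("point", "predictive"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$trials$stimulus
  if (type == "point") {
    slope <- if (!is.null(object$config)) object$config$slope else 0.5
    yes_prob(object$point, object$lambda_point, newdata, slope)
  } else {
    if (is.null(object$grid))
      stop("posterior grid not retained (table-driven session); ",
           "use type = 'point' or refit with fit_session()")
    vapply(newdata, function(x) predictive_yes(object$grid, x), numeric(1))
  }
}

#' @export
residuals.aromat_session <- function(object, ...) {
  obs <- as.numeric(object$trials$response == "Y")
  obs - predict(object, type = "point")
}

#' Plot the fitted psychometric curve of a session
#'
#' Draws the point-estimate YES-probability curve over the card's
#' concentration range, an uncertainty band (curves at the threshold
#' estimate plus/minus one posterior SD), the observed responses, and the
#' reported threshold at the halfway point between curve floor and ceiling.
#'
#' @param x an \code{aromat_session}.
#' @param ... passed to \code{plot}.
#' @export
plot.aromat_session <- function(x, ...) {
  xs <- seq(min(x$trials$stimulus, -4, na.rm = TRUE) - 0.5, 1, by = 0.02)
  slope <- if (!is.null(x$config)) x$config$slope else 0.5
  p_mid <- yes_prob(x$point, x$lambda_point, xs, slope)
  p_lo <- yes_prob(x$point + x$se, x$lambda_point, xs, slope)
  p_hi <- yes_prob(x$point - x$se, x$lambda_point, xs, slope)
  graphics::plot(xs, p_mid, type = "n", ylim = c(0, 1),
                 xlab = "nominal log10 concentration",
                 ylab = "P(YES)", ...)
  graphics::polygon(c(xs, rev(xs)), c(p_lo, rev(p_hi)),
                    col = grDevices::adjustcolor("gold", 0.4), border = NA)
  graphics::lines(xs, p_mid, lwd = 2)
  graphics::abline(v = x$point, lty = 2, col = "purple")
  odor <- !is.na(x$trials$stimulus)
  graphics::points(x$trials$stimulus[odor],
                   as.numeric(x$trials$response[odor] == "Y"),
                   pch = 19, col = ifelse(x$trials$response[odor] == "Y",
                                          "cyan3", "magenta3"))
  invisible(x)
}
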