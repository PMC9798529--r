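#' False-alarm probability implied by a decision criterion
#'
#' In the signal-detection parameterisation used throughout the package, the
#' decision criterion \eqn{\lambda} (standard-normal units) maps to the
#' probability of a YES response to a blank stimulus via
#' \eqn{\gamma(\lambda) = \Phi(-\lambda)}. Larger criteria mean a more
#' conservative observer and a lower false-alarm rate.
#'
#' @param lambda numeric criterion value(s); finite.
#' @return False-alarm probability in (0, 1), vectorised over \code{lambda}.
#' @examples
#' false_alarm_rate(0)   # 0.5
#' false_alarm_rate(1)   # ~0.159
#' @export
false_alarm_rate <- function(lambda) {
  stats::pnorm(-lambda)
}

#' Probability of a YES response
#'
#' The psychometric model is a guess-rate-floored probit. For a blank
#' stimulus the YES probability is the false-alarm rate
#' \eqn{\gamma = \Phi(-\lambda)}. For an odorant at nominal log10
#' concentration \eqn{x},
#' \deqn{P(YES | x) = \gamma + (1 - \gamma)\,\Phi\left(\frac{x - \log\tau}{s}\right),}
#' with \eqn{\log\tau} the detection threshold and \eqn{s} a fixed slope.
#' The curve rises from the floor \eqn{\gamma} to 1 and crosses the midpoint
#' between its floor and ceiling exactly at \eqn{x = \log\tau}, which is the
#' definition of the reported threshold.
#'
#' @param log_tau log10 detection threshold.
#' @param lambda decision criterion.
#' @param stimulus nominal log10 concentration, or \code{NA} for a blank.
#'   Vectorised.
#' @param slope psychometric slope in log10 units (default 0.5, one card
#'   step). Fixed by configuration, never inferred.
#' @return YES probability in (0, 1).
#' @export
yes_prob <- function(log_tau, lambda, stimulus, slope = 0.5) {
  stopifnot(slope > 0)
  gamma <- stats::pnorm(-lambda)
  # blanks carry no odorant signal: code them as -Inf so pnorm gives 0
  x0 <- ifelse(is.na(stimulus), -Inf, stimulus)
  p_detect <- stats::pnorm((x0 - log_tau) / slope)
  gamma + (1 - gamma) * p_detect
}

#' Log-likelihood of a response sequence
#'
#' Sum over trials of the Bernoulli log-probability of the observed YES/NO
#' response under the psychometric model; invariant to trial order.
#'
#' @param log_tau,lambda,slope observer parameters; see \code{\link{yes_prob}}.
#' @param trials data frame with columns \code{stimulus} (log10 concentration
#'   or \code{NA} for blank) and \code{response} ("Y" or "N").
#' @return Scalar log-likelihood (\eqn{\le 0}).
#' @export
response_loglik <- function(log_tau, lambda, trials, slope = 0.5) {
  if (nrow(trials) == 0L) stop("trials must be non-empty")
  if (!all(trials$response %in% c("Y", "N")))
    stop("responses must be 'Y' or 'N'")
  p_yes <- yes_prob(log_tau, lambda, trials$stimulus, slope)
  p <- ifelse(trials$response == "Y", p_yes, 1 - p_yes)
  sum(log(p))
}

# build a trial data frame; stimulus NA encodes a blank
make_trials <- function(label_id, stimulus, response) {
  data.frame(
    trial = seq_along(response),
    label_id = as.integer(label_id),
    stimulus = as.numeric(stimulus),
    response = as.character(response),
    stringsAsFactors = FALSE
  )
}
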