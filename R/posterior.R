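#' Prior and grid configuration for the Bayesian threshold model
#'
#' The model places independent, weakly informative normal priors on the two
#' inferred parameters: the log10 detection threshold,
#' \eqn{\log\tau \sim N(-3, 100)}, and the decision criterion,
#' \eqn{\lambda \sim N(1, 0.5)}. The second argument of each normal is read
#' as a VARIANCE (so SD 10 for \eqn{\log\tau} and SD \eqn{\approx 0.707} for
#' \eqn{\lambda}); both hyperparameters are exposed here so either reading
#' can be configured.
#'
#' The joint posterior is maintained on a fixed rectangular grid. The
#' threshold axis is symmetric about the prior mean (-3) so that the
#' discretised prior keeps its stated mean exactly, and spans the ASTM
#' imputation range (-4.5 to 1.0) with margin; the criterion axis is likewise
#' symmetric about its prior mean.
#'
#' @param tau_mean,tau_var prior mean and variance of log10 threshold.
#' @param lambda_mean,lambda_var prior mean and variance of the criterion.
#' @param tau_grid,lambda_grid grid node vectors (strictly increasing).
#' @param slope fixed psychometric slope (log10 units; default 0.5).
#' @return An object of class \code{aromat_prior} (a list of the above).
#' @export
prior_config <- function(tau_mean = -3, tau_var = 100,
                         lambda_mean = 1, lambda_var = 0.5,
                         tau_grid = seq(-7.5, 1.5, by = 0.05),
                         lambda_grid = seq(-1, 3, by = 0.1),
                         slope = 0.5) {
  if (tau_var <= 0 || lambda_var <= 0)
    stop("prior scales must be positive")
  if (slope <= 0) stop("slope must be positive")
  if (length(tau_grid) < 2L || length(lambda_grid) < 2L ||
      any(diff(tau_grid) <= 0) || any(diff(lambda_grid) <= 0))
    stop("grids must be strictly increasing with >= 2 nodes")
  if (tau_mean < min(tau_grid) || tau_mean > max(tau_grid) ||
      lambda_mean < min(lambda_grid) || lambda_mean > max(lambda_grid))
    stop("grid ranges must contain the prior means")
  structure(
    list(tau_mean = tau_mean, tau_var = tau_var,
         lambda_mean = lambda_mean, lambda_var = lambda_var,
         tau_grid = tau_grid, lambda_grid = lambda_grid,
         slope = slope),
    class = "aromat_prior"
  )
}

prior_fingerprint <- function(config) {
  fingerprint(paste(
    format(c(config$tau_mean, config$tau_var, config$lambda_mean,
             config$lambda_var, config$slope,
             range(config$tau_grid), length(config$tau_grid),
             range(config$lambda_grid), length(config$lambda_grid)),
           digits = 12),
    collapse = "|"))
}

#' Initialise the posterior grid from the prior
#'
#' Grid mass is proportional to the product of the two independent normal
#' prior densities at each node, normalised to total mass 1.
#'
#' @param config an \code{aromat_prior} from \code{\link{prior_config}}.
#' @return An object of class \code{aromat_grid}: list with \code{tau}
#'   (axis), \code{lambda} (axis), \code{mass} (matrix, rows = tau nodes,
#'   columns = lambda nodes, sums to 1) and \code{config}.
#' @export
init_prior <- function(config = prior_config()) {
  d_tau <- stats::dnorm(config$tau_grid, config$tau_mean,
                        sqrt(config$tau_var))
  d_lam <- stats::dnorm(config$lambda_grid, config$lambda_mean,
                        sqrt(config$lambda_var))
  mass <- outer(d_tau, d_lam)
  mass <- mass / sum(mass)
  structure(
    list(tau = config$tau_grid, lambda = config$lambda_grid,
         mass = mass, config = config),
    class = "aromat_grid"
  )
}

# P(YES) at every grid node for one stimulus: rows tau, cols lambda
grid_yes_prob <- function(grid, stimulus) {
  gamma <- stats::pnorm(-grid$lambda)
  if (is.na(stimulus)) {
    matrix(gamma, nrow = length(grid$tau), ncol = length(grid$lambda),
           byrow = TRUE)
  } else {
    phi <- stats::pnorm((stimulus - grid$tau) / grid$config$slope)
    # P = phi + gamma * (1 - phi), outer over (tau, lambda)
    outer(phi, 1 - gamma) + matrix(gamma, nrow = length(phi),
                                   ncol = length(gamma), byrow = TRUE)
  }
}

#' Bayesian update of the posterior grid after one trial
#'
#' Multiplies each node's mass by the Bernoulli likelihood of the observed
#' response under that node's \eqn{(\log\tau, \lambda)} and renormalises.
#' Pure function: the input grid is not modified.
#'
#' @param grid an \code{aromat_grid}.
#' @param stimulus nominal log10 concentration or \code{NA} for a blank.
#' @param response "Y" or "N".
#' @return The updated \code{aromat_grid}.
#' @export
posterior_update <- function(grid, stimulus, response) {
  if (!response %in% c("Y", "N")) stop("response must be 'Y' or 'N'")
  p_yes <- grid_yes_prob(grid, stimulus)
  lik <- if (response == "Y") p_yes else 1 - p_yes
  mass <- grid$mass * lik
  total <- sum(mass)
  if (!is.finite(total) || total <= 0)
    stop("degenerate posterior: response has zero probability everywhere")
  grid$mass <- mass / total
  grid
}

#' Summarise the posterior into a threshold estimate
#'
#' The reported threshold is the posterior mean of \eqn{\log\tau}; its
#' uncertainty (standard error) is the posterior SD. \code{curve_min} is the
#' YES probability on blanks at the point-estimate parameters, and
#' \code{halfway_threshold} is the concentration where the point-estimate
#' curve crosses midway between its floor and ceiling — identically the
#' point estimate under the floored-probit form.
#'
#' @param grid a normalised \code{aromat_grid}.
#' @return List with \code{point}, \code{se}, \code{lambda_point},
#'   \code{curve_min}, \code{halfway_threshold}.
#' @export
posterior_summary <- function(grid) {
  m_tau <- rowSums(grid$mass)
  point <- sum(m_tau * grid$tau)
  v <- sum(m_tau * (grid$tau - point)^2)
  se <- sqrt(max(v, 0))
  m_lam <- colSums(grid$mass)
  lambda_point <- sum(m_lam * grid$lambda)
  curve_min <- false_alarm_rate(lambda_point)
  # midpoint of [gamma, 1] is attained at x = log tau for the floored probit
  list(point = point, se = se, lambda_point = lambda_point,
       curve_min = curve_min, halfway_threshold = point)
}

#' Posterior-predictive probability of a YES response
#'
#' Model-averaged YES probability at a stimulus: the mass-weighted mean of
#' \code{\link{yes_prob}} over all grid nodes. This is the weight used by
#' the adaptive policy to average the two possible outcomes of a candidate
#' trial.
#'
#' @param grid a normalised \code{aromat_grid}.
#' @param stimulus nominal log10 concentration or \code{NA} for a blank.
#' @return Probability in (0, 1).
#' @export
predictive_yes <- function(grid, stimulus) {
  sum(grid$mass * grid_yes_prob(grid, stimulus))
}

#' @export
print.aromat_grid <- function(x, ...) {
  s <- posterior_summary(x)
  cat("Posterior grid over (log tau, lambda):",
      length(x$tau), "x", length(x$lambda), "nodes\n")
  cat(sprintf("  log tau: mean %.3f, sd %.3f\n", s$point, s$se))
  cat(sprintf("  lambda:  mean %.3f (false-alarm rate %.3f)\n",
              s$lambda_point, s$curve_min))
  invisible(x)
}
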