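# all randomness flows from explicit seeds; helpers keep the caller's RNG
# state untouched so library code has no hidden side effects
with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

seeded <- function(seed, expr) {
  with_preserved_rng({
    set.seed(seed)
    expr
  })
}

# derive named substream seeds (< 2^31) from one root seed
substream_seeds <- function(seed, n) {
  seeded(seed, sample.int(.Machine$integer.max - 1L, n))
}

# overflow-safe seed shift, stays within 32-bit integer range
offset_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483645 + 1)
}

#' Create a virtual observer
#'
#' A virtual observer holds true psychometric parameters and a private
#' random stream, so its response sequence is fully reproducible.
#'
#' @param log_tau true log10 detection threshold.
#' @param lambda true decision criterion.
#' @param slope psychometric slope (default 0.5).
#' @param seed integer seed of the observer's private response stream.
#' @return An object of class \code{aromat_observer}.
#' @export
virtual_observer <- function(log_tau, lambda, slope = 0.5, seed = 1L) {
  structure(list(log_tau = log_tau, lambda = lambda, slope = slope,
                 seed = as.integer(seed)),
            class = "aromat_observer")
}

#' Responder function for a virtual observer
#'
#' Returns a closure suitable for \code{\link{run_session}}: on call
#' \eqn{t}, it answers YES with probability \code{yes_prob(log_tau, lambda,
#' stimulus)} using the \eqn{t}-th uniform deviate of the observer's private
#' stream, so replaying the observer yields an identical response sequence.
#'
#' @param observer an \code{aromat_observer}.
#' @param max_trials length of the pre-drawn deviate stream (default 16).
#' @return function(stimulus) -> "Y"/"N".
#' @export
observer_responder <- function(observer, max_trials = 16L) {
  u <- seeded(observer$seed, stats::runif(max_trials))
  i <- 0L
  function(stimulus) {
    i <<- i + 1L
    if (i > max_trials) stop("observer response stream exhausted")
    p <- yes_prob(observer$log_tau, observer$lambda, stimulus,
                  observer$slope)
    if (u[i] < p) "Y" else "N"
  }
}

#' Cohort simulation configuration
#'
#' Defaults emulate the field-study conditions the engine is designed for: a
#' festival cohort with a ~0.50 log10-unit sex difference (females more
#' sensitive), centred age-bin offsets giving a 0.94 log10-unit young-vs-old
#' and 0.61 middle-vs-old difference, 143 MZ and 37 DZ twin pairs with
#' broad-sense heritability 0.55 of the non-fixed variance, ~15% prior-COVID
#' prevalence with zero planted effect, and a residual SD of 1.0 log10
#' units. Observer criteria are drawn N(1.5, 0.5^2), putting the mean
#' blank false-alarm probability near the ~7.5% seen in the field.
#'
#' @param n_per_cell singletons per sex-by-age-bin cell: a scalar, or a 2x3
#'   matrix (rows M, F; columns age bins 18-37, 38-57, 58-77).
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic twin
#'   pairs (added on top of the singletons).
#' @param grand_mean grand mean of true log10 threshold.
#' @param sex_effect female-minus-male difference in true threshold (log10
#'   units; negative = females more sensitive).
#' @param age_effects length-3 numeric, centred age-bin offsets
#'   (young, middle, old).
#' @param covid_prevalence probability of a prior-COVID label.
#' @param covid_effect planted additive effect of prior COVID (log10 units).
#' @param sd_total SD of the familial + unique components combined.
#' @param h2 broad-sense heritability target: the share of
#'   \code{sd_total^2} that is familial. MZ co-twins share the full familial
#'   component; DZ co-twins share half its variance, so Falconer's
#'   \eqn{2(r_{MZ} - r_{DZ})} recovers \code{h2}.
#' @param lambda_mean,lambda_sd distribution of observer criteria.
#' @param retest_jitter SD of day-to-day jitter on true log threshold for
#'   test-retest simulations (default 0: reliability below 1 then reflects
#'   measurement error alone).
#' @param seed root seed; all substreams derive from it.
#' @return An object of class \code{aromat_cohort_config}.
#' @export
cohort_config <- function(n_per_cell = 29,
                          n_mz_pairs = 143, n_dz_pairs = 37,
                          grand_mean = -2.06,
                          sex_effect = -0.50,
                          age_effects = c(-0.94, -0.61, 0) -
                            mean(c(-0.94, -0.61, 0)),
                          covid_prevalence = 0.15,
                          covid_effect = 0,
                          sd_total = 1.0,
                          h2 = 0.55,
                          lambda_mean = 1.5, lambda_sd = 0.5,
                          retest_jitter = 0,
                          seed = 1L) {
  if (sd_total <= 0 || lambda_sd <= 0) stop("SDs must be positive")
  if (h2 < 0 || h2 > 1)
    stop("infeasible variance decomposition: h2 must lie in [0, 1]")
  if (covid_prevalence < 0 || covid_prevalence > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.matrix(n_per_cell)) {
    stopifnot(nrow(n_per_cell) == 2L, ncol(n_per_cell) == 3L)
  } else {
    n_per_cell <- matrix(n_per_cell, 2, 3)
  }
  dimnames(n_per_cell) <- list(c("M", "F"),
                               c("18-37", "38-57", "58-77"))
  structure(
    list(n_per_cell = n_per_cell, n_mz_pairs = n_mz_pairs,
         n_dz_pairs = n_dz_pairs, grand_mean = grand_mean,
         sex_effect = sex_effect, age_effects = age_effects,
         covid_prevalence = covid_prevalence, covid_effect = covid_effect,
         sd_total = sd_total, h2 = h2,
         lambda_mean = lambda_mean, lambda_sd = lambda_sd,
         retest_jitter = retest_jitter, seed = as.integer(seed)),
    class = "aromat_cohort_config"
  )
}

age_bins <- function() {
  data.frame(bin = c("18-37", "38-57", "58-77"),
             lo = c(18, 38, 58), hi = c(37, 57, 77),
             stringsAsFactors = FALSE)
}

bin_of_age <- function(age) {
  b <- age_bins()
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(b)))
    out[age >= b$lo[i] & age <= b$hi[i]] <- b$bin[i]
  out
}

#' Generate a synthetic cohort of true observer parameters and covariates
#'
#' True log10 thresholds follow an additive model: grand mean + sex effect
#' + age-bin effect + COVID effect + familial component + unique residual.
#' The familial/unique split implements the classical twin model: MZ
#' co-twins share the whole familial component, DZ co-twins share a
#' component carrying half the familial variance, so the planted
#' heritability is identified by Falconer's formula.
#'
#' @param config an \code{aromat_cohort_config}.
#' @return Data frame (one row per participant) with columns \code{id},
#'   \code{sex}, \code{age}, \code{age_bin}, \code{twin_id},
#'   \code{zygosity} ("MZ"/"DZ"/"none"), \code{race}, \code{covid},
#'   \code{true_log_tau}, \code{true_lambda}, \code{obs_seed}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  seeds <- substream_seeds(config$seed, 2L)
  seeded(seeds[1], {
    var_f <- config$h2 * config$sd_total^2
    var_e <- (1 - config$h2) * config$sd_total^2
    b <- age_bins()
    rows <- list()
    nid <- 0L
    add_person <- function(sex, bin_i, twin_id, zygosity, familial) {
      nid <<- nid + 1L
      age <- round(stats::runif(1, b$lo[bin_i], b$hi[bin_i]))
      list(id = nid, sex = sex, age = age, age_bin = b$bin[bin_i],
           twin_id = twin_id, zygosity = zygosity, familial = familial)
    }
    # singletons per cell
    for (s in c("M", "F")) for (k in 1:3) {
      n <- config$n_per_cell[s, k]
      for (j in seq_len(n))
        rows[[length(rows) + 1L]] <-
          add_person(s, k, NA_integer_, "none", stats::rnorm(1, 0, sqrt(var_f)))
    }
    # twin pairs: same age bin and age; MZ same sex, DZ sexes independent
    pair_id <- 0L
    for (z in c("MZ", "DZ")) {
      np <- if (z == "MZ") config$n_mz_pairs else config$n_dz_pairs
      for (j in seq_len(np)) {
        pair_id <- pair_id + 1L
        k <- sample.int(3, 1)
        sex1 <- sample(c("M", "F"), 1)
        sex2 <- if (z == "MZ") sex1 else sample(c("M", "F"), 1)
        if (z == "MZ") {
          a <- stats::rnorm(1, 0, sqrt(var_f))
          fam <- c(a, a)
        } else {
          shared <- stats::rnorm(1, 0, sqrt(var_f / 2))
          fam <- shared + stats::rnorm(2, 0, sqrt(var_f / 2))
        }
        p1 <- add_person(sex1, k, pair_id, z, fam[1])
        p2 <- add_person(sex2, k, pair_id, z, fam[2])
        p2$age <- p1$age
        rows[[length(rows) + 1L]] <- p1
        rows[[length(rows) + 1L]] <- p2
      }
    }
    df <- do.call(rbind, lapply(rows, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
    n <- nrow(df)
    df$race <- sample(c("White", "Black", "Asian", "Other"), n,
                      replace = TRUE, prob = c(0.85, 0.06, 0.04, 0.05))
    df$covid <- sample(c("yes", "no"), n, replace = TRUE,
                       prob = c(config$covid_prevalence,
                                1 - config$covid_prevalence))
    sex_half <- ifelse(df$sex == "F", config$sex_effect / 2,
                       -config$sex_effect / 2)
    age_off <- config$age_effects[match(df$age_bin, b$bin)]
    df$true_log_tau <- config$grand_mean + sex_half + age_off +
      ifelse(df$covid == "yes", config$covid_effect, 0) +
      df$familial + stats::rnorm(n, 0, sqrt(var_e))
    df$true_lambda <- stats::rnorm(n, config$lambda_mean, config$lambda_sd)
    df$familial <- NULL
    df$obs_seed <- substream_seeds(seeds[2], n)
    df
  })
}

#' Simulate one measured session per cohort participant
#'
#' Runs the full adaptive test for every participant — table-driven when a
#' precompiled lookup table is supplied (fast; the deployed configuration),
#' otherwise through the online engine — and appends the scored results.
#'
#' @param cohort data frame from \code{\link{generate_cohort}}.
#' @param card an \code{aromat_card}.
#' @param config an \code{aromat_prior}.
#' @param table optional \code{aromat_lookup}; strongly recommended for
#'   cohorts of more than a few dozen participants.
#' @param session_offset integer added to each observer seed, so repeated
#'   measurements (e.g. a retest day) use fresh response randomness.
#' @return The cohort with columns \code{threshold} (final reported
#'   threshold), \code{est_point}, \code{est_se}, \code{qc},
#'   \code{fa_first_blank}, \code{fa_both_blanks} appended.
#' @export
simulate_measured_cohort <- function(cohort, card,
                                     config = prior_config(),
                                     table = NULL, session_offset = 0L) {
  if (is.null(table)) {
    res <- lapply(seq_len(nrow(cohort)), function(i) {
      obs <- virtual_observer(cohort$true_log_tau[i],
                              cohort$true_lambda[i],
                              config$slope,
                              offset_seed(cohort$obs_seed[i], session_offset))
      s <- run_session(observer_responder(obs), card, config)
      list(threshold = s$final_threshold, est_point = s$point,
           est_se = s$se, qc = s$qc,
           fa_first_blank = s$fa_first_blank,
           fa_both_blanks = s$fa_both_blanks)
    })
  } else {
    res <- table_sessions(cohort, card, config, table, session_offset)
  }
  cohort$threshold <- vapply(res, `[[`, numeric(1), "threshold")
  cohort$est_point <- vapply(res, `[[`, numeric(1), "est_point")
  cohort$est_se <- vapply(res, `[[`, numeric(1), "est_se")
  cohort$qc <- vapply(res, `[[`, character(1), "qc")
  cohort$fa_first_blank <- vapply(res, `[[`, logical(1), "fa_first_blank")
  cohort$fa_both_blanks <- vapply(res, `[[`, logical(1), "fa_both_blanks")
  cohort
}

# vectorised table-driven sessions for a whole cohort
table_sessions <- function(cohort, card, config, table, session_offset) {
  n <- nrow(cohort)
  nt <- table$n_trials
  u <- matrix(NA_real_, n, nt)
  for (i in seq_len(n))
    u[i, ] <- seeded(offset_seed(cohort$obs_seed[i], session_offset),
                     stats::runif(16L))[seq_len(nt)]
  hist <- rep("", n)
  for (t in seq_len(nt)) {
    labs <- if (t == 1L) rep(1L, n) else
      vapply(hist, function(h) table$decisions[[h]], integer(1),
             USE.NAMES = FALSE)
    x <- vapply(labs, function(l) card_concentration(card, l), numeric(1))
    p <- yes_prob(cohort$true_log_tau, cohort$true_lambda, x, config$slope)
    hist <- paste0(hist, ifelse(u[, t] < p, "Y", "N"))
  }
  lapply(hist, function(h) {
    term <- table$terminals[[h]]
    list(threshold = term$final_threshold, est_point = term$point,
         est_se = term$se, qc = term$qc,
         fa_first_blank = term$fa_first_blank,
         fa_both_blanks = term$fa_both_blanks)
  })
}

#' Simulate a day-1 / day-2 test-retest experiment
#'
#' Each participant completes two independent sessions (fresh response
#' randomness; optional day-to-day jitter of the true threshold from
#' \code{cohort_config(retest_jitter=)}) and the Pearson correlation of the
#' two reported thresholds is returned.
#'
#' @param cohort data frame from \code{\link{generate_cohort}}.
#' @param card,config,table as in \code{\link{simulate_measured_cohort}}.
#' @param jitter_sd day-to-day SD of true log threshold (default 0).
#' @param seed seed of the jitter stream.
#' @return List with \code{day1}, \code{day2} (reported thresholds) and
#'   \code{r} (their Pearson correlation).
#' @export
simulate_test_retest <- function(cohort, card, config = prior_config(),
                                 table = NULL, jitter_sd = 0, seed = 1L) {
  d1 <- simulate_measured_cohort(cohort, card, config, table,
                                 session_offset = 0L)
  cohort2 <- cohort
  if (jitter_sd > 0)
    cohort2$true_log_tau <- cohort2$true_log_tau +
      seeded(seed, stats::rnorm(nrow(cohort2), 0, jitter_sd))
  d2 <- simulate_measured_cohort(cohort2, card, config, table,
                                 session_offset = 1000003L)
  list(day1 = d1$threshold, day2 = d2$threshold,
       r = stats::cor(d1$threshold, d2$threshold))
}
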