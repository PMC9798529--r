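#' Expected posterior uncertainty after sniffing a label
#'
#' The one-step-ahead objective of the adaptive policy: the expected
#' posterior SD of the log10 threshold after observing the response to the
#' given label, with the two outcomes weighted by their posterior-predictive
#' probabilities,
#' \deqn{E[SE] = p_{yes}\,SE(\mathrm{grid}|YES) + (1 - p_{yes})\,SE(\mathrm{grid}|NO).}
#'
#' @param grid current \code{aromat_grid}.
#' @param card an \code{aromat_card}.
#' @param label_id candidate label (must be available).
#' @param used integer vector of already-used label ids.
#' @return Expected posterior SD of log tau (log10 units).
#' @export
expected_uncertainty <- function(grid, card, label_id, used = integer()) {
  if (!(label_id %in% remaining_labels(card, used)))
    stop("label ", label_id, " is not available")
  x <- card_concentration(card, label_id)
  p_yes <- predictive_yes(grid, x)
  se_yes <- posterior_summary(posterior_update(grid, x, "Y"))$se
  se_no <- posterior_summary(posterior_update(grid, x, "N"))$se
  p_yes * se_yes + (1 - p_yes) * se_no
}

#' Select the next label to sniff
#'
#' Greedy uncertainty minimisation: among the labels still available
#' (blanks included), return the one with the smallest expected posterior SD
#' of the threshold. Ties are broken deterministically in favour of the
#' lowest label id, which also makes consumption of duplicate rungs
#' deterministic — a requirement for the precompiled lookup table.
#'
#' @param grid current \code{aromat_grid}.
#' @param card an \code{aromat_card}.
#' @param used integer vector of label ids already used this session.
#' @return The chosen label id (integer).
#' @export
select_next <- function(grid, card, used = integer()) {
  candidates <- remaining_labels(card, used)
  if (length(candidates) == 0L)
    stop("session exhausted: no labels left on the card")
  eu <- vapply(candidates, function(id)
    expected_uncertainty(grid, card, id, used), numeric(1))
  candidates[which.min(eu)]  # first minimum = lowest id on ties
}

#' Fit the psychometric model to a recorded trial sequence
#'
#' The core fitting function: replays a sequence of yes/no trials through
#' the grid Bayesian update, starting from the prior, and summarises the
#' joint posterior over (log threshold, criterion) into a threshold estimate
#' with its uncertainty. Used both to score recorded sessions and as the
#' engine behind \code{\link{run_session}}.
#'
#' @param trials data frame with columns \code{label_id}, \code{stimulus}
#'   (log10 concentration, \code{NA} for blanks) and \code{response}
#'   ("Y"/"N"), in presentation order.
#' @param config an \code{aromat_prior}.
#' @param card optional \code{aromat_card}; when supplied, ASTM extreme-value
#'   scoring, false-alarm flags and QC classification are attached (see
#'   \code{\link{finalize_threshold}}).
#' @param se_cutoff posterior-SD cutoff (log10 units) above which a
#'   non-imputed session is classified INDETERMINATE.
#' @return An object of class \code{aromat_session}; see
#'   \code{\link{run_session}} for its fields.
#' @export
fit_session <- function(trials, config = prior_config(), card = NULL,
                        se_cutoff = 1.0) {
  grid <- init_prior(config)
  for (i in seq_len(nrow(trials)))
    grid <- posterior_update(grid, trials$stimulus[i], trials$response[i])
  s <- posterior_summary(grid)
  session <- structure(
    list(trials = trials, grid = grid, config = config,
         point = s$point, se = s$se, lambda_point = s$lambda_point,
         curve_min = s$curve_min,
         final_threshold = s$point, qc = NA_character_,
         fa_first_blank = NA, fa_both_blanks = NA,
         se_cutoff = se_cutoff),
    class = "aromat_session"
  )
  if (!is.null(card)) session <- score_session(session, card, se_cutoff)
  session
}

#' Run one adaptive threshold test session
#'
#' Administers the full adaptive test against a responder function: trial 1
#' is always label 1 (an intermediate concentration perceptible to most
#' normosmic observers); every subsequent label is chosen by
#' \code{\link{select_next}} after the posterior is updated with the latest
#' response. The test always runs the fixed number of trials (default 8).
#'
#' @param responder function(stimulus) returning "Y" or "N"; receives the
#'   nominal log10 concentration or \code{NA} for a blank.
#' @param card an \code{aromat_card}.
#' @param config an \code{aromat_prior}.
#' @param n_trials number of scored trials (default 8).
#' @param se_cutoff QC cutoff passed to \code{\link{qc_classify}}.
#' @return An object of class \code{aromat_session} with fields
#'   \item{trials}{data frame of the scored trials.}
#'   \item{point, se}{posterior mean and SD of log10 threshold.}
#'   \item{final_threshold}{reported threshold after ASTM extreme-value
#'     imputation.}
#'   \item{qc}{one of DETERMINATE, INDETERMINATE, FLOOR_IMPUTED,
#'     CEILING_IMPUTED.}
#'   \item{fa_first_blank, fa_both_blanks}{false-alarm flags.}
#' @examples
#' card <- default_card()
#' # a noiseless observer with threshold -2 that never false-alarms
#' resp <- function(x) if (!is.na(x) && x >= -2) "Y" else "N"
#' s <- run_session(resp, card)
#' s$final_threshold
#' @export
run_session <- function(responder, card, config = prior_config(),
                        n_trials = 8, se_cutoff = 1.0) {
  if (n_trials < 1 || n_trials > 16)
    stop("n_trials must be in 1..16 (the card has 16 usable labels)")
  grid <- init_prior(config)
  used <- integer()
  labs <- integer(n_trials); stim <- numeric(n_trials)
  resp <- character(n_trials)
  for (t in seq_len(n_trials)) {
    lab <- if (t == 1L) 1L else select_next(grid, card, used)
    x <- card_concentration(card, lab)
    r <- responder(x)
    if (!r %in% c("Y", "N")) stop("responder must return 'Y' or 'N'")
    grid <- posterior_update(grid, x, r)
    used <- c(used, lab)
    labs[t] <- lab; stim[t] <- x; resp[t] <- r
  }
  trials <- make_trials(labs, stim, resp)
  s <- posterior_summary(grid)
  session <- structure(
    list(trials = trials, grid = grid, config = config,
         point = s$point, se = s$se, lambda_point = s$lambda_point,
         curve_min = s$curve_min,
         final_threshold = s$point, qc = NA_character_,
         fa_first_blank = NA, fa_both_blanks = NA,
         se_cutoff = se_cutoff),
    class = "aromat_session"
  )
  score_session(session, card, se_cutoff)
}

#' Precompile the complete decision lookup table
#'
#' The adaptive computation is demanding for an interactive device (the tree
#' doubles with every trial), so all 2^8 response paths are simulated in
#' advance. The result maps every partial response history (a "Y"/"N" string
#' of length 1..7) to the next label id, and every complete 8-response
#' history to its terminal estimate (posterior mean/SD, ASTM-final
#' threshold, QC class, false-alarm flags). A table-driven session needs no
#' posterior computation at run time.
#'
#' Trial 1 is fixed to label 1, so the decision map has
#' \eqn{2 + 4 + \dots + 2^7 = 254} entries and the terminal map 256.
#'
#' @param card an \code{aromat_card}.
#' @param config an \code{aromat_prior}.
#' @param n_trials number of scored trials (default 8).
#' @param se_cutoff QC cutoff used for terminal QC classes.
#' @return An object of class \code{aromat_lookup}: list with
#'   \code{card_hash}, \code{prior_hash}, \code{n_trials}, \code{decisions}
#'   (named list history -> label id) and \code{terminals} (named list
#'   history -> list(point, se, final_threshold, qc, fa_first_blank,
#'   fa_both_blanks, labels)).
#' @export
compile_lookup <- function(card, config = prior_config(), n_trials = 8,
                           se_cutoff = 1.0) {
  decisions <- new.env(parent = emptyenv())
  terminals <- new.env(parent = emptyenv())
  recurse <- function(grid, used, labs, stim, resp, hist) {
    depth <- length(resp)
    if (depth == n_trials) {
      trials <- make_trials(labs, stim, resp)
      s <- posterior_summary(grid)
      sess <- structure(
        list(trials = trials, point = s$point, se = s$se,
             final_threshold = s$point, qc = NA_character_),
        class = "aromat_session")
      sess <- score_session(sess, card, se_cutoff)
      assign(hist, list(point = s$point, se = s$se,
                        final_threshold = sess$final_threshold,
                        qc = sess$qc,
                        fa_first_blank = sess$fa_first_blank,
                        fa_both_blanks = sess$fa_both_blanks,
                        labels = labs),
             envir = terminals)
      return(invisible())
    }
    lab <- if (depth == 0L) 1L else {
      if (is.null(decisions[[hist]])) {
        decisions[[hist]] <- select_next(grid, card, used)
      }
      decisions[[hist]]
    }
    x <- card_concentration(card, lab)
    for (r in c("Y", "N")) {
      recurse(posterior_update(grid, x, r), c(used, lab),
              c(labs, lab), c(stim, x), c(resp, r), paste0(hist, r))
    }
  }
  recurse(init_prior(config), integer(), integer(), numeric(),
          character(), "")
  structure(
    list(card_hash = card_fingerprint(card),
         prior_hash = prior_fingerprint(config),
         n_trials = n_trials, se_cutoff = se_cutoff,
         decisions = as.list(decisions),
         terminals = as.list(terminals)),
    class = "aromat_lookup"
  )
}

#' Run a session driven by a precompiled lookup table
#'
#' Replays the adaptive test using only table lookups (no posterior
#' computation), as on the deployed device.
#'
#' @param responder function(stimulus) returning "Y"/"N".
#' @param table an \code{aromat_lookup} from \code{\link{compile_lookup}}.
#' @param card the \code{aromat_card} the table was compiled for.
#' @return An \code{aromat_session} (without the \code{grid} field).
#' @export
run_session_table <- function(responder, table, card) {
  if (!identical(table$card_hash, card_fingerprint(card)))
    stop("stale lookup table: card fingerprint mismatch")
  n <- table$n_trials
  labs <- integer(n); stim <- numeric(n); resp <- character(n)
  hist <- ""
  for (t in seq_len(n)) {
    lab <- if (t == 1L) 1L else table$decisions[[hist]]
    x <- card_concentration(card, lab)
    r <- responder(x)
    if (!r %in% c("Y", "N")) stop("responder must return 'Y' or 'N'")
    labs[t] <- lab; stim[t] <- x; resp[t] <- r
    hist <- paste0(hist, r)
  }
  term <- table$terminals[[hist]]
  structure(
    list(trials = make_trials(labs, stim, resp), grid = NULL,
         config = NULL, point = term$point, se = term$se,
         lambda_point = NA_real_, curve_min = NA_real_,
         final_threshold = term$final_threshold, qc = term$qc,
         fa_first_blank = term$fa_first_blank,
         fa_both_blanks = term$fa_both_blanks,
         se_cutoff = table$se_cutoff),
    class = "aromat_session"
  )
}

#' @export
print.aromat_lookup <- function(x, ...) {
  cat("Precompiled adaptive-test lookup table\n")
  cat("  trials:", x$n_trials, "| decisions:", length(x$decisions),
      "| terminals:", length(x$terminals), "\n")
  cat("  card hash:", x$card_hash, " prior hash:", x$prior_hash, "\n")
  invisible(x)
}

#' Write / read a lookup table as versioned JSON
#'
#' The file embeds the card and prior fingerprints; \code{read_lookup_json}
#' refuses a table whose fingerprints do not match the supplied card/config
#' (stale-table protection).
#'
#' @param table an \code{aromat_lookup}.
#' @param path file path.
#' @param card,config optional; when supplied, fingerprints are verified.
#' @return \code{read_lookup_json} returns an \code{aromat_lookup}.
#' @export
write_lookup_json <- function(table, path) {
  obj <- list(card_hash = table$card_hash, prior_hash = table$prior_hash,
              n_trials = table$n_trials, se_cutoff = table$se_cutoff,
              decisions = table$decisions, terminals = table$terminals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lookup_json
#' @export
read_lookup_json <- function(path, card = NULL, config = NULL) {
  obj <- jsonlite::read_json(path)
  if (!is.null(card) && !identical(obj$card_hash, card_fingerprint(card)))
    stop("stale lookup table: card fingerprint mismatch")
  if (!is.null(config) &&
      !identical(obj$prior_hash, prior_fingerprint(config)))
    stop("stale lookup table: prior fingerprint mismatch")
  terminals <- lapply(obj$terminals, function(t) {
    t$labels <- as.integer(unlist(t$labels))
    t$point <- as.numeric(t$point); t$se <- as.numeric(t$se)
    t$final_threshold <- as.numeric(t$final_threshold)
    t$fa_first_blank <- as.logical(t$fa_first_blank)
    t$fa_both_blanks <- as.logical(t$fa_both_blanks)
    t
  })
  structure(
    list(card_hash = obj$card_hash, prior_hash = obj$prior_hash,
         n_trials = as.integer(obj$n_trials),
         se_cutoff = as.numeric(obj$se_cutoff),
         decisions = lapply(obj$decisions, as.integer),
         terminals = terminals),
    class = "aromat_lookup"
  )
}
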