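#' Build the default 17-label odorant test card
#'
#' Constructs the standard card layout used by the adaptive threshold test:
#' 17 peel-and-burst labels numbered 0-16. Label 0 is an unscored blank used
#' to familiarise the participant with the background odor of the card. Among
#' labels 1-16, 14 carry odorant and 2 are blanks. The odorant labels span 8
#' nominal concentrations ("rungs") in half-log (0.5 log10) steps; the highest
#' concentration is denoted 0.0 on the nominal log10 scale (30% w/w in the
#' physical card) and the lowest is -3.5. The extreme rungs appear on one
#' label each; each of the 6 intermediate rungs appears on two labels, which
#' (together with the blanks) lets response bias be separated from
#' sensitivity.
#'
#' The label-to-rung assignment is a fixed, version-controlled constant.
#' Label 1 — always the first label sniffed — holds the intermediate rung
#' -1.5. The adaptive algorithm depends only on rung values, never on label
#' positions, so any permutation with the same rung multiset behaves
#' identically.
#'
#' @return An object of class \code{aromat_card}: a list with
#'   \item{contents}{numeric vector of length 17 named "0".."16"; nominal
#'     log10 concentration, or \code{NA} for a blank label.}
#'   \item{ladder}{sorted vector of the 8 distinct rungs.}
#'   \item{step}{log10 spacing between adjacent rungs (0.5).}
#'   \item{anchor_pct_ww}{\%w/w concentration of rung 0.0 (documentation
#'     only; 30).}
#'   \item{version}{card layout version string.}
#' @examples
#' card <- default_card()
#' card_concentration(card, 1)   # -1.5, the starting label
#' card_concentration(card, 0)   # NA (blank reference label)
#' @export
default_card <- function() {
  # fixed assignment: rungs 0 and -3.5 once; -0.5..-3.0 twice; blanks at 0, 5, 10
  contents <- c(
    "0"  = NA_real_,
    "1"  = -1.5,
    "2"  = -0.5,
    "3"  = -2.5,
    "4"  = 0.0,
    "5"  = NA_real_,
    "6"  = -1.0,
    "7"  = -3.0,
    "8"  = -2.0,
    "9"  = -0.5,
    "10" = NA_real_,
    "11" = -2.5,
    "12" = -1.0,
    "13" = -3.5,
    "14" = -2.0,
    "15" = -3.0,
    "16" = -1.5
  )
  new_card(contents, version = "aromat-card-1")
}

new_card <- function(contents, version = "custom") {
  stopifnot(length(contents) == 17L)
  names(contents) <- as.character(0:16)
  ladder <- sort(unique(contents[!is.na(contents)]))
  steps <- diff(ladder)
  card <- structure(
    list(
      contents = contents,
      ladder = ladder,
      step = if (length(steps)) steps[1] else NA_real_,
      anchor_pct_ww = 30,
      version = version
    ),
    class = "aromat_card"
  )
  validate_card(card)
  card
}

validate_card <- function(card) {
  contents <- card$contents
  if (length(contents) != 17L)
    stop("card must have exactly 17 labels (ids 0..16)")
  if (!is.na(contents[["0"]]))
    stop("label 0 must be blank (reference label)")
  body <- contents[as.character(1:16)]
  if (sum(is.na(body)) != 2L)
    stop("labels 1..16 must contain exactly 2 blanks")
  ladder <- card$ladder
  if (length(ladder) != 8L)
    stop("card ladder must have exactly 8 distinct concentrations")
  if (any(abs(diff(ladder) - card$step) > 1e-12))
    stop("ladder rungs must be evenly spaced")
  counts <- table(body[!is.na(body)])
  n_at <- as.integer(counts[as.character(ladder)])
  if (n_at[1] != 1L || n_at[length(n_at)] != 1L)
    stop("lowest and highest rungs must each appear on exactly 1 label")
  if (any(n_at[2:(length(n_at) - 1L)] != 2L))
    stop("each intermediate rung must appear on exactly 2 labels")
  invisible(card)
}

#' Look up the content of a card label
#'
#' @param card an \code{aromat_card}.
#' @param label_id integer label id in 0..16.
#' @return Nominal log10 concentration of the label, or \code{NA} if the
#'   label is a blank.
#' @export
card_concentration <- function(card, label_id) {
  if (length(label_id) != 1L || is.na(label_id) ||
      label_id != as.integer(label_id) || label_id < 0 || label_id > 16)
    stop("invalid card label id: ", label_id)
  unname(card$contents[[as.character(as.integer(label_id))]])
}

#' Labels still available during a session
#'
#' Physical labels are single-use within a session. Label 0 is the unscored
#' familiarisation blank and is never a candidate.
#'
#' @param card an \code{aromat_card}.
#' @param used integer vector of label ids already peeled (subset of 1..16).
#' @return Integer vector of available label ids, ascending.
#' @export
remaining_labels <- function(card, used = integer()) {
  used <- as.integer(used)
  if (any(used < 1L | used > 16L))
    stop("used label ids must lie in 1..16")
  setdiff(1:16, used)
}

#' @export
print.aromat_card <- function(x, ...) {
  cat("Odor test card (", x$version, ")\n", sep = "")
  cat("  17 labels; blanks at:",
      paste(names(x$contents)[is.na(x$contents)], collapse = ", "), "\n")
  cat("  ladder:", paste(format(x$ladder), collapse = " "),
      "(log10, step", format(x$step), ")\n")
  cat("  rung 0.0 =", x$anchor_pct_ww, "% w/w\n")
  invisible(x)
}

#' Write / read a card specification as JSON
#'
#' The on-disk format is \code{{version, step, anchor_pct_ww, labels:
#' [{id, rung|"BLANK"}]}}; blanks are encoded as the string \code{"BLANK"}.
#'
#' @param card an \code{aromat_card}.
#' @param path file path.
#' @return \code{read_card_json} returns an \code{aromat_card};
#'   \code{write_card_json} returns \code{path} invisibly.
#' @export
write_card_json <- function(card, path) {
  labels <- lapply(0:16, function(id) {
    rung <- card$contents[[as.character(id)]]
    list(id = id, rung = if (is.na(rung)) "BLANK" else rung)
  })
  obj <- list(
    version = card$version,
    step = card$step,
    anchor_pct_ww = card$anchor_pct_ww,
    labels = labels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_card_json
#' @export
read_card_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) stop("cannot parse card spec '", path, "': ",
                             conditionMessage(e))
  )
  contents <- rep(NA_real_, 17)
  names(contents) <- as.character(0:16)
  for (lab in obj$labels) {
    rung <- lab$rung
    contents[[as.character(lab$id)]] <-
      if (identical(rung, "BLANK")) NA_real_ else as.numeric(rung)
  }
  new_card(contents, version = obj$version)
}

# stable content fingerprint (polynomial rolling hash over the canonical JSON);
# used only to reject stale lookup tables, not cryptographic
fingerprint <- function(s) {
  b <- utf8ToInt(s)
  h <- 7
  for (x in b) h <- (h * 131 + x) %% 2147483647
  sprintf("%010d", h)
}

card_fingerprint <- function(card) {
  fingerprint(paste(card$version,
                    paste(ifelse(is.na(card$contents), "B",
                                 format(card$contents)), collapse = ","),
                    sep = "|"))
}
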