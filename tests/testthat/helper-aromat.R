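# shared fixtures, all built in code

# coarse prior/grid for fast tests where resolution is not under test
coarse_prior <- function() {
  prior_config(tau_grid = seq(-7.5, 1.5, by = 0.1),
               lambda_grid = seq(-1, 3, by = 0.2))
}

# tiny 5x5 grid for hand-checkable Bayes updates
toy_grid <- function() {
  cfg <- prior_config(tau_grid = seq(-4, 0, by = 1),
                      lambda_grid = seq(0, 2, by = 0.5))
  init_prior(cfg)
}

# noiseless threshold observer: YES iff odorant at or above cut, NO to blanks
step_responder <- function(cut) {
  function(x) if (!is.na(x) && x >= cut) "Y" else "N"
}

# scripted responder replaying a "YN..." string
scripted_responder <- function(responses) {
  toks <- strsplit(responses, "")[[1]]
  i <- 0L
  function(x) {
    i <<- i + 1L
    toks[i]
  }
}

# card whose ladder is shifted up by 1 log unit (max rung 1.0, min -2.5)
shifted_card <- function() {
  card <- default_card()
  contents <- card$contents + 1
  aromat:::new_card(contents, version = "shifted-test-card")
}

# compile the default lookup table once per test run
cached_lookup <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- compile_lookup(default_card(), prior_config())
    memo
  }
})

# split a simulated twin cohort into per-zygosity pair matrices of a column
twin_pairs <- function(cohort, zygosity, col = "true_log_tau") {
  tz <- cohort[cohort$zygosity == zygosity, ]
  do.call(rbind, lapply(split(tz[[col]], tz$twin_id), function(v) v[1:2]))
}
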