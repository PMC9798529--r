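#' Two-way fixed-effects ANOVA of threshold by sex and age group
#'
#' Fits \code{threshold ~ sex * age_bin} as a fixed-effects linear model,
#' reports type II F tests for sex, age group and their interaction
#' (configurable; type II is appropriate for the unbalanced cohorts the
#' simulator produces), Tukey HSD pairwise comparisons of the age-bin
#' means, and the group means in log10 units.
#'
#' @param table cohort data frame with columns \code{sex} (M/F),
#'   \code{age_bin} and \code{threshold}.
#' @param ss_type "II" (default) or "I" sums of squares.
#' @return List with \code{anova} (data frame: term, df, F, p),
#'   \code{tukey_age} (TukeyHSD table for age bins), \code{group_means},
#'   \code{sex_means} and \code{sex_difference} (female minus male).
#' @export
anova_sex_age <- function(table, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  table$sex <- factor(table$sex)
  table$age_bin <- factor(table$age_bin)
  if (nlevels(table$sex) < 2L || nlevels(table$age_bin) < 2L)
    stop("degenerate design: need >= 2 levels of sex and age_bin")
  cells <- table(table$sex, table$age_bin)
  if (any(cells == 0L))
    stop("degenerate design: empty sex x age_bin cell")
  fit <- stats::aov(threshold ~ sex * age_bin, data = table)
  if (ss_type == "II") {
    a2 <- car::Anova(stats::lm(threshold ~ sex * age_bin, data = table),
                     type = 2)
    terms <- rownames(a2)[rownames(a2) != "Residuals"]
    an <- data.frame(term = terms,
                     df = a2$Df[seq_along(terms)],
                     F = a2$`F value`[seq_along(terms)],
                     p = a2$`Pr(>F)`[seq_along(terms)],
                     stringsAsFactors = FALSE)
  } else {
    a1 <- summary(fit)[[1]]
    terms <- trimws(rownames(a1))
    keep <- terms != "Residuals"
    an <- data.frame(term = terms[keep], df = a1$Df[keep],
                     F = a1$`F value`[keep], p = a1$`Pr(>F)`[keep],
                     stringsAsFactors = FALSE)
  }
  gm <- stats::aggregate(threshold ~ sex + age_bin, data = table, mean)
  sm <- tapply(table$threshold, table$sex, mean)
  list(anova = an,
       tukey_age = stats::TukeyHSD(fit, "age_bin")$age_bin,
       group_means = gm,
       sex_means = sm,
       sex_difference = unname(sm["F"] - sm["M"]))
}

#' Chi-squared test of floor-threshold proportions by sex
#'
#' Tests whether the proportion of participants at the lowest measurable
#' threshold (the ASTM floor imputation value) differs between sexes, using
#' the uncorrected Pearson chi-squared statistic on the 2x2 contingency
#' table.
#'
#' @param table cohort data frame with \code{sex} and \code{threshold}.
#' @param floor floor value (default -4.5, the default card's floor).
#' @return List with \code{counts} (2x2 table), \code{percent} (at-floor
#'   percentage per sex), \code{statistic}, \code{df}, \code{p}.
#' @export
floor_proportion_test <- function(table, floor = -4.5) {
  sex <- factor(table$sex)
  if (nlevels(sex) < 2L) stop("both sexes must be present")
  at_floor <- factor(table$threshold <= floor + 1e-9,
                     levels = c(FALSE, TRUE))
  counts <- table(sex, at_floor)
  pct <- 100 * prop.table(counts, 1)[, "TRUE"]
  if (any(colSums(counts) == 0L) || any(rowSums(counts) == 0L)) {
    warning("degenerate contingency margin; chi-squared undefined")
    return(list(counts = counts, percent = pct,
                statistic = NA_real_, df = NA_integer_, p = NA_real_))
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(counts = counts, percent = pct,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Falconer broad-sense heritability from twin threshold pairs
#'
#' Computes the Pearson correlation of thresholds within monozygotic and
#' dizygotic pairs and Falconer's broad-sense heritability
#' \eqn{H^2 = 2(r_{MZ} - r_{DZ})}. Uncertainty comes from the Fisher
#' transformation: \eqn{Var(z) = 1/(n-3)} per correlation, delta-method
#' back-transformed to the r scale (\eqn{Var(r) \approx (1-r^2)^2/(n-3)})
#' and propagated as \eqn{Var(H^2) = 4(Var(r_{MZ}) + Var(r_{DZ}))}. The MZ
#' vs DZ comparison is the standard two-sample z test on Fisher-z scores;
#' both two-sided (primary) and one-sided p values are reported.
#'
#' @param pairs_mz,pairs_dz two-column matrices or data frames, one row per
#'   twin pair (thresholds of the two co-twins). At least 4 pairs each.
#' @return Object of class \code{aromat_heritability}: list with
#'   \code{r_mz}, \code{r_dz}, \code{se_r_mz}, \code{se_r_dz}, \code{h2},
#'   \code{se_h2}, \code{z_compare}, \code{p_two_sided},
#'   \code{p_one_sided}, \code{n_mz}, \code{n_dz}.
#' @examples
#' # worked example with the rounded field-study correlations:
#' # 2 * (0.46 - 0.19) = 0.54 (the unrounded inputs give 0.55)
#' @export
falconer_heritability <- function(pairs_mz, pairs_dz) {
  pairs_mz <- as.matrix(pairs_mz); pairs_dz <- as.matrix(pairs_dz)
  n_mz <- nrow(pairs_mz); n_dz <- nrow(pairs_dz)
  if (n_mz < 4L || n_dz < 4L)
    stop("insufficient data: need >= 4 twin pairs per zygosity")
  r_mz <- stats::cor(pairs_mz[, 1], pairs_mz[, 2])
  r_dz <- stats::cor(pairs_dz[, 1], pairs_dz[, 2])
  var_r <- function(r, n) (1 - r^2)^2 / (n - 3)
  se_r_mz <- sqrt(var_r(r_mz, n_mz))
  se_r_dz <- sqrt(var_r(r_dz, n_dz))
  h2 <- 2 * (r_mz - r_dz)
  se_h2 <- sqrt(4 * (var_r(r_mz, n_mz) + var_r(r_dz, n_dz)))
  z <- (atanh(r_mz) - atanh(r_dz)) /
    sqrt(1 / (n_mz - 3) + 1 / (n_dz - 3))
  structure(
    list(r_mz = r_mz, r_dz = r_dz, se_r_mz = se_r_mz, se_r_dz = se_r_dz,
         h2 = h2, se_h2 = se_h2, z_compare = z,
         p_two_sided = 2 * stats::pnorm(-abs(z)),
         p_one_sided = stats::pnorm(-z),
         n_mz = n_mz, n_dz = n_dz),
    class = "aromat_heritability"
  )
}

#' @export
print.aromat_heritability <- function(x, ...) {
  cat("Falconer broad-sense heritability from twin correlations\n")
  cat(sprintf("  MZ: r = %.2f +/- %.2f (n = %d pairs)\n",
              x$r_mz, x$se_r_mz, x$n_mz))
  cat(sprintf("  DZ: r = %.2f +/- %.2f (n = %d pairs)\n",
              x$r_dz, x$se_r_dz, x$n_dz))
  cat(sprintf("  H2 = 2(r_MZ - r_DZ) = %.2f +/- %.2f\n", x$h2, x$se_h2))
  cat(sprintf("  MZ vs DZ: z = %.2f, p = %.3f (two-sided), %.3f (one-sided)\n",
              x$z_compare, x$p_two_sided, x$p_one_sided))
  invisible(x)
}

#' 1:1 propensity-score matching
#'
#' Estimates a logistic propensity model for the treatment indicator on the
#' requested covariates and performs greedy 1:1 nearest-neighbour matching
#' without replacement on the linear-predictor scale: treated units are
#' visited in order of decreasing propensity and each takes the closest
#' unused control. The output contains each treated row and its matched
#' control, giving two equally sized groups.
#'
#' @param table cohort data frame.
#' @param treatment name of a two-level column; the rarer interpretation
#'   "yes" (or \code{TRUE}) is treated.
#' @param covariates character vector of covariate column names.
#' @return The matched subset of \code{table} with a \code{subclass} column
#'   (pair id) and a \code{pscore} column.
#' @export
propensity_match <- function(table, treatment = "covid",
                             covariates = c("age", "sex", "race")) {
  tr <- table[[treatment]]
  treated <- if (is.logical(tr)) tr else tr %in% c("yes", "1", "TRUE")
  if (!any(treated) || !any(!treated))
    stop("both treatment groups must be non-empty")
  if (sum(treated) > sum(!treated))
    stop("infeasible matching: more cases than controls")
  # drop covariates with no variation (they cannot enter the model)
  keep <- covariates[vapply(covariates, function(v)
    length(unique(table[[v]])) > 1L, logical(1))]
  if (length(keep) == 0L) {
    ps <- rep(0, nrow(table))   # all units identical in covariate space
  } else {
    f <- stats::as.formula(paste("treated ~",
                                 paste(keep, collapse = " + ")))
    dat <- cbind(treated = treated, table[keep])
    ps <- stats::predict(stats::glm(f, family = stats::binomial(),
                                    data = dat), type = "link")
  }
  idx_t <- which(treated)[order(ps[treated], decreasing = TRUE)]
  idx_c <- which(!treated)
  taken <- logical(length(idx_c))
  pairs <- matrix(NA_integer_, length(idx_t), 2)
  for (k in seq_along(idx_t)) {
    d <- abs(ps[idx_c] - ps[idx_t[k]])
    d[taken] <- Inf
    j <- which.min(d)
    taken[j] <- TRUE
    pairs[k, ] <- c(idx_t[k], idx_c[j])
  }
  out <- table[as.vector(t(pairs)), , drop = FALSE]
  out$subclass <- rep(seq_len(nrow(pairs)), each = 2)
  out$pscore <- ps[as.vector(t(pairs))]
  rownames(out) <- NULL
  out
}

#' COVID-history ANCOVA and distributional comparison on a matched cohort
#'
#' Fixed-effects linear model \code{threshold ~ covid + sex + age} (age
#' continuous) with type II F tests, adjusted for sex and age; group means
#' and SDs by COVID history; and a two-sample Kolmogorov-Smirnov test of
#' the threshold distributions (asymptotic p).
#'
#' @param matched matched cohort from \code{\link{propensity_match}} (any
#'   cohort data frame with \code{threshold}, \code{covid}, \code{sex},
#'   \code{age} works).
#' @return List with \code{anova} (term, df, F, p), \code{group_stats}
#'   (mean/sd/n per COVID group), \code{ks_D}, \code{ks_p}.
#' @export
covid_ancova <- function(matched) {
  matched$covid <- factor(matched$covid)
  matched$sex <- factor(matched$sex)
  terms <- "covid"
  if (nlevels(matched$sex) > 1L) terms <- c(terms, "sex")
  if (stats::sd(matched$age) > 0) terms <- c(terms, "age")
  fit <- stats::lm(stats::as.formula(
    paste("threshold ~", paste(terms, collapse = " + "))), data = matched)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  an <- data.frame(term = terms, df = a2$Df[seq_along(terms)],
                   F = a2$`F value`[seq_along(terms)],
                   p = a2$`Pr(>F)`[seq_along(terms)],
                   stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(split(matched$threshold, matched$covid),
                              function(v) data.frame(mean = mean(v),
                                                     sd = stats::sd(v),
                                                     n = length(v))))
  g <- split(matched$threshold, matched$covid)
  ks <- suppressWarnings(stats::ks.test(g[[1]], g[[2]], exact = FALSE))
  list(anova = an, group_stats = gs,
       ks_D = unname(ks$statistic), ks_p = ks$p.value)
}

#' Test-retest Pearson correlation
#'
#' @param day1,day2 numeric vectors of repeated threshold estimates, same
#'   length, at least 3 pairs.
#' @return Pearson product-moment correlation.
#' @export
pearson_retest <- function(day1, day2) {
  if (length(day1) != length(day2) || length(day1) < 3L)
    stop("need >= 3 complete day1/day2 pairs")
  if (stats::sd(day1) == 0 || stats::sd(day2) == 0)
    stop("undefined correlation: zero variance in one day")
  stats::cor(day1, day2)
}
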