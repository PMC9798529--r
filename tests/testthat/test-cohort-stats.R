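make_toy_table <- function(means, reps = 2, noise = NULL) {
  # balanced 2 x 3 design; means is a 2x3 matrix (rows M,F) of cell means
  sex <- rep(rep(c("M", "F"), each = 3 * reps))
  bin <- rep(rep(c("18-37", "38-57", "58-77"), each = reps), 2)
  mu <- mapply(function(s, b) means[ifelse(s == "M", 1, 2),
                                    match(b, c("18-37", "38-57", "58-77"))],
               sex, bin)
  thr <- mu + if (is.null(noise)) 0 else noise
  data.frame(sex = sex, age_bin = bin, age = 30, threshold = thr,
             stringsAsFactors = FALSE)
}

test_that("null data give near-zero F statistics and no Tukey hits", {
  set.seed(1)
  tab <- make_toy_table(matrix(0, 2, 3), reps = 30,
                        noise = rnorm(180, 0, 1))
  res <- anova_sex_age(tab)
  expect_true(all(res$anova$p > 0.001))
  expect_true(all(res$tukey_age[, "p adj"] > 0.01))
})

test_that("balanced two-way ANOVA matches a hand-computed SS decomposition", {
  # 2 x 3 with 2 replicates; fixed offsets plus a deterministic residual
  means <- rbind(c(-1, -2, -3), c(-2, -3, -4))
  eps <- c(0.1, -0.1)                       # within-cell deviations
  tab <- make_toy_table(means, reps = 2, noise = rep(eps, 6))
  res <- anova_sex_age(tab)
  # independent oracle: textbook sums of squares on the 12 rows
  y <- tab$threshold
  grand <- mean(y)
  cm <- tapply(y, list(tab$sex, tab$age_bin), mean)
  am <- tapply(y, tab$sex, mean)
  bm <- tapply(y, tab$age_bin, mean)
  ss_a <- 6 * sum((am - grand)^2)
  ss_b <- 4 * sum((bm - grand)^2)
  ss_cells <- 2 * sum((cm - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - cm[cbind(tab$sex, tab$age_bin)])^2)
  f_a <- (ss_a / 1) / (ss_e / 6)
  f_b <- (ss_b / 2) / (ss_e / 6)
  f_ab <- (ss_ab / 2) / (ss_e / 6)
  got <- setNames(res$anova$F, res$anova$term)
  expect_equal(got[["sex"]], f_a, tolerance = 1e-8)
  expect_equal(got[["age_bin"]], f_b, tolerance = 1e-8)
  expect_equal(got[["sex:age_bin"]], f_ab, tolerance = 1e-8)
  expect_equal(res$sex_difference, mean(means[2, ]) - mean(means[1, ]),
               tolerance = 0.1)
})

test_that("ANOVA rejects degenerate designs explicitly", {
  tab <- make_toy_table(matrix(0, 2, 3), reps = 2)
  expect_error(anova_sex_age(tab[tab$sex == "M", ]), "degenerate")
  expect_error(anova_sex_age(tab[!(tab$sex == "F" &
                                     tab$age_bin == "58-77"), ]),
               "degenerate")
})

test_that("floor-proportion chi-squared matches the hand statistic", {
  # planted 2x2: 20/100 females vs 5/100 males at floor
  tab <- data.frame(
    sex = rep(c("F", "M"), each = 100),
    threshold = c(rep(-4.5, 20), rep(-2, 80), rep(-4.5, 5), rep(-2, 95)))
  res <- floor_proportion_test(tab)
  O <- matrix(c(80, 20, 95, 5), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
  expect_equal(unname(res$percent), c(20, 5))
  expect_lt(res$p, 0.01)
  # equal proportions: statistic ~ 0
  tab0 <- data.frame(sex = rep(c("F", "M"), each = 50),
                     threshold = rep(c(-4.5, -2, -4.5, -2),
                                     c(10, 40, 10, 40)))
  expect_equal(floor_proportion_test(tab0)$statistic, 0, tolerance = 1e-10)
  # degenerate margin warns instead of crashing
  tab1 <- data.frame(sex = rep(c("F", "M"), each = 5),
                     threshold = rep(-4.5, 10))
  expect_warning(res1 <- floor_proportion_test(tab1), "degenerate")
  expect_true(is.na(res1$statistic))
})

test_that("Falconer formula, its SE and the z comparison are exact", {
  # algebraic identity on arbitrary synthetic pairs
  set.seed(2)
  mz <- matrix(rnorm(80), ncol = 2)
  dz <- matrix(rnorm(40), ncol = 2)
  her <- falconer_heritability(mz, dz)
  expect_equal(her$h2, 2 * (her$r_mz - her$r_dz), tolerance = 1e-12)
  expect_gte(her$se_h2, 0)
  # worked example with the field-study pair counts: rounded correlations
  # 0.46 / 0.19 give h2 = 0.54 and the published-style uncertainties
  mk_pairs_with_r <- function(r, n) {
    x <- rnorm(n); x <- (x - mean(x)) / sd(x)
    e <- rnorm(n); e <- resid(lm(e ~ x)); e <- e / sd(e)
    cbind(x, r * x + sqrt(1 - r^2) * e)    # sample correlation exactly r
  }
  mz46 <- mk_pairs_with_r(0.46, 143)
  dz19 <- mk_pairs_with_r(0.19, 37)
  her2 <- falconer_heritability(mz46, dz19)
  expect_equal(her2$r_mz, 0.46, tolerance = 1e-8)
  expect_equal(her2$r_dz, 0.19, tolerance = 1e-8)
  expect_equal(her2$h2, 0.54, tolerance = 1e-8)
  expect_lt(abs(her2$se_r_mz - 0.07), 0.01)
  expect_lt(abs(her2$se_r_dz - 0.16), 0.01)
  expect_lt(abs(her2$se_h2 - 0.36), 0.01)
  expect_lt(abs(her2$p_one_sided - 0.055), 0.005)
  expect_error(falconer_heritability(mz[1:3, ], dz), "insufficient")
})

test_that("Fisher-z intervals have near-nominal coverage", {
  set.seed(3)
  rho <- 0.4; n <- 60
  hits <- 0; reps <- 600
  for (k in seq_len(reps)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    z <- atanh(cor(x, y))
    ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
    if (rho >= ci[1] && rho <= ci[2]) hits <- hits + 1
  }
  expect_equal(hits / reps, 0.95, tolerance = 0.03)
})

test_that("propensity matching returns equal groups matching a greedy oracle", {
  set.seed(4)
  n_case <- 20; n_ctrl <- 80
  tab <- data.frame(
    age = c(rnorm(n_case, 50, 10), rnorm(n_ctrl, 40, 12)),
    sex = sample(c("M", "F"), n_case + n_ctrl, TRUE),
    race = sample(c("White", "Black"), n_case + n_ctrl, TRUE,
                  prob = c(0.8, 0.2)),
    covid = rep(c("yes", "no"), c(n_case, n_ctrl)),
    threshold = rnorm(n_case + n_ctrl, -2, 1))
  m <- propensity_match(tab)
  expect_equal(nrow(m), 2 * n_case)
  expect_equal(sum(m$covid == "yes"), n_case)
  expect_equal(sum(m$covid == "no"), n_case)
  expect_equal(length(unique(m$subclass)), n_case)
  # brute-force oracle: the same greedy rule enumerated independently
  tr <- tab$covid == "yes"
  ps <- predict(glm(I(covid == "yes") ~ age + sex + race,
                    family = binomial(), data = tab), type = "link")
  order_t <- which(tr)[order(ps[tr], decreasing = TRUE)]
  avail <- which(!tr)
  oracle_pairs <- list()
  for (i in order_t) {
    j <- avail[which.min(abs(ps[avail] - ps[i]))]
    avail <- setdiff(avail, j)
    oracle_pairs[[length(oracle_pairs) + 1]] <- c(i, j)
  }
  oracle_rows <- unlist(oracle_pairs)
  expect_setequal(
    paste(m$age, m$covid),
    paste(tab$age[oracle_rows], tab$covid[oracle_rows]))
  # covariate-identical clones match at distance zero
  clones <- data.frame(age = rep(c(30, 40, 50), 2),
                       sex = rep("M", 6), race = rep("White", 6),
                       covid = rep(c("yes", "no"), each = 3),
                       threshold = 1:6)
  mc <- propensity_match(clones)
  for (s in unique(mc$subclass)) {
    pair <- mc[mc$subclass == s, ]
    expect_equal(pair$age[1], pair$age[2])
  }
  expect_error(propensity_match(tab[c(1:20, 21:30), ]), "infeasible")
})

test_that("matching improves covariate balance on a confounded cohort", {
  set.seed(5)
  n <- 400
  age <- rnorm(n, 45, 12)
  p_covid <- plogis(-4 + 0.06 * age)
  covid <- ifelse(runif(n) < p_covid, "yes", "no")
  tab <- data.frame(age = age, sex = sample(c("M", "F"), n, TRUE),
                    race = "White", covid = covid,
                    threshold = rnorm(n, -2, 1))
  m <- propensity_match(tab, covariates = c("age", "sex"))
  smd <- function(d) {
    a <- d$age[d$covid == "yes"]; b <- d$age[d$covid == "no"]
    abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }
  expect_lt(smd(m), smd(tab))
})

test_that("ANCOVA and KS test behave on null and hand-computed inputs", {
  set.seed(6)
  n <- 80
  tab <- data.frame(age = runif(n, 20, 70),
                    sex = sample(c("M", "F"), n, TRUE),
                    covid = rep(c("yes", "no"), n / 2),
                    threshold = rnorm(n, -2, 1))
  res <- covid_ancova(tab)
  expect_identical(res$anova$term, c("covid", "sex", "age"))
  expect_true(all(res$anova$p > 0 & res$anova$p <= 1))
  # clone each case into an identical control: D = 0, covid F ~ 0
  half <- tab[tab$covid == "yes", ]
  tab2 <- rbind(half, transform(half, covid = "no"))
  res2 <- covid_ancova(tab2)
  expect_equal(res2$ks_D, 0, tolerance = 1e-12)
  expect_lt(res2$anova$F[1], 1e-10)
  # hand-computed KS on 5+5 values
  a <- c(1, 2, 3, 4, 5); b <- c(1.5, 2.5, 3.5, 4.5, 10)
  grid <- sort(unique(c(a, b)))
  D_hand <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  tab3 <- data.frame(age = 30, sex = "M",
                     covid = rep(c("yes", "no"), each = 5),
                     threshold = c(a, b))
  expect_equal(covid_ancova(tab3)$ks_D, D_hand, tolerance = 1e-12)
})

test_that("KS statistic is invariant under common monotone transforms", {
  set.seed(7)
  a <- rnorm(40, -2, 1); b <- rnorm(40, -1.5, 1.2)
  D0 <- suppressWarnings(ks.test(a, b, exact = FALSE))$statistic
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 10^x)) {
    Df <- suppressWarnings(ks.test(f(a), f(b), exact = FALSE))$statistic
    expect_equal(unname(Df), unname(D0), tolerance = 1e-12)
  }
})

test_that("retest correlation matches hand arithmetic and handles edge cases", {
  d1 <- c(-2.1, -3.0, -1.5, -4.5, -2.8, -0.9, -3.3, -2.0, -1.1, -2.6)
  d2 <- c(-2.4, -2.7, -1.8, -4.0, -3.1, -1.2, -2.9, -2.2, -1.5, -2.3)
  # hand oracle: covariance over product of SDs from first principles
  num <- sum((d1 - mean(d1)) * (d2 - mean(d2)))
  den <- sqrt(sum((d1 - mean(d1))^2) * sum((d2 - mean(d2))^2))
  expect_equal(pearson_retest(d1, d2), num / den, tolerance = 1e-12)
  expect_equal(pearson_retest(d1, d1), 1)
  expect_equal(pearson_retest(d1, -d1), -1)
  expect_error(pearson_retest(d1[1:2], d2[1:2]), ">= 3")
  expect_error(pearson_retest(rep(1, 5), d2[1:5]), "zero variance")
})

test_that("planted effects survive the full simulate-analyse pipeline", {
  card <- default_card()
  lut <- cached_lookup()
  cfg <- cohort_config(n_per_cell = 50, seed = 9)
  coh <- generate_cohort(cfg)
  m <- simulate_measured_cohort(coh, card, prior_config(), lut)
  res <- anova_sex_age(m)
  p <- setNames(res$anova$p, res$anova$term)
  expect_lt(p[["sex"]], 0.01)       # planted -0.50 log10 units
  expect_lt(p[["age_bin"]], 0.01)   # planted 0.94 young-vs-old
  expect_equal(res$sex_difference, -0.50, tolerance = 0.25)
})
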