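test_that("logistic fit matches a high-precision IRLS oracle on a hand-built table", {
  x <- c(0.2, 1.1, 2.5, 0.7, 3.0, 1.8, 0.4, 2.2)
  y <- c(1, 0, 0, 1, 0, 1, 1, 0)
  fit <- fit_diagnosis_logistic(x, ifelse(y == 1, "HCC", "healthy"))
  beta <- unname(oracle_logistic(x, y))
  expect_equal(fit$coefficient, beta[2], tolerance = 1e-8)
  expect_equal(fit$odds_ratio, exp(beta[2]), tolerance = 1e-8)
  expect_equal(fit$odds_ratio_per_sd, exp(beta[2] * sd(x)), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 8L)
})

test_that("logistic fit flags separation and rejects degenerate inputs", {
  x <- c(1, 2, 3, 10, 11, 12)
  lab <- rep(c("healthy", "HCC"), each = 3)
  expect_warning(fit <- fit_diagnosis_logistic(x, lab), "separation")
  expect_true(fit$separation)
  expect_error(fit_diagnosis_logistic(rep(1, 6), lab), "constant predictor")
  expect_error(fit_diagnosis_logistic(x, rep("HCC", 6)), "at least one")
})

test_that("t test reproduces the closed form and is antisymmetric", {
  a <- c(1.1, 2.3, 3.1)
  b <- c(2.0, 2.8, 4.4)
  got <- compare_group_means(c(a, b), rep(c("g1", "g2"), each = 3))
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_manual), df = 4), tolerance = 1e-12)
  swapped <- compare_group_means(c(b, a), rep(c("g1", "g2"), each = 3))
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
  ident <- compare_group_means(c(a, a), rep(c("g1", "g2"), each = 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("chi-square matches the 2x2 closed form; df follows (r-1)(c-1)", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  got <- arb_category_chisq(tab)
  n <- sum(tab)
  want <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(got$statistic, want, tolerance = 1e-12)
  expect_equal(got$df, 1L)

  same_rows <- rbind(c(10, 30, 60), c(20, 60, 120))
  got0 <- arb_category_chisq(same_rows)
  expect_equal(got0$statistic, 0, tolerance = 1e-12)
  expect_equal(got0$p_value, 1)

  expect_equal(arb_category_chisq(matrix(5, 3, 4))$df, 6L)
  expect_error(arb_category_chisq(rbind(c(0, 0), c(3, 4))), "expected")
})

test_that("KM and log-rank match hand tabulation on the 6-subject toy", {
  time <- 1:6
  event <- rep(1L, 6)
  strat <- rep(c("A", "B"), 3)
  got <- km_logrank(time, event, strat)
  # stratum A: deaths at 1, 3, 5 with 3, 2, 1 at risk
  a <- got$curves[got$curves$stratum == "A", ]
  expect_equal(a$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(a$n_risk, c(3, 2, 1))
  b <- got$curves[got$curves$stratum == "B", ]
  expect_equal(b$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(got$statistic, oracle_logrank(time, event, strat),
               tolerance = 1e-10)
  # duplicated data across strata: exchangeable, statistic 0
  dup <- km_logrank(rep(time, 2), rep(event, 2), rep(c("A", "B"), each = 6))
  expect_equal(dup$statistic, 0, tolerance = 1e-12)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(21)
  time <- rexp(40)
  got <- km_logrank(c(time, time + 0.1), rep(1, 80),
                    rep(c("A", "B"), each = 40))
  a <- got$curves[got$curves$stratum == "A", ]
  emp <- vapply(a$time, function(t) mean(time > t), numeric(1))
  expect_equal(a$surv, emp, tolerance = 1e-12)
  ora <- oracle_km(time, rep(1, 40))
  expect_equal(a$surv, ora$surv, tolerance = 1e-12)
})

test_that("km_logrank handles missing records and the all-censored corner", {
  expect_message(got <- km_logrank(c(1, 2, 3, NA), c(1, 1, 1, 1),
                                   c("A", "B", "A", "B")),
                 "dropped 1")
  expect_equal(got$n_used, 3L)
  expect_warning(cens <- km_logrank(1:4, rep(0, 4), rep(c("A", "B"), 2)),
                 "censored")
  expect_equal(cens$statistic, 0)
})

test_that("stratified Spearman matches the direct rank formula and handles ties", {
  x <- c(3.1, 1.2, 5.5, 2.2, 4.4, 0.7, 3.3)
  y <- c(2.0, 1.1, 6.2, 2.9, 3.3, 0.4, 5.1)
  got <- stratified_spearman(x, y, rep("s", 7))
  expect_equal(got$rho, oracle_spearman(x, y), tolerance = 1e-12)

  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6)
  gt <- stratified_spearman(xt, yt, rep("s", 7))
  expect_equal(gt$rho, oracle_spearman(xt, yt), tolerance = 1e-12)

  mono <- stratified_spearman(1:8, (1:8)^3, rep("s", 8))
  expect_equal(mono$rho, 1)
  rev_ <- stratified_spearman(1:8, -(1:8)^3, rep("s", 8))
  expect_equal(rev_$rho, -1)

  expect_warning(small <- stratified_spearman(c(1, 2, 1, 2, 3, 4),
                                              c(2, 1, 5, 6, 7, 8),
                                              rep(c("tiny", "ok"), c(2, 4))),
                 "tiny")
  expect_true(is.na(small$rho[small$stratum == "tiny"]))
})

test_that("BH utility delegates to the standard adjustment", {
  p <- c(0.01, 0.04, 0.03, 0.2)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})
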