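test_that("equal weights reproduce the unweighted fits in all three families", {
  d <- make_analysis_table(1500, seed = 41)
  d$weight <- 2
  d$quintile_x <- d$exposure_quintile
  ok <- !is.na(d$abnormal_ggt)

  res <- fit_weighted_logistic(d, "abnormal_ggt", "quintile_x", reference = 5)
  ref <- glm(abnormal_ggt ~ factor(quintile_x, levels = c(5, 1:4)),
             data = d[ok, ], family = binomial())
  expect_equal(log(res$estimate[-1]), unname(coef(ref)[-1]), tolerance = 1e-6)

  lin <- fit_weighted_linear_log(d, "ggt", "quintile_x", reference = 5)
  ref_lm <- lm(log(ggt) ~ factor(quintile_x, levels = c(5, 1:4)),
               data = d[!is.na(d$ggt), ])
  expect_equal(lin$estimate[-1], unname(coef(ref_lm)[-1]), tolerance = 1e-8)

  d$comp <- abnormal_composite(d)
  orl <- fit_ordinal_logistic(d, "comp", "quintile_x", reference = 5)
  ref_polr <- MASS::polr(factor(comp, ordered = TRUE) ~
                           factor(quintile_x, levels = c(5, 1:4)),
                         data = d[!is.na(d$comp), ], Hess = TRUE)
  expect_equal(log(orl$estimate[-1]), unname(coef(ref_polr)), tolerance = 1e-4)
})

test_that("a covariate-free OR equals the weighted cross-product ratio", {
  d <- make_analysis_table(3000,
                           true_log_odds = list(alp = c(log(2.5), 0, 0, 0, 0)),
                           seed = 43)
  d$quintile_x <- d$exposure_quintile
  res <- fit_weighted_logistic(d, "abnormal_alp", "quintile_x", reference = 5)
  ok <- !is.na(d$abnormal_alp)
  wtab <- with(d[ok, ], tapply(weight, list(abnormal_alp, quintile_x), sum))
  oracle <- (wtab["TRUE", "1"] / wtab["FALSE", "1"]) /
    (wtab["TRUE", "5"] / wtab["FALSE", "5"])
  expect_equal(res$estimate[res$level == "1"], oracle, tolerance = 1e-6)
  # reported weighted prevalences match the same table
  expect_equal(res$weighted_pct[res$level == "1"],
               100 * wtab["TRUE", "1"] / sum(wtab[, "1"]), tolerance = 1e-8)
})

test_that("log-linear model is invariant to rescaling levels", {
  d <- make_analysis_table(1200, seed = 47)
  d$quintile_x <- d$exposure_quintile
  a <- fit_weighted_linear_log(d, "alt", "quintile_x",
                               covariates = c("age", "gender"), reference = 5)
  d2 <- dplyr::mutate(d, alt = alt * 10)
  b <- fit_weighted_linear_log(d2, "alt", "quintile_x",
                               covariates = c("age", "gender"), reference = 5)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
  expect_error(
    fit_weighted_linear_log(dplyr::mutate(d, alt = alt - 60), "alt",
                            "quintile_x", reference = 5),
    "strictly positive"
  )
})

test_that("ordinal model collapses to binary logistic with two levels", {
  d <- make_analysis_table(2500, seed = 53)
  d$quintile_x <- d$exposure_quintile
  d$bin_comp <- as.integer(abnormal_composite(d) > 0)
  suppressWarnings({
    orl <- fit_ordinal_logistic(d, "bin_comp", "quintile_x", reference = 5)
  })
  lgl <- fit_weighted_logistic(d, "bin_comp", "quintile_x", reference = 5)
  expect_equal(log(orl$estimate[-1]), log(lgl$estimate[-1]), tolerance = 1e-3)
})

test_that("permuted exposure yields null ordinal ORs", {
  d <- make_analysis_table(4000,
                           true_log_odds = list(ggt = c(1, .5, .3, .1, 0)),
                           seed = 59)
  d$comp <- abnormal_composite(d)
  d$quintile_perm <- withr::with_seed(60, sample(d$exposure_quintile))
  res <- fit_ordinal_logistic(d, "comp", "quintile_perm", reference = 5)
  expect_true(all(abs(log(res$estimate[-1])) < 0.35))
})

test_that("trend p-value is invariant to affine recoding of the index", {
  d <- make_analysis_table(2000,
                           true_log_odds = list(ggt = c(.8, .6, .4, .2, 0)),
                           seed = 61)
  d$quintile_x <- d$exposure_quintile
  p1 <- trend_test(d, "abnormal_ggt", "quintile_x", c("age", "gender"))
  d$quintile_recode <- 10 * d$quintile_x - 3
  p2 <- trend_test(d, "abnormal_ggt", "quintile_recode", c("age", "gender"))
  expect_equal(p1$p.value, p2$p.value, tolerance = 1e-9)
  expect_lt(p1$p.value, 0.05)
  d$const <- 3
  expect_error(trend_test(d, "abnormal_ggt", "const"), "constant")
})

test_that("interaction test demands a varying modifier and detects strong ones", {
  d <- make_analysis_table(4000, seed = 67)
  d$quintile_x <- d$exposure_quintile
  d$const <- "a"
  expect_error(
    interaction_test(d, "abnormal_ggt", "quintile_x", "const"),
    "constant"
  )
  # plant a strong interaction: Q1 effect only among diabetics
  d2 <- withr::with_seed(68, {
    eta <- qlogis(0.12) + ifelse(d$diabetes & d$exposure_quintile == 1, log(6), 0)
    dplyr::mutate(d, abnormal_ggt = rbinom(dplyr::n(), 1, plogis(eta)) == 1)
  })
  suppressWarnings(
    it <- interaction_test(d2, "abnormal_ggt", "quintile_x", "diabetes")
  )
  expect_lt(it$p.value, 0.05)
  expect_equal(it$df, 4L)
})

test_that("stratified runs split as expected and skip empty strata", {
  d <- make_analysis_table(3000, seed = 71)
  d$quintile_x <- d$exposure_quintile
  # duplicating the data into two identical strata gives identical results
  dd <- dplyr::bind_rows(dplyr::mutate(d, g = "s1"), dplyr::mutate(d, g = "s2"))
  res <- stratified_run(dd, "abnormal_ggt", "quintile_x", "g")
  s1 <- res[res$stratum == "s1", c("level", "estimate", "conf.low")]
  s2 <- res[res$stratum == "s2", c("level", "estimate", "conf.low")]
  expect_equal(s1, s2)

  d$g <- ifelse(seq_len(nrow(d)) <= 2990, "big", NA)
  res2 <- stratified_run(d, "abnormal_ggt", "quintile_x", "g")
  expect_equal(unique(res2$stratum), "big")
})

test_that("shift-worker sensitivity refits only the unflagged subset", {
  d <- make_analysis_table(2500, seed = 73)
  d$quintile_x <- d$exposure_quintile
  none <- rep(FALSE, nrow(d))
  main <- fit_weighted_logistic(d, "abnormal_ggt", "quintile_x", reference = 5)
  sens <- sensitivity_exclude_shift(d, none, "abnormal_ggt", "quintile_x",
                                    reference = 5)
  expect_equal(sens$estimate, main$estimate)
  expect_equal(attr(sens, "n_removed"), 0L)
  expect_error(
    sensitivity_exclude_shift(d, rep(TRUE, nrow(d)), "abnormal_ggt",
                              "quintile_x"),
    "empty analysis set"
  )
})

test_that("sandwich CIs bracket the estimate and ORs stay positive", {
  d <- make_analysis_table(2000, true_log_odds = list(alt = c(.7, 0, 0, 0, 0)),
                           seed = 79)
  d$quintile_x <- d$exposure_quintile
  res <- fit_weighted_logistic(d, "abnormal_alt", "quintile_x",
                               covariates = c("age", "gender"), reference = 5)
  nonref <- res[!res$reference, ]
  expect_true(all(nonref$conf.low < nonref$estimate))
  expect_true(all(nonref$estimate < nonref$conf.high))
  expect_true(all(nonref$estimate > 0))
})

test_that("the full battery emits every exposure-outcome-model cell", {
  d <- make_analysis_table(500, seed = 83)
  d <- withr::with_seed(84, dplyr::mutate(
    d,
    pseudo_F = exposure_quintile + runif(500),
    amplitude = runif(500, 50, 150),
    mesor = runif(500, 40, 100),
    amp_mesor_ratio = runif(500, 0.4, 1.9),
    acrophase = runif(500, 10, 18),
    IS = runif(500), IV = runif(500, 0.3, 2),
    sleep_minutes_per_day = rnorm(500, 470, 50),
    total_activity = rlnorm(500, 10, 0.4)
  ))
  s <- score_participants(d)
  suppressWarnings(
    out <- run_full_analysis(s, models = c("model1", "model2", "model3", "model4"),
                             composite = TRUE)
  )
  done <- dplyr::distinct(out$results, exposure, outcome, model)
  primary_failures <- if (nrow(out$failures)) {
    dplyr::filter(out$failures, outcome != "abnormal_composite")
  } else {
    out$failures
  }
  expect_equal(nrow(done) + nrow(primary_failures), 7L * 6L * 4L)
  expect_gte(nrow(done), 7L * 6L * 4L - 8L) # rare small-sample failures only
  expect_true(all(c("estimate", "conf.low", "conf.high", "p_trend",
                    "weighted_pct", "n") %in% names(out$results)))
  if (!is.null(out$composite) && nrow(out$composite)) {
    expect_true(all(out$composite$outcome == "abnormal_composite"))
  }
})

test_that("a seeded synthetic analysis is fully reproducible", {
  run_once <- function() {
    d <- make_analysis_table(800, true_log_odds = list(ggt = c(.5, 0, 0, 0, 0)),
                             seed = 91)
    d$quintile_x <- d$exposure_quintile
    fit_weighted_logistic(d, "abnormal_ggt", "quintile_x",
                          covariates = c("age", "gender"), reference = 5)
  }
  a <- run_once()
  b <- run_once()
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})
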