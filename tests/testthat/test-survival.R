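test_that("KM product-limit and restricted mean match the hand example", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$rmean, 2.0)  # 1*1 + (2/3)*1 + (1/3)*1

  one <- km_estimate(5, FALSE)
  expect_equal(one$surv, 1)
  expect_equal(one$rmean, 5)
  expect_true(is.na(one$median))

  cens <- km_estimate(c(2, 4, 6), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(cens$median))  # never reaches 0.5

  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "> 0")
})

test_that("KM with no censoring equals the empirical survivor function", {
  set.seed(14)
  t <- round(rexp(40, 0.2), 2) + 0.01
  km <- km_estimate(t, rep(TRUE, 40))
  for (i in seq_along(km$time))
    expect_equal(km$surv[i], mean(t > km$time[i]), tolerance = 1e-12)
})

test_that("restricted mean matches an independent step-area oracle", {
  set.seed(15)
  for (rep in 1:5) {
    t <- rexp(30, 0.1)
    e <- runif(30) > 0.3
    if (!any(e)) e[1] <- TRUE
    km <- km_estimate(t, e)
    oracle <- hand_km_rmean(t, e)
    expect_equal(km$rmean, oracle$rmean, tolerance = 1e-12)
    expect_equal(km$surv[km$n_event > 0], oracle$surv, tolerance = 1e-12)
    expect_true(all(diff(km$surv) <= 1e-12))  # nonincreasing
    expect_lte(km$rmean, km$rmean_tmax)
  }
})

test_that("log-rank is null on exchangeable groups, sharp on separation", {
  t <- c(1, 3, 5, 7, 9)
  dup <- c(t, t)
  grp <- rep(c("A", "B"), each = 5)
  lr <- logrank_test(dup, rep(TRUE, 10), grp)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  sep <- logrank_test(c(1, 1.1, 1.2, 1.3, 1.4, 10, 10.1, 10.2, 10.3, 10.4),
                      rep(TRUE, 10), grp)
  expect_lt(sep$p, 0.01)
  expect_equal(sep$df, 1)

  # relabeling the groups leaves the statistic unchanged
  flipped <- logrank_test(c(1, 1.1, 1.2, 1.3, 1.4, 10, 10.1, 10.2, 10.3, 10.4),
                          rep(TRUE, 10), rev(grp))
  expect_equal(flipped$chisq, sep$chisq, tolerance = 1e-12)

  expect_error(logrank_test(t, rep(TRUE, 5), factor(rep("A", 5),
                                                    levels = c("A", "B"))),
               "nonempty")
})

test_that("Cox reports no contrast as a unit hazard ratio", {
  fit <- cox_fit(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE),
                 data.frame(x = rep(2, 4)))
  expect_equal(unname(fit$coefficients), 0)
  expect_equal(unname(fit$hr), 1)
})

test_that("Cox score test equals the log-rank chi-square without ties", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 40
    g <- rep(0:1, n / 2)
    t <- rexp(n, 0.1 * exp(0.5 * g))
    e <- runif(n) > 0.25
    if (sum(e) < 2) e[1:2] <- TRUE
    fit <- cox_fit(t, e, data.frame(g = g))
    lr <- logrank_test(t, e, g)
    expect_equal(fit$score_test, lr$chisq, tolerance = 1e-6)
  }
})

test_that("Cox flags monotone likelihood on separable data", {
  x <- 1:12
  t <- exp(-x)  # perfectly ordered by the covariate
  fit <- cox_fit(t, rep(TRUE, 12), data.frame(x = x))
  expect_true(fit$monotone)
  expect_error(cox_fit(1:3, c(FALSE, FALSE, FALSE), data.frame(x = 1:3)),
               "event")
})

test_that("marker survival report accepts fixed published-style cuts", {
  cfg <- qpcr_sim_config(seed = 19)
  sc <- normalize_ct(simulate_qpcr_cohort(cfg))
  sm <- score_matrix(sc)
  pat <- rownames(sm)[grepl("^P", rownames(sm))]
  sv <- simulate_survival(cfg, sm[pat, ])
  cuts <- c(HOXB13 = -3.8, MAOA = -4.1, FGD4 = 0.4, MOSPD1 = -4.0,
            QKI = 0.5, SDK1 = -2.0)
  rep_tab <- marker_survival_report(sc[sc$group == "patient", ], cuts, sv,
                                    endpoint = "PFS")
  expect_equal(nrow(rep_tab), 12)  # one low/high row pair per marker
  expect_setequal(unique(rep_tab$marker), names(cuts))
  for (m in names(cuts)) {
    rows <- rep_tab[rep_tab$marker == m, ]
    expect_identical(rows$group, c("low", "high"))
    expect_equal(rows$cutoff, rep(cuts[[m]], 2))
    expect_equal(rows$logrank_p[1], rows$logrank_p[2])
    expect_true(all(rows$mean_lcl <= rows$mean & rows$mean <= rows$mean_ucl))
  }
})

test_that("markers with an empty group after the cut are skipped", {
  sc <- data.frame(sample_id = sprintf("P%d", 1:6), gene = "M",
                   score = 1:6)
  sv <- data.frame(sample_id = sprintf("P%d", 1:6),
                   time = c(2, 4, 6, 8, 10, 12), event = TRUE)
  expect_warning(out <- marker_survival_report(sc, c(M = 100), sv),
                 "skipped")
  expect_null(out)
})

test_that("a strong marker effect shortens its high group's survival", {
  cfg <- qpcr_sim_config(n_patients = 60,
                         hazard_coefs = c(1.2, 0, 0, 0, 0, 0),
                         censor_rate = 0.1, seed = 23)
  sc <- normalize_ct(simulate_qpcr_cohort(cfg))
  sm <- score_matrix(sc)
  pat <- rownames(sm)[grepl("^P", rownames(sm))]
  sv <- simulate_survival(cfg, sm[pat, ])
  rep_tab <- marker_survival_report(
    sc[sc$group == "patient" & sc$gene == "HOXB13", ], "median", sv,
    endpoint = "PFS")
  lo <- rep_tab$mean[rep_tab$group == "low"]
  hi <- rep_tab$mean[rep_tab$group == "high"]
  expect_lt(hi, lo)
  expect_lt(rep_tab$logrank_p[1], 0.05)
})
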