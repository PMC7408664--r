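test_that("CD45 normalization follows the 40-Ct convention", {
  rows <- data.frame(
    sample_id = rep("S1", 6), group = "patient",
    gene = c("A", "A", "B", "B", "CD45", "CD45"),
    well = rep(1:2, 3),
    ct = c(30, 30, 25, 25, 25, 25))
  sc <- normalize_ct(make_qpcr(rows))
  expect_equal(sc$score[sc$gene == "A"], (40 - 30) - (40 - 25))  # -5
  expect_equal(sc$score[sc$gene == "B"], 0)                      # Ct equal

  rows$ct[rows$gene == "A"] <- 40  # all replicates at the floor
  sc <- normalize_ct(make_qpcr(rows))
  expect_equal(sc$score[sc$gene == "A"], -15)
})

test_that("replicates are averaged before scoring", {
  rows <- data.frame(
    sample_id = "S1", group = "patient",
    gene = c("A", "A", "CD45", "CD45"), well = rep(1:2, 2),
    ct = c(29, 31, 24, 26))
  sc <- normalize_ct(make_qpcr(rows))
  expect_equal(sc$score, 25 - 30)
})

test_that("a sample without the reference gene is a named error", {
  rows <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S2", "S2"),
    group = "patient",
    gene = c("A", "A", "A", "A", "CD45", "CD45"),
    well = rep(1:2, 3), ct = 30)
  expect_error(normalize_ct(make_qpcr(rows)), "S1")
})

test_that("samples missing a gene score as missing, not zero", {
  rows <- data.frame(
    sample_id = c("S1", "S1", "S1", "S1", "S2", "S2"),
    group = "patient",
    gene = c("A", "A", "CD45", "CD45", "CD45", "CD45"),
    well = rep(1:2, 3), ct = 30)
  sc <- normalize_ct(make_qpcr(rows))
  expect_true(is.na(sc$score[sc$sample_id == "S2" & sc$gene == "A"]))
})

test_that("Mann-Whitney matches the enumeration oracle", {
  mw <- mannwhitney_test(1:3, 4:6)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 * (1/20)

  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(7, 0.5)
    got <- mannwhitney_test(x, y, mode = "exact")
    want <- enumerate_mw_p(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    # and agrees with the reference implementation
    expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("identical groups are a null case, not an error", {
  expect_equal(mannwhitney_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  out <- mannwhitney_test(rep(2, 4), rep(2, 5))
  expect_equal(out$p, 1)
  expect_equal(out$method, "degenerate")
  expect_error(mannwhitney_test(numeric(0), 1), "nonempty")
  expect_error(mannwhitney_test(c(1, 1), c(1, 2), mode = "exact"), "ties")
})

test_that("tie-corrected normal approximation tracks the reference", {
  set.seed(8)
  x <- round(rnorm(20, 0, 2)); y <- round(rnorm(25, 1, 2))
  got <- mannwhitney_test(x, y, mode = "normal")
  want <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(want$statistic))
})

test_that("BH adjustment reproduces the step-up worked examples", {
  q <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.9))
  expect_equal(q, c(0.06, 0.06, 0.06, 0.06, 0.06, 0.9))
  expect_equal(bh_fdr(0.03), 0.03)               # m = 1
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is permutation invariant and monotone in sorted order", {
  set.seed(5)
  p <- runif(25)
  q <- bh_fdr(p)
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("ROC separation, null behavior and the U identity", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(sep$auc, 1.0)

  set.seed(12)
  null <- roc_auc(rnorm(1000), rep(c(TRUE, FALSE), 500))
  expect_lt(abs(null$auc - 0.5), 0.06)

  for (rep in 1:25) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    x <- sample(1:10, n1, replace = TRUE)  # force ties
    y <- sample(1:10, n2, replace = TRUE)
    lab <- c(rep(TRUE, n1), rep(FALSE, n2))
    auc <- roc_auc(c(x, y), lab)$auc
    U <- mannwhitney_test(x, y)$U
    expect_equal(auc, U / (n1 * n2), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("logistic panel flags separation with AUC 1", {
  x <- c(-3, -2, -1, 1, 2, 3)
  fit <- fit_panel_logistic(cbind(g = x), x > 0)
  expect_true(fit$separation)
  expect_equal(fit$auc, 1.0)
})

test_that("logistic panel recovers known coefficients", {
  set.seed(22)
  n <- 1200
  X <- cbind(g1 = rnorm(n), g2 = rnorm(n))
  p <- plogis(X %*% c(2, -1))
  y <- runif(n) < p
  fit <- fit_panel_logistic(X, y)
  expect_lt(abs(fit$coefficients["g1"] - 2) / 2, 0.15)
  expect_lt(abs(fit$coefficients["g2"] + 1) / 1, 0.15)
  expect_false(fit$separation)
  expect_true(fit$converged)

  null <- fit_panel_logistic(X[1:300, ], rep(c(TRUE, FALSE), 150))
  expect_lt(null$auc, 0.65)
})

test_that("panel preconditions are enforced", {
  expect_error(fit_panel_logistic(cbind(a = 1:3, b = 1:3), c(TRUE, FALSE, TRUE)),
               "at least")
  expect_error(fit_panel_logistic(cbind(a = 1:10), rep(TRUE, 10)),
               "both classes")
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  out <- pearson_corr(x, c(2, 1, 4, 3))
  expect_equal(out$r, 0.6)
  expect_equal(out$p, cor.test(x, c(2, 1, 4, 3))$p.value)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "n >= 3")
})

test_that("dichotomization cuts match their definitions", {
  g <- dichotomize(c(1, 2, 3, 4), "median")
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_equal(attr(g, "cutoff"), 2.5)

  g70 <- dichotomize(1:10, "p70")
  expect_equal(attr(g70, "cutoff"), 7)  # nearest rank: ceiling(0.7*10)
  expect_equal(sum(g70 == "low"), 7)
  expect_equal(sum(g70 == "high"), 3)

  gf <- dichotomize(c(-5, -3.9, -3.8, -1), -3.8)
  expect_identical(as.character(gf), c("low", "low", "low", "high"))

  expect_warning(dichotomize(rep(2, 4), "median"), "all samples")
  expect_error(dichotomize(1, "median"), ">= 2")
})

test_that("the marker table finds simulated effects with FDR control", {
  cfg <- qpcr_sim_config(seed = 31)  # default effects of 2 score units
  tab <- marker_test_table(normalize_ct(simulate_qpcr_cohort(cfg)))
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$q < 0.05))
  expect_true(all(tab$q >= tab$p))
  expect_true(all(tab$auc > 0.8))
  expect_true(all(tab$median_patient > tab$median_control))
  expect_equal(tab$n_patient, rep(28, 6))
  expect_equal(tab$n_control, rep(15, 6))
})
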