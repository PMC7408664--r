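test_that("outlier flags are counted under criterion (a) first", {
  exper <- make_spots(signal = rep(100, 10),
                      nonuni = c(TRUE, rep(FALSE, 9)),
                      repout = c(FALSE, TRUE, rep(FALSE, 8)))
  ncs <- make_spots(signal = c(2, 3, 4), above_bg = FALSE,
                    control = "negative_control")
  ncs$probe_id <- paste0("nc", 1:3)
  t <- spot_table(rbind(as.data.frame(exper), as.data.frame(ncs)),
                  "S1", "patient")
  out <- qc_filter_spots(t)
  expect_equal(out$report$n_outlier, 2)
  expect_equal(out$report$n_background, 0)
  expect_equal(out$report$n_negctrl_range, 0)
  expect_equal(out$report$n_controls, 3)
  expect_equal(nrow(out$spots), 8)
  expect_equal(out$report$filtered_spots, 5)
  expect_equal(out$report$filtered_fraction, 5 / 13)
})

test_that("negative-control threshold sits exactly at mean + k*SD", {
  exper <- make_spots(signal = c(100, 100.01))
  ncs <- make_spots(signal = c(100, 100, 100), above_bg = FALSE,
                    control = "negative_control")
  ncs$probe_id <- paste0("nc", 1:3)
  t <- spot_table(rbind(as.data.frame(exper), as.data.frame(ncs)),
                  "S1", "patient")
  expect_equal(negcontrol_threshold(t), 100)  # SD = 0
  out <- qc_filter_spots(t)
  expect_equal(out$spots$probe_id, "p02")  # 100 removed (<= thr), 100.01 kept
  expect_equal(out$report$n_negctrl_range, 1)
})

test_that("a fully disabled policy removes only control spots", {
  exper <- make_spots(signal = c(5, 50, 500), above_bg = FALSE,
                      nonuni = TRUE)
  ctrl <- make_spots(signal = 10, control = "other_control")
  ctrl$probe_id <- "oc1"
  t <- spot_table(rbind(as.data.frame(exper), as.data.frame(ctrl)),
                  "S1", "patient")
  p <- filter_policy(drop_nonuniform_outliers = FALSE,
                     drop_replicate_outliers = FALSE,
                     require_above_background = FALSE,
                     negcontrol_k = 0)
  out <- qc_filter_spots(t, p)
  expect_equal(nrow(out$spots), 3)
  expect_equal(out$report$filtered_spots, 1)
  expect_equal(out$report$n_controls, 1)
})

test_that("a missing negative-control set is a configuration error", {
  t <- make_spots(signal = rep(10, 4))
  expect_error(qc_filter_spots(t), "negative-control")
  expect_error(detection_call(t), "negative-control")
})

test_that("per-criterion counts always sum to the filtered total", {
  sim <- simulate_array_cohort(
    array_sim_config(n_genes = 60, n_ctc_genes = 10, outlier_rate = 0.1,
                     seed = 6))
  for (t in sim$tables[c(1, 5, 12)]) {
    out <- qc_filter_spots(t)
    r <- out$report
    expect_equal(r$n_outlier + r$n_background + r$n_negctrl_range +
                   r$n_controls, r$filtered_spots)
    expect_lte(r$filtered_spots, r$total_spots)
    expect_true(all(out$spots$probe_id %in% t$probe_id))  # subset
  }
})

test_that("quantile normalization matches the rank-mean worked example", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(quantile_normalize(x),
               cbind(a = c(2.5, 3.5, 4.5), b = c(2.5, 3.5, 4.5)))
  # identical samples are a fixed point
  y <- cbind(c(3, 1, 2), c(3, 1, 2))
  expect_equal(quantile_normalize(y), y, ignore_attr = TRUE)
})

test_that("quantile normalization equalizes distributions, keeps ranks", {
  set.seed(10)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 6, sd = i), 40, 6)
    q <- quantile_normalize(x)
    sorted <- apply(q, 2, sort)
    expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
    for (j in 1:6) expect_equal(rank(q[, j]), rank(x[, j]))
  }
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), ">= 2 samples")
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "finite")
})

test_that("detection is monotone in signal for clean spots", {
  sim <- simulate_array_cohort(
    array_sim_config(n_genes = 40, n_ctc_genes = 5, seed = 13))
  t <- sim$tables[[1]]
  d0 <- detection_call(t)
  t2 <- t
  bump <- t2$control_type == "experimental"
  t2$processed_signal[bump] <- t2$processed_signal[bump] * 10
  d1 <- detection_call(t2)
  clean <- t$control_type == "experimental" & t$flag_above_background &
    !t$flag_nonuniform_outlier & !t$flag_replicate_outlier
  expect_true(all(d1[clean] >= d0[clean]))
})

test_that("probe collapse takes the median with an any-detected rule", {
  vals <- rbind(pa1 = c(5, 1), pa2 = c(7, 3), pb1 = c(2, 9))
  det <- rbind(pa1 = c(FALSE, TRUE), pa2 = c(FALSE, FALSE),
               pb1 = c(TRUE, FALSE))
  samples <- data.frame(sample_id = c("P1", "H1"),
                        group = c("patient", "healthy"))
  m <- collapse_probes(vals, c("A", "A", NA), det, samples)
  expect_equal(rownames(m$values), c("A", "pb1"))
  expect_equal(unname(m$values["A", ]), c(6, 2))     # median of {5,7},{1,3}
  expect_equal(unname(m$values["pb1", ]), c(2, 9))   # single probe unchanged
  expect_identical(unname(m$detected["A", ]), c(FALSE, TRUE))
  expect_identical(unname(m$detected["pb1", ]), c(TRUE, FALSE))

  empty <- collapse_probes(matrix(numeric(0), 0, 2), character(0),
                           matrix(logical(0), 0, 2), samples)
  expect_equal(nrow(empty$values), 0)
})

test_that("spike-in detection recovers the ground truth exactly", {
  cfg <- array_sim_config(n_genes = 200, n_ctc_genes = 25,
                          signal_shift = 6, background_sigma = 1,
                          outlier_rate = 0, seed = 21)
  sim <- simulate_array_cohort(cfg)
  m <- build_expression_matrix(sim$tables)$matrix
  det <- m$detected[sim$truth$ctc_genes, , drop = FALSE]
  pat <- m$samples$group == "patient"
  expect_identical(unname(det[, pat]), unname(sim$truth$carriers))
  expect_false(any(det[, !pat]))
})

test_that("the strict common-probe policy yields a retained subset", {
  sim <- simulate_array_cohort(
    array_sim_config(n_genes = 60, n_ctc_genes = 8, outlier_rate = 0.05,
                     seed = 30))
  full <- build_expression_matrix(sim$tables, probe_policy = "all_experimental")
  strict <- build_expression_matrix(sim$tables, probe_policy = "common_retained")
  expect_true(all(rownames(strict$matrix$values) %in%
                    rownames(full$matrix$values)))
  expect_lt(nrow(strict$matrix$values), nrow(full$matrix$values))
  # CTC-specific genes are absent in healthy arrays, so the strict policy
  # drops them from the matrix
  expect_false(any(sim$truth$ctc_genes %in% rownames(strict$matrix$values)))
})
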