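# Independent oracles, kept free of any package internals.

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1+n2, n1) assignments of the pooled values to group 1.
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  u_of <- function(a) {
    xa <- pooled[a]; ya <- pooled[-a]
    sum(outer(xa, ya, ">")) + 0.5 * sum(outer(xa, ya, "=="))
  }
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# Hand-rolled product-limit estimator and step-function area up to the
# largest observed time (events precede censorings at ties).
hand_km_rmean <- function(time, event) {
  event <- as.logical(event)
  tmax <- max(time)
  ts <- sort(unique(time[event]))
  s <- 1
  area <- 0
  prev <- 0
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    area <- area + s * (min(ts[i], tmax) - prev)
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
    prev <- ts[i]
  }
  if (prev < tmax) area <- area + s * (tmax - prev)
  list(time = ts, surv = surv, rmean = area)
}

# Tiny handmade spot table builder for filter tests.
make_spots <- function(signal, above_bg = TRUE, nonuni = FALSE,
                       repout = FALSE, control = "experimental",
                       sample_id = "S1", group = "patient") {
  n <- length(signal)
  df <- data.frame(
    probe_id = sprintf("p%02d", seq_len(n)),
    gene_symbol = sprintf("g%02d", seq_len(n)),
    processed_signal = signal,
    bg_sub_signal = signal - 1,
    bg_estimate = rep(1, n),
    flag_nonuniform_outlier = rep_len(nonuni, n),
    flag_replicate_outlier = rep_len(repout, n),
    flag_above_background = rep_len(above_bg, n),
    control_type = rep_len(control, n),
    stringsAsFactors = FALSE
  )
  spot_table(df, sample_id = sample_id, group = group)
}

# Expression matrix straight from detection counts: gene i detected in the
# first pat[i] patient and first hea[i] healthy samples.
make_presence_matrix <- function(pat, hea, n_patients = 9, n_healthy = 6) {
  genes <- sprintf("G%02d", seq_along(pat))
  n <- n_patients + n_healthy
  det <- matrix(FALSE, length(pat), n, dimnames = list(genes, NULL))
  for (i in seq_along(pat)) {
    if (pat[i] > 0) det[i, seq_len(pat[i])] <- TRUE
    if (hea[i] > 0) det[i, n_patients + seq_len(hea[i])] <- TRUE
  }
  vals <- matrix(8, length(pat), n, dimnames = list(genes, NULL))
  samples <- data.frame(
    sample_id = c(sprintf("P%d", seq_len(n_patients)),
                  sprintf("H%d", seq_len(n_healthy))),
    group = rep(c("patient", "healthy"), c(n_patients, n_healthy)),
    stringsAsFactors = FALSE)
  expression_matrix(vals, det, samples)
}

# Minimal qPCR dataset from explicit well-level Ct values.
make_qpcr <- function(rows, ct_floor = 40, ref_gene = "CD45") {
  structure(rows, ref_gene = ref_gene, ct_floor = ct_floor,
            class = c("qpcr_dataset", "data.frame"))
}
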