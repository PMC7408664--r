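#' Configuration for a synthetic array cohort
#'
#' Describes a two-group microarray experiment in which patient and healthy
#' arrays share a lymphocyte background expression distribution, and a set of
#' spiked "CTC genes" is detectable only in a random subset of patient arrays.
#' The defaults reproduce the discovery design: 9 patient arrays vs 6
#' healthy-donor arrays, 2,000 gene units with 2 probes each, 40 spiked CTC
#' genes each detectable in a given patient array with probability 0.7, a
#' spike signal 6 background-SDs above the blood background, and 2% of spots
#' carrying an outlier flag.
#'
#' Background gene intensities are log-normal on the log2 scale
#' (`N(background_mu, background_sigma)` in log2 units); a detectable CTC-gene
#' spot sits at `background_mu + signal_shift`. Spots of a CTC gene in arrays
#' that do not carry it, and negative-control spots, are drawn from a low
#' noise floor (`N(negctrl_mu, negctrl_sigma)` in log2 units) and carry
#' `flag_above_background = FALSE`.
#'
#' @param n_patients,n_healthy Number of patient / healthy arrays.
#' @param n_genes Number of gene units on the array.
#' @param probes_per_gene Replicate probes per gene unit.
#' @param n_negative_controls Negative-control spots per array.
#' @param n_ctc_genes Number of spiked CTC-specific genes (must be
#'   `<= n_genes`).
#' @param ctc_presence_prob Probability that a CTC gene is detectable in a
#'   given patient array.
#' @param background_mu,background_sigma Mean and SD (log2 units) of the
#'   blood-background intensity distribution.
#' @param signal_shift Log2 shift of detectable CTC-gene spots above the
#'   background mean; must be `>= 0`.
#' @param outlier_rate Fraction of spots flagged as non-uniform or replicate
#'   outliers.
#' @param negctrl_mu,negctrl_sigma Mean and SD (log2 units) of the
#'   noise-floor distribution used for negative controls and absent genes.
#' @param unannotated_fraction Fraction of background genes without a gene
#'   symbol (their probes collapse under their own probe ids).
#' @param seed Integer RNG seed; a fixed seed makes the cohort
#'   bit-reproducible.
#' @return A list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_patients = 9, n_healthy = 6,
                             n_genes = 2000, probes_per_gene = 2,
                             n_negative_controls = 100,
                             n_ctc_genes = 40, ctc_presence_prob = 0.7,
                             background_mu = 8, background_sigma = 1,
                             signal_shift = 6, outlier_rate = 0.02,
                             negctrl_mu = 4, negctrl_sigma = 0.5,
                             unannotated_fraction = 0.05,
                             seed = 1L) {
  cfg <- list(n_patients = n_patients, n_healthy = n_healthy,
              n_genes = n_genes, probes_per_gene = probes_per_gene,
              n_negative_controls = n_negative_controls,
              n_ctc_genes = n_ctc_genes,
              ctc_presence_prob = ctc_presence_prob,
              background_mu = background_mu,
              background_sigma = background_sigma,
              signal_shift = signal_shift, outlier_rate = outlier_rate,
              negctrl_mu = negctrl_mu, negctrl_sigma = negctrl_sigma,
              unannotated_fraction = unannotated_fraction,
              seed = as.integer(seed))
  counts <- c("n_patients", "n_healthy", "n_genes", "probes_per_gene",
              "n_negative_controls")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("'", nm, "' must be a single positive count", call. = FALSE)
  }
  if (cfg$n_ctc_genes < 0) stop("'n_ctc_genes' must be >= 0", call. = FALSE)
  if (cfg$n_ctc_genes > cfg$n_genes)
    stop("'n_ctc_genes' (", cfg$n_ctc_genes, ") exceeds 'n_genes' (",
         cfg$n_genes, ")", call. = FALSE)
  for (nm in c("ctc_presence_prob", "outlier_rate", "unannotated_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$signal_shift < 0) stop("'signal_shift' must be >= 0", call. = FALSE)
  if (cfg$background_sigma < 0 || cfg$negctrl_sigma < 0)
    stop("sigmas must be >= 0", call. = FALSE)
  class(cfg) <- "array_sim_config"
  cfg
}

#' Simulate a two-group array cohort with ground truth
#'
#' Generates one spot table per array plus a ground-truth record of which
#' spiked CTC genes are carried by which patient arrays. The ground truth is
#' emitted alongside the data and is never consumed by the pipeline, so
#' recovery tests cannot leak labels.
#'
#' @param cfg An [array_sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{tables}{list of [spot_table] objects, patients first.}
#'     \item{truth}{list with `ctc_genes` (character), `carriers` (logical
#'       gene x patient matrix of realized detectability), and `occupancy`
#'       (per-gene patient carrier counts).}
#'   }
#' @export
simulate_array_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "array_sim_config"))
  set.seed(cfg$seed)

  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ctc_idx <- if (cfg$n_ctc_genes > 0) sort(sample.int(cfg$n_genes, cfg$n_ctc_genes)) else integer(0)

  # gene symbols: CTC genes always annotated; a fraction of background genes
  # lack a symbol (their probes collapse under their own probe ids)
  symbols <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  bg_idx <- setdiff(seq_len(cfg$n_genes), ctc_idx)
  n_unann <- round(cfg$unannotated_fraction * length(bg_idx))
  if (n_unann > 0) symbols[sample(bg_idx, n_unann)] <- NA_character_
  # ground truth names the spiked genes as the pipeline reports them
  ctc_genes <- symbols[ctc_idx]

  samples <- c(sprintf("P%d", seq_len(cfg$n_patients)),
               sprintf("H%d", seq_len(cfg$n_healthy)))
  groups <- rep(c("patient", "healthy"), c(cfg$n_patients, cfg$n_healthy))

  # realized detectability of each CTC gene in each patient array
  carriers <- matrix(FALSE, nrow = cfg$n_ctc_genes, ncol = cfg$n_patients,
                     dimnames = list(ctc_genes,
                                     samples[seq_len(cfg$n_patients)]))
  if (cfg$n_ctc_genes > 0)
    carriers[] <- stats::runif(length(carriers)) < cfg$ctc_presence_prob

  probe_gene <- rep(seq_len(cfg$n_genes), each = cfg$probes_per_gene)
  probe_ids <- sprintf("P_%s_%d", gene_ids[probe_gene],
                       rep(seq_len(cfg$probes_per_gene), cfg$n_genes))
  n_exp <- length(probe_ids)
  nc_ids <- sprintf("NC_%03d", seq_len(cfg$n_negative_controls))

  is_ctc_probe <- probe_gene %in% ctc_idx
  ctc_row <- match(probe_gene, ctc_idx)  # NA for background probes

  tables <- vector("list", length(samples))
  names(tables) <- samples
  for (j in seq_along(samples)) {
    expressed <- !is_ctc_probe
    if (groups[j] == "patient" && cfg$n_ctc_genes > 0) {
      on <- carriers[, samples[j]]
      expressed[is_ctc_probe] <- on[ctc_row[is_ctc_probe]]
    }
    log2sig <- numeric(n_exp)
    log2sig[expressed] <- stats::rnorm(sum(expressed),
                                       cfg$background_mu, cfg$background_sigma)
    log2sig[expressed & is_ctc_probe] <-
      log2sig[expressed & is_ctc_probe] + cfg$signal_shift
    log2sig[!expressed] <- stats::rnorm(sum(!expressed),
                                        cfg$negctrl_mu, cfg$negctrl_sigma)
    nc_log2 <- stats::rnorm(cfg$n_negative_controls,
                            cfg$negctrl_mu, cfg$negctrl_sigma)

    n_tot <- n_exp + cfg$n_negative_controls
    out_flag <- stats::runif(n_tot) < cfg$outlier_rate
    out_kind <- stats::runif(n_tot) < 0.5  # TRUE -> non-uniform, FALSE -> replicate

    bg_est <- 2^stats::rnorm(n_tot, cfg$negctrl_mu - 1, 0.2)
    processed <- c(2^log2sig, 2^nc_log2)

    tab <- data.frame(
      probe_id = c(probe_ids, nc_ids),
      gene_symbol = c(symbols[probe_gene],
                      rep(NA_character_, cfg$n_negative_controls)),
      processed_signal = processed,
      bg_sub_signal = processed - bg_est,
      bg_estimate = bg_est,
      flag_nonuniform_outlier = out_flag & out_kind,
      flag_replicate_outlier = out_flag & !out_kind,
      flag_above_background = c(expressed,
                                rep(FALSE, cfg$n_negative_controls)),
      control_type = rep(c("experimental", "negative_control"),
                         c(n_exp, cfg$n_negative_controls)),
      stringsAsFactors = FALSE
    )
    tables[[j]] <- spot_table(tab, sample_id = samples[j], group = groups[j])
  }

  list(tables = tables,
       truth = list(ctc_genes = ctc_genes,
                    carriers = carriers,
                    occupancy = if (cfg$n_ctc_genes > 0) rowSums(carriers)
                                else stats::setNames(integer(0), character(0))))
}

#' Configuration for a synthetic qPCR validation cohort
#'
#' Emulates the validation arm: a cohort of mCRPC patients and healthy
#' controls assayed in duplicate qPCR wells for a marker panel plus the CD45
#' reference. A sample's latent normalized score for gene *g* is
#' `base_scores[g] + effect_sizes[g]` for patients and `base_scores[g]` for
#' controls; well-level Ct values add `N(0, ct_sigma)` replicate noise and
#' are clipped at `ct_floor`. Defaults match the validated 6-gene panel
#' (HOXB13, MAOA, FGD4, MOSPD1, QKI, SDK1) in 28 patients vs 15 controls,
#' with control baselines placed so the published per-marker cut-off values
#' (-3.8, -4.1, 0.4, -4.0, 0.5, -2.0) fall midway between the group means at
#' the default effect size of 2 score units.
#'
#' @param n_patients,n_controls Cohort sizes (defaults 28 and 15).
#' @param genes Character vector of marker names.
#' @param effect_sizes Per-gene patient-vs-control shift of the normalized
#'   score (recycled to `length(genes)`).
#' @param base_scores Per-gene control-group mean normalized score.
#' @param ct_sigma Replicate (well-level) noise SD in Ct units; must be
#'   `>= 0`.
#' @param ct_floor Maximum observable cycle (default 40).
#' @param n_replicates Wells per sample per gene (default 2, duplicates).
#' @param cd45_mu,cd45_sigma Distribution of the per-sample true CD45 Ct.
#' @param hazard_coefs Per-marker log-hazard coefficients used by
#'   [simulate_survival()] (recycled; default 0.25 on the PFS-associated
#'   markers MAOA, MOSPD1, QKI, SDK1 and 0 elsewhere when `genes` is the
#'   default panel).
#' @param censor_rate Probability that a patient's follow-up is
#'   right-censored.
#' @param base_hazard Baseline event rate per month (default `log(2)/8`,
#'   i.e. 8-month median time-to-progression at zero log-hazard).
#' @param seed Integer RNG seed.
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(n_patients = 28, n_controls = 15,
                            genes = c("HOXB13", "MAOA", "FGD4",
                                      "MOSPD1", "QKI", "SDK1"),
                            effect_sizes = 2,
                            base_scores = NULL,
                            ct_sigma = 1, ct_floor = 40,
                            n_replicates = 2,
                            cd45_mu = 25, cd45_sigma = 1,
                            hazard_coefs = NULL,
                            censor_rate = 0.2,
                            base_hazard = log(2) / 8,
                            seed = 1L) {
  default_panel <- c("HOXB13", "MAOA", "FGD4", "MOSPD1", "QKI", "SDK1")
  if (is.null(base_scores)) {
    base_scores <- if (identical(genes, default_panel)) {
      # published cut-offs minus half the default effect
      c(-3.8, -4.1, 0.4, -4.0, 0.5, -2.0) - 1
    } else rep(-6, length(genes))
  }
  if (is.null(hazard_coefs)) {
    hazard_coefs <- if (identical(genes, default_panel))
      c(0, 0.25, 0, 0.25, 0.25, 0.25) else rep(0, length(genes))
  }
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              genes = as.character(genes),
              effect_sizes = rep_len(effect_sizes, length(genes)),
              base_scores = rep_len(base_scores, length(genes)),
              ct_sigma = ct_sigma, ct_floor = ct_floor,
              n_replicates = as.integer(n_replicates),
              cd45_mu = cd45_mu, cd45_sigma = cd45_sigma,
              hazard_coefs = rep_len(hazard_coefs, length(genes)),
              censor_rate = censor_rate, base_hazard = base_hazard,
              seed = as.integer(seed))
  if (cfg$n_patients <= 0 || cfg$n_controls <= 0)
    stop("cohort sizes must be positive", call. = FALSE)
  if (length(cfg$genes) == 0) stop("'genes' must be nonempty", call. = FALSE)
  if (anyDuplicated(cfg$genes)) stop("duplicate gene names", call. = FALSE)
  if ("CD45" %in% cfg$genes)
    stop("'CD45' is reserved for the reference gene", call. = FALSE)
  if (cfg$ct_sigma < 0) stop("'ct_sigma' must be >= 0", call. = FALSE)
  if (cfg$ct_floor <= 0) stop("'ct_floor' must be > 0", call. = FALSE)
  if (cfg$n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("'censor_rate' must lie in [0, 1]", call. = FALSE)
  if (cfg$base_hazard <= 0) stop("'base_hazard' must be > 0", call. = FALSE)
  class(cfg) <- "qpcr_sim_config"
  cfg
}

#' Simulate a qPCR validation cohort
#'
#' Draws duplicate Ct wells per sample and gene, plus reference (CD45) wells
#' for every sample. The latent per-sample normalized score (see
#' [normalize_ct()]) equals the configured baseline plus the per-gene effect
#' for patients; gene Ct values are `Ct_CD45 - score` plus replicate noise,
#' clipped to `(0, ct_floor]`.
#'
#' @param cfg A [qpcr_sim_config()].
#' @return A `qpcr_dataset`: a long data frame with columns `sample_id`,
#'   `group` (patient/control), `gene` (including the `"CD45"` reference),
#'   `well`, `ct`; attributes `ref_gene` and `ct_floor`.
#' @export
simulate_qpcr_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  set.seed(cfg$seed)

  samples <- c(sprintf("P%02d", seq_len(cfg$n_patients)),
               sprintf("C%02d", seq_len(cfg$n_controls)))
  groups <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  n <- length(samples)
  ng <- length(cfg$genes)
  nrep <- cfg$n_replicates

  cd45_true <- stats::rnorm(n, cfg$cd45_mu, cfg$cd45_sigma)
  # latent score matrix: samples x genes
  score <- matrix(rep(cfg$base_scores, each = n), n, ng)
  score <- score + outer(groups == "patient", cfg$effect_sizes)
  ct_true <- cd45_true - score  # true gene Ct

  clip <- function(x) pmin(pmax(x, 1e-6), cfg$ct_floor)

  gene_rows <- data.frame(
    sample_id = rep(rep(samples, each = nrep), ng),
    group = rep(rep(groups, each = nrep), ng),
    gene = rep(cfg$genes, each = n * nrep),
    well = rep(seq_len(nrep), n * ng),
    ct = clip(rep(as.vector(ct_true), each = nrep) +
                stats::rnorm(n * ng * nrep, 0, cfg$ct_sigma)),
    stringsAsFactors = FALSE
  )
  ref_rows <- data.frame(
    sample_id = rep(samples, each = nrep),
    group = rep(groups, each = nrep),
    gene = "CD45",
    well = rep(seq_len(nrep), n),
    ct = clip(rep(cd45_true, each = nrep) +
                stats::rnorm(n * nrep, 0, cfg$ct_sigma)),
    stringsAsFactors = FALSE
  )
  d <- rbind(gene_rows, ref_rows)
  rownames(d) <- NULL
  structure(d, ref_gene = "CD45", ct_floor = cfg$ct_floor,
            class = c("qpcr_dataset", "data.frame"))
}

#' Simulate survival outcomes linked to marker scores
#'
#' Event times are exponential with rate
#' `base_hazard * exp(sum_g hazard_coefs[g] * (score_g - mean(score_g)))`;
#' scores are centered within the cohort so `base_hazard` keeps its
#' month-scale interpretation regardless of the score origin. With
#' probability `censor_rate` a subject is right-censored at a time drawn
#' uniformly on `(0, T)` (independent uniform censoring over the realized
#' follow-up).
#'
#' @param cfg A [qpcr_sim_config()] (supplies `hazard_coefs`, `censor_rate`,
#'   `base_hazard`, and the seed offset).
#' @param scores A per-sample score matrix or data frame (samples in rows,
#'   markers in columns, rownames = sample ids) covering all patients, e.g.
#'   from [score_matrix()].
#' @return A `data.frame` with columns `sample_id`, `time` (months, > 0) and
#'   `event` (logical; `TRUE` = progression/death observed).
#' @export
simulate_survival <- function(cfg, scores) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    stop("'scores' must carry sample ids as rownames", call. = FALSE)
  if (!all(cfg$genes %in% colnames(scores)))
    stop("'scores' must contain a column per configured marker",
         call. = FALSE)
  if (anyNA(scores[, cfg$genes]))
    stop("'scores' must cover all samples for all markers", call. = FALSE)
  set.seed(cfg$seed + 1L)

  centered <- scale(scores[, cfg$genes, drop = FALSE],
                    center = TRUE, scale = FALSE)
  lp <- as.vector(centered %*% cfg$hazard_coefs)
  n <- nrow(scores)
  t_event <- stats::rexp(n, rate = cfg$base_hazard * exp(lp))
  censored <- stats::runif(n) < cfg$censor_rate
  time <- t_event
  time[censored] <- stats::runif(sum(censored)) * t_event[censored]
  time <- pmax(time, 1e-9)
  data.frame(sample_id = rownames(scores), time = time, event = !censored,
             stringsAsFactors = FALSE)
}
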