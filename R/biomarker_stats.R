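#' CD45-normalized qPCR expression scores
#'
#' Replicate Ct wells are averaged per sample and gene, then each gene's
#' mean Ct is expressed on the 40-Ct scale and normalized against the CD45
#' reference (a lymphocyte marker quantifying non-specifically captured
#' blood cells):
#' `score = (ct_floor - mean Ct_gene) - (ct_floor - mean Ct_CD45)`,
#' which reduces to `mean Ct_CD45 - mean Ct_gene`. Higher score = higher
#' expression relative to the lymphocyte background. A gene with every
#' replicate at the floor scores `-(ct_floor - mean Ct_CD45)`. Samples with
#' no wells for a gene are emitted with a missing score, not zero.
#'
#' @param d A `qpcr_dataset` (long data frame with `sample_id`, `group`,
#'   `gene`, `well`, `ct`; attribute `ref_gene`, default `"CD45"`).
#' @return Long data frame with `sample_id`, `group`, `gene`, `score`
#'   (reference gene excluded).
#' @export
normalize_ct <- function(d) {
  ref <- attr(d, "ref_gene")
  if (is.null(ref)) ref <- "CD45"
  samples <- unique(d$sample_id)
  genes <- setdiff(unique(d$gene), ref)
  mean_ct <- tapply(d$ct, list(d$sample_id, d$gene), mean)
  mean_ct <- mean_ct[samples, , drop = FALSE]
  if (!ref %in% colnames(mean_ct) || anyNA(mean_ct[, ref])) {
    missing <- if (ref %in% colnames(mean_ct))
      samples[is.na(mean_ct[, ref])] else samples
    stop("sample(s) lacking reference (", ref, ") wells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grp <- d$group[match(samples, d$sample_id)]
  score <- mean_ct[, ref] - mean_ct[, genes, drop = FALSE]
  out <- data.frame(
    sample_id = rep(samples, length(genes)),
    group = rep(grp, length(genes)),
    gene = rep(genes, each = length(samples)),
    score = as.vector(score),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Reshape marker scores to a sample x gene matrix
#'
#' @param scores Long score data frame from [normalize_ct()].
#' @return Numeric matrix, samples in rows (rownames = sample ids, first
#'   appearance order), genes in columns.
#' @export
score_matrix <- function(scores) {
  samples <- unique(scores$sample_id)
  genes <- unique(scores$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(scores$sample_id, samples), match(scores$gene, genes))] <-
    scores$score
  m
}

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic counts pairs with `x > y`, ties contributing 1/2. The
#' two-sided p-value is exact (from the null distribution of U over all
#' rank assignments) when the data are tie-free and `min(n1, n2) <= 8` in
#' `"auto"` mode, or whenever `mode = "exact"`; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Two identical constant groups give p = 1 (degenerate, not an
#' error).
#'
#' @param x,y Numeric score vectors of the two groups (both nonempty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `U`, `p` (two-sided, in `[0, 1]`), `n1`, `n2`, and
#'   `method` used.
#' @export
mannwhitney_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = !ties && min(n1, n2) <= 8)
  if (use_exact && ties)
    stop("exact p-value undefined with ties; use mode = 'normal'",
         call. = FALSE)
  if (use_exact) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "exact"
  } else {
    N <- n1 + n2
    tab <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tab^3 - tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(list(U = U, p = 1, n1 = n1, n2 = n2, method = "degenerate"))
    }
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(max(p, 0), 1), n1 = n1, n2 = n2, method = method)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, clamped at 1,
#' with the original input order restored. Invariant under permutation of
#' the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' Empirical ROC over all distinct thresholds; the AUC equals the
#' Mann-Whitney U statistic divided by `n1 * n2` (ties counted 1/2). The
#' 95% confidence interval uses the DeLong variance, truncated to
#' `[0, 1]`.
#'
#' @param scores Numeric per-sample scores (higher = more case-like).
#' @param labels Logical vector (`TRUE` = case/patient) or a factor/
#'   character vector with `positive` naming the case level.
#' @param positive Case level when `labels` is not logical.
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci` (lower, upper), `points` (data frame
#'   `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = TRUE, conf = 0.95) {
  if (!is.logical(labels)) labels <- labels == positive
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf,
                                                 method = "delong")))
  pts <- pROC::coords(r, "all", ret = c("threshold", "specificity",
                                        "sensitivity"), transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(lower = max(ci[1], 0), upper = min(ci[3], 1)),
       points = data.frame(threshold = pts$threshold,
                           fpr = 1 - pts$specificity,
                           tpr = pts$sensitivity),
       n_pos = sum(labels), n_neg = sum(!labels))
}

#' Per-marker group comparison table
#'
#' For each marker: two-tailed Mann-Whitney test of patients vs controls,
#' BH-FDR adjustment across the panel, per-group sizes and median scores,
#' and the single-marker AUC.
#'
#' @param scores Long score data frame from [normalize_ct()] with `group`
#'   in `{patient, control}`.
#' @param mode Mann-Whitney p-value mode, see [mannwhitney_test()].
#' @return Data frame, one row per marker: `gene`, `n_patient`,
#'   `n_control`, `median_patient`, `median_control`, `U`, `p`, `q`, `auc`.
#' @export
marker_test_table <- function(scores, mode = "auto") {
  genes <- unique(scores$gene)
  rows <- lapply(genes, function(g) {
    s <- scores[scores$gene == g & !is.na(scores$score), ]
    x <- s$score[s$group == "patient"]
    y <- s$score[s$group != "patient"]
    mw <- mannwhitney_test(x, y, mode = mode)
    auc <- roc_auc(s$score, s$group == "patient")$auc
    data.frame(gene = g, n_patient = length(x), n_control = length(y),
               median_patient = stats::median(x),
               median_control = stats::median(y),
               U = mw$U, p = mw$p, auc = auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("gene", "n_patient", "n_control", "median_patient",
          "median_control", "U", "p", "q", "auc")]
}

#' Combined logistic marker panel
#'
#' Fits a binomial-logit model of group membership on the marker scores
#' (iteratively reweighted least squares, relative deviance tolerance 1e-8,
#' at most 100 iterations) and evaluates the panel by the ROC of the fitted
#' linear predictor. Perfect separation is flagged (coefficients are then
#' reported at the iteration cap) but the panel AUC remains valid.
#'
#' @param scores Numeric sample x marker matrix (complete cases only; at
#'   least `ncol + 2` samples).
#' @param labels Logical vector (`TRUE` = patient), aligned with the rows.
#' @param conf Confidence level for the AUC interval.
#' @return List of class `panel_model`: `genes`, `coefficients` (incl.
#'   intercept), `fitted_scores` (linear predictor), `auc`, `auc_ci`,
#'   `separation`, `converged`, `n`.
#' @export
fit_panel_logistic <- function(scores, labels, conf = 0.95) {
  scores <- as.matrix(scores)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    stop("complete cases required", call. = FALSE)
  if (nrow(scores) < ncol(scores) + 2)
    stop("need at least ", ncol(scores) + 2, " samples for ",
         ncol(scores), " markers", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  df <- data.frame(.y = labels, scores, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  lp <- as.vector(stats::predict(fit, type = "link"))
  roc <- roc_auc(lp, labels, conf = conf)
  structure(list(genes = colnames(scores),
                 coefficients = stats::coef(fit),
                 fitted_scores = lp,
                 auc = roc$auc, auc_ci = roc$ci,
                 separation = separation,
                 converged = fit$converged,
                 n = nrow(scores)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("Logistic marker panel (%s): AUC %.3f (%.2f-%.2f), n = %d%s\n",
              paste(x$genes, collapse = ", "), x$auc, x$auc_ci[1],
              x$auc_ci[2], x$n,
              if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

#' Two-sided Pearson correlation
#'
#' Product-moment correlation with the t-based two-sided p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Finite numeric vectors of equal length `n >= 3`, each with
#'   nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Dichotomize marker scores into low/high groups
#'
#' `low` iff `score <= cut value`. Data-driven cuts: the median, or the
#' 70th percentile by the nearest-rank definition
#' (`sorted[ceiling(0.7 * n)]`). A numeric `cut` reproduces published
#' fixed cut-offs.
#'
#' @param scores Numeric vector (>= 2 values for data-driven cuts).
#' @param cut `"median"`, `"p70"`, or a single numeric cut-off.
#' @return Factor with levels `low`, `high`; the cut value is attached as
#'   attribute `cutoff`. If every score falls on one side a warning is
#'   emitted.
#' @export
dichotomize <- function(scores, cut = "median") {
  if (is.numeric(cut)) {
    cutoff <- cut
  } else {
    cut <- match.arg(cut, c("median", "p70"))
    if (length(scores[!is.na(scores)]) < 2)
      stop("data-driven cuts need >= 2 scores", call. = FALSE)
    s <- sort(scores[!is.na(scores)])
    cutoff <- switch(cut,
                     median = stats::median(s),
                     p70 = s[ceiling(0.7 * length(s))])
  }
  g <- factor(ifelse(scores <= cutoff, "low", "high"),
              levels = c("low", "high"))
  if (length(unique(g[!is.na(g)])) < 2)
    warning("all samples fall in the '", unique(as.character(g[!is.na(g)])),
            "' group at cut ", format(cutoff), call. = FALSE)
  attr(g, "cutoff") <- cutoff
  g
}
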