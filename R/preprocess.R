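#' Spot filtering policy
#'
#' Encodes the three spot-quality criteria applied to each array before
#' normalization: (a) removal of non-uniform and population-replicate
#' outliers, (b) removal of spots not distinguishable from their own
#' background (the upstream above-background flag), and (c) removal of spots
#' in the range of the negative controls, operationalized as processed
#' signal at or below `mean + negcontrol_k * SD` of the array's
#' negative-control processed signals.
#'
#' @param drop_nonuniform_outliers,drop_replicate_outliers Apply criterion
#'   (a) to the respective flag (defaults `TRUE`).
#' @param require_above_background Apply criterion (b) (default `TRUE`).
#' @param negcontrol_k Multiplier of the negative-control SD in the
#'   criterion (c) threshold; must be `>= 0`. Default 3, the conventional
#'   mean + 3 SD limit of the negative-control range.
#' @param use_processed_signal Use the processed signal (default) rather
#'   than the background-subtracted signal for criterion (c) and detection.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(drop_nonuniform_outliers = TRUE,
                          drop_replicate_outliers = TRUE,
                          require_above_background = TRUE,
                          negcontrol_k = 3.0,
                          use_processed_signal = TRUE) {
  if (negcontrol_k < 0) stop("'negcontrol_k' must be >= 0", call. = FALSE)
  structure(list(drop_nonuniform_outliers = drop_nonuniform_outliers,
                 drop_replicate_outliers = drop_replicate_outliers,
                 require_above_background = require_above_background,
                 negcontrol_k = negcontrol_k,
                 use_processed_signal = use_processed_signal),
            class = "filter_policy")
}

.signal_column <- function(p) {
  if (isTRUE(p$use_processed_signal)) "processed_signal" else "bg_sub_signal"
}

#' Negative-control threshold of one array
#'
#' `mean + k * SD` of the chosen signal over the array's negative-control
#' spots (all of them; the threshold is a property of the array, computed
#' before any spot removal). With a single negative control the SD term is
#' taken as 0.
#'
#' @param t A [spot_table].
#' @param p A [filter_policy()].
#' @return The threshold (scalar). `-Inf` if there are no negative controls
#'   and `negcontrol_k == 0`; an error if there are none and
#'   `negcontrol_k > 0`.
#' @export
negcontrol_threshold <- function(t, p = filter_policy()) {
  nc <- t[[.signal_column(p)]][t$control_type == "negative_control"]
  if (length(nc) == 0) {
    if (p$negcontrol_k > 0)
      stop("array ", attr(t, "sample_id"),
           " has no negative-control spots; criterion (c) cannot be ",
           "evaluated with negcontrol_k > 0", call. = FALSE)
    return(-Inf)
  }
  s <- if (length(nc) > 1) stats::sd(nc) else 0
  mean(nc) + p$negcontrol_k * s
}

#' Apply spot quality filtering to one array
#'
#' Removes spots failing the policy's criteria and reports per-criterion
#' counts. A spot failing several criteria is counted once, attributed to
#' the first failing criterion in order (a) outlier flags, (b) not above
#' background, (c) within the negative-control range. Control spots
#' (negative and other) are removed from downstream analysis regardless and
#' counted in their own column; the per-criterion counts plus the control
#' count sum to `filtered_spots`.
#'
#' @param t A [spot_table].
#' @param p A [filter_policy()].
#' @return A list with `spots` (the retained [spot_table], original row
#'   order) and `report` (one-row data frame: `sample_id`, `total_spots`,
#'   `filtered_spots`, `filtered_fraction`, `n_outlier`, `n_background`,
#'   `n_negctrl_range`, `n_controls`, `threshold`).
#' @export
qc_filter_spots <- function(t, p = filter_policy()) {
  stopifnot(inherits(t, "spot_table"))
  thr <- negcontrol_threshold(t, p)
  sig <- t[[.signal_column(p)]]
  is_exp <- t$control_type == "experimental"

  fail_a <- (p$drop_nonuniform_outliers & t$flag_nonuniform_outlier) |
            (p$drop_replicate_outliers & t$flag_replicate_outlier)
  fail_b <- p$require_above_background & !t$flag_above_background
  fail_c <- sig <= thr

  drop_ctrl <- !is_exp
  a <- is_exp & fail_a
  b <- is_exp & !fail_a & fail_b
  cc <- is_exp & !fail_a & !fail_b & fail_c
  keep <- is_exp & !fail_a & !fail_b & !fail_c

  report <- data.frame(
    sample_id = attr(t, "sample_id"),
    total_spots = nrow(t),
    filtered_spots = sum(!keep),
    filtered_fraction = sum(!keep) / nrow(t),
    n_outlier = sum(a),
    n_background = sum(b),
    n_negctrl_range = sum(cc),
    n_controls = sum(drop_ctrl),
    threshold = thr,
    stringsAsFactors = FALSE
  )
  kept <- t[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(spots = spot_table(kept, attr(t, "sample_id"), attr(t, "group")),
       report = report)
}

#' Per-spot detection calls for one array
#'
#' A spot is called detected iff it is an experimental spot whose
#' above-background flag is set, whose signal exceeds the array's
#' negative-control threshold, and which carries no outlier flag (each
#' condition subject to the corresponding policy switch). Control spots are
#' never detected. Deterministic given the inputs, and monotone in signal:
#' raising the signal of a clean above-background spot can never turn
#' detection off.
#'
#' @param t A [spot_table] (filtered or unfiltered).
#' @param p A [filter_policy()].
#' @return Named logical vector, one element per spot row (names =
#'   `probe_id`).
#' @export
detection_call <- function(t, p = filter_policy()) {
  stopifnot(inherits(t, "spot_table"))
  thr <- negcontrol_threshold(t, p)
  sig <- t[[.signal_column(p)]]
  det <- t$control_type == "experimental" &
    (!p$require_above_background | t$flag_above_background) &
    sig > thr &
    !(p$drop_nonuniform_outliers & t$flag_nonuniform_outlier) &
    !(p$drop_replicate_outliers & t$flag_replicate_outlier)
  stats::setNames(det, t$probe_id)
}

#' Quantile normalization across samples
#'
#' Classic quantile normalization (as in limma): for each sample the value
#' of rank r is replaced by the across-sample mean of the rank-r values;
#' tied values receive the mean of their tied-rank substitutes. After
#' normalization the sorted columns are identical.
#'
#' @param x Numeric matrix, probes in rows, samples (>= 2) in columns, all
#'   values finite.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  if (!all(is.finite(x)))
    stop("quantile normalization requires finite input", call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse probe-level values to gene level
#'
#' Per gene and sample, the value is the median of the constituent probes'
#' normalized log2 intensities, and the gene is called detected iff at
#' least one constituent probe is detected in that sample. Unannotated
#' probes (missing map entries or `NA` symbols) collapse under their own
#' probe id. Gene order follows first appearance in the probe matrix.
#'
#' @param values Numeric probe x sample matrix (rownames = probe ids).
#' @param probe_gene Character vector mapping each row to a gene name
#'   (`NA` -> the probe id).
#' @param detected Logical probe x sample matrix aligned with `values`.
#' @param samples Data frame with `sample_id`, `group` per column.
#' @return An [expression_matrix()].
#' @export
collapse_probes <- function(values, probe_gene, detected, samples) {
  values <- as.matrix(values)
  detected <- as.matrix(detected)
  stopifnot(identical(dim(values), dim(detected)),
            length(probe_gene) == nrow(values))
  gene <- ifelse(is.na(probe_gene), rownames(values), probe_gene)
  if (nrow(values) == 0) {
    return(expression_matrix(matrix(numeric(0), 0, nrow(samples)),
                             matrix(logical(0), 0, nrow(samples)), samples))
  }
  genes <- unique(gene)
  idx <- split(seq_along(gene), factor(gene, levels = genes))
  val <- t(vapply(idx, function(i) {
    if (length(i) == 1L) values[i, ] else apply(values[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(values))))
  det <- t(vapply(idx, function(i) {
    colSums(detected[i, , drop = FALSE]) > 0
  }, logical(ncol(values))))
  rownames(val) <- rownames(det) <- genes
  expression_matrix(val, det, samples)
}

#' Build a normalized expression matrix from a cohort of arrays
#'
#' End-to-end preprocessing: per-array QC reports and detection calls,
#' log2 transform of the chosen signal, quantile normalization across
#' arrays, and probe-to-gene collapse.
#'
#' All arrays must share the same experimental probe set (one platform).
#' Under the default `probe_policy = "all_experimental"` every experimental
#' probe's measured intensity enters normalization — absence calls
#' (criteria b/c) mark a probe undetected in that array without discarding
#' its intensity, so genes absent from one group (the CTC-specific case)
#' keep finite values everywhere. `probe_policy = "common_retained"`
#' instead restricts normalization (and the matrix) to probes retained by
#' [qc_filter_spots()] in every sample — a conservative subset policy in
#' which any probe undetectable in any array is dropped for all.
#'
#' @param tables List of [spot_table] objects (one cohort).
#' @param policy A [filter_policy()].
#' @param probe_policy `"all_experimental"` (default) or
#'   `"common_retained"`; see Details.
#' @return A list with `matrix` (the [expression_matrix()]) and
#'   `filter_report` (row-bound per-array reports from
#'   [qc_filter_spots()]).
#' @export
build_expression_matrix <- function(tables, policy = filter_policy(),
                                    probe_policy = c("all_experimental",
                                                     "common_retained")) {
  probe_policy <- match.arg(probe_policy)
  if (length(tables) < 2)
    stop("need >= 2 arrays to normalize", call. = FALSE)
  samples <- data.frame(
    sample_id = vapply(tables, attr, "", "sample_id"),
    group = vapply(tables, attr, "", "group"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in cohort", call. = FALSE)

  exp0 <- tables[[1]][tables[[1]]$control_type == "experimental", ]
  probes <- exp0$probe_id
  sig_col <- .signal_column(policy)

  values <- matrix(NA_real_, length(probes), length(tables),
                   dimnames = list(probes, samples$sample_id))
  detected <- matrix(FALSE, length(probes), length(tables),
                     dimnames = list(probes, samples$sample_id))
  retained <- matrix(TRUE, length(probes), length(tables))
  reports <- vector("list", length(tables))

  for (j in seq_along(tables)) {
    t <- tables[[j]]
    texp <- t[t$control_type == "experimental", ]
    if (!identical(sort(texp$probe_id), sort(probes)))
      stop("array ", samples$sample_id[j],
           " has a different experimental probe set", call. = FALSE)
    ord <- match(probes, texp$probe_id)
    values[, j] <- log2(pmax(texp[[sig_col]][ord], .Machine$double.xmin))
    det <- detection_call(t, policy)
    detected[, j] <- det[t$control_type == "experimental"][ord]
    qc <- qc_filter_spots(t, policy)
    reports[[j]] <- qc$report
    retained[, j] <- probes %in% qc$spots$probe_id
  }

  if (probe_policy == "common_retained") {
    keep <- rowSums(retained) == ncol(retained)
    values <- values[keep, , drop = FALSE]
    detected <- detected[keep, , drop = FALSE]
    probes <- probes[keep]
    exp0 <- exp0[exp0$probe_id %in% probes, ]
  }

  norm <- quantile_normalize(values)
  probe_gene <- exp0$gene_symbol[match(probes, exp0$probe_id)]
  m <- collapse_probes(norm, probe_gene, detected, samples)
  list(matrix = m, filter_report = do.call(rbind, reports))
}
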