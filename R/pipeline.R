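#' Run the discovery arm: spot tables to CTC signature
#'
#' Chains spot QC filtering, detection calls, quantile normalization,
#' probe-to-gene collapse and signature selection, and (optionally) writes
#' the artifact set: per-array filter report, normalized expression matrix
#' with detection calls, and the signature report. Outputs are deterministic
#' functions of the inputs; per-array filtering counts are reported via
#' `message()`.
#'
#' @param tables List of [spot_table] objects, or a character vector of
#'   file paths read with [read_spot_table()]. Needs >= 2 patient and >= 2
#'   healthy arrays.
#' @param policy A [filter_policy()].
#' @param rule A [signature_rule()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param dialect Column mapping used when `tables` are file paths.
#' @return List with `signature` (a `signature_result`), `matrix` (the
#'   [expression_matrix()]) and `filter_report`, invisibly when writing.
#' @export
run_discovery <- function(tables, policy = filter_policy(),
                          rule = signature_rule(), out_dir = NULL,
                          dialect = agilent_dialect()) {
  if (is.character(tables)) {
    missing <- tables[!file.exists(tables)]
    if (length(missing))
      stop("discovery stage: input file(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tables <- lapply(tables, read_spot_table, dialect = dialect)
  }
  groups <- vapply(tables, attr, "", "group")
  if (sum(groups == "patient") < 2 || sum(groups == "healthy") < 2)
    stop("discovery stage: need >= 2 patient and >= 2 healthy arrays",
         call. = FALSE)

  pre <- build_expression_matrix(tables, policy)
  fr <- pre$filter_report
  message(sprintf(
    "preprocess: %d arrays; mean %.0f of %d spots filtered (%.2f%%)",
    nrow(fr), mean(fr$filtered_spots), fr$total_spots[1],
    100 * mean(fr$filtered_fraction)))
  sig <- select_ctc_genes(pre$matrix, rule)
  message(sprintf("signature: %d genes selected", length(sig$genes)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fr, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression_matrix(pre$matrix,
                            file.path(out_dir, "expression_matrix.tsv"))
    write_signature(sig, file.path(out_dir, "signature.tsv"))
  }
  invisible(list(signature = sig, matrix = pre$matrix,
                 filter_report = fr))
}

#' Run the validation arm: qPCR scores, marker tests, panel ROC, survival
#'
#' CD45-normalizes the qPCR dataset, runs the per-marker Mann-Whitney /
#' FDR / AUC table, fits the combined logistic panel with its ROC, and —
#' when survival data are supplied — produces the marker-dichotomized
#' survival report. Without survival data that stage is skipped with a
#' warning.
#'
#' @param qpcr A `qpcr_dataset` (see [simulate_qpcr_cohort()]).
#' @param surv Optional data frame `sample_id`, `time`, `event` (patients).
#' @param cuts Cut-offs for [marker_survival_report()]: named numeric
#'   vector, `"median"` (default) or `"p70"`.
#' @param endpoint Endpoint label for the survival report.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return List with `scores`, `marker_table`, `panel` (a `panel_model`),
#'   and `survival_report` (`NULL` when skipped), invisibly when writing.
#' @export
run_validation <- function(qpcr, surv = NULL, cuts = "median",
                           endpoint = "PFS", out_dir = NULL) {
  scores <- tryCatch(normalize_ct(qpcr), error = function(e)
    stop("normalization stage: ", conditionMessage(e), call. = FALSE))
  message(sprintf("validation: %d patients vs %d controls, %d markers",
                  length(unique(scores$sample_id[scores$group == "patient"])),
                  length(unique(scores$sample_id[scores$group != "patient"])),
                  length(unique(scores$gene))))
  tab <- marker_test_table(scores)
  sm <- score_matrix(scores)
  panel <- fit_panel_logistic(
    sm, scores$group[match(rownames(sm), scores$sample_id)] == "patient")

  surv_report <- NULL
  if (is.null(surv)) {
    warning("no survival table supplied; survival stage skipped",
            call. = FALSE)
  } else {
    pat <- scores[scores$group == "patient", ]
    surv_report <- marker_survival_report(pat, cuts, surv,
                                          endpoint = endpoint)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(out_dir, "marker_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    roc <- roc_auc(panel$fitted_scores,
                   scores$group[match(rownames(sm),
                                      scores$sample_id)] == "patient")
    utils::write.table(roc$points, file.path(out_dir, "panel_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("panel_auc\t%.6f\npanel_auc_lower\t%.6f\npanel_auc_upper\t%.6f\nseparation\t%s",
                       panel$auc, panel$auc_ci[1], panel$auc_ci[2],
                       panel$separation),
               file.path(out_dir, "panel_summary.tsv"))
    if (!is.null(surv_report))
      utils::write.table(surv_report,
                         file.path(out_dir, "survival_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(scores = scores, marker_table = tab, panel = panel,
                 survival_report = surv_report))
}
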