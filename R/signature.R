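#' Signature selection rule
#'
#' The k-of-n presence rule for calling a gene CTC-specific: detected in at
#' least `min_patient_count` patient arrays and in at most
#' `max_healthy_count` healthy arrays. The defaults (5 and 0) encode
#' "present in at least five patients after discarding genes expressed in
#' healthy samples": any healthy detection excludes a gene.
#'
#' @param min_patient_count Minimum patient arrays with a detection
#'   (default 5).
#' @param max_healthy_count Maximum healthy arrays with a detection
#'   (default 0).
#' @return A list of class `signature_rule`.
#' @export
signature_rule <- function(min_patient_count = 5, max_healthy_count = 0) {
  if (min_patient_count < 1)
    stop("'min_patient_count' must be >= 1", call. = FALSE)
  if (max_healthy_count < 0)
    stop("'max_healthy_count' must be >= 0", call. = FALSE)
  structure(list(min_patient_count = as.integer(min_patient_count),
                 max_healthy_count = as.integer(max_healthy_count)),
            class = "signature_rule")
}

#' Per-gene detection counts by group
#'
#' Counts, for every gene, the number of patient and healthy samples in
#' which it is called detected.
#'
#' @param m An [expression_matrix()] with at least one patient and one
#'   healthy sample.
#' @return Data frame with columns `gene`, `patient_count`,
#'   `healthy_count`, in the matrix's gene order.
#' @export
presence_counts <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  grp <- m$samples$group
  if (anyNA(grp) || any(!nzchar(grp)))
    stop("every sample needs a group label", call. = FALSE)
  if (!any(grp == "patient") || !any(grp == "healthy"))
    stop("need >= 1 patient and >= 1 healthy sample", call. = FALSE)
  data.frame(
    gene = rownames(m$detected),
    patient_count = as.integer(rowSums(m$detected[, grp == "patient",
                                                  drop = FALSE])),
    healthy_count = as.integer(rowSums(m$detected[, grp == "healthy",
                                                  drop = FALSE])),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Select CTC-specific genes by background subtraction
#'
#' Applies the presence rule to the detection-call matrix: a gene is
#' selected iff its healthy detection count is at most
#' `rule$max_healthy_count` (healthy-donor arrays define the lymphocyte
#' background of the EpCAM-enriched fraction) and its patient detection
#' count is at least `rule$min_patient_count`. Selection uses detection
#' calls, never intensities.
#'
#' @param m An [expression_matrix()].
#' @param rule A [signature_rule()].
#' @return A list of class `signature_result`: `genes` (selected, sorted by
#'   descending patient count then gene name), `counts` (their per-group
#'   presence counts), `rule`, `n_patients`, `n_healthy`.
#' @export
select_ctc_genes <- function(m, rule = signature_rule()) {
  stopifnot(inherits(m, "expression_matrix"), inherits(rule, "signature_rule"))
  n_pat <- sum(m$samples$group == "patient")
  n_hea <- sum(m$samples$group == "healthy")
  if (rule$min_patient_count > n_pat)
    stop("rule infeasible: min_patient_count (", rule$min_patient_count,
         ") exceeds the number of patient samples (", n_pat, ")",
         call. = FALSE)
  if (rule$max_healthy_count > n_hea)
    stop("rule infeasible: max_healthy_count (", rule$max_healthy_count,
         ") exceeds the number of healthy samples (", n_hea, ")",
         call. = FALSE)
  pc <- presence_counts(m)
  sel <- pc[pc$patient_count >= rule$min_patient_count &
              pc$healthy_count <= rule$max_healthy_count, , drop = FALSE]
  sel <- sel[order(-sel$patient_count, sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(genes = sel$gene, counts = sel, rule = rule,
                 n_patients = n_pat, n_healthy = n_hea),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf(
    "CTC signature: %d genes (detected in >= %d of %d patients, <= %d of %d healthy)\n",
    length(x$genes), x$rule$min_patient_count, x$n_patients,
    x$rule$max_healthy_count, x$n_healthy))
  if (!is.null(x$annotated_count))
    cat(sprintf("  annotated: %d, unannotated: %d\n",
                x$annotated_count, x$unannotated_count))
  invisible(x)
}

#' Partition a signature into annotated and unannotated genes
#'
#' @param s A `signature_result` from [select_ctc_genes()].
#' @param annotation Named character vector mapping gene ids to symbols;
#'   may be partial (or empty: everything unannotated). A gene counts as
#'   annotated iff it has a non-`NA`, nonempty symbol in the map.
#' @return `s` augmented with `annotated` / `unannotated` gene vectors and
#'   `annotated_count` / `unannotated_count`.
#' @export
annotate_signature <- function(s, annotation = character(0)) {
  stopifnot(inherits(s, "signature_result"))
  sym <- annotation[s$genes]
  has <- !is.na(sym) & nzchar(sym)
  s$annotated <- s$genes[has]
  s$unannotated <- s$genes[!has]
  s$annotated_count <- sum(has)
  s$unannotated_count <- sum(!has)
  s
}

#' Write a signature report
#'
#' Two-section tab-delimited report: a rule/cohort echo (comment lines)
#' followed by the selected genes with their presence counts.
#'
#' @param s A `signature_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(s, path) {
  stopifnot(inherits(s, "signature_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# min_patient_count: %d", s$rule$min_patient_count),
    sprintf("# max_healthy_count: %d", s$rule$max_healthy_count),
    sprintf("# n_patients: %d", s$n_patients),
    sprintf("# n_healthy: %d", s$n_healthy),
    sprintf("# n_selected: %d", length(s$genes))
  ), con)
  utils::write.table(s$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
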