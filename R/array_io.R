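#' Construct a spot table
#'
#' A spot table holds one array's spot-level records: probe id, gene symbol
#' (possibly missing for unannotated probes), the processed signal (the
#' `gProcessedSignal` analogue, used for all statistics), the
#' background-subtracted signal, a per-spot background estimate, the three
#' Feature-Extraction quality flags, and the control type.
#'
#' @param df Data frame with columns `probe_id`, `gene_symbol`,
#'   `processed_signal`, `bg_sub_signal`, `bg_estimate`,
#'   `flag_nonuniform_outlier`, `flag_replicate_outlier`,
#'   `flag_above_background`, `control_type`.
#' @param sample_id Sample identifier.
#' @param group Group label, `"patient"` or `"healthy"`.
#' @return The data frame with class `spot_table` and attributes
#'   `sample_id`, `group`.
#' @export
spot_table <- function(df, sample_id, group = c("patient", "healthy")) {
  group <- match.arg(group)
  req <- c("probe_id", "gene_symbol", "processed_signal", "bg_sub_signal",
           "bg_estimate", "flag_nonuniform_outlier", "flag_replicate_outlier",
           "flag_above_background", "control_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("spot table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$probe_id)) || anyNA(df$probe_id))
    stop("probe_id must be nonempty", call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("probe_id must be unique within an array", call. = FALSE)
  if (!all(is.finite(df$processed_signal)) || any(df$processed_signal < 0))
    stop("processed_signal must be finite and nonnegative", call. = FALSE)
  ok_ct <- c("experimental", "negative_control", "other_control")
  if (!all(df$control_type %in% ok_ct))
    stop("control_type must be one of: ", paste(ok_ct, collapse = ", "),
         call. = FALSE)
  structure(df[, req], sample_id = sample_id, group = group,
            class = c("spot_table", "data.frame"))
}

#' @export
print.spot_table <- function(x, ...) {
  cat("Spot table: sample", attr(x, "sample_id"),
      sprintf("(%s), %d spots (%d experimental, %d negative controls)\n",
              attr(x, "group"), nrow(x),
              sum(x$control_type == "experimental"),
              sum(x$control_type == "negative_control")))
  invisible(x)
}

#' Default Agilent Feature Extraction column mapping
#'
#' Maps internal spot-table field names to the column names used in Agilent
#' Feature Extraction exports, so real FE-derived files and synthetic
#' fixtures share one reader. Override entries to read other dialects.
#'
#' @return Named character vector (internal name -> file column name).
#' @export
agilent_dialect <- function() {
  c(probe_id = "ProbeName",
    gene_symbol = "GeneName",
    processed_signal = "gProcessedSignal",
    bg_sub_signal = "gBGSubSignal",
    bg_estimate = "gBGMeanSignal",
    flag_nonuniform_outlier = "gIsFeatNonUnifOL",
    flag_replicate_outlier = "gIsFeatPopnOL",
    flag_above_background = "gIsWellAboveBG",
    control_type = "ControlType")
}

# FE ControlType codes: 0 experimental, -1 negative control, else other
.control_type_decode <- function(x) {
  out <- rep("other_control", length(x))
  out[x == "0"] <- "experimental"
  out[x == "-1"] <- "negative_control"
  out
}

.control_type_encode <- function(x) {
  c(experimental = "0", negative_control = "-1", other_control = "1")[x]
}

.parse_numeric <- function(x, column, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x %in% c("NA", "")))
  if (length(bad))
    stop("unparsable numeric value '", x[bad[1]], "' in column '", column,
         "' of ", path, " (data line ", bad[1], ")", call. = FALSE)
  v
}

.parse_flag <- function(x, column, path) {
  v <- rep(NA, length(x))
  v[x %in% c("0", "FALSE", "false")] <- FALSE
  v[x %in% c("1", "TRUE", "true")] <- TRUE
  bad <- which(is.na(v))
  if (length(bad))
    stop("unparsable boolean value '", x[bad[1]], "' in column '", column,
         "' of ", path, " (data line ", bad[1], ")", call. = FALSE)
  v
}

#' Read a spot table from a tab-delimited file
#'
#' Parses a Feature-Extraction-style tab-delimited spot file. Leading
#' comment lines of the form `# sample_id: X` and `# group: patient` supply
#' sample metadata (overridable through the arguments). Row order is
#' preserved exactly as in the file. Missing gene symbols (empty cells) are
#' kept as `NA`, not dropped.
#'
#' @param path File path.
#' @param dialect Named character vector mapping internal field names to file
#'   column names; see [agilent_dialect()].
#' @param sample_id,group Optional overrides for the metadata comment lines.
#' @return A [spot_table].
#' @export
read_spot_table <- function(path, dialect = agilent_dialect(),
                            sample_id = NULL, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else NULL
  }
  if (is.null(sample_id)) sample_id <- get_meta("sample_id")
  if (is.null(group)) group <- get_meta("group")
  if (is.null(sample_id))
    stop("no sample_id: supply one or add a '# sample_id:' header to ", path,
         call. = FALSE)
  if (is.null(group))
    stop("no group label: supply one or add a '# group:' header to ", path,
         call. = FALSE)

  body <- lines[!grepl("^#", lines)]
  raw <- utils::read.delim(text = body, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols))
    stop("column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  gs <- raw[[dialect[["gene_symbol"]]]]
  gs[gs == "" | gs == "NA"] <- NA_character_
  df <- data.frame(
    probe_id = raw[[dialect[["probe_id"]]]],
    gene_symbol = gs,
    processed_signal = .parse_numeric(raw[[dialect[["processed_signal"]]]],
                                      dialect[["processed_signal"]], path),
    bg_sub_signal = .parse_numeric(raw[[dialect[["bg_sub_signal"]]]],
                                   dialect[["bg_sub_signal"]], path),
    bg_estimate = .parse_numeric(raw[[dialect[["bg_estimate"]]]],
                                 dialect[["bg_estimate"]], path),
    flag_nonuniform_outlier = .parse_flag(
      raw[[dialect[["flag_nonuniform_outlier"]]]],
      dialect[["flag_nonuniform_outlier"]], path),
    flag_replicate_outlier = .parse_flag(
      raw[[dialect[["flag_replicate_outlier"]]]],
      dialect[["flag_replicate_outlier"]], path),
    flag_above_background = .parse_flag(
      raw[[dialect[["flag_above_background"]]]],
      dialect[["flag_above_background"]], path),
    control_type = .control_type_decode(raw[[dialect[["control_type"]]]]),
    stringsAsFactors = FALSE
  )
  spot_table(df, sample_id = sample_id, group = group)
}

#' Write a spot table
#'
#' Serializes a [spot_table] in the tab-delimited dialect [read_spot_table()]
#' reads, including `# sample_id:` / `# group:` metadata comment lines.
#' `write_spot_table` followed by `read_spot_table` reproduces the table.
#'
#' @param t A [spot_table].
#' @param path Output file path.
#' @param dialect Column-name mapping, as in [read_spot_table()].
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(t, path, dialect = agilent_dialect()) {
  stopifnot(inherits(t, "spot_table"))
  out <- data.frame(
    t$probe_id,
    ifelse(is.na(t$gene_symbol), "", t$gene_symbol),
    sprintf("%.15g", t$processed_signal),
    sprintf("%.15g", t$bg_sub_signal),
    sprintf("%.15g", t$bg_estimate),
    as.integer(t$flag_nonuniform_outlier),
    as.integer(t$flag_replicate_outlier),
    as.integer(t$flag_above_background),
    .control_type_encode(t$control_type),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(dialect[c("probe_id", "gene_symbol",
                                 "processed_signal", "bg_sub_signal",
                                 "bg_estimate", "flag_nonuniform_outlier",
                                 "flag_replicate_outlier",
                                 "flag_above_background", "control_type")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# sample_id:", attr(t, "sample_id")),
               paste("# group:", attr(t, "group"))), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene x sample expression matrix
#'
#' Bundles normalized log2 intensities with a parallel boolean detection-call
#' matrix and per-sample group labels.
#'
#' @param values Numeric gene x sample matrix of log2 intensities.
#' @param detected Logical gene x sample matrix of detection calls, same
#'   dimensions as `values`.
#' @param samples Data frame with columns `sample_id`, `group`, one row per
#'   column of `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detected, samples) {
  values <- as.matrix(values)
  detected <- as.matrix(detected)
  if (!identical(dim(values), dim(detected)))
    stop("'values' and 'detected' must have identical dimensions",
         call. = FALSE)
  if (nrow(samples) != ncol(values))
    stop("'samples' must describe every column", call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("'samples' needs columns sample_id, group", call. = FALSE)
  if (nrow(values) > 0 && anyDuplicated(rownames(values)))
    stop("duplicate gene names", call. = FALSE)
  if (any(detected & !is.finite(values)))
    stop("values must be finite wherever detected is TRUE", call. = FALSE)
  colnames(values) <- colnames(detected) <- samples$sample_id
  rownames(detected) <- rownames(values)
  structure(list(values = values, detected = detected,
                 samples = as.data.frame(samples)[, c("sample_id", "group")]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$samples$group),
                            names(table(x$samples$group))), collapse = ", ")))
  invisible(x)
}

#' Write / read an expression matrix
#'
#' `write_expression_matrix` writes the values as tab-delimited text (gene
#' rows, sample columns, with a `# groups:` metadata line) and the detection
#' calls to a companion `<path>.detected` file. The round trip reproduces
#' values to at least 12 significant digits. Writing refuses matrices with a
#' non-finite value at a detected position.
#'
#' @param m An [expression_matrix()].
#' @param path Output path for the values file; the detection matrix goes to
#'   `paste0(path, ".detected")`.
#' @return `write_expression_matrix`: `path` invisibly;
#'   `read_expression_matrix`: an [expression_matrix()].
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  if (any(m$detected & !is.finite(m$values)))
    stop("refusing to write: non-finite value at a detected position",
         call. = FALSE)
  hdr <- paste(c("gene", m$samples$sample_id), collapse = "\t")
  meta <- paste("# groups:", paste(m$samples$group, collapse = "\t"))
  write_one <- function(mat, fmt, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(meta, hdr), con)
    if (nrow(mat) > 0) {
      body <- apply(mat, 1, function(r) paste(fmt(r), collapse = "\t"))
      writeLines(paste(rownames(mat), body, sep = "\t"), con)
    }
  }
  write_one(m$values, function(r) sprintf("%.15g", r), path)
  write_one(m$detected, function(r) as.character(as.integer(r)),
            paste0(path, ".detected"))
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  read_one <- function(p) {
    lines <- readLines(p)
    groups <- strsplit(sub("^#\\s*groups:\\s*", "", lines[1]), "\t")[[1]]
    hdr <- strsplit(lines[2], "\t")[[1]]
    body <- lines[-(1:2)]
    n_s <- length(hdr) - 1L
    if (length(groups) != n_s)
      stop("format error in ", p, ": ", length(groups),
           " group labels for ", n_s, " samples", call. = FALSE)
    if (length(body) == 0) {
      mat <- matrix(numeric(0), 0, n_s)
    } else {
      parts <- strsplit(body, "\t")
      if (any(lengths(parts) != length(hdr)))
        stop("format error in ", p, ": ragged rows", call. = FALSE)
      mat <- do.call(rbind, lapply(parts, function(x)
        suppressWarnings(as.numeric(x[-1]))))
      rownames(mat) <- vapply(parts, `[[`, "", 1L)
    }
    colnames(mat) <- hdr[-1]
    list(mat = mat, samples = data.frame(sample_id = hdr[-1], group = groups,
                                         stringsAsFactors = FALSE))
  }
  v <- read_one(path)
  d <- read_one(paste0(path, ".detected"))
  if (!identical(dim(v$mat), dim(d$mat)) ||
      !identical(rownames(v$mat), rownames(d$mat)))
    stop("format error: values and detection matrices disagree in shape",
         call. = FALSE)
  expression_matrix(v$mat, d$mat == 1, v$samples)
}

#' Locate per-sample spot files in a GEO-series-style directory
#'
#' Convenience helper for a directory laid out like an unpacked GEO series
#' (one supplementary spot-level text file per GSM sample). Performs no
#' network access.
#'
#' @param dir Directory to search.
#' @param pattern Filename regular expression (default: GSM-prefixed
#'   `.txt`/`.txt.gz` files).
#' @return Character vector of file paths, sorted for determinism.
#' @export
find_geo_arrays <- function(dir, pattern = "^GSM.*\\.txt(\\.gz)?$") {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  sort(list.files(dir, pattern = pattern, full.names = TRUE,
                  recursive = TRUE))
}
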